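#' Align and validate a counts + metadata (+ taxonomy) bundle
#'
#' Checks that the count table and the sample metadata describe the same set
#' of samples (order-insensitive), that the internal-standard phylotype is
#' present with at least one read in every sample (a zero standard makes the
#' per-sample normalization ratio undefined), and that every sample contains
#' at least one read. Count columns are re-ordered to match the metadata.
#'
#' @param counts Count tibble (see [read_count_table()]); must contain a row
#'   for `standard_id`.
#' @param metadata Sample metadata (see [read_sample_metadata()]).
#' @param standard_id Id of the internal-standard phylotype.
#' @param taxonomy Optional taxonomy tibble (see [read_taxonomy()]).
#' @return An object of class `arnis_dataset`: a list with elements
#'   `counts`, `metadata`, `taxonomy` and `standard_id`.
#' @export
validate_dataset <- function(counts, metadata, standard_id, taxonomy = NULL) {
  counts <- as_tibble(counts)
  metadata <- validate_sample_metadata(metadata)
  if (length(standard_id) != 1L || !is.character(standard_id) || is.na(standard_id)) {
    abort("`standard_id` must be a single phylotype id.")
  }
  dup <- counts$phylotype_id[duplicated(counts$phylotype_id)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicated phylotype id(s): %s", paste(unique(dup), collapse = ", ")))
  }

  count_samples <- sample_ids_of(counts)
  only_counts <- setdiff(count_samples, metadata$sample_id)
  only_meta <- setdiff(metadata$sample_id, count_samples)
  if (length(only_counts) > 0L || length(only_meta) > 0L) {
    abort(paste0(
      "sample sets of counts and metadata differ.",
      if (length(only_counts) > 0L) {
        sprintf(" Only in counts: %s.", paste(only_counts, collapse = ", "))
      },
      if (length(only_meta) > 0L) {
        sprintf(" Only in metadata: %s.", paste(only_meta, collapse = ", "))
      }
    ))
  }
  counts <- counts[c("phylotype_id", metadata$sample_id)]

  m <- counts_matrix(counts)
  if (anyNA(m) || any(m < 0)) abort("counts must be non-negative and complete.")
  empty <- colnames(m)[colSums(m) == 0]
  if (length(empty) > 0L) {
    abort(sprintf("sample(s) with zero total reads: %s", paste(empty, collapse = ", ")))
  }
  if (!standard_id %in% counts$phylotype_id) {
    abort(sprintf("internal standard '%s' absent from count table.", standard_id))
  }
  std <- m[standard_id, ]
  zero_std <- names(std)[std == 0]
  if (length(zero_std) > 0L) {
    abort(sprintf(
      "internal standard '%s' has zero reads in sample(s): %s",
      standard_id, paste(zero_std, collapse = ", ")
    ))
  }
  if (!is.null(taxonomy) && !standard_id %in% taxonomy$phylotype_id) {
    abort(sprintf("internal standard '%s' absent from taxonomy table.", standard_id))
  }

  structure(
    list(
      counts = counts, metadata = metadata,
      taxonomy = taxonomy, standard_id = standard_id
    ),
    class = "arnis_dataset"
  )
}

#' @export
print.arnis_dataset <- function(x, ...) {
  cat(sprintf(
    "<arnis_dataset> %d phylotypes x %d samples (standard: %s)\n",
    nrow(x$counts) - 1L, nrow(x$metadata), x$standard_id
  ))
  cat(sprintf(
    "  treatments: %s; time points (h): %s; replicates: %s\n",
    paste(unique(x$metadata$treatment), collapse = ", "),
    paste(sort(unique(x$metadata$time_h)), collapse = ", "),
    paste(unique(x$metadata$replicate), collapse = ", ")
  ))
  invisible(x)
}
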