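#' Read a phylotype-by-sample count table
#'
#' Reads a tab-separated feature table of amplicon read counts. The default
#' orientation has one row per phylotype (OTU or ASV, including the
#' internal-standard organism) and one column per sample, with phylotype ids
#' in the first column; set `phylotypes_as_rows = FALSE` for the transposed
#' layout. Counts must be non-negative integers.
#'
#' @param path Path to a TSV file with a header row.
#' @param phylotypes_as_rows If `TRUE` (default) rows are phylotypes and
#'   columns samples; if `FALSE` the file is transposed on read.
#' @return A tibble with a `phylotype_id` character column followed by one
#'   integer column per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("phylotype_id\ts1\ts2", "otu1\t10\t0", "std\t5\t250"), tf)
#' read_count_table(tf)
#' @export
read_count_table <- function(path, phylotypes_as_rows = TRUE) {
  tbl <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("malformed TSV '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(tbl) == 0L || ncol(tbl) < 2L) {
    abort(sprintf("no phylotypes: '%s' has no data rows or no sample columns.", path))
  }
  names(tbl)[1] <- if (phylotypes_as_rows) "phylotype_id" else "sample_id"
  tbl[[1]] <- as.character(tbl[[1]])
  if (!phylotypes_as_rows) {
    m <- as.matrix(tbl[-1])
    rownames(m) <- tbl[[1]]
    tbl <- matrix_to_counts(t(m))
  }
  validate_count_values(tbl, path)
  tbl
}

validate_count_values <- function(counts, origin = "count table") {
  dup <- counts$phylotype_id[duplicated(counts$phylotype_id)]
  if (length(dup) > 0L) {
    abort(sprintf(
      "duplicated phylotype id(s) in %s: %s",
      origin, paste(unique(dup), collapse = ", ")
    ))
  }
  m <- counts_matrix(counts)
  if (anyNA(m)) abort(sprintf("missing or non-numeric counts in %s.", origin))
  if (any(m < 0)) abort(sprintf("negative counts in %s.", origin))
  if (any(abs(m - round(m)) > 1e-8)) {
    abort(sprintf("non-integer counts in %s.", origin))
  }
  invisible(counts)
}

#' Write a count table to TSV
#'
#' @param counts A count tibble as returned by [read_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata describes each sequenced sample: which experimental treatment
#' bottle it came from, the sampling time in hours, and the replicate.
#' Optional columns `sample_volume_ml` (> 0) and `spike_volume_ul` (>= 0)
#' record filtration and internal-standard spike volumes.
#'
#' @param path Path to a TSV with columns `sample_id`, `treatment`, `time_h`,
#'   `replicate` (plus optional volume columns).
#' @param treatments Optional character vector of expected treatment labels;
#'   labels outside this set are allowed but reported with a message.
#' @return A tibble of validated sample records.
#' @export
read_sample_metadata <- function(path, treatments = NULL) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(md, treatments = treatments)
}

#' Validate a sample-metadata table
#'
#' @param metadata A data frame with the columns described in
#'   [read_sample_metadata()].
#' @inheritParams read_sample_metadata
#' @return The validated metadata as a tibble.
#' @export
validate_sample_metadata <- function(metadata, treatments = NULL) {
  required <- c("sample_id", "treatment", "time_h", "replicate")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "metadata is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  md <- as_tibble(metadata)
  md$sample_id <- as.character(md$sample_id)
  md$treatment <- as.character(md$treatment)
  md$replicate <- as.character(md$replicate)
  if (!is.numeric(md$time_h) || anyNA(md$time_h) || any(md$time_h < 0)) {
    abort("`time_h` must be numeric and >= 0 for every sample.")
  }
  if (anyDuplicated(md$sample_id)) {
    abort(sprintf(
      "duplicated sample id(s): %s",
      paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", ")
    ))
  }
  key <- paste(md$treatment, md$time_h, md$replicate, sep = "/")
  if (anyDuplicated(key)) {
    abort(sprintf(
      "duplicated (treatment, time_h, replicate) triple(s): %s",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    ))
  }
  if ("sample_volume_ml" %in% names(md) &&
    any(!is.na(md$sample_volume_ml) & md$sample_volume_ml <= 0)) {
    abort("`sample_volume_ml` must be > 0 where present.")
  }
  if ("spike_volume_ul" %in% names(md) &&
    any(!is.na(md$spike_volume_ul) & md$spike_volume_ul < 0)) {
    abort("`spike_volume_ul` must be >= 0 where present.")
  }
  if (!is.null(treatments)) {
    unknown <- setdiff(unique(md$treatment), treatments)
    if (length(unknown) > 0L) {
      inform(sprintf(
        "metadata contains treatment label(s) outside the configured set: %s",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  md
}

#' Read a taxonomy table
#'
#' One row per phylotype; the first column is `phylotype_id`, remaining
#' columns are ordered taxonomic ranks (e.g. domain ... genus) as free text.
#'
#' @param path Path to a TSV file.
#' @param standard_id Optional id of the internal-standard phylotype; if
#'   given, its presence in the table is checked.
#' @return A tibble; the standard id (if any) is stored in the
#'   `"standard_id"` attribute.
#' @export
read_taxonomy <- function(path, standard_id = NULL) {
  tax <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"phylotype_id" %in% names(tax)) names(tax)[1] <- "phylotype_id"
  tax$phylotype_id <- as.character(tax$phylotype_id)
  if (anyDuplicated(tax$phylotype_id)) {
    abort("duplicated phylotype id(s) in taxonomy table.")
  }
  if (!is.null(standard_id) && !standard_id %in% tax$phylotype_id) {
    abort(sprintf("internal standard '%s' not present in taxonomy table.", standard_id))
  }
  attr(tax, "standard_id") <- standard_id
  tax
}

#' Read an absolute cell-count time series
#'
#' Microscopy or flow-cytometry counts used to cross-check sequencing-based
#' growth rates. Columns: `group` (taxon or community label), `treatment`,
#' `time_h`, `replicate`, `cells_per_ml` (> 0).
#'
#' @param path Path to a TSV file.
#' @return A tibble of validated records.
#' @export
read_cell_counts <- function(path) {
  cc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("group", "treatment", "time_h", "replicate", "cells_per_ml")
  missing_cols <- setdiff(required, names(cc))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "cell-count table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(!is.finite(cc$cells_per_ml)) || any(cc$cells_per_ml <= 0)) {
    abort("`cells_per_ml` must be strictly positive.")
  }
  as_tibble(cc)
}
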