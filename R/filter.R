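#' Prevalence-filter a phylotype count table
#'
#' Keeps a phylotype if and only if it reaches at least `min_count` reads in
#' at least a fraction `min_sample_fraction` of all samples. This removes
#' rare, mostly-absent features whose time series cannot support a growth
#' fit, while discarding only a small share of total reads. The default
#' (10 reads in 15% of samples) is the preset for 16S rRNA libraries; for
#' sparser functional-gene libraries (e.g. pufM) use
#' `filter_preset("pufM")`, i.e. 3 reads in 15% of samples.
#'
#' @param counts Count tibble.
#' @param min_count Minimum reads per sample for a sample to count towards
#'   prevalence (>= 0).
#' @param min_sample_fraction Minimum fraction of all samples (pooled across
#'   treatments) in which the phylotype must reach `min_count`; in `[0, 1]`.
#' @param protect Phylotype ids always kept (e.g. the internal standard).
#' @param quiet Suppress the removal-summary message.
#' @return The filtered count tibble, with attributes
#'   `removed_phylotype_fraction` and `removed_read_fraction`.
#' @examples
#' counts <- tibble::tibble(
#'   phylotype_id = c("a", "b", "std"),
#'   s1 = c(12, 2, 100), s2 = c(15, 1, 90)
#' )
#' filter_phylotypes(counts, protect = "std")
#' @export
filter_phylotypes <- function(counts, min_count = 10, min_sample_fraction = 0.15,
                              protect = character(), quiet = FALSE) {
  assert_scalar_number(min_count, "min_count", min = 0)
  assert_scalar_number(min_sample_fraction, "min_sample_fraction", min = 0)
  if (min_sample_fraction > 1) abort("`min_sample_fraction` must be <= 1.")
  m <- counts_matrix(counts)
  prevalence <- rowMeans(m >= min_count)
  keep <- prevalence >= min_sample_fraction | rownames(m) %in% protect
  removed_phylo <- mean(!keep)
  total_reads <- sum(m)
  removed_reads <- if (total_reads > 0) sum(m[!keep, , drop = FALSE]) / total_reads else 0
  out <- counts[keep, , drop = FALSE]
  if (!any(keep & !counts$phylotype_id %in% protect)) {
    warn("prevalence filter removed every non-protected phylotype.")
  }
  if (!quiet) {
    inform(sprintf(
      "prevalence filter (>= %g reads in >= %.0f%% of %d samples): removed %.1f%% of phylotypes, %.2f%% of reads.",
      min_count, 100 * min_sample_fraction, ncol(m),
      100 * removed_phylo, 100 * removed_reads
    ))
  }
  attr(out, "removed_phylotype_fraction") <- removed_phylo
  attr(out, "removed_read_fraction") <- removed_reads
  out
}

#' Prevalence-filter presets
#'
#' `"16S"`: 10 reads in 15% of samples, for dense 16S rRNA libraries.
#' `"pufM"`: 3 reads in 15% of samples, for sparser functional-gene
#' libraries.
#'
#' @param name Preset name.
#' @return A list with `min_count` and `min_sample_fraction`.
#' @export
filter_preset <- function(name = c("16S", "pufM")) {
  name <- match.arg(name)
  switch(name,
    "16S" = list(min_count = 10, min_sample_fraction = 0.15),
    "pufM" = list(min_count = 3, min_sample_fraction = 0.15)
  )
}
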