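#' Compute per-sample internal-standard ratios (ARNIS ratios)
#'
#' For each phylotype and sample, the ratio of the phylotype's reads to the
#' internal standard's reads in that sample:
#' `ratio = reads(phylotype, sample) / reads(standard, sample)`.
#' Because the standard was spiked at a fixed amount per volume before
#' filtration, the ratio cancels sample-to-sample differences in extraction,
#' amplification and sequencing depth. A constant per-phylotype PCR bias
#' multiplies a phylotype's whole ratio series by a constant and therefore
#' does not affect growth rates fitted on the log scale.
#'
#' @param dataset An `arnis_dataset` from [validate_dataset()].
#' @return A long tibble with columns `phylotype_id`, `sample_id`, `ratio`;
#'   the internal-standard row is excluded.
#' @export
compute_arnis <- function(dataset) {
  if (!inherits(dataset, "arnis_dataset")) {
    abort("`dataset` must be created by validate_dataset().")
  }
  m <- counts_matrix(dataset$counts)
  std <- m[dataset$standard_id, ]
  ratios <- sweep(m[setdiff(rownames(m), dataset$standard_id), , drop = FALSE],
    2, std, "/"
  )
  out <- matrix_to_counts(ratios) |>
    tidyr::pivot_longer(-"phylotype_id", names_to = "sample_id", values_to = "ratio")
  attr(out, "standard_id") <- dataset$standard_id
  out
}

#' Assemble per-phylotype growth curves
#'
#' Joins ratio values with sample metadata and orders them in time, giving
#' one record per phylotype, treatment, time point and replicate. Missing
#' replicates at a time point are simply absent (never imputed). Use
#' [curve_means()] for the replicate-averaged curve.
#'
#' @param ratios Long ratio tibble from [compute_arnis()].
#' @param metadata Sample metadata.
#' @return A tibble of class `arnis_curves` with columns `phylotype_id`,
#'   `treatment`, `time_h`, `replicate`, `ratio`.
#' @export
build_growth_curves <- function(ratios, metadata) {
  metadata <- validate_sample_metadata(metadata)
  missing_samples <- setdiff(unique(ratios$sample_id), metadata$sample_id)
  if (length(missing_samples) > 0L) {
    abort(sprintf(
      "sample(s) in ratios but not in metadata: %s",
      paste(missing_samples, collapse = ", ")
    ))
  }
  curves <- ratios |>
    inner_join(
      metadata[c("sample_id", "treatment", "time_h", "replicate")],
      by = "sample_id"
    ) |>
    select("phylotype_id", "treatment", "time_h", "replicate", "ratio") |>
    arrange(.data$phylotype_id, .data$treatment, .data$time_h, .data$replicate)
  n_times <- curves |>
    distinct(.data$treatment, .data$time_h) |>
    dplyr::count(.data$treatment)
  if (any(n_times$n < 1L)) {
    warn("treatment(s) without any time point were dropped.")
  }
  class(curves) <- c("arnis_curves", class(curves))
  attr(curves, "standard_id") <- attr(ratios, "standard_id")
  curves
}

#' Replicate-mean growth curves
#'
#' Arithmetic mean of the replicate ratios present at each (phylotype,
#' treatment, time point).
#'
#' @param curves An `arnis_curves` tibble from [build_growth_curves()].
#' @return A tibble with columns `phylotype_id`, `treatment`, `time_h`,
#'   `ratio_mean`, `n_replicates`.
#' @export
curve_means <- function(curves) {
  curves |>
    as_tibble() |>
    group_by(.data$phylotype_id, .data$treatment, .data$time_h) |>
    summarise(
      ratio_mean = mean(.data$ratio),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
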