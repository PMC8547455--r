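#' Parameter-recovery report for a simulated experiment
#'
#' Compares growth rates estimated by the pipeline against the simulator's
#' ground truth: per-treatment root-mean-square error, mean bias
#' (estimate minus truth) and Pearson correlation over the phylotypes with
#' a non-missing estimate, plus the coverage (fraction of truth cells that
#' received an estimate). When classified response records are supplied,
#' a group-label confusion matrix and the recovery accuracy over
#' phylotypes labelled by both truth and estimate are added.
#'
#' @param sim An `arnis_simulation` (or a long truth tibble with columns
#'   `phylotype_id`, `treatment`, `true_mu` plus optionally a per-phylotype
#'   `group` truth in attribute form).
#' @param rates An `arnis_rates` object or rate tibble.
#' @param classified Optional classified records from [classify_response()]
#'   (needs `phylotype_id` and `group`); requires `sim` to be an
#'   `arnis_simulation` so true labels are available.
#' @return An object of class `arnis_recovery`: list with `per_treatment`
#'   tibble (`treatment`, `n`, `rmse`, `mean_bias`, `pearson_r`),
#'   `coverage`, and (if `classified` given) `confusion` and
#'   `group_accuracy`.
#' @export
recovery_report <- function(sim, rates, classified = NULL) {
  truth_long <- if (inherits(sim, "arnis_simulation")) truth_rates(sim) else as_tibble(sim)
  est <- as_rate_table(rates)
  joined <- inner_join(truth_long, est, by = c("phylotype_id", "treatment"))
  if (nrow(joined) == 0L) abort("no phylotypes shared between truth and estimates.")
  per_treatment <- joined |>
    group_by(.data$treatment) |>
    summarise(
      n = dplyr::n(),
      rmse = sqrt(mean((.data$mean_mu - .data$true_mu)^2)),
      mean_bias = mean(.data$mean_mu - .data$true_mu),
      pearson_r = if (dplyr::n() >= 3L) cor(.data$true_mu, .data$mean_mu) else NA_real_,
      .groups = "drop"
    )
  out <- list(
    per_treatment = per_treatment,
    coverage = nrow(joined) / nrow(truth_long)
  )
  if (!is.null(classified)) {
    if (!inherits(sim, "arnis_simulation")) {
      abort("group-label recovery needs an `arnis_simulation` as `sim`.")
    }
    cmp <- inner_join(
      sim$truth[c("phylotype_id", "group")] |> rename(true_group = "group"),
      classified[c("phylotype_id", "group")] |> rename(est_group = "group"),
      by = "phylotype_id"
    ) |>
      filter(!is.na(.data$est_group))
    levels4 <- c("I", "II", "III", "NR")
    out$confusion <- table(
      truth = factor(cmp$true_group, levels4),
      estimate = factor(cmp$est_group, levels4)
    )
    out$group_accuracy <- mean(cmp$true_group == as.character(cmp$est_group))
    out$n_labelled <- nrow(cmp)
  }
  structure(out, class = "arnis_recovery")
}

#' @export
print.arnis_recovery <- function(x, ...) {
  cat("<arnis_recovery>\n")
  print(x$per_treatment)
  cat(sprintf("coverage: %.1f%% of truth cells estimated\n", 100 * x$coverage))
  if (!is.null(x$confusion)) {
    cat(sprintf(
      "group-label recovery: %.1f%% of %d labelled phylotypes\n",
      100 * x$group_accuracy, x$n_labelled
    ))
    print(x$confusion)
  }
  invisible(x)
}
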