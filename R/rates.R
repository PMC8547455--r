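#' Bulk community growth-rate summary per treatment
#'
#' Arithmetic mean and sample standard deviation of the phylotype growth
#' rates within each treatment, with distribution quantiles for violin-style
#' summaries. A treatment with no rated phylotypes is omitted with a
#' warning; the SD of a single-phylotype treatment is reported as missing.
#'
#' @param rates An `arnis_rates` object or a rate tibble with columns
#'   `treatment` and `mean_mu`.
#' @param probs Quantile probabilities to report.
#' @return A tibble with one row per treatment: `mean_mu`, `sd_mu`, `n`,
#'   and one `q<prob>` column per requested quantile.
#' @export
bulk_rates <- function(rates, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  tbl <- as_rate_table(rates)
  if (nrow(tbl) == 0L) abort("rate table is empty.")
  out <- tbl |>
    group_by(.data$treatment) |>
    summarise(
      sd_mu = if (dplyr::n() >= 2L) sd(.data$mean_mu) else NA_real_,
      mean_mu = mean(.data$mean_mu),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    select("treatment", "mean_mu", "sd_mu", "n")
  qs <- tbl |>
    group_by(.data$treatment) |>
    dplyr::reframe(
      prob = probs,
      q = quantile(.data$mean_mu, probs = probs, names = FALSE, type = 7)
    ) |>
    mutate(prob = sprintf("q%02.0f", 100 * .data$prob)) |>
    tidyr::pivot_wider(names_from = "prob", values_from = "q")
  left_join(out, qs, by = "treatment")
}

#' Net growth rate from two absolute cell counts
#'
#' The specific growth rate implied by a change of abundance over time,
#' `mu = ln(n2 / n1) / dt`, with `dt` converted from hours to days so the
#' result is in day^-1. This is the microscopy/flow-cytometry counterpart
#' to ratio-based rates and measures net growth (gross growth minus
#' mortality).
#'
#' @param n1,n2 Strictly positive abundances (e.g. cells per ml) at times
#'   `t1_h` and `t2_h`.
#' @param t1_h,t2_h Times in hours, `t2_h > t1_h`.
#' @return Growth rate(s) in day^-1 (vectorized).
#' @examples
#' net_growth_from_counts(0.26e6, 1.56e6, 0, 48) # ln(6)/2 days
#' @export
net_growth_from_counts <- function(n1, n2, t1_h, t2_h) {
  if (any(!is.finite(n1) | n1 <= 0) || any(!is.finite(n2) | n2 <= 0)) {
    abort("cell counts must be strictly positive.")
  }
  if (any(t2_h <= t1_h)) abort("`t2_h` must be greater than `t1_h`.")
  log(n2 / n1) / ((t2_h - t1_h) / 24)
}

#' Growth rates from an absolute cell-count time series
#'
#' Log-linear fit of `ln(cells_per_ml)` over the exponential window per
#' (group, treatment, replicate), averaged over replicates — the same
#' estimator applied to microscopy counts that [estimate_rates()] applies
#' to internal-standard ratios, so the two are directly comparable.
#'
#' @param cell_counts Tibble as returned by [read_cell_counts()].
#' @param window Fitting window in hours.
#' @param min_points Minimum points per replicate fit (default 2: endpoint
#'   pairs are a legitimate microscopy design).
#' @return A tibble with columns `group`, `treatment`, `mean_mu`, `sd_mu`,
#'   `n_replicates`.
#' @export
cell_count_rates <- function(cell_counts, window = c(0, 24), min_points = 2) {
  cell_counts |>
    group_by(.data$group, .data$treatment, .data$replicate) |>
    summarise(
      fit_exponential(.data$time_h, .data$cells_per_ml,
        window = window,
        min_points = min_points
      ),
      .groups = "drop"
    ) |>
    filter(is.finite(.data$mu_per_day)) |>
    group_by(.data$group, .data$treatment) |>
    summarise(
      mean_mu = mean(.data$mu_per_day),
      sd_mu = if (dplyr::n() >= 2L) sd(.data$mu_per_day) else NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Pair ratio-based and count-based growth rates
#'
#' Joins growth rates estimated from internal-standard ratios with rates
#' from absolute cell counts for the same group labels, reporting their
#' difference. A positive difference in an early window is the signature of
#' unbalanced growth: gene copies (seen by sequencing) increasing ahead of
#' cell division (seen by microscopy).
#'
#' @param arnis_rates Tibble with columns `group`, `treatment` (optional),
#'   `mean_mu` — e.g. taxon-aggregated ratio-based rates.
#' @param count_rates Tibble with the same key columns and `mean_mu`, e.g.
#'   from [cell_count_rates()].
#' @return A paired tibble with `mu_arnis`, `mu_counts` and `difference`
#'   (`mu_arnis - mu_counts`); unmatched group labels are reported in the
#'   `"unmatched"` attribute and a message.
#' @export
compare_methods <- function(arnis_rates, count_rates) {
  by_cols <- intersect(
    intersect(names(arnis_rates), names(count_rates)),
    c("group", "treatment")
  )
  if (!"group" %in% by_cols) abort("both inputs need a `group` column.")
  a <- arnis_rates |> rename(mu_arnis = "mean_mu")
  b <- count_rates |> rename(mu_counts = "mean_mu")
  paired <- inner_join(
    a[c(by_cols, "mu_arnis")], b[c(by_cols, "mu_counts")],
    by = by_cols
  ) |>
    mutate(difference = .data$mu_arnis - .data$mu_counts)
  if (nrow(paired) == 0L) abort("no overlapping group labels between the two inputs.")
  unmatched <- union(
    anti_join(a, b, by = by_cols)$group,
    anti_join(b, a, by = by_cols)$group
  )
  if (length(unmatched) > 0L) {
    inform(sprintf("unmatched group label(s): %s", paste(unique(unmatched), collapse = ", ")))
  }
  attr(paired, "unmatched") <- unique(unmatched)
  paired
}
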