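#' Log-linear fit of an exponential growth window
#'
#' Fits ordinary least squares of `ln(ratio)` against time (in days) over a
#' closed time window, the standard estimator for a specific growth rate
#' under exponential growth with multiplicative noise: the slope is the rate
#' in day^-1 and the intercept the log ratio at t = 0. Zero ratios inside
#' the window carry no information on the log scale and are dropped before
#' fitting (no pseudocount by default); if fewer than `min_points` positive
#' values remain, the fit is marked failed. When a positive `pseudocount`
#' (in standard-equivalents) is supplied it is added to every ratio instead
#' of dropping zeros.
#'
#' @param time_h Numeric vector of times in hours.
#' @param ratio Numeric vector of internal-standard ratios (same length).
#' @param window Closed fitting window in hours, default `c(0, 24)`.
#' @param min_points Minimum positive points required (default 3).
#' @param pseudocount Optional pseudocount added to all ratios (default 0,
#'   i.e. zeros are dropped).
#' @return A one-row tibble: `mu_per_day`, `intercept`, `r_squared`,
#'   `n_points`, `passed` is `NA` here (the quality gate is applied by
#'   [estimate_rates()], which knows the `r_squared` threshold).
#' @examples
#' fit_exponential(c(0, 12, 24), c(1, 2, 4)) # mu = ln(4) per day
#' @export
fit_exponential <- function(time_h, ratio, window = c(0, 24), min_points = 3,
                            pseudocount = 0) {
  stopifnot(length(time_h) == length(ratio))
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be c(start, end) with start < end (hours).")
  }
  in_win <- time_h >= window[1] & time_h <= window[2] &
    is.finite(time_h) & is.finite(ratio)
  t <- time_h[in_win]
  y <- ratio[in_win] + pseudocount
  pos <- y > 0
  t <- t[pos]
  y <- y[pos]
  n <- length(t)
  failed <- tibble(
    mu_per_day = NA_real_, intercept = NA_real_,
    r_squared = NA_real_, n_points = n, passed = NA
  )
  if (n < min_points || length(unique(t)) < 2L) {
    return(failed)
  }
  t_day <- t / 24
  ly <- log(y)
  fit <- lm(ly ~ t_day)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot < 1e-12) {
    if (ss_res < 1e-12) 1 else 0
  } else {
    1 - ss_res / ss_tot
  }
  tibble(
    mu_per_day = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n_points = n,
    passed = NA
  )
}

#' Estimate per-phylotype growth rates from growth curves
#'
#' For every phylotype x treatment x replicate, fits the exponential window
#' with [fit_exponential()]; a replicate fit passes the quality gate when
#' its coefficient of determination exceeds `r2_min` (strictly) and it used
#' at least `min_points` positive ratios. The reported rate per phylotype x
#' treatment is the arithmetic mean of the passing replicate slopes, with
#' the sample standard deviation (n - 1) where two or more replicates pass.
#' Cells with fewer than `min_replicates` passing replicates are reported
#' as missing (absent from the rate table), never as zero.
#'
#' @param curves An `arnis_curves` tibble from [build_growth_curves()].
#' @param window Exponential-growth window in hours (default `c(0, 24)`).
#' @param r2_min Quality gate on the fit's R-squared (default 0.6, strict).
#' @param min_points Minimum positive points per replicate fit (default 3).
#' @param min_replicates Minimum passing replicates for a reported rate
#'   (default 1).
#' @param pseudocount Passed to [fit_exponential()].
#' @return An object of class `arnis_rates`: a list with `rates` (tibble:
#'   `phylotype_id`, `treatment`, `mean_mu`, `sd_mu`, `n_replicates_passing`),
#'   `fits` (all per-replicate fits, passing or not) and `params`.
#'   [tidy()] returns the rate table, [glance()] a one-row fit summary.
#' @export
estimate_rates <- function(curves, window = c(0, 24), r2_min = 0.6,
                           min_points = 3, min_replicates = 1,
                           pseudocount = 0) {
  fits <- curves |>
    as_tibble() |>
    group_by(.data$phylotype_id, .data$treatment, .data$replicate) |>
    summarise(
      fit_exponential(.data$time_h, .data$ratio,
        window = window,
        min_points = min_points, pseudocount = pseudocount
      ),
      .groups = "drop"
    ) |>
    mutate(passed = !is.na(.data$r_squared) &
      .data$r_squared > r2_min &
      .data$n_points >= min_points &
      is.finite(.data$mu_per_day))

  rates <- fits |>
    filter(.data$passed) |>
    group_by(.data$phylotype_id, .data$treatment) |>
    summarise(
      mean_mu = mean(.data$mu_per_day),
      sd_mu = if (dplyr::n() >= 2L) sd(.data$mu_per_day) else NA_real_,
      n_replicates_passing = dplyr::n(),
      .groups = "drop"
    ) |>
    filter(.data$n_replicates_passing >= min_replicates)

  structure(
    list(
      rates = rates, fits = fits,
      params = list(
        window = window, r2_min = r2_min, min_points = min_points,
        min_replicates = min_replicates, pseudocount = pseudocount
      )
    ),
    class = "arnis_rates"
  )
}

#' @export
print.arnis_rates <- function(x, ...) {
  cat(sprintf(
    "<arnis_rates> %d phylotype x treatment rates (window %g-%g h, R^2 > %g)\n",
    nrow(x$rates), x$params$window[1], x$params$window[2], x$params$r2_min
  ))
  cat(sprintf(
    "  %d of %d replicate fits passed the quality gate\n",
    sum(x$fits$passed), nrow(x$fits)
  ))
  print(x$rates, ...)
  invisible(x)
}

#' @rdname estimate_rates
#' @param x An `arnis_rates` object.
#' @param ... Unused.
#' @export
tidy.arnis_rates <- function(x, ...) x$rates

#' @rdname estimate_rates
#' @export
glance.arnis_rates <- function(x, ...) {
  tibble(
    n_phylotypes = dplyr::n_distinct(x$rates$phylotype_id),
    n_treatments = dplyr::n_distinct(x$rates$treatment),
    n_fits = nrow(x$fits),
    n_fits_passing = sum(x$fits$passed),
    pass_rate = mean(x$fits$passed),
    window_start_h = x$params$window[1],
    window_end_h = x$params$window[2],
    r2_min = x$params$r2_min
  )
}

# accept either an arnis_rates object or a bare rate tibble
as_rate_table <- function(x) {
  if (inherits(x, "arnis_rates")) {
    return(x$rates)
  }
  if (is.data.frame(x)) {
    return(as_tibble(x))
  }
  abort("expected an `arnis_rates` object or a rate tibble.")
}
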