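test_that("a doubling series gives the closed-form slope with a perfect fit", {
  fit <- fit_exponential(c(0, 12, 24), c(1, 2, 4))
  expect_equal(fit$mu_per_day, log(4), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)
})

test_that("flat series fit zero slope; zeros are dropped and can fail the fit", {
  flat <- fit_exponential(c(0, 12, 24), c(1, 1, 1))
  expect_equal(flat$mu_per_day, 0)
  dropped <- fit_exponential(c(0, 12, 24), c(1, 0, 4))
  expect_true(is.na(dropped$mu_per_day))
  expect_equal(dropped$n_points, 2L)
  # a pseudocount keeps the zero point instead
  with_pc <- fit_exponential(c(0, 12, 24), c(1, 0, 4), pseudocount = 0.01)
  expect_equal(with_pc$n_points, 3L)
})

test_that("noise-free exponentials are recovered to machine precision (property)", {
  set.seed(11)
  for (rep in 1:10) {
    mu <- runif(1, -2, 5)
    a0 <- runif(1, 0.01, 10)
    t <- sort(sample(seq(0, 24, by = 4), 4))
    fit <- fit_exponential(t, a0 * exp(mu * t / 24))
    expect_equal(fit$mu_per_day, mu, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("scaling a curve shifts the intercept by log(b) and leaves the slope", {
  t <- c(0, 6, 12, 18, 24)
  y <- exp(1.7 * t / 24) * exp(rnorm(5, sd = 0.05))
  f0 <- fit_exponential(t, y)
  fb <- fit_exponential(t, 5.5 * y)
  expect_equal(fb$mu_per_day, f0$mu_per_day, tolerance = 1e-12)
  expect_equal(fb$intercept, f0$intercept + log(5.5), tolerance = 1e-12)
})

test_that("the day conversion matches an hour-scale regression times 24", {
  t <- c(0, 8, 16, 24)
  y <- c(1.0, 1.9, 4.2, 7.6)
  per_hour <- unname(coef(lm(log(y) ~ t))[2])
  fit <- fit_exponential(t, y)
  expect_equal(fit$mu_per_day, 24 * per_hour, tolerance = 1e-12)
})

test_that("rates average passing replicates with a sample SD and apply the gate", {
  mus <- c(R1 = 1, R2 = 2, R3 = 3)
  curves <- dplyr::bind_rows(lapply(names(mus), function(r) {
    cv <- exact_curves(c(p = mus[[r]]), replicates = r)
    cv$phylotype_id <- "p"
    cv
  }))
  est <- estimate_rates(curves)
  expect_equal(est$rates$mean_mu, 2)
  expect_equal(est$rates$sd_mu, 1)
  expect_equal(est$rates$n_replicates_passing, 3L)

  # wreck one replicate so it fails the R^2 gate: mean over the other two
  noisy <- curves
  noisy$ratio[noisy$replicate == "R3"] <- c(1, 20, 1.2)
  est2 <- estimate_rates(noisy)
  expect_equal(est2$rates$n_replicates_passing, 2L)
  expect_equal(est2$rates$mean_mu, 1.5, tolerance = 1e-9)

  # exact recovery of a noise-free rate
  exact <- estimate_rates(exact_curves(c(fast = 2.5)))
  expect_equal(exact$rates$mean_mu, 2.5, tolerance = 1e-9)
})

test_that("cells with no passing replicate are missing, not zero", {
  curves <- exact_curves(c(p = 1))
  curves$ratio <- 0
  est <- estimate_rates(curves)
  expect_equal(nrow(est$rates), 0L)
  expect_false(any(est$fits$passed))
})

test_that("rate estimation is invariant to row permutations of the curves", {
  set.seed(3)
  curves <- exact_curves(c(a = 0.5, b = 2, c = 3.5))
  curves$ratio <- curves$ratio * exp(rnorm(nrow(curves), sd = 0.1))
  est1 <- tidy(estimate_rates(curves))
  est2 <- tidy(estimate_rates(curves[sample(nrow(curves)), ]))
  expect_equal(est1, est2)
})

test_that("tidy and glance expose the rate table and the gate summary", {
  est <- estimate_rates(exact_curves(c(a = 1, b = 2)))
  expect_s3_class(tidy(est), "tbl_df")
  g <- glance(est)
  expect_equal(g$n_fits_passing, 6L)
  expect_equal(g$r2_min, 0.6)
})
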