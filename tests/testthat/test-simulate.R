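# a degenerate one-phylotype configuration with all rates pinned to mu
pinned_config <- function(mu = 1, ...) {
  synthetic_config(
    n_phylotypes = 1,
    control_rate_range = c(mu, mu),
    fc_grazer_strong = c(1, 1), fc_grazer_weak = c(1, 1),
    fc_phosphate_strong = c(1, 1), fc_phosphate_weak = c(1, 1),
    pcr_bias_sigma = 0,
    ...
  )
}

run_rates <- function(sim, ...) {
  ds <- validate_dataset(sim$counts, sim$metadata, sim$standard_id)
  estimate_rates(build_growth_curves(compute_arnis(ds), sim$metadata), ...)
}

test_that("the configuration enforces its invariants", {
  expect_error(synthetic_config(group_proportions = c(I = 0.9, II = 0.2, III = 0, NR = 0)), "summing to 1")
  expect_error(synthetic_config(n_phylotypes = 0), "n_phylotypes")
  expect_error(synthetic_config(spike_volume_ul = 0), "spike")
  expect_error(synthetic_config(time_points_h = c(5)), "time_points_h")
  expect_equal(standard_concentration(synthetic_config()), 1e4)
})

test_that("the same configuration and seed reproduce counts bit for bit", {
  s1 <- simulate_dataset(small_sim_config(), seed = 4)
  s2 <- simulate_dataset(small_sim_config(), seed = 4)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(small_sim_config(), seed = 5)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("adding a phylotype leaves the other phylotypes' draws untouched", {
  s40 <- simulate_dataset(synthetic_config(n_phylotypes = 40), seed = 2)
  s41 <- simulate_dataset(synthetic_config(n_phylotypes = 41), seed = 2)
  cols <- c("phylotype_id", "group", "mu_control", "mu_filtered", "mu_phosphate", "bias")
  expect_equal(s40$truth[cols], s41$truth[seq_len(40), cols])
})

test_that("expectation mode recovers a pinned unit growth rate exactly", {
  sim <- simulate_dataset(pinned_config(mu = 1), seed = 1, expectation = TRUE)
  ratios <- compute_arnis(validate_dataset(sim$counts, sim$metadata, sim$standard_id))
  curves <- build_growth_curves(ratios, sim$metadata)
  one <- dplyr::filter(curves, treatment == "F", replicate == "R1", time_h <= 24)
  expect_equal(one$ratio[one$time_h == 12] / one$ratio[one$time_h == 0],
    exp(0.5),
    tolerance = 1e-9
  )
  est <- tidy(estimate_rates(curves))
  expect_equal(est$mean_mu, rep(1, 3), tolerance = 1e-9)
})

test_that("growth halts at the stationary plateau", {
  sim <- simulate_dataset(pinned_config(mu = 1, stationary_time_h = 24),
    seed = 1, expectation = TRUE
  )
  ratios <- compute_arnis(validate_dataset(sim$counts, sim$metadata, sim$standard_id))
  curves <- build_growth_curves(ratios, sim$metadata)
  one <- dplyr::filter(curves, treatment == "F", replicate == "R1")
  expect_equal(one$ratio[one$time_h == 36], one$ratio[one$time_h == 24], tolerance = 1e-12)
  expect_equal(one$ratio[one$time_h == 60], one$ratio[one$time_h == 24], tolerance = 1e-12)
})

test_that("the internal standard stays quantifiable in every sample", {
  for (s in 1:3) {
    sim <- simulate_dataset(synthetic_config(), seed = s)
    share <- sim$sample_truth$expected_standard_share
    expect_gte(min(share), 4e-4)
    expect_lte(max(share), 0.2)
    std_reads <- as.numeric(sim$counts[sim$counts$phylotype_id == sim$standard_id, -1])
    expect_gte(min(std_reads), 30)
  }
})

test_that("library sizes respect the truncation floor and the design is complete", {
  sim <- simulate_dataset(small_sim_config(reads_mean = 2000, reads_sd = 3000), seed = 9)
  expect_gte(min(sim$sample_truth$library_size), 1000)
  expect_equal(nrow(sim$metadata), 3 * 3 * 6)
  expect_equal(colSums(as.matrix(sim$counts[-1])),
               setNames(sim$sample_truth$library_size, sim$sample_truth$sample_id))
})

test_that("amplification bias cancels exactly in noise-free rate estimates", {
  base <- simulate_dataset(small_sim_config(pcr_bias_sigma = 0), seed = 6, expectation = TRUE)
  biased <- simulate_dataset(small_sim_config(pcr_bias_sigma = 2), seed = 6, expectation = TRUE)
  expect_equal(base$truth$mu_filtered, biased$truth$mu_filtered)
  r0 <- tidy(run_rates(base))
  rb <- tidy(run_rates(biased))
  expect_equal(rb$mean_mu, r0$mean_mu, tolerance = 1e-9)
})

test_that("doubling sequencing depth does not worsen average rate recovery", {
  rmse_filtered <- function(seed, mult) {
    cfg <- synthetic_config(
      n_phylotypes = 80,
      reads_mean = 127018 * mult, reads_sd = 15026 * mult
    )
    sim <- simulate_dataset(cfg, seed = seed)
    rec <- recovery_report(sim, run_rates(sim))
    rec$per_treatment$rmse[rec$per_treatment$treatment == "F"]
  }
  seeds <- 1:5
  base <- vapply(seeds, rmse_filtered, numeric(1), mult = 1)
  deep <- vapply(seeds, rmse_filtered, numeric(1), mult = 2)
  expect_lte(mean(deep), mean(base))
})
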