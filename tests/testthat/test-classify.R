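rates_tbl <- function(mu_c, mu_f, mu_fp, id = "p") {
  tibble::tibble(
    phylotype_id = id,
    treatment = c("C", "F", "FP"),
    mean_mu = c(mu_c, mu_f, mu_fp)
  )
}

test_that("fold changes divide treatment rates and guard the denominator", {
  fc <- fold_changes(rates_tbl(1, 3, 4.5))
  expect_equal(fc$fc_filtered_control, 3)
  expect_equal(fc$fc_phosphate_filtered, 1.5)

  no_control <- fold_changes(rates_tbl(NA, 3, 4.5)[-1, ])
  expect_true(is.na(no_control$fc_filtered_control))
  expect_equal(no_control$fc_phosphate_filtered, 1.5)

  zero_f <- fold_changes(rates_tbl(1, 0, 4.5))
  expect_true(is.na(zero_f$fc_phosphate_filtered))

  expect_error(fold_changes(rates_tbl(1, 2, 3), roles = c(control = "C")), "filtered")
})

test_that("the derived threshold is the interpolated percentile of pooled values", {
  recs <- tibble::tibble(
    fc_filtered_control = c(1, 2),
    fc_phosphate_filtered = c(3, 4)
  )
  thr <- derive_threshold(recs, percentile = 25)
  expect_equal(thr$value, 1.75)
  expect_equal(thr$source, "derived")
  expect_equal(derive_threshold(recs, percentile = 0)$value, 1)

  same <- tibble::tibble(fc_filtered_control = rep(2.2, 4), fc_phosphate_filtered = rep(2.2, 4))
  expect_equal(derive_threshold(same)$value, 2.2)

  few <- tibble::tibble(fc_filtered_control = c(1, NA), fc_phosphate_filtered = c(NA, 2))
  expect_error(derive_threshold(few), "fixed threshold")
})

test_that("derived thresholds agree with a brute-force sort-and-interpolate oracle", {
  brute_percentile <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p / 100
    lo <- floor(h)
    v[lo + 1] + (h - lo) * (v[min(lo + 2, length(v))] - v[lo + 1])
  }
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:30, 1)
    vals <- round(runif(n, 0.1, 6), 3)
    p <- sample(c(5, 25, 50, 90), 1)
    recs <- tibble::tibble(
      fc_filtered_control = vals,
      fc_phosphate_filtered = NA_real_
    )
    expect_equal(derive_threshold(recs, percentile = p)$value,
      brute_percentile(vals, p),
      tolerance = 1e-12
    )
  }
})

test_that("response groups follow the threshold rule on printed fold-change pairs", {
  recs <- tibble::tibble(
    fc_filtered_control = c(5.36, 5.12, 0.90, 1.0, NA),
    fc_phosphate_filtered = c(1.52, 1.07, 2.98, 1.0, 1.78)
  )
  out <- classify_response(recs, threshold = 1.3)
  expect_equal(as.character(out$group), c("I", "II", "III", "NR", NA))
})

test_that("classification is a total partition agreeing with independent predicates", {
  grid <- tidyr::expand_grid(
    fc_filtered_control = seq(0.1, 5.0, by = 0.35),
    fc_phosphate_filtered = seq(0.1, 5.0, by = 0.35)
  )
  out <- classify_response(grid, threshold = 1.3)
  expect_false(anyNA(out$group))
  independent <- with(grid, ifelse(
    fc_filtered_control > 1.3,
    ifelse(fc_phosphate_filtered > 1.3, "I", "II"),
    ifelse(fc_phosphate_filtered > 1.3, "III", "NR")
  ))
  expect_equal(as.character(out$group), independent)
})

test_that("common rate rescaling changes no fold change and no group", {
  set.seed(23)
  base <- tibble::tibble(
    phylotype_id = rep(sprintf("p%d", 1:20), each = 3),
    treatment = rep(c("C", "F", "FP"), 20),
    mean_mu = runif(60, 0.1, 4)
  )
  scaled <- dplyr::mutate(base, mean_mu = mean_mu * 3.7)
  r1 <- classify_response(fold_changes(base))
  r2 <- classify_response(fold_changes(scaled))
  expect_equal(r1$fc_filtered_control, r2$fc_filtered_control, tolerance = 1e-12)
  expect_equal(r1$group, r2$group)
})

test_that("taxon aggregation averages finite fold changes and partitions groups", {
  records <- tibble::tibble(
    phylotype_id = c("p1", "p2", "p3", "p4"),
    fc_filtered_control = c(2, 4, 1.0, NA),
    fc_phosphate_filtered = c(2, 2, 2, 2),
    group = factor(c("I", "I", "III", NA), levels = c("I", "II", "III", "NR"))
  )
  taxonomy <- tibble::tibble(
    phylotype_id = c("p1", "p2", "p3", "p4"),
    order = c("Alteromonadales", "Alteromonadales", "Alteromonadales", "SAR11")
  )
  agg <- aggregate_by_taxon(records, taxonomy, "order")
  alt <- agg[agg$taxon == "Alteromonadales", ]
  expect_equal(alt$mean_fc_filtered_control, mean(c(2, 4, 1.0)))
  expect_equal(alt$frac_I, 2 / 3)
  expect_equal(alt$frac_III, 1 / 3)
  expect_equal(alt$frac_I + alt$frac_II + alt$frac_III + alt$frac_NR, 1)
  # single-member taxon: means equal that member's values
  s11 <- agg[agg$taxon == "SAR11", ]
  expect_true(is.na(s11$mean_fc_filtered_control))
  expect_equal(s11$mean_fc_phosphate_filtered, 2)
  expect_error(aggregate_by_taxon(records, taxonomy, "family"), "family")
})

test_that("relative shares average replicates and close to 100% per treatment", {
  counts <- tibble::tibble(
    phylotype_id = c("p1", "p2", "std"),
    F_T24_R1 = c(300, 100, 50),
    F_T24_R2 = c(150, 50, 25),
    C_T24_R1 = c(10, 90, 7)
  )
  metadata <- tibble::tibble(
    sample_id = c("F_T24_R1", "F_T24_R2", "C_T24_R1"),
    treatment = c("F", "F", "C"),
    time_h = 24,
    replicate = c("R1", "R2", "R1")
  )
  taxonomy <- tibble::tibble(
    phylotype_id = c("p1", "p2", "std"),
    order = c("Alteromonadales", "SAR11", "Burkholderiales")
  )
  shares <- relative_share(counts, metadata, taxonomy, "order", 24, standard_id = "std")
  f <- shares[shares$treatment == "F", ]
  expect_equal(f$share_pct[f$taxon == "Alteromonadales"], 75)
  expect_equal(f$share_pct[f$taxon == "SAR11"], 25)
  sums <- tapply(shares$share_pct, shares$treatment, sum)
  expect_equal(as.numeric(sums), rep(100, 2))
  expect_error(
    relative_share(counts, metadata, taxonomy, "order", 36, standard_id = "std"),
    "36"
  )
})
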