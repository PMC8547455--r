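ratio_of <- function(ratios, p, s) {
  ratios$ratio[ratios$phylotype_id == p & ratios$sample_id == s]
}

test_that("the internal-standard ratio is reads over standard reads, per sample", {
  ratios <- compute_arnis(toy_dataset())
  expect_equal(ratio_of(ratios, "otu1", "s1"), 500 / 250)
  expect_equal(ratio_of(ratios, "otu2", "s1"), 0)
  expect_equal(ratio_of(ratios, "otu2", "s3"), 0.4)
  expect_false("std" %in% ratios$phylotype_id)
})

test_that("ratios are exactly invariant to sequencing depth changes", {
  counts <- toy_counts()
  deeper <- counts
  for (col in c("s1", "s2", "s3")) deeper[[col]] <- deeper[[col]] * 7L
  r1 <- compute_arnis(validate_dataset(counts, toy_metadata(), "std"))
  r2 <- compute_arnis(validate_dataset(deeper, toy_metadata(), "std"))
  expect_identical(r1$ratio, r2$ratio)
})

test_that("a constant per-phylotype bias multiplies its whole curve by that constant", {
  counts <- toy_counts()
  biased <- counts
  b <- 3L
  biased[biased$phylotype_id == "otu1", c("s1", "s2", "s3")] <-
    biased[biased$phylotype_id == "otu1", c("s1", "s2", "s3")] * b
  r0 <- compute_arnis(validate_dataset(counts, toy_metadata(), "std"))
  rb <- compute_arnis(validate_dataset(biased, toy_metadata(), "std"))
  expect_equal(
    rb$ratio[rb$phylotype_id == "otu1"],
    b * r0$ratio[r0$phylotype_id == "otu1"]
  )
  expect_equal(
    rb$ratio[rb$phylotype_id == "otu2"],
    r0$ratio[r0$phylotype_id == "otu2"]
  )
})

test_that("growth curves average replicates arithmetically and ignore sample order", {
  ratios <- tibble::tibble(
    phylotype_id = "otu1",
    sample_id = c("a", "b", "c", "d"),
    ratio = c(1, 2, 3, 5)
  )
  metadata <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    treatment = "F",
    time_h = c(0, 0, 0, 12),
    replicate = c("R1", "R2", "R3", "R1")
  )
  curves <- build_growth_curves(ratios, metadata)
  means <- curve_means(curves)
  expect_equal(means$ratio_mean[means$time_h == 0], 2)
  expect_equal(means$n_replicates[means$time_h == 0], 3L)
  # single replicate present: mean is that value
  expect_equal(means$ratio_mean[means$time_h == 12], 5)

  shuffled <- build_growth_curves(ratios[c(3, 1, 4, 2), ], metadata[c(4, 2, 1, 3), ])
  expect_equal(as.data.frame(shuffled), as.data.frame(curves))
})

test_that("curve means equal the arithmetic mean of present replicates (property)", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    ratios <- tibble::tibble(
      phylotype_id = "p",
      sample_id = sprintf("s%d", seq_len(n)),
      ratio = runif(n, 0, 10)
    )
    metadata <- tibble::tibble(
      sample_id = ratios$sample_id, treatment = "F",
      time_h = 0, replicate = sprintf("R%d", seq_len(n))
    )
    means <- curve_means(build_growth_curves(ratios, metadata))
    expect_equal(means$ratio_mean, mean(ratios$ratio))
  }
})
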