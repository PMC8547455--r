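#' Configuration for the synthetic manipulation experiment
#'
#' Describes a grazer-removal / phosphate-amendment incubation experiment
#' the way the analysis sees it: a community of exponentially growing
#' phylotypes plus a constant-per-volume internal-standard spike, sequenced
#' multinomially at a realistic library size. Each phylotype belongs to one
#' response archetype: group I (responds to both grazer removal and
#' phosphate), group II (grazer removal only), group III (phosphate only)
#' or NR (neither). Rates are built multiplicatively: a control rate drawn
#' from `control_rate_range`, a grazer-removal fold change drawn from the
#' "strong" or "weak" interval according to the archetype, and a phosphate
#' fold change likewise, so the true response group is well defined
#' relative to the 1.3 fold-change threshold.
#'
#' @param n_phylotypes Number of phylotypes (excluding the standard).
#' @param group_proportions Named proportions over `I`, `II`, `III`, `NR`;
#'   must sum to 1.
#' @param treatments Named character vector mapping roles `control`,
#'   `filtered`, `phosphate` to treatment labels.
#' @param control_rate_range Uniform range of control growth rates
#'   (day^-1).
#' @param fc_grazer_strong,fc_grazer_weak Uniform ranges for the
#'   filtered/control fold change of responding vs non-responding
#'   archetypes.
#' @param fc_phosphate_strong,fc_phosphate_weak Same for the
#'   phosphate/filtered fold change.
#' @param rate_max Upper bound (day^-1) applied to the filtered and
#'   phosphate rates, mirroring the fastest growth observed in such
#'   incubations; the true fold changes are recomputed after capping.
#' @param total_cells_per_ml Named initial community abundance per role
#'   (cells ml^-1); filtration removes about half of the cells, hence lower
#'   starting totals in the filtered treatments.
#' @param abundance_sdlog Lognormal sd of relative initial abundances.
#' @param stationary_time_h Hour at which growth halts (hard plateau).
#'   Incubated bottles stop growing once the liberated substrate is used
#'   up, so the default (24 h, the end of the exponential phase) keeps
#'   community totals, and with them the internal standard's read share,
#'   in the realistic range; set to `NULL` for unbounded exponential
#'   growth.
#' @param pcr_bias_sigma Lognormal sd of the per-phylotype amplification
#'   bias factor, constant across samples (0 disables bias).
#' @param reads_mean,reads_sd,reads_min Per-sample library size: normal
#'   with this mean/sd, truncated at `reads_min` and rounded.
#' @param standard_cells_per_ml Cell concentration of the internal-standard
#'   suspension.
#' @param spike_volume_ul Spike volume added per `sample_volume_ml`.
#' @param sample_volume_ml Filtered sample volume receiving the spike.
#' @param time_points_h Sampling times in hours.
#' @param n_replicates Replicate bottles per treatment.
#' @return A validated list of class `arnis_sim_config`.
#' @export
synthetic_config <- function(n_phylotypes = 200,
                             group_proportions = c(I = 0.50, II = 0.10, III = 0.25, NR = 0.15),
                             treatments = c(control = "C", filtered = "F", phosphate = "FP"),
                             control_rate_range = c(0.1, 0.9),
                             fc_grazer_strong = c(1.8, 5.0),
                             fc_grazer_weak = c(0.6, 1.1),
                             fc_phosphate_strong = c(1.5, 3.0),
                             fc_phosphate_weak = c(0.6, 1.1),
                             rate_max = 6,
                             total_cells_per_ml = c(control = 4.7e5, filtered = 2.6e5, phosphate = 2.2e5),
                             abundance_sdlog = 1.5,
                             stationary_time_h = 24,
                             pcr_bias_sigma = 0.5,
                             reads_mean = 127018, reads_sd = 15026, reads_min = 1000,
                             standard_cells_per_ml = 2e8,
                             spike_volume_ul = 5, sample_volume_ml = 100,
                             time_points_h = c(0, 12, 24, 36, 48, 60),
                             n_replicates = 3) {
  cfg <- list(
    n_phylotypes = n_phylotypes, group_proportions = group_proportions,
    treatments = treatments, control_rate_range = control_rate_range,
    fc_grazer_strong = fc_grazer_strong, fc_grazer_weak = fc_grazer_weak,
    fc_phosphate_strong = fc_phosphate_strong, fc_phosphate_weak = fc_phosphate_weak,
    rate_max = rate_max,
    total_cells_per_ml = total_cells_per_ml, abundance_sdlog = abundance_sdlog,
    stationary_time_h = stationary_time_h, pcr_bias_sigma = pcr_bias_sigma,
    reads_mean = reads_mean, reads_sd = reads_sd, reads_min = reads_min,
    standard_cells_per_ml = standard_cells_per_ml,
    spike_volume_ul = spike_volume_ul, sample_volume_ml = sample_volume_ml,
    time_points_h = time_points_h, n_replicates = n_replicates
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_phylotypes < 1) abort("`n_phylotypes` must be >= 1.")
  gp <- cfg$group_proportions
  if (!setequal(names(gp), c("I", "II", "III", "NR")) ||
    abs(sum(gp) - 1) > 1e-8 || any(gp < 0)) {
    abort("`group_proportions` must be named I/II/III/NR, non-negative, summing to 1.")
  }
  roles <- c("control", "filtered", "phosphate")
  if (!all(roles %in% names(cfg$treatments))) {
    abort("`treatments` must name labels for control, filtered and phosphate roles.")
  }
  if (!all(roles %in% names(cfg$total_cells_per_ml)) ||
    any(cfg$total_cells_per_ml <= 0)) {
    abort("`total_cells_per_ml` must give a positive total per role.")
  }
  if (!is.finite(cfg$rate_max) || cfg$rate_max <= 0) abort("`rate_max` must be > 0.")
  for (f in c(
    "abundance_sdlog", "pcr_bias_sigma", "reads_mean", "reads_sd",
    "reads_min", "standard_cells_per_ml", "spike_volume_ul", "sample_volume_ml"
  )) {
    if (any(!is.finite(cfg[[f]])) || any(cfg[[f]] < 0)) {
      abort(sprintf("`%s` must be finite and non-negative.", f))
    }
  }
  if (cfg$standard_cells_per_ml <= 0 || cfg$sample_volume_ml <= 0 ||
    cfg$spike_volume_ul <= 0) {
    abort("spike parameters must be strictly positive.")
  }
  if (length(cfg$time_points_h) < 2L || any(cfg$time_points_h < 0)) {
    abort("`time_points_h` needs >= 2 non-negative times.")
  }
  if (cfg$n_replicates < 1) abort("`n_replicates` must be >= 1.")
  structure(cfg, class = "arnis_sim_config")
}

#' Internal-standard concentration in the spiked sample
#'
#' Cells of standard per ml of sample implied by the spike parameters:
#' `standard_cells_per_ml * (spike_volume_ul / 1000) / sample_volume_ml`.
#' With the defaults (2e8 cells ml^-1, 5 ul per 100 ml) this is 1e4
#' standard cells per ml of sample.
#'
#' @param config An `arnis_sim_config`.
#' @return Standard cells per ml of sample.
#' @export
standard_concentration <- function(config) {
  config$standard_cells_per_ml * (config$spike_volume_ul / 1000) /
    config$sample_volume_ml
}

#' Simulate a spiked amplicon time-series experiment
#'
#' Draws per-phylotype ground truth (response archetype, per-treatment
#' rates, initial relative abundance, amplification bias) and per-sample
#' sequencing (library size, multinomial read counts over phylotypes plus
#' the internal standard). Growth is deterministic exponential,
#' `A_i(t) = A_i(0) * exp(mu_i * t / 24)`, optionally truncated at
#' `stationary_time_h`; all randomness enters through the phylotype-level
#' draws and the multinomial sequencing. Per-phylotype and per-sample
#' random substreams are derived from the single `seed`, so the output is
#' bit-for-bit reproducible and a phylotype's own draws do not depend on
#' how many other phylotypes exist.
#'
#' @param config An `arnis_sim_config` from [synthetic_config()].
#' @param seed Integer seed.
#' @param expectation If `TRUE`, skip all sequencing noise and return
#'   expected (real-valued) read counts at the mean library size — a
#'   diagnostic mode in which the analysis should recover the true rates
#'   exactly.
#' @return A list of class `arnis_simulation`: `counts`, `metadata`,
#'   `taxonomy`, `truth` (per-phylotype ground truth), `sample_truth`
#'   (per-sample library size and expected standard share), `standard_id`,
#'   `config`, `seed`.
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1,
                             expectation = FALSE) {
  config <- validate_sim_config(unclass(config))
  n <- config$n_phylotypes
  roles <- c("control", "filtered", "phosphate")
  labels <- config$treatments[roles]
  ids <- sprintf("otu_%04d", seq_len(n))
  standard_id <- "internal_standard"

  gp <- config$group_proportions[c("I", "II", "III", "NR")]
  cum_gp <- cumsum(gp)

  draw_phylotype <- function(i) {
    with_seed(substream_seed(seed, "phylotype", i), {
      u <- runif(1)
      group <- names(cum_gp)[which(u <= cum_gp + 1e-12)[1]]
      mu_c <- runif(1, config$control_rate_range[1], config$control_rate_range[2])
      fc1_rng <- if (group %in% c("I", "II")) config$fc_grazer_strong else config$fc_grazer_weak
      fc2_rng <- if (group %in% c("I", "III")) config$fc_phosphate_strong else config$fc_phosphate_weak
      fc1 <- runif(1, fc1_rng[1], fc1_rng[2])
      fc2 <- runif(1, fc2_rng[1], fc2_rng[2])
      mu_f <- min(mu_c * fc1, config$rate_max)
      mu_fp <- min(mu_f * fc2, config$rate_max)
      rel_raw <- rlnorm(1, meanlog = 0, sdlog = config$abundance_sdlog)
      bias <- if (config$pcr_bias_sigma > 0) {
        rlnorm(1, meanlog = 0, sdlog = config$pcr_bias_sigma)
      } else {
        1
      }
      phylum <- sample(c(
        "Proteobacteria", "Bacteroidota", "Cyanobacteria",
        "Actinobacteriota", "Campilobacterota"
      ), 1)
      tibble(
        phylotype_id = ids[i], group = group, mu_control = mu_c,
        mu_filtered = mu_f, mu_phosphate = mu_fp,
        fc_grazer_true = mu_f / mu_c, fc_phosphate_true = mu_fp / mu_f,
        rel_raw = rel_raw, bias = bias, phylum = phylum
      )
    })
  }
  truth <- purrr::map_dfr(seq_len(n), draw_phylotype)
  truth$rel_abundance <- truth$rel_raw / sum(truth$rel_raw)
  truth$rel_raw <- NULL

  taxonomy <- bind_rows(
    tibble(
      phylotype_id = truth$phylotype_id, domain = "Bacteria",
      phylum = truth$phylum, genus = paste0("genus_", truth$phylotype_id)
    ),
    tibble(
      phylotype_id = standard_id, domain = "Bacteria",
      phylum = "Proteobacteria", genus = "spikein_standard"
    )
  )
  truth$phylum <- NULL

  design <- tidyr::expand_grid(
    role = roles,
    time_h = sort(config$time_points_h),
    replicate = sprintf("R%d", seq_len(config$n_replicates))
  ) |>
    mutate(
      treatment = unname(labels[.data$role]),
      sample_id = sprintf("%s_T%02d_%s", .data$treatment, .data$time_h, .data$replicate)
    )
  metadata <- design |>
    mutate(
      sample_volume_ml = config$sample_volume_ml,
      spike_volume_ul = config$spike_volume_ul
    ) |>
    select(
      "sample_id", "treatment", "time_h", "replicate",
      "sample_volume_ml", "spike_volume_ul"
    )

  std_conc <- standard_concentration(config)
  t_cap <- config$stationary_time_h %||% Inf
  mu_cols <- setNames(paste0("mu_", roles), roles)

  count_mat <- matrix(0, nrow = n + 1L, ncol = nrow(design),
    dimnames = list(c(ids, standard_id), design$sample_id)
  )
  lib_sizes <- numeric(nrow(design))
  std_share <- numeric(nrow(design))
  for (s in seq_len(nrow(design))) {
    role <- design$role[s]
    t_eff <- min(design$time_h[s], t_cap)
    a0 <- truth$rel_abundance * config$total_cells_per_ml[[role]]
    abundance <- a0 * exp(truth[[mu_cols[[role]]]] * t_eff / 24)
    w <- c(truth$bias * abundance, std_conc)
    shares <- w / sum(w)
    std_share[s] <- shares[n + 1L]
    if (expectation) {
      lib_sizes[s] <- config$reads_mean
      count_mat[, s] <- config$reads_mean * shares
    } else {
      with_seed(substream_seed(seed, "sample", s), {
        lib_sizes[s] <- max(config$reads_min, round(rnorm(1, config$reads_mean, config$reads_sd)))
        count_mat[, s] <- rmultinom(1, lib_sizes[s], shares)[, 1]
      })
    }
  }

  structure(
    list(
      counts = matrix_to_counts(count_mat),
      metadata = metadata,
      taxonomy = taxonomy,
      truth = truth,
      sample_truth = tibble(
        sample_id = design$sample_id, library_size = lib_sizes,
        expected_standard_share = std_share
      ),
      standard_id = standard_id,
      config = config, seed = seed, expectation = expectation
    ),
    class = "arnis_simulation"
  )
}

#' @export
print.arnis_simulation <- function(x, ...) {
  cat(sprintf(
    "<arnis_simulation> %d phylotypes + standard, %d samples (seed %d%s)\n",
    nrow(x$truth), nrow(x$metadata), x$seed,
    if (isTRUE(x$expectation)) ", expectation mode" else ""
  ))
  print(table(x$truth$group))
  invisible(x)
}

#' True per-treatment rates of a simulation, in long form
#'
#' @param sim An `arnis_simulation`.
#' @return A tibble `phylotype_id`, `treatment`, `true_mu`.
#' @export
truth_rates <- function(sim) {
  roles <- c("control", "filtered", "phosphate")
  labels <- sim$config$treatments[roles]
  purrr::map_dfr(roles, function(r) {
    tibble(
      phylotype_id = sim$truth$phylotype_id,
      treatment = unname(labels[[r]]),
      true_mu = sim$truth[[paste0("mu_", r)]]
    )
  })
}
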