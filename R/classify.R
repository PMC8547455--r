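#' Growth-rate fold changes between manipulation treatments
#'
#' Computes, per phylotype, the fold change of growth rate under grazer
#' removal (`fc_filtered_control` = mu_filtered / mu_control, the top-down
#' response) and under phosphate amendment on top of filtration
#' (`fc_phosphate_filtered` = mu_phosphate / mu_filtered, the bottom-up
#' response). A fold change is missing when its denominator is missing or
#' not strictly positive.
#'
#' @param rates An `arnis_rates` object or rate tibble (`phylotype_id`,
#'   `treatment`, `mean_mu`).
#' @param roles Named character vector mapping the roles `control`,
#'   `filtered`, `phosphate` to treatment labels; default
#'   `c(control = "C", filtered = "F", phosphate = "FP")`.
#' @return A tibble with one row per phylotype: the three per-role rates
#'   (`mu_control`, `mu_filtered`, `mu_phosphate`) and the two fold
#'   changes.
#' @export
fold_changes <- function(rates, roles = c(control = "C", filtered = "F", phosphate = "FP")) {
  missing_roles <- setdiff(c("control", "filtered", "phosphate"), names(roles))
  if (length(missing_roles) > 0L) {
    abort(sprintf(
      "`roles` must name treatments for: %s",
      paste(missing_roles, collapse = ", ")
    ))
  }
  tbl <- as_rate_table(rates)
  wide <- tbl |>
    filter(.data$treatment %in% roles) |>
    mutate(role = names(.env$roles)[match(.data$treatment, .env$roles)]) |>
    select("phylotype_id", "role", "mean_mu") |>
    tidyr::pivot_wider(names_from = "role", values_from = "mean_mu") |>
    as_tibble()
  for (r in c("control", "filtered", "phosphate")) {
    if (!r %in% names(wide)) wide[[r]] <- NA_real_
  }
  safe_ratio <- function(num, den) {
    if_else(!is.na(den) & den > 0 & !is.na(num), num / den, NA_real_)
  }
  wide |>
    mutate(
      fc_filtered_control = safe_ratio(.data$filtered, .data$control),
      fc_phosphate_filtered = safe_ratio(.data$phosphate, .data$filtered)
    ) |>
    rename(
      mu_control = "control", mu_filtered = "filtered",
      mu_phosphate = "phosphate"
    ) |>
    select(
      "phylotype_id", "mu_control", "mu_filtered", "mu_phosphate",
      "fc_filtered_control", "fc_phosphate_filtered"
    )
}

#' Derive a response threshold from the fold-change distribution
#'
#' The response threshold separating "responded" from "weak or no response"
#' is taken as a percentile (default the 25th) of the pooled distribution
#' of finite fold-change values, computed with linear interpolation between
#' order statistics ([stats::quantile()] type 7). A fixed threshold of 1.3
#' — the 25th percentile in the Adriatic reference experiment — is the
#' package default in [classify_response()].
#'
#' @param records Fold-change tibble from [fold_changes()].
#' @param percentile Percentile in (0, 100); default 25.
#' @param columns Which fold-change columns to pool (default both).
#' @return A `threshold_spec` list: `value`, `percentile`, `source`.
#' @export
derive_threshold <- function(records, percentile = 25,
                             columns = c("fc_filtered_control", "fc_phosphate_filtered")) {
  if (percentile < 0 || percentile > 100) abort("`percentile` must be in [0, 100].")
  vals <- unlist(records[columns], use.names = FALSE)
  vals <- vals[is.finite(vals)]
  if (length(vals) < 4L) {
    abort("fewer than 4 finite fold-change values; use a fixed threshold instead.")
  }
  threshold_spec(
    value = quantile(vals, probs = percentile / 100, names = FALSE, type = 7),
    percentile = percentile, source = "derived"
  )
}

#' @rdname derive_threshold
#' @param value Threshold value (> 0).
#' @param source `"fixed"` or `"derived"`.
#' @export
threshold_spec <- function(value = 1.3, percentile = 25, source = "fixed") {
  assert_scalar_number(value, "value", min = 0, strict_min = TRUE)
  structure(list(value = value, percentile = percentile, source = source),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "<threshold_spec> %.4g (%s%s)\n", x$value, x$source,
    if (x$source == "derived") sprintf(", %gth percentile", x$percentile) else ""
  ))
  invisible(x)
}

#' Classify phylotype responses to top-down and bottom-up manipulation
#'
#' With threshold T, a phylotype whose growth-rate fold changes are both
#' above T responded to both grazer removal and phosphate amendment (group
#' I); above T only for grazer removal is group II; above T only for
#' phosphate amendment is group III; neither is "NR" (no response). The
#' "weak response" side is inclusive (<= T). A record with a missing fold
#' change gets `NA`.
#'
#' @param records Fold-change tibble from [fold_changes()], or any tibble
#'   with `fc_filtered_control` and `fc_phosphate_filtered` columns.
#' @param threshold A positive number or a [threshold_spec()] (default 1.3).
#' @return `records` with a `group` factor column
#'   (levels `I`, `II`, `III`, `NR`).
#' @examples
#' classify_response(tibble::tibble(
#'   fc_filtered_control = c(5.36, 5.12, 0.90, 1.0),
#'   fc_phosphate_filtered = c(1.52, 1.07, 2.98, 1.0)
#' )) # I, II, III, NR
#' @export
classify_response <- function(records, threshold = 1.3) {
  t_val <- if (inherits(threshold, "threshold_spec")) threshold$value else threshold
  assert_scalar_number(t_val, "threshold", min = 0, strict_min = TRUE)
  fc1 <- records$fc_filtered_control
  fc2 <- records$fc_phosphate_filtered
  group <- dplyr::case_when(
    is.na(fc1) | is.na(fc2) ~ NA_character_,
    fc1 > t_val & fc2 > t_val ~ "I",
    fc1 > t_val & fc2 <= t_val ~ "II",
    fc1 <= t_val & fc2 > t_val ~ "III",
    .default = "NR"
  )
  records$group <- factor(group, levels = c("I", "II", "III", "NR"))
  records
}

#' Aggregate response records by taxon
#'
#' Summarises classified phylotype responses at a chosen taxonomic rank:
#' the arithmetic mean of each finite fold-change column and the
#' composition of response groups among classified members.
#'
#' @param records Classified records from [classify_response()] with a
#'   `phylotype_id` column.
#' @param taxonomy Taxonomy tibble with `phylotype_id` and rank columns.
#' @param rank Name of the rank column to aggregate at.
#' @return A tibble with one row per taxon: `n_phylotypes`, `n_classified`,
#'   mean fold changes, and `frac_I` ... `frac_NR` (fractions of classified
#'   members, summing to 1 per taxon).
#' @export
aggregate_by_taxon <- function(records, taxonomy, rank) {
  if (!rank %in% names(taxonomy)) {
    abort(sprintf("rank '%s' is not a column of the taxonomy table.", rank))
  }
  joined <- records |>
    inner_join(taxonomy[c("phylotype_id", rank)], by = "phylotype_id") |>
    rename(taxon = all_of(rank))
  if (nrow(joined) == 0L) abort("no phylotypes shared between records and taxonomy.")
  mean_finite <- function(x) if (any(is.finite(x))) mean(x[is.finite(x)]) else NA_real_
  joined |>
    group_by(.data$taxon) |>
    summarise(
      n_phylotypes = dplyr::n(),
      n_classified = sum(!is.na(.data$group)),
      mean_fc_filtered_control = mean_finite(.data$fc_filtered_control),
      mean_fc_phosphate_filtered = mean_finite(.data$fc_phosphate_filtered),
      frac_I = sum(.data$group == "I", na.rm = TRUE) / pmax(.data$n_classified, 1L),
      frac_II = sum(.data$group == "II", na.rm = TRUE) / pmax(.data$n_classified, 1L),
      frac_III = sum(.data$group == "III", na.rm = TRUE) / pmax(.data$n_classified, 1L),
      frac_NR = sum(.data$group == "NR", na.rm = TRUE) / pmax(.data$n_classified, 1L),
      .groups = "drop"
    )
}

#' Relative read share of taxa at a time point
#'
#' Percent of non-standard reads belonging to each taxon at a given time
#' point, computed per replicate and then averaged over the replicates of
#' each treatment.
#'
#' @param counts Count tibble (internal standard row allowed; it is
#'   excluded from the denominator and the shares).
#' @param metadata Sample metadata.
#' @param taxonomy Taxonomy tibble.
#' @param rank Rank column to aggregate at.
#' @param time_h Time point (hours).
#' @param standard_id Id of the internal-standard phylotype, or `NULL`.
#' @return A tibble `taxon` x `treatment` with `share_pct` (summing to 100
#'   per treatment over all taxa, unassigned phylotypes grouped as `NA`).
#' @export
relative_share <- function(counts, metadata, taxonomy, rank, time_h,
                           standard_id = NULL) {
  if (!rank %in% names(taxonomy)) {
    abort(sprintf("rank '%s' is not a column of the taxonomy table.", rank))
  }
  metadata <- validate_sample_metadata(metadata)
  at_time <- metadata |> filter(.data$time_h == .env$time_h)
  if (nrow(at_time) == 0L) {
    abort(sprintf("no sample at time %g h in the metadata.", time_h))
  }
  long <- counts |>
    filter(is.null(.env$standard_id) | .data$phylotype_id != .env$standard_id) |>
    tidyr::pivot_longer(-"phylotype_id", names_to = "sample_id", values_to = "reads") |>
    inner_join(at_time[c("sample_id", "treatment", "replicate")], by = "sample_id") |>
    left_join(taxonomy[c("phylotype_id", rank)], by = "phylotype_id") |>
    rename(taxon = all_of(rank))
  per_replicate <- long |>
    group_by(.data$treatment, .data$replicate, .data$taxon) |>
    summarise(reads = sum(.data$reads), .groups = "drop_last") |>
    mutate(share_pct = 100 * .data$reads / sum(.data$reads)) |>
    ungroup()
  per_replicate |>
    group_by(.data$taxon, .data$treatment) |>
    summarise(share_pct = mean(.data$share_pct), .groups = "drop")
}
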