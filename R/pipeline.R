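#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs. Input tables can be given as
#' file paths (TSV) or in-memory data frames. A YAML file with the same
#' field names can be loaded with `read_pipeline_config()`.
#'
#' @param counts,metadata,taxonomy Paths to TSV files or data frames
#'   (taxonomy may be `NULL`).
#' @param standard_id Internal-standard phylotype id.
#' @param roles Named vector mapping roles `control`, `filtered`,
#'   `phosphate` to treatment labels.
#' @param min_count,min_sample_fraction Prevalence-filter settings (see
#'   [filter_phylotypes()]; `filter_preset()` supplies the 16S and pufM
#'   values).
#' @param window,r2_min,min_points,min_replicates Rate-estimation settings
#'   (see [estimate_rates()]).
#' @param threshold Fixed fold-change threshold, or `NULL` to derive it.
#' @param derive_percentile Percentile used when `threshold` is `NULL`.
#' @param out_dir Output directory for TSV artifacts and the manifest.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A list of class `arnis_config`.
#' @export
pipeline_config <- function(counts, metadata, standard_id,
                            taxonomy = NULL,
                            roles = c(control = "C", filtered = "F", phosphate = "FP"),
                            min_count = 10, min_sample_fraction = 0.15,
                            window = c(0, 24), r2_min = 0.6,
                            min_points = 3, min_replicates = 1,
                            threshold = 1.3, derive_percentile = 25,
                            out_dir = NULL, seed = 1L) {
  structure(
    list(
      counts = counts, metadata = metadata, taxonomy = taxonomy,
      standard_id = standard_id, roles = roles,
      min_count = min_count, min_sample_fraction = min_sample_fraction,
      window = window, r2_min = r2_min, min_points = min_points,
      min_replicates = min_replicates,
      threshold = threshold, derive_percentile = derive_percentile,
      out_dir = out_dir, seed = seed
    ),
    class = "arnis_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose fields match the
#'   `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$roles)) raw$roles <- unlist(raw$roles)
  if (!is.null(raw$window)) raw$window <- as.numeric(unlist(raw$window))
  do.call(pipeline_config, raw)
}

resolve_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else as_tibble(x)
}

#' Run the full normalization-to-classification pipeline
#'
#' Executes, in order: prevalence filtering, dataset validation,
#' internal-standard ratio computation, growth-curve assembly, per-replicate
#' log-linear rate estimation with the quality gate, bulk summaries,
#' fold-change computation, response-group classification, taxon
#' aggregation (when a taxonomy is supplied) and diversity summaries.
#' When `config$out_dir` is set, every result is written as TSV together
#' with a `manifest.json` recording the package version, configuration and
#' a configuration hash. Any stage failure is re-signalled with the stage
#' named.
#'
#' @param config An `arnis_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return Invisibly, a list with all result tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "arnis_config")) abort("`config` must be a pipeline_config().")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  counts <- stage("read_counts", resolve_table(config$counts, read_count_table))
  metadata <- stage("read_metadata", resolve_table(config$metadata, read_sample_metadata))
  taxonomy <- if (!is.null(config$taxonomy)) {
    stage("read_taxonomy", resolve_table(config$taxonomy, read_taxonomy))
  }

  filtered <- stage("filter", filter_phylotypes(
    counts,
    min_count = config$min_count,
    min_sample_fraction = config$min_sample_fraction,
    protect = config$standard_id, quiet = TRUE
  ))
  dataset <- stage("validate", validate_dataset(
    filtered, metadata, config$standard_id,
    taxonomy = taxonomy
  ))
  ratios <- stage("arnis", compute_arnis(dataset))
  curves <- stage("curves", build_growth_curves(ratios, metadata))
  rates <- stage("rates", estimate_rates(curves,
    window = config$window, r2_min = config$r2_min,
    min_points = config$min_points, min_replicates = config$min_replicates
  ))
  bulk <- stage("bulk", bulk_rates(rates))
  records <- stage("fold_changes", fold_changes(rates, roles = config$roles))
  thr <- if (is.null(config$threshold)) {
    stage("threshold", derive_threshold(records, percentile = config$derive_percentile))
  } else {
    threshold_spec(config$threshold, source = "fixed")
  }
  responses <- stage("classify", classify_response(records, thr))
  taxa <- if (!is.null(taxonomy)) {
    rank <- intersect(c("order", "family", "genus"), names(taxonomy))[1]
    if (!is.na(rank)) stage("aggregate", aggregate_by_taxon(responses, taxonomy, rank))
  }
  alpha <- stage("shannon", shannon_index(filtered, standard_id = config$standard_id))
  beta <- stage("bray_curtis", bray_curtis_matrix(filtered, standard_id = config$standard_id))

  cfg_for_hash <- config[setdiff(names(config), c("counts", "metadata", "taxonomy"))]
  manifest <- list(
    package = "arnis",
    version = as.character(packageVersion("arnis")),
    seed = config$seed,
    threshold = thr$value,
    threshold_source = thr$source,
    config = cfg_for_hash,
    config_hash = fnv1a_hash(paste(deparse(cfg_for_hash), collapse = "")),
    n_phylotypes_in = nrow(counts) - 1L,
    n_phylotypes_kept = nrow(filtered) - 1L,
    n_rates = nrow(rates$rates)
  )

  result <- list(
    filtered_counts = filtered, ratios = ratios, curves = curves,
    rates = rates, bulk = bulk, responses = responses, taxa = taxa,
    shannon = alpha, bray_curtis = beta, threshold = thr, manifest = manifest
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$out_dir, name)
    write_count_table(filtered, out("filtered_counts.tsv"))
    readr::write_tsv(ratios, out("arnis_ratios.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(curves), out("growth_curves.tsv"), progress = FALSE)
    readr::write_tsv(rates$fits, out("replicate_fits.tsv"), progress = FALSE)
    readr::write_tsv(rates$rates, out("growth_rates.tsv"), progress = FALSE)
    readr::write_tsv(bulk, out("bulk_rates.tsv"), progress = FALSE)
    readr::write_tsv(responses, out("response_groups.tsv"), progress = FALSE)
    if (!is.null(taxa)) readr::write_tsv(taxa, out("taxon_summary.tsv"), progress = FALSE)
    readr::write_tsv(alpha, out("shannon.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(beta, rownames = "sample_id"),
      out("bray_curtis.tsv"),
      progress = FALSE
    )
    jsonlite::write_json(manifest, out("manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(result)
}
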