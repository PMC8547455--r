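# in-code fixtures shared across test files

toy_counts <- function() {
  tibble::tibble(
    phylotype_id = c("otu1", "otu2", "std"),
    s1 = c(500, 0, 250),
    s2 = c(1000, 20, 500),
    s3 = c(40, 4, 10)
  )
}

toy_metadata <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    treatment = c("F", "F", "F"),
    time_h = c(0, 12, 24),
    replicate = "R1"
  )
}

toy_taxonomy <- function() {
  tibble::tibble(
    phylotype_id = c("otu1", "otu2", "std"),
    domain = "Bacteria",
    order = c("Alteromonadales", "SAR11 clade", "Burkholderiales"),
    genus = c("Glaciecola", "Pelagibacter", "spikein")
  )
}

toy_dataset <- function() {
  validate_dataset(toy_counts(), toy_metadata(), "std", taxonomy = toy_taxonomy())
}

write_tsv_file <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# full-design replicate curves for a set of phylotypes growing exactly
# exponentially: ratio(t) = scale * exp(mu * t / 24)
exact_curves <- function(mu_by_phylotype, treatment = "F",
                         times = c(0, 12, 24), replicates = c("R1", "R2", "R3"),
                         scale = 1) {
  grid <- tidyr::expand_grid(
    phylotype_id = names(mu_by_phylotype),
    treatment = treatment, time_h = times, replicate = replicates
  )
  grid$ratio <- scale * exp(mu_by_phylotype[grid$phylotype_id] * grid$time_h / 24)
  grid
}

# tiny simulation configuration used where full defaults would be slow
small_sim_config <- function(...) {
  synthetic_config(n_phylotypes = 40, ...)
}
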