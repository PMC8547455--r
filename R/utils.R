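# shared internal helpers

# counts tables are tibbles with a `phylotype_id` character column followed by
# one numeric column per sample; several modules need the matrix view
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (!"phylotype_id" %in% names(counts)) {
    abort("`counts` must have a `phylotype_id` column.")
  }
  m <- as.matrix(counts[setdiff(names(counts), "phylotype_id")])
  if (!is.numeric(m)) abort("count columns must be numeric.")
  rownames(m) <- counts$phylotype_id
  m
}

matrix_to_counts <- function(m) {
  out <- as_tibble(m, rownames = "phylotype_id")
  out
}

sample_ids_of <- function(counts) setdiff(names(counts), "phylotype_id")

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) abort(sprintf("`%s` must be > %g.", name, min))
  if (!strict_min && x < min) abort(sprintf("`%s` must be >= %g.", name, min))
  invisible(x)
}

# deterministic substream seed: keeps per-phylotype / per-sample draws
# independent of how many other units exist
substream_seed <- function(seed, stream, index) {
  offset <- c(phylotype = 0, sample = 1, global = 2)[[stream]]
  as.integer((as.double(seed) + offset * 715827883 + as.double(index) * 1000003) %%
    2147483647) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# FNV-1a hash of a character scalar, hex string; used for config manifests
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}
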