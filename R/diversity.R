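#' Shannon diversity of a single count vector
#'
#' `H = -sum(p_i * log(p_i))` over phylotypes with positive counts, natural
#' log by default. Invariant to proportional rescaling of the counts.
#'
#' @param x Non-negative count (or abundance) vector.
#' @param base Logarithm base (default `exp(1)`).
#' @return The Shannon index, a single non-negative number.
#' @examples
#' shannon(c(25, 25, 25, 25)) # log(4)
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(!is.finite(x)) || any(x < 0)) abort("counts must be finite and non-negative.")
  if (sum(x) == 0) abort("all-zero sample: Shannon index undefined.")
  unname(vegan::diversity(x, index = "shannon", base = base))
}

#' Per-sample Shannon diversity of a count table
#'
#' The internal standard is always excluded before computing diversity;
#' whole-library singletons (phylotypes with exactly one read summed over
#' all samples) can be excluded too, as is common when reporting alpha
#' diversity of amplicon libraries.
#'
#' @param counts Count tibble.
#' @param standard_id Internal-standard phylotype id to exclude, or `NULL`.
#' @param exclude_singletons Drop whole-library singletons first.
#' @param base Logarithm base.
#' @return A tibble with `sample_id` and `shannon_h`.
#' @export
shannon_index <- function(counts, standard_id = NULL,
                          exclude_singletons = FALSE, base = exp(1)) {
  m <- counts_matrix(counts)
  if (!is.null(standard_id)) m <- m[setdiff(rownames(m), standard_id), , drop = FALSE]
  if (exclude_singletons) m <- m[rowSums(m) != 1, , drop = FALSE]
  empty <- colnames(m)[colSums(m) == 0]
  if (length(empty) > 0L) {
    abort(sprintf(
      "all-zero sample(s) after exclusions: %s",
      paste(empty, collapse = ", ")
    ))
  }
  tibble(
    sample_id = colnames(m),
    shannon_h = unname(vegan::diversity(t(m), index = "shannon", base = base))
  )
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `BC = 1 - 2 * sum(min(a_i, b_i)) / (sum(a_i) + sum(b_i))`, in `[0, 1]`:
#' 0 for identical samples, 1 for samples sharing no phylotype.
#'
#' @param a,b Non-negative count vectors over the same phylotype universe.
#' @return A single dissimilarity value.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must share the same phylotype universe.")
  if (any(a < 0) || any(b < 0)) abort("counts must be non-negative.")
  if (sum(a) == 0 && sum(b) == 0) abort("both samples are all-zero.")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param counts Count tibble.
#' @param standard_id Internal-standard phylotype id to exclude, or `NULL`.
#' @return A symmetric matrix of dissimilarities with sample ids as
#'   dimnames.
#' @export
bray_curtis_matrix <- function(counts, standard_id = NULL) {
  m <- counts_matrix(counts)
  if (!is.null(standard_id)) m <- m[setdiff(rownames(m), standard_id), , drop = FALSE]
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}
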