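#' Path to a packaged reference data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
arnis_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "arnis")))
  }
  path <- system.file("extdata", file, package = "arnis")
  if (path == "") abort(sprintf("no packaged file '%s'.", file))
  path
}

#' Published taxon-level responses from the Adriatic manipulation experiment
#'
#' Lineage-level summary published for a coastal Adriatic Sea
#' grazer-removal / phosphate-amendment experiment: per taxon, the relative
#' read share at 24 h in each treatment, the growth-rate fold changes under
#' grazer removal (`fc_filtered_control`) and phosphate amendment
#' (`fc_phosphate_filtered`), the published response-group heading and a
#' flag for the two taxa the original analysis marked as borderline. Used
#' as a fixed reference for the fold-change classifier.
#'
#' @return A tibble with columns `taxon`, `published_group`,
#'   `share_C_pct`, `share_F_pct`, `share_FP_pct`, `fc_filtered_control`,
#'   `fc_phosphate_filtered`, `borderline`.
#' @export
adriatic_response_reference <- function() {
  readr::read_tsv(arnis_example("adriatic_response_groups.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Published bulk measurements from the Adriatic manipulation experiment
#'
#' Named scalar quantities published for the same experiment (initial
#' seawater chemistry, community cell counts and treatment endpoints),
#' used for closed-form arithmetic checks such as abundance fold increases
#' and the N:P ratio.
#'
#' @return A tibble with columns `quantity`, `value`, `unit`.
#' @export
adriatic_reference_values <- function() {
  readr::read_tsv(arnis_example("adriatic_reference_values.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
}
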