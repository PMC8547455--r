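Package: arnis
Title: Growth Curves of Bacterioplankton Phylotypes from Internal-Standard
    Normalized Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs lineage-specific growth curves from amplicon
    sequencing time series in which a known quantity of an internal-standard
    organism was spiked into every sample before filtration. Read counts of
    each phylotype are normalized per sample by the reads of the internal
    standard (the ARNIS ratio), which cancels sample-to-sample artifacts of
    extraction, amplification and sequencing depth, so that ratio changes
    over time track phylotype growth. Provides prevalence filtering of
    feature tables, log-linear estimation of specific growth rates over a
    configurable exponential window with a coefficient-of-determination
    gate, replicate averaging, classification of phylotypes by their
    response to top-down (grazer removal) and bottom-up (nutrient
    amendment) manipulations via growth-rate fold changes, alpha/beta
    diversity summaries, and a synthetic-data generator with ground truth
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
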