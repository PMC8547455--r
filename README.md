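# arnis

Lineage-specific growth curves of bacterioplankton from amplicon reads
normalized by an internal standard.

## The problem

Amplicon sequencing (16S rRNA, or functional markers such as *pufM*) resolves
a marine bacterial community into hundreds of phylotypes, but raw read counts
cannot be compared across samples: extraction, PCR bias and sequencing depth
all differ sample to sample. When every sample is spiked — before filtration —
with a fixed quantity per volume of a standard organism absent from the
environment, the per-sample ratio

```
ratio(p, s) = reads(phylotype p, sample s) / reads(internal standard, sample s)
```

cancels those artifacts. A constant per-phylotype PCR bias multiplies the
whole time series by one number and therefore drops out of growth rates
fitted on the log scale:

```
ln ratio(p, t) = const + mu_p * t          mu_p in day^-1
```

This package implements that analysis for manipulation experiments in which
grazers are removed by 1.2-um filtration (top-down release, treatment F) with
or without phosphate amendment (bottom-up release, F+P), against an
unmanipulated control (C):

* TSV readers/validators for count tables, sample metadata, taxonomy and
  cell-count series; prevalence filtering (16S preset: >= 10 reads in >= 15%
  of samples);
* per-sample internal-standard ratios and per-replicate growth curves;
* OLS log-linear rate estimation over the exponential window (0-24 h), an
  R^2 > 0.6 quality gate, replicate averaging, bulk per-treatment summaries;
* response classification from growth-rate fold changes F/C and F+P/F at a
  1.3 threshold (derivable as a percentile of the fold-change distribution):
  group I responds to both releases, II to grazer removal only, III to
  phosphate only, NR to neither;
* Shannon / Bray-Curtis summaries, ggplot2 figures (`autoplot()`,
  `plot_growth_curves()`, `plot_response_plane()`);
* a synthetic-data generator with full ground truth (exponential growth,
  per-phylotype PCR bias, constant-per-volume spike, multinomial sequencing
  at ~127k reads/sample) plus `recovery_report()` for end-to-end validation;
* `run_pipeline()` wiring all stages, writing TSV artifacts and a JSON
  manifest.

## Worked example

Simulate an experiment at the default study conditions (200 phylotypes,
3 treatments x 3 replicates x 6 time points), run the full analysis and
compare against the generator's ground truth:

```r
library(arnis)

sim <- simulate_dataset(synthetic_config(), seed = 1)
res <- run_pipeline(pipeline_config(
  sim$counts, sim$metadata, sim$standard_id, taxonomy = sim$taxonomy
))

res$bulk[, 1:4]
#>   treatment mean_mu sd_mu     n
#> 1 C           0.503 0.245   190
#> 2 F           1.19  0.920   193
#> 3 FP          2.38  1.87    185

table(res$responses$group, useNA = "ifany")
#>    I   II  III   NR <NA>
#>   95   26   38   15   21

recovery_report(sim, res$rates, classified = res$responses)
#>   treatment     n  rmse mean_bias pearson_r
#> 1 C           190 0.121   0.00622     0.874
#> 2 F           193 0.144   0.0185      0.988
#> 3 FP          185 0.225   0.0745      0.994
#> coverage: 94.7% of truth cells estimated
#> group-label recovery: 90.2% of 174 labelled phylotypes
```

Reading: grazer removal lifts the community mean rate from ~0.5 to ~1.2
day^-1 and phosphate amendment to ~2.4 day^-1; estimated rates in the
filtered treatment track the true ones at r = 0.99, and 90% of phylotypes
land in their true response group. `tidy(res$rates)` gives the per-phylotype
rate table, `glance(res$rates)` the fit/gate summary, and
`autoplot(res$rates)` the per-treatment rate violins.

The package also ships the published taxon-level reference tables from a
coastal Adriatic manipulation experiment (`adriatic_response_reference()`,
`adriatic_reference_values()`), used below to check the classifier against
printed results.

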