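---
title: "Growth curves from internal-standard normalized amplicon reads: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth curves from internal-standard normalized amplicon reads: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arnis)
library(dplyr)
```

## The problem

Amplicon sequencing of the 16S rRNA gene (or of functional markers such as
*pufM*) describes the composition of a bacterioplankton community in great
depth, but read counts are not quantitative: extraction efficiency, PCR
amplification bias and sequencing depth differ between samples, so the read
count of the same phylotype cannot be compared across samples directly.
Spiking every sample with a fixed quantity per volume of a standard organism
absent from the environment — added *before* filtration — provides an
internal yardstick. The per-sample ratio

$$\mathrm{ratio}_{p,s} \;=\; \frac{\text{reads of phylotype } p \text{ in } s}
{\text{reads of the internal standard in } s}$$

cancels every multiplicative per-sample artifact. A constant per-phylotype
amplification bias $b_p$ remains, so the ratio is *not* an absolute
abundance; but because $b_p$ is constant across samples it multiplies the
phylotype's entire time series by one number and drops out of any growth
rate fitted on the log scale. That single observation is what turns a
non-quantitative amplicon library into hundreds of lineage-specific growth
curves.

## Growth model and rate estimator

Within the exponential-growth window of a manipulation experiment, each
phylotype is modelled as

$$A_p(t) = A_p(0)\, e^{\mu_p t},$$

with the specific growth rate $\mu_p$ in day$^{-1}$
($\mu = \partial B / B \times 1/\partial t$). `fit_exponential()` therefore
regresses $\ln(\mathrm{ratio})$ on time in days by ordinary least squares,
per replicate bottle; the slope is $\mu_p$ and the intercept the log ratio
at $t=0$. OLS on the log scale (rather than nonlinear least squares on the
ratio scale) is the standard choice under multiplicative, roughly log-normal
noise, and makes $R^2$ well defined on the regression actually performed.

Quality gating and averaging follow the design of the original field
application:

* window: the closed interval 0–24 h by default (configurable) — the phase
  over which growth in such incubations is exponential;
* a replicate fit is kept only when $R^2 > 0.6$ (strict inequality) and at
  least `min_points = 3` strictly positive ratios fall in the window;
* zero ratios carry no information on the log scale and are dropped rather
  than imputed (a pseudocount in standard-equivalents is available but off
  by default; phylotypes that are mostly absent then fail the
  `min_points` gate naturally, which is the honest outcome);
* the reported rate per phylotype × treatment is the arithmetic mean of the
  passing replicate slopes, with the sample SD ($n-1$) when $\ge 2$
  replicates pass; a cell with no passing replicate is *missing*, never
  zero. `min_replicates` defaults to 1.

A flat series fits slope 0 with zero residuals; we define $R^2 = 1$ in that
degenerate case (total and residual sums of squares both below $10^{-12}$),
so a genuinely constant phylotype is reported as non-growing rather than
unfittable.

## Prevalence filtering

Before normalization the feature table is prevalence-filtered: a phylotype
is kept iff it has $\ge$ `min_count` reads in $\ge$ `min_sample_fraction`
of *all* samples (treatments pooled). The 16S preset is 10 reads / 15% of
samples; the preset for sparser functional-gene libraries is 3 reads / 15%.
On a realistic rare-tail community this removes the vast majority of
phylotypes while discarding only a couple of percent of reads, which is the
point: features too rare to fit contribute nothing but noise downstream.
The internal standard is always protected from the filter, and always
excluded from every community statistic.

## Response classification

The experiment crosses two releases: grazer removal by 1.2-µm filtration
(top-down) and phosphate amendment (bottom-up). Per phylotype we form the
fold changes $\mathrm{FC}_{F/C} = \mu_F/\mu_C$ and
$\mathrm{FC}_{F\!P/F} = \mu_{F\!P}/\mu_F$; a fold change is missing when its
denominator is missing or non-positive. With threshold $T$ (default 1.3):

| | $\mathrm{FC}_{F\!P/F} > T$ | $\mathrm{FC}_{F\!P/F} \le T$ |
|---|---|---|
| $\mathrm{FC}_{F/C} > T$ | **I** (both) | **II** (grazing release only) |
| $\mathrm{FC}_{F/C} \le T$ | **III** (phosphate only) | **NR** |

The "weak" side is inclusive ($\le T$). Records with a missing fold change
get `NA`. The default $T = 1.3$ is the fixed reference value; it can instead
be derived from the data as a percentile (default the 25th) of the pooled
finite fold-change distribution. Several choices here were genuinely open
and are pinned as follows:

* the percentile is taken over the *pooled* distribution of both fold-change
  columns by default (each column separately is available via the `columns`
  argument) — the fixed 1.3 default keeps published-table comparisons exact
  while the derivation remains available;
* percentiles use linear interpolation between order statistics
  (`stats::quantile()` type 7), pinned for determinism;
* the both-weak cell is labelled explicitly `NR` rather than left unnamed;
* no significance testing is layered on top of the threshold rule — the
  classification is operationalized purely by the fold-change cut.

## Diversity summaries

`shannon()` / `shannon_index()` report $H = -\sum p_i \ln p_i$ (natural log
by default; a Shannon index of 4–5 on a library of thousands of features is
a natural-log figure) and `bray_curtis()` the usual
$1 - 2\sum \min(a_i,b_i) / (\sum a_i + \sum b_i)$. Both are computed via
**vegan** behind this package's interface. The internal standard is always
excluded; whole-library singletons can be excluded by flag (the per-sample
vs whole-library singleton definition was unstated in the field protocol;
whole-library is assumed). Ordination (NMDS) is out of scope.

## The synthetic experiment

`simulate_dataset()` stands in for the deposited sequencing data and defines
the study conditions under which the pipeline is tested:

* design: 3 treatments (C, F, F+P) × 3 replicates × 6 time points
  (0–60 h, 12-h steps), 200 phylotypes plus the standard;
* response archetypes I/II/III/NR in proportions 0.50/0.10/0.25/0.15,
  mirroring the observed dominance of doubly-responding phylotypes and the
  rarity of grazing-only responders;
* rates built multiplicatively: $\mu_C \sim U(0.1, 0.9)$ day$^{-1}$; the
  grazer-removal fold change $\sim U(1.8, 5)$ for responders and
  $U(0.6, 1.1)$ otherwise; the phosphate fold change $\sim U(1.5, 3)$ /
  $U(0.6, 1.1)$. The margins around the 1.3 threshold make the true group
  labels well defined. Rates are capped at `rate_max = 6` day$^{-1}$, the
  fastest growth plausibly observed in such incubations;
* initial relative abundances are lognormal (sdlog 1.5), scaled to
  realistic community totals (4.7×10⁵ cells ml⁻¹ in the control, about half
  that after 1.2-µm filtration);
* the spike: 2×10⁸ cells ml⁻¹ standard suspension at 5 µl per 100 ml of
  sample, i.e. 10⁴ standard cells per ml — about 4% of reads at $t_0$,
  never less than ~0.05% (tens of reads) even after the community has
  grown;
* amplification bias $b_p$ is lognormal (sdlog 0.5 by default; no
  quantitative bias magnitude is established in the literature, so this is
  a documented modelling choice), constant across samples;
* sequencing: library size $\sim N(127018, 15026^2)$ truncated at 1000 and
  rounded, reads multinomial over phylotypes + standard;
* growth is deterministic exponential, truncated at
  `stationary_time_h = 24` — bottles stop growing once the liberated
  substrate is exhausted, and total abundance in such incubations rises
  ~6–8.5-fold rather than unboundedly. Placing the plateau at the end of the
  fitting window keeps the 0–24 h phase exactly exponential (so truth is
  well defined) while keeping the community total, and with it the
  standard's read share, in the realistic range; unbounded growth can be
  restored with `stationary_time_h = NULL`.

Randomness is hierarchical: each phylotype and each sample has its own
substream derived from the single seed, so the simulation is bit-for-bit
reproducible and adding a phylotype does not perturb the others' draws.

An `expectation = TRUE` mode skips all sequencing noise and returns expected
(real-valued) counts; the pipeline must then recover the generating rates to
numerical precision, which is the package's sharpest self-check and the
noise-free half of the bias-robustness property (estimates with bias sdlog
0 and 2 agree to $10^{-9}$).

What the generator does *not* emulate — and what passing its tests therefore
does not show about real data: chimeras and sequencing error, copy-number
variation of the marker gene within a genome (the unbalanced-growth
signature in which gene copies rise a division ahead of cell counts is
exercised by a hand-constructed fixture instead), demographic stochasticity,
predator–prey dynamics in the control (slow exponential growth stands in),
and any bias that *varies* across samples, which the ratio cannot cancel.

## Problem sizes and run times

The test suite and the acceptance script use the default 200-phylotype,
54-sample configuration for end-to-end recovery (a few seconds per run),
80 phylotypes for the depth-doubling comparison across five seeds, and
40 phylotypes for pipeline plumbing checks. Under the defaults the filtered
treatment's estimated rates correlate with truth at $r \approx 0.99$ and
~90% of true response-group labels are recovered; coverage (truth cells with
an estimate) is ~95%, with losses concentrated in rare, slow phylotypes that
fail the prevalence filter or the $R^2$ gate.

## Known limitations

* Ratio-based rates measure marker-gene dynamics, not cell division; under
  unbalanced growth (slow growers with generation times comparable to the
  24-h window, transient DNA replication after nutrient amendment) they
  exceed microscopy-based net growth rates. `compare_methods()` makes that
  comparison explicit rather than hiding it.
* The ratio is not an absolute abundance; per-phylotype PCR bias survives
  normalization and only cancels in log-slope quantities. Cross-phylotype
  comparisons of ratio *levels* are not meaningful.
* A zero-read standard in any sample makes the ratio undefined;
  `validate_dataset()` refuses such data rather than guessing.
* The derived threshold depends on the analysed community; the fixed 1.3
  default is a reference value, not a universal constant.
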