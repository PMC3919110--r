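---
title: "Differential gene-pair correlation within pathways: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential gene-pair correlation within pathways: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdiffcorr)
```

## The question the method answers

Differential *expression* asks whether a gene's mean level changes between
two conditions. Differential *correlation* asks whether the co-regulation of
a gene pair changes: two genes can keep identical means in relapsing and
non-relapsing tumours while their pairwise correlation collapses from 0.8 to
zero — a signature of rewired regulation that mean-based tests cannot see.
`pathdiffcorr` scores every interacting gene pair of a pathway for exactly
this effect.

## The estimator, step by step

For a probe pair (a, b) within one condition, with `x` the first probe's
log2 expression and `y` the second's over that condition's samples:

1. **Pairwise complete samples.** Samples missing either value are dropped
   first; the remaining count is `n_total`. Pairs with fewer than
   `min_samples` (default 10) complete samples are reported as class
   `undefined` rather than estimated unstably.
2. **Least-squares outlier rejection.** An ordinary least-squares line of
   `y` on `x` gives squared residuals `e²`. A sample is discarded when its
   squared residual strictly exceeds `mean(e²) + 3·SD(e²)`. Two guards
   apply: at most `⌊0.2·n_total⌋` samples may be discarded (largest
   residuals first, ties by sample order), so at least 80% of the data is
   always retained; and a degenerate fit (constant `x`) skips filtering
   entirely. The filter is single-pass — the line is not refitted after
   discarding.
3. **Pearson correlation and classification.** `r` is computed on the
   retained samples. `r > 0.45` is *coexpressed*, `r < −0.45`
   *reverse-expressed*, the closed interval `[−0.45, 0.45]` *unrelated*;
   constant vectors give an *undefined* correlation. All inequalities are
   strict.
4. **Differential selection.** Per pair, `cor_dif = r_ref − r_test`
   (reference condition minus test condition). Over all pairs defined in
   both conditions, the mean AVG and standard deviation SD of `cor_dif`
   define the selection band `AVG ± 3·SD`; pairs strictly outside it are
   selected. A difference exactly equal to a bound is not selected.

Interacting pairs are parsed from KGML files: each `relation` of a requested
type (default PPrel and GErel; ECrel/PCrel/maplink are available) expands to
the cartesian product of its endpoint entries' gene sets, `group` entries
expand to the union of their components, self-pairs are removed, and
duplicate pairs merge with the union of their relation types and pathways.
Gene pairs become probe pairs through the annotation: every probe of the
first gene crosses every probe of the second.

## Parameters that matter

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `corr_threshold` | 0.45 | correlation | the field's working definition of co-expression used by this method |
| `sd_multiplier` | 3 | SD units | both the outlier threshold and the selection band; 3·SD ≈ 0.27% two-sided tail under normality |
| `retention_floor` | 0.8 | fraction | at least 80% of samples always used, bounding the filter's aggressiveness |
| `min_samples` | 10 | samples | below ~10 pairs, r is too unstable to classify; reported undefined instead |
| `sd_type` | population | — | divide-by-n SD; switchable to sample SD, which only matters at small pair counts |
| `relation_types` | PPrel, GErel | — | protein–protein and transcription-factor→target relations are where rewiring is interpretable |
| `aggregate` | max | — | gene pairs with several probe pairs are represented by the probe pair of maximum \|cor_dif\| with alternates listed (auditable); `mean` averages instead |
| `workers`, `chunk_size` | 1, 1000 | — | engine only; results are identical for any setting |

## Numerical and design choices

* **Regression axis.** OLS residuals are axis-asymmetric. The x axis is
  always the first element of the ordered pair — the KGML `entry1` gene, or
  the lexicographically smaller probe id in all-pairs mode. This is
  deterministic; swapping the pair can change the discard set (not the
  direction convention of `cor_dif`).
* **Strictness.** Both classification (±0.45) and selection (AVG ± 3·SD)
  use strict inequalities; boundary values fall inside the null category.
* **Population SD.** Thresholds use the divide-by-n SD by default; a
  `sd_type = "sample"` flag switches both the filter and the selection band.
* **Eligible set for AVG/SD.** All pathway-mapped pairs with defined
  correlations in both conditions. Pairs undefined in either condition are
  excluded and counted (`n_excluded`).
* **Filter-cap arithmetic.** The discard cap adds a 1e-9 guard before
  `floor()` so that e.g. `(1 − 0.8)·20` caps at 4, not at 3 via
  floating-point error.
* **Degenerate inputs.** Constant x: no filtering, correlation may still be
  defined. Constant y (or fewer than 3 points): undefined correlation,
  class `undefined`. Fewer than 2 defined `cor_dif` values: the fit stops —
  an SD over one pair is meaningless.
* **Ties.** Discards tie-break by sample order; selected pairs sort by
  |cor_dif| descending, then pair key, making reports reproducible.
* **Determinism.** The per-pair task is pure, chunks are combined in input
  order, and every report number is written with 17 significant digits, so
  reruns — and any workers × chunk-size combination — are byte-identical,
  and stage-wise runs (correlate per condition, then select from the written
  files) reproduce the monolithic pipeline exactly. The JSON metadata file
  echoes the engine configuration and therefore differs across engine
  settings by design.

## Properties of the outlier filter worth knowing

Two behaviours follow from thresholding *squared residuals* at
mean + 3·SD and are easy to miss:

* **The cap rarely binds at multiplier 3.** At most n/10 samples can ever
  exceed mean + 3·(population SD) of any nonnegative variable (a Chebyshev
  bound), so the 80% retention floor is a guarantee rather than an active
  constraint unless a smaller multiplier is configured.
* **Gentle trimming inflates strong correlations.** On clean bivariate
  normal data (n = 200) the filter trims the ~2% largest-residual samples.
  Those samples carry a disproportionate share of the residual variance, so
  at |ρ| = 0.8 the filtered r moves ≈ 0.02 *away from zero* — tightly
  concentrated, and within 0.05 of the unfiltered r in over 99% of
  replicates. At ρ = 0 there is no systematic shift but more spread
  (within 0.05 in ≈ 92%).
* **A contaminated threshold can miss moderate outliers.** The filter is
  single-pass: the line and the threshold are estimated on contaminated
  data. With 5% outliers offset by 8 log2 units, at least one outlier
  escapes in roughly a quarter of replicates; with larger offsets the escape
  probability vanishes. An iterative refit would fix this but is
  deliberately out of scope — the method applies one threshold, once.

## What the synthetic generator emulates — and what it does not

`generate_expression()` draws each planted pair from a bivariate normal with
the requested correlation per condition, on a log2-intensity scale
(N(8, 1) by default), at the 160/89 nonrelapse/relapse sample split of a
real relapse cohort. Outliers are additive offsets (default 8 log2 units,
an aberrant/saturated probe) on the pair's y-axis probe, so the filter's
effect is isolated from the correlation structure. Null probes are
independent. Gene ids must be unique across planted pairs — one gene cannot
satisfy two independent correlation targets — and `probes_per_gene > 1`
adds noisy probe copies for exercising gene-level aggregation.

Real microarray data are not bivariate normal: intensity-dependent variance,
probe saturation, batch effects and correlated background all exist in GEO
matrices and are not simulated. A green recovery test therefore establishes
that the estimator and plumbing are correct, not that 0.45/3·SD are optimal
thresholds for any particular dataset. Counts reported on public cohorts
additionally depend on the KEGG release used for the pathway files, so
published tallies are not reproduction targets.

## Known limitations

* Pearson r only; no rank-based or robust-regression alternatives.
* The 3·SD selection rule is not a calibrated test — no p-values, no
  multiple-testing correction; under an approximately normal null it selects
  ≈ 0.27% of pairs by construction.
* Outlier filtering is per condition and per pair; a sample that is an
  outlier for many pairs is not flagged globally.
* The AVG ± 3·SD band is estimated from the same pairs it selects from; with
  many true differential pairs the band widens and sensitivity drops (at 1%
  prevalence this effect is negligible, see the recovery tests).
* Normalization, array QC and probe-level processing are upstream; inputs
  are assumed log2 RMA-style intensities.
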