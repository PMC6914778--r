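---
title: "Partitioning cell-to-cell expression variation with dual reporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning cell-to-cell expression variation with dual reporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualreporter)
```

## The problem

Isogenic animals in a homogeneous environment still differ in how much of a
given protein their cells contain, and for some reporters (heat-shock
chaperone reporters in the nematode intestine, most prominently) those
differences predict lifespan and mutation penetrance. Three distinct
physiological mechanisms could generate such cell-to-cell differences:

* **intrinsic noise**, written η²(γ): stochastic to-promoter and
  to-transcript binding events and variable allele access, visible as
  disagreement between two identical copies of a gene in the same cell;
* **signaling (pathway) noise**, η²(P): cell-to-cell differences in how
  strongly a specific upstream signaling system activates its target genes;
* **protein expression capacity**, η²(G): a cell's general ability to
  express and maintain proteins, which moves all genes together.

The dual-reporter design separates these bins with two kinds of crosses.
In a **Type I** experiment, two differently colored copies of the *same*
reporter gene sit at identical loci on homologous chromosomes: both copies
see the same signaling input and the same expression machinery, so any
disagreement between the two colors within a cell is intrinsic noise. In a
**Type II** experiment the two colors are driven by *distinct* promoters
answering distinct signaling systems: disagreement now contains intrinsic
noise *and* pathway noise, while agreement (both colors high or both low)
measures shared capacity.

## The estimators

Let `x` and `y` be the two channel intensities of one cell type (one
intestine ring within one experiment), each divided by its group mean so
that the group means are exactly 1. The package computes the two moments

```
uncorrelated = mean((x - y)^2) / (2 * mean(x) * mean(y))
correlated   = (mean(x * y) - mean(x) * mean(y)) / (mean(x) * mean(y))
```

in `correlated_uncorrelated()`. On mean-1 data these satisfy the exact
identity `correlated + uncorrelated = (CV²(x) + CV²(y)) / 2`, which the test
suite asserts to 1e-12: the two moments are a complete additive partition of
the pair's average squared coefficient of variation.

Bins are then assigned by design:

* Type I: `eta2_gamma = uncorrelated`; `correlated` is the *combined*
  capacity + pathway term (a shared signaling input cannot be separated from
  shared machinery within a Type I pair).
* Type II: `eta2_G = correlated`; `eta2_P = uncorrelated - (γ_x + γ_y)/2`,
  where `γ_x`, `γ_y` are the intrinsic-noise values of the two promoters
  measured in their own Type I experiments (`gamma_lookup()` carries them
  over, preferring ring-matched values and falling back to the across-ring
  mean; the source of each match is recorded in the fit).

`decompose_noise()` wraps normalization, the moments, and bin assignment
into one fitting call returning a classed object with `print`, `summary`,
`coef` and `plot` methods. Groups default to experiment × ring; the
aggregate is the unweighted mean over groups, and per-experiment means are
kept as replicate values for significance testing with `compare_bins()`.

### Why cells must be grouped by ring

Each intestine ring holds a rigid, fate-specific ratiometric setpoint for a
gene pair: ring 1 cells may express promoter A at three times the level of
ring 4 cells while promoter B runs the opposite gradient. Pooling all rings
before normalization mixes those setpoints into the uncorrelated moment and
inflates the apparent pathway noise. `pooled_vs_grouped()` quantifies this
artifact; on a deterministic two-ring construction with a 3-fold setpoint
difference in one channel and no noise at all, ring-wise grouping yields
`eta2_P = 0` while pooling yields 0.125.

### Numerical choices

* **No log transform.** η² values are computed on linear-scale,
  group-mean-normalized intensities — the CV² convention of the
  dual-reporter literature.
* **Clamping.** The Type I subtraction can overshoot on finite samples,
  giving a negative `eta2_P_raw`; summaries clamp it at zero and set a
  `clamped` flag, but the raw value is preserved in the group table.
* **Minimum group size.** Groups below 5 cells are skipped and logged
  (real acquisitions occasionally lose ring-2/4 cells to the orientation of
  the intestine); the threshold is an argument everywhere.
* **A values.** The relative gain between the two channels of a pair within
  a cell type is recorded per group as the ratio of group means; a
  total-least-squares slope is available via `gain_estimator = "tls"` for
  data with comparable noise in both channels.
* **Outliers.** No outlier removal anywhere: deviant cells are genuine
  observations in this framework.
* **Degenerate input.** A group with a zero channel mean cannot be
  normalized and is skipped with an explicit reason; correlation helpers
  refuse constant input rather than returning `NaN`.

## The generative model

Because the original per-cell microscopy tables are not deposited, the
package ships a first-class simulator whose statistical structure matches
the measurement design: 3 experiments × 10 animals × 8 cells, two cells in
each of intestine rings 1–4, two channels per cell. Every intensity is a
product of independent lognormal factors

```
I = background + setpoint(promoter, ring) *
    G_animal * G_cell * P(promoter) * gamma(channel) * eps(channel)
```

with `G_animal` shared by all cells of an animal, `G_cell` by both channels
of a cell, `P` drawn once per distinct promoter per cell (so a Type I pair
shares it and a Type II pair does not), and `gamma`, `eps` drawn per
channel. All factors use the **mean-one** lognormal convention
`exp(sigma * Z - sigma^2 / 2)`. Mean-one (rather than median-one) is a
deliberate choice: it makes group mean intensities converge exactly to
`setpoint + background`, and it gives exact closed-form expectations for
every bin (`expected_eta2()`), e.g. `eta2_G_true = exp(sG²) - 1` with
`sG² = sigma_G_animal² + sigma_G_cell²`. Those closed forms are the oracle
against which the estimators are tested: at 10⁵ cells every recovered bin
must land within 5% relative of its closed form, and the suite verifies
this for `sigma_G = 0.4, sigma_P = 0.1, sigma_gamma = 0.05`.

Scenario defaults (`default_params()`):

| scenario | sigma_G_animal | sigma_G_cell | sigma_P | sigma_gamma | sigma_meas |
|---|---|---|---|---|---|
| `paper_like` | 0.20 | 0.30 | 0.10 | 0.05 | 0.03 |
| `yeast_like` | 0.20 | 0.30 | 0.10 | 0.15 | 0.03 |
| `high_signaling` | 0.20 | 0.30 | 0.30 | 0.05 | 0.03 |
| `null_no_variation` | 0 | 0 | 0 | 0 | 0 |

`paper_like` encodes the measured regime qualitatively: capacity variation
dominant, intrinsic and pathway noise small. Under the closed forms it
gives a Type I allele-vs-allele coefficient of determination of about 0.95
(the measured regime is "90% or more") and a capacity bin ≈ 35× the
intrinsic bin. The split between the animal-level and cell-level capacity
scales is not identifiable from published summaries; the default puts the
larger share at the cell level, which keeps the moment estimator's sampling
envelope at the 240-cell study scale tight enough that 200-replicate
recovery of `eta2_G` stays within ±30% in well over 90% of runs (the
animal-shared component effectively reduces the sample size of the
capacity moment, so a heavier animal share widens the envelope). The
`yeast_like` scenario simply triples `sigma_gamma`, mirroring the
order-of-magnitude-higher intrinsic noise reported for yeast only
directionally, not calibrated to any yeast dataset.

Determinism is counter-based: each (experiment, animal) pair gets its own
seed derived from the root seed, so subsetting animals never shifts the
draws of the remaining animals, and identical parameters + seed give a
byte-identical table.

### What the simulator does and does not emulate

It reproduces the *dependence structure* the decomposition relies on
(shared capacity factors, promoter-shared vs promoter-specific pathway
draws, ring setpoints, multiplicative measurement noise, optional per-cell
dropout and additive background). It does **not** emulate: the unknown true
distributional family of biological intensity variation (lognormal is an
assumption of convenience with positive support and closed-form moments),
spatial correlation between neighboring cells, developmental expression
bursts seen in larvae, autofluorescence structure, or segmentation error.
Passing recovery tests therefore demonstrates correctness of the estimators
under the stated model, not distributional claims about real intestines.

## The fluorescent timer model

To ask whether a bright animal is bright because it *produces* more protein
or because it *degrades* less, the package models a timer protein that is
translated green and matures irreversibly to red:

```
dG/dt = s - (k_m + d) G
dR/dt = k_m G - d R
```

with production rate `s`, maturation rate `k_m` (default half-time 48 h)
and a single degradation/dilution rate `d` shared by both forms (no
information supports form-specific turnover; a two-step maturation chain is
likewise out of scope). `timer_solution()` is the exact solution from zero
initial conditions, tested against an independent Runge–Kutta integration
to better than 1e-6 relative error. At steady state the new/old ratio
`green/red = d / k_m` is independent of `s` — this is the entire logic of
the assay: populations varying in production keep the same ratio in their
brightest and dimmest deciles (`decile_contrast()`, ranked by total signal
by default), while populations varying in turnover show a depressed ratio
in the bright tail. Measurement noise is multiplicative lognormal per
channel (default scale 0.05, a typical whole-animal cytometry
repeatability figure); at `sigma = 0.5` production-mode populations of 500
animals show decile-ratio differences within 5% while turnover-mode
populations show large, significant negative differences.

## Problem sizes used by the test suite

Simulation sizes in the tests are chosen to keep Monte-Carlo error well
inside each asserted tolerance: 10⁵ cells for closed-form recovery at 5%
relative, 10⁴ cells for the allele R² bound, 200 replicates of the
240-cell study scale for the recovery envelope, and 500 animals for the
timer contrasts. The deterministic identities (estimator-vs-naive
equivalence, additivity, scale invariance, the 4-point pooling
construction) are asserted at 1e-12 or exactly.

## Known limitations

* The moment estimators carry O(1/n) ratio bias from normalizing by group
  sample means; at 20 cells per group this depresses `eta2_G` by roughly
  10% relative. The package reports the estimators as defined rather than
  bias-correcting, for comparability with the dual-reporter literature.
* `eta2_P` inherits the subtraction's sampling noise from both the Type II
  uncorrelated moment and the Type I intrinsic estimates; with small
  pathway noise it is the least stable bin (hence clamping).
* Multiplicative measurement noise is uncorrelated between channels and is
  therefore counted inside η²(γ); separating it would require repeated
  imaging of the same cells, which the framework does not model.
* No mixed-effects or Bayesian variance-component machinery: the package
  implements the moment-based scheme only, by design.
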