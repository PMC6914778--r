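# dualreporter

Partition cell-to-cell variation in gene expression into intrinsic noise,
signaling noise, and general protein expression capacity, from paired
fluorescent-reporter measurements of single cells.

## The problem

Genetically identical animals raised together still express different
amounts of protein, and in the nematode intestine those differences predict
organism-level traits such as lifespan and mutation penetrance. Three
mechanisms can make one cell brighter than another for a given reporter:
stochastic allele-level events (**intrinsic noise**, η²(γ)), cell-to-cell
differences in a specific signaling pathway's activity (**pathway noise**,
η²(P)), and differences in the cell's general capacity to express and
maintain proteins (**expression capacity**, η²(G)). Measuring two reporters
per cell separates the three. With two differently colored copies of the
*same* gene (a Type I pair), disagreement between the colors within a cell
is intrinsic noise. With two reporters driven by *distinct* promoters (a
Type II pair), disagreement contains intrinsic plus pathway noise, and
agreement along the diagonal measures shared capacity.

The package is for quantitative biologists analyzing per-cell image
cytometry tables of reporter pairs (and for anyone needing a tested
reference implementation of the dual-reporter moment estimators with a
generative model whose answers are known in closed form).

## The estimators

For paired intensities x, y of one cell type, each normalized by its group
mean (groups default to experiment × intestine ring, because each ring has
its own ratiometric expression setpoint):

    uncorrelated = mean((x − y)²) / (2 · x̄ · ȳ)
    correlated   = (mean(x·y) − x̄·ȳ) / (x̄·ȳ)

On mean-1 normalized data these add up exactly to (CV²(x) + CV²(y))/2.
Type I pairs: η²(γ) = uncorrelated. Type II pairs: η²(G) = correlated and
η²(P) = uncorrelated − (γ_x + γ_y)/2, subtracting the promoters' Type I
intrinsic noise (ring-matched where available). The companion fluorescent
timer module models a green→red maturing protein (maturation rate k_m,
turnover d); its steady-state new/old ratio d/k_m is independent of the
production rate, which distinguishes production-driven from turnover-driven
brightness differences.

## Worked example

Simulate the measurement design (3 experiments × 10 animals × 8 cells in
rings 1–4) under the capacity-dominated regime, then decompose a Type II
pair using intrinsic noise measured from Type I pairs:

```r
library(dualreporter)

# Type I: two colors of the same promoter -> intrinsic noise per promoter
fit_hsp <- decompose_noise(
  simulate_cells(default_params("paper_like", "TypeI", seed = 42)),
  reporter_pair(c("ch_green", "ch_red"), c("Phsp-16.2", "Phsp-16.2"), "I"))
fit_vit <- decompose_noise(
  simulate_cells(default_params("paper_like", "TypeI", seed = 43,
    channels = c(ch_green = "Pvit-2", ch_red = "Pvit-2"))),
  reporter_pair(c("ch_green", "ch_red"), c("Pvit-2", "Pvit-2"), "I"))
gam <- rbind(gamma_lookup(fit_hsp), gamma_lookup(fit_vit))

# Type II: distinct promoters -> pathway and capacity bins
fit2 <- decompose_noise(
  simulate_cells(default_params("paper_like", "TypeII", seed = 44)),
  reporter_pair(c("ch_green", "ch_red"), c("Phsp-16.2", "Pvit-2"), "II"),
  gamma = gam)
fit2
#> Dual-reporter noise decomposition (Type II pair)
#>   channels: ch_green ~ ch_red   promoters: Phsp-16.2 ~ Pvit-2
#>   240 cells in 12 group(s) [experiment_id x ring]
#>   aggregate bins (unweighted mean over groups):
#>   eta2_gamma   eta2_P_raw       eta2_P       eta2_G   correlated uncorrelated
#>       0.0036       0.0102       0.0102       0.1226       0.1226       0.0138
```

`coef(fit2)` returns the three bins: η²(γ) = 0.0036, η²(P) = 0.0102,
η²(G) = 0.1226 — capacity variation dominates, an order of magnitude above
both noise terms, which is the regime the generative defaults encode
(closed-form truth from `expected_eta2()`: 0.0039, 0.0117, 0.1388; the
study-scale estimate of η²(G) sits slightly low because the moment
estimator normalizes by 20-cell group means). `summary(fit2)` adds
per-group partitions, per-experiment replicates and the per-group relative
gains (A values); `plot(fit2)` draws the normalized scatter.

The timer module, same logic in two lines:

```r
k <- timer_kinetics()            # 48 h maturation, 24 h turnover
steady_state_ratio(k)
#> [1] 2
decile_contrast(simulate_timer_population(k, "turnover", 500, 0.5, seed = 45))
#> Top/bottom 10% new/old timer ratio (ranked by total)
#>   top: 0.7187   bottom: 4.515   difference: -3.797 (-84.08%)
#>   green-red linearity (Pearson r): 0.9085
```

Turnover-driven brightness depresses the new/old ratio in the bright tail;
rerun with `"production"` and the tails agree to about 1%.

`run_pipeline()` chains everything (simulate or read tables → Type I fits →
Type II fits → ANOVA/Tukey bin comparisons → pooling check → timer) from a
single list or YAML config and writes `partitions.csv`, `tests.csv`,
`scatter.csv`, `timer.csv` and a plain-text summary, byte-identically for a
fixed seed.

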