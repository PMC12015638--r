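# gradientflow

Dynamic and static functional-connectivity-gradient analysis for
parcellated fMRI time series.

Cortical connectivity is organized along smooth axes ("gradients"); the
principal gradient runs from unimodal somatomotor/visual cortex to the
transmodal default-mode network. gradientflow asks whether that gradient is
*dynamic* over the course of a task, and how it differs between groups. It
is written for researchers with ROI-by-time matrices in hand (one per
subject, e.g. Schaefer-400 parcel series with Yeo-7 network labels) who
want the full sliding-window gradient pipeline without the MRI
preprocessing stack.

## What it computes

For each subject and each sliding window (40 s windows, 20 s steps by
default — 14 windows of a 300 s task):

1. Pearson connectivity, row-wise binarization at 10 % density,
   normalized-angle affinity `1 − acos(ρ)/π`;
2. diffusion-map embedding (α = 0.5, automatic diffusion time
   `λ/(1−λ)`); the first component is the principal gradient;
3. Procrustes alignment to the control-group static gradient, then
   equal-count discretization into K = 20 bins.

From the binned windows: **allegiance** `P_ij` (probability two ROIs share
a bin across subjects and windows), **flexibility** (fraction of
contiguous-window bin changes per ROI), and **recruitment** (probability an
ROI shares a bin with its same-network peers). Genuine dynamics are
demonstrated by a two-sample Kolmogorov–Smirnov comparison of allegiance
against phase-randomized surrogates that preserve the static correlation
structure exactly. Task betas (OLS with a canonical double-gamma HRF),
loading scores (beta × reference gradient, voxel-weighted network means),
rank-based covariate-adjusted ANCOVA per network with Benjamini–Hochberg
correction across the 7 networks, and permutation tests of
activation–gradient coupling complete the pipeline. A synthetic cohort
generator with a planted unimodal→transmodal axis, genuine window dynamics
and injectable group effects provides ground truth for every stage.

## Worked example

```r
library(gradientflow)
library(dplyr)

cfg <- run_config(
  synth = synth_params(n_roi = 100, n_subjects = c(HC = 10L, TLE = 10L),
                       seed = 55),
  n_perm = 500, seed = 5
)
res <- run_pipeline(cfg)

glance(res)
#> # A tibble: 1 × 8
#>     ks_D     ks_p coupling_delta_r coupling_p preference_delta_r preference_p
#>    <dbl>    <dbl>            <dbl>      <dbl>              <dbl>        <dbl>
#> 1 0.0672 2.33e-13          0.00147      0.844              0.242      0.00200

tidy(res) |> filter(measure == "recruitment") |> arrange(p_unc)
#> # A tibble: 7 × 10
#>   measure     network statistic   df1   df2   p_unc  p_fdr ...
#> 1 recruitment LIM       10.7        1    18 0.00429 0.0201
#> 2 recruitment SMC        9.82       1    18 0.00574 0.0201
#> 3 recruitment DAN        6.42       1    18 0.0208  0.0484
#> ...

res$spans |> filter(network == "DMN")
#> # A tibble: 1 × 5
#>   network span_ctrl span_pat span_ratio      p_mw
#> 1 DMN        0.0385   0.0109      0.283 0.0000113
```

Reading the output: the KS statistic D = 0.067 with p ≈ 2e-13 says the
windowed bin structure of the real cohort differs from its static
surrogates — the gradient is genuinely dynamic. The recruitment table puts
the planted deficit networks (LIM, SMC) at the smallest p-values after
covariate adjustment, and the DMN span ratio of 0.28 (< 1) recovers the
planted gradient contraction in the patient group. `autoplot()` methods
exist for gradients and allegiance matrices, and `plot_network_comparison()`
charts the per-network p-values.

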