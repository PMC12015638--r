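---
title: "Dynamic and static connectivity gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic and static connectivity gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradientflow)
```

## The scientific problem

Cortical functional connectivity is organized along a small number of smooth
axes — *gradients* — of which the principal one runs from unimodal
(somatomotor, visual) to transmodal (default-mode) cortex. gradientflow
implements a sliding-window version of gradient analysis for parcellated
task-fMRI time series: per-window connectivity matrices are embedded with
diffusion maps, the windowed gradients are discretized into bins, and the
temporal reorganization of the binning is summarized by allegiance,
flexibility and recruitment. Static surrogate data provide the null against
which genuine gradient dynamics are demonstrated, and rank-based
covariate-adjusted statistics compare patient and control groups network by
network.

## The pipeline, stage by stage

1. **Windowing.** A series of `total_s` seconds is divided into windows of
   `window_s = 40` in steps of `step_s = 20` (both in seconds); the window
   count is `floor((total - window)/step) + 1`, so a 300 s task yields 14
   windows. Windows are half-open sample ranges starting at sample 0.
2. **Connectivity.** Pearson correlation of the ROI rows within the window
   (series are de-meaned per window by construction of the correlation).
   Whether to z-score within windows is an open choice in this literature;
   plain per-window Pearson is used here, which is invariant to per-ROI
   positive affine rescaling anyway.
3. **Sparsification.** Each row keeps its top `ceiling(0.10 * (R - 1))`
   off-diagonal entries (10 % row density, i.e. sparsity 0.9); ties break
   toward lower column indices. Row-wise (not global) thresholding is used,
   matching the convention of the gradient toolboxes; the resulting
   asymmetry is absorbed by the affinity kernel.
4. **Affinity.** The normalized angle between sparsified connectivity
   profiles: `1 - acos(cosine)/pi`, in [0, 1], 0.5 for orthogonal profiles.
5. **Embedding.** Diffusion-map embedding with anisotropic normalization
   `alpha = 0.5` and automatic diffusion time (`lambda/(1 - lambda)`
   scaling), the toolbox defaults. Eigenvectors are normalized against the
   stationary distribution, which makes the trivial eigenvector exactly
   constant; signs are fixed so each component's largest-magnitude entry is
   positive, and near-degenerate spectra trigger a warning since components
   are then defined only up to rotation.
6. **Alignment.** Eigenvector sign and rotation are arbitrary across windows
   and subjects, so every window- and subject-level gradient is rotated
   (orthogonal Procrustes, reflections allowed, no scaling) onto a common
   template — the control-group static gradient — before binning. Binning
   unaligned gradients is also possible (`align = FALSE`) but makes bins
   incomparable across windows.
7. **Binning.** Equal-count bins: ROIs sorted by principal-gradient value
   (ties by ROI index) are cut into K = 20 consecutive runs whose sizes
   differ by at most one. Equal-count rather than equal-width is used so the
   allegiance and recruitment denominators are comparable across windows;
   with 400 ROIs and K = 20 every bin holds exactly 20 ROIs. A sensitivity
   setting of K = 7 (the network count) is supported.
8. **Dynamic measures.** Allegiance is the probability over all
   (subject, window) pairs that two ROIs share a bin; flexibility the
   fraction of contiguous-window transitions at which an ROI changes bin;
   recruitment the probability that an ROI shares a bin with its
   same-network peers, averaged over windows and peers. Subject-level
   metrics feed the group statistics; allegiance additionally pools all
   subjects of a group. Network summaries are voxel-count-weighted means,
   because parcels differ in size; ROIs from singleton networks are
   excluded (not zero-filled) so network means are not biased.
9. **Static null.** Multivariate phase-randomized surrogates: one common
   conjugate-symmetric random phase vector added to all ROIs' Fourier
   phases preserves every amplitude spectrum and all cross-spectra — hence
   the full-length correlation structure exactly — while destroying genuine
   nonstationarity. Each null *set* phase-randomizes every subject once, so
   a null allegiance matrix pools exactly as many observations as the real
   one; this matched granularity is what makes real and null allegiance
   exchangeable when the data truly are static. The real and pooled-null
   upper-triangle distributions are compared by a two-sample
   Kolmogorov–Smirnov test. Allegiance entries are weakly dependent, so the
   effect size D is the primary quantity and the dispersions of both
   samples are reported alongside the p-value.
10. **Activation.** Per-ROI task betas from OLS on an intercept, linear
    drift and the HRF-convolved block design. The HRF is the canonical
    double-gamma (gamma shapes 6 and 16, rate 1, undershoot ratio 6),
    normalized to unit sum so a sustained block plateaus near 1 and the
    beta is interpretable as the plateau amplitude. Loading scores are
    betas weighted by a reference gradient (per ROI), aggregated by
    voxel-weighted network means; the reference defaults to a supplied
    resting-state-style gradient to avoid correlating a gradient with
    betas estimated from the same series.
11. **Group statistics.** Per network, a rank-based ANCOVA: response and
    covariates are ranked, the ranked response is residualized on the
    ranked covariates, and a one-way F test on the residuals compares
    groups (df k−1, n−k); age, sex, education and the MoCA are the default
    covariates. Raw p-values are Benjamini–Hochberg-adjusted across the 7
    networks of one measure family — never across families. The
    nonparametric path is taken unconditionally (no normality gate), which
    keeps the pipeline deterministic. Permutation tests (add-one two-sided
    p-values) compare activation–gradient coupling between groups (label
    shuffling) and between two gradients for the same activation pattern
    (per-ROI sign exchange of the paired difference).

## The synthetic cohort generator

Real task-fMRI underlying studies of this kind cannot ship with a package,
so `simulate_cohort()` generates cohorts in which every downstream claim has
planted ground truth:

* **Latent axis.** Each ROI has a position on a unit axis; the seven
  networks occupy contiguous near-equal blocks ordered
  SMC, VIS, SAN, DAN, LIM, CCN, DMN (unimodal to transmodal). Baseline
  covariance decays exponentially with axis distance
  (`axis_corr_scale = 0.15`) plus a small within-network boost (0.05), with
  a 1e-6 diagonal nugget for Cholesky stability. The boost is deliberately
  small: at 10 % row density a strong boost turns each network into a
  near-clique, the embedding spectrum degenerates into per-network block
  modes, and no principal axis is recoverable — the small-boost regime is
  the one in which gradient analysis is well-posed.
* **Dynamics.** Time is divided into 20 s segments; at each boundary each
  network's ROI positions jitter (per-ROI Gaussian, SD 0.1, reflected at
  the axis boundaries) with probability 0.3, and the segment is sampled
  from the covariance implied by the current positions. Windows therefore
  share samples, as in the real sliding-window pipeline, and the planted
  gradient remains the object the embedding should recover per window.
* **Activation.** True betas are `beta_gain * position` plus a small
  per-network offset; the HRF-convolved design times the betas is added to
  the series, plus white noise (SD 0.5). With `beta_gain = 1` the
  task-evoked share of variance is ~7 %, large enough for reliable GLM
  recovery (r > 0.9 against truth) and small enough not to dominate the
  connectivity structure.
* **Group effects.** The patient group receives (a) contraction of the DMN
  latent positions toward the network's own mean position
  (`dmn_contraction_factor = 0.7`), modelling a compressed gradient range
  without relocating the network among its neighbours — contraction toward
  the global axis midpoint was rejected because it slides the DMN onto the
  CCN range and manufactures spurious effects there; (b) reduced
  within-network coherence for SMC and LIM, implemented both as a
  multiplier on their boost (`coherence_reduction = 0.1`) and as extra
  independent per-segment jitter of their ROIs
  (`deficit_jitter_sd = 0.12`). The jitter component is essential for SMC:
  a network at the end of the axis keeps high co-binning whatever its
  boost, because the extreme bins must be filled from the extreme ROIs;
  desynchronized excursions are what genuinely lower its recruitment.
* **Covariates.** Age, sex, education and MoCA are drawn independently of
  the planted effects (MoCA slightly lower in patients), so covariate
  adjustment is exercised without confounding the recovery tests.
* **Determinism.** All randomness flows from one master seed through a
  fixed integer sub-seed stream; cohorts are bit-reproducible.

Effect sizes were calibrated once so that the recovery analyses are
well-powered at desk scale; they are modelling conveniences, not claims
about temporal lobe epilepsy physiology. What the generator does *not*
emulate: haemodynamic and physiological autocorrelation, head motion,
spatial smoothness within parcels, inter-subject anatomical variability,
and non-Gaussian noise. Passing recovery tests therefore demonstrates that
the estimators track their targets under the stated statistical model, not
that any particular clinical effect is real.

## Numerical choices and degenerate inputs

* Ties in density thresholding break toward lower column indices; ties in
  binning toward lower ROI indices; both make the pipeline deterministic.
* A disconnected sparsified graph (isolated ROI or split components) is an
  error advising lower sparsity rather than a silently wrong embedding.
* Zero-variance ROIs within a window are an error naming the ROIs.
* `adjusted_correlation()` returns r = 0, p = 1 when a variable is fully
  explained by the covariates (no residual variance), avoiding 0/0.
* Flexibility is invariant to a bin relabelling shared by all windows, but
  not to independent per-window relabellings (it compares bins across
  windows); allegiance and recruitment are invariant to both.
* BH adjustment is monotone in the p-value ranks and capped at 1; it is not
  idempotent on arbitrary monotone lists (flat lists are fixed points).

## Problem sizes used by the test-suite and acceptance analyses

The package's own analyses run at desk scale: recovery and calibration
suites use 60–100 ROIs and 6–10 subjects per group with 14 windows, 20
phase-randomized surrogate series for the dynamics comparison, and 200
replicates for false-positive calibration; the planted-axis and beta
recovery checks run once at the full design (400 ROIs, 29 + 30 subjects).
These sizes were chosen so each suite completes in minutes while keeping
the Monte-Carlo error of the assessed rates small relative to the margins
being asserted.

## Known limitations

* k = 2 embedding components are kept; higher-order gradients are out of
  scope.
* The KS p-value treats allegiance entries as independent samples, which
  they are not; it is reported for comparability but D and the dispersion
  summary carry the inferential weight.
* Group-level gradient spans are descriptive (one gradient per group);
  their between-group "tests" are Mann–Whitney comparisons of per-ROI
  values of two group-level embeddings and should be read as such.
* The generator's group-exchangeability under null parameters holds by
  construction, but empirical type-I rates inherit the usual Monte-Carlo
  noise of the replicate counts above.
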