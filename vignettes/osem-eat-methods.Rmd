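---
title: "Methods: ordered-subset EM reconstruction and epicardial fat analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ordered-subset EM reconstruction and epicardial fat analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osemeat)
```

# Scope

`osemeat` couples two stages of a low-dose cardiac CT analysis workflow:

1. **Image formation**: maximum-likelihood expectation-maximization (MLEM)
   reconstruction and its ordered-subset acceleration (OSEM), with a
   simulation bench (Shepp-Logan phantom, parallel-beam projector) to
   measure convergence and error;
2. **Cardiac analysis**: epicardial adipose tissue (EAT) volumetry by
   Hounsfield-unit windowing, Gensini coronary severity scoring with
   stenosed-vessel (NSCV) classification, and the cohort statistics that
   relate EAT to coronary heart disease (CHD): logistic risk modelling,
   Spearman correlation and ROC analysis, driven by a calibrated synthetic
   cohort generator.

# The reconstruction model

## Forward model

The scanned object is a pixel image $g_j \ge 0$. Each detector reading is
modelled as a line integral: $\hat y_i = \sum_j q_{ij} g_j$, where $q_{ij}$
is the length of the intersection of ray $i$ with pixel $j$, computed
exactly by Siddon ray tracing (compiled code; one ray per detector bin).
The weights are deliberately *not* row-normalized: the EM update divides by
the sensitivity $\sum_{i \in S} q_{ij}$, so any per-ray scale cancels.

Geometry conventions: square pixels centred on the origin; angle 0° sends
rays parallel to the y-axis; angles increase counter-clockwise over
$[0, 180°)$ (parallel-beam data repeat beyond 180°, so spans above 180° are
rejected). The default detector array is the smallest odd count of
unit-spaced bins at least $n\sqrt 2 + 4$ — the image diagonal plus a
two-bin margin per side — which is 367 bins for the 256×256 bench and
guarantees every pixel is seen at every angle.

## MLEM and OSEM

With measured data $y_i$ and Poisson likelihood, MLEM iterates

$$ g_j^{k+1} = g_j^{k}\,
   \frac{\sum_i q_{ij}\, y_i / \hat y_i^{k}}{\sum_i q_{ij}} $$

from a uniform positive start (all ones; any positive constant works for a
multiplicative update, and ones make the first correction factor directly
readable as a data/model ratio). Each iteration decomposes into the
explicit steps exposed by the API: subset forward projection
(`forward_project_subset`), residual $r_i = y_i/\max(\hat y_i,
\varepsilon)$ (`compute_residual`), back-projected correction
$c_j = \sum q_{ij} r_i / \sum q_{ij}$ (`compute_correction`), and the
multiplicative update $g_j \leftarrow g_j c_j$ (`apply_update`).

OSEM partitions the projection angles into $L$ equal subsets and applies
that update once per subset, so one pass over the data corrects the image
$L$ times. On the noiseless bench this yields the classic $L$-fold
acceleration: with $L = 30$, one full OSEM iteration reaches an error that
MLEM needs on the order of 30 iterations to match. MLEM is the $L = 1$
special case of the same code path, which is also how the package tests
their equivalence bitwise.

## Subset construction and ordering

Two rules govern the partition (`partition_subsets`):

* **Balance/uniformity** — subset $m$ takes angle indices
  $\{m, m+L, m+2L, \dots\}$ (stride-$L$ interleave), so every subset is the
  same size and uniformly covers the angular range.
* **Ordering** — the `optimized` strategy processes subsets so that each
  successive subset's lead angle is as far as possible from the previous
  one in the circular metric of the subset pattern (lead indices modulo
  $L$), greedy, ties to the lowest subset index. For $L = 4$ this
  reproduces the familiar bit-reversed access order $S_1, S_3, S_2, S_4$.
  Feeding maximally different directions consecutively reduces the
  redundancy between successive sub-iterations; on the 256×256 bench the
  optimized ordering lowers the one-iteration error from 0.274
  (sequential) to 0.250.

## Error metric and numerical guards

* **Error metric**: relative RMSE
  $\lVert g - g_{\rm true}\rVert_2 / \lVert g_{\rm true}\rVert_2$, the
  standard phantom-study metric. Headline numbers (the error floor reached
  within 20 OSEM iterations) are reported under this metric; any other
  norm would change the absolute values.
* **Division guards**: $\varepsilon = 10^{-12}$ in the residual and in the
  log of the Poisson likelihood; a pixel with zero subset sensitivity
  receives correction 1 (left untouched). `recon_config` restricts
  $\varepsilon \le 10^{-6}$ so the guard can never distort well-scaled
  data.
* **Degenerate inputs**: zero observed with zero predicted gives residual
  0 (the pixel evidence is absent, not infinite); zero image pixels are
  absorbing, as in any multiplicative EM.
* The bench experiment is noiseless by default; Poisson noise can be
  injected by resampling the sinogram when dose simulation is wanted, and
  the EM monotonicity tests run on both noiseless and Poisson-resampled
  data.

## The phantom

`generate_shepp_logan` rasterizes the standard ten-ellipse Shepp-Logan
head phantom, with the original low-contrast amplitude table (rim
amplitude 1.0, interior 0.02, features 0.01–0.04; intensities in
$[0,1]$), evaluated at pixel centres. Centre-point rasterization leaves
boundary aliasing of order one pixel around each ellipse edge; the
cross-resolution consistency of the rasterizer (block-averaged $2n$ vs
$n$) improves monotonically with $n$ and is below 0.05 RMS at the bench
size 256. Note the standard ellipse table is *not* left-right symmetric
(the two large "ventricle" ellipses differ in size), so no mirror symmetry
is asserted anywhere.

# EAT volumetry

`segment_fat` thresholds a CT volume to the adipose window, default
**−150 to −50 HU** — the universal CT fat window — between explicit axial
slice bounds, and `measure_eat` converts the voxel count to millilitres
(count × voxel volume / 1000). The slice bounds mirror the manual
workstation step of delimiting the span from the left pulmonary artery
origin to the left-ventricular apex; automatic anatomical landmarking and
pericardium delineation are out of scope, so the bounds (and the
pericardial sac) are inputs, not inferences. A helper (`average_eat`)
averages two readers' measurements, as in the clinical protocol.

The synthetic volume generator (`generate_synthetic_ct`) builds an air
background (−1000 HU), a soft-tissue ellipsoid (+40 HU) and a fat shell
(−100 HU) occupying a requested fraction of the ellipsoid, plus Gaussian
HU noise, and returns the exact shell voxel count. With the window centred
at −100 HU and half-width 50 HU, noise of 10 HU leaves 5σ of margin, so
recovery stays within 2%; noiseless recovery is exact. What the generator
does **not** emulate: partial-volume voxels at tissue interfaces, contrast
enhancement, beam-hardening or motion artefacts — so passing tests
demonstrate the correctness of the windowing/counting arithmetic, not
segmentation robustness on clinical data.

# Gensini score and NSCV

`stenosis_points` maps percent diameter stenosis to the doubling point
scale 1, 2, 4, 8, 16, 32 at the thresholds 25/50/75/90/100% (right-closed
buckets; 0% scores 0). The published bucket list in the source material
omits the 26–50% range; the standard Gensini 2-point bucket is restored
there. `gensini_score` multiplies the points by the fixed segment
coefficients (left main 5; proximal LAD/LCX 2.5; mid-LAD 1.5; distal
segments, OM, RCA, PDA 1; second diagonal 0.5) and sums over lesions —
making the score additive over lesions and monotone in stenosis by
construction. `classify_nscv` counts a vessel (LAD, LCX, RCA) as diseased
when any of its segments reaches the threshold (default 50%, the usual
angiographic definition, configurable); a left-main lesion marks both LAD
and LCX, i.e. counts as two-vessel disease.

A caution for users comparing against published worked examples: under
this (standard) table, a mid-LAD 80% plus proximal-LCX 72% case scores
$8 \times 1.5 + 4 \times 2.5 = 22$.

# The synthetic cohort and its statistics

## Generator

`generate_cohort` draws a control group and a CHD group. EAT volumes are
zero-truncated normal with the default calibration **124.50 ± 26.72 mL
(control)** and **159.41 ± 38.51 mL (CHD)**. Within the CHD group, EAT,
Gensini score and NSCV are drawn jointly through a Gaussian copula; the
copula correlations are set by $\rho_z = 2\sin(\pi\rho_s/6)$ so the
*rank* correlations hit their targets (defaults 0.327 for EAT–Gensini,
0.416 for EAT–NSCV, 0.5 between the two severity measures; a non-PSD
combination is rejected). The Gensini margin is gamma (shape 1.5, scale 20
→ mean 30, right-skewed, as severity scores are); NSCV cuts its latent
uniform at the case mix 10 : 19 : 19 for single/double/multi-vessel
disease. Because NSCV is a three-level category, heavy ties shrink its
*observed* Spearman correlation below the latent target (≈ 0.38 observed
for a 0.416 target) — an inherent property of rank correlation under
ties, not a calibration error.

Covariates are drawn once-chosen realistic margins: age 59.85 ± 7.67
(control) vs 61.67 ± 6.28 (CHD) years; male fraction 28/42 vs 42/68;
smoking 25% vs 45%; hypertension 30% vs 50%; diabetes 15% vs 30%; BMI
24.5 ± 3.2 kg/m² and uric acid 340 ± 80 µmol/L in both groups. Thus age,
smoking, hypertension, diabetes and EAT are higher in the CHD group in
expectation while BMI, sex and uric acid are not. Controls receive small
sub-threshold Gensini scores (gamma, mean ≈ 2.4) and NSCV "none". All
randomness flows from the single `seed` in `cohort_params`, restoring the
caller's RNG state afterwards.

The generator is a stand-in for unavailable clinical data: it makes
*parameter recovery* testable (do the fitted means, slopes and
correlations recover what was planted?) but cannot reproduce any
particular clinical table.

## Statistics

* `logistic_fit`: maximum-likelihood logistic regression (IRLS via
  `stats::glm`), reporting per covariate the log-odds coefficient $B$, SE
  from the inverse observed information, Wald $(B/\mathrm{SE})^2$ with
  $\chi^2_1$ p-value, and $\mathrm{OR} = e^B$ with 95% CI
  $e^{B \pm 1.96\,\mathrm{SE}}$ — the OR and CI are definitional
  transforms of $B$ and SE, never independently tabulated. Separation is
  flagged (`converged = FALSE`) rather than silently reported; singular
  designs are an error.
* `spearman_cor`: Pearson correlation of mid-ranks, p from the
  $t_{n-2}$ approximation.
* `roc_analysis`: empirical ROC over all distinct thresholds
  (positive if score ≥ threshold), trapezoidal AUC (equal to the
  Mann-Whitney probability with half credit for ties), operating point by
  Youden's $J$, ties resolved at the lower threshold.
* `group_compare`: Welch's t for numeric fields, continuity-corrected
  chi-square for binary fields — robust defaults chosen because the
  source material does not state its tests.

No multiplicity correction is applied, matching the reporting style the
package emulates; users comparing many fields should adjust externally.

# Problem sizes and test design

The package's own verification runs at these sizes (chosen to exercise
every claim at full fidelity while keeping the suite quick):

* unit/property tests: 32×32 phantom, 36 angles (dense-oracle equivalence
  to machine precision, EM monotonicity, fixed-point and partition
  properties);
* the headline bench: 256×256 phantom, 180 angles at 1°, 30 subsets of 6
  — 20 OSEM and 40 MLEM iterations (the $L$-fold law, the error floor,
  and the ordering comparison), plus a 64×64 / 60-angle / 10-subset
  variant of the acceleration law;
* cohort calibration: $10^5$ patients per group (EAT means to ±0.5 mL);
  slope recovery at $n = 10^4$ × 100 replicates and null calibration at
  $n = 200$ × 200 replicates from a single declared RNG stream.

# Known limitations

* The projector is a single-line-per-bin intersection-length model: no
  strip/footprint integration, no fan/cone-beam geometry, no scatter or
  beam-hardening physics. Per-angle total-mass consistency therefore holds
  to ~0.05% only for smooth, well-resolved images and degrades on small
  pixelized ones.
* Iteration wall-clock time is hardware-dependent and deliberately not a
  package claim; convergence is measured in iterations.
* EAT bounds and pericardium delineation are manual inputs; the HU window
  is a global threshold with no partial-volume modelling.
* The cohort generator's covariate margins beyond EAT are plausible
  conventions, not estimates; only the planted quantities (EAT means/sds,
  rank correlations, logistic slopes) are recoverable truths.
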