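---
title: "Methods: fetal lung T2* relaxometry, normative modelling and heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fetal lung T2* relaxometry, normative modelling and heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalt2star)
```

## The problem

T2\* relaxometry of the fetal lung measures the effective transverse
relaxation time of a multi-echo gradient-echo signal. Because oxygenated and
deoxygenated haemoglobin differ in their paramagnetic effect, lung T2\* is an
indirect marker of tissue oxygenation and composition, and its change over
gestation tracks normal pulmonary development. The quantitative chain is:

1. acquire magnitude images at several echo times (TE);
2. fit the mono-exponential decay `S(TE) = S0 * exp(-TE / T2*)` per voxel;
3. summarise T2\* over manually segmented right/left lung masks (mean,
   volume, histogram, heterogeneity);
4. regress the per-scan summaries on gestational age (GA) to obtain a
   normative model, and convert an individual observation to a z-score and
   centile;
5. quantify observer reliability of the summaries with intraclass
   correlations.

Real fetal scans are not distributable with this package, so every stage is
validated against a synthetic-data module with exact ground truth: a digital
thorax phantom, a multi-echo signal simulator, and a cohort generator. The
synthetic module is first-class, tested code, not a fixture.

## Acquisition model and defaults

`acquisition_params()` defaults to the multi-echo gradient-echo EPI protocol
the pipeline targets: five echoes at 13.8, 70.4, 127.0, 183.6 and 240.2 ms,
TR 3000 ms, flip angle 90 degrees, 3 mm isotropic voxels. The flip angle is
metadata only — its effect on signal amplitude is folded into S0. Voxel
sizes are carried in the NIfTI header (pixdim) and all per-voxel arithmetic
(volumes in mL, box sizes in voxels) uses them.

## The digital thorax phantom

The phantom (`make_phantom()`) is deliberately minimal geometry with an
analytic volume oracle: a body cylinder along the head–foot axis, a
spherical heart, and two lung ellipsoids with fixed axis ratios. Design
choices:

* **Growth**: total analytic lung volume is linear in GA,
  `V(ga) = 3 (ga - 15)` mL. At 3 mm resolution this keeps several hundred
  lung voxels at the youngest gestations (≥ 600 at 21 weeks) and realistic
  tens-of-mL volumes near term. Growth is strictly monotone by
  construction, so volume ordering across GA is exactly testable.
* **Asymmetry**: the left lung's analytic volume is fixed at 0.85 times the
  right lung's, encoding the smaller left lung (heart displacement); the
  paired right-left comparison should therefore detect right > left in any
  adequately sized synthetic cohort.
* **Tissue values**: lung T2\* defaults to the published normative mean
  evaluated at the phantom's GA, so an end-to-end noiseless run lands on
  the reference curve by construction (the closed-loop test). Body (35 ms)
  and heart (45 ms) use fixed representative 3 T values; they only need to
  be distinct from lung, nothing downstream depends on them.
* **Texture**: a tissue with `heterogeneity_sd = h` receives a voxelwise
  independent multiplicative log-normal field with unit mean and fractional
  SD exactly `h`. This emulates within-tissue heterogeneity with a known
  generating SD; it has no spatial correlation, so it does not emulate the
  spatially structured heterogeneity of real lungs (see Limitations).

## Signal simulation and noise

`simulate_multiecho()` evaluates the decay closed-form and applies noise.
The default noise model is Rician — the physically correct distribution for
magnitude MRI — implemented as the magnitude of the complex signal plus
bivariate Gaussian noise; `snr` is defined as mean lung S0 divided by the
per-channel noise SD. At high SNR the Rician sample mean exceeds the true
signal by approximately `sigma^2 / (2 S)`, which the suite verifies by Monte
Carlo against the first-order expansion. A plain Gaussian model (clipped at
zero to respect magnitude non-negativity) and a noiseless mode are provided
for estimator studies.

## T2* fitting

The decay-fitting algorithm is not fully pinned down by common practice, so
both standard estimators are implemented:

* `fit_loglinear()`: OLS of `log(S)` on TE; closed-form, vectorised over a
  whole volume. Non-positive samples are dropped per voxel before the log;
  fewer than three usable echoes gives status `failed` (never an
  exception — map fitting must always complete).
* `fit_nlls()`: bounded Levenberg–Marquardt least squares in the signal
  domain (via minpack.lm), initialised from the log-linear solution. The
  returned solution never has a larger residual sum of squares than its
  initialisation. This is the default for maps, because the log transform
  makes the log-linear estimator biased under Rician noise; the suite
  verifies by simulation that NLLS has smaller absolute bias at SNR 20.

T2\* estimates are clamped to [1, 500] ms — values outside are non-physical
at 3 T — with clamping recorded per voxel in a status volume; a non-decaying
signal is reported as `clamped_high`. R² is reported in the domain the fit
was performed in (log domain for log-linear, signal domain for NLLS). No
Rician-bias correction term is applied in either model; this is a known
limitation at low SNR.

## ROI statistics

`summarize_roi()` pools voxels: the "both lungs" summary is computed over
the union of right and left voxels, so it equals the voxel-count-weighted
mean of the per-lung means (exactly, and tested as an identity) — matching
the voxel-histogram framing of the per-scan analyses rather than an
average-of-means. Volumes are `n_voxels x voxel volume / 1000` mL and depend
only on mask and spacing, never intensity. Empty ROIs yield flagged
summaries, not errors, so batch runs never abort. Label convention is fixed:
0 background, 1 right lung, 2 left lung, validated at mask construction and
file read.

## Lacunarity

The heterogeneity score is continuous-mass gliding-box lacunarity computed
on T2\* intensities (not a binarised field — the maps are quantitative): a
cubic box of edge `r` slides at unit step over the mask bounding box; boxes
with at least 90% of voxels in the mask are retained; box mass is the sum of
in-mask intensities; `Lambda(r) = mean(M^2) / mean(M)^2`. Properties tested:
`Lambda >= 1` (Cauchy–Schwarz), invariance to intensity scaling and to joint
translation of map and mask, and exact agreement with an exhaustive
all-positions enumeration on small random volumes. Note that with the plain
mass sum, partially covered retained boxes make `Lambda` marginally exceed 1
even on constant fields over irregular masks (~0.1%); on full-coverage masks
equality is exact. Default box sizes {2, 3, 4, 6, 8} voxels span sub-lobe
scales at 3 mm resolution; the default scalar score is the mean of
`log(Lambda)` over unflagged sizes, which stabilises scale mixing. Whether
the original per-scan score used intensities or a derived field, and which
box sizes, is not documented anywhere; these defaults are this package's
choice and are recorded with every output.

## Cohort generation and the normative model

`published_model()` packages the printed reference coefficients exactly:
mean `1.488884 ga + 21.997645` ms and SD `1.488884 ga - 18.451005` ms, with
domain [20.6, 38.3] weeks — the study's observed GA range. The SD line is
negative below ~12.4 weeks, so evaluating outside the domain is an error by
design. The identical slope digit-for-digit in both lines may be a
transcription artefact of the source; the coefficients are encoded exactly
as printed and never "reconciled" with the separately printed OLS results
(slope 1.61, intercept 19.61, R² 0.13 on the real 87-scan cohort), which
are real-data results this package documents but cannot and does not
reproduce.

`simulate_cohort()` draws GA from a truncated normal on [20.6, 38.3] and
the metric from `Normal(mean(ga), SD(ga))`; ~11.5% of subjects (10/87)
receive a second scan at GA + U(2, 8) weeks, clipped to the range. Because
truncation and the clipped repeat scans both shift moments, the parent
(mu, sigma) are calibrated by numerical moment matching (quadrature over
the truncated density and the repeat-delta distribution) so that the
**scan-level** GA distribution has mean 29.9 and SD 4.3 weeks — the
generator's contract is to match the published cohort summary, not to use
it as a parent parameter. The calibration residual is below 1e-6 and the
matched parent is approximately mu 29.43, sigma 4.95.

`fit_trend()` is OLS of a metric on GA; with `cluster_by_subject = TRUE`
standard errors (and the slope p-value) are cluster-robust over subjects
(HC1-type small-sample correction — with ~77-87 clusters a mild correction
is adequate), leaving point estimates untouched. The SD-vs-GA line is
estimated either from absolute mean-fit residuals scaled by `sqrt(pi/2)`
(`E|N(0,s)| = s sqrt(2/pi)`; uses every scan, the default) or from sample
SDs in integer-GA bins regressed on GA (used for round-trip calibration
checks). GAMLSS-style or quantile centile modelling is out of scope.
Z-scores are `(obs - mean(ga)) / SD(ga)` and centiles use the exact normal
CDF, `100 * pnorm(z)`.

## Reliability

`icc_a1()` implements the absolute-agreement, two-way model ICC from the
ANOVA mean squares, single-measures by default — one observer's measurement
being the clinical unit of use — with average-measures via the
Spearman-Brown relation as an option. Confidence intervals are the standard
F-based (McGraw–Wong) form at 95%. The implementation computes mean squares
from closed-form sums; the suite checks it to 1e-10 against an independent
`aov()`-based computation, and verifies affine invariance and permutation
invariance.

## Problem sizes and numerical choices

Phantom grids of 32 x 28 x 24 voxels (96 x 84 x 72 mm at 3 mm) are the
package's working size: they accommodate the lung geometry at any GA in
[18, 40] and keep whole-suite runtimes interactive; nothing in the methods
depends on grid size beyond discretisation error, and the digitised-volume
tests bound that error at 5%. Cohort calibration checks use 5000 subjects;
SD-recovery round trips use 200 scans per integer GA 21-38 (3600 scans), at
which size the binned-SD intercept still carries ~1.7 ms sampling SD —
parameter-recovery tests therefore average over replicate simulations to
isolate bias from single-draw noise. All randomness flows through one
explicit seed per call (restored afterwards, no global state), and derived
per-scan seeds keep full-pipeline reruns byte-identical.

## Limitations

* The phantom is geometric, not anatomical; its texture is spatially white,
  so lacunarity's absolute scale on phantoms is not comparable to real
  lungs — only orderings and invariances are meaningful.
* The simulator produces motion-free volumes; motion correction /
  slice-to-volume reconstruction is explicitly out of scope, and the
  pipeline consumes already-reconstructed volumes.
* No Rician-bias correction in the fitters; at SNR well below ~10 the long
  echoes of low-T2\* tissue approach the noise floor and both estimators
  degrade.
* The published-model coefficients and the real-cohort OLS results are
  distinct artifacts; only the former are machine-checkable here, and all
  real-cohort values are context, not targets.
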