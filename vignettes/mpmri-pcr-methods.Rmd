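---
title: "Methods: multiparametric MRI biomarkers and classifier comparison for pCR prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric MRI biomarkers and classifier comparison for pCR prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpMRIpcr)
```

# Overview

`mpMRIpcr` implements an end-to-end analysis for predicting pathological
complete response (pCR) to neoadjuvant chemotherapy in breast cancer from
pre-treatment multiparametric MRI: voxel-wise semi-quantitative perfusion
biomarkers from DCE-MRI, mono-exponential and bi-exponential (IVIM)
diffusion fits from multi-b DWI, IBSI-style first-order and texture
radiomics on the ADC and iAUC60 maps, a two-step variance/correlation
feature selection with per-feature group statistics, and a balanced
leave-one-out comparison of ten classifier families over imaging-only,
clinical-only and combined feature sets.

Because the cohort the analysis emulates is not publicly deposited, the
package ships a synthetic mpMRI generator with known voxel-wise ground
truth. Every downstream stage is validated against that truth or against
independent brute-force oracles; the published cohort's headline accuracy
percentages are *not* reproduction targets, only the qualitative ordering
of the three model configurations is.

# The synthetic cohort generator

## DCE forward model

Each voxel's contrast-concentration curve is a gamma-variate,

$$c(t) \;=\; c_\mathrm{peak}\,\tau^{\alpha} e^{\alpha(1-\tau)},
  \qquad \tau = \frac{t - t_0}{T_p - t_0},$$

zero before the arrival delay $t_0$, with analytic maximum $c_\mathrm{peak}$
at $t = T_p$ (time-to-peak, measured from injection start). The gamma
variate is the standard smooth unimodal bolus model — an initial rapid
rise with slower washout — and its closed-form peak location and height
give exact oracles for the extraction stage. The scanner signal is
$S(t) = S_0\,(1 + c(t))$ plus additive Gaussian noise (`noise_dce`, default
SD 1 on a baseline of 100).

Acquisition timing follows the emulated protocol: 40 s temporal
resolution, each dynamic time-stamped at its end, and contrast injection
20 s after the end of the first (pre-contrast baseline) dynamic. One
protocol-level inconsistency had to be resolved: the emulated acquisition
has six dynamics (a 240 s window) while the group-level time-to-peak
values the generator is calibrated to run out to roughly 300 s, which no
240 s acquisition can contain. The generator therefore defaults to 16
dynamics at the same 40 s resolution and injection timing, so that the
calibrated TTP distribution lies inside the sampled window; the 6-dynamic
protocol remains available through `n_dynamics`.

Voxel-level truth TTP is defined *on the post-injection sampling comb*
(each voxel's drawn TTP is snapped to the nearest sample time): a dynamic
scan with 40 s resolution cannot localise a peak more finely, and for an
asymmetric uptake curve the sampled argmax of an off-comb peak can fall
marginally beyond half the sampling interval. With truth defined at
sample resolution, noiseless extraction recovers TTP exactly.
Patient-level mean TTP stays continuous.

## Group structure and calibration

Patients carry a hierarchical parameter structure: patient-level means
drawn from group-level distributions, voxel-level values drawn around the
patient mean. The defaults encode the emulated study conditions:

* cohort of 12 responders and 46 non-responders;
* patient-level TTP: mean 187.47 s (SD 51.27) in responders versus
  237.67 s (SD 79.20) in non-responders — shorter TTP in responders
  (higher vascularity), with a 30 s voxel-level SD;
* voxel-wise D\* dispersion per patient (the `D_star_std` feature):
  group means 0.006 versus 0.007 mm²/s (SD 0.002) — tighter
  pseudo-diffusion spread in responders;
* ADC texture: the pure-diffusion field is a spatially smoothed,
  negatively skewed Gaussian random field whose smoothing width is set by
  `texture_homogeneity` (unitless, [0, 1]). Responders default to 0.85,
  non-responders to 0.25: the emulated study reports roughly a factor-two
  difference in the absolute GLCM cluster shade between groups, and this
  gap produces a clearly separated texture signal of that character. Only
  the *direction* (smoother in responders) is taken from the emulated
  findings; the magnitude is a package design choice, fixed once.
* four binary clinical covariates (age over 40, premenopausal status,
  stage III, grade III) drawn with group-conditional probabilities whose
  exact Bayes accuracy is 63% — deliberately *weakly* informative, so the
  clinical-only model sits near the low-60s accuracy regime the combined
  model is compared against. The probabilities are configuration, not
  epidemiological claims.

With 500 patients per group the sample means of the voxel-median TTP sit
within two standard errors of the calibrated group means (checked in the
test suite).

## DWI forward model

Signals follow the bi-exponential intravoxel-incoherent-motion model
$$S(b) = S_0\left[\tfrac{f}{100} e^{-b D^*} + \left(1 - \tfrac{f}{100}\right) e^{-b D}\right]$$
at b = 0, 150, 400 and 1000 s/mm², with Rician noise of scale
$S_0/\mathrm{SNR}$ (magnitude MRI; default SNR 50). Voxel-level truth:
$D \sim 1.1\times10^{-3}$ mm²/s with spatial structure shared with the
ADC texture field, $f \sim 10\,\%$ (SD 2), and $D^*$ centred at
0.020 mm²/s with the patient's calibrated dispersion, floored at
0.008 mm²/s — pseudo-diffusion an order of magnitude above tissue
diffusion, as values overlapping $D$ are not physically meaningful IVIM.

# Perfusion extraction

The concentration proxy is relative enhancement,
$c(t) = s\,(S(t)-S_0)/S_0$ with per-voxel baseline $S_0$ estimated from
the pre-injection dynamics and a configurable scale $s$ (default 1): no
T1-mapping conversion is attempted, and the downstream biomarkers are
either invariant to $s$ (TTP) or scale linearly with it. Per voxel:

* **peak** — maximum over post-injection samples;
* **TTP** — time of the *first* sample attaining the maximum, from
  injection start (first-attainment is the deterministic plateau rule);
* **iAUC60** — trapezoidal integral over [injection, injection + 60 s],
  with linear interpolation where a window endpoint falls between
  samples. Units are mM·s (a time-integral of a concentration; reports
  that follow the emulated study's table layout label the quantity as it
  is labelled there, but the package carries mM·s);
* **initial slope** — the maximum forward difference between consecutive
  samples from contrast onset (first sample above 5% of peak,
  configurable) up to the peak sample.

At the 40 s protocol resolution, trapezoidal integration of a late-peak
gamma-variate over the first minute has a discretisation error of several
percent — that is a property of the sampling, not of the integrator. The
forward-inverse consistency check therefore evaluates `compute_iauc60()`
on the same continuous truth curves sampled at 5 s, where the trapezoid
agrees with fine-grid (0.1 s) integration to well under 1%; TTP recovery
is checked at the protocol resolution, where it is exact.

# Diffusion fitting

ADC is the ordinary least-squares slope of $-\log S(b)$ against $b$ over
all b-values — deterministic, closed-form, and scale-invariant. On IVIM
signals ADC exceeds $D$ (perfusion contamination), which is itself a
tested property.

The IVIM fit is segmented with a joint refinement:

1. log-linear fit over $b \ge 200$ s/mm² gives an initial $D$ and
   high-b intercept;
2. $f = 1 - \mathrm{intercept}/S(0)$;
3. the estimated fast compartment is subtracted and $D$, $f$ are re-fit
   by weighted log-linear least squares over *all* b-values (weights
   $\propto S^2$, the standard correction for log-transformed magnitude
   data), iterating with a bounded one-dimensional re-fit of $D^*$;
4. a bounded joint least-squares polish (L-BFGS-B over $(D, f, D^*)$,
   constrained to $D^* \ge D$, $0 \le f \le 60\,\%$) from the segmented
   solution.

The polish matters on noiseless data: the alternating scheme can converge
to a slightly biased fixed point when $D^*$ sits near its physical floor,
while the joint solution is exact (relative errors around $10^{-5}$
across the generator's whole $D^*$ range). Plain two-point segmented
fitting is available with `refit = FALSE`. Hard constraints
($D^* \ge D$, $f \in [0, 100]\,\%$) hold for every fitted voxel.

**What the data can and cannot determine.** With four b-values at
SNR 50, the achievable per-voxel precision is limited by the design
itself: the derivative of the signal with respect to $f$ vanishes at
$b = 0$, so $f$ is informed essentially by the single b = 150 point, and
$D$ rests on the two high-b points. Simulation at the default truth
setting gives median relative errors around 7% for $D$ and 30–40% for
$f$, and $D^*$ is essentially unstable (consistent with the poor
reproducibility this coefficient is known for). Across plain segmented,
iterative, fixed-$D^*$ and joint variants — including oracle fits given
the true nuisance parameters — no estimator does materially better; the
package reports these errors as measured rather than claiming precision
the protocol cannot support. At SNR $\to \infty$ the bias vanishes
(tested at SNR 20/50/∞).

# Radiomics

Maps are discretised inside the mask with a fixed bin number
($N_g = 32$ by default; equal-width bins from masked min to max), which
makes all texture features invariant under positive affine rescaling of
the input map — a property the oracle tests exploit.

Texture matrices follow the IBSI conventions: GLCM over the 13 unique 3D
directions at distance 1, symmetrised and *merged* (pooled before
normalisation) so each feature is a single number; GLRLM runs merged over
the same 13 directions; GLSZM zones by 26-connectivity; NGTDM over the
26-neighbourhood. Every feature of every family equals an independent
exhaustive-enumeration oracle (explicit pair/run/zone/neighbourhood
loops, written separately from the vectorised production code) to
$10^{-10}$ relative on random 4×4×1 and 3×3×3 masked images.

Degenerate inputs take documented fallbacks: a constant ROI has GLCM
energy 1 and contrast 0, correlation and both information measures are
defined as 0 for a single-level image, and NGTDM coarseness is capped at
$10^6$.

The default panel is engineered to the published width of 251 imaging
features per patient: 8 biomarkers × 5 ROI statistics (mean, median, SD,
25th, 75th percentile; linear-interpolation convention) = 40, plus per
map (ADC and iAUC60) 43 first-order, 25 GLCM, 16 GLRLM, 16 GLSZM and 5
NGTDM features, plus the absolute-value variant of the ADC GLCM cluster
shade — the form in which the emulated study tabulates that feature
(cluster shade is stored signed; the sign carries the direction of the
co-occurrence skew). The exact membership is configuration
(`radiomics_config()`), since the full published appendix list is not
reproduced anywhere.

# Feature selection and group statistics

The two-step selection removes (i) features with sample variance at or
below 0.1 — *inclusive*, computed on raw values by default — then (ii)
greedily eliminates correlated pairs ($|r| > 0.8$, Pearson on raw
values), visiting pairs in order of descending $|r|$ and keeping the
higher-raw-variance member (lexicographic tie-break), until no violating
pair remains. Selection is idempotent and the retained set never contains
a pair above the threshold.

The variance-filter scale is the single most consequential unstated
choice in this pipeline, so it is a config switch. Raw units is the
default for two reasons: a column min-max-scaled by its own sample range
can never exceed variance 0.25 and typically sits near 0.06–0.08, so a
0.1 threshold on min-max-scaled data removes essentially *everything*;
and only the raw-units reading plausibly produces a reduction of the
observed magnitude (251 → a few dozen), because it eliminates wholesale
the small-magnitude features (diffusion coefficients in mm²/s,
entropies, fractions of unity). Under z-scoring the filter degenerates to
removing constants only. On default synthetic cohorts the raw filter
retains on the order of 20–30 features; the exact count for any cohort is
in the selection log.

Group comparisons are two-sample pooled-variance t-tests per feature,
two-sided, reported with group means (SD) in the layout of the emulated
study's table. No multiple-testing correction is applied — matching the
emulated analysis, which reports unadjusted p < 0.05 — and the result
object flags this explicitly. Under a null generator the rejection rate
at 0.05 is calibrated (≈5% over 1000 simulated features), and under the
calibrated TTP effect at n = 46/12 the TTP 25th-percentile difference is
detected in the majority of generator seeds.

# Classifier comparison

The cohort is first balanced by random undersampling: all responders are
kept and an equal-sized uniform subset of non-responders is drawn
(seeded). One draw of 12 from 46 is high-variance, so
`compare_configurations()` accepts multiple balancing seeds and reports
the dispersion across draws; the single-draw mode mirrors the emulated
analysis.

Ten classifier families run under leave-one-out cross-validation: k-NN
(k = 5), decision tree (rpart), random forest (200 trees), AdaBoost.M1
over exhaustive-search decision stumps (30 rounds), gradient boosting
(xgboost, depth 2, 30 rounds), Gaussian naive Bayes, LDA and QDA, a
one-hidden-layer MLP (nnet, 4 units, decay 0.1) and logistic regression.
Hyperparameters are fixed — the package's claims are ordering properties,
not tuned percentages — and every stochastic learner is seeded per fold.

Three learners needed regularisation to be *defined* at this data shape
(23 training rows, ~25–40 features):

* LDA/QDA use covariance shrinkage towards a scaled identity
  ($\lambda = 0.2$ pooled, $0.5$ per-class); at $\lambda = 0$ on
  well-conditioned data they reproduce the textbook fits (tested against
  an independent reference implementation);
* logistic regression is ridge-penalised (glmnet, fixed small
  $\lambda = 0.05$ on fold-standardised features), since the unpenalised
  MLE does not exist under the perfect separation this shape guarantees;
* naive Bayes carries a per-feature variance floor so that a binary
  clinical flag constant within one 11-row class still yields defined
  densities (cross-checked against a reference implementation on
  well-behaved data).

Fold hygiene: the per-feature z-scoring used by the scale-sensitive
learners (k-NN, MLP, logistic ridge, LDA, QDA) is fitted on the n−1
training rows of each fold only; an instrumentation hook exposes each
fold's training indices so tests verify the held-out row is never seen.
Label-permuted runs stay within sampling error of 50% accuracy — the
leakage guard. A training fold degenerating to a single class predicts
its majority.

Metrics use pCR as the positive class throughout: accuracy, sensitivity,
specificity and error rate in percent, with zero-denominator ratios
reported as `NA`, never silently 0. (The emulated study's own sensitivity
and false-negative figures are not mutually consistent under a single
positive-class convention on 24 cases, which is why one convention is
declared here and its exact percentages are not treated as targets.)
Best-per-configuration ranking is by accuracy, ties broken by fewer false
negatives, then classifier name.

# Problem sizes and runtime

The shipped checks use tumour masks of radius 3–5 voxels (≈120–500
voxels) on 15³–17³ grids, cohorts of 24–58 patients, 50 balancing draws
for the configuration-ordering property, 200 generator seeds for the TTP
power check and 1000 simulated features for the null calibration. These
sizes were chosen so the full suite exercises every stage end-to-end in
minutes on a single core while leaving the statistical checks adequately
powered; all of them scale up through the corresponding arguments.

# Known limitations

* The generator draws Gaussian parameter fields; real tumour biology is
  not Gaussian, masks are not spheres, and no motion, coil profile, B0/B1
  inhomogeneity or partial-volume effects are simulated. Passing tests
  demonstrate internal consistency of the pipeline, not clinical validity.
* The concentration proxy is relative enhancement, not a quantitative
  T1-based concentration; iAUC60 and peak are therefore in proxy units.
* Per-voxel IVIM at four b-values is information-limited (see above);
  D\*-derived features should be read as noisy descriptors.
* The 251-feature panel composition is a documented configuration, not a
  reproduction of an unpublished appendix.
* With 24 balanced cases, single-draw LOOCV accuracies carry large
  sampling error; conclusions should rest on the multi-seed dispersion
  the comparison report provides.
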