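---
title: "Models and methods behind fnirspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fnirspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`fnirspipe` analyses continuous-wave (CW) functional near-infrared
spectroscopy recordings of block-design motor tasks — the setting of
whole-head studies of grasping in Parkinson's disease, with two patient
groups (early, `ePD`, and moderate, `mPD`), left- and right-grasp
conditions (`LG`, `RG`), and a clinical covariate table per subject.  The
pipeline has five stages:

1. **Optical density.** Dual-wavelength intensities become optical-density
   changes, `dOD = -ln(I / I_ref)`.
2. **Motion-artifact correction.** A Daubechies-2 discrete wavelet
   transform with interquartile-range outlier rejection removes spikes and
   baseline steps.
3. **Filtering and superficial removal.** A zero-phase 3rd-order
   Butterworth high-pass (0.01 Hz) removes drifts; principal-component
   removal strips the spatially global scalp/systemic signal.
4. **Hemoglobin and subject-level GLM.** The modified Beer–Lambert law
   converts OD to `dHbO2`/`dHbR` (µM); a pre-whitened robust GLM (AR-IRLS)
   with canonical-HRF block regressors estimates task-vs-rest contrasts
   per channel and chromophore, with Benjamini–Hochberg FDR across each
   channel map.
5. **Group level and ROI correlation.** A cell-means linear mixed-effects
   model (`beta ~ -1 + group:condition + (1 | subject)`, REML) produces
   per-group activation maps and `ePD - mPD` contrast maps; a two-step
   ROI-based correlation analysis relates subject-level contrast
   coefficients to clinical covariates by plain and age-partialled
   Spearman correlation.

Because clinical recordings of this kind are rarely shareable, the package
ships a synthetic-study generator with full ground truth; every
methodological claim made here is exercised by the test suite and by
`scripts/acceptance.R` on generated data.

# Conventions and key modelling decisions

## Optical density reference and CW identifiability

CW instruments measure intensity attenuation only, so concentration
*changes* are identified only up to a per-channel baseline.
`intensity_to_od()` references each trace to its **geometric** temporal
mean, `I_ref = exp(mean(log I))`.  With this convention a constant trace
maps to exactly zero, and the composition `forward projection -> OD ->
Beer–Lambert inversion` recovers the planted hemoglobin series exactly
(to ~1e-12 µM) after removing each channel's temporal mean.  An
arithmetic-mean reference would differ by a per-channel constant and break
this exact-inverse property; the constant is absorbed by the GLM's
intercept either way.

## Beer–Lambert inversion

Per channel and time point the 2×2 system

    dOD(lambda) = ln(10) [eps_HbO2(lambda) dHbO2 + eps_HbR(lambda) dHbR] d DPF(lambda)

is solved for the two chromophores.  Extinction coefficients are a
versioned literature table (`inst/extdata/extinction_coefficients.tsv`,
base-10, cm⁻¹ mM⁻¹); the differential pathlength factor defaults to 6 at
both wavelengths and the source–detector distance comes from the montage
(default 30 mm), the conventional adult values.  The inversion refuses
wavelength pairs whose extinction matrix is near singular.

## Wavelet motion correction

Each channel/wavelength trace is reflection-padded to a dyadic length and
decomposed with a periodized orthogonal Daubechies-2 filter bank (written
in the package; periodization gives exact perfect reconstruction, which
the identity limit `iqr_factor = Inf` exposes).  Detail coefficients lying
more than `iqr_factor` (default 1.5) interquartile ranges beyond their
level's quartiles are zeroed.  Three numerical guards matter in practice:

* Levels with fewer than 16 coefficients are not thresholded — with 8–16
  samples the quartile estimate is dominated by the very artifacts it is
  meant to flag, and legitimate slow physiology gets zeroed.
* On strongly coloured backgrounds a spike's mid-level coefficients can
  sit *inside* that level's fences (physiological oscillations set wide
  fences exactly where the spike's coefficients have decayed to moderate
  size).  A second pass therefore *time-gates*: an artifact is confirmed
  when outliers from at least two distinct levels align in time —
  isolated single-level flags are ordinary noise tails — and near a
  confirmed artifact time the evidence threshold drops to a quarter of
  the global fence, at every level up to the 32-sample scale (beyond
  that the artifact's `2^(-j/2)`-decaying coefficients are negligible
  while the gate window `~2^j` grows).  The local threshold is surgical
  on purpose: blanket zeroing of whole windows at the task-band levels
  measurably attenuates the block response, while away from confirmed
  events nothing changes — artifact-free traces confirm no events and
  are untouched by this pass.
* Coefficients supported in the reflection pad are never treated as
  outliers.

The smooth remnant of a corrected baseline step is drift-like and is
handled by the high-pass and PCA stages downstream.  On clean
block-design responses the correction distorts the signal by well under
5% RMS; planted 10×-SD spikes are attenuated by more than 80% at the
spike sample.

## High-pass filtering and the design matrix

The 0.01 Hz 3rd-order Butterworth is applied forward–backward
(`filtfilt`), so event timing is not shifted; the trace is demeaned first
because `filtfilt`'s edge handling is numerically poor with a large DC
offset at very low normalised cutoffs.  When the data have been high-pass
filtered, `fit_subject_glm()` applies the *same* filter to the task
regressors (not the constant column): the model of `H y` is `H X beta`,
and regressing on unfiltered `X` would bias the task coefficient downward
by the regressors' own sub-cutoff power (block designs with randomized
condition orderings have real power below 0.01 Hz).

## PCA removal of superficial components

Superficial scalp hemodynamics and systemic physiology are spatially
global, so the subject's pooled channel-by-time matrix (both wavelengths)
is decomposed by uncentered SVD and the smallest leading set of
components reaching 80% cumulative variance is subtracted.  The "smallest
set reaching the target" reading (rather than a cap) is what makes the
rank-1 limit exact: identical traces on all channels are annihilated
completely.  The price of the method is a small systematic attenuation of
focal task responses — the leading eigenvector overlaps the task's
spatial pattern in proportion to the fraction of channels active — which
the validation suite bounds at well under 10% median bias under the
generator's default conditions.  With a weak superficial component this
rule removes the task component itself; that is a property of
variance-targeted PCA cleanup in general, and the reason the generator's
default superficial amplitude dominates the eigenspectrum (see below).

## AR-IRLS subject-level GLM

Per channel and chromophore, `fit_ar_irls()` iterates

1. residuals from the current fit;
2. AR(p) estimation by Levinson–Durbin on the residual autocovariances,
   with p in [0, `round(4 fs)` ≈ 8] chosen by **BIC** — under white noise
   the selected order is 0 in ≥ 95% of runs, where AIC would overselect;
3. pre-whitening of both trace and design by the AR filter (dropping the
   first p samples);
4. Tukey-bisquare iteratively reweighted least squares (tuning constant
   4.685, MAD scale) on the whitened system, with the standard
   small-sample robustness correction on the coefficient covariance;

until the coefficients move less than 1e-4, at most 10 outer iterations
(non-convergence is flagged, not raised).  Degenerate noiseless traces
short-circuit to the exact OLS solution with zero covariance.  Residual
degrees of freedom are `n - p - rank(X)`.  Under AR(1) noise with
coefficient 0.8 the channel-wise two-sided test holds its nominal 5%
level (empirically ≈ 0.05–0.07 at recording lengths of 600+ samples,
where naive OLS rejects at ≈ 0.4); the bisquare weights additionally
downweight residual motion outliers.  Contrasts test the condition's cHRF
coefficient only; the temporal-derivative companion absorbs latency
jitter but is not tested.

The canonical HRF is the double-gamma `dgamma(t, 7, 1) - dgamma(t, 17, 1)/6`,
normalised to unit peak, peaking at 6 s.  Condition regressors are
cHRF-convolved boxcars scaled so one isolated task block elicits a
unit-peak response — the regression coefficient is therefore the peak
concentration change (µM) attributable to a block, and the generator
plants amplitudes on the same scale.

## Group level

`fit_lmem()` fits the cell-means model with a per-subject random
intercept by REML (`lme4`).  Subject-level precisions are *not* used as
weights.  Inference uses the conservative containment-style
approximation `dof = n_obs - n_cells - n_subjects + 1`; when every subject
contributes a single observation the random intercept is unidentified and
the OLS `n_obs - n_cells` applies, which makes the single-cell case reduce
exactly to the one-sample t-test.  Zero-residual-variance inputs (or
mixed-model failures) fall back to an exact cell-means OLS fit, flagged in
the result.  Contrast maps encode `ePD > mPD` as positive t and emit both
uncorrected p and BH-adjusted q, since channel-map figures in this
literature are conventionally reported uncorrected while tables are
FDR-adjusted.

## ROI-based correlation analysis

`roi_ca()` implements the two-step procedure: (1) channels with
uncorrected `p < 0.05` in the between-group contrast map, per chromophore
and condition, intersected with each ROI's membership; (2) each subject's
contrast coefficients averaged over the selected channels (all subjects
pooled); (3) Spearman correlation with each clinical variable,
pairwise-complete over missing values, plus an age-partialled Spearman
(first-order partial correlation on mid-ranks, p at `n - 3` dof).  The
uncorrected step-1 threshold follows the uncorrected-map convention and is
configurable.  No correction is applied across the ROI × variable grid
(matching how such tables are conventionally reported); a BH-adjusted
companion column is emitted for transparency.  ROI membership can come
from explicit channel lists, source–detector pairs, or a sensitivity
matrix thresholded at 20% ("collects at least 20% of the region's
signal", inclusive).

Averaging signed statistics over an ROI can cancel balanced
positive/negative channels; member counts are always reported so this is
visible.

## Group characterisation

Per clinical variable, a Shapiro–Wilk test on the pooled sample gates the
two-group comparison: equal-variance t-test when normality is not rejected
at 0.05, Mann–Whitney U otherwise.  The pooled (rather than per-group)
gate is a deliberate simplification; with 39 subjects the two gates rarely
disagree.

# The synthetic-study generator

`simulate_study()` emulates a two-group whole-head block study.  Defaults
are the study conditions; they were fixed once, on the grounds below, and
all validation statements refer to them.

* **Paradigm**: 10 trials per side, 10 s task / 20 s rest, randomized
  left/right order, 15 s lead-in; 1.9531 Hz sampling; 102 channels in ten
  ROIs (left/right SMN, VIS1, VIS2, PFC1, PFC2).  Each ROI's first half
  is the "focal" subset carrying the planted response.
* **Planted effects** (peak `dHbO2` per block, µM): contralateral SMN
  0.3 (ePD) / 0.2 (mPD); prefrontal ROIs 0.05 / 0.1 (the inverted,
  compensation-like pattern); secondary visual 0.13 / 0.05 (matching the
  ~0.08 µM printed group contrast for those areas); primary visual
  0.05 / 0.05 (a null-contrast region).  `dHbR = -0.5 dHbO2`.  A
  per-subject, per-ROI amplitude deviation (SD 0.08 µM) is shared across
  the ROI's channels and conditions.
* **Noise**: AR(1) with coefficient 0.8 (at the emitted rate) and
  marginal SD 0.08 µM — strong serial correlation that stresses the
  pre-whitening; sinusoids at 1.1 Hz (cardiac), 0.1 Hz (Mayer), 0.25 Hz
  (respiration) and 0.005 Hz (drift) with seeded random phases and
  amplitudes 0.05 / 0.04 / 0.03 / 0.03 µM.  Physiology is synthesised at
  4× the sampling rate and decimated *without* anti-aliasing, so cardiac
  power aliases into the passband exactly as in real ~2 Hz recordings.
  HbR noise is scaled by 0.5.
* **Superficial component**: one shared AR(1) time course (5 s
  correlation time, marginal SD 1.2 µM) loading positively on all
  channels (U(0.7, 1.3); HbR factor 0.4).  The amplitude is chosen so the
  scalp component dominates the eigenspectrum, as it does in raw CW
  recordings — which is precisely the regime in which removing the
  leading ~80% of variance by PCA is the correct remedy rather than a
  task-destroying one.
* **Motion artifacts**: a Poisson stream (default 0.5 events/min) of
  spikes (1–3 samples, 10× reference SD) and baseline steps (3×).  For
  multi-channel data the default event times are *shared* across channels
  with independent signs and U(0.5, 1.5) amplitude jitter — head
  movements are spatially global — while per-trace independent streams
  remain available.  Amplitudes are referenced to the stochastic
  background (AR + oscillation) SD, not the total trace SD, so artifact
  size tracks the hemodynamic scale instead of growing with the
  superficial component.
* **Clinical covariates**: per-group normal models with the published
  two-group demographics (13 ePD / 26 mPD; e.g. age 63.5 ± 6.0 vs
  71.7 ± 7.0 years), non-negative variables truncated at their floor, and
  2 / 3 missing Stroop error/time scores.  The designated target
  covariate (default UPDRS) is drawn through a Gaussian copula on the
  empirical normal scores of the subjects' target-ROI amplitudes with
  copula correlation `2 sin(pi rho / 6)`, so its population Spearman
  correlation with the amplitude equals the requested `rho` (default 0.5
  against the right secondary-visual ROI).  The coupled covariate uses
  the pooled two-group distribution.
* **Determinism**: every draw goes through a named seed substream, so
  identical `(params, seed)` reproduce the study bit for bit and adding
  subjects never perturbs existing ones.

What the generator does **not** emulate: photon transport and
channel-specific partial-volume sensitivity (ROI membership is by
construction, or by a user-supplied sensitivity matrix); spatially
correlated neural background activity; non-stationary noise; optode
decoupling episodes; condition-dependent HRF shape differences.  Passing
the validation suite therefore demonstrates the statistical machinery is
calibrated and unbiased under realistic serially-correlated, confounded,
artifact-laden conditions — not that any particular clinical effect size
will be recovered from a given real dataset.

# Validation conditions and problem sizes

The acceptance checks run at these sizes, chosen to make Monte-Carlo error
small relative to the tested tolerances: Beer–Lambert inversion on a
10-channel 5-minute noiseless recording (error < 1e-9 µM); type-I
calibration over 2000 AR(1) traces of 600 samples (band [0.03, 0.07] at
α = 0.05, naive OLS > 0.10); full-pipeline recovery on 20 subjects with
0.3 µM planted contralateral amplitude (median bias < 10%, detection at
q < 0.05 ≥ 80%); FDR false-discovery proportion over 500 mixed
null/alternative maps (≤ 0.05 + 2 MC SE) and exact agreement with a
brute-force step-up oracle on all families of ≤ 12 p-values;
group-contrast sign recovery over 50 replicates at n = 13/26 (≥ 90%) with
a null-compatible rejection level under equal amplitudes; ROI-correlation
recovery over 100 replicates at n = 39 (mean recovered ρ within 0.15 of
the planted 0.5; age-partialled within 0.05 of plain when age is
independent); spike attenuation ≥ 80% with < 5% clean-signal distortion;
and byte-identical reruns of the full 39-subject, 102-channel pipeline.

# Known limitations

* The PCA stage attenuates focal responses by a few percent even in its
  intended regime; with many simultaneously active channels or a weak
  superficial component the attenuation grows.  The variance fraction is
  configurable, and `"pca_removed"`/`"pca_explained"` attributes expose
  what was removed.
* Wavelet correction converts baseline steps into smooth drifts rather
  than removing them outright; residual step energy is handled
  statistically (high-pass, PCA, bisquare weights) rather than exactly.
* The LMEM degrees of freedom are an approximation (no Satterthwaite /
  Kenward–Roger); with 39 subjects the practical difference is small.
* The type-I level of the pre-whitened test inflates mildly (to ≈ 0.08)
  for very short traces (~300 samples), where the AR coefficients are
  estimated poorly; recordings of this paradigm are 4× longer.
* Partial Spearman correlation uses the first-order formula on mid-ranks;
  it is exact for the Gaussian-copula coupling the generator uses but is
  an approximation for general dependence structures.
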