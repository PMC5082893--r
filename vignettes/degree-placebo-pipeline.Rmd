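---
title: "Degree-count connectomes and placebo-response prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-count connectomes and placebo-response prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

`placebonet` implements a resting-state fMRI analysis chain built around one
quantity: the **nodal degree count** of a voxel-wise functional connectivity
graph. For a subject with N gray-matter voxel time series, all N(N-1)/2
Pearson correlations are computed and the graph keeps exactly
M = round(d * N(N-1)/2) edges with the largest |R| — the link density d fixes
M, so the |R| threshold is subject-specific. A node's degree is its number of
incident edges. Because any single density is arbitrary, the analysis sweeps
d = 2%, 4%, ..., 20% (ten values); edge sets are nested across the sweep, so
per-voxel degree is non-decreasing in d.

Group inference on degree maps (treatment responders vs nonresponders) uses a
voxel-wise pooled-variance two-sample t statistic, threshold-free cluster
enhancement (TFCE: the integral of e(v,h)^E * h^H dh over suprathreshold
component extents e at all heights h), and family-wise error correction by
the permutation distribution of the image-wide maximum TFCE score. The
discovery map is the **conjunction** of voxels significant with a consistent
contrast sign in at least 8 of the 10 densities; its largest cluster is the
region of interest (ROI).

Prediction then proceeds in two fixed steps:

1. **Discovery fit.** Ordinary least squares of percent analgesia
   (100 * (pre - post) / pre; responder = analgesia >= 20%, inclusive) on the
   ROI mean degree count: y = a x + b.
2. **Validation transfer.** The same a, b applied to a held-out cohort's
   pretreatment degree counts gives each subject's *predicted placebo
   response*; validation uses the correlation of predicted vs observed
   analgesia and the ROC AUC of the degree count against responder status.

For a drug-treated arm the additive decomposition

    empirical analgesia = predicted placebo + drug response + error,  error := 0

defines each subject's **drug delta** = empirical - predicted. Subjects with
empirical analgesia >= 20% but predicted placebo below a small ceiling are
*mostly-drug responders*; contrasting their whole-brain degree maps with the
remaining responders by voxel-wise exact Mann-Whitney tests, and taking the
largest connected component among voxels where the mostly-drug group ranks
uniformly highest, yields a candidate drug-predictive region, validated by
correlating its degree counts with the deltas over the whole arm.

# Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| density grid | 2–20% step 2% | fraction | ten densities; `density_grid()` |
| outcome density | 10% | fraction | density at which ROI degrees are read |
| TFCE E, H | 0.5, 2 | – | standard published defaults |
| TFCE steps | 100 | – | right-endpoint Riemann heights |
| connectivity | 26 | – | 3D neighbourhood for components |
| permutations | 500 (pipeline), 5000 (flag) | – | exhaustive when arrangements <= n_perm |
| FWE alpha | 0.05 | – | two one-sided max-null tests at alpha/2 |
| conjunction min count | 8 of 10 | densities | consistent sign required |
| responder threshold | 20 | % analgesia | inclusive (>=) |
| neutrality half-width epsilon | 10 | % analgesia | drug delta categories |
| placebo ceiling | 5 | % analgesia | mostly-drug responder selection |
| high-pass cutoff | 150 | s | DCT projection |
| smoothing FWHM | 5 | mm | edge-renormalized Gaussian |
| discarded frames | 5 | – | equilibration period |

# The synthetic cohort generator

Because the pipeline is meant to be testable without imaging data, the
package generates cohorts whose statistical structure matches what the
analysis assumes.

**Signal model.** Each 4D volume is latent factors times spatial loadings
plus i.i.d. unit-variance Gaussian noise and a baseline of 100. Gray voxels
load ±0.3 on a shared network factor with a sign-alternating spatial parity
pattern — the alternation makes the factor nearly orthogonal to the global
mean, so global-signal regression removes noise, not the planted structure,
and both correlation signs contribute edges under absolute-value
thresholding. Three local factor blocks (loading 0.9) add mid-level regional
structure; surrogate white-matter and ventricle blocks carry their own
physiological factors and feed the confound regressors. The planted **hub**
region loads base + g*pi on the shared factor (g = 0.35), where pi is the
subject's latent placebo propensity, so hub degree rises monotonically with
pi; a disjoint **drug region** does the same with an independent latent.

**Propensity distribution.** pi is an equal mixture of U(0, 0.4) and
U(1.2, 2). The dichotomy emulates the bimodal responder/nonresponder
structure of placebo-treated cohorts: on the default 12x12x12 grid
(~510 gray voxels, 300 frames at TR 2.5 s, 5 discarded) the hub degree at
10% density centres near 108 for the low component and 190 for the high one,
a ratio close to the roughly two-fold responder/nonresponder degree contrast
such studies report.

**Outcome model.** Placebo-arm percent analgesia is
a_true * hub_degree + b_true + noise with a_true = 0.65, b_true = -70,
noise sd = 10: the low-propensity mode centres at ~0% analgesia and the high
mode at ~54%, giving ~half responders at the 20% threshold and a responder
mean near the mid-50s. The drug arm adds d_true * (drug_degree - drug_deg0)
with d_true = 0.3 and drug_deg0 = 110. The reference degree matters: degree
counts have a floor (~110 here), and a drug term proportional to the raw
count would hand every drug-arm subject a uniform ~+30% offset, erasing the
distinction between drug-driven and placebo-driven responders that the
drug-region search exists to detect. Anchoring the term at the
low-propensity degree level keeps the slope in degree units while letting
low-connectivity subjects show essentially no drug effect. The no-treatment
arm is outcome noise only; the healthy arm contributes volumes only.
Behavioral covariates (three VAS baselines uniform on [4, 9] per the >= 4/10
entry criterion, WOMAC, age, gender, pain duration, BDI, PCS, medication
score) complete each record. WOMAC analgesia is 0.7 times the VAS analgesia
plus noise, mirroring the ~0.7 ratio of responder means on the two scales.

**Reproducibility.** Every subject draws from a stream derived from
(master seed, subject index), so a cohort can grow without rewriting earlier
subjects, and identical seeds give bit-identical volumes and tables.

**What the generator does not emulate.** Hemodynamic response shapes,
physiological noise spectra (cardiac/respiratory), head motion (motion
traces are generated for the confound interface but inject no artefact),
anatomical realism, and spatial autocorrelation of noise. Passing tests on
this generator therefore demonstrate the *inferential machinery* — exact
thresholding, calibrated permutation FWE, unbiased transfer of the
discovery fit — not robustness to real-scanner artefacts. Two deliberate
simplifications of the outcome side: a single outcome noise sd (10%) makes
the no-treatment arm's responder rate ~2%, lower than observational cohorts
(20–35%) where symptom fluctuation is larger; and the planted drug effect is
strong enough to be detectable at n = 19, which pushes the drug-arm
responder rate above the near-parity seen in double-blind trials.

**ROI degrees during generation** are computed through the same canonical
preprocessing + graph pipeline the analysis uses (discard 5, smooth 5 mm,
150 s high-pass, confound regression, 10% density), so the planted linear
model lives in exactly the units the analysis measures and slope recovery is
a genuine parameter-recovery check rather than a units coincidence.

# Numerical choices

- **Edge count rounding.** M = round(d N(N-1)/2) with round-half-to-even
  (base R `round`); the original rounding convention is unknowable from a
  printed density grid, so the deterministic default is declared.
- **Ties at the density cut** break by ascending node-index pair order, making
  thresholding fully deterministic.
- **Constant voxel series** are flagged as excluded nodes; they never win
  edges.
- **High-pass filter** is projection removal of the discrete-cosine basis
  functions with frequency below 1/cutoff (cutoff-matched, SPM-style) rather
  than a Gaussian-weighted running line; it is spectrally transparent and
  testable by Fourier amplitudes (>= 99% attenuation at period 2x cutoff,
  <= 1% loss at cutoff/4 on the default geometry). Documented as an
  approximation of the FEAT filter.
- **Smoothing** uses a separable, truncated (4 sigma), row-renormalized
  Gaussian: constant fields are preserved exactly and total intensity within
  1% at BOLD-like baselines.
- **Preprocessing order** is fixed: discard, smooth, filter, confound-regress,
  mask/down-sample. Published pipelines rarely state this order precisely;
  here it is declared, not inferred.
- **TFCE** integrates at right-endpoint heights h = s*dh, s = 1..steps, with
  suprathreshold membership stat >= h; negative lobes are enhanced on the
  negated map and returned signed. The implementation processes heights
  descending with an incremental union-find (components only merge), which
  is algebraically identical to per-threshold labelling and is tested
  against a naive labelling oracle to 1e-8.
- **Two-sidedness** is two one-sided max-null tests; the reported corrected
  p is min(1, 2 min(p_pos, p_neg)), so p < alpha corresponds to one-sided
  significance at alpha/2. Group inference reports both signs because both
  directions of degree difference are meaningful.
- **Permutation p-values** use the add-one estimator (1 + exceedances) /
  (n_perm + 1) in sampled mode, so p = 0 is unattainable; when the number of
  distinct group assignments is at most n_perm, all arrangements are
  enumerated and p = count/total, making small-sample p-values exact. A
  permutation seed is required, never defaulted.
- **Exact Mann-Whitney** p-values come from full enumeration of subset
  rank-sums (midranks for ties), two-sided as 2 min(P(U <= u), P(U >= u))
  capped at 1; the normal approximation is used only above 20,000
  arrangements.
- **Fisher's exact test** sums hypergeometric probabilities <= that of the
  observed table (the common two-sided convention; conventions differ, so it
  is declared). Zero-margin tables return p = 1 with a flag.
- **Percent display rounding** is half away from zero (8/17 prints as 47%).
- **Responder threshold** is inclusive (>= 20%).
- **Degenerate inputs**: zero pooled variance gives t = 0 with a flag;
  constant degree vectors give flagged undefined correlations; an empty
  conjunction yields an empty cluster table and the pipeline reports the
  downstream stages as absent rather than erroring.

# Design decisions that were genuinely open

- **Candidate drug region selection** uses the top rank statistic in the
  drug-predictive direction (degree higher in mostly-drug responders), then
  the largest connected component among tied voxels; the exact two-sided
  Mann-Whitney p is reported for the region's mean degrees. A two-sided
  minimum-p selection would simply rediscover the placebo ROI (where
  mostly-drug responders rank lowest by construction of their selection),
  which carries no new information.
- **Consistent sign across densities** is required in the conjunction; a
  voxel flipping direction across the sweep is not a coherent marker.
- **Accuracy at the ROC optimum** uses the Youden-optimal cut, declared
  because the basis of a single printed accuracy figure is otherwise
  underdetermined.
- **Neutrality half-width** epsilon defaults to 10 percentage points for the
  enhanced/neutral/diminished categories and is echoed in every report; the
  category boundary is graphical in origin and has no canonical value.
- **Mostly-drug responder ceiling** defaults to 5% predicted analgesia.
  Worth knowing: with a discovery fit at n = 17 the intercept's standard
  error is ~9 percentage points, so in a sizeable minority of replicate
  studies the fitted intercept shifts every predicted value past a fixed 5%
  ceiling and no subject qualifies — the search then cannot run. This is a
  real small-sample property of the design, not an implementation artefact;
  reports treat an empty selection as an empty result.

# Problem sizes

The package's own testing and reproduction runs use a 12x12x12 grid
(~510 gray nodes) with 300 frames for the end-to-end studies (17 discovery,
20 + 19 validation, 20 no-treatment subjects; 500 permutations per density),
and an 8x8x8 grid with 60 frames, 16 subjects and 199 permutations for the
200-replicate null calibration of the FWE procedure. These sizes give
full-rank correlation matrices and minute-scale runtimes while preserving
every structural property the inference relies on; nothing in the code is
specific to them, and `cohort_spec()`/`default_run_config()` scale to larger
grids.

# Known limitations

- Degree counts, thresholds and cluster sizes are grid-dependent; numbers
  from the desk-scale grid are not comparable to full-resolution (~29,000
  node) analyses in absolute units, only in structure.
- The generator's noise is spatially white; smoothing therefore induces the
  only spatial autocorrelation, which makes TFCE conservative relative to
  real data.
- The additive placebo/drug decomposition assumes the error term is zero for
  each subject; the estimated deltas absorb outcome noise, so their
  correlations understate the planted drug slope.
- Stepwise selection inherits the known instabilities of forward/backward
  p-value selection at small n; it is provided because it mirrors the
  clinical analysis style, not as a recommended model-building tool.
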