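# placebonet

Voxel-wise degree-count connectomes and placebo-response prediction for
resting-state fMRI, with a synthetic-cohort generator that makes the whole
chain testable end to end without imaging data.

## The problem

In chronic-pain trials a large share of the treatment-arm response is placebo
response. If a pretreatment brain marker predicts who will respond to
placebo, a validation trial can (a) forecast placebo analgesia per subject
and (b) subtract it from the empirical response of drug-treated patients to
estimate their drug-specific benefit. This package implements that analysis
for the marker class used in the osteoarthritis placebo literature:
**nodal degree counts** of voxel-wise functional connectivity graphs
thresholded at fixed link densities.

It is aimed at neuroimaging methodologists and biostatisticians who want the
full chain — graph construction, permutation/TFCE group inference,
discovery-to-validation transfer, additive placebo/drug decomposition — as
tested, reusable R functions rather than a one-off scripting pipeline.

## The model

For N gray-matter voxel time series, the graph at link density d keeps the
M = round(d·N(N−1)/2) edges with largest |Pearson R| (the |R| threshold is
subject-specific; positive and negative correlations both count). Degree
maps are computed for d = 2%…20% in 2% steps. Responders (≥ 20% decrease in
VAS pain from baseline, inclusive) are contrasted with nonresponders by
voxel-wise t statistics, threshold-free cluster enhancement
(TFCE(v) = Σ_h e(v,h)^E · h^H · Δh, E = 0.5, H = 2), and max-statistic
permutation FWE correction; the discovery region is the conjunction of
voxels significant with consistent sign in ≥ 8 of the 10 densities.

The discovery cohort then fixes a linear model

    y = a·x + b        (y = % analgesia, x = ROI mean degree count)

which is applied unchanged to a validation cohort (`y2 = a·x2 + b`). For
drug-arm subjects the additive model

    empirical = predicted placebo + drug response + error,   error ≡ 0

defines a per-subject drug delta; "mostly-drug responders" (≥ 20% empirical
analgesia, predicted placebo < 5%) are contrasted against the other
responders by exact Mann-Whitney tests to search for a drug-predictive
region.

## Worked example

```r
library(placebonet)

report <- run_pipeline(default_run_config(seed = 7))
report
#> <run_report>
#>   discovery: 11/17 responders; conjunction 27 voxels in 1 cluster(s)
#>   model: y = 0.679 x -75.3 (R2 0.92)
#>   validation: prediction r = 0.935 (p = 1.63e-09), placebo AUC = 1.000
#>   drug arm: enhanced=14, neutral=2, diminished=3
```

Reading this: the simulated discovery cohort (17 placebo-treated subjects)
had 11 responders; the cross-density conjunction found one 27-voxel cluster
— exactly the planted hub region; the discovery fit estimated a slope of
0.679 %/degree against a planted 0.65 (inside its 95% CI); carried to the
held-out validation placebo arm, predicted analgesia correlated 0.94 with
observed and the degree count separated future responders from
nonresponders with AUC 1.0; the drug-arm decomposition categorized 14/2/3
subjects as drug-enhanced/neutral/diminished under the default ±10-point
band.

Worked examples on printed-style numbers:

```r
fisher_exact_2x2(10, 10, 8, 11)$p          # responder table 10/20 vs 8/19
#> [1] 0.7511863
mann_whitney_exact(c(201, 188), c(80, 95, 102, 110, 121, 135))$p
#> [1] 0.07142857                            # 2-vs-6 complete separation, 2/28
classify_responders(c(rep(40, 8), rep(2, 9)), 20)$percent
#> [1] 47                                    # 8/17
```

A thin command-line wrapper lives at `inst/cli/placebonet.R`
(`simulate`, `degree`, `run-all` subcommands over the same functions).

## Layout

- `R/synthdata.R` — cohort specification and the latent-factor volume /
  cohort generator
- `R/preprocess.R` — frame discarding, Gaussian smoothing, DCT high-pass,
  confound regression, masking/down-sampling
- `R/connectome.R` — correlation matrices, fixed-density thresholding,
  degree sweeps
- `R/groupinf.R` — t maps, TFCE, permutation FWE, conjunction, cluster
  reports (compiled kernels in `src/tfce.cpp`)
- `R/outcomes.R` — analgesia, responder classification, discovery fit,
  ROC/AUC and ROC comparison, Fisher exact, stepwise regression
- `R/placebo.R` — additive decomposition, mostly-drug responder selection,
  drug-region search and validation
- `R/pipeline.R` — `run_pipeline()` end-to-end driver with manifest
- `vignettes/degree-placebo-pipeline.Rmd` — the methods vignette: model,
  generator, numerical choices, limitations
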