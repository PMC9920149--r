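# gazeou

Model-based eye-movement biometrics in R: who is looking, inferred from
*how* they look.

Eye movements during free viewing alternate between **fixations** (gaze
held on a patch of the stimulus, drifting locally) and **saccades** (rapid
relocations to a new patch). `gazeou` models both regimes with the same
law — a two-dimensional Ornstein-Uhlenbeck (O-U) process pulled towards an
attractor μ (the fixation centre, or the saccade landing point):

    dx(t) = B (μ − x(t)) dt + Γ dW(t)

with a symmetric positive-definite drift matrix **B** (pull strength,
1/sample) and diffusion amplitude **Γ** (px/√sample). The conditional
transition density is Gaussian in closed form,

    x(t′) | x(t) ~ N( μ + e^{−Bδt} (x(t) − μ),  Ψ ),
    Ψ = D − e^{−Bδt} D e^{−Bᵀδt},   B D + D Bᵀ = Γ²,

so per-event likelihoods are exact. For every parsed event the package
infers the posterior over (B, Γ) with SPD-respecting priors (LKJ
correlations + half-normal scales) by Laplace or mean-field variational
approximation, summarises each of the six free matrix entries by its
posterior mean and highest-density-interval width, and stacks them into a
12-dimensional event descriptor. Per-kind one-vs-rest SVMs on those
descriptors, fused at the score level across a trajectory's fixations and
saccades, identify the subject; evaluation reports accuracy, F1, EER,
AUC, the confusion matrix and the cumulative match score under
scan-path-level cross-validation. A composite switching O-U simulator
generates labelled multi-subject cohorts so every stage is testable
against known ground truth.

Audience: researchers in eye-movement analysis, behavioural biometrics and
oculomotor modelling who want an interpretable, feature-selection-free
alternative to hand-crafted gaze statistics.

## Worked example

```r
library(gazeou)

# a labelled synthetic cohort: 3 subjects, 4 scan paths each, 900 samples
co <- generate_cohort(cohort_spec(n_subjects = 3, n_scanpaths = 4,
                                  length = 900, separation = 2, seed = 11))
tr <- co$scanpaths[[1]]$trajectory
tr
#> gaze trajectory s01/k01: 900 samples @ 1000 Hz

# parse into alternating events and inspect the first two
evs <- segment_velocity(tr)
evs[[1]]; evs[[2]]
#> fixation [0, 335)  mu = (878.9, 389.3)
#> saccade [335, 361)  mu = (489.7, 341.6)

# per-event posterior over (B, Gamma)
ps <- infer_event_posterior(evs[[1]])
as.data.frame(ps)
#>   component     mean hdi_lower hdi_upper
#> 1      b_ii  0.02492   0.00932    0.0423
#> 2      b_ij -0.00406  -0.01941    0.0105
#> 3      b_jj  0.05739   0.03422    0.0865
#> 4      g_ii  0.41034   0.37920    0.4389
#> 5      g_ij  0.16434   0.14476    0.1856
#> 6      g_jj  0.29153   0.27183    0.3136
```

The fixation's drift is weak (`b_ii` ≈ 0.025/sample: gaze relaxes towards
the fixation centre on a ~40-sample timescale) and its diffusion quiet
(`g_ii` ≈ 0.41 px/√sample); the positive `g_ij` says this subject's
fixational jitter is correlated across the horizontal and vertical axes.
The HDI bounds become the uncertainty half of the descriptor:

```r
event_descriptor(ps, kind = "fixation", "s01", "k01")
#> b_ii_avg b_ii_hdi b_ij_avg b_ij_hdi b_jj_avg b_jj_hdi g_ii_avg g_ii_hdi
#>    0.025    0.033   -0.004    0.030    0.057    0.052    0.410    0.060
#> g_ij_avg g_ij_hdi g_jj_avg g_jj_hdi
#>    0.164    0.041    0.292    0.042

# featurise every event, then cross-validated identification
feats <- build_features(unlist(lapply(co$scanpaths, function(s)
  segment_velocity(s$trajectory)), recursive = FALSE))
crossvalidate(feats, k = 4, seed = 1)
#> identification metrics (12 probes): accuracy 1.000  F1 1.000  EER 0.000  AUC 1.000
#>   CMS: 1.00 1.00 1.00
```

On this well-separated synthetic cohort every probe scan path is assigned
to the right subject (chance would be 1/3); EER 0 and AUC 1 say the fused
scores separate genuine from impostor comparisons completely.

The same flow is available from a shell:

```sh
Rscript inst/cli/gazeou.R all --seed 7 --out-dir run1
```

## Layout

- `R/` — gaze I/O and config, segmentation, exact O-U core, simulator,
  Bayesian inference, descriptors, identification, evaluation, pipeline.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
- `vignettes/gaze-ou-biometrics.Rmd` — the model, priors, design
  decisions, synthetic study conditions and limitations.
- `inst/cli/gazeou.R` — command-line pipeline driver.
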