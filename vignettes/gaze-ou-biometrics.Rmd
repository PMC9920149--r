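---
title: "Modelling gaze dynamics with switching Ornstein-Uhlenbeck processes"
author: "gazeou authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gaze dynamics with switching Ornstein-Uhlenbeck processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeou)
```

## The model

Free-viewing eye movements alternate between two functional regimes:
*fixations*, where gaze wanders locally around a region of interest, and
*saccades*, rapid relocations towards a new target. `gazeou` treats both as
realisations of the same stochastic law — a two-dimensional
Ornstein-Uhlenbeck (O-U) diffusion

$$dx(t) = B\,(\mu - x(t))\,dt + \Gamma\,dW(t),$$

where $x(t)$ is the on-screen gaze position (px), $\mu$ is the *attractor*
(the fixation centre or the saccade landing point), $B$ is a symmetric
positive-definite *drift* matrix (1/sample) scaling the pull towards
$\mu$, and $\Gamma$ is the symmetric positive-definite *diffusion
amplitude* (px/$\sqrt{\text{sample}}$) of the driving white noise. The two
regimes differ only in their $(B, \Gamma)$: fixations have weak drift and
quiet diffusion, saccades strong drift. A scan path is generated by a
switching version of the same equation whose state variable alternates
between the two parameter sets.

Three exact consequences of linear-Gaussian structure carry the whole
package:

* **Transition density.** Conditional on $x(t)$, the position $\delta t$
  later is Gaussian with mean $\mu + e^{-B\delta t}(x(t)-\mu)$ and
  covariance $\Psi = D - e^{-B\delta t} D e^{-B^\top\delta t}$.
* **Stationary covariance.** $D$ solves the continuous Lyapunov equation
  $BD + DB^\top = \Gamma^2$. When $B$ and $\Gamma$ commute this is the
  familiar scalar form $D = \Gamma^2 (2B)^{-1}$; the Lyapunov route is what
  the code uses because it stays exact for non-commuting matrices. We read
  $\Gamma$ as a noise *amplitude*, so the instantaneous noise covariance
  is $\Gamma^2$ — the only reading under which the scalar reduction and
  the general matrix case agree.
* **Likelihood.** With the unit time step used throughout (one sample; the
  device rate only enters the documentation of units), an event slice
  $x_e = [x_m, \dots, x_q]$ has a Markov-factorised Gaussian likelihood
  with constant propagator $A = e^{-B}$ and step covariance $\Psi$.

Because $B$ and $\Gamma$ are symmetric, all matrix exponentials and the
Lyapunov solve are done spectrally (eigendecomposition), which is exact —
no approximate matrix-exponential algorithm is involved. $\Psi$ is
symmetrised and eigenvalue-clipped at zero; inside the likelihood a
configurable jitter (default $10^{-9}$ px$^2$) is added to the diagonal
when $\Psi$ is nearly singular, which stabilises short, low-noise
fixations.

## From raw gaze to events

The estimation pipeline first parses a raw trajectory into events.
`segment_velocity()` is a deliberately plain I-VT-style parser: smoothed
speed (centred differences, 5-sample moving average) above a threshold
marks saccadic samples, sub-minimum runs are absorbed into their
neighbours, and the output strictly alternates kinds. Defaults — threshold
0.8 px/sample, minimum fixation 40 samples, minimum saccade 10 samples —
are typical magnitudes for 1000-Hz screen recordings and are configuration,
not constants. The attractor is then fixed by rule, never inferred: the
centroid of a fixation's samples, the final sample of a saccade.

The parser is plumbing, not the point. Event classification only provides
a coarse exploration/exploitation partition; the inference works from the
raw samples inside each span, which makes the downstream descriptors
robust to the exact parser. Labels from an external classifier can be
supplied through `import_external_segmentation()`, which honours maximal
label runs and drops `other` samples (smooth pursuit, post-saccadic
oscillations).

Events with fewer than `min_transitions` (default 5) transitions are
flagged and excluded from inference rather than deleted, and the pipeline
logs how many were excluded.

## Per-event Bayesian inference

For each event the posterior over $(B_e, \Gamma_e)$ is approximated with
the attractor $\mu_e$ held fixed. Both matrices are parameterised as
$S\,C\,S$ — positive scales $S$ and a correlation matrix $C$ — mapped to an
unconstrained 6-vector (log-scales, atanh-correlations), so every iterate
is symmetric positive-definite by construction. Priors complete the LKJ
correlation prior with half-normal scale priors:

| parameter | prior | default | units |
|---|---|---|---|
| scales of $B$ | half-normal | sd 1.0 | $1/\sqrt{\text{sample}}$ |
| scales of $\Gamma$ | half-normal | sd 5.0 | px$^{1/2}$/sample$^{1/4}$ |
| correlations | LKJ | $\eta = 2$ | — |
| HDI mass | — | 0.94 | — |

These are weakly informative at the pixel/sample scale of the data. The
HDI mass default follows the common convention of modern Bayesian
summaries; it is configurable.

Two approximation routes share one contract:

* `map_laplace` (default): BFGS maximisation of the log posterior from a
  moment-matched start (per-dimension lag-1 autoregression), then draws
  from the Gaussian curvature approximation at the mode. Deterministic
  given a seed and roughly 0.1–0.3 s per event, which is what makes
  desk-scale cohorts and the test suite practical.
* `vi`: mean-field Gaussian variational inference in the same
  unconstrained space, maximising the reparameterised evidence bound with
  Adam (finite-difference gradients of the log posterior; single-sample
  estimator; early stopping on a smoothed-ELBO patience window). This
  mirrors ADVI-style inference and is cross-checked against the Laplace
  route in the tests; iteration count, learning rate and draw count are
  configuration, not claims.

Both return `n_draws` (default 1000) draws transformed back to the six
free entries, summarised by the sample mean and the highest density
interval — the narrowest contiguous interval of sorted draws holding the
configured mass. Non-convergence (optimiser failure, non-PD curvature
needing a ridge, non-finite ELBO) sets a diagnostic flag and warns rather
than failing silently.

Calibration is tested by a reduced simulation-based-calibration loop:
parameters drawn from the prior, events of 800 samples simulated and
re-inferred, and per-component 94% HDI coverage checked; event length 800
is the package's choice of a regime where the Laplace asymptotics are
expected to be adequate (coverage degrades gracefully for much shorter
events, which is why very short events are excluded from inference).

## The descriptor and identification

Each event is summarised by the fixed-order 12-vector
$$v_e = [B_{ii}^{avg}, B_{ii}^{hdi}, B_{ij}^{avg}, B_{ij}^{hdi},
        B_{jj}^{avg}, B_{jj}^{hdi},
        \Gamma_{ii}^{avg}, \Gamma_{ii}^{hdi}, \Gamma_{ij}^{avg},
        \Gamma_{ij}^{hdi}, \Gamma_{jj}^{avg}, \Gamma_{jj}^{hdi}],$$
interleaving each posterior mean with its uncertainty. The `hdi` entries
are interval *widths*: the descriptor allots a single slot per component
and width is the natural scalar uncertainty. Scan-path descriptors average
the event vectors within each kind and concatenate (fixation block first,
24 values); subject summaries average a subject's scan-path descriptors.
When a scan path lacks one kind entirely (possible for short recordings
after the minimum-length filter), that block is a missing-value sentinel
with a zero count, and averages renormalise over the blocks present.

Identification trains, per event kind, one margin classifier per enrolled
subject (one-vs-rest SVMs; `e1071`/libsvm behind the module surface).
Features are z-scored with statistics fitted on training data only — the
HDI widths and means differ by orders of magnitude, and fitting the
standardiser inside each training fold avoids leakage. Kernel choices are
unclaimed territory: the default is a radial-basis kernel with
regularisation constant 1.0 and the median-distance heuristic for the
kernel width, all configurable. Raw margins (no calibration) are used, per
the linear form of the decision function.

A trajectory is identified by score-level fusion: the decision vectors of
its fixation events are averaged, likewise its saccade events, the two
averages are summed and the argmax over classes is the predicted identity.
An absent kind contributes a zero vector — neutral under additive fusion.
Ties break by class-list order.

## Evaluation protocol

`crossvalidate()` splits at the scan-path level (events of one trajectory
are statistically dependent; splitting them across folds would leak
identity), stratified by subject so every subject appears in every
training split; a subject with fewer scan paths than folds is an error
rather than a silent imbalance. Metrics: accuracy; macro-averaged F1
(balanced synthetic cohorts make macro and micro nearly identical); ROC,
AUC and EER from micro-averaged one-vs-rest pooling of (probe, class)
scores, with the EER located by linear interpolation at the
FAR $=$ FRR crossing; the confusion matrix; and the cumulative match
score curve. The EER implementation is verified against a brute-force
threshold search, and the AUC against an independent ROC library, in the
test suite.

The correlation analyses quantify why identification works: the ensemble
of correlations between scan-path descriptors of the *same* subject
(intra) should be tight and high, the ensemble across *different* subjects
(inter) wide. Both ensembles get Gaussian-kernel density estimates with
the standard reference bandwidth rule, and pairs involving a zero-variance
vector are excluded with a log entry rather than propagating `NaN`.

## The synthetic cohort generator

There is no public, redistributable raw-gaze corpus small enough to ship,
so every stage is exercised against the package's own generative model —
which is also the honest test: the inference should recover what the
simulator planted. `simulate_scanpath()` alternates fixations and saccades
from the switching O-U model by *exact* transition sampling (no Euler
discretisation error), starting with a fixation at a uniform on-screen
point; each saccade is pulled towards a fresh uniform target (50-px
screen inset) and each fixation's attractor is the preceding saccade's
landing point, so trajectories are continuous. Trajectories are not
clipped at the screen edge — clipping would distort the O-U statistics.

Study conditions, chosen once to echo a typical 1000-Hz, 2-second
free-viewing recording setup on a 1024 x 768 screen:

* hyper-means $B_{fix} = \mathrm{diag}(0.03)$,
  $\Gamma_{fix} = \mathrm{diag}(0.4)$, $B_{sac} = \mathrm{diag}(0.5)$,
  $\Gamma_{sac} = \mathrm{diag}(3)$ — fixational excursions of a few px,
  saccades that land within a few px of their target in 20–60 samples;
* fixation durations log-normal (mean 250, sd 80 samples), saccade
  durations uniform 20–60 samples;
* a `separation` knob scaling between-subject spread: subject-level
  scales are jittered log-normally (log-sd $0.35 \times$ separation) and
  correlations on the atanh scale (sd $0.3 \times$ separation), so
  separation 0 collapses all subjects onto the hyper-means.

Subject draws are rejection-sampled under a *regime-contrast guard*
(fixation diffusion diagonal at most 1.2, fixation drift at most 0.3,
saccade drift at least 0.15, saccade diffusion at least 0.5): without it,
large separations can draw "fixations" noisier than saccades, and the
generated event labels would stop meaning anything a functional event
definition could recover. The guard keeps the separation knob monotone
while preserving the semantics of the two regimes.

What passing tests on this cohort do **not** show: real eye-tracking data
carry measurement noise, blinks, smooth pursuit, post-saccadic
oscillations, saliency-driven (not uniform) target selection, and
main-sequence kinematics that the generator does not emulate. Synthetic
results demonstrate the internal consistency of the method — segmentation
recovers planted boundaries, inference recovers planted parameters,
classification recovers planted identities — not field performance.

## Numerical choices and problem sizes

Tolerances and tie-breaks that matter: $\Psi$ eigenvalue clipping at 0
(tolerance $10^{-12}$ relative); likelihood jitter $10^{-9}$ px$^2$ when
$\Psi$ is nearly singular; optimiser relative tolerance $10^{-10}$ with
at most 500 BFGS iterations; a Cholesky ridge escalating from $10^{-6}$
when the curvature matrix is not positive-definite (flagged); argmax ties
broken by class order; degenerate (zero-variance) correlation pairs
excluded with a message.

The shipped tests and the acceptance script run at desk scale by design:
cohorts of 5 subjects x 12 scan paths of 1100 samples (roughly 360
events), 20-event parameter-recovery batches at 1000 samples per event,
and 20,000-draw Monte-Carlo checks — sizes at which the fast Laplace mode
keeps a full end-to-end run around a minute while leaving every
statistical property testable. The permutation null control averages five
label shuffles because a single shuffle's AUC over 60 probes still has
about $\pm 0.08$ sampling noise.

## Known limitations

* `map_laplace` is a Gaussian approximation in the unconstrained space;
  for very short events its HDIs can undercover, which is why events with
  fewer than 5 transitions are excluded and calibration is only claimed
  at the tested event lengths.
* The variational route uses finite-difference gradients — fine for a
  6-parameter model, not a template for higher-dimensional extensions.
* Fusion assumes raw SVM margins are comparable across the two per-kind
  models; no score calibration is applied.
* The velocity parser has no notion of smooth pursuit; dynamic stimuli
  need external labels through the import adapter.
* Off-diagonal (correlation) entries of $B$ are weakly identified in
  short, quiet fixations; their posterior means shrink towards the prior
  — visible in the recovery tests as larger relative (but small absolute)
  errors.
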