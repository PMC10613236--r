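---
title: "Functional network motifs in multi-region recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional network motifs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(motifnet)
```

# Scope

motifnet analyzes trial-structured, multi-region deconvolved calcium
recordings of a two-alternative delayed-response task (1 s tactile
stimulus, 2 s delay, go cue, response window), and provides a synthetic
session generator with planted ground truth so that every analysis stage
can be validated by recovery rather than by eye. This vignette documents
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic worlds do and do not establish.

# Session model and epochs

A session is a nonnegative activity matrix (neurons x frames at 9.35 Hz by
default), per-neuron region labels and stable ids, a learning-stage tag and
a trial table. Frames are 0-based; epochs are half-open `[start, end)`
windows anchored at the stimulus onset or the go cue, converted to frames
by truncation toward zero. Truncation (not floor) is deliberate: the
pre-action epoch `[-1, 0)` s at 9.35 Hz must span the 9 frames before the
cue, and `floor(-9.35) = -10` would make negative offsets one frame wider
than positive ones. The default epoch registry: stimulus `[0,1)` s and
delay `[1,3)` s from stimulus onset, pre-action `[-1,0)` s from the go cue,
ITI baseline `[-1,0)` s and spontaneous ITI `[-2,0)` s from stimulus onset.

The inclusion filter keeps neurons whose whole-session z-scored activity
exceeds 10 at least once in every 10-minute window. Windows are disjoint
(the convention when a publication says "once every 10 minutes" without
further detail); a trailing partial window merges into the last full one so
a 2-frame remainder cannot disqualify a neuron, and z-scores use
whole-session moments, which is both simpler and stricter than
window-local scaling.

# Synthetic sessions: the stated world

`generate_session()` draws activity from the same family the encoding model
fits: a log-link point process with per-frame Poisson draws,

    rate_i(t) = exp( b0_i + task kernels + sum_j w_ij * min(a_j(t - lag_ij), 1)
                     + movement gain * speed(t) + noise ),

with planted directed coupling at lags 1-2 frames (~107/214 ms at 9.35 Hz).
Key choices:

* **Coupling acts on event occurrence** (source activity clipped at 1).
  Coupling on raw counts lets a single burst multiply through the graph and
  saturate the network at the rate cap; occurrence coupling keeps the
  cascade subcritical while preserving per-edge effect size.
* **Mixed-sign weights** (55% excitatory by default). A purely excitatory
  graph at the naive-stage density (0.30) is supercritical at any useful
  weight; near-balanced signs keep dense stages stable without weakening
  individual couplings, and are the physiologically expected situation.
* **Stability guard.** The generator refuses configurations whose
  rate-scaled coupling matrix (first-order branching matrix `rate_i w_ij`,
  both lags) has spectral radius at or above 0.95. The radius of the raw
  log-scale weight matrix does not govern runaway in a log-link cascade, so
  the guard is applied on the branching matrix; a log-rate cap (rate 5)
  remains as a backstop.
* **Enrichment is planted exactly.** A tuned target draws each incoming
  edge from same-tuned sources with probability `enrichment_level` and from
  differently-tuned sources otherwise, so the realized same-tuning fraction
  is the configured level in expectation.
* **Stage defaults** follow the learning trajectory the analyses are meant
  to recover: planted densities 0.30/0.18/0.10, enrichment 0.5/0.6/0.75,
  tuning SNR 0.4/0.7/1.0 and behavioral error rates 0.45/0.30/0.15 for
  naive/intermediate/expert (expert corresponds to ~85% correct). Later
  stages keep a configured fraction (default 0.32) of the previous stage's
  edges; fresh edges avoid eliminated pairs so the planted
  retained/eliminated split is exact. Retention is quota-based: the kept
  subset preferentially contains same-tuned couplings (quota = the new
  stage's enrichment level), because uniform retention would mix the old
  stage's enrichment into the new one and the configured trajectory would
  never be realized — and because selective survival of like-tuned
  couplings is precisely the biological phenomenon the enrichment index
  is meant to detect.
* **Error trials** flip the choice with probability `choice_noise`, and
  choice kernels follow the *choice*, so stimulus and choice decoding
  dissociate on error trials as in the task.

Movement is generated at 60 Hz in the tracking-export dialect (bodypart,
frame, x, y, likelihood): per-trial baseline posture, a response-locked
reach blending a shared per-side template (weight `stereotypy`) with
trial-unique smooth noise, plus configured dropout (likelihood < 0.95) and
isolated outliers recorded in a ground-truth attribute.

What the generator does **not** emulate: biophysical calcium dynamics and
imaging noise, across-hemisphere structure, slow drift, and non-Poisson
dispersion. A green recovery test therefore establishes that the estimators
work when the generative family matches their assumptions — not that they
are robust to deconvolution artifacts.

# Movement cleaning and stereotypy

Cleaning applies, in order: (1) linear interpolation across points with
likelihood below 0.95 between the nearest confident neighbors; (2)
replacement of points deviating more than 3 unscaled MADs within a centered
5-frame window by the previous cleaned value (the next valid value for the
first frame); (3) a centered 3-frame moving average. The MAD carries no
1.4826 consistency factor and the window is centered — both conventions
chosen and documented because the source methods name the rule but not the
scale or alignment. Stereotypy correlates baseline-subtracted epoch
trajectories (x then y, concatenated in that fixed order) across same-type
trial pairs and reports the full set and median; zero-variance
trajectories are excluded with a count.

# Coding directions

The choice (stimulus) axis is the unit-norm vector of per-neuron activity
differences between right and left choice (stimulus) trials averaged over
the pre-action (stimulus) epoch; right-preferring neurons get positive
weights. Incorrect trials are included in the choice grouping — the axis
follows the lick direction, not the instruction. Gram-Schmidt
orthogonalization keeps the choice axis fixed and removes its projection
from the stimulus axis (that order), erroring when the residual norm falls
below 1e-12. Projections are baseline-subtracted per condition using the
trial-averaged ITI-epoch projection. Regions under 20 neurons and sessions
under 5 trials per side are excluded by default. Orthogonalization is
applied by default and can be disabled by simply not calling
`orthogonalize_axes()`; published results in this family are reported as
robust either way.

# Encoding model

Each neuron is fit independently by a Poisson elastic-net GLM on z-scored
predictors: per-side stimulus (3 raised cosines over 1 s), delay (5 over
1.5 s from stimulus offset), response (5 over 1.5 s starting 0.75 s before
the delay ends, split by lick side), reward (3 over 1 s), per-forelimb
movement speed (3 bases), and every other neuron's activity at lags 1 and
2 frames. Raised cosines are half-overlapping with evenly spaced peaks and
unit peak value; their sum is constant away from the span edges.

Numerical choices:

* continuous nonnegative deconvolved activity enters the Poisson
  likelihood directly (quasi-likelihood reading);
* the 70/30 train/test split is contiguous in time, as are the five CV
  fold blocks — interleaved splits would leak autocorrelated frames;
* alpha = 0.95, a 100-value lambda path, lambda selected at minimum mean
  CV deviance (a 1-SE rule is available);
* the intercept is unpenalized; an intercept-only design has the closed
  form `b0 = log(mean(y))`;
* pseudo-explained variance is `1 - D(model)/D(null)` with the Poisson
  deviance and the null model at the mean of the evaluated frames; the
  convention `y log(y/mu) = 0` at `y = 0` applies.

Predictor-group significance zeroes the group's columns with coefficients
fixed (no refit by default — this matches the reconstruction decomposition
`exp(X_task b_task + X_cpl b_cpl + b0)` exactly). The null rotates the
group's fitted contribution circularly in 2-s blocks (random
block-quantized offsets, not aligned to trial boundaries) and recomputes
the drop against the same reduced model; one-tailed add-one p-values are
BH-FDR corrected across groups within the neuron. Coupling is tested per
(source, lag); an edge exists when either lag survives. Two practical
notes: groups with all-zero coefficients have a drop of exactly 0 and are
never significant, and individual negative drops are legal (the test is
one-tailed). The rotation null runs in chunks with sequential early
stopping — once 25 exceedances accumulate the p-value cannot reach any
reasonable FDR threshold, so remaining rotations are skipped and the
add-one p uses the rotations actually drawn; this is conservative and cuts
the per-neuron cost several-fold.

# Motif indices, retained/eliminated coupling and in-silico ablation

The convergence index of a target neuron is its significant in-degree from
a source region divided by the number of candidate sources (neurons, not
lag terms; the target is excluded from its own region's candidates). The
enrichment index is the same-tuned fraction of its significant incoming
couplings, where "same-tuned" means same variable and same preferred side
under the Wilcoxon classifier; neurons that are untuned or have no
incoming couplings are undefined and excluded with counts. The
random-coupling null redraws each target's in-edges uniformly from its
candidates, preserving in-degree.

Retained/eliminated partitions are exact set arithmetic on (source,
target) pairs between two stages of matched cells; equal-sized subsamples
(the smaller count) drive the paired coupling-only reconstructions.

Selective ablation removes, per target neuron, all significant couplings
from the probed source region (targeted) or an equal count drawn at random
from the other regions (control); the coupling-only reconstruction of the
population is projected on the observed-activity choice axis,
baseline-subtracted at stimulus offset, normalized by the trace SD, and
averaged over iterations. The scrambled-ITI control keeps the couplings
but replaces the ablated predictors' pre-action values with resampled
ITI values of the same column.

# Reduced-rank regression

The rank-r fit projects the OLS solution onto the top right-singular
structure of the fitted values; at full rank it equals OLS. Predictive
performance is cross-validated fraction of variance explained over
contiguous folds (10 by default) — the validation scheme is a package
choice since the source methods do not state one. The
correlation-matching control removes neurons whose mean pairwise
spontaneous-ITI correlation falls below 0.0274 and averages performance
over 20 draws of 20 source and 20 target neurons; trial frames
(stimulus onset to go cue) are used, with the full session available by
calling `fit_rrr()` directly.

# FORCE-trained attractor network

The rate network integrates `tau dx/dt = -x + J r + W_s I_s + W_c I_c +
noise` with tau = 10 ms, dt = 1 ms, sigmoidal transfer (beta = 0.8,
theta = 3), `J ~ N(0, g/sqrt(n))`, `W_s ~ N(0,1)`, `W_c ~ N(0,0.1)`,
state noise SD 0.15 drawn each step. Training is recursive least squares
on the full recurrent matrix at every 1-ms step with a single
network-wide inverse-correlation matrix `P` (initialized at `0.01 I`,
learning rate 0.05), alternating right/left episodes with the right-trial
stimulus peak redrawn from N(1, 0.1); targets are inverse-sigmoid
transformed, 10x upsampled, boxcar-smoothed currents, held
piecewise-constant between samples.

One initialization choice matters and is documented: each training episode
starts the membrane current at the episode's first target sample (and
simulation at the two conditions' mean first sample). Starting from x = 0
visits a degenerate corner of state space where every unit's rate is
nearly identical and tiny, so those samples enter the least-squares state
permanently and poison the fit; empirically this single choice separates
converging from non-converging training.

The trained-network analysis of this architecture has a structural
subtlety worth recording. With every unit clamped to a target, a fixed
point at current `x` is linearly self-destabilizing when
`beta * x * (1 - r(x)) > 1` — a band around theta (roughly x in [2, 4.2]
at the default transfer). Synthetic targets must therefore either keep
their operating points out of that band (the `"driven"` style:
heterogeneous baselines below ~1.5 or in ~4.5-5.8, with stimulus-locked
bumps; trackable to normalized MSE well under 1%) or exploit it
deliberately (the `"attractor"` style: double wells straddling theta so
the separatrix sits at maximum slope). One target family cannot be both
precisely trackable and bistable at desk scale; the package's convergence
checks use the driven style and the perturbation/ablation assays use the
attractor style. Trained attractor models are screened like the source
methods screen them: a mean + SD MSE filter (`mse_filter()`; the wording
"MSEs more than mean + SD were analyzed" contradicts its stated purpose,
so the implementation retains low-MSE models and flags the reading) and a
reference-separation check (`decision_switch_fraction()` errors when the
unperturbed right/left end values do not separate).

The distractor is a constant-amplitude 500-ms pulse through the stimulus
channel (`W_s`), per-trial amplitude ~ N(mean, 0.025); the waveform and
entry route are package choices where the source specifies only timing and
amplitude. External-connection ablation zeroes a random fraction of both
principal-external blocks of `J`, independently per block, with an option
to restrict to the external-to-principal block.

A candid limitation: in the desk-scale attractor world, the engagement
threshold for switching sits near distractor amplitudes of ~0.7-1.0
(relative to the trained stimulus peak of 1.0), well above the probed
0.25-0.35 range, so amplitude dose-dependence in that range is weak; the
acceptance suite tests it with paired common-random-number trials and
reports honestly. The full-scale (807 + 128 unit) profile is available via
`pipeline_config(rnn = "paper")`.

# Statistics conventions

All resampling tests use add-one (pseudo-count) p-values so p = 0 is
impossible; AUCs use midrank tie handling (deconvolved data are full of
zeros); one-tailed directions follow the claim under test (increases with
learning). BH-FDR is the standard step-up rule. All thresholds (0.95
likelihood, 3 MAD, z > 10, p < 0.05, P < 1e-4, q = 0.05, 0.0274, 40
trials, 20 neurons, 1000 shuffles, 100 iterations, 128 external units,
500 epochs) are configuration defaults, never hard-coded.

# Seeds and determinism

Every stochastic stage takes an explicit seed; `derive_seed()` hashes a
global seed with a stage name (staying below 2^31) so pipeline stages are
decoupled but jointly reproducible. Identical-seed pipeline reruns
reproduce the JSON report to the last digit.

# Known limitations

* The coupling GLM identifies lagged statistical dependence, not causal
  connectivity; common input at sub-lag timescales masquerades as
  coupling, which is why the correlation-graph control exists.
* Significance power at small sample sizes is limited by the add-one floor
  `1/(n_shuffles + 1)` interacting with FDR thresholds; at the default
  1000 shuffles the floor is well below `q/m` for realistic group counts,
  but reduced-shuffle runs lose exactly the marginal edges first.
* The desk-scale RNN worlds establish algorithmic correctness and
  qualitative attractor behavior; quantitative robustness values at the
  published scale require the full-scale profile and hours of compute.
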