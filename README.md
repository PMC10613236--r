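# motifnet

Functional network motifs in multi-region neural recordings of a
delayed-response task.

## The problem

During learning of a two-alternative delayed-response task (a 1 s tactile
stimulus, a 2 s delay, a go cue, a lick response), cortical population
activity reorganizes: choice information concentrates along low-dimensional
coding directions, inter-areal activity becomes coordinated, and the
directed functional couplings between neurons sparsen while becoming
enriched among similarly tuned cells. motifnet implements the analysis
chain used to quantify this reorganization, for researchers working with
trial-structured, multi-region deconvolved calcium recordings (or wanting
a validated reference implementation):

* **Coding directions** — the choice (stimulus) mode is the unit-norm
  vector of per-neuron right-minus-left trial-averaged activity in the
  pre-action (stimulus) epoch, `w = Δr̄ / ‖Δr̄‖₂`; population projections
  `p_k = X_k w` yield selectivity and trial-by-trial inter-areal
  coordination, with Gram-Schmidt orthogonalization of stimulus against
  choice and a 40-trial balanced resampling control.
* **Encoding model** — a per-neuron Poisson elastic-net GLM
  (`α = 0.95`, 100-λ path, 5-fold CV on a contiguous 70/30 split) over
  raised-cosine task predictors, movement speed, and every other neuron's
  activity at lags 1–2 frames. Model quality is pseudo-explained variance
  `1 − D(ŷ)/D(ȳ)` (Poisson deviance); predictor-group significance comes
  from zeroing a group's fitted contribution and comparing its EV drop
  against circular 2-s block rotations (add-one p, BH-FDR per neuron).
  A significant lagged coupling defines a directed edge.
* **Motif indices** — convergence (significant in-degree over candidate
  sources, Eq. `n_coupled / n_total`) and enrichment (same-tuned fraction
  of incoming couplings), with random-coupling nulls, retained/eliminated
  coupling partitions between learning stages, correlation-graph controls,
  and in-silico region-specific coupling ablation read out on the choice
  axis.
* **Reduced-rank regression** — rank-constrained prediction of one
  region's population from another's, with the 0.0274 ITI-correlation
  matching filter and 20-neuron subsampling control.
* **FORCE-trained attractor RNN** — a rate network
  (`τ ẋ = −x + J r + W_s I_s + W_c I_c + ε`, sigmoidal transfer) trained
  by full-matrix recursive least squares to reproduce trial-averaged
  activity plus reconstructed external input, then probed with delay-epoch
  distractors and random ablation of principal–external connections.
* **Synthetic sessions** — a generator that plants directed coupling with
  controllable density, same-tuning enrichment, learning-stage
  trajectories, behavioral error rates and movement covariates, so every
  estimator above is validated by ground-truth recovery.

See `vignettes/network-motifs.Rmd` for the models, parameter defaults and
numerical conventions.

## Worked example

```r
library(motifnet)

cfg <- sim_config(n_neurons = c(ALM = 15, PPC = 15), n_trials = 80,
                  coupling_density = 0.10)
g <- generate_session(cfg, seed = 2)
s <- g$session
s
#> motif_session: 30 neurons x 6000 frames @ 9.35 Hz (expert)
#>   regions: ALM=15 PPC=15
#>   trials: 80 (66 correct)

## choice coding direction and selectivity
axis <- compute_mode_axis(s, "ALM", "choice", min_neurons = 10)
round(choice_selectivity(project_trials(s, axis)), 3)
#> [1] 0.615

## encoding models + coupling graph for six target neurons
sg <- fit_session_glms(s, movement = g$movement,
                       targets = s$neuron_ids[1:6],
                       n_lambda = 30, n_shuffles = 1000, seed = 3)
sg$graph
#> coupling_graph (expert): 11 edges over 30 neurons
unlist(coupling_recovery(sg$graph, g$ground_truth))
#>         sensitivity false_positive_rate              n_true          n_detected
#>           0.5789474           0.0000000          19.0000000          11.0000000
```

The selectivity (0.615) is the right-minus-left mean pre-action projection
in activity units — positive because right-preferring neurons carry
positive axis weights. `coupling_recovery` compares detected directed edges
with the planted ground truth restricted to the six fitted targets: 11 of
the 19 planted incoming couplings are recovered with no false positives at
this small-session scale (the acceptance suite's full-size recovery world
reaches sensitivity 0.88 at a 0.003 false-positive rate).

## Command line

```sh
Rscript inst/cli/motifnet.R simulate --seed 3 --out demo --trials 40
Rscript inst/cli/motifnet.R validate demo/session
Rscript inst/cli/motifnet.R run --seed 1 --out demo_run
```

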