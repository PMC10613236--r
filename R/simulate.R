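#' Simulation configuration
#'
#' Describes the synthetic world: region sizes, trial counts and the
#' stage-dependent parameters (coupling density, same-tuning enrichment of
#' planted edges, tuning signal strength, behavioral error rate). Defaults
#' emulate an expert session of the 8-area delayed-response preparation:
#' 1 s stimulus, 2 s delay, go cue, response ~0.3 s later, with a 3 s
#' inter-trial interval ahead of each stimulus.
#'
#' @param n_neurons Named integer vector of neurons per region.
#' @param n_trials Total trial count (balanced L/R; >= 10 per side).
#' @param frame_rate Imaging rate, Hz.
#' @param coupling_density Probability that an ordered neuron pair carries a
#'   directed coupling (per target, Binomial over candidate sources).
#' @param enrichment_level Fraction of a tuned target's incoming couplings
#'   drawn from same-tuned sources (exactly this fraction in expectation).
#' @param tuning_snr Multiplies all task-kernel amplitudes (log-rate scale);
#'   0 removes every task dependence.
#' @param choice_noise Probability that the choice flips the stimulus side
#'   (error trial); choice-tuned kernels follow the choice, not the stimulus.
#' @param coupling_strength Mean log-rate magnitude of a planted coupling.
#' @param excitatory_fraction Probability that a planted coupling is
#'   positive (default 0.55); the near-balanced mix keeps dense graphs
#'   subcritical without weakening individual couplings.
#' @param lag2_fraction Fraction of planted edges acting at lag 2 frames
#'   (the rest act at lag 1).
#' @param baseline_rate Baseline event rate per frame (events/frame).
#' @param rate_noise_sd SD of per-frame Gaussian log-rate noise.
#' @param tuning_fractions Named probabilities over tuning classes
#'   `stimL, stimR, choiceL, choiceR, none`.
#' @param movement List of movement-trace parameters: `stereotypy` in [0,1],
#'   `noise_px`, `dropout_fraction`, `outlier_fraction`, `gain_sd` (SD of the
#'   per-neuron movement gain on standardized movement speed).
#' @param stage Learning-stage label stamped on generated sessions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_neurons = c(ALM = 12, M1a = 12, M1p = 12, S1fl = 12,
                                     vS1 = 12, M2 = 12, RSC = 12, PPC = 12),
                       n_trials = 150, frame_rate = 9.35,
                       coupling_density = 0.08, enrichment_level = 0.75,
                       tuning_snr = 1.0, choice_noise = 0.15,
                       coupling_strength = 0.5, excitatory_fraction = 0.55,
                       lag2_fraction = 0.4,
                       baseline_rate = 0.15, rate_noise_sd = 0.10,
                       tuning_fractions = c(stimL = 0.2, stimR = 0.2,
                                            choiceL = 0.2, choiceR = 0.2,
                                            none = 0.2),
                       movement = list(stereotypy = 0.8, noise_px = 1.0,
                                       dropout_fraction = 0.02,
                                       outlier_fraction = 0.005,
                                       gain_sd = 0.10),
                       stage = "expert") {
  stopifnot(length(n_neurons) >= 1, !is.null(names(n_neurons)),
            n_trials >= 20, frame_rate > 0,
            coupling_density >= 0, coupling_density <= 1,
            enrichment_level >= 0, enrichment_level <= 1,
            choice_noise >= 0, choice_noise <= 1,
            lag2_fraction >= 0, lag2_fraction <= 1,
            abs(sum(tuning_fractions) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

# task timing in seconds, shared by generator and trial-table layout
sim_timing <- function() {
  list(iti = 3, stim = 1, delay = 2, resp_lag = 0.32, post = 2)
}

sim_trial_table <- function(config) {
  tm <- sim_timing()
  fr <- config$frame_rate
  block <- as.integer(ceiling((tm$iti + tm$stim + tm$delay + tm$post) * fr))
  nt <- config$n_trials
  sides <- sample(rep(c("L", "R"), length.out = nt))
  flip <- stats::runif(nt) < config$choice_noise
  choice <- ifelse(flip, ifelse(sides == "L", "R", "L"), sides)
  start <- (seq_len(nt) - 1L) * block
  stim_on <- start + sec_to_frames(tm$iti, fr)
  go_cue <- stim_on + sec_to_frames(tm$stim + tm$delay, fr)
  resp <- go_cue + sec_to_frames(tm$resp_lag, fr)
  tt <- trial_table(sides, choice, stim_on, go_cue, resp)
  attr(tt, "block_frames") <- block
  tt
}

sample_tuning <- function(n, fractions) {
  sample(names(fractions), n, replace = TRUE, prob = fractions)
}

# Per-target incoming edges: count ~ Binomial(candidates, density), sources
# split between same-tuned and differently-tuned pools so the realized
# same-tuning fraction is exactly `enrichment` in expectation.
sample_coupling <- function(neuron_ids, tuning, density, enrichment,
                            strength, lag2_fraction, excitatory = 0.55,
                            forbidden = NULL, extra_per_target = NULL) {
  n <- length(neuron_ids)
  src <- tgt <- integer(0)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    k <- if (is.null(extra_per_target)) stats::rbinom(1L, length(cand), density)
         else extra_per_target[i]
    if (k <= 0) next
    if (!is.null(forbidden)) cand <- setdiff(cand, forbidden[[i]])
    k <- min(k, length(cand))
    if (k <= 0) next
    same <- cand[tuning[cand] == tuning[i] & tuning[i] != "none"]
    other <- setdiff(cand, same)
    k_same <- min(stats::rbinom(1L, k, enrichment), length(same))
    k_other <- min(k - k_same, length(other))
    pick <- c(if (k_same > 0) same[sample.int(length(same), k_same)],
              if (k_other > 0) other[sample.int(length(other), k_other)])
    src <- c(src, pick); tgt <- c(tgt, rep(i, length(pick)))
  }
  if (!length(src)) {
    return(data.frame(source_id = integer(0), target_id = integer(0),
                      lag = integer(0), weight = numeric(0)))
  }
  sign_ <- ifelse(stats::runif(length(src)) < excitatory, 1, -1)
  data.frame(
    source_id = neuron_ids[src], target_id = neuron_ids[tgt],
    lag = ifelse(stats::runif(length(src)) < lag2_fraction, 2L, 1L),
    weight = sign_ * strength * stats::runif(length(src), 0.75, 1.25)
  )
}

coupling_matrices <- function(edges, neuron_ids) {
  n <- length(neuron_ids)
  mk <- function(lag) {
    e <- edges[edges$lag == lag, , drop = FALSE]
    Matrix::sparseMatrix(
      i = match(e$target_id, neuron_ids), j = match(e$source_id, neuron_ids),
      x = e$weight, dims = c(n, n))
  }
  list(W1 = mk(1L), W2 = mk(2L))
}

# Task + movement log-rate drive, neurons x frames, before coupling
task_drive <- function(config, tt, tuning, move_speed, move_gain) {
  fr <- config$frame_rate
  n <- sum(config$n_neurons)
  nf <- attr(tt, "block_frames") * nrow(tt)
  snr <- config$tuning_snr
  eta <- matrix(0, n, nf)
  stim_amp <- snr * stats::runif(n, 0.8, 1.2)
  choice_amp <- snr * stats::runif(n, 0.8, 1.2)
  act_pref <- sample(c("L", "R"), n, replace = TRUE)
  act_amp <- snr * abs(stats::rnorm(n, 0, 0.3)) *
    (stats::runif(n) < 0.3)
  rew_amp <- snr * 0.5 * (stats::runif(n) < 0.2)
  stim_len <- sec_to_frames(1, fr)
  delay_cols <- seq.int(sec_to_frames(1, fr), sec_to_frames(3, fr) - 1L)
  ramp <- seq(0, 1, length.out = length(delay_cols))
  for (k in seq_len(nrow(tt))) {
    trial <- tt[k, ]
    s0 <- trial$stimulus_onset_frame + 1L        # 1-based column
    stim_cols <- s0:(s0 + stim_len - 1L)
    for (side in c("L", "R")) {
      if (trial$stimulus_side == side) {
        idx <- which(tuning == paste0("stim", side))
        eta[idx, stim_cols] <- eta[idx, stim_cols] + stim_amp[idx]
      }
      if (trial$choice_side == side) {
        idx <- which(tuning == paste0("choice", side))
        eta[idx, s0 + delay_cols] <- eta[idx, s0 + delay_cols] +
          outer(choice_amp[idx], ramp)
        idx2 <- which(act_pref == side & act_amp > 0)
        go <- trial$go_cue_frame + 1L
        eta[idx2, go:(go + stim_len - 1L)] <-
          eta[idx2, go:(go + stim_len - 1L)] + act_amp[idx2]
      }
    }
    if (isTRUE(trial$rewarded) && !is.na(trial$response_frame)) {
      r0 <- trial$response_frame + 1L
      rc <- r0:min(r0 + stim_len - 1L, nf)
      eta[, rc] <- eta[, rc] + rew_amp
    }
  }
  if (!is.null(move_speed)) {
    z <- (move_speed - mean(move_speed)) / max(stats::sd(move_speed), 1e-12)
    eta <- eta + outer(move_gain, z)
  }
  list(eta = eta,
       kernels = data.frame(stim_amp = stim_amp, choice_amp = choice_amp,
                            action_pref = act_pref, action_amp = act_amp,
                            reward_amp = rew_amp))
}

# Coupling acts on event occurrence (source activity clipped at 1) so a
# burst cannot multiply through the graph; the log-rate is capped as a
# backstop against saturation.
simulate_activity <- function(eta_task, W1, W2, rate_cap = 5) {
  n <- nrow(eta_task); nf <- ncol(eta_task)
  a <- matrix(0, n, nf)
  log_cap <- log(rate_cap)
  for (t in seq_len(nf)) {
    eta <- eta_task[, t]
    if (t > 1L) eta <- eta + as.numeric(W1 %*% pmin(a[, t - 1L], 1))
    if (t > 2L) eta <- eta + as.numeric(W2 %*% pmin(a[, t - 2L], 1))
    a[, t] <- stats::rpois(n, exp(pmin(eta, log_cap)))
  }
  a
}

#' Generate a synthetic multi-region session with known ground truth
#'
#' Activity is drawn from a log-link point process: each neuron's per-frame
#' Poisson rate is `exp(baseline + task kernels + coupling terms at lags 1-2
#' + movement term + noise)`, the same generative family the encoding model
#' fits. The returned ground truth records every planted effect.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (all randomness derives from it).
#' @param edges Optional explicit edge table (`source_id`, `target_id`,
#'   `lag`, `weight`) planted verbatim instead of sampled coupling.
#' @param tuning Optional explicit per-neuron tuning class vector
#'   (`stimL/stimR/choiceL/choiceR/none`) instead of sampled classes.
#' @return List with elements `session` ([session()]), `ground_truth`
#'   (class `ground_truth`: `$coupling` edge table with lag and weight,
#'   `$tuning`, `$movement_gain`, `$baseline_log_rate`) and `movement`
#'   (60 Hz trace from [generate_movement()]).
#' @export
generate_session <- function(config, seed = 1L, edges = NULL, tuning = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- sum(config$n_neurons)
  regions <- rep(names(config$n_neurons), config$n_neurons)
  neuron_ids <- seq_len(n)
  tt <- sim_trial_table(config)
  nf <- attr(tt, "block_frames") * nrow(tt)

  if (is.null(tuning)) tuning <- sample_tuning(n, config$tuning_fractions)
  stopifnot(length(tuning) == n)
  if (is.null(edges)) {
    edges <- sample_coupling(neuron_ids, tuning, config$coupling_density,
                             config$enrichment_level,
                             config$coupling_strength, config$lag2_fraction,
                             config$excitatory_fraction)
  } else {
    stopifnot(all(c("source_id", "target_id", "lag", "weight") %in%
                    names(edges)))
  }
  gt <- build_ground_truth(config, neuron_ids, tuning, edges)

  movement <- generate_movement(config, tt, n_frames = nf)
  speed <- movement_imaging_speed(movement, config$frame_rate, nf)
  move_gain <- stats::rnorm(n, 0, config$movement$gain_sd)
  td <- task_drive(config, tt, tuning, speed, move_gain)
  b0 <- log(config$baseline_rate) + stats::rnorm(n, 0, 0.1)
  eta <- td$eta + b0 +
    matrix(stats::rnorm(n * nf, 0, config$rate_noise_sd), n, nf)

  W <- coupling_matrices(edges, neuron_ids)
  check_coupling_stability(W, exp(b0))
  act <- simulate_activity(eta, W$W1, W$W2)

  gt$movement_gain <- move_gain
  gt$baseline_log_rate <- b0
  gt$kernels <- td$kernels
  s <- session(act, tt, regions, neuron_ids, config$frame_rate, config$stage)
  list(session = s, ground_truth = gt, movement = movement)
}

build_ground_truth <- function(config, neuron_ids, tuning, edges) {
  structure(
    list(coupling = edges,
         tuning = data.frame(neuron_id = neuron_ids, class = tuning,
                             stringsAsFactors = FALSE),
         movement_gain = NULL, baseline_log_rate = NULL,
         config = config),
    class = "ground_truth")
}

# Runaway guard: in a log-link cascade the first-order branching matrix is
# rate_i * w_ij, not the raw weight matrix, so the radius is taken on the
# rate-scaled couplings (both lags summed).
check_coupling_stability <- function(W, baseline_rates, threshold = 0.95) {
  M <- (W$W1 + W$W2) * baseline_rates
  if (length(M@x) == 0) return(invisible(0))
  rho <- max(Mod(eigen(as.matrix(M), only.values = TRUE)$values))
  if (rho >= threshold) {
    stop("generate_session: rate-scaled coupling spectral radius ",
         signif(rho, 3), " >= ", threshold,
         "; reduce coupling_strength, density or baseline_rate")
  }
  invisible(rho)
}

#' Generate a matched naive/intermediate/expert session series
#'
#' Neuron identities, regions, tuning classes and baselines persist across
#' stages (matched cells); coupling evolves stage to stage with a planted
#' retained fraction: each later stage keeps `retained_fraction` of the
#' earlier stage's edges and draws fresh edges (avoiding eliminated pairs)
#' to hit its target density.
#'
#' @param config A [sim_config()] giving the shared world (region sizes,
#'   trial counts, timing).
#' @param stage_params Named list `naive`, `intermediate`, `expert`; each a
#'   list overriding `coupling_density`, `enrichment_level`, `tuning_snr`,
#'   `choice_noise` (defaults follow the learning trajectory: densities
#'   0.30/0.18/0.10, enrichment 0.5/0.6/0.75, SNR 0.4/0.7/1.0, choice noise
#'   0.45/0.30/0.15).
#' @param retained_fraction Fraction of a stage's edges kept at the next
#'   stage (default 0.32).
#' @param seed Integer seed.
#' @return Named list of per-stage results as returned by
#'   [generate_session()].
#' @export
generate_learning_series <- function(config,
                                     stage_params = default_stage_params(),
                                     retained_fraction = 0.32, seed = 1L) {
  stages <- c("naive", "intermediate", "expert")
  if (!identical(sort(names(stage_params)), sort(stages))) {
    stop("stage_params must be a named list over naive/intermediate/expert")
  }
  lens <- lengths(stage_params)
  if (length(unique(lens)) != 1L) stop("stage parameter lists of unequal length")
  set.seed(seed)
  n <- sum(config$n_neurons)
  neuron_ids <- seq_len(n)
  regions <- rep(names(config$n_neurons), config$n_neurons)
  tuning <- sample_tuning(n, config$tuning_fractions)
  b0 <- log(config$baseline_rate) + stats::rnorm(n, 0, 0.1)
  move_gain <- stats::rnorm(n, 0, config$movement$gain_sd)

  out <- list()
  prev_edges <- NULL
  for (st in stages) {
    cfg <- config
    for (f in names(stage_params[[st]])) cfg[[f]] <- stage_params[[st]][[f]]
    cfg$stage <- st
    edges <- sample_stage_edges(neuron_ids, tuning, cfg, prev_edges,
                                retained_fraction)
    tt <- sim_trial_table(cfg)
    nf <- attr(tt, "block_frames") * nrow(tt)
    movement <- generate_movement(cfg, tt, n_frames = nf)
    speed <- movement_imaging_speed(movement, cfg$frame_rate, nf)
    td <- task_drive(cfg, tt, tuning, speed, move_gain)
    eta <- td$eta + b0 +
      matrix(stats::rnorm(n * nf, 0, cfg$rate_noise_sd), n, nf)
    W <- coupling_matrices(edges, neuron_ids)
    check_coupling_stability(W, exp(b0))
    act <- simulate_activity(eta, W$W1, W$W2)
    gt <- build_ground_truth(cfg, neuron_ids, tuning, edges)
    gt$movement_gain <- move_gain
    gt$baseline_log_rate <- b0
    gt$kernels <- td$kernels
    out[[st]] <- list(
      session = session(act, tt, regions, neuron_ids, cfg$frame_rate, st),
      ground_truth = gt, movement = movement)
    prev_edges <- edges
  }
  out
}

#' @rdname generate_learning_series
#' @export
default_stage_params <- function() {
  list(
    naive        = list(coupling_density = 0.30, enrichment_level = 0.5,
                        tuning_snr = 0.4, choice_noise = 0.45),
    intermediate = list(coupling_density = 0.18, enrichment_level = 0.6,
                        tuning_snr = 0.7, choice_noise = 0.30),
    expert       = list(coupling_density = 0.10, enrichment_level = 0.75,
                        tuning_snr = 1.0, choice_noise = 0.15)
  )
}

sample_stage_edges <- function(neuron_ids, tuning, cfg, prev_edges,
                               retained_fraction) {
  n <- length(neuron_ids)
  target_per <- stats::rbinom(n, n - 1L, cfg$coupling_density)
  if (is.null(prev_edges) || nrow(prev_edges) == 0) {
    return(sample_coupling(neuron_ids, tuning, cfg$coupling_density,
                           cfg$enrichment_level, cfg$coupling_strength,
                           cfg$lag2_fraction, cfg$excitatory_fraction,
                           extra_per_target = target_per))
  }
  n_keep <- round(retained_fraction * nrow(prev_edges))
  # retention preferentially keeps same-tuned couplings so the retained
  # portion carries the new stage's enrichment level (the biological
  # story: behaviorally relevant couplings survive learning); the retained
  # count itself is exact
  src_cls <- tuning[match(prev_edges$source_id, neuron_ids)]
  tgt_cls <- tuning[match(prev_edges$target_id, neuron_ids)]
  is_same <- src_cls == tgt_cls & tgt_cls != "none"
  n_same_keep <- min(round(cfg$enrichment_level * n_keep), sum(is_same))
  n_other_keep <- min(n_keep - n_same_keep, sum(!is_same))
  pick <- c(which(is_same)[sample.int(sum(is_same), n_same_keep)],
            which(!is_same)[sample.int(sum(!is_same), n_other_keep)])
  kept <- prev_edges[pick, , drop = FALSE]
  dropped <- prev_edges[!rownames(prev_edges) %in% rownames(kept), ,
                        drop = FALSE]
  # new edges must avoid the eliminated pairs so the planted retained
  # fraction stays exact, and avoid duplicating kept pairs
  forbidden <- lapply(seq_len(n), function(i) {
    id <- neuron_ids[i]
    match(c(kept$source_id[kept$target_id == id],
            dropped$source_id[dropped$target_id == id]), neuron_ids)
  })
  kept_per <- tabulate(match(kept$target_id, neuron_ids), nbins = n)
  extra <- pmax(target_per - kept_per, 0L)
  new <- sample_coupling(neuron_ids, tuning, cfg$coupling_density,
                         cfg$enrichment_level, cfg$coupling_strength,
                         cfg$lag2_fraction, cfg$excitatory_fraction,
                         forbidden = forbidden, extra_per_target = extra)
  rbind(kept, new)
}

#' Generate a 60 Hz movement trace for a session
#'
#' Emits forelimb x/y coordinates with per-point likelihood in the tracking
#' CSV dialect (`bodypart, frame, x, y, likelihood`). Each trial has a
#' baseline posture plus a response-locked reach whose shape is a mixture of
#' a shared per-side template (weight `stereotypy`) and trial-unique smooth
#' noise; a configured fraction of points get likelihood < 0.95 (dropouts)
#' and isolated large-displacement outliers are injected and recorded in
#' the `"planted"` attribute.
#'
#' @param config A [sim_config()].
#' @param trials A [trial_table()].
#' @param seed Optional seed; `NULL` (default) inherits the caller's RNG
#'   stream so [generate_session()] stays single-seeded.
#' @param n_frames Imaging frame count (trace covers the same wall-clock).
#' @return A `data.frame` trace (both forelimbs), class `movement_trace`.
#' @export
generate_movement <- function(config, trials, seed = NULL, n_frames) {
  if (!is.null(seed)) set.seed(seed)
  mv <- config$movement
  fr60 <- 60
  nf60 <- as.integer(ceiling(n_frames / config$frame_rate * fr60))
  smooth_noise <- function(m) {
    z <- stats::rnorm(m)
    stats::filter(z, rep(1 / 15, 15), circular = TRUE)
  }
  reach_len <- as.integer(0.8 * fr60)
  templ <- list(
    L = cbind(x = -30 * sin(seq(0, pi, length.out = reach_len)),
              y = 15 * sin(seq(0, 2 * pi, length.out = reach_len))),
    R = cbind(x = 30 * sin(seq(0, pi, length.out = reach_len)),
              y = 15 * sin(seq(0, 2 * pi, length.out = reach_len))))
  out <- list(); planted_outliers <- list()
  for (bp in c("forelimb_l", "forelimb_r")) {
    x <- 100 + as.numeric(smooth_noise(nf60)) * mv$noise_px
    y <- 80 + as.numeric(smooth_noise(nf60)) * mv$noise_px
    amp <- if (bp == "forelimb_r") 1 else 0.6
    for (k in seq_len(nrow(trials))) {
      trial <- trials[k, ]
      if (trial$choice_side == "none" || is.na(trial$response_frame)) next
      r0 <- as.integer(round(trial$response_frame / config$frame_rate * fr60))
      idx <- r0 + seq_len(reach_len)
      idx <- idx[idx <= nf60]
      if (!length(idx)) next
      tpl <- templ[[trial$choice_side]][seq_along(idx), , drop = FALSE]
      w <- mv$stereotypy
      x[idx] <- x[idx] + amp * (w * tpl[, "x"] +
        (1 - w) * 20 * as.numeric(smooth_noise(length(idx))))
      y[idx] <- y[idx] + amp * (w * tpl[, "y"] +
        (1 - w) * 20 * as.numeric(smooth_noise(length(idx))))
    }
    x <- x + stats::rnorm(nf60, 0, mv$noise_px)
    y <- y + stats::rnorm(nf60, 0, mv$noise_px)
    lik <- rep(1, nf60)
    n_drop <- as.integer(round(mv$dropout_fraction * nf60))
    if (n_drop > 0) {
      drop_idx <- sample(nf60, n_drop)
      lik[drop_idx] <- stats::runif(n_drop, 0, 0.94)
    }
    n_out <- as.integer(round(mv$outlier_fraction * nf60))
    out_idx <- integer(0)
    if (n_out > 0) {
      out_idx <- sample(nf60, n_out)
      x[out_idx] <- x[out_idx] + sample(c(-1, 1), n_out, TRUE) * 200
      y[out_idx] <- y[out_idx] + sample(c(-1, 1), n_out, TRUE) * 200
    }
    planted_outliers[[bp]] <- sort(out_idx)
    out[[bp]] <- data.frame(bodypart = bp, frame = seq_len(nf60) - 1L,
                            x = x, y = y, likelihood = lik,
                            stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, out)
  rownames(trace) <- NULL
  class(trace) <- c("movement_trace", "data.frame")
  attr(trace, "planted") <- list(outlier_frames = planted_outliers)
  trace
}

# right-forelimb speed (px per 60Hz frame) averaged into imaging frames
movement_imaging_speed <- function(movement, frame_rate, n_frames) {
  tr <- movement[movement$bodypart == "forelimb_r", , drop = FALSE]
  if (!nrow(tr)) return(rep(0, n_frames))
  d <- c(0, sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  bin <- pmin(as.integer(trunc(tr$frame / 60 * frame_rate)) + 1L, n_frames)
  out <- rep(0, n_frames)
  agg <- tapply(d, bin, mean)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}
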