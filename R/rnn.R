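#' Build FORCE training targets from trial-averaged activity
#'
#' Trial-averaged activity (units x frames at the imaging rate, one matrix
#' per trial type) is clipped to `[0.01, 4.99]`, normalized by 5, passed
#' through the inverse sigmoid `f = theta + log(r / (1 - r)) / beta`,
#' up-sampled x10 (9.35 -> 93.5 Hz) by linear interpolation and smoothed
#' with a ~400 ms (37-sample) boxcar. Units whose normalized activity never
#' exceeds 1 SD (taken across all timesteps and units of both conditions)
#' are excluded. External-unit activity (e.g. coupling-only reconstructions
#' from another region) is processed identically and sampled with
#' replacement to `n_external` traces.
#'
#' @param activity List with `right` and `left` matrices (units x frames).
#' @param external_activity Optional list like `activity` for external
#'   units.
#' @param n_external External unit count (default 128).
#' @param beta,theta Transfer parameters (defaults 0.8, 3.0).
#' @param seed Integer seed (external resampling).
#' @return Object of class `rnn_targets`: `f_right`, `f_left` (units x
#'   target samples), `roles` (`"principal"`/`"external"`), `beta`,
#'   `theta`, `rate_hz = 93.5`.
#' @export
prepare_targets <- function(activity, external_activity = NULL,
                            n_external = 128, beta = 0.8, theta = 3.0,
                            seed = 1L) {
  set.seed(seed)
  norm_block <- function(lst) {
    lapply(lst, function(m) pmin(pmax(as.matrix(m), 0.01), 4.99) / 5)
  }
  pr <- norm_block(activity)
  ex <- if (!is.null(external_activity)) norm_block(external_activity)
  sd_all <- stats::sd(c(unlist(pr), unlist(ex)))
  keep_units <- function(lst) {
    apply(pmax(lst$right, lst$left), 1L, max) >= sd_all
  }
  kp <- keep_units(pr)
  if (!any(kp)) stop("prepare_targets: all principal units excluded")
  pr <- lapply(pr, function(m) m[kp, , drop = FALSE])
  if (!is.null(ex)) {
    ke <- keep_units(ex)
    if (!any(ke)) stop("prepare_targets: all external units excluded")
    pick <- which(ke)[sample.int(sum(ke), n_external, replace = TRUE)]
    ex <- lapply(ex, function(m) m[pick, , drop = FALSE])
  }
  to_f <- function(m) {
    f <- theta + log(m / (1 - m)) / beta
    t(apply(f, 1L, function(v) {
      up <- stats::approx(seq_along(v), v,
                          xout = seq(1, length(v), length.out = 10 * length(v)))$y
      moving_average(up, 37L)
    }))
  }
  f_r <- to_f(pr$right); f_l <- to_f(pr$left)
  roles <- rep("principal", nrow(f_r))
  if (!is.null(ex)) {
    f_r <- rbind(f_r, to_f(ex$right))
    f_l <- rbind(f_l, to_f(ex$left))
    roles <- c(roles, rep("external", n_external))
  }
  structure(list(f_right = f_r, f_left = f_l, roles = roles, beta = beta,
                 theta = theta, rate_hz = 93.5),
            class = "rnn_targets")
}

#' Initialize a rate RNN for FORCE training
#'
#' `J ~ N(0, g / sqrt(n))` (mean/SD convention), `W_stimulus ~ N(0, 1)`,
#' `W_cue ~ N(0, 0.1)`, inverse-correlation estimate `P = 0.01 I`. With
#' `g > 1` the untrained network is chaotic. Integration uses tau = 10 ms,
#' dt = 1 ms; transfer `r = 1 / (1 + exp(-beta (x - theta)))` with
#' beta = 0.8, theta = 3; state noise SD 0.15.
#'
#' @param n_principal,n_external Unit counts (total >= 2).
#' @param g Gain in `{1.1, 1.2, 1.3, 1.4}` typically (default 1.2).
#' @param seed Integer seed.
#' @return Object of class `rnn_model`.
#' @export
init_rnn <- function(n_principal, n_external = 0, g = 1.2, seed = 1L) {
  n <- n_principal + n_external
  stopifnot(n >= 2)
  set.seed(seed)
  structure(
    list(J = matrix(stats::rnorm(n * n, 0, g / sqrt(n)), n, n),
         Wstim = stats::rnorm(n, 0, 1), Wcue = stats::rnorm(n, 0, 0.1),
         P = diag(0.01, n), n_principal = n_principal,
         n_external = n_external, g = g, tau = 10, dt = 1,
         beta = 0.8, theta = 3.0, noise_sd = 0.15,
         trained = FALSE, mse = NA_real_, nmse = NA_real_),
    class = "rnn_model")
}

#' One Euler step of the rate network
#'
#' `z = J r + drive + noise`; `x' = x + (dt/tau)(-x + z)`; `r' = sigmoid`.
#' With `J = 0`, no drive and no noise, `x` decays geometrically by
#' `1 - dt/tau` per step.
#'
#' @param model An `rnn_model`.
#' @param x Current state vector.
#' @param drive External input drive vector (default 0).
#' @param noise Noise vector (default 0).
#' @return List `x`, `r`.
#' @export
rnn_step <- function(model, x, drive = 0, noise = 0) {
  r <- 1 / (1 + exp(-model$beta * (x - model$theta)))
  z <- as.numeric(model$J %*% r) + drive + noise
  x2 <- x + (model$dt / model$tau) * (-x + z)
  list(x = x2, r = 1 / (1 + exp(-model$beta * (x2 - model$theta))))
}

# per-step input waveforms over the 3.5-s trial, time relative to the
# action: stimulus triangle on [-3, -2] s, cue triangle on [-2.1, -2] s,
# distractor boxcar on [-1.75, -1.25] s
rnn_input_shapes <- function(n_steps, duration_s = 3.5) {
  t <- -duration_s + duration_s * seq_len(n_steps) / n_steps
  list(stim = pmax(0, 1 - abs(t + 2.5) / 0.5),
       cue = pmax(0, 1 - abs(t + 2.05) / 0.05),
       distractor = as.numeric(t >= -1.75 & t < -1.25),
       t = t)
}

#' FORCE-train a rate RNN on two-condition targets
#'
#' Recursive-least-squares updates of `J` at every 1-ms step, alternating
#' right/left episodes; the right-trial stimulus peak is redrawn each
#' episode from N(1, 0.1). After training, the MSE between generated and
#' target activity (sigmoid space, one noisy validation run per condition)
#' is stored along with the target-variance-normalized MSE.
#'
#' @param model An `rnn_model` from [init_rnn()].
#' @param targets An `rnn_targets` with unit count matching the model.
#' @param epochs Training episodes (default 500).
#' @param alpha_learn Learning rate (default 0.05).
#' @param seed Integer seed.
#' @return The trained `rnn_model` (updated `J`, `P`, `mse`, `nmse`).
#' @export
force_train <- function(model, targets, epochs = 500, alpha_learn = 0.05,
                        seed = 1L) {
  stopifnot(inherits(model, "rnn_model"), inherits(targets, "rnn_targets"))
  n <- nrow(model$J)
  if (nrow(targets$f_right) != n || nrow(targets$f_left) != n) {
    stop("force_train: target/model dimension mismatch")
  }
  T_s <- ncol(targets$f_right)
  n_steps <- 10L * T_s
  sh <- rnn_input_shapes(n_steps)
  tidx <- rep(seq_len(T_s), each = 10L)
  set.seed(seed)
  res <- force_train_cpp(model$J, model$Wstim, model$Wcue, model$P,
                         targets$f_right, targets$f_left, sh$stim, sh$cue,
                         tidx, model$dt / model$tau, model$beta, model$theta,
                         model$noise_sd, alpha_learn, as.integer(epochs),
                         1.0, 0.1)
  model$J <- res$J
  model$P <- res$P
  model$trained <- TRUE
  # condition-independent pre-trial state: mean of the two first targets
  model$x0 <- (targets$f_right[, 1L] + targets$f_left[, 1L]) / 2
  sig <- function(f) 1 / (1 + exp(-model$beta * (f - model$theta)))
  err <- 0; tgt_var <- stats::var(c(sig(targets$f_right),
                                    sig(targets$f_left)))
  for (type in c("right", "left")) {
    peak <- if (type == "right") stats::rnorm(1, 1, 0.1) else 0
    r_out <- sim_trial_cpp(model$J, model$Wstim, model$Wcue,
                           peak * sh$stim, sh$cue, model$dt / model$tau,
                           model$beta, model$theta, model$noise_sd, 10L,
                           model$x0)
    f <- if (type == "right") targets$f_right else targets$f_left
    err <- err + mean((r_out - sig(f))^2) / 2
  }
  model$mse <- err
  model$nmse <- err / tgt_var
  model$targets_dim <- c(n, T_s)
  model
}

#' Filter trained models by MSE
#'
#' Retains models whose MSE does not exceed `mean + SD` of the MSEs across
#' all supplied models (high-MSE models are poorly fit and excluded).
#'
#' @param models List of trained `rnn_model`s (>= 2).
#' @return The retained sublist, with attribute `excluded` (indices).
#' @export
mse_filter <- function(models) {
  stopifnot(length(models) >= 2)
  mses <- vapply(models, function(m) m$mse, numeric(1))
  thr <- mean(mses) + stats::sd(mses)
  keep <- mses <= thr
  out <- models[keep]
  attr(out, "excluded") <- which(!keep)
  out
}

#' Reference trajectories and choice axis of a trained RNN
#'
#' Runs noisy no-distractor right and left trials, computes the choice
#' axis from principal-unit mean activity differences in the last 1 s of
#' the delay (unit norm), and the mean projection traces normalized by the
#' maximum of the right-trial choice activity.
#'
#' @param model Trained `rnn_model`.
#' @param n_trials Reference trials per condition (default 20).
#' @param seed Integer seed.
#' @return List `axis`, `norm`, `proj_R`, `proj_L` (normalized mean
#'   traces), `end_R`, `end_L`, `halfway`.
#' @export
rnn_reference <- function(model, n_trials = 20, seed = 1L) {
  stopifnot(isTRUE(model$trained))
  set.seed(seed)
  T_s <- model$targets_dim[2L]
  sh <- rnn_input_shapes(10L * T_s)
  pidx <- seq_len(model$n_principal)
  run_mean <- function(type) {
    acc <- 0
    for (i in seq_len(n_trials)) {
      peak <- if (type == "right") stats::rnorm(1, 1, 0.1) else 0
      acc <- acc + sim_trial_cpp(model$J, model$Wstim, model$Wcue,
                                 peak * sh$stim, sh$cue,
                                 model$dt / model$tau, model$beta,
                                 model$theta, model$noise_sd, 10L, model$x0)
    }
    (acc / n_trials)[pidx, , drop = FALSE]
  }
  mR <- run_mean("right"); mL <- run_mean("left")
  pre <- seq.int(max(1L, T_s - round(93.5) + 1L), T_s)
  d <- rowMeans(mR[, pre, drop = FALSE]) - rowMeans(mL[, pre, drop = FALSE])
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("rnn_reference: degenerate choice axis")
  w <- d / nrm
  pR <- as.numeric(crossprod(mR, w)); pL <- as.numeric(crossprod(mL, w))
  norm_c <- max(pR)
  if (norm_c <= 0) stop("rnn_reference: nonpositive right-choice maximum")
  pR <- pR / norm_c; pL <- pL / norm_c
  list(axis = w, norm = norm_c, proj_R = pR, proj_L = pL,
       end_R = pR[T_s], end_L = pL[T_s],
       halfway = (pR[T_s] + pL[T_s]) / 2)
}

#' Simulate trials of a trained RNN with choice-axis readout
#'
#' @param model Trained `rnn_model`.
#' @param trial_type `"right"` or `"left"`.
#' @param n_trials Trials (default 100).
#' @param distractor `NULL`, or list `mean` (and optional `sd`, default
#'   0.025) for a 500-ms delay-epoch pulse through the stimulus channel.
#' @param ref Reference from [rnn_reference()] (computed if `NULL`).
#' @param seed Integer seed.
#' @return List `proj` (trials x target samples, normalized), `end_values`,
#'   `ref`.
#' @export
run_trials <- function(model, trial_type = c("right", "left"),
                       n_trials = 100, distractor = NULL, ref = NULL,
                       seed = 1L) {
  trial_type <- match.arg(trial_type)
  stopifnot(isTRUE(model$trained))
  if (is.null(ref)) ref <- rnn_reference(model,
                                         seed = derive_seed(seed, "ref"))
  set.seed(seed)
  T_s <- model$targets_dim[2L]
  sh <- rnn_input_shapes(10L * T_s)
  pidx <- seq_len(model$n_principal)
  proj <- matrix(NA_real_, n_trials, T_s)
  for (i in seq_len(n_trials)) {
    peak <- if (trial_type == "right") stats::rnorm(1, 1, 0.1) else 0
    stim <- peak * sh$stim
    if (!is.null(distractor)) {
      amp <- stats::rnorm(1, distractor$mean,
                          if (is.null(distractor$sd)) 0.025 else distractor$sd)
      stim <- stim + amp * sh$distractor
    }
    r <- sim_trial_cpp(model$J, model$Wstim, model$Wcue, stim, sh$cue,
                       model$dt / model$tau, model$beta, model$theta,
                       model$noise_sd, 10L, model$x0)
    proj[i, ] <- as.numeric(crossprod(r[pidx, , drop = FALSE], ref$axis)) /
      ref$norm
  }
  list(proj = proj, end_values = proj[, T_s], ref = ref)
}

#' Decision-switch fraction under a delay distractor
#'
#' Fraction of left trials with a distractor whose end-of-delay choice
#' value ends above the halfway point between the unperturbed right and
#' left end values.
#'
#' @param model Trained `rnn_model`.
#' @param distractor List `mean` (and optional `sd`).
#' @param n_trials Distractor trials (default 100).
#' @param ref Optional precomputed [rnn_reference()].
#' @param seed Integer seed.
#' @return Fraction in `[0, 1]` with attribute `end_values`.
#' @export
decision_switch_fraction <- function(model, distractor, n_trials = 100,
                                     ref = NULL, seed = 1L) {
  if (is.null(ref)) ref <- rnn_reference(model,
                                         seed = derive_seed(seed, "ref"))
  if (ref$end_R <= ref$end_L) {
    stop("decision_switch_fraction: reference trajectories unseparated ",
         "(untrained or unstable model)")
  }
  rt <- run_trials(model, "left", n_trials = n_trials,
                   distractor = distractor, ref = ref, seed = seed)
  out <- mean(rt$end_values > ref$halfway)
  attr(out, "end_values") <- rt$end_values
  out
}

#' Switch fraction under random ablation of external connections
#'
#' Zeroes a random `fraction` of the entries in both principal/external
#' off-diagonal blocks of `J` (sampled independently per block), recomputes
#' the distractor switch fraction against the intact model's reference, and
#' repeats. Iterations in which the ablated model's mean distractor
#' end-of-delay choice value falls below its own left-trial mean are
#' excluded (poor fit rather than reduced robustness) and counted.
#'
#' @param model Trained `rnn_model` with external units.
#' @param fraction Ablated fraction in `[0, 1]`.
#' @param iters Ablation iterations (default 100).
#' @param distractor Distractor parameters (default mean 0.30).
#' @param n_trials Distractor trials per iteration (default 100).
#' @param n_left Plain left trials per iteration for the exclusion rule
#'   (default 10).
#' @param ref Optional precomputed [rnn_reference()].
#' @param seed Integer seed.
#' @return List `mean_switch_fraction`, `per_iteration`, `n_excluded`.
#' @export
ablate_external <- function(model, fraction, iters = 100,
                            distractor = list(mean = 0.30), n_trials = 100,
                            n_left = 10, ref = NULL, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("ablate_external: fraction outside [0, 1]")
  stopifnot(model$n_external > 0)
  if (is.null(ref)) ref <- rnn_reference(model,
                                         seed = derive_seed(seed, "ref"))
  if (ref$end_R <= ref$end_L) stop("ablate_external: unseparated reference")
  pidx <- seq_len(model$n_principal)
  eidx <- model$n_principal + seq_len(model$n_external)
  sf <- rep(NA_real_, iters)
  n_excl <- 0L
  set.seed(seed)
  for (it in seq_len(iters)) {
    m2 <- model
    zero_block <- function(J, rows, cols) {
      nb <- length(rows) * length(cols)
      k <- as.integer(round(fraction * nb))
      if (k > 0) {
        pick <- sample.int(nb, k)
        block <- J[rows, cols]
        block[pick] <- 0
        J[rows, cols] <- block
      }
      J
    }
    m2$J <- zero_block(m2$J, pidx, eidx)
    m2$J <- zero_block(m2$J, eidx, pidx)
    it_seed <- derive_seed(seed, paste0("abl", it))
    rt_d <- run_trials(m2, "left", n_trials = n_trials,
                       distractor = distractor, ref = ref, seed = it_seed)
    rt_l <- run_trials(m2, "left", n_trials = n_left, ref = ref,
                       seed = derive_seed(it_seed, "plain"))
    if (mean(rt_d$end_values) < mean(rt_l$end_values)) {
      n_excl <- n_excl + 1L
      next
    }
    sf[it] <- mean(rt_d$end_values > ref$halfway)
  }
  list(mean_switch_fraction = mean(sf, na.rm = TRUE),
       per_iteration = sf, n_excluded = n_excl)
}
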