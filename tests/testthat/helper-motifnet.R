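# tiny deterministic fixtures built in code; no files on disk

toy_trials <- function(n_trials = 6, block = 80, frame_rate = 9.35) {
  sides <- rep(c("L", "R"), length.out = n_trials)
  start <- (seq_len(n_trials) - 1L) * block
  stim <- start + 30L
  go <- stim + sec_to_frames_t(3, frame_rate)
  trial_table(sides, sides, stim, go, go + 3L)
}

sec_to_frames_t <- function(s, rate) as.integer(trunc(s * rate))

toy_session <- function(n_neurons = 4, n_trials = 6, block = 80,
                        frame_rate = 9.35, seed = 1) {
  set.seed(seed)
  tt <- toy_trials(n_trials, block, frame_rate)
  nf <- n_trials * block
  act <- matrix(rpois(n_neurons * nf, 0.3), n_neurons, nf)
  session(act, tt, regions = rep("ALM", n_neurons), frame_rate = frame_rate)
}

small_sim <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_neurons = c(ALM = 12, PPC = 12), n_trials = 40,
                   coupling_density = 0.15, tuning_snr = 1,
                   choice_noise = 0.15)
  defaults[names(args)] <- args
  generate_session(do.call(sim_config, defaults), seed = seed)
}

# independent oracle: Poisson pseudo-EV from raw log-likelihoods
# (saturated model has mu = y, contributing y log y - y where y > 0 and 0
# where y = 0)
pseudo_ev_oracle <- function(y, mu) {
  loglik <- function(y, m) sum(ifelse(y > 0, y * log(m), 0) - m)
  ll_sat <- sum(ifelse(y > 0, y * log(y) - y, 0))
  d_model <- 2 * (ll_sat - loglik(y, mu))
  d_null <- 2 * (ll_sat - loglik(y, rep(mean(y), length(y))))
  1 - d_model / d_null
}

# independent oracle: AUC by exhaustive pair counting
auc_oracle <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (y > x) + 0.5 * (y == x)
  s / (length(a) * length(b))
}

# independent oracle: BH step-up by literal enumeration
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
  mask <- logical(m)
  if (k > 0) mask[o[seq_len(k)]] <- TRUE
  mask
}
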