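test_that("generation is deterministic and structurally valid", {
  cfg <- sim_config(n_neurons = c(ALM = 8, PPC = 8), n_trials = 24)
  a <- generate_session(cfg, seed = 5)
  b <- generate_session(cfg, seed = 5)
  expect_identical(a$session$activity, b$session$activity)
  expect_identical(a$ground_truth$coupling, b$ground_truth$coupling)
  expect_true(all(a$session$activity >= 0))
  expect_true(all(a$ground_truth$coupling$source_id !=
                    a$ground_truth$coupling$target_id))
  expect_true(all(a$ground_truth$coupling$lag %in% 1:2))
})

test_that("density 0 plants no edges; realized density tracks the config", {
  g0 <- small_sim(seed = 2, coupling_density = 0)
  expect_equal(nrow(g0$ground_truth$coupling), 0L)

  cfg <- sim_config(n_neurons = c(ALM = 30, PPC = 30), n_trials = 24,
                    coupling_density = 0.1)
  g <- generate_session(cfg, seed = 7)
  n_pairs <- 60 * 59
  realized <- nrow(unique(g$ground_truth$coupling[, c("source_id", "target_id")]))
  ci <- qbinom(c(0.025, 0.975), n_pairs, 0.1)
  expect_gte(realized, ci[1]); expect_lte(realized, ci[2])
})

test_that("planted enrichment approaches the configured level", {
  cfg <- sim_config(n_neurons = c(ALM = 40, PPC = 40), n_trials = 24,
                    coupling_density = 0.12, enrichment_level = 0.7)
  g <- generate_session(cfg, seed = 3)
  e <- g$ground_truth$coupling
  cls <- g$ground_truth$tuning$class
  tuned_target <- cls[e$target_id] != "none"
  same <- cls[e$source_id[tuned_target]] == cls[e$target_id[tuned_target]]
  expect_gt(sum(tuned_target), 200)
  expect_lt(abs(mean(same) - 0.7), 0.05)
})

test_that("choice labels flip at the configured error rate", {
  g <- small_sim(seed = 11, n_trials = 200, choice_noise = 0.3)
  expect_lt(abs(mean(!g$session$trials$correct) - 0.3), 0.08)
  expect_true(all(g$session$trials$correct ==
                    (g$session$trials$choice_side ==
                       g$session$trials$stimulus_side)))
})

test_that("unstable coupling configurations are rejected", {
  cfg <- sim_config(n_neurons = c(ALM = 20, PPC = 20), n_trials = 24,
                    coupling_density = 0.5, coupling_strength = 3,
                    baseline_rate = 0.8)
  expect_error(generate_session(cfg, seed = 1), "spectral radius")
})

test_that("learning series keeps ids and plants the retained fraction", {
  cfg <- sim_config(n_neurons = c(ALM = 12, PPC = 12), n_trials = 24)
  series <- generate_learning_series(cfg, retained_fraction = 0.32, seed = 4)
  expect_named(series, c("naive", "intermediate", "expert"))
  ids <- lapply(series, function(x) x$session$neuron_ids)
  expect_identical(ids$naive, ids$expert)

  g2 <- ground_truth_graph(series$intermediate$ground_truth,
                           series$intermediate$session)
  g3 <- ground_truth_graph(series$expert$ground_truth,
                           series$expert$session)
  part <- retained_eliminated(g2, g3)
  expect_lt(abs(part$retained_fraction - 0.32), 0.03)

  # planted densities decrease across stages
  dens <- sapply(series, function(x) nrow(x$ground_truth$coupling))
  expect_true(all(diff(dens) < 0))

  expect_error(generate_learning_series(
    cfg, stage_params = list(naive = list(coupling_density = 0.1),
                             intermediate = list(),
                             expert = list(coupling_density = 0.1))),
    "unequal length")
})

test_that("movement traces carry dropouts, outliers and stereotypy", {
  cfg <- sim_config(n_neurons = c(ALM = 5, PPC = 5), n_trials = 30,
                    movement = list(stereotypy = 0.95, noise_px = 0.5,
                                    dropout_fraction = 0, outlier_fraction = 0,
                                    gain_sd = 0.1))
  g <- generate_session(cfg, seed = 6)
  mv <- g$movement
  expect_true(all(mv$likelihood >= 0.95))

  cfg2 <- sim_config(n_neurons = c(ALM = 5, PPC = 5), n_trials = 30,
                     movement = list(stereotypy = 0.95, noise_px = 0.5,
                                     dropout_fraction = 0.05,
                                     outlier_fraction = 0.01, gain_sd = 0.1))
  g2 <- generate_session(cfg2, seed = 6)
  planted <- attr(g2$movement, "planted")$outlier_frames$forelimb_r
  expect_gt(length(planted), 0)
  tr <- g2$movement[g2$movement$bodypart == "forelimb_r", ]
  expect_gt(max(abs(diff(tr$x))), 100)  # injected outliers are visible

  # high stereotypy -> high trial-by-trial correlations after cleaning
  tr1 <- clean_movement_trace(g$movement)
  tr1 <- tr1[tr1$bodypart == "forelimb_r", ]
  class(tr1) <- c("movement_trace", "data.frame")
  st <- movement_stereotypy(tr1, g$session$trials,
                            epoch_spec("resp", "go_cue", 0, 1), "R",
                            frame_rate = g$session$frame_rate, by = "choice")
  expect_gt(st$median, 0.6)
})

test_that("zero tuning SNR leaves choice decoding at chance (shuffle-calibrated)", {
  g <- small_sim(seed = 21, tuning_snr = 0, coupling_density = 0,
                 n_trials = 40)
  s <- g$session
  em <- motifnet:::trial_epoch_means(s, 1:5, default_epochs()$pre_action)
  pv <- sapply(1:5, function(j) {
    shuffle_null_decoding(em[, j], s$trials$choice_side,
                          n_shuffles = 200, seed = j)$p_value
  })
  expect_gt(min(pv), 0.01)   # no spurious strong decoding
})
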