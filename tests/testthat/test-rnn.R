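test_that("init_rnn draws the specified weight distributions", {
  m <- init_rnn(100, 0, g = 1.2, seed = 3)
  expect_equal(sd(m$J), 1.2 / 10, tolerance = 0.012)   # within ~10%
  expect_equal(mean(m$J), 0, tolerance = 0.01)
  expect_equal(diag(m$P), rep(0.01, 100))
  expect_equal(m$P[1, 2], 0)
  expect_equal(sd(m$Wcue), 0.1, tolerance = 0.03)
  expect_identical(init_rnn(100, 0, seed = 3)$J, m$J)   # same seed, same model
})

test_that("a single step decays by 1 - dt/tau and saturates correctly", {
  m <- init_rnn(4, 0, seed = 1)
  m$J[] <- 0
  st <- rnn_step(m, x = rep(1, 4))
  expect_equal(st$x, rep(0.9, 4))                     # decay factor 0.9
  # closed-form geometric decay over many steps
  x <- rep(2, 4)
  for (i in 1:30) x <- rnn_step(m, x)$x
  expect_equal(x, rep(2 * 0.9^30, 4), tolerance = 1e-12)
  # sigmoid midpoint (x = theta -> r = 0.5 after pure decay accounted) and
  # saturation
  st_theta <- rnn_step(m, rep(m$theta / 0.9, 4))  # decays exactly to theta
  expect_equal(st_theta$r, rep(0.5, 4), tolerance = 1e-12)
  big <- rnn_step(m, rep(100, 4))
  expect_true(all(big$r > 0.999))
})

test_that("prepare_targets clips, rescales, inverts and upsamples", {
  act <- list(right = matrix(c(2.5, 2.5, 2.5, 2.5), 1, 4),
              left = matrix(c(2.5, 2.5, 2.5, 2.5), 1, 4))
  tg <- prepare_targets(act, seed = 1)
  # normalized r = 0.5 -> f = theta + ln(1)/beta = 3.0
  expect_equal(unname(tg$f_right[1, 5]), 3.0, tolerance = 1e-8)
  expect_equal(ncol(tg$f_right), 40L)                 # x10 upsampling

  # clipping keeps the inverse sigmoid finite
  act2 <- list(right = matrix(c(7, 7, 0, 0), 2, 2),
               left = matrix(c(7, 7, 0, 0), 2, 2))
  tg2 <- prepare_targets(act2, seed = 1)
  expect_true(all(is.finite(tg2$f_right)))

  # units that never exceed 1 SD of the normalized pool are excluded
  act3 <- list(right = rbind(c(4, 4, 4), c(0.02, 0.02, 0.02)),
               left = rbind(c(4, 4, 4), c(0.02, 0.02, 0.02)))
  tg3 <- prepare_targets(act3, seed = 1)
  expect_equal(nrow(tg3$f_right), 1L)
})

test_that("mse_filter removes high-MSE models by the mean + SD rule", {
  mk <- function(mse) structure(list(mse = mse), class = "rnn_model")
  models <- lapply(c(1, 1, 10), mk)
  kept <- mse_filter(models)
  expect_length(kept, 2L)                  # threshold 4 + 5.196 = 9.196
  expect_identical(attr(kept, "excluded"), 3L)
  all_same <- lapply(c(2, 2, 2), mk)
  expect_length(mse_filter(all_same), 3L)
})

test_that("trial inputs live on their stated supports", {
  sh <- motifnet:::rnn_input_shapes(3500)
  t <- sh$t
  expect_true(all(sh$stim[t < -3 | t > -2] == 0))
  expect_true(all(sh$cue[t < -2.1 | t > -2] == 0))
  expect_true(all(sh$distractor[t < -1.75 | t >= -1.25] == 0))
  expect_equal(max(sh$stim), 1, tolerance = 1e-3)
  expect_equal(max(sh$cue), 1, tolerance = 0.05)
})

test_that("training runs, records MSE, and is seed-reproducible", {
  tg <- synthetic_rnn_targets(12, 4, n_samples = 60, seed = 2)
  m0 <- init_rnn(12, 4, seed = 2)
  m1 <- force_train(m0, tg, epochs = 6, seed = 5)
  m2 <- force_train(m0, tg, epochs = 6, seed = 5)
  expect_identical(m1$J, m2$J)
  expect_true(is.finite(m1$mse))
  expect_false(isTRUE(all.equal(m1$J, m0$J)))
  # P stays symmetric through the rank-1 downdates
  expect_lt(max(abs(m1$P - t(m1$P))), 1e-8)
  expect_error(force_train(init_rnn(5, 0, seed = 1), tg), "dimension")
})

test_that("ablate_external zeroes only the off-diagonal blocks", {
  tg <- synthetic_rnn_targets(10, 4, n_samples = 50, seed = 3)
  m <- force_train(init_rnn(10, 4, seed = 3), tg, epochs = 4, seed = 4)
  # fabricate a separated reference to isolate the ablation mechanics
  ref <- list(axis = rep(1 / sqrt(10), 10), norm = 1, end_R = 1, end_L = 0,
              halfway = 0.5)
  res <- ablate_external(m, fraction = 1, iters = 1,
                         distractor = list(mean = 0), n_trials = 2,
                         n_left = 2, ref = ref, seed = 9)
  expect_true(is.list(res))
  expect_error(ablate_external(m, fraction = 1.5), "fraction")
  m_noext <- force_train(init_rnn(8, 0, seed = 1),
                         synthetic_rnn_targets(8, 0, n_samples = 40, seed = 1),
                         epochs = 2, seed = 2)
  expect_error(ablate_external(m_noext, 0.5), "n_external")
})

test_that("run_trials with zero-amplitude distractor matches plain trials", {
  tg <- synthetic_rnn_targets(10, 0, n_samples = 50, seed = 4)
  m <- force_train(init_rnn(10, 0, seed = 4), tg, epochs = 4, seed = 5)
  ref <- list(axis = rep(1 / sqrt(10), 10), norm = 1, end_R = 1, end_L = 0,
              halfway = 0.5)
  a <- run_trials(m, "left", n_trials = 3, ref = ref, seed = 6,
                  distractor = list(mean = 0, sd = 0))
  b <- run_trials(m, "left", n_trials = 3, ref = ref, seed = 6)
  expect_equal(a$proj, b$proj, tolerance = 1e-10)
})
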