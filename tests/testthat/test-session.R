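test_that("epoch_frames follows the truncation convention and bounds", {
  trial <- data.frame(stimulus_onset_frame = 0L, go_cue_frame = 100L)
  pre <- epoch_spec("pre_action", "go_cue", -1, 0)
  fr <- epoch_frames(pre, trial, 9.35)
  expect_identical(attr(fr, "range"), c(start = 91L, end = 100L))
  expect_length(fr, 9L)

  stim <- epoch_spec("stimulus", "stimulus_onset", 0, 1)
  fr2 <- epoch_frames(stim, trial, 9.35)
  expect_identical(as.integer(fr2), 0:8)

  # epoch leaving the recording start errors so callers can skip the trial
  spont <- epoch_spec("spont", "stimulus_onset", -2, 0)
  trial2 <- data.frame(stimulus_onset_frame = 5L, go_cue_frame = 40L)
  expect_error(epoch_frames(spont, trial2, 9.35), "outside")

  # conversion is idempotent / deterministic
  expect_identical(epoch_frames(pre, trial, 9.35), epoch_frames(pre, trial, 9.35))
})

test_that("trial_table and session validate their invariants", {
  expect_error(trial_table("L", "L", 10L, 5L), "ordering")
  tt <- trial_table(c("L", "R"), c("L", "L"), c(0L, 50L), c(30L, 80L),
                    c(33L, 83L))
  expect_identical(tt$correct, c(TRUE, FALSE))
  expect_error(session(matrix(-1, 1, 100), tt, "ALM"), "nonnegative")
  expect_error(session(matrix(1, 2, 100), tt, c("ALM", "PPC"),
                       neuron_ids = c(1L, 1L)), "unique")
  expect_error(session(matrix(1, 1, 50), tt, "ALM"), "outside")
})

test_that("filter_active_neurons applies the per-window z rule", {
  # 2 windows of 60 frames at rate 1 Hz with window_s = 60
  nf <- 120L
  base <- rep(0.1, nf)
  mk <- function(spikes) { v <- base; v[spikes] <- 10; v }
  act <- rbind(
    mk(c(10, 70)),   # event in both windows -> kept
    mk(c(10)),       # only first window -> removed
    rep(0.1, nf)     # constant -> removed (z undefined)
  )
  tt <- trial_table("L", "L", 5L, 20L, 22L)
  s <- session(act, tt, rep("ALM", 3), frame_rate = 1)
  kept <- filter_active_neurons(s, z_threshold = 5, window_s = 60)
  expect_identical(kept$neuron_ids, 1L)
  expect_error(filter_active_neurons(s, z_threshold = 1e6, window_s = 60),
               "all neurons removed")
})

test_that("filter_active_neurons is monotone in the threshold", {
  s <- toy_session(n_neurons = 8, seed = 42)
  kept_hi <- tryCatch(
    filter_active_neurons(s, z_threshold = 4, window_s = 20)$neuron_ids,
    error = function(e) integer(0))
  kept_lo <- filter_active_neurons(s, z_threshold = 2, window_s = 20)$neuron_ids
  expect_true(all(kept_hi %in% kept_lo))
})

test_that("session round-trips losslessly through the text container", {
  s <- toy_session(n_neurons = 10, n_trials = 3, seed = 7)
  s$trials$choice_side[2] <- "none"
  s$trials$response_frame[2] <- NA_integer_
  s$trials$correct[2] <- FALSE
  s$trials$rewarded[2] <- FALSE
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$activity, s$activity, ignore_attr = TRUE)
  expect_identical(s2$neuron_ids, s$neuron_ids)
  expect_identical(s2$regions, s$regions)
  expect_identical(s2$stage, s$stage)
  expect_equal(s2$frame_rate, s$frame_rate)
  expect_equal(as.data.frame(s2$trials), as.data.frame(s$trials))

  file.remove(file.path(dir, "neurons.csv"))
  expect_error(read_session(dir), "neurons.csv")
})

test_that("trial table CSV schema errors name the missing column", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(stimulus_side = "L"), path, row.names = FALSE)
  expect_error(read_trials_csv(path), "choice_side")
})
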