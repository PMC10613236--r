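#' Compute a stimulus or choice coding direction
#'
#' The mode axis is the unit-norm vector of per-neuron trial-averaged
#' activity differences between right and left trials in the defining
#' epoch: `w = (rbar_R - rbar_L) / ||rbar_R - rbar_L||`. Choice mode groups
#' trials by lick side regardless of stimulus (error trials included);
#' stimulus mode groups by stimulus side regardless of choice. Positive
#' weights mark right-preferring neurons.
#'
#' @param s A [session()].
#' @param region Region label; neurons of this region define the axis.
#' @param mode `"choice"` or `"stimulus"`.
#' @param epoch Defining [epoch_spec()]; defaults to the pre-action epoch
#'   for choice and the stimulus epoch for stimulus.
#' @param min_neurons,min_trials Exclusion thresholds (defaults 20 neurons,
#'   5 trials per side).
#' @return Object of class `mode_axis`: `weights` (unit l2 norm), `mode`,
#'   `region`, `neuron_ids`, `defining_epoch`, `orthogonalized`.
#' @export
compute_mode_axis <- function(s, region, mode = c("choice", "stimulus"),
                              epoch = NULL, min_neurons = 20, min_trials = 5) {
  mode <- match.arg(mode)
  if (is.null(epoch)) {
    epoch <- default_epochs()[[if (mode == "choice") "pre_action" else "stimulus"]]
  }
  idx <- region_index(s, region)
  if (length(idx) < min_neurons) {
    stop("compute_mode_axis: region '", region, "' has ", length(idx),
         " neurons (< ", min_neurons, "), excluded")
  }
  side <- if (mode == "choice") s$trials$choice_side else s$trials$stimulus_side
  usable <- side %in% c("L", "R")
  if (sum(side == "L") < min_trials || sum(side == "R") < min_trials) {
    stop("compute_mode_axis: fewer than ", min_trials,
         " trials per side, session excluded")
  }
  em <- trial_epoch_means(s, idx, epoch)     # trials x neurons (NA if skipped)
  ok <- usable & !is.na(em[, 1L])
  rbar_R <- colMeans(em[ok & side == "R", , drop = FALSE])
  rbar_L <- colMeans(em[ok & side == "L", , drop = FALSE])
  d <- rbar_R - rbar_L
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("compute_mode_axis: degenerate axis (zero difference)")
  structure(
    list(weights = d / nrm, mode = mode, region = region,
         neuron_ids = s$neuron_ids[idx], defining_epoch = epoch,
         orthogonalized = FALSE),
    class = "mode_axis")
}

# per-trial epoch-mean activity for a neuron subset; trials whose epoch
# leaves the recording yield NA rows (logged once)
trial_epoch_means <- function(s, idx, epoch) {
  nt <- nrow(s$trials)
  out <- matrix(NA_real_, nt, length(idx))
  skipped <- 0L
  for (k in seq_len(nt)) {
    fr <- tryCatch(epoch_frames(epoch, s$trials[k, ], s$frame_rate,
                                n_frames(s)),
                   error = function(e) NULL)
    if (is.null(fr)) { skipped <- skipped + 1L; next }
    out[k, ] <- rowMeans(s$activity[idx, frame_cols(fr), drop = FALSE])
  }
  if (skipped > 0L) {
    warning("trial_epoch_means: ", skipped,
            " trial(s) skipped (epoch outside recording)")
  }
  out
}

#' Gram-Schmidt orthogonalization of the stimulus axis against choice
#'
#' The choice axis is kept fixed; the stimulus axis has its projection onto
#' choice removed and is renormalized. The output axes have dot product
#' below 1e-10.
#'
#' @param choice,stimulus `mode_axis` objects over the same neuron set.
#' @return List `(choice, stimulus)` of `mode_axis` objects.
#' @export
orthogonalize_axes <- function(choice, stimulus) {
  stopifnot(inherits(choice, "mode_axis"), inherits(stimulus, "mode_axis"))
  if (!identical(choice$neuron_ids, stimulus$neuron_ids)) {
    stop("orthogonalize_axes: axes defined on different neuron sets")
  }
  v <- stimulus$weights - sum(stimulus$weights * choice$weights) * choice$weights
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) {
    stop("orthogonalize_axes: stimulus axis parallel to choice (degenerate)")
  }
  stimulus$weights <- v / nrm
  stimulus$orthogonalized <- TRUE
  choice$orthogonalized <- TRUE
  list(choice = choice, stimulus = stimulus)
}

#' Project trials onto a mode axis
#'
#' Computes the per-trial projection time series `p_k = X_k w` over a
#' stimulus-locked window, then subtracts the condition-specific baseline:
#' the trial-averaged projection during the ITI baseline epoch for trials of
#' the same condition (the axis's mode labels).
#'
#' @param s A [session()].
#' @param axis A `mode_axis` from [compute_mode_axis()].
#' @param window_s Length-2 window in seconds relative to stimulus onset
#'   (default `c(-2, 5)`).
#' @param baseline_epoch [epoch_spec()] for the baseline (default ITI
#'   `[-1, 0)` s from stimulus onset); `NULL` skips baseline subtraction.
#' @return Object of class `trial_projection`: `proj` (trials x window
#'   frames, NA rows for skipped trials), `offsets_s`, labels and per-trial
#'   event frames.
#' @export
project_trials <- function(s, axis, window_s = c(-2, 5),
                           baseline_epoch = default_epochs()$iti_baseline) {
  stopifnot(inherits(axis, "mode_axis"))
  idx <- match(axis$neuron_ids, s$neuron_ids)
  if (anyNA(idx)) stop("project_trials: axis neurons missing from session")
  if (length(axis$weights) != length(idx)) stop("project_trials: dimension error")
  fr <- s$frame_rate
  off <- seq.int(sec_to_frames(window_s[1L], fr),
                 sec_to_frames(window_s[2L], fr) - 1L)
  nt <- nrow(s$trials)
  proj <- matrix(NA_real_, nt, length(off))
  w <- axis$weights
  for (k in seq_len(nt)) {
    cols <- s$trials$stimulus_onset_frame[k] + off + 1L
    if (cols[1L] < 1L || cols[length(cols)] > n_frames(s)) next
    proj[k, ] <- as.numeric(crossprod(s$activity[idx, cols, drop = FALSE], w))
  }
  side <- if (axis$mode == "choice") s$trials$choice_side else s$trials$stimulus_side
  tp <- structure(
    list(proj = proj, offsets_s = off / fr, frame_offsets = off,
         mode = axis$mode, side = side,
         stimulus_side = s$trials$stimulus_side,
         choice_side = s$trials$choice_side,
         trials = s$trials, frame_rate = fr),
    class = "trial_projection")
  if (!is.null(baseline_epoch)) {
    bl <- projection_epoch_means(tp, baseline_epoch)
    for (cond in c("L", "R")) {
      rows <- which(side == cond & !is.na(proj[, 1L]))
      if (!length(rows)) next
      tp$proj[rows, ] <- tp$proj[rows, , drop = FALSE] -
        mean(bl[rows], na.rm = TRUE)
    }
  }
  tp
}

#' Per-trial epoch means of a projection
#'
#' @param tp A `trial_projection`.
#' @param epoch An [epoch_spec()] (anchored to stimulus onset or go cue).
#' @return Numeric vector, one mean per trial (NA where unavailable).
#' @export
projection_epoch_means <- function(tp, epoch) {
  fr <- tp$frame_rate
  nt <- nrow(tp$proj)
  out <- rep(NA_real_, nt)
  for (k in seq_len(nt)) {
    if (is.na(tp$proj[k, 1L])) next
    ev_abs <- switch(epoch$reference_event,
                     stimulus_onset = tp$trials$stimulus_onset_frame[k],
                     go_cue = tp$trials$go_cue_frame[k])
    ev_rel <- ev_abs - tp$trials$stimulus_onset_frame[k]
    a <- ev_rel + sec_to_frames(epoch$start_offset_s, fr)
    b <- ev_rel + sec_to_frames(epoch$end_offset_s, fr)
    pos <- match(seq.int(a, b - 1L), tp$frame_offsets)
    if (anyNA(pos)) next
    out[k] <- mean(tp$proj[k, pos])
  }
  out
}

#' Choice selectivity of projected population activity
#'
#' Difference of right minus left mean epoch-averaged projection.
#'
#' @param tp A `trial_projection` (choice mode).
#' @param epoch Epoch over which to average (default pre-action).
#' @return Scalar selectivity.
#' @export
choice_selectivity <- function(tp, epoch = default_epochs()$pre_action) {
  em <- projection_epoch_means(tp, epoch)
  r <- em[tp$side == "R"]; l <- em[tp$side == "L"]
  if (!sum(!is.na(r)) || !sum(!is.na(l))) {
    stop("choice_selectivity: a condition is missing")
  }
  mean(r, na.rm = TRUE) - mean(l, na.rm = TRUE)
}

#' Trial-by-trial inter-areal coordination
#'
#' Pearson correlation of epoch-averaged projections between two regions of
#' the same session, either within each trial type (`same_type`, returns a
#' correlation per type) or pooled over all trials (`both_types`).
#'
#' @param tpA,tpB `trial_projection`s from the same session (aligned trials).
#' @param epoch Averaging epoch.
#' @param scope `"same_type"` or `"both_types"`.
#' @return Named numeric (per type) or scalar; fewer than 3 usable trials
#'   in a scope yields NA.
#' @export
interregion_coordination <- function(tpA, tpB,
                                     epoch = default_epochs()$pre_action,
                                     scope = c("same_type", "both_types")) {
  scope <- match.arg(scope)
  if (nrow(tpA$proj) != nrow(tpB$proj)) {
    stop("interregion_coordination: trial tables not aligned")
  }
  a <- projection_epoch_means(tpA, epoch)
  b <- projection_epoch_means(tpB, epoch)
  ok <- !is.na(a) & !is.na(b)
  if (scope == "both_types") {
    if (sum(ok) < 3L) return(NA_real_)
    return(stats::cor(a[ok], b[ok]))
  }
  vapply(c(L = "L", R = "R"), function(side) {
    sel <- ok & tpA$side == side
    if (sum(sel) < 3L) return(NA_real_)
    stats::cor(a[sel], b[sel])
  }, numeric(1))
}

#' Trial-balanced coordination estimate
#'
#' Controls trial-type imbalance by resampling `n_per_type` trials with
#' replacement per type, recomputing the coordination, and averaging over
#' `iters` iterations.
#'
#' @inheritParams interregion_coordination
#' @param n_per_type Resample size per trial type (default 40).
#' @param iters Resampling iterations (default 100).
#' @param seed Integer seed.
#' @return Mean correlation over iterations (per-type named vector for
#'   `same_type`, scalar for `both_types`).
#' @export
balanced_coordination <- function(tpA, tpB,
                                  epoch = default_epochs()$pre_action,
                                  scope = c("same_type", "both_types"),
                                  n_per_type = 40, iters = 100, seed = 1L) {
  scope <- match.arg(scope)
  a <- projection_epoch_means(tpA, epoch)
  b <- projection_epoch_means(tpB, epoch)
  ok <- !is.na(a) & !is.na(b)
  rows <- list(L = which(ok & tpA$side == "L"),
               R = which(ok & tpA$side == "R"))
  if (!length(rows$L) || !length(rows$R)) {
    stop("balanced_coordination: a trial type is absent")
  }
  set.seed(seed)
  acc <- NULL
  for (it in seq_len(iters)) {
    pick <- lapply(rows, function(r) r[sample.int(length(r), n_per_type,
                                                  replace = TRUE)])
    if (scope == "both_types") {
      sel <- c(pick$L, pick$R)
      r <- stats::cor(a[sel], b[sel])
    } else {
      r <- vapply(pick, function(sel) stats::cor(a[sel], b[sel]), numeric(1))
      names(r) <- names(pick)
    }
    acc <- if (is.null(acc)) r else acc + r
  }
  acc / iters
}
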