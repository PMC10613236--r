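#' Raised-cosine temporal basis
#'
#' `n_bases` half-overlapping raised cosines `0.5 (1 + cos(pi (t - c_j)/w))`
#' tiling `[0, span_s)`: peak centers `c_j = (j - 1/2) span / n` are evenly
#' spaced, the half-width `w` equals the center spacing so interior bases
#' sum to a constant, and each column is rescaled to peak value 1 on the
#' frame grid. Clipped to zero outside each support.
#'
#' @param n_bases Number of bases (>= 1).
#' @param span_s Span in seconds (> 1 frame).
#' @param frame_rate Hz.
#' @return Matrix `frames x n_bases` with attributes `span_s`, `frame_rate`.
#' @export
raised_cosine_basis <- function(n_bases, span_s, frame_rate) {
  stopifnot(n_bases >= 1, span_s > 0)
  nf <- sec_to_frames(span_s, frame_rate)
  if (nf < 1L) stop("raised_cosine_basis: span shorter than one frame")
  t <- (seq_len(nf) - 0.5) / frame_rate
  w <- span_s / n_bases
  centers <- (seq_len(n_bases) - 0.5) * w
  B <- vapply(centers, function(c0) {
    v <- 0.5 * (1 + cos(pi * (t - c0) / w))
    v[abs(t - c0) > w] <- 0
    v
  }, numeric(nf))
  B <- matrix(B, nrow = nf)
  peak <- apply(B, 2L, max)
  B <- sweep(B, 2L, peak, "/")
  attr(B, "span_s") <- span_s
  attr(B, "frame_rate") <- frame_rate
  B
}

# convolve an impulse train with one basis column (causal, anchored at the
# impulse plus anchor_frames)
convolve_events <- function(impulse, basis_col, anchor_frames = 0L) {
  nf <- length(impulse)
  out <- numeric(nf)
  pos <- which(impulse != 0)
  for (p in pos) {
    start <- p + anchor_frames
    idx <- start:(start + length(basis_col) - 1L)
    keep <- idx >= 1L & idx <= nf
    out[idx[keep]] <- out[idx[keep]] + impulse[p] * basis_col[keep]
  }
  out
}

# task-variable predictor block shared by all target neurons of a session
task_predictors <- function(s, movement = NULL) {
  fr <- s$frame_rate
  nf <- n_frames(s)
  tt <- s$trials
  imp <- function(frames0) {
    v <- numeric(nf)
    f <- frames0[!is.na(frames0)] + 1L
    v[f[f >= 1L & f <= nf]] <- 1
    v
  }
  b_stim <- raised_cosine_basis(3, 1.0, fr)
  b_delay <- raised_cosine_basis(5, 1.5, fr)
  b_resp <- raised_cosine_basis(5, 1.5, fr)
  b_rew <- raised_cosine_basis(3, 1.0, fr)
  b_move <- raised_cosine_basis(3, 1.0, fr)
  delay_on <- tt$stimulus_onset_frame + sec_to_frames(1, fr)
  resp_anchor <- sec_to_frames(-0.75, fr)   # 0.75 s before end of delay
  cols <- list(); groups <- character(0)
  add <- function(impulse, basis, group, anchor = 0L) {
    for (b in seq_len(ncol(basis))) {
      cols[[length(cols) + 1L]] <<- convolve_events(impulse, basis[, b], anchor)
      groups <<- c(groups, group)
    }
  }
  for (side in c("L", "R")) {
    add(imp(tt$stimulus_onset_frame[tt$stimulus_side == side]), b_stim,
        paste0("stim", side))
    add(imp(delay_on[tt$stimulus_side == side]), b_delay, paste0("delay", side))
    add(imp(tt$go_cue_frame[tt$choice_side == side]), b_resp,
        paste0("resp", side), anchor = resp_anchor)
  }
  add(imp(tt$response_frame[tt$rewarded]), b_rew, "reward")
  if (!is.null(movement)) {
    for (side in c("l", "r")) {
      bp <- paste0("forelimb_", side)
      sp <- movement_imaging_speed(movement[movement$bodypart == bp, ,
                                            drop = FALSE], fr, nf)
      for (b in seq_len(ncol(b_move))) {
        cols[[length(cols) + 1L]] <- as.numeric(
          stats::filter(sp, b_move[, b], sides = 1L, method = "convolution"))
        groups <- c(groups, paste0("move", toupper(side)))
      }
    }
  }
  X <- do.call(cbind, cols)
  X[is.na(X)] <- 0
  colnames(X) <- make.unique(groups, sep = "_b")
  list(X = X, groups = groups)
}

# lagged (1 and 2 frame) activity of every neuron, frames x (2n)
coupling_predictors <- function(s) {
  a <- t(s$activity)                 # frames x neurons
  nf <- nrow(a)
  lag_shift <- function(m, k) rbind(matrix(0, k, ncol(m)),
                                    m[seq_len(nf - k), , drop = FALSE])
  L1 <- lag_shift(a, 1L); L2 <- lag_shift(a, 2L)
  colnames(L1) <- paste0("cpl_", s$neuron_ids, "_lag1")
  colnames(L2) <- paste0("cpl_", s$neuron_ids, "_lag2")
  list(L1 = L1, L2 = L2)
}

zscore_cols <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  keep <- sd_ > 0
  Xz <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd_[keep], "/")
  list(X = Xz, dropped = colnames(X)[!keep])
}

#' Build the encoding-model design matrix for one target neuron
#'
#' Task predictors are event impulses convolved with their raised-cosine
#' sets (stimulus 3 bases over 1 s; delay 5 over 1.5 s from stimulus
#' offset; response 5 over 1.5 s starting 0.75 s before the delay ends,
#' split by lick side; reward 3 over 1 s; per-forelimb movement speed
#' convolved with 3 bases). Cell-coupling predictors are every other
#' neuron's activity at lags 1 and 2 frames. All columns are z-scored;
#' constant columns are dropped and recorded.
#'
#' @param s A [session()].
#' @param target_id Neuron id being predicted (its own activity is never a
#'   predictor).
#' @param movement Optional 60 Hz `movement_trace`; `NULL` omits movement
#'   columns.
#' @return List of class `design_matrix`: `X` (z-scored), `groups`
#'   (per-column predictor-group tag, coupling tagged
#'   `cpl_<source>_lag<k>`), `dropped` column names.
#' @export
build_design_matrix <- function(s, target_id, movement = NULL) {
  task <- task_predictors(s, movement)
  cpl <- coupling_predictors(s)
  keep <- s$neuron_ids != target_id
  if (all(keep)) stop("build_design_matrix: unknown target_id ", target_id)
  X <- cbind(task$X, cpl$L1[, keep, drop = FALSE], cpl$L2[, keep, drop = FALSE])
  groups <- c(task$groups,
              colnames(cpl$L1)[keep], colnames(cpl$L2)[keep])
  z <- zscore_cols(X)
  groups <- groups[colnames(X) %in% colnames(z$X)]
  if (length(z$dropped)) {
    warning("build_design_matrix: dropped constant column(s): ",
            paste(z$dropped, collapse = ", "))
  }
  structure(list(X = z$X, groups = groups, dropped = z$dropped,
                 target_id = target_id),
            class = "design_matrix")
}
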