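#' Read a tracking-export CSV
#'
#' Expects the columns `bodypart, frame, x, y, likelihood` (60 Hz pose
#' estimates with per-point confidence).
#'
#' @param path CSV file.
#' @return A `movement_trace` data.frame.
#' @export
read_tracking_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bodypart", "frame", "x", "y", "likelihood")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("read_tracking_csv: missing column(s): ", paste(miss, collapse = ", "))
  }
  class(tr) <- c("movement_trace", "data.frame")
  tr
}

#' Clean a movement trace
#'
#' Three steps, in order, applied per body part:
#' 1. points with likelihood < `lik_threshold` are replaced by linear
#'    interpolation between the nearest flanking high-likelihood points
#'    (edges extend the nearest valid value);
#' 2. points deviating more than `mad_factor` times the median absolute
#'    deviation within a centered 5-frame window are replaced by the
#'    previous (already cleaned) value — the next valid value for frame 1;
#' 3. a 3-frame centered moving-average smooth.
#' The MAD is unscaled (no 1.4826 consistency factor).
#'
#' @param trace A `movement_trace` data.frame.
#' @param lik_threshold Likelihood cutoff (default 0.95).
#' @param mad_factor Outlier threshold in MADs (default 3).
#' @return The cleaned trace (likelihood set to 1 at interpolated points).
#' @export
clean_movement_trace <- function(trace, lik_threshold = 0.95, mad_factor = 3) {
  stopifnot(is.data.frame(trace), nrow(trace) >= 5)
  parts <- split(seq_len(nrow(trace)), trace$bodypart)
  for (idx in parts) {
    ord <- idx[order(trace$frame[idx])]
    for (col in c("x", "y")) {
      v <- trace[[col]][ord]
      lik <- trace$likelihood[ord]
      v <- interp_low_likelihood(v, lik, lik_threshold)
      v <- replace_mad_outliers(v, mad_factor, window = 5L)
      v <- moving_average(v, 3L)
      trace[[col]][ord] <- v
    }
    trace$likelihood[ord] <- pmax(trace$likelihood[ord], 1)
  }
  trace
}

interp_low_likelihood <- function(v, lik, threshold) {
  good <- lik >= threshold
  if (!any(good)) stop("clean_movement_trace: no point with likelihood >= ",
                       threshold)
  if (all(good)) return(v)
  out <- stats::approx(which(good), v[good], xout = seq_along(v),
                       rule = 2)$y
  out
}

replace_mad_outliers <- function(v, mad_factor, window = 5L) {
  n <- length(v)
  half <- window %/% 2L
  out <- v
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- v[lo:hi]
    med <- stats::median(w)
    mad_ <- stats::median(abs(w - med))
    if (mad_ > 0 && abs(v[i] - med) > mad_factor * mad_) {
      out[i] <- if (i > 1L) out[i - 1L] else v[which(abs(v - med) <=
                                                       mad_factor * mad_)[1L]]
    }
  }
  out
}

moving_average <- function(v, k = 3L) {
  n <- length(v)
  out <- v
  half <- k %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(v[lo:hi])
  }
  out
}

#' Path length within an epoch
#'
#' Euclidean distance (pixels) travelled across consecutive frames of a
#' cleaned single-bodypart trace restricted to `frames` (0-based, 60 Hz).
#'
#' @param trace Single-bodypart `movement_trace`.
#' @param frames Integer vector of 0-based 60 Hz frame indices.
#' @return Total distance in pixels (0 with a warning if < 2 frames fall
#'   in the epoch).
#' @export
epoch_distance <- function(trace, frames) {
  sel <- trace[trace$frame %in% frames, , drop = FALSE]
  sel <- sel[order(sel$frame), , drop = FALSE]
  if (nrow(sel) < 2L) {
    warning("epoch_distance: epoch shorter than 2 frames; returning 0")
    return(0)
  }
  sum(sqrt(diff(sel$x)^2 + diff(sel$y)^2))
}

#' Movement stereotypy across trials
#'
#' For every trial of the requested type, the epoch trajectory is baseline
#' subtracted (coordinates at the trial's first frame) and flattened as
#' `c(x, y)`; all trial pairs are Pearson-correlated. Pairs involving a
#' zero-variance trajectory are undefined and excluded (count reported).
#'
#' @param trace Single-bodypart cleaned `movement_trace` (60 Hz).
#' @param trials A [trial_table()] (imaging-frame indices).
#' @param epoch An [epoch_spec()].
#' @param trial_type `"L"` or `"R"`; trials are selected by `by`.
#' @param frame_rate Imaging rate used by the trial table (Hz).
#' @param by Label trials by `"stimulus"` or `"choice"` side.
#' @return List with `correlations` (vector over trial pairs), `median`,
#'   and `n_excluded`.
#' @export
movement_stereotypy <- function(trace, trials, epoch, trial_type,
                                frame_rate = 9.35,
                                by = c("stimulus", "choice")) {
  by <- match.arg(by)
  side <- if (by == "stimulus") trials$stimulus_side else trials$choice_side
  rows <- which(side == trial_type)
  if (length(rows) < 2L) stop("movement_stereotypy: need >= 2 trials of type ",
                              trial_type)
  trajs <- list()
  for (k in rows) {
    fr_img <- tryCatch(epoch_frames(epoch, trials[k, ], frame_rate),
                       error = function(e) NULL)
    if (is.null(fr_img)) next
    rng <- attr(fr_img, "range")
    f60 <- seq.int(as.integer(floor(rng[["start"]] / frame_rate * 60)),
                   as.integer(ceiling(rng[["end"]] / frame_rate * 60)) - 1L)
    sel <- trace[trace$frame %in% f60, , drop = FALSE]
    sel <- sel[order(sel$frame), , drop = FALSE]
    if (nrow(sel) < 2L) next
    # baseline = position at the beginning of the trial (stimulus onset)
    f0 <- as.integer(floor(trials$stimulus_onset_frame[k] / frame_rate * 60))
    t0 <- trace[trace$frame == f0, , drop = FALSE]
    bx <- if (nrow(t0)) t0$x[1L] else sel$x[1L]
    by0 <- if (nrow(t0)) t0$y[1L] else sel$y[1L]
    trajs[[length(trajs) + 1L]] <- list(x = sel$x - bx, y = sel$y - by0)
  }
  if (length(trajs) < 2L) stop("movement_stereotypy: < 2 usable trials")
  len <- min(vapply(trajs, function(z) length(z$x), integer(1)))
  trajs <- lapply(trajs, function(z) c(z$x[seq_len(len)], z$y[seq_len(len)]))
  m <- length(trajs)
  cors <- c(); n_excl <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (stats::sd(trajs[[i]]) == 0 || stats::sd(trajs[[j]]) == 0) {
        n_excl <- n_excl + 1L
        next
      }
      cors <- c(cors, stats::cor(trajs[[i]], trajs[[j]]))
    }
  }
  list(correlations = cors,
       median = if (length(cors)) stats::median(cors) else NA_real_,
       n_excluded = n_excl)
}
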