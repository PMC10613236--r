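#' Reduced-rank regression
#'
#' Multivariate linear regression of a target population on a source
#' population with a rank constraint: the OLS solution is projected onto
#' the top-`rank` right singular structure of the fitted values. Inputs
#' are centered internally. Cross-validated performance is the fraction of
#' (centered) target variance explained, averaged over contiguous folds.
#'
#' @param x Source matrix, samples x p.
#' @param y Target matrix, samples x q.
#' @param rank Rank constraint (<= min(p, q)).
#' @param cv_folds Folds for predictive performance (default 10); 0 skips.
#' @return Object of class `rrr_fit`: `coef` (p x q, rank <= `rank`),
#'   `rank`, `x_center`, `y_center`, `performance` (CV fraction of
#'   variance explained, NA when `cv_folds = 0`),
#'   `training_r2`.
#' @export
fit_rrr <- function(x, y, rank, cv_folds = 10) {
  x <- as.matrix(x); y <- as.matrix(y)
  p <- ncol(x); q <- ncol(y)
  if (rank > min(p, q)) stop("fit_rrr: rank > min(p, q)")
  if (nrow(x) != nrow(y)) stop("fit_rrr: sample mismatch")
  if (nrow(x) <= max(p, q)) stop("fit_rrr: need samples > max(p, q)")
  solve_rrr <- function(xtr, ytr) {
    xc <- scale(xtr, scale = FALSE); yc <- scale(ytr, scale = FALSE)
    b_ols <- qr.coef(qr(xc), yc)
    b_ols[is.na(b_ols)] <- 0
    fitted <- xc %*% b_ols
    sv <- svd(fitted, nu = 0, nv = rank)
    v <- sv$v[, seq_len(rank), drop = FALSE]
    list(coef = b_ols %*% v %*% t(v),
         x_center = attr(xc, "scaled:center"),
         y_center = attr(yc, "scaled:center"))
  }
  full <- solve_rrr(x, y)
  pred_full <- sweep(sweep(x, 2L, full$x_center) %*% full$coef, 2L,
                     full$y_center, "+")
  yc_all <- sweep(y, 2L, colMeans(y))
  training_r2 <- 1 - sum((y - pred_full)^2) / sum(yc_all^2)
  perf <- NA_real_
  if (cv_folds > 0) {
    n <- nrow(x)
    foldid <- as.integer(cut(seq_len(n), breaks = cv_folds, labels = FALSE))
    sse <- sst <- 0
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f; te <- !tr
      m <- solve_rrr(x[tr, , drop = FALSE], y[tr, , drop = FALSE])
      pr <- sweep(sweep(x[te, , drop = FALSE], 2L, m$x_center) %*% m$coef,
                  2L, m$y_center, "+")
      sse <- sse + sum((y[te, , drop = FALSE] - pr)^2)
      sst <- sst + sum(sweep(y[te, , drop = FALSE], 2L, m$y_center)^2)
    }
    perf <- 1 - sse / sst
  }
  structure(list(coef = full$coef, rank = rank, x_center = full$x_center,
                 y_center = full$y_center, performance = perf,
                 training_r2 = training_r2),
            class = "rrr_fit")
}

#' @export
predict.rrr_fit <- function(object, newdata, ...) {
  sweep(sweep(as.matrix(newdata), 2L, object$x_center) %*% object$coef, 2L,
        object$y_center, "+")
}

#' Correlation-matched reduced-rank performance across stages
#'
#' Matches pairwise ITI correlation distributions across learning stages by
#' removing neurons whose mean pairwise Pearson correlation (spontaneous
#' ITI frames, all-pairs average per neuron) falls below `corr_threshold`,
#' then repeatedly samples `n_sample` source and target neurons and
#' averages cross-validated reduced-rank performance over iterations.
#'
#' @param sessions Named list of [session()] objects (one per stage).
#' @param source_region,target_region Region labels.
#' @param rank Rank constraint (default 4).
#' @param corr_threshold Mean-correlation removal threshold (default
#'   0.0274).
#' @param n_sample Neurons sampled per side (default 20).
#' @param iters Sampling iterations (default 20).
#' @param cv_folds CV folds inside [fit_rrr()] (default 10).
#' @param seed Integer seed.
#' @return Named numeric vector of stagewise mean performance (NA, with a
#'   message, for stages lacking `n_sample` qualifying neurons per side).
#' @export
correlation_matched_rrr <- function(sessions, source_region, target_region,
                                    rank = 4, corr_threshold = 0.0274,
                                    n_sample = 20, iters = 20, cv_folds = 10,
                                    seed = 1L) {
  set.seed(seed)
  ep <- default_epochs()$spontaneous_iti
  out <- stats::setNames(rep(NA_real_, length(sessions)), names(sessions))
  for (st in names(sessions)) {
    s <- sessions[[st]]
    iti_cols <- unique(unlist(lapply(seq_len(nrow(s$trials)), function(k)
      tryCatch(frame_cols(epoch_frames(ep, s$trials[k, ], s$frame_rate,
                                       n_frames(s))),
               error = function(e) integer(0)))))
    a_iti <- s$activity[, sort(iti_cols), drop = FALSE]
    r <- suppressWarnings(stats::cor(t(a_iti)))
    diag(r) <- NA
    mean_r <- rowMeans(r, na.rm = TRUE)
    qualified <- which(!is.na(mean_r) & mean_r >= corr_threshold)
    src_pool <- intersect(qualified, region_index(s, source_region))
    tgt_pool <- intersect(qualified, region_index(s, target_region))
    if (length(src_pool) < n_sample || length(tgt_pool) < n_sample) {
      message("correlation_matched_rrr: stage '", st, "' skipped (",
              length(src_pool), " source / ", length(tgt_pool),
              " target qualifying neurons, need ", n_sample, ")")
      next
    }
    # trial frames only: concatenated stimulus-to-cue windows
    win <- unique(unlist(lapply(seq_len(nrow(s$trials)), function(k) {
      a <- s$trials$stimulus_onset_frame[k]
      b <- s$trials$go_cue_frame[k]
      if (b < n_frames(s)) seq.int(a, b) + 1L else integer(0)
    })))
    perf <- numeric(iters)
    for (it in seq_len(iters)) {
      si <- src_pool[sample.int(length(src_pool), n_sample)]
      ti <- tgt_pool[sample.int(length(tgt_pool), n_sample)]
      fit <- fit_rrr(t(s$activity[si, win, drop = FALSE]),
                     t(s$activity[ti, win, drop = FALSE]),
                     rank = rank, cv_folds = cv_folds)
      perf[it] <- fit$performance
    }
    out[st] <- mean(perf)
  }
  out
}
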