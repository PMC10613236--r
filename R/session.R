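#' Trial table constructor
#'
#' Validates the per-trial event table. Frame indices are 0-based. A trial
#' with no response has `choice_side == "none"` and `response_frame = NA`.
#'
#' @param stimulus_side Character, `"L"` or `"R"` per trial.
#' @param choice_side Character, `"L"`, `"R"` or `"none"`.
#' @param stimulus_onset_frame,go_cue_frame,response_frame Integer 0-based
#'   frame indices (`response_frame` may be `NA` for no-response trials).
#' @param rewarded Logical; defaults to `correct`.
#' @param distractor Logical; default `FALSE`.
#' @return A `data.frame` with class `trial_table`.
#' @export
trial_table <- function(stimulus_side, choice_side, stimulus_onset_frame,
                        go_cue_frame, response_frame = NA_integer_,
                        rewarded = NULL, distractor = FALSE) {
  n <- length(stimulus_side)
  stopifnot(all(stimulus_side %in% c("L", "R")),
            all(choice_side %in% c("L", "R", "none")),
            length(choice_side) == n)
  correct <- choice_side == stimulus_side
  if (is.null(rewarded)) rewarded <- correct
  tt <- data.frame(
    stimulus_side = as.character(stimulus_side),
    choice_side = as.character(choice_side),
    correct = as.logical(correct),
    rewarded = as.logical(rewarded),
    stimulus_onset_frame = as.integer(stimulus_onset_frame),
    go_cue_frame = as.integer(go_cue_frame),
    response_frame = as.integer(rep_len(response_frame, n)),
    distractor = as.logical(rep_len(distractor, n)),
    stringsAsFactors = FALSE
  )
  bad <- with(tt, stimulus_onset_frame >= go_cue_frame |
                (!is.na(response_frame) & go_cue_frame > response_frame))
  if (any(bad)) {
    stop("trial_table: event ordering violated (stimulus < go cue <= response) ",
         "on trial(s) ", paste(which(bad), collapse = ", "))
  }
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Multi-region session container
#'
#' Bundles a nonnegative deconvolved-activity matrix (neurons x frames) with
#' stable neuron identifiers, per-neuron region labels, the learning stage
#' and a [trial_table()]. Deconvolution is assumed upstream; the container
#' never touches raw fluorescence.
#'
#' @param activity Numeric matrix, neurons x frames, no negative entries.
#' @param trials A [trial_table()].
#' @param regions Character vector, one region label per neuron.
#' @param neuron_ids Integer vector of unique stable identifiers
#'   (default `seq_len(nrow(activity))`).
#' @param frame_rate Imaging rate in Hz (default 9.35).
#' @param stage One of `"naive"`, `"intermediate"`, `"expert"`.
#' @return An object of class `motif_session`.
#' @export
session <- function(activity, trials, regions,
                    neuron_ids = seq_len(nrow(activity)),
                    frame_rate = 9.35,
                    stage = c("expert", "naive", "intermediate")) {
  stage <- match.arg(stage)
  activity <- as.matrix(activity)
  storage.mode(activity) <- "double"
  if (anyNA(activity) || any(activity < 0)) {
    stop("session: activity must be nonnegative and NA-free")
  }
  n <- nrow(activity)
  neuron_ids <- as.integer(neuron_ids)
  if (anyDuplicated(neuron_ids)) stop("session: neuron_ids must be unique")
  if (length(neuron_ids) != n) stop("session: neuron_ids length != neuron count")
  if (length(regions) != n) stop("session: regions length != neuron count")
  if (!inherits(trials, "trial_table")) stop("session: trials must be a trial_table")
  nf <- ncol(activity)
  ev <- c(trials$stimulus_onset_frame, trials$go_cue_frame,
          trials$response_frame[!is.na(trials$response_frame)])
  if (length(ev) && (min(ev) < 0L || max(ev) >= nf)) {
    stop("session: trial event frames outside [0, ", nf, ")")
  }
  rownames(activity) <- as.character(neuron_ids)
  structure(
    list(activity = activity, frame_rate = frame_rate,
         neuron_ids = neuron_ids, regions = as.character(regions),
         stage = stage, trials = trials),
    class = "motif_session"
  )
}

#' @export
print.motif_session <- function(x, ...) {
  cat(sprintf("motif_session: %d neurons x %d frames @ %.3g Hz (%s)\n",
              nrow(x$activity), ncol(x$activity), x$frame_rate, x$stage))
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s=%d", names(table(x$regions)),
                            as.integer(table(x$regions))), collapse = " ")))
  cat(sprintf("  trials: %d (%d correct)\n", nrow(x$trials), sum(x$trials$correct)))
  invisible(x)
}

n_neurons <- function(s) nrow(s$activity)
n_frames <- function(s) ncol(s$activity)

region_index <- function(s, region) {
  idx <- which(s$regions == region)
  if (!length(idx)) stop("no neurons in region '", region, "'")
  idx
}

subset_neurons <- function(s, idx) {
  session(s$activity[idx, , drop = FALSE], s$trials, s$regions[idx],
          s$neuron_ids[idx], s$frame_rate, s$stage)
}

#' Inclusion filter for active neurons
#'
#' Keeps neurons whose whole-session z-scored activity exceeds `z_threshold`
#' at least once in every `window_s` window. Windows are disjoint; a trailing
#' partial window is merged into the last full one, and a session shorter
#' than one window is treated as a single window. Constant (silent) neurons
#' have undefined z-scores and are removed.
#'
#' @param s A [session()].
#' @param z_threshold Z-score a neuron must exceed (default 10).
#' @param window_s Window length in seconds (default 600).
#' @return A filtered `motif_session`.
#' @export
filter_active_neurons <- function(s, z_threshold = 10, window_s = 600) {
  stopifnot(inherits(s, "motif_session"))
  a <- s$activity
  mu <- rowMeans(a)
  sd_ <- apply(a, 1L, stats::sd)
  nf <- ncol(a)
  wlen <- max(1L, as.integer(trunc(window_s * s$frame_rate)))
  n_win <- max(1L, nf %/% wlen)
  starts <- (seq_len(n_win) - 1L) * wlen + 1L
  ends <- c(starts[-1L] - 1L, nf)  # last window absorbs the remainder
  keep <- rep(TRUE, nrow(a))
  for (i in seq_len(nrow(a))) {
    if (is.na(sd_[i]) || sd_[i] == 0) { keep[i] <- FALSE; next }
    z <- (a[i, ] - mu[i]) / sd_[i]
    for (w in seq_len(n_win)) {
      if (max(z[starts[w]:ends[w]]) <= z_threshold) { keep[i] <- FALSE; break }
    }
  }
  if (!any(keep)) stop("filter_active_neurons: all neurons removed")
  subset_neurons(s, which(keep))
}

#' Write / read a session as a plain-text directory
#'
#' The container is a directory with `meta.json` (frame_rate, stage),
#' `neurons.csv` (neuron_id, region), `activity.csv` (neurons x frames,
#' no header) and `trials.csv` (the exact [trial_table()] columns). The
#' round trip is lossless. An HDF5 variant is deliberately not provided:
#' no HDF5 R binding is assumed, and text keeps artifacts diffable.
#'
#' @param s A [session()].
#' @param path Directory to create/read.
#' @return `read_session` returns a `motif_session`; `write_session`
#'   returns `path` invisibly.
#' @export
write_session <- function(s, path) {
  stopifnot(inherits(s, "motif_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(frame_rate = s$frame_rate, stage = s$stage,
         n_neurons = nrow(s$activity), n_frames = ncol(s$activity)),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(neuron_id = s$neuron_ids, region = s$regions),
                   file.path(path, "neurons.csv"), row.names = FALSE)
  utils::write.table(s$activity, file.path(path, "activity.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write_trials_csv(s$trials, file.path(path, "trials.csv"))
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  need <- c("meta.json", "neurons.csv", "activity.csv", "trials.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("read_session: missing field file(s): ", paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  for (f in c("frame_rate", "stage")) {
    if (is.null(meta[[f]])) stop("read_session: meta.json lacks field '", f, "'")
  }
  nrn <- utils::read.csv(file.path(path, "neurons.csv"))
  if (is.null(nrn$region)) stop("read_session: neurons.csv lacks field 'region'")
  if (is.null(nrn$neuron_id)) stop("read_session: neurons.csv lacks field 'neuron_id'")
  act <- as.matrix(utils::read.table(file.path(path, "activity.csv"), sep = ","))
  dimnames(act) <- NULL
  trials <- read_trials_csv(file.path(path, "trials.csv"))
  session(act, trials, nrn$region, nrn$neuron_id, meta$frame_rate, meta$stage)
}

#' Trial table CSV round trip
#'
#' Reads/writes a [trial_table()] with its exact column names as a sidecar
#' CSV (the same schema `read_session` consumes).
#'
#' @param trials A [trial_table()].
#' @param path CSV file path.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus_side", "choice_side", "stimulus_onset_frame",
            "go_cue_frame", "response_frame", "rewarded", "distractor")
  miss <- setdiff(need, names(tt))
  if (length(miss)) {
    stop("read_trials_csv: missing column(s): ", paste(miss, collapse = ", "))
  }
  trial_table(tt$stimulus_side, tt$choice_side, tt$stimulus_onset_frame,
              tt$go_cue_frame, tt$response_frame, tt$rewarded, tt$distractor)
}
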