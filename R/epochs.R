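#' Epoch specification
#'
#' An epoch is a half-open time window `[start, end)` in seconds, anchored to
#' a per-trial event (stimulus onset or go cue). Frame conversion truncates
#' toward zero, so the pre-action epoch `[-1, 0)` s at 9.35 Hz spans the 9
#' frames immediately preceding the go cue.
#'
#' @param name Label for the epoch.
#' @param reference_event One of `"stimulus_onset"`, `"go_cue"`.
#' @param start_offset_s,end_offset_s Signed offsets in seconds; must satisfy
#'   `start_offset_s < end_offset_s`.
#' @return An object of class `epoch_spec`.
#' @examples
#' epoch_spec("pre_action", "go_cue", -1, 0)
#' @export
epoch_spec <- function(name, reference_event = c("stimulus_onset", "go_cue"),
                       start_offset_s, end_offset_s) {
  reference_event <- match.arg(reference_event)
  stopifnot(is.numeric(start_offset_s), is.numeric(end_offset_s))
  if (!(start_offset_s < end_offset_s)) {
    stop("epoch_spec: start_offset_s must be < end_offset_s")
  }
  structure(
    list(name = as.character(name), reference_event = reference_event,
         start_offset_s = start_offset_s, end_offset_s = end_offset_s),
    class = "epoch_spec"
  )
}

#' Default epoch registry
#'
#' Named epochs used throughout the pipeline: `stimulus` `[0,1)` s and
#' `delay` `[1,3)` s from stimulus onset, `pre_action` `[-1,0)` s from the
#' go cue, `iti_baseline` `[-1,0)` s and `spontaneous_iti` `[-2,0)` s from
#' stimulus onset.
#'
#' @return Named list of [epoch_spec()] objects.
#' @export
default_epochs <- function() {
  list(
    stimulus        = epoch_spec("stimulus", "stimulus_onset", 0, 1),
    delay           = epoch_spec("delay", "stimulus_onset", 1, 3),
    pre_action      = epoch_spec("pre_action", "go_cue", -1, 0),
    iti_baseline    = epoch_spec("iti_baseline", "stimulus_onset", -1, 0),
    spontaneous_iti = epoch_spec("spontaneous_iti", "stimulus_onset", -2, 0)
  )
}

# seconds -> frames, truncation toward zero (deterministic; ties never arise
# because offsets are finite decimals and the rate is fixed per session)
sec_to_frames <- function(offset_s, frame_rate) {
  as.integer(trunc(offset_s * frame_rate))
}

#' Frames covered by an epoch on one trial
#'
#' Converts an epoch to a half-open 0-based frame range anchored at the
#' trial's reference event. Returns the 0-based frame indices (integer
#' vector); the range endpoints are attached as the `"range"` attribute.
#'
#' @param epoch An [epoch_spec()].
#' @param trial One row of a session trial table (data.frame with
#'   `stimulus_onset_frame` and `go_cue_frame` columns, 0-based).
#' @param frame_rate Imaging rate in Hz.
#' @param n_frames Total number of frames in the recording; when supplied,
#'   an epoch extending outside `[0, n_frames)` raises an error so callers
#'   can skip the trial.
#' @return Integer vector of 0-based frame indices, with attribute `range`.
#' @export
epoch_frames <- function(epoch, trial, frame_rate, n_frames = NULL) {
  stopifnot(inherits(epoch, "epoch_spec"))
  ev <- switch(epoch$reference_event,
    stimulus_onset = trial$stimulus_onset_frame,
    go_cue         = trial$go_cue_frame
  )
  if (length(ev) != 1L || is.na(ev)) {
    stop("epoch_frames: reference event '", epoch$reference_event,
         "' missing for trial")
  }
  start <- as.integer(ev) + sec_to_frames(epoch$start_offset_s, frame_rate)
  end   <- as.integer(ev) + sec_to_frames(epoch$end_offset_s, frame_rate)
  if (start < 0L || (!is.null(n_frames) && end > n_frames)) {
    stop("epoch_frames: epoch '", epoch$name,
         "' extends outside the recording [", start, ", ", end, ")")
  }
  if (end <= start) stop("epoch_frames: empty epoch '", epoch$name, "'")
  out <- seq.int(start, end - 1L)
  attr(out, "range") <- c(start = start, end = end)
  out
}

# 0-based frame indices -> 1-based matrix column indices
frame_cols <- function(frames) as.integer(frames) + 1L
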