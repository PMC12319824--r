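#' Parcellated fMRI scan
#'
#' The atom all computation consumes: a frames x regions numeric matrix of
#' parcellated (ROI-averaged) fMRI signal, together with the repetition time
#' and the scan condition. Frame indices used throughout the package
#' (event \code{center_frame}, window centers, profile timepoints) are
#' 0-based, so frame \code{t} is row \code{t + 1} of \code{signal}.
#'
#' @param signal numeric matrix, frames (T >= 2) x regions (N >= 2), no
#'   missing values.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param subject_id subject identifier.
#' @param scan_kind \code{"task"} or \code{"rest"}.
#' @return an object of class \code{parcellated_scan} with fields
#'   \code{subject_id}, \code{signal}, \code{tr_seconds}, \code{scan_kind}.
#' @export
parcellated_scan <- function(signal, tr_seconds, subject_id = "subj",
                             scan_kind = c("task", "rest")) {
  scan_kind <- match.arg(scan_kind)
  signal <- as.matrix(signal)
  if (!is.numeric(signal))
    stop("signal must be numeric", call. = FALSE)
  if (nrow(signal) < 2L)
    stop("scan must have at least 2 frames (T >= 2)", call. = FALSE)
  if (ncol(signal) < 2L)
    stop("scan must have at least 2 regions (N >= 2)", call. = FALSE)
  if (anyNA(signal))
    stop("signal contains missing values", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), signal = signal,
         tr_seconds = as.numeric(tr_seconds), scan_kind = scan_kind),
    class = "parcellated_scan")
}

#' @export
print.parcellated_scan <- function(x, ...) {
  cat(sprintf("<parcellated_scan> subject %s: %d frames x %d regions, TR %.3g s, %s\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$tr_seconds, x$scan_kind))
  invisible(x)
}

#' @export
dim.parcellated_scan <- function(x) dim(x$signal)

n_frames  <- function(scan) nrow(scan$signal)
n_regions <- function(scan) ncol(scan$signal)

# Replace the signal matrix, keeping metadata.
with_signal <- function(scan, signal) {
  scan$signal <- signal
  scan
}

#' Window specification
#'
#' Describes how instantaneous connectivity frames are averaged into
#' windowed estimates. Windows are closed intervals of frames
#' \code{[c - (w-1)/2, c + (w-1)/2]} around a 0-based center \code{c};
#' event-centered windows must therefore have odd length so that equal
#' numbers of frames fall before and after the response. In sweep mode,
#' centers are enumerated across the scan at \code{stride} frames.
#'
#' @param length_frames window length in frames (>= 1; odd when
#'   \code{mode = "event_centered"}).
#' @param mode \code{"sweep"} (enumerate centers by stride) or
#'   \code{"event_centered"} (caller supplies centers, e.g. trial responses).
#' @param stride center spacing in frames for sweep mode (default 1: a
#'   window at every timepoint).
#' @param boundary_policy \code{"exclude_partial"} (default: windows that
#'   would cross the scan boundary are dropped) or \code{"truncate"}
#'   (clipped to the available frames).
#' @return an object of class \code{window_spec}.
#' @export
window_spec <- function(length_frames, mode = c("sweep", "event_centered"),
                        stride = 1L,
                        boundary_policy = c("exclude_partial", "truncate")) {
  mode <- match.arg(mode)
  boundary_policy <- match.arg(boundary_policy)
  if (length_frames < 1 || length_frames != round(length_frames))
    stop("length_frames must be a positive integer", call. = FALSE)
  if (mode == "event_centered" && length_frames %% 2 == 0)
    stop("event-centered windows must have odd length", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  structure(list(length_frames = as.integer(length_frames), mode = mode,
                 stride = as.integer(stride), boundary_policy = boundary_policy),
            class = "window_spec")
}

#' Window duration in seconds
#'
#' @param length_frames window length in frames.
#' @param tr_seconds repetition time in seconds.
#' @return duration \code{length_frames * tr_seconds} in seconds (29 frames
#'   at TR 0.72 s span 20.88 s).
#' @export
window_duration_seconds <- function(length_frames, tr_seconds) {
  stopifnot(length_frames >= 1, tr_seconds > 0)
  length_frames * tr_seconds
}
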