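# Null comparison conditions: within-scan temporal shuffling (destroys
# temporal/task structure while preserving the multiset of frames, hence all
# order-invariant statistics such as static FC) and resting-state
# substitution (same nuisance processes, no task-driven cognition).

# Counter-based seed substreams: one master seed expands deterministically
# into per-purpose, per-subject seeds so any single draw is reproducible in
# isolation. Kept below 2^31 - 1.
substream_seed <- function(master, stream, index = 0L) {
  stream_id <- sum(utf8ToInt(as.character(stream)))
  as.integer((as.numeric(master) + 1000003 * stream_id + 10007 * index) %%
               2147483629)
}

#' Temporally shuffle a scan's frames
#'
#' Draws one uniform permutation of the frame order (rows of the signal
#' matrix). The multiset of frames is unchanged, so any statistic invariant
#' to frame order -- notably the static connectome -- is unchanged, while
#' phase dynamics and event-locked structure are destroyed.
#'
#' @param scan a \code{\link{parcellated_scan}}.
#' @param seed integer seed; the same seed reproduces the same permutation.
#' @return the scan with permuted frames; the permutation (1-based row
#'   order) is attached as attribute \code{"permutation"}.
#' @export
shuffle_frames <- function(scan, seed) {
  t_frames <- n_frames(scan)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  perm <- sample.int(t_frames)
  out <- with_signal(scan, scan$signal[perm, , drop = FALSE])
  attr(out, "permutation") <- perm
  out
}

#' Build a dataset condition
#'
#' Returns the view of a multi-subject dataset corresponding to one of the
#' three comparison conditions: temporally ordered task scans
#' (\code{"ordered_task"}, identity), within-scan temporally shuffled task
#' scans (\code{"shuffled_task"}, an independent seeded permutation per
#' subject), or each subject's resting-state scan truncated to the first
#' \code{n_frames_required} frames so frame counts match the task scans
#' (\code{"rest"}).
#'
#' @param scans list of task \code{parcellated_scan}s (one per subject).
#' @param condition \code{"ordered_task"}, \code{"shuffled_task"} or
#'   \code{"rest"}.
#' @param seed master seed for the shuffled condition; per-subject seeds are
#'   derived by a counter-based substream scheme and recorded in the result's
#'   \code{"shuffle_seeds"} attribute.
#' @param rest_scans list of rest scans, required for \code{condition =
#'   "rest"}.
#' @param n_frames_required frame count the rest scans must supply; shorter
#'   rest scans are an error, longer ones are truncated to their first
#'   \code{n_frames_required} frames.
#' @return a list of scans satisfying the condition.
#' @export
make_condition <- function(scans, condition = c("ordered_task",
                                                "shuffled_task", "rest"),
                           seed = NULL, rest_scans = NULL,
                           n_frames_required = NULL) {
  condition <- match.arg(condition)
  if (condition == "ordered_task") return(scans)
  if (condition == "shuffled_task") {
    if (is.null(seed)) stop("shuffled_task requires a seed", call. = FALSE)
    seeds <- vapply(seq_along(scans), function(s)
      substream_seed(seed, "shuffle", s), integer(1L))
    out <- Map(shuffle_frames, scans, seeds)
    attr(out, "shuffle_seeds") <- seeds
    return(out)
  }
  # rest
  if (is.null(rest_scans))
    stop("rest condition requires rest_scans", call. = FALSE)
  if (is.null(n_frames_required))
    n_frames_required <- n_frames(scans[[1L]])
  lapply(rest_scans, function(sc) {
    if (n_frames(sc) < n_frames_required)
      stop(sprintf("rest scan %s has %d frames, %d required",
                   sc$subject_id, n_frames(sc), n_frames_required),
           call. = FALSE)
    with_signal(sc, sc$signal[seq_len(n_frames_required), , drop = FALSE])
  })
}
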