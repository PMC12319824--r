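# Post-parcellation cleaning: nuisance regression, linear detrend, low-pass
# filtering. Operates on already-parcellated region series; image-space steps
# (registration, motion estimation, ICA denoising) are out of scope.

#' Regress confound series out of a scan
#'
#' Removes, by ordinary least squares, the linear contribution of each
#' confound column (e.g. mean white-matter / CSF / gray-matter time courses,
#' motion-related series) plus an intercept from every region's series. The
#' residuals are orthogonal to every confound column and to the constant.
#'
#' @param scan a \code{\link{parcellated_scan}}.
#' @param confounds numeric matrix, frames x C (C >= 0). \code{NULL} or a
#'   zero-column matrix demeans only.
#' @return the scan with residual signal.
#' @export
regress_confounds <- function(scan, confounds = NULL) {
  x <- scan$signal
  t_frames <- nrow(x)
  if (is.null(confounds)) confounds <- matrix(numeric(0), t_frames, 0L)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != t_frames)
    stop("confound matrix must have the same number of frames as the scan",
         call. = FALSE)
  design <- cbind(intercept = rep(1, t_frames), confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    warning("rank-deficient confound matrix; using pseudoinverse fit",
            call. = FALSE)
  resid <- qr.resid(qrd, x)   # handles rank deficiency via the QR basis
  with_signal(scan, resid)
}

#' Remove the best-fit line from each region's series
#'
#' @param scan a \code{parcellated_scan} with at least 3 frames.
#' @return the scan with per-region linear trend (slope and intercept)
#'   removed.
#' @export
detrend_linear <- function(scan) {
  if (n_frames(scan) < 3L)
    stop("detrend requires at least 3 frames", call. = FALSE)
  tt <- seq_len(n_frames(scan))
  qrd <- qr(cbind(1, tt))
  with_signal(scan, qr.resid(qrd, scan$signal))
}

#' Zero-phase low-pass filter
#'
#' Butterworth low-pass (order 5) applied forward and backward
#' (\code{signal::filtfilt}) so that the filter introduces no phase shift --
#' essential here, since a phase-shifted signal would bias the downstream
#' phase-coherence connectivity. The first and last
#' \code{ceil(1 / (cutoff * TR))} frames are flagged as edge-affected in the
#' returned scan's \code{edge_frames} attribute rather than dropped.
#'
#' @param scan a \code{parcellated_scan}.
#' @param cutoff_hz cutoff frequency in Hz (default 0.12); must be below the
#'   Nyquist frequency \code{1 / (2 * TR)}.
#' @param order filter order (default 5).
#' @return the filtered scan.
#' @export
lowpass_filter <- function(scan, cutoff_hz = 0.12, order = 5L) {
  nyquist <- 1 / (2 * scan$tr_seconds)
  if (cutoff_hz >= nyquist)
    stop(sprintf("cutoff %.4g Hz is not below Nyquist %.4g Hz",
                 cutoff_hz, nyquist), call. = FALSE)
  if (cutoff_hz <= 0) stop("cutoff must be positive", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  # demean before filtering (and restore after) so the zero-padded
  # forward-backward pass has no step transient at the scan boundaries
  mu <- colMeans(scan$signal)
  centered <- sweep(scan$signal, 2L, mu)
  filtered <- apply(centered, 2L, function(col) signal::filtfilt(bf, col))
  filtered <- sweep(filtered, 2L, mu, `+`)
  out <- with_signal(scan, filtered)
  n_edge <- min(ceiling(1 / (cutoff_hz * scan$tr_seconds)), n_frames(scan))
  attr(out, "edge_frames") <- n_edge
  attr(out, "filter") <- list(family = "butterworth", order = order,
                              cutoff_hz = cutoff_hz, zero_phase = TRUE)
  out
}

#' Full preprocessing pipeline
#'
#' Applies, in order: confound regression, linear detrend, zero-phase
#' low-pass filtering.
#'
#' @inheritParams regress_confounds
#' @inheritParams lowpass_filter
#' @return the cleaned scan.
#' @export
preprocess_scan <- function(scan, confounds = NULL, cutoff_hz = 0.12,
                            order = 5L) {
  scan <- regress_confounds(scan, confounds)
  scan <- detrend_linear(scan)
  lowpass_filter(scan, cutoff_hz = cutoff_hz, order = order)
}
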