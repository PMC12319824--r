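# Phase-coherence dynamic functional connectivity. The connectivity measure
# is computed in three steps: (1) take the instantaneous phase of each
# region's analytic (Hilbert) signal, (2) form pairwise phase differences,
# (3) apply the cosine. This yields one full connectivity matrix per frame,
# bounded in [-1, 1]: 1 = phases maximally aligned, 0 = unaligned (quadrature),
# -1 = anti-aligned.

#' Instantaneous phase of the analytic signal
#'
#' Demeans each region's series and computes its analytic signal by the
#' FFT construction (zero the negative-frequency half-spectrum, double the
#' positive half), then takes the argument. No tapering is applied; the few
#' frames at either end of the scan are the least reliable.
#'
#' @param scan a \code{\link{parcellated_scan}}.
#' @return a T x N matrix of instantaneous phases, wrapped to (-pi, pi].
#' @export
analytic_phase <- function(scan) {
  x <- scan$signal
  t_frames <- nrow(x)
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    stop(sprintf("phase undefined for constant/zero region(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  x <- sweep(x, 2L, colMeans(x))
  h <- numeric(t_frames)
  if (t_frames %% 2L == 0L) {
    h[1L] <- 1; h[t_frames / 2L + 1L] <- 1
    h[2L:(t_frames / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((t_frames + 1L) / 2L)] <- 2
  }
  analytic <- stats::mvfft(x * (1 + 0i)) * h
  analytic <- stats::mvfft(analytic, inverse = TRUE) / t_frames
  ph <- Arg(analytic)
  dimnames(ph) <- dimnames(x)
  ph
}

#' Phase-coherence connectivity at every frame
#'
#' \code{edges[t, k] = cos(theta_i(t) - theta_j(t))} for edge \code{k}
#' corresponding to the region pair \code{(i, j)} (see
#' \code{\link{edge_pairs}}). One undirected connectivity matrix per
#' timepoint, vectorized: a 268-region parcellation yields 35,778 edge
#' features per frame.
#'
#' @param phases a T x N phase matrix from \code{\link{analytic_phase}}.
#' @return a T x E matrix of class \code{dynamic_connectivity} with
#'   attribute \code{n_regions}.
#' @export
phase_connectivity <- function(phases) {
  n <- ncol(phases)
  p <- edge_pairs(n)
  co <- cos(phases); si <- sin(phases)
  edges <- co[, p[, 1L], drop = FALSE] * co[, p[, 2L], drop = FALSE] +
           si[, p[, 1L], drop = FALSE] * si[, p[, 2L], drop = FALSE]
  structure(edges, n_regions = n, class = c("dynamic_connectivity", "matrix"))
}

# Enumerate valid 0-based window centers for a spec over a scan of T frames.
# Returns list(kept, dropped, lo) with lo the 0-based first frame per kept
# center. For even lengths the window is [c - floor((w-1)/2), ...+w-1].
resolve_windows <- function(spec, t_frames, centers = NULL) {
  w <- spec$length_frames
  half_lo <- floor((w - 1) / 2)
  if (spec$mode == "sweep") {
    if (!is.null(centers)) centers <- as.integer(centers)
    else centers <- seq.int(0L, t_frames - 1L, by = spec$stride)
  } else {
    if (is.null(centers))
      stop("event-centered windows require centers", call. = FALSE)
    centers <- as.integer(centers)
  }
  lo <- centers - half_lo
  hi <- lo + w - 1L
  if (spec$boundary_policy == "exclude_partial") {
    ok <- lo >= 0L & hi <= t_frames - 1L
    dropped <- centers[!ok]
    if (length(dropped))
      message(sprintf("dropped %d partial window(s) at center(s): %s",
                      length(dropped),
                      paste(utils::head(dropped, 10L), collapse = ", ")))
    list(centers = centers[ok], lo = lo[ok], hi = hi[ok], dropped = dropped)
  } else {
    list(centers = centers, lo = pmax(lo, 0L),
         hi = pmin(hi, t_frames - 1L), dropped = integer(0))
  }
}

#' Windowed mean of dynamic connectivity
#'
#' Averages the instantaneous edge tensor over the frames of each window.
#' Windows are closed frame intervals centered (0-based) at \code{centers};
#' overlapping windows are allowed. With \code{length_frames = 1} the window
#' mean is the instantaneous value; a full-scan sweep window equals the
#' temporal mean of the tensor.
#'
#' @param dfc a T x E \code{dynamic_connectivity} matrix (or any numeric
#'   frames x features matrix).
#' @param spec a \code{\link{window_spec}}.
#' @param centers 0-based window centers (required for event-centered mode;
#'   optional override of the stride enumeration in sweep mode).
#' @return a list with \code{centers} (0-based centers kept), \code{means}
#'   (centers x E matrix of window means) and \code{dropped} (centers
#'   excluded by the boundary policy).
#' @export
window_mean <- function(dfc, spec, centers = NULL) {
  t_frames <- nrow(dfc)
  rw <- resolve_windows(spec, t_frames, centers)
  cs <- apply(dfc, 2L, cumsum)
  cs <- rbind(0, cs)
  means <- (cs[rw$hi + 2L, , drop = FALSE] - cs[rw$lo + 1L, , drop = FALSE]) /
    (rw$hi - rw$lo + 1L)
  rownames(means) <- rw$centers
  list(centers = rw$centers, means = means, dropped = rw$dropped)
}

# Cos/sin of the instantaneous phases of a scan; cached building block for
# windowed edge means.
phase_cos_sin <- function(scan) {
  ph <- analytic_phase(scan)
  list(C = cos(ph), S = sin(ph), n = ncol(ph), t = nrow(ph))
}

# Window-mean edge values straight from cos/sin phases, without
# materializing the full T x E tensor. `pairs` (E' x 2) restricts to a
# subset of edges (e.g. an aggregated model's active set).
window_edge_means <- function(cs, spec, centers = NULL, pairs = NULL) {
  rw <- resolve_windows(spec, cs$t, centers)
  nc <- length(rw$centers)
  if (is.null(pairs)) {
    e_tot <- n_edges(cs$n)
    means <- matrix(NA_real_, nc, e_tot)
    for (m in seq_len(nc)) {
      rows <- (rw$lo[m] + 1L):(rw$hi[m] + 1L)
      cw <- cs$C[rows, , drop = FALSE]; sw <- cs$S[rows, , drop = FALSE]
      mat <- (crossprod(cw) + crossprod(sw)) / length(rows)
      means[m, ] <- vectorize_edges(mat)
    }
  } else {
    i <- pairs[, 1L]; j <- pairs[, 2L]
    prod_mat <- cs$C[, i, drop = FALSE] * cs$C[, j, drop = FALSE] +
                cs$S[, i, drop = FALSE] * cs$S[, j, drop = FALSE]
    csum <- rbind(0, apply(prod_mat, 2L, cumsum))
    means <- (csum[rw$hi + 2L, , drop = FALSE] -
              csum[rw$lo + 1L, , drop = FALSE]) / (rw$hi - rw$lo + 1L)
  }
  rownames(means) <- rw$centers
  list(centers = rw$centers, means = means, dropped = rw$dropped)
}

#' Static functional connectome
#'
#' Whole-scan Pearson correlation of every region pair, Fisher
#' z-transformed (\code{atanh}), vectorized in the shared edge order.
#' Correlations are clipped to \code{+/-(1 - 1e-7)} before \code{atanh} so
#' perfectly collinear regions yield a large finite z rather than infinity.
#'
#' @param scan a \code{parcellated_scan}; every region must have nonzero
#'   variance.
#' @return a length-E numeric vector of Fisher z values.
#' @export
static_fc <- function(scan) {
  v <- apply(scan$signal, 2L, stats::var)
  if (any(v == 0))
    stop(sprintf("correlation undefined for zero-variance region(s): %s",
                 paste(which(v == 0), collapse = ", ")), call. = FALSE)
  r <- stats::cor(scan$signal)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  atanh(vectorize_edges(r))
}

#' Matched window length at a different repetition time
#'
#' Finds the window length (in frames) at a target TR covering about the
#' same scan time as a reference window at a reference TR, respecting a
#' parity constraint. The default policy rounds the frame count down to the
#' requested parity, so a 29-frame window at TR 0.72 s (20.88 s) maps to a
#' 25-frame window at TR 0.8 s.
#'
#' @param ref_length reference window length in frames.
#' @param ref_tr,target_tr repetition times in seconds.
#' @param parity \code{"odd"}, \code{"even"} or \code{"any"}.
#' @param rounding \code{"down"} (default) or \code{"nearest"} (ties broken
#'   downward).
#' @return an integer window length (>= 1).
#' @export
equivalent_window_length <- function(ref_length, ref_tr, target_tr,
                                     parity = c("odd", "even", "any"),
                                     rounding = c("down", "nearest")) {
  parity <- match.arg(parity)
  rounding <- match.arg(rounding)
  stopifnot(ref_tr > 0, target_tr > 0, ref_length >= 1)
  duration <- ref_length * ref_tr
  raw <- duration / target_tr
  has_parity <- function(k) switch(parity, odd = k %% 2L == 1L,
                                   even = k %% 2L == 0L, any = TRUE)
  down_to_parity <- function(k) { while (k >= 1L && !has_parity(k)) k <- k - 1L; k }
  up_to_parity   <- function(k) { while (!has_parity(k)) k <- k + 1L; k }
  if (rounding == "down") {
    k <- down_to_parity(as.integer(floor(raw)))
    return(max(k, up_to_parity(1L)))
  }
  lo <- down_to_parity(as.integer(floor(raw)))
  hi <- up_to_parity(as.integer(ceiling(raw)))
  lo <- max(lo, up_to_parity(1L))
  if (abs(lo * target_tr - duration) <= abs(hi * target_tr - duration)) lo else hi
}
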