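# Resample aggregation: pool feature selection and model parameters across
# cross-validation folds into one frequency-thresholded "mean model" per
# timepoint, then evaluate it on unseen subjects across time and subsamples.

#' Aggregate cross-validation folds into a mean model
#'
#' Builds the per-edge selection-frequency vector (fraction of resamples in
#' which each edge passed feature selection) and averages fold slopes and
#' intercepts. The active edge set keeps edges whose frequency meets the
#' threshold, inclusively: at the default 0.9, edges occurring in 90% or
#' more of resamples survive.
#'
#' @param cv a \code{\link{split_half_cv}} result with at least 2 folds.
#' @param threshold frequency threshold in (0, 1]; default 0.9.
#' @param window optional \code{\link{window_spec}} recorded as provenance.
#' @param center_timepoint optional 0-based training center frame recorded
#'   as provenance.
#' @return an object of class \code{aggregated_model}: \code{frequency}
#'   (per-edge selection frequency in [0, 1]), \code{threshold},
#'   \code{selected} (active set, \code{frequency >= threshold}),
#'   \code{slope}, \code{intercept} (fold means), \code{center_timepoint},
#'   \code{window}, \code{provenance}.
#' @export
aggregate_cv <- function(cv, threshold = 0.9, window = NULL,
                         center_timepoint = NULL) {
  stopifnot(inherits(cv, "cv_result"), length(cv$folds) >= 2L,
            threshold > 0, threshold <= 1)
  sel <- vapply(cv$folds, function(f) f$model$selected,
                logical(length(cv$folds[[1L]]$model$selected)))
  freq <- rowMeans(sel)
  active <- freq >= threshold
  if (!any(active))
    warning("no edges reach the frequency threshold; aggregated model is degenerate",
            call. = FALSE)
  structure(list(
    frequency = freq,
    threshold = threshold,
    selected = active,
    slope = mean(vapply(cv$folds, function(f) f$model$slope, numeric(1L))),
    intercept = mean(vapply(cv$folds, function(f) f$model$intercept, numeric(1L))),
    center_timepoint = center_timepoint,
    window = window,
    provenance = list(seed = cv$seed, iterations = cv$iterations,
                      resamples = length(cv$folds),
                      n_subjects = cv$n_subjects,
                      p_threshold = cv$p_threshold)),
    class = c("aggregated_model", "cpm_model"))
}

#' @export
print.aggregated_model <- function(x, ...) {
  cat(sprintf(
    "<aggregated_model> %d active edges at threshold %.2f (of %d); yhat = %.4g * score + %.4g\n",
    sum(x$selected), x$threshold, length(x$frequency), x$slope, x$intercept))
  if (!is.null(x$center_timepoint))
    cat(sprintf("  trained at center timepoint %d, window %d frames\n",
                x$center_timepoint,
                if (!is.null(x$window)) x$window$length_frames else NA_integer_))
  invisible(x)
}

#' Evaluate a model on repeated test subsamples
#'
#' Applies a fixed model to \code{n_subsamples} random subsamples (drawn
#' without replacement within each draw) of a held-out test set, returning
#' one performance value per draw. The spread across draws quantifies
#' evaluation variance.
#'
#' @param model a \code{cpm_model} or \code{aggregated_model}.
#' @param edge_matrix held-out subjects x E matrix of windowed edge values.
#' @param y held-out targets.
#' @param n_subsamples number of draws (default 50).
#' @param subsample_size subjects per draw; must not exceed the test set.
#' @param seed integer seed.
#' @return numeric vector of \code{n_subsamples} R^2 values.
#' @export
evaluate_subsampled <- function(model, edge_matrix, y, n_subsamples = 50L,
                                subsample_size, seed = 1L) {
  n <- nrow(edge_matrix)
  if (subsample_size > n)
    stop(sprintf("subsample_size %d exceeds test set size %d",
                 subsample_size, n), call. = FALSE)
  set.seed(as.integer(seed))
  vapply(seq_len(n_subsamples), function(k) {
    idx <- sample.int(n, subsample_size)
    r_squared(y[idx], predict(model, edge_matrix[idx, , drop = FALSE]))
  }, numeric(1L))
}

#' Temporal performance profile of a fixed model
#'
#' Applies a fixed model (its active edge set and linear parameters, frozen)
#' to the windowed phase-coherence connectivity of every center timepoint of
#' a test dataset, returning the R^2 trace across the scan. Only the
#' model's active edges are computed, so full scans are profiled cheaply.
#' Centers whose window crosses the scan boundary are dropped (missing from
#' the profile, not zero). Optionally the profile is repeated on random
#' subsamples of the test subjects, giving a distribution of R^2 per
#' timepoint.
#'
#' @param model a \code{cpm_model} or \code{aggregated_model}.
#' @param scans list of test-subject \code{parcellated_scan}s.
#' @param y per-subject targets, same order as \code{scans}.
#' @param spec a \code{\link{window_spec}}.
#' @param centers 0-based centers to profile; default: sweep over the scan.
#' @param n_subsamples,subsample_size,seed when \code{n_subsamples > 0},
#'   also evaluate each timepoint on this many random subject subsamples.
#' @return an object of class \code{performance_profile}: a data.frame with
#'   columns \code{center}, \code{r2} (full test set), and when subsampled,
#'   \code{r2_mean} and \code{r2_sd} across draws; the per-draw matrix is in
#'   attribute \code{"subsample_r2"}.
#' @export
temporal_profile <- function(model, scans, y, spec, centers = NULL,
                             n_subsamples = 0L, subsample_size = NULL,
                             seed = 1L) {
  stopifnot(length(scans) == length(y))
  pairs_all <- edge_pairs(attr_n_regions(model, scans))
  active <- which(model$selected)
  if (length(active) == 0L) {
    pairs <- pairs_all[1L, , drop = FALSE]  # placeholder; score is 0 anyway
  } else pairs <- pairs_all[active, , drop = FALSE]
  scores <- NULL
  kept_centers <- NULL
  for (s in seq_along(scans)) {
    cs <- phase_cos_sin(scans[[s]])
    wm <- suppressMessages(window_edge_means(cs, spec, centers, pairs))
    sc <- if (length(active)) rowSums(wm$means) else rep(0, length(wm$centers))
    if (is.null(scores)) {
      scores <- matrix(NA_real_, length(wm$centers), length(scans))
      kept_centers <- wm$centers
    }
    scores[, s] <- sc
  }
  preds <- model$slope * scores + model$intercept
  r2 <- apply(preds, 1L, function(p) r_squared(y, p))
  out <- data.frame(center = kept_centers, r2 = r2)
  if (n_subsamples > 0L) {
    if (is.null(subsample_size))
      subsample_size <- max(2L, floor(length(y) * 0.9))
    set.seed(as.integer(seed))
    draws <- replicate(n_subsamples, sample.int(length(y), subsample_size))
    sub_r2 <- apply(draws, 2L, function(idx)
      apply(preds[, idx, drop = FALSE], 1L, function(p) r_squared(y[idx], p)))
    out$r2_mean <- rowMeans(sub_r2)
    out$r2_sd <- apply(sub_r2, 1L, stats::sd)
    attr(out, "subsample_r2") <- sub_r2
  }
  class(out) <- c("performance_profile", "data.frame")
  out
}

# Number of regions implied by a model's edge-vector length.
attr_n_regions <- function(model, scans) {
  e_len <- length(if (!is.null(model$frequency)) model$frequency else model$selected)
  n <- (1 + sqrt(1 + 8 * e_len)) / 2
  if (n != round(n))
    stop("model edge vector length is not a valid N(N-1)/2", call. = FALSE)
  if (length(scans) && ncol(scans[[1L]]$signal) != n)
    stop("model and scans disagree on region count", call. = FALSE)
  as.integer(n)
}

#' Similarity of two feature vectors
#'
#' Pearson correlation of two per-edge vectors (e.g. the selection-frequency
#' vector of a windowed model against the static-FC model's), used to ask
#' whether short-time models select the same anatomy as static models.
#'
#' @param vector_a,vector_b numeric vectors of equal length E, each with
#'   nonzero variance.
#' @return correlation in [-1, 1].
#' @export
feature_similarity <- function(vector_a, vector_b) {
  stopifnot(length(vector_a) == length(vector_b))
  if (stats::sd(vector_a) == 0 || stats::sd(vector_b) == 0)
    stop("feature similarity undefined for a zero-variance vector",
         call. = FALSE)
  stats::cor(vector_a, vector_b)
}

#' Anatomical summary of a model's features
#'
#' Computes (a) the frequency-weighted degree of every region over the
#' model's active edges, and (b) a network-pair matrix: the summed
#' frequencies of active edges joining networks A and B, normalized by the
#' number of possible A-B edges (\code{n_A * n_B} off-diagonal,
#' \code{n_A * (n_A - 1) / 2} on the diagonal).
#'
#' @param model an \code{aggregated_model}.
#' @param networks a network-assignment data.frame with columns
#'   \code{region_index} (1-based, covering every region) and
#'   \code{network_label}.
#' @return a list with \code{degree} (named per-region vector) and
#'   \code{network_pairs} (symmetric labels x labels matrix).
#' @export
summarize_features <- function(model, networks) {
  e_len <- length(model$frequency)
  n <- (1 + sqrt(1 + 8 * e_len)) / 2
  if (!all(seq_len(n) %in% networks$region_index))
    stop("network assignment does not cover all regions", call. = FALSE)
  labels <- networks$network_label[match(seq_len(n), networks$region_index)]
  p <- edge_pairs(n)
  w <- ifelse(model$selected, model$frequency, 0)
  degree <- numeric(n)
  for (k in which(w > 0)) {
    degree[p[k, 1L]] <- degree[p[k, 1L]] + w[k]
    degree[p[k, 2L]] <- degree[p[k, 2L]] + w[k]
  }
  names(degree) <- labels
  nets <- sort(unique(labels))
  sizes <- table(factor(labels, levels = nets))
  pair_sum <- matrix(0, length(nets), length(nets), dimnames = list(nets, nets))
  for (k in which(w > 0)) {
    a <- labels[p[k, 1L]]; b <- labels[p[k, 2L]]
    pair_sum[a, b] <- pair_sum[a, b] + w[k]
    if (a != b) pair_sum[b, a] <- pair_sum[b, a] + w[k]
  }
  possible <- outer(as.numeric(sizes), as.numeric(sizes))
  diag(possible) <- as.numeric(sizes) * (as.numeric(sizes) - 1) / 2
  dimnames(possible) <- dimnames(pair_sum)
  list(degree = degree, network_pairs = pair_sum / possible)
}

#' Shared active edges across models
#'
#' Intersection of the active edge sets of several aggregated models,
#' re-thresholded at \code{threshold}. Lowering the threshold can only grow
#' each active set, so the overlap is monotone non-decreasing as the
#' threshold drops.
#'
#' @param models list of \code{aggregated_model}s over a common edge
#'   convention.
#' @param threshold frequency threshold applied to every model's frequency
#'   vector; default: each model's own stored threshold.
#' @return integer vector of edge indices active in every model.
#' @export
overlap_edges <- function(models, threshold = NULL) {
  stopifnot(length(models) >= 1L)
  active_sets <- lapply(models, function(m) {
    thr <- if (is.null(threshold)) m$threshold else threshold
    which(m$frequency >= thr)
  })
  Reduce(intersect, active_sets)
}
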