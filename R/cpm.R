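# Connectome-based predictive modeling (CPM) with motion-partialed feature
# selection. Per training set: (1) partially correlate every edge with the
# target, removing the motion covariate (mean framewise displacement) from
# both; (2) keep positively correlated edges with p < 0.1 (no
# multiple-testing correction -- deliberate, as in standard CPM); (3) sum the
# selected edge values per subject; (4) fit an unregularized linear model of
# the target on that sum; (5) apply to held-out subjects. Only the positive
# network is modeled.

residualize <- function(mat, z) {
  qrd <- qr(cbind(1, z))
  qr.resid(qrd, as.matrix(mat))
}

#' Partial correlation with a single covariate
#'
#' Removes the covariate \code{z} (with intercept) from both \code{x} and
#' \code{y} by least squares, then computes the Pearson correlation of the
#' residuals. The two-sided p-value uses a t reference with \code{df = n - 3}
#' (one covariate); with \code{z} constant or \code{NULL} the statistic
#' degenerates to the plain Pearson correlation with \code{df = n - 2}.
#'
#' @param x,y numeric vectors of length n >= 4.
#' @param z covariate vector (e.g. per-subject mean framewise displacement),
#'   or \code{NULL}.
#' @return a list with \code{r}, \code{p} and \code{df}.
#' @export
partial_correlation <- function(x, y, z = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L)
  plain <- is.null(z) || stats::sd(z) == 0
  if (plain) {
    rx <- x - mean(x); ry <- y - mean(y)
    df <- n - 2L
  } else {
    stopifnot(length(z) == n)
    res <- residualize(cbind(x, y), z)
    rx <- res[, 1L]; ry <- res[, 2L]
    df <- n - 3L
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(r = NA_real_, p = NA_real_, df = df))
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

# Vectorized partial correlation of every column of X with y, covariate z.
# Returns list(r, p, df); columns with zero-variance residuals get NA.
partial_cor_cols <- function(X, y, z = NULL) {
  n <- nrow(X)
  plain <- is.null(z) || stats::sd(z) == 0
  if (plain) {
    RX <- sweep(X, 2L, colMeans(X))
    ry <- y - mean(y)
    df <- n - 2L
  } else {
    qrd <- qr(cbind(1, z))
    RX <- qr.resid(qrd, X)
    ry <- qr.resid(qrd, y)
    df <- n - 3L
  }
  ssx <- colSums(RX^2)
  ssy <- sum(ry^2)
  r <- as.vector(crossprod(RX, ry)) / sqrt(ssx * ssy)
  r[ssx == 0 | ssy == 0] <- NA_real_
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' CPM feature selection
#'
#' Selects edges whose partial correlation with the target is positive with
#' \code{p < p_threshold}. No multiple-testing correction is applied
#' (faithful to the CPM family). Edges with undefined correlation
#' (zero-variance residuals) are never selected.
#'
#' @param edge_matrix subjects x E matrix of (windowed) edge values.
#' @param y per-subject target (trait or behavior).
#' @param z per-subject covariate (mean framewise displacement), or
#'   \code{NULL}.
#' @param p_threshold selection threshold in (0, 1); default 0.1.
#' @return logical vector of length E.
#' @export
select_edges <- function(edge_matrix, y, z = NULL, p_threshold = 0.1) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  pc <- partial_cor_cols(edge_matrix, y, z)
  sel <- !is.na(pc$r) & pc$r > 0 & pc$p < p_threshold
  if (!any(sel))
    warning("no edges passed feature selection (empty model)", call. = FALSE)
  sel
}

#' Fit a CPM linear model
#'
#' Sums the selected edge values per subject and fits ordinary least squares
#' of the target on the summed score (no regularization). With an empty
#' selection the model degenerates to predicting the training mean and is
#' flagged.
#'
#' @inheritParams select_edges
#' @param selected optional logical selection vector; computed via
#'   \code{\link{select_edges}} when \code{NULL}.
#' @return an object of class \code{cpm_model}: fields \code{selected},
#'   \code{slope}, \code{intercept}, \code{sign} (always \code{"positive"}),
#'   \code{p_threshold}, \code{covariates}, \code{degenerate},
#'   \code{n_train}.
#' @export
fit_cpm <- function(edge_matrix, y, z = NULL, p_threshold = 0.1,
                    selected = NULL) {
  if (is.null(selected))
    selected <- select_edges(edge_matrix, y, z, p_threshold)
  degenerate <- !any(selected)
  if (degenerate) {
    slope <- 0; intercept <- mean(y)
  } else {
    score <- rowSums(edge_matrix[, selected, drop = FALSE])
    if (stats::sd(score) == 0)
      stop("singular fit: summed edge score is constant across subjects",
           call. = FALSE)
    slope <- stats::cov(score, y) / stats::var(score)
    intercept <- mean(y) - slope * mean(score)
  }
  structure(list(selected = selected, slope = slope, intercept = intercept,
                 sign = "positive", p_threshold = p_threshold,
                 covariates = if (is.null(z)) character(0) else "mean_fd",
                 degenerate = degenerate, n_train = length(y)),
            class = "cpm_model")
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf("<cpm_model> %d/%d edges selected; yhat = %.4g * score + %.4g%s\n",
              sum(x$selected), length(x$selected), x$slope, x$intercept,
              if (isTRUE(x$degenerate)) " [degenerate: mean predictor]" else ""))
  invisible(x)
}

#' Predict from a CPM (or aggregated) model
#'
#' @param object a fitted \code{cpm_model}.
#' @param edge_matrix subjects x E matrix in the training edge convention.
#' @param ... unused.
#' @return per-subject predictions \code{slope * sum(selected edges) +
#'   intercept}.
#' @export
predict.cpm_model <- function(object, edge_matrix, ...) {
  score <- if (any(object$selected))
    rowSums(edge_matrix[, object$selected, drop = FALSE]) else
      numeric(nrow(edge_matrix))
  object$slope * score + object$intercept
}

#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot} on held-out predictions. May be negative (a
#' model worse than predicting the mean); never clipped. This is the strict
#' variance-explained reading, not squared Pearson correlation (see
#' \code{\link{r_squared_cor}} for the latter).
#'
#' @param y_true observed targets (non-constant, length >= 2).
#' @param y_pred predictions.
#' @return a single number.
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop("R^2 undefined: y_true is constant", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' @rdname r_squared
#' @export
r_squared_cor <- function(y_true, y_pred) {
  if (stats::sd(y_pred) == 0) return(0)
  stats::cor(y_true, y_pred)^2
}

#' Repeated split-half cross-validation
#'
#' Each iteration draws one random 50/50 partition of the subjects; each
#' half serves once as training set and once as test set, giving two folds
#' per iteration -- 50 iterations yield exactly 100 trained resamples. With
#' an odd subject count the halves differ by one subject.
#'
#' @inheritParams select_edges
#' @param iterations number of split-half iterations (default 50).
#' @param seed integer seed; identical seeds give identical partitions and
#'   fold statistics.
#' @param score \code{"cod"} (coefficient of determination, default) or
#'   \code{"cor2"} (squared Pearson correlation) for fold test performance.
#' @return an object of class \code{cv_result}: \code{folds} (a list of
#'   \code{2 * iterations} entries with \code{model}, \code{test_r2},
#'   \code{train}, \code{test} subject indices, \code{iteration},
#'   \code{fold}), plus \code{iterations}, \code{seed}, \code{p_threshold}.
#' @export
split_half_cv <- function(edge_matrix, y, z = NULL, iterations = 50L,
                          p_threshold = 0.1, seed = 1L,
                          score = c("cod", "cor2")) {
  score <- match.arg(score)
  n <- nrow(edge_matrix)
  if (n < 8L) stop("split-half CV requires at least 8 subjects", call. = FALSE)
  score_fun <- if (score == "cod") r_squared else r_squared_cor
  folds <- vector("list", 2L * iterations)
  set.seed(as.integer(seed))
  for (it in seq_len(iterations)) {
    perm <- sample.int(n)
    half_a <- sort(perm[seq_len(n %/% 2L)])
    half_b <- sort(perm[(n %/% 2L + 1L):n])
    for (f in 1:2) {
      tr <- if (f == 1L) half_a else half_b
      te <- if (f == 1L) half_b else half_a
      model <- suppressWarnings(
        fit_cpm(edge_matrix[tr, , drop = FALSE], y[tr],
                if (is.null(z)) NULL else z[tr], p_threshold))
      pred <- predict(model, edge_matrix[te, , drop = FALSE])
      folds[[2L * (it - 1L) + f]] <-
        list(model = model, test_r2 = score_fun(y[te], pred),
             train = tr, test = te, iteration = it, fold = f)
    }
  }
  structure(list(folds = folds, iterations = iterations, seed = seed,
                 p_threshold = p_threshold, n_subjects = n, score = score),
            class = "cv_result")
}

#' Fold test performances of a cross-validation result
#' @param cv a \code{cv_result}.
#' @return numeric vector of per-fold held-out performance values.
#' @export
cv_test_r2 <- function(cv) {
  vapply(cv$folds, `[[`, numeric(1L), "test_r2")
}

#' @export
print.cv_result <- function(x, ...) {
  r2 <- cv_test_r2(x)
  cat(sprintf("<cv_result> %d iterations x 2 folds = %d resamples; mean test R^2 %.4f (sd %.4f)\n",
              x$iterations, length(x$folds), mean(r2), stats::sd(r2)))
  invisible(x)
}
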