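# Independent oracle: explicit two-stage residualize-then-correlate using lm().
oracle_partial <- function(x, y, z) {
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  r <- cor(rx, ry)
  df <- length(x) - 3
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df))
}

test_that("partial correlation matches the two-stage regression oracle", {
  set.seed(31)
  for (rep in 1:200) {
    n <- 40L
    x <- rnorm(n); z <- rnorm(n)
    y <- 0.4 * x + 0.3 * z + rnorm(n)
    got <- partial_correlation(x, y, z)
    want <- oracle_partial(x, y, z)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("partial correlation degenerates gracefully", {
  set.seed(5)
  x <- rnorm(30); y <- 2 * x; z <- rnorm(30)
  got <- partial_correlation(x, y, z)
  expect_equal(got$r, 1, tolerance = 1e-10)
  expect_lt(got$p, 1e-12)
  # constant covariate: plain Pearson with df = n - 2
  got <- partial_correlation(x, y + rnorm(30), rep(1, 30))
  ct <- cor.test(x, y + 0)   # r known exactly = 1 only without noise; use cor.test on same data
  y2 <- y + rnorm(30, sd = 0.5)
  got <- partial_correlation(x, y2, rep(3, 30))
  ct <- cor.test(x, y2)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  expect_equal(got$df, 28L)
  # zero-variance residual
  got <- partial_correlation(rep(2, 30), y2, NULL)
  expect_true(is.na(got$r))
})

test_that("vectorized selection agrees with the scalar path", {
  set.seed(7)
  n <- 50L; e <- 40L
  X <- matrix(rnorm(n * e), n, e)
  z <- rnorm(n)
  y <- X[, 5] * 0.8 + 0.5 * z + rnorm(n, sd = 0.6)
  cols <- statecpm:::partial_cor_cols(X, y, z)
  for (k in c(1L, 5L, 17L, 40L)) {
    sc <- partial_correlation(X[, k], y, z)
    expect_equal(cols$r[k], sc$r, tolerance = 1e-12)
    expect_equal(cols$p[k], sc$p, tolerance = 1e-12)
  }
})

test_that("edge selection keeps positive informative edges only", {
  set.seed(13)
  n <- 100L; e <- 60L
  X <- matrix(rnorm(n * e), n, e)
  y <- X[, 7] + rnorm(n, sd = 0.3)
  sel <- select_edges(X, y, NULL, p_threshold = 0.1)
  expect_true(sel[7])
  # selection of an anti-correlated copy is impossible (positive network only)
  X2 <- cbind(X, -X[, 7])
  sel2 <- select_edges(X2, y, NULL, p_threshold = 0.1)
  expect_false(sel2[e + 1])
  # p_threshold -> 0 empties the selection (target independent of edges)
  y_null <- rnorm(n)
  expect_warning(sel3 <- select_edges(X, y_null, NULL, p_threshold = 1e-12),
                 "empty")
  expect_equal(sum(sel3), 0L)
})

test_that("null edge selection fraction is about half the p threshold", {
  set.seed(17)
  fracs <- replicate(60, {
    n <- 40L; e <- 120L
    X <- matrix(rnorm(n * e), n, e)
    y <- rnorm(n)
    z <- rnorm(n)
    mean(suppressWarnings(select_edges(X, y, z, 0.1)))
  })
  # positive half of p < 0.1 under the null, within +/- 0.02
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("CPM fit recovers exact linear targets and matches OLS", {
  set.seed(19)
  n <- 60L; e <- 30L
  X <- matrix(runif(n * e), n, e)
  sel <- rep(FALSE, e); sel[c(2, 9, 21)] <- TRUE
  score <- rowSums(X[, sel])
  y <- 2 * score + 3
  model <- fit_cpm(X, y, NULL, selected = sel)
  expect_equal(model$slope, 2, tolerance = 1e-10)
  expect_equal(model$intercept, 3, tolerance = 1e-10)
  expect_equal(predict(model, X), y, tolerance = 1e-10)

  # noisy target: slope/intercept match lm() closed form
  y2 <- 1.5 * score + rnorm(n)
  model2 <- fit_cpm(X, y2, NULL, selected = sel)
  ols <- unname(coef(lm(y2 ~ score)))
  expect_equal(model2$intercept, ols[1], tolerance = 1e-10)
  expect_equal(model2$slope, ols[2], tolerance = 1e-10)

  # a duplicated subject makes the score constant -> singular
  Xdup <- X[rep(1, 10), ]
  expect_error(fit_cpm(Xdup, rnorm(10), NULL, selected = sel), "singular")

  # all-zero edges predict the intercept
  expect_equal(predict(model, matrix(0, 3, e)), rep(3, 3), tolerance = 1e-10)
})

test_that("coefficient of determination follows its closed forms", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 7, 1, 9)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  # can be negative, never clipped
  expect_lt(r_squared(c(1, 2, 3), c(9, 9, 9)), -1)
  expect_error(r_squared(rep(2, 5), rnorm(5)), "constant")
})

test_that("split-half CV produces two disjoint covering folds per iteration", {
  set.seed(23)
  n <- 21L
  X <- matrix(rnorm(n * 20), n, 20)
  y <- rnorm(n)
  cv <- suppressWarnings(split_half_cv(X, y, NULL, iterations = 1, seed = 4))
  expect_length(cv$folds, 2L)
  f1 <- cv$folds[[1]]; f2 <- cv$folds[[2]]
  expect_identical(f1$train, f2$test)
  expect_identical(f1$test, f2$train)
  expect_length(intersect(f1$train, f1$test), 0L)
  expect_setequal(c(f1$train, f1$test), seq_len(n))
  # odd n: halves differ by one
  expect_equal(abs(length(f1$train) - length(f1$test)), 1L)

  cv_a <- suppressWarnings(split_half_cv(X, y, NULL, iterations = 3, seed = 9))
  cv_b <- suppressWarnings(split_half_cv(X, y, NULL, iterations = 3, seed = 9))
  expect_identical(cv_test_r2(cv_a), cv_test_r2(cv_b))
  expect_error(split_half_cv(X[1:5, ], y[1:5], NULL), "8 subjects")
})

test_that("held-out R^2 increases with planted coupling strength", {
  spec <- window_spec(21, "event_centered")
  stats <- vapply(c(0, 0.5, 1, 2), function(b) {
    co <- simulate_cohort(small_config(coupling_slope = b), master_seed = 37)
    em <- cohort_edge_matrix(co$scans, spec, 100)
    cv <- suppressWarnings(
      split_half_cv(em, co$phenotypes$rt_ms, co$phenotypes$mean_fd,
                    iterations = 10, seed = 3))
    r2 <- cv_test_r2(cv)
    c(mean = mean(r2), se = sd(r2) / sqrt(length(r2)))
  }, numeric(2))
  # non-decreasing within one standard error
  for (k in 1:3)
    expect_gt(stats["mean", k + 1] - stats["mean", k], -stats["se", k + 1])
  expect_gt(stats["mean", 4], 0.3)  # strong coupling is clearly predictable
})

test_that("with no planted effect, held-out R^2 shows no optimism", {
  co <- cached("small_null", function()
    simulate_cohort(small_config(coupling_slope = 0, rt_gamma = 0),
                    master_seed = 29))
  em <- cohort_edge_matrix(co$scans, window_spec(21, "event_centered"), 100)
  cv <- suppressWarnings(
    split_half_cv(em, co$phenotypes$rt_ms, co$phenotypes$mean_fd,
                  iterations = 15, seed = 6))
  r2 <- cv_test_r2(cv)
  expect_lt(mean(r2), 0 + 3 * sd(r2) / sqrt(length(r2)))
})
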