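# A hand-built cv_result with known selection counts and parameters.
fake_cv <- function(sel_counts, n_folds, slopes = NULL, intercepts = NULL) {
  e <- length(sel_counts)
  if (is.null(slopes)) slopes <- rep(1, n_folds)
  if (is.null(intercepts)) intercepts <- rep(0, n_folds)
  folds <- lapply(seq_len(n_folds), function(f) {
    sel <- seq_len(e) %in% which(sel_counts >= 1) & sel_counts >= f
    # fold f selects edge k iff sel_counts[k] >= f, giving exact frequencies
    list(model = structure(list(selected = sel_counts >= f,
                                slope = slopes[f], intercept = intercepts[f],
                                degenerate = FALSE),
                           class = "cpm_model"),
         test_r2 = 0, train = 1:4, test = 5:8, iteration = f, fold = 1L)
  })
  structure(list(folds = folds, iterations = n_folds, seed = 0L,
                 p_threshold = 0.1, n_subjects = 8L, score = "cod"),
            class = "cv_result")
}

test_that("aggregation thresholds selection frequencies inclusively", {
  # 100 folds; edge 1 selected 95 times, edge 2 89 times, edge 3 90 times
  cv <- fake_cv(c(95, 89, 90, 0), 100)
  m <- aggregate_cv(cv, threshold = 0.9)
  expect_equal(m$frequency, c(0.95, 0.89, 0.90, 0))
  expect_identical(unname(m$selected), c(TRUE, FALSE, TRUE, FALSE))
  # fold slopes (1, 3) average to 2
  cv2 <- fake_cv(c(2, 0), 2, slopes = c(1, 3), intercepts = c(10, 20))
  m2 <- aggregate_cv(cv2, threshold = 0.9)
  expect_equal(m2$slope, 2)
  expect_equal(m2$intercept, 15)
  expect_warning(aggregate_cv(fake_cv(c(1, 0), 100), 0.9), "degenerate")
})

test_that("subsampled evaluation is seeded and bounded by the test set", {
  set.seed(44)
  e <- 20L
  X <- matrix(rnorm(60 * e), 60, e)
  sel <- rep(FALSE, e); sel[3] <- TRUE
  y <- X[, 3] * 2 + 1 + rnorm(60, sd = 0.4)
  model <- fit_cpm(X, y, NULL, selected = sel)
  r2 <- evaluate_subsampled(model, X, y, n_subsamples = 50,
                            subsample_size = 40, seed = 8)
  expect_length(r2, 50L)
  expect_identical(r2, evaluate_subsampled(model, X, y, 50, 40, seed = 8))
  # full test set in every draw: zero spread
  r2f <- evaluate_subsampled(model, X, y, 10, subsample_size = 60, seed = 8)
  expect_equal(sd(r2f), 0)
  expect_error(evaluate_subsampled(model, X, y, 10, 61, 8), "exceeds")
})

test_that("a fixed model peaks at its own planted event", {
  co <- small_cohort()
  gt <- co$ground_truth
  ph <- co$phenotypes
  em <- cohort_edge_matrix(co$scans, window_spec(21, "event_centered"),
                           gt$state_center)
  cv <- split_half_cv(em, ph$rt_ms, ph$mean_fd, iterations = 10, seed = 3)
  model <- aggregate_cv(cv, 0.9, window = window_spec(21, "event_centered"),
                        center_timepoint = gt$state_center)
  prof <- temporal_profile(model, co$scans, ph$rt_ms, window_spec(21, "sweep"))
  rep <- recovery_report(model, gt, prof)
  expect_lte(abs(rep$peak_offset_frames), 3)
  expect_gt(rep$timepoint_contrast, 0)
  # boundary windows are missing, not zero
  expect_false(0 %in% prof$center)
  expect_equal(min(prof$center), 10)
})

test_that("two models trained on disjoint planted events are temporally specific", {
  co <- cached("two_state", function() simulate_cohort(
    sim_config(n_subjects = 50, n_regions = 30, n_frames = 300,
               state_modules = list(1:4, 5:8), state_center = 80,
               second_state_modules = list(9:12, 13:16),
               second_state_center = 220,
               trait_modules = list(21:24, 25:28),
               trial_centers = c(80, 220), include_rest = FALSE),
    master_seed = 5))
  ph <- co$phenotypes
  spec <- window_spec(21, "event_centered")
  m1 <- aggregate_cv(split_half_cv(cohort_edge_matrix(co$scans, spec, 80),
                                   ph$rt_ms, ph$mean_fd, 10, seed = 2), 0.9)
  m2 <- aggregate_cv(split_half_cv(cohort_edge_matrix(co$scans, spec, 220),
                                   ph$rt2_ms, ph$mean_fd, 10, seed = 2), 0.9)
  sweep21 <- window_spec(21, "sweep")
  p1 <- temporal_profile(m1, co$scans, ph$rt_ms, sweep21)
  p2 <- temporal_profile(m2, co$scans, ph$rt2_ms, sweep21)
  expect_lte(abs(p1$center[which.max(p1$r2)] - 80), 3)
  expect_lte(abs(p2$center[which.max(p2$r2)] - 220), 3)
  # each model beats the other at its own event
  expect_gt(p1$r2[p1$center == 80], p1$r2[p1$center == 220])
  expect_gt(p2$r2[p2$center == 220], p2$r2[p2$center == 80])
  # and their 90% active sets do not overlap
  expect_length(overlap_edges(list(m1, m2)), 0L)
})

test_that("zero-slope models trace the constant-predictor baseline", {
  co <- small_cohort()
  ph <- co$phenotypes
  e <- n_edges(30)
  model <- structure(list(frequency = rep(1, e), threshold = 0.9,
                          selected = rep(TRUE, e), slope = 0,
                          intercept = mean(ph$rt_ms)),
                     class = c("aggregated_model", "cpm_model"))
  prof <- temporal_profile(model, co$scans[1:10], ph$rt_ms[1:10],
                           window_spec(21, "sweep"), centers = c(50, 100, 150))
  base <- r_squared(ph$rt_ms[1:10], rep(mean(ph$rt_ms), 10))
  expect_equal(prof$r2, rep(base, 3), tolerance = 1e-12)
})

test_that("feature similarity is the Pearson correlation of feature vectors", {
  set.seed(55)
  a <- runif(100)
  expect_equal(feature_similarity(a, a), 1)
  expect_equal(feature_similarity(a, -a), -1)
  b <- runif(100)
  expect_equal(feature_similarity(a, b), cor(a, b), tolerance = 1e-12)
  expect_error(feature_similarity(a, rep(0.5, 100)), "zero-variance")
})

test_that("feature anatomy: degrees and normalized network pairs", {
  # 5 regions: network A = {1, 2}, network B = {3, 4, 5}
  networks <- data.frame(region_index = 1:5,
                         network_label = c("A", "A", "B", "B", "B"))
  e <- n_edges(5)
  freq <- rep(0, e); sel <- rep(FALSE, e)
  k13 <- edge_index(1, 3, 5)
  freq[k13] <- 1; sel[k13] <- TRUE
  model <- structure(list(frequency = freq, selected = sel, threshold = 0.9,
                          slope = 1, intercept = 0),
                     class = c("aggregated_model", "cpm_model"))
  fs <- summarize_features(model, networks)
  expect_equal(unname(fs$degree), c(1, 0, 1, 0, 0))
  expect_equal(fs$network_pairs["A", "B"], 1 / 6)  # one of 2*3 possible A-B edges
  expect_equal(fs$network_pairs["B", "A"], 1 / 6)
  expect_equal(fs$network_pairs["A", "A"], 0)

  # all within-B edges at frequency 1 -> diagonal cell exactly 1
  freq2 <- rep(0, e)
  kk <- edge_index(c(3, 3, 4), c(4, 5, 5), 5)
  freq2[kk] <- 1
  model2 <- structure(list(frequency = freq2, selected = freq2 > 0,
                           threshold = 0.9, slope = 1, intercept = 0),
                      class = c("aggregated_model", "cpm_model"))
  fs2 <- summarize_features(model2, networks)
  expect_equal(fs2$network_pairs["B", "B"], 1)

  # empty model: zero degree everywhere
  model0 <- structure(list(frequency = rep(0, e), selected = rep(FALSE, e),
                           threshold = 0.9, slope = 0, intercept = 0),
                      class = c("aggregated_model", "cpm_model"))
  expect_equal(sum(summarize_features(model0, networks)$degree), 0)
  expect_error(summarize_features(model, networks[1:4, ]), "cover")
})

test_that("model overlap is monotone in the frequency threshold", {
  set.seed(66)
  e <- 50L
  mk <- function(freq) structure(list(frequency = freq, threshold = 0.9,
                                      selected = freq >= 0.9),
                                 class = c("aggregated_model", "cpm_model"))
  m1 <- mk(runif(e)); m2 <- mk(runif(e))
  expect_identical(overlap_edges(list(m1, m1)), which(m1$frequency >= 0.9))
  lo <- overlap_edges(list(m1, m2), threshold = 0.3)
  hi <- overlap_edges(list(m1, m2), threshold = 0.9)
  expect_true(all(hi %in% lo))
  # disjoint active sets -> empty overlap
  f1 <- rep(0, e); f1[1:5] <- 1
  f2 <- rep(0, e); f2[6:10] <- 1
  expect_length(overlap_edges(list(mk(f1), mk(f2))), 0L)
})

test_that("aggregated models track mean fold performance on training data", {
  co <- small_cohort()
  ph <- co$phenotypes
  em <- cohort_edge_matrix(co$scans, window_spec(21, "event_centered"), 100)
  cv <- split_half_cv(em, ph$rt_ms, ph$mean_fd, iterations = 10, seed = 3)
  model <- aggregate_cv(cv, 0.9)
  agg_r2 <- r_squared(ph$rt_ms, predict(model, em))
  fold_r2 <- mean(cv_test_r2(cv))
  expect_lt(abs(agg_r2 - fold_r2), 3 * sd(cv_test_r2(cv)))
})

test_that("models do not transfer across sites with different planted states", {
  spec_a <- window_spec(21, "event_centered")
  site_a <- small_cohort()   # TR 0.72, state at frame 100, modules 1:8
  site_b <- cached("site_b", function() simulate_cohort(
    sim_config(n_subjects = 50, n_regions = 30, n_frames = 200,
               tr_seconds = 0.8,
               state_modules = list(11:14, 15:18), state_center = 60,
               trait_modules = list(21:24, 25:28),
               trial_centers = c(60, 140), include_rest = FALSE),
    master_seed = 13))
  ph_a <- site_a$phenotypes; ph_b <- site_b$phenotypes
  em_a <- cohort_edge_matrix(site_a$scans, spec_a, 100)
  model_a <- aggregate_cv(
    split_half_cv(em_a, ph_a$rt_ms, ph_a$mean_fd, 10, seed = 2), 0.9)
  # match covered scan time at the other site's TR
  w_b <- equivalent_window_length(21, 0.72, 0.8, "odd")
  spec_b <- window_spec(w_b, "event_centered")
  em_b <- cohort_edge_matrix(site_b$scans, spec_b, 60)
  transfer_r2 <- r_squared(ph_b$rt_ms, predict(model_a, em_b))
  own_cv <- split_half_cv(em_b, ph_b$rt_ms, ph_b$mean_fd, 10, seed = 2)
  expect_gt(mean(cv_test_r2(own_cv)), 0.1)   # site B predicts itself
  expect_lt(transfer_r2, 0.05)               # site A's model does not transfer
})
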