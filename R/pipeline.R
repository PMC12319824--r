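# End-to-end orchestration: simulate (or load) -> condition -> preprocess ->
# windowed dFC -> CPM split-half CV -> resample aggregation -> held-out
# evaluation -> anatomical summary, with a manifest capturing every seed and
# parameter needed to re-run bit-identically. Deterministic by default:
# every stochastic stage must be given a seed in the config; a missing seed
# is an error, never a silent default.

#' Run the full brain-state modeling pipeline
#'
#' Executes the pipeline described by a structured config (a YAML file path
#' or an equivalent nested list) and writes all outputs to a run directory.
#' Config sections: \code{simulate} (passed to \code{\link{sim_config}},
#' plus \code{master_seed}) or \code{inputs} (paths to scan tables +
#' \code{tr_seconds} + phenotype/event tables); \code{condition}
#' (\code{ordered_task}/\code{shuffled_task}/\code{rest}, with
#' \code{seed} for shuffling); \code{preprocess} (\code{enabled},
#' \code{lowpass_hz}); \code{dfc} (\code{window}, \code{mode},
#' \code{center}); \code{cpm} (\code{target} column of the phenotype table,
#' \code{iterations}, \code{p_threshold}, \code{seed},
#' \code{test_fraction}); \code{aggregate} (\code{threshold});
#' \code{apply} (\code{subsamples}, \code{subsample_size}, \code{seed},
#' \code{profile}); \code{out_dir}.
#'
#' @param config path to a YAML config file, or a nested list.
#' @return (invisibly) a list with the run directory, the fitted
#'   \code{cv_result}, the \code{aggregated_model}, held-out subsampled
#'   R^2 values and (optionally) the temporal profile.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(x, what) {
    if (is.null(x)) stop("pipeline config missing required entry: ", what,
                         call. = FALSE)
    x
  }
  out_dir <- need(config$out_dir, "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("statecpm")),
                   config = config)

  # ---- stage: data -----------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    master_seed <- need(sim_args$master_seed, "simulate$master_seed")
    sim_args$master_seed <- NULL
    sim_args <- lapply(sim_args, function(v)
      if (is.list(v)) lapply(v, as.integer) else v)
    cohort <- simulate_cohort(do.call(sim_config, sim_args),
                              master_seed = master_seed)
    scans <- cohort$scans; rest_scans <- cohort$rest_scans
    phenotypes <- cohort$phenotypes
    events <- cohort$events
  } else {
    inputs <- need(config$inputs, "simulate or inputs")
    tr <- need(inputs$tr_seconds, "inputs$tr_seconds")
    paths <- need(inputs$scans, "inputs$scans")
    scans <- lapply(paths, read_scan, tr_seconds = tr)
    rest_scans <- if (!is.null(inputs$rest_scans))
      lapply(inputs$rest_scans, read_scan, tr_seconds = tr,
             scan_kind = "rest") else NULL
    phenotypes <- read_phenotypes(need(inputs$phenotypes, "inputs$phenotypes"))
    events <- if (!is.null(inputs$events)) read_events(inputs$events) else NULL
    cohort <- NULL
  }
  utils::write.csv(phenotypes, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE)
  if (!is.null(events))
    utils::write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)

  # ---- stage: condition ------------------------------------------------
  condition <- if (is.null(config$condition)) "ordered_task" else config$condition
  if (condition == "shuffled_task") {
    cseed <- need(config$condition_seed, "condition_seed")
    scans <- make_condition(scans, "shuffled_task", seed = cseed)
    manifest$shuffle_seeds <- attr(scans, "shuffle_seeds")
  } else if (condition == "rest") {
    scans <- make_condition(scans, "rest", rest_scans = rest_scans,
                            n_frames_required = nrow(scans[[1L]]$signal))
  }
  manifest$condition <- condition

  # ---- stage: preprocess ----------------------------------------------
  pp <- config$preprocess
  if (is.null(pp) || isTRUE(pp$enabled)) {
    cutoff <- if (!is.null(pp$lowpass_hz)) pp$lowpass_hz else 0.12
    scans <- lapply(scans, preprocess_scan, cutoff_hz = cutoff)
    manifest$preprocess <- list(enabled = TRUE, lowpass_hz = cutoff,
                                filter = "butterworth-5 zero-phase")
  } else manifest$preprocess <- list(enabled = FALSE)

  # ---- stage: dFC + CPM ------------------------------------------------
  dfc_cfg <- need(config$dfc, "dfc")
  w <- need(dfc_cfg$window, "dfc$window")
  mode <- if (is.null(dfc_cfg$mode)) "event_centered" else dfc_cfg$mode
  spec <- window_spec(w, mode = mode)
  center <- need(dfc_cfg$center, "dfc$center")

  cpm_cfg <- need(config$cpm, "cpm")
  target <- need(cpm_cfg$target, "cpm$target")
  if (!target %in% names(phenotypes))
    stop("cpm$target column not found in phenotype table: ", target,
         call. = FALSE)
  cv_seed <- need(cpm_cfg$seed, "cpm$seed")
  iterations <- if (is.null(cpm_cfg$iterations)) 50L else cpm_cfg$iterations
  p_thr <- if (is.null(cpm_cfg$p_threshold)) 0.1 else cpm_cfg$p_threshold
  test_fraction <- if (is.null(cpm_cfg$test_fraction)) 0.4 else
    cpm_cfg$test_fraction

  n <- length(scans)
  set.seed(substream_seed(cv_seed, "split"))
  test_idx <- sort(sample.int(n, round(n * test_fraction)))
  train_idx <- setdiff(seq_len(n), test_idx)
  manifest$split <- list(seed = cv_seed, test_fraction = test_fraction,
                         n_train = length(train_idx), n_test = length(test_idx))

  y <- phenotypes[[target]]
  z <- phenotypes$mean_fd
  edge_train <- cohort_edge_matrix(scans[train_idx], spec, center)
  utils::write.table(
    round(edge_train, 8), file.path(out_dir, "edges_train.tsv"),
    sep = "\t", row.names = FALSE, col.names = FALSE)
  cv <- split_half_cv(edge_train, y[train_idx], z[train_idx],
                      iterations = iterations, p_threshold = p_thr,
                      seed = cv_seed)
  cv_summary <- data.frame(iteration = vapply(cv$folds, `[[`, numeric(1), "iteration"),
                           fold = vapply(cv$folds, `[[`, numeric(1), "fold"),
                           test_r2 = cv_test_r2(cv),
                           n_selected = vapply(cv$folds, function(f)
                             sum(f$model$selected), numeric(1)))
  utils::write.table(cv_summary, file.path(out_dir, "cv_folds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # ---- stage: aggregate ------------------------------------------------
  thr <- if (is.null(config$aggregate$threshold)) 0.9 else
    config$aggregate$threshold
  model <- aggregate_cv(cv, threshold = thr, window = spec,
                        center_timepoint = center)
  write_model(model, file.path(out_dir, "model.json"))

  # ---- stage: apply ----------------------------------------------------
  ap <- config$apply
  subs_r2 <- NULL; profile <- NULL
  if (!is.null(ap)) {
    ap_seed <- need(ap$seed, "apply$seed")
    nsub <- if (is.null(ap$subsamples)) 50L else ap$subsamples
    ssize <- if (is.null(ap$subsample_size))
      max(8L, floor(length(test_idx) * 0.6)) else ap$subsample_size
    edge_test <- cohort_edge_matrix(scans[test_idx], spec, center)
    subs_r2 <- evaluate_subsampled(model, edge_test, y[test_idx],
                                   n_subsamples = nsub,
                                   subsample_size = ssize, seed = ap_seed)
    utils::write.table(data.frame(subsample = seq_along(subs_r2),
                                  r2 = subs_r2),
                       file.path(out_dir, "subsample_r2.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (isTRUE(ap$profile)) {
      profile <- temporal_profile(model, scans[test_idx], y[test_idx],
                                  window_spec(w, mode = "sweep"))
      utils::write.table(as.data.frame(profile),
                         file.path(out_dir, "profile.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    manifest$apply <- list(seed = ap_seed, subsamples = nsub,
                           subsample_size = ssize)
  }

  # ---- stage: summarize ------------------------------------------------
  if (!is.null(config$networks)) {
    networks <- read_networks(config$networks)
    fs <- summarize_features(model, networks)
    utils::write.table(data.frame(region = seq_along(fs$degree),
                                  network = names(fs$degree),
                                  degree = fs$degree),
                       file.path(out_dir, "degree.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(fs$network_pairs,
                       file.path(out_dir, "network_pairs.tsv"), sep = "\t",
                       quote = FALSE)
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(out_dir = out_dir, cv = cv, model = model,
                 subsample_r2 = subs_r2, profile = profile,
                 cohort = cohort, test_idx = test_idx))
}
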