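# Synthetic multi-subject cohorts with planted, behavior-coupled
# phase-locking. Regions are modeled as noisy oscillators (random-walk phase
# around a jittered base frequency); coupling is planted directly in the
# measured quantity -- the instantaneous phase -- by mixing region phases
# toward a shared driver with subject-specific strength. Two kinds of
# structure are planted:
#
#   * a behavior state: two small region modules lock to their drivers during
#     one event-centered window, with strength kappa_s = a + b * z_s (z_s the
#     subject's latent behavior, clamped to [0, 1] as a mixing weight); the
#     response time at the event trial decreases with the measured state
#     expression.
#   * a trait process: other modules lock during several episodes whose
#     onsets are random per subject (spontaneous, not task-locked); the trait
#     score follows the subject's mean scan-wide expression. Because the
#     episodes are not time-locked across subjects, ordered windows at any
#     fixed timepoint see them inconsistently, while temporally shuffled
#     windows sample the whole scan and recover the scan-wide expression --
#     the trait/behavior dissociation the pipeline is designed to expose.

#' Simulation configuration
#'
#' Defaults define the reference cohort used throughout the test-suite:
#' 200 subjects, 60 regions, 405 frames at TR 0.72 s, one planted 12-edge
#' behavior state (two 4-region modules, all within-module pairs) of 21
#' frames centered at frame 200, coupling \code{kappa = 0.5 + 1.0 * z}
#' clamped to [0, 1], behavior noise SD 0.5 (standardized units), and a
#' trait carried by spontaneous episodes of two other modules.
#'
#' @param n_subjects,n_regions,n_frames,tr_seconds cohort dimensions.
#' @param base_frequency_hz,freq_jitter_sd_hz oscillator base frequency and
#'   per-region jitter (Hz); the default 0.05 Hz sits inside the 0.12 Hz
#'   low-pass band.
#' @param phase_noise_sd per-frame random-walk phase noise (radians).
#' @param sensor_noise_sd additive white measurement noise on the signal.
#' @param state_modules list of two integer vectors: the region modules of
#'   the behavior state; the planted edges are all within-module pairs.
#' @param state_center,state_duration 0-based center frame and duration
#'   (frames) of the behavior state window.
#' @param coupling_base,coupling_slope a and b of
#'   \code{kappa_s = a + b * z_s}.
#' @param behavior_noise_sd,rt_gamma behavior model: standardized RT =
#'   \code{-rt_gamma * scale(expression) + N(0, behavior_noise_sd)}. The
#'   sign of \code{rt_gamma} sets whether state expression speeds
#'   (\code{> 0}) or slows (\code{< 0}) responses; the default \code{-1}
#'   couples stronger phase locking to slower responses, so the
#'   behaviorally relevant edges lie in the positive network that CPM
#'   models.
#' @param rt_mean_ms,rt_sd_ms affine map from standardized RT to
#'   milliseconds.
#' @param trait_modules,trait_episodes,trait_episode_duration,
#'   trait_coupling_base,trait_coupling_slope the spontaneous trait process.
#' @param trait_loading,trait_noise_sd trait =
#'   \code{trait_loading * scale(scan-wide expression) + N(0, trait_noise_sd)}.
#' @param fd_mean,fd_sd,fd_target_cor,fd_confound_strength mean framewise
#'   displacement distribution (mm), its correlation with the behavior
#'   latent, and the amplitude of the motion-locked global artifact added to
#'   the signal.
#' @param trial_centers 0-based trial center frames (the behavior state
#'   center must be one of them).
#' @param second_state_modules,second_state_center optional second planted
#'   behavior state (same duration and coupling parameters, its own latent
#'   and its own target \code{rt2_ms}), for temporal-specificity analyses
#'   where two models should each peak at their own event.
#' @param include_rest also generate a rest scan per subject (same
#'   oscillators, nothing planted).
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects = 200L, n_regions = 60L, n_frames = 405L,
                       tr_seconds = 0.72,
                       base_frequency_hz = 0.05, freq_jitter_sd_hz = 0.01,
                       phase_noise_sd = 0.1, sensor_noise_sd = 0.1,
                       state_modules = list(1:4, 5:8),
                       state_center = 200L, state_duration = 21L,
                       coupling_base = 0.5, coupling_slope = 1.0,
                       behavior_noise_sd = 0.5, rt_gamma = -1.0,
                       rt_mean_ms = 800, rt_sd_ms = 150,
                       trait_modules = list(41:44, 45:48),
                       trait_episodes = 8L, trait_episode_duration = 21L,
                       trait_coupling_base = 0.5, trait_coupling_slope = 0.35,
                       trait_loading = 1.0, trait_noise_sd = 0.5,
                       fd_mean = 0.12, fd_sd = 0.05, fd_target_cor = 0.2,
                       fd_confound_strength = 0.3,
                       trial_centers = seq(40L, 380L, by = 40L),
                       second_state_modules = NULL,
                       second_state_center = NULL,
                       include_rest = TRUE) {
  cfg <- as.list(environment())
  stopifnot(n_regions >= max(unlist(c(state_modules, trait_modules,
                                      second_state_modules))),
            state_center - (state_duration - 1) / 2 >= 0,
            state_center + (state_duration - 1) / 2 <= n_frames - 1,
            state_center %in% trial_centers)
  structure(cfg, class = "sim_config")
}

module_edges <- function(modules, n_regions) {
  unlist(lapply(modules, function(m) {
    p <- t(utils::combn(sort(m), 2L))
    edge_index(p[, 1L], p[, 2L], n_regions)
  }))
}

# Random-walk oscillator phases for one subject: T x N matrix.
oscillator_phases <- function(t_frames, n_regions, tr, f0, f_jit, noise_sd) {
  freqs <- f0 + stats::rnorm(n_regions, 0, f_jit)
  incr <- matrix(stats::rnorm(t_frames * n_regions, 0, noise_sd),
                 t_frames, n_regions)
  incr <- sweep(incr, 2L, 2 * pi * freqs * tr, `+`)
  incr[1L, ] <- stats::runif(n_regions, -pi, pi)  # initial phase
  apply(incr, 2L, cumsum)
}

# Mix phases of `regions` toward a driver phase over `rows`, weight kappa.
mix_toward <- function(theta, rows, regions, driver, kappa) {
  if (kappa <= 0) return(theta)
  u <- (1 - kappa) * exp(1i * theta[rows, regions, drop = FALSE]) +
    kappa * exp(1i * as.numeric(driver))  # recycled down columns
  theta[rows, regions] <- Arg(u)
  theta
}

#' Simulate a multi-subject cohort
#'
#' Generates task (and optionally rest) parcellated scans with planted
#' phase-locking, a trial/event table, a phenotype table (trait, mean FD and
#' the per-subject behavior target \code{rt_ms}), and the ground truth
#' needed for recovery scoring. All randomness flows from \code{master_seed}
#' through named counter-based substreams, so identical seeds give
#' byte-identical cohorts.
#'
#' @param config a \code{\link{sim_config}}.
#' @param master_seed integer master seed.
#' @return a list of class \code{sim_cohort} with elements \code{scans},
#'   \code{rest_scans} (or \code{NULL}), \code{events} (one data.frame, all
#'   subjects), \code{phenotypes}, \code{ground_truth}, \code{config},
#'   \code{master_seed}.
#' @export
simulate_cohort <- function(config = sim_config(), master_seed = 1L) {
  cfg <- config
  tt <- cfg$n_frames; nn <- cfg$n_regions; ns <- cfg$n_subjects
  planted_edges <- module_edges(cfg$state_modules, nn)
  trait_edges <- module_edges(cfg$trait_modules, nn)
  pairs <- edge_pairs(nn)
  half <- (cfg$state_duration - 1L) %/% 2L
  event_rows <- (cfg$state_center - half):(cfg$state_center + half) + 1L

  has_state2 <- !is.null(cfg$second_state_modules)
  if (has_state2) {
    stopifnot(!is.null(cfg$second_state_center))
    planted_edges2 <- module_edges(cfg$second_state_modules, nn)
    event_rows2 <- (cfg$second_state_center - half):(cfg$second_state_center + half) + 1L
    pe2_pairs <- pairs[planted_edges2, , drop = FALSE]
    expr_beh2 <- numeric(ns)
  }

  set.seed(substream_seed(master_seed, "behavior"))
  z <- stats::rnorm(ns)
  if (has_state2) {
    set.seed(substream_seed(master_seed, "behavior2"))
    z2 <- stats::rnorm(ns)
    kappa_beh2 <- pmin(pmax(cfg$coupling_base + cfg$coupling_slope * z2, 0), 1)
  }
  set.seed(substream_seed(master_seed, "trait"))
  w <- stats::rnorm(ns)
  set.seed(substream_seed(master_seed, "fd"))
  eps_fd <- stats::rnorm(ns)
  mean_fd <- pmax(cfg$fd_mean + cfg$fd_sd *
                    (cfg$fd_target_cor * z +
                       sqrt(1 - cfg$fd_target_cor^2) * eps_fd), 0.01)
  kappa_beh <- pmin(pmax(cfg$coupling_base + cfg$coupling_slope * z, 0), 1)
  kappa_trait <- pmin(pmax(cfg$trait_coupling_base +
                             cfg$trait_coupling_slope * w, 0), 1)

  scans <- vector("list", ns)
  rest_scans <- if (cfg$include_rest) vector("list", ns) else NULL
  expr_beh <- numeric(ns)
  expr_trait <- numeric(ns)
  episode_onsets <- vector("list", ns)
  pe_pairs <- pairs[planted_edges, , drop = FALSE]
  te_pairs <- pairs[trait_edges, , drop = FALSE]

  for (s in seq_len(ns)) {
    set.seed(substream_seed(master_seed, "signals", s))
    theta <- oscillator_phases(tt, nn, cfg$tr_seconds, cfg$base_frequency_hz,
                               cfg$freq_jitter_sd_hz, cfg$phase_noise_sd)
    # behavior state: each module locks to its own driver over the event rows
    for (m in cfg$state_modules) {
      driver <- oscillator_phases(length(event_rows), 1L, cfg$tr_seconds,
                                  cfg$base_frequency_hz, 0, cfg$phase_noise_sd)
      theta <- mix_toward(theta, event_rows, m, driver, kappa_beh[s])
    }
    if (has_state2) {
      for (m in cfg$second_state_modules) {
        driver <- oscillator_phases(length(event_rows2), 1L, cfg$tr_seconds,
                                    cfg$base_frequency_hz, 0, cfg$phase_noise_sd)
        theta <- mix_toward(theta, event_rows2, m, driver, kappa_beh2[s])
      }
    }
    # trait process: episodes at subject-specific onsets
    onsets <- sort(sample.int(tt - cfg$trait_episode_duration,
                              cfg$trait_episodes))
    episode_onsets[[s]] <- onsets - 1L  # 0-based
    for (on in onsets) {
      rows <- on:(on + cfg$trait_episode_duration - 1L)
      for (m in cfg$trait_modules) {
        driver <- oscillator_phases(length(rows), 1L, cfg$tr_seconds,
                                    cfg$base_frequency_hz, 0,
                                    cfg$phase_noise_sd)
        theta <- mix_toward(theta, rows, m, driver, kappa_trait[s])
      }
    }
    # measured expressions from the generated phases
    dphi_b <- theta[event_rows, pe_pairs[, 1L], drop = FALSE] -
      theta[event_rows, pe_pairs[, 2L], drop = FALSE]
    expr_beh[s] <- mean(cos(dphi_b))
    dphi_t <- theta[, te_pairs[, 1L], drop = FALSE] -
      theta[, te_pairs[, 2L], drop = FALSE]
    expr_trait[s] <- mean(cos(dphi_t))
    if (has_state2) {
      dphi_b2 <- theta[event_rows2, pe2_pairs[, 1L], drop = FALSE] -
        theta[event_rows2, pe2_pairs[, 2L], drop = FALSE]
      expr_beh2[s] <- mean(cos(dphi_b2))
    }
    # observed signal: oscillation + sensor noise + motion-locked artifact
    artifact <- cfg$fd_confound_strength *
      ((mean_fd[s] - cfg$fd_mean) / cfg$fd_sd) *
      stats::filter(stats::rnorm(tt), rep(1 / 5, 5), sides = 2L,
                    circular = TRUE)
    x <- cos(theta) +
      matrix(stats::rnorm(tt * nn, 0, cfg$sensor_noise_sd), tt, nn) +
      as.numeric(artifact)
    scans[[s]] <- parcellated_scan(x, cfg$tr_seconds,
                                   subject_id = sprintf("sub%04d", s),
                                   scan_kind = "task")
    if (cfg$include_rest) {
      set.seed(substream_seed(master_seed, "rest", s))
      theta_r <- oscillator_phases(tt, nn, cfg$tr_seconds,
                                   cfg$base_frequency_hz,
                                   cfg$freq_jitter_sd_hz, cfg$phase_noise_sd)
      xr <- cos(theta_r) +
        matrix(stats::rnorm(tt * nn, 0, cfg$sensor_noise_sd), tt, nn)
      rest_scans[[s]] <- parcellated_scan(xr, cfg$tr_seconds,
                                          subject_id = sprintf("sub%04d", s),
                                          scan_kind = "rest")
    }
  }

  # behavior and trait targets from the measured expressions
  set.seed(substream_seed(master_seed, "targets"))
  rt_std <- -cfg$rt_gamma * as.numeric(scale(expr_beh)) +
    stats::rnorm(ns, 0, cfg$behavior_noise_sd)
  rt_ms <- cfg$rt_mean_ms + cfg$rt_sd_ms * rt_std
  trait <- cfg$trait_loading * as.numeric(scale(expr_trait)) +
    stats::rnorm(ns, 0, cfg$trait_noise_sd)
  if (has_state2) {
    set.seed(substream_seed(master_seed, "targets2"))
    rt2_std <- -cfg$rt_gamma * as.numeric(scale(expr_beh2)) +
      stats::rnorm(ns, 0, cfg$behavior_noise_sd)
    rt2_ms <- cfg$rt_mean_ms + cfg$rt_sd_ms * rt2_std
  }

  # trial table: common trial grid; the planted trial carries the coupled RT
  set.seed(substream_seed(master_seed, "trials"))
  events <- do.call(rbind, lapply(seq_len(ns), function(s) {
    rt_other <- cfg$rt_mean_ms +
      cfg$rt_sd_ms * stats::rnorm(length(cfg$trial_centers))
    rt <- ifelse(cfg$trial_centers == cfg$state_center, rt_ms[s], rt_other)
    data.frame(subject_id = sprintf("sub%04d", s),
               trial_index = seq_along(cfg$trial_centers),
               center_frame = cfg$trial_centers,
               block_type = rep(c("0-back", "2-back"),
                                length.out = length(cfg$trial_centers)),
               response_time_ms = rt)
  }))

  phenotypes <- data.frame(subject_id = sprintf("sub%04d", seq_len(ns)),
                           trait = trait, mean_fd = mean_fd, rt_ms = rt_ms)
  if (has_state2) phenotypes$rt2_ms <- rt2_ms

  structure(list(
    scans = scans, rest_scans = rest_scans, events = events,
    phenotypes = phenotypes,
    ground_truth = list(planted_edges = planted_edges,
                        trait_edges = trait_edges,
                        state_center = cfg$state_center,
                        state_duration = cfg$state_duration,
                        z = z, w = w, kappa_behavior = kappa_beh,
                        kappa_trait = kappa_trait,
                        expression_behavior = expr_beh,
                        expression_trait = expr_trait,
                        episode_onsets = episode_onsets,
                        planted_edges_2 = if (has_state2) planted_edges2,
                        second_state_center = if (has_state2)
                          cfg$second_state_center,
                        z2 = if (has_state2) z2),
    config = cfg, master_seed = as.integer(master_seed)),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects, %d regions x %d frames (TR %.3g s); %d planted behavior edges at frame %d\n",
              length(x$scans), x$config$n_regions, x$config$n_frames,
              x$config$tr_seconds, length(x$ground_truth$planted_edges),
              x$ground_truth$state_center))
  invisible(x)
}

#' Windowed edge matrix for a cohort at one center
#'
#' Convenience wrapper: computes each subject's phase-coherence window mean
#' at a single 0-based center, stacking into a subjects x E matrix ready for
#' the CPM engine.
#'
#' @param scans list of \code{parcellated_scan}s.
#' @param spec a \code{\link{window_spec}}.
#' @param center 0-based window center frame.
#' @return subjects x E numeric matrix.
#' @export
cohort_edge_matrix <- function(scans, spec, center) {
  out <- NULL
  for (s in seq_along(scans)) {
    cs <- phase_cos_sin(scans[[s]])
    wm <- window_edge_means(cs, spec, centers = center)
    if (length(wm$centers) == 0L)
      stop("window at center ", center, " does not fit the scan",
           call. = FALSE)
    if (is.null(out)) out <- matrix(NA_real_, length(scans), ncol(wm$means))
    out[s, ] <- wm$means[1L, ]
  }
  out
}

#' Recovery of planted structure by a fitted model
#'
#' Scores an aggregated model against a simulation's ground truth:
#' precision and recall of the planted edge set, and (when a temporal
#' profile is supplied) the timepoint contrast -- mean R^2 at centers inside
#' the planted event window minus mean R^2 at non-event centers.
#'
#' @param model an \code{aggregated_model} (or \code{cpm_model}).
#' @param ground_truth the \code{ground_truth} element of a
#'   \code{\link{simulate_cohort}} result.
#' @param profile optional \code{\link{temporal_profile}} result.
#' @return a list with \code{precision} (NA when the active set is empty),
#'   \code{recall}, \code{n_active}, and (with a profile)
#'   \code{timepoint_contrast}, \code{peak_center},
#'   \code{peak_offset_frames}.
#' @export
recovery_report <- function(model, ground_truth, profile = NULL) {
  active <- which(model$selected)
  planted <- ground_truth$planted_edges
  hits <- length(intersect(active, planted))
  out <- list(
    precision = if (length(active)) hits / length(active) else NA_real_,
    recall = hits / length(planted),
    n_active = length(active))
  if (!is.null(profile)) {
    half <- (ground_truth$state_duration - 1) / 2
    near <- abs(profile$center - ground_truth$state_center) <= half
    far <- abs(profile$center - ground_truth$state_center) >
      ground_truth$state_duration
    out$timepoint_contrast <- mean(profile$r2[near]) - mean(profile$r2[far])
    out$peak_center <- profile$center[which.max(profile$r2)]
    out$peak_offset_frames <- out$peak_center - ground_truth$state_center
  }
  out
}
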