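# Shared fixtures, built in code. Cohorts are cached per (name) so that the
# test files reuse one simulation instead of regenerating it.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cohort_cache))
    assign(name, builder(), envir = .cohort_cache)
  get(name, envir = .cohort_cache)
}

# Small cohort: fast enough for per-module tests.
small_config <- function(...) {
  defaults <- list(n_subjects = 60, n_regions = 30, n_frames = 200,
                   state_modules = list(1:4, 5:8), state_center = 100,
                   trait_modules = list(21:24, 25:28),
                   trial_centers = seq(20, 180, by = 40),
                   include_rest = FALSE)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_cohort <- function() {
  cached("small", function() simulate_cohort(small_config(), master_seed = 7))
}

# Full study-condition cohort (simulator defaults): 200 subjects, 60 regions,
# one planted 12-edge state, b = 1, behavior noise SD 0.5.
default_cohort <- function() {
  cached("default", function() simulate_cohort(sim_config(), master_seed = 11))
}

default_cohort_shuffled <- function() {
  cached("default_shuffled", function()
    make_condition(default_cohort()$scans, "shuffled_task", seed = 5))
}

# Null cohort: behavior fully decoupled from connectivity (b = 0, gamma = 0).
null_cohort <- function() {
  cached("null", function()
    simulate_cohort(sim_config(coupling_slope = 0, rt_gamma = 0,
                               include_rest = FALSE), master_seed = 11))
}

# A deterministic sinusoidal scan: region r = cos(2*pi*f*t + phase[r]).
sinusoid_scan <- function(freqs_hz, phases = rep(0, length(freqs_hz)),
                          t_frames = 200L, tr = 1) {
  tt <- (seq_len(t_frames) - 1L) * tr
  sig <- sapply(seq_along(freqs_hz), function(r)
    cos(2 * pi * freqs_hz[r] * tt + phases[r]))
  parcellated_scan(sig, tr_seconds = tr)
}

interior <- function(n, margin) (margin + 1L):(n - margin)
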