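# Shared fixtures: small synthetic configurations and cohort runners used
# across test files. All problem sizes are scaled down from the 5-min
# study recordings to keep the suite fast; seeds are fixed.

quick_cfg <- function(...) {
  synth_config(duration_s = 60, ...)
}

# Generate one subject's windowed slope values + analysis-side phases.
subject_slope_data <- function(cfg, peaks = FALSE) {
  r <- gen_respiration(cfg)
  neural <- gen_neural_recording(cfg, true_phase_series(r))
  sts <- parameterize_recording(neural, peaks = peaks)
  phase <- interpolate_phase(detect_extrema(normalize_trace(r)))
  list(resp = r,
       sts = sts,
       values = sts$fits$exponent,
       phases = phase_at_windows(phase, sts$window_centers))
}

# Cohort-level modulation test against the synthetic ground truth.
cohort_modulation_test <- function(seed, A, phi0 = pi, n_sub = 20,
                                   dur = 60, k = 200, subject_sd = 0.1,
                                   mode = "shift") {
  base <- synth_config(duration_s = dur, exponent_mod_amp = A,
                       exponent_mod_phase = phi0, peaks = list(),
                       subject_sd = subject_sd, seed = seed)
  cohort <- gen_cohort(n_sub, base)
  vals <- list(); phs <- list()
  for (j in seq_along(cohort)) {
    sts <- parameterize_recording(cohort[[j]]$neural, peaks = FALSE)
    phase <- interpolate_phase(detect_extrema(normalize_trace(cohort[[j]]$resp)))
    vals[[j]] <- sts$fits$exponent
    phs[[j]] <- phase_at_windows(phase, sts$window_centers)
  }
  harmonic_modulation_test(vals, phs, k = k, seed = seed + 13L, mode = mode)
}
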