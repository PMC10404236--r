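# End-to-end orchestration: synthetic cohorts through preprocessing,
# parameterization, phase binning and inference, for the three study
# workflows (sensor-level slope modulation, parcel slope-vs-power
# dynamics, two-condition comparison).

#' Configuration of a pipeline run
#'
#' @param synth a [synth_config()] providing the recording conditions
#'   (duration, rates, baseline spectrum, noise).
#' @param n_subjects cohort size (>= 2).
#' @param channels named list of channel (or parcel) definitions; each
#'   element is a list of [synth_config()] field overrides, typically
#'   `exponent_mod_amp`, `exponent_mod_phase` and `peaks`. An empty
#'   override list means an unmodulated channel.
#' @param k_perm number of null iterations for the modulation test.
#' @param null_mode null construction, see [harmonic_modulation_test()].
#' @param min_prominence peak prominence for respiratory extrema
#'   detection (on the z-scored trace).
#' @param fit_peaks extract oscillatory peaks per window (required for
#'   power courses; slope-only analyses run faster without).
#' @param bands named list of frequency bands for accumulated power.
#' @param alpha significance level applied to permutation p-values.
#' @param seed master seed; every random draw in the run derives from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), n_subjects = 20,
                       channels = list(ch1 = list()), k_perm = 200,
                       null_mode = "shift", min_prominence = 1,
                       fit_peaks = FALSE,
                       bands = list(full = c(1, 40), theta = c(4, 8),
                                    alpha = c(8, 13), beta = c(13, 30)),
                       alpha = 0.05, seed = 1L) {
  stopifnot(inherits(synth, "synth_config"))
  if (n_subjects < 2) abort("need >= 2 subjects", "respcouple_config_error")
  if (length(channels) < 1 || is.null(names(channels))) {
    abort("channels must be a named list", "respcouple_config_error")
  }
  structure(list(synth = synth, n_subjects = as.integer(n_subjects),
                 channels = channels, k_perm = k_perm, null_mode = null_mode,
                 min_prominence = min_prominence, fit_peaks = fit_peaks,
                 bands = bands, alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

apply_overrides <- function(synth, overrides) {
  args <- unclass(synth)
  for (nm in names(overrides)) {
    if (!nm %in% names(args)) {
      abort(sprintf("unknown channel override `%s`", nm),
            "respcouple_config_error")
    }
    args[[nm]] <- overrides[[nm]]
  }
  do.call(synth_config, args)  # re-validates and normalizes peak entries
}

# Generate and analyze one cohort: respiration + derived phase per subject,
# one recording per channel, windowed slope (and optionally power) values
# aligned with the derived phase.
collect_cohort_data <- function(cfg) {
  n_ch <- length(cfg$channels)
  subj_seeds <- derive_seeds(cfg$seed, cfg$n_subjects)
  out <- vector("list", cfg$n_subjects)
  for (j in seq_len(cfg$n_subjects)) {
    seeds_j <- derive_seeds(subj_seeds[j], n_ch + 2L)
    cfg_resp <- cfg$synth
    cfg_resp$seed <- seeds_j[n_ch + 1L]
    resp <- gen_respiration(cfg_resp)
    inj_phase <- true_phase_series(resp)
    # analysis-side phase: re-derived from the noisy trace
    phase <- interpolate_phase(
      detect_extrema(normalize_trace(resp), cfg$min_prominence))
    A_seeds <- derive_seeds(seeds_j[n_ch + 2L], n_ch)
    chans <- vector("list", n_ch)
    for (c_i in seq_len(n_ch)) {
      cfg_ch <- apply_overrides(cfg$synth, cfg$channels[[c_i]])
      cfg_ch$seed <- seeds_j[c_i]
      # per-subject modulation depth around the channel's population mean
      cfg_ch$exponent_mod_amp <- with_seed(A_seeds[c_i], pmax(0,
        stats::rnorm(1, cfg_ch$exponent_mod_amp, cfg_ch$subject_sd)))
      neural <- gen_neural_recording(cfg_ch, inj_phase)
      sts <- parameterize_recording(neural, peaks = cfg$fit_peaks)
      win_phase <- phase_at_windows(phase, sts$window_centers)
      chans[[c_i]] <- list(slope = sts$fits$exponent,
                           phases = win_phase,
                           sts = sts,
                           truth_A = cfg_ch$exponent_mod_amp)
    }
    names(chans) <- names(cfg$channels)
    out[[j]] <- list(resp = resp, phase = phase, channels = chans)
  }
  out
}

#' Sensor-level slope-modulation pipeline
#'
#' For every channel of a synthetic cohort: generate recordings, derive
#' respiratory phase from the (noisy) belt trace, parameterize windows,
#' bin 1/f exponents by phase, and test phase locking with the harmonic
#' model and surrogate null. Channel-wise circular means of the group
#' courses are tested for directional consistency with a Rayleigh test
#' when at least 3 channels are analyzed.
#'
#' @param cfg a [run_config()].
#' @return object of class `sensor_result`: list with `table` (one row
#'   per channel: v, z, p, significance flag, circular mean direction),
#'   `courses` (group-average `phase_course` per channel), `fits`
#'   (the full `harmonic_fit` per channel), and `rayleigh` (a
#'   `circ_result`, or `NA` with an explanatory `rayleigh_note` when
#'   fewer than 3 channels are available).
#' @export
run_sensor_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  data <- collect_cohort_data(cfg)
  ch_names <- names(cfg$channels)
  test_seeds <- derive_seeds(cfg$seed + 1L, length(ch_names))
  fits <- list(); courses <- list()
  rows <- list(); failed <- character(0)
  for (c_i in seq_along(ch_names)) {
    res <- tryCatch({
      vals <- lapply(data, function(s) s$channels[[c_i]]$slope)
      phs <- lapply(data, function(s) s$channels[[c_i]]$phases)
      fit <- harmonic_modulation_test(vals, phs, k = cfg$k_perm,
                                      seed = test_seeds[c_i],
                                      mode = cfg$null_mode)
      group <- group_course(fit$courses)
      dir <- tryCatch(course_circular_mean(group)$mean_direction,
                      error = function(e) NA_real_)
      list(fit = fit, group = group, dir = dir)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, ch_names[c_i])
      next
    }
    fits[[ch_names[c_i]]] <- res$fit
    courses[[ch_names[c_i]]] <- res$group
    rows[[ch_names[c_i]]] <- data.frame(
      channel = ch_names[c_i], v = res$fit$v, z = res$fit$z, p = res$fit$p,
      significant = res$fit$p <= cfg$alpha, circ_mean = res$dir)
  }
  if (!length(rows)) {
    abort("all channels failed", "respcouple_data_error")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  dirs <- tab$circ_mean[!is.na(tab$circ_mean)]
  ray <- NULL; note <- NULL
  if (length(dirs) >= 3) {
    ray <- rayleigh_test(dirs)
  } else {
    note <- "Rayleigh test skipped: fewer than 3 channel directions"
  }
  structure(list(table = tab, courses = courses, fits = fits,
                 rayleigh = ray, rayleigh_note = note,
                 failed_channels = failed, config = cfg),
            class = "sensor_result")
}

# group-average course from per-subject courses (bins averaged over
# subjects, empty bins ignored)
group_course <- function(courses) {
  M <- course_matrix(courses)
  structure(list(bin_centers = courses[[1]]$bin_centers,
                 means = colMeans(M, na.rm = TRUE),
                 counts = colSums(!is.na(M))),
            class = "phase_course")
}

#' Parcel-level dynamics of slope vs oscillatory power
#'
#' For each "parcel" (channel definition with both exponent and peak-power
#' modulation): slope and band-accumulated periodic power courses per
#' subject, harmonic modulation tests for slope and for each power band,
#' the phase difference between the group slope and power courses, a
#' two-sample Watson U2 test of the per-subject preferred phases of slope
#' vs power, and per-subject Watson U2 non-uniformity statistics.
#'
#' The slope-vs-power comparison (phase difference and U2) uses the power
#' course of the *first* band in `cfg$bands`. The default band list puts
#' the full 1-40 Hz range first; when a parcel's oscillatory activity is
#' confined to a known band, listing that band first concentrates the
#' comparison on the frequencies that actually carry periodic power.
#'
#' @param cfg a [run_config()].
#' @return list (class `parcel_result`) with one element per parcel.
#' @export
run_parcel_dynamics <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  data <- collect_cohort_data(cfg)
  ch_names <- names(cfg$channels)
  test_seeds <- derive_seeds(cfg$seed + 2L, 3L * length(ch_names))
  out <- vector("list", length(ch_names))
  names(out) <- ch_names
  for (c_i in seq_along(ch_names)) {
    phs <- lapply(data, function(s) s$channels[[c_i]]$phases)
    slope_vals <- lapply(data, function(s) s$channels[[c_i]]$slope)
    slope_fit <- harmonic_modulation_test(slope_vals, phs, k = cfg$k_perm,
                                          seed = test_seeds[3 * c_i - 2],
                                          mode = cfg$null_mode)
    band_fits <- list()
    for (b in names(cfg$bands)) {
      # residual mode: binning this window-wise band sum reproduces the
      # accumulated power of the bin-averaged periodic spectrum
      pw_vals <- lapply(data, function(s) {
        accumulated_power_course(s$channels[[c_i]]$sts, cfg$bands[[b]],
                                 mode = "residual")
      })
      band_fits[[b]] <- harmonic_modulation_test(
        pw_vals, phs, k = cfg$k_perm,
        seed = test_seeds[3 * c_i - 1], mode = cfg$null_mode)
    }
    power_fit <- band_fits[[1]]
    slope_group <- group_course(slope_fit$courses)
    power_group <- group_course(power_fit$courses)
    dphi <- tryCatch(phase_difference(slope_group, power_group),
                     error = function(e) NA_real_)
    subj_dir <- function(fit) {
      vapply(fit$courses, function(cc) {
        tryCatch(course_circular_mean(cc)$mean_direction,
                 error = function(e) NA_real_)
      }, numeric(1))
    }
    ds <- subj_dir(slope_fit); dp <- subj_dir(power_fit)
    ok <- !is.na(ds) & !is.na(dp)
    u2 <- if (sum(ok) >= 4) {
      watson_u2_two_sample(ds[ok], dp[ok], k_perm = cfg$k_perm,
                           seed = test_seeds[3 * c_i])
    } else NULL
    subj_u2 <- function(fit) {
      vapply(fit$courses, function(cc) {
        tryCatch(watson_u2_uniformity(cc)$statistic,
                 error = function(e) NA_real_)
      }, numeric(1))
    }
    out[[c_i]] <- list(
      slope = slope_fit, power = power_fit, bands = band_fits,
      slope_course = slope_group, power_course = power_group,
      phase_difference = dphi, slope_vs_power_u2 = u2,
      subject_u2_slope = subj_u2(slope_fit),
      subject_u2_power = subj_u2(power_fit))
  }
  structure(out, class = "parcel_result")
}

#' Two-condition comparison of modulation ranges
#'
#' Runs the slope pipeline on two condition configurations (e.g. deep vs
#' normal breathing), extracts per-subject course ranges
#' (max - min of the slope course over the respiratory cycle), and
#' compares them with a two-sided signed-rank test (paired) or rank-sum
#' test (unpaired). Both conditions' group-level modulation tests are
#' reported alongside.
#'
#' @param cfg_a,cfg_b [run_config()] objects (single channel each). In
#'   paired mode the cohorts must have equal size.
#' @param paired are the two conditions recorded from the same subjects?
#' @return list (class `condition_compare`) with per-condition ranges and
#'   fits and the `range_test` result (or its error message when the
#'   comparison is degenerate, e.g. all differences zero).
#' @export
run_condition_compare <- function(cfg_a, cfg_b, paired = TRUE) {
  stopifnot(inherits(cfg_a, "run_config"), inherits(cfg_b, "run_config"))
  if (paired && cfg_a$n_subjects != cfg_b$n_subjects) {
    abort("paired comparison requires equal cohort sizes",
          "respcouple_config_error")
  }
  one <- function(cfg) {
    data <- collect_cohort_data(cfg)
    vals <- lapply(data, function(s) s$channels[[1]]$slope)
    phs <- lapply(data, function(s) s$channels[[1]]$phases)
    fit <- harmonic_modulation_test(vals, phs, k = cfg$k_perm,
                                    seed = cfg$seed + 7L,
                                    mode = cfg$null_mode)
    list(fit = fit,
         ranges = vapply(fit$courses, course_range, numeric(1)))
  }
  a <- one(cfg_a); b <- one(cfg_b)
  test <- tryCatch({
    if (paired) signed_rank_compare(a$ranges, b$ranges)
    else rank_sum_compare(a$ranges, b$ranges)
  }, error = function(e) list(error = conditionMessage(e)))
  structure(list(ranges_a = a$ranges, ranges_b = b$ranges,
                 fit_a = a$fit, fit_b = b$fit,
                 paired = paired, range_test = test),
            class = "condition_compare")
}
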