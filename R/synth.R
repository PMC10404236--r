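# Synthetic respiration + neural recordings with known phase-locked
# modulation of the aperiodic exponent and of oscillatory peak power.
# These generators define the ground truth against which every downstream
# stage of the package is validated.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions the analysis is built for:
#' 5-min recordings sampled at 300 Hz, quasi-periodic nasal breathing at
#' ~15 breaths/min (0.25 Hz) with mild cycle-length and depth variability,
#' a 1/f-shaped neural background whose exponent is sinusoidally modulated
#' by respiratory phase, and an alpha-band oscillation whose power is
#' modulated with its own preferred phase.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (both respiration and neural channels).
#' @param breath_rate_bpm mean breathing rate, breaths per minute.
#' @param rate_jitter fractional SD of breath-cycle length.
#' @param depth_jitter fractional SD of breath-cycle amplitude.
#' @param resp_noise_sd SD of additive Gaussian sensor noise on the
#'   respiration trace (a.u.; cycle amplitude is ~1).
#' @param aperiodic_offset aperiodic offset, log10(power) at 1 Hz.
#' @param aperiodic_exponent_base baseline aperiodic exponent chi0 (the
#'   "1/f slope" steepness; > 0).
#' @param exponent_mod_amp modulation depth A of the exponent:
#'   chi(t) = chi0 + A * cos(phase(t) - exponent_mod_phase).
#' @param exponent_mod_phase preferred respiratory phase of the steepest
#'   slope, radians (pi = expiration-to-inspiration transition, where the
#'   slope is steepest in resting-state M/EEG).
#' @param peaks list of oscillatory components; each a numeric vector
#'   `c(center, height, width, power_mod_amp, power_mod_phase)` with center
#'   and width (Gaussian SD) in Hz, height in log10(power) above the
#'   aperiodic background, and the peak's linear power scaled by
#'   `1 + power_mod_amp * cos(phase - power_mod_phase)`.
#' @param subject_sd between-subject SD of the exponent modulation depth
#'   (amplitudes are truncated at 0: modulation depth is norm-like).
#' @param seed integer seed; all randomness in the generators derives from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 300, fs = 300,
                         breath_rate_bpm = 15,
                         rate_jitter = 0.1, depth_jitter = 0.1,
                         resp_noise_sd = 0.05,
                         aperiodic_offset = 1,
                         aperiodic_exponent_base = 1.5,
                         exponent_mod_amp = 0.4,
                         exponent_mod_phase = pi,
                         peaks = list(c(center = 10, height = 0.6, width = 2,
                                        power_mod_amp = 0.5,
                                        power_mod_phase = 0)),
                         subject_sd = 0.1,
                         seed = 1L) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(fs, "fs")
  check_positive_scalar(breath_rate_bpm, "breath_rate_bpm")
  check_positive_scalar(aperiodic_exponent_base, "aperiodic_exponent_base")
  for (nm in c("rate_jitter", "depth_jitter", "resp_noise_sd",
               "exponent_mod_amp", "subject_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("`%s` must be a non-negative scalar", nm),
            "respcouple_config_error")
    }
  }
  peaks <- lapply(peaks, function(p) {
    p <- as.numeric(p)
    if (length(p) < 3) {
      abort("each peak needs at least (center, height, width)",
            "respcouple_config_error")
    }
    if (length(p) < 5) p <- c(p, rep(0, 5 - length(p)))
    names(p) <- c("center", "height", "width", "power_mod_amp",
                  "power_mod_phase")
    if (p["width"] <= 0) abort("peak width must be > 0", "respcouple_config_error")
    p
  })
  structure(list(duration_s = duration_s, fs = fs,
                 breath_rate_bpm = breath_rate_bpm,
                 rate_jitter = rate_jitter, depth_jitter = depth_jitter,
                 resp_noise_sd = resp_noise_sd,
                 aperiodic_offset = aperiodic_offset,
                 aperiodic_exponent_base = aperiodic_exponent_base,
                 exponent_mod_amp = exponent_mod_amp,
                 exponent_mod_phase = exponent_mod_phase,
                 peaks = peaks, subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic respiration trace
#'
#' Builds a quasi-sinusoidal belt-like signal from a sequence of breathing
#' cycles with lengths ~ Normal(60/rate, rate_jitter * mean) and amplitudes
#' ~ Normal(1, depth_jitter), plus additive Gaussian noise. The waveform is
#' an asymmetric sinusoid (inspiration occupies 40% of the cycle), which
#' mimics belt morphology and exercises the asymmetry of trough-to-peak vs
#' peak-to-trough phase interpolation.
#'
#' The true (noise-free) extrema are attached as attributes
#' `true_peaks` / `true_troughs` (sample indices) so that recovery of the
#' injected ground truth can be tested downstream.
#'
#' @param cfg a [synth_config()].
#' @return a [resp_trace()] with ground-truth attributes.
#' @export
gen_respiration <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  seeds <- derive_seeds(cfg$seed, 4L)
  n <- round(cfg$duration_s * cfg$fs)
  mean_cycle <- 60 / cfg$breath_rate_bpm
  insp_frac <- 0.4
  with_seed(seeds[1], {
    # draw cycles until they cover the recording with margin
    n_cycles <- ceiling(cfg$duration_s / mean_cycle) + 10L
    lens <- pmax(0.3 * mean_cycle,
                 stats::rnorm(n_cycles, mean_cycle, cfg$rate_jitter * mean_cycle))
    amps <- pmax(0.1, stats::rnorm(n_cycles, 1, cfg$depth_jitter))
  })
  # extrema times: trough_i, peak_i = trough_i + insp_frac * len_i, ...
  trough_t <- c(0, cumsum(lens))
  peak_t <- trough_t[-length(trough_t)] + insp_frac * lens
  ext_t <- as.vector(rbind(trough_t[-length(trough_t)], peak_t))
  ext_t <- c(ext_t, trough_t[length(trough_t)])
  ext_v <- numeric(length(ext_t))
  ext_v[seq(1, length(ext_t), by = 2)] <- -amps[c(seq_len(n_cycles), n_cycles)][
    seq_len((length(ext_t) + 1) / 2)]
  ext_v[seq(2, length(ext_t), by = 2)] <- amps[seq_len(n_cycles)]
  t <- (seq_len(n) - 1) / cfg$fs
  x <- numeric(n)
  # cosine half-wave between consecutive extrema: smooth, zero slope at ends
  for (i in seq_len(length(ext_t) - 1L)) {
    a <- ext_t[i]; b <- ext_t[i + 1L]
    lo <- ceiling(a * cfg$fs) + 1L
    hi <- min(n, floor(b * cfg$fs) + 1L)
    if (lo > n) break
    if (lo > hi) next
    u <- (t[lo:hi] - a) / (b - a)
    x[lo:hi] <- ext_v[i] + (ext_v[i + 1L] - ext_v[i]) * (1 - cos(pi * u)) / 2
  }
  if (cfg$resp_noise_sd > 0) {
    x <- x + with_seed(seeds[2], stats::rnorm(n, 0, cfg$resp_noise_sd))
  }
  out <- resp_trace(x, cfg$fs, "synthetic")
  pk_idx <- round(peak_t * cfg$fs) + 1L
  tr_idx <- round(trough_t * cfg$fs) + 1L
  attr(out, "true_peaks") <- pk_idx[pk_idx <= n]
  attr(out, "true_troughs") <- tr_idx[tr_idx <= n]
  attr(out, "n_cycles_generated") <- sum(peak_t <= cfg$duration_s)
  out
}

#' Ground-truth phase series of a synthetic respiration trace
#'
#' Interpolates phase from the generator's noise-free extrema (attached by
#' [gen_respiration()]) rather than from re-detected ones. Used to inject
#' phase-locked modulation into neural recordings; the analysis pipeline
#' re-derives phase from the noisy trace, so the two only agree up to
#' detection error.
#'
#' @param trace a trace from [gen_respiration()].
#' @return a `phase_series`.
#' @export
true_phase_series <- function(trace) {
  pk <- attr(trace, "true_peaks")
  tr <- attr(trace, "true_troughs")
  if (is.null(pk) || is.null(tr)) {
    abort("trace carries no ground-truth extrema", "respcouple_contract_error")
  }
  ext <- structure(list(peak_indices = pk, trough_indices = tr,
                        n_samples = length(trace$samples), fs = trace$fs),
                   class = "extrema_set")
  interpolate_phase(ext)
}

#' Generate a neural recording with phase-locked spectral modulation
#'
#' Synthesizes a time series whose short-window power spectrum follows
#' `log10 P(f) = offset - chi(t) * log10 f` with
#' `chi(t) = chi0 + A * cos(phase(t) - phi0)`, plus Gaussian-profile
#' oscillatory peaks whose linear power is scaled by
#' `1 + m * cos(phase(t) - phi_m)`. The signal is built from piecewise
#' stationary 1-s segments of spectrally shaped Gaussian noise,
#' overlap-added every 250 ms with a Hann cross-fade: the 1-s segment
#' length gives the synthesis a 1-Hz frequency resolution (the spectrum
#' is controlled down to the 1-Hz edge of the analysis range) while the
#' 250-ms hop lets the exponent track respiratory phase at the temporal
#' resolution of the moving-window analysis, without boundary artifacts.
#'
#' @param cfg a [synth_config()].
#' @param resp_phase a `phase_series` covering the configured duration
#'   (e.g. from [true_phase_series()]); samples with undefined phase get
#'   the unmodulated baseline spectrum.
#' @return object of class `neural_recording`: list with `samples`, `fs`,
#'   plus ground-truth attributes `true_chi` and `segment_centers_s`.
#' @export
gen_neural_recording <- function(cfg, resp_phase) {
  stopifnot(inherits(cfg, "synth_config"), inherits(resp_phase, "phase_series"))
  n <- round(cfg$duration_s * cfg$fs)
  if (length(resp_phase$phase) < n) {
    abort("phase series shorter than requested duration", "respcouple_contract_error")
  }
  seg <- round(1.0 * cfg$fs)           # 1-s stationary segments (1-Hz grid)
  hop <- seg %/% 4L                    # 75% overlap Hann cross-fade
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg) - 1) / seg)
  nfreq <- seg %/% 2L
  f_pos <- (seq_len(nfreq)) * cfg$fs / seg   # positive FFT frequencies
  starts <- seq(1L, n, by = hop)
  x <- numeric(n + seg)
  wsum <- numeric(n + seg)
  chi_track <- numeric(length(starts))
  seeds <- derive_seeds(cfg$seed, 2L)
  peak_mat <- if (length(cfg$peaks)) do.call(rbind, cfg$peaks) else NULL
  with_seed(seeds[2], {
    noise <- matrix(stats::rnorm(seg * length(starts)), nrow = seg)
  })
  for (s in seq_along(starts)) {
    c_idx <- min(n, starts[s] + seg %/% 2L)
    ph <- resp_phase$phase[c_idx]
    chi <- cfg$aperiodic_exponent_base
    if (!is.na(ph)) {
      chi <- chi + cfg$exponent_mod_amp * cos(ph - cfg$exponent_mod_phase)
    }
    chi_track[s] <- chi
    p_ap <- 10^cfg$aperiodic_offset * f_pos^(-chi)
    p_tot <- p_ap
    if (!is.null(peak_mat)) {
      for (k in seq_len(nrow(peak_mat))) {
        g <- peak_mat[k, "height"] *
          exp(-(f_pos - peak_mat[k, "center"])^2 / (2 * peak_mat[k, "width"]^2))
        m <- peak_mat[k, "power_mod_amp"]
        fac <- if (is.na(ph)) 1 else max(0, 1 + m * cos(ph - peak_mat[k, "power_mod_phase"]))
        p_tot <- p_tot + p_ap * (10^g - 1) * fac
      }
    }
    amp <- sqrt(p_tot)
    # hermitian amplitude profile: [DC=0, pos freqs, mirrored]
    amp_full <- c(0, amp, rev(amp[seq_len(nfreq - 1L)]))
    Z <- stats::fft(noise[, s])
    xs <- Re(stats::fft(Z * amp_full, inverse = TRUE)) / seg
    rng <- starts[s]:(starts[s] + seg - 1L)
    x[rng] <- x[rng] + xs * w
    wsum[rng] <- wsum[rng] + w
  }
  x <- x[seq_len(n)] / pmax(wsum[seq_len(n)], 1e-3)
  out <- structure(list(samples = x, fs = cfg$fs, label = "synthetic"),
                   class = "neural_recording")
  attr(out, "true_chi") <- chi_track
  attr(out, "segment_centers_s") <- (pmin(n, starts + hop) - 1) / cfg$fs
  out
}

#' Generate a multi-subject synthetic cohort
#'
#' Draws per-subject exponent-modulation depths `A_j ~ Normal(A, subject_sd)`
#' truncated at 0 (depth is norm-like), generates each subject's respiration
#' and neural recording from subject-specific seeds derived from `cfg$seed`,
#' and records the injected ground truth for recovery tests.
#'
#' @param n_subjects number of subjects (>= 2; a mixed model over subjects
#'   is undefined otherwise).
#' @param cfg a [synth_config()]; `exponent_mod_amp` is the population mean
#'   modulation depth.
#' @return object of class `synth_cohort`: list of per-subject lists with
#'   elements `resp`, `neural`, `truth` (list of `A`, `phi0`, `seed`).
#' @export
gen_cohort <- function(n_subjects, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("need at least 2 subjects for mixed-model inference",
          "respcouple_config_error")
  }
  n_subjects <- as.integer(n_subjects)
  seeds <- derive_seeds(cfg$seed, n_subjects + 1L)
  A_j <- with_seed(seeds[n_subjects + 1L],
                   pmax(0, stats::rnorm(n_subjects, cfg$exponent_mod_amp,
                                        cfg$subject_sd)))
  subjects <- vector("list", n_subjects)
  for (j in seq_len(n_subjects)) {
    cfg_j <- cfg
    cfg_j$exponent_mod_amp <- A_j[j]
    cfg_j$seed <- seeds[j]
    resp <- gen_respiration(cfg_j)
    phase <- true_phase_series(resp)
    neural <- gen_neural_recording(cfg_j, phase)
    subjects[[j]] <- list(resp = resp, neural = neural,
                          truth = list(A = A_j[j],
                                       phi0 = cfg$exponent_mod_phase,
                                       seed = seeds[j]))
  }
  structure(subjects, class = "synth_cohort")
}

#' Generate synthetic head-position channels
#'
#' Six smooth low-frequency signals emulating continuous head tracking:
#' x/y/z coordinates of the head centre and three rotation angles, each a
#' smoothed Gaussian random walk plus a configurable linear drift. With
#' zero drift and zero noise the channels are constant.
#'
#' @param duration_s,fs duration (s) and sampling rate (Hz).
#' @param seed integer seed.
#' @param drift linear drift per second; scalar or length-6 vector.
#' @param noise_sd innovation SD of the random walk (per sqrt(s)).
#' @param smooth_s moving-average smoothing width in seconds.
#' @return numeric matrix (n_samples x 6) with columns Hx, Hy, Hz,
#'   Hpsi, Htheta, Hphi.
#' @export
gen_head_motion <- function(duration_s, fs, seed = NULL, drift = 0,
                            noise_sd = 0.01, smooth_s = 2) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(fs, "fs")
  n <- round(duration_s * fs)
  drift <- rep_len(drift, 6L)
  t <- (seq_len(n) - 1) / fs
  out <- matrix(0, n, 6L,
                dimnames = list(NULL, c("Hx", "Hy", "Hz", "Hpsi", "Htheta", "Hphi")))
  walks <- if (noise_sd > 0) {
    with_seed(seed, matrix(stats::rnorm(n * 6L, 0, noise_sd / sqrt(fs)), n, 6L))
  } else {
    matrix(0, n, 6L)
  }
  k <- max(1L, round(smooth_s * fs))
  kern <- rep(1 / k, k)
  for (j in seq_len(6L)) {
    w <- cumsum(walks[, j])
    if (k > 1L && noise_sd > 0) {
      sm <- stats::filter(w, kern, sides = 2)
      # fill edge NAs with nearest smoothed value
      sm <- as.numeric(sm)
      first <- which(!is.na(sm))[1]
      last <- max(which(!is.na(sm)))
      sm[seq_len(first - 1)] <- sm[first]
      if (last < n) sm[(last + 1):n] <- sm[last]
      w <- sm
    }
    out[, j] <- drift[j] * t + w
  }
  out
}
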