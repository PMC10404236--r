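# Time-resolved spectral parameterization: moving-window spectra, robust
# aperiodic (offset, exponent) fits, iterative Gaussian peak extraction,
# flattened spectra, band-accumulated periodic power, and head-motion
# confound regression.

#' Moving-window power spectra
#'
#' One Hann-tapered FFT power spectrum per window, no averaging between
#' neighbouring windows (the respiratory signal is slow, so per-window
#' estimates are kept to preserve temporal resolution). With the default
#' 1-s window and 75% overlap the window centres are spaced 250 ms apart
#' and the spectrum has 1-Hz resolution over 1-40 Hz.
#'
#' @param signal numeric vector or a `neural_recording`.
#' @param fs sampling rate in Hz (>= 80 so 40 Hz is below Nyquist);
#'   taken from the recording if one is supplied.
#' @param win_s window length in seconds.
#' @param overlap fractional overlap between neighbouring windows.
#' @param f_range inclusive frequency range in Hz; must align with the
#'   window's 1/win_s Hz resolution.
#' @return object of class `timefreq`: list with `window_centers` (s),
#'   `freqs` (Hz) and `power` (n_windows x n_freqs, linear power).
#' @export
stft_spectra <- function(signal, fs = NULL, win_s = 1.0, overlap = 0.75,
                         f_range = c(1, 40)) {
  if (inherits(signal, "neural_recording")) {
    if (is.null(fs)) fs <- signal$fs
    signal <- signal$samples
  }
  check_positive_scalar(fs, "fs")
  if (fs < 80) abort("fs must be >= 80 Hz (Nyquist above 40 Hz)",
                     "respcouple_config_error")
  nwin <- round(win_s * fs)
  if (length(signal) < nwin) {
    abort("signal shorter than one analysis window", "respcouple_config_error")
  }
  hop <- round(win_s * (1 - overlap) * fs)
  if (hop < 1) abort("overlap too large", "respcouple_config_error")
  starts <- seq(1L, length(signal) - nwin + 1L, by = hop)
  centers <- (starts - 1) / fs + win_s / 2
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))
  freqs <- seq(f_range[1], f_range[2], by = 1 / win_s)
  bin_idx <- freqs * win_s + 1
  if (any(abs(bin_idx - round(bin_idx)) > 1e-9)) {
    abort("frequency grid does not align with window resolution",
          "respcouple_config_error")
  }
  bin_idx <- round(bin_idx)
  seg <- matrix(signal[outer(seq_len(nwin) - 1L, starts, `+`) + 0L],
                nrow = nwin)
  seg <- seg * w
  sp <- stats::mvfft(seg)
  scale <- 2 / (fs * sum(w^2))
  power <- t(Mod(sp[bin_idx, , drop = FALSE])^2 * scale)
  structure(list(window_centers = centers, freqs = freqs, power = power),
            class = "timefreq")
}

#' Robust aperiodic fit of one power spectrum
#'
#' Fits `log10 P = offset - exponent * log10 f` by least squares, then
#' refits using only points that do not ride above the initial line:
#' residuals are clamped at zero from below and points above the 2.5th
#' percentile of the clamped residuals are discarded (oscillatory peaks
#' produce large positive residuals and are excluded wholesale; on a
#' peak-free spectrum the threshold is ~0 and nothing informative is
#' lost). The exponent is positive for decreasing spectra; larger values
#' mean a steeper 1/f slope (conventionally read as stronger inhibition).
#'
#' @param spectrum linear power at each frequency (all > 0).
#' @param freqs frequencies in Hz.
#' @return named numeric vector `c(offset, exponent)` (offset in
#'   log10 power).
#' @export
fit_aperiodic <- function(spectrum, freqs = seq_along(spectrum)) {
  if (any(!is.finite(spectrum)) || any(spectrum <= 0)) {
    abort("power spectrum must be positive and finite", "respcouple_data_error")
  }
  res <- fit_aperiodic_matrix(matrix(spectrum, nrow = 1), freqs)
  c(offset = res$offset[1], exponent = res$exponent[1])
}

# Vectorized robust aperiodic fit across windows (rows of `power`).
fit_aperiodic_matrix <- function(power, freqs) {
  lx <- log10(freqs)
  ly <- t(log10(power))                     # nfreq x nwin
  nf <- length(freqs)
  X <- cbind(1, lx)
  B0 <- solve(crossprod(X), crossprod(X, ly))   # 2 x nwin
  R <- ly - X %*% B0
  # peak exclusion: clamp negative residuals to zero and keep only points
  # at or below the 2.5th percentile of the clamped residuals (i.e. points
  # not riding above the initial line)
  Rc <- pmax(R, 0)
  h <- (nf - 1) * 0.025 + 1
  lo <- floor(h); fr <- h - lo
  Rs <- apply(Rc, 2, sort)
  thr <- Rs[lo, ] + fr * (Rs[min(lo + 1, nf), ] - Rs[lo, ])
  keep <- Rc <= rep(thr, each = nf) + 1e-12
  sw <- colSums(keep)
  sx <- colSums(keep * lx)
  sxx <- colSums(keep * lx^2)
  sy <- colSums(keep * ly)
  sxy <- colSums(keep * lx * ly)
  denom <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / denom
  inter <- (sy - slope * sx) / sw
  list(offset = inter, exponent = -slope)
}

gauss_model <- function(f, h, c, w) h * exp(-(f - c)^2 / (2 * w^2))

peaks_model <- function(peaks, freqs) {
  out <- numeric(length(freqs))
  if (is.null(peaks) || nrow(peaks) == 0) return(out)
  for (k in seq_len(nrow(peaks))) {
    out <- out + gauss_model(freqs, peaks$height[k], peaks$center[k],
                             peaks$width[k])
  }
  out
}

fit_one_gaussian <- function(r, freqs, h0, c0, w0, width_limits) {
  obj <- function(p) sum((r - gauss_model(freqs, p[1], p[2], p[3]))^2)
  fit <- try(stats::optim(c(h0, c0, w0), obj, method = "L-BFGS-B",
                          lower = c(1e-6, min(freqs), width_limits[1]),
                          upper = c(Inf, max(freqs), width_limits[2]),
                          control = list(maxit = 50)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    c(h0, c0, max(width_limits[1], min(w0, width_limits[2])))
  } else {
    fit$par
  }
}

#' Iterative Gaussian peak extraction from a flattened spectrum
#'
#' Repeatedly locates the largest residual; if it exceeds
#' `peak_threshold` standard deviations of the current residual, fits a
#' Gaussian (height, centre, width) by bounded least squares, subtracts it,
#' and continues, up to `max_n_peaks` peaks. When the original log-power
#' spectrum is supplied, all Gaussians and the aperiodic line are then
#' jointly refit; the updated aperiodic parameters are attached as the
#' `"aperiodic"` attribute. Peaks whose width leaves `width_limits` or
#' whose height collapses are dropped. An empty result is valid: a
#' peak-free spectrum has no oscillatory component.
#'
#' @param flattened log10-power residual after removing the aperiodic fit.
#' @param freqs frequencies in Hz.
#' @param peak_threshold detection threshold in SD of the residual.
#' @param max_n_peaks maximum number of peaks to extract.
#' @param width_limits allowed Gaussian SD range in Hz.
#' @param log_spectrum optional full log10-power spectrum; triggers the
#'   joint refit of peaks + aperiodic component.
#' @return data.frame with columns `center`, `height`, `width`
#'   (possibly 0 rows).
#' @export
fit_peaks <- function(flattened, freqs = seq_along(flattened),
                      peak_threshold = 2, max_n_peaks = 3,
                      width_limits = c(1, 12), log_spectrum = NULL) {
  r <- as.numeric(flattened)
  guesses <- list()
  for (k in seq_len(max_n_peaks)) {
    i <- which.max(r)
    h0 <- r[i]
    if (!is.finite(h0) || h0 < peak_threshold * stats::sd(r)) break
    c0 <- freqs[i]
    # width guess from the half-height extent around the maximum
    half <- h0 / 2
    li <- i; while (li > 1 && r[li - 1] > half) li <- li - 1
    ri <- i; while (ri < length(r) && r[ri + 1] > half) ri <- ri + 1
    fwhm <- max(freqs[ri] - freqs[li], diff(range(freqs)) / length(freqs))
    w0 <- min(max(fwhm / 2.355, width_limits[1]), width_limits[2])
    par <- fit_one_gaussian(r, freqs, h0, c0, w0, width_limits)
    guesses[[length(guesses) + 1L]] <- par
    r <- r - gauss_model(freqs, par[1], par[2], par[3])
  }
  peaks <- if (length(guesses)) {
    g <- do.call(rbind, guesses)
    data.frame(center = g[, 2], height = g[, 1], width = g[, 3])
  } else {
    data.frame(center = numeric(0), height = numeric(0), width = numeric(0))
  }
  if (!is.null(log_spectrum) && nrow(peaks) > 0) {
    refit <- refine_joint_fit(log_spectrum, freqs, peaks, width_limits)
    peaks <- refit$peaks
    attr(peaks, "aperiodic") <- refit$aperiodic
  }
  ok <- peaks$height > 1e-3 &
    peaks$width >= width_limits[1] - 1e-9 &
    peaks$width <= width_limits[2] + 1e-9
  peaks <- peaks[ok, , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

# Joint least-squares refit of aperiodic line + all Gaussians on the
# log10 spectrum, bounded, warm-started from the stagewise estimates.
refine_joint_fit <- function(log_spectrum, freqs, peaks, width_limits) {
  lx <- log10(freqs)
  k <- nrow(peaks)
  ap0 <- fit_aperiodic(10^log_spectrum, freqs)
  p0 <- c(ap0[["offset"]], ap0[["exponent"]],
          rbind(peaks$height, peaks$center, peaks$width))
  lower <- c(-Inf, -Inf, rep(c(1e-6, min(freqs), width_limits[1]), k))
  upper <- c(Inf, Inf, rep(c(Inf, max(freqs), width_limits[2]), k))
  obj <- function(p) {
    model <- p[1] - p[2] * lx
    for (j in seq_len(k)) {
      model <- model + gauss_model(freqs, p[3 * j], p[3 * j + 1], p[3 * j + 2])
    }
    sum((log_spectrum - model)^2)
  }
  fit <- try(stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 60)),
             silent = TRUE)
  p <- if (inherits(fit, "try-error")) p0 else fit$par
  list(aperiodic = c(offset = p[1], exponent = p[2]),
       peaks = data.frame(center = p[3 * seq_len(k) + 1],
                          height = p[3 * seq_len(k)],
                          width = p[3 * seq_len(k) + 2]))
}

#' Time-resolved spectral parameterization of a recording
#'
#' Runs [stft_spectra()], optionally regresses out head-motion confounds,
#' then applies the robust aperiodic fit (and, optionally, Gaussian peak
#' extraction with joint refit) to every window. The flattened spectrum
#' (log10 power minus the aperiodic model) is stored per window.
#'
#' @param signal numeric vector or `neural_recording`.
#' @param fs sampling rate (Hz); from the recording if supplied.
#' @param win_s,overlap,f_range windowing parameters, see [stft_spectra()].
#' @param peaks logical: extract Gaussian peaks per window? Slope-only
#'   analyses can skip this for speed.
#' @param peak_threshold,max_n_peaks,width_limits see [fit_peaks()].
#' @param motion optional head-motion matrix resampled to window centres
#'   (n_windows x 6); triggers [regress_head_motion()].
#' @return object of class `spectral_ts`: list with `window_centers`,
#'   `freqs`, `fits` (data.frame offset, exponent, fit_error, n_peaks),
#'   `peaks` (list of per-window data.frames, if requested) and
#'   `flattened` (n_windows x n_freqs matrix).
#' @export
parameterize_recording <- function(signal, fs = NULL, win_s = 1.0,
                                   overlap = 0.75, f_range = c(1, 40),
                                   peaks = TRUE, peak_threshold = 2,
                                   max_n_peaks = 3, width_limits = c(1, 12),
                                   motion = NULL) {
  tfm <- stft_spectra(signal, fs, win_s, overlap, f_range)
  if (!is.null(motion)) tfm <- regress_head_motion(tfm, motion)
  pw <- tfm$power
  if (any(pw <= 0)) {
    # confound regression can push individual bins non-positive; floor at
    # a tiny fraction of the window's own median power
    floor_w <- apply(pw, 1, function(x) stats::median(x[x > 0])) * 1e-6
    pw <- pmax(pw, floor_w)
  }
  ap <- fit_aperiodic_matrix(pw, tfm$freqs)
  ly <- log10(pw)
  lx <- log10(tfm$freqs)
  nwin <- nrow(ly)
  flattened <- ly - (matrix(ap$offset, nwin, length(lx)) -
                       outer(ap$exponent, lx))
  peak_list <- vector("list", nwin)
  fit_error <- numeric(nwin)
  n_peaks <- integer(nwin)
  offs <- ap$offset; expo <- ap$exponent
  for (i in seq_len(nwin)) {
    if (peaks) {
      pk <- fit_peaks(flattened[i, ], tfm$freqs, peak_threshold, max_n_peaks,
                      width_limits, log_spectrum = ly[i, ])
      ap_ref <- attr(pk, "aperiodic")
      if (!is.null(ap_ref)) {
        offs[i] <- ap_ref[["offset"]]
        expo[i] <- ap_ref[["exponent"]]
        flattened[i, ] <- ly[i, ] - (offs[i] - expo[i] * lx)
      }
      attr(pk, "aperiodic") <- NULL
      peak_list[[i]] <- pk
      n_peaks[i] <- nrow(pk)
      fit_error[i] <- mean(abs(flattened[i, ] - peaks_model(pk, tfm$freqs)))
    } else {
      peak_list[[i]] <- NULL
      fit_error[i] <- mean(abs(flattened[i, ]))
    }
  }
  structure(list(window_centers = tfm$window_centers, freqs = tfm$freqs,
                 fits = data.frame(window_center_s = tfm$window_centers,
                                   offset = offs, exponent = expo,
                                   fit_error = fit_error, n_peaks = n_peaks),
                 peaks = if (peaks) peak_list else NULL,
                 flattened = flattened),
            class = "spectral_ts")
}

#' Band-accumulated periodic power
#'
#' Sums the fitted peak model (sum of Gaussians, log10-power units above
#' the aperiodic background) over the in-band frequency grid. This
#' quantifies "true" oscillatory activity after the 1/f characteristic is
#' removed; canonical bands are theta 4-8 Hz, alpha 8-13 Hz,
#' beta 13-30 Hz, and the full analysis range 1-40 Hz.
#'
#' @param peaks data.frame of peaks (from [fit_peaks()]) or one element of
#'   a `spectral_ts$peaks` list.
#' @param band `c(f_lo, f_hi)` in Hz, f_lo < f_hi.
#' @param freqs frequency grid over which to accumulate.
#' @return scalar accumulated power (0 when there are no peaks).
#' @export
accumulated_power <- function(peaks, band = c(1, 40), freqs = 1:40) {
  if (length(band) != 2 || band[1] >= band[2]) {
    abort("band must be c(f_lo, f_hi) with f_lo < f_hi", "respcouple_config_error")
  }
  f <- freqs[freqs >= band[1] & freqs <= band[2]]
  if (!length(f)) abort("band contains no grid frequencies", "respcouple_config_error")
  if (is.null(peaks) || nrow(peaks) == 0) return(0)
  sum(peaks_model(peaks, f))
}

#' Accumulated-power time course of a parameterized recording
#'
#' Two modes. `"peaks"` evaluates the fitted per-window peak model over
#' the band (see [accumulated_power()]). `"residual"` sums the flattened
#' (aperiodic-removed) spectrum itself over the band; because that sum is
#' linear in the spectrum, averaging it within phase bins is exactly the
#' accumulated power of the bin-averaged periodic spectrum, and it is far
#' less sensitive to peak-fitting noise in single 1-s windows.
#'
#' @param sts a `spectral_ts` (fitted with `peaks = TRUE` for the
#'   `"peaks"` mode).
#' @param band frequency band, see [accumulated_power()].
#' @param mode `"peaks"` or `"residual"`.
#' @return numeric vector, one value per window.
#' @export
accumulated_power_course <- function(sts, band = c(1, 40),
                                     mode = c("peaks", "residual")) {
  stopifnot(inherits(sts, "spectral_ts"))
  mode <- match.arg(mode)
  if (mode == "residual") {
    sel <- sts$freqs >= band[1] & sts$freqs <= band[2]
    if (!any(sel)) abort("band contains no grid frequencies",
                         "respcouple_config_error")
    return(rowSums(sts$flattened[, sel, drop = FALSE]))
  }
  if (is.null(sts$peaks)) {
    abort("recording was parameterized without peak fitting",
          "respcouple_contract_error")
  }
  vapply(sts$peaks, accumulated_power, numeric(1), band = band,
         freqs = sts$freqs)
}

#' Head-motion confound regression on moving-window spectra
#'
#' From the six head-position signals (three coordinates, three rotation
#' angles) sampled at the window centres, builds their first derivatives
#' (12 signals) and polynomial expansions of order 1-3, yielding 36
#' regressors. Each regressor is detrended with a third-order polynomial
#' to remove slow drifts, collinear columns are dropped (with a warning),
#' and each frequency's power time series is replaced by its regression
#' residual plus intercept.
#'
#' @param tfm a `timefreq` from [stft_spectra()].
#' @param motion numeric matrix, n_windows x 6, head position at the
#'   window centres.
#' @return a `timefreq` with confound-cleaned power.
#' @export
regress_head_motion <- function(tfm, motion) {
  stopifnot(inherits(tfm, "timefreq"))
  motion <- as.matrix(motion)
  n <- length(tfm$window_centers)
  if (nrow(motion) != n || ncol(motion) != 6) {
    abort("motion must be an n_windows x 6 matrix resampled to window centres",
          "respcouple_config_error")
  }
  dt <- diff(tfm$window_centers[1:2])
  d1 <- diff(motion)
  deriv <- rbind(d1[1, , drop = FALSE], d1) / dt
  base12 <- cbind(motion, deriv)
  design <- do.call(cbind, lapply(1:3, function(p) base12^p))
  stopifnot(ncol(design) == 36)
  tpoly <- stats::poly(tfm$window_centers, 3)
  design <- apply(design, 2, function(col) {
    stats::lm.fit(cbind(1, tpoly), col)$residuals
  })
  # drop (near-)constant and collinear columns
  keep <- apply(design, 2, function(col) stats::sd(col) > 1e-12)
  design <- design[, keep, drop = FALSE]
  n_dropped <- 36 - ncol(design)
  if (ncol(design) > 0) {
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
      n_dropped <- 36 - ncol(design)
    }
  }
  if (n_dropped > 0 && ncol(design) > 0) {
    warning(sprintf("dropped %d collinear/constant motion regressors", n_dropped))
  }
  out <- tfm
  if (ncol(design) == 0) {
    attr(out, "n_regressors") <- 0L
    return(out)
  }
  # the slow-drift polynomial joins the nuisance model so that drift
  # components shared by power and motion are removed consistently
  X <- cbind(1, tpoly, design)
  fit <- stats::lm.fit(X, tfm$power)
  resid <- tfm$power - X %*% fit$coefficients
  out$power <- sweep(resid, 2, fit$coefficients[1, ], `+`)
  attr(out, "n_regressors") <- ncol(design)
  out
}
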