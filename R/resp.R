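# Respiration-belt preprocessing: normalization, extrema detection,
# two-way phase interpolation, breathing metrics, IAAFT surrogates.

#' Construct a respiration trace
#'
#' A single-channel respiration amplitude series (arbitrary units, e.g.
#' thoracic circumference from a belt transducer) with its sampling rate.
#'
#' @param samples numeric vector of amplitudes; all values must be finite.
#' @param fs sampling rate in Hz.
#' @param label optional channel label.
#' @return an object of class `resp_trace`: a list with elements `samples`,
#'   `fs` and `label`.
#' @export
resp_trace <- function(samples, fs, label = "resp") {
  if (!is.numeric(samples) || anyNA(samples) || !all(is.finite(samples))) {
    abort("respiration samples must be finite numerics", "respcouple_config_error")
  }
  check_positive_scalar(fs, "fs")
  if (length(samples) < 2 * fs) {
    abort("respiration trace must cover at least ~2 s", "respcouple_config_error")
  }
  structure(list(samples = as.numeric(samples), fs = fs, label = label),
            class = "resp_trace")
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace '%s': %d samples @ %g Hz (%.1f s)>\n",
              x$label, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Normalize a respiration trace
#'
#' Z-scores the amplitude series (zero mean, unit variance). Normalizing
#' makes the default peak-prominence threshold of 1 scale-free, so traces
#' recorded with different belt gains are treated identically.
#'
#' @param raw a [resp_trace()].
#' @return a `resp_trace` with standardized samples.
#' @export
normalize_trace <- function(raw) {
  stopifnot(inherits(raw, "resp_trace"))
  s <- stats::sd(raw$samples)
  if (!is.finite(s) || s < .Machine$double.eps^0.5 * max(1, abs(mean(raw$samples)))) {
    abort("cannot normalize a (near-)constant trace", "respcouple_degenerate_error")
  }
  resp_trace((raw$samples - mean(raw$samples)) / s, raw$fs, raw$label)
}

# Local maxima of x (strict rise before, fall after; flat tops take the
# first sample of the plateau).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # collapse zero steps to the sign of the previous non-zero step so that
  # plateaus count once
  sgn <- sign(d)
  for (i in seq_along(sgn)) {
    if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  }
  which(diff(sgn) < 0) + 1L
}

# Topographic prominence of each candidate peak: on each side walk outward
# until a strictly higher sample (or the signal border) is met; take the
# minimum over that stretch; the reference level is the higher of the two
# side minima.
peak_prominence <- function(x, idx) {
  n <- length(x)
  k <- length(idx)
  if (k == 0L) return(numeric(0))
  h <- x[idx]
  # valley minimum between consecutive maxima, plus border prefix/suffix
  vmin <- numeric(k)
  vmin[1] <- NA_real_
  if (k > 1L) {
    for (i in 2:k) vmin[i] <- min(x[idx[i - 1L]:idx[i]])
  }
  prefix_min <- min(x[1:idx[1]])
  suffix_min <- min(x[idx[k]:n])
  # one monotonic-stack pass per side: for each peak, the minimum of the
  # stretch to the first strictly higher sample (or the border)
  side_min <- function(heights, valleys, border_min) {
    kk <- length(heights)
    out <- numeric(kk)
    st_h <- numeric(kk + 1L); st_m <- numeric(kk + 1L)
    st_h[1] <- Inf; st_m[1] <- border_min  # border sentinel
    top <- 1L
    for (i in seq_len(kk)) {
      cur <- if (i == 1L) Inf else valleys[i]
      while (st_h[top] <= heights[i]) {
        cur <- min(cur, st_m[top])
        top <- top - 1L
      }
      if (top == 1L) cur <- min(cur, border_min)
      out[i] <- cur
      top <- top + 1L
      st_h[top] <- heights[i]; st_m[top] <- cur
    }
    out
  }
  left <- side_min(h, vmin, prefix_min)
  right <- rev(side_min(rev(h), rev(c(vmin[-1], NA_real_, NA_real_))[-1],
                        suffix_min))
  left[!is.finite(left)] <- prefix_min
  right[!is.finite(right)] <- suffix_min
  h - pmax(left, right)
}

#' Detect inspiratory peaks and expiratory troughs
#'
#' Peaks are local maxima with topographic prominence at or above
#' `min_prominence`; troughs are found by the same rule on the negated
#' trace. Strict peak/trough alternation is then enforced: between two
#' consecutive extrema of the same type only the more extreme one is kept.
#'
#' @param trace a [resp_trace()], normally after [normalize_trace()]
#'   (the default prominence of 1 is meant for z-scored traces).
#' @param min_prominence minimal topographic prominence (a.u.).
#' @return an object of class `extrema_set`: list with strictly increasing
#'   `peak_indices` and `trough_indices` (1-based sample indices) that
#'   alternate in time.
#' @export
detect_extrema <- function(trace, min_prominence = 1) {
  stopifnot(inherits(trace, "resp_trace"))
  x <- trace$samples
  pk <- local_maxima(x)
  pk <- pk[peak_prominence(x, pk) >= min_prominence]
  tr <- local_maxima(-x)
  tr <- tr[peak_prominence(-x, tr) >= min_prominence]
  if (length(pk) < 2 || length(tr) < 2) {
    abort("fewer than 2 peaks or 2 troughs detected; not enough breathing cycles",
          "respcouple_insufficient_cycles_error")
  }
  # enforce alternation on the merged, time-ordered sequence
  idx <- c(pk, tr)
  typ <- rep(c(1L, -1L), c(length(pk), length(tr)))
  o <- order(idx)
  idx <- idx[o]; typ <- typ[o]
  keep <- rep(TRUE, length(idx))
  i <- 1L
  while (i < length(idx)) {
    j <- i + 1L
    while (j <= length(idx) && !keep[j]) j <- j + 1L
    if (j > length(idx)) break
    if (typ[i] == typ[j]) {
      # same type in a row: keep the more extreme one
      vi <- x[idx[i]] * typ[i]
      vj <- x[idx[j]] * typ[j]
      if (vj > vi) { keep[i] <- FALSE; i <- j } else keep[j] <- FALSE
    } else {
      i <- j
    }
  }
  idx <- idx[keep]; typ <- typ[keep]
  pk <- idx[typ == 1L]; tr <- idx[typ == -1L]
  if (length(pk) < 2 || length(tr) < 2) {
    abort("fewer than 2 peaks or 2 troughs after alternation pruning",
          "respcouple_insufficient_cycles_error")
  }
  structure(list(peak_indices = pk, trough_indices = tr,
                 n_samples = length(x), fs = trace$fs),
            class = "extrema_set")
}

#' Two-way linear interpolation of respiratory phase
#'
#' Assigns each sample a phase in (-pi, pi] with 0 at peak inspiration and
#' +/-pi at peak expiration: within every trough-to-peak segment the phase
#' rises linearly from -pi to 0 (inspiration), within every peak-to-trough
#' segment from 0 to +pi (expiration). Samples before the first and after
#' the last detected extremum carry `NA` (phase undefined; downstream
#' analysis windows falling there are dropped rather than extrapolated).
#'
#' @param extrema an [detect_extrema()] result (alternating extrema).
#' @param n_samples length of the phase series to produce; defaults to the
#'   trace length recorded in `extrema`.
#' @param fs sampling rate in Hz; defaults to the rate recorded in `extrema`.
#' @return an object of class `phase_series`: list with `phase` (radians,
#'   `NA` outside the covered stretch) and `fs`.
#' @export
interpolate_phase <- function(extrema, n_samples = extrema$n_samples,
                              fs = extrema$fs) {
  stopifnot(inherits(extrema, "extrema_set"))
  idx <- sort(c(extrema$peak_indices, extrema$trough_indices))
  typ <- ifelse(idx %in% extrema$peak_indices, 1L, -1L)
  if (any(diff(typ) == 0)) {
    abort("extrema do not alternate; contract violation", "respcouple_contract_error")
  }
  if (max(idx) > n_samples) {
    abort("extrema indices exceed trace length", "respcouple_contract_error")
  }
  phase <- rep(NA_real_, n_samples)
  for (i in seq_len(length(idx) - 1L)) {
    a <- idx[i]; b <- idx[i + 1L]
    if (typ[i] == -1L) {
      seg <- seq(-pi, 0, length.out = b - a + 1L)  # trough -> peak
    } else {
      seg <- seq(0, pi, length.out = b - a + 1L)   # peak -> trough
    }
    phase[a:b] <- seg
  }
  # troughs sit at the wrap point; represent them as +pi, the value in (-pi, pi]
  phase[extrema$trough_indices] <- pi
  phase[extrema$peak_indices] <- 0
  structure(list(phase = phase, fs = fs), class = "phase_series")
}

#' Breathing rate and depth
#'
#' Rate is the mean interval between inspiratory peaks; depth is the
#' trapezoidal integral of the (raw, un-normalized) trace divided by the
#' number of breathing cycles (`n_peaks - 1`). Depth is an amplitude
#' quantity, so it should be computed on the raw trace: z-scoring would
#' erase the scale it is meant to capture.
#'
#' @param trace a [resp_trace()] (raw scale for meaningful depth).
#' @param extrema matching [detect_extrema()] result.
#' @return list with `rate_s` (s), `rate_bpm` (breaths/min), `depth`
#'   (a.u. * s).
#' @export
breathing_metrics <- function(trace, extrema) {
  stopifnot(inherits(trace, "resp_trace"), inherits(extrema, "extrema_set"))
  pk <- extrema$peak_indices
  if (length(pk) < 2) {
    abort("need at least 2 inspiratory peaks", "respcouple_insufficient_cycles_error")
  }
  rate_s <- mean(diff(pk)) / trace$fs
  x <- trace$samples
  integral <- sum((x[-1] + x[-length(x)]) / 2) / trace$fs
  list(rate_s = rate_s,
       rate_bpm = 60 / rate_s,
       depth = integral / (length(pk) - 1L))
}

#' IAAFT surrogate of a respiration trace
#'
#' Iterated amplitude-adjusted Fourier transform: returns a surrogate whose
#' sorted sample values equal the original's exactly (the closing rank-remap
#' step) and whose power spectrum matches the original's to within the
#' algorithm's convergence, while phase relations to any other signal are
#' destroyed. Iteration stops when the rank permutation no longer changes or
#' after `max_iter` iterations.
#'
#' @param trace a [resp_trace()].
#' @param seed integer seed for the initial random permutation.
#' @param max_iter maximum number of spectrum/amplitude adjustment rounds.
#' @return a `resp_trace` surrogate.
#' @export
iaaft_surrogate <- function(trace, seed = NULL, max_iter = 100) {
  stopifnot(inherits(trace, "resp_trace"))
  x <- trace$samples
  n <- length(x)
  sorted_x <- sort(x)
  target_amp <- Mod(stats::fft(x))
  y <- with_seed(seed, sample(x))
  prev_rank <- integer(0)
  for (it in seq_len(max_iter)) {
    # impose the target amplitude spectrum, keep current phases
    Y <- stats::fft(y)
    phases <- Y / pmax(Mod(Y), .Machine$double.xmin)
    y <- Re(stats::fft(target_amp * phases, inverse = TRUE)) / n
    # restore the exact amplitude distribution by rank remapping
    r <- rank(y, ties.method = "first")
    y <- sorted_x[r]
    if (identical(r, prev_rank)) break
    prev_rank <- r
  }
  resp_trace(y, trace$fs, paste0(trace$label, "_surr"))
}

#' Read / write respiration traces and phase series as CSV
#'
#' The on-disk format is a two-column CSV: `time_s, amplitude` for traces
#' and `time_s, phase_rad` for phase series (undefined phase written as
#' empty fields).
#'
#' @param path file path.
#' @param trace a [resp_trace()].
#' @name resp_io
NULL

#' @rdname resp_io
#' @export
read_respiration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) abort("expected columns time_s, amplitude", "respcouple_io_error")
  dt <- diff(d[[1]])
  fs <- 1 / stats::median(dt)
  resp_trace(d[[2]], fs)
}

#' @rdname resp_io
#' @export
write_respiration_csv <- function(trace, path) {
  stopifnot(inherits(trace, "resp_trace"))
  t <- (seq_along(trace$samples) - 1) / trace$fs
  utils::write.csv(data.frame(time_s = t, amplitude = trace$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname resp_io
#' @param phase a `phase_series` as returned by [interpolate_phase()].
#' @export
write_phase_csv <- function(phase, path) {
  stopifnot(inherits(phase, "phase_series"))
  t <- (seq_along(phase$phase) - 1) / phase$fs
  utils::write.csv(data.frame(time_s = t, phase_rad = phase$phase),
                   path, row.names = FALSE)
  invisible(path)
}
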