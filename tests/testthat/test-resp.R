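# Respiration preprocessing: normalization, prominence-based extrema
# detection, two-way phase interpolation, breathing metrics, IAAFT.

make_trace <- function(x, fs = 60) resp_trace(x, fs)

test_that("normalization z-scores, is idempotent and affine-invariant", {
  set.seed(1)
  tr <- make_trace(cos(2 * pi * 0.25 * seq(0, 30, 1 / 60)) + rnorm(1801, 0, 0.1))
  nz <- normalize_trace(tr)
  expect_lt(abs(mean(nz$samples)), 1e-10)
  expect_lt(abs(stats::sd(nz$samples) - 1), 1e-10)
  expect_equal(normalize_trace(nz)$samples, nz$samples, tolerance = 1e-12)
  aff <- make_trace(3.7 * tr$samples - 11)
  expect_equal(normalize_trace(aff)$samples, nz$samples, tolerance = 1e-10)
  expect_error(normalize_trace(make_trace(rep(2, 500))),
               class = "respcouple_degenerate_error")
})

test_that("extrema of a pure cosine fall at analytic positions", {
  # peaks at t = 0.1, 4.1, ... (offset keeps the first maximum off the
  # signal border, where a local maximum is undefined)
  t <- seq(0, 60, 1 / 60)
  tr <- normalize_trace(make_trace(cos(2 * pi * 0.25 * (t - 0.1))))
  e <- detect_extrema(tr)
  peak_times <- (e$peak_indices - 1) / 60
  # 14-15 of the 15 interior maxima survive: a maximum flush against the
  # signal border has near-zero topographic prominence and is excluded
  expect_true(length(e$peak_indices) %in% c(14, 15))
  expect_true(all(abs((peak_times - 0.1) %% 4) < 0.02 |
                    abs((peak_times - 0.1) %% 4 - 4) < 0.02))
  trough_times <- (e$trough_indices - 1) / 60
  expect_true(all(abs((trough_times - 2.1) %% 4) < 0.02 |
                    abs((trough_times - 2.1) %% 4 - 4) < 0.02))
})

test_that("low-prominence ripple extrema are rejected", {
  t <- seq(0, 60, 1 / 60)
  x <- cos(2 * pi * 0.25 * (t - 0.1)) + 0.1 * cos(2 * pi * 3 * t)
  e <- detect_extrema(make_trace(x), min_prominence = 1)
  # the ripple creates many local maxima of prominence ~0.2; only the
  # breath peaks survive the prominence threshold
  expect_gt(length(respcouple:::local_maxima(x)), 100)
  expect_true(length(e$peak_indices) %in% c(14, 15))
  peak_times <- (e$peak_indices - 1) / 60
  expect_true(all(abs((peak_times - 0.1) %% 4) < 0.2 |
                    abs((peak_times - 0.1) %% 4 - 4) < 0.2))
})

test_that("prominence matches a brute-force oracle on random traces", {
  brute_prom <- function(x, idx) {
    vapply(idx, function(i) {
      h <- x[i]
      hl <- which(x[seq_len(i - 1)] > h)
      lo <- if (length(hl)) max(hl) + 1L else 1L
      left <- min(x[lo:(i - 1)])
      rest <- x[(i + 1):length(x)]
      hr <- which(rest > h)
      hi <- if (length(hr)) min(hr) - 1L else length(rest)
      right <- min(rest[seq_len(hi)])
      h - max(left, right)
    }, numeric(1))
  }
  for (s in 1:6) {
    set.seed(s)
    x <- cumsum(rnorm(800))
    idx <- respcouple:::local_maxima(x)
    idx <- idx[idx > 1 & idx < length(x)]
    if (!length(idx)) next
    expect_equal(respcouple:::peak_prominence(x, idx), brute_prom(x, idx),
                 tolerance = 1e-12)
  }
})

test_that("alternation is enforced by dropping the weaker same-type extremum", {
  # the dip to 4 between the 5 and 4.8 summits is a prominent trough,
  # while the 4.8 summit itself is below the peak-prominence threshold:
  # detection initially yields two troughs in a row (4, then 0.5) and the
  # alternation rule must keep only the deeper one
  knots <- c(0, 5, 0.5, 5, 4, 4.8, 0.5, 5, 0.4, 5, 0)
  x <- stats::approx(seq_along(knots), knots,
                     n = (length(knots) - 1) * 40 + 1)$y
  e <- detect_extrema(make_trace(x, fs = 10), min_prominence = 1)
  merged <- sort(c(e$peak_indices, e$trough_indices))
  types <- merged %in% e$peak_indices
  expect_true(all(diff(types) != 0))
  expect_true(all(diff(merged) > 0))
  trough_vals <- x[e$trough_indices]
  expect_false(any(abs(trough_vals - 4) < 0.5))  # shallow dip was dropped
  expect_true(all(trough_vals < 1))
})

test_that("alternation invariant holds for random traces", {
  for (s in 1:8) {
    set.seed(100 + s)
    x <- stats::filter(rnorm(2000), rep(1 / 30, 30), circular = TRUE)
    e <- try(detect_extrema(make_trace(as.numeric(scale(x)), fs = 100),
                            min_prominence = 0.5), silent = TRUE)
    if (inherits(e, "try-error")) next
    merged <- sort(c(e$peak_indices, e$trough_indices))
    types <- merged %in% e$peak_indices
    expect_true(all(diff(types) != 0))
    expect_true(all(diff(merged) > 0))
  }
})

test_that("phase interpolation is linear with the documented conventions", {
  ext <- structure(list(peak_indices = c(101L, 301L),
                        trough_indices = c(1L, 201L, 401L),
                        n_samples = 450L, fs = 100),
                   class = "extrema_set")
  ph <- interpolate_phase(ext)
  expect_equal(ph$phase[51], -pi / 2, tolerance = 1e-12)  # mid trough->peak
  expect_equal(ph$phase[151], pi / 2, tolerance = 1e-12)  # mid peak->trough
  expect_identical(ph$phase[101], 0)
  expect_identical(ph$phase[201], pi)
  expect_true(all(is.na(ph$phase[402:450])))  # after last extremum
})

test_that("interpolated phase of a pure sinusoid matches the analytic signal", {
  fs <- 100
  t <- seq(0, 40 - 1 / fs, 1 / fs)
  x <- cos(2 * pi * 0.25 * t)
  tr <- make_trace(x, fs)
  ph <- interpolate_phase(detect_extrema(normalize_trace(tr)))
  # analytic-signal oracle (phase of cos via Hilbert transform)
  n <- length(x)
  X <- stats::fft(x)
  h <- if (n %% 2 == 0) {
    c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  } else {
    c(1, rep(2, (n - 1) / 2), rep(0, (n - 1) / 2))
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  ref <- wrap_angle(Arg(analytic))
  ok <- which(!is.na(ph$phase))
  away <- ok[abs(abs(ph$phase[ok]) - pi) > 0.3 & abs(ph$phase[ok]) > 0.3]
  expect_lt(max(abs(wrap_angle(ph$phase[away] - ref[away]))), 0.05)
})

test_that("phase is exactly zero at every injected peak of a clean breath train", {
  cfg <- quick_cfg(resp_noise_sd = 0, seed = 5)
  r <- gen_respiration(cfg)
  e <- detect_extrema(normalize_trace(r))
  ph <- interpolate_phase(e)
  expect_true(all(ph$phase[e$peak_indices] == 0))
  expect_true(all(ph$phase[e$trough_indices] == pi))
})

test_that("breathing metrics follow their definitions", {
  fs <- 100
  x <- rep(0, 60 * fs)
  ext <- structure(list(peak_indices = as.integer(seq(1, 56 * fs + 1, 4 * fs)),
                        trough_indices = as.integer(seq(2 * fs + 1, 58 * fs + 1,
                                                        4 * fs)),
                        n_samples = length(x), fs = fs),
                   class = "extrema_set")
  m <- breathing_metrics(resp_trace(x, fs), ext)
  expect_equal(m$rate_s, 4)
  expect_equal(m$rate_bpm, 15)
  expect_equal(m$depth, 0)
  # doubled amplitude doubles depth, leaves rate unchanged
  t <- seq(0, 60 - 1 / fs, 1 / fs)
  tr1 <- resp_trace(1 + cos(2 * pi * 0.25 * t), fs)
  tr2 <- resp_trace(2 * (1 + cos(2 * pi * 0.25 * t)), fs)
  e1 <- detect_extrema(normalize_trace(tr1))
  m1 <- breathing_metrics(tr1, e1)
  m2 <- breathing_metrics(tr2, e1)
  expect_equal(m2$depth, 2 * m1$depth, tolerance = 1e-12)
  expect_equal(m2$rate_s, m1$rate_s)
})

test_that("IAAFT surrogates preserve amplitudes exactly and spectra closely", {
  set.seed(7)
  tr <- resp_trace(rnorm(4096), 300)
  s1 <- iaaft_surrogate(tr, seed = 1)
  expect_identical(sort(s1$samples), sort(tr$samples))
  a0 <- Mod(stats::fft(tr$samples))
  a1 <- Mod(stats::fft(s1$samples))
  expect_lt(sqrt(sum((a1 - a0)^2) / sum(a0^2)), 0.05)
  s2 <- iaaft_surrogate(tr, seed = 2)
  expect_false(identical(s1$samples, s2$samples))
  expect_identical(iaaft_surrogate(tr, seed = 1)$samples, s1$samples)
  # also holds for a structured (breath-like) trace
  cfg <- quick_cfg(seed = 8)
  r <- gen_respiration(cfg)
  sr <- iaaft_surrogate(r, seed = 3)
  expect_identical(sort(sr$samples), sort(r$samples))
  ar0 <- Mod(stats::fft(r$samples)); ar1 <- Mod(stats::fft(sr$samples))
  expect_lt(sqrt(sum((ar1 - ar0)^2) / sum(ar0^2)), 0.05)
})

test_that("surrogate phases break phase locking in a modulated recording", {
  cfg <- synth_config(duration_s = 90, exponent_mod_amp = 0.5,
                      exponent_mod_phase = pi, peaks = list(), seed = 9)
  s <- subject_slope_data(cfg)
  # empirical locking is strong
  emp <- harmonic_modulation_test(list(s$values, s$values),
                                  list(s$phases, s$phases),
                                  k = 100, seed = 1)
  expect_lt(emp$p, 0.05)
  hits <- 0L
  for (i in 1:8) {
    surr <- iaaft_surrogate(s$resp, seed = 20 + i)
    phs <- tryCatch(
      interpolate_phase(detect_extrema(normalize_trace(surr))),
      error = function(e) NULL)
    if (is.null(phs)) next
    wp <- phase_at_windows(phs, s$sts$window_centers)
    f <- harmonic_modulation_test(list(s$values, s$values), list(wp, wp),
                                  k = 100, seed = 30 + i)
    if (f$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})

test_that("respiration CSV round-trips", {
  cfg <- synth_config(duration_s = 4, seed = 10)
  r <- gen_respiration(cfg)
  f <- tempfile(fileext = ".csv")
  write_respiration_csv(r, f)
  r2 <- read_respiration_csv(f)
  expect_equal(r2$samples, r$samples, tolerance = 1e-9)
  expect_equal(r2$fs, r$fs, tolerance = 1e-6)
  unlink(f)
})
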