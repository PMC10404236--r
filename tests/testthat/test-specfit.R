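# Time-resolved spectral parameterization: windowing contract, robust
# aperiodic fits, Gaussian peak recovery, accumulated power, confound
# regression.

test_that("window grid follows the 1-s / 75%-overlap contract", {
  set.seed(1)
  x <- rnorm(60 * 300)
  tf <- stft_spectra(x, fs = 300)
  expect_equal(length(tf$window_centers), 237)
  expect_equal(tf$window_centers[1:3], c(0.5, 0.75, 1.0))
  expect_equal(tf$window_centers[237], 59.5)
  expect_true(all(abs(diff(tf$window_centers) - 0.25) < 1e-12))
  expect_equal(tf$freqs, 1:40)
  expect_true(all(tf$power > 0))
  # spacing is win_s * (1 - overlap) for other settings too
  tf2 <- stft_spectra(x, fs = 300, win_s = 2, overlap = 0.5)
  expect_true(all(abs(diff(tf2$window_centers) - 1) < 1e-12))
  expect_error(stft_spectra(rnorm(100), fs = 300),
               class = "respcouple_config_error")
  expect_error(stft_spectra(x, fs = 60), class = "respcouple_config_error")
})

test_that("a pure 10-Hz sinusoid peaks at 10 Hz in every window", {
  t <- seq(0, 20, 1 / 300)
  tf <- stft_spectra(sin(2 * pi * 10 * t), fs = 300)
  expect_true(all(apply(tf$power, 1, which.max) == 10))
})

test_that("white noise yields a flat spectrum (|exponent| < 0.1)", {
  set.seed(2)
  x <- rnorm(300 * 300, sd = 2)
  mp <- colMeans(stft_spectra(x, fs = 300)$power)
  ap <- fit_aperiodic(mp, 1:40)
  expect_lt(abs(ap[["exponent"]]), 0.1)
})

test_that("aperiodic fit is exact on a pure power law", {
  f <- 1:40
  ap <- fit_aperiodic(10^1 * f^-2, f)
  expect_equal(ap[["offset"]], 1, tolerance = 1e-10)
  expect_equal(ap[["exponent"]], 2, tolerance = 1e-10)
  flat <- fit_aperiodic(rep(3.7, 40), f)
  expect_lt(abs(flat[["exponent"]]), 1e-10)
  expect_error(fit_aperiodic(c(-1, rep(1, 39)), f),
               class = "respcouple_data_error")
})

test_that("robust step protects the exponent from an oscillatory bump", {
  f <- 1:40
  bump <- 0.8 * exp(-(f - 10)^2 / (2 * 2^2))
  p <- 10^(1 - 2 * log10(f) + bump)
  ap <- fit_aperiodic(p, f)
  expect_lt(abs(ap[["exponent"]] - 2), 0.1)
})

test_that("exponent recovery on noiseless model spectra is tight", {
  # 200 windows with exact model spectra (power law + random peaks)
  set.seed(17)
  f <- 1:40
  chis <- sample(c(1, 1.5, 2), 200, replace = TRUE)
  est <- vapply(seq_along(chis), function(i) {
    ly <- 0.8 - chis[i] * log10(f)
    if (i %% 2 == 0) {
      ly <- ly + runif(1, 0.3, 0.7) *
        exp(-(f - runif(1, 5, 25))^2 / (2 * runif(1, 1.5, 2.5)^2))
    }
    fit_aperiodic(10^ly, f)[["exponent"]]
  }, numeric(1))
  err <- est - chis
  expect_lt(abs(mean(err)), 0.05)
  expect_lt(stats::sd(err), 0.15)
})

test_that("window-wise exponent estimates are centred on the truth", {
  for (chi in c(1, 1.5, 2)) {
    cfg <- quick_cfg(exponent_mod_amp = 0, peaks = list(),
                     aperiodic_exponent_base = chi,
                     seed = 200 + round(10 * chi))
    ph <- true_phase_series(gen_respiration(cfg))
    rec <- gen_neural_recording(cfg, ph)
    sts <- parameterize_recording(rec, peaks = FALSE)
    expect_lt(abs(stats::median(sts$fits$exponent) - chi), 0.1)
    expect_equal(nrow(sts$fits), nrow(sts$flattened))
  }
})

test_that("Gaussian peaks are recovered from flattened spectra", {
  f <- 1:40
  expect_equal(nrow(fit_peaks(rep(0, 40), f)), 0)
  g1 <- 0.6 * exp(-(f - 10)^2 / (2 * 2^2))
  pk <- fit_peaks(g1, f)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$center - 10), 0.5)
  expect_lt(abs(pk$height - 0.6), 0.1)
  g2 <- 0.5 * exp(-(f - 6)^2 / (2 * 1.5^2)) + 0.4 * exp(-(f - 20)^2 / (2 * 2^2))
  pk2 <- fit_peaks(g2, f)
  expect_equal(nrow(pk2), 2)
  expect_true(any(abs(pk2$center - 6) < 0.5))
  expect_true(any(abs(pk2$center - 20) < 0.5))
})

test_that("joint refit corrects the aperiodic estimate under a strong peak", {
  f <- 1:40
  ly <- 1 - 1.5 * log10(f) + 0.8 * exp(-(f - 10)^2 / (2 * 2^2))
  ap0 <- fit_aperiodic(10^ly, f)
  flat0 <- ly - (ap0[["offset"]] - ap0[["exponent"]] * log10(f))
  pk <- fit_peaks(flat0, f, log_spectrum = ly)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$center - 10), 0.5)
})

test_that("model with peaks reconstructs the spectrum better than aperiodic alone", {
  cfg <- synth_config(duration_s = 30, exponent_mod_amp = 0,
                      peaks = list(c(10, 0.8, 2, 0, 0)), seed = 220)
  ph <- true_phase_series(gen_respiration(cfg))
  sts <- parameterize_recording(gen_neural_recording(cfg, ph), peaks = TRUE)
  has_peak <- sts$fits$n_peaks >= 1
  expect_gt(mean(has_peak), 0.5)
  ap_only_err <- rowMeans(abs(sts$flattened))
  expect_true(all(sts$fits$fit_error[has_peak] <=
                    ap_only_err[has_peak] + 1e-9))
})

test_that("accumulated power sums the fitted peak model over bands", {
  expect_equal(accumulated_power(data.frame(center = numeric(0),
                                            height = numeric(0),
                                            width = numeric(0)),
                                 c(8, 13)), 0)
  # a well-contained alpha peak (narrow enough that its Gaussian tails
  # barely reach the neighbouring bands)
  pk <- data.frame(center = 10, height = 0.6, width = 0.8)
  a <- accumulated_power(pk, c(8, 13))
  th <- accumulated_power(pk, c(4, 8))
  be <- accumulated_power(pk, c(13, 30))
  tot <- accumulated_power(pk, c(1, 40))
  expect_gt(a, 0)
  expect_lt((th + be) / tot, 0.05)  # tail mass outside alpha is small
  # additivity over a partition covering two disjoint peaks
  pk2 <- data.frame(center = c(6, 20), height = c(0.5, 0.4),
                    width = c(1, 1.5))
  expect_equal(accumulated_power(pk2, c(1, 12)) +
                 accumulated_power(pk2, c(13, 40)),
               accumulated_power(pk2, c(1, 40)), tolerance = 1e-12)
  expect_error(accumulated_power(pk, c(13, 8)),
               class = "respcouple_config_error")
})

test_that("motion regression removes injected confound variance", {
  set.seed(5)
  n_win <- 200
  centers <- 0.5 + 0.25 * (0:(n_win - 1))
  motion <- gen_head_motion(centers[n_win] + 1, 4, seed = 9,
                            noise_sd = 0.5, smooth_s = 3)
  motion <- motion[round(centers * 4) + 1, ]
  tf <- structure(list(window_centers = centers, freqs = 1:40,
                       power = matrix(rexp(n_win * 40, 1), n_win, 40) + 1),
                  class = "timefreq")
  # inject a quadratic leak of channel 1 into every frequency
  leak <- 0.8 * scale(motion[, 1])^2
  tf_leak <- tf
  tf_leak$power <- tf$power + as.vector(leak) %o% rep(1, 40)
  out <- regress_head_motion(tf_leak, motion)
  expect_identical(attr(out, "n_regressors"), 36L)
  # variance explained by the leak, before and after
  v_before <- mean(apply(tf_leak$power, 2, function(p) {
    summary(stats::lm(p ~ as.vector(leak)))$r.squared
  }))
  v_after <- mean(apply(out$power, 2, function(p) {
    summary(stats::lm(p ~ as.vector(leak)))$r.squared
  }))
  expect_gt(v_before, 0.3)
  expect_lt(v_after, 0.1 * v_before)
})

test_that("zero motion leaves spectra untouched; collinear columns warn", {
  set.seed(6)
  tf <- structure(list(window_centers = 0.5 + 0.25 * (0:99), freqs = 1:40,
                       power = matrix(rexp(100 * 40) + 1, 100, 40)),
                  class = "timefreq")
  out <- regress_head_motion(tf, matrix(0, 100, 6))
  expect_identical(out$power, tf$power)
  # duplicated channels create collinear polynomial regressors
  m <- gen_head_motion(26, 4, seed = 2, noise_sd = 0.5)[1:100, ]
  m[, 2] <- m[, 1]
  expect_warning(regress_head_motion(tf, m), "collinear")
})
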