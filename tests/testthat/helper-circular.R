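# von Mises sampler (Best & Fisher 1979) for power/calibration simulations.
rvm <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  wrap_angle(out)
}

# classical one-sample Watson U2 for a sample of unit-mass angles
classical_watson_u2 <- function(ang) {
  u <- sort(((ang + pi) %% (2 * pi)) / (2 * pi))
  n <- length(u)
  sum((u - (2 * seq_len(n) - 1) / (2 * n))^2) - n * (mean(u) - 0.5)^2 +
    1 / (12 * n)
}

# course with unit masses at `ang` (plus one zero-mass anchor so that the
# min-subtraction leaves exactly unit weights at the sample angles)
unit_mass_course <- function(ang, anchor = 0.123) {
  structure(list(bin_centers = c(anchor, ang),
                 means = c(0, rep(1, length(ang))),
                 counts = rep(1L, length(ang) + 1L)),
            class = "phase_course")
}

cosine_course <- function(depth = 1, phi0 = 0, base = 1, n_bins = 60) {
  om <- phase_bin_centers(n_bins)
  structure(list(bin_centers = om, means = base + depth * cos(om - phi0),
                 counts = rep(1L, n_bins)),
            class = "phase_course")
}
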