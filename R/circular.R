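# Circular statistics: weighted circular means of phase courses, Rayleigh
# uniformity test, Watson's U2 (one- and two-sample, permutation-based),
# phase differences, and Fisher's common-median test for circular samples.

circ_result <- function(mean_direction = NA_real_, resultant_length = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        method = "") {
  structure(list(mean_direction = mean_direction,
                 resultant_length = resultant_length,
                 statistic = statistic, p_value = p_value, method = method),
            class = "circ_result")
}

#' @export
print.circ_result <- function(x, ...) {
  cat(sprintf("<circ_result %s: direction %.3f rad, R %.3f, stat %.4g, p %.4g>\n",
              x$method, x$mean_direction, x$resultant_length, x$statistic,
              x$p_value))
  invisible(x)
}

#' Weighted circular mean of a phase course
#'
#' The preferred respiratory phase of a course: bin means are shifted to
#' non-negative weights `w_k = means_k - min(means)` and the direction is
#' `Arg(sum w_k exp(i omega_k))`, with resultant length
#' `|sum w_k exp(i omega_k)| / sum w_k`. The min-subtraction makes the
#' weights location-free, so adding a constant to the whole course does
#' not move the direction. A constant course has no direction and errors.
#'
#' @param course a `phase_course` with at least 2 defined, non-equal bins.
#' @return a `circ_result` with `mean_direction` and `resultant_length`.
#' @export
course_circular_mean <- function(course) {
  stopifnot(inherits(course, "phase_course"))
  ok <- !is.na(course$means)
  if (sum(ok) < 2) abort("need at least 2 defined bins", "respcouple_data_error")
  m <- course$means[ok]
  om <- course$bin_centers[ok]
  w <- m - min(m)
  if (sum(w) <= 0) {
    abort("constant course: circular mean direction undefined",
          "respcouple_degenerate_error")
  }
  z <- sum(w * exp(1i * om))
  circ_result(mean_direction = Arg(z),
              resultant_length = Mod(z) / sum(w),
              method = "weighted circular mean")
}

#' Rayleigh test of circular uniformity
#'
#' @param angles sample of angles in radians (n >= 3).
#' @return a `circ_result`; `statistic` is z = n * R^2, `p_value` the
#'   standard large-sample approximation.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 3) abort("Rayleigh test needs n >= 3 angles", "respcouple_data_error")
  z_c <- mean(exp(1i * angles))
  R <- Mod(z_c)
  z <- n * R^2
  Rn <- n * R
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  circ_result(mean_direction = Arg(z_c), resultant_length = R,
              statistic = z, p_value = min(1, p), method = "Rayleigh")
}

# Two-sample Watson U2 statistic on pooled (mid-rank style) ordering.
watson_u2_stat <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  x <- c(a, b)
  grp <- rep(c(TRUE, FALSE), c(n, m))
  o <- order(x)
  x <- x[o]; grp <- grp[o]
  ca <- cumsum(grp) / n
  cb <- cumsum(!grp) / m
  # ties: every member of a tie block takes the block-final cumulative counts
  if (anyDuplicated(x)) {
    last_of_block <- rev(!duplicated(rev(x)))
    idx <- cumsum(last_of_block)
    pos <- which(last_of_block)
    ca <- ca[pos][idx]
    cb <- cb[pos][idx]
  }
  d <- ca - cb
  (n * m / N^2) * (sum(d^2) - sum(d)^2 / N)
}

#' Two-sample Watson's U2 permutation test
#'
#' Rotation-invariant comparison of two circular samples, sensitive to
#' multimodal differences that the circular mean misses. Significance is
#' assessed by randomly permuting sample labels.
#'
#' @param sample_a,sample_b angle samples in radians (each n >= 4).
#' @param k_perm number of label permutations.
#' @param seed integer seed for reproducible permutations.
#' @return a `circ_result`; `statistic` is U2, `p_value` the permutation
#'   estimate `(1 + #{U2_perm >= U2}) / (1 + k_perm)`.
#' @export
watson_u2_two_sample <- function(sample_a, sample_b, k_perm = 5000,
                                 seed = NULL) {
  n <- length(sample_a); m <- length(sample_b)
  if (n < 4 || m < 4) abort("each sample needs n >= 4", "respcouple_data_error")
  a <- wrap_angle(sample_a); b <- wrap_angle(sample_b)
  u2 <- watson_u2_stat(a, b)
  pool <- c(a, b)
  null <- with_seed(seed, {
    vapply(seq_len(k_perm), function(i) {
      lab <- sample.int(n + m, n)
      watson_u2_stat(pool[lab], pool[-lab])
    }, numeric(1))
  })
  p <- (1 + sum(null >= u2)) / (1 + k_perm)
  circ_result(statistic = u2, p_value = p,
              method = "Watson U2 two-sample (permutation)")
}

#' Watson's U2 of a phase course against circular uniformity
#'
#' The course is converted to a mass distribution over its bin centres by
#' min-subtracting the bin means; the statistic is the Watson functional
#' `W * integral (Fhat - F0 - mean)^2 dF0` of the weighted empirical CDF
#' against the uniform circular CDF, with the total (unnormalized) weight
#' `W` playing the role of the sample size. It is rotation-invariant,
#' increases with modulation depth, and is exactly 0 for a constant
#' course (returned without error: a flat course is perfectly uniform).
#'
#' @param course a `phase_course` with all bins defined.
#' @return a `circ_result`; `statistic` is U2 (no p-value: used as a
#'   descriptive non-uniformity measure per subject/parcel).
#' @export
watson_u2_uniformity <- function(course) {
  stopifnot(inherits(course, "phase_course"))
  if (anyNA(course$means)) {
    abort("course has undefined bins", "respcouple_data_error")
  }
  m <- course$means
  w <- m - min(m)
  W <- sum(w)
  if (W <= 0) {
    return(circ_result(statistic = 0, method = "Watson U2 vs uniform"))
  }
  u <- ((course$bin_centers + pi) %% (2 * pi)) / (2 * pi)
  o <- order(u)
  u <- u[o]
  p_mass <- (w / W)[o]
  cum <- cumsum(p_mass)
  # piecewise-exact Watson functional: D(u) = Fhat(u) - u is linear between
  # mass points
  brk <- c(0, u, 1)
  Cvals <- c(0, cum)
  du <- diff(brk)
  i1 <- sum(Cvals * du - (brk[-1]^2 - brk[-length(brk)]^2) / 2)
  i2 <- sum(((Cvals - brk[-length(brk)])^3 - (Cvals - brk[-1])^3) / 3)
  u2 <- W * (i2 - i1^2)
  circ_result(statistic = u2, method = "Watson U2 vs uniform")
}

#' Phase difference between the circular means of two courses
#'
#' @param course_a,course_b `phase_course` objects with defined circular
#'   means.
#' @return wrapped difference (a minus b) in (-pi, pi].
#' @export
phase_difference <- function(course_a, course_b) {
  da <- course_circular_mean(course_a)$mean_direction
  db <- course_circular_mean(course_b)$mean_direction
  wrap_angle(da - db)
}

# pooled circular median: sample angle minimizing the mean absolute
# circular deviation
circular_median <- function(angles) {
  cand <- unique(angles)
  dev <- vapply(cand, function(m) sum(abs(wrap_angle(angles - m))), numeric(1))
  cand[which.min(dev)]
}

#' Fisher's common-median test for circular samples
#'
#' Nonparametric comparison of two (or more) circular samples, analogous
#' to a Kruskal-Wallis test for linear data: counts observations on either
#' side of the pooled circular median per group and forms a chi-square
#' statistic with `groups - 1` degrees of freedom.
#'
#' @param sample_a,sample_b angle samples in radians (each n >= 5).
#' @return a `circ_result`; `statistic` is the chi-square P statistic.
#' @export
circular_median_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 5 || length(sample_b) < 5) {
    abort("each sample needs n >= 5", "respcouple_data_error")
  }
  groups <- list(wrap_angle(sample_a), wrap_angle(sample_b))
  pooled <- unlist(groups)
  if (length(unique(pooled)) < 2) {
    abort("all angles identical: median test degenerate",
          "respcouple_degenerate_error")
  }
  med <- circular_median(pooled)
  side <- lapply(groups, function(g) {
    s <- wrap_angle(g - med)
    s[s != 0]  # observations at the median carry no sign information
  })
  n_i <- vapply(side, length, integer(1))
  m_i <- vapply(side, function(s) sum(s < 0), numeric(1))
  N <- sum(n_i); M <- sum(m_i)
  if (M == 0 || M == N) {
    abort("degenerate split at the pooled median", "respcouple_degenerate_error")
  }
  P <- N^2 / (M * (N - M)) * sum(m_i^2 / n_i) - N * M / (N - M)
  p <- stats::pchisq(P, df = length(groups) - 1, lower.tail = FALSE)
  circ_result(mean_direction = med, statistic = P, p_value = p,
              method = "Fisher common-median test")
}
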