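# Harmonic mixed-effects inference: first-harmonic regression of phase
# courses, the vector-norm modulation statistic, surrogate/permutation
# nulls, z-scoring, and bin-wise percentile bands.

# Coerce a list of phase_course objects (or a matrix) to subjects x bins.
course_matrix <- function(courses) {
  if (is.matrix(courses)) return(courses)
  if (inherits(courses, "phase_course")) courses <- list(courses)
  do.call(rbind, lapply(courses, function(cc) {
    stopifnot(inherits(cc, "phase_course"))
    cc$means
  }))
}

harmonic_design <- function(n_bins) {
  om <- phase_bin_centers(n_bins)
  cbind(intercept = 1, sinw = sin(om), cosw = cos(om))
}

#' Euclidean norm of the harmonic beta weights
#'
#' `v = sqrt(beta_sin^2 + beta_cos^2)`: the strength of phase-locked
#' modulation irrespective of its preferred phase.
#'
#' @param beta_sin,beta_cos fixed-effect coefficients of sin and cos of
#'   respiratory phase.
#' @return scalar vector norm.
#' @export
vector_norm <- function(beta_sin, beta_cos) {
  if (!is.finite(beta_sin) || !is.finite(beta_cos)) {
    abort("beta weights must be finite", "respcouple_data_error")
  }
  sqrt(beta_sin^2 + beta_cos^2)
}

#' Harmonic mixed-effects model of phase courses
#'
#' Models each subject's phase course as
#' `value = beta0 + (S1_j + beta_sin) * sin(omega) + (S2_j + beta_cos) * cos(omega) + e`
#' with independent per-subject random slopes and Gaussian error. Subject
#' courses are demeaned before fitting (subjects differ in their baseline
#' slope/power level; the model carries no random intercept), which makes
#' the result invariant to per-subject constants.
#'
#' Engines: for balanced designs (every subject defined on the same full
#' bin grid) the ML fixed effects of this random-coefficient model equal
#' the average of per-subject OLS coefficients exactly, so a closed form
#' is used; `"lmer"` fits the model via [lme4::lmer()] (ML) and is the
#' default for unbalanced data. On non-convergence the function falls back
#' to pooled fixed-effects OLS and flags `converged = FALSE`.
#'
#' @param courses list of `phase_course` objects (one per subject, >= 2,
#'   each with >= 10 defined bins) or an equivalent subjects x bins matrix.
#' @param demean demean each subject's course first (recommended).
#' @param engine `"auto"`, `"closed_form"` or `"lmer"`.
#' @return object of class `harmonic_fit` with elements `beta0`,
#'   `beta_sin`, `beta_cos`, `v`, `preferred_phase` (= atan2(beta_sin,
#'   beta_cos), the phase at which the fitted harmonic peaks),
#'   `random_slopes` (per-subject deviations), `sigma2`, `engine`,
#'   `converged`.
#' @export
fit_harmonic_lmem <- function(courses, demean = TRUE,
                              engine = c("auto", "closed_form", "lmer")) {
  engine <- match.arg(engine)
  Y <- course_matrix(courses)
  n_sub <- nrow(Y)
  if (n_sub < 2) abort("need >= 2 subjects", "respcouple_data_error")
  if (any(rowSums(!is.na(Y)) < 10)) {
    abort("every subject needs >= 10 defined bins", "respcouple_data_error")
  }
  balanced <- !anyNA(Y)
  if (engine == "auto") engine <- if (balanced) "closed_form" else "lmer"
  X <- harmonic_design(ncol(Y))
  if (demean) Y <- Y - rowMeans(Y, na.rm = TRUE)
  if (engine == "closed_form") {
    if (!balanced) {
      abort("closed-form engine requires a balanced course set",
            "respcouple_contract_error")
    }
    pinv <- solve(crossprod(X), t(X))          # 3 x n_bins
    B <- Y %*% t(pinv)                          # n_sub x 3
    beta <- unname(colMeans(B))
    resid <- Y - B %*% t(X)
    fit <- list(beta0 = beta[1], beta_sin = beta[2], beta_cos = beta[3],
                sigma2 = mean(resid^2),
                random_slopes = data.frame(subject = seq_len(n_sub),
                                           S1 = B[, 2] - beta[2],
                                           S2 = B[, 3] - beta[3]),
                engine = "closed_form", converged = TRUE)
  } else {
    om <- phase_bin_centers(ncol(Y))
    d <- data.frame(value = as.vector(t(Y)),
                    sinw = rep(sin(om), n_sub),
                    cosw = rep(cos(om), n_sub),
                    subject = factor(rep(seq_len(n_sub), each = ncol(Y))))
    d <- d[!is.na(d$value), ]
    m <- tryCatch(
      lme4::lmer(value ~ sinw + cosw + (0 + sinw | subject) +
                   (0 + cosw | subject), data = d, REML = FALSE),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(m)) {
      ols <- stats::lm(value ~ sinw + cosw, data = d)
      cf <- stats::coef(ols)
      fit <- list(beta0 = unname(cf[1]), beta_sin = unname(cf[2]),
                  beta_cos = unname(cf[3]),
                  sigma2 = mean(stats::resid(ols)^2),
                  random_slopes = NULL, engine = "ols_fallback",
                  converged = FALSE)
    } else {
      cf <- lme4::fixef(m)
      re <- lme4::ranef(m)$subject
      fit <- list(beta0 = unname(cf["(Intercept)"]),
                  beta_sin = unname(cf["sinw"]), beta_cos = unname(cf["cosw"]),
                  sigma2 = stats::sigma(m)^2,
                  random_slopes = data.frame(subject = seq_len(n_sub),
                                             S1 = re$sinw, S2 = re$cosw),
                  engine = "lmer", converged = TRUE)
    }
  }
  fit$v <- vector_norm(fit$beta_sin, fit$beta_cos)
  fit$preferred_phase <- atan2(fit$beta_sin, fit$beta_cos)
  fit$n_subjects <- n_sub
  structure(fit, class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf(
    "<harmonic_fit (%s): v = %.4g, preferred phase = %.3f rad%s>\n",
    x$engine, x$v, x$preferred_phase,
    if (!is.null(x$p)) sprintf(", p = %.4g, z = %.3g", x$p, x$z) else ""))
  invisible(x)
}

#' Null distribution of vector norms by bin-value shuffling
#'
#' Per iteration, independently permutes each subject's (defined) bin
#' values over the bin grid, refits the harmonic model, and records the
#' vector norm. Note: bin-level shuffling ignores the strong bin-to-bin
#' correlation introduced by overlapping analysis windows and overlapping
#' bins, and is therefore anti-conservative as a test of phase locking;
#' the pipeline-level test in [harmonic_modulation_test()] uses a
#' phase-preserving circular-shift null by default for that reason. This
#' function is retained for comparability.
#'
#' @param courses as in [fit_harmonic_lmem()].
#' @param k number of null iterations.
#' @param seed integer seed.
#' @param demean demean subject courses.
#' @return numeric vector of k null vector norms.
#' @export
null_vector_norms <- function(courses, k = 5000, seed = NULL, demean = TRUE) {
  Y <- course_matrix(courses)
  if (demean) Y <- Y - rowMeans(Y, na.rm = TRUE)
  X <- harmonic_design(ncol(Y))
  with_seed(seed, {
    vapply(seq_len(k), function(i) {
      for (attempt in 1:3) {
        res <- try({
          b <- vapply(seq_len(nrow(Y)), function(j) {
            y <- Y[j, ]
            ok <- !is.na(y)
            y[ok] <- y[ok][sample.int(sum(ok))]
            stats::lm.fit(X[ok, , drop = FALSE], y[ok])$coefficients[2:3]
          }, numeric(2))
          beta <- rowMeans(b)
          sqrt(sum(beta^2))
        }, silent = TRUE)
        if (!inherits(res, "try-error")) return(res)
      }
      NA_real_
    }, numeric(1))
  })
}

#' Permutation significance of a modulation vector norm
#'
#' `p = (1 + #{null >= v}) / (1 + k)` (never exactly zero) and
#' `z = (v - mean(null)) / sd(null)`: the modulation strength in units of
#' the null distribution's standard deviation.
#'
#' @param fit a `harmonic_fit` (or any list with element `v`).
#' @param null_v numeric vector of null vector norms.
#' @return list with `p` and `z` (`z` is `NA` if the null has zero
#'   variance).
#' @export
modulation_significance <- function(fit, null_v = fit$null_v) {
  if (is.null(null_v) || !length(null_v)) {
    abort("null distribution is empty", "respcouple_data_error")
  }
  null_v <- null_v[is.finite(null_v)]
  k <- length(null_v)
  p <- (1 + sum(null_v >= fit$v)) / (1 + k)
  s <- stats::sd(null_v)
  z <- if (is.na(s) || s == 0) NA_real_ else (fit$v - mean(null_v)) / s
  list(p = p, z = z)
}

#' Phase-locking test of windowed values against respiratory phase
#'
#' The package's workhorse test: bins each subject's window values into 60
#' overlapping phase bins, fits the harmonic model to the courses, and
#' assesses the vector norm against a surrogate null.
#'
#' Null modes:
#' \describe{
#'   \item{`"shift"` (default)}{per iteration, circularly shifts each
#'     subject's window-value sequence by a random lag relative to its
#'     phase sequence before re-binning. This preserves both the temporal
#'     autocorrelation of the values (75%-overlapping windows) and the
#'     structure of the phase sequence while destroying their alignment,
#'     which is what makes the test well calibrated.}
#'   \item{`"shuffle_windows"`}{random permutation of window values before
#'     re-binning (exchangeability null; ignores value autocorrelation).}
#'   \item{`"shuffle_bins"`}{permutation of the 60 binned values
#'     (ignores both window autocorrelation and bin overlap; strongly
#'     anti-conservative, retained for comparability).}
#' }
#'
#' @param values_list per-subject numeric vectors of window values.
#' @param phases_list per-subject window phases (radians, `NA` excluded).
#' @param k number of null iterations.
#' @param seed integer seed.
#' @param mode null construction, see above.
#' @param halfwidth,step binning parameters, see [bin_course()].
#' @param demean demean subject courses before fitting.
#' @return a `harmonic_fit` augmented with `null_v`, `p`, `z`, and
#'   `courses` (the per-subject `phase_course` list).
#' @export
harmonic_modulation_test <- function(values_list, phases_list, k = 200,
                                     seed = NULL,
                                     mode = c("shift", "shuffle_windows",
                                              "shuffle_bins"),
                                     halfwidth = pi / 10, step = pi / 30,
                                     demean = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(values_list) == length(phases_list))
  n_sub <- length(values_list)
  courses <- mapply(bin_course, values_list, phases_list,
                    MoreArgs = list(halfwidth = halfwidth, step = step),
                    SIMPLIFY = FALSE)
  fit <- fit_harmonic_lmem(courses, demean = demean)
  n_bins <- length(courses[[1]]$bin_centers)
  X <- harmonic_design(n_bins)
  pinv_sc <- solve(crossprod(X), t(X))[2:3, ]   # sin/cos rows
  if (mode == "shuffle_bins") {
    null_v <- null_vector_norms(courses, k = k, seed = seed, demean = demean)
  } else {
    # precompute per-subject projection: coefs = (pinv %*% M) %*% values
    proj <- vector("list", n_sub)
    vals <- vector("list", n_sub)
    for (j in seq_len(n_sub)) {
      mm <- bin_membership_matrix(phases_list[[j]], halfwidth, step)
      if (any(rowSums(mm$M) == 0)) {
        abort("surrogate null with empty bins: recording too short",
              "respcouple_data_error")
      }
      # demeaning the course does not move the sin/cos coefficients
      # (harmonics are orthogonal to the intercept on the full grid)
      proj[[j]] <- pinv_sc %*% mm$M             # 2 x n_valid
      vals[[j]] <- values_list[[j]][mm$valid]
    }
    null_v <- with_seed(seed, {
      acc <- matrix(0, 2, k)
      for (j in seq_len(n_sub)) {
        v <- vals[[j]]
        nv <- length(v)
        Vperm <- if (mode == "shift") {
          lags <- sample.int(nv - 1L, k, replace = TRUE)
          vapply(lags, function(l) v[c((l + 1):nv, 1:l)], numeric(nv))
        } else {
          vapply(seq_len(k), function(i) v[sample.int(nv)], numeric(nv))
        }
        acc <- acc + proj[[j]] %*% Vperm
      }
      sqrt(colSums((acc / n_sub)^2))
    })
  }
  fit$null_v <- null_v
  sig <- modulation_significance(fit)
  fit$p <- sig$p
  fit$z <- sig$z
  fit$k <- length(null_v)
  fit$null_mode <- mode
  fit$courses <- courses
  fit
}

#' Bin-wise null bands from surrogate respiratory phases
#'
#' For each of k surrogate iterations, re-bins every subject's window
#' values by that subject's surrogate phase sequence (e.g. derived from
#' IAAFT surrogates of the respiration trace, which preserve its
#' autocorrelation), averages over subjects per bin, and extracts the 5th
#' and 95th percentile of the resulting group-level null per bin. The
#' empirical group mean is scored against its bin's band; bins above the
#' 95th (below the 5th) percentile mark respiratory phases at which the
#' quantity is significantly elevated (reduced).
#'
#' @param values_list per-subject window values.
#' @param phases_list per-subject empirical window phases.
#' @param surrogate_phases list (per subject) of lists (per iteration) of
#'   surrogate window phases; all subjects need the same iteration count.
#' @param probs lower/upper percentile of the band.
#' @param halfwidth,step binning parameters.
#' @return object of class `bin_band_result`: data.frame with per-bin
#'   group mean, null percentiles, empirical percentile, and
#'   significance flags.
#' @export
binwise_null_bands <- function(values_list, phases_list, surrogate_phases,
                               probs = c(0.05, 0.95),
                               halfwidth = pi / 10, step = pi / 30) {
  n_sub <- length(values_list)
  stopifnot(length(phases_list) == n_sub, length(surrogate_phases) == n_sub)
  k <- length(surrogate_phases[[1]])
  emp <- vapply(seq_len(n_sub), function(j) {
    bin_course(values_list[[j]], phases_list[[j]], halfwidth, step)$means
  }, numeric(round(2 * pi / step)))
  emp_mean <- rowMeans(emp, na.rm = TRUE)
  n_bins <- length(emp_mean)
  null_mat <- matrix(NA_real_, k, n_bins)
  for (i in seq_len(k)) {
    bm <- vapply(seq_len(n_sub), function(j) {
      bin_course(values_list[[j]], surrogate_phases[[j]][[i]],
                 halfwidth, step)$means
    }, numeric(n_bins))
    null_mat[i, ] <- rowMeans(bm, na.rm = TRUE)
  }
  p_lo <- apply(null_mat, 2, stats::quantile, probs = probs[1], na.rm = TRUE)
  p_hi <- apply(null_mat, 2, stats::quantile, probs = probs[2], na.rm = TRUE)
  pct <- vapply(seq_len(n_bins), function(b) {
    mean(null_mat[, b] <= emp_mean[b], na.rm = TRUE)
  }, numeric(1))
  structure(
    data.frame(bin_center_rad = phase_bin_centers(n_bins),
               group_mean = emp_mean, null_p_lo = p_lo, null_p_hi = p_hi,
               percentile = pct,
               above = emp_mean > p_hi, below = emp_mean < p_lo),
    class = c("bin_band_result", "data.frame"))
}
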