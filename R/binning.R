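# Align spectral-fit windows with respiratory phase and compute
# quasi-continuous phase courses over 60 overlapping bins.

#' Bin-centre grid over the respiratory cycle
#'
#' @param n_bins number of bins (default 60).
#' @return angles `omega_k = -pi + k * 2*pi/n_bins`, k = 0..n_bins-1.
#' @export
phase_bin_centers <- function(n_bins = 60) {
  -pi + (seq_len(n_bins) - 1) * 2 * pi / n_bins
}

#' Respiratory phase at analysis-window centres
#'
#' Looks up the phase of the sample nearest each window centre (phase is
#' piecewise-linear at the sampling rate, so sub-sample interpolation would
#' change nothing measurable). Centres falling where phase is undefined
#' (before the first / after the last respiratory extremum) yield `NA`
#' and are excluded downstream.
#'
#' @param phase a `phase_series`.
#' @param window_centers times in seconds.
#' @return numeric vector of angles (radians, `NA` where undefined).
#' @export
phase_at_windows <- function(phase, window_centers) {
  stopifnot(inherits(phase, "phase_series"))
  idx <- round(window_centers * phase$fs) + 1L
  if (any(idx < 1L | idx > length(phase$phase))) {
    abort("window centre outside the recording", "respcouple_contract_error")
  }
  phase$phase[idx]
}

#' Overlapping phase-bin course of a windowed quantity
#'
#' Moving along the respiratory cycle in steps of `step` (pi/30), bin k
#' collects all window values whose circular distance to the bin centre
#' omega_k is at most `halfwidth` (pi/10, wrap-around across +/-pi
#' included; the boundary is closed and ties are measure-zero). With the
#' defaults every valid window contributes to exactly 6 bins, yielding a
#' quasi-continuous course of the quantity over the cycle.
#'
#' @param values one value per analysis window (slope, power, ...).
#' @param phases respiratory phase per window (`NA` = excluded).
#' @param halfwidth bin half-width in radians.
#' @param step bin spacing in radians; `2*pi/step` must be an integer
#'   number of bins.
#' @return object of class `phase_course`: list with `bin_centers`,
#'   `means` (`NA` where a bin is empty) and `counts`.
#' @export
bin_course <- function(values, phases, halfwidth = pi / 10, step = pi / 30) {
  if (length(values) != length(phases)) {
    abort("values and phases must have equal length", "respcouple_contract_error")
  }
  ok <- !is.na(values) & !is.na(phases)
  if (!any(ok)) abort("no valid (value, phase) pairs", "respcouple_data_error")
  v <- values[ok]; p <- phases[ok]
  n_bins <- round(2 * pi / step)
  centers <- -pi + (seq_len(n_bins) - 1) * step
  means <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  for (k in seq_len(n_bins)) {
    member <- circ_dist(p, centers[k]) <= halfwidth
    counts[k] <- sum(member)
    if (counts[k] > 0) means[k] <- mean(v[member])
  }
  structure(list(bin_centers = centers, means = means, counts = counts),
            class = "phase_course")
}

# membership weight matrix: n_bins x n_windows, rows scaled by bin counts,
# so that course means = M %*% values. Membership depends on phases only,
# which permutation/shift nulls leave fixed -- precomputing M makes null
# iterations a single matrix product.
bin_membership_matrix <- function(phases, halfwidth = pi / 10, step = pi / 30) {
  ok <- which(!is.na(phases))
  n_bins <- round(2 * pi / step)
  centers <- -pi + (seq_len(n_bins) - 1) * step
  M <- matrix(0, n_bins, length(ok))
  for (k in seq_len(n_bins)) {
    member <- circ_dist(phases[ok], centers[k]) <= halfwidth
    if (any(member)) M[k, member] <- 1 / sum(member)
  }
  list(M = M, valid = ok, centers = centers)
}

#' Range of a phase course
#'
#' `max - min` of the bin means over the respiratory cycle; the
#' per-subject modulation range used to compare breathing conditions
#' (e.g. deep vs normal breathing).
#'
#' @param course a `phase_course`.
#' @return scalar range.
#' @export
course_range <- function(course) {
  stopifnot(inherits(course, "phase_course"))
  m <- course$means[!is.na(course$means)]
  if (length(m) < 2) {
    abort("need at least 2 defined bins", "respcouple_data_error")
  }
  max(m) - min(m)
}

#' Write a phase course as CSV
#'
#' Columns: `bin_center_rad, mean, count`.
#'
#' @param course a `phase_course`.
#' @param path file path.
#' @export
write_course_csv <- function(course, path) {
  stopifnot(inherits(course, "phase_course"))
  utils::write.csv(data.frame(bin_center_rad = course$bin_centers,
                              mean = course$means, count = course$counts),
                   path, row.names = FALSE)
  invisible(path)
}
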