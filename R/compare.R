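# Paired and unpaired rank comparisons of per-subject modulation ranges
# (e.g. deep vs normal breathing, nasal vs oral breathing).

#' Wilcoxon signed-rank comparison of paired values
#'
#' Two-sided signed-rank test with the normal approximation (mid-ranks for
#' ties, tie-corrected variance, continuity correction). Zero differences
#' are dropped; if every difference is zero the comparison is undefined
#' and an error is raised.
#'
#' @param values_a,values_b paired numeric vectors, length >= 6.
#' @return list with `z`, `p`, `statistic` (V, the positive-rank sum) and
#'   `n_effective` (pairs with non-zero difference).
#' @export
signed_rank_compare <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 6) {
    abort("need paired vectors of equal length >= 6", "respcouple_data_error")
  }
  d <- values_a - values_b
  d <- d[d != 0]
  if (!length(d)) {
    abort("all paired differences are zero: signed-rank test undefined",
          "respcouple_degenerate_error")
  }
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  num <- V - mu
  z <- if (num == 0) 0 else (num - 0.5 * sign(num)) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(z = z, p = p, statistic = V, n_effective = n)
}

#' Rank-sum (Mann-Whitney) comparison of unpaired values
#'
#' Two-sided Wilcoxon rank-sum test with the tie-corrected normal
#' approximation and continuity correction; the unpaired counterpart of
#' [signed_rank_compare()] used when the two conditions have different
#' subjects.
#'
#' @param values_a,values_b numeric vectors (each length >= 4).
#' @return list with `z`, `p`, `statistic` (U for sample a).
#' @export
rank_sum_compare <- function(values_a, values_b) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 4 || n2 < 4) abort("each sample needs n >= 4", "respcouple_data_error")
  N <- n1 + n2
  r <- rank(c(values_a, values_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) {
    abort("degenerate ranks: rank-sum test undefined",
          "respcouple_degenerate_error")
  }
  num <- U - mu
  z <- if (num == 0) 0 else (num - 0.5 * sign(num)) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(z = z, p = p, statistic = U)
}
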