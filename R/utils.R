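# Internal helpers shared across modules.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles mapped into the half-open interval (-pi, pi], with the
#'   wrap point represented as +pi (the convention used for peak expiration).
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[!is.na(y) & y <= -pi + 1e-300] <- pi
  # exact -pi from the modulo maps to +pi
  y[!is.na(y) & y == -pi] <- pi
  y
}

# absolute circular distance between angles
circ_dist <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  d
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed; keeps values well
# below 2^31 so they survive as.integer round trips.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483600L, n))
}

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "respcouple_error")))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar", name),
          "respcouple_config_error")
  }
  invisible(x)
}
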