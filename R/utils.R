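#' @keywords internal
#' @importFrom survival clogit coxph strata Surv
#' @importFrom stats setNames
"_PACKAGE"

## Angles are handled in degrees throughout, reported on (-180, 180].

#' Wrap an angle to (-180, 180] degrees
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector on (-180, 180].
#' @keywords internal
wrap_angle <- function(theta) {
  w <- ((theta + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Circular midpoint and width of an arc
#'
#' The midpoint is taken on the shorter arc between the two boundary angles;
#' only arcs narrower than 180 degrees are meaningful here.
#'
#' @param a1,a2 boundary angles in degrees.
#' @return list with `midpoint` and `width` (both degrees, width > 0).
#' @keywords internal
circular_midpoint <- function(a1, a2) {
  d <- wrap_angle(a2 - a1)
  list(midpoint = wrap_angle(a1 + d / 2), width = abs(d))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Raw moments E[X^k] of a normal distribution, by the standard recursion
## m_k = mu * m_{k-1} + (k-1) * sigma^2 * m_{k-2}.
normal_raw_moments <- function(kmax, mu, sigma) {
  m <- numeric(kmax + 1)
  m[1] <- 1
  if (kmax >= 1) m[2] <- mu
  if (kmax >= 2) {
    for (k in 2:kmax) {
      m[k + 1] <- mu * m[k] + (k - 1) * sigma^2 * m[k - 1]
    }
  }
  m
}

## Product of two polynomials given as coefficient vectors (ascending powers).
poly_mult <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1)] <- out[i:(i + length(q) - 1)] + p[i] * q
  }
  out
}

## Mean and variance of a polynomial of a normal variable, exactly via raw
## moments (used when deriving the generative cubic from calibration anchors).
poly_normal_moments <- function(coefs, mu, sigma) {
  deg <- length(coefs) - 1
  m <- normal_raw_moments(2 * deg, mu, sigma)
  ex <- sum(coefs * m[seq_len(deg + 1)])
  sq <- poly_mult(coefs, coefs)
  ex2 <- sum(sq * m[seq_len(2 * deg + 1)])
  list(mean = ex, var = ex2 - ex^2)
}

stop_geometry <- function(msg) {
  stop(structure(
    class = c("crvt_geometry_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
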