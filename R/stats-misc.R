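#' Axial length minimising a cubic offset-index model
#'
#' Closed-form minimisation of `c0 + c1 x + c2 x^2 + c3 x^3` on a finite
#' range: the derivative's quadratic roots are solved analytically, the
#' interior stationary point with positive second derivative is taken if
#' one lies inside the range, otherwise the minimising boundary is
#' returned with a flag. The diagnosis term, if present, shifts the curve
#' vertically and does not move the argmin.
#'
#' @param coefs named list with `c0`, `c1`, `c2`, `c3` (and optionally
#'   `c_diag`), e.g. `calibration$cubic_printed` or `gee_cubic(...)$cubic`.
#' @param al_range length-2 numeric range in mm (default `c(20, 30)`).
#' @return list with `al_min` (mm), `value` (offset index at the minimum,
#'   diagnosis = 0), `interior` (logical), `second_derivative` (at the
#'   argmin) and `flag` (`"none"` or `"boundary_minimum"`).
#' @export
cubic_argmin <- function(coefs, al_range = c(20, 30)) {
  c1 <- coefs$c1; c2 <- coefs$c2; c3 <- coefs$c3
  if (is.null(c3) || c3 == 0) stop("cubic coefficient c3 must be non-zero")
  if (any(!is.finite(al_range)) || length(al_range) != 2) {
    stop("al_range must be a finite length-2 range")
  }
  lo <- min(al_range); hi <- max(al_range)
  f <- function(x) coefs$c0 + c1 * x + c2 * x^2 + c3 * x^3
  fpp <- function(x) 2 * c2 + 6 * c3 * x
  cand <- c(lo, hi)
  interior <- NULL
  disc <- (2 * c2)^2 - 4 * (3 * c3) * c1
  if (disc > 0) {
    roots <- (-2 * c2 + c(-1, 1) * sqrt(disc)) / (2 * 3 * c3)
    interior <- roots[roots > lo & roots < hi & fpp(roots) > 0]
    cand <- c(cand, interior)
  }
  vals <- f(cand)
  best <- cand[which.min(vals)]
  is_interior <- length(interior) > 0 && any(abs(best - interior) < 1e-12 * (1 + abs(best)))
  list(
    al_min = best,
    value = f(best),
    interior = is_interior,
    second_derivative = fpp(best),
    flag = if (is_interior) "none" else "boundary_minimum"
  )
}

## tricube kernel on [0, 1)
tricube <- function(u) ifelse(abs(u) < 1, (1 - abs(u)^3)^3, 0)

loess_fit_point <- function(x, y, x0, span, robust_w) {
  n <- length(x)
  q <- max(2L, min(n, as.integer(ceiling(span * n))))
  d <- abs(x - x0)
  h <- sort(d, partial = q)[q]
  if (h == 0) h <- max(d[d > 0], 1)  # guard against all-coincident x
  w <- tricube(d / h) * robust_w
  if (sum(w > 0) < 2 || sum(w * (x - mean(x[w > 0]))^2) == 0) {
    ## fall back to weighted mean when the local design is degenerate
    return(sum(w * y) / sum(w))
  }
  xc <- x - x0
  sw <- sum(w); swx <- sum(w * xc); swy <- sum(w * y)
  swxx <- sum(w * xc^2); swxy <- sum(w * xc * y)
  det <- sw * swxx - swx^2
  if (abs(det) < 1e-300) return(swy / sw)
  ## local linear fit evaluated at x0 (i.e. the intercept in centred x)
  (swxx * swy - swx * swxy) / det
}

#' Locally weighted scatterplot smoothing (LOESS)
#'
#' Classical LOESS: tricube-weighted local linear regression with a
#' nearest-neighbour bandwidth (`span` fraction of the points) and
#' iterative robustness reweighting (bisquare weights on the scaled
#' residuals, Cleveland's scheme). The algorithm is fully specified here
#' so fitted values can be verified point-by-point against a direct
#' weighted-least-squares computation.
#'
#' @param x,y data vectors (equal length, no missing values).
#' @param span smoothing fraction in (0, 1]; default 0.75.
#' @param query_points abscissae at which to evaluate the fit (defaults to
#'   `x`).
#' @param iterations number of robustness iterations (default 4; 1 means
#'   no reweighting).
#' @return numeric vector of fitted values at `query_points`.
#' @export
loess_curve <- function(x, y, span = 0.75, query_points = x, iterations = 4) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain missing values")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  n <- length(x)
  q <- max(2L, as.integer(ceiling(span * n)))
  if (n < max(5L, q)) stop("fewer points than the local window")
  robust_w <- rep(1, n)
  for (it in seq_len(max(1L, iterations))) {
    fitted_at_x <- vapply(x, function(x0) loess_fit_point(x, y, x0, span, robust_w),
                          numeric(1))
    if (it == max(1L, iterations)) break
    r <- y - fitted_at_x
    s <- stats::median(abs(r))
    if (s == 0) break
    u <- r / (6 * s)
    robust_w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(robust_w == 0)) robust_w <- rep(1, n)
  }
  vapply(query_points, function(x0) loess_fit_point(x, y, x0, span, robust_w),
         numeric(1))
}

#' Correlation of CRVT angular deviation with RNFL-defect angle
#'
#' Pearson correlation, over glaucoma eyes with both angles defined,
#' between the CRVT angular deviation (nasal-midline convention) and the
#' RNFL-defect midpoint angle (temporal-midline convention), with the
#' p-value from the t-distribution. Subgroups: `temporal_crvt` keeps eyes
#' with `|angular deviation| > 90` degrees (trunk on the temporal side),
#' `nasal_crvt` the rest.
#'
#' @param cohort cohort tibble with `eye_role`, `angular_deviation_deg`,
#'   `rnfl_defect_angle_deg`.
#' @param subgroup `"all"`, `"temporal_crvt"` or `"nasal_crvt"`.
#' @return list with `r`, `p`, `n`.
#' @export
angle_correlation <- function(cohort, subgroup = c("all", "temporal_crvt", "nasal_crvt")) {
  subgroup <- match.arg(subgroup)
  g <- cohort[cohort$eye_role == "glaucoma", ]
  g <- g[!is.na(g$angular_deviation_deg) & !is.na(g$rnfl_defect_angle_deg), ]
  if (subgroup == "temporal_crvt") g <- g[abs(g$angular_deviation_deg) > 90, ]
  if (subgroup == "nasal_crvt") g <- g[abs(g$angular_deviation_deg) <= 90, ]
  if (nrow(g) < 3) stop("need at least 3 eyes with both angles defined")
  ct <- stats::cor.test(g$angular_deviation_deg, g$rnfl_defect_angle_deg,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(g))
}
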