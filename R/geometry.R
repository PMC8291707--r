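## Planar geometry of the BMO margin polygon and the CRVT landmark.
##
## Conventions (right-eye internal frame): +x = nasal, +y = superior.
## Left-eye (OS) records are mirrored about the vertical axis (x -> -x)
## before any angle is computed, so all reported angles are in right-eye
## orientation. Distances are in millimetres, angles in degrees.

as_margin_matrix <- function(margin_points) {
  m <- margin_points
  if (is.data.frame(m)) m <- as.matrix(m[, c(1, 2)])
  if (is.list(m) && !is.matrix(m)) m <- do.call(rbind, lapply(m, as.numeric))
  m <- unname(as.matrix(m))
  if (ncol(m) != 2 || !is.numeric(m)) {
    stop_geometry("margin points must be an n x 2 numeric matrix of (x, y) in mm")
  }
  if (anyNA(m)) stop_geometry("margin points contain missing values")
  ## drop an explicitly repeated closing vertex
  n <- nrow(m)
  if (n >= 2 && isTRUE(all(m[1, ] == m[n, ]))) m <- m[-n, , drop = FALSE]
  m
}

## signed shoelace area (positive for counter-clockwise order)
signed_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

## orientation of the triplet (p, q, r): >0 counter-clockwise, <0 clockwise
orient2d <- function(px, py, qx, qy, rx, ry) {
  (qx - px) * (ry - py) - (qy - py) * (rx - px)
}

polygon_is_simple <- function(m) {
  ## vectorised proper-intersection test over all non-adjacent edge pairs
  n <- nrow(m)
  nxt <- c(2:n, 1)
  p <- m
  q <- m[nxt, , drop = FALSE]
  pr <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  adjacent <- (j == nxt[i]) | (nxt[j] == i)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  scale <- max(abs(m)) + 1
  tol <- 1e-12 * scale^2
  d1 <- orient2d(p[j, 1], p[j, 2], q[j, 1], q[j, 2], p[i, 1], p[i, 2])
  d2 <- orient2d(p[j, 1], p[j, 2], q[j, 1], q[j, 2], q[i, 1], q[i, 2])
  d3 <- orient2d(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[j, 1], p[j, 2])
  d4 <- orient2d(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[j, 1], q[j, 2])
  cross <- (((d1 > tol) & (d2 < -tol)) | ((d1 < -tol) & (d2 > tol))) &
    (((d3 > tol) & (d4 < -tol)) | ((d3 < -tol) & (d4 > tol)))
  !any(cross)
}

validate_margin_polygon <- function(margin_points, min_vertices = 3) {
  m <- as_margin_matrix(margin_points)
  if (nrow(m) < min_vertices) {
    stop_geometry(sprintf("margin polygon needs at least %d vertices", min_vertices))
  }
  a <- signed_area(m)
  scale2 <- (max(abs(m)) + 1)^2
  if (abs(a) <= 1e-12 * scale2) {
    stop_geometry("degenerate margin polygon (zero area)")
  }
  if (!polygon_is_simple(m)) {
    stop_geometry("margin polygon is self-intersecting")
  }
  m
}

#' Area and centroid of a delineated BMO margin
#'
#' Computes the shoelace area and the area centroid of the closed polygon
#' formed by the ordered margin points. The centroid is the package's
#' definition of the BMO "centre": it is stable, orientation-free, and
#' coincides with the geometric centre for an elliptical margin.
#'
#' @param margin_points ordered margin vertices: an n x 2 matrix,
#'   data frame, or list of `c(x, y)` pairs, in mm. The polygon is closed
#'   implicitly; a repeated closing vertex is tolerated.
#' @return list with `center` (length-2 numeric, mm) and `area` (mm^2).
#'   Both are invariant under cyclic rotation and reversal of the vertex
#'   order, and equivariant under translation.
#' @examples
#' bmo_center_and_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' @export
bmo_center_and_area <- function(margin_points) {
  m <- validate_margin_polygon(margin_points)
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  cx <- sum((x + xn) * cross) / (6 * a)
  cy <- sum((y + yn) * cross) / (6 * a)
  list(center = c(x = cx, y = cy), area = abs(a))
}

point_in_polygon <- function(pt, m) {
  ## even-odd rule ray crossing test
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  j <- c(n, seq_len(n - 1))
  xi <- x; yi <- y; xj <- x[j]; yj <- y[j]
  cross <- ((yi > pt[2]) != (yj > pt[2])) &
    (pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
  sum(cross) %% 2 == 1
}

distance_to_boundary <- function(pt, m) {
  n <- nrow(m)
  p1 <- m
  p2 <- m[c(2:n, 1), , drop = FALSE]
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  len2 <- dx^2 + dy^2
  t <- ((pt[1] - p1[, 1]) * dx + (pt[2] - p1[, 2]) * dy) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  qx <- p1[, 1] + t * dx; qy <- p1[, 2] + t * dy
  min(sqrt((pt[1] - qx)^2 + (pt[2] - qy)^2))
}

#' Distance from an interior point to the margin along a direction
#'
#' Casts a ray from `center` in the given direction and returns the distance
#' to its first crossing of the polygon boundary (the smallest strictly
#' positive ray parameter over all boundary segments). A ray that grazes a
#' vertex resolves to the nearest positive crossing. Non-convex margins are
#' accepted (BMO margins are near-elliptical in practice); the first
#' crossing is used.
#'
#' @param center interior point, length-2 numeric (mm).
#' @param direction_deg ray direction in degrees (standard mathematical
#'   convention in the margin's own coordinate frame).
#' @param margin_points margin polygon as in [bmo_center_and_area()].
#' @return distance in mm (positive, finite).
#' @export
boundary_distance <- function(center, direction_deg, margin_points) {
  m <- validate_margin_polygon(margin_points)
  center <- as.numeric(center)
  scale <- max(abs(m)) + 1
  if (!point_in_polygon(center, m) || distance_to_boundary(center, m) <= 1e-12 * scale) {
    stop_geometry("center must lie strictly inside the margin polygon")
  }
  th <- direction_deg * pi / 180
  u <- c(cos(th), sin(th))
  n <- nrow(m)
  p1 <- m
  p2 <- m[c(2:n, 1), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  ## solve center + t*u = p1 + s*e for each edge
  det <- u[1] * (-ey) - u[2] * (-ex)
  bx <- p1[, 1] - center[1]; by <- p1[, 2] - center[2]
  ok <- abs(det) > 1e-14 * scale
  t <- (bx * (-ey) + by * ex) / det
  s <- (u[1] * by - u[2] * bx) / det
  eps_s <- 1e-9
  hit <- ok & s >= -eps_s & s <= 1 + eps_s & t > 1e-12 * scale
  if (!any(hit)) stop_geometry("ray does not intersect the margin polygon")
  min(t[hit])
}

#' Angular deviation of the CRVT from the BMO centre
#'
#' Direction of the centre-to-CRVT vector in right-eye orientation: the
#' nasal horizontal midline is 0 degrees, superior positive (+90), inferior
#' negative. Left-eye (OS) coordinates are mirrored about the vertical axis
#' before the angle is taken, so a nasally displaced trunk reads 0 degrees
#' in either eye.
#'
#' @param center BMO centre, length-2 numeric (mm).
#' @param crvt_point CRVT landmark, length-2 numeric (mm), in the same
#'   (native) coordinate frame as `center`.
#' @param laterality `"OD"` or `"OS"`.
#' @return angle in degrees on (-180, 180], or `NA` if the CRVT coincides
#'   with the centre (direction undefined; flagged, not an error).
#' @export
angular_deviation <- function(center, crvt_point, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  d <- as.numeric(crvt_point) - as.numeric(center)
  if (sqrt(sum(d^2)) < 1e-12 * (max(abs(c(center, crvt_point))) + 1)) {
    return(NA_real_)
  }
  if (laterality == "OS") d[1] <- -d[1]
  wrap_angle(atan2(d[2], d[1]) * 180 / pi)
}

#' Measure CRVT offset index and angular deviation for one eye
#'
#' The offset index is the ratio a/b: the distance of the CRVT from the BMO
#' centre (a), divided by the distance from the centre to the BMO margin in
#' the same direction (b). An eye whose CRVT lies outside the BMO has
#' offset index exactly 1.0 and an undefined angular deviation. A CRVT
#' numerically beyond the interpolated margin while flagged inside is
#' clipped to 1.0 (polygonal discretisation cannot exceed the margin).
#'
#' @param delineation an [eye_delineation()] object.
#' @return object of class `crvt_measurement`: a list with `offset_index`
#'   (in `[0, 1]`), `center_to_crvt` (a, mm), `center_to_margin` (b, mm),
#'   `angular_deviation_deg` (degrees or `NA`), `bmo_center`, `bmo_area`
#'   (mm^2) and a character vector `flags`.
#' @export
measure_crvt <- function(delineation) {
  d <- validate_delineation(delineation)
  ca <- bmo_center_and_area(d$margin_points)
  flags <- character()
  if (isTRUE(d$crvt_outside_bmo)) {
    out <- list(
      offset_index = 1.0,
      center_to_crvt = NA_real_,
      center_to_margin = NA_real_,
      angular_deviation_deg = NA_real_,
      bmo_center = ca$center,
      bmo_area = ca$area,
      flags = "crvt_outside_bmo"
    )
    class(out) <- "crvt_measurement"
    return(out)
  }
  center <- as.numeric(ca$center)
  crvt <- as.numeric(d$crvt_point)
  a <- sqrt(sum((crvt - center)^2))
  scale <- max(abs(d$margin_points)) + 1
  if (a < 1e-12 * scale) {
    out <- list(
      offset_index = 0.0,
      center_to_crvt = 0.0,
      center_to_margin = NA_real_,
      angular_deviation_deg = NA_real_,
      bmo_center = ca$center,
      bmo_area = ca$area,
      flags = "crvt_at_center"
    )
    class(out) <- "crvt_measurement"
    return(out)
  }
  ## ray direction in the native frame (distances are mirror-invariant)
  theta_native <- atan2(crvt[2] - center[2], crvt[1] - center[1]) * 180 / pi
  b <- boundary_distance(center, theta_native, d$margin_points)
  idx <- a / b
  if (idx > 1) {
    idx <- 1.0
    flags <- c(flags, "offset_clipped")
  }
  out <- list(
    offset_index = idx,
    center_to_crvt = a,
    center_to_margin = b,
    angular_deviation_deg = angular_deviation(center, crvt, d$laterality),
    bmo_center = ca$center,
    bmo_area = ca$area,
    flags = if (length(flags)) flags else "none"
  )
  class(out) <- "crvt_measurement"
  out
}

#' @export
print.crvt_measurement <- function(x, ...) {
  cat("CRVT measurement\n")
  cat(sprintf("  offset index       : %.4f\n", x$offset_index))
  cat(sprintf("  angular deviation  : %s\n",
              if (is.na(x$angular_deviation_deg)) "undefined"
              else sprintf("%+.2f deg", x$angular_deviation_deg)))
  cat(sprintf("  BMO area           : %.3f mm^2\n", x$bmo_area))
  cat(sprintf("  flags              : %s\n", paste(x$flags, collapse = ";")))
  invisible(x)
}

#' Midpoint angle and width of the widest RNFL defect
#'
#' Boundary angles follow the temporal-midline convention (temporal
#' horizontal midline = 0 degrees, superior positive) in right-eye
#' orientation; inputs are assumed already expressed anatomically, so the
#' value is laterality-independent (the argument is kept for interface
#' symmetry). When defects are present in both hemispheres, the one with
#' the larger angular width is reported.
#'
#' @param defects list of length-2 numeric vectors `c(start_deg, end_deg)`,
#'   each spanning less than 180 degrees; may be empty.
#' @param laterality `"OD"` or `"OS"` (no effect on anatomical angles).
#' @return `NULL` for an empty defect list, otherwise a list with
#'   `midpoint_angle_deg` (circular midpoint on the shorter arc, degrees on
#'   (-180, 180]) and `angular_width_deg` (> 0).
#' @export
rnfl_defect_angle <- function(defects, laterality = c("OD", "OS")) {
  match.arg(laterality)
  if (is.null(defects) || length(defects) == 0) return(NULL)
  if (is.matrix(defects)) defects <- asplit(defects, 1)
  meas <- lapply(defects, function(p) {
    p <- as.numeric(p)
    if (length(p) != 2 || anyNA(p)) {
      stop("each RNFL defect must be a pair of boundary angles in degrees")
    }
    cm <- circular_midpoint(p[1], p[2])
    if (cm$width <= 0 || cm$width >= 180) {
      stop("RNFL defect angular width must lie in (0, 180) degrees")
    }
    cm
  })
  widths <- vapply(meas, `[[`, numeric(1), "width")
  best <- meas[[which.max(widths)]]
  list(midpoint_angle_deg = best$midpoint, angular_width_deg = best$width)
}

#' Parapapillary atrophy zone areas
#'
#' beta-zone PPA area = RPE-opening area minus clinical-disc-margin area;
#' gamma-zone PPA area = BMO area minus clinical-disc-margin area. Negative
#' results indicate an inconsistent delineation; they are returned as-is
#' with a warning so the caller can flag the eye.
#'
#' @param rpeo_area,cdm_area,bmo_area areas in mm^2, all non-negative.
#' @return list with `beta_zone_area` and `gamma_zone_area` (mm^2).
#' @export
ppa_areas <- function(rpeo_area, cdm_area, bmo_area) {
  areas <- c(rpeo = rpeo_area, cdm = cdm_area, bmo = bmo_area)
  if (anyNA(areas) || any(areas < 0)) {
    stop("all PPA input areas must be non-negative")
  }
  beta <- rpeo_area - cdm_area
  gamma <- bmo_area - cdm_area
  if (beta < 0 || gamma < 0) {
    warning("negative PPA zone area: delineation inconsistency",
            call. = FALSE)
  }
  list(beta_zone_area = beta, gamma_zone_area = gamma)
}
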