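# Geometric fixtures are built in code: ellipse-sampled polygons and an
# independent ray-crossing oracle used to verify boundary_distance.

make_ellipse_polygon <- function(a, b, n = 48, center = c(0, 0), rot = 0) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ex <- a * cos(phi); ey <- b * sin(phi)
  cbind(center[1] + ex * cos(rot) - ey * sin(rot),
        center[2] + ex * sin(rot) + ey * cos(rot))
}

random_convex_polygon <- function() {
  make_ellipse_polygon(
    a = runif(1, 0.5, 2.5), b = runif(1, 0.5, 2.5),
    n = 48, center = runif(2, -3, 3), rot = runif(1, 0, pi)
  )
}

# Independent ray-crossing computation: rotate the polygon into the frame
# where the ray is the positive x-axis, then find boundary crossings of
# y = 0 with x > 0 by linear interpolation along each edge.
oracle_boundary_distance <- function(center, direction_deg, poly) {
  th <- direction_deg * pi / 180
  R <- rbind(c(cos(-th), -sin(-th)), c(sin(-th), cos(-th)))
  q <- t(R %*% t(sweep(poly, 2, center)))
  n <- nrow(q)
  hits <- c()
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    y1 <- q[i, 2]; y2 <- q[j, 2]
    x1 <- q[i, 1]; x2 <- q[j, 1]
    if (y1 == 0 && x1 > 0) hits <- c(hits, x1)
    if ((y1 > 0) != (y2 > 0)) {
      t <- y1 / (y1 - y2)
      x <- x1 + t * (x2 - x1)
      if (x > 0) hits <- c(hits, x)
    }
  }
  if (!length(hits)) stop("oracle: no crossing")
  min(hits)
}

make_delineation <- function(index = 0.5, angle = 30, laterality = "OD",
                             area = 2.7, seed = 1, ...) {
  synthesize_eye_geometry(index, angle, laterality, area, seed = seed, ...)
}
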