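test_that("polygon centroid and area match analytic shapes", {
  sq <- bmo_center_and_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(unname(sq$center), c(0.5, 0.5))
  expect_equal(sq$area, 1.0)

  ell <- bmo_center_and_area(make_ellipse_polygon(0.94, 0.90, n = 48))
  expect_lt(abs(ell$area - pi * 0.94 * 0.90) / (pi * 0.94 * 0.90), 0.005)
  expect_equal(unname(ell$center), c(0, 0), tolerance = 1e-12)
})

test_that("centroid/area are invariant to vertex order and equivariant to translation", {
  set.seed(11)
  for (i in 1:10) {
    poly <- random_convex_polygon()
    ref <- bmo_center_and_area(poly)
    rev_ <- bmo_center_and_area(poly[rev(seq_len(nrow(poly))), ])
    rot <- bmo_center_and_area(poly[c(17:nrow(poly), 1:16), ])
    expect_equal(rev_$area, ref$area)
    expect_equal(rev_$center, ref$center)
    expect_equal(rot$center, ref$center)
    shift <- runif(2, -5, 5)
    tr <- bmo_center_and_area(sweep(poly, 2, -shift))
    expect_equal(tr$area, ref$area)
    expect_equal(unname(tr$center), unname(ref$center) + shift, tolerance = 1e-10)
  }
})

test_that("degenerate and self-intersecting margins are rejected", {
  expect_error(bmo_center_and_area(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))),
               "zero area|degenerate")
  # symmetric bowtie: the two lobes cancel to zero signed area
  expect_error(bmo_center_and_area(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "degenerate")
  # asymmetric bowtie: nonzero area but self-crossing edges
  expect_error(bmo_center_and_area(rbind(c(0, 0), c(3, 1), c(2, 0), c(0, 2))),
               "self-intersecting")
})

test_that("boundary distance recovers analytic radii", {
  circ <- make_ellipse_polygon(1, 1, n = 360)
  for (ang in c(0, 33.3, 90, -120, 180)) {
    expect_equal(boundary_distance(c(0, 0), ang, circ), 1.0, tolerance = 1e-3)
  }
  ell <- make_ellipse_polygon(2, 1, n = 720)
  expect_equal(boundary_distance(c(0, 0), 0, ell), 2.0, tolerance = 1e-3)
  expect_equal(boundary_distance(c(0, 0), 90, ell), 1.0, tolerance = 1e-3)
})

test_that("boundary distance matches the independent ray-crossing oracle", {
  set.seed(21)
  for (i in 1:200) {
    poly <- random_convex_polygon()
    ctr <- bmo_center_and_area(poly)$center
    ang <- runif(1, -180, 180)
    expect_equal(boundary_distance(ctr, ang, poly),
                 oracle_boundary_distance(ctr, ang, poly),
                 tolerance = 1e-9)
  }
})

test_that("rays grazing a vertex resolve to the nearest crossing", {
  # square centered at origin: the 45-degree ray passes exactly through
  # the corner (1, 1), shared by two edges
  sq <- rbind(c(1, -1), c(1, 1), c(-1, 1), c(-1, -1))
  expect_equal(boundary_distance(c(0, 0), 45, sq), sqrt(2), tolerance = 1e-12)
})

test_that("boundary distance rejects an exterior or on-margin origin", {
  poly <- make_ellipse_polygon(1, 1)
  expect_error(boundary_distance(c(2, 0), 0, poly), "inside")
  expect_error(boundary_distance(c(1, 0), 0, poly), "inside")
})

test_that("offset index follows the a/b definition on the unit circle", {
  circ <- make_ellipse_polygon(1, 1, n = 720)
  d <- eye_delineation("p1", "OD", circ, crvt_point = c(0.5, 0))
  m <- measure_crvt(d)
  expect_equal(m$offset_index, 0.5, tolerance = 1e-4)
  expect_equal(m$angular_deviation_deg, 0, tolerance = 1e-6)
})

test_that("CRVT at the centroid gives offset 0 with undefined angle", {
  poly <- make_ellipse_polygon(1.1, 0.9)
  ctr <- bmo_center_and_area(poly)$center
  m <- measure_crvt(eye_delineation("p1", "OD", poly, crvt_point = ctr))
  expect_identical(m$offset_index, 0.0)
  expect_true(is.na(m$angular_deviation_deg))
  expect_identical(m$flags, "crvt_at_center")
})

test_that("outside-BMO branch returns offset exactly 1.0 with undefined angle", {
  poly <- make_ellipse_polygon(1, 0.9)
  m <- measure_crvt(eye_delineation("p1", "OD", poly, crvt_point = c(3, 0),
                                    crvt_outside_bmo = TRUE))
  expect_identical(m$offset_index, 1.0)
  expect_true(is.na(m$angular_deviation_deg))
  expect_identical(m$flags, "crvt_outside_bmo")
  # flag without an explicit point behaves identically
  m2 <- measure_crvt(eye_delineation("p2", "OS", poly, crvt_outside_bmo = TRUE))
  expect_identical(m2$offset_index, 1.0)
})

test_that("angular deviation uses right-eye orientation with OS mirroring", {
  expect_equal(angular_deviation(c(0, 0), c(1, 0), "OD"), 0)
  expect_equal(angular_deviation(c(0, 0), c(0, 1), "OD"), 90)
  expect_equal(angular_deviation(c(0, 0), c(0, -1), "OD"), -90)
  expect_equal(angular_deviation(c(0, 0), c(-1, 0), "OD"), 180)
  # OS: a trunk displaced nasally in native coordinates (mirrored x) reads 0
  expect_equal(angular_deviation(c(0, 0), c(-1, 0), "OS"), 0)
  expect_equal(angular_deviation(c(0, 0), c(0, 1), "OS"), 90)
  expect_true(is.na(angular_deviation(c(1, 2), c(1, 2), "OD")))
})

test_that("offset and angle are invariant under similarity transforms", {
  set.seed(31)
  base <- make_delineation(0.62, -48, "OD", seed = 5)
  ref <- measure_crvt(base)
  for (i in 1:5) {
    s <- runif(1, 0.3, 3)
    shift <- runif(2, -4, 4)
    scaled <- eye_delineation("p", "OD",
                              sweep(base$margin_points * s, 2, shift, `+`),
                              crvt_point = base$crvt_point * s + shift)
    m <- measure_crvt(scaled)
    expect_equal(m$offset_index, ref$offset_index, tolerance = 1e-9)
    expect_equal(m$angular_deviation_deg, ref$angular_deviation_deg, tolerance = 1e-9)
  }
  # rotation of the whole delineation with the reference axes co-rotated:
  # offset index (axis-free) is preserved
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rotated <- eye_delineation("p", "OD", t(R %*% t(base$margin_points)),
                             crvt_point = as.vector(R %*% base$crvt_point))
  mrot <- measure_crvt(rotated)
  expect_equal(mrot$offset_index, ref$offset_index, tolerance = 1e-9)
  expect_equal(crvtoffset:::wrap_angle(mrot$angular_deviation_deg - th * 180 / pi),
               ref$angular_deviation_deg, tolerance = 1e-9)
})

test_that("an OS delineation measures like its mirrored OD counterpart", {
  d_os <- make_delineation(0.44, 67, "OS", seed = 9)
  mirrored <- d_os$margin_points
  mirrored[, 1] <- -mirrored[, 1]
  d_od <- eye_delineation("p", "OD", mirrored,
                          crvt_point = c(-d_os$crvt_point[1], d_os$crvt_point[2]))
  m_os <- measure_crvt(d_os)
  m_od <- measure_crvt(d_od)
  expect_equal(m_os$offset_index, m_od$offset_index, tolerance = 1e-12)
  expect_equal(m_os$angular_deviation_deg, m_od$angular_deviation_deg,
               tolerance = 1e-12)
})

test_that("offset index clips to 1 for a trunk beyond the interpolated margin", {
  poly <- make_ellipse_polygon(1, 1, n = 12)  # coarse polygon, chord well inside circle
  d <- eye_delineation("p", "OD", poly,
                       crvt_point = 0.99 * c(cos(pi / 12), sin(pi / 12)))
  m <- measure_crvt(d)
  expect_identical(m$offset_index, 1.0)
  expect_true("offset_clipped" %in% m$flags)
})

test_that("RNFL defect measurement picks the widest defect and signs correctly", {
  one <- rnfl_defect_angle(list(c(30, 60)), "OD")
  expect_equal(one$midpoint_angle_deg, 45)
  expect_equal(one$angular_width_deg, 30)

  two <- rnfl_defect_angle(list(c(-20, -60), c(10, 30)), "OD")
  expect_equal(two$midpoint_angle_deg, -40)
  expect_equal(two$angular_width_deg, 40)

  inf <- rnfl_defect_angle(list(c(-20, -60)), "OS")
  expect_equal(inf$midpoint_angle_deg, -40)

  # circular midpoint across the 180-degree wrap stays on the shorter arc
  wrap <- rnfl_defect_angle(list(c(170, -170)), "OD")
  expect_equal(wrap$midpoint_angle_deg, 180)
  expect_equal(wrap$angular_width_deg, 20)

  expect_null(rnfl_defect_angle(list(), "OD"))
  expect_error(rnfl_defect_angle(list(c(0, 180)), "OD"), "width")
})

test_that("PPA zone arithmetic follows the rpeo/cdm/bmo definitions", {
  pa <- ppa_areas(2.0, 1.5, 1.8)
  expect_equal(pa$beta_zone_area, 0.5)
  expect_equal(pa$gamma_zone_area, 0.3)
  expect_equal(ppa_areas(1.5, 1.5, 1.8)$beta_zone_area, 0)
  expect_warning(pa2 <- ppa_areas(1.0, 1.2, 1.1), "inconsistency")
  expect_equal(pa2$beta_zone_area, -0.2, tolerance = 1e-12)
  expect_error(ppa_areas(-1, 0.5, 1), "non-negative")
})
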