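cal <- default_calibration()

test_that("calibration loads, validates and round-trips through YAML", {
  expect_s3_class(cal, "crvt_calibration")
  expect_equal(cal$n_patients, 112)
  expect_equal(cal$cubic_printed$c_diag, 0.158)
  expect_equal(cal$beta_offset_log, log(31.625))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(cal2$table1_moments, cal$table1_moments)
  expect_equal(cal2$cubic_generative, cal$cubic_generative, tolerance = 1e-12)
  expect_error(read_calibration(system.file("DESCRIPTION", package = "crvtoffset")))
})

test_that("the derived generative cubic honours its anchors", {
  g <- cal$cubic_generative
  # stationary point with positive curvature at the reported argmin
  expect_equal(g$c1 + 2 * g$c2 * g$al_min + 3 * g$c3 * g$al_min^2, 0,
               tolerance = 1e-10)
  expect_gt(2 * g$c2 + 6 * g$c3 * g$al_min, 0)
  expect_equal(cubic_argmin(g, c(20, 30))$al_min, 23.4, tolerance = 1e-9)
  # control-eye marginal mean anchored at the calibrated value (exact
  # normal-moment computation, checked by quadrature here)
  al <- cal$table1_moments$axial_length$control
  f <- function(x) cubic_predict(g, x) * dnorm(x, al[1], al[2])
  expect_equal(integrate(f, al[1] - 12 * al[2], al[1] + 12 * al[2])$value,
               cal$table1_moments$offset_index$control[1], tolerance = 1e-6)
})

test_that("generated cohorts satisfy the pairing contract and are reproducible", {
  co <- generate_cohort(cal, 93, seed = 7, assign_flags = FALSE)
  expect_equal(nrow(co), 186)
  tab <- table(co$patient_id, co$eye_role)
  expect_true(all(tab == 1))
  expect_true(all(co$offset_index >= 0 & co$offset_index <= 1))
  expect_true(all(co$exclusion_flag == "none"))
  # fellow eyes have opposite laterality
  lat <- tapply(co$laterality, co$patient_id, function(x) sort(x))
  expect_true(all(vapply(lat, identical, logical(1), c("OD", "OS"))))

  co2 <- generate_cohort(cal, 93, seed = 7, assign_flags = FALSE)
  expect_identical(co, co2)
  co3 <- generate_cohort(cal, 93, seed = 8, assign_flags = FALSE)
  expect_false(identical(co$offset_index, co3$offset_index))
})

test_that("zero-noise simulation is exactly the generative cubic", {
  cal0 <- cal
  cal0$sigma_resid <- 0
  cal0$rho_pair <- 0
  co <- generate_cohort(cal0, 200, seed = 5, assign_flags = FALSE)
  expect_true(all(co$offset_index > 0.01 & co$offset_index < 1))
  # independent regression in a centred basis, mapped back analytically
  ctr <- 25
  xc <- co$axial_length - ctr
  fit <- lm(offset_index ~ I(eye_role == "glaucoma") + xc + I(xc^2) + I(xc^3),
            data = co)
  b <- unname(coef(fit))
  g <- cal$cubic_generative
  expect_equal(b[2], g$c_diag, tolerance = 1e-6)
  expect_equal(b[5], g$c3, tolerance = 1e-6)
  expect_equal(b[4] - 3 * ctr * b[5], g$c2, tolerance = 1e-6)
  expect_equal(b[3] - 2 * ctr * b[4] + 3 * ctr^2 * b[5], g$c1, tolerance = 1e-6)
  expect_equal(b[1] - ctr * b[3] + ctr^2 * b[4] - ctr^3 * b[5], g$c0,
               tolerance = 1e-6)
})

test_that("group moments of the directly drawn variables converge", {
  co <- generate_cohort(cal, 6000, seed = 13, assign_flags = FALSE)
  for (v in c("baseline_iop", "bmo_area", "rnfl_thickness", "mrw", "md", "psd",
              "axial_length", "angular_deviation_deg")) {
    for (role in c("glaucoma", "control")) {
      mom <- cal$table1_moments[[v]][[role]]
      x <- co[[v]][co$eye_role == role]
      expect_lt(abs(mean(x) - mom[1]), 4 * mom[2] / sqrt(length(x)))
      expect_lt(abs(sd(x) / mom[2] - 1), 0.06)
    }
  }
})

test_that("pair and angle correlation structure matches the calibration", {
  co <- generate_cohort(cal, 6000, seed = 17, assign_flags = FALSE)
  g <- co[co$eye_role == "glaucoma", ]
  c_ <- co[co$eye_role == "control", ]
  expect_identical(g$patient_id, c_$patient_id)
  # axial length pairing
  expect_equal(cor(g$axial_length, c_$axial_length), cal$rho_axial,
               tolerance = 0.01)
  # offset-index noise correlation: remove the cubic signal first
  res_g <- g$offset_index - cubic_predict(cal$cubic_generative, g$axial_length, 1)
  res_c <- c_$offset_index - cubic_predict(cal$cubic_generative, c_$axial_length, 0)
  expect_equal(cor(res_g, res_c), cal$rho_pair, tolerance = 0.05)
  # CRVT-angle / RNFL-defect-angle correlation
  expect_equal(cor(g$angular_deviation_deg, g$rnfl_defect_angle_deg),
               cal$r_angle, tolerance = 0.04)
  expect_true(all(is.na(c_$rnfl_defect_angle_deg)))
})

test_that("geometry synthesis round-trips the target measurement", {
  cases <- expand.grid(
    index = c(0.1, 0.37, 0.5, 0.85, 0.99),
    angle = c(-179, -90, -30, 0, 45, 135, 180),
    lat = c("OD", "OS"), stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(cases))) {
    d <- synthesize_eye_geometry(cases$index[k], cases$angle[k], cases$lat[k],
                                 bmo_area = 2.3, seed = 100 + k)
    m <- measure_crvt(d)
    expect_equal(m$offset_index, cases$index[k], tolerance = 1e-6)
    expect_equal(m$angular_deviation_deg, cases$angle[k], tolerance = 1e-6)
    expect_equal(m$bmo_area, 2.3, tolerance = 1e-9)
  }
  # degenerate targets
  d0 <- synthesize_eye_geometry(0, NA, "OD", seed = 3)
  expect_identical(measure_crvt(d0)$offset_index, 0.0)
  d1 <- synthesize_eye_geometry(1, 20, "OD", seed = 4, outside = TRUE)
  m1 <- measure_crvt(d1)
  expect_identical(m1$offset_index, 1.0)
  expect_true(is.na(m1$angular_deviation_deg))
  expect_error(synthesize_eye_geometry(1.2, 0, "OD"), "\\[0, 1\\]")
})

test_that("the exclusion cascade removes and retains the calibrated categories", {
  co <- generate_cohort(cal, 112, seed = 23)
  res <- apply_exclusions(co)
  expect_equal(sum(res$tally), 19)
  expect_equal(length(unique(res$included$patient_id)), 93)
  expect_equal(res$n_retained_invisible, 14)
  forced <- res$included[res$included$exclusion_flag == "invisible_confirmed" &
                           res$included$eye_role == "glaucoma", ]
  expect_true(all(forced$offset_index == 1.0))
  expect_true(all(is.na(forced$angular_deviation_deg)))
  # accounting invariant
  expect_equal(length(unique(co$patient_id)),
               length(unique(res$included$patient_id)) + sum(res$tally))

  empty <- apply_exclusions(co[0, ])
  expect_equal(nrow(empty$included), 0)
  expect_equal(sum(empty$tally), 0)

  clean <- generate_cohort(cal, 30, seed = 2, assign_flags = FALSE)
  res2 <- apply_exclusions(clean)
  expect_identical(res2$included, clean)
  expect_error(generate_cohort(cal, 20, seed = 1, assign_flags = TRUE),
               "smaller than")
})

test_that("matched-pair simulation assigns labels by the conditional law", {
  mp <- simulate_matched_pairs(cal, 4000, seed = 31)
  expect_equal(nrow(mp), 8000)
  expect_true(all(table(mp$patient_id, mp$eye_role) == 1))
  # the eye with the larger offset should be the case more often
  w <- reshape(as.data.frame(mp), idvar = "patient_id", timevar = "eye_role",
               direction = "wide")
  frac <- mean(w$offset_index.glaucoma > w$offset_index.control)
  expect_gt(frac, 0.6)
})
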