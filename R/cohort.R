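## Synthetic paired-eye cohort generation. One patient contributes one
## glaucoma eye and one fellow control eye; the generator reproduces the
## calibrated group moments, the cubic axial-length dependence of the
## offset index, the within-pair correlation structure, the CRVT/RNFL
## angle correlation and the screening cascade.

exclusion_levels <- c("poor_quality", "bifurcation", "invisible_no_angio",
                      "outside_both_eyes", "invisible_confirmed")

draw_group_var <- function(cal, var, n_g, n_c) {
  mom <- cal$table1_moments[[var]]
  list(
    glaucoma = stats::rnorm(n_g, mom$glaucoma[1], mom$glaucoma[2]),
    control = stats::rnorm(n_c, mom$control[1], mom$control[2])
  )
}

#' Generate a synthetic paired-eye cohort
#'
#' Per patient, axial lengths for the two eyes are drawn bivariate normal
#' with the calibrated group means/SDs and within-pair correlation
#' `rho_axial`. The offset index follows the generative cubic plus the
#' diagnosis effect, a shared pair random intercept (SD
#' `sigma_resid * sqrt(rho_pair / (1 - rho_pair))`) and a Gaussian residual
#' (SD `sigma_resid`), clipped to `[offset_clip_min, 1]`. The glaucoma
#' eye's CRVT angular deviation and RNFL-defect midpoint angle are drawn
#' bivariate normal at the calibrated correlation `r_angle`; the control
#' eye's angle is drawn independently (control eyes carry no RNFL defect).
#' All remaining tabulated variables are drawn per-group Gaussian and
#' independently (no cross-covariances are reported for them). Exclusion
#' flags are assigned to the first patients according to the calibrated
#' counts when `assign_flags = TRUE`.
#'
#' @param calibration a `crvt_calibration` object.
#' @param n_patients number of patients (two rows each).
#' @param seed integer RNG seed; the output is bit-reproducible given the
#'   seed.
#' @param assign_flags assign the calibrated exclusion-flag counts to the
#'   leading patients (default `TRUE`). Requires `n_patients` at least the
#'   total flagged count.
#' @return tibble with one row per eye (columns: `patient_id`, `eye_role`,
#'   `laterality`, `axial_length`, `offset_index`,
#'   `angular_deviation_deg`, `rnfl_defect_angle_deg`, `baseline_iop`,
#'   `bmo_area`, `beta_ppa`, `gamma_ppa`, `rnfl_thickness`, `mrw`, `md`,
#'   `psd`, `exclusion_flag`).
#' @export
generate_cohort <- function(calibration, n_patients = calibration$n_patients,
                            seed, assign_flags = TRUE) {
  cal <- calibration
  if (!inherits(cal, "crvt_calibration")) stop("calibration must be a 'crvt_calibration'")
  n <- as.integer(n_patients)
  if (n < 1) stop("n_patients must be positive")
  counts <- unlist(cal$exclusion_counts)[exclusion_levels]
  if (assign_flags && sum(counts) > n) {
    stop("n_patients is smaller than the total calibrated exclusion count")
  }
  set.seed(as.integer(seed))

  ## axial length: bivariate normal across the two eyes of a patient
  al_g_mom <- cal$table1_moments$axial_length$glaucoma
  al_c_mom <- cal$table1_moments$axial_length$control
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  al_g <- al_g_mom[1] + al_g_mom[2] * z1
  al_c <- al_c_mom[1] + al_c_mom[2] *
    (cal$rho_axial * z1 + sqrt(1 - cal$rho_axial^2) * z2)

  ## offset index: generative cubic + pair intercept + residual
  gen <- cal$cubic_generative
  sigma_pair <- cal$sigma_resid * sqrt(cal$rho_pair / (1 - cal$rho_pair))
  u <- stats::rnorm(n, 0, sigma_pair)
  off_g <- cubic_predict(gen, al_g, diagnosis = 1) + u + stats::rnorm(n, 0, cal$sigma_resid)
  off_c <- cubic_predict(gen, al_c, diagnosis = 0) + u + stats::rnorm(n, 0, cal$sigma_resid)
  clip <- function(x) pmin(pmax(x, cal$offset_clip_min), 1)
  off_g <- clip(off_g); off_c <- clip(off_c)

  ## CRVT angle (both eyes) and RNFL-defect angle (glaucoma eye),
  ## correlated at r_angle within the glaucoma eye
  ang_g_mom <- cal$table1_moments$angular_deviation_deg$glaucoma
  ang_c_mom <- cal$table1_moments$angular_deviation_deg$control
  def_mom <- cal$rnfl_defect_angle
  za <- stats::rnorm(n); zb <- stats::rnorm(n)
  ang_g <- ang_g_mom[1] + ang_g_mom[2] * za
  def_g <- def_mom[1] + def_mom[2] *
    (cal$r_angle * za + sqrt(1 - cal$r_angle^2) * zb)
  ang_c <- stats::rnorm(n, ang_c_mom[1], ang_c_mom[2])

  other_vars <- c("baseline_iop", "bmo_area", "beta_ppa", "gamma_ppa",
                  "rnfl_thickness", "mrw", "md", "psd")
  others <- lapply(other_vars, function(v) draw_group_var(cal, v, n, n))
  names(others) <- other_vars

  glaucoma_is_od <- stats::runif(n) < 0.5

  flags <- rep("none", n)
  if (assign_flags) {
    flags[seq_len(sum(counts))] <- rep(exclusion_levels, counts)
  }

  pid <- sprintf("P%04d", seq_len(n))
  build <- function(role) {
    g <- role == "glaucoma"
    tibble::tibble(
      patient_id = pid,
      eye_role = role,
      laterality = ifelse(xor(glaucoma_is_od, !g), "OD", "OS"),
      axial_length = if (g) al_g else al_c,
      offset_index = if (g) off_g else off_c,
      angular_deviation_deg = if (g) ang_g else ang_c,
      rnfl_defect_angle_deg = if (g) def_g else NA_real_,
      baseline_iop = others$baseline_iop[[if (g) "glaucoma" else "control"]],
      bmo_area = others$bmo_area[[if (g) "glaucoma" else "control"]],
      beta_ppa = others$beta_ppa[[if (g) "glaucoma" else "control"]],
      gamma_ppa = others$gamma_ppa[[if (g) "glaucoma" else "control"]],
      rnfl_thickness = others$rnfl_thickness[[if (g) "glaucoma" else "control"]],
      mrw = others$mrw[[if (g) "glaucoma" else "control"]],
      md = others$md[[if (g) "glaucoma" else "control"]],
      psd = others$psd[[if (g) "glaucoma" else "control"]],
      exclusion_flag = flags
    )
  }
  cohort <- rbind(build("glaucoma"), build("control"))
  cohort <- cohort[order(cohort$patient_id, cohort$eye_role), ]
  rownames(cohort) <- NULL
  cohort
}

#' Apply the screening cascade to a cohort
#'
#' Removes patients flagged `poor_quality`, `bifurcation`,
#' `invisible_no_angio` or `outside_both_eyes`. Patients flagged
#' `invisible_confirmed` (trunk confirmed outside the BMO by angiography)
#' are retained with the affected glaucoma eye forced to offset index 1.0
#' and undefined angular deviation.
#'
#' @param cohort cohort tibble from [generate_cohort()] (or read from CSV).
#' @return list with `included` (retained rows) and `tally` (named integer
#'   vector of removed patients per category; the retained
#'   invisible-confirmed count is reported separately as
#'   `n_retained_invisible`).
#' @export
apply_exclusions <- function(cohort) {
  removed_levels <- setdiff(exclusion_levels, "invisible_confirmed")
  if (nrow(cohort) == 0) {
    return(list(
      included = cohort,
      tally = stats::setNames(integer(length(removed_levels)), removed_levels),
      n_retained_invisible = 0L
    ))
  }
  per_patient <- cohort[!duplicated(cohort$patient_id), c("patient_id", "exclusion_flag")]
  tally <- vapply(removed_levels, function(l) sum(per_patient$exclusion_flag == l),
                  integer(1))
  keep <- !(cohort$exclusion_flag %in% removed_levels)
  included <- cohort[keep, , drop = FALSE]
  invis <- included$exclusion_flag == "invisible_confirmed" &
    included$eye_role == "glaucoma"
  included$offset_index[invis] <- 1.0
  included$angular_deviation_deg[invis] <- NA_real_
  included$rnfl_defect_angle_deg[invis] <- NA_real_
  rownames(included) <- NULL
  list(
    included = included,
    tally = tally,
    n_retained_invisible = sum(per_patient$exclusion_flag == "invisible_confirmed")
  )
}

#' Synthesize an eye delineation hitting a target measurement
#'
#' Emits a 48-point near-elliptical BMO margin of the requested area with a
#' CRVT point placed so that [measure_crvt()] recovers the requested offset
#' index and angular deviation (to numerical precision). The inverse
#' construction places the CRVT on the ray from the margin centroid at the
#' target angle, at the target fraction of the centre-to-margin distance.
#' With `outside = TRUE` the CRVT is placed outside the margin and the
#' outside flag is set, so the measurement returns offset index 1.0 with
#' undefined angle.
#'
#' @param target_index offset index in `[0, 1]`.
#' @param target_angle_deg angular deviation in degrees (right-eye
#'   orientation, nasal midline 0, superior positive). Ignored when
#'   `target_index` is 0.
#' @param laterality `"OD"` or `"OS"`; OS output is stored mirrored so
#'   that measurement (which mirrors back) recovers the target angle.
#' @param bmo_area target margin area in mm^2.
#' @param seed integer seed for the margin's random orientation and axis
#'   ratio.
#' @param outside place the CRVT outside the BMO and set the flag
#'   (requires `target_index = 1`).
#' @param n_points number of margin vertices (default 48: 24 radial scans,
#'   two margin crossings each).
#' @param patient_id identifier for the emitted record.
#' @return an [eye_delineation()] object.
#' @export
synthesize_eye_geometry <- function(target_index, target_angle_deg, laterality = "OD",
                                    bmo_area = 2.7, seed = 1, outside = FALSE,
                                    n_points = 48, patient_id = "synthetic") {
  if (is.na(target_index) || target_index < 0 || target_index > 1) {
    stop("target_index must lie in [0, 1]")
  }
  if (outside && target_index != 1) {
    stop("outside = TRUE requires target_index = 1")
  }
  if (bmo_area <= 0) stop("bmo_area must be positive")
  set.seed(as.integer(seed))
  ratio <- stats::runif(1, 0.88, 0.98)       # near-elliptical, mildly oval
  rot <- stats::runif(1, 0, pi)
  phi <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  a0 <- 1; b0 <- ratio
  ex <- a0 * cos(phi); ey <- b0 * sin(phi)
  margin <- cbind(ex * cos(rot) - ey * sin(rot),
                  ex * sin(rot) + ey * cos(rot))
  ## scale the polygon (not the ellipse) to the exact requested area
  s <- sqrt(bmo_area / abs(signed_area(margin)))
  margin <- margin * s
  ## small random decentration so the frame origin is not special
  margin <- sweep(margin, 2, stats::runif(2, -0.3, 0.3), `+`)

  ca <- bmo_center_and_area(margin)
  center <- as.numeric(ca$center)
  theta <- if (is.na(target_angle_deg)) 0 else target_angle_deg
  b <- boundary_distance(center, theta, margin)
  u <- c(cos(theta * pi / 180), sin(theta * pi / 180))
  crvt <- if (outside) center + 1.25 * b * u else center + target_index * b * u

  if (laterality == "OS") {
    ## store mirrored native coordinates; measurement mirrors back
    margin[, 1] <- -margin[, 1]
    crvt[1] <- -crvt[1]
  }
  eye_delineation(
    patient_id = patient_id,
    laterality = laterality,
    margin_points = margin,
    crvt_point = crvt,
    crvt_outside_bmo = outside
  )
}

#' Simulate matched pairs under a conditional logistic effect
#'
#' Draws per-eye offset indices with realistic within-pair spread and
#' assigns the glaucoma label *within* each pair by the conditional
#' logistic law: the probability that eye 1 is the case is
#' `plogis(beta * (x1 - x2))` with `beta = log(calibration$matched_or_offset)`.
#' This is the generative counterpart of the matched-pair conditional
#' logistic stage and is used for effect-size recovery experiments.
#'
#' @param calibration a `crvt_calibration` object (supplies the log-odds
#'   coefficient and marginal offset-index scale).
#' @param n_pairs number of patient pairs.
#' @param seed integer RNG seed.
#' @return cohort-shaped tibble with columns `patient_id`, `eye_role` and
#'   `offset_index`.
#' @export
simulate_matched_pairs <- function(calibration, n_pairs, seed) {
  cal <- calibration
  set.seed(as.integer(seed))
  beta <- cal$beta_offset_log
  mu <- mean(c(cal$table1_moments$offset_index$glaucoma[1],
               cal$table1_moments$offset_index$control[1]))
  sdx <- mean(c(cal$table1_moments$offset_index$glaucoma[2],
                cal$table1_moments$offset_index$control[2]))
  clip <- function(x) pmin(pmax(x, cal$offset_clip_min), 1)
  x1 <- clip(stats::rnorm(n_pairs, mu, sdx))
  x2 <- clip(stats::rnorm(n_pairs, mu, sdx))
  p1 <- stats::plogis(beta * (x1 - x2))
  first_is_case <- stats::runif(n_pairs) < p1
  pid <- sprintf("P%05d", seq_len(n_pairs))
  tibble::tibble(
    patient_id = rep(pid, each = 2),
    eye_role = as.vector(rbind(ifelse(first_is_case, "glaucoma", "control"),
                               ifelse(first_is_case, "control", "glaucoma"))),
    offset_index = as.vector(rbind(x1, x2))
  )
}
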