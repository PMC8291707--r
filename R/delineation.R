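#' Per-eye delineation record
#'
#' Container for the raw landmarks delineated on one eye: the ordered BMO
#' margin points, the CRVT point (or an outside-BMO flag when the trunk
#' could not be localised within the opening), laterality, optional RNFL
#' defect boundary angles and the optional RPE-opening / clinical disc
#' margin areas used for parapapillary atrophy arithmetic.
#'
#' Coordinates are in mm in the image plane. For OD records the internal
#' convention is +x = nasal, +y = superior; OS records are stored in their
#' native (mirror-image) frame and mirrored on angle computation.
#'
#' @param patient_id opaque patient identifier.
#' @param laterality `"OD"` or `"OS"`.
#' @param margin_points ordered margin vertices (>= 8) forming a simple
#'   closed polygon; matrix, data frame, or list of `c(x, y)` pairs, mm.
#' @param crvt_point CRVT landmark `c(x, y)` in mm, or `NULL` when
#'   `crvt_outside_bmo` is `TRUE`. A point supplied together with the
#'   outside flag must actually lie outside the margin polygon.
#' @param crvt_outside_bmo logical: CRVT confirmed to lie outside the BMO.
#' @param rnfl_defects list of boundary-angle pairs (degrees, temporal
#'   midline convention); may be empty.
#' @param rpeo_area,cdm_area,bmo_area_input optional areas in mm^2.
#' @return object of class `eye_delineation`.
#' @export
eye_delineation <- function(patient_id,
                            laterality = c("OD", "OS"),
                            margin_points,
                            crvt_point = NULL,
                            crvt_outside_bmo = FALSE,
                            rnfl_defects = list(),
                            rpeo_area = NA_real_,
                            cdm_area = NA_real_,
                            bmo_area_input = NA_real_) {
  laterality <- match.arg(laterality)
  obj <- structure(
    list(
      patient_id = as.character(patient_id),
      laterality = laterality,
      margin_points = as_margin_matrix(margin_points),
      crvt_point = if (is.null(crvt_point)) NULL else as.numeric(crvt_point),
      crvt_outside_bmo = isTRUE(crvt_outside_bmo),
      rnfl_defects = rnfl_defects %||% list(),
      rpeo_area = as.numeric(rpeo_area),
      cdm_area = as.numeric(cdm_area),
      bmo_area_input = as.numeric(bmo_area_input)
    ),
    class = "eye_delineation"
  )
  validate_delineation(obj)
}

validate_delineation <- function(d) {
  if (!inherits(d, "eye_delineation")) {
    stop("expected an 'eye_delineation' object")
  }
  m <- validate_margin_polygon(d$margin_points, min_vertices = 8)
  d$margin_points <- m
  if (d$crvt_outside_bmo) {
    if (!is.null(d$crvt_point)) {
      if (length(d$crvt_point) != 2 || anyNA(d$crvt_point)) {
        stop("crvt_point must be a finite (x, y) pair")
      }
      if (point_in_polygon(d$crvt_point, m)) {
        stop("crvt_outside_bmo is set but the CRVT point lies inside the margin")
      }
    }
  } else {
    if (is.null(d$crvt_point)) {
      stop("crvt_point is required unless crvt_outside_bmo is TRUE")
    }
    if (length(d$crvt_point) != 2 || anyNA(d$crvt_point)) {
      stop("crvt_point must be a finite (x, y) pair")
    }
  }
  d
}

#' @export
print.eye_delineation <- function(x, ...) {
  cat(sprintf("Eye delineation: patient %s, %s\n", x$patient_id, x$laterality))
  cat(sprintf("  margin vertices : %d\n", nrow(x$margin_points)))
  cat(sprintf("  CRVT            : %s\n",
              if (x$crvt_outside_bmo) "outside BMO"
              else sprintf("(%.3f, %.3f) mm", x$crvt_point[1], x$crvt_point[2])))
  cat(sprintf("  RNFL defects    : %d\n", length(x$rnfl_defects)))
  invisible(x)
}

#' Read delineation records from JSON
#'
#' Expects either a single record or an array of records of the form
#' `{patient_id, laterality, margin: [[x,y],...], crvt: [x,y] | null,`
#' `crvt_outside_bmo, rnfl_defects: [[a1,a2],...], rpeo_area, cdm_area}`,
#' with coordinates in mm and angles in degrees.
#'
#' @param path path to a JSON file.
#' @return list of [eye_delineation()] objects.
#' @export
read_delineations_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(raw$patient_id)) raw <- list(raw)
  lapply(raw, function(r) {
    eye_delineation(
      patient_id = r$patient_id,
      laterality = r$laterality,
      margin_points = do.call(rbind, lapply(r$margin, function(p) as.numeric(unlist(p)))),
      crvt_point = if (is.null(r$crvt)) NULL else as.numeric(unlist(r$crvt)),
      crvt_outside_bmo = isTRUE(r$crvt_outside_bmo),
      rnfl_defects = lapply(r$rnfl_defects %||% list(),
                            function(p) as.numeric(unlist(p))),
      rpeo_area = r$rpeo_area %||% NA_real_,
      cdm_area = r$cdm_area %||% NA_real_,
      bmo_area_input = r$bmo_area %||% NA_real_
    )
  })
}

#' Write delineation records to JSON
#'
#' Inverse of [read_delineations_json()].
#'
#' @param delineations list of [eye_delineation()] objects.
#' @param path output path.
#' @export
write_delineations_json <- function(delineations, path) {
  if (inherits(delineations, "eye_delineation")) delineations <- list(delineations)
  recs <- lapply(delineations, function(d) {
    list(
      patient_id = d$patient_id,
      laterality = d$laterality,
      margin = apply(d$margin_points, 1, function(p) as.numeric(p), simplify = FALSE),
      crvt = if (is.null(d$crvt_point)) NULL else as.numeric(d$crvt_point),
      crvt_outside_bmo = d$crvt_outside_bmo,
      rnfl_defects = d$rnfl_defects,
      rpeo_area = d$rpeo_area,
      cdm_area = d$cdm_area,
      bmo_area = d$bmo_area_input
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read delineations from long-format CSV
#'
#' One margin point per row; per-eye attributes are repeated on every row
#' of that eye. Required columns: `patient_id`, `laterality`, `x`, `y`.
#' Optional: `crvt_x`, `crvt_y`, `crvt_outside_bmo`, `rpeo_area`,
#' `cdm_area`. RNFL defects are not representable in the long CSV; use the
#' JSON format when they are needed.
#'
#' @param path path to a CSV file.
#' @return list of [eye_delineation()] objects.
#' @export
read_delineations_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "laterality", "x", "y")
  if (!all(need %in% names(tab))) {
    stop("long-format delineation CSV needs columns: ",
         paste(need, collapse = ", "))
  }
  key <- interaction(tab$patient_id, tab$laterality, drop = TRUE)
  lapply(split(tab, key), function(g) {
    first <- g[1, ]
    outside <- isTRUE(as.logical(first$crvt_outside_bmo %||% FALSE))
    has_crvt <- all(c("crvt_x", "crvt_y") %in% names(g)) &&
      !is.na(first$crvt_x) && !is.na(first$crvt_y)
    eye_delineation(
      patient_id = first$patient_id,
      laterality = first$laterality,
      margin_points = cbind(g$x, g$y),
      crvt_point = if (has_crvt) c(first$crvt_x, first$crvt_y) else NULL,
      crvt_outside_bmo = outside,
      rpeo_area = if ("rpeo_area" %in% names(g)) first$rpeo_area else NA_real_,
      cdm_area = if ("cdm_area" %in% names(g)) first$cdm_area else NA_real_
    )
  })
}

#' Measure a batch of delineations
#'
#' Runs [measure_crvt()], [rnfl_defect_angle()] and [ppa_areas()] on each
#' record and assembles the per-eye measurement table.
#'
#' @param delineations list of [eye_delineation()] objects.
#' @return tibble with one row per eye: `patient_id`, `laterality`,
#'   `offset_index`, `angular_deviation_deg`, `rnfl_defect_angle_deg`,
#'   `rnfl_defect_width_deg`, `bmo_area_mm2`, `beta_ppa_mm2`,
#'   `gamma_ppa_mm2`, `flags` (semicolon-separated).
#' @export
measure_eyes <- function(delineations) {
  if (inherits(delineations, "eye_delineation")) delineations <- list(delineations)
  rows <- lapply(delineations, function(d) {
    m <- measure_crvt(d)
    flags <- setdiff(m$flags, "none")
    defect <- rnfl_defect_angle(d$rnfl_defects, d$laterality)
    beta <- NA_real_; gamma <- NA_real_
    if (!is.na(d$rpeo_area) && !is.na(d$cdm_area)) {
      pa <- withCallingHandlers(
        ppa_areas(d$rpeo_area, d$cdm_area,
                  if (!is.na(d$bmo_area_input)) d$bmo_area_input else m$bmo_area),
        warning = function(w) {
          flags <<- c(flags, "negative_ppa_area")
          invokeRestart("muffleWarning")
        }
      )
      beta <- pa$beta_zone_area
      gamma <- pa$gamma_zone_area
    }
    tibble::tibble(
      patient_id = d$patient_id,
      laterality = d$laterality,
      offset_index = m$offset_index,
      angular_deviation_deg = m$angular_deviation_deg,
      rnfl_defect_angle_deg = if (is.null(defect)) NA_real_ else defect$midpoint_angle_deg,
      rnfl_defect_width_deg = if (is.null(defect)) NA_real_ else defect$angular_width_deg,
      bmo_area_mm2 = m$bmo_area,
      beta_ppa_mm2 = beta,
      gamma_ppa_mm2 = gamma,
      flags = if (length(flags)) paste(flags, collapse = ";") else "none"
    )
  })
  do.call(rbind, rows)
}

#' Write a measurement table to CSV
#'
#' @param measurements tibble from [measure_eyes()].
#' @param path output path.
#' @export
write_measurements_csv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, na = "")
  invisible(path)
}
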