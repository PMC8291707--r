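## Matched-pair (1 case : 1 control per patient) analysis of eye-level
## glaucoma status. With exactly one case and one control per stratum the
## conditional likelihood of the pair-matched design is exact, depends only
## on within-pair predictor differences, and avoids fragile random-intercept
## logistic fits on small cluster counts; it is fitted via the Cox
## conditional-likelihood equivalence (survival::clogit).

## within-pair (glaucoma minus control) differences of a predictor
pair_differences <- function(dat, predictor) {
  w <- pair_wide(dat, predictor)
  w$glaucoma - w$control
}

fit_clogit_terms <- function(cohort, predictors) {
  dat <- as.data.frame(cohort)
  dat$case <- as.integer(dat$eye_role == "glaucoma")
  per <- table(dat$patient_id, dat$case)
  if (!all(per == 1)) {
    stop("each patient must contribute exactly one glaucoma and one control eye")
  }
  ## a predictor constant within every pair carries no conditional
  ## information: OR 1, p 1 by construction (no discordance)
  concordant <- vapply(predictors, function(p) {
    all(abs(pair_differences(dat, p)) < .Machine$double.eps^0.5)
  }, logical(1))
  if (all(concordant)) {
    return(tibble::tibble(
      term = predictors, or = 1, ci_low = NA_real_, ci_high = NA_real_,
      p = 1, flag = "no_discordance"
    ))
  }
  predictors_fit <- predictors[!concordant]
  f <- stats::as.formula(paste(
    "case ~", paste(predictors_fit, collapse = " + "), "+ strata(patient_id)"
  ))
  fit <- suppressWarnings(survival::clogit(f, data = dat))
  s <- summary(fit)
  co <- s$coefficients
  est <- co[, "coef"]
  se <- co[, "se(coef)"]
  separated <- abs(est) > 10 | se > 100 | !is.finite(se)
  lo <- exp(est - stats::qnorm(0.975) * se)
  hi <- exp(est + stats::qnorm(0.975) * se)
  lo[separated] <- 0
  hi[separated] <- Inf
  fitted_rows <- tibble::tibble(
    term = rownames(co),
    or = exp(est),
    ci_low = lo,
    ci_high = hi,
    p = co[, "Pr(>|z|)"],
    flag = ifelse(separated, "possible_separation", "none")
  )
  if (any(concordant)) {
    fitted_rows <- rbind(fitted_rows, tibble::tibble(
      term = predictors[concordant], or = 1, ci_low = NA_real_,
      ci_high = NA_real_, p = 1, flag = "no_discordance"
    ))
    fitted_rows <- fitted_rows[match(predictors, fitted_rows$term), ]
  }
  fitted_rows
}

#' Matched-pair conditional logistic modelling with univariable screening
#'
#' Fits one conditional (matched-pair) logistic model per candidate
#' predictor of eye-level glaucoma status, then a multivariable model over
#' the predictors whose univariable p-value falls below the screening
#' threshold. Odds ratios are per unit of the predictor, with Wald 95%
#' confidence intervals on the log scale. Predictors with no within-pair
#' discordance carry no conditional information (OR 1, p 1 by
#' construction); complete separation is flagged and the interval reported
#' unbounded.
#'
#' @param cohort cohort tibble (`patient_id`, `eye_role`, predictors).
#' @param candidate_predictors character vector of predictor column names.
#' @param screen_p univariable p-value threshold for entry into the
#'   multivariable model (default 0.20).
#' @return object of class `matched_logistic_fit`: list with `univariable`
#'   (tibble, one row per candidate), `multivariable` (tibble over selected
#'   predictors, or `NULL` when none pass the screen), `selected`, and
#'   `screen_p`.
#' @export
matched_logistic <- function(cohort, candidate_predictors, screen_p = 0.20) {
  stopifnot(length(candidate_predictors) >= 1)
  missing_cols <- setdiff(candidate_predictors, names(cohort))
  if (length(missing_cols)) {
    stop("predictors not found in cohort: ", paste(missing_cols, collapse = ", "))
  }
  ## structural pairing must hold before any NA filtering
  per <- table(cohort$patient_id, cohort$eye_role == "glaucoma")
  if (ncol(per) != 2 || !all(per == 1)) {
    stop("each patient must contribute exactly one glaucoma and one control eye")
  }
  ## restrict to patients with both eyes observed for the model's variables
  complete_pairs <- function(vars) {
    dat <- as.data.frame(cohort)
    ok <- stats::complete.cases(dat[, vars, drop = FALSE])
    full <- names(which(table(dat$patient_id[ok]) == 2))
    cohort[ok & dat$patient_id %in% full, , drop = FALSE]
  }
  uni <- do.call(rbind, lapply(candidate_predictors, function(p) {
    row <- fit_clogit_terms(complete_pairs(p), p)
    row$stage <- "univariable"
    row
  }))
  selected <- uni$term[!is.na(uni$p) & uni$p < screen_p]
  multi <- NULL
  if (length(selected)) {
    multi <- fit_clogit_terms(complete_pairs(selected), selected)
    multi$stage <- "multivariable"
  }
  out <- list(
    univariable = uni,
    multivariable = multi,
    selected = selected,
    screen_p = screen_p
  )
  class(out) <- "matched_logistic_fit"
  out
}

#' @export
print.matched_logistic_fit <- function(x, ...) {
  cat("Matched-pair conditional logistic analysis\n")
  cat("Univariable:\n")
  print(as.data.frame(x$univariable[, c("term", "or", "ci_low", "ci_high", "p")]),
        digits = 4)
  if (!is.null(x$multivariable)) {
    cat(sprintf("Multivariable (univariable p < %.2f):\n", x$screen_p))
    print(as.data.frame(x$multivariable[, c("term", "or", "ci_low", "ci_high", "p")]),
          digits = 4)
  } else {
    cat("No predictor passed the univariable screen.\n")
  }
  invisible(x)
}
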