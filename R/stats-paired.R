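pair_wide <- function(cohort, variable) {
  if (!variable %in% names(cohort)) {
    stop("variable not found in cohort: ", variable)
  }
  g <- cohort[cohort$eye_role == "glaucoma", c("patient_id", variable)]
  c_ <- cohort[cohort$eye_role == "control", c("patient_id", variable)]
  if (any(duplicated(g$patient_id)) || any(duplicated(c_$patient_id))) {
    stop("each patient must contribute exactly one glaucoma and one control eye")
  }
  m <- merge(g, c_, by = "patient_id", suffixes = c("_g", "_c"))
  names(m) <- c("patient_id", "glaucoma", "control")
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Paired intra-individual comparison of one variable
#'
#' Paired t-test on glaucoma-minus-control differences, with the Wilcoxon
#' signed-rank test as a distribution-free companion, and per-group
#' means/SDs in the style of a demographics table.
#'
#' @param cohort cohort tibble with `patient_id`, `eye_role` and the
#'   variable column.
#' @param variable name of the variable to compare.
#' @return object of class `paired_comparison`: a one-row tibble with the
#'   group means/SDs, the mean paired difference, `t_stat`, `df`, `p_t`,
#'   `p_wilcoxon`, `n_pairs` and a `flag` (`"none"` or
#'   `"degenerate_zero_variance"` when all paired differences are equal,
#'   in which case the t-based p-value is undefined).
#' @export
paired_compare <- function(cohort, variable) {
  w <- pair_wide(cohort, variable)
  n <- nrow(w)
  if (n < 2) stop("need at least 2 complete pairs for ", variable)
  d <- w$glaucoma - w$control
  sd_d <- stats::sd(d)
  flag <- "none"
  if (sd_d == 0) {
    flag <- "degenerate_zero_variance"
    t_stat <- NA_real_
    p_t <- NA_real_
    p_w <- NA_real_
  } else {
    tt <- stats::t.test(w$glaucoma, w$control, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_t <- tt$p.value
    p_w <- tryCatch(
      suppressWarnings(
        stats::wilcox.test(w$glaucoma, w$control, paired = TRUE,
                           exact = FALSE)$p.value
      ),
      error = function(e) NA_real_
    )
  }
  out <- tibble::tibble(
    variable = variable,
    n_pairs = n,
    mean_glaucoma = mean(w$glaucoma),
    sd_glaucoma = stats::sd(w$glaucoma),
    mean_control = mean(w$control),
    sd_control = stats::sd(w$control),
    mean_diff = mean(d),
    t_stat = t_stat,
    df = n - 1,
    p_t = p_t,
    p_wilcoxon = p_w,
    flag = flag
  )
  class(out) <- c("paired_comparison", class(out))
  out
}
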