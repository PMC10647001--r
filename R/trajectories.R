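#' Random-slope, random-intercept longitudinal model of a marker
#'
#' Fits, by maximum likelihood, the mixed model
#' `value ~ group + group:time + age + (1 + time | patient)`:
#' group-specific intercepts and slopes over months from baseline, an
#' optional age-at-first-draw covariate, and correlated per-patient
#' random intercepts and slopes. Each group's slope is tested against
#' zero by a likelihood-ratio test of the model with that slope removed.
#' Singular (non-positive-definite) random-effect covariances trigger a
#' refit with independent random intercept and slope, flagged in the
#' result.
#'
#' @param values Marker values (one per sample).
#' @param times Months from baseline.
#' @param patient_ids Patient identifier per sample.
#' @param group_labels Two-level progression group per sample.
#' @param age_at_first_draw Optional per-sample age covariate (constant
#'   within patient); `NULL` omits it.
#' @return List of class `lmm_fit`: `fixed_intercept` and `fixed_slope`
#'   (named per group, units/month), `age_covariate_coef`,
#'   `slope_p_value` (named per group, LRT), `random_intercept_var`,
#'   `random_slope_var`, `residual_var`, `converged`, `diagonal_cov`.
#' @export
fit_random_slope_model <- function(values, times, patient_ids, group_labels,
                                   age_at_first_draw = NULL) {
  grp <- factor(as.character(group_labels))
  if (nlevels(grp) != 2) stop("two groups required", call. = FALSE)
  if (min(table(unique(data.frame(patient_ids, grp))$grp)) < 3) {
    stop("at least 3 patients per group required", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    lv <- levels(grp)
    return(structure(list(
      fixed_intercept = stats::setNames(rep(values[1], 2), lv),
      fixed_slope = stats::setNames(c(0, 0), lv),
      age_covariate_coef = if (is.null(age_at_first_draw)) NA_real_ else 0,
      slope_p_value = stats::setNames(c(1, 1), lv),
      random_intercept_var = 0, random_slope_var = 0, residual_var = 0,
      converged = TRUE, diagonal_cov = FALSE
    ), class = "lmm_fit"))
  }
  df <- data.frame(
    value = values, time = times,
    patient = factor(patient_ids), group = grp
  )
  lv <- levels(grp)
  # one slope column per group so each can be dropped for its LRT
  for (g in lv) df[[paste0("slope_", g)]] <- df$time * (df$group == g)
  slope_terms <- paste0("slope_", lv)
  has_age <- !is.null(age_at_first_draw)
  if (has_age) df$age <- age_at_first_draw
  rhs_fixed <- c("0", "group", slope_terms, if (has_age) "age")

  fit_one <- function(fixed_terms, diag_cov) {
    re <- if (diag_cov) "(1 | patient) + (0 + time | patient)" else
      "(1 + time | patient)"
    form <- stats::as.formula(paste(
      "value ~", paste(c(fixed_terms, re), collapse = " + ")
    ))
    suppressWarnings(suppressMessages(
      lme4::lmer(form, data = df, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore")
      )
    ))
  }
  diag_cov <- FALSE
  full <- fit_one(rhs_fixed, diag_cov)
  if (lme4::isSingular(full, tol = 1e-5)) {
    diag_cov <- TRUE
    full <- fit_one(rhs_fixed, diag_cov)
  }
  p <- stats::setNames(numeric(2), lv)
  for (g in lv) {
    reduced <- fit_one(setdiff(rhs_fixed, paste0("slope_", g)), diag_cov)
    lr <- 2 * (stats::logLik(full) - stats::logLik(reduced))
    p[g] <- stats::pchisq(max(0, as.numeric(lr)), df = 1, lower.tail = FALSE)
  }
  fx <- lme4::fixef(full)
  vc <- as.data.frame(lme4::VarCorr(full))
  ri <- vc$vcov[vc$var1 == "(Intercept)" & is.na(vc$var2) &
    vc$grp != "Residual"]
  rs <- vc$vcov[vc$var1 == "time" & is.na(vc$var2)]
  res <- vc$vcov[vc$grp == "Residual"]
  conv <- length(full@optinfo$conv$lme4) == 0 &&
    full@optinfo$conv$opt == 0
  structure(list(
    fixed_intercept = stats::setNames(fx[paste0("group", lv)], lv),
    fixed_slope = stats::setNames(fx[slope_terms], lv),
    age_covariate_coef = if (has_age) unname(fx["age"]) else NA_real_,
    slope_p_value = p,
    random_intercept_var = if (length(ri)) ri[1] else 0,
    random_slope_var = if (length(rs)) rs[1] else 0,
    residual_var = res[1],
    converged = conv,
    diagonal_cov = diag_cov,
    model = full
  ), class = "lmm_fit")
}

#' Baseline group comparison of a marker
#'
#' Two-sided Mann-Whitney comparison of first-visit marker values
#' between the two progression groups; delegates to
#' [exact_mann_whitney()], so small cohorts get the exact enumeration.
#'
#' @param first_visit_values Baseline value per patient.
#' @param group_labels Group per patient (two levels).
#' @return Two-sided p-value.
#' @export
baseline_compare <- function(first_visit_values, group_labels) {
  grp <- as.character(group_labels)
  lv <- unique(grp[!is.na(grp)])
  if (length(lv) != 2) stop("two nonempty groups required", call. = FALSE)
  exact_mann_whitney(
    first_visit_values[grp == lv[1]],
    first_visit_values[grp == lv[2]]
  )
}
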