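#' Published ALS cohort demographics
#'
#' The per-patient demographics of the two longitudinal ALS CSF cohorts
#' this package models: discovery (11 patients) and validation (11
#' patients), with visit counts, follow-up span, sex, ages, monthly
#' ALSFRS-R decline and onset site. These printed values are the inputs
#' for the cohort-labelling and demographic worked examples
#' (see [demographics_tests()]).
#'
#' @param cohort `"discovery"`, `"validation"` or `"both"` (default).
#' @return Data frame, one row per patient.
#' @export
als_demographics <- function(cohort = c("both", "discovery", "validation")) {
  cohort <- match.arg(cohort)
  path <- system.file("extdata", "patient_demographics.tsv",
    package = "proteostate"
  )
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (cohort != "both") df <- df[df$cohort == cohort, ]
  rownames(df) <- NULL
  df
}

#' Cohort labelling and demographic tests on the published table
#'
#' Applies the progression-rate thresholds to the published ALSFRS-R
#' slopes and runs the standard demographic group tests on one cohort:
#' Fisher's exact test for sex and onset site, and the exact Mann-Whitney
#' test for age at symptom onset (patients with missing age dropped).
#'
#' @param cohort `"discovery"` (default) or `"validation"`.
#' @return List with `n_fast`, `n_slow`, `sex_fisher_p`,
#'   `onset_site_fisher_p`, `age_onset_mw_p`.
#' @export
demographics_tests <- function(cohort = c("discovery", "validation")) {
  cohort <- match.arg(cohort)
  df <- als_demographics(cohort)
  label <- progression_label(df$alsfrsr_slope)
  fast <- label == "fast"
  slow <- label == "slow"
  sex_tab <- rbind(
    table(factor(df$sex[fast], levels = c("M", "F"))),
    table(factor(df$sex[slow], levels = c("M", "F")))
  )
  site_tab <- rbind(
    table(factor(df$onset_site[fast], levels = c("Limb", "Bulbar"))),
    table(factor(df$onset_site[slow], levels = c("Limb", "Bulbar")))
  )
  age_f <- df$age_at_onset[fast & !is.na(df$age_at_onset)]
  age_s <- df$age_at_onset[slow & !is.na(df$age_at_onset)]
  list(
    n_fast = sum(fast),
    n_slow = sum(slow),
    sex_fisher_p = fisher_exact_2x2(sex_tab),
    onset_site_fisher_p = fisher_exact_2x2(site_tab),
    age_onset_mw_p = exact_mann_whitney(age_s, age_f)
  )
}
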