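#' Neuropsychological scoring: Z transforms, domain composites, impairment
#'
#' Raw test scores are standardized against the analyzed cohort's own mean
#' and SD, averaged into six domain composites, and screened for cognitive
#' impairment using education-adjusted MMSE/MoCA cutoffs. Timed tests
#' (TMT-A/B, SCWT-A, Stroop-C) are standardized in their native direction
#' (higher = slower); no sign inversion is applied, so composites built on
#' them must be interpreted accordingly.
#'
#' @name cognitive-scoring
NULL

#' Domain composite definitions
#'
#' Constituent tests per cognitive domain. Each composite is the arithmetic
#' mean of its constituents' Z scores.
#' @export
DOMAIN_DEFS <- list(
  global           = c("mmse", "moca"),
  processing_speed = c("tmt_a", "scwt_a"),
  memory           = c("vr_dr", "avlt_dr"),
  executive        = c("cvf", "tmt_a", "tmt_b", "stroop_c"),
  language         = c("bnt", "cvf"),
  visuospatial     = c("vr_copy", "cdt")
)

#' All raw test columns used in scoring
#' @export
COGNITIVE_TESTS <- unique(unlist(DOMAIN_DEFS))

#' Z transform
#'
#' @param raw raw score(s).
#' @param cohort_mean,cohort_sd reference mean and SD; `sd` must be > 0.
#' @return `(raw - cohort_mean) / cohort_sd`.
#' @export
z_transform <- function(raw, cohort_mean, cohort_sd) {
  if (any(cohort_sd <= 0)) stop("z_transform: sd must be > 0")
  (raw - cohort_mean) / cohort_sd
}

#' Standardize raw test columns against the cohort
#'
#' Adds a `z_<test>` column for each test present, using the full cohort's
#' mean/SD (the reference population is the analyzed cohort itself).
#'
#' @param cohort data.frame with raw test columns.
#' @param tests character vector of test column names.
#' @return cohort with `z_*` columns appended.
#' @export
z_score_cohort <- function(cohort, tests = COGNITIVE_TESTS) {
  for (test in intersect(tests, names(cohort))) {
    x <- cohort[[test]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s <= 0)
      stop("z_score_cohort: degenerate distribution for ", test)
    cohort[[paste0("z_", test)]] <- z_transform(x, mean(x, na.rm = TRUE), s)
  }
  cohort
}

#' Domain composite scores
#'
#' Each composite is the mean of its constituent Z scores. A subject
#' missing any constituent gets `NA` for that composite; a domain whose
#' constituent columns are entirely absent raises an error.
#'
#' @param cohort data.frame containing `z_<test>` columns (see
#'   [z_score_cohort()]).
#' @param domains named list of constituent tests, default [DOMAIN_DEFS].
#' @return cohort with `domain_<name>` columns appended.
#' @export
domain_composites <- function(cohort, domains = DOMAIN_DEFS) {
  for (dom in names(domains)) {
    zcols <- paste0("z_", domains[[dom]])
    present <- zcols %in% names(cohort)
    if (!any(present))
      stop("domain_composites: no constituent of domain '", dom, "' present")
    if (!all(present))
      warning("domain_composites: domain '", dom, "' missing constituents: ",
              paste(zcols[!present], collapse = ", "),
              "; composite set to NA")
    vals <- if (all(present))
      rowMeans(as.matrix(cohort[zcols])) else NA_real_
    cohort[[paste0("domain_", dom)]] <- vals
  }
  cohort
}

# education-stratified screening cutoffs; scores <= cutoff are impaired
.mmse_cutoff <- function(edu) ifelse(edu > 6, 26L, ifelse(edu >= 1, 22L, 19L))
.moca_cutoff <- function(edu) ifelse(edu > 12, 25L,
                              ifelse(edu >= 7, 24L,
                               ifelse(edu >= 1, 19L, 13L)))

#' Classify cognitive impairment from MMSE/MoCA with education cutoffs
#'
#' A subject is impaired when a provided score is at or below its
#' education-specific cutoff. MMSE cutoffs: <=26 for >6 education years,
#' <=22 for 1-6 years, <=19 for 0 years. MoCA cutoffs: <=25 for >12 years,
#' <=24 for 7-12, <=19 for 1-6, <=13 for 0. When both instruments are
#' available the default rule is the sensitive OR combination.
#'
#' @param mmse,moca scores (either may be `NA`, not both).
#' @param education_years non-negative integers.
#' @param rule `"or"` (default), `"and"`, `"mmse"` or `"moca"`.
#' @return data.frame: `impaired` (logical), `mmse_impaired`,
#'   `moca_impaired`, `rule_fired` (which instrument(s) triggered).
#' @export
classify_ci <- function(mmse, moca, education_years, rule = c("or", "and",
                                                              "mmse", "moca")) {
  rule <- match.arg(rule)
  n <- max(length(mmse), length(moca), length(education_years))
  mmse <- rep_len(mmse, n); moca <- rep_len(moca, n)
  education_years <- rep_len(education_years, n)
  if (any(education_years < 0, na.rm = TRUE))
    stop("classify_ci: education_years must be >= 0")
  if (any(is.na(mmse) & is.na(moca)))
    stop("classify_ci: at least one of MMSE/MoCA must be provided per subject")
  mm <- mmse <= .mmse_cutoff(education_years)
  mo <- moca <= .moca_cutoff(education_years)
  imp <- switch(rule,
    or   = (mm %in% TRUE) | (mo %in% TRUE),
    and  = ifelse(is.na(mm), mo, ifelse(is.na(mo), mm, mm & mo)),
    mmse = mm %in% TRUE,
    moca = mo %in% TRUE)
  fired <- ifelse(mm %in% TRUE & mo %in% TRUE, "mmse+moca",
           ifelse(mm %in% TRUE, "mmse", ifelse(mo %in% TRUE, "moca", "none")))
  data.frame(impaired = as.logical(imp), mmse_impaired = mm,
             moca_impaired = mo, rule_fired = fired,
             stringsAsFactors = FALSE)
}

#' Score a cohort end to end
#'
#' Z-standardizes raw tests, builds domain composites, and adds the
#' impairment flag `ci_flag`.
#'
#' @param cohort data.frame with raw test columns and `education_years`.
#' @param rule impairment combination rule, see [classify_ci()].
#' @return scored cohort.
#' @export
score_cohort <- function(cohort, rule = "or") {
  cohort <- z_score_cohort(cohort)
  cohort <- domain_composites(cohort)
  cls <- classify_ci(cohort$mmse, cohort$moca, cohort$education_years,
                     rule = rule)
  cohort$ci_flag <- cls$impaired
  cohort
}
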