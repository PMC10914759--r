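#' Screening-triage model parameters
#'
#' Inputs to the deterministic expected-value model of lung-cancer
#' screening outcomes in a population of at-risk individuals. Defaults:
#' 100,000 individuals, 0.91% prevalence, 3.9% LDCT screening compliance
#' versus 75% blood-test compliance, blood-test operating point 90%
#' sensitivity / 82% specificity, and the Lung-RADS LDCT operating point of
#' 84.9% sensitivity / 87.2% specificity.
#'
#' @param population Size of the at-risk population.
#' @param prevalence Lung-cancer prevalence among them.
#' @param ldct_compliance Fraction accepting LDCT screening directly.
#' @param leap_compliance Fraction accepting the blood test.
#' @param leap_sensitivity,leap_specificity Blood-test operating point.
#' @param ldct_sensitivity,ldct_specificity LDCT (Lung-RADS) operating
#'   point.
#' @return A `triage_params` list.
#' @export
triage_params <- function(population = 100000, prevalence = 0.0091,
                          ldct_compliance = 0.039, leap_compliance = 0.75,
                          leap_sensitivity = 0.90, leap_specificity = 0.82,
                          ldct_sensitivity = 0.849, ldct_specificity = 0.872) {
  fr <- c(prevalence = prevalence, ldct_compliance = ldct_compliance,
          leap_compliance = leap_compliance, leap_sensitivity = leap_sensitivity,
          leap_specificity = leap_specificity, ldct_sensitivity = ldct_sensitivity,
          ldct_specificity = ldct_specificity)
  if (any(fr < 0 | fr > 1))
    stop(sprintf("fractions must lie in [0, 1]: %s",
                 paste(names(fr)[fr < 0 | fr > 1], collapse = ", ")),
         call. = FALSE)
  stopifnot(population >= 1)
  structure(c(list(population = population), as.list(fr)),
            class = "triage_params")
}

triage_result <- function(scenario, screened, tp, fp, detected, params) {
  expected_cancers <- screened * params$prevalence
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  ci <- if (is.na(ppv)) list(lower = NA_real_, upper = NA_real_)
  else clopper_pearson(round(tp), round(tp) + round(fp))
  structure(list(scenario = scenario, screened = screened,
                 expected_cancers = expected_cancers,
                 true_positives = tp, false_positives = fp,
                 detected_raw = tp, detected = detected,
                 ppv = ppv, ppv_lower = ci$lower, ppv_upper = ci$upper),
            class = "triage_result")
}

#' Expected outcomes of LDCT-only screening
#'
#' Expected-value arithmetic: `screened = population * ldct_compliance`;
#' detected cancers are `screened * prevalence * ldct_sensitivity` (rounded
#' to the nearest integer for reporting; the raw value is retained), false
#' positives `screened * (1 - prevalence) * (1 - ldct_specificity)`, and
#' PPV their ratio. Under the defaults this yields 30 detected cancers and
#' a PPV of 5.7%.
#'
#' @param params A [triage_params()].
#' @return A `triage_result`: `screened`, `expected_cancers`,
#'   `true_positives`, `false_positives`, `detected_raw`, `detected`
#'   (reporting-rounded), `ppv` with Clopper-Pearson bounds.
#' @export
simulate_ldct_only <- function(params = triage_params()) {
  screened <- params$population * params$ldct_compliance
  tp <- screened * params$prevalence * params$ldct_sensitivity
  fp <- screened * (1 - params$prevalence) * (1 - params$ldct_specificity)
  triage_result("ldct_only", screened, tp, fp, round(tp), params)
}

#' Expected outcomes of blood-test-triaged LDCT screening
#'
#' The blood test screens `population * leap_compliance` individuals; its
#' positives proceed to LDCT, so a cancer is detected when both tests are
#' positive and a false positive requires both tests to err:
#' `TP = screened * prevalence * leap_sensitivity * ldct_sensitivity`,
#' `FP = screened * (1 - prevalence) * (1 - leap_specificity) * (1 - ldct_specificity)`.
#' The detected count is reported rounded to the nearest ten (matching the
#' printed precision of such projections; the raw value is retained). Under
#' the defaults: 520 detected cancers.
#'
#' @inheritParams simulate_ldct_only
#' @return A `triage_result`.
#' @export
simulate_leap_triage <- function(params = triage_params()) {
  screened <- params$population * params$leap_compliance
  tp <- screened * params$prevalence * params$leap_sensitivity *
    params$ldct_sensitivity
  fp <- screened * (1 - params$prevalence) * (1 - params$leap_specificity) *
    (1 - params$ldct_specificity)
  triage_result("leap_triage", screened, tp, fp, round(tp / 10) * 10, params)
}

#' Fold increase in detected cancers between two scenarios
#'
#' Ratio of unrounded detected counts, rounded to the nearest integer.
#' Under the default parameters, triaged screening detects 17-fold more
#' cancers than LDCT-only screening.
#'
#' @param baseline,alternative `triage_result`s; `baseline` must detect a
#'   positive number of cancers.
#' @return Integer fold increase.
#' @export
fold_increase <- function(baseline, alternative) {
  if (!isTRUE(baseline$detected_raw > 0))
    stop("baseline scenario detects no cancers; fold increase undefined",
         call. = FALSE)
  as.integer(round(alternative$detected_raw / baseline$detected_raw))
}
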