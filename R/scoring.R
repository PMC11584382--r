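# Eligibility screen, surgical-risk factors, BAPT scoring and diabetes
# remission classification.

# vectorised category lookups. Conventions (documented in the vignette):
# duration <4 is [0,4), 4-8 is [4,8], >8 is (8,Inf); BMI bands are half-open
# [35,40), [40,45), [45,50), [50,Inf) with >=50 used consistently for both the
# top band and the risk factor; age bands [18,30), [30,50), [50,Inf); ages
# below 18 (ineligible, scored only under force) use the youngest band.
.dur_band <- function(d) ifelse(d < 4, 3L, ifelse(d <= 8, 2L, 1L))
.bmi_band <- function(b) ifelse(b >= 50, 4L, ifelse(b >= 45, 3L, ifelse(b >= 40, 2L, 1L)))
.age_band <- function(a) ifelse(a >= 50, 1L, ifelse(a >= 30, 2L, 3L))

# shared scorer. co: logical matrix with the eight canonical comorbidity
# columns; male, pe logical vectors.
.score_components <- function(age, bmi, male, pe, duration, co, instrument) {
  cr <- instrument$criteria
  needed <- c("comorbidity", "duration", "bmi", "age", "risk")
  if (!all(needed %in% names(cr)))
    stop("instrument is not BAPT-compatible (criteria ",
         paste(needed, collapse = "/"), " required)", call. = FALSE)
  co_pts <- cr$comorbidity$points[COMORBIDITIES]
  if (anyNA(co_pts))
    stop("instrument comorbidity criterion must cover the eight canonical conditions",
         call. = FALSE)
  comorbidity <- as.vector(co %*% co_pts)
  dur_p <- unname(cr$duration$points)[.dur_band(duration)]
  bmi_p <- unname(cr$bmi$points)[.bmi_band(bmi)]
  age_p <- unname(cr$age$points)[.age_band(age)]
  rf <- male + (age >= 45) + (bmi >= 50) + co[, "hypertension"] + pe
  risk_band <- ifelse(rf <= 1, 3L, ifelse(rf <= 3, 2L, 1L))
  risk_p <- unname(cr$risk$points)[risk_band]
  data.frame(comorbidity_points = comorbidity, duration_points = dur_p,
             bmi_points = bmi_p, age_points = age_p, risk_points = risk_p,
             risk_factor_count = as.integer(rf),
             total = comorbidity + dur_p + bmi_p + age_p + risk_p)
}

#' Eligibility screen for bariatric-surgery referral
#'
#' Inclusions: age 18-65, BMI > 35 kg/m2, poorly managed type 2 diabetes
#' (HbA1c > 7% despite treatment) and at least one potentially reversible
#' comorbidity. Exclusions: ASA class IV (incapacitating systemic disease that
#' is a constant threat to life) and any recorded contraindication flag.
#'
#' @param patients patient data.frame ([read_patients()] dialect).
#' @return data.frame with `patient_id`, `eligible` and `reasons`
#'   (semicolon-separated failed-rule identifiers, empty iff eligible).
#' @export
check_eligibility <- function(patients) {
  req <- c("age_years", "bmi", "hba1c_pct", "on_treatment", "asa_class")
  for (f in req)
    if (!(f %in% names(patients)) || anyNA(patients[[f]]))
      stop("eligibility check: missing required field '", f, "'", call. = FALSE)
  co <- .comorbidity_matrix(patients)
  if (anyNA(co)) stop("eligibility check: missing comorbidity flags", call. = FALSE)
  n <- nrow(patients)
  reasons <- vector("list", n)
  add <- function(cond, id) for (i in which(cond)) reasons[[i]] <<- c(reasons[[i]], id)
  add(patients$age_years < 18 | patients$age_years > 65, "age_outside_18_65")
  add(patients$bmi <= 35, "bmi_not_above_35")
  add(patients$hba1c_pct <= 7 | !patients$on_treatment, "glycaemia_not_above_7_despite_treatment")
  add(rowSums(co) < 1, "no_reversible_comorbidity")
  add(patients$asa_class == 4L, "asa_class_iv")
  add(nzchar(.contra_list(patients)), "contraindication_flag")
  data.frame(patient_id = patients$patient_id,
             eligible = lengths(reasons) == 0L,
             reasons = vapply(reasons, function(r) paste(r, collapse = ";"), character(1)))
}

#' Count surgical-risk factors
#'
#' The five factors: male sex, age 45+, BMI >= 50 kg/m2, hypertension, risk of
#' pulmonary embolism.
#'
#' @param patients patient data.frame.
#' @return integer vector in 0-5.
#' @export
count_risk_factors <- function(patients) {
  co <- .comorbidity_matrix(patients)
  as.integer((patients$sex == "male") + (patients$age_years >= 45) +
               (patients$bmi >= 50) + co[, "hypertension"] + patients$pe_risk)
}

#' Score patients with the BAPT
#'
#' Per-criterion breakdown and total: comorbidity sub-scores summed over
#' present conditions (max 30), duration/BMI/age category points, and surgical
#' risk points (20 for 0-1 factors, 10 for 2-3, 0 for 4-5). Hypertension and
#' age deliberately double-count (comorbidity + risk factor; age band + 45+
#' factor) — that is how the published instrument works.
#'
#' @param patients patient data.frame.
#' @param instrument a BAPT-compatible instrument (default canonical).
#' @param force score ineligible patients too (default FALSE: any ineligible
#'   row is an error carrying its failed rules).
#' @return data.frame: patient_id, eligibility columns, the five point
#'   components, risk_factor_count and total.
#' @export
score_patients <- function(patients, instrument = bapt_instrument(), force = FALSE) {
  elig <- check_eligibility(patients)
  if (!force && !all(elig$eligible)) {
    bad <- which(!elig$eligible)[1L]
    cond <- simpleError(paste0("patient '", patients$patient_id[bad],
                               "' is ineligible (", elig$reasons[bad],
                               "); use force = TRUE to score anyway"))
    cond$eligibility <- elig[!elig$eligible, , drop = FALSE]
    stop(cond)
  }
  br <- .score_components(age = patients$age_years, bmi = patients$bmi,
                          male = patients$sex == "male", pe = patients$pe_risk,
                          duration = patients$diabetes_duration_years,
                          co = .comorbidity_matrix(patients),
                          instrument = instrument)
  cbind(elig, br)
}

#' Classify diabetes remission at follow-up
#'
#' Remission: HbA1c strictly below 6.5% in the absence of glucose-lowering
#' medications (neither insulin nor oral agents) at 12 months.
#'
#' @param followup data.frame with `hba1c_pct_12m`, `on_insulin_12m`,
#'   `on_oral_meds_12m`.
#' @return logical vector; `NA` (indeterminate, excluded from denominators)
#'   where a required field is missing.
#' @export
classify_remission <- function(followup) {
  req <- c("hba1c_pct_12m", "on_insulin_12m", "on_oral_meds_12m")
  miss <- setdiff(req, names(followup))
  if (length(miss))
    stop("remission classification: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- followup$hba1c_pct_12m < 6.5 & !followup$on_insulin_12m & !followup$on_oral_meds_12m
  out[is.na(followup$hba1c_pct_12m) | is.na(followup$on_insulin_12m) |
        is.na(followup$on_oral_meds_12m)] <- NA  # indeterminate, not inferred
  n_ind <- sum(is.na(out))
  if (n_ind) message(n_ind, " record(s) indeterminate for remission (missing fields)")
  out
}
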