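# Seeded synthetic referral cohorts and 12-month outcomes. The generator
# emulates the marginal structure of the pilot cohort (n = 292: age 52 +/- 8.7,
# 57.1% female, BMI 46.1 +/- 7.0, HbA1c 8.77 +/- 1.5, hypertension 86.3%,
# dyslipidaemia 85.2%, sleep apnoea 66.0%) and the reported outcome trends:
# flat percent weight loss across scores, HbA1c improvement and oral-medication
# discontinuation increasing with score, insulin discontinuation flat.

#' Synthetic cohort configuration
#'
#' Defaults are the published cohort marginals and outcome anchors; see the
#' methods vignette for the provenance of every number.
#'
#' @param n cohort size.
#' @param seed integer seed; outcomes use `seed + 1`.
#' @param age_mean,age_sd,female_frac,bmi_mean,bmi_sd,hba1c_mean,hba1c_sd
#'   referral marginals (truncated to the eligibility window).
#' @param comorbidity_prevalence named probabilities for the eight conditions.
#' @param duration_mix probabilities for duration <4 / 4-8 / >8 years.
#' @param dur_age_coupling logit shift per age SD moving younger patients
#'   toward shorter duration (0 = independent).
#' @param htn_age_coupling logit shift per age SD for hypertension.
#' @param pe_prev,insulin_prev,oral_prev,indigenous_frac remaining marginals.
#' @param wl_mean,wl_sd percent weight loss at 12 months.
#' @param hba1c_impr_base,hba1c_impr_slope,hba1c_impr_sd percent HbA1c
#'   improvement as a linear function of BAPT score plus noise.
#' @param oral_logit_base,oral_logit_slope oral-medication discontinuation
#'   logit as a function of score.
#' @param insulin_discont_rate score-independent insulin discontinuation.
#' @param aqol_pre_mean,aqol_pre_sd baseline AQoL-4D utility.
#' @param aqol_change_lo,aqol_change_lo_sd,aqol_change_hi,aqol_change_hi_sd
#'   AQoL change for scores < 40 / >= 40.
#' @param aqol_split score splitting the AQoL change bands.
#' @param co_status_probs probabilities of unchanged/improved/resolved for
#'   each comorbidity present at referral.
#' @param ae_rate mean adverse events per patient (Poisson).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n = 292L, seed = 1L,
                         age_mean = 52, age_sd = 8.7, female_frac = 0.571,
                         bmi_mean = 46.1, bmi_sd = 7.0,
                         hba1c_mean = 8.77, hba1c_sd = 1.5,
                         comorbidity_prevalence = c(
                           hypertension = 0.863, dyslipidaemia = 0.852, osa = 0.660,
                           joint_pain = 0.555, nash = 0.123, albuminuria = 0.15,
                           renal_impairment = 0.075, reproductive_issues = 0.209),
                         duration_mix = c(lt4 = 0.116, m4to8 = 0.281, gt8 = 0.603),
                         dur_age_coupling = 1.2, htn_age_coupling = 0.3,
                         pe_prev = 0.10, insulin_prev = 0.64, oral_prev = 0.997,
                         indigenous_frac = 0.219,
                         wl_mean = 23, wl_sd = 9,
                         hba1c_impr_base = -5.8, hba1c_impr_slope = 0.696,
                         hba1c_impr_sd = 12,
                         oral_logit_base = -2.2, oral_logit_slope = 0.05,
                         insulin_discont_rate = 0.7,
                         aqol_pre_mean = 0.56, aqol_pre_sd = 0.23,
                         aqol_change_lo = 0.058, aqol_change_lo_sd = 0.277,
                         aqol_change_hi = 0.174, aqol_change_hi_sd = 0.235,
                         aqol_split = 40,
                         co_status_probs = c(unchanged = 0.20, improved = 0.45,
                                             resolved = 0.35),
                         ae_rate = 0.15) {
  cfg <- as.list(environment())
  stopifnot(cfg$n >= 0, cfg$age_sd > 0, cfg$bmi_sd > 0, cfg$hba1c_sd > 0,
            all(cfg$comorbidity_prevalence >= 0 & cfg$comorbidity_prevalence <= 1),
            abs(sum(cfg$duration_mix) - 1) < 1e-6)
  structure(cfg, class = "synth_config")
}

# truncated normal by batched rejection; errors (rather than silently
# resampling forever) when the window mass is negligible
.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf, what = "draw") {
  if (n == 0L) return(numeric(0))
  mass <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  if (mass < 1e-6)
    stop("unsatisfiable synthetic config: truncation window [", lo, ", ", hi,
         "] retains ~no mass for ", what, " ~ N(", mean, ", ", sd, ")", call. = FALSE)
  out <- numeric(0); tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 1000L) stop("truncated sampling failed for ", what, call. = FALSE)
    x <- rnorm(max(n, ceiling((n - length(out)) / mass * 1.2)), mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

.plogis <- function(x) 1 / (1 + exp(-x))
.qlogis <- function(p) log(p / (1 - p))

#' Generate a synthetic referral cohort
#'
#' Draws `cfg$n` records that always pass [check_eligibility()]: continuous
#' variables are truncated to the eligibility windows (age 18-65, BMI > 35,
#' HbA1c > 7 on treatment) and at least one comorbidity is guaranteed
#' (dyslipidaemia is switched on for the rare all-negative draw, with a
#' message). Hypertension is mildly positively coupled to age and diabetes
#' duration negatively coupled to youth, mirroring the pilot cohort gradients;
#' both couplings are configurable. Deterministic under `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return patient data.frame in the [read_patients()] CSV dialect (plus an
#'   `indigenous` passthrough column).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- as.integer(cfg$n)
  if (n == 0L) return(data.frame())
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  age <- .rtrunc_norm(n, cfg$age_mean, cfg$age_sd, 18, 65, "age")
  z_age <- (age - cfg$age_mean) / cfg$age_sd
  female <- runif(n) < cfg$female_frac
  height <- round(.rtrunc_norm(n, 1.66, 0.08, 1.45, 2.05, "height") +
                    ifelse(female, 0, 0.12), 2)
  bmi <- round(.rtrunc_norm(n, cfg$bmi_mean, cfg$bmi_sd, 35.05, 80, "bmi"), 1)
  weight <- round(bmi * height^2, 1)
  hba1c <- round(.rtrunc_norm(n, cfg$hba1c_mean, cfg$hba1c_sd, 7.05, 18, "hba1c"), 2)

  prev <- cfg$comorbidity_prevalence
  co <- matrix(FALSE, n, 8, dimnames = list(NULL, COMORBIDITIES))
  for (cm in COMORBIDITIES) {
    p <- unname(prev[cm])
    if (cm == "hypertension")
      p <- .plogis(.qlogis(p) + cfg$htn_age_coupling * z_age)
    co[, cm] <- runif(n) < p
  }
  none <- rowSums(co) == 0L
  if (any(none)) {
    message(sum(none), " record(s) drew no comorbidity; dyslipidaemia forced on")
    co[none, "dyslipidaemia"] <- TRUE
  }

  # duration category: multinomial with logits shifted so younger patients
  # lean toward shorter duration
  lm <- log(cfg$duration_mix)
  sh <- cfg$dur_age_coupling * z_age
  logits <- cbind(lm[1] - sh, lm[2], lm[3] + sh)
  pr <- exp(logits) / rowSums(exp(logits))
  u <- runif(n)
  cat3 <- 1L + (u > pr[, 1]) + (u > pr[, 1] + pr[, 2])
  duration <- round(c(0.5, 4, 8.01)[cat3] + runif(n) * c(3.5, 4, 12)[cat3], 1)

  on_insulin <- runif(n) < .plogis(.qlogis(cfg$insulin_prev) + 0.6 * (duration - 8) / 5)
  on_oral <- runif(n) < cfg$oral_prev
  neither <- !(on_insulin | on_oral)
  on_oral[neither] <- TRUE  # treated despite poor control, per eligibility

  df <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age_years = round(age, 1), sex = ifelse(female, "female", "male"),
    weight_kg = weight, height_m = height, bmi = bmi, hba1c_pct = hba1c,
    on_treatment = TRUE, diabetes_duration_years = duration,
    on_insulin = on_insulin, on_oral_meds = on_oral)
  for (cm in COMORBIDITIES) df[[CO_COLS[cm]]] <- co[, cm]
  df$pe_risk <- runif(n) < cfg$pe_prev
  df$asa_class <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  df$indigenous <- runif(n) < cfg$indigenous_frac
  validate_patients(df)
}

#' Generate 12-month outcomes for a cohort
#'
#' Percent weight loss is drawn independently of the BAPT score; percent HbA1c
#' improvement is linear in score plus noise; oral-medication discontinuation
#' is Bernoulli with a logit linear in score; insulin discontinuation is
#' score-independent; AQoL-4D change has a larger mean above `cfg$aqol_split`.
#' Deterministic under `cfg$seed + 1`.
#'
#' @param cohort referral data.frame from [generate_cohort()].
#' @param cfg the [synth_config()].
#' @param scores optional precomputed BAPT totals (defaults to
#'   [score_patients()] on the cohort).
#' @return data.frame of follow-up fields keyed by `patient_id`.
#' @export
generate_outcomes <- function(cohort, cfg = synth_config(), scores = NULL) {
  n <- nrow(cohort)
  if (is.null(scores)) scores <- score_patients(cohort, force = TRUE)$total
  stopifnot(length(scores) == n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)

  wl <- if (cfg$wl_sd > 0) .rtrunc_norm(n, cfg$wl_mean, cfg$wl_sd, 0, 60, "weight loss")
        else rep(cfg$wl_mean, n)
  impr <- cfg$hba1c_impr_base + cfg$hba1c_impr_slope * scores +
    (if (cfg$hba1c_impr_sd > 0) rnorm(n, 0, cfg$hba1c_impr_sd) else 0)
  impr <- pmin(pmax(impr, -10), 80)
  oral_disc <- runif(n) < .plogis(cfg$oral_logit_base + cfg$oral_logit_slope * scores)
  ins_disc <- runif(n) < cfg$insulin_discont_rate
  aqol_pre <- pmin(pmax(.rtrunc_norm(n, cfg$aqol_pre_mean, cfg$aqol_pre_sd, 0, 1,
                                     "aqol baseline"), 0), 1)
  hi <- scores >= cfg$aqol_split
  chg <- ifelse(hi, rnorm(n, cfg$aqol_change_hi, cfg$aqol_change_hi_sd),
                rnorm(n, cfg$aqol_change_lo, cfg$aqol_change_lo_sd))

  out <- data.frame(
    patient_id = cohort$patient_id, months = 12L,
    weight_kg_12m = round(cohort$weight_kg * (1 - wl / 100), 1),
    hba1c_pct_12m = round(pmax(4.5, cohort$hba1c_pct * (1 - impr / 100)), 2),
    on_insulin_12m = cohort$on_insulin & !ins_disc,
    on_oral_meds_12m = cohort$on_oral_meds & !oral_disc,
    aqol_pre = round(aqol_pre, 3),
    aqol_12m = round(pmin(pmax(aqol_pre + chg, 0), 1), 3))

  co <- .comorbidity_matrix(cohort)
  pst <- cfg$co_status_probs / sum(cfg$co_status_probs)
  for (cm in COMORBIDITIES) {
    u <- runif(n)
    status <- ifelse(u < pst[1], "u", ifelse(u < pst[1] + pst[2], "i", "r"))
    out[[paste0(CO_COLS[cm], "_12m")]] <- ifelse(co[, cm], status, "")
  }
  n_ae <- rpois(n, cfg$ae_rate)
  labels <- c("readmission_28d", "nausea_vomiting", "wound_infection", "other")
  out$ae_list <- vapply(n_ae, function(k)
    paste(sample(labels, k, replace = TRUE, prob = c(0.45, 0.25, 0.15, 0.15)),
          collapse = ";"), character(1))
  out
}

#' Generate a full synthetic cohort with follow-up, merged
#'
#' @param cfg a [synth_config()].
#' @return referral + follow-up columns in one data.frame, plus `score`.
#' @export
simulate_cohort <- function(cfg = synth_config()) {
  cohort <- generate_cohort(cfg)
  if (!nrow(cohort)) return(cohort)
  scores <- score_patients(cohort)$total
  fu <- generate_outcomes(cohort, cfg, scores = scores)
  out <- merge(cohort, fu, by = "patient_id", sort = FALSE)
  out$score <- scores
  out
}
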