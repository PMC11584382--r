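# Shared fixtures, all built in code.

# tiny instruments for elicitation / LP tests
two_binary <- function()
  new_instrument(list(
    criterion_spec("x", c("x0", "x1"), points = c(0, 60)),
    criterion_spec("y", c("y0", "y1"), points = c(0, 40))), name = "two_binary")

three_binary <- function()
  new_instrument(list(
    criterion_spec("x", c("x0", "x1"), points = c(0, 50)),
    criterion_spec("y", c("y0", "y1"), points = c(0, 30)),
    criterion_spec("z", c("z0", "z1"), points = c(0, 20))), name = "three_binary")

small_mixed <- function()  # 3 x 2 x 3 = 18 states
  new_instrument(list(
    criterion_spec("a", c("a0", "a1", "a2"), points = c(0, 5, 10)),
    criterion_spec("b", c("b0", "b1"), points = c(0, 7)),
    criterion_spec("c", c("c0", "c1", "c2"), points = c(0, 2, 4))), name = "small_mixed")

weights_from_points <- function(instrument, respondent = "truth") {
  vals <- lapply(instrument$criteria, function(cr) {
    v <- unname(cr$points)
    if (cr$mode == "additive_subscore") v <- cumsum(v)  # not used in tests
    v
  })
  structure(list(respondent_id = respondent, values = vals, margin = NA_real_),
            class = "level_weights")
}

# one fully specified eligible patient row; override fields via ...
patient_row <- function(patient_id = "P1", age_years = 50, sex = "female",
                        bmi = 40, weight_kg = NA, height_m = NA,
                        hba1c_pct = 8.5, on_treatment = 1,
                        diabetes_duration_years = 10, on_insulin = 0,
                        on_oral_meds = 1, co_htn = 1, co_dyslip = 0, co_nash = 0,
                        co_albuminuria = 0, co_joint = 0, co_repro = 0,
                        co_renal = 0, co_osa = 0, pe_risk = 0, asa_class = 2) {
  data.frame(patient_id = patient_id, age_years = age_years, sex = sex,
             weight_kg = weight_kg, height_m = height_m, bmi = bmi,
             hba1c_pct = hba1c_pct, on_treatment = on_treatment,
             diabetes_duration_years = diabetes_duration_years,
             on_insulin = on_insulin, on_oral_meds = on_oral_meds,
             co_htn = co_htn, co_dyslip = co_dyslip, co_nash = co_nash,
             co_albuminuria = co_albuminuria, co_joint = co_joint,
             co_repro = co_repro, co_renal = co_renal, co_osa = co_osa,
             pe_risk = pe_risk, asa_class = asa_class)
}

patients_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, rows)
  validate_patients(df)
}

# comorbidity means of the published elicitation, named
reference_comorbidity_means <- function() {
  ref <- bapt_reference_weights()
  ref <- ref[ref$criterion == "comorbidity" & ref$level != "minimal_impact", ]
  setNames(ref$mean, ref$level)
}
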