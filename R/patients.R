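# Patient tables. A patient record is one row of a data.frame in the CSV
# dialect documented in read_patients(); follow-up fields live in *_12m columns
# of the same table (or a separate table joined on patient_id).

CO_COLS <- c(hypertension = "co_htn", dyslipidaemia = "co_dyslip", nash = "co_nash",
             albuminuria = "co_albuminuria", joint_pain = "co_joint",
             reproductive_issues = "co_repro", renal_impairment = "co_renal",
             osa = "co_osa")

REQUIRED_PATIENT_COLS <- c("patient_id", "age_years", "sex", "hba1c_pct",
                           "on_treatment", "diabetes_duration_years", "on_insulin",
                           "on_oral_meds", unname(CO_COLS), "pe_risk", "asa_class")

.num_col <- function(df, col, rows_label = "row") {
  x <- df[[col]]
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(as.character(x)))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad))
    stop("column '", col, "': unparseable numeric value '", x[bad[1]],
         "' at row ", bad[1], call. = FALSE)
  out
}

.flag_col <- function(df, col) {
  if (is.logical(df[[col]])) return(df[[col]])
  x <- .num_col(df, col)
  if (any(!is.na(x) & !(x %in% c(0, 1))))
    stop("column '", col, "': flags must be 0/1", call. = FALSE)
  x == 1
}

#' Read a referral patient table
#'
#' CSV, UTF-8, header row. Required columns: `patient_id`, `age_years`, `sex`
#' (male/female), `weight_kg` + `height_m` and/or `bmi`, `hba1c_pct`,
#' `on_treatment`, `diabetes_duration_years`, `on_insulin`, `on_oral_meds`, the
#' eight comorbidity flags `co_htn`, `co_dyslip`, `co_nash`, `co_albuminuria`,
#' `co_joint`, `co_repro`, `co_renal`, `co_osa`, `pe_risk`, `asa_class`. Flags
#' are 0/1. Optional: `contraindications` (semicolon-separated rule ids) and
#' any extra columns, which are preserved untouched. Follow-up data may be
#' present as `weight_kg_12m`, `hba1c_pct_12m`, `on_insulin_12m`,
#' `on_oral_meds_12m`, `aqol_pre`, `aqol_12m`, `co_*_12m` status columns
#' (u/i/r) and `ae_list`.
#'
#' BMI is derived from weight and height when absent; when both BMI and
#' anthropometrics are given they must agree to 0.1. Age must be positive and
#' HbA1c strictly inside (3, 20)%.
#'
#' @param path CSV file.
#' @return data.frame, one row per patient.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("patient table not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    warning("empty patient table: ", path)
    return(df)
  }
  validate_patients(df)
}

#' Validate (and complete) a patient table held in memory
#' @param df data.frame in the [read_patients()] dialect.
#' @return the validated data.frame with `bmi` filled in.
#' @export
validate_patients <- function(df) {
  have_anthro <- all(c("weight_kg", "height_m") %in% names(df))
  if (!("bmi" %in% names(df)) && !have_anthro)
    stop("missing required column(s): bmi (or weight_kg + height_m)", call. = FALSE)
  missing_cols <- setdiff(REQUIRED_PATIENT_COLS, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  for (col in intersect(c("age_years", "weight_kg", "height_m", "bmi", "hba1c_pct",
                          "diabetes_duration_years"), names(df)))
    df[[col]] <- .num_col(df, col)
  for (col in c("on_treatment", "on_insulin", "on_oral_meds", unname(CO_COLS), "pe_risk"))
    df[[col]] <- .flag_col(df, col)
  df$asa_class <- as.integer(.num_col(df, "asa_class"))
  if (any(!is.na(df$asa_class) & !(df$asa_class %in% 1:4)))
    stop("asa_class must be an integer 1-4", call. = FALSE)

  derived <- if (have_anthro) df$weight_kg / df$height_m^2 else rep(NA_real_, nrow(df))
  if (!("bmi" %in% names(df))) df$bmi <- NA_real_
  use_derived <- is.na(df$bmi) & !is.na(derived)
  df$bmi[use_derived] <- round(derived[use_derived], 1)
  both <- !is.na(df$bmi) & !is.na(derived)
  # printed BMI is conventionally 1 dp, so compare at that resolution
  if (any(both & abs(df$bmi - round(derived, 1)) > 0.1 + 1e-9)) {
    bad <- which(both & abs(df$bmi - round(derived, 1)) > 0.1 + 1e-9)[1]
    stop("row ", bad, ": bmi ", df$bmi[bad], " disagrees with weight/height (",
         round(derived[bad], 1), ")", call. = FALSE)
  }
  if (any(is.na(df$bmi)))
    stop("row ", which(is.na(df$bmi))[1], ": no bmi and no weight/height", call. = FALSE)

  if (any(!is.na(df$age_years) & df$age_years <= 0))
    stop("age_years must be positive", call. = FALSE)
  if (any(!is.na(df$hba1c_pct) & (df$hba1c_pct <= 3 | df$hba1c_pct >= 20)))
    stop("hba1c_pct out of plausible range (3, 20)", call. = FALSE)
  bad_sex <- !(df$sex %in% c("male", "female"))
  if (any(bad_sex))
    stop("row ", which(bad_sex)[1], ": sex must be 'male' or 'female'", call. = FALSE)
  df
}

#' Write a patient table
#' @param df patient data.frame.
#' @param path output CSV.
#' @export
write_patients <- function(df, path) {
  out <- df
  for (col in names(out)) if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# comorbidity presence matrix (rows = patients, cols = canonical names)
.comorbidity_matrix <- function(df) {
  m <- sapply(CO_COLS, function(col) as.logical(df[[col]]))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df), dimnames = list(NULL, names(CO_COLS)))
  colnames(m) <- names(CO_COLS)
  m
}

.contra_list <- function(df) {
  if (!("contraindications" %in% names(df))) return(rep("", nrow(df)))
  x <- as.character(df$contraindications)
  x[is.na(x)] <- ""
  x
}
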