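# Evaluation pipeline: score-bin stratification with chi-square / one-way
# ANOVA, age and BMI cut-point comparisons, diabetes-remission rates, and
# AQoL-4D utility change against the minimum important difference. All
# functions are pure functions of the input table.

#' Percentage change from baseline
#'
#' `100 * (baseline - followup) / baseline`: positive for a decrease
#' (weight, BMI, HbA1c improvements are all reported this way).
#'
#' @param baseline,followup numeric vectors; baseline must be positive.
#' @export
pct_change <- function(baseline, followup) {
  if (any(!is.na(baseline) & baseline <= 0))
    stop("pct_change: baseline must be positive", call. = FALSE)
  100 * (baseline - followup) / baseline
}

DEFAULT_BINS <- data.frame(lo = seq(10, 70, 10), hi = seq(19, 79, 10))

.bin_label <- function(bins) paste0(bins$lo, "-", bins$hi)

# integer-inclusive bin membership; NA for unbinned scores
.bin_of <- function(score, bins) {
  idx <- rep(NA_integer_, length(score))
  for (i in seq_len(nrow(bins)))
    idx[score >= bins$lo[i] & score <= bins$hi[i]] <- i
  idx
}

.mean_sd <- function(x) c(mean = mean(x, na.rm = TRUE),
                          sd = if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) else 0)

# classic one-way ANOVA (equal-variance F test) across bin labels
.anova_p <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  g <- factor(g[ok]); x <- x[ok]
  if (nlevels(droplevels(g)) < 2L) return(c(statistic = NA_real_, p = NA_real_))
  fit <- anova(aov(x ~ droplevels(g)))
  c(statistic = fit$`F value`[1L], p = fit$`Pr(>F)`[1L])
}

.chisq_p <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  tab <- table(g[ok], x[ok])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(c(statistic = NA_real_, p = NA_real_))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  c(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Stratify a cohort by BAPT score bins
#'
#' Per-bin descriptives (mean ± SD for interval variables, proportions for
#' categorical ones) with a one-way ANOVA across bins for means and a
#' chi-square test for categorical variables. When 12-month columns are
#' present, per-bin percent weight loss, percent HbA1c improvement,
#' oral-medication discontinuation and remission are included.
#'
#' @param cohort data.frame in the [read_patients()] dialect (optionally with
#'   follow-up columns and/or a `score` column; scores are computed with
#'   [score_patients()] `force = TRUE` when absent).
#' @param instrument instrument used if scores must be computed.
#' @param bins data.frame with `lo`, `hi` integer columns (default the
#'   published 10-19 ... 70-79 layout). Membership is inclusive of both ends;
#'   out-of-range scores are counted in `n_unbinned`.
#' @return list of class `strata_table`: `bins` (per-bin stats; empty bins
#'   carry `n = 0` and NA descriptives), `tests` (variable, statistic, p),
#'   `n_unbinned`.
#' @export
stratify <- function(cohort, instrument = bapt_instrument(), bins = DEFAULT_BINS) {
  score <- if ("score" %in% names(cohort)) cohort$score
           else score_patients(cohort, instrument, force = TRUE)$total
  bi <- .bin_of(score, bins)
  n_unbinned <- sum(is.na(bi))
  if (n_unbinned) warning(n_unbinned, " score(s) fall outside the bin layout")
  lab <- .bin_label(bins)
  g <- factor(lab[bi], levels = lab)

  co <- .comorbidity_matrix(cohort)
  dcat <- .dur_band(cohort$diabetes_duration_years)  # 3 = <4y, 2 = 4-8, 1 = >8
  cont <- list(age = cohort$age_years, weight = cohort$weight_kg,
               bmi = cohort$bmi, hba1c = cohort$hba1c_pct)
  catg <- c(list(female = cohort$sex == "female", insulin = cohort$on_insulin,
                 oral_meds = cohort$on_oral_meds,
                 dur_lt4 = dcat == 3L, dur_4to8 = dcat == 2L, dur_gt8 = dcat == 1L),
            setNames(lapply(COMORBIDITIES, function(cm) co[, cm]), COMORBIDITIES))

  has_fu <- all(c("weight_kg_12m", "hba1c_pct_12m", "on_oral_meds_12m",
                  "on_insulin_12m") %in% names(cohort))
  if (has_fu) {
    cont$pct_weight_loss <- pct_change(cohort$weight_kg, cohort$weight_kg_12m)
    cont$pct_hba1c_improvement <- pct_change(cohort$hba1c_pct, cohort$hba1c_pct_12m)
    catg$oral_discontinued <- cohort$on_oral_meds & !cohort$on_oral_meds_12m
    catg$remission <- classify_remission(cohort)
  }

  per_bin <- data.frame(bin = lab, n = as.vector(table(g)))
  for (nm in names(cont)) {
    ms <- t(vapply(lab, function(l) {
      x <- cont[[nm]][!is.na(g) & g == l]
      if (!length(x)) c(mean = NA_real_, sd = NA_real_) else .mean_sd(x)
    }, numeric(2)))
    per_bin[[paste0(nm, "_mean")]] <- ms[, 1]
    per_bin[[paste0(nm, "_sd")]] <- ms[, 2]
  }
  for (nm in names(catg))
    per_bin[[paste0(nm, "_prop")]] <- vapply(lab, function(l) {
      x <- catg[[nm]][!is.na(g) & g == l]
      if (!length(x)) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))

  tests <- rbind(
    do.call(rbind, lapply(names(cont), function(nm) {
      r <- .anova_p(cont[[nm]], g)
      data.frame(variable = nm, test = "anova", statistic = r[1], p = r[2])
    })),
    do.call(rbind, lapply(names(catg), function(nm) {
      r <- .chisq_p(catg[[nm]], g)
      data.frame(variable = nm, test = "chisq", statistic = r[1], p = r[2])
    })))
  rownames(tests) <- NULL
  structure(list(bins = per_bin, tests = tests, n_unbinned = n_unbinned),
            class = "strata_table")
}

#' @export
print.strata_table <- function(x, ...) {
  cat("<strata_table> ", sum(x$bins$n), " patients in ", nrow(x$bins), " bins (",
      x$n_unbinned, " unbinned)\n", sep = "")
  print(x$bins[, c("bin", "n")], row.names = FALSE)
  invisible(x)
}

#' Two-group outcome comparison at age / BMI cut-points
#'
#' For each cutoff `c`, patients are split into `[min, c)` vs `[c, Inf)`
#' (e.g. 18-49 vs 50 and over) and compared on percent BMI decrease, percent
#' HbA1c improvement (Welch t-tests) and the proportion off all diabetes
#' medications at 12 months (chi-square without continuity correction).
#'
#' @param cohort data.frame with referral and 12-month columns.
#' @param variable `"age"` or `"bmi"`.
#' @param cutoffs numeric cut-points (defaults: 50/55/60 for age, 40/45/50
#'   for BMI).
#' @return data.frame, one row per cutoff; groups with fewer than 2 patients
#'   get NA p-values and `tested = FALSE`.
#' @export
cutpoint_analysis <- function(cohort, variable = c("age", "bmi"), cutoffs = NULL) {
  variable <- match.arg(variable)
  if (is.null(cutoffs)) cutoffs <- if (variable == "age") c(50, 55, 60) else c(40, 45, 50)
  x <- if (variable == "age") cohort$age_years else cohort$bmi
  bmi_dec <- pct_change(cohort$weight_kg, cohort$weight_kg_12m)
  hb_impr <- pct_change(cohort$hba1c_pct, cohort$hba1c_pct_12m)
  no_meds <- !cohort$on_insulin_12m & !cohort$on_oral_meds_12m

  one <- function(cut) {
    hi <- x >= cut
    n_lo <- sum(!hi); n_hi <- sum(hi)
    tested <- n_lo >= 2L && n_hi >= 2L
    tt <- function(y) if (!tested) NA_real_ else
      tryCatch(t.test(y[hi], y[!hi])$p.value, error = function(e) NA_real_)
    pchi <- if (!tested) NA_real_ else
      .chisq_p(no_meds, hi)["p"]
    data.frame(
      variable = variable, cutoff = cut, n_below = n_lo, n_above = n_hi,
      bmi_dec_below_mean = mean(bmi_dec[!hi]), bmi_dec_below_sd = sd(bmi_dec[!hi]),
      bmi_dec_above_mean = mean(bmi_dec[hi]), bmi_dec_above_sd = sd(bmi_dec[hi]),
      hba1c_impr_below_mean = mean(hb_impr[!hi]), hba1c_impr_below_sd = sd(hb_impr[!hi]),
      hba1c_impr_above_mean = mean(hb_impr[hi]), hba1c_impr_above_sd = sd(hb_impr[hi]),
      no_meds_below_n = sum(no_meds[!hi]), no_meds_below_pct = 100 * mean(no_meds[!hi]),
      no_meds_above_n = sum(no_meds[hi]), no_meds_above_pct = 100 * mean(no_meds[hi]),
      p_bmi_dec = tt(bmi_dec), p_hba1c_impr = tt(hb_impr),
      p_no_meds = unname(pchi), tested = tested)
  }
  out <- do.call(rbind, lapply(cutoffs, one))
  rownames(out) <- NULL
  out
}

#' Diabetes remission proportions above/below a score threshold
#'
#' @param cohort data.frame with 12-month columns and a `score` column (or
#'   scorable referral fields).
#' @param threshold score threshold (default 50, as in the pilot analysis).
#' @param instrument instrument used if scores must be computed.
#' @return list with `overall`, `above`, `below` proportions, counts, and the
#'   number of indeterminate records excluded.
#' @export
remission_report <- function(cohort, threshold = 50, instrument = bapt_instrument()) {
  score <- if ("score" %in% names(cohort)) cohort$score
           else score_patients(cohort, instrument, force = TRUE)$total
  rem <- classify_remission(cohort)
  ok <- !is.na(rem)
  if (!any(ok)) stop("no classifiable records for remission", call. = FALSE)
  prop <- function(sel) {
    k <- sum(rem[sel & ok]); m <- sum(sel & ok)
    list(n = m, remitted = k, proportion = if (m) k / m else NA_real_)
  }
  list(overall = prop(rep(TRUE, length(rem))),
       above = prop(score >= threshold), below = prop(score < threshold),
       threshold = threshold, n_indeterminate = sum(!ok))
}

#' AQoL-4D utility change by score group
#'
#' Change = 12-month utility minus baseline; groups split at `split_score`
#' (default 40). `mid_met` uses the >= 0.06 convention for the minimum
#' important difference; groups are compared by Welch t-test.
#'
#' @param cohort data.frame with `aqol_pre`, `aqol_12m` and scores.
#' @param split_score score splitting low/high groups.
#' @param mid minimum important difference (0.06).
#' @param instrument instrument used if scores must be computed.
#' @return list with per-group n/pre-mean/change mean ± sd/`mid_met`, the
#'   Welch p-value and the number of records excluded for missing utilities.
#' @export
aqol_summary <- function(cohort, split_score = 40, mid = 0.06,
                         instrument = bapt_instrument()) {
  if (!all(c("aqol_pre", "aqol_12m") %in% names(cohort)))
    stop("aqol_summary: aqol_pre / aqol_12m columns required", call. = FALSE)
  score <- if ("score" %in% names(cohort)) cohort$score
           else score_patients(cohort, instrument, force = TRUE)$total
  ok <- !is.na(cohort$aqol_pre) & !is.na(cohort$aqol_12m)
  chg <- cohort$aqol_12m - cohort$aqol_pre
  grp <- function(sel) {
    sel <- sel & ok
    list(n = sum(sel), pre_mean = mean(cohort$aqol_pre[sel]),
         change_mean = mean(chg[sel]), change_sd = sd(chg[sel]),
         mid_met = isTRUE(mean(chg[sel]) >= mid))
  }
  lo <- grp(score < split_score); hi <- grp(score >= split_score)
  p <- if (lo$n >= 2 && hi$n >= 2)
    tryCatch(t.test(chg[ok & score >= split_score],
                    chg[ok & score < split_score])$p.value,
             error = function(e) NA_real_)  # e.g. constant data
  else NA_real_
  list(low = lo, high = hi, split_score = split_score, mid = mid, p = p,
       n_excluded = sum(!ok))
}

#' Run the full evaluation report over a cohort table
#'
#' Writes `strata.csv`, `cutpoints.csv`, `remission.json`, `aqol.json` and a
#' plain-text `summary.txt` into `out_dir`.
#'
#' @param cohort merged referral + follow-up data.frame.
#' @param out_dir output directory (created if needed).
#' @param instrument scoring instrument.
#' @return invisibly, the list of computed results.
#' @export
analyze_cohort <- function(cohort, out_dir, instrument = bapt_instrument()) {
  if (!("score" %in% names(cohort)))
    cohort$score <- score_patients(cohort, instrument, force = TRUE)$total
  strata <- stratify(cohort, instrument)
  cuts <- rbind(cutpoint_analysis(cohort, "age"), cutpoint_analysis(cohort, "bmi"))
  rem <- remission_report(cohort, instrument = instrument)
  aq <- aqol_summary(cohort, instrument = instrument)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(strata$bins, file.path(out_dir, "strata.csv"), row.names = FALSE)
  write.csv(cuts, file.path(out_dir, "cutpoints.csv"), row.names = FALSE)
  jsonlite::write_json(rem, file.path(out_dir, "remission.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(aq, file.path(out_dir, "aqol.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- c(
    sprintf("n = %d patients; scores %d-%d", nrow(cohort), min(cohort$score),
            max(cohort$score)),
    sprintf("remission overall %.1f%% (>=%d: %.1f%% vs <%d: %.1f%%)",
            100 * rem$overall$proportion, rem$threshold, 100 * rem$above$proportion,
            rem$threshold, 100 * rem$below$proportion),
    sprintf("AQoL change: <%d %.3f vs >=%d %.3f (MID met: %s/%s; p = %.3f)",
            aq$split_score, aq$low$change_mean, aq$split_score, aq$high$change_mean,
            aq$low$mid_met, aq$high$mid_met, aq$p))
  writeLines(txt, file.path(out_dir, "summary.txt"))
  invisible(list(strata = strata, cutpoints = cuts, remission = rem, aqol = aq))
}
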