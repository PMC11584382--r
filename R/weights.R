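# Level-weight derivation from pairwise judgements (max-margin LP), weight
# aggregation across respondents, the comorbidity rescaling that turns the
# nine-level elicitation attribute into additive per-condition sub-scores, and
# the brute-force score-range check.

#' Derive additive level weights from one respondent's judgements
#'
#' Solves the max-margin linear programme: variables `v[c][l] >= 0` (one per
#' level, worst fixed at 0, non-decreasing within each criterion — level order
#' is an instrument assumption, so monotonicity is non-strict); each strict
#' judgement `a > b` contributes `sum v(a) >= sum v(b) + delta`, each
#' indifference an equality; the best levels are normalised to sum to 100; the
#' shared margin `delta` is maximised, then ties among optima are resolved by
#' minimising `sum v` (smallest representation) at the optimal margin.
#'
#' @param judgements a `preference_store`, a [run_session()] result, or a list
#'   of judgements (`a`, `b` 0-based level vectors, `verdict` `"a_preferred"`
#'   or `"indifferent"`).
#' @param instrument a `bapt_instrument`.
#' @return A `level_weights` object: `respondent_id`, `values` (named list,
#'   one non-decreasing numeric vector per criterion, worst first), `margin`
#'   (the achieved delta; > 0 for a consistent respondent, 0 when no strict
#'   judgement was supplied).
#' @export
derive_level_weights <- function(judgements, instrument) {
  if (inherits(judgements, "preference_store")) judgements <- judgements$judgements
  if (is.list(judgements) && !is.null(judgements$store))
    judgements <- judgements$store$judgements
  nl <- .n_levels(instrument)
  k <- length(nl)
  # variable layout: v[j][l] for l = 2..nl[j] (worst level eliminated at 0)
  off <- c(0L, cumsum(nl - 1L))
  nv <- off[k + 1L]
  vix <- function(j, l) off[j] + l - 1L   # l is 1-based level, l >= 2
  coef_state <- function(lev) {
    z <- numeric(nv)
    for (j in seq_len(k)) if (lev[j] > 0L) z[vix(j, lev[j] + 1L)] <- z[vix(j, lev[j] + 1L)] + 1
    z
  }
  strict <- Filter(function(j) j$verdict != "indifferent", judgements)
  indiff <- Filter(function(j) j$verdict == "indifferent", judgements)
  has_delta <- length(strict) > 0L
  ncol_tot <- nv + if (has_delta) 2L else 0L  # delta = dplus - dminus (free)

  rows <- list(); rhs <- numeric(0); dir <- character(0)
  add_row <- function(z, d, r) {
    rows[[length(rows) + 1L]] <<- z; dir <<- c(dir, d); rhs <<- c(rhs, r)
  }
  for (j in strict) {
    z <- numeric(ncol_tot)
    z[seq_len(nv)] <- coef_state(j$a) - coef_state(j$b)
    z[nv + 1L] <- -1; z[nv + 2L] <- 1
    add_row(z, ">=", 0)
  }
  for (j in indiff) {
    z <- numeric(ncol_tot)
    z[seq_len(nv)] <- coef_state(j$a) - coef_state(j$b)
    add_row(z, "==", 0)
  }
  for (j in seq_len(k)) for (l in seq_len(nl[j] - 2L) + 1L) {  # v[l+1] >= v[l]
    z <- numeric(ncol_tot)
    z[vix(j, l + 1L)] <- 1; z[vix(j, l)] <- -1
    add_row(z, ">=", 0)
  }
  z <- numeric(ncol_tot)
  for (j in seq_len(k)) z[vix(j, nl[j])] <- 1
  add_row(z, "==", 100)

  A <- do.call(rbind, rows)
  margin <- 0
  if (has_delta) {
    obj1 <- numeric(ncol_tot); obj1[nv + 1L] <- -1; obj1[nv + 2L] <- 1  # max delta
    s1 <- simplex_lp(obj1, A, rhs, dir)
    if (s1$status != "optimal")
      stop("internal error: margin LP ", s1$status, call. = FALSE)
    margin <- -s1$objval
    if (margin <= 1e-7)
      stop("inconsistent judgements: no additive weights can satisfy all strict ",
           "preferences with positive margin (max margin = ",
           format(margin, digits = 3), ")", call. = FALSE)
    z <- numeric(ncol_tot); z[nv + 1L] <- 1; z[nv + 2L] <- -1
    A <- rbind(A, z); rhs <- c(rhs, margin); dir <- c(dir, "==")
  }
  obj2 <- c(rep(1, nv), numeric(ncol_tot - nv))  # smallest representation
  s2 <- simplex_lp(obj2, A, rhs, dir)
  if (s2$status != "optimal")
    stop("internal error: secondary LP ", s2$status, call. = FALSE)

  vals <- lapply(seq_len(k), function(j) c(0, s2$x[off[j] + seq_len(nl[j] - 1L)]))
  names(vals) <- names(instrument$criteria)
  w <- structure(list(
    respondent_id = if (length(judgements)) judgements[[1L]]$respondent else "none",
    values = vals, margin = margin), class = "level_weights")
  .verify_weights(w, strict, indiff, margin)
  w
}

# post-solve check: every recorded judgement satisfied with slack >= margin
# (strict) or exactly (indifference)
.verify_weights <- function(w, strict, indiff, margin, tol = 1e-6) {
  tot <- function(lev) sum(vapply(seq_along(lev), function(j)
    w$values[[j]][lev[j] + 1L], numeric(1)))
  for (j in strict)
    if (tot(j$a) - tot(j$b) < margin - tol)
      stop("internal error: derived weights violate a strict judgement", call. = FALSE)
  for (j in indiff)
    if (abs(tot(j$a) - tot(j$b)) > tol)
      stop("internal error: derived weights violate an indifference", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.level_weights <- function(x, ...) {
  cat("<level_weights> respondent ", x$respondent_id, ", margin ",
      format(x$margin, digits = 4), "\n", sep = "")
  for (nm in names(x$values))
    cat("  ", nm, ": ", paste(round(x$values[[nm]], 2), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Total additive value of states under level weights
#' @param weights a `level_weights` object.
#' @param states integer state matrix from [enumerate_states()].
#' @return numeric vector of totals.
#' @export
state_totals <- function(weights, states) {
  tot <- numeric(nrow(states))
  for (j in seq_len(ncol(states))) tot <- tot + weights$values[[j]][states[, j] + 1L]
  tot
}

#' Do two total-score vectors order the states identically?
#'
#' TRUE when `derived` never strictly reverses `truth`: grouping states by
#' equal truth totals, every state of a higher group must score at least as
#' much as every state of a lower group (ties permitted where truth ties).
#'
#' @param truth,derived numeric vectors of state totals.
#' @param tol comparison tolerance.
#' @export
ranking_consistent <- function(truth, derived, tol = 1e-7) {
  o <- order(truth)
  t_sorted <- truth[o]; d_sorted <- derived[o]
  grp <- cumsum(c(TRUE, diff(t_sorted) > tol))
  gmax <- tapply(d_sorted, grp, max)
  gmin <- tapply(d_sorted, grp, min)
  ng <- length(gmax)
  ng < 2L || all(gmin[-1L] >= gmax[-ng] - tol)
}

#' Rescale weights so the best levels sum to 100
#'
#' @param w a `level_weights` object with a positive top-level sum.
#' @return the rescaled `level_weights`.
#' @export
normalise_respondent <- function(w) {
  top <- sum(vapply(w$values, max, numeric(1)))
  if (top <= 0) stop("cannot normalise all-zero weights", call. = FALSE)
  w$values <- lapply(w$values, function(v) v * 100 / top)
  w
}

#' Aggregate level weights across respondents
#'
#' Per-level arithmetic mean and sample standard deviation, as reported for
#' the nine-clinician panel behind the canonical instrument.
#'
#' @param respondents list of `level_weights` over the same instrument.
#' @return An `aggregated_weights` object: `mean` and `sd` (named lists of
#'   per-level vectors) and `n_respondents`.
#' @export
aggregate_weights <- function(respondents) {
  if (!length(respondents)) stop("need at least one respondent", call. = FALSE)
  shapes <- lapply(respondents, function(w) lengths(w$values))
  if (!all(vapply(shapes, identical, logical(1), shapes[[1L]])))
    stop("respondents cover different instruments", call. = FALSE)
  nms <- names(respondents[[1L]]$values)
  mean_l <- sd_l <- setNames(vector("list", length(nms)), nms)
  for (nm in nms) {
    m <- do.call(rbind, lapply(respondents, function(w) w$values[[nm]]))
    mean_l[[nm]] <- colMeans(m)
    sd_l[[nm]] <- if (nrow(m) > 1L) apply(m, 2, sd) else rep(0, ncol(m))
  }
  structure(list(mean = mean_l, sd = sd_l, n_respondents = length(respondents)),
            class = "aggregated_weights")
}

#' Rescale comorbidity attribute means into additive sub-scores
#'
#' The elicitation treats "impact on potentially reversible conditions" as one
#' nine-level single-select attribute; the instrument scores each condition
#' additively instead. Each condition's mean weight is multiplied by
#' `max(means) / sum(means)`, so the rescaled values sum to the comorbidity
#' criterion weight (its largest mean). Reproduces the published normalised
#' sub-scores to ±0.01.
#'
#' @param means named vector of 8 positive mean weights (minimal-impact level
#'   excluded at 0).
#' @return named vector of rescaled sub-scores (unrounded; report to 2 dp).
#' @export
rescale_comorbidities <- function(means) {
  means <- unlist(means)
  if (any(means <= 0) || sum(means) <= 0)
    stop("comorbidity means must be positive", call. = FALSE)
  means * max(means) / sum(means)
}

#' Draft nearest-integer rounding against the canonical points
#'
#' Rounds normalised scores half away from zero and flags where the canonical
#' instrument diverges — the reference group hand-adjusted several BMI, age
#' and risk entries away from nearest-integer rounding.
#'
#' @param normalised data.frame with columns `criterion`, `level`,
#'   `normalised` (defaults to [bapt_reference_weights()]).
#' @param instrument canonical instrument to compare against.
#' @return the input with `draft_points` (integer) and `matches_canonical`
#'   columns.
#' @export
draft_rounding <- function(normalised = bapt_reference_weights(),
                           instrument = bapt_instrument()) {
  df <- normalised
  df$draft_points <- as.integer(sign(df$normalised) * floor(abs(df$normalised) + 0.5))
  canon <- vapply(seq_len(nrow(df)), function(i) {
    cr <- instrument$criteria[[df$criterion[i]]]
    if (is.null(cr) || !(df$level[i] %in% names(cr$points))) NA_real_
    else unname(cr$points[df$level[i]])
  }, numeric(1))
  df$canonical_points <- canon
  df$matches_canonical <- !is.na(canon) & df$draft_points == canon
  df
}

#' Achievable score range of the instrument
#'
#' With `coupled = TRUE` (default), brute-force enumeration over internally
#' consistent eligible profiles: representative ages 25/40/47/55, BMIs
#' 37/42/47/55, both sexes, PE-risk flag on/off, diabetes durations 2/6/10
#' years and every non-empty comorbidity subset. Consistency couplings are
#' enforced by construction: hypertension counts in both the comorbidity score
#' and the risk-factor tally; BMI >= 50 drives the top BMI category and a risk
#' factor; age drives the age category and the 45+ factor; eligibility
#' requires at least one comorbidity. With `coupled = FALSE` levels are free
#' and the comorbidity set may be empty, giving the per-criterion min/max
#' sums.
#'
#' @param instrument a `bapt_instrument` with the canonical criterion layout.
#' @param coupled enforce cross-criterion consistency (default TRUE).
#' @return list with integer `min` and `max`.
#' @export
score_range <- function(instrument = bapt_instrument(), coupled = TRUE) {
  if (!coupled) {
    lo <- sum(vapply(instrument$criteria, function(cr)
      if (cr$mode == "additive_subscore") 0 else min(cr$points), numeric(1)))
    hi <- sum(instrument$criterion_maxima)
    return(list(min = as.integer(round(lo)), max = as.integer(round(hi))))
  }
  ages <- c(25, 40, 47, 55); bmis <- c(37, 42, 47, 55)
  sexes <- c(TRUE, FALSE); pes <- c(FALSE, TRUE); durs <- c(2, 6, 10)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 8)))[-1L, , drop = FALSE]
  colnames(subsets) <- COMORBIDITIES
  grid <- expand.grid(age = ages, bmi = bmis, male = sexes, pe = pes, dur = durs,
                      sub = seq_len(nrow(subsets)))
  co <- subsets[grid$sub, , drop = FALSE]
  tot <- .score_components(age = grid$age, bmi = grid$bmi, male = grid$male,
                           pe = grid$pe, duration = grid$dur, co = co,
                           instrument = instrument)$total
  list(min = as.integer(min(tot)), max = as.integer(max(tot)))
}
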