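#' @useDynLib bapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate anova aov chisq.test oneway.test pnorm qnorm
#'   rbinom rnorm rpois runif sd setNames t.test
#' @importFrom utils read.csv write.csv
"_PACKAGE"

COMORBIDITIES <- c("hypertension", "dyslipidaemia", "nash", "albuminuria",
                   "joint_pain", "reproductive_issues", "renal_impairment", "osa")

#' Define a scoring criterion
#'
#' A criterion is an attribute of a hypothetical patient (health state) with an
#' ordered set of levels, worst first. In `single_select` mode a patient sits on
#' exactly one level and scores its points; in `additive_subscore` mode (the
#' comorbidity criterion) every level beyond the worst is a condition that may
#' be present or absent and the points of all present conditions are summed.
#'
#' @param name short identifier.
#' @param levels character vector of level labels, worst to best; at least 2,
#'   unique.
#' @param mode `"single_select"` or `"additive_subscore"`.
#' @param points non-negative numeric vector, one per level. For
#'   `single_select` the worst level must score 0 and points must be
#'   non-decreasing along the level order.
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(name, levels, mode = c("single_select", "additive_subscore"),
                           points) {
  mode <- match.arg(mode)
  if (!is.character(levels) || length(levels) < 2L)
    stop("criterion '", name, "': needs >= 2 levels", call. = FALSE)
  if (anyDuplicated(levels))
    stop("criterion '", name, "': duplicate level labels", call. = FALSE)
  points <- as.numeric(points)
  if (length(points) != length(levels))
    stop("criterion '", name, "': 'points' must have one entry per level", call. = FALSE)
  if (any(is.na(points)) || any(points < 0))
    stop("criterion '", name, "': points must be non-negative numbers", call. = FALSE)
  if (mode == "single_select") {
    if (points[1L] != 0)
      stop("criterion '", name, "': worst level of a single_select criterion must score 0",
           call. = FALSE)
    if (is.unsorted(points))
      stop("criterion '", name, "': single_select points must be non-decreasing worst to best",
           call. = FALSE)
  }
  structure(list(name = as.character(name), levels = levels, mode = mode,
                 points = setNames(points, levels)),
            class = "criterion_spec")
}

#' Assemble an instrument from criteria
#'
#' @param criteria list of [criterion_spec()] objects.
#' @param name instrument name.
#' @return Object of class `bapt_instrument` with elements `name`, `criteria`
#'   (named list) and `criterion_maxima` (max single level for single-select
#'   criteria, sum of level points for additive ones).
#' @export
new_instrument <- function(criteria, name = "custom") {
  if (!length(criteria)) stop("an instrument needs at least one criterion", call. = FALSE)
  ok <- vapply(criteria, inherits, logical(1), "criterion_spec")
  if (!all(ok)) stop("'criteria' must be a list of criterion_spec objects", call. = FALSE)
  nms <- vapply(criteria, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate criterion names", call. = FALSE)
  names(criteria) <- nms
  maxima <- vapply(criteria, function(cr)
    if (cr$mode == "additive_subscore") sum(cr$points) else max(cr$points), numeric(1))
  structure(list(name = name, criteria = criteria, criterion_maxima = maxima),
            class = "bapt_instrument")
}

#' @export
print.bapt_instrument <- function(x, ...) {
  cat("<bapt_instrument> ", x$name, "\n", sep = "")
  for (cr in x$criteria)
    cat(sprintf("  %-12s %s, %d levels, max %g\n", cr$name, cr$mode,
                length(cr$levels), x$criterion_maxima[cr$name]))
  invisible(x)
}

# Canonical rounded points shipped as constants: the published instrument was
# hand-adjusted by its clinical reference group after rounding, so several
# entries differ from nearest-integer rounding of the elicited weights.
.bapt_v1 <- function() {
  new_instrument(name = "bapt_v1", criteria = list(
    criterion_spec("comorbidity",
      levels = c("minimal_impact", COMORBIDITIES),
      mode = "additive_subscore",
      points = c(0, 2, 2, 3, 3, 4, 4, 5, 7)),
    criterion_spec("duration",
      levels = c("gt8y", "4to8y", "lt4y"),
      points = c(0, 12, 20)),
    criterion_spec("bmi",
      levels = c("35to40", "40to45", "45to50", "ge50"),
      points = c(0, 10, 13, 15)),
    criterion_spec("age",
      levels = c("ge50", "30to49", "18to29"),
      points = c(0, 10, 15)),
    criterion_spec("risk",
      levels = c("factors4to5", "factors2to3", "factors0to1"),
      points = c(0, 10, 20))
  ))
}

#' The canonical BAPT instrument
#'
#' Returns the published instrument: five criteria (comorbidity impact,
#' duration of diabetes, BMI category, age group, surgical risk) whose rounded
#' points give maximum criterion scores of 30/20/15/15/20 and a total score
#' range of 0-100 (2-98 over internally consistent eligible patients, see
#' [score_range()]).
#'
#' @param name instrument identifier; `"bapt_v1"` is the only built-in.
#' @return A `bapt_instrument`.
#' @export
bapt_instrument <- function(name = "bapt_v1") {
  if (!identical(name, "bapt_v1"))
    stop("unknown built-in instrument '", name, "'", call. = FALSE)
  .bapt_v1()
}

#' Mean elicited level weights behind the canonical instrument
#'
#' The per-level preference weights (mean and SD over the nine clinician
#' respondents), the normalised scores, and the canonical rounded points of the
#' published instrument. For single-select criteria the normalised score equals
#' the mean; for the comorbidity criterion the nine-level attribute means are
#' rescaled into additive per-condition sub-scores (see
#' [rescale_comorbidities()]).
#'
#' @return data.frame with columns criterion, level, mean, sd, normalised,
#'   rounded.
#' @export
bapt_reference_weights <- function() {
  df <- rbind(
    data.frame(criterion = "comorbidity",
               level = c("minimal_impact", COMORBIDITIES),
               mean = c(0, 8.72, 9.93, 13.36, 15.43, 16.06, 17.41, 23.43, 30.28),
               sd = c(0, 4.88, 4.9, 4.54, 5.52, 5.19, 4.49, 5.11, 7.46),
               normalised = c(0, 1.96, 2.23, 3.01, 3.47, 3.61, 3.92, 5.27, 6.81),
               rounded = c(0, 2, 2, 3, 3, 4, 4, 5, 7)),
    data.frame(criterion = "duration", level = c("gt8y", "4to8y", "lt4y"),
               mean = c(0, 11.92, 19.92), sd = c(0, 8.1, 14.42),
               normalised = c(0, 11.92, 19.92), rounded = c(0, 12, 20)),
    data.frame(criterion = "bmi", level = c("35to40", "40to45", "45to50", "ge50"),
               mean = c(0, 8.63, 11.58, 14.92), sd = c(0, 4.9, 4.77, 4.54),
               normalised = c(0, 8.63, 11.58, 14.92), rounded = c(0, 10, 13, 15)),
    data.frame(criterion = "age", level = c("ge50", "30to49", "18to29"),
               mean = c(0, 8.76, 15.17), sd = c(0, 3.66, 7.84),
               normalised = c(0, 8.76, 15.17), rounded = c(0, 10, 15)),
    data.frame(criterion = "risk",
               level = c("factors4to5", "factors2to3", "factors0to1"),
               mean = c(0, 11.34, 19.7), sd = c(0, 9.04, 1.62),
               normalised = c(0, 11.34, 19.7), rounded = c(0, 10, 20)))
  rownames(df) <- NULL
  df
}

#' Read an instrument from a JSON config (or fetch a built-in)
#'
#' Config schema: `{"name": ..., "criteria": [{"name", "mode",
#' "levels": [{"label", "points"}, ...]}, ...]}`, levels worst first.
#'
#' @param path file path, or the name of a built-in instrument ("bapt_v1").
#' @return A validated `bapt_instrument`.
#' @export
load_instrument <- function(path) {
  if (identical(path, "bapt_v1")) return(bapt_instrument(path))
  if (!file.exists(path)) stop("instrument config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$criteria) || !length(cfg$criteria))
    stop("instrument config: missing field 'criteria'", call. = FALSE)
  crit <- lapply(cfg$criteria, function(cr) {
    for (f in c("name", "mode", "levels"))
      if (is.null(cr[[f]])) stop("instrument config: criterion missing field '", f, "'",
                                 call. = FALSE)
    labs <- vapply(cr$levels, function(l) as.character(l$label), character(1))
    pts <- vapply(cr$levels, function(l) {
      if (is.null(l$points)) stop("instrument config: level without 'points' in criterion '",
                                  cr$name, "'", call. = FALSE)
      as.numeric(l$points)
    }, numeric(1))
    criterion_spec(cr$name, labs, cr$mode, pts)
  })
  new_instrument(crit, name = if (is.null(cfg$name)) "unnamed" else cfg$name)
}

#' Write an instrument config to JSON
#'
#' Round-trips losslessly through [load_instrument()].
#' @param instrument a `bapt_instrument`.
#' @param path output file.
#' @export
save_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "bapt_instrument"))
  cfg <- list(
    name = instrument$name,
    criteria = lapply(unname(instrument$criteria), function(cr)
      list(name = cr$name, mode = cr$mode,
           levels = lapply(seq_along(cr$levels), function(i)
             list(label = cr$levels[i], points = unname(cr$points[i]))))))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# number of levels per criterion, in instrument order
.n_levels <- function(instrument)
  vapply(instrument$criteria, function(cr) length(cr$levels), integer(1))
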