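# Expected values for the simplex fixtures below were computed with
# scipy.optimize.linprog (HiGHS) as an independent oracle and frozen.

test_that("simplex solves small reference problems", {
  # max 3x + 5y st x <= 4, 2y <= 12, 3x + 2y <= 18  (classic; optimum 36 at (2,6))
  s <- simplex_lp(c(-3, -5), rbind(c(1, 0), c(0, 2), c(3, 2)),
                  c(4, 12, 18), rep("<=", 3))
  expect_equal(s$status, "optimal")
  expect_equal(s$x, c(2, 6), tolerance = 1e-8)
  expect_equal(s$objval, -36, tolerance = 1e-8)

  # equality + >= : min x + y st x + y >= 2, x == 0.5  -> (0.5, 1.5)
  s2 <- simplex_lp(c(1, 1), rbind(c(1, 1), c(1, 0)), c(2, 0.5), c(">=", "=="))
  expect_equal(s2$x, c(0.5, 1.5), tolerance = 1e-8)

  # infeasible: x <= 1, x >= 2
  s3 <- simplex_lp(c(1), rbind(1, 1), c(1, 2), c("<=", ">="))
  expect_equal(s3$status, "infeasible")

  # unbounded: min -x, x >= 0
  s4 <- simplex_lp(c(-1), matrix(1, 1, 1), 3, ">=")
  expect_equal(s4$status, "unbounded")

  # negative rhs handled by row flip: x >= -1 is vacuous under x >= 0
  s5 <- simplex_lp(c(1), matrix(1, 1, 1), -1, ">=")
  expect_equal(s5$status, "optimal")
  expect_equal(s5$objval, 0)
})

test_that("derive_level_weights recovers a two-criterion respondent exactly", {
  # with two criteria every state pair differs on <= 2 criteria, so the
  # elicited information determines the full order
  ins <- new_instrument(list(
    criterion_spec("p", c("p0", "p1", "p2"), points = c(0, 20, 45)),
    criterion_spec("q", c("q0", "q1", "q2", "q3"), points = c(0, 10, 30, 55))),
    name = "two_crit")
  for (seed in c(2, 5, 8)) {
    tw <- random_weights(ins, seed = seed)
    ses <- run_session(ins, tw)
    w <- derive_level_weights(ses$store, ins)
    st <- enumerate_states(ins)
    expect_true(ranking_consistent(state_totals(tw, st), state_totals(w, st)),
                info = paste("seed", seed))
    expect_gt(w$margin, 0)
  }
})

test_that("derived weights honour every judgement with the achieved margin", {
  ins <- small_mixed()
  tw <- random_weights(ins, seed = 4)
  ses <- run_session(ins, tw, forced = FALSE, tie_tol = 0.5)
  w <- derive_level_weights(ses$store, ins)
  tot <- function(lev) sum(vapply(seq_along(lev), function(j)
    w$values[[j]][lev[j] + 1L], numeric(1)))
  for (j in ses$store$judgements) {
    d <- tot(j$a) - tot(j$b)
    if (j$verdict == "indifferent") expect_lt(abs(d), 1e-6)
    else expect_gte(d, w$margin - 1e-6)
  }
  # monotone, worst = 0, top-sum normalised
  for (v in w$values) {
    expect_equal(v[1], 0)
    expect_true(all(diff(v) >= -1e-9))
  }
  expect_equal(sum(vapply(w$values, max, numeric(1))), 100, tolerance = 1e-6)
})

test_that("derived weights reproduce all candidate-pair orderings of the truth", {
  ins <- small_mixed()
  st <- enumerate_states(ins)
  cand <- candidate_tasks(ins)
  for (seed in c(3, 6)) {
    tw <- random_weights(ins, seed = seed)
    ses <- run_session(ins, tw)
    w <- derive_level_weights(ses$store, ins)
    t <- state_totals(tw, st); d <- state_totals(w, st)
    expect_true(all(sign(t[cand$a] - t[cand$b]) *
                      sign(d[cand$a] - d[cand$b]) >= 0), info = paste("seed", seed))
  }
})

test_that("empty and contradictory judgement sets behave as specified", {
  ins <- two_binary()
  w <- derive_level_weights(list(), ins)
  expect_equal(w$margin, 0)
  expect_equal(sum(vapply(w$values, max, numeric(1))), 100, tolerance = 1e-9)
  for (v in w$values) expect_true(all(diff(v) >= -1e-9))

  # contradictory pair A > B, B > A is infeasible at positive margin
  contradictory <- list(
    list(seq = 1, respondent = "r", a = c(1L, 0L), b = c(0L, 1L), verdict = "a_preferred"),
    list(seq = 2, respondent = "r", a = c(0L, 1L), b = c(1L, 0L), verdict = "a_preferred"))
  expect_error(derive_level_weights(contradictory, ins), "inconsistent")
})

test_that("normalise_respondent scales to a 100-point instrument", {
  ref <- bapt_reference_weights()
  tops <- tapply(ref$mean, ref$criterion, max)
  expect_equal(sum(tops), 100, tolerance = 0.05)  # published means: 99.99

  w <- structure(list(respondent_id = "r", margin = 1,
                      values = list(a = c(0, 30), b = c(0, 20))),
                 class = "level_weights")
  n1 <- normalise_respondent(w)
  expect_equal(sum(vapply(n1$values, max, numeric(1))), 100)
  expect_equal(normalise_respondent(n1), n1)  # idempotent
  w2 <- w; w2$values <- lapply(w$values, `*`, 2)
  expect_equal(normalise_respondent(w2), n1)  # scale-invariant
  w0 <- w; w0$values <- list(a = c(0, 0), b = c(0, 0))
  expect_error(normalise_respondent(w0), "all-zero")
})

test_that("aggregate_weights gives per-level mean and sample SD", {
  mk <- function(v, id) structure(list(respondent_id = id, margin = 1,
                                       values = list(a = c(0, v))),
                                  class = "level_weights")
  one <- aggregate_weights(list(mk(10, "r1")))
  expect_equal(one$mean$a, c(0, 10))
  expect_equal(one$sd$a, c(0, 0))
  two <- aggregate_weights(list(mk(10, "r1"), mk(20, "r2")))
  expect_equal(two$mean$a, c(0, 15))
  expect_equal(two$sd$a[2], 7.07, tolerance = 0.005)  # sd(c(10, 20)) = 7.0711
  expect_equal(aggregate_weights(list(mk(20, "r2"), mk(10, "r1")))$mean, two$mean)
  bad <- structure(list(respondent_id = "r3", margin = 1,
                        values = list(a = c(0, 1, 2))), class = "level_weights")
  expect_error(aggregate_weights(list(mk(1, "r1"), bad)), "different instruments")
})

test_that("comorbidity rescaling reproduces the published normalised scores", {
  means <- reference_comorbidity_means()
  r <- rescale_comorbidities(means)
  expect_equal(sum(r), max(means), tolerance = 1e-9)  # sums to criterion weight
  ref <- bapt_reference_weights()
  ref <- ref[ref$criterion == "comorbidity" & ref$level != "minimal_impact", ]
  expect_equal(unname(r[ref$level]), ref$normalised, tolerance = 0.011)
  expect_equal(unname(round(r["osa"], 2)), 6.81)
  expect_equal(unname(round(r["nash"], 2)), 3.01)
  # all-equal means collapse to largest/8 each
  eq <- rescale_comorbidities(setNames(rep(12, 8), names(means)))
  expect_equal(unname(eq), rep(12 / 8, 8))
  expect_error(rescale_comorbidities(c(means[-1], bad = 0)), "positive")
})

test_that("draft rounding matches the canonical table except adjusted rows", {
  dr <- draft_rounding()
  expect_equal(dr$draft_points[dr$level == "joint_pain"], 4L)       # 3.61 -> 4
  expect_equal(dr$draft_points[dr$level == "lt4y"], 20L)            # 19.92 -> 20
  # every comorbidity and duration row matches the canonical points
  cd <- dr$criterion %in% c("comorbidity", "duration")
  expect_true(all(dr$matches_canonical[cd]))
  # the committee-adjusted BMI/age/risk rows diverge from nearest-integer
  expect_false(dr$matches_canonical[dr$level == "40to45"])      # 8.63 -> 9, canon 10
  expect_false(dr$matches_canonical[dr$level == "45to50"])      # 11.58 -> 12, canon 13
  expect_false(dr$matches_canonical[dr$level == "30to49"])      # 8.76 -> 9, canon 10
  expect_false(dr$matches_canonical[dr$level == "factors2to3"]) # 11.34 -> 11, canon 10
  # half rounds away from zero
  df <- data.frame(criterion = "x", level = "l", normalised = 2.5)
  expect_equal(draft_rounding(df)$draft_points, 3L)
})

test_that("score_range reproduces 2-98 coupled and 0-100 uncoupled", {
  r <- score_range(bapt_instrument(), coupled = TRUE)
  expect_equal(r$min, 2L)
  expect_equal(r$max, 98L)
  free <- score_range(bapt_instrument(), coupled = FALSE)
  expect_equal(free$min, 0L)
  expect_equal(free$max, 100L)
})

test_that("score_range extremes agree with directly constructed witnesses", {
  ins <- bapt_instrument()
  # minimum: male, >= 50y, BMI 35-<40, hypertension only, duration > 8y, PE risk
  lo <- validate_patients(patient_row(sex = "male", age_years = 55, bmi = 37,
                                      diabetes_duration_years = 10, pe_risk = 1))
  expect_equal(score_patients(lo)$total, 2L)
  # maximum: female, 18-29y, BMI 45-<50, all 8 comorbidities, < 4y, no PE
  hi <- validate_patients(patient_row(sex = "female", age_years = 25, bmi = 47,
                                      diabetes_duration_years = 2,
                                      co_htn = 1, co_dyslip = 1, co_nash = 1,
                                      co_albuminuria = 1, co_joint = 1,
                                      co_repro = 1, co_renal = 1, co_osa = 1))
  expect_equal(score_patients(hi)$total, 98L)
})
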