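test_that("enumerate_states spans the full Cartesian product", {
  expect_equal(nrow(enumerate_states(bapt_instrument())), 972L)  # 9*3*4*3*3
  expect_equal(nrow(enumerate_states(two_binary())), 4L)
  one <- new_instrument(list(criterion_spec("a", c("a0", "a1", "a2"),
                                            points = c(0, 1, 2))))
  expect_equal(nrow(enumerate_states(one)), 3L)
  # lexicographic: first row all-worst, last all-best, first criterion slowest
  st <- enumerate_states(small_mixed())
  expect_equal(unname(st[1, ]), c(0L, 0L, 0L))
  expect_equal(unname(st[nrow(st), ]), c(2L, 1L, 2L))
  expect_true(all(diff(st[, 1]) >= 0))
})

test_that("dominates is strict Pareto dominance", {
  ins <- small_mixed()
  expect_true(dominates(c(2, 1, 2), c(0, 0, 0), ins))
  expect_false(dominates(c(1, 0, 1), c(1, 0, 1), ins))  # a == b
  expect_false(dominates(c(1, 0, 0), c(0, 1, 0), ins))  # mixed
  expect_true(dominates(c(a = 1, b = 0, c = 0), c(0, 0, 0), ins))
  expect_error(dominates(c(1, 0), c(0, 0, 0), ins), "one level per")
  expect_error(dominates(c(5, 0, 0), c(0, 0, 0), ins), "out of range")
})

test_that("candidate_tasks matches a brute-force pair scan", {
  # oracle: O(n^2) scan over all state pairs, keep those differing on exactly
  # two criteria with neither dominating
  brute_count <- function(ins) {
    st <- enumerate_states(ins)
    n <- nrow(st); cnt <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- st[i, ] != st[j, ]
      if (sum(d) != 2L) next
      if (dominates(st[i, ], st[j, ], ins) || dominates(st[j, ], st[i, ], ins)) next
      cnt <- cnt + 1L
    }
    cnt
  }
  for (ins in list(two_binary(), three_binary(), small_mixed())) {
    ct <- candidate_tasks(ins)
    expect_equal(nrow(ct), brute_count(ins), info = ins$name)
    st <- enumerate_states(ins)
    expect_true(all(rowSums(st[ct$a, , drop = FALSE] !=
                              st[ct$b, , drop = FALSE]) == 2L))
  }
  # two binary criteria -> exactly the single (1,0) vs (0,1) trade-off
  ct <- candidate_tasks(two_binary())
  expect_equal(nrow(ct), 1L)
  st <- enumerate_states(two_binary())
  expect_setequal(c(unname(st[ct$a, ])), c(1L, 0L))
  # one criterion only -> empty
  one <- new_instrument(list(criterion_spec("a", c("a0", "a1"), points = c(0, 1))))
  expect_equal(nrow(candidate_tasks(one)), 0L)
})

test_that("canonical candidate count agrees with the closed-form tally", {
  # independent tally: sum over criterion pairs of C(n1,2)*C(n2,2)*prod(others)
  nl <- c(9, 3, 4, 3, 3)
  expected <- 0
  for (i in 1:4) for (j in (i + 1):5)
    expected <- expected + choose(nl[i], 2) * choose(nl[j], 2) * prod(nl[-c(i, j)])
  expect_equal(nrow(candidate_tasks(bapt_instrument())), expected)  # 24786
})

test_that("judged pairs imply transitive consequences with provenance", {
  ins <- small_mixed()
  store <- preference_store(ins, generalise = FALSE)
  # three mutually non-dominated states: A = (2,0,0), B = (0,1,0), C = (0,0,2)
  A <- c(2, 0, 0); B <- c(0, 1, 0); C <- c(0, 0, 2)
  record_judgement(store, A, B, "a_preferred")
  record_judgement(store, B, C, "a_preferred")
  iA <- bapt:::.state_index(A, store$nl); iC <- bapt:::.state_index(C, store$nl)
  expect_equal(as.integer(pref_status(store$W, iA, iC)), 1L)  # A > C implied
  expect_equal(as.integer(store$prov[iA, iC]), 3L)            # by transitivity
  # direct reversal is an inconsistency naming a chain
  expect_error(record_judgement(store, C, A, "a_preferred"), "inconsistent")
  expect_error(record_judgement(store, B, A, "a_preferred"), "chain")
})

test_that("indifference participates in the closure", {
  ins <- small_mixed()
  store <- preference_store(ins, generalise = FALSE)
  A <- c(2, 0, 0); B <- c(0, 1, 0); C <- c(0, 0, 2)
  record_judgement(store, A, B, "indifferent")
  record_judgement(store, B, C, "a_preferred")
  iA <- bapt:::.state_index(A, store$nl); iC <- bapt:::.state_index(C, store$nl)
  # A ~ B and B > C  =>  A > C
  expect_equal(as.integer(pref_status(store$W, iA, iC)), 1L)
  expect_error(record_judgement(store, C, A, "indifferent"), "inconsistent")
})

test_that("closure agrees with a Floyd-Warshall oracle on random sessions", {
  ins <- small_mixed()
  st <- enumerate_states(ins)
  n <- nrow(st)
  for (seed in 1:5) {
    set.seed(seed)
    store <- preference_store(ins, generalise = FALSE)
    # oracle adjacency: weak dominance
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- all(st[i, ] >= st[j, ])
    for (k in 1:6) {
      i <- sample(n, 1); j <- sample(n, 1)
      if (i == j) next
      verdict <- sample(c("a_preferred", "indifferent"), 1)
      res <- suppressWarnings(try(record_judgement(store, st[i, ], st[j, ], verdict,
                                                   respondent_id = "fw"),
                                  silent = TRUE))
      if (inherits(res, "try-error")) next  # oracle path only tracks accepted
      adj[i, j] <- TRUE
      if (verdict == "indifferent") adj[j, i] <- TRUE
    }
    # Floyd-Warshall closure
    fw <- adj
    for (k in seq_len(n)) fw <- fw | (fw[, k] %o% fw[k, ] > 0)
    expect_equal(matrix(as.logical(store$W), n), fw, info = paste("seed", seed))
  }
})

test_that("next_task never returns a decided task and sessions conserve pairs", {
  ins <- small_mixed()
  tw <- random_weights(ins, seed = 42)
  store <- preference_store(ins)
  asked <- 0L
  repeat {
    task <- next_task(store)
    if (is.null(task)) break
    expect_equal(as.integer(pref_status(store$W, task$ia, task$ib)), 0L)
    expect_false(dominates(task$a, task$b, ins) || dominates(task$b, task$a, ins))
    expect_length(task$differing, 2L)
    record_judgement(store, task$a, task$b, simulate_respondent(tw, task, forced = TRUE))
    asked <- asked + 1L
  }
  ps <- provenance_summary(store)
  expect_equal(unname(ps["undecided"]), 0L)
  expect_equal(unname(ps["judged"]), asked)
  expect_equal(unname(ps["dominance"]), 0L)  # candidates are non-dominated
  expect_equal(sum(ps[c("judged", "dominance", "transitivity")]),
               unname(ps["total"]))
})

test_that("fresh two-binary session asks exactly the single trade-off", {
  ins <- two_binary()
  store <- preference_store(ins)
  task <- next_task(store)
  expect_setequal(task$differing, c("x", "y"))
  record_judgement(store, task$a, task$b, "a_preferred")
  expect_null(next_task(store))
})

test_that("simulate_respondent follows the additive value difference", {
  ins <- two_binary()
  tw <- structure(list(respondent_id = "t", margin = NA_real_,
                       values = list(x = c(0, 60), y = c(0, 40))),
                  class = "level_weights")
  task <- list(a = c(1L, 0L), b = c(0L, 1L))
  expect_equal(simulate_respondent(tw, task), "a_preferred")
  expect_equal(simulate_respondent(tw, list(a = c(0L, 1L), b = c(1L, 0L))),
               "b_preferred")
  even <- structure(list(respondent_id = "t", margin = NA_real_,
                         values = list(x = c(0, 50), y = c(0, 50))),
                    class = "level_weights")
  expect_equal(simulate_respondent(even, task, tie_tol = 0), "indifferent")
  expect_equal(simulate_respondent(even, task, tie_tol = 0, forced = TRUE),
               "a_preferred")
})

test_that("reference weights decide the OSA/duration trade-off as published", {
  # a = {OSA, duration > 8y} vs b = {hypertension, duration < 4y}:
  # (30.28 - 8.72) - (19.92 - 0) = +1.64 -> a preferred
  ins <- bapt_instrument()
  ref <- bapt_reference_weights()
  vals <- lapply(split(ref, ref$criterion), function(d) d$mean)
  vals <- lapply(names(ins$criteria), function(nm) {
    d <- ref[ref$criterion == nm, ]
    d$mean[match(ins$criteria[[nm]]$levels, d$level)]
  })
  names(vals) <- names(ins$criteria)
  tw <- structure(list(respondent_id = "panel", values = vals, margin = NA_real_),
                  class = "level_weights")
  osa_idx <- which(ins$criteria$comorbidity$levels == "osa") - 1L
  htn_idx <- which(ins$criteria$comorbidity$levels == "hypertension") - 1L
  a <- c(osa_idx, 0L, 0L, 0L, 0L)   # OSA, duration > 8y
  b <- c(htn_idx, 2L, 0L, 0L, 0L)   # hypertension, duration < 4y
  expect_equal(simulate_respondent(tw, list(a = a, b = b)), "a_preferred")
})

test_that("sessions are deterministic and replayable from JSONL", {
  ins <- small_mixed()
  tw <- random_weights(ins, seed = 9)
  s1 <- run_session(ins, tw)
  s2 <- run_session(ins, tw)
  expect_identical(s1$transcript, s2$transcript)

  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session(s1, path)
  store2 <- replay_session(path, ins)
  expect_identical(store2$W, s1$store$W)
  expect_equal(length(store2$judgements), nrow(s1$transcript))
})
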