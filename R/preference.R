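# Preference store: judged, dominance-implied and transitively implied
# (weak) preferences over the full state space, kept transitively closed after
# every accepted judgement. Backed by a raw n x n closure matrix updated in C++.

#' Create a preference store for an instrument
#'
#' The store starts pre-loaded with all Pareto-dominance relations (provenance
#' `"dominance"`); judgements are added with [record_judgement()]. With
#' `generalise = TRUE` (the PAPRIKA ceteris-paribus rule, default) a judgement
#' on a task that leaves some criteria untouched is applied to every background
#' on those criteria — under an additive value model the trade-off between the
#' differing criteria cannot depend on the unchanged ones. Replicated and
#' chained pairs both carry provenance `"transitivity"`.
#'
#' @param instrument a `bapt_instrument`.
#' @param generalise apply judgements ceteris paribus (default TRUE). With
#'   FALSE the store closes over plain transitivity only.
#' @return An environment of class `preference_store`.
#' @export
preference_store <- function(instrument, generalise = TRUE) {
  states <- enumerate_states(instrument)
  n <- nrow(states)
  nl <- .n_levels(instrument)
  # weak dominance closure: a >= b on every criterion
  ge <- matrix(TRUE, n, n)
  for (j in seq_along(nl))
    ge <- ge & outer(states[, j], states[, j], `>=`)
  W <- matrix(as.raw(ge), n, n)
  prov <- matrix(as.raw(0L), n, n)
  strict_dom <- ge & !t(ge)
  prov[strict_dom] <- as.raw(2L)
  prov[ge & t(ge) & row(ge) != col(ge)] <- as.raw(2L)  # level-identical twins

  st <- new.env(parent = emptyenv())
  st$instrument <- instrument
  st$states <- states
  st$nl <- nl
  st$n <- n
  st$W <- W
  st$prov <- prov
  st$generalise <- isTRUE(generalise)
  st$judgements <- list()
  st$edges_from <- integer(0)   # base edges (judged + replicated), for chains
  st$edges_to <- integer(0)
  st$patterns <- .trade_off_patterns(instrument)
  if (nrow(st$patterns)) {
    reps <- lapply(seq_len(nrow(st$patterns)), function(p)
      .pattern_states(st$patterns[p, ], length(nl)))
    st$pat_a <- vapply(reps, function(r) .state_index(r$a, nl), integer(1))
    st$pat_b <- vapply(reps, function(r) .state_index(r$b, nl), integer(1))
  } else {
    st$pat_a <- st$pat_b <- integer(0)
  }
  st$pat_gen <- logical(nrow(st$patterns))  # pattern already generalised
  class(st) <- "preference_store"
  st
}

#' @export
print.preference_store <- function(x, ...) {
  cat("<preference_store> ", x$n, " states, ", length(x$judgements),
      " judgements, generalise=", x$generalise, "\n", sep = "")
  invisible(x)
}

# all ceteris-paribus translates of the ordered state pair (a, b): every
# background on the criteria where a and b agree
.translate_edges <- function(st, a_lev, b_lev) {
  k <- length(st$nl)
  diff <- which(a_lev != b_lev)
  same <- setdiff(seq_len(k), diff)
  if (!st$generalise || !length(same))
    return(cbind(.state_index(a_lev, st$nl), .state_index(b_lev, st$nl)))
  g <- do.call(expand.grid, lapply(same, function(j) 0:(st$nl[j] - 1L)))
  am <- bm <- matrix(0L, nrow = nrow(g), ncol = k)
  am[, same] <- as.matrix(g); bm[, same] <- as.matrix(g)
  for (j in diff) { am[, j] <- a_lev[j]; bm[, j] <- b_lev[j] }
  cbind(.state_indices(am, st$nl), .state_indices(bm, st$nl))
}

# one-step successors for chain reconstruction: judged/replicated base edges
# plus direct dominance
.successors <- function(st, u) {
  succ <- st$edges_to[st$edges_from == u]
  dom <- which(as.logical(st$W[u, ]) & as.raw(st$prov[u, ]) == as.raw(2L))
  lev_u <- st$states[u, ]
  if (length(dom)) {
    keep <- vapply(dom, function(v) all(lev_u >= st$states[v, ]), logical(1))
    dom <- dom[keep]
  }
  unique(c(succ, dom))
}

# BFS path u -> v through base relations, as a vector of state indices
.find_chain <- function(st, u, v) {
  prev <- integer(st$n); seen <- logical(st$n)
  queue <- u; seen[u] <- TRUE
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    if (x == v) {
      path <- v
      while (path[1L] != u) path <- c(prev[path[1L]], path)
      return(path)
    }
    nxt <- .successors(st, x)
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE; prev[nxt] <- x
    queue <- c(queue, nxt)
  }
  c(u, v)  # closure guarantees reachability; fallback
}

.state_label <- function(st, i) paste0("s", i, "(", paste(st$states[i, ], collapse = ""), ")")

#' Record a judgement and re-close the store
#'
#' Adds a judged pair, replicates it ceteris paribus when the store
#' generalises, recomputes the transitive closure incrementally, and raises an
#' inconsistency error (identifying an offending chain of earlier relations)
#' if the verdict contradicts anything already judged or implied.
#'
#' @param store a `preference_store`.
#' @param a,b the two states: 0-based level vectors (instrument order or
#'   named) or state row indices.
#' @param verdict `"a_preferred"`, `"b_preferred"` or `"indifferent"`.
#' @param respondent_id respondent label stored with the judgement.
#' @return the store, invisibly (modified in place).
#' @export
record_judgement <- function(store, a, b, verdict = c("a_preferred", "b_preferred",
                                                      "indifferent"),
                             respondent_id = "r1") {
  verdict <- match.arg(verdict)
  to_lev <- function(s) {
    if (length(s) == 1L && is.null(names(s))) return(store$states[s, ])
    nms <- names(store$instrument$criteria)
    if (!is.null(names(s))) s <- s[nms]
    as.integer(s)
  }
  a_lev <- to_lev(a); b_lev <- to_lev(b)
  ia <- .state_index(a_lev, store$nl); ib <- .state_index(b_lev, store$nl)
  if (ia == ib) stop("a judgement needs two distinct states", call. = FALSE)

  status <- pref_status(store$W, ia, ib)  # 0 none, 1 a>b, 2 b>a, 3 indiff
  want <- switch(verdict, a_preferred = 1L, b_preferred = 2L, indifferent = 3L)
  if (status != 0L) {
    if (status == want) {
      warning("pair already decided consistently; judgement recorded as no-op")
      return(invisible(store))
    }
    # contradiction: explain with a chain of prior relations
    chain <- if (want == 1L || (want == 3L && status == 2L)) .find_chain(store, ib, ia)
             else .find_chain(store, ia, ib)
    stop("inconsistent judgement (", verdict, " for ", .state_label(store, ia),
         " vs ", .state_label(store, ib), "): store already implies the chain ",
         paste(vapply(chain, function(i) .state_label(store, i), character(1)),
               collapse = " >= "),
         call. = FALSE)
  }

  if (verdict == "b_preferred") { tmp <- a_lev; a_lev <- b_lev; b_lev <- tmp }
  edges <- .translate_edges(store, a_lev, b_lev)
  if (verdict == "indifferent") edges <- rbind(edges, edges[, 2:1, drop = FALSE])
  iw <- .state_index(a_lev, store$nl); il <- .state_index(b_lev, store$nl)
  codes <- ifelse(edges[, 1L] == iw & edges[, 2L] == il, 1L, 3L)
  if (verdict == "indifferent")
    codes[edges[, 1L] == il & edges[, 2L] == iw] <- 1L
  pref_add_edges(store$W, store$prov, edges[, 1L], edges[, 2L], codes)
  store$edges_from <- c(store$edges_from, edges[, 1L])
  store$edges_to <- c(store$edges_to, edges[, 2L])
  store$judgements[[length(store$judgements) + 1L]] <-
    list(seq = length(store$judgements) + 1L, respondent = respondent_id,
         a = a_lev, b = b_lev,
         verdict = if (verdict == "indifferent") "indifferent" else "a_preferred")
  invisible(store)
}

# patterns whose representative instantiation is already decided; generalise
# any that were decided by chains rather than by a replicated judgement, so a
# decided pattern is decided for every background
.sweep_patterns <- function(store) {
  if (!nrow(store$patterns)) return(integer(0))
  repeat {
    stat <- pref_status(store$W, store$pat_a, store$pat_b)
    und <- which(stat == 0L)
    if (!store$generalise) return(und)
    todo <- which(stat != 0L & !store$pat_gen)
    if (!length(todo)) return(und)
    for (p in todo) {
      ps <- .pattern_states(store$patterns[p, ], length(store$nl))
      win <- if (stat[p] == 2L) ps$b else ps$a
      los <- if (stat[p] == 2L) ps$a else ps$b
      edges <- .translate_edges(store, win, los)
      if (stat[p] == 3L) edges <- rbind(edges, edges[, 2:1, drop = FALSE])
      miss <- !as.logical(store$W[cbind(edges[, 1L], edges[, 2L])])
      if (any(miss)) {
        pref_add_edges(store$W, store$prov, edges[miss, 1L], edges[miss, 2L],
                       rep(3L, sum(miss)))
        store$edges_from <- c(store$edges_from, edges[miss, 1L])
        store$edges_to <- c(store$edges_to, edges[miss, 2L])
      }
      store$pat_gen[p] <- TRUE
    }
  }
}

#' Select the next choice task to ask
#'
#' Returns an undecided candidate trade-off task — never one already settled by
#' dominance or implied by the closure. Selection heuristic (documented,
#' swappable): among undecided trade-off patterns, pick the one sharing a
#' partial state with the most other undecided patterns on the same criterion
#' pair (a greedy proxy for how many open comparisons the answer can reach
#' through transitivity); ties are broken lexicographically by pattern order.
#' Tasks are instantiated with the all-worst background.
#'
#' @param store a `preference_store`.
#' @return A list with elements `a`, `b` (0-based level vectors), `ia`, `ib`
#'   (state indices), `differing` (criterion names) and `pattern`; or `NULL`
#'   when every candidate pair is decided or implied.
#' @export
next_task <- function(store) {
  und <- .sweep_patterns(store)
  if (!length(und)) return(NULL)
  pat <- store$patterns[und, , drop = FALSE]
  # cell usage counts per criterion-pair grid
  keyA <- paste(pat$c1, pat$c2, pat$hi1, pat$lo2)
  keyB <- paste(pat$c1, pat$c2, pat$lo1, pat$hi2)
  usage <- table(c(keyA, keyB))
  score <- as.vector(usage[keyA]) + as.vector(usage[keyB]) - 2L
  best <- und[which.max(score)]  # which.max: first max -> lexicographic ties
  ps <- .pattern_states(store$patterns[best, ], length(store$nl))
  nms <- names(store$instrument$criteria)
  list(a = ps$a, b = ps$b,
       ia = .state_index(ps$a, store$nl), ib = .state_index(ps$b, store$nl),
       differing = nms[c(store$patterns$c1[best], store$patterns$c2[best])],
       pattern = best)
}

#' Simulate a respondent with known true weights
#'
#' Answers a choice task by the additive value difference under `true_weights`:
#' `a_preferred` when the difference exceeds `tie_tol`, `b_preferred` below
#' `-tie_tol`, otherwise `indifferent` — unless `forced = TRUE`, in which case
#' ties go to `a_preferred` (respondents were forced to choose).
#'
#' @param true_weights a `level_weights` object (see [derive_level_weights()]).
#' @param task a task from [next_task()] (or a list with `a`, `b` level
#'   vectors).
#' @param tie_tol indifference half-width on the 0-100 value scale.
#' @param forced disallow the indifferent verdict.
#' @return verdict string.
#' @export
simulate_respondent <- function(true_weights, task, tie_tol = 0, forced = FALSE) {
  vals <- true_weights$values
  tot <- function(lev) sum(vapply(seq_along(lev), function(j)
    vals[[j]][lev[j] + 1L], numeric(1)))
  d <- tot(task$a) - tot(task$b)
  if (d > tie_tol) "a_preferred"
  else if (d < -tie_tol) "b_preferred"
  else if (forced) "a_preferred" else "indifferent"
}

#' Run a full simulated elicitation session
#'
#' Repeatedly asks [next_task()] and answers with [simulate_respondent()] until
#' every candidate pair is decided or implied. Deterministic given the
#' instrument and the true weights.
#'
#' @inheritParams simulate_respondent
#' @param instrument a `bapt_instrument`.
#' @param respondent_id label for the transcript.
#' @param max_questions safety cap.
#' @return list with `store`, and `transcript` (data.frame seq, ia, ib,
#'   verdict).
#' @export
run_session <- function(instrument, true_weights, tie_tol = 0, forced = TRUE,
                        respondent_id = "sim", max_questions = 5000L) {
  store <- preference_store(instrument, generalise = TRUE)
  seqs <- ias <- ibs <- integer(0); verdicts <- character(0)
  repeat {
    task <- next_task(store)
    if (is.null(task)) break
    if (length(seqs) >= max_questions)
      stop("session exceeded max_questions = ", max_questions, call. = FALSE)
    v <- simulate_respondent(true_weights, task, tie_tol = tie_tol, forced = forced)
    record_judgement(store, task$a, task$b, v, respondent_id = respondent_id)
    seqs <- c(seqs, length(seqs) + 1L)
    ias <- c(ias, task$ia); ibs <- c(ibs, task$ib); verdicts <- c(verdicts, v)
  }
  list(store = store,
       transcript = data.frame(seq = seqs, ia = ias, ib = ibs, verdict = verdicts,
                               respondent = respondent_id))
}

#' Provenance accounting over the candidate pairs
#'
#' For every candidate trade-off pair, how it was decided: asked directly
#' (`judged`), settled by `dominance` (never, by construction: candidates are
#' mutually non-dominated), implied (`transitivity`), or still `undecided`.
#'
#' @param store a `preference_store`.
#' @return named integer vector with components judged, dominance,
#'   transitivity, undecided, and total.
#' @export
provenance_summary <- function(store) {
  cand <- candidate_tasks(store$instrument)
  code_ab <- as.integer(store$prov[cbind(cand$a, cand$b)])
  code_ba <- as.integer(store$prov[cbind(cand$b, cand$a)])
  stat <- pref_status(store$W, cand$a, cand$b)
  first <- ifelse(stat == 0L, 0L,
                  ifelse(code_ab == 1L | code_ba == 1L, 1L,
                         ifelse(code_ab == 2L | code_ba == 2L, 2L, 3L)))
  c(judged = sum(first == 1L), dominance = sum(first == 2L),
    transitivity = sum(first == 3L), undecided = sum(first == 0L),
    total = nrow(cand))
}

#' Write / read a session transcript as JSONL
#'
#' One judgement per line: `{"seq", "respondent", "state_a", "state_b",
#' "verdict", "snapshot_hash"}`; states are 0-based level vectors. Replayable
#' with [replay_session()].
#'
#' @param session result of [run_session()], or a store.
#' @param path JSONL file.
#' @export
write_session <- function(session, path) {
  store <- if (inherits(session, "preference_store")) session else session$store
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  hash <- 0L
  for (j in store$judgements) {
    hash <- (hash * 31L + sum(j$a) * 7L + sum(j$b) + nchar(j$verdict)) %% 999983L
    writeLines(jsonlite::toJSON(list(seq = j$seq, respondent = j$respondent,
                                     state_a = j$a, state_b = j$b,
                                     verdict = j$verdict, snapshot_hash = hash),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_session
#' @param instrument instrument the session was recorded against.
#' @param generalise see [preference_store()].
#' @return `replay_session()`: a rebuilt `preference_store`.
#' @export
replay_session <- function(path, instrument, generalise = TRUE) {
  store <- preference_store(instrument, generalise = generalise)
  for (line in readLines(path, encoding = "UTF-8")) {
    if (!nzchar(line)) next
    j <- jsonlite::fromJSON(line)
    record_judgement(store, as.integer(j$state_a), as.integer(j$state_b),
                     if (j$verdict == "indifferent") "indifferent" else "a_preferred",
                     respondent_id = j$respondent)
  }
  store
}

#' Random monotone true level weights
#'
#' Utility for recovery experiments: draws, per criterion, increasing level
#' values (worst fixed at 0) with a random criterion importance, then rescales
#' so the best levels sum to 100.
#'
#' @param instrument a `bapt_instrument`.
#' @param seed integer seed.
#' @return a `level_weights` object.
#' @export
random_weights <- function(instrument, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nl <- .n_levels(instrument)
  vals <- lapply(seq_along(nl), function(j) {
    v <- c(0, sort(runif(nl[j] - 1L)))
    v / max(v) * runif(1, 0.2, 1)
  })
  names(vals) <- names(instrument$criteria)
  top <- sum(vapply(vals, max, numeric(1)))
  vals <- lapply(vals, function(v) v / top * 100)
  structure(list(respondent_id = paste0("truth_seed", seed), values = vals,
                 margin = NA_real_), class = "level_weights")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
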