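# Health states: one level index per criterion (0 = worst). States are rows of
# an integer matrix in lexicographic order (first criterion most significant),
# so state ids are stable for a given instrument.

#' Enumerate all health states of an instrument
#'
#' Full Cartesian product of level indices, in deterministic lexicographic
#' order (first criterion most significant, 0 = worst level).
#'
#' @param instrument a `bapt_instrument`.
#' @return integer matrix, one row per state, one column per criterion.
#' @export
enumerate_states <- function(instrument) {
  nl <- .n_levels(instrument)
  n <- prod(nl)
  k <- length(nl)
  out <- matrix(0L, nrow = n, ncol = k, dimnames = list(NULL, names(instrument$criteria)))
  rep_each <- n
  for (j in seq_len(k)) {
    rep_each <- rep_each / nl[j]
    out[, j] <- rep(rep(0:(nl[j] - 1L), each = rep_each), length.out = n)
  }
  out
}

# state (vector of 0-based levels) -> row index in enumerate_states order
.state_index <- function(levels, nl) {
  idx <- 0L
  for (j in seq_along(nl)) idx <- idx * nl[j] + levels[j]
  idx + 1L
}

# vectorised: matrix of states -> indices
.state_indices <- function(m, nl) {
  idx <- rep(0, nrow(m))
  for (j in seq_along(nl)) idx <- idx * nl[j] + m[, j]
  as.integer(idx + 1)
}

#' Pareto dominance between two health states
#'
#' `a` dominates `b` when `a`'s level index is at least `b`'s on every
#' criterion and strictly greater on at least one (levels are ordered worst to
#' best, so a higher index is unambiguously better).
#'
#' @param a,b integer vectors of 0-based level indices, one per criterion (in
#'   instrument order, or named).
#' @param instrument the shared `bapt_instrument`.
#' @return logical.
#' @export
dominates <- function(a, b, instrument) {
  nms <- names(instrument$criteria)
  if (!is.null(names(a))) a <- a[nms]
  if (!is.null(names(b))) b <- b[nms]
  if (length(a) != length(nms) || length(b) != length(nms) || anyNA(a) || anyNA(b))
    stop("states must supply one level per instrument criterion", call. = FALSE)
  nl <- .n_levels(instrument)
  if (any(a < 0 | a >= nl) || any(b < 0 | b >= nl))
    stop("level index out of range", call. = FALSE)
  all(a >= b) && any(a > b)
}

# All two-criterion trade-off patterns: a pattern fixes a pair of criteria
# (c1 < c2 in instrument order) and two levels on each, and opposes
#   a = (c1 = hi1, c2 = lo2)   vs   b = (c1 = lo1, c2 = hi2),
# the only non-dominated pairing. Every candidate choice task is a pattern
# instantiated with some background on the remaining criteria.
.trade_off_patterns <- function(instrument) {
  nl <- .n_levels(instrument)
  k <- length(nl)
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    li <- utils::combn(0:(nl[i] - 1L), 2L)  # lo, hi pairs on criterion i
    lj <- utils::combn(0:(nl[j] - 1L), 2L)
    g <- expand.grid(pi = seq_len(ncol(li)), pj = seq_len(ncol(lj)))
    g <- g[order(g$pi, g$pj), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      c1 = i, c2 = j,
      lo1 = li[1L, g$pi], hi1 = li[2L, g$pi],
      lo2 = lj[1L, g$pj], hi2 = lj[2L, g$pj])
  }
  pat <- do.call(rbind, rows)
  rownames(pat) <- NULL
  pat
}

# instantiate a pattern with a background (default all-worst): returns the two
# full state level vectors
.pattern_states <- function(pat_row, k, background = NULL) {
  a <- b <- if (is.null(background)) integer(k) else as.integer(background)
  a[pat_row$c1] <- pat_row$hi1; a[pat_row$c2] <- pat_row$lo2
  b[pat_row$c1] <- pat_row$lo1; b[pat_row$c2] <- pat_row$hi2
  list(a = a, b = b)
}

#' Candidate two-criterion choice tasks
#'
#' All unordered pairs of states that agree on all but exactly two criteria and
#' where neither state dominates the other. These are the only pairs a
#' PAPRIKA-style elicitation ever asks about; everything else is settled by
#' dominance or implied by earlier answers. Order is deterministic: by
#' criterion pair, level pattern, then background (lexicographic).
#'
#' @param instrument a `bapt_instrument`.
#' @return data.frame with columns `a`, `b` (state row indices into
#'   [enumerate_states()]), `c1`, `c2` (differing criterion names) and the
#'   pattern columns `lo1`, `hi1`, `lo2`, `hi2`. State `a` is the one better on
#'   the earlier criterion.
#' @export
candidate_tasks <- function(instrument) {
  nl <- .n_levels(instrument)
  k <- length(nl)
  if (k < 2L)
    return(data.frame(a = integer(0), b = integer(0), c1 = character(0),
                      c2 = character(0)))
  pat <- .trade_off_patterns(instrument)
  nms <- names(instrument$criteria)
  out <- vector("list", nrow(pat))
  for (p in seq_len(nrow(pat))) {
    others <- setdiff(seq_len(k), c(pat$c1[p], pat$c2[p]))
    bg <- if (length(others)) {
      g <- do.call(expand.grid, rev(lapply(others, function(j) 0:(nl[j] - 1L))))
      as.matrix(g[, rev(seq_along(others)), drop = FALSE])  # lexicographic
    } else matrix(integer(0), nrow = 1, ncol = 0)
    am <- bm <- matrix(0L, nrow = nrow(bg), ncol = k)
    if (length(others)) { am[, others] <- bg; bm[, others] <- bg }
    am[, pat$c1[p]] <- pat$hi1[p]; am[, pat$c2[p]] <- pat$lo2[p]
    bm[, pat$c1[p]] <- pat$lo1[p]; bm[, pat$c2[p]] <- pat$hi2[p]
    out[[p]] <- data.frame(a = .state_indices(am, nl), b = .state_indices(bm, nl),
                           c1 = nms[pat$c1[p]], c2 = nms[pat$c2[p]],
                           lo1 = pat$lo1[p], hi1 = pat$hi1[p],
                           lo2 = pat$lo2[p], hi2 = pat$hi2[p],
                           pattern = p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
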