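# Small deterministic dense simplex, sufficient for the max-margin weight LPs
# (tens of variables, a few hundred constraints). Bland's rule throughout:
# slower than Dantzig but cycle-free and fully deterministic.

#' Solve a small linear programme
#'
#' Minimises `obj %*% x` subject to `A x (<=|==|>=) b`, `x >= 0`, by the
#' two-phase tableau simplex with Bland's anti-cycling rule.
#'
#' @param obj objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand sides (length m).
#' @param dir character vector of `"<="`, `"=="`, `">="` per row.
#' @param tol numerical tolerance.
#' @return list with `status` ("optimal", "infeasible", "unbounded"), `x`,
#'   `objval`.
#' @export
simplex_lp <- function(obj, A, b, dir, tol = 1e-9) {
  A <- as.matrix(A); b <- as.numeric(b); obj <- as.numeric(obj)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(dir) == m, length(obj) == n)
  # make b >= 0
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  dir[neg] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[neg]]

  n_slack <- sum(dir != "==")
  n_art <- sum(dir != "<=")
  N <- n + n_slack + n_art
  Tb <- matrix(0, m, N)
  Tb[, seq_len(n)] <- A
  basis <- integer(m)
  si <- n; ai <- n + n_slack
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      si <- si + 1L; Tb[i, si] <- 1; basis[i] <- si
    } else if (dir[i] == ">=") {
      si <- si + 1L; Tb[i, si] <- -1
      ai <- ai + 1L; Tb[i, ai] <- 1; basis[i] <- ai; art_cols <- c(art_cols, ai)
    } else {
      ai <- ai + 1L; Tb[i, ai] <- 1; basis[i] <- ai; art_cols <- c(art_cols, ai)
    }
  }
  rhs <- b

  pivot <- function(Tb, rhs, basis, r, c) {
    piv <- Tb[r, c]
    Tb[r, ] <- Tb[r, ] / piv
    rhs[r] <- rhs[r] / piv
    for (i in seq_len(nrow(Tb))) {
      if (i == r) next
      f <- Tb[i, c]
      if (abs(f) > 0) {
        Tb[i, ] <- Tb[i, ] - f * Tb[r, ]
        rhs[i] <- rhs[i] - f * rhs[r]
      }
    }
    basis[r] <- c
    list(Tb = Tb, rhs = rhs, basis = basis)
  }

  # Dantzig pivoting (most negative reduced cost) with a deterministic switch
  # to Bland's rule after many iterations, guaranteeing termination
  run_phase <- function(Tb, rhs, basis, cost, allowed) {
    iter <- 0L
    bland_after <- 50L * (nrow(Tb) + ncol(Tb))
    repeat {
      iter <- iter + 1L
      cb <- cost[basis]
      red <- cost - as.vector(cb %*% Tb)
      red[!allowed] <- Inf
      enter <- which(red < -tol)
      if (!length(enter)) return(list(Tb = Tb, rhs = rhs, basis = basis,
                                      status = "optimal"))
      c <- if (iter > bland_after) min(enter)           # Bland: smallest index
           else enter[which.min(red[enter])]            # Dantzig, first-min ties
      col <- Tb[, c]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, rhs = rhs, basis = basis,
                                    status = "unbounded"))
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]  # leave smallest basis index
      p <- pivot(Tb, rhs, basis, r, c)
      Tb <- p$Tb; rhs <- p$rhs; basis <- p$basis
    }
  }

  allowed <- rep(TRUE, N)
  if (n_art > 0) {
    cost1 <- numeric(N); cost1[art_cols] <- 1
    ph1 <- run_phase(Tb, rhs, basis, cost1, allowed)
    Tb <- ph1$Tb; rhs <- ph1$rhs; basis <- ph1$basis
    if (sum(rhs[basis %in% art_cols]) > 1e-7)
      return(list(status = "infeasible", x = NULL, objval = NA_real_))
    # pivot remaining artificials out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      row <- Tb[i, seq_len(n + n_slack)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        p <- pivot(Tb, rhs, basis, i, min(j))
        Tb <- p$Tb; rhs <- p$rhs; basis <- p$basis
      }
    }
    allowed[art_cols] <- FALSE
  }
  cost2 <- c(obj, numeric(N - n))
  ph2 <- run_phase(Tb, rhs, basis, cost2, allowed)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  x <- numeric(N)
  x[ph2$basis] <- ph2$rhs
  list(status = "optimal", x = x[seq_len(n)],
       objval = sum(obj * x[seq_len(n)]))
}
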