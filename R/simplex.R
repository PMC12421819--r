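# Dense two-phase simplex for the small LPs arising from core-model FBA.
# No LP solver ships with the supported R stack, and the models solved here
# are tiny (tens of rows/columns), so a tableau implementation is adequate
# and easy to verify against enumeration oracles.

#' Solve a small dense linear program
#'
#' Minimises `obj %*% x` subject to `A %*% x == b` and `lower <= x <= upper`,
#' using a two-phase tableau simplex with Bland's anti-cycling rule.
#'
#' Intended for the package's internal flux balance problems; sizes beyond a
#' few hundred variables will be slow.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lower,upper variable bounds; `upper` may contain `Inf`.
#' @param maximize if `TRUE`, maximise instead of minimise.
#' @param tol feasibility/optimality tolerance.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` (solution on the original scale) and `objval`.
#' @keywords internal
solve_lp <- function(obj, A, b, lower = NULL, upper = NULL,
                     maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  A <- as.matrix(A)
  stopifnot(ncol(A) == n, nrow(A) == length(b))
  if (is.null(lower)) lower <- rep(0, n)
  if (is.null(upper)) upper <- rep(Inf, n)
  if (any(lower > upper + tol)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  cvec <- if (maximize) -obj else obj

  # Shift lower bounds to zero: y = x - lower.
  finite_l <- is.finite(lower)
  if (!all(finite_l)) stop("solve_lp requires finite lower bounds")
  b2 <- b - as.numeric(A %*% lower)
  ub <- upper - lower

  # Fixed variables (ub == 0 after shift) drop out.
  fixed <- ub <= tol
  keep <- which(!fixed)
  A2 <- A[, keep, drop = FALSE]
  c2 <- cvec[keep]
  ub2 <- ub[keep]
  nk <- length(keep)

  # Finite upper bounds become slack rows y_i + s_i = ub_i.
  fin_ub <- which(is.finite(ub2))
  m0 <- nrow(A2)
  mu <- length(fin_ub)
  m <- m0 + mu
  ntot <- nk + mu
  Afull <- matrix(0, m, ntot)
  Afull[seq_len(m0), seq_len(nk)] <- A2
  if (mu > 0) {
    for (k in seq_along(fin_ub)) {
      Afull[m0 + k, fin_ub[k]] <- 1
      Afull[m0 + k, nk + k] <- 1
    }
  }
  bfull <- c(b2, ub2[fin_ub])
  cfull <- c(c2, rep(0, mu))

  res <- simplex_two_phase(cfull, Afull, bfull, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, objval = NA_real_))
  }
  x <- numeric(n)
  x[keep] <- res$x[seq_len(nk)]
  x <- x + lower
  objval <- sum(obj * x)
  list(status = "optimal", x = x, objval = objval)
}

# Two-phase tableau simplex: min c'x s.t. Ax = b, x >= 0.
simplex_two_phase <- function(cvec, A, b, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # Phase 1 tableau with m artificial columns.
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  Tb <- run_simplex(Tb, basis, cost1, tol)
  basis <- attr(Tb, "basis")
  if (attr(Tb, "status") != "optimal") {
    return(list(status = "infeasible", x = NULL))
  }
  p1 <- sum(cost1[basis] * Tb[, ncol(Tb)])
  if (p1 > 1e-7) return(list(status = "infeasible", x = NULL))

  # Drive artificials out of the basis where possible; redundant rows are
  # left in place (their artificial stays basic at zero and is frozen).
  art <- which(basis > n)
  for (r in art) {
    piv <- which(abs(Tb[r, seq_len(n)]) > tol)
    if (length(piv) > 0) {
      Tb <- pivot_tableau(Tb, r, piv[1])
      basis[r] <- piv[1]
    }
  }

  cost2 <- c(cvec, rep(Inf, m))  # Inf marks artificials as never-entering
  Tb2 <- Tb
  attr(Tb2, "basis") <- basis
  Tb2 <- run_simplex(Tb2, basis, cost2, tol)
  basis <- attr(Tb2, "basis")
  status <- attr(Tb2, "status")
  if (status != "optimal") return(list(status = status, x = NULL))
  x <- numeric(n)
  rhs <- Tb2[, ncol(Tb2)]
  inb <- basis <= n
  x[basis[inb]] <- rhs[inb]
  list(status = "optimal", x = x)
}

run_simplex <- function(Tb, basis, cost, tol, max_iter = 20000L) {
  m <- nrow(Tb)
  ncols <- ncol(Tb) - 1L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("simplex iteration limit reached")
    cb <- cost[basis]
    cb[!is.finite(cb)] <- 0  # frozen artificials at zero contribute nothing
    # reduced costs
    red <- cost - as.numeric(cb %*% Tb[, seq_len(ncols), drop = FALSE])
    red[!is.finite(cost)] <- Inf  # artificials barred in phase 2
    cand <- which(red < -tol)
    if (length(cand) == 0) {
      attr(Tb, "status") <- "optimal"
      attr(Tb, "basis") <- basis
      return(Tb)
    }
    # Dantzig early, Bland once iterations pile up (anti-cycling).
    enter <- if (iter < 2L * (m + ncols)) cand[which.min(red[cand])] else min(cand)
    col <- Tb[, enter]
    pos <- which(col > tol)
    if (length(pos) == 0) {
      attr(Tb, "status") <- "unbounded"
      attr(Tb, "basis") <- basis
      return(Tb)
    }
    ratios <- Tb[pos, ncols + 1L] / col[pos]
    rmin <- min(ratios)
    tiespos <- pos[ratios <= rmin + tol]
    leave <- tiespos[which.min(basis[tiespos])]  # Bland tie-break
    Tb <- pivot_tableau(Tb, leave, enter)
    basis[leave] <- enter
  }
}

pivot_tableau <- function(Tb, r, s) {
  Tb[r, ] <- Tb[r, ] / Tb[r, s]
  other <- setdiff(seq_len(nrow(Tb)), r)
  Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, s], Tb[r, ])
  Tb
}
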