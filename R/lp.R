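# Dense bounded-variable primal simplex, two phases, Bland's rule.
#
# Solves  max/min  c'x   s.t.  A x = b,  lb <= x <= ub.
#
# Written for the desk-scale problems this package actually solves
# (toy networks, tens of variables): the basis inverse is recomputed by a
# dense solve at every iteration, trading speed for numerical hygiene and
# simplicity. Bland's smallest-index rule is used throughout, so the
# method cannot cycle. Infinite bounds are clamped to +-1e6; a solution
# pressed against a clamped bound is reported as unbounded.

LP_BIG <- 1e6

#' Solve a linear program with bounded variables
#'
#' A small, dependency-free simplex solver for problems of the form
#' max (or min) `c'x` subject to `A x = b` and `lb <= x <= ub`. It
#' returns an optimal basic (vertex) solution; the optimal objective
#' value is unique even when the solution vector is degenerate.
#'
#' @param obj Objective coefficient vector `c`.
#' @param A Constraint matrix (dense or sparse; coerced to dense).
#' @param rhs Right-hand side `b`.
#' @param lb,ub Variable bounds; infinite entries are clamped to
#'   +-1e6 and flagged in the status when active at the optimum.
#' @param sense `"max"` or `"min"`.
#' @param tol Pivot/reduced-cost tolerance.
#' @param maxit Iteration cap per phase.
#' @return List with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective` and the solution vector `x`.
#' @export
solve_lp <- function(obj, A, rhs, lb, ub, sense = c("max", "min"),
                     tol = 1e-9, maxit = 50000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  clamped <- is.infinite(lb) | is.infinite(ub)
  lb <- pmax(lb, -LP_BIG)
  ub <- pmin(ub, LP_BIG)
  cc <- if (sense == "min") -obj else obj

  # start nonbasic at the bound nearer zero
  x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)
  start_at_lb <- abs(lb) <= abs(ub)
  resid <- rhs - as.vector(A %*% x0)
  artsign <- ifelse(resid >= 0, 1, -1)
  Aext <- cbind(A, diag(artsign, nrow = m, ncol = m))
  art <- n + seq_len(m)
  xval <- c(x0, abs(resid))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  nbstat <- c(ifelse(start_at_lb, 1L, 2L), rep(0L, m))  # 0 basic, 1 at lb, 2 at ub
  basis <- art

  # phase 1: drive artificials to zero
  p1 <- simplex_core(Aext, rhs, lbe, ube, c(rep(0, n), rep(-1, m)),
                     basis, xval, nbstat, tol, maxit)
  if (p1$status == "maxit") {
    rlang::abort("simplex iteration limit reached (phase 1).",
                 class = "fluxscape_lp_error")
  }
  if (sum(p1$xval[art]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  # pin artificials at zero and optimize the real objective
  lbe[art] <- 0; ube[art] <- 0
  p1$xval[art] <- pmax(p1$xval[art], 0)
  p2 <- simplex_core(Aext, rhs, lbe, ube, c(cc, rep(0, m)),
                     p1$basis, p1$xval, p1$nbstat, tol, maxit)
  if (p2$status == "maxit") {
    rlang::abort("simplex iteration limit reached (phase 2).",
                 class = "fluxscape_lp_error")
  }
  x <- p2$xval[seq_len(n)]
  objective <- sum(cc * x)
  status <- "optimal"
  if (p2$status == "unbounded" ||
      any(clamped & (abs(x - LP_BIG) < 1e-6 | abs(x + LP_BIG) < 1e-6))) {
    status <- "unbounded"
  }
  if (sense == "min") objective <- -objective
  list(status = status, objective = objective, x = x)
}

simplex_core <- function(Aext, b, lbe, ube, cost, basis, xval, nbstat,
                         tol, maxit) {
  ncols <- ncol(Aext)
  for (it in seq_len(maxit)) {
    B <- Aext[, basis, drop = FALSE]
    nonbas <- which(nbstat != 0L)
    rhsB <- b - as.vector(Aext[, nonbas, drop = FALSE] %*% xval[nonbas])
    xB <- tryCatch(solve(B, rhsB), error = function(e) {
      rlang::abort("singular basis in simplex.", class = "fluxscape_lp_error")
    })
    xval[basis] <- xB
    y <- solve(t(B), cost[basis])
    d <- cost[nonbas] - as.vector(crossprod(Aext[, nonbas, drop = FALSE], y))
    movable <- (ube[nonbas] - lbe[nonbas]) > tol
    eligible <- movable &
      ((nbstat[nonbas] == 1L & d > tol) | (nbstat[nonbas] == 2L & d < -tol))
    if (!any(eligible)) {
      return(list(status = "optimal", basis = basis, xval = xval, nbstat = nbstat))
    }
    e <- nonbas[eligible][1L]  # Bland: smallest index
    dir <- if (nbstat[e] == 1L) 1 else -1
    w <- solve(B, Aext[, e])
    # basic values move as xB - dir * w * step
    coef <- dir * w
    step_basic <- rep(Inf, length(basis))
    up <- coef > tol
    dn <- coef < -tol
    step_basic[up] <- (xB[up] - lbe[basis[up]]) / coef[up]
    step_basic[dn] <- (xB[dn] - ube[basis[dn]]) / coef[dn]
    step_flip <- ube[e] - lbe[e]
    step <- min(c(step_basic, step_flip))
    if (!is.finite(step)) {
      return(list(status = "unbounded", basis = basis, xval = xval, nbstat = nbstat))
    }
    step <- max(step, 0)
    xval[e] <- xval[e] + dir * step
    xval[basis] <- xB - coef * step
    if (step_flip <= min(step_basic) + 1e-12 && step_flip <= step + 1e-12) {
      nbstat[e] <- if (nbstat[e] == 1L) 2L else 1L  # bound flip, basis unchanged
    } else {
      blockers <- which(step_basic <= step + 1e-12)
      r <- blockers[which.min(basis[blockers])]     # Bland on the leaving side
      leave <- basis[r]
      if (coef[r] > 0) {
        xval[leave] <- lbe[leave]; nbstat[leave] <- 1L
      } else {
        xval[leave] <- ube[leave]; nbstat[leave] <- 2L
      }
      basis[r] <- e
      nbstat[e] <- 0L
    }
  }
  list(status = "maxit", basis = basis, xval = xval, nbstat = nbstat)
}
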