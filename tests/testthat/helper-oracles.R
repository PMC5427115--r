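# Independent oracles used to cross-check the solvers.

# Exhaustive vertex (basic feasible solution) enumeration for
#   max c'x  s.t.  S x = 0, lb <= x <= ub.
# Independent of the simplex path: tries every candidate basis and every
# lower/upper assignment of the nonbasic variables.
enumerate_lp_optimum <- function(obj, S, lb, ub, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  qs <- qr(t(S))
  r <- qs$rank
  S2 <- S[qs$pivot[seq_len(r)], , drop = FALSE]  # independent rows (b = 0 stays consistent)
  best <- -Inf
  for (basic in utils::combn(n, r, simplify = FALSE)) {
    B <- S2[, basic, drop = FALSE]
    if (qr(B)$rank < r) next
    nonbasic <- setdiff(seq_len(n), basic)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nonbasic)))
    for (g in seq_len(max(nrow(grid), 1L))) {
      x <- numeric(n)
      if (length(nonbasic)) {
        at_ub <- unlist(grid[g, ])
        x[nonbasic] <- ifelse(at_ub, ub[nonbasic], lb[nonbasic])
      }
      rhs <- -S2[, nonbasic, drop = FALSE] %*% x[nonbasic]
      xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xb) || any(!is.finite(xb))) next
      x[basic] <- xb
      if (any(x < lb - tol) || any(x > ub + tol)) next
      if (max(abs(S %*% x)) > 1e-6) next
      best <- max(best, sum(obj * x))
    }
  }
  best
}

# Dual of  max c'x s.t. A x = b, l <= x <= u  (all bounds finite):
#   min b'y + u'mu - l'lambda  s.t.  A'y + mu - lambda = c, mu, lambda >= 0.
# Solving it is an independent route to the same optimal value.
solve_lp_dual <- function(obj, A, rhs, lb, ub) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  Ad <- cbind(t(A), diag(n), -diag(n))
  cd <- c(rhs, ub, -lb)
  fluxscape::solve_lp(cd, Ad, obj,
                      lb = c(rep(-Inf, m), rep(0, 2 * n)),
                      ub = rep(Inf, m + 2 * n),
                      sense = "min")
}

# Brute-force iMAT oracle: enumerate which HIGH calls are satisfied (and
# in which direction) and which LOW calls are satisfied, check each
# pattern for LP feasibility, and return the best satisfiable count.
imat_brute_force <- function(model, classes, fix = NULL, epsilon = 1e-3) {
  if (!is.null(fix)) {
    for (id in names(fix)) model <- fluxscape::fix_flux(model, id, fix[[id]])
  }
  S <- as.matrix(fluxscape::build_stoich_matrix(model))
  ids <- model$reactions$id
  lb0 <- model$reactions$lb
  ub0 <- model$reactions$ub
  cls <- as.character(classes$class)[match(ids, classes$reaction_id)]
  high <- which(cls == "HIGH")
  low <- which(cls == "LOW")
  # per HIGH reaction: 0 = unsat, 1 = forward >= eps, 2 = reverse <= -eps
  # per LOW reaction: 0 = unsat, 1 = v == 0
  states <- c(rep(list(0:2), length(high)), rep(list(0:1), length(low)))
  if (length(states) == 0L) return(0L)
  grid <- expand.grid(states)
  best <- -1L
  for (g in seq_len(nrow(grid))) {
    s <- unlist(grid[g, ])
    sat <- sum(s[seq_along(high)] > 0) +
      sum(s[length(high) + seq_along(low)] > 0)
    if (sat <= best) next
    lb <- lb0; ub <- ub0
    ok <- TRUE
    for (k in seq_along(high)) {
      r <- high[k]
      if (s[k] == 1) lb[r] <- max(lb[r], epsilon)
      if (s[k] == 2) ub[r] <- min(ub[r], -epsilon)
      if (lb[r] > ub[r]) { ok <- FALSE; break }
    }
    if (ok) for (k in seq_along(low)) {
      r <- low[k]
      if (s[length(high) + k] == 1) {
        # "carries no flux" at the solver's feasibility tolerance, so the
        # oracle and the MILP share one numerical definition of zero
        # (e.g. a token growth rate of 1e-10 counts as zero for both)
        lb[r] <- max(lb[r], -1e-7); ub[r] <- min(ub[r], 1e-7)
        if (lb[r] > ub[r]) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    feas <- fluxscape::solve_lp(rep(0, length(ids)), S, rep(0, nrow(S)),
                                lb, ub)
    if (feas$status == "optimal") best <- sat
  }
  max(best, 0L)
}
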