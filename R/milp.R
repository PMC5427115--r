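# Mixed-integer LP by LP-relaxation branch and bound, for the small
# consistency-maximization problems of the transcriptome-integration
# stage. Binary variables only; depth-first search, best-first branch
# on the most fractional variable, pruning against the incumbent.

#' Solve a mixed-integer linear program with binary variables
#'
#' Branch and bound over the LP relaxation solved by [solve_lp()].
#' Intended for the small problems this package generates (tens of
#' binaries at most).
#'
#' @param obj,A,rhs,lb,ub,sense As in [solve_lp()].
#' @param int_idx Indices of variables required to be integral (in
#'   practice binary, bounds 0/1).
#' @param int_tol Integrality tolerance.
#' @return List with `status` (`"optimal"` or `"infeasible"`),
#'   `objective` and `x`.
#' @export
solve_milp <- function(obj, A, rhs, lb, ub, int_idx, sense = c("max", "min"),
                       int_tol = 1e-6) {
  sense <- match.arg(sense)
  sgn <- if (sense == "min") -1 else 1
  best <- list(objective = -Inf, x = NULL)

  explore <- function(lb, ub) {
    rel <- solve_lp(sgn * obj, A, rhs, lb, ub, sense = "max")
    if (rel$status != "optimal") return(invisible(NULL))
    if (rel$objective <= best$objective + 1e-9) return(invisible(NULL))
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (all(frac <= int_tol)) {
      # a binary at 1 - O(eps/M) can pass the tolerance while voiding its
      # big-M constraint: accept only after re-solving with the binaries
      # pinned to their rounded values.
      lbf <- lb; ubf <- ub
      lbf[int_idx] <- ubf[int_idx] <- round(rel$x[int_idx])
      chk <- solve_lp(sgn * obj, A, rhs, lbf, ubf, sense = "max")
      if (chk$status == "optimal") {
        if (chk$objective > best$objective + 1e-9) {
          best <<- list(objective = chk$objective, x = chk$x)
        }
        return(invisible(NULL))
      }
      free <- int_idx[lb[int_idx] < ub[int_idx]]
      if (length(free) == 0L) return(invisible(NULL))
      # binaries only: pin the chosen variable to each of its two values
      j <- free[which.max(frac[match(free, int_idx)])]
      lo_ub <- ub; lo_ub[j] <- lb[j]
      hi_lb <- lb; hi_lb[j] <- ub[j]
      explore(hi_lb, ub); explore(lb, lo_ub)
      return(invisible(NULL))
    }
    j <- int_idx[which.max(frac)]
    v <- rel$x[j]
    # explore the rounding-preferred side first
    lo_ub <- ub; lo_ub[j] <- floor(v)
    hi_lb <- lb; hi_lb[j] <- ceiling(v)
    if (v - floor(v) < 0.5) {
      explore(lb, lo_ub); explore(hi_lb, ub)
    } else {
      explore(hi_lb, ub); explore(lb, lo_ub)
    }
    invisible(NULL)
  }
  explore(lb, ub)

  if (is.null(best$x)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, length(obj))))
  }
  list(status = "optimal", objective = sgn * best$objective, x = best$x)
}
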