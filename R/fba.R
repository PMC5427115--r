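#' Zero-flux threshold used across the package
#'
#' Fluxes below this magnitude (mmol/gDW/h) are treated as numerically
#' zero when counting active ("flux-carrying") reactions and when
#' deciding whether a flux increased during the overexpression scan.
#' @export
FLUX_ZERO <- 1e-6

lp_from_model <- function(model) {
  S <- as.matrix(build_stoich_matrix(model))
  list(
    S = S,
    rhs = rep(0, nrow(S)),
    lb = model$reactions$lb,
    ub = model$reactions$ub,
    ids = model$reactions$id
  )
}

new_flux_result <- function(status, objective_value, fluxes, objective_id,
                            sense, method) {
  structure(
    list(status = status, objective_value = objective_value, fluxes = fluxes,
         objective_id = objective_id, sense = sense, method = method),
    class = "flux_result"
  )
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result> ", x$method, " ", x$sense, " ", x$objective_id,
      "\n  status: ", x$status,
      "\n  objective: ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Flux balance analysis
#'
#' Solves the canonical FBA linear program: find a steady-state flux
#' vector `v` (`S v = 0`, the net production and consumption of every
#' internal metabolite balancing to zero) within the bounds
#' `lb <= v <= ub` that maximizes (or minimizes) the flux through one
#' objective reaction. The optimal objective value is unique; the flux
#' vector is one optimal vertex and may be degenerate — use [pfba()]
#' for a deterministic representative.
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id to optimize; defaults to the model's
#'   objective (biomass).
#' @param sense `"max"` or `"min"`.
#' @return A `flux_result`: `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective_value`, and `fluxes` (named vector,
#'   mmol/gDW/h). Infeasibility is reported in `status`, never
#'   silently.
#' @examples
#' m <- generate_toy_model(toy_model_spec())$model
#' fba(m)$objective_value
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  objective <- objective %||% model$objective
  rxn_row(model, objective)  # validates
  lp <- lp_from_model(model)
  cc <- as.numeric(lp$ids == objective)
  sol <- solve_lp(cc, lp$S, lp$rhs, lp$lb, lp$ub, sense = sense)
  fluxes <- stats::setNames(sol$x, lp$ids)
  new_flux_result(sol$status,
                  if (sol$status == "optimal") sol$objective else NA_real_,
                  if (sol$status == "optimal") fluxes else
                    stats::setNames(rep(NA_real_, length(lp$ids)), lp$ids),
                  objective, sense, "fba")
}

#' Parsimonious FBA
#'
#' Among the (possibly many) flux vectors attaining the FBA optimum,
#' returns the one minimizing total absolute flux `sum(|v|)`. This is
#' the package's deterministic representative of a degenerate optimum:
#' it removes thermodynamically meaningless flux cycles and makes
#' downstream flux profiles (Pareto sweeps, enforced-objective scans,
#' activity censuses) reproducible across solvers and orderings.
#'
#' @inheritParams fba
#' @param optimum_tol Relative slack allowed on the optimal objective
#'   when minimizing total flux.
#' @return A `flux_result` with `method = "pfba"`; `objective_value`
#'   is the FBA optimum.
#' @export
pfba <- function(model, objective = NULL, sense = c("max", "min"),
                 optimum_tol = 1e-9) {
  sense <- match.arg(sense)
  objective <- objective %||% model$objective
  base <- fba(model, objective, sense)
  if (base$status != "optimal") return(base)
  opt <- base$objective_value

  lp <- lp_from_model(model)
  n <- length(lp$ids)
  cc <- as.numeric(lp$ids == objective)
  # split v = p - q, p,q >= 0; pin the objective within tolerance of the
  # optimum via a slack column, then minimize sum(p + q).
  eps <- optimum_tol * (1 + abs(opt))
  sense_sgn <- if (sense == "max") 1 else -1
  # sense max: c'v >= opt - eps ; sense min: c'v <= opt + eps
  A2 <- rbind(
    cbind(lp$S, -lp$S, 0),
    c(sense_sgn * cc, -sense_sgn * cc, -1)
  )
  rhs2 <- c(lp$rhs, sense_sgn * opt - eps)
  lb2 <- c(pmax(lp$lb, 0), pmax(-lp$ub, 0), 0)
  ub2 <- c(pmax(lp$ub, 0), pmax(-lp$lb, 0), 2 * eps + 1)
  obj2 <- c(rep(1, 2 * n), 0)
  sol <- solve_lp(obj2, A2, rhs2, lb2, ub2, sense = "min")
  if (sol$status != "optimal") {
    rlang::abort("parsimonious step failed unexpectedly.",
                 class = "fluxscape_lp_error")
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  new_flux_result("optimal", opt, stats::setNames(v, lp$ids),
                  objective, sense, "pfba")
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimum and maximum steady-state
#' flux compatible with the bounds and, optionally, with retaining a
#' fraction of the optimal objective.
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reactions to scan (default: all).
#' @param fraction Fraction (0-1) of the optimal objective that must be
#'   retained; 0 drops the objective constraint entirely.
#' @param objective Objective reaction for the fraction constraint.
#' @return Tibble with `id`, `min`, `max` (mmol/gDW/h).
#' @export
fva <- function(model, reaction_ids = NULL, fraction = 0, objective = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  objective <- objective %||% model$objective
  reaction_ids <- reaction_ids %||% model$reactions$id
  purrr::walk(reaction_ids, rxn_row, model = model)
  lp <- lp_from_model(model)
  n <- length(lp$ids)
  A <- lp$S; rhs <- lp$rhs; lb <- lp$lb; ub <- lp$ub
  if (fraction > 0) {
    base <- fba(model, objective, "max")
    if (base$status != "optimal") {
      rlang::abort(paste0("model infeasible; cannot run FVA (status ",
                          base$status, ")."),
                   class = "fluxscape_infeasible_error")
    }
    cc <- as.numeric(lp$ids == objective)
    A <- rbind(cbind(A, 0), c(cc, -1))           # c'v - s = f * opt, s >= 0
    rhs <- c(rhs, fraction * base$objective_value)
    lb <- c(lb, 0); ub <- c(ub, Inf)
  } else if (ncol(A) == n) {
    A <- cbind(A)  # no-op; keep shapes aligned
  }
  res <- purrr::map(reaction_ids, function(id) {
    cc <- c(as.numeric(lp$ids == id), rep(0, ncol(A) - n))
    lo <- solve_lp(cc, A, rhs, lb, ub, sense = "min")
    hi <- solve_lp(cc, A, rhs, lb, ub, sense = "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      rlang::abort(paste0("FVA subproblem not optimal for ", id),
                   class = "fluxscape_infeasible_error")
    }
    tibble::tibble(id = id, min = lo$objective, max = hi$objective)
  })
  dplyr::bind_rows(res)
}

#' Define a growth medium as exchange uptake bounds
#'
#' A medium is the set of exchange reactions allowed to take material
#' up, each with a positive uptake magnitude; by the exchange sign
#' convention, uptake is negative flux, so applying a medium sets each
#' listed exchange's lower bound to minus its magnitude.
#'
#' @param components Named numeric vector: exchange reaction id ->
#'   uptake magnitude (>= 0, mmol/gDW/h).
#' @param closed_default If `TRUE` (default), every exchange not listed
#'   has its uptake blocked (`lb = 0`); secretion is never touched.
#' @return A `medium_spec`.
#' @export
medium_spec <- function(components, closed_default = TRUE) {
  stopifnot(is.numeric(components), !is.null(names(components)),
            all(nzchar(names(components))))
  if (any(components < 0)) {
    rlang::abort("uptake magnitudes must be >= 0.",
                 class = "fluxscape_medium_error")
  }
  structure(list(components = components, closed_default = closed_default),
            class = "medium_spec")
}

#' Apply a medium to a model
#'
#' @param model A `metabolic_model`.
#' @param medium A [medium_spec()] (a plain named numeric vector is
#'   promoted with `closed_default = TRUE`).
#' @return The constrained model.
#' @export
apply_medium <- function(model, medium) {
  if (!inherits(medium, "medium_spec")) medium <- medium_spec(medium)
  ex <- exchanges(model)
  unknown <- setdiff(names(medium$components), ex$id)
  if (length(unknown)) {
    rlang::abort(paste0("unknown exchange reactions in medium: ",
                        paste(unknown, collapse = ", ")),
                 class = "fluxscape_medium_error")
  }
  if (medium$closed_default) {
    for (id in setdiff(ex$id, names(medium$components))) {
      i <- rxn_row(model, id)
      model$reactions$lb[i] <- max(model$reactions$lb[i], 0)
    }
  }
  for (id in names(medium$components)) {
    i <- rxn_row(model, id)
    model$reactions$lb[i] <- -medium$components[[id]]
  }
  validate_model(model)
}
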