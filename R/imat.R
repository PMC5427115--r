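#' Quartile expression thresholds per time point
#'
#' The first and third quartiles of the RPKM distribution at each time
#' point define lowly and highly expressed genes. Quartiles use the
#' standard linear-interpolation definition (R's type 7).
#'
#' @param profile Expression tibble: `gene_id` plus one numeric RPKM
#'   column per time point.
#' @param timepoints Time points to compute (default: all expression
#'   columns).
#' @return Tibble: `timepoint`, `q1`, `q3`.
#' @export
compute_thresholds <- function(profile, timepoints = NULL) {
  cols <- setdiff(names(profile), "gene_id")
  timepoints <- timepoints %||% cols
  missing <- setdiff(timepoints, cols)
  if (length(missing)) {
    rlang::abort(paste0("time points not in profile: ",
                        paste(missing, collapse = ", ")),
                 class = "fluxscape_spec_error")
  }
  purrr::map_dfr(timepoints, function(tp) {
    x <- profile[[tp]]
    x <- x[!is.na(x)]
    if (length(x) < 4) {
      rlang::abort(paste0("need >= 4 expression values at ", tp),
                   class = "fluxscape_spec_error")
    }
    if (any(x < 0)) {
      rlang::abort("RPKM values must be >= 0.", class = "fluxscape_spec_error")
    }
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    tibble::tibble(timepoint = tp, q1 = q[1], q3 = q[2])
  })
}

#' Classify reactions as highly/lowly/moderately expressed
#'
#' Maps gene expression onto reactions through the GPR rules (AND ->
#' min over complex subunits, OR -> max over isozymes) and thresholds
#' the result: above the third quartile is HIGH, below the first is
#' LOW, anything else (including reactions with no GPR or with
#' unresolvable missing genes) is MODERATE.
#'
#' @param model A `metabolic_model`.
#' @param profile Expression tibble (`gene_id` + RPKM columns).
#' @param timepoint Which time point column to use.
#' @param thresholds Optional precomputed [compute_thresholds()]
#'   result; computed on the fly when `NULL`. Quartiles are taken over
#'   the whole expression table (all measured genes), not only those in
#'   the model.
#' @return Tibble: `reaction_id`, `expression`, `class` (factor
#'   HIGH/MODERATE/LOW).
#' @export
classify_reactions <- function(model, profile, timepoint, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- compute_thresholds(profile, timepoint)
  th <- thresholds[thresholds$timepoint == timepoint, ]
  if (nrow(th) != 1L) {
    rlang::abort(paste0("no thresholds for time point ", timepoint),
                 class = "fluxscape_spec_error")
  }
  values <- stats::setNames(profile[[timepoint]], profile$gene_id)
  n_missing <- length(setdiff(model$genes, profile$gene_id))
  if (n_missing > 0) {
    rlang::inform(paste0(n_missing, " model gene(s) missing from the ",
                         "expression profile; treated as absent."))
  }
  expr <- purrr::map_dbl(model$reactions$rule, eval_gpr, values = values)
  cls <- dplyr::case_when(
    is.na(expr) ~ "MODERATE",
    expr > th$q3 ~ "HIGH",
    expr < th$q1 ~ "LOW",
    TRUE ~ "MODERATE"
  )
  tibble::tibble(
    reaction_id = model$reactions$id,
    expression = expr,
    class = factor(cls, levels = c("HIGH", "MODERATE", "LOW"))
  )
}

#' iMAT: consistency-maximizing flux prediction
#'
#' Finds a steady-state flux distribution maximally consistent with a
#' HIGH/LOW reaction classification: each HIGH reaction is rewarded for
#' carrying at least `epsilon` flux (in either direction), each LOW
#' reaction for carrying none, subject to mass balance, bounds, and any
#' fixed fluxes (measured growth and production rates; when no growth
#' was observed experimentally, fix an arbitrary residual rate such as
#' 1e-10/h to retain maintenance costs). The maximization is a MILP
#' with one or two indicator binaries per classified reaction, solved
#' by branch and bound.
#'
#' @param model A `metabolic_model`.
#' @param classes A [classify_reactions()] tibble (or any tibble with
#'   `reaction_id` and `class`).
#' @param fix Named numeric vector of fluxes to pin (e.g.
#'   `c(BIOMASS = 0.012, EX_product = 0.0017)`).
#' @param epsilon Activation flux: the minimum magnitude a HIGH
#'   reaction must carry to count as active (default 0.001
#'   mmol/gDW/h).
#' @param zero_threshold Magnitude above which a reaction counts as
#'   flux-carrying in the returned activity calls.
#' @return An `imat_result`: `status`, `fluxes` (named), `active`
#'   (named logical), `score` (satisfied HIGH + LOW calls),
#'   `n_high`, `n_low`, `epsilon`, `fixed`.
#' @export
imat <- function(model, classes, fix = NULL, epsilon = 1e-3,
                 zero_threshold = FLUX_ZERO) {
  stopifnot(all(c("reaction_id", "class") %in% names(classes)))
  if (!is.null(fix)) {
    for (id in names(fix)) model <- fix_flux(model, id, fix[[id]])
  }
  lp <- lp_from_model(model)
  n <- length(lp$ids)
  m <- nrow(lp$S)
  cls <- as.character(classes$class)[match(lp$ids, classes$reaction_id)]
  cls[is.na(cls)] <- "MODERATE"
  high <- which(cls == "HIGH")
  low <- which(cls == "LOW")

  # columns: v (n) | y+ (high) | y- (high) | y0 (low) | slacks
  nh <- length(high); nl <- length(low)
  nbin <- 2L * nh + nl
  rows <- list(); rhs <- c(); slack_sign <- c()
  add_row <- function(v_coef, bin_coef, b, sense) {
    rows[[length(rows) + 1L]] <<- c(v_coef, bin_coef)
    rhs <<- c(rhs, b)
    slack_sign <<- c(slack_sign, switch(sense, le = 1, ge = -1, eq = 0))
  }
  unit <- function(len, i, x = 1) {
    out <- rep(0, len); out[i] <- x; out
  }
  for (k in seq_along(high)) {
    r <- high[k]
    # y+ = 1  =>  v_r >= epsilon
    add_row(unit(n, r), unit(nbin, k, lp$lb[r] - epsilon), lp$lb[r], "ge")
    # y- = 1  =>  v_r <= -epsilon
    add_row(unit(n, r), unit(nbin, nh + k, lp$ub[r] + epsilon), lp$ub[r], "le")
    # at most one direction rewarded
    add_row(rep(0, n), unit(nbin, k) + unit(nbin, nh + k), 1, "le")
  }
  for (k in seq_along(low)) {
    r <- low[k]
    # y0 = 1  =>  v_r = 0
    add_row(unit(n, r), unit(nbin, 2L * nh + k, lp$ub[r]), lp$ub[r], "le")
    add_row(unit(n, r), unit(nbin, 2L * nh + k, lp$lb[r]), lp$lb[r], "ge")
  }
  n_extra <- length(rows)
  A <- cbind(lp$S, matrix(0, m, nbin), matrix(0, m, n_extra))
  if (n_extra > 0) {
    A <- rbind(A, cbind(do.call(rbind, rows),
                        diag(slack_sign, n_extra, n_extra)))
  }
  b <- c(lp$rhs, rhs)
  lb <- c(lp$lb, rep(0, nbin), rep(0, n_extra))
  ub <- c(lp$ub, rep(1, nbin), rep(Inf, n_extra))
  obj <- c(rep(0, n), rep(1, nbin), rep(0, n_extra))
  # the at-most-one rows reuse binary objective slots; correct the count:
  # score counts y+ + y- + y0, which is exactly sum of binaries.
  int_idx <- n + seq_len(nbin)
  sol <- solve_milp(obj, A, b, lb, ub, int_idx, sense = "max")
  if (sol$status != "optimal") {
    fixed_msg <- if (is.null(fix)) "" else
      paste0(" with fixed fluxes ",
             paste(names(fix), "=", fix, collapse = ", "))
    rlang::abort(paste0("iMAT MILP infeasible", fixed_msg,
                        "; the fixed rates and bounds admit no steady state."),
                 class = "fluxscape_infeasible_error")
  }
  # parsimonious representative: fix the optimal activity pattern as
  # bounds and minimize total absolute flux, so the reported vector (and
  # the downstream census) is not an arbitrary degenerate vertex.
  yv <- round(sol$x[n + seq_len(nbin)])
  lb2 <- lp$lb; ub2 <- lp$ub
  for (k in seq_along(high)) {
    r <- high[k]
    if (yv[k] == 1) lb2[r] <- max(lb2[r], epsilon)
    if (yv[nh + k] == 1) ub2[r] <- min(ub2[r], -epsilon)
  }
  for (k in seq_along(low)) {
    r <- low[k]
    if (yv[2L * nh + k] == 1) {
      lb2[r] <- max(lb2[r], 0); ub2[r] <- min(ub2[r], 0)
    }
  }
  A3 <- cbind(lp$S, -lp$S)
  l1 <- solve_lp(rep(1, 2L * n), A3, lp$rhs,
                 lb = c(pmax(lb2, 0), pmax(-ub2, 0)),
                 ub = c(pmax(ub2, 0), pmax(-lb2, 0)), sense = "min")
  v <- if (l1$status == "optimal") {
    l1$x[seq_len(n)] - l1$x[n + seq_len(n)]
  } else sol$x[seq_len(n)]
  v <- stats::setNames(v, lp$ids)
  structure(
    list(status = "optimal",
         fluxes = v,
         active = abs(v) > zero_threshold,
         score = round(sol$objective),
         n_high = nh, n_low = nl,
         epsilon = epsilon,
         fixed = fix),
    class = "imat_result"
  )
}

#' @export
print.imat_result <- function(x, ...) {
  cat("<imat_result> status: ", x$status,
      "\n  consistency score: ", x$score, " of ", x$n_high + x$n_low,
      " classified reactions\n  flux-carrying reactions: ",
      sum(x$active), "\n", sep = "")
  invisible(x)
}

#' Census of flux-carrying reactions
#'
#' Counts the reactions carrying flux above a threshold in an iMAT (or
#' any flux) result, overall and per subsystem when a model is
#' supplied — the per-time-point activity census of the integrated
#' flux states.
#'
#' @param result An `imat_result` or `flux_result`.
#' @param zero_threshold Activity threshold (mmol/gDW/h).
#' @param model Optional `metabolic_model` for per-subsystem counts.
#' @return Tibble: `subsystem` (`"(all)"` first), `n_active`.
#' @export
census_active <- function(result, zero_threshold = FLUX_ZERO, model = NULL) {
  fluxes <- result$fluxes
  active <- abs(fluxes) > zero_threshold
  out <- tibble::tibble(subsystem = "(all)", n_active = sum(active))
  if (!is.null(model)) {
    idx <- match(names(fluxes), model$reactions$id)
    per <- tibble::tibble(
      subsystem = model$reactions$subsystem[idx],
      active = active
    )
    per <- dplyr::summarise(
      dplyr::group_by(per, .data$subsystem),
      n_active = sum(.data$active), .groups = "drop"
    )
    out <- dplyr::bind_rows(out, dplyr::arrange(per, dplyr::desc(.data$n_active)))
  }
  out
}
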