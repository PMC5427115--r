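#' Trace the Pareto front between two objectives
#'
#' The growth-production trade-off computed by the stepwise sweep:
#' (i) the minimal and maximal flux of objective `a` (flux variability
#' on `a` alone), (ii) `a` fixed (equality bounds) at `n_steps` evenly
#' spaced values spanning that range inclusive, (iii) objective `b`
#' maximized at each step. Sweeping with the objectives exchanged
#' (`direction = "b_fixed"`) traces the same boundary from the other
#' side.
#'
#' @param model A `metabolic_model` (already constrained to the medium
#'   of interest).
#' @param a_id,b_id Reaction ids of the two objectives; conventionally
#'   `a` is biomass assembly and `b` the antibiotic synthesis reaction.
#' @param n_steps Number of fixed values (>= 2; 2 gives exactly the two
#'   single-objective extreme points).
#' @param direction Which objective is fixed during the sweep.
#' @return A `pareto_front`: a tibble with `step`, `fixed_id`,
#'   `fixed_flux`, `max_id`, `max_flux`, `status`; infeasible fixed
#'   points are recorded with `status != "optimal"`, never dropped.
#' @examples
#' toy <- generate_toy_model(toy_model_spec())
#' compute_pareto(toy$model, "BIOMASS", "EX_product", n_steps = 5)
#' @export
compute_pareto <- function(model, a_id = NULL, b_id, n_steps = 20,
                           direction = c("a_fixed", "b_fixed")) {
  direction <- match.arg(direction)
  a_id <- a_id %||% model$objective
  rxn_row(model, a_id); rxn_row(model, b_id)
  if (n_steps < 2) {
    rlang::abort("n_steps must be >= 2.", class = "fluxscape_spec_error")
  }
  fixed_id <- if (direction == "a_fixed") a_id else b_id
  max_id <- if (direction == "a_fixed") b_id else a_id

  rng <- fva(model, fixed_id, fraction = 0)
  steps <- seq(rng$min, rng$max, length.out = n_steps)
  rows <- purrr::imap(steps, function(value, k) {
    fixed <- fix_flux(model, fixed_id, value)
    res <- fba(fixed, objective = max_id, sense = "max")
    tibble::tibble(
      step = k, fixed_id = fixed_id, fixed_flux = value,
      max_id = max_id,
      max_flux = if (res$status == "optimal") res$objective_value else NA_real_,
      status = res$status
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("pareto_front", class(out)),
            a_id = a_id, b_id = b_id, direction = direction,
            n_steps = n_steps)
}

#' Plot a Pareto front
#'
#' @param object A `pareto_front`.
#' @param ... Ignored.
#' @return A ggplot: maximized flux against fixed flux.
#' @method autoplot pareto_front
#' @export
autoplot.pareto_front <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$status == "optimal")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fixed_flux, y = .data$max_flux)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste0("fixed flux: ", object$fixed_id[1], " (mmol/gDW/h)"),
      y = paste0("maximal flux: ", object$max_id[1], " (mmol/gDW/h)"),
      title = "Growth-production Pareto front"
    ) +
    ggplot2::theme_minimal()
}
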