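#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flux result into a reaction/flux table
#'
#' @param x A `flux_result`.
#' @param zero_threshold Activity threshold for the `active` column.
#' @param ... Ignored.
#' @return Tibble: `reaction_id`, `flux`, `active`.
#' @method tidy flux_result
#' @export
tidy.flux_result <- function(x, zero_threshold = FLUX_ZERO, ...) {
  tibble::tibble(
    reaction_id = names(x$fluxes),
    flux = unname(x$fluxes),
    active = abs(unname(x$fluxes)) > zero_threshold
  )
}

#' One-row summary of a flux result
#'
#' @param x A `flux_result`.
#' @param ... Ignored.
#' @return Tibble: `status`, `method`, `sense`, `objective_id`,
#'   `objective_value`, `total_abs_flux`, `n_active`.
#' @method glance flux_result
#' @export
glance.flux_result <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    method = x$method,
    sense = x$sense,
    objective_id = x$objective_id,
    objective_value = x$objective_value,
    total_abs_flux = sum(abs(x$fluxes)),
    n_active = sum(abs(x$fluxes) > FLUX_ZERO, na.rm = TRUE)
  )
}

#' Tidy an iMAT result
#'
#' @param x An `imat_result`.
#' @param ... Ignored.
#' @return Tibble: `reaction_id`, `flux`, `active`.
#' @method tidy imat_result
#' @export
tidy.imat_result <- function(x, ...) {
  tibble::tibble(
    reaction_id = names(x$fluxes),
    flux = unname(x$fluxes),
    active = unname(x$active)
  )
}

#' One-row summary of an iMAT result
#'
#' @param x An `imat_result`.
#' @param ... Ignored.
#' @return Tibble: `status`, `score`, `n_high`, `n_low`, `epsilon`,
#'   `n_active`.
#' @method glance imat_result
#' @export
glance.imat_result <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    score = x$score,
    n_high = x$n_high,
    n_low = x$n_low,
    epsilon = x$epsilon,
    n_active = sum(x$active)
  )
}

#' Tidy a Pareto front
#'
#' @param x A `pareto_front`.
#' @param ... Ignored.
#' @return The front as a plain tibble.
#' @method tidy pareto_front
#' @export
tidy.pareto_front <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a Pareto front
#'
#' @param x A `pareto_front`.
#' @param ... Ignored.
#' @return Tibble with the sweep setup and the extreme points.
#' @method glance pareto_front
#' @export
glance.pareto_front <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  ok <- tb[tb$status == "optimal", ]
  tibble::tibble(
    a_id = attr(x, "a_id"),
    b_id = attr(x, "b_id"),
    direction = attr(x, "direction"),
    n_steps = attr(x, "n_steps"),
    n_feasible = nrow(ok),
    fixed_min = min(tb$fixed_flux),
    fixed_max = max(tb$fixed_flux),
    max_flux_at_fixed_min = ok$max_flux[which.min(ok$fixed_flux)],
    max_flux_at_fixed_max = ok$max_flux[which.max(ok$fixed_flux)]
  )
}

#' Tidy an FSEOF scan into long flux profiles
#'
#' @param x An `fseof_scan`.
#' @param ... Ignored.
#' @return Long tibble: `reaction_id`, `step` (0 = baseline), `flux`,
#'   `selected`.
#' @method tidy fseof_scan
#' @export
tidy.fseof_scan <- function(x, ...) {
  tb <- tibble::as_tibble(x)[, c("reaction_id", "profile", "selected")]
  tb$step <- purrr::map(tb$profile, ~ seq_along(.x) - 1L)
  out <- tidyr::unnest_longer(tb, c("profile", "step"))
  dplyr::rename(out, flux = "profile")
}

#' One-row summary of an FSEOF scan
#'
#' @param x An `fseof_scan`.
#' @param ... Ignored.
#' @return Tibble with the scan setup, the theoretical maximum and the
#'   selection count.
#' @method glance fseof_scan
#' @export
glance.fseof_scan <- function(x, ...) {
  tibble::tibble(
    product_id = attr(x, "product_id"),
    biomass_id = attr(x, "biomass_id"),
    base_rate = attr(x, "base_rate"),
    theoretical_max = attr(x, "theoretical_max"),
    n_steps = attr(x, "n_steps"),
    flux_representative = attr(x, "flux_representative"),
    enforcement = attr(x, "enforcement"),
    n_selected = sum(x$selected)
  )
}

#' One-row summary of filtered FSEOF targets
#'
#' @param x An `fseof_targets`.
#' @param ... Ignored.
#' @return Tibble: counts of surviving reactions and genes and of each
#'   exclusion reason.
#' @method glance fseof_targets
#' @export
glance.fseof_targets <- function(x, ...) {
  reason <- x$exclusion_reason
  tibble::tibble(
    n_targets = sum(is.na(reason)),
    n_genes = length(attr(x, "genes")),
    n_excluded_gap_fill = sum(reason == "gap_fill", na.rm = TRUE),
    n_excluded_exchange = sum(reason == "exchange", na.rm = TRUE),
    n_excluded_multi_gene = sum(reason == "multi_gene", na.rm = TRUE)
  )
}
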