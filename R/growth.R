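#' Predict growth on a defined minimal medium
#'
#' Applies the medium (conventionally: every salt exchange opened at a
#' non-limiting uptake of 10 mmol/gDW/h, the single carbon source at
#' its measured uptake rate) and maximizes the biomass assembly
#' reaction.
#'
#' @param model A `metabolic_model`.
#' @param medium A [medium_spec()] or named numeric vector of uptake
#'   magnitudes.
#' @param biomass_id Biomass reaction id; defaults to the model
#'   objective.
#' @return One-row tibble: `status`, `growth_rate` (1/h; 0 when the
#'   medium is infeasible, with the status flagging it).
#' @export
simulate_minimal_medium <- function(model, medium, biomass_id = NULL) {
  biomass_id <- biomass_id %||% model$objective
  constrained <- apply_medium(model, medium)
  res <- fba(constrained, objective = biomass_id, sense = "max")
  tibble::tibble(
    status = res$status,
    growth_rate = if (res$status == "optimal") res$objective_value else 0
  )
}

#' Predict the product synthesis rate on a complex medium
#'
#' Emulates growth on a rich (yeast-extract-like) medium: every listed
#' amino-acid exchange is opened at a common small uptake, the growth
#' rate is pinned to its measured value, and the maximal product
#' synthesis rate compatible with that growth is computed.
#'
#' @param model A `metabolic_model`.
#' @param product_id Product synthesis/excretion reaction id.
#' @param growth_rate Measured growth rate to fix (1/h).
#' @param amino_acid_exchanges Ids of the amino-acid exchange
#'   reactions; may be empty if the base medium already provides
#'   nutrients.
#' @param aa_uptake Common uptake magnitude for each amino-acid
#'   exchange (default 0.015 mmol/gDW/h).
#' @param base_medium Optional [medium_spec()] applied first (e.g. the
#'   carbon/salt part of the medium).
#' @param biomass_id Biomass reaction id; defaults to the model
#'   objective.
#' @return One-row tibble: `status`, `growth_rate`, `product_rate`
#'   (mmol/gDW/h).
#' @export
simulate_complex_medium <- function(model, product_id, growth_rate,
                                    amino_acid_exchanges = character(0),
                                    aa_uptake = 0.015, base_medium = NULL,
                                    biomass_id = NULL) {
  biomass_id <- biomass_id %||% model$objective
  rxn_row(model, product_id)
  if (growth_rate < 0) {
    rlang::abort("growth_rate must be >= 0.", class = "fluxscape_spec_error")
  }
  if (!is.null(base_medium)) model <- apply_medium(model, base_medium)
  if (length(amino_acid_exchanges)) {
    aa <- medium_spec(stats::setNames(rep(aa_uptake, length(amino_acid_exchanges)),
                                      amino_acid_exchanges),
                      closed_default = FALSE)
    model <- apply_medium(model, aa)
  }
  model <- fix_flux(model, biomass_id, growth_rate)
  res <- fba(model, objective = product_id, sense = "max")
  if (res$status != "optimal") {
    rlang::abort(paste0("growth rate ", growth_rate,
                        " is not attainable under this medium (status ",
                        res$status, ")."),
                 class = "fluxscape_infeasible_error")
  }
  tibble::tibble(status = res$status, growth_rate = growth_rate,
                 product_rate = res$objective_value)
}

#' Compare predicted and observed growth rates
#'
#' Pearson product-moment correlation (with its two-sided test) between
#' paired predicted and observed growth rates across media.
#'
#' @param predicted,observed Numeric vectors of equal length >= 3.
#' @return One-row tibble: `n`, `pearson_r`, `p_value`.
#' @export
compare_growth <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3) {
    rlang::abort("need paired vectors of equal length >= 3.",
                 class = "fluxscape_spec_error")
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    rlang::abort("correlation undefined: an input has zero variance.",
                 class = "fluxscape_spec_error")
  }
  ct <- stats::cor.test(predicted, observed, method = "pearson",
                        alternative = "two.sided")
  tibble::tibble(n = length(predicted),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value)
}
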