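#' Flux scanning with enforced objective flux (FSEOF)
#'
#' Identifies candidate overexpression targets for product
#' overproduction. The scan: (1) fix the product synthesis rate at its
#' experimentally measured base value and maximize growth (baseline
#' flux state); (2) compute the theoretical maximum product rate; (3)
#' enforce the product rate at `n_steps` values spaced from the base
#' rate up to that maximum (endpoint included, baseline excluded),
#' re-maximizing growth at each; (4) select the reactions whose
#' absolute flux increases over the baseline in at least one step
#' without the reaction ever changing direction. Parsimonious FBA
#' supplies the flux state at every step, so the profile is a
#' deterministic representative of each degenerate optimum.
#'
#' @param model A `metabolic_model`, already constrained to the
#'   production medium.
#' @param product_id Product synthesis/excretion reaction id.
#' @param base_rate Measured base production rate (mmol/gDW/h).
#' @param n_steps Number of enforced steps (default 10 optimizations
#'   beyond the baseline).
#' @param biomass_id Growth objective; defaults to the model objective.
#' @param zero_threshold Fluxes below this magnitude count as zero for
#'   both the increase test and the sign-consistency test.
#' @return An `fseof_scan` tibble: one row per reaction with `genes`
#'   (list column), `baseline` flux, `profile` (list column of the
#'   n_steps + 1 fluxes), `max_abs_flux`, `slope` (least-squares slope
#'   of |flux| per enforcement step) and `selected`.
#' @export
fseof_scan <- function(model, product_id, base_rate, n_steps = 10,
                       biomass_id = NULL, zero_threshold = FLUX_ZERO) {
  biomass_id <- biomass_id %||% model$objective
  rxn_row(model, product_id)
  if (base_rate < 0 || n_steps < 2) {
    rlang::abort("base_rate must be >= 0 and n_steps >= 2.",
                 class = "fluxscape_spec_error")
  }
  vmax <- fba(model, objective = product_id, sense = "max")
  if (vmax$status != "optimal") {
    rlang::abort(paste0("product maximization not optimal (status ",
                        vmax$status, ")."),
                 class = "fluxscape_infeasible_error")
  }
  if (base_rate > vmax$objective_value + 1e-9) {
    rlang::abort(paste0("base rate ", base_rate,
                        " exceeds the theoretical maximum ",
                        format(vmax$objective_value), "."),
                 class = "fluxscape_infeasible_error")
  }
  enforced <- base_rate +
    seq_len(n_steps) * (vmax$objective_value - base_rate) / n_steps
  states <- purrr::map(c(base_rate, enforced), function(q) {
    st <- pfba(fix_flux(model, product_id, q), objective = biomass_id)
    if (st$status != "optimal") {
      rlang::abort(paste0("growth maximization infeasible at enforced rate ",
                          format(q), "."),
                   class = "fluxscape_infeasible_error")
    }
    st
  })
  profiles <- do.call(cbind, purrr::map(states, "fluxes"))  # reactions x (n+1)

  base_abs <- abs(profiles[, 1L])
  max_abs <- apply(abs(profiles), 1L, max)
  increased <- max_abs > base_abs + zero_threshold
  sign_ok <- apply(profiles, 1L, function(v) {
    nz <- v[abs(v) > zero_threshold]
    length(nz) == 0L || all(nz > 0) || all(nz < 0)
  })
  k <- 0:n_steps
  slope <- apply(abs(profiles), 1L, function(a) {
    stats::cov(a, k) / stats::var(k)
  })

  out <- tibble::tibble(
    reaction_id = model$reactions$id,
    genes = purrr::map(model$reactions$rule, "genes"),
    baseline = profiles[, 1L],
    profile = purrr::array_branch(profiles, 1L),
    max_abs_flux = max_abs,
    slope = slope,
    selected = increased & sign_ok
  )
  structure(out,
            class = c("fseof_scan", class(out)),
            product_id = product_id, biomass_id = biomass_id,
            base_rate = base_rate, n_steps = n_steps,
            theoretical_max = vmax$objective_value,
            zero_threshold = zero_threshold,
            enforcement = "equality", flux_representative = "pfba")
}

#' Filter FSEOF targets down to actionable single-gene reactions
#'
#' Applies the three exclusion rules used to turn a raw scan into an
#' amplifiable gene list: drop (i) gap-filled reactions (not
#' gene-encoded, so nothing to amplify), (ii) exchange reactions
#' (modeling artifacts importing/exporting nutrients), and (iii)
#' reactions encoded by two or more genes — enzymatic complexes
#' (AND) or alternative paralogs (OR) — where the gene to amplify is
#' ambiguous.
#'
#' @param scan An `fseof_scan`.
#' @param model The model the scan was computed on.
#' @return An `fseof_targets` tibble: the selected rows with an
#'   `exclusion_reason` column (`NA` for survivors, else `"gap_fill"`,
#'   `"exchange"` or `"multi_gene"`). The surviving reactions' genes
#'   (one per reaction, unioned) are in `attr(x, "genes")` and via
#'   [target_genes()].
#' @export
filter_targets <- function(scan, model) {
  stopifnot(inherits(scan, "fseof_scan"))
  idx <- match(scan$reaction_id, model$reactions$id)
  if (anyNA(idx)) {
    rlang::abort("scan and model disagree on reaction ids.",
                 class = "fluxscape_model_error")
  }
  out <- tibble::as_tibble(scan)[scan$selected, ]
  idx <- idx[scan$selected]
  rx <- model$reactions[idx, ]
  n_genes <- purrr::map_int(rx$rule, ~ length(.x$genes))
  reason <- dplyr::case_when(
    rx$is_gap_fill ~ "gap_fill",
    rx$is_exchange ~ "exchange",
    n_genes >= 2L ~ "multi_gene",
    n_genes == 0L ~ "gap_fill",   # gene-less by any route: nothing to amplify
    TRUE ~ NA_character_
  )
  out$exclusion_reason <- reason
  out$subsystem <- rx$subsystem
  genes <- sort(unique(unlist(out$genes[is.na(reason)], use.names = FALSE)))
  structure(out,
            class = c("fseof_targets", class(tibble::as_tibble(out))),
            genes = genes,
            product_id = attr(scan, "product_id"),
            base_rate = attr(scan, "base_rate"))
}

#' Genes behind the surviving FSEOF targets
#'
#' @param targets An `fseof_targets`.
#' @return Character vector: the union of the single genes encoding the
#'   surviving reactions.
#' @export
target_genes <- function(targets) {
  stopifnot(inherits(targets, "fseof_targets"))
  attr(targets, "genes")
}

#' Ranked overexpression-target report
#'
#' Surviving targets ranked by the slope of their absolute-flux
#' profile (flux increase per enforcement step), ties broken by
#' reaction id.
#'
#' @param targets An `fseof_targets`.
#' @param model The model the scan was computed on (for names and
#'   subsystems).
#' @param path Optional TSV output path.
#' @return Tibble: `reaction_id`, `name`, `subsystem`, `genes`
#'   (collapsed), `slope`, `baseline`, `max_abs_flux`, sorted by
#'   decreasing slope.
#' @export
report_targets <- function(targets, model, path = NULL) {
  stopifnot(inherits(targets, "fseof_targets"))
  keep <- tibble::as_tibble(targets)
  keep <- keep[is.na(keep$exclusion_reason), ]
  idx <- match(keep$reaction_id, model$reactions$id)
  out <- tibble::tibble(
    reaction_id = keep$reaction_id,
    name = model$reactions$name[idx],
    subsystem = model$reactions$subsystem[idx],
    genes = purrr::map_chr(keep$genes, paste, collapse = ";"),
    slope = keep$slope,
    baseline = keep$baseline,
    max_abs_flux = keep$max_abs_flux
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$slope), .data$reaction_id)
  if (!is.null(path)) readr::write_tsv(out, path, progress = FALSE)
  out
}

#' Plot FSEOF flux profiles
#'
#' @param object An `fseof_scan`.
#' @param reactions Optional reaction ids to show (default: selected
#'   reactions).
#' @param ... Ignored.
#' @return A ggplot of |flux| against enforcement step.
#' @method autoplot fseof_scan
#' @export
autoplot.fseof_scan <- function(object, reactions = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(reactions)) reactions <- df$reaction_id[df$selected]
  df <- df[df$reaction_id %in% reactions, c("reaction_id", "profile")]
  long <- tidyr::unnest_longer(
    dplyr::mutate(df, step = purrr::map(.data$profile, ~ seq_along(.x) - 1L)),
    c("profile", "step")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = abs(.data$profile),
                                     colour = .data$reaction_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "enforcement step", y = "|flux| (mmol/gDW/h)",
                  colour = "reaction",
                  title = "Flux response to enforced product synthesis") +
    ggplot2::theme_minimal()
}
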