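#' Construct a metabolic model
#'
#' A `metabolic_model` is the package's central container: a validated,
#' tabular representation of a genome-scale (or toy) stoichiometric
#' network. It is a light S3 list of tibbles, so every component is
#' directly usable with dplyr verbs.
#'
#' @param reactions A tibble/data frame with columns `id` (unique
#'   strings), `stoich` (list column of named numeric vectors:
#'   metabolite id -> stoichiometric coefficient, negative = consumed),
#'   and optionally `name`, `lb`, `ub` (flux bounds, mmol/gDW/h), `gpr`
#'   (rule strings), `subsystem`, `is_exchange`, `is_gap_fill`.
#'   Missing bounds default to the reversible convention (-1000, 1000);
#'   a logical `reversible` column, if present, switches absent bounds
#'   to (0, 1000) for irreversible rows.
#' @param metabolites Optional tibble with columns `id` and optionally
#'   `name`, `compartment`, `formula`. Metabolites referenced by
#'   reactions but absent here are added with defaults (compartment
#'   `"c"`).
#' @param objective Reaction id of the objective (typically the biomass
#'   assembly pseudo-reaction). Defaults to the first reaction whose id
#'   or name contains "biomass" (case-insensitive), else the last
#'   reaction.
#' @param name Model name.
#' @return A validated object of class `metabolic_model` with elements
#'   `name`, `metabolites`, `reactions` (including parsed `rule` list
#'   column and derived `is_exchange`/`is_gap_fill` flags), `genes`
#'   (character vector) and `objective`.
#' @details
#' Exchange reactions are detected as reactions touching exactly one
#' metabolite (boundary reactions; negative flux = uptake by
#' convention). A reaction is flagged gap-fill when it has an empty GPR
#' and is not an exchange: gap-filled steps are by construction not
#' gene-encoded. Explicit `is_exchange`/`is_gap_fill` columns override
#' the heuristics.
#' @export
metabolic_model <- function(reactions, metabolites = NULL, objective = NULL,
                            name = "model") {
  reactions <- tibble::as_tibble(reactions)
  if (!all(c("id", "stoich") %in% names(reactions))) {
    rlang::abort("`reactions` needs `id` and `stoich` columns.",
                 class = "fluxscape_model_error")
  }
  if (nrow(reactions) == 0L) {
    rlang::abort("empty model: no reactions.", class = "fluxscape_model_error")
  }
  if (anyDuplicated(reactions$id)) {
    dup <- unique(reactions$id[duplicated(reactions$id)])
    rlang::abort(paste0("duplicate reaction ids: ", paste(dup, collapse = ", ")),
                 class = "fluxscape_model_error")
  }

  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  rev_default <- if ("reversible" %in% names(reactions)) reactions$reversible else TRUE
  if (!"lb" %in% names(reactions)) reactions$lb <- NA_real_
  if (!"ub" %in% names(reactions)) reactions$ub <- NA_real_
  reactions$lb <- ifelse(is.na(reactions$lb), ifelse(rev_default, -1000, 0), reactions$lb)
  reactions$ub <- ifelse(is.na(reactions$ub), 1000, reactions$ub)
  reactions$reversible <- NULL

  reactions$rule <- purrr::map(reactions$gpr, parse_gpr)

  n_mets_touched <- purrr::map_int(reactions$stoich, length)
  detected_exchange <- n_mets_touched == 1L
  if (!"is_exchange" %in% names(reactions) || all(is.na(reactions$is_exchange))) {
    reactions$is_exchange <- detected_exchange
  } else {
    reactions$is_exchange <- ifelse(is.na(reactions$is_exchange),
                                    detected_exchange, reactions$is_exchange)
  }
  gpr_empty <- purrr::map_lgl(reactions$rule, ~ length(.x$genes) == 0L)
  if (!"is_gap_fill" %in% names(reactions) || all(is.na(reactions$is_gap_fill))) {
    reactions$is_gap_fill <- gpr_empty & !reactions$is_exchange
  } else {
    reactions$is_gap_fill <- ifelse(is.na(reactions$is_gap_fill),
                                    gpr_empty & !reactions$is_exchange,
                                    reactions$is_gap_fill)
  }

  met_ids <- unique(unlist(purrr::map(reactions$stoich, names), use.names = FALSE))
  if (is.null(metabolites)) {
    metabolites <- tibble::tibble(id = met_ids)
  } else {
    metabolites <- tibble::as_tibble(metabolites)
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  metabolites$compartment[is.na(metabolites$compartment) |
                            !nzchar(metabolites$compartment)] <- "c"
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  missing_mets <- setdiff(met_ids, metabolites$id)
  if (length(missing_mets)) {
    metabolites <- dplyr::bind_rows(
      metabolites,
      tibble::tibble(id = missing_mets, name = missing_mets,
                     compartment = "c", formula = NA_character_)
    )
  }

  genes <- sort(unique(unlist(purrr::map(reactions$rule, "genes"), use.names = FALSE)))

  if (is.null(objective)) {
    hit <- grepl("biomass", reactions$id, ignore.case = TRUE) |
      grepl("biomass", reactions$name, ignore.case = TRUE)
    objective <- if (any(hit)) reactions$id[which(hit)[1L]] else
      reactions$id[nrow(reactions)]
  }

  model <- structure(
    list(
      name = name,
      metabolites = dplyr::select(metabolites, "id", "name", "compartment", "formula"),
      reactions = dplyr::select(
        reactions, "id", "name", "stoich", "lb", "ub", "gpr", "rule",
        "subsystem", "is_exchange", "is_gap_fill"
      ),
      genes = genes,
      objective = objective
    ),
    class = "metabolic_model"
  )
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants every downstream stage relies on:
#' unique ids, resolvable stoichiometry references, lb <= ub, exchange
#' reactions touching exactly one metabolite, gap-fill reactions having
#' no gene rule, and a resolvable objective.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly usable in pipes (returned visibly).
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  if (nrow(rx) == 0L) {
    rlang::abort("empty model: no reactions.", class = "fluxscape_model_error")
  }
  if (anyDuplicated(model$metabolites$id)) {
    rlang::abort("duplicate metabolite ids.", class = "fluxscape_model_error")
  }
  bad_bounds <- rx$id[rx$lb > rx$ub]
  if (length(bad_bounds)) {
    rlang::abort(paste0("lb > ub for reactions: ", paste(bad_bounds, collapse = ", ")),
                 class = "fluxscape_model_error")
  }
  refs <- unique(unlist(purrr::map(rx$stoich, names), use.names = FALSE))
  dangling <- setdiff(refs, model$metabolites$id)
  if (length(dangling)) {
    rlang::abort(paste0("stoichiometry references unknown metabolites: ",
                        paste(dangling, collapse = ", ")),
                 class = "fluxscape_model_error")
  }
  empty_stoich <- rx$id[purrr::map_int(rx$stoich, length) == 0L]
  if (length(empty_stoich)) {
    rlang::abort(paste0("reactions with empty stoichiometry: ",
                        paste(empty_stoich, collapse = ", ")),
                 class = "fluxscape_model_error")
  }
  bad_ex <- rx$id[rx$is_exchange & purrr::map_int(rx$stoich, length) != 1L]
  if (length(bad_ex)) {
    rlang::abort(paste0("exchange reactions must touch exactly one metabolite: ",
                        paste(bad_ex, collapse = ", ")),
                 class = "fluxscape_model_error")
  }
  gf_with_genes <- rx$id[rx$is_gap_fill &
                           purrr::map_int(rx$rule, ~ length(.x$genes)) > 0L]
  if (length(gf_with_genes)) {
    rlang::abort(paste0("gap-fill reactions must not be gene-encoded: ",
                        paste(gf_with_genes, collapse = ", ")),
                 class = "fluxscape_model_error")
  }
  rule_genes <- unique(unlist(purrr::map(rx$rule, "genes"), use.names = FALSE))
  if (!all(rule_genes %in% model$genes)) {
    rlang::abort("GPR leaves reference genes missing from the gene set.",
                 class = "fluxscape_model_error")
  }
  if (!model$objective %in% rx$id) {
    rlang::abort(paste0("objective reaction not in model: ", model$objective),
                 class = "fluxscape_model_error")
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$name, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      "   genes: ", length(x$genes), "\n", sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Build the stoichiometric matrix S
#'
#' Returns the m x n sparse matrix S whose entry (i, j) is the
#' coefficient of metabolite i in reaction j; the steady-state
#' constraint of flux balance analysis is S v = 0. Row order follows
#' the model's metabolite table, column order its reaction table.
#'
#' @param model A `metabolic_model`.
#' @return A `Matrix::sparseMatrix` with metabolite ids as rownames and
#'   reaction ids as colnames; all-zero rows (isolated metabolites) are
#'   retained.
#' @export
build_stoich_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  triplets <- purrr::imap(model$reactions$stoich, function(s, j) {
    tibble::tibble(i = match(names(s), met_ids), j = j, x = unname(s))
  })
  tr <- dplyr::bind_rows(triplets)
  Matrix::sparseMatrix(
    i = tr$i, j = tr$j, x = tr$x,
    dims = c(length(met_ids), length(rxn_ids)),
    dimnames = list(met_ids, rxn_ids)
  )
}

#' Summarise a model's size and gene coverage
#'
#' The usual headline statistics of a metabolic reconstruction: gene,
#' reaction and metabolite counts and the split of reactions into
#' gene-associated, non-gene-associated and exchange.
#'
#' @param model A `metabolic_model`.
#' @return A two-column tibble (`metric`, `value`).
#' @export
model_stats <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  gene_assoc <- purrr::map_int(rx$rule, ~ length(.x$genes)) > 0L
  tibble::tibble(
    metric = c("genes", "reactions", "gene_associated_reactions",
               "non_gene_associated_reactions", "exchange_reactions",
               "gap_fill_reactions", "metabolites"),
    value = c(length(model$genes), nrow(rx), sum(gene_assoc),
              sum(!gene_assoc), sum(rx$is_exchange),
              sum(rx$is_gap_fill), nrow(model$metabolites))
  )
}

rxn_row <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) {
    rlang::abort(paste0("unknown reaction id: ", id),
                 class = "fluxscape_model_error")
  }
  i
}

#' Set the flux bounds of one reaction
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id.
#' @param lb,ub New bounds (either may be `NULL` to keep the current
#'   value).
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- rxn_row(model, id)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  if (model$reactions$lb[i] > model$reactions$ub[i]) {
    rlang::abort(paste0("lb > ub for reaction ", id),
                 class = "fluxscape_model_error")
  }
  model
}

#' Fix a reaction's flux to a constant value
#'
#' Sets lb = ub = `value`, e.g. pinning the growth rate to a measured
#' value before maximizing product synthesis.
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id.
#' @param value Flux value; must lie within the reaction's current
#'   bounds.
#' @return The modified model.
#' @export
fix_flux <- function(model, id, value) {
  i <- rxn_row(model, id)
  lb <- model$reactions$lb[i]
  ub <- model$reactions$ub[i]
  if (value < lb - 1e-12 || value > ub + 1e-12) {
    rlang::abort(
      paste0("cannot fix ", id, " at ", value, ": outside bounds [",
             lb, ", ", ub, "]"),
      class = "fluxscape_bounds_error"
    )
  }
  model$reactions$lb[i] <- value
  model$reactions$ub[i] <- value
  model
}

#' List a model's exchange reactions
#'
#' @param model A `metabolic_model`.
#' @return Tibble with `id`, the exchanged `metabolite`, `lb`, `ub`.
#' @export
exchanges <- function(model) {
  rx <- dplyr::filter(model$reactions, .data$is_exchange)
  tibble::tibble(
    id = rx$id,
    metabolite = purrr::map_chr(rx$stoich, ~ names(.x)[1L]),
    lb = rx$lb,
    ub = rx$ub
  )
}
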