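#' Specify a synthetic toy metabolic network
#'
#' Describes a small, fully analyzable network emulating the structure
#' that matters for an antibiotic producer: a single carbon source, a
#' linear core, a biomass assembly reaction, and a multi-precursor
#' product branch whose flux is capped by one planted precursor-supply
#' step (the in-silico analog of the crotonyl-CoA carboxylase/reductase
#' step supplying the rare ethylmalonyl-CoA extender unit of polyketide
#' synthesis). Every optimum of the generated model has a closed form,
#' recorded as ground truth.
#'
#' @param n_core_reactions Length of the linear carbon backbone
#'   (>= 1).
#' @param uptake_capacity Carbon uptake bound (mmol/gDW/h).
#' @param biomass_yield Biomass yield on the core precursor
#'   (gDW/mmol): the biomass reaction drains `1/biomass_yield`
#'   precursor per unit growth.
#' @param product_precursors Named numeric vector: precursor metabolite
#'   name -> stoichiometry in the product assembly reaction. The last
#'   entry is the planted (rate-limiting) precursor. Default mirrors the
#'   three polyketide extender units (malonyl-, methylmalonyl-,
#'   ethylmalonyl-CoA analogs), so precursor competition with biomass
#'   is structurally present.
#' @param product_capacity Cap on product flux imposed through the
#'   planted supply reaction (mmol/gDW/h).
#' @param planted_supply_reaction Id given to the planted supply step.
#' @param decoys Add filterable decoys: an AND-ruled (complex) supply,
#'   a gap-filled (gene-less) supply, an OR-ruled (paralog) assembly.
#'   Requires at least as many precursors as decoy slots touched.
#' @param cofactor_branch Add a salt-fed cofactor branch used only by
#'   biomass (a growth-only decoy for the overexpression scan).
#' @param seed Integer seed controlling gene-id assignment.
#' @return A `toy_model_spec` list.
#' @export
toy_model_spec <- function(n_core_reactions = 2,
                           uptake_capacity = 10,
                           biomass_yield = 0.1,
                           product_precursors = c(malonyl_like = 1,
                                                  methylmalonyl_like = 1,
                                                  ethylmalonyl_like = 1),
                           product_capacity = 2,
                           planted_supply_reaction = "CCR",
                           decoys = TRUE,
                           cofactor_branch = TRUE,
                           seed = 1L) {
  if (uptake_capacity <= 0) {
    rlang::abort("inconsistent spec: uptake_capacity must be > 0 (a positive yield is demanded).",
                 class = "fluxscape_spec_error")
  }
  if (biomass_yield <= 0 || product_capacity <= 0) {
    rlang::abort("inconsistent spec: yields and capacities must be > 0.",
                 class = "fluxscape_spec_error")
  }
  if (n_core_reactions < 1) {
    rlang::abort("n_core_reactions must be >= 1.", class = "fluxscape_spec_error")
  }
  if (length(product_precursors) < 1 || is.null(names(product_precursors)) ||
      any(product_precursors <= 0)) {
    rlang::abort("product_precursors must be a named vector of positive stoichiometries.",
                 class = "fluxscape_spec_error")
  }
  structure(
    list(n_core_reactions = as.integer(n_core_reactions),
         uptake_capacity = uptake_capacity,
         biomass_yield = biomass_yield,
         product_precursors = product_precursors,
         product_capacity = product_capacity,
         planted_supply_reaction = planted_supply_reaction,
         decoys = decoys,
         cofactor_branch = cofactor_branch,
         seed = as.integer(seed)),
    class = "toy_model_spec"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy metabolic model with analytic ground truth
#'
#' Builds the network described by a [toy_model_spec()] and derives its
#' optima in closed form. With uptake `U`, biomass yield `Y`, total
#' product precursor stoichiometry `a = sum(stoich)` and planted
#' capacity `K`: the maximal growth rate is `U * Y`, the maximal
#' product rate is `min(K, U / a)`, and the growth-production
#' trade-off over the carbon-limited region is the line
#' `mu / Y + a * q_p = U` (clipped at `q_p = K`).
#'
#' @param spec A [toy_model_spec()].
#' @return List with `model` (a validated `metabolic_model`) and
#'   `ground_truth`: analytic `max_growth`, `max_product`, the planted
#'   reaction/gene, per-decoy expected exclusion reasons, and the gene
#'   sets active in growth-only vs production-only flux states.
#' @export
generate_toy_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  n_prec <- length(spec$product_precursors)
  prec_names <- names(spec$product_precursors)
  planted_k <- n_prec  # last precursor is the planted one

  n_genes_needed <- spec$n_core_reactions + n_prec + 4L
  gene_pool <- with_seed(spec$seed,
                         paste0("g", sprintf("%04d", sample.int(9999, n_genes_needed))))
  gi <- 0L
  next_gene <- function() {
    gi <<- gi + 1L
    gene_pool[gi]
  }

  rows <- list()
  add <- function(id, stoich, lb = 0, ub = 1000, gpr = "", subsystem = "",
                  is_gap_fill = NA, name = id) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      id = id, name = name, stoich = list(stoich), lb = lb, ub = ub,
      gpr = gpr, subsystem = subsystem, is_gap_fill = is_gap_fill
    )
  }

  add("EX_carbon", c(carbon_e = -1), lb = -spec$uptake_capacity,
      subsystem = "exchange")
  core_genes <- character(spec$n_core_reactions)
  nodes <- c("carbon_e",
             if (spec$n_core_reactions > 1)
               paste0("pool_", seq_len(spec$n_core_reactions - 1L)),
             "precursor_c")
  for (k in seq_len(spec$n_core_reactions)) {
    core_genes[k] <- next_gene()
    add(paste0("CORE", k),
        stats::setNames(c(-1, 1), c(nodes[k], nodes[k + 1L])),
        gpr = core_genes[k], subsystem = "central carbon metabolism")
  }

  cof_gene <- NULL
  if (spec$cofactor_branch) {
    add("EX_salt", c(salt_e = -1), lb = -1000, subsystem = "exchange")
    cof_gene <- next_gene()
    add("COF", c(salt_e = -1, cofactor_c = 1), gpr = cof_gene,
        subsystem = "cofactor biosynthesis")
  }

  # precursor supply branch; the planted (last) step carries the cap
  supply_ids <- character(n_prec)
  supply_genes <- vector("list", n_prec)
  decoy_reasons <- character(0)
  for (k in seq_len(n_prec)) {
    planted <- k == planted_k
    id <- if (planted) spec$planted_supply_reaction else paste0("SUPPLY", k)
    supply_ids[k] <- id
    a_k <- spec$product_precursors[[k]]
    if (planted) {
      g <- next_gene()
      gpr <- g
      supply_genes[[k]] <- g
      ub <- spec$product_capacity * a_k
    } else if (spec$decoys && k == 1L) {
      g <- c(next_gene(), next_gene())
      gpr <- paste(g, collapse = " and ")  # enzymatic complex decoy
      supply_genes[[k]] <- g
      ub <- 1000
      decoy_reasons[id] <- "multi_gene"
    } else if (spec$decoys && k == 2L) {
      gpr <- ""                            # gap-filled, not gene-encoded
      supply_genes[[k]] <- character(0)
      ub <- 1000
      decoy_reasons[id] <- "gap_fill"
    } else {
      g <- next_gene()
      gpr <- g
      supply_genes[[k]] <- g
      ub <- 1000
    }
    add(id, stats::setNames(c(-1, 1), c("precursor_c", prec_names[k])),
        ub = ub, gpr = gpr, subsystem = "precursor supply")
  }

  if (spec$decoys) {
    pks_genes <- c(next_gene(), next_gene())
    asm_gpr <- paste(pks_genes, collapse = " or ")  # paralog decoy
    decoy_reasons["ASSEMBLY"] <- "multi_gene"
  } else {
    pks_genes <- next_gene()
    asm_gpr <- pks_genes
  }
  asm_stoich <- stats::setNames(c(-spec$product_precursors, 1),
                                c(prec_names, "product_c"))
  add("ASSEMBLY", asm_stoich, gpr = asm_gpr,
      subsystem = "antibiotic biosynthesis")

  bio_stoich <- c(precursor_c = -1 / spec$biomass_yield, biomass_c = 1)
  if (spec$cofactor_branch) bio_stoich <- c(bio_stoich, cofactor_c = -1)
  add("BIOMASS", bio_stoich, subsystem = "biomass assembly",
      name = "biomass assembly")

  add("EX_biomass", c(biomass_c = -1), subsystem = "exchange")
  add("EX_product", c(product_c = -1), subsystem = "exchange")
  decoy_reasons["EX_product"] <- "exchange"

  model <- metabolic_model(
    dplyr::bind_rows(rows),
    objective = "BIOMASS",
    name = paste0("toy_antibiotic_producer_seed", spec$seed)
  )

  a_tot <- sum(spec$product_precursors)
  U <- spec$uptake_capacity
  ground_truth <- list(
    spec = spec,
    max_growth = U * spec$biomass_yield,
    max_product = min(spec$product_capacity, U / a_tot),
    total_precursor_stoich = a_tot,
    planted_supply_reaction = spec$planted_supply_reaction,
    planted_gene = supply_genes[[planted_k]],
    decoy_reasons = decoy_reasons,
    biomass_id = "BIOMASS",
    product_id = "EX_product",
    genes_growth_mode = c(core_genes, cof_gene),
    genes_product_mode = c(core_genes,
                           unlist(supply_genes, use.names = FALSE), pks_genes)
  )
  list(model = model, ground_truth = ground_truth)
}

#' Analytic maximal product rate at a fixed growth rate
#'
#' The closed-form counterpart of one Pareto sweep point on a toy
#' model: carbon left after growth, divided by the total precursor
#' stoichiometry, clipped at the planted supply capacity (and at 0).
#'
#' @param ground_truth The `ground_truth` element of
#'   [generate_toy_model()].
#' @param mu Fixed growth rate(s) (1/h).
#' @return Numeric vector of maximal product rates (mmol/gDW/h).
#' @export
toy_max_product_at <- function(ground_truth, mu) {
  spec <- ground_truth$spec
  carbon_left <- spec$uptake_capacity - mu / spec$biomass_yield
  pmin(spec$product_capacity,
       pmax(carbon_left, 0) / ground_truth$total_precursor_stoich)
}

#' Generate a synthetic RPKM expression table
#'
#' Emulates the quartile structure of an RPKM table over a growth time
#' course: a planted set of active genes is drawn from a high
#' log-normal component, all other genes from a low one. With the
#' default separation (about two orders of magnitude) and
#' `noise_sd = 1.2` the two components overlap by roughly 5%; with
#' `noise_sd = 0` they separate perfectly and quartile classification
#' recovers the planted sets exactly (provided the active fraction
#' lies between the quartiles).
#'
#' @param genes Character vector of gene ids (e.g. `model$genes`).
#' @param active_genes Planted highly expressed genes: a character
#'   vector (same set at every time point) or a named list with one
#'   vector per time point.
#' @param timepoints Time-point labels; defaults to the four sampled
#'   culture times T1 = 48 h ... T4 = 120 h.
#' @param noise_sd Log-scale standard deviation of both components.
#' @param seed Integer seed; the table is deterministic per seed.
#' @param high_meanlog,low_meanlog Log-means of the active and
#'   inactive components (defaults 200 and 2 RPKM, straddling the
#'   conventional RPKM > 10 expression baseline).
#' @return Tibble: `gene_id` plus one RPKM column per time point.
#' @export
generate_expression <- function(genes, active_genes,
                                timepoints = c("T1", "T2", "T3", "T4"),
                                noise_sd = 1.2, seed = 1L,
                                high_meanlog = log(200),
                                low_meanlog = log(2)) {
  if (!is.list(active_genes)) {
    active_genes <- stats::setNames(
      rep(list(active_genes), length(timepoints)), timepoints)
  }
  stopifnot(length(active_genes) == length(timepoints))
  bad <- setdiff(unique(unlist(active_genes)), genes)
  if (length(bad)) {
    rlang::abort(paste0("active genes not in the gene set: ",
                        paste(bad, collapse = ", ")),
                 class = "fluxscape_spec_error")
  }
  out <- tibble::tibble(gene_id = genes)
  with_seed(seed, {
    for (k in seq_along(timepoints)) {
      act <- genes %in% active_genes[[k]]
      meanlog <- ifelse(act, high_meanlog, low_meanlog)
      out[[timepoints[k]]] <- exp(stats::rnorm(length(genes), meanlog, noise_sd))
    }
  })
  out
}
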