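# SBML reader/writer. Level 3 + fbc (version 2) is the primary dialect:
# bounds as flux-bound parameters, GPRs as geneProductAssociation trees,
# objective from the active fbc objective. Level 2 COBRA-style exports are
# supported on read through the kineticLaw LOWER_BOUND/UPPER_BOUND
# parameters and the GENE_ASSOCIATION/SUBSYSTEM notes conventions.
# Identifiers are taken verbatim (no namespace mangling); gene products
# are matched by fbc:label when present, else fbc:id.

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# attribute lookup ignoring namespace prefixes
sbml_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit) == 0L) NA_character_ else unname(at[hit[1L]])
}

sbml_children <- function(node, local) {
  xml2::xml_find_all(node, paste0("./*[local-name()='", local, "']"))
}

sbml_find_all <- function(node, path_locals) {
  xp <- paste0(vapply(path_locals, function(p) paste0("*[local-name()='", p, "']"),
                      character(1)), collapse = "/")
  xml2::xml_find_all(node, paste0("./", xp))
}

#' Read a metabolic model from SBML
#'
#' @param path SBML file path.
#' @param objective Optional reaction id overriding the file's active
#'   flux objective.
#' @param name Optional model name override.
#' @return A validated `metabolic_model`.
#' @seealso [read_model()] for format auto-detection.
#' @export
read_model_sbml <- function(path, objective = NULL, name = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "fluxscape_io_error")
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    rlang::abort(paste0("malformed SBML: ", conditionMessage(e)),
                 class = "fluxscape_parse_error")
  })
  model_node <- xml2::xml_find_first(doc, "/*/*[local-name()='model']")
  if (inherits(model_node, "xml_missing")) {
    rlang::abort("malformed SBML: no <model> element.",
                 class = "fluxscape_parse_error")
  }

  species <- sbml_find_all(model_node, c("listOfSpecies", "species"))
  met_tbl <- tibble::tibble(
    id = vapply(species, sbml_attr, character(1), "id"),
    name = vapply(species, sbml_attr, character(1), "name"),
    compartment = vapply(species, sbml_attr, character(1), "compartment"),
    formula = vapply(species, function(s) {
      f <- sbml_attr(s, "chemicalFormula")
      if (is.na(f)) NA_character_ else f
    }, character(1)),
    boundary = vapply(species, function(s) {
      identical(sbml_attr(s, "boundaryCondition"), "true")
    }, logical(1))
  )
  met_tbl$name <- ifelse(is.na(met_tbl$name), met_tbl$id, met_tbl$name)
  boundary_ids <- met_tbl$id[met_tbl$boundary]

  params <- sbml_find_all(model_node, c("listOfParameters", "parameter"))
  param_val <- stats::setNames(
    vapply(params, function(p) as.numeric(sbml_attr(p, "value")), numeric(1)),
    vapply(params, sbml_attr, character(1), "id")
  )

  gps <- sbml_find_all(model_node, c("listOfGeneProducts", "geneProduct"))
  gp_label <- stats::setNames(
    vapply(gps, function(g) {
      lab <- sbml_attr(g, "label")
      if (is.na(lab)) sbml_attr(g, "id") else lab
    }, character(1)),
    vapply(gps, sbml_attr, character(1), "id")
  )

  rxn_nodes <- sbml_find_all(model_node, c("listOfReactions", "reaction"))
  if (length(rxn_nodes) == 0L) {
    rlang::abort("empty model: SBML file declares no reactions.",
                 class = "fluxscape_model_error")
  }
  rows <- purrr::map(rxn_nodes, function(rn) {
    id <- sbml_attr(rn, "id")
    if (is.na(id)) {
      rlang::abort("malformed SBML: reaction without id.",
                   class = "fluxscape_parse_error")
    }
    sp_ref <- function(list_name, sign) {
      refs <- sbml_find_all(rn, c(list_name, "speciesReference"))
      s <- vapply(refs, function(r) {
        st <- sbml_attr(r, "stoichiometry")
        if (is.na(st)) 1 else as.numeric(st)
      }, numeric(1))
      stats::setNames(sign * s, vapply(refs, sbml_attr, character(1), "species"))
    }
    stoich <- c(sp_ref("listOfReactants", -1), sp_ref("listOfProducts", +1))
    stoich <- stoich[!(names(stoich) %in% boundary_ids)]
    reversible <- !identical(sbml_attr(rn, "reversible"), "false")

    lb <- ub <- NA_real_
    lb_ref <- sbml_attr(rn, "lowerFluxBound")
    ub_ref <- sbml_attr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(param_val)) lb <- param_val[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(param_val)) ub <- param_val[[ub_ref]]
    if (is.na(lb) || is.na(ub)) {  # L2 fallback: kineticLaw parameters
      kl <- sbml_find_all(rn, c("kineticLaw", "listOfParameters", "parameter"))
      for (p in kl) {
        pid <- sbml_attr(p, "id")
        if (is.na(pid)) next
        if (pid == "LOWER_BOUND" && is.na(lb)) lb <- as.numeric(sbml_attr(p, "value"))
        if (pid == "UPPER_BOUND" && is.na(ub)) ub <- as.numeric(sbml_attr(p, "value"))
      }
    }

    gpr <- ""
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      child <- xml2::xml_find_first(gpa, "./*")
      gpr <- sbml_gpa_to_text(child, gp_label)
    }
    subsystem <- ""
    notes <- xml2::xml_find_first(rn, "./*[local-name()='notes']")
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(xml2::xml_find_all(notes, ".//text()"))
      ga <- grep("GENE[_ ]ASSOCIATION\\s*:", txt, value = TRUE)
      if (!nzchar(gpr) && length(ga)) {
        gpr <- trimws(sub(".*GENE[_ ]ASSOCIATION\\s*:", "", ga[1]))
      }
      ss <- grep("SUBSYSTEM\\s*:", txt, value = TRUE)
      if (length(ss)) subsystem <- trimws(sub(".*SUBSYSTEM\\s*:", "", ss[1]))
    }

    tibble::tibble(
      id = id,
      name = {
        nm <- sbml_attr(rn, "name")
        if (is.na(nm)) id else nm
      },
      stoich = list(stoich),
      lb = lb, ub = ub, reversible = reversible,
      gpr = gpr, subsystem = subsystem
    )
  })
  rx <- dplyr::bind_rows(rows)
  empty <- rx$id[purrr::map_int(rx$stoich, length) == 0L]
  if (length(empty)) {
    rlang::abort(paste0("reactions with only boundary species: ",
                        paste(empty, collapse = ", ")),
                 class = "fluxscape_model_error")
  }

  if (is.null(objective)) {
    fo <- sbml_find_all(model_node,
      c("listOfObjectives", "objective", "listOfFluxObjectives", "fluxObjective"))
    if (length(fo)) objective <- sbml_attr(fo[[1L]], "reaction")
  }
  mname <- name %||% sbml_attr(model_node, "id")
  if (is.na(mname)) mname <- "sbml_model"

  metabolic_model(
    rx,
    metabolites = dplyr::select(
      dplyr::filter(met_tbl, !.data$boundary),
      "id", "name", "compartment", "formula"
    ),
    objective = objective,
    name = mname
  )
}

sbml_gpa_to_text <- function(node, gp_label) {
  if (is.null(node) || inherits(node, "xml_missing")) return("")
  local <- xml2::xml_name(node)
  if (local == "geneProductRef") {
    ref <- sbml_attr(node, "geneProduct")
    return(if (ref %in% names(gp_label)) gp_label[[ref]] else ref)
  }
  if (local %in% c("and", "or")) {
    parts <- vapply(xml2::xml_children(node), sbml_gpa_to_text, character(1),
                    gp_label = gp_label)
    return(paste0("(", paste(parts, collapse = paste0(" ", local, " ")), ")"))
  }
  ""
}

#' Write a metabolic model as SBML Level 3 with fbc
#'
#' Bounds become shared flux-bound parameters, GPR trees become
#' `geneProductAssociation` elements, and the model objective becomes
#' the active fbc objective (maximize).
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_L3_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mn <- xml2::xml_add_child(doc, "model", id = model$name, "fbc:strict" = "false")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  for (cc in comps) {
    xml2::xml_add_child(lc, "compartment", id = cc, constant = "true")
  }

  ls <- xml2::xml_add_child(mn, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      ls, "species", id = m$id, name = m$name, compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false"
    )
    if (!is.na(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }

  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bound_id <- stats::setNames(
    paste0("fb_", seq_along(bounds)), sprintf("%.17g", bounds)
  )
  lp <- xml2::xml_add_child(mn, "listOfParameters")
  for (b in bounds) {
    xml2::xml_add_child(lp, "parameter", id = bound_id[[sprintf("%.17g", b)]],
                        value = sprintf("%.17g", b), constant = "true",
                        "sboTerm" = "SBO:0000625")
  }

  lr <- xml2::xml_add_child(mn, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml2::xml_add_child(
      lr, "reaction", id = r$id, name = r$name,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = bound_id[[sprintf("%.17g", r$lb)]],
      "fbc:upperFluxBound" = bound_id[[sprintf("%.17g", r$ub)]]
    )
    if (nzchar(r$subsystem)) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    s <- r$stoich[[1L]]
    reactants <- s[s < 0]
    products <- s[s > 0]
    if (length(reactants)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(reactants)) {
        xml2::xml_add_child(lre, "speciesReference", species = m,
                            stoichiometry = sprintf("%.17g", -reactants[[m]]),
                            constant = "true")
      }
    }
    if (length(products)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(products)) {
        xml2::xml_add_child(lpr, "speciesReference", species = m,
                            stoichiometry = sprintf("%.17g", products[[m]]),
                            constant = "true")
      }
    }
    rule <- r$rule[[1L]]
    if (length(rule$genes)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      sbml_add_gpa_node(gpa, rule$root)
    }
  }

  lo <- xml2::xml_add_child(mn, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = model$objective,
                      "fbc:coefficient" = "1")

  lgp <- xml2::xml_add_child(mn, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    xml2::xml_add_child(lgp, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", gsub("[^A-Za-z0-9_]", "_", g)),
                        "fbc:label" = g)
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_add_gpa_node <- function(parent, node) {
  if (is.character(node)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", gsub("[^A-Za-z0-9_]", "_", node)))
    return(invisible(NULL))
  }
  grp <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
  for (a in node$args) sbml_add_gpa_node(grp, a)
  invisible(NULL)
}
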