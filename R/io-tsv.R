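#' Read a metabolic model from file
#'
#' Dispatches on `format` (or the file extension when `"auto"`):
#' `.xml`/`.sbml` files are parsed as SBML (Level 3 with the `fbc`
#' extension preferred, Level 2 notes-field conventions as fallback),
#' anything else as the package's native reactions TSV.
#'
#' @param path File path.
#' @param format `"auto"`, `"sbml"` or `"tsv"`.
#' @param ... Passed to the format-specific reader.
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "tsv"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  }
  switch(format,
    sbml = read_model_sbml(path, ...),
    tsv = read_model_tsv(path, ...)
  )
}

#' Write a metabolic model to file
#'
#' @param model A `metabolic_model`.
#' @param path Output path; extension chooses the format when `format`
#'   is `"auto"`.
#' @param format `"auto"`, `"sbml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  }
  switch(format,
    sbml = write_model_sbml(model, path),
    tsv = write_model_tsv(model, path)
  )
  invisible(path)
}

#' Parse a reaction equation string
#'
#' Equations use the conventional arrow notation, e.g.
#' `"2 nadph + crotonyl_coa -> ethylmalonyl_coa"`; `<=>` (or `<->`)
#' marks a reversible reaction. One side may be empty, as in exchange
#' reactions (`"glc_e <=>"`). Coefficients default to 1.
#'
#' @param eq Equation string.
#' @return List with `stoich` (named numeric, consumed metabolites
#'   negative) and `reversible` (logical).
#' @export
parse_equation <- function(eq) {
  eq <- trimws(eq)
  m <- regexpr("<=>|<->|-->|=>|->", eq)
  if (m == -1L) {
    rlang::abort(paste0("no reaction arrow in equation: '", eq, "'"),
                 class = "fluxscape_parse_error")
  }
  arrow <- regmatches(eq, m)
  reversible <- arrow %in% c("<=>", "<->")
  sides <- strsplit(eq, "<=>|<->|-->|=>|->")[[1]]
  lhs <- if (length(sides) >= 1L) sides[1] else ""
  rhs <- if (length(sides) >= 2L) sides[2] else ""
  stoich <- c(parse_equation_side(lhs, -1), parse_equation_side(rhs, +1))
  # a metabolite on both sides nets out
  if (anyDuplicated(names(stoich))) {
    stoich <- tapply(stoich, names(stoich), sum)
    stoich <- stoich[abs(stoich) > 0]
  }
  if (length(stoich) == 0L) {
    rlang::abort(paste0("equation has no net stoichiometry: '", eq, "'"),
                 class = "fluxscape_parse_error")
  }
  list(stoich = stoich, reversible = reversible)
}

parse_equation_side <- function(side, sign) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "\\+")[[1]])
  terms <- terms[nzchar(terms)]
  out <- numeric(length(terms))
  ids <- character(length(terms))
  for (k in seq_along(terms)) {
    parts <- strsplit(terms[k], "\\s+")[[1]]
    coef <- suppressWarnings(as.numeric(parts[1]))
    if (length(parts) > 1L && !is.na(coef)) {
      ids[k] <- paste(parts[-1], collapse = " ")
      out[k] <- sign * coef
    } else {
      ids[k] <- terms[k]
      out[k] <- sign
    }
  }
  stats::setNames(out, ids)
}

#' Render a stoichiometry map as an equation string
#'
#' @param stoich Named numeric vector (negative = consumed).
#' @param reversible Logical; use `<=>` instead of `->`.
#' @return Equation string.
#' @export
format_equation <- function(stoich, reversible = FALSE) {
  fmt_side <- function(s) {
    if (length(s) == 0L) return("")
    paste(ifelse(abs(s) == 1, names(s), paste(format(abs(s)), names(s))),
          collapse = " + ")
  }
  lhs <- fmt_side(stoich[stoich < 0])
  rhs <- fmt_side(stoich[stoich > 0])
  trimws(paste(lhs, if (reversible) "<=>" else "->", rhs))
}

#' Read a model from the native reactions TSV
#'
#' A hand-writable tabular model format: one row per reaction with
#' columns `id`, `equation` and optionally `lb`, `ub`, `gpr`,
#' `subsystem`, `name`. When bounds are absent, reversible equations
#' (`<=>`) get (-1000, 1000) and irreversible ones (0, 1000).
#'
#' @param path Reactions TSV path.
#' @param metabolites_path Optional metabolites TSV (`id`, `name`,
#'   `compartment`, `formula`).
#' @param objective,name Passed to [metabolic_model()].
#' @return A validated `metabolic_model`.
#' @export
read_model_tsv <- function(path, metabolites_path = NULL, objective = NULL,
                           name = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "fluxscape_io_error")
  }
  rx <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("id", "equation") %in% names(rx))) {
    rlang::abort("reactions TSV needs `id` and `equation` columns.",
                 class = "fluxscape_parse_error")
  }
  if (nrow(rx) == 0L) {
    rlang::abort("empty model: reactions TSV has no rows.",
                 class = "fluxscape_model_error")
  }
  parsed <- purrr::map(rx$equation, parse_equation)
  rx$stoich <- purrr::map(parsed, "stoich")
  rx$reversible <- purrr::map_lgl(parsed, "reversible")
  rx$equation <- NULL
  mets <- if (!is.null(metabolites_path)) {
    readr::read_tsv(metabolites_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  metabolic_model(rx, metabolites = mets, objective = objective,
                  name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a model to the native reactions TSV
#'
#' @param model A `metabolic_model`.
#' @param path Reactions TSV path.
#' @param metabolites_path Optional path for the metabolites table.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path, metabolites_path = NULL) {
  rx <- model$reactions
  out <- tibble::tibble(
    id = rx$id,
    name = rx$name,
    equation = purrr::map2_chr(rx$stoich, rx$lb < 0, format_equation),
    lb = rx$lb,
    ub = rx$ub,
    gpr = rx$gpr,
    subsystem = rx$subsystem
  )
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(metabolites_path)) {
    readr::write_tsv(model$metabolites, metabolites_path, progress = FALSE)
  }
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
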