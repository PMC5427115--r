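#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers linking a
#' reaction to the genes whose products catalyse it: `and` joins subunits
#' of an enzymatic complex, `or` joins isozymes or paralogs. Rules are
#' parsed into a small expression tree used for gene accounting, for the
#' multi-gene exclusion filter of the overexpression-target scan, and for
#' mapping expression values onto reactions (AND -> min, OR -> max).
#'
#' @param rule_text A single rule string, e.g. `"g1 and (g2 or g3)"`.
#'   Operators are case-insensitive; parentheses group. The empty string
#'   (or `NA`) yields the empty rule.
#' @return An object of class `gpr_rule`: a list with `root` (the
#'   expression tree: leaves are gene-id strings; internal nodes are lists
#'   with `op` in `"and"`/`"or"` and `args`), `genes` (character vector of
#'   distinct gene ids), and logicals `has_and`, `has_or`.
#' @examples
#' r <- parse_gpr("g1 and (g2 or g3)")
#' r$genes
#' r$has_and
#' @export
parse_gpr <- function(rule_text) {
  if (length(rule_text) != 1L) {
    rlang::abort("`rule_text` must be a single string.", class = "fluxscape_gpr_error")
  }
  if (is.na(rule_text) || !nzchar(trimws(rule_text))) {
    return(new_gpr_rule(NULL))
  }
  toks <- gpr_tokenize(rule_text)
  st <- list(toks = toks, pos = 1L)
  res <- gpr_parse_or(st)
  if (res$st$pos <= length(toks)) {
    rlang::abort(
      paste0("Trailing input in GPR rule at token '", toks[res$st$pos], "': ", rule_text),
      class = "fluxscape_gpr_error"
    )
  }
  new_gpr_rule(res$node)
}

new_gpr_rule <- function(root) {
  genes <- gpr_collect_genes(root)
  structure(
    list(
      root = root,
      genes = genes,
      has_and = gpr_has_op(root, "and"),
      has_or = gpr_has_op(root, "or")
    ),
    class = "gpr_rule"
  )
}

#' @export
print.gpr_rule <- function(x, ...) {
  if (is.null(x$root)) {
    cat("<gpr_rule: empty>\n")
  } else {
    cat("<gpr_rule> ", deparse_gpr(x), "\n", sep = "")
  }
  invisible(x)
}

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# recursive-descent grammar: or_expr := and_expr ('or' and_expr)*
gpr_parse_or <- function(st) {
  res <- gpr_parse_and(st)
  args <- list(res$node)
  st <- res$st
  while (st$pos <= length(st$toks) && tolower(st$toks[st$pos]) == "or") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_and(st)
    args <- c(args, list(res$node))
    st <- res$st
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  list(node = node, st = st)
}

gpr_parse_and <- function(st) {
  res <- gpr_parse_atom(st)
  args <- list(res$node)
  st <- res$st
  while (st$pos <= length(st$toks) && tolower(st$toks[st$pos]) == "and") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_atom(st)
    args <- c(args, list(res$node))
    st <- res$st
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  list(node = node, st = st)
}

gpr_parse_atom <- function(st) {
  if (st$pos > length(st$toks)) {
    rlang::abort("Unexpected end of GPR rule.", class = "fluxscape_gpr_error")
  }
  tok <- st$toks[st$pos]
  if (tok == "(") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_or(st)
    st <- res$st
    if (st$pos > length(st$toks) || st$toks[st$pos] != ")") {
      rlang::abort("Unbalanced parentheses in GPR rule.", class = "fluxscape_gpr_error")
    }
    st$pos <- st$pos + 1L
    return(list(node = res$node, st = st))
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    rlang::abort(
      paste0("Unexpected token '", tok, "' in GPR rule."),
      class = "fluxscape_gpr_error"
    )
  }
  st$pos <- st$pos + 1L
  list(node = tok, st = st)
}

gpr_collect_genes <- function(node) {
  if (is.null(node)) return(character(0))
  if (is.character(node)) return(node)
  unique(unlist(lapply(node$args, gpr_collect_genes), use.names = FALSE))
}

gpr_has_op <- function(node, op) {
  if (is.null(node) || is.character(node)) return(FALSE)
  node$op == op || any(vapply(node$args, gpr_has_op, logical(1), op = op))
}

#' Render a GPR rule back to its text form
#'
#' @param rule A `gpr_rule`.
#' @return A single string; the empty rule renders as `""`.
#' @export
deparse_gpr <- function(rule) {
  stopifnot(inherits(rule, "gpr_rule"))
  deparse_gpr_node(rule$root)
}

deparse_gpr_node <- function(node) {
  if (is.null(node)) return("")
  if (is.character(node)) return(node)
  parts <- vapply(node$args, function(a) {
    s <- deparse_gpr_node(a)
    if (!is.character(a) && a$op != node$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", node$op, " "))
}

#' Evaluate a GPR rule against per-gene expression values
#'
#' Maps gene-level expression onto a reaction-level value using the
#' standard iMAT-family convention: AND (complex) takes the minimum over
#' subunits, OR (isozymes) the maximum. Genes missing from `values` are
#' dropped from OR branches; an AND branch with any missing gene is
#' unresolvable and returns `NA` (the caller treats the reaction as
#' unclassifiable, i.e. MODERATE).
#'
#' @param rule A `gpr_rule`.
#' @param values Named numeric vector of per-gene expression (e.g. RPKM).
#' @return A single numeric value, or `NA_real_` when the rule is empty or
#'   cannot be resolved.
#' @export
eval_gpr <- function(rule, values) {
  stopifnot(inherits(rule, "gpr_rule"))
  eval_gpr_node(rule$root, values)
}

eval_gpr_node <- function(node, values) {
  if (is.null(node)) return(NA_real_)
  if (is.character(node)) {
    if (node %in% names(values)) return(unname(values[[node]]))
    return(NA_real_)
  }
  vals <- vapply(node$args, eval_gpr_node, numeric(1), values = values)
  if (node$op == "and") {
    if (anyNA(vals)) return(NA_real_)  # missing complex subunit
    min(vals)
  } else {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    max(vals)
  }
}
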