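#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene ids with `and` (enzyme complex)
#' and `or` (isozymes), e.g. `"(G1 and G2) or G3"`. The parse tree drives
#' expression-to-reaction mapping: `and` nodes take the minimum of their
#' operands (a complex is limited by its scarcest subunit), `or` nodes the sum
#' (isozymes contribute additively).
#'
#' @param rule_text GPR rule as text; `and`/`or` are case-insensitive;
#'   `""`/`NA` denote no gene association.
#' @return A parse tree: `NULL` for the empty rule, otherwise nested lists with
#'   `op` in `c("gene", "and", "or")`; gene nodes carry `gene`, boolean nodes
#'   carry `args` (a list of subtrees).
#' @examples
#' parse_gpr("(G1 and G2) or G3")
#' @export
parse_gpr <- function(rule_text) {
  if (is.null(rule_text) || is.na(rule_text)) rule_text <- ""
  rule_text <- trimws(rule_text)
  if (rule_text == "") return(NULL)

  toks <- gpr_tokenize(rule_text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  tree <- gpr_parse_or(state)
  if (state$pos <= length(state$toks))
    stop("GPR parse error in '", rule_text, "': unexpected token '",
         state$toks[state$pos], "'")
  tree
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^\\s()]+"
  toks <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  bad <- grepl("[()]", toks) & !toks %in% c("(", ")")
  if (any(bad)) stop("GPR parse error: malformed token '", toks[bad][1], "'")
  toks
}

gpr_peek <- function(state) {
  if (state$pos > length(state$toks)) NA_character_ else state$toks[state$pos]
}

gpr_parse_or <- function(state) {
  args <- list(gpr_parse_and(state))
  while (!is.na(tk <- gpr_peek(state)) && tolower(tk) == "or") {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_and(state)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(state) {
  args <- list(gpr_parse_atom(state))
  while (!is.na(tk <- gpr_peek(state)) && tolower(tk) == "and") {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_atom(state)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(state) {
  tk <- gpr_peek(state)
  if (is.na(tk)) stop("GPR parse error: unexpected end of rule")
  if (tk == "(") {
    state$pos <- state$pos + 1L
    inner <- gpr_parse_or(state)
    if (is.na(gpr_peek(state)) || gpr_peek(state) != ")")
      stop("GPR parse error: unbalanced parentheses")
    state$pos <- state$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("GPR parse error: unexpected token '", tk, "'")
  state$pos <- state$pos + 1L
  list(op = "gene", gene = tk)
}

#' Genes referenced by a GPR parse tree
#'
#' @param tree a parse tree from [parse_gpr()].
#' @return character vector of gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR parse tree against expression values
#'
#' `and` -> min of operands, `or` -> sum; genes missing from `values` score 0.
#'
#' @param tree a parse tree from [parse_gpr()].
#' @param values named numeric vector of per-gene expression (TPM).
#' @return numeric score, or `NA_real_` for the empty tree.
#' @export
eval_gpr <- function(tree, values) {
  if (is.null(tree)) return(NA_real_)
  if (tree$op == "gene") {
    v <- values[tree$gene]
    return(if (is.na(v)) 0 else unname(v))
  }
  parts <- vapply(tree$args, eval_gpr, 0, values = values)
  if (tree$op == "and") min(parts) else sum(parts)
}

#' Render a GPR parse tree back to rule text
#'
#' Inverse of [parse_gpr()] up to whitespace and redundant parentheses; used by
#' the SBML writer.
#'
#' @param tree a parse tree from [parse_gpr()].
#' @return rule text (`""` for `NULL`).
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$op == "gene") return(tree$gene)
  sep <- if (tree$op == "and") " and " else " or "
  parts <- vapply(tree$args, function(a) {
    txt <- deparse_gpr(a)
    if (!is.null(a$op) && a$op %in% c("and", "or")) paste0("(", txt, ")") else txt
  }, "")
  paste(parts, collapse = sep)
}
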