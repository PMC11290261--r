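#' Read an expression table
#'
#' Delimited text with a header, either genes x samples or samples x genes;
#' orientation is auto-detected by matching row and column identifiers
#' against the model's gene list (the axis sharing more identifiers with the
#' model is taken as the gene axis).
#'
#' @param path TSV file path.
#' @param model a [metabolic_model] used for orientation detection.
#' @param sep field separator.
#' @return genes x samples numeric matrix (TPM).
#' @export
read_expression_table <- function(path, model, sep = "\t") {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids

  genes_in_rows <- sum(rownames(mat) %in% model$genes)
  genes_in_cols <- sum(colnames(mat) %in% model$genes)
  if (genes_in_rows == 0 && genes_in_cols == 0)
    stop("no identifier in '", path, "' matches a model gene; ",
         "cannot detect orientation")
  if (genes_in_cols > genes_in_rows) mat <- t(mat)
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("expression values must be finite and nonnegative")
  mat
}

#' Map a cohort expression matrix onto reactions
#'
#' Applies [map_expression_to_reactions()] to every sample column.
#'
#' @param expr genes x samples TPM matrix.
#' @param model a [metabolic_model].
#' @return reactions x samples matrix of expression scores (GPR-bearing
#'   reactions only).
#' @export
map_cohort_expression <- function(expr, model) {
  out <- apply(expr, 2, function(col)
    map_expression_to_reactions(stats::setNames(col, rownames(expr)), model))
  has_gpr <- names(model$gpr)[!vapply(model$gpr, is.null, TRUE)]
  matrix(out, nrow = length(has_gpr), dimnames = list(has_gpr, colnames(expr)))
}
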