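#' Construct a metabolic model
#'
#' The central container of the package: a stoichiometric model with flux
#' bounds, gene-protein-reaction (GPR) rules and pathway (subsystem) labels.
#' All downstream stages (flux fitting, flux-sum analysis, MGP prediction)
#' consume this object.
#'
#' @param metabolites data.frame with columns `id` (unique, compartment-tagged,
#'   e.g. `"akg_c"`), optionally `name` and `compartment`. When `compartment`
#'   is absent it is derived from the trailing underscore-delimited tag of the
#'   id (`"akg_c"` -> `"c"`).
#' @param reactions data.frame with columns `id` (unique), `lb`, `ub` (flux
#'   bounds, `lb <= ub`), `gpr` (GPR rule text, `""` for none), `pathway`
#'   (subsystem label; `NA`/`""` become `"unassigned"`), and a list-column
#'   `stoich` of named numeric vectors (metabolite id -> stoichiometric
#'   coefficient, negative for substrates).
#' @param genes optional character vector of gene ids; defaults to the union of
#'   genes appearing in the GPR rules.
#' @param id model identifier.
#' @return An object of class `metabolic_model`: a list with elements
#'   `id`, `metabolites`, `reactions`, `genes` and `gpr` (parsed GPR trees,
#'   one per reaction, `NULL` when the reaction has no gene association).
#' @examples
#' mets <- data.frame(id = c("a_c", "b_c"))
#' rxns <- data.frame(id = c("EX_a", "R1", "EX_b"), lb = c(-10, 0, 0),
#'                    ub = 1000, gpr = c("", "G1", ""),
#'                    pathway = c("", "Toy pathway", ""))
#' rxns$stoich <- list(c(a_c = -1), c(a_c = -1, b_c = 1), c(b_c = -1))
#' m <- metabolic_model(mets, rxns)
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(is.character(metabolites$id) || is.factor(metabolites$id))
  metabolites$id <- as.character(metabolites$id)
  if (anyDuplicated(metabolites$id))
    stop("duplicated metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- vapply(metabolites$id, met_compartment, "")
  if (any(is.na(metabolites$compartment) | metabolites$compartment == ""))
    stop("every metabolite id must carry exactly one compartment tag (e.g. '_c')")

  required <- c("id", "lb", "ub", "gpr", "pathway", "stoich")
  missing_cols <- setdiff(required, names(reactions))
  if (length(missing_cols))
    stop("reactions table lacks columns: ", paste(missing_cols, collapse = ", "))
  reactions$id <- as.character(reactions$id)
  if (anyDuplicated(reactions$id))
    stop("duplicated reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  reactions$gpr <- ifelse(is.na(reactions$gpr), "", as.character(reactions$gpr))
  reactions$pathway <- as.character(reactions$pathway)
  reactions$pathway[is.na(reactions$pathway) | reactions$pathway == ""] <- "unassigned"
  if (!all(is.finite(reactions$lb)) || !all(is.finite(reactions$ub)))
    stop("non-finite flux bounds")
  bad <- reactions$lb > reactions$ub
  if (any(bad))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(reactions$id[bad], collapse = ", "))

  met_ids <- metabolites$id
  for (k in seq_len(nrow(reactions))) {
    s <- reactions$stoich[[k]]
    if (length(s) == 0L)
      stop("reaction '", reactions$id[k], "' has empty stoichiometry")
    if (is.null(names(s)) || any(names(s) == ""))
      stop("reaction '", reactions$id[k], "' has unnamed stoichiometric coefficients")
    if (!all(is.finite(s)) || any(s == 0))
      stop("reaction '", reactions$id[k], "' has non-finite or zero coefficients")
    unknown <- setdiff(names(s), met_ids)
    if (length(unknown))
      stop("reaction '", reactions$id[k], "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(names(s)))
      stop("reaction '", reactions$id[k], "' repeats a metabolite")
  }

  gpr_trees <- lapply(reactions$gpr, parse_gpr)
  gpr_genes <- sort(unique(unlist(lapply(gpr_trees, gpr_genes))))
  if (is.null(genes)) {
    genes <- gpr_genes
  } else {
    genes <- as.character(genes)
    orphan <- setdiff(gpr_genes, genes)
    if (length(orphan))
      stop("GPR rules reference genes absent from the gene list: ",
           paste(orphan, collapse = ", "))
  }

  structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         genes = genes, gpr = stats::setNames(gpr_trees, reactions$id)),
    class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, %d genes, %d pathways>\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes),
              length(unique(x$reactions$pathway))))
  invisible(x)
}

#' Compartment tag and base id of a metabolite id
#'
#' Metabolite ids follow the convention `<base>_<compartment>` with a single
#' trailing underscore-delimited tag (`"akg_c"`, `"akg_m"`). The base id is
#' compartment-agnostic and is what currency lookups and compartment
#' deduplication key on.
#'
#' @param met_id character vector of metabolite ids.
#' @return `met_compartment`: the trailing tag; `met_base_id`: the id with the
#'   tag removed.
#' @export
met_base_id <- function(met_id) {
  sub("_[A-Za-z0-9]+$", "", met_id)
}

#' @rdname met_base_id
#' @export
met_compartment <- function(met_id) {
  m <- regmatches(met_id, regexpr("_([A-Za-z0-9]+)$", met_id))
  if (length(m) == 0 || m == met_id) return("")
  sub("^_", "", m)
}

#' Stoichiometric matrix of a model
#'
#' @param model a [metabolic_model].
#' @return dense numeric matrix S (metabolites x reactions), `S[i, j]` the
#'   coefficient of metabolite i in reaction j (0 when absent).
#' @export
stoichiometry_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (k in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[k]]
    S[names(s), k] <- s
  }
  S
}
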