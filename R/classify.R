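#' Classify a reaction
#'
#' Reactions are partitioned into five classes used by the MGP exclusion
#' rules: `exchange` (single-metabolite boundary reaction on an extracellular
#' species), `demand` (single-metabolite intracellular sink), `transport`
#' (the same metabolite base ids moved between compartments), `unassigned`
#' (no subsystem annotation) and `metabolic` (everything else). Mixed
#' transport-plus-transformation reactions classify as `metabolic`.
#'
#' @param model a [metabolic_model].
#' @param rxn_id reaction id in the model.
#' @param extracellular compartment tags treated as extracellular.
#' @return one of `"exchange"`, `"demand"`, `"transport"`, `"unassigned"`,
#'   `"metabolic"`.
#' @export
classify_reaction <- function(model, rxn_id, extracellular = c("e", "x")) {
  k <- match(rxn_id, model$reactions$id)
  if (is.na(k)) stop("unknown reaction id: ", rxn_id)
  s <- model$reactions$stoich[[k]]
  mets <- names(s)
  comp <- vapply(mets, met_compartment, "")

  if (length(s) == 1L) {
    return(if (comp %in% extracellular) "exchange" else "demand")
  }

  subs <- mets[s < 0]
  prods <- mets[s > 0]
  if (length(subs) && length(prods)) {
    sub_base <- sort(met_base_id(subs))
    prod_base <- sort(met_base_id(prods))
    pure_transport <- identical(sub_base, prod_base) &&
      !identical(sort(subs), sort(prods))
    if (pure_transport) return("transport")
  }

  if (model$reactions$pathway[k] == "unassigned") return("unassigned")
  "metabolic"
}

#' Classify all reactions of a model
#'
#' @inheritParams classify_reaction
#' @return named character vector, one class per reaction.
#' @export
classify_reactions <- function(model, extracellular = c("e", "x")) {
  stats::setNames(
    vapply(model$reactions$id, classify_reaction, "", model = model,
           extracellular = extracellular),
    model$reactions$id)
}

#' Classify a pathway label for the MGP exclusion rules
#'
#' A pathway is excluded from MGP candidates when it is `"unassigned"`, when
#' all of its reactions are boundary reactions (exchange/demand), or when all
#' of its reactions are transports that do not move an essential amino acid.
#'
#' @param model a [metabolic_model].
#' @param pathway pathway (subsystem) label.
#' @param essential_aa character vector of essential-amino-acid base ids
#'   granting the transport exception.
#' @return one of `"metabolic"`, `"exchange_demand"`, `"transport"`,
#'   `"transport_essential_aa"`, `"unassigned"`.
#' @export
classify_pathway <- function(model, pathway,
                             essential_aa = default_essential_aa()) {
  if (pathway == "unassigned") return("unassigned")
  idx <- which(model$reactions$pathway == pathway)
  if (!length(idx)) stop("unknown pathway label: ", pathway)
  cls <- vapply(model$reactions$id[idx], classify_reaction, "", model = model)
  if (all(cls %in% c("exchange", "demand"))) return("exchange_demand")
  if (all(cls %in% c("transport", "exchange", "demand")) && any(cls == "transport")) {
    moved <- unlist(lapply(idx[cls[match(model$reactions$id[idx],
                                         names(cls))] == "transport"], function(k) {
      met_base_id(names(model$reactions$stoich[[k]]))
    }))
    if (any(tolower(moved) %in% tolower(essential_aa)))
      return("transport_essential_aa")
    return("transport")
  }
  "metabolic"
}

#' Pathway labels eligible as MGP target pathways
#'
#' @inheritParams classify_pathway
#' @return character vector of pathway labels whose class is `metabolic` or
#'   `transport_essential_aa`.
#' @export
eligible_pathways <- function(model, essential_aa = default_essential_aa()) {
  labs <- unique(model$reactions$pathway)
  keep <- vapply(labs, function(p)
    classify_pathway(model, p, essential_aa) %in%
      c("metabolic", "transport_essential_aa"), TRUE)
  labs[keep]
}

#' Default currency metabolites
#'
#' Ubiquitous cofactors excluded from metabolite-level association testing
#' (compartment-agnostic base ids). Overridable by a plain-text
#' one-id-per-line file via [read_id_list()].
#'
#' @return character vector of base ids.
#' @export
default_currency_metabolites <- function() {
  read_id_list(system.file("extdata", "currency_metabolites.txt",
                           package = "mgpflux", mustWork = TRUE))
}

#' Default essential amino acids
#'
#' The nine essential amino acids (His, Ile, Leu, Lys, Met, Phe, Thr, Trp,
#' Val) as compartment-agnostic base ids in BiGG style, granting the transport
#' exception in the pathway exclusion rules.
#'
#' @return character vector of base ids.
#' @export
default_essential_aa <- function() {
  read_id_list(system.file("extdata", "essential_amino_acids.txt",
                           package = "mgpflux", mustWork = TRUE))
}

#' Read a one-id-per-line plain-text list
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("id list file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[x != "" & !startsWith(x, "#")]
  if (!length(x)) stop("id list file is empty: ", path)
  x
}

#' Is a metabolite a currency metabolite?
#'
#' Lookup is compartment-invariant: `atp_c` and `atp_m` both match base id
#' `atp`. Matching is case-insensitive.
#'
#' @param met_id character vector of (compartmented) metabolite ids.
#' @param currency character vector of currency base ids.
#' @return logical vector.
#' @export
is_currency <- function(met_id, currency = default_currency_metabolites()) {
  tolower(met_base_id(met_id)) %in% tolower(currency)
}
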