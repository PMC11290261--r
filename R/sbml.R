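SBML_NS <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  groups = "http://www.sbml.org/sbml/level3/version1/groups/version1"
)

#' Read a metabolic model from SBML (Level 3 + FBC)
#'
#' Reads the COBRA-compliant SBML dialect: species/reaction ids with `M_`/`R_`
#' prefixes, flux bounds as `fbc` parameter references, GPR rules as
#' `fbc:geneProductAssociation` trees, and subsystems either as `groups`
#' plugin groups or as `SUBSYSTEM:` notes. Reactions without a subsystem get
#' pathway label `"unassigned"`.
#'
#' @param path path to an SBML file.
#' @return a [metabolic_model].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML parse error: file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  model_node <- xml2::xml_find_first(doc, "/sbml:sbml/sbml:model", SBML_NS)
  if (inherits(model_node, "xml_missing"))
    stop("SBML parse error: no <model> element in ", path)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  params <- xml2::xml_find_all(
    model_node, "./sbml:listOfParameters/sbml:parameter", SBML_NS)
  param_vals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                                xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(model_node, "./sbml:listOfSpecies/sbml:species", SBML_NS)
  if (!length(sp)) stop("SBML parse error: model has no species")
  met_sids <- xml2::xml_attr(sp, "id")
  metabolites <- data.frame(
    id = strip_sid_prefix(met_sids, "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  strip_sid_prefix(met_sids, "M_"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  sid2met <- stats::setNames(metabolites$id, met_sids)

  gp <- xml2::xml_find_all(
    model_node, "./fbc:listOfGeneProducts/fbc:geneProduct", SBML_NS)
  gp_label <- xml2::xml_attr(gp, "fbc:label", ns = SBML_NS)
  gp_id <- xml2::xml_attr(gp, "fbc:id", ns = SBML_NS)
  gid2gene <- stats::setNames(
    ifelse(is.na(gp_label), strip_sid_prefix(gp_id, "G_"), gp_label), gp_id)

  rx <- xml2::xml_find_all(model_node, "./sbml:listOfReactions/sbml:reaction", SBML_NS)
  if (!length(rx)) stop("SBML parse error: model has no reactions")
  rxn_sids <- xml2::xml_attr(rx, "id")
  n <- length(rx)
  lb <- ub <- numeric(n)
  gpr <- pathway <- character(n)
  stoich <- vector("list", n)
  for (k in seq_len(n)) {
    node <- rx[[k]]
    lb_ref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = SBML_NS)
    ub_ref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = SBML_NS)
    if (is.na(lb_ref) || is.na(ub_ref) ||
        is.na(param_vals[lb_ref]) || is.na(param_vals[ub_ref]))
      stop("SBML parse error: reaction '", rxn_sids[k],
           "' lacks fbc flux bounds")
    lb[k] <- param_vals[[lb_ref]]
    ub[k] <- param_vals[[ub_ref]]

    s <- c(sbml_species_refs(node, "listOfReactants", -1),
           sbml_species_refs(node, "listOfProducts", +1))
    if (!length(s))
      stop("SBML parse error: reaction '", rxn_sids[k], "' has no species")
    unknown <- setdiff(names(s), names(sid2met))
    if (length(unknown))
      stop("SBML parse error: reaction '", rxn_sids[k],
           "' references unknown species '", unknown[1], "'")
    names(s) <- unname(sid2met[names(s)])
    stoich[[k]] <- s

    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", SBML_NS)
    gpr[k] <- if (inherits(gpa, "xml_missing")) "" else
      deparse_gpr(sbml_gpa_tree(gpa, gid2gene))

    note <- xml2::xml_find_first(
      node, ".//sbml:notes//*[starts-with(normalize-space(text()), 'SUBSYSTEM:')]",
      SBML_NS)
    pathway[k] <- if (inherits(note, "xml_missing")) NA_character_ else
      trimws(sub("^\\s*SUBSYSTEM:\\s*", "", xml2::xml_text(note)))
  }

  grp <- xml2::xml_find_all(
    model_node, "./groups:listOfGroups/groups:group", SBML_NS)
  for (g in grp) {
    lab <- xml2::xml_attr(g, "groups:name", ns = SBML_NS)
    if (is.na(lab)) lab <- xml2::xml_attr(g, "groups:id", ns = SBML_NS)
    members <- xml2::xml_attr(
      xml2::xml_find_all(g, "./groups:listOfMembers/groups:member", SBML_NS),
      "groups:idRef", ns = SBML_NS)
    pathway[match(members, rxn_sids)] <- lab
  }

  reactions <- data.frame(id = strip_sid_prefix(rxn_sids, "R_"),
                          lb = lb, ub = ub, gpr = gpr, pathway = pathway,
                          stringsAsFactors = FALSE)
  reactions$stoich <- stoich
  genes_listed <- sort(unique(unname(gid2gene)))
  genes <- if (!length(genes_listed)) NULL else {
    in_rules <- unique(unlist(lapply(gpr, function(g) gpr_genes(parse_gpr(g)))))
    sort(union(genes_listed, in_rules))
  }
  metabolic_model(metabolites, reactions, genes = genes, id = model_id)
}

sbml_species_refs <- function(rxn_node, list_name, sign) {
  refs <- xml2::xml_find_all(
    rxn_node, sprintf("./sbml:%s/sbml:speciesReference", list_name), SBML_NS)
  if (!length(refs)) return(stats::setNames(numeric(), character()))
  st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
  st[is.na(st)] <- 1
  stats::setNames(sign * st, xml2::xml_attr(refs, "species"))
}

sbml_gpa_tree <- function(node, gid2gene) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "fbc:geneProduct", ns = SBML_NS)
    gene <- gid2gene[gid]
    if (is.na(gene)) gene <- strip_sid_prefix(gid, "G_")
    return(list(op = "gene", gene = unname(gene)))
  }
  if (!nm %in% c("and", "or"))
    stop("SBML parse error: unexpected GPR element <", nm, ">")
  kids <- xml2::xml_children(node)
  list(op = nm, args = lapply(kids, sbml_gpa_tree, gid2gene = gid2gene))
}

strip_sid_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

#' Write a metabolic model to SBML (Level 3 + FBC)
#'
#' Emits the same dialect [read_sbml()] consumes; `write_sbml()` followed by
#' `read_sbml()` reproduces the model exactly (ids, stoichiometry, bounds, GPR
#' structure, pathway labels). Output is deterministic: the same model always
#' yields byte-identical SBML.
#'
#' @param model a [metabolic_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- xml_escape
  num <- function(x) sprintf("%.15g", x)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_NS[["sbml"]], '" xmlns:fbc="', SBML_NS[["fbc"]],
           '" xmlns:groups="', SBML_NS[["groups"]],
           '" level="3" version="1" fbc:required="false" groups:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>')
  for (cmp in sort(unique(model$metabolites$compartment)))
    out <- c(out, sprintf('      <compartment id="%s" constant="true"/>', esc(cmp)))
  out <- c(out, '    </listOfCompartments>', '    <listOfSpecies>')
  for (k in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[k, ]
    out <- c(out, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>'),
      esc(m$id), esc(m$name), esc(m$compartment)))
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions[k, ]
    out <- c(out,
      sprintf('      <parameter id="P_lb_%s" value="%s" constant="true"/>',
              esc(r$id), num(r$lb)),
      sprintf('      <parameter id="P_ub_%s" value="%s" constant="true"/>',
              esc(r$id), num(r$ub)))
  }
  out <- c(out, '    </listOfParameters>', '    <listOfReactions>')
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions[k, ]
    s <- r$stoich[[1]]
    out <- c(out, sprintf(
      paste0('      <reaction id="R_%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="P_lb_%s" fbc:upperFluxBound="P_ub_%s">'),
      esc(r$id), if (r$lb < 0) "true" else "false", esc(r$id), esc(r$id)))
    out <- c(out,
      '        <notes>',
      '          <body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('            <p>SUBSYSTEM: %s</p>', esc(r$pathway)),
      '          </body>',
      '        </notes>')
    for (side in list(c("listOfReactants", -1), c("listOfProducts", 1))) {
      sel <- if (side[[2]] == -1) s < 0 else s > 0
      if (any(sel)) {
        out <- c(out, sprintf('        <%s>', side[[1]]))
        for (met in names(s)[sel])
          out <- c(out, sprintf(
            '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
            esc(met), num(abs(s[[met]]))))
        out <- c(out, sprintf('        </%s>', side[[1]]))
      }
    }
    tree <- model$gpr[[r$id]]
    if (!is.null(tree))
      out <- c(out, '        <fbc:geneProductAssociation>',
               sbml_gpa_xml(tree, indent = "          "),
               '        </fbc:geneProductAssociation>')
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')

  if (length(model$genes)) {
    out <- c(out, '    <fbc:listOfGeneProducts>')
    for (g in model$genes)
      out <- c(out, sprintf(
        '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
        esc(sanitize_sid(g)), esc(g)))
    out <- c(out, '    </fbc:listOfGeneProducts>')
  }

  paths <- setdiff(unique(model$reactions$pathway), "unassigned")
  if (length(paths)) {
    out <- c(out, '    <groups:listOfGroups>')
    for (i in seq_along(paths)) {
      out <- c(out, sprintf(
        '      <groups:group groups:id="g%d" groups:kind="partonomy" groups:name="%s">',
        i, esc(paths[i])),
        '        <groups:listOfMembers>')
      for (rid in model$reactions$id[model$reactions$pathway == paths[i]])
        out <- c(out, sprintf('          <groups:member groups:idRef="R_%s"/>',
                              esc(rid)))
      out <- c(out, '        </groups:listOfMembers>', '      </groups:group>')
    }
    out <- c(out, '    </groups:listOfGroups>')
  }

  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

sbml_gpa_xml <- function(tree, indent) {
  if (tree$op == "gene")
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   indent, xml_escape(sanitize_sid(tree$gene))))
  tag <- paste0("fbc:", tree$op)
  c(sprintf('%s<%s>', indent, tag),
    unlist(lapply(tree$args, sbml_gpa_xml, indent = paste0(indent, "  "))),
    sprintf('%s</%s>', indent, tag))
}

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
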