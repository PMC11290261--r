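#' Specification for a toy genome-scale metabolic model
#'
#' Describes the multi-pathway toy GEM built by [generate_toy_gem()]: a set
#' of linear biosynthetic pathways fed by exchange/transport reactions and
#' draining into shared "hub" metabolites that are produced by more than one
#' pathway (so the pathway decomposition of flux-sums is non-trivial), plus a
#' constitutive high-expression "housekeeping" pathway that anchors the
#' expression-to-flux rescaling the way highly expressed constitutive genes
#' do in genome-scale data.
#'
#' @param n_pathways number of biosynthetic pathways (>= 1). The default (6)
#'   gives quantile normalization a workably fine value grid; see the
#'   methods vignette.
#' @param rxns_per_pathway internal chain reactions per pathway (>= 2).
#' @param n_shared number of shared hub metabolites (>= 1, <= `n_pathways`).
#' @param bound flux bound magnitude (default 1000).
#' @param housekeeping include the housekeeping pathway (default `TRUE`).
#' @param seed integer seed controlling the GPR structure draw.
#' @return object of class `toy_gem_spec`.
#' @export
toy_gem_spec <- function(n_pathways = 12, rxns_per_pathway = 4, n_shared = 4,
                         bound = 1000, housekeeping = TRUE, seed = 1) {
  if (n_pathways < 1) stop("toy GEM needs at least one pathway")
  if (rxns_per_pathway < 2) stop("each pathway needs at least two reactions")
  if (n_shared < 1 || n_shared > n_pathways)
    stop("n_shared must be between 1 and n_pathways")
  if (bound <= 0) stop("bound must be positive")
  structure(list(n_pathways = n_pathways, rxns_per_pathway = rxns_per_pathway,
                 n_shared = n_shared, bound = bound,
                 housekeeping = housekeeping, seed = seed),
            class = "toy_gem_spec")
}

#' Generate a toy genome-scale metabolic model
#'
#' Deterministic for a fixed spec (including its seed). Pathway `p` is a
#' linear chain: an exchange reaction supplies substrate `sub<p>_e`, a
#' transport reaction moves it into the cytosol, `rxns_per_pathway` internal
#' reactions convert it stepwise, and the terminal reaction condenses two
#' units of the last intermediate into one unit of a hub metabolite
#' `hub<h>_c` shared across pathways (round-robin assignment, so each hub is
#' produced by every pathway `p` with `p mod n_shared == h mod n_shared`).
#' The 2:1 condensation keeps hub turnover on the same scale as the chain
#' fluxes instead of strictly above them, which matters for rank-based
#' normalization downstream. Hubs drain through transport plus exchange. Every internal
#' reaction carries a GPR (most single-gene; some `and`/`or` rules, drawn
#' from the seed); every reaction can carry flux in some steady state.
#'
#' @param spec a [toy_gem_spec()].
#' @return a [metabolic_model] with pathway labels `"Pathway <p>"`,
#'   `"Housekeeping"`, `"Transport reactions"` and `"Exchange/demand
#'   reactions"`.
#' @export
generate_toy_gem <- function(spec = toy_gem_spec()) {
  stopifnot(inherits(spec, "toy_gem_spec"))
  b <- spec$bound
  mets <- character(); rxns <- list()
  add_rxn <- function(id, stoich, lb, ub, gpr, pathway) {
    rxns[[length(rxns) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                       ub = ub, gpr = gpr, pathway = pathway)
    mets <<- union(mets, names(stoich))
  }

  gpr_style <- withr_seed(spec$seed, {
    sample(c("single", "and", "or"), spec$n_pathways * spec$rxns_per_pathway,
           replace = TRUE, prob = c(0.6, 0.2, 0.2))
  })

  hub_of <- function(p) ((p - 1L) %% spec$n_shared) + 1L
  for (h in seq_len(spec$n_shared)) {
    hub <- sprintf("hub%d", h)
    add_rxn(sprintf("T_%s", hub),
            stats::setNames(c(-1, 1), sprintf("%s_%s", hub, c("c", "e"))),
            0, b, "", "Transport reactions")
    add_rxn(sprintf("EX_%s", hub),
            stats::setNames(-1, sprintf("%s_e", hub)),
            0, b, "", "Exchange/demand reactions")
  }

  g <- 0L
  for (p in seq_len(spec$n_pathways)) {
    pw <- sprintf("Pathway %d", p)
    sub <- sprintf("sub%d", p)
    add_rxn(sprintf("EX_%s", sub), stats::setNames(1, sprintf("%s_e", sub)),
            0, b, "", "Exchange/demand reactions")
    add_rxn(sprintf("T_%s", sub),
            stats::setNames(c(-1, 1), sprintf("%s_%s", sub, c("e", "c"))),
            0, b, "", "Transport reactions")
    prev <- sprintf("%s_c", sub)
    for (k in seq_len(spec$rxns_per_pathway)) {
      g <- g + 1L
      terminal <- k == spec$rxns_per_pathway
      nxt <- if (terminal) sprintf("hub%d_c", hub_of(p)) else
        sprintf("m%d_%d_c", p, k)
      gpr <- switch(gpr_style[g],
                    single = sprintf("G%d_%d", p, k),
                    and = sprintf("G%d_%d and G%d_%da", p, k, p, k),
                    or = sprintf("G%d_%d or G%d_%db", p, k, p, k))
      add_rxn(sprintf("R%d_%d", p, k),
              stats::setNames(c(if (terminal) -2 else -1, 1), c(prev, nxt)),
              0, b, gpr, pw)
      prev <- nxt
    }
  }

  if (spec$housekeeping) {
    add_rxn("EX_hksub", c(hksub_e = 1), 0, b, "", "Exchange/demand reactions")
    add_rxn("T_hksub", c(hksub_e = -1, hksub_c = 1), 0, b, "",
            "Transport reactions")
    add_rxn("HK1", c(hksub_c = -1, hkprod_c = 1), 0, b, "GHK1", "Housekeeping")
    add_rxn("T_hkprod", c(hkprod_c = -1, hkprod_e = 1), 0, b, "",
            "Transport reactions")
    add_rxn("EX_hkprod", c(hkprod_e = -1), 0, b, "", "Exchange/demand reactions")
  }

  metabolites <- data.frame(id = sort(mets), stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = vapply(rxns, `[[`, "", "id"),
    lb = vapply(rxns, `[[`, 0, "lb"),
    ub = vapply(rxns, `[[`, 0, "ub"),
    gpr = vapply(rxns, `[[`, "", "gpr"),
    pathway = vapply(rxns, `[[`, "", "pathway"),
    stringsAsFactors = FALSE)
  reactions$stoich <- lapply(rxns, `[[`, "stoich")
  metabolic_model(metabolites, reactions,
                  id = sprintf("toy_gem_p%d_r%d_s%d", spec$n_pathways,
                               spec$rxns_per_pathway, spec$seed))
}

#' Specification for a simulated cohort
#'
#' Describes the synthetic multi-omics cohort built by [simulate_cohort()]:
#' a stated world of baseline log-normal expression with per-sample noise, a
#' planted multiplicative mutation effect on one pathway's reaction genes, a
#' variant table passing the mutation filter cascade, and a metabolome with
#' planted log-fold changes and missing-at-random entries.
#'
#' @param n_samples cohort size (default 40).
#' @param n_mutant mutant samples per planted gene (default 10; both groups
#'   must have >= 3 samples so the mutation filters pass).
#' @param effects list of planted effects, each a list with `gene` (a model
#'   gene), `pathway` (the affected pathway label), `expr_multiplier`
#'   (multiplicative shift on that pathway's reaction genes in mutants;
#'   1 = null), and optionally `met_lfc` (log2 fold change planted in the
#'   metabolome for the pathway's product metabolites, default 1).
#' @param noise_sd per-gene per-sample log-normal noise sd on the natural-log
#'   scale (default 0.3).
#' @param baseline_meanlog,baseline_sdlog log-normal draw for per-gene
#'   baseline TPM (defaults `log(100)`, 0.7).
#' @param pathway_sdlog sd of an additional log-normal per-pathway baseline
#'   factor shared by a pathway's genes (default 0.5), emulating coherent
#'   pathway-level expression so pathway fluxes interleave in rank.
#' @param hk_expression baseline TPM of housekeeping genes (default 5000),
#'   anchoring the expression-to-flux rescaling.
#' @param missing_rate metabolome missing-at-random rate (default 0.1).
#' @param met_noise_sd metabolome log-normal noise sd (default 0.3).
#' @param seed integer seed.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_samples = 40, n_mutant = 10, effects = list(),
                            noise_sd = 0.3, baseline_meanlog = log(100),
                            baseline_sdlog = 0.7, pathway_sdlog = 0.5,
                            hk_expression = 5000,
                            missing_rate = 0.1, met_noise_sd = 0.3, seed = 1) {
  if (n_mutant < 3 || n_samples - n_mutant < 3)
    stop("need >= 3 mutant and >= 3 wild-type samples")
  for (e in effects) {
    stopifnot(!is.null(e$gene), !is.null(e$pathway), !is.null(e$expr_multiplier))
    if (e$expr_multiplier <= 0) stop("effect multipliers must be positive")
  }
  structure(list(n_samples = n_samples, n_mutant = n_mutant, effects = effects,
                 noise_sd = noise_sd, baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, pathway_sdlog = pathway_sdlog,
                 hk_expression = hk_expression,
                 missing_rate = missing_rate, met_noise_sd = met_noise_sd,
                 seed = seed),
            class = "cohort_sim_spec")
}

#' Simulate a cohort with planted mutation effects
#'
#' Bit-for-bit reproducible from `(model, spec)`. Baseline expression is
#' log-normal per gene (housekeeping genes fixed high); mutant samples have
#' every gene of the planted pathway scaled by the effect multiplier; the
#' variant table gives mutants nonsynonymous variants with >= 7 alternative
#' reads; metabolome peaks (one per non-currency cytosolic metabolite, plus
#' unannotated and currency decoys) are log-normal, with the planted
#' pathway's product metabolites shifted by `met_lfc` in mutants and entries
#' missing completely at random.
#'
#' @param model a [metabolic_model] (typically from [generate_toy_gem()]).
#' @param spec a [cohort_sim_spec()]; every planted gene must appear in the
#'   model's GPR rules.
#' @return list with `expression` (genes x samples TPM matrix), `variants`
#'   (data.frame: sample, gene, alt_reads, consequence), `metabolome` (a
#'   `metabolome_matrix` with annotation columns `peak`, `name`, `in_model`,
#'   `currency`), `truth` (data.frame of planted (metabolite base id, gene,
#'   pathway) triples; `primary` flags the hub product), and `mutant_samples`
#'   (named list gene -> sample ids).
#' @export
simulate_cohort <- function(model, spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  for (e in spec$effects) {
    if (!e$gene %in% model$genes)
      stop("planted gene '", e$gene, "' absent from the model's GPR rules")
    if (!e$pathway %in% model$reactions$pathway)
      stop("planted pathway '", e$pathway, "' absent from the model")
  }

  withr_seed(spec$seed, {
    samples <- sprintf("S%02d", seq_len(spec$n_samples))
    genes <- model$genes

    hk_genes <- hk_gene_set(model)
    baseline <- stats::setNames(
      stats::rlnorm(length(genes), spec$baseline_meanlog, spec$baseline_sdlog),
      genes)
    pathways <- setdiff(unique(model$reactions$pathway),
                        c("Housekeeping", "unassigned"))
    pw_factor <- stats::setNames(
      stats::rlnorm(length(pathways), 0, spec$pathway_sdlog), pathways)
    for (pw in pathways) {
      pg <- tryCatch(pathway_gene_set(model, pw), error = function(e) character())
      baseline[pg] <- baseline[pg] * pw_factor[[pw]]
    }
    baseline[hk_genes] <- spec$hk_expression

    mutant_samples <- list()
    for (e in spec$effects)
      mutant_samples[[e$gene]] <- sort(sample(samples, spec$n_mutant))

    expr <- matrix(
      baseline * stats::rlnorm(length(genes) * length(samples), 0, spec$noise_sd),
      nrow = length(genes), dimnames = list(genes, samples))
    for (e in spec$effects) {
      pw_genes <- pathway_gene_set(model, e$pathway)
      expr[pw_genes, mutant_samples[[e$gene]]] <-
        expr[pw_genes, mutant_samples[[e$gene]], drop = FALSE] * e$expr_multiplier
    }

    variants <- do.call(rbind, lapply(spec$effects, function(e) {
      data.frame(sample = mutant_samples[[e$gene]], gene = e$gene,
                 alt_reads = 7L + stats::rpois(spec$n_mutant, 20),
                 consequence = "nonsynonymous", stringsAsFactors = FALSE)
    }))
    if (is.null(variants))
      variants <- data.frame(sample = character(), gene = character(),
                             alt_reads = integer(), consequence = character())

    truth <- do.call(rbind, lapply(spec$effects, function(e) {
      prods <- pathway_product_bases(model, e$pathway)
      if (!nrow(prods)) return(NULL)
      data.frame(metabolite_base_id = prods$base, gene = e$gene,
                 pathway = e$pathway, expr_multiplier = e$expr_multiplier,
                 met_lfc = e$met_lfc %||% 1, primary = prods$primary,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(truth))
      truth <- data.frame(metabolite_base_id = character(), gene = character(),
                          pathway = character(), expr_multiplier = numeric(),
                          met_lfc = numeric(), primary = logical())

    cyto <- model$metabolites$id[model$metabolites$compartment == "c"]
    annotated <- cyto[!is_currency(cyto)]
    peak_base <- unique(met_base_id(annotated))
    peaks <- c(peak_base, sprintf("unk_peak_%d", 1:3), "atp")
    ann <- data.frame(
      peak = sprintf("P%03d", seq_along(peaks)),
      name = c(peak_base, rep(NA_character_, 3), "atp"),
      in_model = c(rep(TRUE, length(peak_base)), rep(FALSE, 3), TRUE),
      currency = c(rep(FALSE, length(peak_base) + 3), TRUE),
      stringsAsFactors = FALSE)
    met_baseline <- stats::rlnorm(length(peaks), log(1e5), 0.5)
    met <- matrix(
      met_baseline * stats::rlnorm(length(peaks) * length(samples), 0,
                                   spec$met_noise_sd),
      nrow = length(peaks), dimnames = list(ann$peak, samples))
    for (e in spec$effects) {
      planted <- ann$peak[!is.na(ann$name) &
                            ann$name %in% truth$metabolite_base_id[truth$gene == e$gene]]
      lfc <- e$met_lfc %||% 1
      met[planted, mutant_samples[[e$gene]]] <-
        met[planted, mutant_samples[[e$gene]], drop = FALSE] * 2^lfc
    }
    if (spec$missing_rate > 0) {
      drop <- matrix(stats::runif(length(met)) < spec$missing_rate,
                     nrow = nrow(met))
      met[drop] <- NA_real_
    }

    list(expression = expr, variants = variants,
         metabolome = metabolome_matrix(met, ann), truth = truth,
         mutant_samples = mutant_samples)
  })
}

hk_gene_set <- function(model) {
  idx <- model$reactions$pathway == "Housekeeping"
  unique(unlist(lapply(model$gpr[model$reactions$id[idx]], gpr_genes)))
}

pathway_gene_set <- function(model, pathway) {
  idx <- model$reactions$pathway == pathway
  g <- unique(unlist(lapply(model$gpr[model$reactions$id[idx]], gpr_genes)))
  if (!length(g)) stop("pathway '", pathway, "' has no GPR-bearing reactions")
  g
}

# base ids of metabolites produced by a pathway's reactions (forward sense);
# primary = produced by the pathway's terminal (hub-producing) reaction
pathway_product_bases <- function(model, pathway) {
  idx <- which(model$reactions$pathway == pathway)
  prods <- lapply(idx, function(k) {
    s <- model$reactions$stoich[[k]]
    names(s)[s > 0]
  })
  all_prods <- unique(unlist(prods))
  if (!length(all_prods)) return(data.frame(base = character(), primary = logical()))
  data.frame(base = met_base_id(all_prods),
             primary = startsWith(all_prods, "hub"),
             stringsAsFactors = FALSE)
}

#' Write simulated cohort tables to disk
#'
#' Emits the exact file formats the pipeline consumes: the model as SBML,
#' expression and variant tables as TSV, the metabolome as TSV with
#' annotation columns and blank missing entries.
#'
#' @param sim result of [simulate_cohort()].
#' @param model the [metabolic_model] used for the simulation.
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths written.
#' @export
write_cohort <- function(sim, model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(model = file.path(dir, "model.xml"),
             expression = file.path(dir, "expression.tsv"),
             variants = file.path(dir, "variants.tsv"),
             metabolome = file.path(dir, "metabolome.tsv"))
  write_sbml(model, paths[["model"]])
  utils::write.table(
    data.frame(gene = rownames(sim$expression), sim$expression,
               check.names = FALSE),
    paths[["expression"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$variants, paths[["variants"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  met <- data.frame(sim$metabolome$annotation,
                    sim$metabolome$values, check.names = FALSE)
  utils::write.table(met, paths[["metabolome"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  paths
}
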