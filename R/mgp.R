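#' Pair a metabolite with a mutated gene (workflow step 2)
#'
#' Compares the normalized flux-sum of one metabolite between mutant and
#' wild-type samples of one gene by the two-sided Wilcoxon rank-sum test; a
#' metabolite-gene (MG) pair candidate is emitted when `p < alpha`.
#'
#' @param norm a `normalized_flux_sum_matrix` from [quantile_normalize()].
#' @param mutations a `mutation_matrix` from [filter_mutations()].
#' @param gene gene id (must be present in the mutation matrix).
#' @param metabolite compartmented metabolite id.
#' @param alpha significance level (default 0.05).
#' @return list with fields `metabolite`, `gene`, `p`, `n_mutant`,
#'   `n_wildtype` when significant, otherwise `NULL`.
#' @export
pair_metabolite_gene <- function(norm, mutations, gene, metabolite,
                                 alpha = 0.05) {
  grp <- mutation_groups(mutations, gene, rownames(norm$F))
  vals <- norm$F[, metabolite]
  w <- wilcoxon_rank_sum(vals[grp$mutant], vals[grp$wildtype])
  if (w$p >= alpha) return(NULL)
  list(metabolite = metabolite, gene = gene, p = w$p,
       n_mutant = length(grp$mutant), n_wildtype = length(grp$wildtype))
}

mutation_groups <- function(mutations, gene, samples) {
  if (!gene %in% colnames(mutations$status))
    stop("gene '", gene, "' absent from the mutation matrix")
  status <- mutations$status[, gene]
  samples <- intersect(samples, names(status))
  list(mutant = samples[status[samples] == 1],
       wildtype = samples[status[samples] == 0])
}

#' Significant target pathways for an MG pair (workflow step 3)
#'
#' Tests, per pathway producing the target metabolite, whether the adjusted
#' target flux-sums differ between mutant and wild-type samples (two-sided
#' Wilcoxon, `p < alpha`). Pathways classified exchange/demand or unassigned,
#' and transport pathways not moving an essential amino acid, are excluded
#' before testing. An empty result means the MG pair is dropped from the
#' workflow.
#'
#' @inheritParams pair_metabolite_gene
#' @param candidate an MG pair from [pair_metabolite_gene()].
#' @param model the [metabolic_model] the flux-sums came from.
#' @param essential_aa essential-amino-acid base ids for the transport
#'   exception.
#' @return data.frame with columns `pathway`, `p` (possibly 0 rows).
#' @export
pathway_significance <- function(norm, mutations, candidate, model,
                                 alpha = 0.05,
                                 essential_aa = default_essential_aa()) {
  tm <- norm$target[[candidate$metabolite]]
  if (is.null(tm) || !ncol(tm))
    return(data.frame(pathway = character(), p = numeric()))
  keep <- vapply(colnames(tm), function(p)
    classify_pathway(model, p, essential_aa) %in%
      c("metabolic", "transport_essential_aa"), TRUE)
  tm <- tm[, keep, drop = FALSE]
  if (!ncol(tm)) return(data.frame(pathway = character(), p = numeric()))

  grp <- mutation_groups(mutations, candidate$gene, rownames(tm))
  p <- vapply(colnames(tm), function(pw) {
    wilcoxon_rank_sum(tm[grp$mutant, pw], tm[grp$wildtype, pw])$p
  }, 0)
  out <- data.frame(pathway = colnames(tm), p = unname(p),
                    stringsAsFactors = FALSE)
  out[out$p < alpha, , drop = FALSE]
}

#' Select final MGPs by modified Z-score (workflow step 4)
#'
#' Within each (metabolite, pathway) group of MGP candidates, the per-gene
#' mean adjusted target flux-sum is converted to the modified Z-score
#' ([modified_zscore()]); genes with `|Z| > z_threshold` are selected
#' (`reason = "z_threshold"`). Groups with fewer than three candidates are
#' selected wholesale (`reason = "small_group"`).
#'
#' @param candidates data.frame of MGP candidates with columns `metabolite`,
#'   `gene`, `pathway`, `p_mg`, `p_pathway`, `mean_target_flux_sum`.
#' @param z_threshold modified Z-score selection threshold (default 3.5).
#' @return data.frame of MGP records: the candidate columns plus
#'   `modified_z` and `selection_reason`.
#' @export
select_mgps <- function(candidates, z_threshold = 3.5) {
  cols <- c("metabolite", "gene", "pathway", "p_mg", "p_pathway",
            "mean_target_flux_sum")
  if (!nrow(candidates))
    return(cbind(candidates[, intersect(cols, names(candidates)), drop = FALSE],
                 data.frame(modified_z = numeric(), selection_reason = character())))
  stopifnot(all(cols %in% names(candidates)))
  out <- list()
  for (key in unique(paste(candidates$metabolite, candidates$pathway, sep = "\r"))) {
    grp <- candidates[paste(candidates$metabolite, candidates$pathway,
                            sep = "\r") == key, , drop = FALSE]
    if (nrow(grp) < 3) {
      grp$modified_z <- modified_zscore(grp$mean_target_flux_sum)
      grp$selection_reason <- "small_group"
      out[[key]] <- grp
    } else {
      z <- modified_zscore(grp$mean_target_flux_sum)
      grp$modified_z <- z
      grp$selection_reason <- "z_threshold"
      out[[key]] <- grp[abs(z) > z_threshold, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count metabolite-gene pairs with compartments merged
#'
#' MG pairs whose metabolites differ only by compartment (e.g. `akg_c` and
#' `akg_m` with the same gene) are counted as one.
#'
#' @param pairs data.frame with columns `metabolite`, `gene`.
#' @return list with `n_unique` (count of unique (base id, gene) keys) and
#'   `mapping` (the input plus `metabolite_base_id` and `key`).
#' @export
dedup_compartment_pairs <- function(pairs) {
  if (!nrow(pairs))
    return(list(n_unique = 0L,
                mapping = cbind(pairs, data.frame(metabolite_base_id = character(),
                                                  key = character()))))
  base <- met_base_id(pairs$metabolite)
  key <- paste(base, pairs$gene, sep = "\r")
  list(n_unique = length(unique(key)),
       mapping = cbind(pairs, data.frame(metabolite_base_id = base, key = key,
                                         stringsAsFactors = FALSE)))
}

#' Predict metabolite-gene-pathway sets (workflow steps 2-4)
#'
#' Runs the full association workflow over every (metabolite, gene)
#' combination: step 2 pairs metabolites with mutated genes on normalized
#' flux-sums, step 3 keeps pairs with at least one significant eligible
#' producing pathway, step 4 selects final MGPs per (metabolite, pathway)
#' group by modified Z-score. Currency metabolites are never tested.
#'
#' @inheritParams pathway_significance
#' @param currency currency metabolite base ids to exclude.
#' @param z_threshold modified Z-score threshold (default 3.5).
#' @param x_mean_samples samples over which the per-gene mean adjusted target
#'   flux-sum (the step-4 statistic) is taken: `"mutant"` (default) or
#'   `"all"`.
#' @param metabolites metabolite ids to test; defaults to all non-currency
#'   model metabolites present in the flux-sum matrix.
#' @return list with `pairs` (step-2 MG pairs), `candidates` (step-3 MGP
#'   candidates), `mgps` (final records), and `tally` (stage counts).
#' @export
predict_mgps <- function(norm, mutations, model, alpha = 0.05,
                         z_threshold = 3.5,
                         currency = default_currency_metabolites(),
                         essential_aa = default_essential_aa(),
                         x_mean_samples = c("mutant", "all"),
                         metabolites = NULL) {
  x_mean_samples <- match.arg(x_mean_samples)
  if (is.null(metabolites))
    metabolites <- colnames(norm$F)[!is_currency(colnames(norm$F), currency)]
  genes <- colnames(mutations$status)

  pairs <- list(); cand <- list()
  for (met in metabolites) {
    for (g in genes) {
      pr <- pair_metabolite_gene(norm, mutations, g, met, alpha)
      if (is.null(pr)) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        metabolite = met, gene = g, p_mg = pr$p,
        n_mutant = pr$n_mutant, n_wildtype = pr$n_wildtype,
        stringsAsFactors = FALSE)
      sig <- pathway_significance(norm, mutations, pr, model, alpha,
                                  essential_aa)
      if (!nrow(sig)) next
      grp <- mutation_groups(mutations, g, rownames(norm$F))
      rows <- if (x_mean_samples == "mutant") grp$mutant else
        c(grp$mutant, grp$wildtype)
      for (i in seq_len(nrow(sig))) {
        cand[[length(cand) + 1L]] <- data.frame(
          metabolite = met, gene = g, pathway = sig$pathway[i],
          p_mg = pr$p, p_pathway = sig$p[i],
          mean_target_flux_sum =
            mean(norm$target[[met]][rows, sig$pathway[i]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(metabolite = character(), gene = character(), p_mg = numeric(),
               n_mutant = integer(), n_wildtype = integer())
  cand_df <- if (length(cand)) do.call(rbind, cand) else
    data.frame(metabolite = character(), gene = character(),
               pathway = character(), p_mg = numeric(), p_pathway = numeric(),
               mean_target_flux_sum = numeric())
  mgps <- select_mgps(cand_df, z_threshold)
  mgps$metabolite_base_id <- met_base_id(mgps$metabolite)

  list(pairs = pairs_df, candidates = cand_df, mgps = mgps,
       tally = c(metabolites_tested = length(metabolites),
                 genes_tested = length(genes),
                 mg_pairs = nrow(pairs_df),
                 mg_pairs_unique = dedup_compartment_pairs(pairs_df)$n_unique,
                 mgp_candidates = nrow(cand_df),
                 mgps = nrow(mgps)))
}
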