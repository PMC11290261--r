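#' Read and validate a pipeline run configuration
#'
#' The configuration is a JSON file with nested sections:
#' \preformatted{
#' {
#'   "paths":  {"model": "...", "expression": "...", "variants": "...",
#'              "metabolome": null, "currency": null, "essential_aa": null,
#'              "gene_groups": null},
#'   "cohort": "toy",
#'   "params": {"alpha": 0.05, "z_threshold": 3.5, "scale_cap": 1000,
#'              "knn_k": 10, "missing_threshold": 0.2,
#'              "auc_threshold": 0.7, "empirical_resamples": 100000},
#'   "seed":   1,
#'   "output": "out/"
#' }
#' }
#' Optional paths may be omitted or `null`; `currency`/`essential_aa` point
#' at one-id-per-line files overriding the shipped defaults.
#'
#' @param config path to a JSON config file, or an equivalent named list.
#' @return validated config list (class `mgp_run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(alpha = 0.05, z_threshold = 3.5, scale_cap = 1000,
                   knn_k = 10, missing_threshold = 0.2, auc_threshold = 0.7,
                   empirical_resamples = 1e5)
  config$params <- utils::modifyList(defaults, as.list(config$params %||% list()))
  p <- config$params
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must be in (0, 1)")
  if (p$z_threshold <= 0) stop("z_threshold must be positive")
  if (p$scale_cap <= 0) stop("scale_cap must be positive")
  if (p$missing_threshold < 0 || p$missing_threshold > 1)
    stop("missing_threshold must be in [0, 1]")
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$output)) stop("config must set an output directory")
  for (key in c("model", "expression", "variants")) {
    path <- config$paths[[key]]
    if (is.null(path)) stop("config paths.", key, " is required")
    if (!file.exists(path)) stop("input not found: ", key, " = ", path)
  }
  for (key in c("metabolome", "currency", "essential_aa", "gene_groups")) {
    path <- config$paths[[key]]
    if (!is.null(path) && !file.exists(path))
      stop("input not found: ", key, " = ", path)
  }
  config$cohort <- config$cohort %||% "cohort"
  class(config) <- "mgp_run_config"
  config
}

#' Run the full MGP prediction pipeline
#'
#' Wires the four workflow steps end to end: reads the model and cohort
#' tables, applies the mutation filter cascade, fits per-sample fluxes by
#' least absolute deviation, computes flux-sums and their pathway
#' decomposition, quantile-normalizes per cohort, predicts MG pairs, MGP
#' candidates and final MGPs, and (when a metabolome table is configured)
#' runs the metabolome validation arm (peak filter, KNN imputation,
#' normalization, per-MG-pair ROC AUC, empirical p-value). All tabular
#' outputs are TSV; a JSON manifest records the configuration, seed and
#' per-stage tallies.
#'
#' @param config a config file path or list accepted by [read_run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `mgps`, `pairs`, `candidates`, `auc`,
#'   `manifest`, and the output file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                           sprintf(...))
  out_dir <- config$output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  say("reading model %s", config$paths$model)
  model <- read_sbml(config$paths$model)
  currency <- if (!is.null(config$paths$currency))
    read_id_list(config$paths$currency) else default_currency_metabolites()
  essential_aa <- if (!is.null(config$paths$essential_aa))
    read_id_list(config$paths$essential_aa) else default_essential_aa()

  say("reading cohort tables")
  expr <- read_expression_table(config$paths$expression, model)
  variants <- read_variant_table(config$paths$variants)
  cohort_samples <- colnames(expr)

  say("mutation filter cascade (%d variant rows)", nrow(variants))
  mutations <- filter_mutations(variants, cohort_samples)
  if (!is.null(config$paths$gene_groups))
    mutations <- apply_gene_groups(mutations,
                                   read_gene_groups(config$paths$gene_groups))
  if (!ncol(mutations$status))
    stop("pipeline stage 'mutation filtering': no gene survives the cascade")

  say("LAD flux fitting (%d samples)", ncol(expr))
  rxn_expr <- map_cohort_expression(expr, model)
  states <- fit_fluxes_cohort(model, rxn_expr,
                              scale_cap = config$params$scale_cap)

  say("flux-sums and pathway decomposition")
  fsm <- flux_sum_matrix(model, states)
  norm <- quantile_normalize(fsm)

  say("MGP prediction (steps 2-4)")
  res <- predict_mgps(norm, mutations, model,
                      alpha = config$params$alpha,
                      z_threshold = config$params$z_threshold,
                      currency = currency, essential_aa = essential_aa)

  auc_df <- NULL
  empirical_p <- NULL
  if (!is.null(config$paths$metabolome)) {
    say("metabolome validation arm")
    mm <- read_metabolome_table(config$paths$metabolome,
                                annotation_cols = metabolome_annotation_cols(
                                  config$paths$metabolome))
    mm <- filter_peaks(mm, config$params$missing_threshold)
    mm <- knn_impute(mm, config$params$knn_k)
    mm <- normalize_metabolome(mm)
    val <- validate_mgps_with_metabolome(
      res$mgps, mm, mutations, threshold = config$params$auc_threshold,
      n_resamples = config$params$empirical_resamples, seed = config$seed)
    auc_df <- val$auc
    empirical_p <- val$empirical_p
  }

  paths <- c(mg_pairs = file.path(out_dir, "mg_pairs.tsv"),
             candidates = file.path(out_dir, "mgp_candidates.tsv"),
             mgps = file.path(out_dir, "mgps.tsv"),
             flux_sums = file.path(out_dir, "flux_sums.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_tsv <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(res$pairs, paths[["mg_pairs"]])
  write_tsv(res$candidates, paths[["candidates"]])
  mgp_out <- res$mgps[, c("metabolite", "metabolite_base_id", "gene",
                          "pathway", "p_mg", "p_pathway",
                          "mean_target_flux_sum", "modified_z",
                          "selection_reason")]
  write_tsv(mgp_out, paths[["mgps"]])
  write_tsv(data.frame(sample = rownames(norm$F), norm$F, check.names = FALSE),
            paths[["flux_sums"]])
  if (!is.null(auc_df)) {
    paths[["auc"]] <- file.path(out_dir, "auc.tsv")
    write_tsv(auc_df, paths[["auc"]])
  }

  manifest <- list(
    package = "mgpflux",
    version = as.character(utils::packageVersion("mgpflux")),
    cohort = config$cohort, seed = config$seed,
    params = config$params,
    config_hash = config_hash(config),
    mutation_tally = mutations$tally,
    stage_tally = as.list(res$tally),
    empirical_p = empirical_p)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: %d MG pairs, %d candidates, %d MGPs",
      res$tally[["mg_pairs"]], res$tally[["mgp_candidates"]],
      res$tally[["mgps"]])
  invisible(list(mgps = res$mgps, pairs = res$pairs,
                 candidates = res$candidates, auc = auc_df,
                 empirical_p = empirical_p, manifest = manifest,
                 paths = paths))
}

# annotation columns of a metabolome TSV: leading non-sample columns
metabolome_annotation_cols <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  known <- c("peak", "name", "mode", "kegg", "in_model", "currency",
             "co_eluted")
  n <- 0L
  for (h in header) {
    if (tolower(h) %in% known) n <- n + 1L else break
  }
  max(n, 1L)
}

#' Validate final MGPs against metabolome data
#'
#' For every unique MG pair among the final MGPs whose metabolite base id is
#' annotated in the (normalized) metabolome matrix, computes the classical
#' univariate ROC AUC of the metabolite level against the gene's mutation
#' status, then the empirical p-value of the observed count of AUCs above
#' the threshold against the pool of all annotated peak x gene AUCs.
#'
#' @param mgps data.frame of final MGP records.
#' @param mm normalized, complete `metabolome_matrix` with a `name`
#'   annotation column.
#' @param mutations a `mutation_matrix`.
#' @param threshold AUC threshold (default 0.7).
#' @param n_resamples,seed passed to [empirical_pvalue()].
#' @return list with `auc` (data.frame per detected MG pair), `pool`
#'   (background AUC values), `empirical_p` (NULL when no pair is detected).
#' @export
validate_mgps_with_metabolome <- function(mgps, mm, mutations, threshold = 0.7,
                                          n_resamples = 1e5, seed = 1) {
  samples <- intersect(colnames(mm$values), rownames(mutations$status))
  if (length(samples) < 6) stop("too few samples shared between metabolome ",
                                "and mutation data")
  name_col <- mm$annotation$name
  pairs <- unique(data.frame(base = met_base_id(mgps$metabolite),
                             gene = mgps$gene, stringsAsFactors = FALSE))
  pairs <- pairs[pairs$gene %in% colnames(mutations$status), , drop = FALSE]

  auc_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    peak <- which(!is.na(name_col) & name_col == pairs$base[i])
    if (!length(peak)) next
    status <- mutations$status[samples, pairs$gene[i]]
    if (sum(status) == 0 || sum(status) == length(status)) next
    a <- compute_auc(mm$values[peak[1], samples], status)
    auc_rows[[length(auc_rows) + 1L]] <- data.frame(
      metabolite = pairs$base[i], gene = pairs$gene[i], auc = a$auc,
      n_mutant = a$n_mutant, n_wildtype = a$n_wildtype,
      stringsAsFactors = FALSE)
  }
  auc_df <- if (length(auc_rows)) do.call(rbind, auc_rows) else
    data.frame(metabolite = character(), gene = character(), auc = numeric(),
               n_mutant = integer(), n_wildtype = integer())

  genes <- unique(pairs$gene)
  pool <- c()
  for (g in genes) {
    status <- mutations$status[samples, g]
    if (sum(status) == 0 || sum(status) == length(status)) next
    for (peak in which(!is.na(name_col)))
      pool <- c(pool, compute_auc(mm$values[peak, samples], status)$auc)
  }

  empirical_p <- NULL
  if (nrow(auc_df) > 0 && length(pool) >= nrow(auc_df)) {
    empirical_p <- empirical_pvalue(
      observed_hits = sum(auc_df$auc > threshold), n_pairs = nrow(auc_df),
      pool = pool, threshold = threshold, n_resamples = n_resamples,
      seed = seed)
  }
  list(auc = auc_df, pool = pool, empirical_p = empirical_p)
}

config_hash <- function(config) {
  x <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small deterministic polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(x))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
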