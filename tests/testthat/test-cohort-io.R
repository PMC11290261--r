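make_variants <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df) <- c("sample", "gene", "alt_reads", "consequence")[seq_along(df)]
  df
}

test_that("mutation filter cascade applies every rule at its boundary", {
  cohort <- sprintf("S%d", 1:10)
  v <- rbind(
    make_variants(c("S1", "S2", "S3"), "KEEP", 7L, "nonsynonymous"),
    make_variants("S4", "KEEP", 6L, "nonsynonymous"),        # < 7 alt reads
    make_variants("S5", "KEEP", 50L, "synonymous"),          # synonymous
    make_variants(c("S1", "S2"), "RARE", 20L, "nonsynonymous"),  # < 3 mutant
    make_variants(sprintf("S%d", 1:8), "COMMON", 20L, "nonsynonymous"))
  mut <- filter_mutations(v, cohort)
  # KEEP survives with exactly the >= 7-read nonsynonymous mutants
  expect_equal(colnames(mut$status), "KEEP")
  expect_equal(sum(mut$status[, "KEEP"]), 3)
  expect_equal(unname(mut$n_wildtype["KEEP"]), 7)
  # COMMON dropped: wild-type in only 2 samples
  t <- mut$tally
  expect_equal(t$genes_few_wildtype, 1)
  expect_equal(t$genes_few_mutant, 1)
  # row conservation: rows_in = rows_kept + dropped rows
  expect_equal(t$rows_in,
               t$rows_kept + t$rows_off_cohort + t$rows_low_alt_reads +
                 t$rows_synonymous)
  # off-cohort rows warn and are ignored
  expect_warning(filter_mutations(
    rbind(v, make_variants("NOT_IN_COHORT", "KEEP", 9L, "nonsynonymous")),
    cohort), "outside the cohort")
})

test_that("subset gene mutations are removed deterministically", {
  cohort <- sprintf("S%d", 1:12)
  v <- rbind(
    make_variants(sprintf("S%d", 1:5), "BIG", 20L, "nonsynonymous"),
    make_variants(sprintf("S%d", 1:3), "SUB", 20L, "nonsynonymous"),   # strict subset of BIG
    make_variants(sprintf("S%d", c(1, 2, 6)), "OTHER", 20L, "nonsynonymous"))
  mut <- filter_mutations(v, cohort)
  expect_setequal(colnames(mut$status), c("BIG", "OTHER"))
  expect_equal(mut$tally$genes_subset, 1)
  # identical mutant sets are not strict subsets: both retained
  v2 <- rbind(
    make_variants(sprintf("S%d", 1:4), "A1", 20L, "nonsynonymous"),
    make_variants(sprintf("S%d", 1:4), "A2", 20L, "nonsynonymous"))
  expect_setequal(colnames(filter_mutations(v2, cohort)$status), c("A1", "A2"))
  # the rule can be disabled
  expect_setequal(colnames(filter_mutations(v, cohort,
                                            subset_filter = FALSE)$status),
                  c("BIG", "SUB", "OTHER"))
})

test_that("gene-group merging unions mutation status", {
  cohort <- sprintf("S%d", 1:12)
  v <- rbind(
    make_variants(sprintf("S%d", 1:3), "IDH1", 20L, "nonsynonymous"),
    make_variants(sprintf("S%d", 4:6), "IDH2", 20L, "nonsynonymous"))
  mut <- filter_mutations(v, cohort)
  merged <- apply_gene_groups(mut, data.frame(group = "IDH",
                                              gene = c("IDH1", "IDH2")))
  expect_equal(unname(merged$n_mutant["IDH"]), 6)
  expect_equal(sum(merged$status[, "IDH"] !=
                     pmax(merged$status[, "IDH1"], merged$status[, "IDH2"])), 0)
})

test_that("peak filter drops peaks missing in more than the threshold", {
  # 17 samples: 4 missing (23.5%) dropped, 3 missing (17.6%) kept
  vals <- matrix(1, 3, 17, dimnames = list(c("p1", "p2", "p3"), NULL))
  colnames(vals) <- sprintf("S%d", 1:17)
  vals["p1", 1:4] <- NA
  vals["p2", 1:3] <- NA
  mm <- metabolome_matrix(vals)
  out <- filter_peaks(mm)
  expect_setequal(rownames(out$values), c("p2", "p3"))
  expect_equal(attr(out, "n_survivors"), 2)
  # idempotent
  out2 <- filter_peaks(out)
  expect_identical(out2$values, out$values)
})

test_that("KNN imputation is feature-wise, order-safe and conservative", {
  # perfectly correlated donor peak: its value is copied at k = 1
  vals <- rbind(p1 = c(1, 2, NA), p2 = c(1, 2, 3), p3 = c(50, 60, 70))
  colnames(vals) <- sprintf("S%d", 1:3)
  mm <- metabolome_matrix(vals)
  out <- suppressWarnings(knn_impute(mm, k = 1))
  expect_equal(out$values["p1", "S3"], 3)
  # observed entries never altered
  obs <- !is.na(vals)
  expect_identical(out$values[obs], vals[obs])
  # no missing entries remain; k > donors warns but imputes
  expect_false(anyNA(suppressWarnings(knn_impute(mm, k = 10))$values))
  expect_warning(knn_impute(mm, k = 10), "donor")
  # identity on complete data
  full <- metabolome_matrix(vals[2:3, ])
  expect_identical(knn_impute(full, 10), full)
  # a peak missing everywhere violates the precondition
  bad <- metabolome_matrix(rbind(p1 = c(NA_real_, NA_real_), p2 = c(1, 2)))
  expect_error(knn_impute(bad), "filter_peaks")
})

test_that("metabolome normalization chain meets its postconditions", {
  withr::with_seed(11, {
    vals <- matrix(stats::rlnorm(20 * 12, log(1000), 1), 20, 12,
                   dimnames = list(sprintf("p%d", 1:20), sprintf("S%d", 1:12)))
    mm <- metabolome_matrix(vals)
    # sum normalization: columns sum to 1 before glog
    sums <- colSums(sweep(vals, 2, colSums(vals), "/"))
    expect_equal(unname(sums), rep(1, 12))
    out <- normalize_metabolome(mm)
    expect_equal(unname(rowMeans(out$values)), rep(0, 20), tolerance = 1e-9)
    expect_equal(unname(apply(out$values, 1, stats::sd)), rep(1, 20),
                 tolerance = 1e-9)
    # glog is monotone on positive values
    x <- sort(stats::rlnorm(100))
    g <- log2((x + sqrt(x^2 + 1)) / 2)
    expect_true(all(diff(g) > 0))
    neg <- vals; neg[, 1] <- -neg[, 1]
    expect_error(normalize_metabolome(metabolome_matrix(neg)), "nonpositive")
  })
})

test_that("AUC equals pairwise counting and the Mann-Whitney identity", {
  expect_equal(compute_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(compute_auc(c(1, 2, 1, 2), c(1, 1, 0, 0))$auc, 0.5)
  withr::with_seed(13, {
    for (i in 1:50) {
      n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
      mutant <- stats::rnorm(n1); wildtype <- stats::rnorm(n0)
      a <- compute_auc(c(mutant, wildtype),
                       c(rep(1, n1), rep(0, n0)))
      pw <- pairwise_auc(mutant, wildtype)
      expect_equal(a$auc_raw, pw, tolerance = 1e-12)
      expect_equal(a$auc, max(pw, 1 - pw), tolerance = 1e-12)
      # Mann-Whitney U identity on tie-free data
      U <- stats::wilcox.test(mutant, wildtype, exact = FALSE)$statistic
      expect_equal(a$auc_raw, unname(U) / (n1 * n0), tolerance = 1e-12)
      # invariance under strictly monotone transforms
      expect_equal(compute_auc(exp(c(mutant, wildtype)),
                               c(rep(1, n1), rep(0, n0)))$auc, a$auc)
    }
  })
  expect_error(compute_auc(1:4, rep(1, 4)), "non-empty")
})

test_that("empirical p-value matches the hypergeometric tail", {
  # pool with 10% of AUCs above threshold, draw 6, observe >= 4
  pool <- c(rep(0.9, 10), rep(0.6, 90))
  p <- empirical_pvalue(4, 6, pool, threshold = 0.7, n_resamples = 1e5,
                        seed = 2)
  exact <- stats::phyper(3, 10, 90, 6, lower.tail = FALSE)
  se <- sqrt(exact * (1 - exact) / 1e5)
  expect_lt(abs(p - exact), 3 * se + 2 / 1e5)
  # degenerate pools
  expect_gt(empirical_pvalue(0, 3, pool, n_resamples = 1000, seed = 1), 0.99)
  expect_gt(empirical_pvalue(3, 3, rep(0.9, 10), n_resamples = 1000, seed = 1),
            0.99)
  expect_error(empirical_pvalue(1, 20, pool[1:5], n_resamples = 1000, seed = 1),
               "pool smaller")
  expect_error(empirical_pvalue(1, 2, pool, n_resamples = 1000), "seed")
  # seeded: reproducible
  expect_identical(empirical_pvalue(4, 6, pool, n_resamples = 2000, seed = 5),
                   empirical_pvalue(4, 6, pool, n_resamples = 2000, seed = 5))
})

test_that("variant and metabolome readers round-trip the simulated formats", {
  model <- generate_toy_gem(toy_gem_spec(n_pathways = 3, n_shared = 1, seed = 2))
  sim <- simulate_cohort(model, cohort_sim_spec(
    n_samples = 10, n_mutant = 4,
    effects = list(list(gene = "G1_1", pathway = "Pathway 1",
                        expr_multiplier = 2, met_lfc = 1)),
    seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, model, dir)

  v <- read_variant_table(paths[["variants"]])
  expect_equal(nrow(v), nrow(sim$variants))
  expect_true(all(v$consequence == "nonsynonymous"))

  e <- read_expression_table(paths[["expression"]], model)
  expect_equal(dim(e), dim(sim$expression))
  expect_equal(unname(e), unname(sim$expression), tolerance = 1e-6)
  # orientation auto-detect: transposed table reads identically
  tpath <- file.path(dir, "expr_t.tsv")
  utils::write.table(data.frame(sample = colnames(sim$expression),
                                t(sim$expression), check.names = FALSE),
                     tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  et <- read_expression_table(tpath, model)
  expect_equal(unname(et[rownames(e), colnames(e)]), unname(e),
               tolerance = 1e-6)

  mm <- read_metabolome_table(paths[["metabolome"]], annotation_cols = 4)
  expect_equal(dim(mm$values), dim(sim$metabolome$values))
  expect_equal(mean(is.na(mm$values)), mean(is.na(sim$metabolome$values)))
})
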