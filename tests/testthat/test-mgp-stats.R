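test_that("Wilcoxon p-values match full enumeration for small tie-free groups", {
  withr::with_seed(17, {
    for (n1 in 2:4) for (n2 in n1:4) {
      for (rep in 1:5) {
        x <- stats::rnorm(n1)
        y <- stats::rnorm(n2)
        expect_equal(wilcoxon_rank_sum(x, y)$p, enum_wilcoxon_p(x, y),
                     tolerance = 1e-12,
                     label = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
      }
    }
  })
  # the two worked examples: fully separated 3v3 and 4v4
  w33 <- wilcoxon_rank_sum(c(10, 11, 12), c(1, 2, 3))
  expect_true(w33$exact)
  expect_equal(w33$p, 0.1, tolerance = 1e-12)
  w44 <- wilcoxon_rank_sum(c(10, 11, 12, 13), c(1, 2, 3, 4))
  expect_equal(w44$p, 2 / 70, tolerance = 1e-12)
  # identical groups: no rank separation
  expect_equal(wilcoxon_rank_sum(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("large or tied samples switch to the corrected normal approximation", {
  withr::with_seed(3, {
    x <- stats::rnorm(20); y <- stats::rnorm(25)
    w <- wilcoxon_rank_sum(x, y)
    expect_false(w$exact)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
    # ties take the tie-corrected variance
    xt <- c(1, 2, 2, 3); yt <- c(2, 3, 3, 4, 4)
    wt <- suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE,
                                              correct = TRUE))
    expect_equal(wilcoxon_rank_sum(xt, yt)$p, wt$p.value, tolerance = 1e-10)
  })
})

test_that("quantile normalization follows the rank-mean convention", {
  # two samples [1,2,3] and [4,5,6] -> both become [2.5, 3.5, 4.5]
  Fm <- rbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  colnames(Fm) <- c("m1", "m2", "m3")
  out <- quantile_normalize(Fm)
  expect_equal(unname(out["s1", ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out["s2", ]), c(2.5, 3.5, 4.5))
  # identical samples are a fixed point
  Fi <- rbind(s1 = c(2, 7, 4), s2 = c(2, 7, 4))
  expect_equal(quantile_normalize(Fi), Fi)
  expect_error(quantile_normalize(Fm[1, , drop = FALSE]), "at least 2")
})

test_that("quantile normalization agrees with the limma oracle", {
  withr::with_seed(31, {
    X <- matrix(stats::rlnorm(200), 20, 10)  # metabolites x samples
    ours <- t(quantile_normalize(t(X)))
    ref <- limma::normalizeQuantiles(X, ties = TRUE)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
    # post-normalization (pre zero restoration) columns share sorted values
    sorted <- apply(ours, 2, sort)
    expect_lt(max(sorted - sorted[, 1]), 1e-12)
  })
})

test_that("zero restoration and the Eq.3 adjustment hold after normalization", {
  pl <- run_toy_pipeline(seed = 21, multiplier = 1)
  fsm <- pl$fsm
  # plant exact zeros: pretend one metabolite had no production in 3 samples
  met <- colnames(fsm$F)[1]
  fsm$F[1:3, met] <- 0
  fsm$target[[met]][1:3, ] <- 0
  norm <- quantile_normalize(fsm)
  expect_true(all(norm$F[1:3, met] == 0))
  expect_true(all(norm$F[fsm$F == 0] == 0))
  # f*_{i_p} = (F*_i / F_i) f_{i_p} wherever F_i > 0
  for (m in colnames(fsm$F)) {
    pos <- fsm$F[, m] > 0
    ratio <- norm$F[pos, m] / fsm$F[pos, m]
    expect_equal(norm$target[[m]][pos, , drop = FALSE],
                 fsm$target[[m]][pos, , drop = FALSE] * ratio,
                 tolerance = 1e-9)
    if (any(!pos))
      expect_true(all(norm$target[[m]][!pos, ] == 0))
  }
})

test_that("modified Z-score reproduces hand-derived values and both branches", {
  z <- modified_zscore(c(1, 2, 3, 4, 5))
  expect_equal(z[5], 2 / (1 / stats::qnorm(0.75) * 1), tolerance = 1e-9)
  expect_equal(z[5], 1.3490, tolerance = 1e-3)
  # MAD = 0 branch: [1,1,1,1,10] -> MeanAD = 1.8
  z2 <- modified_zscore(c(1, 1, 1, 1, 10))
  expect_equal(z2[5], 9 / (sqrt(pi / 2) * 1.8), tolerance = 1e-9)
  expect_equal(z2[5], 3.9899, tolerance = 1e-3)
  # constant input: all zeros
  expect_equal(modified_zscore(rep(7, 3)), c(0, 0, 0))
  expect_error(modified_zscore(numeric()), "empty")
})

test_that("modified Z-score is shift-invariant and scale-equivariant", {
  withr::with_seed(8, {
    for (i in 1:200) {
      x <- stats::rnorm(sample(3:20, 1))
      a <- stats::runif(1, 0.1, 10)
      b <- stats::rnorm(1, sd = 5)
      expect_equal(modified_zscore(a * x + b), modified_zscore(x),
                   tolerance = 1e-9)
    }
  })
})

test_that("step-2 pairing applies the alpha gate and errors on unknown genes", {
  # build a minimal normalized matrix by hand
  samples <- sprintf("S%d", 1:8)
  Fm <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13), 8, 1,
               dimnames = list(samples, "b_c"))
  norm <- structure(list(F = Fm, target = list(b_c = Fm)),
                    class = c("normalized_flux_sum_matrix", "flux_sum_matrix"))
  status <- matrix(c(rep(0L, 4), rep(1L, 4)), 8, 1,
                   dimnames = list(samples, "G1"))
  mut <- structure(list(status = status, n_mutant = 4, n_wildtype = 4),
                   class = "mutation_matrix")
  pr <- pair_metabolite_gene(norm, mut, "G1", "b_c")
  expect_equal(pr$p, 2 / 70, tolerance = 1e-12)
  expect_equal(pr$n_mutant, 4)
  # 3v3 fully separated has exact p = 0.1 > 0.05: no candidate
  norm6 <- structure(list(F = Fm[1:6, , drop = FALSE],
                          target = list(b_c = Fm[1:6, , drop = FALSE])),
                     class = c("normalized_flux_sum_matrix", "flux_sum_matrix"))
  mut6 <- structure(list(status = status[1:6, , drop = FALSE]),
                    class = "mutation_matrix")
  mut6$status[, 1] <- c(0L, 0L, 0L, 1L, 1L, 1L)
  expect_null(pair_metabolite_gene(norm6, mut6, "G1", "b_c"))
  expect_error(pair_metabolite_gene(norm, mut, "NOPE", "b_c"), "absent")
})

test_that("step-3 pathway testing excludes ineligible pathways", {
  pl <- run_toy_pipeline(seed = 33)
  truth <- pl$sim$truth[pl$sim$truth$primary, ][1, ]
  hub <- paste0(truth$metabolite_base_id, "_c")
  cand <- list(metabolite = hub, gene = truth$gene)
  sig <- pathway_significance(pl$norm, pl$mutations, cand, pl$model)
  # the planted pathway is recovered as significant
  expect_true(truth$pathway %in% sig$pathway)
  # no excluded class ever appears among tested pathways
  expect_false(any(c("Transport reactions", "Exchange/demand reactions",
                     "unassigned") %in% sig$pathway))
})

test_that("step-4 selection: small groups pass, outliers are flagged", {
  # group of 2 candidates: all selected as small_group
  two <- data.frame(metabolite = "b_c", gene = c("G1", "G2"), pathway = "P",
                    p_mg = 0.01, p_pathway = 0.01,
                    mean_target_flux_sum = c(5, 50))
  sel <- select_mgps(two)
  expect_equal(nrow(sel), 2)
  expect_true(all(sel$selection_reason == "small_group"))

  # 42 per-gene means with 2 planted outliers: exactly those selected
  withr::with_seed(6, {
    means <- c(stats::rnorm(40, 10, 0.5), 40, 45)
    genes <- sprintf("G%02d", 1:42)
    grp <- data.frame(metabolite = "b_c", gene = genes, pathway = "P",
                      p_mg = 0.01, p_pathway = 0.01,
                      mean_target_flux_sum = means)
    sel2 <- select_mgps(grp)
    expect_setequal(sel2$gene, c("G41", "G42"))
    expect_true(all(sel2$selection_reason == "z_threshold"))
    expect_true(all(abs(sel2$modified_z) > 3.5))
  })

  # near-identical means: nothing selected
  flat <- data.frame(metabolite = "b_c", gene = sprintf("G%d", 1:10),
                     pathway = "P", p_mg = 0.01, p_pathway = 0.01,
                     mean_target_flux_sum = 10 + stats::rnorm(10, sd = 1e-6))
  expect_equal(nrow(select_mgps(flat)), 0)
})

test_that("compartment deduplication counts base-id pairs once", {
  pairs <- data.frame(metabolite = c("akg_c", "akg_m", "cit_c"),
                      gene = c("IDH1", "IDH1", "IDH1"))
  dd <- dedup_compartment_pairs(pairs)
  expect_equal(dd$n_unique, 2)
  expect_equal(dd$mapping$metabolite_base_id, c("akg", "akg", "cit"))
  expect_equal(dedup_compartment_pairs(pairs[0, , drop = FALSE])$n_unique, 0)
})

test_that("pipeline monotonicity: steps only remove", {
  pl <- run_toy_pipeline(seed = 44)
  res <- pl$res
  pair_keys <- paste(res$pairs$metabolite, res$pairs$gene)
  cand_keys <- paste(res$candidates$metabolite, res$candidates$gene)
  expect_true(all(cand_keys %in% pair_keys))
  mgp_keys <- paste(res$mgps$metabolite, res$mgps$gene, res$mgps$pathway)
  expect_true(all(mgp_keys %in% paste(res$candidates$metabolite,
                                      res$candidates$gene,
                                      res$candidates$pathway)))
  tally <- res$tally
  # every candidate descends from a pair; every MGP from a candidate
  expect_lte(length(unique(cand_keys)), tally[["mg_pairs"]])
  expect_lte(tally[["mgps"]], tally[["mgp_candidates"]])
})
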