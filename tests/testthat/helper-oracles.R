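# Independent oracles used across the suite. These deliberately reimplement
# the statistics by brute force (enumeration, pairwise counting) and must not
# call the package functions they check.

# exact two-sided Wilcoxon rank-sum p by full enumeration of group assignments
enum_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# flux-sum by looping over all (reaction, metabolite) pairs with signed
# contributions; counts only realized production
brute_flux_sum <- function(model, flux, metabolite) {
  total <- 0
  for (k in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[k]]
    for (met in names(s)) {
      if (met != metabolite) next
      contrib <- s[[met]] * flux$flux[[model$reactions$id[k]]]
      if (contrib > 0) total <- total + contrib
    }
  }
  total
}

# AUC by explicit pairwise comparison, ties counting one half
pairwise_auc <- function(mutant, wildtype) {
  wins <- 0
  for (a in mutant) for (b in wildtype)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(mutant) * length(wildtype))
}

# hand-built 3-reaction chain: EX_a -> A, A -> B (the target), B -> EX;
# upper bound on the middle reaction configurable
chain_model <- function(ab_ub = 1000) {
  mets <- data.frame(id = c("a_c", "b_c"))
  rxns <- data.frame(id = c("EX_a", "R_ab", "EX_b"),
                     lb = 0, ub = c(1000, ab_ub, 1000),
                     gpr = c("", "G1", ""),
                     pathway = c("", "Chain pathway", ""))
  rxns$stoich <- list(c(a_c = 1), c(a_c = -1, b_c = 1), c(b_c = -1))
  metabolic_model(mets, rxns, id = "chain")
}

# small random flux vector within bounds for a model (no steady state needed
# for flux-sum arithmetic checks)
random_flux_state <- function(model) {
  v <- stats::runif(nrow(model$reactions), model$reactions$lb,
                    model$reactions$ub)
  structure(list(flux = stats::setNames(v, model$reactions$id),
                 objective = NA_real_, total_flux = sum(abs(v))),
            class = "flux_state")
}

# one standard simulated cohort end-to-end, reused by several tests
run_toy_pipeline <- function(seed, multiplier = 5, gem_seed = 7) {
  model <- generate_toy_gem(toy_gem_spec(seed = gem_seed))
  sim <- simulate_cohort(model, cohort_sim_spec(
    effects = list(list(gene = "G1_1", pathway = "Pathway 1",
                        expr_multiplier = multiplier, met_lfc = 1)),
    seed = seed))
  rxn_expr <- map_cohort_expression(sim$expression, model)
  states <- fit_fluxes_cohort(model, rxn_expr)
  fsm <- flux_sum_matrix(model, states)
  norm <- quantile_normalize(fsm)
  mutations <- filter_mutations(sim$variants, colnames(sim$expression))
  res <- predict_mgps(norm, mutations, model)
  list(model = model, sim = sim, states = states, fsm = fsm, norm = norm,
       mutations = mutations, res = res)
}
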