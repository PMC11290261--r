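#' Map a gene expression profile onto reactions
#'
#' Scores every GPR-bearing reaction by recursive evaluation of its GPR tree:
#' `and` nodes take the minimum of their operand scores (a complex is limited
#' by its scarcest subunit), `or` nodes the sum (isozymes contribute
#' additively). Genes absent from the profile score 0. Reactions without a
#' GPR are absent from the result.
#'
#' @param profile named numeric vector of per-gene expression (TPM,
#'   nonnegative) for one sample.
#' @param model a [metabolic_model].
#' @return named numeric vector reaction id -> expression score.
#' @export
map_expression_to_reactions <- function(profile, model) {
  if (!length(profile)) stop("empty expression profile")
  if (any(!is.finite(profile)) || any(profile < 0))
    stop("expression values must be finite and nonnegative")
  has_gpr <- !vapply(model$gpr, is.null, TRUE)
  vapply(model$gpr[has_gpr], eval_gpr, 0, values = profile)
}

#' Fit per-sample fluxes by least absolute deviation
#'
#' Predicts intracellular fluxes from expression by minimizing
#' \eqn{\sum_j |u_j - \hat e_j|} over the GPR-bearing (target) reactions,
#' subject to steady state \eqn{S v = 0} and the model's flux bounds, where
#' \eqn{u_j} is the total flux magnitude of reaction j (forward plus backward
#' after splitting reversible reactions) and \eqn{\hat e_j} is the reaction
#' expression score rescaled so that its maximum equals `scale_cap` (making
#' the fit invariant to library-size rescaling). Ties between alternate
#' optima are broken by a second LP stage minimizing total flux
#' \eqn{\sum_j u_j}, which makes the returned fluxes deterministic.
#'
#' The LP is solved with the HiGHS backend of `scipy.optimize.linprog`
#' through a bundled Python helper (see `system.file("python", "lad_lp.py",
#' package = "mgpflux")`); set `options(mgpflux.python = ...)` to point at a
#' specific interpreter.
#'
#' @param model a [metabolic_model].
#' @param rxn_expr named numeric vector from [map_expression_to_reactions()].
#' @param scale_cap positive flux value the largest expression score is
#'   mapped to; default 1000, the conventional bound magnitude.
#' @param tie_break run the second minimization stage (default `TRUE`).
#' @return a `flux_state`: list with `flux` (named numeric, net flux per
#'   reaction), `objective` (attained LAD objective) and `total_flux`.
#'   Steady state (`max |S v| <= 1e-6`) and bound feasibility are asserted
#'   before returning.
#' @export
fit_fluxes_lad <- function(model, rxn_expr, scale_cap = 1000, tie_break = TRUE) {
  res <- fit_fluxes_cohort(model, matrix(rxn_expr, ncol = 1,
                                         dimnames = list(names(rxn_expr), "s1")),
                           scale_cap = scale_cap, tie_break = tie_break)
  res[[1]]
}

#' Fit fluxes for a cohort of samples in one solver call
#'
#' Batch interface to [fit_fluxes_lad()]: one Python/HiGHS invocation solves
#' the LAD problem for every column of `expr_matrix`, amortizing interpreter
#' startup across the cohort.
#'
#' @inheritParams fit_fluxes_lad
#' @param expr_matrix reaction expression scores, reactions x samples (rows
#'   named by reaction id, columns by sample id). Rows for reactions without
#'   a GPR must be absent.
#' @return named list of `flux_state` objects, one per sample column.
#' @export
fit_fluxes_cohort <- function(model, expr_matrix, scale_cap = 1000,
                              tie_break = TRUE) {
  stopifnot(is.matrix(expr_matrix), !is.null(rownames(expr_matrix)))
  if (scale_cap <= 0) stop("scale_cap must be positive")
  rxn_ids <- model$reactions$id
  unknown <- setdiff(rownames(expr_matrix), rxn_ids)
  if (length(unknown))
    stop("expression scores for unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  target_idx <- match(rownames(expr_matrix), rxn_ids)

  ehat <- apply(expr_matrix, 2, function(e) {
    m <- max(e)
    if (m > 0) e * (scale_cap / m) else e
  })
  ehat <- matrix(ehat, nrow = nrow(expr_matrix),
                 dimnames = dimnames(expr_matrix))

  S <- stoichiometry_matrix(model)
  nz <- which(S != 0, arr.ind = TRUE)
  prob <- list(
    n_met = nrow(S), n_rxn = ncol(S),
    S = list(i = nz[, 1] - 1L, j = nz[, 2] - 1L, x = S[nz]),
    lb = model$reactions$lb, ub = model$reactions$ub,
    target_idx = target_idx - 1L,
    ehat = lapply(seq_len(ncol(ehat)), function(k) unname(ehat[, k])),
    tie_break = tie_break, stage_tol = 1e-9)

  sols <- run_lad_solver(prob)
  states <- vector("list", ncol(ehat))
  names(states) <- colnames(ehat)
  for (k in seq_along(sols)) {
    sol <- sols[[k]]
    if (sol$status != 0)
      stop("LAD flux fitting failed for model '", model$id, "', sample '",
           colnames(ehat)[k], "': ",
           if (sol$status == 2) "infeasible constraint system"
           else if (sol$status == 3) "unbounded problem"
           else paste0("solver status ", sol$status))
    v <- stats::setNames(as.numeric(sol$flux), rxn_ids)
    resid <- max(abs(S %*% v))
    if (resid > 1e-6)
      stop("steady-state violation (max |S v| = ", format(resid), ")")
    if (any(v < model$reactions$lb - 1e-6) || any(v > model$reactions$ub + 1e-6))
      stop("flux bound violation in LAD solution")
    states[[k]] <- structure(
      list(flux = v, objective = sol$objective, total_flux = sol$total_flux),
      class = "flux_state")
  }
  states
}

run_lad_solver <- function(prob) {
  python <- getOption("mgpflux.python", Sys.which("python"))
  if (!nzchar(python)) stop("no python interpreter found for the LP backend; ",
                            "set options(mgpflux.python = ...)")
  script <- system.file("python", "lad_lp.py", package = "mgpflux",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(prob, fin, auto_unbox = TRUE, digits = NA)
  status <- system2(python, c(script, fin, fout), stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(fout))
    stop("LP backend failed (exit status ", status, ")")
  jsonlite::fromJSON(fout, simplifyVector = FALSE)$solutions
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("<flux_state: %d reactions, LAD objective %.6g, total flux %.6g>\n",
              length(x$flux), x$objective, x$total_flux))
  invisible(x)
}

#' Flux-sum of a metabolite
#'
#' The flux-sum \eqn{F_i = \sum_{j \in P_i} S_{ij} v_j} totals the production
#' flux of metabolite i over the set \eqn{P_i} of reactions producing it — a
#' turnover-rate proxy for the metabolite's intracellular importance.
#' "Producing" is decided from the realized sign \eqn{S_{ij} v_j > 0}, so a
#' reversible reaction running in reverse counts on the side it actually
#' produces. Consumption is never counted.
#'
#' @param model a [metabolic_model].
#' @param flux a `flux_state` from [fit_fluxes_lad()].
#' @param metabolite compartmented metabolite id.
#' @return nonnegative flux-sum (0 when no producing reaction carries flux).
#' @export
compute_flux_sum <- function(model, flux, metabolite) {
  sum(producing_contributions(model, flux, metabolite))
}

#' Pathway decomposition of a flux-sum
#'
#' Groups the producing contributions of [compute_flux_sum()] by the
#' producing reaction's pathway label: the target flux-sum
#' \eqn{f_{i_p}} of pathway p, with \eqn{\sum_p f_{i_p} = F_i}.
#'
#' @inheritParams compute_flux_sum
#' @return named numeric vector pathway -> target flux-sum (empty when the
#'   metabolite has no producing flux).
#' @export
compute_target_flux_sum <- function(model, flux, metabolite) {
  contrib <- producing_contributions(model, flux, metabolite)
  if (!length(contrib)) return(stats::setNames(numeric(), character()))
  pw <- model$reactions$pathway[match(names(contrib), model$reactions$id)]
  out <- tapply(contrib, pw, sum)
  stats::setNames(as.numeric(out), names(out))
}

producing_contributions <- function(model, flux, metabolite) {
  if (!metabolite %in% model$metabolites$id)
    stop("unknown metabolite id: ", metabolite)
  contrib <- numeric()
  for (k in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[k]]
    if (!metabolite %in% names(s)) next
    x <- s[[metabolite]] * flux$flux[[model$reactions$id[k]]]
    if (x > 0) contrib[model$reactions$id[k]] <- x
  }
  contrib
}

#' Cohort flux-sum matrix with pathway decomposition
#'
#' Computes flux-sums and their pathway decomposition for every metabolite
#' and every sample of a cohort.
#'
#' @param model a [metabolic_model].
#' @param flux_states named list of `flux_state` objects (one per sample).
#' @param metabolites metabolite ids to include; defaults to all metabolites.
#' @return a `flux_sum_matrix`: list with `F` (samples x metabolites matrix
#'   of flux-sums) and `target` (named list: per metabolite, a samples x
#'   pathways matrix of target flux-sums; only pathways that ever produce the
#'   metabolite appear).
#' @export
flux_sum_matrix <- function(model, flux_states,
                            metabolites = model$metabolites$id) {
  samples <- names(flux_states)
  stopifnot(!is.null(samples))
  Fm <- matrix(0, length(samples), length(metabolites),
               dimnames = list(samples, metabolites))
  target <- stats::setNames(vector("list", length(metabolites)), metabolites)
  for (m in metabolites) {
    per_sample <- lapply(flux_states, compute_target_flux_sum,
                         model = model, metabolite = m)
    pws <- sort(unique(unlist(lapply(per_sample, names))))
    tm <- matrix(0, length(samples), length(pws),
                 dimnames = list(samples, pws))
    for (s in samples) {
      v <- per_sample[[s]]
      if (length(v)) tm[s, names(v)] <- v
    }
    target[[m]] <- tm
    Fm[, m] <- rowSums(tm)
  }
  structure(list(F = Fm, target = target), class = "flux_sum_matrix")
}

#' @export
print.flux_sum_matrix <- function(x, ...) {
  cat(sprintf("<flux_sum_matrix: %d samples x %d metabolites>\n",
              nrow(x$F), ncol(x$F)))
  invisible(x)
}

#' Export a flux state as a two-column TSV
#'
#' @param flux a `flux_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(flux, path) {
  utils::write.table(
    data.frame(reaction = names(flux$flux), flux = unname(flux$flux)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
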