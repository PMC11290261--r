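#' Two-sided Wilcoxon rank-sum test
#'
#' The mutation-stratified test used at steps 2 and 3 of the MGP workflow.
#' Exact tail probabilities (full null distribution of the rank-sum) are used
#' when `min(n1, n2) <= exact_max` and the data are tie-free; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (e.g. mutant and wild-type groups).
#' @param exact_max largest group minimum for which the exact null is used.
#' @return list with `p` (two-sided p-value), `U` (Mann-Whitney statistic for
#'   `x`), and `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0

  if (!ties && min(n1, n2) <= exact_max) {
    # exact: U takes integer values under the tie-free null
    lower <- stats::pwilcox(U, n1, n2)
    upper <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    return(list(p = p, U = U, exact = TRUE))
  }

  N <- n1 + n2
  tie_tab <- table(r)
  tie_adj <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- (n1 * n2 / 12) * (N + 1 - tie_adj)
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) return(list(p = 1, U = U, exact = FALSE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(p = min(1, 2 * stats::pnorm(-abs(z))), U = U, exact = FALSE)
}

#' Quantile-normalize a flux-sum matrix across samples
#'
#' Forces every sample's flux-sum distribution onto the common reference
#' distribution (the mean of the per-sample order statistics; rank-mean
#' convention, ties receiving the mean of the reference values at their tied
#' rank positions). Applied per cohort. Two rules follow normalization:
#' entries whose original value was exactly 0 are reset to 0, and target
#' flux-sums are rescaled proportionally,
#' \eqn{f^*_{i_p} = (F^*_i / F_i) f_{i_p}} (all 0 when \eqn{F_i = 0}), so the
#' relative pathway contributions to each metabolite are preserved.
#'
#' @param fsm a `flux_sum_matrix` from [flux_sum_matrix()], or a plain
#'   samples x metabolites matrix.
#' @return same shape as the input with normalized `F` (and, for a
#'   `flux_sum_matrix`, adjusted `target` decomposition); class
#'   `normalized_flux_sum_matrix` in the latter case.
#' @export
quantile_normalize <- function(fsm) {
  plain <- is.matrix(fsm)
  Fm <- if (plain) fsm else fsm$F
  if (nrow(Fm) < 2) stop("quantile normalization needs at least 2 samples")

  Fn <- quantile_normalize_columns(t(Fm))  # columns = samples
  Fn <- t(Fn)
  Fn[Fm == 0] <- 0
  dimnames(Fn) <- dimnames(Fm)
  if (plain) return(Fn)

  target <- fsm$target
  for (m in names(target)) {
    tm <- target[[m]]
    if (!ncol(tm)) next
    ratio <- ifelse(Fm[, m] > 0, Fn[, m] / Fm[, m], 0)
    target[[m]] <- tm * ratio
  }
  structure(list(F = Fn, F_raw = Fm, target = target),
            class = c("normalized_flux_sum_matrix", "flux_sum_matrix"))
}

quantile_normalize_columns <- function(X) {
  # X: features x samples; every column forced onto the mean order statistics
  ref <- rowMeans(apply(X, 2, sort))
  idx <- seq_len(nrow(X))
  out <- apply(X, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(idx, ref, xout = r)$y
  })
  matrix(out, nrow = nrow(X), dimnames = dimnames(X))
}

#' Modified Z-score
#'
#' Robust outlier score used at step 4 of the MGP workflow:
#' \deqn{Z_k = \frac{x_k - \tilde x}{\mathrm{MAD} / \Phi^{-1}(3/4)}}
#' when the median absolute deviation (MAD) is nonzero, falling back to
#' \deqn{Z_k = \frac{x_k - \tilde x}{\sqrt{\pi/2}\,\mathrm{MeanAD}}}
#' (mean absolute deviation from the median) when MAD = 0. When both are 0
#' (constant input) all scores are 0 — no outlier exists by construction.
#'
#' @param values numeric vector (e.g. per-gene mean target flux-sums).
#' @return numeric vector of modified Z-scores, same length as `values`.
#' @export
modified_zscore <- function(values) {
  if (!length(values)) stop("empty input to modified_zscore")
  if (any(!is.finite(values))) stop("non-finite values in modified_zscore")
  med <- stats::median(values)
  dev <- values - med
  mad_ <- stats::median(abs(dev))
  if (mad_ != 0) return(dev / (mad_ / stats::qnorm(3 / 4)))
  mean_ad <- mean(abs(dev))
  if (mean_ad == 0) return(rep(0, length(values)))
  dev / (sqrt(pi / 2) * mean_ad)
}
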