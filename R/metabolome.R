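#' Read a metabolome peak table
#'
#' Delimited text with peak annotation columns followed by one column per
#' sample; missing entries are blank or `NA`. The first column is taken as
#' the peak identifier.
#'
#' @param path file path.
#' @param sep field separator (`"\t"` or `","`).
#' @param annotation_cols names (or count) of leading annotation columns;
#'   every remaining column is a sample.
#' @return a `metabolome_matrix`: list with `values` (peaks x samples numeric
#'   matrix, `NA` for missing) and `annotation` (data.frame, one row per
#'   peak).
#' @export
read_metabolome_table <- function(path, sep = "\t", annotation_cols = 1L) {
  if (!file.exists(path)) stop("metabolome table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ann_idx <- if (is.numeric(annotation_cols)) seq_len(annotation_cols) else
    match(annotation_cols, names(df))
  ann <- df[, ann_idx, drop = FALSE]
  vals <- as.matrix(df[, -ann_idx, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(ann[[1]])
  metabolome_matrix(vals, ann)
}

#' Construct a metabolome matrix
#'
#' @param values peaks x samples numeric matrix (`NA` = missing); rows named
#'   by peak id.
#' @param annotation optional data.frame of per-peak annotation (first column
#'   the peak id).
#' @return a `metabolome_matrix`.
#' @export
metabolome_matrix <- function(values, annotation = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (is.null(annotation))
    annotation <- data.frame(peak = rownames(values), stringsAsFactors = FALSE)
  stopifnot(nrow(annotation) == nrow(values))
  structure(list(values = values, annotation = annotation),
            class = "metabolome_matrix")
}

#' @export
print.metabolome_matrix <- function(x, ...) {
  cat(sprintf("<metabolome_matrix: %d peaks x %d samples, %.1f%% missing>\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Drop peaks with too many missing values
#'
#' A peak is removed when its fraction of missing samples is strictly
#' greater than `max_missing_frac` (default 0.20: "missing in more than 20%
#' of samples"). Idempotent.
#'
#' @param mm a `metabolome_matrix`.
#' @param max_missing_frac maximum tolerated missing fraction.
#' @return the filtered `metabolome_matrix`; the number of surviving peaks is
#'   attached as attribute `n_survivors`.
#' @export
filter_peaks <- function(mm, max_missing_frac = 0.20) {
  frac <- rowMeans(is.na(mm$values))
  keep <- frac <= max_missing_frac
  out <- metabolome_matrix(mm$values[keep, , drop = FALSE],
                           mm$annotation[keep, , drop = FALSE])
  attr(out, "n_survivors") <- sum(keep)
  out
}

#' Impute missing peaks by feature-wise k-nearest neighbors
#'
#' For every missing entry, the `k` peaks nearest to the target peak
#' (Euclidean distance over co-observed samples, rescaled by the number of
#' co-observed samples so overlaps of different sizes are comparable) that
#' are observed in that sample donate their values; the imputed value is
#' their unweighted mean. Observed entries are never altered.
#'
#' @param mm a `metabolome_matrix`.
#' @param k number of neighbors (default 10).
#' @return a complete `metabolome_matrix`.
#' @export
knn_impute <- function(mm, k = 10) {
  if (k < 1) stop("k must be >= 1")
  X <- mm$values
  if (!anyNA(X)) return(mm)
  if (any(rowSums(!is.na(X)) == 0))
    stop("peak(s) with no observed value; run filter_peaks() first")

  n <- nrow(X)
  dist2 <- function(a, b) {
    co <- !is.na(a) & !is.na(b)
    if (!any(co)) return(Inf)
    sqrt(mean((a[co] - b[co])^2))
  }
  out <- X
  for (i in which(rowSums(is.na(X)) > 0)) {
    d <- vapply(seq_len(n), function(j)
      if (j == i) Inf else dist2(X[i, ], X[j, ]), 0)
    for (s in which(is.na(X[i, ]))) {
      donors <- which(!is.na(X[, s]) & is.finite(d))
      if (!length(donors))
        stop("no donor peak observed in sample '", colnames(X)[s], "'")
      if (length(donors) < k)
        warning("only ", length(donors), " donor peak(s) available (k = ",
                k, ") for peak '", rownames(X)[i], "'")
      nearest <- donors[order(d[donors], rownames(X)[donors])][seq_len(min(k, length(donors)))]
      out[i, s] <- mean(X[nearest, s])
    }
  }
  metabolome_matrix(out, mm$annotation)
}

#' Normalize a metabolome matrix
#'
#' The three-stage normalization applied before ROC analysis: per-sample
#' normalization by sum (each sample column divided by its total), the
#' generalized logarithm \eqn{glog(x) = \log_2((x + \sqrt{x^2 +
#' \lambda^2})/2)}, and autoscaling (per-peak mean centering and division by
#' the standard deviation). By default \eqn{\lambda} is the smallest positive
#' value of the sum-normalized matrix.
#'
#' @param mm a complete `metabolome_matrix` (run [knn_impute()] first).
#' @param glog_lambda transform parameter; `NULL` (default) uses the global
#'   minimum positive value after sum normalization.
#' @return the normalized `metabolome_matrix`: every peak has mean 0 and unit
#'   standard deviation across samples.
#' @export
normalize_metabolome <- function(mm, glog_lambda = NULL) {
  X <- mm$values
  if (anyNA(X)) stop("matrix has missing values; run knn_impute() first")
  tot <- colSums(X)
  if (any(tot <= 0)) stop("nonpositive sample total; cannot normalize by sum")
  X <- sweep(X, 2, tot, "/")
  if (is.null(glog_lambda)) {
    pos <- X[X > 0]
    glog_lambda <- if (length(pos)) min(pos) else 1
  }
  X <- log2((X + sqrt(X^2 + glog_lambda^2)) / 2)
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " constant peak(s) dropped during autoscaling")
    keep <- sdv > 0
    X <- X[keep, , drop = FALSE]
    mm$annotation <- mm$annotation[keep, , drop = FALSE]
    mu <- mu[keep]; sdv <- sdv[keep]
  }
  X <- (X - mu) / sdv
  metabolome_matrix(X, mm$annotation)
}

#' Classical univariate ROC AUC for a metabolite against a mutation
#'
#' The probability that a random mutant sample's level ranks above a random
#' wild-type sample's (ties count 1/2), reported direction-agnostic as
#' `max(a, 1 - a)` so that "AUC > 0.7" captures discrimination in either
#' direction.
#'
#' @param values named numeric vector of per-sample metabolite levels.
#' @param status logical or 0/1 vector (same order/names): `TRUE`/1 = mutant.
#' @return list with `auc`, `auc_raw` (the mutant-high direction),
#'   `n_mutant`, `n_wildtype`.
#' @export
compute_auc <- function(values, status) {
  status <- as.logical(status)
  if (length(values) != length(status)) stop("values/status length mismatch")
  n1 <- sum(status); n0 <- sum(!status)
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty")
  r <- rank(values)
  u <- sum(r[status]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n0)
  list(auc = max(a, 1 - a), auc_raw = a, n_mutant = n1, n_wildtype = n0)
}

#' Empirical significance of an AUC hit count
#'
#' Estimates the probability of observing at least `observed_hits` AUC values
#' above `threshold` among `n_pairs` AUCs drawn without replacement from a
#' background pool, by seeded Monte-Carlo resampling with add-one smoothing:
#' \eqn{p = (1 + \#\{resamples \ge observed\}) / (N + 1)}.
#'
#' @param observed_hits observed number of pairs with AUC above threshold.
#' @param n_pairs number of pairs drawn per resample.
#' @param pool numeric vector of background AUC values (length >= `n_pairs`).
#' @param threshold AUC threshold (default 0.7).
#' @param n_resamples number of resamples (default 1e5).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return empirical p-value.
#' @export
empirical_pvalue <- function(observed_hits, n_pairs, pool, threshold = 0.7,
                             n_resamples = 1e5, seed) {
  if (length(pool) < n_pairs) stop("pool smaller than n_pairs")
  if (n_resamples < 1000) stop("n_resamples must be >= 1000")
  if (missing(seed)) stop("seed is mandatory")
  above <- pool > threshold
  hits <- withr_seed(seed, {
    vapply(seq_len(n_resamples), function(i)
      sum(sample(above, n_pairs)), 0L)
  })
  (1 + sum(hits >= observed_hits)) / (n_resamples + 1)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
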