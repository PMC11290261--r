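#' Read a somatic variant table
#'
#' MAF-like delimited text with columns for sample, gene, alternative read
#' count and consequence class. Column names are matched case-insensitively
#' against common aliases (`sample`/`Tumor_Sample_Barcode`, `gene`/
#' `Hugo_Symbol`, `alt_reads`/`t_alt_count`, `consequence`/
#' `Variant_Classification`).
#'
#' @param path TSV/CSV file path.
#' @param sep field separator (default tab).
#' @return data.frame with columns `sample`, `gene`, `alt_reads`,
#'   `consequence` (one of `synonymous`, `nonsynonymous`, `other`).
#' @export
read_variant_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("variant table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(aliases) {
    hit <- match(tolower(aliases), tolower(names(df)))
    hit <- hit[!is.na(hit)]
    if (!length(hit)) stop("variant table lacks a column among: ",
                           paste(aliases, collapse = ", "))
    df[[hit[1]]]
  }
  out <- data.frame(
    sample = as.character(pick(c("sample", "sample_id", "Tumor_Sample_Barcode"))),
    gene = as.character(pick(c("gene", "Hugo_Symbol"))),
    alt_reads = as.integer(pick(c("alt_reads", "t_alt_count"))),
    consequence = normalize_consequence(
      pick(c("consequence", "Variant_Classification"))),
    stringsAsFactors = FALSE)
  if (any(is.na(out$alt_reads)) || any(out$alt_reads < 0))
    stop("alt-read counts must be nonnegative integers")
  out
}

normalize_consequence <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("other", length(x))
  out[x %in% c("synonymous", "silent", "synonymous_variant")] <- "synonymous"
  out[x %in% c("nonsynonymous", "missense", "missense_mutation",
               "missense_variant", "nonsense_mutation", "stop_gained",
               "frame_shift_del", "frame_shift_ins", "frameshift_variant",
               "nonstop_mutation", "splice_site", "in_frame_del",
               "in_frame_ins")] <- "nonsynonymous"
  out
}

#' Mutation filter cascade
#'
#' Builds the binary sample x gene mutation matrix from a variant table,
#' applying the filter cascade: variants covered by fewer than `min_alt_reads`
#' alternative reads are dropped; synonymous variants are dropped; genes
#' mutant in fewer than `min_group` cohort samples, or wild-type in fewer
#' than `min_group` cohort samples, are dropped; finally, "subset" genes —
#' genes whose mutant-sample set is a strict subset of another retained
#' gene's mutant-sample set (statistically inseparable from it) — are
#' dropped, retaining the gene with the larger mutant set (ties broken
#' lexicographically).
#'
#' @param variants data.frame as from [read_variant_table()].
#' @param cohort character vector of cohort sample ids; rows for samples
#'   outside the cohort are ignored with a warning.
#' @param min_alt_reads minimum alternative read count (default 7; variants
#'   with fewer are dropped).
#' @param min_group minimum mutant and wild-type group size per gene
#'   (default 3).
#' @param subset_filter apply the subset-gene rule (default `TRUE`).
#' @return a `mutation_matrix`: list with `status` (samples x genes 0/1
#'   matrix over the whole cohort), `n_mutant`, `n_wildtype` (per gene) and
#'   `tally` (per-rule drop counts; row-level counts satisfy
#'   `rows_in = rows_kept + sum(dropped)`).
#' @export
filter_mutations <- function(variants, cohort, min_alt_reads = 7,
                             min_group = 3, subset_filter = TRUE) {
  if (!length(cohort)) stop("empty cohort")
  stopifnot(all(c("sample", "gene", "alt_reads", "consequence") %in%
                  names(variants)))
  rows_in <- nrow(variants)

  off <- !variants$sample %in% cohort
  if (any(off)) {
    warning(sum(off), " variant row(s) for samples outside the cohort ignored")
    variants <- variants[!off, , drop = FALSE]
  }
  low <- variants$alt_reads < min_alt_reads
  variants <- variants[!low, , drop = FALSE]
  syn <- variants$consequence == "synonymous"
  variants <- variants[!syn, , drop = FALSE]

  status <- matrix(0L, length(cohort), 0, dimnames = list(cohort, NULL))
  if (nrow(variants)) {
    genes <- sort(unique(variants$gene))
    status <- matrix(0L, length(cohort), length(genes),
                     dimnames = list(cohort, genes))
    status[cbind(match(variants$sample, cohort),
                 match(variants$gene, genes))] <- 1L
  }
  n_mut <- colSums(status)
  n_wt <- nrow(status) - n_mut
  few_mut <- n_mut < min_group
  few_wt <- n_wt < min_group
  status <- status[, !few_mut & !few_wt, drop = FALSE]

  dropped_subset <- character()
  if (subset_filter && ncol(status) > 1) {
    sets <- lapply(colnames(status), function(g) rownames(status)[status[, g] == 1])
    names(sets) <- colnames(status)
    ord <- order(-lengths(sets), names(sets))
    kept <- character()
    for (g in names(sets)[ord]) {
      is_subset <- any(vapply(kept, function(k) {
        all(sets[[g]] %in% sets[[k]]) && length(sets[[g]]) < length(sets[[k]])
      }, TRUE))
      if (is_subset) dropped_subset <- c(dropped_subset, g) else kept <- c(kept, g)
    }
    status <- status[, sort(setdiff(colnames(status), dropped_subset)),
                     drop = FALSE]
  }

  structure(
    list(status = status,
         n_mutant = colSums(status),
         n_wildtype = nrow(status) - colSums(status),
         tally = list(
           rows_in = rows_in,
           rows_off_cohort = sum(off),
           rows_low_alt_reads = sum(low),
           rows_synonymous = sum(syn),
           rows_kept = nrow(variants),
           genes_in = length(n_mut),
           genes_few_mutant = sum(few_mut),
           genes_few_wildtype = sum(few_wt & !few_mut),
           genes_subset = length(dropped_subset),
           genes_kept = ncol(status))),
    class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("<mutation_matrix: %d samples x %d genes>\n",
              nrow(x$status), ncol(x$status)))
  invisible(x)
}

#' Merge mutation status across a gene group
#'
#' Supports family-level mutation calls (e.g. "IDH" = IDH1 or IDH2 mutant):
#' a sample is group-mutant if it is mutant for any member gene. Group
#' columns are appended to the matrix; member columns are retained.
#'
#' @param mutations a `mutation_matrix`.
#' @param groups data.frame with columns `group`, `gene` (a gene-group alias
#'   table, as read from a two-column TSV).
#' @return the `mutation_matrix` with one extra column per group that has at
#'   least one member present.
#' @export
apply_gene_groups <- function(mutations, groups) {
  stopifnot(all(c("group", "gene") %in% names(groups)))
  status <- mutations$status
  for (g in unique(groups$group)) {
    members <- intersect(groups$gene[groups$group == g], colnames(status))
    if (!length(members)) next
    merged <- as.integer(rowSums(status[, members, drop = FALSE]) > 0)
    status <- cbind(status, stats::setNames(data.frame(merged), g))
    status <- as.matrix(status)
  }
  mutations$status <- status
  mutations$n_mutant <- colSums(status)
  mutations$n_wildtype <- nrow(status) - colSums(status)
  mutations
}

#' Read a gene-group alias table
#'
#' @param path two-column TSV (`group`, `gene`).
#' @return data.frame with columns `group`, `gene`.
#' @export
read_gene_groups <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("group", "gene") %in% names(df)))
  df
}
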