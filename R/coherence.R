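# Expression coherence: gene-pair Pearson correlation with the
# max-over-probesets rule, and the mean-pairwise-correlation coherence of a
# gene set.  A precomputed gene-level correlation cache makes the
# randomization tests in significance.R affordable.

# Correlation between two sets of probeset rows under the max rule.
# Zero-variance probeset pairs are skipped; returns NA when every pair is
# degenerate.
max_probeset_cor <- function(values, rows_a, rows_b) {
  a <- values[rows_a, , drop = FALSE]
  b <- values[rows_b, , drop = FALSE]
  r <- suppressWarnings(cor(t(a), t(b)))
  r <- r[is.finite(r)]
  if (length(r) == 0L) return(NA_real_)
  max(r)
}

#' Pearson correlation of a gene pair under the max-over-probesets rule
#'
#' When a gene is measured by several probesets, the correlation of a gene
#' pair is the maximum Pearson correlation over all probeset pairs.
#' Probeset pairs in which either member has zero variance are skipped; if
#' every pair is degenerate the correlation is undefined (`NA`).
#'
#' @param expr an [expression_matrix()].
#' @param gene_a,gene_b gene IDs present in the probeset-to-gene map.
#' @return a single numeric correlation in \[-1, 1\], or `NA` if undefined.
#' @export
gene_pair_correlation <- function(expr, gene_a, gene_b) {
  stopifnot(inherits(expr, "expression_matrix"))
  rows_a <- expr$gene_index[[gene_a]]
  rows_b <- expr$gene_index[[gene_b]]
  if (is.null(rows_a)) stop(sprintf("gene '%s' has no probeset", gene_a), call. = FALSE)
  if (is.null(rows_b)) stop(sprintf("gene '%s' has no probeset", gene_b), call. = FALSE)
  if (ncol(expr$values) < 3L) {
    stop("at least 3 samples are required for correlation", call. = FALSE)
  }
  max_probeset_cor(expr$values, rows_a, rows_b)
}

#' All pairwise gene correlations of a gene set
#'
#' Genes absent from the expression matrix are dropped.  Pairs are unordered
#' and enumerated in lexicographic gene order, so output order is
#' deterministic.
#'
#' @param expr an [expression_matrix()].
#' @param genes character vector of gene IDs.
#' @return data frame with columns `gene_a`, `gene_b`, `r` (one row per
#'   unordered pair; zero rows when fewer than two genes are usable).
#' @export
pairwise_correlations <- function(expr, genes) {
  stopifnot(inherits(expr, "expression_matrix"))
  genes <- sort(unique(intersect(genes, names(expr$gene_index))))
  if (length(genes) < 2L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0)))
  }
  idx <- combn(length(genes), 2L)
  r <- vapply(seq_len(ncol(idx)), function(k) {
    max_probeset_cor(expr$values,
                     expr$gene_index[[genes[idx[1L, k]]]],
                     expr$gene_index[[genes[idx[2L, k]]]])
  }, numeric(1L))
  data.frame(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]], r = r)
}

#' Coherence of a gene set
#'
#' Coherence is the mean Pearson correlation over all unordered gene pairs
#' in the set, each pair scored under the max-over-probesets rule.
#' Undefined (zero-variance) pairs are excluded from the mean.
#'
#' @param expr an [expression_matrix()].
#' @param genes character vector of gene IDs (at least two must have
#'   expression data).
#' @return numeric coherence in \[-1, 1\], or `NA` when fewer than two genes
#'   are usable or all pairs are undefined.
#' @export
coherence <- function(expr, genes) {
  pc <- pairwise_correlations(expr, genes)
  r <- pc$r[!is.na(pc$r)]
  if (length(r) == 0L) return(NA_real_)
  mean(r)
}

#' Precompute a gene-level correlation matrix
#'
#' Builds the symmetric matrix of max-over-probesets Pearson correlations
#' for a set of genes in one pass, for repeated coherence evaluation during
#' randomization tests.  In the common one-probeset-per-gene case this is a
#' single `cor()` call.
#'
#' @param expr an [expression_matrix()].
#' @param genes gene IDs to include (genes without expression are dropped).
#' @return an object of class `cor_cache`: list with `genes` and the
#'   correlation matrix `R` (NA where undefined; diagonal 1).
#' @export
gene_cor_cache <- function(expr, genes) {
  stopifnot(inherits(expr, "expression_matrix"))
  genes <- sort(unique(intersect(genes, names(expr$gene_index))))
  n <- length(genes)
  idx <- expr$gene_index[genes]
  if (n == 0L) {
    return(structure(list(genes = genes,
                          R = matrix(numeric(0), 0L, 0L)),
                     class = "cor_cache"))
  }
  if (all(lengths(idx) == 1L)) {
    rows <- unlist(idx, use.names = FALSE)
    R <- suppressWarnings(cor(t(expr$values[rows, , drop = FALSE])))
    R[!is.finite(R)] <- NA_real_
  } else {
    rows <- unlist(idx, use.names = FALSE)
    P <- suppressWarnings(cor(t(expr$values[rows, , drop = FALSE])))
    offsets <- c(0L, cumsum(lengths(idx)))
    R <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      ri <- (offsets[i] + 1L):offsets[i + 1L]
      for (j in i:n) {
        rj <- (offsets[j] + 1L):offsets[j + 1L]
        sub <- P[ri, rj, drop = FALSE]
        sub <- sub[is.finite(sub)]
        if (length(sub) > 0L) R[i, j] <- R[j, i] <- max(sub)
      }
    }
  }
  diag(R) <- 1
  dimnames(R) <- list(genes, genes)
  structure(list(genes = genes, R = R), class = "cor_cache")
}

#' Coherence of a gene set evaluated against a precomputed cache
#'
#' Genes missing from the cache are dropped (they had no usable
#' expression); equivalent to [coherence()] on the cached genes.
#'
#' @param cache a [gene_cor_cache()].
#' @param genes gene IDs.
#' @return numeric coherence, `NA` when fewer than two genes are usable.
#' @export
coherence_cached <- function(cache, genes) {
  g <- intersect(genes, cache$genes)
  if (length(g) < 2L) return(NA_real_)
  sub <- cache$R[g, g]
  vals <- sub[upper.tri(sub)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}
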