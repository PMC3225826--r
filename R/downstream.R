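# Downstream analyses: host-gene/CRM sharing, and hierarchical clustering
# of module genes under the one-minus-correlation distance.

#' CRMs shared between a miRNA and its host gene
#'
#' For each intronic miRNA with a known host gene, finds the CRMs that both
#' regulate the miRNA (a CRM-to-miRNA edge) and target the host gene.
#'
#' @param host_map named character vector, miRNA ID -> host gene ID.
#' @param c2m_edges data frame with columns `crm_id`, `mirna_id`.
#' @param crm_targets a [target_map()] of CRM target genes.
#' @return data frame with columns `mirna_id`, `host_gene_id`,
#'   `n_shared_crms` and a list column `shared_crms`; the
#'   `n_mirnas_with_shared_crm` attribute holds the summary count of
#'   miRNAs sharing at least one CRM with their host gene.
#' @export
shared_crm_hostgenes <- function(host_map, c2m_edges, crm_targets) {
  stopifnot(inherits(crm_targets, "target_map"))
  mirnas <- names(host_map)
  shared <- lapply(mirnas, function(m) {
    crms <- unique(c2m_edges$crm_id[c2m_edges$mirna_id == m])
    sort(crms[vapply(crms, function(cid)
      host_map[[m]] %in% crm_targets$entries[[cid]], logical(1L))])
  })
  out <- data.frame(mirna_id = mirnas,
                    host_gene_id = unname(host_map),
                    n_shared_crms = lengths(shared))
  out$shared_crms <- I(shared)
  attr(out, "n_mirnas_with_shared_crm") <- sum(lengths(shared) > 0L)
  out
}

#' Hierarchical clustering of genes under the 1 - r distance
#'
#' Agglomerative clustering of a gene set where the distance between two
#' genes is one minus their Pearson correlation (max-over-probesets rule).
#' Undefined correlations are assigned the maximal distance 2 with a
#' warning.
#'
#' @param expr an [expression_matrix()].
#' @param genes character vector of gene IDs (at least two usable).
#' @param method agglomeration method passed to [stats::hclust()]
#'   (default `"average"`; `"complete"` and `"single"` also supported).
#' @return an `hclust` object whose labels are the gene IDs.
#' @export
cluster_genes <- function(expr, genes,
                          method = c("average", "complete", "single")) {
  method <- match.arg(method)
  cache <- gene_cor_cache(expr, genes)
  if (length(cache$genes) < 2L) {
    stop("need at least two genes with usable expression", call. = FALSE)
  }
  D <- 1 - cache$R
  if (anyNA(D)) {
    warning("undefined correlations assigned maximal distance 2", call. = FALSE)
    D[is.na(D)] <- 2
  }
  diag(D) <- 0
  hclust(as.dist(D), method = method)
}

#' Write a dendrogram as Newick text
#'
#' @param hc an `hclust` object (e.g. from [cluster_genes()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dendrogram_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
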