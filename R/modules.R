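# CRM-miRNA module construction: one module per (CRM, miRNA) pair whose
# target-set intersection reaches the minimum size.

#' Build CRM-miRNA combinatorial modules
#'
#' For every (CRM, miRNA) pair, the module gene set is the intersection of
#' the CRM's and the miRNA's target genes; pairs whose intersection holds
#' fewer than `min_size` genes are eliminated (default 2, i.e. gene sets
#' with less than two genes are dropped).
#'
#' @param crm_targets a [target_map()] of CRM target genes.
#' @param mirna_targets a [target_map()] of miRNA target genes.
#' @param min_size minimum module size (default 2).
#' @return a `module_table` data frame with columns `crm_id`, `mirna_id`,
#'   `n_genes`, list column `genes` (sorted gene IDs), and `coherence`,
#'   `p_value`, `q_value` initialized to `NA`.  Rows are ordered by
#'   (crm_id, mirna_id); an empty table is a valid result.
#' @export
build_modules <- function(crm_targets, mirna_targets, min_size = 2L) {
  stopifnot(inherits(crm_targets, "target_map"),
            inherits(mirna_targets, "target_map"))
  if (length(crm_targets$entries) == 0L || length(mirna_targets$entries) == 0L) {
    stop("both target maps must be non-empty", call. = FALSE)
  }
  crm_ids <- sort(names(crm_targets$entries))
  mir_ids <- sort(names(mirna_targets$entries))
  out_crm <- character(0)
  out_mir <- character(0)
  out_genes <- list()
  for (c_id in crm_ids) {
    cg <- crm_targets$entries[[c_id]]
    for (m_id in mir_ids) {
      shared <- intersect(cg, mirna_targets$entries[[m_id]])
      if (length(shared) >= min_size) {
        out_crm <- c(out_crm, c_id)
        out_mir <- c(out_mir, m_id)
        out_genes[[length(out_genes) + 1L]] <- sort(shared)
      }
    }
  }
  tab <- data.frame(crm_id = out_crm, mirna_id = out_mir,
                    n_genes = lengths(out_genes) %||% integer(0),
                    stringsAsFactors = FALSE)
  tab$genes <- I(out_genes)
  tab$coherence <- rep(NA_real_, nrow(tab))
  tab$p_value <- rep(NA_real_, nrow(tab))
  tab$q_value <- rep(NA_real_, nrow(tab))
  class(tab) <- c("module_table", "data.frame")
  tab
}

#' Annotate a module table with coherence values
#'
#' @param modules a `module_table` from [build_modules()].
#' @param expr an [expression_matrix()].
#' @return the module table with the `coherence` column filled (NA where
#'   undefined, e.g. fewer than two module genes on the array).
#' @export
module_coherences <- function(modules, expr) {
  cache <- gene_cor_cache(expr, unique(unlist(modules$genes, use.names = FALSE)))
  modules$coherence <- vapply(modules$genes, function(g)
    coherence_cached(cache, g), numeric(1L))
  modules
}
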