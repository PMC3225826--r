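# Randomization tests for module coherence: the two backgrounds of the
# module test, the whole-gene-set null for plain CRM/miRNA coherence,
# empirical p-values on the 1/n_reps grid, and BH-FDR correction.

#' Background specification for coherence randomization tests
#'
#' @param kind `"BG1_CRM_POOL"` (module genes redrawn from the CRM target
#'   pool, size preserved), `"BG2_ARTIFICIAL_MIRNA"` (degree-matched
#'   artificial miRNA intersected with the CRM targets), or
#'   `"WHOLE_GENE_SET"` (regulator targets redrawn from the whole gene set).
#' @param n_reps number of randomizations: 100 for p-values, 5 for plotting
#'   background distributions.
#' @param seed integer seed for the run; per-module streams are derived from
#'   it by module index.
#' @param bg1_pool for BG1, `"crm"` draws from the module's own CRM target
#'   set, `"union"` from the union of all CRM target genes.
#' @return an object of class `background_spec`.
#' @export
background_spec <- function(kind = c("BG1_CRM_POOL", "BG2_ARTIFICIAL_MIRNA",
                                     "WHOLE_GENE_SET"),
                            n_reps = 100L, seed = 1L,
                            bg1_pool = c("crm", "union")) {
  kind <- match.arg(kind)
  bg1_pool <- match.arg(bg1_pool)
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  structure(list(kind = kind, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), bg1_pool = bg1_pool),
            class = "background_spec")
}

#' Background 1: redraw module genes from the CRM target pool
#'
#' Draws a uniform sample without replacement, the same size as the module
#' gene set, from the CRM pool: by default the module's own CRM target set,
#' optionally the union of all CRM target genes.
#'
#' @param module one-row slice of a module table (list with `crm_id` and
#'   `genes`).
#' @param crm_targets a [target_map()] of CRM targets.
#' @param pool `"crm"` or `"union"`.
#' @return character vector of sampled gene IDs.
#' @export
sample_background1 <- function(module, crm_targets, pool = c("crm", "union")) {
  pool <- match.arg(pool)
  genes <- if (is.list(module$genes)) module$genes[[1L]] else module$genes
  size <- length(genes)
  candidates <- if (pool == "crm") {
    crm_targets$entries[[module$crm_id]]
  } else {
    unique(unlist(crm_targets$entries, use.names = FALSE))
  }
  if (length(candidates) < size) {
    stop(sprintf("CRM pool (%d genes) smaller than module (%d genes)",
                 length(candidates), size), call. = FALSE)
  }
  sample(candidates, size)
}

#' Background 2: artificial miRNA intersected with the CRM targets
#'
#' Builds an artificial miRNA by sampling as many genes as the real miRNA
#' targets from the union of all miRNA target genes (preserving the
#' distribution of miRNA target-gene numbers), then returns its
#' intersection with the module's CRM target set.  The intersection may
#' have any size, including fewer than two genes.
#'
#' @param module one-row slice of a module table.
#' @param crm_targets,mirna_targets [target_map()]s.
#' @return character vector of gene IDs (possibly empty).
#' @export
sample_background2 <- function(module, crm_targets, mirna_targets) {
  universe <- unique(unlist(mirna_targets$entries, use.names = FALSE))
  k <- length(mirna_targets$entries[[module$mirna_id]])
  k <- min(k, length(universe))
  artificial <- sample(universe, k)
  intersect(crm_targets$entries[[module$crm_id]], artificial)
}

#' Whole-gene-set null for a single regulator
#'
#' Redraws a regulator's target set uniformly from the whole gene universe,
#' preserving its size; the null for plain CRM or miRNA coherence.
#'
#' @param target_count number of genes to draw.
#' @param gene_universe character vector of all gene IDs.
#' @return character vector of sampled gene IDs.
#' @export
sample_regulator_background <- function(target_count, gene_universe) {
  if (target_count > length(gene_universe)) {
    stop("requested target count exceeds the gene universe", call. = FALSE)
  }
  sample(gene_universe, target_count)
}

# One background draw for a module under a spec; redraws degenerate (<2
# usable genes) background-2 sets up to `max_redraw` times, then signals
# degeneracy with NULL.
draw_background_set <- function(module, spec, crm_targets, mirna_targets,
                                gene_universe, max_redraw = 1000L) {
  if (spec$kind == "BG1_CRM_POOL") {
    return(sample_background1(module, crm_targets, spec$bg1_pool))
  }
  if (spec$kind == "WHOLE_GENE_SET") {
    genes <- if (is.list(module$genes)) module$genes[[1L]] else module$genes
    return(sample_regulator_background(length(genes), gene_universe))
  }
  for (i in seq_len(max_redraw)) {
    s <- sample_background2(module, crm_targets, mirna_targets)
    if (length(s) >= 2L) return(s)
  }
  NULL
}

#' Empirical coherence p-value of one module
#'
#' The p-value is the proportion of `n_reps` random gene sets whose
#' coherence is the same as, or higher than, the observed module coherence
#' (ties count).  Background-2 draws with fewer than two genes are redrawn;
#' a rep that stays degenerate after 1000 redraws scores below any observed
#' coherence and its redraw is logged.
#'
#' @param expr an [expression_matrix()].
#' @param module one-row slice of a module table.
#' @param background a [background_spec()].
#' @param crm_targets,mirna_targets [target_map()]s.
#' @param gene_universe gene universe for `WHOLE_GENE_SET` (defaults to all
#'   mapped genes in `expr`).
#' @param cache optional [gene_cor_cache()] covering the background pool.
#' @return list with `p_value` (NA when the observed coherence is
#'   undefined), `observed`, `background` (numeric vector of background
#'   coherences, `-Inf` marking degenerate reps), and `n_degenerate`.
#' @export
module_pvalue <- function(expr, module, background, crm_targets, mirna_targets,
                          gene_universe = NULL, cache = NULL) {
  stopifnot(inherits(background, "background_spec"))
  genes <- if (is.list(module$genes)) module$genes[[1L]] else module$genes
  if (is.null(gene_universe)) gene_universe <- names(expr$gene_index)
  if (is.null(cache)) {
    pool <- switch(background$kind,
      BG1_CRM_POOL = if (background$bg1_pool == "crm")
        crm_targets$entries[[module$crm_id]]
      else unique(unlist(crm_targets$entries, use.names = FALSE)),
      BG2_ARTIFICIAL_MIRNA = crm_targets$entries[[module$crm_id]],
      WHOLE_GENE_SET = gene_universe)
    cache <- gene_cor_cache(expr, unique(c(pool, genes)))
  }
  observed <- coherence_cached(cache, genes)
  bg <- numeric(background$n_reps)
  n_degenerate <- 0L
  for (i in seq_len(background$n_reps)) {
    s <- draw_background_set(module, background, crm_targets, mirna_targets,
                             gene_universe)
    ci <- if (is.null(s)) NA_real_ else coherence_cached(cache, s)
    if (is.null(s) || is.na(ci)) {
      n_degenerate <- n_degenerate + 1L
      bg[i] <- -Inf
    } else {
      bg[i] <- ci
    }
  }
  p <- if (is.na(observed)) NA_real_ else mean(bg >= observed)
  list(p_value = p, observed = observed, background = bg,
       n_degenerate = n_degenerate)
}

#' Coherence significance test for a whole module table
#'
#' Runs [module_pvalue()] for every module with a per-module RNG stream
#' derived from the background seed and the module index, fills the `coherence`,
#' `p_value` and `q_value` (BH-FDR) columns, and returns the table.
#'
#' @param modules a `module_table` from [build_modules()].
#' @param expr an [expression_matrix()].
#' @param background a [background_spec()].
#' @param crm_targets,mirna_targets [target_map()]s.
#' @param gene_universe optional gene universe for `WHOLE_GENE_SET`.
#' @return the module table with coherence, p and q columns filled.
#' @export
test_module_coherence <- function(modules, expr, background, crm_targets,
                                  mirna_targets, gene_universe = NULL) {
  needed <- unique(c(unlist(modules$genes, use.names = FALSE),
                     unlist(crm_targets$entries, use.names = FALSE),
                     if (!is.null(gene_universe)) gene_universe))
  cache <- gene_cor_cache(expr, needed)
  for (k in seq_len(nrow(modules))) {
    res <- with_seed(child_seed(background$seed, k), module_pvalue(
      expr, modules[k, ], background, crm_targets, mirna_targets,
      gene_universe = gene_universe, cache = cache))
    modules$coherence[k] <- res$observed
    modules$p_value[k] <- res$p_value
  }
  ok <- !is.na(modules$p_value)
  modules$q_value[ok] <- fdr_correct(modules$p_value[ok])
  modules
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate adjustment; order-preserving, q-values in
#' \[0, 1\].
#'
#' @param pvalues numeric vector of p-values.
#' @return numeric vector of q-values, same order as the input.
#' @export
fdr_correct <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}
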