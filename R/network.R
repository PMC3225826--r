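# The tripartite regulatory network: typed nodes (CRM / MIRNA / GENE),
# typed directed edges (C2G, M2G, C2M, M2C), an exhaustive catalog of
# connected regulation patterns on up to three nodes, an exact subgraph
# census, and degree-preserving edge-swap null networks with Z-scores.

EDGE_TYPES <- c("C2G", "M2G", "C2M", "M2C")
EDGE_ENDPOINTS <- list(C2G = c("C", "G"), M2G = c("M", "G"),
                       C2M = c("C", "M"), M2C = c("M", "C"))

#' Construct a typed regulatory network
#'
#' @param edges data frame with columns `source`, `target`, `type`
#'   (`C2G`, `M2G`, `C2M`, `M2C`).  Duplicate edges are collapsed.
#' @return an object of class `regulatory_network` with components `nodes`
#'   (named character vector, ID -> type in `C`/`M`/`G`) and `edges`.
#' @export
regulatory_network <- function(edges = data.frame(source = character(0),
                                                  target = character(0),
                                                  type = character(0))) {
  stopifnot(all(c("source", "target", "type") %in% names(edges)))
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      type = as.character(edges$type))
  bad <- setdiff(edges$type, EDGE_TYPES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown edge type '%s'", bad[1L]), call. = FALSE)
  }
  if (any(edges$source == edges$target)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  edges <- unique(edges)
  src_type <- vapply(edges$type, function(t) EDGE_ENDPOINTS[[t]][1L], "")
  dst_type <- vapply(edges$type, function(t) EDGE_ENDPOINTS[[t]][2L], "")
  nodes <- c(setNames(src_type, edges$source), setNames(dst_type, edges$target))
  nodes <- nodes[!duplicated(names(nodes))]
  conflict <- tapply(c(src_type, dst_type), c(edges$source, edges$target),
                     function(x) length(unique(x)))
  if (any(conflict > 1L)) {
    stop(sprintf("node '%s' appears with more than one type",
                 names(conflict)[conflict > 1L][1L]), call. = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  tn <- table(factor(x$nodes, levels = c("C", "M", "G")))
  te <- table(factor(x$edges$type, levels = EDGE_TYPES))
  cat(sprintf("regulatory_network: %d CRMs, %d miRNAs, %d genes; edges: %s\n",
              tn[["C"]], tn[["M"]], tn[["G"]],
              paste(sprintf("%s=%d", names(te), te), collapse = " ")))
  invisible(x)
}

#' Derive miRNA-to-CRM edges through transcription-factor genes
#'
#' A miRNA is predicted to target a CRM when at least one TF whose motif
#' belongs to the CRM has a corresponding gene targeted by the miRNA.
#'
#' @param mirna_targets a [target_map()] of miRNA target genes.
#' @param crms named list of motif-ID vectors (CRM definitions).
#' @param pwm_gene_map named list mapping motif IDs to TF gene IDs; motifs
#'   missing from the map are skipped with a warning.
#' @return data frame with columns `mirna_id`, `crm_id`.
#' @export
derive_mirna_crm_edges <- function(mirna_targets, crms, pwm_gene_map) {
  stopifnot(inherits(mirna_targets, "target_map"))
  missing <- setdiff(unique(unlist(crms, use.names = FALSE)),
                     names(pwm_gene_map))
  if (length(missing) > 0L) {
    warning(sprintf("no TF gene mapping for motif(s): %s; skipped",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  crm_tf_genes <- lapply(crms, function(motifs) {
    unique(unlist(pwm_gene_map[intersect(motifs, names(pwm_gene_map))],
                  use.names = FALSE))
  })
  out_mir <- character(0)
  out_crm <- character(0)
  for (mid in sort(names(mirna_targets$entries))) {
    targets <- mirna_targets$entries[[mid]]
    for (cid in sort(names(crms))) {
      if (length(intersect(crm_tf_genes[[cid]], targets)) > 0L) {
        out_mir <- c(out_mir, mid)
        out_crm <- c(out_crm, cid)
      }
    }
  }
  data.frame(mirna_id = out_mir, crm_id = out_crm)
}

#' Assemble the tripartite regulatory network
#'
#' Union of the four typed edge sets: CRM-target and miRNA-target edges
#' from the target maps, plus predicted CRM-to-miRNA and miRNA-to-CRM
#' regulatory edges.
#'
#' @param crm_targets,mirna_targets [target_map()]s (may be `NULL`).
#' @param c2m_edges data frame with columns `crm_id`, `mirna_id`, or `NULL`.
#' @param m2c_edges data frame with columns `mirna_id`, `crm_id`, or `NULL`.
#' @return a [regulatory_network()].
#' @export
build_network <- function(crm_targets = NULL, mirna_targets = NULL,
                          c2m_edges = NULL, m2c_edges = NULL) {
  parts <- list()
  map_edges <- function(map, type) {
    data.frame(source = rep(names(map$entries), lengths(map$entries)),
               target = unlist(map$entries, use.names = FALSE),
               type = type)
  }
  if (!is.null(crm_targets) && length(crm_targets$entries) > 0L) {
    parts <- c(parts, list(map_edges(crm_targets, "C2G")))
  }
  if (!is.null(mirna_targets) && length(mirna_targets$entries) > 0L) {
    parts <- c(parts, list(map_edges(mirna_targets, "M2G")))
  }
  if (!is.null(c2m_edges) && nrow(c2m_edges) > 0L) {
    parts <- c(parts, list(data.frame(source = c2m_edges$crm_id,
                                      target = c2m_edges$mirna_id,
                                      type = "C2M")))
  }
  if (!is.null(m2c_edges) && nrow(m2c_edges) > 0L) {
    parts <- c(parts, list(data.frame(source = m2c_edges$mirna_id,
                                      target = m2c_edges$crm_id,
                                      type = "M2C")))
  }
  if (length(parts) == 0L) return(regulatory_network())
  regulatory_network(do.call(rbind, parts))
}

# ---- pattern catalog ------------------------------------------------------

# Allowed typed edges between two placeholder node types.
allowed_edge_types <- function(type_from, type_to) {
  key <- paste0(type_from, type_to)
  switch(key, CG = "C2G", MG = "M2G", CM = "C2M", MC = "M2C", character(0))
}

pattern_edge_string <- function(node_labels, edges) {
  paste(sort(sprintf("%s>%s", node_labels[edges$from], node_labels[edges$to])),
        collapse = "+")
}

# Canonical label per node: type plus index among same-type nodes.
pattern_node_labels <- function(node_types) {
  idx <- stats::ave(seq_along(node_types), node_types, FUN = seq_along)
  paste0(node_types, idx)
}

# Type-preserving permutations of pattern nodes.
type_permutations <- function(node_types) {
  n <- length(node_types)
  perms <- list(seq_len(n))
  if (n >= 2L) {
    all_perms <- if (n == 2L) list(c(1L, 2L), c(2L, 1L)) else {
      list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L), c(2L,3L,1L),
           c(3L,1L,2L), c(3L,2L,1L))
    }
    perms <- Filter(function(p) all(node_types[p] == node_types), all_perms)
  }
  perms
}

canonical_pattern <- function(node_types, edges) {
  labels <- pattern_node_labels(node_types)
  best <- NULL
  for (p in type_permutations(node_types)) {
    # node i takes role p[i]
    remapped <- data.frame(from = p[edges$from], to = p[edges$to])
    s <- pattern_edge_string(labels, remapped)
    if (is.null(best) || s < best) best <- s
  }
  best
}

pattern_automorphisms <- function(node_types, edges) {
  labels <- pattern_node_labels(node_types)
  ref <- pattern_edge_string(labels, edges)
  sum(vapply(type_permutations(node_types), function(p) {
    remapped <- data.frame(from = p[edges$from], to = p[edges$to])
    pattern_edge_string(labels, remapped) == ref
  }, logical(1L)))
}

weakly_connected <- function(n_nodes, edges) {
  if (n_nodes == 1L) return(nrow(edges) == 0L)
  comp <- seq_len(n_nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$from[k]; b <- edges$to[k]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp)) == 1L
}

# Names for the regulation patterns the text singles out.
pattern_name_for <- function(type_multiset, edge_types_sorted) {
  key <- paste(type_multiset, collapse = "")
  et <- paste(edge_types_sorted, collapse = "+")
  if (key == "CGM") {
    if (et == "C2G+C2M+M2G") return("ffl_crm_to_mirna")
    if (et == "C2G+M2C+M2G") return("ffl_mirna_to_crm")
    if (et == "C2G+M2G") return("coregulation_fork")
    if (et == "C2M+M2G") return("cascade_crm_mirna_gene")
    if (et == "C2G+M2C") return("cascade_mirna_crm_gene")
  }
  if (key == "CM" && et == "C2M+M2C") return("crm_mirna_feedback_cycle")
  NA_character_
}

#' Exhaustive catalog of connected regulation patterns on up to 3 nodes
#'
#' Enumerates every weakly connected simple typed digraph with at most
#' three nodes over the allowed edge types (CRM->gene, miRNA->gene,
#' CRM->miRNA, miRNA->CRM), deduplicated up to type-preserving node
#' permutation.  The catalog includes both feed-forward-loop variants, the
#' co-regulation fork, the two regulator cascades, and the CRM-miRNA
#' feedback cycle, each annotated by name.
#'
#' @return list of pattern entries, each a list with `pattern_id`,
#'   `node_types` (character vector), `edges` (data frame `from`, `to`,
#'   `type`, placeholder indices), `automorphisms`, and `name`
#'   (NA for unnamed patterns).
#' @export
generate_pattern_catalog <- function() {
  type_sets <- list()
  for (n in 2:3) {
    combos <- expand.grid(rep(list(c("C", "M", "G")), n),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      ts <- sort(unlist(combos[i, ], use.names = FALSE))
      key <- paste(ts, collapse = "")
      if (is.null(type_sets[[key]])) type_sets[[key]] <- ts
    }
  }
  catalog <- list()
  seen <- character(0)
  for (ts in type_sets) {
    n <- length(ts)
    # all possible typed edges among placeholders
    cand <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (et in allowed_edge_types(ts[i], ts[j])) {
        cand[[length(cand) + 1L]] <- list(from = i, to = j, type = et)
      }
    }
    if (length(cand) == 0L) next
    for (mask in seq_len(2^length(cand) - 1L)) {
      sel <- which(bitwAnd(mask, 2^(seq_along(cand) - 1L)) > 0L)
      edges <- do.call(rbind, lapply(cand[sel], function(e)
        data.frame(from = e$from, to = e$to, type = e$type)))
      touched <- unique(c(edges$from, edges$to))
      if (length(touched) < n) next
      if (!weakly_connected(n, edges)) next
      canon <- canonical_pattern(ts, edges)
      key <- paste(paste(ts, collapse = ""), canon, sep = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      catalog[[length(catalog) + 1L]] <- list(
        pattern_id = canon,
        node_types = ts,
        edges = edges,
        automorphisms = pattern_automorphisms(ts, edges),
        name = pattern_name_for(ts, sort(edges$type)))
    }
  }
  ord <- order(vapply(catalog, function(p) length(p$node_types), integer(1L)),
               vapply(catalog, function(p) nrow(p$edges), integer(1L)),
               vapply(catalog, `[[`, "", "pattern_id"))
  catalog[ord]
}

# ---- census ---------------------------------------------------------------

# Dense 0/1 adjacency matrices per edge type, with per-type node orderings.
network_adjacency <- function(network) {
  ids <- list(C = sort(names(network$nodes)[network$nodes == "C"]),
              M = sort(names(network$nodes)[network$nodes == "M"]),
              G = sort(names(network$nodes)[network$nodes == "G"]))
  adj <- list()
  for (et in EDGE_TYPES) {
    ep <- EDGE_ENDPOINTS[[et]]
    e <- network$edges[network$edges$type == et, , drop = FALSE]
    m <- matrix(0, length(ids[[ep[1L]]]), length(ids[[ep[2L]]]),
                dimnames = list(ids[[ep[1L]]], ids[[ep[2L]]]))
    if (nrow(e) > 0L) {
      m[cbind(match(e$source, ids[[ep[1L]]]), match(e$target, ids[[ep[2L]]]))] <- 1
    }
    adj[[et]] <- m
  }
  adj$ids <- ids
  adj
}

# Indicator matrix (rows: row_type nodes, cols: col_type nodes) that a typed
# edge is present between a (row, col) node pair.
edge_indicator <- function(edge_type, row_type, col_type, adj) {
  ep <- EDGE_ENDPOINTS[[edge_type]]
  if (identical(ep, c(row_type, col_type))) return(adj[[edge_type]])
  if (identical(ep, c(col_type, row_type))) return(t(adj[[edge_type]]))
  stop("edge type incompatible with node types")   # nocov
}

# Product of required-edge indicators between two placeholder roles; ones
# matrix when no edge is required.
role_pair_indicator <- function(pattern, role_a, role_b, type_a, type_b, adj) {
  n_row <- length(adj$ids[[type_a]])
  n_col <- length(adj$ids[[type_b]])
  m <- matrix(1, n_row, n_col)
  e <- pattern$edges
  for (k in seq_len(nrow(e))) {
    if ((e$from[k] == role_a && e$to[k] == role_b)) {
      m <- m * edge_indicator(e$type[k], type_a, type_b, adj)
    } else if (e$from[k] == role_b && e$to[k] == role_a) {
      m <- m * edge_indicator(e$type[k], type_a, type_b, adj)
    }
  }
  m
}

count_one_pattern <- function(pattern, adj) {
  ts <- pattern$node_types
  n <- length(ts)
  if (n == 2L) {
    ind <- role_pair_indicator(pattern, 1L, 2L, ts[1L], ts[2L], adj)
    return(sum(ind) / pattern$automorphisms)
  }
  dup <- unique(ts[duplicated(ts)])
  if (length(dup) == 0L) {
    # three distinct types; sum over the third role's nodes
    roles <- seq_len(3L)
    # fix roles of types C, M, G by position in ts
    rC <- which(ts == "C"); rM <- which(ts == "M"); rG <- which(ts == "G")
    S_cm <- role_pair_indicator(pattern, rC, rM, "C", "M", adj)
    X <- role_pair_indicator(pattern, rC, rG, "C", "G", adj)
    Y <- role_pair_indicator(pattern, rM, rG, "M", "G", adj)
    return(sum(S_cm * (X %*% t(Y))) / pattern$automorphisms)
  }
  # two nodes of the duplicated type, one of the other type
  tdup <- dup[1L]
  other_role <- which(ts != tdup)
  tother <- ts[other_role]
  dup_roles <- which(ts == tdup)
  R1 <- role_pair_indicator(pattern, dup_roles[1L], other_role, tdup, tother, adj)
  R2 <- role_pair_indicator(pattern, dup_roles[2L], other_role, tdup, tother, adj)
  n1 <- colSums(R1)
  n2 <- colSums(R2)
  n12 <- colSums(R1 * R2)
  if (pattern$automorphisms == 2L) {
    # the two duplicated roles have identical requirements; unordered pairs
    return(sum(n1 * (n1 - 1) / 2))
  }
  sum(n1 * n2 - n12)
}

#' Census of regulation patterns in a network
#'
#' Counts, for each catalog pattern, the number of distinct subgraph
#' occurrences: injective type-respecting node assignments in which every
#' pattern edge is present (extra edges are allowed, i.e. subgraph rather
#' than induced matching), divided by the pattern's automorphism count.
#'
#' @param network a [regulatory_network()].
#' @param catalog pattern catalog from [generate_pattern_catalog()].
#' @return named numeric vector of counts, names are pattern IDs.
#' @export
count_patterns <- function(network, catalog = generate_pattern_catalog()) {
  adj <- network_adjacency(network)
  counts <- vapply(catalog, function(p) count_one_pattern(p, adj), numeric(1L))
  names(counts) <- vapply(catalog, `[[`, "", "pattern_id")
  counts
}

# ---- edge-swap null -------------------------------------------------------

#' Degree-preserving randomization of a network
#'
#' Repeated double-edge swaps within each edge type independently:
#' `(a -> b, c -> d)` becomes `(a -> d, c -> b)`, rejecting swaps that would
#' create duplicate edges.  Every node keeps its in- and out-degree for
#' every edge type, and every edge-type count is preserved, so the random
#' networks have the same numbers of CRM-gene, miRNA-gene and CRM-miRNA
#' interaction pairs as the real one.
#'
#' @param network a [regulatory_network()].
#' @param seed integer seed.
#' @param swaps_per_edge attempted swaps per edge within each type
#'   (default 10).
#' @return a randomized [regulatory_network()].
#' @export
random_network <- function(network, seed = 1L, swaps_per_edge = 10L) {
  with_seed(seed, {
    parts <- lapply(EDGE_TYPES, function(et) {
      e <- network$edges[network$edges$type == et, , drop = FALSE]
      n_e <- nrow(e)
      if (n_e < 2L) return(e)
      src <- e$source
      dst <- e$target
      keys <- new.env(hash = TRUE, parent = emptyenv())
      for (k in seq_len(n_e)) assign(paste0(src[k], "\r", dst[k]), TRUE, keys)
      n_try <- swaps_per_edge * n_e
      for (t in seq_len(n_try)) {
        # draw with replacement: the resulting random number of accepted
        # swaps mixes over both parities of the target permutation
        i <- sample.int(n_e, 1L)
        j <- sample.int(n_e, 1L)
        if (i == j || src[i] == src[j] || dst[i] == dst[j]) next
        k1 <- paste0(src[i], "\r", dst[j])
        k2 <- paste0(src[j], "\r", dst[i])
        if (exists(k1, keys, inherits = FALSE) ||
            exists(k2, keys, inherits = FALSE)) next
        rm(list = c(paste0(src[i], "\r", dst[i]), paste0(src[j], "\r", dst[j])),
           envir = keys)
        assign(k1, TRUE, keys)
        assign(k2, TRUE, keys)
        tmp <- dst[i]; dst[i] <- dst[j]; dst[j] <- tmp
      }
      data.frame(source = src, target = dst, type = et)
    })
    regulatory_network(do.call(rbind, parts))
  })
}

#' Pattern significance against edge-swap null networks
#'
#' Compares each pattern's observed count with its counts in `n_random`
#' degree-preserving random networks.  The Z-score is the observed count
#' minus the mean random count, normalized by the standard deviation of the
#' random counts; when that standard deviation is zero the Z-score is
#' undefined and reported as `NA`.
#'
#' @param network a [regulatory_network()].
#' @param catalog pattern catalog from [generate_pattern_catalog()].
#' @param n_random number of random networks (default 100).
#' @param seed integer seed; per-network seeds are derived from it.
#' @param swaps_per_edge swaps per edge for each randomization.
#' @return data frame with columns `pattern_id`, `name`, `observed`,
#'   `null_mean`, `null_sd`, `z`.
#' @export
pattern_zscores <- function(network, catalog = generate_pattern_catalog(),
                            n_random = 100L, seed = 1L, swaps_per_edge = 10L) {
  observed <- count_patterns(network, catalog)
  rand <- matrix(0, n_random, length(catalog))
  for (r in seq_len(n_random)) {
    rn <- random_network(network, seed = child_seed(seed, r),
                         swaps_per_edge = swaps_per_edge)
    rand[r, ] <- count_patterns(rn, catalog)
  }
  null_mean <- colMeans(rand)
  null_sd <- apply(rand, 2L, sd)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  data.frame(pattern_id = names(observed),
             name = vapply(catalog, `[[`, "", "name"),
             observed = unname(observed),
             null_mean = null_mean,
             null_sd = null_sd,
             z = round(z, 4L))
}
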