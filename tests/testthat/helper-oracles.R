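# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Mean of max-over-probeset-pair Pearson correlations over all unordered
# gene pairs, via explicit double loops.
oracle_coherence <- function(expr, genes) {
  genes <- intersect(genes, names(expr$gene_index))
  if (length(genes) < 2L) return(NA_real_)
  vals <- c()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (j <= i) next
      vals <- c(vals, oracle_gene_cor(expr, genes[i], genes[j]))
    }
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

oracle_gene_cor <- function(expr, a, b) {
  rows_a <- which(!is.na(expr$probeset_to_gene) & expr$probeset_to_gene == a)
  rows_b <- which(!is.na(expr$probeset_to_gene) & expr$probeset_to_gene == b)
  best <- NA_real_
  for (i in rows_a) {
    for (j in rows_b) {
      x <- expr$values[i, ]
      y <- expr$values[j, ]
      if (sd(x) == 0 || sd(y) == 0) next
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      if (is.na(best) || r > best) best <- r
    }
  }
  best
}

# Sort-based Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  ro <- order(ord)
  q <- pmin(1, cummin(m / (m:1) * p[ord]))[ro]
  q
}

# Per-window scan by direct substring scoring on both strands.
oracle_scan <- function(pwm, seq, cutoff, config) {
  L <- crmmir::pwm_length(pwm)
  n <- nchar(seq) - L + 1L
  out <- data.frame(start = integer(0), strand = character(0),
                    score = numeric(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  for (s in seq_len(n)) {
    win <- substr(seq, s, s + L - 1L)
    sc <- crmmir::score_site(pwm, win, config)
    if (sc > cutoff) {
      out <- rbind(out, data.frame(start = s - 1L, strand = "+", score = sc))
    }
    if (config$both_strands) {
      # forward-coordinate start s-1 corresponds to rc window at n - s
      win_rc <- substr(rc, nchar(seq) - (s - 1L) - L + 1L, nchar(seq) - (s - 1L))
      sc2 <- crmmir::score_site(pwm, win_rc, config)
      if (sc2 > cutoff) {
        out <- rbind(out, data.frame(start = s - 1L, strand = "-", score = sc2))
      }
    }
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# Exhaustive pattern census by enumerating injective node assignments.
oracle_count_patterns <- function(network, catalog) {
  has_edge <- function(src, dst, type) {
    any(network$edges$source == src & network$edges$target == dst &
          network$edges$type == type)
  }
  ids_by_type <- list(C = names(network$nodes)[network$nodes == "C"],
                      M = names(network$nodes)[network$nodes == "M"],
                      G = names(network$nodes)[network$nodes == "G"])
  counts <- numeric(length(catalog))
  names(counts) <- vapply(catalog, `[[`, "", "pattern_id")
  for (k in seq_along(catalog)) {
    pat <- catalog[[k]]
    pools <- lapply(pat$node_types, function(t) ids_by_type[[t]])
    if (any(lengths(pools) == 0L)) next
    grid <- expand.grid(pools, stringsAsFactors = FALSE)
    total <- 0
    for (row in seq_len(nrow(grid))) {
      nodes <- as.character(grid[row, ])
      if (anyDuplicated(nodes)) next
      ok <- TRUE
      for (e in seq_len(nrow(pat$edges))) {
        if (!has_edge(nodes[pat$edges$from[e]], nodes[pat$edges$to[e]],
                      pat$edges$type[e])) {
          ok <- FALSE
          break
        }
      }
      if (ok) total <- total + 1
    }
    counts[k] <- total / pat$automorphisms
  }
  counts
}

# OLS estimate, standard errors and two-sided t-test p-values from the
# normal equations.
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  n <- nrow(X)
  p <- ncol(X)
  s2 <- sum(resid^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)
  list(beta = as.numeric(beta), se = as.numeric(se), p = as.numeric(pval),
       rss = sum(resid^2))
}

# Per-edge-type in/out degree tables of a network.
degree_tables <- function(network) {
  lapply(split(network$edges, network$edges$type), function(e) {
    list(out = table(e$source), incoming = table(e$target))
  })
}

# Does the dendrogram contain a cluster whose members are exactly `genes`?
has_exact_cluster <- function(hc, genes) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get_side <- function(v) if (v < 0) hc$labels[-v] else members[[v]]
    members[[i]] <- c(get_side(hc$merge[i, 1L]), get_side(hc$merge[i, 2L]))
  }
  any(vapply(members, function(m) setequal(m, genes), logical(1L)))
}

make_expr <- function(values, map = NULL) {
  if (is.null(map)) {
    map <- setNames(rownames(values), rownames(values))
  }
  crmmir::expression_matrix(values, map)
}
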