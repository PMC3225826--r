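# Seeded generators for every input the pipeline consumes, with ground
# truth, so each stage is testable without external downloads.  The
# co-expression model is an equicorrelated Gaussian per planted block (the
# pipeline only consumes pairwise Pearson correlations, so this is the
# minimal sufficient structure); miRNA out-degrees follow a discretized
# power law by default; planted binding sites are sampled from the PWM.

#' Generate block-correlated expression data
#'
#' Genes inside a planted block share a latent factor so that every pair
#' has correlation `rho` (equicorrelated Gaussian); remaining genes are
#' independent.  Each gene gets `probesets_per_gene` probesets: the first
#' carries measurement noise `noise_sd`, additional ones the larger
#' `extra_probeset_noise_sd`, to exercise the max-over-probesets rule.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples.
#' @param blocks list of `list(size =, rho =)` planted blocks; sizes must
#'   sum to at most `n_genes`, each `rho` in \[0, 1).
#' @param noise_sd measurement noise sd of the primary probeset
#'   (default 0.1; latent profiles have unit variance).
#' @param seed integer seed.
#' @param probesets_per_gene probesets per gene (default 1).
#' @param extra_probeset_noise_sd noise sd of additional probesets
#'   (default 0.5).
#' @return list with `expr` (an [expression_matrix()]) and `truth` (list
#'   with `planted_blocks`: list of `list(genes, rho)`).
#' @export
gen_expression <- function(n_genes, n_samples, blocks = list(),
                           noise_sd = 0.1, seed = 1L,
                           probesets_per_gene = 1L,
                           extra_probeset_noise_sd = 0.5) {
  sizes <- vapply(blocks, function(b) as.integer(b$size), integer(1L))
  rhos <- vapply(blocks, function(b) as.numeric(b$rho), numeric(1L))
  if (any(rhos < 0 | rhos >= 1)) {
    stop("block `rho` must lie in [0, 1)", call. = FALSE)
  }
  if (sum(sizes) > n_genes) {
    stop("block sizes exceed `n_genes`", call. = FALSE)
  }
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- sprintf("s%03d", seq_len(n_samples))
    latent <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    planted <- list()
    offset <- 0L
    for (b in seq_along(blocks)) {
      members <- (offset + 1L):(offset + sizes[b])
      common <- rnorm(n_samples)
      for (g in members) {
        latent[g, ] <- sqrt(rhos[b]) * common + sqrt(1 - rhos[b]) * rnorm(n_samples)
      }
      planted[[b]] <- list(genes = genes[members], rho = rhos[b])
      offset <- offset + sizes[b]
    }
    n_ps <- n_genes * probesets_per_gene
    values <- matrix(0, n_ps, n_samples)
    ps_ids <- character(n_ps)
    ps_gene <- character(n_ps)
    row <- 0L
    for (g in seq_len(n_genes)) {
      for (k in seq_len(probesets_per_gene)) {
        row <- row + 1L
        sdk <- if (k == 1L) noise_sd else extra_probeset_noise_sd
        values[row, ] <- latent[g, ] + rnorm(n_samples, sd = sdk)
        ps_ids[row] <- sprintf("%s_at%d", genes[g], k)
        ps_gene[row] <- genes[g]
      }
    }
    rownames(values) <- ps_ids
    colnames(values) <- samples
    expr <- expression_matrix(values, setNames(ps_gene, ps_ids))
    list(expr = expr, truth = list(planted_blocks = planted))
  })
}

# Sample one out-degree from a degree law spec.
sample_degree <- function(law, universe_size) {
  if (law$type == "fixed") return(as.integer(law$k))
  if (law$type == "uniform") {
    return(sample(law$min:law$max, 1L))
  }
  if (law$type == "powerlaw") {
    k <- law$kmin:law$kmax
    p <- k^(-law$alpha)
    return(sample(k, 1L, prob = p / sum(p)))
  }
  stop(sprintf("unknown degree law '%s'", law$type), call. = FALSE)
}

#' Generate CRM and miRNA target maps
#'
#' CRM out-degrees are uniform on `crm_degree_range`; miRNA out-degrees
#' follow `mirna_degree_law` (default a discretized power law, giving the
#' heavy-tailed target-number distribution the randomization tests
#' preserve).  `overlap_spec` forces chosen CRM-miRNA pairs to share a
#' planted gene set, so the pair's module is genuinely co-regulated.
#'
#' @param n_crms,n_mirnas numbers of regulators.
#' @param gene_universe character vector of gene IDs.
#' @param crm_degree_range length-2 integer vector (min, max targets).
#' @param mirna_degree_law list: `list(type = "powerlaw", alpha, kmin,
#'   kmax)`, `list(type = "uniform", min, max)`, or
#'   `list(type = "fixed", k)`.
#' @param overlap_spec list of `list(crm =, mirna =, genes =)` entries
#'   (IDs `crm###` / `mir###`) planting `genes` into both target sets.
#' @param seed integer seed.
#' @return list with `crm_targets`, `mirna_targets` ([target_map()]s) and
#'   `truth` (list with `planted_overlaps`).
#' @export
gen_target_maps <- function(n_crms, n_mirnas, gene_universe,
                            crm_degree_range = c(10L, 40L),
                            mirna_degree_law = list(type = "powerlaw",
                                                    alpha = 1.5, kmin = 5L,
                                                    kmax = 60L),
                            overlap_spec = list(), seed = 1L) {
  n_u <- length(gene_universe)
  max_deg <- max(crm_degree_range[2L],
                 switch(mirna_degree_law$type,
                        fixed = mirna_degree_law$k,
                        uniform = mirna_degree_law$max,
                        powerlaw = mirna_degree_law$kmax))
  if (max_deg > n_u) {
    stop("requested degree exceeds the gene universe size", call. = FALSE)
  }
  with_seed(seed, {
    crm_ids <- sprintf("crm%03d", seq_len(n_crms))
    mir_ids <- sprintf("mir%03d", seq_len(n_mirnas))
    crm_entries <- lapply(crm_ids, function(cid) {
      sample(gene_universe, sample(crm_degree_range[1L]:crm_degree_range[2L], 1L))
    })
    names(crm_entries) <- crm_ids
    mir_entries <- lapply(mir_ids, function(mid) {
      sample(gene_universe, sample_degree(mirna_degree_law, n_u))
    })
    names(mir_entries) <- mir_ids
    for (ov in overlap_spec) {
      if (!ov$crm %in% crm_ids || !ov$mirna %in% mir_ids) {
        stop("overlap_spec refers to an unknown regulator", call. = FALSE)
      }
      crm_entries[[ov$crm]] <- unique(c(crm_entries[[ov$crm]], ov$genes))
      mir_entries[[ov$mirna]] <- unique(c(mir_entries[[ov$mirna]], ov$genes))
    }
    list(crm_targets = target_map(crm_entries, "CRM"),
         mirna_targets = target_map(mir_entries, "MIRNA"),
         truth = list(planted_overlaps = overlap_spec))
  })
}

#' Generate random PWMs
#'
#' Each column is a Dirichlet draw with concentration `sharp` on one
#' random dominant base and `diffuse` on the others, giving
#' information-rich motifs of the kind TF databases contain.
#'
#' @param n number of PWMs.
#' @param length_range length-2 integer vector of motif lengths.
#' @param sharp,diffuse Dirichlet concentrations of the dominant and the
#'   other bases (defaults 25 and 0.25, about 0.97 expected dominant
#'   probability, roughly 1.7 bits per position as in curated TF motif
#'   collections).
#' @param seed integer seed.
#' @return named list of [pwm()]s with IDs `M001`, `M002`, ...
#' @export
gen_pwms <- function(n, length_range = c(8L, 12L), sharp = 25, diffuse = 0.25,
                     seed = 1L) {
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n)) {
      L <- sample(length_range[1L]:length_range[2L], 1L)
      probs <- vapply(seq_len(L), function(j) {
        alpha <- rep(diffuse, 4L)
        alpha[sample.int(4L, 1L)] <- sharp
        x <- rgamma(4L, shape = alpha)
        x / sum(x)
      }, numeric(4L))
      id <- sprintf("M%03d", i)
      out[[id]] <- pwm(id, probs)
    }
    out
  })
}

# Sample one site (character string) from a PWM, or its consensus.
sample_site <- function(pwm, consensus = FALSE) {
  L <- pwm_length(pwm)
  vapply(seq_len(L), function(j) {
    p <- pwm$probs[, j]
    if (consensus) DNA_BASES[which.max(p)]
    else sample(DNA_BASES, 1L, prob = p)
  }, character(1L)) |> paste(collapse = "")
}

#' Generate upstream sequences with planted motif sites
#'
#' Background bases are i.i.d. from `background_freqs`.  For each planting
#' directive, one site per listed motif is placed (sampled from the PWM,
#' or its consensus) so that all sites fall inside a window of
#' `cluster_width` bases, without overlapping each other; positions and
#' strands are recorded in the truth object.
#'
#' @param pwms named list of [pwm()]s.
#' @param n_seqs number of sequences; IDs `mir001`, ... (one upstream
#'   region per pri-miRNA).
#' @param length sequence length in bases (default 5000, the upstream
#'   window the scan assumes).
#' @param planting list of `list(seq =, motifs =, cluster_width = 200)`
#'   directives (seq is a sequence ID).
#' @param background_freqs base probabilities (A, C, G, T).
#' @param seed integer seed.
#' @param consensus plant consensus rather than PWM-sampled sites.
#' @return list with `seqs` (named character vector) and `truth` (list
#'   with `planted_sites`: data frame seq_id, motif_id, start (0-based),
#'   strand).
#' @export
gen_upstream_sequences <- function(pwms, n_seqs, length = 5000L,
                                   planting = list(),
                                   background_freqs = rep(0.25, 4),
                                   seed = 1L, consensus = FALSE) {
  with_seed(seed, {
    ids <- sprintf("mir%03d", seq_len(n_seqs))
    seqs <- vapply(ids, function(i)
      paste(sample(DNA_BASES, length, replace = TRUE, prob = background_freqs),
            collapse = ""), character(1L))
    truth <- data.frame(seq_id = character(0), motif_id = character(0),
                        start = integer(0), strand = character(0))
    for (pl in planting) {
      sid <- pl$seq
      if (!sid %in% ids) stop(sprintf("unknown sequence '%s'", sid), call. = FALSE)
      width <- as.integer(pl$cluster_width %||% 200L)
      motifs <- pl$motifs
      lens <- vapply(pwms[motifs], pwm_length, integer(1L))
      if (any(lens > width)) {
        stop("cluster_width smaller than a motif length", call. = FALSE)
      }
      if (sum(lens) > width) {
        stop("motifs cannot fit without overlap in the cluster window",
             call. = FALSE)
      }
      if (width > length) stop("cluster window exceeds sequence length", call. = FALSE)
      win_start <- sample.int(length - width + 1L, 1L) - 1L   # 0-based
      # distribute the slack among the gaps before/between sites
      slack <- width - sum(lens)
      k <- length(motifs)
      gaps <- as.integer(rmultinom(1L, slack, rep(1 / (k + 1L), k + 1L)))
      order_m <- sample(motifs)
      pos <- win_start
      chars <- strsplit(seqs[[sid]], "", fixed = TRUE)[[1L]]
      for (t in seq_along(order_m)) {
        m <- order_m[t]
        pos <- pos + gaps[t]
        site <- sample_site(pwms[[m]], consensus = consensus)
        strand <- sample(c("+", "-"), 1L)
        planted_seq <- if (strand == "+") site else reverse_complement(site)
        L <- nchar(site)
        chars[(pos + 1L):(pos + L)] <- strsplit(planted_seq, "", fixed = TRUE)[[1L]]
        truth <- rbind(truth, data.frame(seq_id = sid, motif_id = m,
                                         start = pos, strand = strand))
        pos <- pos + L
      }
      seqs[[sid]] <- paste(chars, collapse = "")
    }
    list(seqs = seqs, truth = list(planted_sites = truth))
  })
}

#' Generate knockdown log-ratios from the linear co-regulation model
#'
#' Log-ratios follow
#' `g = c + a_TF b_TF + sum_i a_mir_i b_mir_i + N(0, noise_sd^2)`, with
#' indicators derived from the supplied target sets.
#'
#' @param tf_targets character vector of TF target genes.
#' @param mirna_targets a [target_map()] of miRNA targets.
#' @param a_tf TF effect size.
#' @param a_mir named numeric vector of miRNA effects; names must be
#'   miRNAs of `mirna_targets` (miRNAs absent from the names have zero
#'   effect).
#' @param c intercept (default 0).
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @param genes gene universe (default: union of all target genes).
#' @return list with `data` (a [knockdown_dataset()]) and `truth` (list
#'   with `active_mirnas`, `coefficients`).
#' @export
gen_knockdown <- function(tf_targets, mirna_targets, a_tf, a_mir = numeric(0),
                          c = 0, noise_sd = 0.3, seed = 1L, genes = NULL) {
  stopifnot(inherits(mirna_targets, "target_map"))
  bad <- setdiff(names(a_mir), names(mirna_targets$entries))
  if (length(bad) > 0L) {
    stop(sprintf("effect given for miRNA(s) absent from the target map: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- sort(unique(c(tf_targets,
                           unlist(mirna_targets$entries, use.names = FALSE))))
  }
  with_seed(seed, {
    data <- knockdown_dataset(genes, rep(0, length(genes)), tf_targets,
                              mirna_targets)
    mu <- c + a_tf * data$b_tf
    if (length(a_mir) > 0L) {
      mu <- mu + as.numeric(data$b_mir[, names(a_mir), drop = FALSE] %*% a_mir)
    }
    data$g <- mu + rnorm(length(genes), sd = noise_sd)
    truth <- list(active_mirnas = names(a_mir)[a_mir != 0],
                  coefficients = as.list(c(intercept = unname(c),
                                           a_tf = unname(a_tf), a_mir)))
    list(data = data, truth = truth)
  })
}

#' Generate a random tripartite regulatory network
#'
#' Each allowed edge type is sampled independently with its own Bernoulli
#' probability; planted feed-forward loops add the triple
#' (C->M, C->G, M->G) on fresh node triples.
#'
#' @param n_crms,n_mirnas,n_genes numbers of background nodes per type.
#' @param edge_probs list with elements `c2g`, `m2g`, `c2m`, `m2c`
#'   (Bernoulli probabilities; missing elements default to 0).
#' @param planted_ffl_count number of planted FFL triples (default 0).
#' @param seed integer seed.
#' @return list with `network` (a [regulatory_network()]) and `truth`
#'   (list with `planted_ffls`: data frame crm_id, mirna_id, gene_id).
#' @export
gen_network <- function(n_crms, n_mirnas, n_genes,
                        edge_probs = list(), planted_ffl_count = 0L,
                        seed = 1L) {
  p <- list(c2g = edge_probs$c2g %||% 0, m2g = edge_probs$m2g %||% 0,
            c2m = edge_probs$c2m %||% 0, m2c = edge_probs$m2c %||% 0)
  with_seed(seed, {
    crm_ids <- sprintf("crm%03d", seq_len(n_crms))
    mir_ids <- sprintf("mir%03d", seq_len(n_mirnas))
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    bip <- function(from, to, prob, type) {
      if (prob <= 0 || length(from) == 0L || length(to) == 0L) {
        return(data.frame(source = character(0), target = character(0),
                          type = character(0)))
      }
      hit <- which(matrix(runif(length(from) * length(to)), length(from)) < prob,
                   arr.ind = TRUE)
      data.frame(source = from[hit[, 1L]], target = to[hit[, 2L]],
                 type = rep(type, nrow(hit)))
    }
    edges <- rbind(bip(crm_ids, gene_ids, p$c2g, "C2G"),
                   bip(mir_ids, gene_ids, p$m2g, "M2G"),
                   bip(crm_ids, mir_ids, p$c2m, "C2M"),
                   bip(mir_ids, crm_ids, p$m2c, "M2C"))
    ffls <- data.frame(crm_id = character(0), mirna_id = character(0),
                       gene_id = character(0))
    if (planted_ffl_count > 0L) {
      fc <- sprintf("crmF%03d", seq_len(planted_ffl_count))
      fm <- sprintf("mirF%03d", seq_len(planted_ffl_count))
      fg <- sprintf("gF%04d", seq_len(planted_ffl_count))
      edges <- rbind(edges,
                     data.frame(source = fc, target = fm, type = "C2M"),
                     data.frame(source = fc, target = fg, type = "C2G"),
                     data.frame(source = fm, target = fg, type = "M2G"))
      ffls <- data.frame(crm_id = fc, mirna_id = fm, gene_id = fg)
    }
    list(network = regulatory_network(edges),
         truth = list(planted_ffls = ffls))
  })
}
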