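# End-to-end orchestration: a seeded synthetic fixture writer and a
# pipeline runner that wires the stages together and records a manifest.
# Identical configuration and seeds produce byte-identical outputs.

#' Write a complete synthetic input fixture
#'
#' Generates every input the pipeline needs with the statistical structure
#' the analysis assumes -- block-correlated expression, heavy-tailed
#' miRNA target maps with planted CRM-miRNA overlaps, PWMs, upstream
#' sequences with motif sites planted within the cluster window,
#' motif-to-TF-gene and host-gene maps, and knockdown log-ratios from the
#' linear model -- and writes them to `dir` in the pipeline's text formats,
#' together with a ground-truth JSON.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param n_genes,n_samples expression dimensions.
#' @param n_crms,n_mirnas regulator counts.
#' @param n_blocks number of planted co-expression blocks (each of size
#'   `block_size`, correlation `block_rho`); block b is planted as the
#'   overlap of CRM b and miRNA b.
#' @param block_size,block_rho planted block geometry.
#' @return invisibly, a named list of the written file paths plus `truth`.
#' @export
simulate_fixture <- function(dir, seed = 1L, n_genes = 300L, n_samples = 40L,
                             n_crms = 8L, n_mirnas = 6L, n_blocks = 3L,
                             block_size = 8L, block_rho = 0.9) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  blocks <- rep(list(list(size = block_size, rho = block_rho)), n_blocks)
  ex <- gen_expression(n_genes, n_samples, blocks, seed = child_seed(seed, 1))
  overlap <- lapply(seq_len(n_blocks), function(b) {
    list(crm = sprintf("crm%03d", b), mirna = sprintf("mir%03d", b),
         genes = ex$truth$planted_blocks[[b]]$genes)
  })
  tm <- gen_target_maps(n_crms, n_mirnas, genes,
                        overlap_spec = overlap, seed = child_seed(seed, 2))
  pwms <- gen_pwms(6L, seed = child_seed(seed, 3))
  pwm_ids <- names(pwms)
  crm_ids <- names(tm$crm_targets$entries)
  crm_defs <- with_seed(child_seed(seed, 4), {
    defs <- lapply(crm_ids, function(cid)
      sort(sample(pwm_ids, sample(2:3, 1L))))
    names(defs) <- crm_ids
    defs
  })
  # plant the motif sites of CRM b upstream of miRNA b, clustered in 200 bp
  planting <- lapply(seq_len(min(n_blocks, n_mirnas)), function(b)
    list(seq = sprintf("mir%03d", b), motifs = crm_defs[[sprintf("crm%03d", b)]],
         cluster_width = 200L))
  up <- gen_upstream_sequences(pwms, n_mirnas, planting = planting,
                               seed = child_seed(seed, 5))
  # each motif binds one TF gene drawn from the universe
  pwm_gene_map <- with_seed(child_seed(seed, 6), {
    m <- lapply(pwm_ids, function(x) sample(genes, 1L))
    names(m) <- pwm_ids
    m
  })
  # hosted miRNAs: the first n_blocks miRNAs sit in introns of genes targeted
  # by the CRM that also regulates them upstream, the rest in random genes
  host_map <- with_seed(child_seed(seed, 7), {
    mir_ids <- names(tm$mirna_targets$entries)
    hosts <- sample(genes, n_mirnas)
    for (b in seq_len(min(n_blocks, n_mirnas))) {
      hosts[b] <- sample(tm$crm_targets$entries[[sprintf("crm%03d", b)]], 1L)
    }
    setNames(hosts, mir_ids)
  })
  active <- head(names(tm$mirna_targets$entries), 2L)
  kd <- gen_knockdown(tf_targets = tm$crm_targets$entries[[1L]],
                      mirna_targets = tm$mirna_targets,
                      a_tf = -0.8,
                      a_mir = setNames(c(0.6, -0.7), active),
                      c = 0.05, noise_sd = 0.3,
                      seed = child_seed(seed, 8), genes = genes)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    gene_map = file.path(dir, "probeset_gene_map.tsv"),
    crm_targets = file.path(dir, "crm_targets.tsv"),
    mirna_targets = file.path(dir, "mirna_targets.tsv"),
    pwms = file.path(dir, "pwms.txt"),
    crm_definitions = file.path(dir, "crm_definitions.tsv"),
    upstream = file.path(dir, "upstream.fasta"),
    pwm_gene_map = file.path(dir, "pwm_gene_map.tsv"),
    host_map = file.path(dir, "host_genes.tsv"),
    logratios = file.path(dir, "knockdown_logratios.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression_matrix(ex$expr, paths$expression, paths$gene_map)
  write_target_map(tm$crm_targets, paths$crm_targets)
  write_target_map(tm$mirna_targets, paths$mirna_targets)
  write_pwms(pwms, paths$pwms)
  write_crm_definitions(crm_defs, paths$crm_definitions)
  write_fasta(up$seqs, paths$upstream)
  write.table(data.frame(motif = rep(names(pwm_gene_map),
                                     lengths(pwm_gene_map)),
                         gene = unlist(pwm_gene_map, use.names = FALSE)),
              paths$pwm_gene_map, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(mirna = names(host_map), gene = unname(host_map)),
              paths$host_map, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(gene = kd$data$gene_ids, logratio = kd$data$g),
              paths$logratios, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  truth <- list(expression = ex$truth, targets = tm$truth,
                upstream = up$truth, knockdown = kd$truth,
                tf_targets_crm = crm_ids[1L])
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(truth_data = truth)))
}

PIPELINE_STAGES <- c("simulate", "modules", "coherence", "significance",
                     "scan", "network", "motifs", "knockdown", "hostgenes")

#' Run the combinatorial-regulation pipeline end to end
#'
#' Executes, as requested: fixture simulation (or loading of an existing
#' input directory), module construction, coherence annotation,
#' coherence significance testing, PWM scanning with CRM-to-miRNA edge
#' prediction, network assembly, pattern census with edge-swap Z-scores,
#' the knockdown model, and the host-gene analysis.  A manifest recording
#' seeds, per-stage row counts and output digests is written to
#' `out_dir/manifest.json`; identical configuration and seeds give
#' byte-identical outputs.
#'
#' @param out_dir output directory; inputs are read from (and, when the
#'   simulate stage runs, written to) `out_dir/input`.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param stages character vector of stages to run (default all, in
#'   pipeline order).  Later stages require the outputs of earlier ones.
#' @param n_reps randomization count for coherence p-values (default 100).
#' @param n_random_networks random networks for pattern Z-scores
#'   (default 100).
#' @param scan_cfg a [scan_config()].
#' @param verbose log stage progress to stderr.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, seed = 1L, stages = PIPELINE_STAGES,
                         n_reps = 100L, n_random_networks = 100L,
                         scan_cfg = scan_config(), verbose = FALSE) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  input_dir <- file.path(out_dir, "input")
  log_stage <- function(name) {
    if (verbose) message(sprintf("[%s] running", name))
  }
  manifest <- list(seed = seed,
                   stages = setNames(vector("list", length(PIPELINE_STAGES)),
                                     PIPELINE_STAGES))
  run_stage <- function(name, fun) {
    if (!name %in% stages) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    log_stage(name)
    info <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "done"), info)
    invisible(NULL)
  }
  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    simulate_fixture(input_dir, seed = seed)
    list(n_files = length(list.files(input_dir)))
  })
  load_inputs <- function() {
    if (is.null(state$expr)) {
      state$expr <- read_expression_matrix(
        file.path(input_dir, "expression.tsv"),
        file.path(input_dir, "probeset_gene_map.tsv"))
      state$crm_targets <- read_target_map(
        file.path(input_dir, "crm_targets.tsv"), "CRM")
      state$mirna_targets <- read_target_map(
        file.path(input_dir, "mirna_targets.tsv"), "MIRNA")
      state$pwms <- read_pwms(file.path(input_dir, "pwms.txt"))
      state$crm_defs <- read_crm_definitions(
        file.path(input_dir, "crm_definitions.tsv"))
      state$upstream <- read_fasta(file.path(input_dir, "upstream.fasta"))
      state$pwm_gene_map <- read_pwm_gene_map(
        file.path(input_dir, "pwm_gene_map.tsv"))
      host <- read_tsv_pairs(file.path(input_dir, "host_genes.tsv"))
      state$host_map <- setNames(host$V2, host$V1)
      state$logratios <- read_logratios(
        file.path(input_dir, "knockdown_logratios.tsv"))
    }
  }
  run_stage("modules", function() {
    load_inputs()
    state$modules <- build_modules(state$crm_targets, state$mirna_targets)
    write_modules_table(state$modules, file.path(out_dir, "modules.tsv"))
    list(n_modules = nrow(state$modules))
  })
  run_stage("coherence", function() {
    load_inputs()
    state$modules <- module_coherences(state$modules, state$expr)
    write_modules_table(state$modules, file.path(out_dir, "modules.tsv"))
    list(n_with_coherence = sum(!is.na(state$modules$coherence)))
  })
  run_stage("significance", function() {
    load_inputs()
    bg <- background_spec("BG1_CRM_POOL", n_reps = n_reps,
                          seed = child_seed(seed, 11))
    state$modules <- test_module_coherence(state$modules, state$expr, bg,
                                           state$crm_targets,
                                           state$mirna_targets)
    write_modules_table(state$modules, file.path(out_dir, "modules.tsv"))
    list(n_significant_p05 = sum(state$modules$p_value <= 0.05, na.rm = TRUE))
  })
  run_stage("scan", function() {
    load_inputs()
    cutoffs <- calibrate_cutoffs(state$pwms, scan_cfg,
                                 seed = child_seed(seed, 12))
    hits <- scan_sequences(state$pwms, state$upstream, cutoffs, scan_cfg)
    hits_out <- hits
    hits_out$start <- hits_out$start + 1L   # 1-based in TSV output
    write.table(hits_out, file.path(out_dir, "hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$c2m <- predict_crm_mirna_edges(state$crm_defs, state$upstream,
                                         state$pwms, scan_cfg,
                                         cutoffs = cutoffs)
    write.table(state$c2m, file.path(out_dir, "c2m_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(n_hits = nrow(hits), n_c2m_edges = nrow(state$c2m))
  })
  run_stage("network", function() {
    load_inputs()
    state$m2c <- derive_mirna_crm_edges(state$mirna_targets, state$crm_defs,
                                        state$pwm_gene_map)
    state$network <- build_network(state$crm_targets, state$mirna_targets,
                                   state$c2m, state$m2c)
    write_edge_list(state$network, file.path(out_dir, "network_edges.tsv"))
    list(n_nodes = length(state$network$nodes),
         n_edges = nrow(state$network$edges),
         n_m2c_edges = nrow(state$m2c))
  })
  run_stage("motifs", function() {
    catalog <- generate_pattern_catalog()
    stats <- pattern_zscores(state$network, catalog,
                             n_random = n_random_networks,
                             seed = child_seed(seed, 13))
    write.table(stats, file.path(out_dir, "pattern_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(n_patterns = nrow(stats))
  })
  run_stage("knockdown", function() {
    load_inputs()
    tf_crm <- names(state$crm_targets$entries)[1L]
    kd <- knockdown_dataset(names(state$logratios), state$logratios,
                            state$crm_targets$entries[[tf_crm]],
                            state$mirna_targets)
    fit <- select_mirna_regulators(kd)
    sel <- fit$coefficients
    write.table(data.frame(term = rownames(sel), sel, check.names = FALSE),
                file.path(out_dir, "knockdown_fit.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$kd_fit <- fit
    list(n_selected = length(fit$selected), aic = fit$aic)
  })
  run_stage("hostgenes", function() {
    load_inputs()
    hg <- shared_crm_hostgenes(state$host_map, state$c2m, state$crm_targets)
    out <- data.frame(mirna_id = hg$mirna_id, host_gene_id = hg$host_gene_id,
                      n_shared_crms = hg$n_shared_crms,
                      shared_crms = vapply(hg$shared_crms, paste,
                                           character(1L), collapse = ","))
    write.table(out, file.path(out_dir, "host_genes_shared.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(n_mirnas = nrow(hg),
         n_with_shared_crm = attr(hg, "n_mirnas_with_shared_crm"))
  })

  outputs <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
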