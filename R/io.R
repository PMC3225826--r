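# Readers and writers for the external formats the pipeline touches.
# Everything is plain text: TSV tables, FASTA sequence files, and
# TRANSFAC-style matrix blocks (see pwm.R).

#' Construct an expression matrix object
#'
#' Bundles a probeset-by-sample value matrix with a partial probeset-to-gene
#' map.  Probesets without a mapped gene are retained but excluded from all
#' gene-level computation.
#'
#' @param values numeric matrix, probesets in rows (rownames required),
#'   samples in columns (colnames required).
#' @param probeset_to_gene named character vector mapping probeset IDs to
#'   gene IDs; probesets absent from the map are kept unmapped.
#' @return an object of class `expression_matrix` with components `values`,
#'   `probeset_to_gene` (aligned to the rows, `NA` where unmapped) and
#'   `gene_index` (list of row indices per gene).
#' @export
expression_matrix <- function(values, probeset_to_gene = character(0)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have probeset rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate probeset IDs in expression matrix", call. = FALSE)
  }
  map <- rep(NA_character_, nrow(values))
  names(map) <- rownames(values)
  hit <- intersect(names(probeset_to_gene), rownames(values))
  map[hit] <- unname(probeset_to_gene[hit])
  genes <- unique(map[!is.na(map)])
  gene_index <- lapply(genes, function(g) which(!is.na(map) & map == g))
  names(gene_index) <- genes
  structure(list(values = values,
                 probeset_to_gene = map,
                 gene_index = gene_index),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probesets x %d samples, %d mapped genes\n",
              nrow(x$values), ncol(x$values), length(x$gene_index)))
  invisible(x)
}

#' Read an expression matrix and probeset-to-gene map from TSV
#'
#' The matrix file is a GEO series-matrix-style TSV: a header row of sample
#' IDs and a first column of probeset IDs.  The gene map is a two-column TSV
#' (probeset, gene); probesets absent from the map are retained unmapped.
#'
#' @param matrix_path path to the expression TSV.
#' @param gene_map_path path to the probeset-to-gene TSV, or `NULL` for no map.
#' @return an [expression_matrix()] object.
#' @export
read_expression_matrix <- function(matrix_path, gene_map_path = NULL) {
  if (!file.exists(matrix_path)) {
    stop(sprintf("file not found: %s", matrix_path), call. = FALSE)
  }
  lines <- readLines(matrix_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop(sprintf("%s: line 1: expected a header row and at least one data row",
                 matrix_path), call. = FALSE)
  }
  nfield <- count.fields(textConnection(lines), sep = "\t", quote = "")
  if (length(unique(nfield)) > 1L) {
    bad <- which(nfield != nfield[1L])[1L]
    stop_format(matrix_path, bad, sprintf(
      "ragged row: %d fields where %d expected", nfield[bad], nfield[1L]))
  }
  tab <- read.delim(textConnection(lines), header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  probesets <- as.character(tab[[1L]])
  if (anyDuplicated(probesets)) {
    stop(sprintf("%s: duplicate probeset ID '%s'", matrix_path,
                 probesets[duplicated(probesets)][1L]), call. = FALSE)
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values)) {
    stop(sprintf("%s: non-numeric expression values", matrix_path), call. = FALSE)
  }
  rownames(values) <- probesets
  map <- character(0)
  if (!is.null(gene_map_path)) {
    pairs <- read_tsv_pairs(gene_map_path)
    map <- setNames(pairs$V2, pairs$V1)
  }
  expression_matrix(values, map)
}

#' Write an expression matrix (and its gene map) to TSV
#'
#' @param expr an [expression_matrix()] object.
#' @param matrix_path output path for the value matrix.
#' @param gene_map_path optional output path for the probeset-to-gene map.
#' @return invisibly, `matrix_path`.
#' @export
write_expression_matrix <- function(expr, matrix_path, gene_map_path = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  tab <- data.frame(probeset = rownames(expr$values), expr$values,
                    check.names = FALSE)
  write.table(tab, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gene_map_path)) {
    mapped <- !is.na(expr$probeset_to_gene)
    write.table(data.frame(probeset = names(expr$probeset_to_gene)[mapped],
                           gene = unname(expr$probeset_to_gene[mapped])),
                gene_map_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(matrix_path)
}

#' Construct a target map
#'
#' A target map associates regulators of one class (CRM, miRNA, or a derived
#' module) with their target-gene sets.
#'
#' @param entries named list of character vectors (regulator ID -> gene IDs).
#' @param regulator_class one of `"CRM"`, `"MIRNA"`, `"MODULE"`.
#' @return an object of class `target_map`.
#' @export
target_map <- function(entries, regulator_class = c("CRM", "MIRNA", "MODULE")) {
  regulator_class <- match.arg(regulator_class)
  if (length(entries) > 0L) {
    if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
      stop("every regulator must have a non-empty ID", call. = FALSE)
    }
    entries <- lapply(entries, function(g) unique(as.character(g)))
  }
  structure(list(regulator_class = regulator_class, entries = entries),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map [%s]: %d regulators, %d distinct target genes\n",
              x$regulator_class, length(x$entries),
              length(unique(unlist(x$entries, use.names = FALSE)))))
  invisible(x)
}

#' Read a regulator-to-target map from a two-column TSV
#'
#' Duplicate (regulator, gene) lines are collapsed into sets.
#'
#' @param path path to a TSV with columns (regulator ID, gene ID).
#' @param regulator_class one of `"CRM"`, `"MIRNA"`, `"MODULE"`.
#' @return a [target_map()].
#' @export
read_target_map <- function(path, regulator_class = c("CRM", "MIRNA", "MODULE")) {
  regulator_class <- match.arg(regulator_class)
  pairs <- read_tsv_pairs(path)
  if (nrow(pairs) == 0L) {
    return(target_map(list(), regulator_class))
  }
  entries <- lapply(split(pairs$V2, pairs$V1), unique)
  target_map(entries, regulator_class)
}

#' Write a target map as a two-column TSV
#'
#' @param map a [target_map()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_target_map <- function(map, path) {
  stopifnot(inherits(map, "target_map"))
  regs <- rep(names(map$entries), lengths(map$entries))
  genes <- unlist(map$entries, use.names = FALSE)
  df <- data.frame(regulator = regs %||% character(0),
                   gene = genes %||% character(0))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read CRM definitions (CRM ID to motif IDs) from TSV
#'
#' @param path two-column TSV (crm_id, motif_id); one row per motif.
#' @return named list of character vectors of motif IDs per CRM.
#' @export
read_crm_definitions <- function(path) {
  pairs <- read_tsv_pairs(path)
  if (nrow(pairs) == 0L) return(list())
  lapply(split(pairs$V2, pairs$V1), unique)
}

#' Write CRM definitions to TSV
#' @param crms named list of motif-ID vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_crm_definitions <- function(crms, path) {
  df <- data.frame(crm_id = rep(names(crms), lengths(crms)),
                   motif_id = unlist(crms, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read DNA sequences from FASTA
#'
#' Sequences are uppercased on read; only A, C, G, T and N are accepted.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are the first word of
#'   each record header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(sprintf("%s: sequence '%s' contains characters outside {A,C,G,T,N}",
                 path, names(seqs)[bad][1L]), call. = FALSE)
  }
  seqs
}

#' Write DNA sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Write a typed edge list to TSV
#'
#' @param network a [regulatory_network()].
#' @param path output path; columns are (source, target, edge_type).
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges[order(network$edges$type, network$edges$source,
                           network$edges$target), , drop = FALSE]
  write.table(data.frame(source = e$source, target = e$target,
                         edge_type = e$type),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a typed edge list written by [write_edge_list()]
#' @param path TSV with header (source, target, edge_type).
#' @return a [regulatory_network()].
#' @export
read_edge_list <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("source", "target", "edge_type") %in% names(tab))) {
    stop(sprintf("%s: expected columns source, target, edge_type", path),
         call. = FALSE)
  }
  regulatory_network(data.frame(source = tab$source, target = tab$target,
                                type = tab$edge_type))
}

#' Write a CRM-miRNA module table to TSV
#'
#' @param modules a module table from [build_modules()] (optionally annotated
#'   with coherence, p and q values).
#' @param path output path; columns (crm_id, mirna_id, n_genes, coherence,
#'   p_value, q_value, gene_ids), genes comma-separated.
#' @return invisibly, `path`.
#' @export
write_modules_table <- function(modules, path) {
  df <- data.frame(
    crm_id = modules$crm_id,
    mirna_id = modules$mirna_id,
    n_genes = modules$n_genes,
    coherence = modules$coherence,
    p_value = modules$p_value,
    q_value = modules$q_value,
    gene_ids = vapply(modules$genes, function(g) paste(sort(g), collapse = ","),
                      character(1L))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module table written by [write_modules_table()]
#' @param path modules TSV.
#' @return a module table data frame with a list column `genes`.
#' @export
read_modules_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tab$genes <- I(strsplit(as.character(tab$gene_ids), ",", fixed = TRUE))
  tab$gene_ids <- NULL
  class(tab) <- c("module_table", "data.frame")
  tab
}

#' Read a knockdown log-ratio vector from TSV
#' @param path two-column TSV (gene ID, log-ratio).
#' @return named numeric vector of per-gene log-ratios.
#' @export
read_logratios <- function(path) {
  pairs <- read_tsv_pairs(path)
  vals <- suppressWarnings(as.numeric(pairs$V2))
  if (anyNA(vals) && nrow(pairs) > 0L) {
    stop(sprintf("%s: non-numeric log-ratio for gene '%s'",
                 path, pairs$V1[which(is.na(vals))[1L]]), call. = FALSE)
  }
  setNames(vals, pairs$V1)
}
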