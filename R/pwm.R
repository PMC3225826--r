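# Position weight matrices: construction and TRANSFAC-dialect text I/O.
# A PWM stores per-position base probabilities; pseudocounting toward the
# background happens at scoring time (scan.R), never here.

#' Construct a position weight matrix
#'
#' @param motif_id motif identifier.
#' @param probs 4 x L numeric matrix of base probabilities, rows in order
#'   A, C, G, T.  Columns that do not sum to 1 are renormalized; all-zero
#'   columns are rejected.
#' @return an object of class `pwm`.
#' @export
pwm <- function(motif_id, probs) {
  if (!is.matrix(probs) || nrow(probs) != 4L || ncol(probs) < 1L) {
    stop("`probs` must be a 4 x L matrix with L >= 1", call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop(sprintf("PWM '%s': probabilities must be finite and non-negative",
                 motif_id), call. = FALSE)
  }
  csums <- colSums(probs)
  if (any(csums == 0)) {
    stop(sprintf("PWM '%s': column %d sums to zero", motif_id,
                 which(csums == 0)[1L]), call. = FALSE)
  }
  probs <- sweep(probs, 2L, csums, "/")
  rownames(probs) <- DNA_BASES
  structure(list(motif_id = as.character(motif_id), probs = probs),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d\n", x$motif_id, ncol(x$probs)))
  invisible(x)
}

#' Length (number of positions) of a PWM
#' @param pwm a [pwm()] object.
#' @return integer motif length.
#' @export
pwm_length <- function(pwm) ncol(pwm$probs)

#' Read PWMs from TRANSFAC-style matrix text
#'
#' Each block is an ID line, a `P0  A  C  G  T` header, numbered position
#' rows of four counts or frequencies, and a `//` terminator.  Counts and
#' frequencies are both accepted; each column is normalized to
#' probabilities by its own sum.
#'
#' @param path path to the matrix text file.
#' @return list of [pwm()] objects, named by motif ID.
#' @export
read_pwms <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  pwms <- list()
  block_id <- NULL
  rows <- list()
  row_lines <- integer(0)
  flush_block <- function(lineno) {
    if (is.null(block_id) && length(rows) == 0L) return(invisible(NULL))
    if (is.null(block_id)) {
      stop_format(path, lineno, "matrix block without an ID line")
    }
    if (length(rows) == 0L) {
      stop_format(path, lineno, sprintf("matrix '%s' has no position rows", block_id))
    }
    probs <- t(do.call(rbind, rows))
    if (any(colSums(probs) == 0)) {
      stop(sprintf("%s: matrix '%s': position %d has all-zero counts",
                   path, block_id, which(colSums(probs) == 0)[1L]), call. = FALSE)
    }
    pwms[[block_id]] <<- pwm(block_id, probs)
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (line == "//") {
      flush_block(i)
      block_id <- NULL
      rows <- list()
      next
    }
    tok <- strsplit(line, "\\s+")[[1L]]
    if (tok[1L] == "ID" || tok[1L] == "NA") {
      if (length(tok) < 2L) stop_format(path, i, "ID line without an identifier")
      block_id <- tok[2L]
      next
    }
    if (tok[1L] == "P0" || tok[1L] == "PO") next   # column header
    if (grepl("^[0-9]+$", tok[1L])) {
      if (length(tok) < 5L) {
        stop_format(path, i, "position row needs 4 values (A C G T)")
      }
      vals <- suppressWarnings(as.numeric(tok[2:5]))
      if (anyNA(vals)) stop_format(path, i, "non-numeric matrix cell")
      rows[[length(rows) + 1L]] <- vals
      next
    }
    if (is.null(block_id) && length(rows) == 0L) {
      # tolerate other TRANSFAC annotation lines (AC, XX, BF, ...) and treat
      # a bare first token before any rows as the motif ID
      if (length(tok) == 1L && !tok[1L] %in% c("AC", "XX", "BF", "CC", "DE")) {
        block_id <- tok[1L]
      }
      next
    }
  }
  flush_block(length(lines))
  pwms
}

#' Write PWMs in the TRANSFAC matrix dialect read by [read_pwms()]
#'
#' Probabilities are written as frequencies with 6 decimal places.
#'
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf("ID %s", p$motif_id), con)
    writeLines("P0      A       C       G       T", con)
    for (j in seq_len(ncol(p$probs))) {
      writeLines(sprintf("%02d  %.6f  %.6f  %.6f  %.6f", j,
                         p$probs[1L, j], p$probs[2L, j],
                         p$probs[3L, j], p$probs[4L, j]), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a motif-to-TF-gene map from TSV
#'
#' Maps each PWM identifier to the gene(s) encoding the transcription
#' factor(s) that bind it; used to derive miRNA-to-CRM edges.
#'
#' @param path two-column TSV (motif ID, TF gene ID).
#' @return named list of character vectors of TF gene IDs per motif.
#' @export
read_pwm_gene_map <- function(path) {
  pairs <- read_tsv_pairs(path)
  if (nrow(pairs) == 0L) return(list())
  lapply(split(pairs$V2, pairs$V1), unique)
}
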