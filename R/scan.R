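# PWM log-likelihood-ratio scanning of pri-miRNA upstream sequences.
# Scores are natural-log odds of the pseudocounted PWM against an i.i.d.
# background; per-motif cutoffs come from the empirical 99.99% quantile of
# a long random sequence; CRM -> miRNA edges require every motif of the CRM
# to hit within one 200 bp window.

#' Scan configuration
#'
#' @param background_freqs probability 4-vector over A, C, G, T used both
#'   as the scoring background and to generate calibration sequence.
#' @param pseudocount_weight blend weight `w` toward the background: a PWM
#'   column `p` is scored as `(1 - w) p + w q`.  Keeps zero-probability
#'   columns finite.  Default 0.01.
#' @param quantile score quantile of random sequence used as the binding
#'   cutoff; default 0.9999 (the 99.99% quantile).
#' @param calibration_length length in bases of the random calibration
#'   sequence; default 1e6.
#' @param both_strands scan forward and reverse-complement strands
#'   (default `TRUE`).
#' @param upstream_length expected upstream sequence length in bases
#'   (default 5000).
#' @param cluster_window maximum span in bases within which all motifs of a
#'   CRM must have binding sites for a CRM-to-miRNA edge (default 200).
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(background_freqs = rep(0.25, 4),
                        pseudocount_weight = 0.01,
                        quantile = 0.9999,
                        calibration_length = 1e6,
                        both_strands = TRUE,
                        upstream_length = 5000L,
                        cluster_window = 200L) {
  if (length(background_freqs) != 4L || any(background_freqs <= 0) ||
      abs(sum(background_freqs) - 1) > 1e-9) {
    stop("`background_freqs` must be 4 positive values summing to 1",
         call. = FALSE)
  }
  if (quantile <= 0 || quantile >= 1) stop("`quantile` must be in (0, 1)", call. = FALSE)
  if (pseudocount_weight < 0) stop("`pseudocount_weight` must be >= 0", call. = FALSE)
  structure(list(background_freqs = setNames(background_freqs, DNA_BASES),
                 pseudocount_weight = pseudocount_weight,
                 quantile = quantile,
                 calibration_length = as.integer(calibration_length),
                 both_strands = isTRUE(both_strands),
                 upstream_length = as.integer(upstream_length),
                 cluster_window = as.integer(cluster_window)),
            class = "scan_config")
}

# Natural-log odds matrix of the pseudocounted PWM against the background;
# 4 x L, rows A,C,G,T.
pwm_log_odds <- function(pwm, config) {
  w <- config$pseudocount_weight
  q <- config$background_freqs
  p <- (1 - w) * pwm$probs + w * q
  log(p / q)
}

# Reverse-complement a PWM: reverse positions, swap A<->T and C<->G.
pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(pwm$probs))), drop = FALSE]
  rownames(probs) <- DNA_BASES
  structure(list(motif_id = pwm$motif_id, probs = probs), class = "pwm")
}

# Scores of all windows of `codes` (integer 1..4, NA for N) under a 4 x L
# log-odds matrix; N contributes 0 at its position.
window_scores <- function(codes, lo) {
  L <- ncol(lo)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  for (j in seq_len(L)) {
    term <- unname(lo[, j])[codes[j:(j + n - 1L)]]
    term[is.na(term)] <- 0
    scores <- scores + term
  }
  scores
}

#' Log-likelihood-ratio score of one site
#'
#' Scores a window of PWM length as the sum over positions of
#' `log(p'_j(base) / q(base))`, where `p'` is the pseudocounted column and
#' `q` the background.  `N` bases contribute 0.
#'
#' @param pwm a [pwm()].
#' @param window DNA string of exactly the PWM's length.
#' @param config a [scan_config()].
#' @return numeric score in natural-log units.
#' @export
score_site <- function(pwm, window, config = scan_config()) {
  codes <- dna_codes(window)
  if (length(codes) != pwm_length(pwm)) {
    stop(sprintf("window length %d does not match PWM length %d",
                 length(codes), pwm_length(pwm)), call. = FALSE)
  }
  window_scores(codes, pwm_log_odds(pwm, config))
}

#' Random background sequence from the configured base frequencies
#'
#' @param length sequence length in bases.
#' @param config a [scan_config()].
#' @param seed integer seed.
#' @return a DNA string.
#' @export
random_background_sequence <- function(length, config = scan_config(), seed = 1L) {
  with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE,
                               prob = config$background_freqs), collapse = ""))
}

#' Empirical score cutoff of a PWM
#'
#' Scores every window of a random i.i.d. background sequence (both strands
#' when configured, pooled) and returns the configured quantile (type-7
#' interpolation).  The default is the 99.99% quantile, so roughly one
#' window in ten thousand scores above the cutoff by construction.
#'
#' @param pwm a [pwm()].
#' @param config a [scan_config()].
#' @param calibration_seq optional pre-generated calibration sequence
#'   shared across PWMs; generated from `seed` when `NULL`.
#' @param seed seed for the calibration sequence.
#' @param strict error when the calibration sequence is too short to
#'   resolve the quantile (fewer than 100 expected exceedances).
#' @return numeric cutoff score.
#' @export
compute_cutoff <- function(pwm, config = scan_config(), calibration_seq = NULL,
                           seed = 1L, strict = FALSE) {
  if (is.null(calibration_seq)) {
    calibration_seq <- random_background_sequence(config$calibration_length,
                                                  config, seed)
  }
  min_len <- 100 / (1 - config$quantile)
  if (nchar(calibration_seq) + 0.5 < min_len) {
    msg <- sprintf("calibration sequence (%d bases) shorter than %g needed for the %.4f quantile",
                   nchar(calibration_seq), min_len, config$quantile)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  codes <- dna_codes(calibration_seq)
  scores <- window_scores(codes, pwm_log_odds(pwm, config))
  if (config$both_strands) {
    scores <- c(scores, window_scores(codes, pwm_log_odds(pwm_revcomp(pwm), config)))
  }
  unname(quantile(scores, config$quantile, type = 7))
}

#' Per-PWM cutoffs from one shared calibration sequence
#'
#' Generates a single seeded random sequence per background model and
#' computes every motif's cutoff on it.
#'
#' @param pwms list of [pwm()]s.
#' @param config a [scan_config()].
#' @param seed seed for the shared calibration sequence.
#' @return named numeric vector of cutoffs.
#' @export
calibrate_cutoffs <- function(pwms, config = scan_config(), seed = 1L) {
  calib <- random_background_sequence(config$calibration_length, config, seed)
  vapply(pwms, function(p)
    compute_cutoff(p, config, calibration_seq = calib), numeric(1L))
}

#' Scan one sequence with one PWM
#'
#' Reports every window with score strictly greater than the cutoff, on
#' both strands when configured.  Reverse-strand hits are reported in
#' forward coordinates: `start` is the 0-based position of the site's
#' leftmost base on the forward strand.
#'
#' @param pwm a [pwm()].
#' @param seq DNA string.
#' @param cutoff score cutoff (from [compute_cutoff()]).
#' @param config a [scan_config()].
#' @return data frame with columns `motif_id`, `start` (0-based), `strand`
#'   (`"+"`/`"-"`), `score`.
#' @export
scan_sequence <- function(pwm, seq, cutoff, config = scan_config()) {
  codes <- dna_codes(seq)
  fwd <- window_scores(codes, pwm_log_odds(pwm, config))
  hits_start <- which(fwd > cutoff) - 1L
  hits_strand <- rep("+", length(hits_start))
  hits_score <- fwd[fwd > cutoff]
  if (config$both_strands) {
    rev <- window_scores(codes, pwm_log_odds(pwm_revcomp(pwm), config))
    sel <- which(rev > cutoff)
    hits_start <- c(hits_start, sel - 1L)
    hits_strand <- c(hits_strand, rep("-", length(sel)))
    hits_score <- c(hits_score, rev[sel])
  }
  ord <- order(hits_start, hits_strand)
  data.frame(motif_id = rep(pwm$motif_id, length(hits_start)),
             start = as.integer(hits_start[ord]),
             strand = hits_strand[ord],
             score = hits_score[ord])
}

#' Scan many sequences with many PWMs
#'
#' @param pwms list of [pwm()]s.
#' @param seqs named character vector of DNA sequences.
#' @param cutoffs named numeric vector of per-motif cutoffs.
#' @param config a [scan_config()].
#' @return data frame of hits with columns `motif_id`, `seq_id`, `start`,
#'   `strand`, `score`.
#' @export
scan_sequences <- function(pwms, seqs, cutoffs, config = scan_config()) {
  out <- list()
  for (p in pwms) {
    for (sid in names(seqs)) {
      h <- scan_sequence(p, seqs[[sid]], cutoffs[[p$motif_id]], config)
      if (nrow(h) > 0L) {
        h$seq_id <- sid
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif_id = character(0), seq_id = character(0),
                      start = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[, c("motif_id", "seq_id", "start", "strand", "score")]
}

# Do the motifs of one CRM have hits clustered within `window` bases?
# Requires, for some anchor start s, one hit per motif with start >= s and
# start + L <= s + window (site span max(end) - min(start) <= window).
crm_hits_clustered <- function(hits_by_motif, motif_lengths, window) {
  if (any(vapply(hits_by_motif, nrow, integer(1L)) == 0L)) return(FALSE)
  anchors <- sort(unique(unlist(lapply(hits_by_motif, `[[`, "start"))))
  for (s in anchors) {
    ok <- TRUE
    for (m in names(hits_by_motif)) {
      st <- hits_by_motif[[m]]$start
      if (!any(st >= s & st + motif_lengths[[m]] <= s + window)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Predict CRM-to-miRNA edges from upstream-sequence scans
#'
#' A CRM is predicted to regulate a miRNA when every motif of the CRM has a
#' binding site (score above its cutoff) in the pri-miRNA's upstream
#' sequence and all those sites fall within one `cluster_window` span
#' (default 200 bp): there must exist one hit per motif with
#' `max(start + L) - min(start) <= cluster_window`.
#'
#' @param crms named list of motif-ID vectors (CRM definitions).
#' @param upstream named character vector of upstream sequences, one per
#'   miRNA (names are miRNA IDs).
#' @param pwms list of [pwm()]s covering every motif used by `crms`.
#' @param config a [scan_config()].
#' @param cutoffs optional named cutoff vector; computed by
#'   [calibrate_cutoffs()] with `seed` when `NULL`.
#' @param seed seed for cutoff calibration.
#' @return data frame with columns `crm_id`, `mirna_id`, one row per
#'   predicted edge, ordered lexicographically.
#' @export
predict_crm_mirna_edges <- function(crms, upstream, pwms,
                                    config = scan_config(), cutoffs = NULL,
                                    seed = 1L) {
  pwm_ids <- vapply(pwms, `[[`, "", "motif_id")
  names(pwms) <- pwm_ids
  needed <- unique(unlist(crms, use.names = FALSE))
  missing <- setdiff(needed, pwm_ids)
  if (length(missing) > 0L) {
    stop(sprintf("no PWM for motif(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cutoffs)) {
    cutoffs <- calibrate_cutoffs(pwms[needed], config, seed)
  }
  motif_lengths <- vapply(pwms, pwm_length, integer(1L))
  out_crm <- character(0)
  out_mir <- character(0)
  for (mid in sort(names(upstream))) {
    seq <- upstream[[mid]]
    hits <- lapply(pwms[needed], function(p)
      scan_sequence(p, seq, cutoffs[[p$motif_id]], config))
    names(hits) <- needed
    for (cid in sort(names(crms))) {
      motifs <- crms[[cid]]
      if (crm_hits_clustered(hits[motifs], motif_lengths[motifs],
                             config$cluster_window)) {
        out_crm <- c(out_crm, cid)
        out_mir <- c(out_mir, mid)
      }
    }
  }
  res <- data.frame(crm_id = out_crm, mirna_id = out_mir)
  res[order(res$crm_id, res$mirna_id), , drop = FALSE]
}
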