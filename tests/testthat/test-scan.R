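# PWM scanning: scoring arithmetic, cutoff calibration, strand symmetry,
# and the clustered-sites edge rule.

uniform_pwm <- function(L = 6) {
  pwm("U", matrix(0.25, 4, L))
}

# sharp PWM whose consensus is the given word
consensus_pwm <- function(id, word, p = 0.97) {
  bases <- strsplit(word, "")[[1L]]
  probs <- vapply(bases, function(b) {
    col <- rep((1 - p) / 3, 4)
    col[match(b, c("A", "C", "G", "T"))] <- p
    col
  }, numeric(4L))
  pwm(id, probs)
}

test_that("site scoring follows the pseudocounted log-odds formula", {
  cfg <- scan_config(pseudocount_weight = 0)
  expect_equal(score_site(uniform_pwm(), "ACGTAC", cfg), 0)

  p <- pwm("P", matrix(c(1, 0, 0, 0), 4, 1))
  cfg2 <- scan_config(pseudocount_weight = 0.01)
  expect_equal(score_site(p, "A", cfg2), log(0.9925 / 0.25))
  expect_equal(score_site(p, "N", cfg2), 0)
  expect_error(score_site(p, "AA", cfg2), "length")
})

test_that("cutoffs are zero for uninformative PWMs and monotone in quantile", {
  cfg <- scan_config(pseudocount_weight = 0, calibration_length = 2e4,
                     quantile = 0.99)
  expect_equal(compute_cutoff(uniform_pwm(), cfg, seed = 2), 0)

  pw <- gen_pwms(1, seed = 3)[[1L]]
  calib <- random_background_sequence(2e4, cfg, seed = 4)
  cuts <- vapply(c(0.9, 0.99, 0.995), function(q) {
    compute_cutoff(pw, scan_config(quantile = q, calibration_length = 2e4),
                   calibration_seq = calib)
  }, numeric(1L))
  expect_true(all(diff(cuts) >= 0))
  expect_error(compute_cutoff(pw, scan_config(quantile = 0.9999,
                                              calibration_length = 1e4),
                              seed = 5, strict = TRUE), "calibration")
})

test_that("scanning equals the per-window oracle and recovers planted sites", {
  cfg <- scan_config(calibration_length = 5e4, quantile = 0.998)
  pwms <- gen_pwms(3, seed = 31)
  cutoffs <- calibrate_cutoffs(pwms, cfg, seed = 32)
  for (id in names(pwms)) {
    seq <- random_background_sequence(1000, cfg, seed = 33 + match(id, names(pwms)))
    got <- scan_sequence(pwms[[id]], seq, cutoffs[[id]], cfg)
    exp <- oracle_scan(pwms[[id]], seq, cutoffs[[id]], cfg)
    expect_equal(got$start, exp$start)
    expect_equal(got$strand, exp$strand)
    expect_equal(got$score, exp$score, tolerance = 1e-12)
  }

  up <- gen_upstream_sequences(pwms, 1, length = 3000,
                               planting = list(list(seq = "mir001",
                                                    motifs = "M001",
                                                    cluster_width = 200)),
                               seed = 35, consensus = TRUE)
  site <- up$truth$planted_sites
  hits <- scan_sequence(pwms$M001, up$seqs[[1L]], cutoffs[["M001"]], cfg)
  expect_true(site$start %in% hits$start)

  none <- scan_sequence(pwms$M001, up$seqs[[1L]], Inf, cfg)
  expect_equal(nrow(none), 0L)
})

test_that("scan results are strand-symmetric under reverse complement", {
  cfg <- scan_config(calibration_length = 5e4, quantile = 0.998)
  pw <- gen_pwms(1, seed = 41)[[1L]]
  cutoff <- compute_cutoff(pw, cfg, seed = 42)
  seq <- random_background_sequence(2000, cfg, seed = 43)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- scan_sequence(pw, seq, cutoff, cfg)
  rev <- scan_sequence(pw, rc, cutoff, cfg)
  L <- pwm_length(pw)
  mapped <- sort(nchar(seq) - rev$start - L)
  expect_equal(sort(fwd$start), mapped)
  expect_setequal(round(fwd$score, 10), round(rev$score, 10))
})

test_that("the 200bp rule calls edges only for clustered complete motif sets", {
  # sequence of 1kb background with consensus words planted by hand
  m1 <- consensus_pwm("m1", "ACGTACGTAC")
  m2 <- consensus_pwm("m2", "TTGACCTTGA")
  cfg <- scan_config(both_strands = FALSE)
  base <- strsplit(random_background_sequence(1000, cfg, seed = 51), "")[[1L]]
  put <- function(chars, word, at) {   # 0-based start
    chars[(at + 1):(at + nchar(word))] <- strsplit(word, "")[[1L]]
    chars
  }
  cutoffs <- c(m1 = 10, m2 = 10)

  near <- paste(put(put(base, "ACGTACGTAC", 100), "TTGACCTTGA", 150),
                collapse = "")
  far <- paste(put(put(base, "ACGTACGTAC", 100), "TTGACCTTGA", 400),
               collapse = "")
  crms <- list(crmA = c("m1", "m2"))
  e_near <- predict_crm_mirna_edges(crms, c(mirX = near), list(m1, m2),
                                    cfg, cutoffs = cutoffs)
  expect_equal(nrow(e_near), 1L)   # span 160 <= 200
  e_far <- predict_crm_mirna_edges(crms, c(mirX = far), list(m1, m2),
                                   cfg, cutoffs = cutoffs)
  expect_equal(nrow(e_far), 0L)    # span 310 > 200

  # one motif lacking any binding site blocks the edge
  only1 <- paste(put(base, "ACGTACGTAC", 100), collapse = "")
  e_missing <- predict_crm_mirna_edges(crms, c(mirX = only1), list(m1, m2),
                                       cfg, cutoffs = cutoffs)
  expect_equal(nrow(e_missing), 0L)
  expect_error(predict_crm_mirna_edges(list(cA = "zz"), c(mirX = near),
                                       list(m1), cfg, cutoffs = cutoffs),
               "no PWM")
})

test_that("edge calling is monotone in window size and cutoff", {
  m1 <- consensus_pwm("m1", "ACGTACGTAC")
  m2 <- consensus_pwm("m2", "TTGACCTTGA")
  cfg_narrow <- scan_config(both_strands = FALSE, cluster_window = 40L)
  cfg_wide <- scan_config(both_strands = FALSE, cluster_window = 300L)
  base <- strsplit(random_background_sequence(1000, cfg_wide, seed = 52), "")[[1L]]
  base[101:110] <- strsplit("ACGTACGTAC", "")[[1L]]
  base[251:260] <- strsplit("TTGACCTTGA", "")[[1L]]
  seq <- paste(base, collapse = "")
  crms <- list(crmA = c("m1", "m2"))
  lo <- predict_crm_mirna_edges(crms, c(mirX = seq), list(m1, m2), cfg_narrow,
                                cutoffs = c(m1 = 10, m2 = 10))
  hi <- predict_crm_mirna_edges(crms, c(mirX = seq), list(m1, m2), cfg_wide,
                                cutoffs = c(m1 = 10, m2 = 10))
  expect_equal(nrow(lo), 0L)
  expect_equal(nrow(hi), 1L)
  # raising the cutoff can only remove edges
  hi2 <- predict_crm_mirna_edges(crms, c(mirX = seq), list(m1, m2), cfg_wide,
                                 cutoffs = c(m1 = 1e6, m2 = 1e6))
  expect_equal(nrow(hi2), 0L)
})
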