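# The generators must be deterministic under seed and produce the
# statistical structure each downstream stage assumes.

test_that("expression generator plants equicorrelated blocks", {
  gen <- gen_expression(60, 200, blocks = list(list(size = 10, rho = 0.9)),
                        seed = 11)
  block <- gen$truth$planted_blocks[[1L]]$genes
  rows <- match(paste0(block, "_at1"), rownames(gen$expr$values))
  R <- cor(t(gen$expr$values[rows, ]))
  mean_r <- mean(R[upper.tri(R)])
  expect_gt(mean_r, 0.8)
  expect_lt(mean_r, 0.95)

  null <- gen_expression(40, 200, seed = 12)
  Rn <- cor(t(null$expr$values))
  expect_lt(mean(abs(Rn[upper.tri(Rn)])), 0.1)

  expect_identical(gen_expression(15, 10, seed = 3)$expr$values,
                   gen_expression(15, 10, seed = 3)$expr$values)
  expect_error(gen_expression(10, 5, blocks = list(list(size = 2, rho = 1))),
               "rho")
  expect_error(gen_expression(4, 5, blocks = list(list(size = 9, rho = 0.5))),
               "exceed")
})

test_that("target maps honor overlap planting and degree laws", {
  universe <- sprintf("g%04d", 1:500)
  block <- universe[1:6]
  tm <- gen_target_maps(3, 3, universe,
                        overlap_spec = list(list(crm = "crm001",
                                                 mirna = "mir002",
                                                 genes = block)),
                        seed = 21)
  expect_true(all(block %in% tm$crm_targets$entries$crm001))
  expect_true(all(block %in% tm$mirna_targets$entries$mir002))

  fixed <- gen_target_maps(2, 10, universe,
                           mirna_degree_law = list(type = "fixed", k = 7),
                           seed = 22)
  expect_true(all(lengths(fixed$mirna_targets$entries) == 7L))

  # out-degree histogram matches the requested discretized power law
  law <- list(type = "powerlaw", alpha = 1.5, kmin = 5L, kmax = 20L)
  big <- gen_target_maps(1, 10000, universe, mirna_degree_law = law,
                         seed = 23)
  deg <- lengths(big$mirna_targets$entries)
  k <- law$kmin:law$kmax
  p <- k^(-law$alpha); p <- p / sum(p)
  obs <- tabulate(deg, nbins = law$kmax)[k]
  expect_gt(suppressWarnings(chisq.test(obs, p = p)$p.value), 0.01)

  expect_error(gen_target_maps(2, 2, universe[1:5],
                               crm_degree_range = c(10L, 40L)),
               "exceeds")
})

test_that("upstream sequences carry clustered planted sites deterministically", {
  pwms <- gen_pwms(4, seed = 5)
  gen <- gen_upstream_sequences(
    pwms, 3, length = 2000,
    planting = list(list(seq = "mir002", motifs = c("M001", "M003"),
                         cluster_width = 200)),
    seed = 6)
  sites <- gen$truth$planted_sites
  expect_equal(nrow(sites), 2L)
  lens <- vapply(pwms[sites$motif_id], pwm_length, integer(1L))
  span <- max(sites$start + lens) - min(sites$start)
  expect_lte(span, 200L)
  # the planted letters at a + site equal a PWM-plausible word
  for (i in seq_len(nrow(sites))) {
    expect_true(sites$start[i] >= 0 &&
                  sites$start[i] + lens[i] <= nchar(gen$seqs[[sites$seq_id[i]]]))
  }
  expect_identical(
    gen_upstream_sequences(pwms, 2, length = 500, seed = 8)$seqs,
    gen_upstream_sequences(pwms, 2, length = 500, seed = 8)$seqs)
  expect_error(gen_upstream_sequences(
    pwms, 1, length = 500,
    planting = list(list(seq = "mir001",
                         motifs = rep(names(pwms), 10), cluster_width = 30))),
    "fit|motif length")
})

test_that("knockdown generator follows the linear model exactly when noiseless", {
  mt <- target_map(list(mirA = c("g1", "g3"), mirB = c("g3")), "MIRNA")
  gen <- gen_knockdown(tf_targets = c("g2", "g3"), mirna_targets = mt,
                       a_tf = -0.5, a_mir = c(mirA = 0.4, mirB = -0.3),
                       c = 0.1, noise_sd = 0, seed = 2,
                       genes = c("g1", "g2", "g3", "g4"))
  g <- setNames(gen$data$g, gen$data$gene_ids)
  expect_equal(g[["g4"]], 0.1)                      # intercept only
  expect_equal(g[["g2"]], 0.1 - 0.5)                # TF only
  expect_equal(g[["g1"]], 0.1 + 0.4)                # one miRNA
  expect_equal(g[["g3"]], 0.1 - 0.5 + 0.4 - 0.3)    # TF + both miRNAs
  expect_error(gen_knockdown("g1", mt, a_tf = 1, a_mir = c(nope = 1)),
               "absent")
})

test_that("OLS on the true support recovers generator coefficients", {
  universe <- sprintf("g%05d", 1:5000)
  set.seed(44)
  mt <- target_map(list(mirA = sample(universe, 900),
                        mirB = sample(universe, 700)), "MIRNA")
  tf <- sample(universe, 1200)
  gen <- gen_knockdown(tf, mt, a_tf = -0.8,
                       a_mir = c(mirA = 0.5, mirB = -0.6),
                       c = 0.2, noise_sd = 1, seed = 45, genes = universe)
  fit <- fit_full_model(gen$data, c("mirA", "mirB"))
  cf <- fit$coefficients
  truth <- c(0.2, -0.8, 0.5, -0.6)
  expect_true(all(abs(cf[, "Estimate"] - truth) <= 3 * cf[, "Std. Error"]))
})

test_that("network generator plants FFLs on fresh triples", {
  gen <- gen_network(5, 5, 20, planted_ffl_count = 7, seed = 3)
  counts <- count_patterns(gen$network)
  expect_equal(unname(counts[["C1>G1+C1>M1+M1>G1"]]), 7)
  empty <- gen_network(3, 3, 5, seed = 4)
  expect_equal(nrow(empty$network$edges), 0L)
})
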