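# The knockdown co-regulation model: prescreen, stepwise-AIC selection,
# and the full OLS fit.

kd_sim <- function(seed, n_genes = 2000, n_mirnas = 10,
                   active = c(mir001 = -1), noise_sd = 0.5,
                   targets_per_mirna = 200, a_tf = -0.8) {
  universe <- sprintf("g%05d", seq_len(n_genes))
  withr::with_seed(seed, {
    mt <- target_map(setNames(lapply(seq_len(n_mirnas), function(i)
      sample(universe, targets_per_mirna)), sprintf("mir%03d", seq_len(n_mirnas))),
      "MIRNA")
    tf <- sample(universe, round(n_genes / 4))
    gen <- gen_knockdown(tf, mt, a_tf = a_tf, a_mir = active, c = 0.1,
                         noise_sd = noise_sd, seed = seed + 1, genes = universe)
    gen$data
  })
}

test_that("prescreen agrees with a normal-equations oracle", {
  data <- kd_sim(201)
  for (m in c("mir001", "mir004")) {
    X <- cbind(1, data$b_tf, data$b_mir[, m])
    orc <- oracle_ols(X, data$g)
    p_got <- prescreen_mirna(data, m)
    expect_equal(p_got, orc$p[3L], tolerance = 1e-8)
    fit <- fit_full_model(data, m)
    expect_equal(unname(coef(fit)), orc$beta, tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[, "Std. Error"]), orc$se,
                 tolerance = 1e-8)
    n <- length(data$g)
    expect_equal(fit$aic, n * log(orc$rss / n) + 2 * 3, tolerance = 1e-8)
  }
  # planted effect at the stated size is overwhelmingly significant
  expect_lt(prescreen_mirna(kd_sim(202), "mir001"), 1e-6)
})

test_that("rank-deficient miRNA designs are excluded with a warning", {
  universe <- sprintf("g%03d", 1:50)
  mt <- target_map(list(mirAll = universe, mirNone = "not_a_gene"), "MIRNA")
  gen <- gen_knockdown(universe[1:20], mt, a_tf = -1, noise_sd = 0.1,
                       seed = 7, genes = universe)
  expect_warning(p1 <- prescreen_mirna(gen$data, "mirAll"), "rank")
  expect_true(is.na(p1))
  expect_warning(p2 <- prescreen_mirna(gen$data, "mirNone"), "rank")
  expect_true(is.na(p2))
})

test_that("noiseless data is recovered exactly", {
  universe <- sprintf("g%04d", 1:300)
  set.seed(11)
  mt <- target_map(list(mirA = sample(universe, 60),
                        mirB = sample(universe, 50)), "MIRNA")
  gen <- gen_knockdown(sample(universe, 100), mt, a_tf = -0.7,
                       a_mir = c(mirA = 0.4, mirB = -0.9), c = 0.25,
                       noise_sd = 0, seed = 12, genes = universe)
  fit <- suppressWarnings(fit_full_model(gen$data, c("mirA", "mirB")))
  expect_equal(fit$intercept, 0.25, tolerance = 1e-10)
  expect_equal(fit$a_tf, -0.7, tolerance = 1e-10)
  expect_equal(unname(fit$a_mir), c(0.4, -0.9), tolerance = 1e-10)
  expect_equal(sum(residuals(fit)^2), 0, tolerance = 1e-16)
})

test_that("stepwise selection recovers planted miRNAs and guards collinearity", {
  data <- kd_sim(301, n_genes = 3000, n_mirnas = 20,
                 active = c(mir002 = 0.6, mir007 = -0.8, mir015 = 0.5),
                 noise_sd = 0.3, targets_per_mirna = 250)
  fit <- select_mirna_regulators(data)
  expect_true(all(c("mir002", "mir007", "mir015") %in% fit$selected))
  expect_lte(length(setdiff(fit$selected, c("mir002", "mir007", "mir015"))), 2L)

  # duplicated candidate column: its twin is never co-selected
  dup <- data
  dup$b_mir <- cbind(dup$b_mir, mirdup = dup$b_mir[, "mir007"])
  dup$mirna_ids <- c(dup$mirna_ids, "mirdup")
  fit2 <- select_mirna_regulators(dup)
  expect_false(all(c("mir007", "mirdup") %in% fit2$selected))
})

test_that("pure-noise data selects nothing beyond chance", {
  data <- kd_sim(401, n_genes = 1500, n_mirnas = 15, active = numeric(0),
                 noise_sd = 0.5)
  fit <- select_mirna_regulators(data)
  # prescreen at alpha=0.05 passes ~0.75 of 15 by chance; allow stepwise slack
  expect_lte(length(fit$selected), 3L)
  expect_equal(length(attr(fit, "survivors")),
               sum(attr(fit, "prescreen") < 0.05, na.rm = TRUE))
})

test_that("selection is invariant to gene row order", {
  data <- kd_sim(501, n_genes = 1000, n_mirnas = 8,
                 active = c(mir003 = 0.7), noise_sd = 0.4)
  perm <- withr::with_seed(502, sample(length(data$gene_ids)))
  shuffled <- knockdown_dataset(
    data$gene_ids[perm], data$g[perm],
    data$gene_ids[data$b_tf == 1],
    target_map(setNames(lapply(data$mirna_ids, function(m)
      data$gene_ids[data$b_mir[, m] == 1]), data$mirna_ids), "MIRNA"))
  f1 <- select_mirna_regulators(data)
  f2 <- select_mirna_regulators(shuffled)
  expect_setequal(f1$selected, f2$selected)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("adding a truly active miRNA never increases the RSS", {
  data <- kd_sim(601, n_genes = 1200, n_mirnas = 6,
                 active = c(mir001 = 0.9, mir002 = -0.5), noise_sd = 0.4)
  rss <- function(fit) sum(residuals(fit)^2)
  f0 <- fit_full_model(data, character(0))
  f1 <- fit_full_model(data, "mir001")
  f2 <- fit_full_model(data, c("mir001", "mir002"))
  expect_lte(rss(f1), rss(f0))
  expect_lte(rss(f2), rss(f1))
})
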