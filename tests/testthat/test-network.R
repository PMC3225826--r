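# Typed network assembly, the pattern catalog, the exact census, and the
# degree-preserving edge-swap null.

random_typed_network <- function(seed, n_c = 6, n_m = 6, n_g = 15,
                                 p = list(c2g = 0.15, m2g = 0.15,
                                          c2m = 0.15, m2c = 0.15)) {
  gen_network(n_c, n_m, n_g, edge_probs = p, seed = seed)$network
}

test_that("miRNA-to-CRM edges go through TF genes and match a triple loop", {
  mm <- target_map(list(m1 = c("Gtf", "g9"), m2 = "g5"), "MIRNA")
  crms <- list(cA = c("mot1", "mot2"), cB = "mot3")
  pmap <- list(mot1 = "Gtf", mot2 = "g7", mot3 = "g8")
  edges <- derive_mirna_crm_edges(mm, crms, pmap)
  expect_equal(edges, data.frame(mirna_id = "m1", crm_id = "cA"))

  none <- derive_mirna_crm_edges(target_map(list(m1 = "g1"), "MIRNA"),
                                 crms, pmap)
  expect_equal(nrow(none), 0L)
  expect_warning(derive_mirna_crm_edges(mm, list(cC = "unknown"), pmap),
                 "skipped")

  # random fixture vs brute-force triple loop
  set.seed(61)
  genes <- sprintf("g%02d", 1:30)
  mm2 <- target_map(setNames(lapply(1:5, function(i) sample(genes, 8)),
                             sprintf("m%d", 1:5)), "MIRNA")
  crms2 <- setNames(lapply(1:4, function(i) sample(sprintf("mot%d", 1:6), 2)),
                    sprintf("c%d", 1:4))
  pmap2 <- setNames(lapply(1:6, function(i) sample(genes, 2)),
                    sprintf("mot%d", 1:6))
  got <- derive_mirna_crm_edges(mm2, crms2, pmap2)
  for (mi in names(mm2$entries)) {
    for (ci in names(crms2)) {
      hit <- FALSE
      for (mot in crms2[[ci]]) {
        for (tf in pmap2[[mot]]) {
          if (tf %in% mm2$entries[[mi]]) hit <- TRUE
        }
      }
      expect_equal(any(got$mirna_id == mi & got$crm_id == ci), hit)
    }
  }
})

test_that("network assembly collapses duplicates and infers typed nodes", {
  cm <- target_map(list(c1 = "g1"), "CRM")
  mm <- target_map(list(m1 = "g1"), "MIRNA")
  c2m <- data.frame(crm_id = "c1", mirna_id = "m1")
  net <- build_network(cm, mm, c2m, NULL)
  expect_equal(length(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(unname(net$nodes[c("c1", "m1", "g1")]), c("C", "M", "G"))

  expect_equal(nrow(build_network()$edges), 0L)
  expect_error(regulatory_network(data.frame(source = "x", target = "x",
                                             type = "C2G")), "self")
  dup <- regulatory_network(data.frame(source = c("c1", "c1"),
                                       target = c("g1", "g1"),
                                       type = c("C2G", "C2G")))
  expect_equal(nrow(dup$edges), 1L)
})

test_that("the catalog equals an independent igraph-isomorphism enumeration", {
  catalog <- generate_pattern_catalog()
  expect_true(any(vapply(catalog, function(p)
    identical(p$name, "ffl_crm_to_mirna"), logical(1L))))
  # no parallel duplicate edges within any pattern
  for (p in catalog) {
    expect_false(anyDuplicated(paste(p$edges$from, p$edges$to, p$edges$type)) > 0)
  }

  # independent enumeration: all typed digraphs on <=3 labelled nodes,
  # deduplicated with igraph vertex-colored isomorphism
  type_combos <- c(
    lapply(list(c("C","G"), c("M","G"), c("C","M"), c("C","C"), c("M","M"),
                c("G","G")), identity),
    lapply(list(c("C","M","G"), c("C","C","M"), c("C","C","G"), c("M","M","C"),
                c("M","M","G"), c("G","G","C"), c("G","G","M"), c("C","C","C"),
                c("M","M","M"), c("G","G","G")), identity))
  allowed <- function(a, b) {
    (a == "C" && b == "G") || (a == "M" && b == "G") ||
      (a == "C" && b == "M") || (a == "M" && b == "C")
  }
  reps <- list()
  for (ts in type_combos) {
    n <- length(ts)
    cand <- list()
    for (i in 1:n) for (j in 1:n) {
      if (i != j && allowed(ts[i], ts[j])) {
        cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
    if (length(cand) == 0L) next
    for (mask in 1:(2^length(cand) - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0)
      el <- do.call(rbind, cand[sel])
      g <- igraph::graph_from_edgelist(el, directed = TRUE)
      if (igraph::vcount(g) < n) {
        g <- igraph::add_vertices(g, n - igraph::vcount(g))
      }
      if (!igraph::is_connected(g, mode = "weak")) next
      col <- match(ts, c("C", "M", "G"))
      new <- TRUE
      for (r in reps) {
        if (length(r$col) == n &&
            igraph::ecount(r$g) == igraph::ecount(g) &&
            igraph::isomorphic(r$g, g, method = "vf2",
                               vertex.color1 = r$col, vertex.color2 = col)) {
          new <- FALSE
          break
        }
      }
      if (new) reps[[length(reps) + 1L]] <- list(g = g, col = col)
    }
  }
  expect_equal(length(catalog), length(reps))
})

test_that("the census equals brute-force enumeration on random networks", {
  catalog <- generate_pattern_catalog()
  for (s in 1:5) {
    net <- random_typed_network(seed = 700 + s)
    expect_equal(count_patterns(net, catalog),
                 oracle_count_patterns(net, catalog))
  }
  # hand-checked single FFL: each sub-pattern occurs once
  ffl <- regulatory_network(data.frame(source = c("c1", "c1", "m1"),
                                       target = c("m1", "g1", "g1"),
                                       type = c("C2M", "C2G", "M2G")))
  ct <- count_patterns(ffl, catalog)
  expect_equal(unname(ct[["C1>G1+C1>M1+M1>G1"]]), 1)
  expect_equal(unname(ct[["C1>G1+M1>G1"]]), 1)
  expect_equal(unname(ct[["C1>M1+M1>G1"]]), 1)
  expect_equal(sum(ct), 7)  # 3 single edges + 3 two-edge + the FFL
  empty <- regulatory_network()
  expect_true(all(count_patterns(empty, catalog) == 0))
})

test_that("edge swaps preserve per-type degrees and never duplicate", {
  net <- random_typed_network(seed = 81, n_c = 8, n_m = 8, n_g = 20)
  d0 <- degree_tables(net)
  for (s in 1:20) {
    rn <- random_network(net, seed = s)
    expect_equal(degree_tables(rn), d0)
    expect_false(any(duplicated(rn$edges)))
    expect_equal(table(rn$edges$type), table(net$edges$type))
  }
})

test_that("swap randomization reaches attainable states uniformly", {
  # 4 disjoint C2G edges: the attainable configurations are the 4! = 24
  # perfect matchings between the fixed sources and targets
  net <- regulatory_network(data.frame(source = sprintf("c%d", 1:4),
                                       target = sprintf("g%d", 1:4),
                                       type = "C2G"))
  set.seed(5)
  draws <- vapply(1:10000, function(i) {
    rn <- random_network(net, seed = i, swaps_per_edge = 25L)
    e <- rn$edges[order(rn$edges$source), ]
    paste(e$target, collapse = "")
  }, character(1L))
  freq <- table(draws)
  expect_length(freq, 24L)
  expect_gt(suppressWarnings(chisq.test(freq)$p.value), 0.001)
})

test_that("Z-scores flag planted FFL enrichment and stay defined-or-NA", {
  catalog <- generate_pattern_catalog()
  gen <- gen_network(10, 10, 40,
                     edge_probs = list(c2g = 0.08, m2g = 0.08, c2m = 0.05,
                                       m2c = 0.05),
                     planted_ffl_count = 30, seed = 91)
  zs <- pattern_zscores(gen$network, catalog, n_random = 50, seed = 92)
  ffl_z <- zs$z[zs$name == "ffl_crm_to_mirna" & !is.na(zs$name)]
  expect_gt(ffl_z, 2)

  # a pattern type absent from real and random networks has undefined z
  no_m2c <- gen_network(5, 5, 15, edge_probs = list(c2g = 0.2, m2g = 0.2),
                        seed = 93)$network
  zs2 <- pattern_zscores(no_m2c, catalog, n_random = 10, seed = 94)
  cyc <- zs2[zs2$name == "crm_mirna_feedback_cycle" & !is.na(zs2$name), ]
  expect_equal(cyc$observed, 0)
  expect_true(is.na(cyc$z))
})
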