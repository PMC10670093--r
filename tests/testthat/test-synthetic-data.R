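test_that("catalog counts follow largest-remainder apportionment exactly", {
  cat_paper <- generate_catalog(
    2941, c(ER = 243, mitochondria = 1399, cytosol = 1299) / 2941, seed = 1)
  expect_equal(unname(compartment_counts(cat_paper)),
               c(243L, 1399L, 1299L))

  cat3 <- generate_catalog(3, c(ER = 1, mitochondria = 1, cytosol = 1) / 3,
                           seed = 2)
  expect_equal(unname(compartment_counts(cat3)), c(1L, 1L, 1L))
})

test_that("multilocal proteins appear at the requested rate", {
  cat100 <- generate_catalog(100, multilocal_rate = 0.1, seed = 7)
  multi <- grepl(";", cat100$compartments, fixed = TRUE)
  expect_equal(sum(multi), 10L)
  # counted once per compartment the labels sum to n + n_multilocal
  expect_equal(sum(lengths(strsplit(cat100$compartments, ";"))), 110L)
})

test_that("catalog generation rejects bad inputs and is deterministic", {
  expect_error(generate_catalog(0), "positive")
  expect_error(generate_catalog(10, c(ER = 0.5, mitochondria = 0.5,
                                      cytosol = 0.5)), "sum to 1")
  expect_error(generate_catalog(10, multilocal_rate = 1), "multilocal_rate")
  a <- generate_catalog(200, multilocal_rate = 0.05, seed = 11)
  b <- generate_catalog(200, multilocal_rate = 0.05, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- generate_catalog(200, multilocal_rate = 0.05, seed = 12)
  expect_false(identical(a$primary, d$primary))
})

test_that("degenerate probabilities give exactly a planted clique", {
  cat8 <- generate_catalog(8, seed = 5)
  net <- generate_network(cat8,
                          complex_specs = list(list(size = 5, p_in = 1)),
                          p_bg = 0, seed = 5)
  g <- net$graph
  expect_equal(igraph::vcount(g), 8L)
  expect_equal(igraph::ecount(g), 10L) # C(5,2)
  members <- net$truth$planted_complexes[[1]]
  sub <- igraph::induced_subgraph(g, members)
  expect_equal(graph_density(sub), 1)
  expect_true(igraph::is_simple(g))
})

test_that("background edge count matches its binomial expectation", {
  cat200 <- generate_catalog(200, seed = 11)
  net <- generate_network(cat200, complex_specs = list(), p_bg = 0.02,
                          seed = 11)
  n_pairs <- choose(200, 2)
  expected <- 0.02 * n_pairs
  sdev <- sqrt(n_pairs * 0.02 * 0.98)
  expect_lt(abs(igraph::ecount(net$graph) - expected), 4 * sdev)
})

test_that("planted complex density converges to p_in", {
  cat60 <- generate_catalog(60, seed = 13)
  net <- generate_network(cat60,
                          complex_specs = list(list(size = 50, p_in = 0.6)),
                          p_bg = 0, seed = 13)
  dens <- graph_density(igraph::induced_subgraph(
    net$graph, net$truth$planted_complexes[[1]]))
  tol <- 3 * sqrt(0.6 * 0.4 / choose(50, 2))
  expect_lt(abs(dens - 0.6), tol)
})

test_that("the linker motif has the bridge geometry", {
  cat12 <- generate_catalog(
    12, c(ER = 1, mitochondria = 7, cytosol = 4) / 12, seed = 21)
  net <- generate_network(
    cat12,
    complex_specs = list(list(
      size = 10, mix = c(ER = 1, mitochondria = 6, cytosol = 3),
      p_in = 0.3)),
    p_bg = 0.01, linker_motif = TRUE, seed = 21)
  g <- net$graph
  linker <- net$truth$planted_linker
  comp <- setNames(igraph::V(g)$compartment, igraph::V(g)$name)
  expect_equal(unname(comp[linker]), "cytosol")
  d <- bfs_distances(g, linker)
  mito <- names(comp)[comp == "mitochondria"]
  er <- names(comp)[comp == "ER"]
  expect_equal(min(d[mito]), 1)
  expect_equal(min(d[er]), 2)
})

test_that("oversized complex specs are rejected", {
  cat5 <- generate_catalog(5, seed = 1)
  expect_error(
    generate_network(cat5, complex_specs = list(list(size = 9, p_in = 1))),
    "exceed")
  expect_error(
    generate_network(cat5, complex_specs = list(list(size = 3, p_in = 2))),
    "probabilities")
})

test_that("a large planted effect is detected in every study", {
  cat50 <- generate_catalog(50, seed = 31)
  sim <- generate_expression(cat50, n_studies = 3, n_per_group = 10,
                             deg_fraction = 0.2, delta = 5, noise_sd = 0.5,
                             seed = 31)
  for (study in sim$studies) {
    for (gene in sim$truth$planted_deg_set) {
      grp <- study$groups
      p <- t.test(study$matrix[gene, grp == "case"],
                  study$matrix[gene, grp == "control"],
                  var.equal = TRUE)$p.value
      expect_lt(p, 0.001)
    }
  }
})

test_that("the generator supports the 277-sample multi-study design", {
  cat20 <- generate_catalog(20, seed = 41)
  sim <- generate_expression(
    cat20, n_studies = 3,
    n_per_group = list(c(57, 57), c(47, 47), c(35, 34)),
    deg_fraction = 0.1, delta = 1, noise_sd = 1, seed = 41)
  total <- sum(vapply(sim$studies, function(s) ncol(s$matrix), integer(1)))
  expect_equal(total, 277L)
  expect_identical(
    generate_expression(cat20, seed = 41)$studies[[1]]$matrix,
    generate_expression(cat20, seed = 41)$studies[[1]]$matrix)
})

test_that("Ct tables encode fold changes as -log2 shifts of the target", {
  ct0 <- generate_ct_table(c("control", "treated"), n_per_group = 3,
                           true_fold_changes = c(treated = 0.5),
                           ct_noise_sd = 0, seed = 1)
  expect_equal(unique(ct0$ct_target[ct0$group == "control"]), 25)
  expect_equal(unique(ct0$ct_target[ct0$group == "treated"]), 26)
  expect_equal(unique(ct0$ct_reference), 20)
  expect_error(generate_ct_table(c("a", "b")), "control")
  expect_error(
    generate_ct_table(c("control", "t"), true_fold_changes = c(t = -1)),
    "positive")
})

test_that("generators restore the caller's RNG state", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_catalog(10, seed = 1))
  expect_identical(runif(1), before)
})
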