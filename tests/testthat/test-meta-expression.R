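make_study <- function(mat, n_case, n_control, id = "s1") {
  groups <- c(rep("case", n_case), rep("control", n_control))
  colnames(mat) <- sprintf("%s_%s_%d", id, groups, seq_along(groups))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  structure(list(matrix = mat, groups = setNames(groups, colnames(mat)),
                 study_id = id), class = "expression_study")
}

test_that("flat and perfectly separated genes hit the p-value extremes", {
  flat <- make_study(matrix(5, nrow = 3, ncol = 8), 4, 4)
  de <- differential_expression(flat)
  expect_equal(de$statistic, rep(0, 3))
  expect_equal(de$p, rep(1, 3))

  sep <- make_study(cbind(matrix(6, 2, 4), matrix(5, 2, 4)), 4, 4)
  de2 <- differential_expression(sep)
  expect_true(all(de2$degenerate))
  # with df = 6 the t tail is polynomial; the epsilon guard still drives p
  # many orders of magnitude below any attainable sampling p-value
  expect_true(all(de2$p < 1e-40))

  small <- make_study(matrix(rnorm(10), nrow = 5), 1, 1)
  expect_error(differential_expression(small), ">=2 samples")
})

test_that("t statistics and p-values match the per-gene closed form", {
  set.seed(123)
  mat <- matrix(rnorm(200 * 14), nrow = 200)
  study <- make_study(mat, 6, 8)
  de <- differential_expression(study)
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, 1:6]; y <- mat[i, 7:14]
    sp2 <- (5 * var(x) + 7 * var(y)) / 12
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 6 + 1 / 8))
    expect_equal(de$statistic[i], tt, tolerance = 1e-12)
    expect_equal(de$p[i], 2 * pt(abs(tt), 12, lower.tail = FALSE),
                 tolerance = 1e-12)
    if (i <= 5) { # spot-check against stats::t.test as well
      expect_equal(de$p[i],
                   t.test(x, y, var.equal = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("Fisher combination reproduces its closed forms", {
  for (p in c(0.01, 0.2, 0.5, 0.77)) {
    expect_equal(fisher_combine(p)$p, p, tolerance = 1e-12) # k = 1 identity
  }
  fc <- fisher_combine(c(0.5, 0.5))
  expect_equal(fc$chisq, -2 * log(0.25), tolerance = 1e-12)
  expect_equal(fc$df, 4L)
  x <- fc$chisq
  expect_equal(fc$p, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(fc$p, 0.5966, tolerance = 1e-4)

  ones <- fisher_combine(c(1, 1, 1))
  expect_equal(ones$chisq, 0)
  expect_equal(ones$p, 1)
})

test_that("Fisher combination validates and clamps its inputs", {
  expect_error(fisher_combine(numeric(0)), "non-empty")
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
  expect_error(fisher_combine(-0.1), "0, 1")
  expect_warning(res <- fisher_combine(c(0, 0.5)), "clamping")
  expect_true(res$p > 0 && res$p < 1e-100)
})

test_that("Fisher combination is permutation-invariant and monotone", {
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(2:6, 1), min = 1e-6, max = 1)
    base <- fisher_combine(p)$p
    expect_equal(fisher_combine(sample(p))$p, base, tolerance = 1e-12)
    j <- sample(length(p), 1)
    lowered <- p; lowered[j] <- lowered[j] / 2
    expect_lte(fisher_combine(lowered)$p, base)
  }
})

test_that("meta_de combines across studies with per-gene available df", {
  set.seed(11)
  s1 <- make_study(matrix(rnorm(5 * 8), 5,
                          dimnames = list(sprintf("g%03d", 1:5), NULL)),
                   4, 4, "s1")
  s2 <- make_study(matrix(rnorm(3 * 10), 3,
                          dimnames = list(sprintf("g%03d", 3:5), NULL)),
                   5, 5, "s2")
  meta <- meta_de(list(s1, s2))
  expect_equal(nrow(meta), 5L)
  expect_equal(meta$df[meta$gene == "g001"], 2)
  expect_equal(meta$df[meta$gene == "g004"], 4)
  # the combined p of a two-study gene equals the scalar combination
  g4 <- meta[meta$gene == "g004", ]
  expect_equal(g4$combined_p,
               fisher_combine(c(g4$p_s1, g4$p_s2))$p, tolerance = 1e-12)
  expect_equal(meta$deg_flag, meta$combined_p < 0.05)
})

test_that("DEG calling uses a strict threshold and supports BH adjustment", {
  meta <- structure(
    data.frame(gene = c("a", "b", "c"),
               combined_p = c(0.05, 0.049999, 0.9)),
    class = c("meta_de", "data.frame"))
  expect_equal(call_degs(meta, alpha = 0.05), "b")
  expect_equal(call_degs(meta, alpha = 0.05, adjust = "bh"), character(0))
  expect_error(call_degs(meta, alpha = 0), "alpha")
})

test_that("DEG-to-cluster mapping counts hits by set intersection", {
  mk <- function(members, rank) {
    structure(list(members = members, seed = members[1], score = 1,
                   rank = rank, n_edges = 1L), class = "mcode_complex")
  }
  clusters <- structure(list(mk(paste0("x", 1:10), 1L),
                             mk(paste0("y", 1:5), 2L)),
                        class = "mcode_result")
  none <- map_degs_to_clusters(clusters, c("q1", "q2"))
  expect_false(any(vapply(none, `[[`, logical(1), "pd")))

  all_in <- map_degs_to_clusters(clusters, paste0("y", 1:5))
  expect_equal(length(all_in[[2]]$hits), 5L)

  seven <- map_degs_to_clusters(clusters, paste0("x", c(1:7)), min_hits = 7)
  expect_equal(length(seven[[1]]$hits), 7L)
  expect_true(seven[[1]]$pd)
  expect_false(seven[[2]]$pd)
  expect_error(map_degs_to_clusters(clusters, "x1", min_hits = 0))
})

test_that("planted effects are called at a higher rate than null genes", {
  cat0 <- generate_catalog(300, seed = 55)
  sim <- generate_expression(cat0, n_studies = 3, n_per_group = 10,
                             deg_fraction = 0.2, delta = 2, noise_sd = 1,
                             seed = 55)
  meta <- meta_de(sim$studies)
  degs <- call_degs(meta)
  planted <- sim$truth$planted_deg_set
  rate_on <- mean(planted %in% degs)
  rate_off <- mean(setdiff(cat0$symbol, planted) %in% degs)
  expect_gt(rate_on, rate_off)
  expect_gt(rate_on, 0.9)
})

test_that("the moderated-t switch agrees with limma", {
  skip_if_not_installed("limma")
  set.seed(31)
  study <- make_study(matrix(rnorm(50 * 12), 50), 6, 6)
  de <- differential_expression(study, moderated = TRUE)
  design <- cbind(Intercept = 1,
                  case = as.integer(study$groups == "case"))
  ref <- limma::eBayes(limma::lmFit(study$matrix, design))
  expect_equal(de$p, unname(ref$p.value[, "case"]), tolerance = 1e-12)
})
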