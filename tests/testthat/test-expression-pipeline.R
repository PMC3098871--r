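test_that("cyclic loess leaves identical arrays untouched in one cycle", {
  set.seed(1)
  x <- stats::rnorm(500, 8, 1.5)
  em <- make_em(cbind(x, x), time_h = 0, arm = "DMSO", replicate = 1:2,
                genes = paste0("g", rep(1:250, each = 2)))
  nm <- suppressWarnings(cyclic_loess_normalize(em, subset_size = 400,
                                                seed = 2))
  expect_equal(attr(nm, "iterations"), 1)
  expect_true(attr(nm, "converged"))
  expect_equal(nm$intensity, em$intensity, tolerance = 1e-8)
})

test_that("a constant log2 offset between two arrays is removed", {
  set.seed(3)
  x <- stats::rnorm(2000, 8, 1.5)
  em <- make_em(cbind(x, x + 1), time_h = 0, arm = "DMSO", replicate = 1:2,
                genes = paste0("g", rep(1:1000, each = 2)))
  nm <- cyclic_loess_normalize(em, subset_size = 1000, seed = 4)
  M <- log2(nm$intensity[, 1]) - log2(nm$intensity[, 2])
  expect_lt(abs(mean(M)), 0.01)
})

test_that("probe summaries are per-gene means, order invariant", {
  lm <- matrix(c(4, 6, 5, 7, 3, 3), 3, 2, byrow = TRUE)
  rownames(lm) <- c("p1", "p2", "p3")
  em <- make_em(lm, time_h = c(0, 0), arm = "DMSO", replicate = 1:2,
                genes = c("gA", "gA", "gB"))
  gm <- summarize_probes_to_genes(em)
  expect_equal(gm$log2["gA", ], c(a1 = (4 + 5) / 2, a2 = (6 + 7) / 2))
  expect_equal(gm$log2["gB", ], c(a1 = 3, a2 = 3)) # single probe: identity
  em2 <- make_em(lm[c(3, 1, 2), ], time_h = c(0, 0), arm = "DMSO",
                 replicate = 1:2, genes = c("gB", "gA", "gA"))
  gm2 <- summarize_probes_to_genes(em2)
  expect_equal(gm2$log2, gm$log2)
})

test_that("baseline normalization is the log-scale geometric-mean ratio", {
  lm <- rbind(gA = c(3, 5, 6), gB = c(7, 7, 7))
  em <- make_em(lm, time_h = c(0, 0, 24), arm = "DMSO",
                replicate = c(1, 2, 1), genes = c("gA", "gB"))
  tc <- normalize_to_baseline(summarize_probes_to_genes(em))
  # 0 h replicates (3, 5): mean 4; 24 h value 6 -> normalized 2
  expect_equal(unname(tc$log2ratio["gA", 3]), 2)
  # constant gene: all zeros
  expect_equal(unname(tc$log2ratio["gB", ]), c(0, 0, 0))
  # 0 h values average zero per gene
  expect_equal(unname(rowMeans(tc$log2ratio[, 1:2])), c(0, 0))
  # doubling every intensity changes nothing
  em2 <- make_em(lm + 1, time_h = c(0, 0, 24), arm = "DMSO",
                 replicate = c(1, 2, 1), genes = c("gA", "gB"))
  tc2 <- normalize_to_baseline(summarize_probes_to_genes(em2))
  expect_equal(tc2$log2ratio, tc$log2ratio)
})

test_that("baseline normalization requires 0 h arrays per arm", {
  lm <- rbind(gA = c(3, 5))
  em <- make_em(lm, time_h = c(2, 24), arm = "DMSO", replicate = 1,
                genes = "gA")
  expect_error(normalize_to_baseline(summarize_probes_to_genes(em)),
               "no 0 h")
})

test_that("exact permutation p matches independent enumeration", {
  # independent oracle: walk all 20 splits of 6 values into 3 + 3
  oracle <- function(x, y) {
    pool <- c(x, y)
    obs <- mean(x) - mean(y)
    cnt <- 0; tot <- 0
    for (i in 1:4) for (j in (i + 1):5) for (k in (j + 1):6) {
      g1 <- pool[c(i, j, k)]; g2 <- pool[-c(i, j, k)]
      tot <- tot + 1
      if (abs(mean(g1) - mean(g2)) >= abs(obs) - 1e-12) cnt <- cnt + 1
    }
    cnt / tot
  }
  expect_equal(permutation_de_test(c(0, 0, 0), c(5, 5, 5)), 0.1)
  expect_equal(oracle(c(0, 0, 0), c(5, 5, 5)), 0.1)
  set.seed(5)
  for (i in 1:10) {
    x <- stats::rnorm(3); y <- stats::rnorm(3)
    expect_equal(permutation_de_test(x, y), oracle(x, y))
  }
  # identical groups: every split at least as extreme
  expect_equal(permutation_de_test(c(1, 2, 3), c(1, 2, 3)), 1)
})

test_that("sampled permutation path is seeded and guarded", {
  set.seed(6)
  x <- stats::rnorm(15, 1); y <- stats::rnorm(15)
  p1 <- permutation_de_test(x, y, B = 199, seed = 7)
  p2 <- permutation_de_test(x, y, B = 199, seed = 7)
  expect_equal(p1, p2)
  expect_gte(p1, 1 / 200)
  expect_error(permutation_de_test(x, y, B = 50, seed = 1), "at least 99")
  expect_error(permutation_de_test(1, c(1, 2)), "at least 2")
})

test_that("pooled DE test recovers planted genes and respects SIS3", {
  tr <- plant_expression_truth(sprintf("e%04d", 1:300), 15, 15,
                               effect_log2 = 1.5, sis3_attenuation = 0,
                               seed = 8)
  em <- simulate_expression_timecourse(300, truth = tr,
                                       noise_sd_log2 = 0.25, seed = 9)
  tc <- normalize_to_baseline(summarize_probes_to_genes(em))
  de <- de_test_timepoint(tc, "DMSO", 24)
  planted <- tr$gene_id[tr$direction != "null"]
  expect_gte(mean(de$p_adj[match(planted, de$gene_id)] < 0.1), 0.8)
  # directions match the planted signs
  up <- tr$gene_id[tr$direction == "up"]
  expect_true(all(de$stat[match(up, de$gene_id)] > 0))
  # fully attenuated arm: the same genes are quiet
  de_s <- de_test_timepoint(tc, "SIS3", 24)
  expect_lte(mean(de_s$p_adj[match(planted, de_s$gene_id)] < 0.1), 0.1)
})

test_that("p-value adjustment wraps the standard corrections", {
  expect_equal(adjust_pvalues(c(0.01, rep(1, 9)), "bonferroni")[1], 0.1)
  p <- rep(0.03, 5)
  expect_equal(adjust_pvalues(p, "bh"), p)
  set.seed(10)
  p <- stats::runif(20)
  adj <- adjust_pvalues(p, "bh")
  expect_true(all(diff(adj[order(p)]) >= 0)) # monotone in input ranks
  expect_error(adjust_pvalues(numeric(0)), "empty")
})

test_that("delta-delta-Ct gives the textbook fold changes", {
  expect_equal(delta_delta_ct(20, 15, 20, 15),
               list(ddct = 0, fold_change = 1))
  expect_equal(delta_delta_ct(19, 15, 20, 15)$fold_change, 2)
  expect_equal(delta_delta_ct(22, 15, 20, 15)$fold_change, 0.25)
  expect_error(delta_delta_ct(NA, 1, 1, 1), "finite")
})
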