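test_that("the binding filter applies the p/height/replicate rules", {
  p <- rbind(gA = c(0.005, 0.02, 0.005),
             gB = c(0.02, 0.02, 0.005),
             gC = c(0.005, 0.005, 0.005))
  h <- rbind(gA = c(2.0, 1.2, 2.2),
             gB = c(2.0, 2.0, 2.0),
             gC = c(1.2, 1.3, 1.4))
  ctr <- matrix(-500, 3, 3, dimnames = dimnames(p))
  res <- apply_binding_filter(p, h, ctr)
  # gA: 2 reps below 0.01, median passing height (2.0, 2.2) = 2.1 > 1.5
  expect_true(res$passes[res$gene_id == "gA"])
  expect_equal(res$consensus_height[res$gene_id == "gA"], 2.1)
  # gB: only 1 replicate below 0.01
  expect_false(res$passes[res$gene_id == "gB"])
  # gC: replicate support but median height 1.3 fails the 1.5 filter
  expect_false(res$passes[res$gene_id == "gC"])
  expect_equal(res$n_pass_reps, c(2L, 1L, 3L))
})

test_that("tightening thresholds never adds a passing gene", {
  set.seed(30)
  p <- matrix(stats::runif(60, 0, 0.05), 20, 3)
  h <- matrix(stats::runif(60, 1, 3), 20, 3)
  ctr <- matrix(0, 20, 3)
  base <- apply_binding_filter(p, h, ctr, p_thresh = 0.01,
                               height_thresh = 1.5)
  tighter_p <- apply_binding_filter(p, h, ctr, p_thresh = 0.005,
                                    height_thresh = 1.5)
  tighter_h <- apply_binding_filter(p, h, ctr, p_thresh = 0.01,
                                    height_thresh = 2)
  expect_true(all(!tighter_p$passes | base$passes))
  expect_true(all(!tighter_h$passes | base$passes))
})

test_that("call_condition recovers a strong planted event end to end", {
  layout <- generate_layout(40, seed = 31)
  truth <- plant_chip_truth(layout, 0.2, 4, "stimulated", seed = 32)
  arr <- simulate_chip_arrays(layout, truth, noise_sd_log2 = 0.05,
                              n_replicates = 3, seed = 33)
  calls <- call_condition(arr, "stimulated", shape_uniform, B = 99,
                          seed = 34)
  bound <- truth$gene_id[truth$true_fold > 1]
  # at this small scale the pooled null is coarse; most events must pass
  expect_gte(mean(bound %in% calls$gene_id[calls$passes]), 0.75)
  # fitted centers land near the planted centers for every planted event
  ctr_err <- abs(calls$consensus_center[match(bound, calls$gene_id)] -
                   truth$true_center[match(bound, truth$gene_id)])
  expect_true(all(ctr_err <= 150))
  # replicate detail is exposed
  rc <- attr(calls, "replicate_calls")
  expect_equal(nrow(rc), 40 * 3)
})

test_that("call_condition validates replicates and conditions", {
  layout <- generate_layout(5, seed = 35)
  truth <- chip_truth(unique(layout$gene_id), 0L, 1, "basal")
  arr <- simulate_chip_arrays(layout, truth, n_replicates = 1, seed = 36)
  expect_error(call_condition(arr, "basal", shape_uniform, min_reps = 2),
               "at least 2 replicates")
  expect_error(call_condition(arr, "stimulated", shape_uniform),
               "no arrays")
})

test_that("condition comparison partitions genes exhaustively", {
  basal <- data.frame(gene_id = c("g1", "g2", "g3"),
                      consensus_height = c(2.0, 1.2, 1.8),
                      passes = c(TRUE, FALSE, TRUE))
  stim <- data.frame(gene_id = c("g1", "g2", "g4"),
                     consensus_height = c(3.0, 2.5, 1.1),
                     passes = c(TRUE, TRUE, FALSE))
  part <- compare_conditions(basal, stim)
  expect_setequal(part$gene_id, c("g1", "g2", "g3", "g4"))
  expect_equal(part$status[part$gene_id == "g1"], "both")
  expect_equal(part$status[part$gene_id == "g2"], "stimulated_only")
  expect_equal(part$status[part$gene_id == "g3"], "basal_only")
  expect_equal(part$status[part$gene_id == "g4"], "neither")
  expect_equal(part$height_delta[part$gene_id == "g1"], 1.0)
  # exhaustive and disjoint by construction: one status per gene
  expect_equal(anyDuplicated(part$gene_id), 0)
  empty <- compare_conditions(basal[0, ], stim[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("bound regions are 201 bp, truncated and flagged at edges", {
  seqs <- c(gA = paste(rep("A", 2801), collapse = ""),
            gB = paste(rep("C", 2801), collapse = ""))
  calls <- data.frame(gene_id = c("gA", "gB"),
                      consensus_center = c(-500, -1990),
                      passes = c(TRUE, TRUE),
                      condition = "stimulated")
  reg <- extract_bound_regions(calls, seqs)
  expect_equal(reg$start_offset[1], -600)
  expect_equal(reg$end_offset[1], -400)
  expect_equal(reg$width[1], 201)
  expect_false(reg$truncated[1])
  # center 10 bp from the upstream end: truncated and flagged
  expect_equal(reg$start_offset[2], -2000)
  expect_lt(reg$width[2], 201)
  expect_true(reg$truncated[2])
  expect_equal(nchar(reg$sequence), reg$width)
})

test_that("region extraction errors on missing sequences, empty in empty out", {
  calls <- data.frame(gene_id = "gZ", consensus_center = 0, passes = TRUE,
                      condition = "basal")
  expect_error(extract_bound_regions(calls, c(gA = "ACGT")), "gZ")
  none <- extract_bound_regions(
    data.frame(gene_id = "gA", consensus_center = 0, passes = FALSE,
               condition = "basal"),
    c(gA = paste(rep("A", 2801), collapse = ""))
  )
  expect_equal(nrow(none), 0)
})
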