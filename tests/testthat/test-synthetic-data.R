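test_that("generated layouts satisfy the tiling invariants", {
  layout <- generate_layout(1000, seed = 1)
  expect_true(all(layout$offset_bp >= -2000 & layout$offset_bp <= 800))
  counts <- table(layout$gene_id)
  expect_true(all(counts %in% 4:6))
  gaps <- unlist(tapply(layout$offset_bp, layout$gene_id, diff))
  expect_true(all(gaps >= 250 & gaps <= 350))
})

test_that("layout generation is deterministic and validates input", {
  expect_identical(generate_layout(25, seed = 7), generate_layout(25, seed = 7))
  expect_false(identical(generate_layout(25, seed = 7),
                         generate_layout(25, seed = 8)))
  expect_error(generate_layout(0, seed = 1), "at least 1")
})

test_that("zero-noise null simulation gives IP/mock ratios of exactly 1", {
  layout <- generate_layout(10, seed = 2)
  truth <- chip_truth(unique(layout$gene_id), 0L, 1, "basal")
  arr <- simulate_chip_arrays(layout, truth, noise_sd_log2 = 0,
                              n_replicates = 2, seed = 3)
  expect_equal(arr$ip_intensity / arr$mock_intensity,
               rep(1, nrow(arr)))
})

test_that("zero-noise planted event reproduces the forward model at probes", {
  layout <- manual_layout(c(-800, -500, -200, 100))
  truth <- chip_truth("gX", -500L, 3, "stimulated")
  arr <- simulate_chip_arrays(layout, truth, noise_sd_log2 = 0,
                              n_replicates = 1, seed = 4)
  ratio <- arr$ip_intensity / arr$mock_intensity
  expect_equal(ratio[arr$offset_bp == -500], 3) # s(0) = 1
  expect_equal(ratio, 1 + 2 * shape_at(shape_uniform, arr$offset_bp + 500))
})

test_that("truth referencing an unknown gene is a consistency error", {
  layout <- generate_layout(5, seed = 5)
  truth <- chip_truth("not_a_gene", 0L, 2, "basal")
  expect_error(simulate_chip_arrays(layout, truth), "absent from the layout")
})

test_that("chip array simulation is deterministic given the seed", {
  layout <- generate_layout(8, seed = 6)
  truth <- plant_chip_truth(layout, 0.25, 3, seed = 7)
  a1 <- simulate_chip_arrays(layout, truth, seed = 8)
  a2 <- simulate_chip_arrays(layout, truth, seed = 8)
  expect_identical(a1, a2)
})

test_that("promoter sequences are deterministic and carry planted instances", {
  layout <- generate_layout(6, seed = 9)
  m <- sharp_motif()
  genes <- unique(layout$gene_id)
  s1 <- generate_promoter_sequences(layout, m, plant_in = genes[1:3],
                                    seed = 10)
  s2 <- generate_promoter_sequences(layout, m, plant_in = genes[1:3],
                                    seed = 10)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_equal(nrow(s1$truth), 3)
  # each planted instance sits where the truth table says
  for (i in seq_len(nrow(s1$truth))) {
    g <- s1$truth$gene_id[i]
    pos <- s1$truth$start_offset[i] - (-2000) + 1
    found <- substr(as.character(s1$sequences[[g]]), pos,
                    pos + m$width - 1)
    expect_equal(found, s1$truth$instance[i])
  }
  # all sequences cover the tiled span
  expect_true(all(Biostrings::width(s1$sequences) == 2801))
})

test_that("planting without a motif or with bad GC fraction errors", {
  layout <- generate_layout(3, seed = 11)
  expect_error(generate_promoter_sequences(layout, NULL,
                                           plant_in = layout$gene_id[1]),
               "requires a motif")
  expect_error(generate_promoter_sequences(layout, background_gc = 1),
               "in \\(0, 1\\)")
})

test_that("expression simulation honors zero-effect identities", {
  tr <- expression_truth(sprintf("e%04d", 1:20))
  em <- simulate_expression_timecourse(20, truth = tr, dye_bias = 0,
                                       noise_sd_log2 = 0, seed = 12)
  # no effects, no bias, no noise: every array is identical
  expect_equal(max(apply(em$intensity, 1, stats::sd)), 0)
})

test_that("full SIS3 attenuation cancels the planted effect", {
  tr <- expression_truth(sprintf("e%04d", 1:10),
                         direction = c("up", rep("null", 9)),
                         effect_log2 = c(2, rep(0, 9)),
                         sis3_attenuation = 0)
  em <- simulate_expression_timecourse(10, truth = tr, dye_bias = 0,
                                       noise_sd_log2 = 0, seed = 13)
  des <- em$design
  i24 <- which(des$arm == "SIS3" & des$time_h == 24)[1]
  i0 <- which(des$arm == "SIS3" & des$time_h == 0)[1]
  expect_equal(em$intensity[, i24], em$intensity[, i0])
  # and the DMSO arm keeps it
  j24 <- which(des$arm == "DMSO" & des$time_h == 24)[1]
  j0 <- which(des$arm == "DMSO" & des$time_h == 0)[1]
  up_probes <- em$probe_genes == "e0001"
  expect_equal(unname(log2(em$intensity[up_probes, j24]) -
                        log2(em$intensity[up_probes, j0])),
               rep(2, sum(up_probes)))
})

test_that("expression design must include the 0 h baseline", {
  expect_error(simulate_expression_timecourse(5, times = c(2, 12, 24)),
               "0 h baseline")
})

test_that("gene sets are deterministic, sized, and validated", {
  u <- sprintf("g%03d", 1:100)
  s1 <- generate_gene_sets(u, 5, c(10, 20), enriched_genes = u[1:10],
                           seed = 14)
  s2 <- generate_gene_sets(u, 5, c(10, 20), enriched_genes = u[1:10],
                           seed = 14)
  expect_identical(s1, s2)
  expect_equal(lengths(s1, use.names = FALSE), c(10, 20, 10, 20, 10))
  expect_gte(length(intersect(s1$enriched_set, u[1:10])), 8)
  expect_error(generate_gene_sets(u, 2, 0), "positive")
  expect_error(generate_gene_sets(u, 2, 1000), "universe")
})
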