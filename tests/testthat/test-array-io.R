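test_that("chip tables survive a write/read round trip", {
  dir <- withr::local_tempdir()
  layout <- generate_layout(6, seed = 1)
  truth <- plant_chip_truth(layout, 0.5, 3, seed = 2)
  arr <- simulate_chip_arrays(layout, truth, n_replicates = 2, seed = 3)
  manifest <- write_chip_tables(arr, dir)
  back <- read_chip_tables(manifest, layout)
  key <- function(x) x[order(x$condition, x$replicate, x$probe_id), ]
  a <- key(as.data.frame(arr))
  b <- key(as.data.frame(back))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b[names(a)], a, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(attr(back, "n_dropped"), 0L)
})

test_that("alien probe ids are dropped with a warning and counted", {
  dir <- withr::local_tempdir()
  layout <- generate_layout(3, seed = 4)
  truth <- chip_truth(unique(layout$gene_id), 0L, 1, "basal")
  arr <- simulate_chip_arrays(layout, truth, n_replicates = 1, seed = 5)
  manifest <- write_chip_tables(arr, dir)
  tab <- utils::read.table(manifest$path[1], header = TRUE, sep = "\t")
  tab <- rbind(tab, data.frame(probe_id = "alien_probe", gene_id = "zz",
                               offset_bp = 0, ip_intensity = 1,
                               mock_intensity = 1))
  utils::write.table(tab, manifest$path[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_warning(back <- read_chip_tables(manifest, layout), "unknown probe")
  expect_equal(attr(back, "n_dropped"), 1L)
  expect_false("alien_probe" %in% back$probe_id)
})

test_that("empty and invalid chip tables are structured errors", {
  dir <- withr::local_tempdir()
  layout <- generate_layout(2, seed = 6)
  empty <- file.path(dir, "empty.tsv")
  file.create(empty)
  manifest <- data.frame(path = empty, condition = "basal", replicate = 1)
  expect_error(read_chip_tables(manifest, layout), "empty|unreadable")
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("probe_id\tgene_id\toffset_bp\tip_intensity\tmock_intensity",
               sprintf("%s\t%s\t%d\t-5\t10", layout$probe_id[1],
                       layout$gene_id[1], layout$offset_bp[1])), bad)
  manifest$path <- bad
  expect_error(read_chip_tables(manifest, layout), "non-positive")
})

test_that("peak tables round trip at 6 decimals and come out sorted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  peaks <- data.frame(
    gene_id = c("g2", "g1", "g1"),
    center = c(-100.1234567, 250, -75),
    height = c(2.3456789, 1.9, 3.1),
    llr = c(8.1, 5.5, 9.9),
    pvalue = c(0.001, 0.02, 0.0005),
    condition = c("basal", "stimulated", "basal")
  )
  write_peaks(peaks, path)
  back <- read_peaks(path)
  expect_equal(back$gene_id, c("g1", "g1", "g2"))
  expect_equal(back$center_offset[back$gene_id == "g2"], -100.123457,
               tolerance = 1e-9)
  expect_equal(sort(back$height), sort(round(peaks$height, 6)))
})

test_that("an empty peak list writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peaks(data.frame(), path)
  back <- read_peaks(path)
  expect_equal(nrow(back), 0)
  expect_true(all(c("gene_id", "center_offset", "height", "llr", "pvalue",
                    "condition") %in% names(back)))
})

test_that("TRANSFAC count blocks are parsed and column-normalized", {
  path <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID test_matrix", "XX", "P0 A C G T",
               "01 10 0 0 0 A", "02 0 10 0 0 C", "XX", "//"), path)
  m <- read_motif_matrix(path, "transfac_counts")
  expect_equal(m$width, 2)
  expect_equal(unname(m$freq[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(m$freq[, 2]), c(0, 1, 0, 0))
  expect_equal(m$name, "test_matrix")
})

test_that("TRANSFAC parsing rejects zero columns, ragged and negative rows", {
  bad1 <- withr::local_tempfile()
  writeLines(c("P0 A C G T", "01 0 0 0 0 N", "XX"), bad1)
  expect_error(read_motif_matrix(bad1, "transfac_counts"), "zero")
  bad2 <- withr::local_tempfile()
  writeLines(c("P0 A C G T", "01 1 2 3", "XX"), bad2)
  expect_error(read_motif_matrix(bad2, "transfac_counts"), "ragged|row")
  bad3 <- withr::local_tempfile()
  writeLines(c("P0 A C G T", "01 1 -2 3 4 N", "XX"), bad3)
  expect_error(read_motif_matrix(bad3, "transfac_counts"), "negative")
})

test_that("UniPROBE probability rows are accepted when columns sum to 1", {
  m <- read_motif_matrix(
    system.file("extdata", "smad_like_synthetic_uniprobe.txt",
                package = "tilepeak"),
    "uniprobe_prob"
  )
  expect_equal(m$width, 10)
  expect_equal(colSums(m$freq), rep(1, 10), tolerance = 1e-6)
  # agrees with the count-dialect version of the same synthetic matrix
  mt <- read_motif_matrix(
    system.file("extdata", "smad_like_synthetic.transfac",
                package = "tilepeak"),
    "transfac_counts"
  )
  expect_equal(motif_consensus(m), motif_consensus(mt))
})

test_that("UniPROBE columns that do not sum to 1 are rejected", {
  bad <- withr::local_tempfile()
  writeLines(c("A: 0.5 0.5", "C: 0.5 0.5", "G: 0.5 0.5", "T: 0.5 0.5"), bad)
  expect_error(read_motif_matrix(bad, "uniprobe_prob"), "sum to 1")
})

test_that("GMT files round trip and malformed lines error", {
  path <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9"))
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("only_name\tdesc", bad)
  expect_error(read_gmt(bad), "fewer than 3")
})

test_that("expression tables round trip through the long TSV format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tr <- expression_truth(sprintf("e%04d", 1:4))
  em <- simulate_expression_timecourse(4, truth = tr, probes_per_gene = 2,
                                       seed = 20)
  write_expression_table(em, path)
  back <- read_expression_table(path)
  expect_equal(dim(back$intensity), dim(em$intensity))
  common <- intersect(rownames(back$intensity), rownames(em$intensity))
  expect_equal(back$intensity[common, em$design$array_id],
               em$intensity[common, ], tolerance = 1e-6)
})

test_that("fasta round trips preserve ids and sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  layout <- generate_layout(3, seed = 21)
  s <- generate_promoter_sequences(layout, seed = 22)
  write_fasta(s$sequences, path)
  back <- read_fasta(path)
  expect_equal(names(back), names(s$sequences))
  expect_equal(as.character(back), as.character(s$sequences))
})
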