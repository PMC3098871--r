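# Shared fixtures: built once per test run.

shape_uniform <- peak_shape(frag_dist_uniform())

# A small layout with a probe exactly at a chosen center, for forward-model
# identities.
manual_layout <- function(offsets, gene = "gX") {
  data.frame(
    probe_id = sprintf("%s_p%d", gene, seq_along(offsets)),
    gene_id = gene,
    offset_bp = as.integer(offsets),
    stringsAsFactors = FALSE
  )
}

# A sharp-ish, non-palindromic test motif used across motif tests.
sharp_motif <- function(width = 8, p = 0.85) {
  freq <- matrix((1 - p) / 3, 4, width,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- rep(c("G", "T", "C", "T", "A", "G", "G", "A"), length.out = width)
  for (j in seq_len(width)) freq[cons[j], j] <- p
  motif_matrix(freq)
}

# Enumerate the full background score distribution of a motif (uniform base
# model, equal mass per sequence); independent of the sampling path.
enumerate_scores <- function(m) {
  sc <- 0
  for (j in seq_len(m$width)) {
    sc <- as.vector(outer(sc, m$log_odds[, j], "+"))
  }
  sort(sc)
}

# Minimal expression matrix from a log2 value matrix.
make_em <- function(log2mat, time_h, arm, replicate, genes = NULL) {
  n <- nrow(log2mat)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (is.null(rownames(log2mat))) {
    rownames(log2mat) <- paste0("p", seq_len(n))
  }
  des <- data.frame(
    array_id = sprintf("a%d", seq_len(ncol(log2mat))),
    time_h = time_h, arm = arm, replicate = replicate,
    stringsAsFactors = FALSE
  )
  expr_matrix(2^log2mat, des, genes)
}
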