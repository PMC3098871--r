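#' Construct a position weight matrix with log-odds scores
#'
#' Per-position base frequencies over A, C, G, T are converted to log-odds
#' scores against a uniform background with a pseudocount:
#' `log_odds = ln((freq + pc) / (1 + 4 pc) / 0.25)` per cell. Frequencies
#' must be column-normalized (each position sums to 1 within 1e-6).
#'
#' @param freq A 4 x width numeric matrix with rownames `A`, `C`, `G`, `T`
#'   (a width x 4 matrix is transposed automatically).
#' @param pseudocount Pseudocount `pc` added to each frequency.
#' @param name Optional matrix name.
#' @return An object of class `motif_matrix` with elements `name`, `width`,
#'   `freq`, `log_odds`, `pseudocount`, `cutoff` (NA until
#'   [calibrate_cutoff()] is run) and `alpha`.
#' @export
motif_matrix <- function(freq, pseudocount = 0.01, name = "motif") {
  freq <- as.matrix(freq)
  if (ncol(freq) == 4L && nrow(freq) != 4L) freq <- t(freq)
  if (nrow(freq) != 4L) stop("'freq' must have 4 rows (A, C, G, T)")
  if (is.null(rownames(freq))) rownames(freq) <- c("A", "C", "G", "T")
  freq <- freq[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(freq) < 1L) stop("motif matrix must have at least one position")
  if (any(!is.finite(freq)) || any(freq < 0)) {
    stop("motif frequencies must be finite and non-negative")
  }
  cs <- colSums(freq)
  if (any(cs <= 0)) stop("motif matrix has an all-zero column")
  if (any(abs(cs - 1) > 1e-6)) stop("motif frequency columns must sum to 1")
  lo <- log((freq + pseudocount) / (1 + 4 * pseudocount) / 0.25)
  structure(
    list(name = name, width = ncol(freq), freq = freq, log_odds = lo,
         pseudocount = pseudocount, cutoff = NA_real_, alpha = NA_real_),
    class = "motif_matrix"
  )
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("Motif matrix '%s': width %d, consensus %s%s\n",
              x$name, x$width, motif_consensus(x),
              if (is.na(x$cutoff)) " (no cutoff calibrated)"
              else sprintf(", cutoff %.3f at alpha %g", x$cutoff, x$alpha)))
  invisible(x)
}

#' Consensus sequence of a motif matrix
#'
#' @param m A [motif_matrix()].
#' @return The most probable base at each position, as a string.
#' @export
motif_consensus <- function(m) {
  paste(rownames(m$freq)[apply(m$freq, 2L, which.max)], collapse = "")
}

## Encode a DNA string as indices into ACGT; other letters (incl. N) -> NA.
encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  code
}

## Score every width-window of an encoded sequence with a log-odds matrix.
## Windows containing non-ACGT letters score NA.
score_windows_encoded <- function(code, lo) {
  w <- ncol(lo)
  n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    b <- code[j:(j + n - 1L)]
    sc <- sc + ifelse(is.na(b), NA_real_, lo[cbind(b, j)])
  }
  sc
}

#' Calibrate the type-I score cutoff by background sampling
#'
#' Samples `n_samples` i.i.d. sequences of the motif width with uniform base
#' probabilities (0.25 each), scores them with the log-odds matrix, and sets
#' the cutoff to the empirical `(1 - alpha)` quantile (inverse-ECDF order
#' statistic). A random background window then exceeds the cutoff with
#' probability approximately `alpha`.
#'
#' @param m A [motif_matrix()].
#' @param alpha Per-window type-I rate in `(0, 1)`.
#' @param n_samples Number of background samples (at least 100).
#' @param seed Optional integer seed.
#' @return `m` with `cutoff` and `alpha` filled in.
#' @export
calibrate_cutoff <- function(m, alpha = 0.05, n_samples = 10000, seed = NULL) {
  if (!inherits(m, "motif_matrix")) stop("'m' must be a motif_matrix")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (n_samples < 100) stop("'n_samples' must be at least 100")
  if (any(!is.finite(m$log_odds))) {
    stop("degenerate matrix: non-finite log-odds (increase the pseudocount)")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- m$width
  sc <- numeric(n_samples)
  for (j in seq_len(w)) {
    sc <- sc + m$log_odds[cbind(sample.int(4L, n_samples, replace = TRUE), j)]
  }
  idx <- max(1L, ceiling((1 - alpha) * n_samples))
  m$cutoff <- sort(sc)[idx]
  m$alpha <- alpha
  m
}

#' Scan a sequence for motif hits on both strands
#'
#' Slides the motif over every width-window of the sequence; minus-strand
#' windows are scored by scanning with the reverse-complemented matrix.
#' Windows containing `N` (or any non-ACGT letter) are skipped. A hit is a
#' window scoring at or above the calibrated cutoff.
#'
#' @param seq A single DNA string (character or [Biostrings::DNAString]).
#' @param m A [motif_matrix()] with a calibrated cutoff (or supply `cutoff`).
#' @param cutoff Score threshold; defaults to `m$cutoff`.
#' @return A `data.frame` of hits: `position` (0-based window start on the
#'   plus strand), `strand` (`"+"`/`"-"`), `score`.
#' @export
scan_region <- function(seq, m, cutoff = m$cutoff) {
  if (!inherits(m, "motif_matrix")) stop("'m' must be a motif_matrix")
  if (is.na(cutoff)) stop("no cutoff: run calibrate_cutoff() first")
  seq <- as.character(seq)
  if (length(seq) != 1L) stop("'seq' must be a single sequence")
  if (nchar(seq) < m$width) {
    stop("sequence shorter than the motif width (", m$width, ")")
  }
  code <- encode_dna(seq)
  lo <- m$log_odds
  # reverse complement of the matrix: complement rows (A<->T, C<->G),
  # reverse columns; scanning plus-strand windows with it scores the minus
  # strand at the same window start.
  lo_rc <- lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
  sc_p <- score_windows_encoded(code, lo)
  sc_m <- score_windows_encoded(code, lo_rc)
  # tolerance so windows scoring exactly at the cutoff are treated the same
  # on both strands despite summation-order float jitter
  thr <- cutoff - 1e-9 * max(1, abs(cutoff))
  hit_p <- which(!is.na(sc_p) & sc_p >= thr)
  hit_m <- which(!is.na(sc_m) & sc_m >= thr)
  out <- data.frame(
    position = c(hit_p, hit_m) - 1L,
    strand = rep(c("+", "-"), c(length(hit_p), length(hit_m))),
    score = c(sc_p[hit_p], sc_m[hit_m]),
    stringsAsFactors = FALSE
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

## Best score over both strands (NA windows ignored); -Inf if no scorable
## window.
best_score <- function(seq, m) {
  code <- encode_dna(as.character(seq))
  lo <- m$log_odds
  lo_rc <- lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
  sc <- c(score_windows_encoded(code, lo), score_windows_encoded(code, lo_rc))
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0) -Inf else max(sc)
}

#' Fraction of bound regions containing a motif hit
#'
#' Scans each region on both strands with the calibrated cutoff and reports
#' the fraction of regions with at least one hit, plus a per-region table of
#' best scores. Invariant to the order of regions.
#'
#' @param regions A `data.frame` with columns `gene_id` and `sequence` (as
#'   from [extract_bound_regions()]), a named character vector, or a
#'   [Biostrings::DNAStringSet].
#' @param m A [motif_matrix()] with a calibrated cutoff.
#' @return A list with `fraction` and `table` (`gene_id`, `best_score`,
#'   `hit`).
#' @export
fraction_with_hit <- function(regions, m) {
  if (!inherits(m, "motif_matrix")) stop("'m' must be a motif_matrix")
  if (is.na(m$cutoff)) stop("no cutoff: run calibrate_cutoff() first")
  if (is.data.frame(regions)) {
    ids <- if ("gene_id" %in% names(regions)) regions$gene_id
           else as.character(seq_len(nrow(regions)))
    seqs <- regions$sequence
  } else {
    seqs <- as.character(regions)
    ids <- if (!is.null(names(seqs))) names(seqs)
           else as.character(seq_along(seqs))
  }
  if (length(seqs) < 1) stop("'regions' must contain at least one region")
  best <- vapply(seqs, best_score, numeric(1), m = m, USE.NAMES = FALSE)
  hit <- is.finite(best) & best >= m$cutoff - 1e-9 * max(1, abs(m$cutoff))
  list(
    fraction = mean(hit),
    table = data.frame(gene_id = ids, best_score = best, hit = hit,
                       stringsAsFactors = FALSE)
  )
}
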