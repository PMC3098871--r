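#' Generate a promoter tiling-array probe layout
#'
#' Emulates a promoter array in which each promoter is tiled by 4-6 probes
#' placed on a jittered ~300 bp grid spanning 2000 bp upstream to 800 bp
#' downstream of the TSS: consecutive probe offsets within a gene differ by
#' 250-350 bp and all offsets lie in `span`.
#'
#' @param n_genes Number of promoters (at least 1).
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @param span Tiled span in bp relative to the TSS (0 at the TSS).
#' @param probes_range Inclusive range of probes per gene.
#' @param spacing_range Inclusive range of consecutive probe spacings in bp.
#' @return A `data.frame` with columns `probe_id`, `gene_id`, `offset_bp`.
#' @examples
#' head(generate_layout(2, seed = 7))
#' @export
generate_layout <- function(n_genes, seed, span = c(-2000L, 800L),
                            probes_range = c(4L, 6L),
                            spacing_range = c(250L, 350L)) {
  if (n_genes < 1) stop("'n_genes' must be at least 1")
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  n_probes <- sample(seq.int(probes_range[1], probes_range[2]),
                     n_genes, replace = TRUE)
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    k <- n_probes[i]
    gaps <- sample(seq.int(spacing_range[1], spacing_range[2]),
                   k - 1L, replace = TRUE)
    total <- sum(gaps)
    first <- sample(seq.int(span[1], span[2] - total), 1L)
    off <- as.integer(first + c(0L, cumsum(gaps)))
    rows[[i]] <- data.frame(
      probe_id = sprintf("%s_p%d", gene_ids[i], seq_len(k)),
      gene_id = gene_ids[i],
      offset_bp = off,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a ChIP truth table
#'
#' One row per (gene, condition): the planted binding-event center (bp
#' offset) and fold enrichment. `true_fold = 1` encodes "no event".
#'
#' @param gene_id,true_center,true_fold,condition Vectors recycled to a
#'   common length; `condition` values are typically `"basal"` or
#'   `"stimulated"`.
#' @return A `data.frame` with those four columns.
#' @export
chip_truth <- function(gene_id, true_center = 0L, true_fold = 1,
                       condition = "stimulated") {
  if (any(true_fold < 1)) stop("'true_fold' must be >= 1 (1 = no event)")
  data.frame(
    gene_id = as.character(gene_id),
    true_center = as.integer(true_center),
    true_fold = as.numeric(true_fold),
    condition = as.character(condition),
    stringsAsFactors = FALSE
  )
}

#' Plant binding events in a fraction of promoters
#'
#' Picks `round(frac_bound * n_genes)` genes at random and assigns each a
#' binding event at a uniform position within its probe span; all other
#' genes get `true_fold = 1`.
#'
#' @param layout A probe layout from [generate_layout()].
#' @param frac_bound Fraction of genes with an event.
#' @param fold Fold enrichment of planted events.
#' @param condition Condition label for the truth rows.
#' @param seed Integer seed.
#' @param on_grid Optional grid step; when given, planted centers are
#'   snapped to multiples of it (useful for exact-inversion checks).
#' @return A [chip_truth()] table covering every gene in the layout.
#' @export
plant_chip_truth <- function(layout, frac_bound = 0.1, fold = 3,
                             condition = "stimulated", seed = 1,
                             on_grid = NULL) {
  set.seed(seed)
  genes <- unique(layout$gene_id)
  n_bound <- round(frac_bound * length(genes))
  bound <- sample(genes, n_bound)
  centers <- integer(length(genes))
  folds <- rep(1, length(genes))
  names(centers) <- names(folds) <- genes
  for (g in bound) {
    off <- layout$offset_bp[layout$gene_id == g]
    ctr <- sample(seq.int(min(off), max(off)), 1L)
    if (!is.null(on_grid)) ctr <- on_grid * round(ctr / on_grid)
    centers[g] <- as.integer(ctr)
    folds[g] <- fold
  }
  chip_truth(genes, centers, folds, condition)
}

#' Simulate two-color ChIP tiling arrays with planted binding events
#'
#' Forward model: the expected IP/mock ratio at a probe at offset `x` of a
#' gene with a planted event `(c, f)` is `1 + (f - 1) * s(x - c)` with `s`
#' from [peak_shape()]. The mock channel is centered at a common background
#' intensity; both channels receive independent multiplicative log-normal
#' noise with standard deviation `noise_sd_log2` on the log2 scale, drawn
#' independently per probe, replicate and channel.
#'
#' @param layout A probe layout from [generate_layout()].
#' @param truth A [chip_truth()] table; every `gene_id` must be in the
#'   layout. May contain several conditions.
#' @param frag_dist A [fragment_length_dist()] driving the event shape.
#' @param noise_sd_log2 Per-channel log2 noise standard deviation (>= 0).
#' @param n_replicates Number of array replicates per condition (>= 1).
#' @param background Common mock-channel background intensity.
#' @param seed Integer seed.
#' @return A `chip_array_set`: a long `data.frame` with columns `probe_id`,
#'   `gene_id`, `offset_bp`, `ip_intensity`, `mock_intensity`, `condition`,
#'   `replicate`, with the truth table attached as attribute `"truth"`.
#' @export
simulate_chip_arrays <- function(layout, truth,
                                 frag_dist = frag_dist_uniform(),
                                 noise_sd_log2 = 0.1, n_replicates = 3,
                                 background = 1000, seed = 1) {
  if (noise_sd_log2 < 0) stop("'noise_sd_log2' must be non-negative")
  if (n_replicates < 1) stop("'n_replicates' must be at least 1")
  missing <- setdiff(truth$gene_id, layout$gene_id)
  if (length(missing) > 0) {
    stop("truth references genes absent from the layout: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  shape <- peak_shape(frag_dist)
  set.seed(seed)
  conditions <- unique(truth$condition)
  out <- vector("list", length(conditions) * n_replicates)
  k <- 0L
  for (cond in conditions) {
    tr <- truth[truth$condition == cond, ]
    ctr <- tr$true_center[match(layout$gene_id, tr$gene_id)]
    fld <- tr$true_fold[match(layout$gene_id, tr$gene_id)]
    ctr[is.na(ctr)] <- 0L
    fld[is.na(fld)] <- 1
    ratio <- 1 + (fld - 1) * shape_at(shape, layout$offset_bp - ctr)
    for (rep_i in seq_len(n_replicates)) {
      n <- nrow(layout)
      e_ip <- stats::rnorm(n, 0, noise_sd_log2)
      e_mock <- stats::rnorm(n, 0, noise_sd_log2)
      k <- k + 1L
      out[[k]] <- data.frame(
        probe_id = layout$probe_id,
        gene_id = layout$gene_id,
        offset_bp = layout$offset_bp,
        ip_intensity = background * ratio * 2^e_ip,
        mock_intensity = background * 2^e_mock,
        condition = cond,
        replicate = rep_i,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- truth
  class(res) <- c("chip_array_set", "data.frame")
  res
}

#' Validate a chip_array_set
#'
#' Checks positive intensities in both channels and unique
#' `(probe_id, condition, replicate)` rows.
#'
#' @param x A long probe table as returned by [simulate_chip_arrays()] or
#'   [read_chip_tables()].
#' @return `x`, classed as `chip_array_set`, invisibly on success.
#' @export
validate_chip_array_set <- function(x) {
  need <- c("probe_id", "gene_id", "offset_bp", "ip_intensity",
            "mock_intensity", "condition", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(x$ip_intensity)) || any(x$ip_intensity <= 0) ||
      any(!is.finite(x$mock_intensity)) || any(x$mock_intensity <= 0)) {
    stop("all channel intensities must be finite and positive")
  }
  key <- paste(x$probe_id, x$condition, x$replicate)
  if (anyDuplicated(key)) stop("duplicated (probe, condition, replicate) rows")
  if (!inherits(x, "chip_array_set")) class(x) <- c("chip_array_set", class(x))
  invisible(x)
}

#' Generate promoter sequences with optionally planted motif instances
#'
#' One random sequence per gene covering the tiled span, with i.i.d. bases
#' at the requested GC fraction. Genes in `plant_in` receive one planted
#' instance of the motif at a recorded position: by default the consensus
#' sequence of the matrix (`mode = "consensus"`); `mode = "sample"` draws
#' each base from the per-position frequencies instead.
#'
#' @param layout A probe layout (defines the gene set).
#' @param motif A [motif_matrix()] (required if `plant_in` is non-empty).
#' @param plant_in Character vector of gene ids to receive an instance.
#' @param plant_at Optional named integer vector: planting start offset (bp
#'   relative to TSS) per gene in `plant_in`; default is uniform within the
#'   span.
#' @param background_gc Background GC fraction in `(0, 1)`.
#' @param seed Integer seed.
#' @param span Sequence span in bp relative to the TSS.
#' @param mode `"consensus"` or `"sample"` (see above).
#' @return A list with `sequences` (a [Biostrings::DNAStringSet] named by
#'   gene id) and `truth` (a `data.frame` of planted instances: `gene_id`,
#'   `start_offset`, `strand`, `instance`).
#' @export
generate_promoter_sequences <- function(layout, motif = NULL,
                                        plant_in = character(),
                                        plant_at = NULL,
                                        background_gc = 0.5, seed = 1,
                                        span = c(-2000L, 800L),
                                        mode = c("consensus", "sample")) {
  mode <- match.arg(mode)
  if (background_gc <= 0 || background_gc >= 1) {
    stop("'background_gc' must be in (0, 1)")
  }
  if (length(plant_in) > 0) {
    if (is.null(motif)) stop("planting requires a motif matrix")
    if (!inherits(motif, "motif_matrix") || motif$width < 1) {
      stop("'motif' must be a non-empty motif_matrix")
    }
  }
  genes <- unique(layout$gene_id)
  unknown <- setdiff(plant_in, genes)
  if (length(unknown) > 0) {
    stop("plant_in genes absent from layout: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  set.seed(seed)
  len <- span[2] - span[1] + 1L
  base_prob <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
                 G = background_gc / 2, T = (1 - background_gc) / 2)
  bases <- names(base_prob)
  seqs <- character(length(genes))
  names(seqs) <- genes
  for (g in genes) {
    seqs[g] <- paste(sample(bases, len, replace = TRUE, prob = base_prob),
                     collapse = "")
  }
  truth <- data.frame(gene_id = character(), start_offset = integer(),
                      strand = character(), instance = character(),
                      stringsAsFactors = FALSE)
  if (length(plant_in) > 0) {
    w <- motif$width
    for (g in plant_in) {
      if (!is.null(plant_at) && !is.na(plant_at[g])) {
        start_off <- as.integer(plant_at[g])
      } else {
        start_off <- sample(seq.int(span[1], span[2] - w + 1L), 1L)
      }
      start_off <- max(span[1], min(start_off, span[2] - w + 1L))
      inst <- if (mode == "consensus") {
        motif_consensus(motif)
      } else {
        paste(vapply(seq_len(w), function(j) {
          sample(rownames(motif$freq), 1L, prob = motif$freq[, j])
        }, character(1)), collapse = "")
      }
      pos <- start_off - span[1] + 1L
      substr(seqs[g], pos, pos + w - 1L) <- inst
      truth <- rbind(truth, data.frame(
        gene_id = g, start_offset = start_off, strand = "+",
        instance = inst, stringsAsFactors = FALSE
      ))
    }
  }
  list(
    sequences = Biostrings::DNAStringSet(seqs),
    truth = truth,
    span = span
  )
}

#' Generate random gene sets with one designated enriched set
#'
#' Samples `n_sets` gene sets from `universe`; the first set (named
#' `"enriched_set"`) draws `overlap_frac` of its members from
#' `enriched_genes`, the rest uniformly.
#'
#' @param universe Character vector of all gene ids.
#' @param n_sets Number of sets.
#' @param set_sizes Integer sizes, recycled across sets; each must be
#'   positive and at most `length(universe)`.
#' @param enriched_genes Genes the designated set should overlap heavily.
#' @param overlap_frac Fraction of the designated set drawn from
#'   `enriched_genes`.
#' @param seed Integer seed.
#' @return A named list of character vectors (GMT-style).
#' @export
generate_gene_sets <- function(universe, n_sets = 10, set_sizes = 50,
                               enriched_genes = character(),
                               overlap_frac = 0.8, seed = 1) {
  set_sizes <- rep_len(as.integer(set_sizes), n_sets)
  if (any(set_sizes < 1)) stop("set sizes must be positive")
  if (any(set_sizes > length(universe))) {
    stop("set sizes must not exceed the universe size")
  }
  set.seed(seed)
  sets <- vector("list", n_sets)
  names(sets) <- c("enriched_set", sprintf("random_set_%02d",
                                           seq_len(max(n_sets - 1, 0))))[seq_len(n_sets)]
  for (i in seq_len(n_sets)) {
    sz <- set_sizes[i]
    if (i == 1L && length(enriched_genes) > 0) {
      n_in <- min(round(overlap_frac * sz), length(enriched_genes))
      inside <- sample(enriched_genes, n_in)
      outside <- sample(setdiff(universe, inside), sz - n_in)
      sets[[i]] <- sample(c(inside, outside))
    } else {
      sets[[i]] <- sample(universe, sz)
    }
  }
  sets
}
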