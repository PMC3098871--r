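#' Apply the binding-event significance and height filters
#'
#' Implements the bound-gene rule: a gene is called bound when its peak
#' p-value is below `p_thresh` in at least `min_reps` replicates AND the
#' consensus height (median across the passing replicates) exceeds
#' `height_thresh`. The consensus center is the median of passing-replicate
#' centers. For genes with no passing replicate the consensus falls back to
#' the median across all replicates (so downstream binding-change rankings
#' have a height for every gene); such genes never pass.
#'
#' @param pvalues,heights,centers Numeric gene x replicate matrices (rows
#'   named by gene id).
#' @param p_thresh Per-replicate p-value threshold.
#' @param height_thresh Consensus fold-enrichment threshold (exclusive).
#' @param min_reps Minimum number of replicates below `p_thresh`.
#' @return A `data.frame` with `gene_id`, `n_pass_reps`, `consensus_center`,
#'   `consensus_height`, `passes`.
#' @examples
#' p <- rbind(gA = c(0.005, 0.02, 0.005))
#' h <- rbind(gA = c(2.0, 1.2, 2.2))
#' ctr <- rbind(gA = c(-500, -480, -510))
#' apply_binding_filter(p, h, ctr)$passes # TRUE
#' @export
apply_binding_filter <- function(pvalues, heights, centers,
                                 p_thresh = 0.01, height_thresh = 1.5,
                                 min_reps = 2) {
  pvalues <- as.matrix(pvalues)
  heights <- as.matrix(heights)
  centers <- as.matrix(centers)
  stopifnot(dim(pvalues) == dim(heights), dim(pvalues) == dim(centers))
  genes <- rownames(pvalues)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(pvalues)))
  n_pass <- integer(nrow(pvalues))
  cons_c <- cons_h <- numeric(nrow(pvalues))
  for (i in seq_len(nrow(pvalues))) {
    pass <- pvalues[i, ] < p_thresh
    n_pass[i] <- sum(pass)
    use <- if (any(pass)) pass else rep(TRUE, ncol(pvalues))
    cons_c[i] <- stats::median(centers[i, use])
    cons_h[i] <- stats::median(heights[i, use])
  }
  data.frame(
    gene_id = genes,
    n_pass_reps = n_pass,
    consensus_center = cons_c,
    consensus_height = cons_h,
    passes = n_pass >= min_reps & cons_h > height_thresh,
    stringsAsFactors = FALSE
  )
}

#' Call bound genes in one condition
#'
#' For every gene and replicate, fits the binding-event model
#' ([fit_peak()]) to the IP/mock probe ratios and assigns an empirical LLR
#' p-value, then applies the replicate-support and height filters
#' ([apply_binding_filter()]).
#'
#' Statistic. With 4-6 probes per promoter the pure ratio LLR
#' `(k/2) ln(rss0/rss1)` explodes on pure-noise promoters (tiny `rss0`,
#' tinier `rss1`), costing power. The default `statistic = "moderated"`
#' therefore regularizes both residual sums with an array-wide variance
#' floor, `(k/2) ln((rss0 + k s0^2) / (rss1 + k s0^2))`, where `s0^2` is
#' the replicate-wide median of `rss1/(k - 2)` - the moderated-statistic
#' idea familiar from small-sample microarray analysis. Permutation
#' p-values are valid for either statistic; `statistic = "ratio"` gives the
#' plain LLR of [llr_statistic()].
#'
#' Null. The default `null = "pooled"` permutes ratio values within each
#' promoter (preserving its marginal intensity distribution) and pools the
#' null statistics across promoters within strata of equal probe count,
#' giving p-values with resolution `1 / (B * n_genes_in_stratum + 1)`.
#' Because truly bound promoters contribute peak-like permutations that
#' fatten the pooled tail, one refinement pass removes promoters whose
#' initial p-value falls below `null_exclude` from the pool and recomputes
#' (skipped if more than half the promoters would be removed).
#' `null = "within"` uses each promoter's own `B` permutations alone, whose
#' granularity with 4-6 probes makes p below about 1/24 unreachable for
#' 4-probe promoters.
#'
#' @param arrays A `chip_array_set` (long probe table).
#' @param condition Condition to analyze (default: the single condition
#'   present).
#' @param shape A [peak_shape()].
#' @param p_thresh,height_thresh,min_reps Filter thresholds (see
#'   [apply_binding_filter()]).
#' @param B Number of permutation rounds (at least 99).
#' @param grid_step Candidate-center grid step in bp.
#' @param seed Integer seed for the permutation draws.
#' @param null `"pooled"` (within-promoter permutations pooled across
#'   promoters) or `"within"` (per-promoter only).
#' @param statistic `"moderated"` (variance-floored LLR) or `"ratio"`.
#' @param null_exclude Initial-p threshold below which promoters are
#'   excluded from the refined null pool (0 disables refinement).
#' @param verbose Emit per-stage counts as messages.
#' @return A `data.frame` as from [apply_binding_filter()], plus a
#'   `condition` column; per-replicate fits are attached as attribute
#'   `"replicate_calls"` (`gene_id`, `replicate`, `center`, `height`,
#'   `llr`, `pvalue`).
#' @export
call_condition <- function(arrays, condition = NULL, shape,
                           p_thresh = 0.01, height_thresh = 1.5,
                           min_reps = 2, B = 199, grid_step = 25, seed = 1,
                           null = c("pooled", "within"),
                           statistic = c("moderated", "ratio"),
                           null_exclude = 0.05,
                           verbose = getOption("tilepeak.verbose", FALSE)) {
  null <- match.arg(null)
  statistic <- match.arg(statistic)
  if (B < 99) stop("'B' must be at least 99")
  validate_chip_array_set(arrays)
  if (is.null(condition)) {
    condition <- unique(arrays$condition)
    if (length(condition) != 1L) {
      stop("several conditions present; pick one via 'condition'")
    }
  }
  d <- arrays[arrays$condition == condition, , drop = FALSE]
  if (nrow(d) == 0) stop("no arrays for condition '", condition, "'")
  reps <- sort(unique(d$replicate))
  if (length(reps) < min_reps) {
    stop("need at least ", min_reps, " replicates, found ", length(reps))
  }
  # consistent layout across replicates
  key0 <- NULL
  for (r in reps) {
    dr <- d[d$replicate == r, ]
    key <- paste(dr$probe_id, dr$gene_id, dr$offset_bp)[order(dr$probe_id)]
    if (is.null(key0)) key0 <- key
    else if (!identical(key, key0)) stop("replicate layouts disagree")
  }
  genes <- unique(d$gene_id)
  # per-gene fit designs are shared across replicates (same layout)
  d1 <- d[d$replicate == reps[1L], ]
  idx_by_gene <- split(seq_len(nrow(d1)), d1$gene_id)[genes]
  designs <- lapply(idx_by_gene, function(ii) {
    peak_fit_design(d1$offset_bp[ii], shape, grid_step)
  })
  k_by_gene <- vapply(idx_by_gene, length, integer(1))

  set.seed(seed)
  nm_gene <- genes
  centers <- heights <- llrs <- pvals <-
    matrix(NA_real_, length(genes), length(reps),
           dimnames = list(nm_gene, paste0("rep", reps)))
  for (ri in seq_along(reps)) {
    dr <- d[d$replicate == reps[ri], ]
    dr <- dr[match(d1$probe_id, dr$probe_id), ] # align to the design order
    ratio <- dr$ip_intensity / dr$mock_intensity
    # first pass: fits (also yields the replicate-wide variance floor)
    rss0_g <- rss1_g <- numeric(length(genes))
    for (gi in seq_along(genes)) {
      ii <- idx_by_gene[[gi]]
      f <- fit_peak(d1$offset_bp[ii], ratio[ii], shape, grid_step)
      centers[gi, ri] <- f$center
      heights[gi, ri] <- f$height
      rss0_g[gi] <- f$rss0
      rss1_g[gi] <- f$rss1
    }
    s0sq <- stats::median(rss1_g / pmax(k_by_gene - 2, 1))
    stat_fun <- if (statistic == "moderated" && s0sq > 1e-12) {
      function(rss0, rss1, k) {
        (k / 2) * log((rss0 + k * s0sq) / (rss1 + k * s0sq))
      }
    } else {
      function(rss0, rss1, k) llr_statistic(rss0, rss1, k)
    }
    obs_stat <- stat_fun(rss0_g, rss1_g, k_by_gene)
    llrs[, ri] <- llr_statistic(rss0_g, rss1_g, k_by_gene)
    if (null == "pooled") {
      # within-promoter permutations, pooled across promoters by probe count
      null_g <- vector("list", length(genes))
      for (gi in seq_along(genes)) {
        ii <- idx_by_gene[[gi]]
        k <- length(ii)
        R <- vapply(seq_len(B), function(b) sample(ratio[ii]), numeric(k))
        fitb <- peak_fit_many(designs[[gi]], R)
        null_g[[gi]] <- stat_fun(fitb$rss0, fitb$rss1, k)
      }
      pool_p <- function(keep) {
        pool_by_k <- lapply(split(which(keep), k_by_gene[keep]),
                            function(gg) unlist(null_g[gg]))
        vapply(seq_along(genes), function(gi) {
          pool <- pool_by_k[[as.character(k_by_gene[gi])]]
          if (is.null(pool)) { # whole stratum excluded: fall back to all
            pool <- unlist(null_g[which(k_by_gene == k_by_gene[gi])])
          }
          (1 + sum(pool >= obs_stat[gi])) / (length(pool) + 1)
        }, numeric(1))
      }
      p0 <- pool_p(rep(TRUE, length(genes)))
      if (null_exclude > 0) {
        keep <- p0 >= null_exclude
        if (sum(keep) >= length(genes) / 2 && any(!keep)) p0 <- pool_p(keep)
      }
      pvals[, ri] <- p0
    } else {
      for (gi in seq_along(genes)) {
        ii <- idx_by_gene[[gi]]
        k <- length(ii)
        R <- vapply(seq_len(B), function(b) sample(ratio[ii]), numeric(k))
        fitb <- peak_fit_many(designs[[gi]], R)
        nl <- stat_fun(fitb$rss0, fitb$rss1, k)
        pvals[gi, ri] <- (1 + sum(nl >= obs_stat[gi])) / (B + 1)
      }
    }
  }
  calls <- apply_binding_filter(pvals, heights, centers,
                                p_thresh, height_thresh, min_reps)
  calls$condition <- condition
  attr(calls, "replicate_calls") <- data.frame(
    gene_id = rep(genes, times = length(reps)),
    replicate = rep(reps, each = length(genes)),
    center = as.numeric(centers),
    height = as.numeric(heights),
    llr = as.numeric(llrs),
    pvalue = as.numeric(pvals),
    stringsAsFactors = FALSE
  )
  if (verbose) {
    message(sprintf("call_condition[%s]: %d genes, %d replicates, %d pass",
                    condition, length(genes), length(reps),
                    sum(calls$passes)))
  }
  calls
}

#' Partition genes by binding across two conditions
#'
#' @param basal,stimulated Call tables from [call_condition()].
#' @return A `data.frame` with `gene_id`, `status` (one of `basal_only`,
#'   `stimulated_only`, `both`, `neither`; exhaustive and disjoint) and
#'   `height_delta` (stimulated minus basal consensus height, the binding
#'   change).
#' @export
compare_conditions <- function(basal, stimulated) {
  genes <- sort(union(basal$gene_id, stimulated$gene_id))
  if (length(genes) == 0) {
    return(data.frame(gene_id = character(), status = character(),
                      height_delta = numeric(), stringsAsFactors = FALSE))
  }
  bi <- match(genes, basal$gene_id)
  si <- match(genes, stimulated$gene_id)
  pb <- !is.na(bi) & basal$passes[bi]
  ps <- !is.na(si) & stimulated$passes[si]
  status <- ifelse(pb & ps, "both",
            ifelse(pb, "basal_only",
            ifelse(ps, "stimulated_only", "neither")))
  hb <- ifelse(is.na(bi), NA_real_, basal$consensus_height[bi])
  hs <- ifelse(is.na(si), NA_real_, stimulated$consensus_height[si])
  data.frame(gene_id = genes, status = status, height_delta = hs - hb,
             stringsAsFactors = FALSE)
}

#' Extract the sequence around each called peak
#'
#' Returns the `+/- flank` bp window (201 bp at the default flank of 100)
#' around the consensus peak center of each passing call, truncated (and
#' flagged) at the ends of the promoter sequence.
#'
#' @param calls A call table from [call_condition()]; only rows with
#'   `passes == TRUE` are used.
#' @param sequences Promoter sequences named by gene id
#'   ([Biostrings::DNAStringSet] or named character), each covering `span`.
#' @param flank Half-width of the extracted window in bp.
#' @param span Sequence span in bp relative to the TSS.
#' @return A `data.frame` with `gene_id`, `condition`, `start_offset`,
#'   `end_offset`, `width`, `truncated`, `sequence`.
#' @export
extract_bound_regions <- function(calls, sequences, flank = 100,
                                  span = c(-2000L, 800L)) {
  seqs <- as.character(sequences)
  if (is.null(names(seqs))) names(seqs) <- names(sequences)
  if (is.null(names(seqs))) stop("'sequences' must be named by gene id")
  use <- calls[calls$passes, , drop = FALSE]
  if (nrow(use) == 0) {
    return(data.frame(gene_id = character(), condition = character(),
                      start_offset = integer(), end_offset = integer(),
                      width = integer(), truncated = logical(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  missing <- setdiff(use$gene_id, names(seqs))
  if (length(missing) > 0) {
    stop("no sequence for gene(s): ", paste(missing, collapse = ", "))
  }
  out <- vector("list", nrow(use))
  for (i in seq_len(nrow(use))) {
    g <- use$gene_id[i]
    ctr <- round(use$consensus_center[i])
    s_len <- nchar(seqs[g])
    hi_off <- span[1] + s_len - 1L
    start <- max(span[1], ctr - flank)
    end <- min(hi_off, ctr + flank)
    trunc <- (ctr - flank) < span[1] || (ctr + flank) > hi_off
    pos1 <- start - span[1] + 1L
    pos2 <- end - span[1] + 1L
    out[[i]] <- data.frame(
      gene_id = g,
      condition = if ("condition" %in% names(use)) use$condition[i] else NA,
      start_offset = as.integer(start), end_offset = as.integer(end),
      width = as.integer(end - start + 1L), truncated = trunc,
      sequence = substr(seqs[g], pos1, pos2),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
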