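#' One-color expression matrix with design metadata
#'
#' Container for background-subtracted probe intensities (probes x arrays,
#' linear scale, strictly positive) plus per-array design metadata.
#'
#' @param intensity Numeric probes x arrays matrix with probe rownames.
#' @param design `data.frame` with one row per array: `array_id`, `time_h`,
#'   `arm`, `replicate`.
#' @param probe_genes Character vector mapping each probe (row) to a gene.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(intensity, design, probe_genes) {
  intensity <- as.matrix(intensity)
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    stop("intensities must be finite and positive before log transform")
  }
  need <- c("array_id", "time_h", "arm", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) stop("design misses columns: ",
                             paste(miss, collapse = ", "))
  if (nrow(design) != ncol(intensity)) {
    stop("design must have one row per array column")
  }
  if (length(probe_genes) != nrow(intensity)) {
    stop("'probe_genes' must have one entry per probe row")
  }
  if (anyDuplicated(design$array_id)) stop("duplicate array ids")
  colnames(intensity) <- design$array_id
  structure(
    list(intensity = intensity, design = design,
         probe_genes = as.character(probe_genes)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "Expression matrix: %d probes (%d genes) x %d arrays [%s | %s h]\n",
    nrow(x$intensity), length(unique(x$probe_genes)), ncol(x$intensity),
    paste(unique(x$design$arm), collapse = ", "),
    paste(sort(unique(x$design$time_h)), collapse = "/")
  ))
  invisible(x)
}

#' Construct an expression truth table
#'
#' One row per gene: planted direction (`up`, `down`, `null`), per-timepoint
#' log2 effects, and the SIS3 attenuation multiplier in `[0, 1]` (retained
#' fraction of the effect under SMAD3 inhibition; 0 = fully blocked).
#'
#' @param gene_id Character vector of gene ids.
#' @param direction `"up"`, `"down"` or `"null"` per gene.
#' @param effect_log2 Numeric matrix (genes x non-baseline timepoints) or a
#'   single magnitude applied to all timepoints (signed by direction).
#' @param sis3_attenuation Retained-effect multiplier per gene.
#' @param times Non-baseline timepoints the effects apply to.
#' @return A `data.frame` with columns `gene_id`, `direction`,
#'   `effect_log2_<t>h`, `sis3_attenuation`.
#' @export
expression_truth <- function(gene_id, direction = "null", effect_log2 = 0,
                             sis3_attenuation = 0.2,
                             times = c(2, 12, 24)) {
  n <- length(gene_id)
  direction <- rep_len(direction, n)
  sis3_attenuation <- rep_len(sis3_attenuation, n)
  if (any(sis3_attenuation < 0 | sis3_attenuation > 1)) {
    stop("'sis3_attenuation' must lie in [0, 1]")
  }
  if (is.matrix(effect_log2)) {
    if (nrow(effect_log2) != n || ncol(effect_log2) != length(times)) {
      stop("'effect_log2' matrix must be genes x timepoints")
    }
    eff <- effect_log2
  } else {
    sgn <- ifelse(direction == "up", 1, ifelse(direction == "down", -1, 0))
    eff <- outer(sgn * rep_len(abs(effect_log2), n), rep(1, length(times)))
  }
  if (any(eff[direction == "null", ] != 0)) {
    stop("null genes must have all effects 0")
  }
  out <- data.frame(gene_id = as.character(gene_id), direction = direction,
                    stringsAsFactors = FALSE)
  for (j in seq_along(times)) {
    out[[sprintf("effect_log2_%gh", times[j])]] <- eff[, j]
  }
  out$sis3_attenuation <- sis3_attenuation
  out
}

#' Plant up/down-regulated genes in a gene universe
#'
#' @param gene_ids All gene ids.
#' @param n_up,n_down Numbers of up- and down-regulated genes.
#' @param effect_log2 Effect magnitude in log2 units.
#' @param sis3_attenuation Retained-effect multiplier under SIS3.
#' @param seed Integer seed.
#' @return An [expression_truth()] table covering every gene.
#' @export
plant_expression_truth <- function(gene_ids, n_up = 50, n_down = 50,
                                   effect_log2 = 1.5, sis3_attenuation = 0.2,
                                   seed = 1) {
  set.seed(seed)
  picked <- sample(gene_ids, n_up + n_down)
  dir <- rep("null", length(gene_ids))
  names(dir) <- gene_ids
  dir[picked[seq_len(n_up)]] <- "up"
  dir[picked[n_up + seq_len(n_down)]] <- "down"
  eff <- ifelse(dir == "null", 0, effect_log2)
  expression_truth(gene_ids, dir, eff, sis3_attenuation)
}

#' Simulate one-color expression time-course arrays
#'
#' Log2 intensity of a probe = gene baseline + probe affinity + planted
#' arm/timepoint effect (scaled by `sis3_attenuation` under the SIS3 arm) +
#' smooth intensity-dependent array bias + i.i.d. Gaussian noise. The bias
#' of each array is a random quadratic curve in the probe's expected log2
#' intensity with amplitude `dye_bias` (log2 units); 0 disables it.
#'
#' @param n_genes Number of genes (ids `e0001` ... unless `gene_ids` is
#'   given).
#' @param gene_ids Optional explicit gene ids (overrides `n_genes`), e.g.
#'   the genes of a ChIP layout so both assays share a namespace.
#' @param truth Optional [expression_truth()] table; defaults to all-null.
#' @param probes_per_gene Probes per gene (>= 1).
#' @param times Timepoints in hours (must include 0, the baseline).
#' @param arms Treatment arms; effects are attenuated in `"SIS3"`.
#' @param n_replicates Replicate arrays per (time, arm).
#' @param dye_bias Amplitude of the intensity-dependent bias, log2 units.
#' @param noise_sd_log2 Probe-level noise standard deviation, log2 units.
#' @param baseline_mean,baseline_sd Gene baseline distribution, log2 units.
#' @param probe_affinity_sd Probe-specific offset SD, log2 units.
#' @param seed Integer seed.
#' @return An [expr_matrix()] with the truth table attached as attribute
#'   `"truth"`.
#' @export
simulate_expression_timecourse <- function(n_genes, gene_ids = NULL,
                                           truth = NULL,
                                           probes_per_gene = 3,
                                           times = c(0, 2, 12, 24),
                                           arms = c("DMSO", "SIS3"),
                                           n_replicates = 3,
                                           dye_bias = 0,
                                           noise_sd_log2 = 0.25,
                                           baseline_mean = 8,
                                           baseline_sd = 1.5,
                                           probe_affinity_sd = 0.3,
                                           seed = 1) {
  if (probes_per_gene < 1) stop("'probes_per_gene' must be at least 1")
  if (!0 %in% times) stop("design must include the 0 h baseline timepoint")
  if (length(arms) < 1) stop("design must include at least one arm")
  if (is.null(gene_ids)) gene_ids <- sprintf("e%04d", seq_len(n_genes))
  n_genes <- length(gene_ids)
  if (is.null(truth)) truth <- expression_truth(gene_ids)
  if (!setequal(truth$gene_id, gene_ids)) {
    stop("truth must cover exactly the simulated genes")
  }
  t_nonzero <- setdiff(times, 0)
  eff_cols <- sprintf("effect_log2_%gh", t_nonzero)
  miss <- setdiff(eff_cols, names(truth))
  if (length(miss) > 0) stop("truth misses effect columns: ",
                             paste(miss, collapse = ", "))
  set.seed(seed)
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  names(baseline) <- gene_ids
  probe_genes <- rep(gene_ids, each = probes_per_gene)
  probe_ids <- sprintf("%s_p%d", probe_genes,
                       rep(seq_len(probes_per_gene), times = n_genes))
  affinity <- stats::rnorm(length(probe_ids), 0, probe_affinity_sd)
  expected_log2 <- baseline[probe_genes] + affinity
  u <- (expected_log2 - baseline_mean) / (2 * baseline_sd)

  design <- expand.grid(replicate = seq_len(n_replicates), time_h = times,
                        arm = arms, stringsAsFactors = FALSE)
  design <- design[order(design$arm, design$time_h, design$replicate), ]
  design$array_id <- sprintf("%s_t%g_r%d", design$arm, design$time_h,
                             design$replicate)
  rownames(design) <- NULL
  tr_idx <- match(probe_genes, truth$gene_id)
  atten <- truth$sis3_attenuation[tr_idx]

  mat <- matrix(NA_real_, length(probe_ids), nrow(design),
                dimnames = list(probe_ids, design$array_id))
  for (a in seq_len(nrow(design))) {
    t_h <- design$time_h[a]
    eff <- if (t_h == 0) 0 else truth[[sprintf("effect_log2_%gh", t_h)]][tr_idx]
    if (design$arm[a] == "SIS3") eff <- eff * atten
    bias <- if (dye_bias > 0) {
      w <- stats::runif(2, -1, 1)
      dye_bias * (w[1] * u + w[2] * (u^2 - mean(u^2)))
    } else 0
    noise <- if (noise_sd_log2 > 0) {
      stats::rnorm(length(probe_ids), 0, noise_sd_log2)
    } else 0
    mat[, a] <- 2^(expected_log2 + eff + bias + noise)
  }
  em <- expr_matrix(mat, design[, c("array_id", "time_h", "arm", "replicate")],
                    probe_genes)
  attr(em, "truth") <- truth
  em
}
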