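#' Cyclic loess normalization across arrays
#'
#' For every pair of arrays, fits a local linear smoother (degree-1
#' `stats::loess`) of M (log2 intensity difference) on A (mean log2
#' intensity) over a randomly selected probe subset, predicts the fit for
#' all probes, and moves each array of the pair half the fitted curve
#' toward the other. One iteration is a complete cycle over all array
#' pairs; iteration stops once the maximum absolute adjustment in a cycle
#' drops below `epsilon` (typically after two or three iterations on smooth
#' dye bias) or after `max_iter` cycles.
#'
#' @param em An [expr_matrix()].
#' @param subset_size Probes used for each loess fit (clamped with a
#'   warning when larger than the probe count); the subset is drawn once
#'   per run.
#' @param epsilon Convergence threshold on the maximum absolute per-probe
#'   adjustment, log2 units. Note the stopping statistic is a maximum over
#'   all array pairs and probes, so it has a sampling floor set by the
#'   loess fit's own variability (about 0.01-0.03 at a 5000-probe subset
#'   and 0.25 log2 probe noise); the default 0.02 sits at that floor and
#'   stops within two or three cycles once the systematic bias is gone.
#' @param max_iter Maximum number of cycles.
#' @param span Loess span. The default 0.7 is wide enough that the cyclic
#'   updates settle below the default epsilon within a few cycles; narrower
#'   spans chase probe-level noise and can oscillate above epsilon.
#' @param seed Optional seed for the subset draw.
#' @param verbose Emit per-iteration maximum changes as messages.
#' @return The normalized [expr_matrix()], with attributes `iterations`,
#'   `converged` and `max_change` (per-cycle trace).
#' @export
cyclic_loess_normalize <- function(em, subset_size = 5000, epsilon = 0.02,
                                   max_iter = 10, span = 0.7, seed = NULL,
                                   verbose = getOption("tilepeak.verbose",
                                                       FALSE)) {
  stopifnot(inherits(em, "expr_matrix"))
  X <- log2(em$intensity)
  n_probes <- nrow(X)
  n_arrays <- ncol(X)
  if (n_arrays < 2) stop("cyclic loess needs at least 2 arrays")
  if (subset_size > n_probes) {
    warning("subset_size exceeds probe count; using all probes")
    subset_size <- n_probes
  }
  if (!is.null(seed)) set.seed(seed)
  sub <- sort(sample.int(n_probes, subset_size))
  pairs <- utils::combn(n_arrays, 2)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    max_change <- 0
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]
      j <- pairs[2, p]
      M <- X[, i] - X[, j]
      A <- (X[, i] + X[, j]) / 2
      df <- data.frame(M = M[sub], A = A[sub])
      fit <- stats::loess(M ~ A, data = df, span = span, degree = 1,
                          family = "gaussian")
      # clamp A into the fitted range to avoid wild extrapolation
      A_pred <- pmin(pmax(A, min(df$A)), max(df$A))
      adj <- stats::predict(fit, newdata = data.frame(A = A_pred)) / 2
      X[, i] <- X[, i] - adj
      X[, j] <- X[, j] + adj
      max_change <- max(max_change, max(abs(adj)))
    }
    trace <- c(trace, max_change)
    if (verbose) message(sprintf("cyclic loess iteration %d: max change %.4f",
                                 it, max_change))
    if (max_change < epsilon) {
      converged <- TRUE
      break
    }
  }
  out <- expr_matrix(2^X, em$design, em$probe_genes)
  attr(out, "truth") <- attr(em, "truth")
  attr(out, "iterations") <- length(trace)
  attr(out, "converged") <- converged
  attr(out, "max_change") <- trace
  out
}

#' Average probe log2 intensities into gene values
#'
#' Per gene and array, the arithmetic mean of the gene's probe log2
#' intensities.
#'
#' @param em An [expr_matrix()].
#' @return A `gene_matrix`: list with `log2` (genes x arrays matrix) and
#'   `design`.
#' @export
summarize_probes_to_genes <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  keep <- !is.na(em$probe_genes) & nzchar(em$probe_genes)
  if (!all(keep)) {
    warning(sum(!keep), " probe(s) without a gene excluded")
  }
  X <- log2(em$intensity[keep, , drop = FALSE])
  g <- em$probe_genes[keep]
  sums <- rowsum(X, g)
  counts <- as.vector(table(g)[rownames(sums)])
  structure(
    list(log2 = sums / counts, design = em$design),
    class = "gene_matrix"
  )
}

#' Normalize gene time courses to the 0 h baseline
#'
#' Per gene and arm, subtracts the mean 0 h log2 value from every array of
#' that arm: the log-scale equivalent of dividing by the geometric mean of
#' the 0 h replicates. Baseline-normalized 0 h values therefore average 0
#' per gene per arm.
#'
#' @param gm A `gene_matrix` from [summarize_probes_to_genes()].
#' @return A `gene_timecourse`: list with `log2ratio` (genes x arrays) and
#'   `design`.
#' @export
normalize_to_baseline <- function(gm) {
  stopifnot(inherits(gm, "gene_matrix"))
  des <- gm$design
  out <- gm$log2
  for (arm in unique(des$arm)) {
    arm_cols <- which(des$arm == arm)
    ref_cols <- which(des$arm == arm & des$time_h == 0)
    if (length(ref_cols) == 0) stop("arm '", arm, "' has no 0 h arrays")
    ref <- rowMeans(gm$log2[, ref_cols, drop = FALSE])
    out[, arm_cols] <- gm$log2[, arm_cols, drop = FALSE] - ref
  }
  structure(list(log2ratio = out, design = des), class = "gene_timecourse")
}

#' Two-sample permutation test on replicate values
#'
#' Statistic: difference of group means. When the number of distinct
#' group-label splits `choose(n1 + n2, n1)` is at most `exact_limit`, all
#' splits are enumerated and the two-sided p-value is the fraction of
#' splits with `|stat| >= |observed|` (the observed split counts itself).
#' Otherwise `B` random permutations are drawn and
#' `p = (1 + #\{|null| >= |observed|\}) / (B + 1)`.
#'
#' @param x,y Replicate values of the two groups (at least 2 each).
#' @param B Number of sampled permutations when enumeration is infeasible
#'   (at least 99).
#' @param seed Optional integer seed (sampling path only).
#' @param exact_limit Maximum number of splits to enumerate.
#' @return Two-sided p-value.
#' @examples
#' permutation_de_test(c(0, 0, 0), c(5, 5, 5)) # 2/20 = 0.1
#' @export
permutation_de_test <- function(x, y, B = 999, seed = NULL,
                                exact_limit = 252) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 replicates")
  }
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  n1 <- length(x)
  n <- length(pool)
  n_split <- choose(n, n1)
  tol <- 1e-12 * max(1, abs(obs))
  if (n_split <= exact_limit) {
    splits <- utils::combn(n, n1)
    stats <- apply(splits, 2L, function(ii) {
      mean(pool[ii]) - mean(pool[-ii])
    })
    mean(abs(stats) >= abs(obs) - tol)
  } else {
    if (B < 99) stop("'B' must be at least 99 when sampling permutations")
    if (!is.null(seed)) set.seed(seed)
    stats <- vapply(seq_len(B), function(b) {
      ii <- sample.int(n, n1)
      mean(pool[ii]) - mean(pool[-ii])
    }, numeric(1))
    (1 + sum(abs(stats) >= abs(obs) - tol)) / (B + 1)
  }
}

#' Permutation differential-expression test between two timepoints
#'
#' For every gene, compares replicate log2 ratios at `time_h` against
#' `ref_time` within one arm using the mean-difference statistic. With
#' `pool_null = TRUE` (default) the label-split statistics of all genes are
#' pooled into a common null distribution, giving near-continuous p-values
#' (resolution `1 / (n_splits * n_genes)`) suitable for FDR control; this
#' assumes comparable per-gene noise scales. Because truly regulated genes
#' contribute large split statistics that fatten the pooled tail, one
#' refinement pass removes genes with initial pooled p below
#' `pool_exclude` from the pool and recomputes (skipped if more than half
#' the genes would be removed). With `pool_null = FALSE` each gene is
#' tested by its own splits alone, as in [permutation_de_test()] (at
#' n = 3 vs 3 the smallest achievable two-sided p is 0.1).
#'
#' @param tc A `gene_timecourse` from [normalize_to_baseline()].
#' @param arm Arm to test.
#' @param time_h Timepoint to compare against the reference.
#' @param ref_time Reference timepoint (default 0 h).
#' @param pool_null Pool permutation statistics across genes.
#' @param pool_exclude Initial-p threshold for the pool refinement pass
#'   (0 disables it).
#' @param adjust Multiple-testing method passed to [adjust_pvalues()].
#' @return A `data.frame` with `gene_id`, `stat` (mean log2-ratio
#'   difference), `pvalue`, `p_adj`.
#' @export
de_test_timepoint <- function(tc, arm, time_h, ref_time = 0,
                              pool_null = TRUE, pool_exclude = 0.05,
                              adjust = "bh") {
  stopifnot(inherits(tc, "gene_timecourse"))
  des <- tc$design
  c1 <- which(des$arm == arm & des$time_h == time_h)
  c0 <- which(des$arm == arm & des$time_h == ref_time)
  if (length(c1) < 2 || length(c0) < 2) {
    stop("need at least 2 replicates per timepoint in arm '", arm, "'")
  }
  V <- cbind(tc$log2ratio[, c1, drop = FALSE],
             tc$log2ratio[, c0, drop = FALSE])
  n1 <- length(c1)
  n <- ncol(V)
  splits <- utils::combn(n, n1)
  W <- matrix(-1 / (n - n1), n, ncol(splits))
  for (s in seq_len(ncol(splits))) W[splits[, s], s] <- 1 / n1
  stats <- V %*% W                      # genes x splits; split 1 = observed
  obs <- stats[, 1L]
  if (pool_null) {
    pooled_p <- function(keep) {
      null_sorted <- sort(abs(as.numeric(stats[keep, , drop = FALSE])))
      n_null <- length(null_sorted)
      ge <- n_null - findInterval(abs(obs) * (1 - 1e-12), null_sorted)
      pmax(ge, 1) / n_null
    }
    pval <- pooled_p(rep(TRUE, length(obs)))
    if (pool_exclude > 0) {
      keep <- pval >= pool_exclude
      if (sum(keep) >= length(obs) / 2 && any(!keep)) pval <- pooled_p(keep)
    }
  } else {
    pval <- rowMeans(abs(stats) >= abs(obs) * (1 - 1e-12))
  }
  data.frame(
    gene_id = rownames(tc$log2ratio),
    stat = obs,
    pvalue = pval,
    p_adj = adjust_pvalues(pval, adjust),
    stringsAsFactors = FALSE
  )
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up, via
#' [stats::p.adjust()].
#'
#' @param pvalues Numeric p-values in `(0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(pvalues, method = c("bonferroni", "bh")) {
  method <- match.arg(tolower(method), c("bonferroni", "bh"))
  if (length(pvalues) == 0) stop("empty p-value vector")
  stats::p.adjust(pvalues, method = if (method == "bh") "BH" else "bonferroni")
}

#' Relative quantification from qPCR Ct values
#'
#' `delta Ct = Ct_target - Ct_reference` per condition;
#' `delta delta Ct = delta Ct_treated - delta Ct_control`;
#' `fold change = 2^(-delta delta Ct)`.
#'
#' @param ct_target_treated,ct_ref_treated Ct of target and reference gene
#'   in the treated condition.
#' @param ct_target_control,ct_ref_control Same for the control condition.
#' @return A list with `ddct` and `fold_change`.
#' @examples
#' delta_delta_ct(20, 15, 22, 15)$fold_change # ddCt = -2 -> fold 4
#' @export
delta_delta_ct <- function(ct_target_treated, ct_ref_treated,
                           ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control,
            ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  list(ddct = ddct, fold_change = 2^(-ddct))
}
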