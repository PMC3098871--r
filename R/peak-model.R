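#' Expected coverage shape of a single binding event
#'
#' A fragment of length `L` immunoprecipitated because it contains the
#' binding site covers a position at signed distance `d` from the site with
#' probability `max(0, 1 - |d|/L)` (the fragment's placement is uniform among
#' placements covering the site). Averaging over the fragment-length
#' distribution gives the expected relative coverage
#' `s(d) = sum_L mass(L) * max(0, 1 - |d|/L)`, tabulated at 1 bp resolution.
#' `s(0) = 1`, `s` is symmetric and non-increasing in `|d|`, and `s(d) = 0`
#' for `|d| >=` the maximum fragment length.
#'
#' @param frag_dist A [fragment_length_dist()].
#' @return An object of class `peak_shape` with elements `s` (numeric vector
#'   of `s(d)` for `d = 0 .. dmax`) and `dmax` (maximum fragment length).
#' @examples
#' sh <- peak_shape(fragment_length_dist(400))
#' shape_at(sh, c(0, 200, 400)) # 1, 0.5, 0
#' @export
peak_shape <- function(frag_dist) {
  if (!inherits(frag_dist, "fragment_length_dist")) {
    stop("'frag_dist' must be a fragment_length_dist")
  }
  dmax <- max(frag_dist$lengths)
  d <- 0:dmax
  # s(d) = sum_L mass(L) * max(0, 1 - d/L); outer() is fine at this scale
  cov <- pmax(1 - outer(d, frag_dist$lengths, "/"), 0)
  s <- as.numeric(cov %*% frag_dist$mass)
  structure(list(s = s, dmax = dmax), class = "peak_shape")
}

#' Evaluate a peak shape at signed distances
#'
#' @param shape A [peak_shape()].
#' @param d Numeric vector of signed distances in bp (rounded to the 1 bp
#'   tabulation grid).
#' @return `s(|d|)`, zero beyond the maximum fragment length.
#' @export
shape_at <- function(shape, d) {
  if (!inherits(shape, "peak_shape")) stop("'shape' must be a peak_shape")
  ad <- abs(round(d))
  out <- numeric(length(ad))
  inside <- ad <= shape$dmax
  out[inside] <- shape$s[ad[inside] + 1L]
  dim(out) <- dim(d)
  out
}

#' @export
print.peak_shape <- function(x, ...) {
  half <- which(x$s <= 0.5)[1L] - 1L
  cat(sprintf(
    "Binding-event shape: s(0) = 1, half width %d bp, support +/- %d bp\n",
    half, x$dmax
  ))
  invisible(x)
}

## Precompute the per-promoter fit design: candidate centers and centered
## shape columns. Centers sit on an absolute grid (multiples of grid_step)
## covering the probe span, so planted centers on the grid are recovered
## exactly.
peak_fit_design <- function(offsets, shape, grid_step = 25) {
  n <- length(offsets)
  if (n < 3L) stop("fit_peak needs at least 3 probes")
  lo <- grid_step * floor(min(offsets) / grid_step)
  hi <- grid_step * ceiling(max(offsets) / grid_step)
  centers <- seq.int(lo, hi, by = grid_step)
  S <- shape_at(shape, outer(offsets, centers, "-")) # n x m
  smean <- colMeans(S)
  Sc <- sweep(S, 2L, smean)
  sxx <- colSums(Sc^2)
  list(
    n = n, centers = centers, S = S, Sc = Sc, smean = smean, sxx = sxx,
    # tie-break order: smaller |c| first, then smaller c
    tie_order = order(abs(centers), centers)
  )
}

## Vectorised least-squares over all candidate centers for a matrix of ratio
## vectors (one column per replicate/permutation). Returns per-column rss0,
## rss1 and the index of the winning candidate. The slope is constrained
## non-negative (fold >= 1) and the baseline positive; violating candidates
## fall back to the flat model.
peak_fit_many <- function(design, R) {
  R <- as.matrix(R)
  ncol_r <- ncol(R)
  rmean <- colMeans(R)
  Rc <- sweep(R, 2L, rmean)
  rss0 <- colSums(Rc^2)
  cross <- crossprod(design$Sc, Rc)            # m x B
  slope <- cross / design$sxx
  slope[design$sxx < 1e-12, ] <- 0
  slope[slope < 0] <- 0
  base <- matrix(rmean, nrow = length(design$centers), ncol = ncol_r,
                 byrow = TRUE) - slope * design$smean
  slope[base <= 0] <- 0
  rss <- matrix(rss0, nrow = length(design$centers), ncol = ncol_r,
                byrow = TRUE) - slope^2 * design$sxx
  rss[rss < 0] <- 0
  # argmin per column with ties resolved toward smaller |center|
  ord <- design$tie_order
  rss_o <- rss[ord, , drop = FALSE]
  best_o <- max.col(-t(rss_o), ties.method = "first")
  idx <- ord[best_o]
  pick <- cbind(idx, seq_len(ncol_r))
  list(
    rss0 = rss0, rss1 = rss[pick], idx = idx,
    slope = slope[pick], baseline = base[pick]
  )
}

#' Fit the binding-event model to one promoter's probe ratios
#'
#' Over candidate centers `c` on an absolute grid (multiples of `grid_step`
#' covering the probe span), fits by least squares the ratio model
#' `ratio_i = b + (f - 1) * b * s(offset_i - c)` with fold enrichment
#' `f >= 1` and baseline `b > 0`, and returns the candidate minimising the
#' residual sum of squares. Exact ties are broken toward the smaller `|c|`
#' (then the smaller `c`).
#'
#' @param offsets Integer probe offsets in bp relative to the TSS.
#' @param ratios Positive IP/mock intensity ratios, one per probe.
#' @param shape A [peak_shape()].
#' @param grid_step Candidate-center grid step in bp.
#' @return A list with `center`, `height` (fold enrichment `f`), `baseline`
#'   (`b`), `rss1` (best peak-model RSS) and `rss0` (flat-model RSS).
#' @examples
#' sh <- peak_shape(frag_dist_uniform())
#' x <- seq(-900, 300, by = 300)
#' r <- 1 + (3 - 1) * shape_at(sh, x - (-300))
#' fit_peak(x, r, sh) # recovers center -300, height 3, baseline 1
#' @export
fit_peak <- function(offsets, ratios, shape, grid_step = 25) {
  if (length(offsets) != length(ratios)) {
    stop("'offsets' and 'ratios' must have equal length")
  }
  if (length(offsets) < 3L) stop("fit_peak needs at least 3 probes")
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("'ratios' must be finite and positive")
  }
  design <- peak_fit_design(offsets, shape, grid_step)
  fit <- peak_fit_many(design, matrix(ratios, ncol = 1L))
  # re-resolve ties within numerical tolerance toward smaller |center|
  rssv <- {
    rmean <- mean(ratios)
    rc <- ratios - rmean
    rss0 <- sum(rc^2)
    slope <- as.numeric(crossprod(design$Sc, rc)) / design$sxx
    slope[design$sxx < 1e-12] <- 0
    slope[slope < 0] <- 0
    base <- rmean - slope * design$smean
    slope[base <= 0] <- 0
    pmax(rss0 - slope^2 * design$sxx, 0)
  }
  tol <- 1e-12 + 1e-9 * max(fit$rss0, 1)
  tie <- which(rssv <= fit$rss1 + tol)
  best <- tie[order(abs(design$centers[tie]), design$centers[tie])][1L]
  rmean <- mean(ratios)
  rc <- ratios - rmean
  sl <- sum(design$Sc[, best] * rc) / max(design$sxx[best], 1e-12)
  if (!is.finite(sl) || sl < 0) sl <- 0
  b <- rmean - sl * design$smean[best]
  if (b <= 0) {
    sl <- 0
    b <- rmean
  }
  list(
    center = design$centers[best],
    height = 1 + sl / b,
    baseline = b,
    rss1 = pmax(fit$rss0[1L] - sl^2 * design$sxx[best], 0),
    rss0 = fit$rss0[1L]
  )
}

#' Log-likelihood-ratio statistic for a fitted peak
#'
#' Under homoscedastic Gaussian residuals on the ratio scale, the
#' log-likelihood ratio of the peak model against the flat (no-event) model
#' is `(n/2) * ln(rss0 / rss1)`. A perfect fit (`rss1 = 0` with `rss0 > 0`)
#' returns the finite `cap`, flagged with attribute `perfect_fit`.
#'
#' @param rss0 Flat-model residual sum of squares.
#' @param rss1 Peak-model residual sum of squares (`rss1 <= rss0`).
#' @param n_probes Number of probes (at least 3).
#' @param cap Finite sentinel returned for perfect fits.
#' @return Non-negative LLR value(s).
#' @export
llr_statistic <- function(rss0, rss1, n_probes, cap = 1e6) {
  if (any(n_probes < 3L)) stop("'n_probes' must be at least 3")
  if (any(rss1 < 0) || any(rss0 < 0)) stop("residual sums must be non-negative")
  # tolerate float jitter from the vectorised fit path
  bad <- rss0 < rss1 - 1e-9 * pmax(rss1, 1)
  if (any(bad)) stop("rss0 < rss1: flat model cannot fit worse than the peak model")
  rss1 <- pmin(rss1, rss0)
  n_out <- max(length(rss0), length(rss1))
  out <- numeric(n_out)
  r0 <- rep_len(rss0, n_out)
  r1 <- rep_len(rss1, n_out)
  np <- rep_len(n_probes, n_out)
  perfect <- r1 == 0 & r0 > 0
  zero <- r0 == r1
  mid <- !perfect & !zero
  out[zero] <- 0
  out[perfect] <- cap
  out[mid] <- pmin((np[mid] / 2) * log(r0[mid] / r1[mid]), cap)
  if (any(perfect)) attr(out, "perfect_fit") <- perfect
  out
}

#' Empirical permutation p-value for a fitted peak
#'
#' Permutes the ratio values across the promoter's probe offsets `B` times,
#' refits the peak model for each permutation, and reports
#' `p = (1 + #\{null LLR >= observed\}) / (B + 1)`. With 4-6 probes the
#' permutation space is small (at most 720 distinct arrangements, including
#' the identity), so achievable p-values are coarse; the array-wide pooled
#' null used by [call_condition()] avoids this granularity.
#'
#' @param offsets,ratios Probe offsets and ratios as in [fit_peak()].
#' @param shape A [peak_shape()].
#' @param observed_llr Observed LLR; computed from the data when `NULL`.
#' @param B Number of permutations (at least 99).
#' @param seed Optional integer seed for the permutation draw.
#' @param grid_step Candidate-center grid step in bp.
#' @return p-value in `(0, 1]`, never below `1/(B+1)`.
#' @export
empirical_pvalue <- function(offsets, ratios, shape, observed_llr = NULL,
                             B = 199, seed = NULL, grid_step = 25) {
  if (B < 99) stop("'B' must be at least 99")
  design <- peak_fit_design(offsets, shape, grid_step)
  n <- design$n
  if (is.null(observed_llr)) {
    f <- fit_peak(offsets, ratios, shape, grid_step)
    observed_llr <- llr_statistic(f$rss0, f$rss1, n)
  }
  if (!is.null(seed)) set.seed(seed)
  R <- vapply(seq_len(B), function(i) sample(ratios), numeric(n))
  fit <- peak_fit_many(design, R)
  null_llr <- llr_statistic(fit$rss0, fit$rss1, n)
  (1 + sum(null_llr >= observed_llr)) / (B + 1)
}
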