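#' Fragment length distributions
#'
#' A `fragment_length_dist` describes the lengths of sheared chromatin
#' fragments after sonication as a discrete probability distribution on
#' integer base-pair lengths. It determines the expected coverage shape of a
#' single binding event on a tiling array (see [peak_shape()]).
#'
#' @param lengths Integer vector of fragment lengths in bp (each in
#'   `[1, 10000]`).
#' @param mass Optional non-negative weights, one per length; normalized to
#'   sum to one. Defaults to equal mass (a discrete uniform distribution).
#' @return An object of class `fragment_length_dist` with elements `lengths`
#'   and `mass`.
#' @examples
#' fd <- fragment_length_dist(c(200, 700))
#' fd$mass
#' @export
fragment_length_dist <- function(lengths, mass = NULL) {
  if (length(lengths) < 1L) {
    stop("fragment length distribution needs at least one length")
  }
  if (any(lengths != round(lengths)) || any(lengths < 1) || any(lengths > 10000)) {
    stop("fragment lengths must be integers in [1, 10000]")
  }
  lengths <- as.integer(lengths)
  if (is.null(mass)) mass <- rep(1, length(lengths))
  if (length(mass) != length(lengths)) {
    stop("'mass' must have one entry per length")
  }
  if (any(mass < 0) || !all(is.finite(mass))) {
    stop("fragment length masses must be finite and non-negative")
  }
  if (sum(mass) <= 0) stop("fragment length masses sum to zero")
  o <- order(lengths)
  structure(
    list(lengths = lengths[o], mass = (mass / sum(mass))[o]),
    class = "fragment_length_dist"
  )
}

#' Uniform fragment-length distribution on a bp range
#'
#' The default sonication model: every integer length between `min` and `max`
#' bp equally likely (typical shearing protocols report a 200-700 bp range).
#'
#' @param min,max Integer bp bounds (inclusive).
#' @return A [fragment_length_dist()].
#' @export
frag_dist_uniform <- function(min = 200, max = 700) {
  if (min > max) stop("'min' must not exceed 'max'")
  fragment_length_dist(seq.int(min, max))
}

#' Truncated-normal fragment-length distribution
#'
#' Alternative shearing model: lengths follow a normal distribution truncated
#' to `[min, max]` bp.
#'
#' @param mean,sd Normal location and scale in bp.
#' @param min,max Truncation bounds (inclusive).
#' @return A [fragment_length_dist()].
#' @export
frag_dist_truncnorm <- function(mean = 450, sd = 120, min = 200, max = 700) {
  if (min > max) stop("'min' must not exceed 'max'")
  l <- seq.int(min, max)
  fragment_length_dist(l, stats::dnorm(l, mean, sd))
}

#' @export
print.fragment_length_dist <- function(x, ...) {
  cat(sprintf(
    "Fragment length distribution: %d lengths in [%d, %d] bp (mean %.1f bp)\n",
    length(x$lengths), min(x$lengths), max(x$lengths),
    sum(x$lengths * x$mass)
  ))
  invisible(x)
}
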