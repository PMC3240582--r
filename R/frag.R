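#' Fragment-length distributions
#'
#' A `frag_dist` is a discrete probability mass function over fragment
#' lengths `1..max(lengths)` in bp. It stands in for the gel-densitometry
#' profile of the precipitated input DNA: the score matrix used to extend
#' sequenced 5' tags over downstream bins is its survival function
#' (see [score_matrix()]).
#'
#' `frag_dist()` builds one from explicit lengths and weights;
#' `frag_triangular()` is the package default, a triangular mass on
#' 100-500 bp with mode 200 mirroring a mono/di/poly-nucleosome smear;
#' `frag_uniform()` and `frag_fixed()` are simple shapes used mainly in
#' examples and tests.
#'
#' @param lengths Integer vector of fragment lengths (bp), all >= 1.
#' @param weights Nonnegative weights, same length as `lengths`; normalized
#'   to sum to 1.
#' @return A `frag_dist`: tibble with columns `length` and `prob`.
#' @export
frag_dist <- function(lengths, weights) {
  lengths <- as.integer(lengths)
  if (length(lengths) == 0 || any(lengths < 1)) {
    abort("fragment lengths must be positive integers")
  }
  if (length(weights) != length(lengths) || any(weights < 0) || any(!is.finite(weights))) {
    abort("weights must be nonnegative, finite, and match lengths")
  }
  tot <- sum(weights)
  if (tot <= 0) abort("fragment-length distribution has zero total mass")
  out <- tibble(length = lengths, prob = weights / tot) %>%
    group_by(.data$length) %>%
    summarise(prob = sum(.data$prob), .groups = "drop") %>%
    arrange(.data$length)
  structure(out, class = c("frag_dist", class(out)))
}

#' @rdname frag_dist
#' @param min,max,mode Support and mode of the triangular distribution (bp).
#' @export
frag_triangular <- function(min = 100L, max = 500L, mode = 200L) {
  stopifnot(min >= 1, min < mode, mode < max)
  len <- seq.int(min, max)
  w <- ifelse(len <= mode,
              (len - min) / (mode - min),
              (max - len) / (max - mode))
  w[len == mode] <- 1
  frag_dist(len, w + 1e-9)
}

#' @rdname frag_dist
#' @export
frag_uniform <- function(min = 1L, max = 500L) {
  frag_dist(seq.int(min, max), rep(1, max - min + 1L))
}

#' @rdname frag_dist
#' @param length Single fragment length for a point mass (bp).
#' @export
frag_fixed <- function(length = 200L) frag_dist(length, 1)

#' Survival function of a fragment-length distribution
#'
#' @param frag A [frag_dist()].
#' @param at Lengths (bp) at which to evaluate `Pr(L > at)`.
#' @return Numeric vector of survival probabilities.
#' @export
frag_survival <- function(frag, at) {
  stopifnot(inherits(frag, "frag_dist"))
  vapply(at, function(a) sum(frag$prob[frag$length > a]), numeric(1))
}

#' Draw fragment lengths
#' @noRd
sample_frag_lengths <- function(frag, n) {
  if (n == 0) return(integer(0))
  frag$length[sample.int(nrow(frag), n, replace = TRUE, prob = frag$prob)]
}
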