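#' Qn robust scale estimator
#'
#' The Qn estimator of scale from pairwise order statistics: `d` times the
#' `m`-th smallest of the `S(S-1)/2` pairwise absolute differences
#' `|x_i - x_j|` (`i < j`), with `h = floor(S/2) + 1` and
#' `m = h(h-1)/2 = choose(h, 2)`. For even `S` this `m` equals
#' `(S/4)(S/2 + 1)`. Qn has a 50% breakdown point and a smooth influence
#' function, and remains suitable for the asymmetric, heavy-tailed
#' distributions of per-taxon relative frequencies across samples — the
#' reason it drives the crossover outlier test instead of the MAD.
#'
#' The default constant `d = 3.4760` is tuned for asymmetric non-Gaussian
#' models similar to the negative exponential distribution; no
#' finite-sample correction beyond `d` is applied. The sample size here is
#' the number of samples in a study (tens at most), so the plain
#' `O(S^2 log S)` enumeration is used.
#'
#' @param values Numeric vector of length `S >= 2` (finite).
#' @param d Scale constant.
#' @return Nonnegative scalar; 0 iff all values are equal. Location
#'   invariant and absolutely scale equivariant:
#'   `qn(a + b * x) = |b| * qn(x)`.
#' @export
qn <- function(values, d = 3.4760) {
  values <- as.numeric(values)
  s <- length(values)
  if (s < 2L) stop("qn requires at least 2 values")
  if (any(!is.finite(values))) stop("qn requires finite values")
  dists <- sort(as.numeric(stats::dist(values)))
  h <- s %/% 2L + 1L
  m <- (h * (h - 1L)) %/% 2L
  d * dists[m]
}
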