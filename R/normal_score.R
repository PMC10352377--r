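#' Normal-score transform for continuous variables
#'
#' Continuous variables are modelled on a Gaussian scale: the empirical
#' CDF maps each value to a probability and the standard-normal quantile
#' function maps that to a normal score. To keep the scores finite the
#' empirical CDF uses the `rank/(n+1)` convention, so the largest
#' observation maps to `qnorm(n/(n+1))` rather than infinity. The inverse
#' applies `pnorm` followed by the empirical quantile function with linear
#' interpolation between support points, clipping to the observed range.
#'
#' @param x Numeric sample with at least 2 distinct finite values
#'   (missing values are ignored at fit time).
#' @return `normal_score_fit` returns an object of class
#'   `normal_score_transform` holding the sorted support and its CDF
#'   probabilities.
#' @export
normal_score_fit <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L)
    stop("degenerate variable: fewer than 2 distinct values; synthesize as constant")
  ord <- order(x)
  p <- rank(x, ties.method = "average") / (n + 1)
  structure(
    list(support = x[ord], probs = p[ord], n = n,
         range = range(x)),
    class = "normal_score_transform"
  )
}

#' @rdname normal_score_fit
#' @param t A fitted `normal_score_transform`; when `NULL`,
#'   `normal_score_forward` fits the transform on `x` itself.
#' @return `normal_score_forward` returns the normal scores
#'   `qnorm(F(x))`; `normal_score_inverse` returns original-scale values.
#' @export
normal_score_forward <- function(x, t = NULL) {
  if (is.null(t)) {
    t <- normal_score_fit(x)
    return(stats::qnorm(rank(x, ties.method = "average") / (t$n + 1)))
  }
  # interpolate the training CDF for new values; constant outside the range
  cdf <- collapse_ties(t)
  p <- stats::approx(cdf$support, cdf$probs, xout = x, rule = 2,
                     ties = "ordered")$y
  stats::qnorm(p)
}

# unique support with one (averaged-rank) probability per value
collapse_ties <- function(t) {
  keep <- !duplicated(t$support)
  list(support = t$support[keep], probs = t$probs[keep])
}

#' @rdname normal_score_fit
#' @param z Numeric vector of normal scores.
#' @export
normal_score_inverse <- function(z, t) {
  stopifnot(inherits(t, "normal_score_transform"))
  cdf <- collapse_ties(t)
  p <- stats::pnorm(z)
  out <- stats::approx(cdf$probs, cdf$support, xout = p, rule = 2,
                       ties = "ordered")$y
  pmin(pmax(out, t$range[1]), t$range[2])
}
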