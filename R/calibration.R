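#' Beta calibration of classifier probabilities
#'
#' Boosted trees do not output well-calibrated probabilities, and training
#' with minority-class weights distorts them further. Beta calibration
#' corrects this with the three-parameter monotone family
#' \deqn{\mu(p) = 1 / (1 + 1/(e^c p^a (1-p)^{-b}))}
#' equivalently `plogis(c + a*log(p) - b*log(1-p))`. Parameters are
#' obtained by a maximum-likelihood logistic fit of the outcome on the
#' features `log(p)` and `-log(1-p)`; probabilities are clipped to
#' `[1e-6, 1 - 1e-6]` before taking logs. If the unconstrained fit gives a
#' negative `a` or `b` (a non-monotone map), the model is refit on the
#' single feature `log(p/(1-p))` (forcing `a = b >= 0`), falling back to an
#' intercept-only map (the base rate) if even that slope is negative or
#' the input probabilities are constant.
#'
#' @param raw_probs Numeric vector of raw predicted probabilities in (0,1).
#' @param labels Binary outcome vector (0/1 or logical); both classes must
#'   be present.
#' @return An object of class `beta_calibration_map` with fields `a`, `b`, `c`.
#' @references Kull, Silva Filho & Flach (2017), beta calibration for
#'   binary classifiers.
#' @export
fit_beta_calibration <- function(raw_probs, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; calibration undefined")
  eps <- 1e-6
  p <- pmin(pmax(raw_probs, eps), 1 - eps)
  base <- mean(y)
  newmap <- function(a, b, c)
    structure(list(a = a, b = b, c = c), class = "beta_calibration_map")
  if (diff(range(p)) < 1e-12)
    return(newmap(0, 0, stats::qlogis(base)))
  f1 <- log(p); f2 <- -log(1 - p)
  fit <- suppressWarnings(stats::glm(y ~ f1 + f2, family = stats::binomial()))
  cf <- stats::coef(fit)
  a <- unname(cf["f1"]); b <- unname(cf["f2"]); c <- unname(cf["(Intercept)"])
  if (is.na(a) || is.na(b) || a < 0 || b < 0) {
    g <- log(p / (1 - p))
    fit <- suppressWarnings(stats::glm(y ~ g, family = stats::binomial()))
    s <- unname(stats::coef(fit)["g"]); c <- unname(stats::coef(fit)[1])
    if (is.na(s) || s < 0) return(newmap(0, 0, stats::qlogis(base)))
    a <- s; b <- s
  }
  newmap(a, b, c)
}

#' @rdname fit_beta_calibration
#' @param map A `beta_calibration_map`.
#' @param p Raw probabilities to calibrate.
#' @return `apply_beta_calibration` returns calibrated probabilities in
#'   `[0, 1]`.
#' @export
apply_beta_calibration <- function(map, p) {
  stopifnot(inherits(map, "beta_calibration_map"))
  eps <- 1e-6
  p <- pmin(pmax(p, eps), 1 - eps)
  stats::plogis(map$c + map$a * log(p) - map$b * log(1 - p))
}

#' Calibrate a matrix of class probabilities
#'
#' Multiclass probabilities are calibrated one-vs-rest: each class column
#' is passed through its own beta-calibration map and the rows are then
#' renormalized to sum to 1.
#'
#' @param maps A list of `beta_calibration_map`, one per class (column).
#' @param probs Numeric matrix of raw class probabilities; each row must
#'   sum to 1 within 1e-6.
#' @return Matrix of calibrated probabilities with unit row sums.
#' @export
apply_calibration <- function(maps, probs) {
  probs <- as.matrix(probs)
  stopifnot(length(maps) == ncol(probs))
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("raw class probabilities must sum to 1 per row")
  out <- vapply(seq_along(maps),
                function(k) apply_beta_calibration(maps[[k]], probs[, k]),
                numeric(nrow(probs)))
  out <- matrix(out, nrow = nrow(probs))
  out / rowSums(out)
}
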