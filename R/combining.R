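#' Partial-synthesis combining rules
#'
#' Turns the per-replicate estimates of one model parameter into a single
#' inference across the m synthetic replicates. With per-replicate
#' estimates \eqn{q_i} and variances \eqn{v_i}:
#' \deqn{\bar q_m = \frac{1}{m}\sum_i q_i, \qquad
#'       \bar v_m = \frac{1}{m}\sum_i v_i,}
#' \deqn{b_m = \frac{1}{m-1}\sum_i (q_i - \bar q_m)^2, \qquad
#'       T_p = b_m/m + \bar v_m,}
#' with the adjusted large-sample 95% confidence interval
#' \eqn{\bar q_m \pm 1.96\sqrt{T_p}} and a two-sided p-value from the
#' normal reference distribution. These are the partial-synthesis rules;
#' fully-synthetic variance rules are out of scope.
#'
#' @param q Numeric vector of per-replicate estimates (length m >= 2).
#' @param v Numeric vector of per-replicate variances (same length, >= 0).
#' @return An object of class `combined_estimate` with fields `q_bar`,
#'   `v_bar`, `b_m`, `T_p`, `ci_low`, `ci_high`, `p_value`, `m`.
#' @export
combine <- function(q, v) {
  m <- length(q)
  if (length(v) != m) stop("q and v must have equal length")
  if (m == 1L)
    stop("m = 1: no between-replicate variance is estimable; ",
         "use single-dataset inference instead")
  if (any(v < 0)) stop("negative variance supplied")
  q_bar <- mean(q)
  v_bar <- mean(v)
  b_m <- sum((q - q_bar)^2) / (m - 1)
  T_p <- b_m / m + v_bar
  se <- sqrt(T_p)
  z <- if (se > 0) q_bar / se else ifelse(q_bar == 0, 0, Inf * sign(q_bar))
  structure(
    list(q_bar = q_bar, v_bar = v_bar, b_m = b_m, T_p = T_p,
         ci_low = q_bar - 1.96 * se, ci_high = q_bar + 1.96 * se,
         p_value = 2 * stats::pnorm(-abs(z)), m = m),
    class = "combined_estimate"
  )
}

#' Combine all coefficients of one regression across replicates
#'
#' @param estimates Matrix (or data.frame) of per-replicate coefficient
#'   estimates, replicates in rows, coefficients in columns.
#' @param variances Matrix of per-replicate coefficient variances, same
#'   shape and column names.
#' @return A data.frame, one row per coefficient: `coefficient`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `significant` (at the
#'   p < 0.05 convention), plus `b_m`, `v_bar`, `T_p`.
#' @export
combine_model <- function(estimates, variances) {
  estimates <- as.matrix(estimates)
  variances <- as.matrix(variances)
  if (!identical(dim(estimates), dim(variances)))
    stop("estimate and variance matrices must share shape (same m, ",
         "same coefficients)")
  if (!identical(colnames(estimates), colnames(variances)))
    stop("coefficient names differ between estimates and variances")
  rows <- lapply(seq_len(ncol(estimates)), function(j) {
    ce <- combine(estimates[, j], variances[, j])
    data.frame(coefficient = colnames(estimates)[j], estimate = ce$q_bar,
               ci_low = ce$ci_low, ci_high = ce$ci_high,
               p_value = ce$p_value, significant = ce$p_value < 0.05,
               b_m = ce$b_m, v_bar = ce$v_bar, T_p = ce$T_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
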