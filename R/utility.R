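#' Standardized mean difference between two samples
#'
#' Continuous and ordinal variables (ordinal via their numeric codes) use
#' \eqn{|m_a - m_b| / \sqrt{(s_a^2 + s_b^2)/2}}. Binary variables use the
#' same form with Bernoulli variances \eqn{p(1-p)}. Multi-level
#' categorical variables use the multivariate Mahalanobis-type SMD over
#' the level-proportion vectors: one level is omitted and the pooled
#' multinomial covariance \eqn{S = (S_a + S_b)/2},
#' \eqn{S_k = diag(p_k) - p_k p_k'}, gives
#' \eqn{\sqrt{d' S^{-1} d}} for the proportion difference d. Missing
#' values are dropped. A zero pooled variance yields 0 when the means are
#' equal and `Inf` with a warning otherwise.
#'
#' @param a,b Vectors of the variable's values in the two samples.
#' @param def The variable's [variable_schema()] entry.
#' @return A single non-negative SMD value.
#' @export
smd <- function(a, b, def) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 non-missing values per sample for '", def$name, "'")
  num_smd <- function(ma, mb, va, vb) {
    pooled <- (va + vb) / 2
    if (pooled <= 0) {
      if (isTRUE(all.equal(ma, mb))) return(0)
      warning("zero pooled variance with unequal means for '", def$name, "'")
      return(Inf)
    }
    abs(ma - mb) / sqrt(pooled)
  }
  if (def$kind == "continuous")
    return(num_smd(mean(a), mean(b), stats::var(a), stats::var(b)))
  if (def$kind == "ordinal") {
    xa <- def$codes[match(a, def$levels)]
    xb <- def$codes[match(b, def$levels)]
    return(num_smd(mean(xa), mean(xb), stats::var(xa), stats::var(xb)))
  }
  lev <- def$levels
  if (length(lev) == 2L) {
    pa <- mean(a == lev[2]); pb <- mean(b == lev[2])
    return(num_smd(pa, pb, pa * (1 - pa), pb * (1 - pb)))
  }
  pa <- vapply(lev, function(l) mean(a == l), numeric(1))
  pb <- vapply(lev, function(l) mean(b == l), numeric(1))
  keep <- seq_len(length(lev) - 1L)
  d <- (pa - pb)[keep]
  Sk <- function(p) diag(p[keep], length(keep)) - tcrossprod(p[keep])
  S <- (Sk(pa) + Sk(pb)) / 2
  qr_S <- qr(S)
  if (qr_S$rank < length(keep)) {
    if (max(abs(d)) < 1e-12) return(0)
    warning("singular pooled proportion covariance for '", def$name, "'")
    return(Inf)
  }
  sqrt(drop(t(d) %*% solve(qr_S, d)))
}

#' SMD balance report across synthetic replicates
#'
#' Computes, per variable, the SMD between a reference (ground-truth
#' pooled) table and each replicate's pooled table, averages across
#' replicates, and flags variables whose mean SMD exceeds the
#' conventional 0.1 imbalance threshold. Optionally also reports SMDs
#' within strata (e.g. by sex).
#'
#' @param reference The ground-truth pooled data.frame.
#' @param pooled_tables List of pooled data.frames, one per synthetic
#'   replicate (each typically `rbind(synthetic_A, real_B)`).
#' @param schema A `survey_schema`.
#' @param variables Variables to report; default all schema variables
#'   except `country`.
#' @param strata Optional stratifying variable name (e.g. `"sex"`).
#' @param threshold Flagging threshold; default 0.1.
#' @return A list of class `smd_report`: `table` (data.frame with mean
#'   SMD and flag per variable), `per_replicate` (matrix), and `strata`
#'   (named list of sub-reports) when requested.
#' @export
smd_report <- function(reference, pooled_tables, schema,
                       variables = NULL, strata = NULL, threshold = 0.1) {
  if (inherits(pooled_tables, "synthetic_replicates"))
    pooled_tables <- pooled_tables$tables
  if (is.data.frame(pooled_tables)) pooled_tables <- list(pooled_tables)
  if (is.null(variables))
    variables <- setdiff(intersect(schema_names(schema), names(reference)),
                         "country")
  per <- vapply(pooled_tables, function(tab)
    vapply(variables, function(v)
      smd(reference[[v]], tab[[v]], schema[[v]]), numeric(1)),
    numeric(length(variables)))
  per <- matrix(per, nrow = length(variables),
                dimnames = list(variables, NULL))
  mean_smd <- rowMeans(per)
  out <- list(
    table = data.frame(variable = variables, mean_smd = unname(mean_smd),
                       flagged = unname(mean_smd > threshold)),
    per_replicate = per, threshold = threshold)
  if (!is.null(strata)) {
    lv <- schema[[strata]]$levels
    out$strata <- lapply(stats::setNames(lv, lv), function(l)
      smd_report(reference[reference[[strata]] %in% l, , drop = FALSE],
                 lapply(pooled_tables, function(tab)
                   tab[tab[[strata]] %in% l, , drop = FALSE]),
                 schema, setdiff(variables, strata), strata = NULL,
                 threshold = threshold))
  }
  structure(out, class = "smd_report")
}

#' Concordance between an oracle fit and a combined synthetic-data fit
#'
#' For each shared coefficient, three agreement flags: sign agreement
#' (both estimates on the same side of 0, or both confidence intervals
#' containing 0), significance agreement at p < 0.05, and confidence
#' interval overlap. The intercept is excluded.
#'
#' @param oracle An `ols_fit` (the federated ground truth).
#' @param combined A data.frame from [combine_model()].
#' @return A list of class `comparison_report`: `table` (per-coefficient
#'   flags and both estimates/CIs) and `summary` (agreement counts).
#' @export
compare_fits <- function(oracle, combined) {
  oc <- setdiff(oracle$columns, "(Intercept)")
  cc <- setdiff(combined$coefficient, "(Intercept)")
  if (!setequal(oc, cc))
    stop("coefficient mismatch between fits; only in oracle: ",
         paste(setdiff(oc, cc), collapse = ", "), "; only in combined: ",
         paste(setdiff(cc, oc), collapse = ", "))
  rows <- lapply(oc, function(nm) {
    i <- match(nm, combined$coefficient)
    o_est <- oracle$coefficients[[nm]]
    o_lo <- oracle$ci_low[[nm]]; o_hi <- oracle$ci_high[[nm]]
    o_sig <- oracle$p_value[[nm]] < 0.05
    c_est <- combined$estimate[i]
    c_lo <- combined$ci_low[i]; c_hi <- combined$ci_high[i]
    c_sig <- combined$significant[i]
    zero_o <- o_lo <= 0 && o_hi >= 0
    zero_c <- c_lo <= 0 && c_hi >= 0
    data.frame(
      coefficient = nm, oracle_estimate = o_est, combined_estimate = c_est,
      oracle_ci_low = o_lo, oracle_ci_high = o_hi,
      combined_ci_low = c_lo, combined_ci_high = c_hi,
      sign_agree = (sign(o_est) == sign(c_est)) || (zero_o && zero_c),
      significance_agree = o_sig == c_sig,
      ci_overlap = o_lo <= c_hi && c_lo <= o_hi)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(
    list(table = tab,
         summary = c(n_coefficients = nrow(tab),
                     sign_agree = sum(tab$sign_agree),
                     significance_agree = sum(tab$significance_agree),
                     ci_overlap = sum(tab$ci_overlap))),
    class = "comparison_report"
  )
}
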