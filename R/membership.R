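#' Configuration of the membership-disclosure attack
#'
#' The attack models an adversary who knows a target person's
#' quasi-identifiers and the released synthetic table, and predicts that
#' the target was a member of the training data if some synthetic record
#' lies within distance `h` of the target on the quasi-identifiers.
#'
#' @param quasi_identifiers Character vector of variable names the
#'   adversary is assumed to know; default is the demographic set (sex,
#'   age group, marital status, household size, education, income,
#'   immigrant status).
#' @param h Distance threshold in `[0, 1]`; the default 0 demands an exact
#'   match on all quasi-identifiers (the strictest attack).
#' @param mix Intended member share among attack targets (recorded for
#'   reporting; the attack itself uses whatever samples it is given).
#' @return A list of class `attack_config`.
#' @export
attack_config <- function(quasi_identifiers = c("sex", "age_group",
                                                "marital_status",
                                                "household_size", "education",
                                                "household_income",
                                                "immigrant"),
                          h = 0, mix = 0.5) {
  if (h < 0 || h > 1) stop("h must lie in [0, 1]")
  if (!length(quasi_identifiers)) stop("no quasi-identifiers supplied")
  structure(list(quasi_identifiers = quasi_identifiers, h = h, mix = mix),
            class = "attack_config")
}

# minimum mean per-variable distance from each target row to any synthetic
# row; categorical: 0/1 mismatch, continuous: |diff|/range capped at 1
min_hamming_distance <- function(targets, synthetic, qi, schema,
                                 chunk = 2048L) {
  nt <- nrow(targets)
  ns <- nrow(synthetic)
  best <- rep(Inf, nt)
  cont <- vapply(qi, function(v) schema[[v]]$kind == "continuous", logical(1))
  rng <- lapply(qi, function(v) {
    if (schema[[v]]$kind == "continuous")
      diff(range(synthetic[[v]], na.rm = TRUE)) else NA_real_
  })
  for (s0 in seq(1L, ns, by = chunk)) {
    s1 <- min(s0 + chunk - 1L, ns)
    acc <- matrix(0, nt, s1 - s0 + 1L)
    for (j in seq_along(qi)) {
      v <- qi[j]
      xs <- synthetic[[v]][s0:s1]
      xt <- targets[[v]]
      if (cont[j]) {
        d <- abs(outer(xt, xs, `-`)) / max(rng[[j]], .Machine$double.eps)
        d[is.na(d)] <- 1  # one side missing: maximal distance
        both_na <- outer(is.na(xt), is.na(xs), `&`)
        d[both_na] <- 0
        acc <- acc + pmin(d, 1)
      } else {
        xt_c <- as.character(xt); xs_c <- as.character(xs)
        xt_c[is.na(xt_c)] <- "\r(NA)"; xs_c[is.na(xs_c)] <- "\r(NA)"
        acc <- acc + (outer(xt_c, xs_c, `!=`)) * 1
      }
    }
    best <- pmin(best, apply(acc, 1, min) / length(qi))
  }
  best
}

attack_one <- function(members, non_members, synthetic, cfg, schema) {
  qi <- cfg$quasi_identifiers
  all_cat <- all(vapply(qi, function(v) schema[[v]]$kind != "continuous",
                        logical(1)))
  targets <- rbind(members[, qi, drop = FALSE],
                   non_members[, qi, drop = FALSE])
  truth <- rep(c(TRUE, FALSE), c(nrow(members), nrow(non_members)))
  if (cfg$h == 0 && all_cat) {
    key <- function(df) do.call(paste, c(lapply(df[qi], as.character),
                                         sep = "\r"))
    pred <- key(targets) %in% key(synthetic[, qi, drop = FALSE])
  } else {
    d <- min_hamming_distance(targets, synthetic, qi, schema)
    pred <- d <= cfg$h
  }
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Membership-disclosure attack with relative F1 scoring
#'
#' For each target the nearest-record distance to the synthetic table is
#' computed over the quasi-identifiers; the target is predicted a member
#' iff that distance is at most `h`. F1 is computed against true
#' membership and compared to the naive baseline of predicting every
#' target a member: `relative_f1 = f1 - naive_f1`. Values near 0 (or
#' below) indicate the synthetic data gives the adversary no usable
#' membership signal. When a list of synthetic replicates is supplied the
#' attack runs per replicate and the mean is reported.
#'
#' @param members Data.frame of targets that were in the training data.
#' @param non_members Data.frame of targets that were not (disjoint from
#'   `members`).
#' @param synthetic A synthetic data.frame, a list of them, or a
#'   `synthetic_replicates` object.
#' @param cfg An [attack_config()].
#' @param schema A `survey_schema`.
#' @return An object of class `membership_attack_result`: per-replicate
#'   precision/recall/F1 plus mean `precision`, `recall`, `f1`,
#'   `naive_f1`, `relative_f1`.
#' @export
membership_attack <- function(members, non_members, synthetic, cfg, schema) {
  if (inherits(synthetic, "synthetic_replicates")) synthetic <- synthetic$tables
  if (is.data.frame(synthetic)) synthetic <- list(synthetic)
  if (!length(synthetic) || any(!vapply(synthetic, nrow, 1L)))
    stop("empty synthetic table")
  qi <- cfg$quasi_identifiers
  bad <- setdiff(qi, names(members))
  if (length(bad))
    stop("quasi-identifiers not present: ", paste(bad, collapse = ", "))
  per <- t(vapply(synthetic, function(s)
    attack_one(members, non_members, s, cfg, schema), numeric(3)))
  n_m <- nrow(members); n_t <- n_m + nrow(non_members)
  naive_prec <- n_m / n_t
  naive_f1 <- 2 * naive_prec * 1 / (naive_prec + 1)
  mu <- colMeans(per)
  structure(
    list(per_replicate = as.data.frame(per),
         precision = unname(mu["precision"]), recall = unname(mu["recall"]),
         f1 = unname(mu["f1"]), naive_f1 = naive_f1,
         relative_f1 = unname(mu["f1"]) - naive_f1,
         n_members = n_m, n_non_members = nrow(non_members),
         h = cfg$h, quasi_identifiers = qi),
    class = "membership_attack_result"
  )
}
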