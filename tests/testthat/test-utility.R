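bin_def <- variable_schema("b", "categorical", c("no", "yes"))
cont_def <- variable_schema("c", "continuous")

test_that("SMD closed forms: identical samples, binary proportions, normal means", {
  x <- stats::rnorm(100)
  expect_equal(smd(x, x, cont_def), 0)
  a <- rep(c("yes", "no"), c(50, 50))
  b <- rep(c("yes", "no"), c(60, 40))
  expect_equal(smd(a, b, bin_def), 0.1 / sqrt((0.25 + 0.24) / 2))
  expect_equal(round(smd(a, b, bin_def), 5), 0.20203)
  set.seed(81)
  expect_equal(smd(stats::rnorm(1e5), stats::rnorm(1e5, 0.5), cont_def),
               0.5, tolerance = 0.04)
})

test_that("SMD is symmetric and scale-invariant for continuous variables", {
  set.seed(82)
  a <- stats::rnorm(500, 1, 2)
  b <- stats::rnorm(500, 1.4, 1.5)
  expect_equal(smd(a, b, cont_def), smd(b, a, cont_def))
  expect_equal(smd(7 * a, 7 * b, cont_def), smd(a, b, cont_def),
               tolerance = 1e-12)
})

test_that("ordinal SMD uses the level codes", {
  def <- variable_schema("o", "ordinal", c("l", "m", "h"), codes = 1:3)
  a <- rep(c("l", "m", "h"), c(30, 40, 30))
  b <- rep(c("l", "m", "h"), c(20, 40, 40))
  xa <- rep(1:3, c(30, 40, 30)); xb <- rep(1:3, c(20, 40, 40))
  expect_equal(smd(a, b, def),
               abs(mean(xa) - mean(xb)) /
                 sqrt((stats::var(xa) + stats::var(xb)) / 2))
})

test_that("multi-level categorical SMD is a Mahalanobis distance on proportions", {
  def <- variable_schema("m", "categorical", c("a", "b", "c"))
  x <- rep(c("a", "b", "c"), c(30, 30, 40))
  y <- rep(c("a", "b", "c"), c(40, 30, 30))
  got <- smd(x, y, def)
  # independent direct computation
  pa <- c(0.3, 0.3); pb <- c(0.4, 0.3)
  S <- ((diag(pa) - outer(pa, pa)) + (diag(pb) - outer(pb, pb))) / 2
  d <- pa - pb
  expect_equal(got, sqrt(drop(t(d) %*% solve(S) %*% d)), tolerance = 1e-12)
  expect_equal(smd(x, x, def), 0)
})

test_that("degenerate SMD inputs follow the 0 / Inf contract", {
  expect_equal(smd(rep("no", 10), rep("no", 12), bin_def), 0)
  expect_warning(v <- smd(rep(1, 10), rep(2, 10), cont_def), "zero pooled")
  expect_identical(v, Inf)
})

test_that("smd_report averages per-replicate SMDs and flags at the threshold", {
  spec <- canada_like_spec(n = 800, missing = FALSE)
  ref <- simulate_country(spec, 83)
  reps <- list(simulate_country(spec, 84), simulate_country(spec, 85))
  rep_identical <- smd_report(ref, list(ref, ref), spec$schema)
  expect_true(all(rep_identical$table$mean_smd == 0))
  expect_false(any(rep_identical$table$flagged))
  r <- smd_report(ref, reps, spec$schema)
  expect_equal(unname(rowMeans(r$per_replicate)), r$table$mean_smd)
  # forced degenerate partner is heavily imbalanced and must flag
  far <- simulate_country(forced_spec(800), 86)
  r2 <- smd_report(ref, list(far), spec$schema,
                   variables = c("sex", "household_income"))
  expect_true(all(r2$table$flagged))
  # stratified reports cover each level
  rs <- smd_report(ref, reps, spec$schema, strata = "sex")
  expect_named(rs$strata, c("male", "female"))
})

test_that("compare_fits flags sign, significance and CI overlap correctly", {
  mk_oracle <- function(est, se, cols = names(est)) {
    z <- est / se
    structure(list(coefficients = est, variances = se^2, se = se,
                   ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                   p_value = stats::setNames(2 * stats::pnorm(-abs(z)),
                                             cols),
                   columns = c("(Intercept)", cols)),
              class = "ols_fit")
  }
  est <- c(`(Intercept)` = 1, x1 = 0.19, x2 = -0.3)
  se <- c(`(Intercept)` = 0.1, x1 = 0.005, x2 = 0.01)
  oracle <- mk_oracle(est, se)
  combined <- data.frame(coefficient = c("(Intercept)", "x1", "x2"),
                         estimate = c(1, 0.18, -0.28),
                         ci_low = c(0.9, 0.17, -0.30),
                         ci_high = c(1.1, 0.20, -0.26),
                         p_value = c(0, 1e-10, 1e-10),
                         significant = c(TRUE, TRUE, TRUE))
  cmp <- compare_fits(oracle, combined)
  expect_true(all(cmp$table$sign_agree))
  expect_true(all(cmp$table$significance_agree))
  expect_true(all(cmp$table$ci_overlap))
  expect_equal(unname(cmp$summary["n_coefficients"]), 2)  # intercept excluded
  # oracle significant, combined CI straddling 0 with the same sign
  combined2 <- combined
  combined2[2, c("ci_low", "ci_high", "significant", "p_value")] <-
    list(-0.01, 0.37, FALSE, 0.2)
  cmp2 <- compare_fits(oracle, combined2)
  expect_true(cmp2$table$sign_agree[cmp2$table$coefficient == "x1"])
  expect_false(cmp2$table$significance_agree[cmp2$table$coefficient == "x1"])
  # coefficient mismatch errors with the difference listed
  combined3 <- combined[-2, ]
  expect_error(compare_fits(oracle, combined3), "only in oracle: x1")
})
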