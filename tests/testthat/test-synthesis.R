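test_that("calibrated probabilities recover the prevalence of an independent target", {
  set.seed(31)
  n <- 5000
  dat <- data.frame(x = sample(c("a", "b"), n, TRUE),
                    y = ifelse(stats::runif(n) < 0.3, "b", "a"))
  cm <- fit_conditional(dat, "y", "x", toy_schema(), quick_config(), seed = 1)
  P <- synthpool:::conditional_class_probs(cm, dat)
  p_b <- P[, match("b", cm$levels)]
  expect_true(all(abs(p_b - 0.3) < 0.05))
})

test_that("a deterministic relation is learned with held-out accuracy 1", {
  set.seed(32)
  dat <- data.frame(x = sample(c("a", "b"), 2000, TRUE))
  dat$y <- dat$x
  cm <- fit_conditional(dat[1:1500, ], "y", "x", toy_schema(),
                        quick_config(), seed = 2)
  P <- synthpool:::conditional_class_probs(cm, dat[1501:2000, ])
  pred <- cm$levels[max.col(P)]
  expect_equal(mean(pred == dat$y[1501:2000]), 1)
})

test_that("hyperparameter search is deterministic under a fixed seed", {
  set.seed(33)
  dat <- data.frame(x = sample(c("a", "b"), 400, TRUE))
  dat$y <- ifelse(stats::runif(400) < ifelse(dat$x == "a", 0.2, 0.7), "b", "a")
  cfg <- synthesis_config(tune_trials = 5, tune_init = 3, nrounds = 30)
  cm1 <- fit_conditional(dat, "y", "x", toy_schema(), cfg, seed = 3)
  cm2 <- fit_conditional(dat, "y", "x", toy_schema(), cfg, seed = 3)
  expect_identical(cm1$params, cm2$params)
  expect_identical(cm1$booster_raw, cm2$booster_raw)
})

test_that("second model of two independent binaries ignores the first", {
  set.seed(34)
  n <- 5000
  dat <- data.frame(x = sample(c("a", "b"), n, TRUE),
                    y = sample(c("a", "b"), n, TRUE, prob = c(0.6, 0.4)))
  m <- fit_sequential(dat, toy_schema(), config = quick_config(), seed = 4)
  P <- synthpool:::conditional_class_probs(
    m$models$y, data.frame(x = c("a", "b"), stringsAsFactors = FALSE))
  expect_lt(abs(diff(P[, 1])), 0.05)
  expect_lt(abs(P[1, 2] - 0.4), 0.05)
})

test_that("an order of length one stores only a marginal sampler", {
  dat <- data.frame(x = sample(c("a", "b", "a"), 100, TRUE))
  sch <- structure(list(x = variable_schema("x", "categorical", c("a", "b"))),
                   class = "survey_schema")
  m <- fit_sequential(dat, sch, config = quick_config(), seed = 5)
  expect_length(m$models, 1)
  expect_identical(m$models$x$kind, "empirical")
  reps <- generate_replicates(m, 500, 1, seed = 6)
  expect_lt(abs(mean(reps$tables[[1]]$x == "a") - mean(dat$x == "a")), 0.1)
})

test_that("a deterministic chain x -> y -> z keeps z consistent with x", {
  set.seed(35)
  n <- 3000
  sch <- structure(list(
    x = variable_schema("x", "categorical", c("a", "b")),
    y = variable_schema("y", "categorical", c("a", "b")),
    z = variable_schema("z", "categorical", c("a", "b"))),
    class = "survey_schema")
  dat <- data.frame(x = sample(c("a", "b"), n, TRUE))
  dat$y <- dat$x
  dat$z <- dat$y
  m <- fit_sequential(dat, sch, config = quick_config(), seed = 7)
  s <- generate_replicates(m, n, 1, seed = 8)$tables[[1]]
  expect_gte(mean(s$z == s$x), 0.99)
})

test_that("a constant column synthesizes as that constant", {
  dat <- data.frame(x = rep("a", 200), y = sample(c("a", "b"), 200, TRUE))
  m <- fit_sequential(dat, toy_schema(), config = quick_config(), seed = 9)
  s <- generate_replicates(m, 100, 1, seed = 10)$tables[[1]]
  expect_true(all(s$x == "a"))
})

test_that("replicate generation is fully deterministic and replicates differ", {
  spec <- canada_like_spec(n = 1500)
  dat <- simulate_country(spec, 41)
  m <- fit_sequential(dat, spec$schema, config = quick_config(), seed = 11)
  r1 <- generate_replicates(m, 1000, 2, seed = 12)
  r2 <- generate_replicates(m, 1000, 2, seed = 12)
  expect_identical(r1, r2)
  expect_false(identical(r1$tables[[1]], r1$tables[[2]]))
  r3 <- generate_replicates(m, 1000, 2, seed = 13)
  expect_false(identical(r1$tables[[1]], r3$tables[[1]]))
})

test_that("m replicates of the training shape are produced on request", {
  spec <- canada_like_spec(n = 500)
  dat <- simulate_country(spec, 49)
  m <- fit_sequential(dat, spec$schema, config = quick_config(), seed = 50)
  reps <- generate_replicates(m, n = nrow(dat), m = 10, seed = 51)
  expect_equal(reps$m, 10)
  expect_length(reps$tables, 10)
  for (tab in reps$tables) {
    expect_equal(nrow(tab), nrow(dat))
    expect_identical(names(tab), names(dat))
  }
})

test_that("synthetic marginals track training marginals within 3 SE", {
  spec <- canada_like_spec(n = 8000, missing = FALSE)
  dat <- simulate_country(spec, 42)
  m <- fit_sequential(dat, spec$schema, config = quick_config(), seed = 14)
  s <- generate_replicates(m, nrow(dat), 1, seed = 15)$tables[[1]]
  checks <- 0L; ok <- 0L
  for (v in setdiff(names(dat), "country")) {
    for (l in spec$schema[[v]]$levels) {
      p <- mean(dat[[v]] == l)
      if (p < 0.02 || p > 0.98) next
      tol <- 3 * sqrt(p * (1 - p) / nrow(dat))
      checks <- checks + 1L
      ok <- ok + as.integer(abs(mean(s[[v]] == l) - p) < tol)
    }
  }
  expect_gte(ok / checks, 0.95)
})

test_that("adjacent-pair association (Cramer's V) is preserved", {
  spec <- canada_like_spec(n = 8000, missing = FALSE)
  dat <- simulate_country(spec, 43)
  m <- fit_sequential(dat, spec$schema, config = quick_config(), seed = 16)
  s <- generate_replicates(m, nrow(dat), 1, seed = 17)$tables[[1]]
  vars <- setdiff(names(dat), "country")
  for (i in seq_len(length(vars) - 1)) {
    v_train <- cramers_v(dat[[vars[i]]], dat[[vars[i + 1]]])
    v_synth <- cramers_v(s[[vars[i]]], s[[vars[i + 1]]])
    expect_lt(abs(v_train - v_synth), 0.05,
              label = paste("Cramer's V drift", vars[i], vars[i + 1]))
  }
})

test_that("synthetic rows copy training rows no more often than training duplicates itself", {
  spec <- canada_like_spec(n = 5000, missing = FALSE)
  dat <- simulate_country(spec, 44)
  m <- fit_sequential(dat, spec$schema, config = quick_config(), seed = 18)
  s <- generate_replicates(m, nrow(dat), 1, seed = 19)$tables[[1]]
  key <- function(df) do.call(paste, c(df, sep = "\r"))
  train_keys <- key(dat)
  # leave-one-out duplicate rate of the training data itself
  dup_rate <- mean(duplicated(train_keys) | duplicated(train_keys,
                                                       fromLast = TRUE))
  match_rate <- mean(key(s) %in% train_keys)
  expect_lte(match_rate, dup_rate)
})

test_that("categorical and continuous missingness is reproduced and restored", {
  spec <- canada_like_spec(n = 4000, continuous_bmi = TRUE)
  spec$missing_rates <- c(spec$missing_rates, bmi = 0.15)
  dat <- simulate_country(spec, 45)
  m <- fit_sequential(dat, spec$schema, config = quick_config(), seed = 20)
  s <- generate_replicates(m, nrow(dat), 1, seed = 21)$tables[[1]]
  expect_identical(names(s), names(dat))
  # missing rates carried through within sampling error
  expect_lt(abs(mean(is.na(s$bmi_lt25)) - mean(is.na(dat$bmi_lt25))), 0.03)
  expect_lt(abs(mean(is.na(s$bmi)) - mean(is.na(dat$bmi))), 0.03)
  # continuous values stay inside the training range (clipping contract)
  expect_gte(min(s$bmi, na.rm = TRUE), min(dat$bmi, na.rm = TRUE))
  expect_lte(max(s$bmi, na.rm = TRUE), max(dat$bmi, na.rm = TRUE))
  # and the continuous marginal is close in distribution
  expect_lt(abs(stats::median(s$bmi, na.rm = TRUE) -
                  stats::median(dat$bmi, na.rm = TRUE)), 1)
})

test_that("a saved model reloads to bit-identical sampling behavior", {
  spec <- canada_like_spec(n = 1200, continuous_bmi = TRUE)
  dat <- simulate_country(spec, 46)
  m <- fit_sequential(dat, spec$schema, config = quick_config(), seed = 22)
  f <- withr::local_tempfile(fileext = ".json")
  save_synthesis_model(m, f)
  m2 <- load_synthesis_model(f)
  r1 <- generate_replicates(m, 800, 2, seed = 23)
  r2 <- generate_replicates(m2, 800, 2, seed = 23)
  expect_identical(r1$tables, r2$tables)
})

test_that("order validation and error propagation name the offending variable", {
  spec <- canada_like_spec(n = 200)
  dat <- simulate_country(spec, 47)
  expect_error(fit_sequential(dat, spec$schema, order = c("sex", "sex"),
                              config = quick_config(), seed = 1),
               "permutation")
  tiny <- dat[1:20, ]
  expect_error(fit_sequential(tiny, spec$schema,
                              config = synthesis_config(tune_trials = 0,
                                                        min_rows = 50),
                              seed = 1),
               "too few rows")
})

test_that("the opt-in greedy ordering returns a permutation and is logged", {
  set.seed(48)
  n <- 400
  dat <- data.frame(x = sample(c("a", "b"), n, TRUE))
  dat$y <- ifelse(stats::runif(n) < 0.9, dat$x, sample(c("a", "b"), n, TRUE))
  expect_message(
    m <- fit_sequential(dat, toy_schema(), order = "auto",
                        config = quick_config(cv_folds = 2), seed = 24),
    "greedy synthesis order")
  expect_setequal(m$order, c("x", "y"))
})
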