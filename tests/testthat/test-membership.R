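test_that("a memorizing synthesizer is fully exposed by the attack", {
  spec <- canada_like_spec(n = 400, missing = FALSE)
  members <- simulate_country(spec, 51)
  # non-members from a disjoint region: forced single-cell population
  non_members <- simulate_country(forced_spec(400), 52)
  cfg <- attack_config(h = 0)
  res <- membership_attack(members, non_members, members, cfg, spec$schema)
  expect_equal(res$recall, 1)
  expect_equal(res$precision, 1)
  expect_equal(res$f1, 1)
  expect_equal(res$relative_f1, 1 - res$naive_f1)
  expect_gt(res$relative_f1, 0)
})

test_that("h = 1 predicts everyone a member, giving relative F1 = 0", {
  spec <- canada_like_spec(n = 300, missing = FALSE)
  pop <- simulate_country(spec, 53)
  sp <- split_members_holdout(pop, 0.5, 54)
  synth <- simulate_country(spec, 55)
  cfg <- attack_config(h = 1)
  res <- membership_attack(sp$members, sp$holdout, synth, cfg, spec$schema)
  expect_equal(res$f1, res$naive_f1)
  expect_equal(res$relative_f1, 0, tolerance = 1e-12)
})

test_that("the metric is invariant to row order of all three tables", {
  spec <- canada_like_spec(n = 300)
  pop <- simulate_country(spec, 56)
  sp <- split_members_holdout(pop, 0.5, 57)
  synth <- simulate_country(spec, 58)
  cfg <- attack_config()
  r1 <- membership_attack(sp$members, sp$holdout, synth, cfg, spec$schema)
  set.seed(59)
  shuf <- function(df) df[sample.int(nrow(df)), , drop = FALSE]
  r2 <- membership_attack(shuf(sp$members), shuf(sp$holdout), shuf(synth),
                          cfg, spec$schema)
  expect_equal(r1$f1, r2$f1)
  expect_equal(r1$relative_f1, r2$relative_f1)
})

test_that("recall is non-decreasing in the distance threshold h", {
  spec <- canada_like_spec(n = 500, missing = FALSE)
  pop <- simulate_country(spec, 60)
  sp <- split_members_holdout(pop, 0.5, 61)
  synth <- simulate_country(spec, 62)
  rec <- vapply(c(0, 0.15, 0.3, 0.6, 1), function(h)
    membership_attack(sp$members[1:100, ], sp$holdout[1:100, ], synth,
                      attack_config(h = h), spec$schema)$recall,
    numeric(1))
  expect_true(all(diff(rec) >= 0))
})

test_that("multiple replicates are attacked per replicate and averaged", {
  spec <- canada_like_spec(n = 300, missing = FALSE)
  members <- simulate_country(spec, 63)
  non_members <- simulate_country(forced_spec(300), 64)
  synth <- list(members, simulate_country(spec, 65))
  res <- membership_attack(members, non_members, synth, attack_config(),
                           spec$schema)
  expect_equal(nrow(res$per_replicate), 2)
  expect_equal(res$per_replicate$f1[1], 1)  # the memorized replicate
  expect_equal(res$f1, mean(res$per_replicate$f1))
})

test_that("the sequential synthesizer leaks less than a memorizing one", {
  spec <- canada_like_spec(n = 2000, missing = FALSE)
  pop <- simulate_country(spec, 66)
  sp <- split_members_holdout(pop, 0.5, 67)
  m <- fit_sequential(sp$members, spec$schema, config = quick_config(),
                      seed = 68)
  synth <- generate_replicates(m, 1000, 1, seed = 69)$tables[[1]]
  cfg <- attack_config()
  targets_m <- sp$members[1:300, ]
  targets_n <- simulate_country(forced_spec(300), 70)
  r_memo <- membership_attack(targets_m, targets_n, sp$members, cfg,
                              spec$schema)
  r_seq <- membership_attack(targets_m, targets_n, synth, cfg, spec$schema)
  expect_gt(r_memo$relative_f1, r_seq$relative_f1)
})

test_that("invalid attack inputs raise the contracted errors", {
  spec <- canada_like_spec(n = 50)
  tab <- simulate_country(spec, 71)
  expect_error(attack_config(h = 2), "\\[0, 1\\]")
  expect_error(attack_config(quasi_identifiers = character()),
               "no quasi-identifiers")
  expect_error(membership_attack(tab, tab, tab[0, ], attack_config(),
                                 spec$schema),
               "empty synthetic")
  cfg <- attack_config(quasi_identifiers = "not_a_column")
  expect_error(membership_attack(tab, tab, tab, cfg, spec$schema),
               "not present")
})

test_that("continuous quasi-identifiers use range-scaled distance", {
  sch <- structure(list(z = variable_schema("z", "continuous")),
                   class = "survey_schema")
  members <- data.frame(z = c(0, 10))
  non <- data.frame(z = c(100, 200))
  synth <- data.frame(z = seq(0, 20, by = 1))
  cfg <- attack_config(quasi_identifiers = "z", h = 0.05)
  res <- membership_attack(members, non, synth, cfg, sch)
  expect_equal(res$recall, 1)   # members within 5% of the synthetic range
  expect_equal(res$precision, 1)  # far-away non-members capped at distance 1
})
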