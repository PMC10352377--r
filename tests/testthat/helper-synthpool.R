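# Shared fixtures, all generated in code.

# fast synthesis settings for unit tests
quick_config <- function(...) synthesis_config(tune_trials = 0, nrounds = 40,
                                               max_depth = 3, ...)

# a small two-variable schema for focused synthesis tests
toy_schema <- function(continuous = FALSE) {
  defs <- list(
    variable_schema("x", "categorical", c("a", "b")),
    variable_schema("y", "categorical", c("a", "b"))
  )
  if (continuous)
    defs <- c(defs, list(variable_schema("z", "continuous",
                                         missing_allowed = TRUE)))
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  structure(defs, class = "survey_schema")
}

# degenerate country spec: every demographic forced to one level and the
# risk factors forced to prevalence 0 or 1
forced_spec <- function(n = 1) {
  marg <- list(
    sex = c(male = 1, female = 0),
    age_group = c(1, 0, 0, 0, 0, 0, 0),
    marital_status = c(1, 0, 0),
    household_size = c(1, 0, 0, 0, 0),
    education = c(1, 0, 0, 0),
    household_income = c(1, 0, 0),
    immigrant = c(no = 1, yes = 0)
  )
  targets <- list(bmi_lt25 = c(male = 1, female = 1),
                  hypertension = c(male = 0, female = 0),
                  diabetes = c(male = 0, female = 0),
                  smoking = c(male = 0, female = 0))
  logits <- lapply(default_effect_logits(), function(l) {
    l[c("age", "income", "education")] <- 0
    l
  })
  country_spec("CA", n, marg, targets, effect_logits = logits)
}

# Cramer's V between two categorical columns
cramers_v <- function(a, b) {
  tab <- table(a, b)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  sqrt(as.numeric(chi) / (sum(tab) * (min(dim(tab)) - 1)))
}
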