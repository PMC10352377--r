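#' Specification of one simulated country
#'
#' Bundles everything needed to simulate one country's harmonized survey
#' table: the sample size, per-variable marginal distributions for the
#' demographic variables, per-sex prevalence targets for the four
#' cardiometabolic risk factors, the logistic effect structure tying the
#' risk factors to sex and socio-economic position, and per-variable
#' missingness rates.
#'
#' Risk factors (BMI under 25, hypertension, diabetes, smoking) are drawn
#' from a logistic model in sex, ordinal age score (1-7), household-income
#' score (1-3, low to high) and education score (1-4). When
#' `effect_logits` carries `intercept = NA` and `sex = NA` for a factor,
#' those two parameters are calibrated by root-finding so that the implied
#' male and female prevalences match `risk_targets` exactly under the
#' spec's demographic marginals; the remaining covariate logits are taken
#' as given.
#'
#' @param name Country label stored in the `country` column.
#' @param n Number of respondents (>= 1).
#' @param marginals Named list of probability vectors (must each sum to 1
#'   within 1e-9) for `sex`, `age_group`, `marital_status`,
#'   `household_size`, `education`, `household_income`, `immigrant`.
#' @param risk_targets Named list, one `c(male=, female=)` prevalence pair
#'   per risk factor (`bmi_lt25` is the prevalence of BMI < 25).
#' @param effect_logits Named list, one numeric vector
#'   `c(intercept, sex, age, income, education)` per risk factor; `NA`
#'   intercept/sex entries are calibrated against `risk_targets`.
#' @param missing_rates Named numeric vector of per-variable
#'   missing-completely-at-random rates in `[0, 1)`.
#' @param country_shift Additive logit shift applied to every risk factor
#'   (on top of any calibrated intercept); default 0.
#' @param continuous_bmi Include a continuous `bmi` column consistent with
#'   the `bmi_lt25` indicator.
#' @return An object of class `country_spec`.
#' @seealso [canada_like_spec()], [austria_like_spec()], [simulate_country()]
#' @export
country_spec <- function(name, n, marginals, risk_targets,
                         effect_logits = default_effect_logits(),
                         missing_rates = numeric(),
                         country_shift = 0,
                         continuous_bmi = FALSE) {
  stopifnot(length(n) == 1L, n >= 1)
  schema <- survey_schema(continuous_bmi = continuous_bmi)
  for (nm in names(marginals)) {
    p <- marginals[[nm]]
    if (any(p < 0))
      stop("invalid marginal for '", nm, "': negative proportion")
    if (abs(sum(p) - 1) > 1e-9)
      stop("invalid marginal for '", nm, "': proportions sum to ",
           format(sum(p)), ", not 1")
    lev <- schema[[nm]]$levels
    if (length(p) != length(lev))
      stop("marginal for '", nm, "' must have ", length(lev), " entries")
  }
  need <- c("sex", "age_group", "marital_status", "household_size",
            "education", "household_income", "immigrant")
  miss <- setdiff(need, names(marginals))
  if (length(miss))
    stop("marginals missing for: ", paste(miss, collapse = ", "))
  if (length(missing_rates) &&
      (any(missing_rates < 0) || any(missing_rates >= 1)))
    stop("missing rates must lie in [0, 1)")
  rf <- c("bmi_lt25", "hypertension", "diabetes", "smoking")
  stopifnot(all(rf %in% names(risk_targets)), all(rf %in% names(effect_logits)))
  structure(
    list(name = name, n = as.integer(n), marginals = marginals,
         risk_targets = risk_targets, effect_logits = effect_logits,
         missing_rates = missing_rates, country_shift = country_shift,
         continuous_bmi = isTRUE(continuous_bmi), schema = schema),
    class = "country_spec"
  )
}

risk_factor_names <- function() c("bmi_lt25", "hypertension", "diabetes", "smoking")

#' Default covariate effect logits for the risk factors
#'
#' One vector `c(intercept, sex, age, income, education)` per risk factor.
#' `NA` intercept and sex entries request calibration against the spec's
#' per-sex prevalence targets. The covariate slopes encode the usual
#' epidemiological gradients: hypertension and diabetes rise steeply with
#' age; smoking falls with income and education; normal BMI becomes less
#' common with age and more common with education.
#'
#' @return Named list of numeric vectors.
#' @export
default_effect_logits <- function() {
  v <- function(age, income, education)
    c(intercept = NA_real_, sex = NA_real_, age = age,
      income = income, education = education)
  list(
    bmi_lt25     = v(-0.35,  0.05,  0.15),
    hypertension = v( 0.75, -0.05, -0.05),
    diabetes     = v( 0.65, -0.10, -0.10),
    smoking      = v(-0.10, -0.20, -0.25)
  )
}

norm1 <- function(x) x / sum(x)

#' Built-in country parameter sets
#'
#' `canada_like_spec()` and `austria_like_spec()` return [country_spec()]
#' objects whose demographic marginals, per-sex risk-factor prevalences
#' and per-variable missingness rates approximate the published baseline
#' characteristics of the two harmonized 2014 health surveys the package's
#' analyses are modelled on (a large Canadian community health survey and
#' the Austrian health interview survey).
#'
#' @param n Number of respondents; defaults are desk-scale, not the
#'   original survey sizes.
#' @param continuous_bmi Include the optional continuous BMI column.
#' @param missing Apply the survey-like per-variable missingness rates;
#'   set `FALSE` for fully observed tables.
#' @return A `country_spec`.
#' @export
canada_like_spec <- function(n = 20000, continuous_bmi = FALSE, missing = TRUE) {
  marg <- list(
    sex = c(male = 0.447, female = 0.553),
    age_group = norm1(c(10.2, 10.5, 11.2, 10.4, 17.0, 20.0, 20.8)),
    marital_status = norm1(c(28.1, 20.9, 51.0)),
    household_size = norm1(c(27.8, 39.4, 13.1, 12.9, 6.9)),
    education = norm1(c(24.1, 19.6, 4.7, 51.6)),
    household_income = norm1(c(10.2, 39.7, 50.1)),
    immigrant = c(no = 0.856, yes = 0.144)
  )
  targets <- list(
    bmi_lt25     = c(male = 0.392, female = 0.506),
    hypertension = c(male = 0.242, female = 0.251),
    diabetes     = c(male = 0.103, female = 0.085),
    smoking      = c(male = 0.203, female = 0.163)
  )
  mr <- if (missing) c(
    bmi_lt25 = 0.0673, hypertension = 0.0034, diabetes = 0.0014,
    smoking = 0.0087, marital_status = 0.0020, household_size = 0.0006,
    education = 0.0161, household_income = 0.0010, immigrant = 0.0323
  ) else numeric()
  country_spec("CA", n, marg, targets, missing_rates = mr,
               continuous_bmi = continuous_bmi)
}

#' @rdname canada_like_spec
#' @export
austria_like_spec <- function(n = 5000, continuous_bmi = FALSE, missing = TRUE) {
  marg <- list(
    sex = c(male = 0.443, female = 0.557),
    age_group = norm1(c(3.5, 12.1, 16.3, 22.2, 22.2, 14.1, 9.4)),
    marital_status = norm1(c(30.3, 15.0, 54.7)),
    household_size = norm1(c(15.0, 37.1, 20.7, 18.7, 8.6)),
    education = norm1(c(15.6, 52.1, 20.0, 12.3)),
    household_income = norm1(c(36.0, 21.1, 42.9)),
    immigrant = c(no = 0.913, yes = 0.087)
  )
  targets <- list(
    bmi_lt25     = c(male = 0.428, female = 0.616),
    hypertension = c(male = 0.214, female = 0.189),
    diabetes     = c(male = 0.051, female = 0.037),
    smoking      = c(male = 0.440, female = 0.315)
  )
  mr <- if (missing) c(age_group = 0.0063, smoking = 0.2249) else numeric()
  country_spec("AT", n, marg, targets, missing_rates = mr,
               continuous_bmi = continuous_bmi)
}

# Expected prevalence of a logistic risk factor within one sex, integrating
# exactly over the independent (age, income, education) marginal grid.
expected_prevalence <- function(alpha, logits, marginals) {
  grid <- expand.grid(age = 1:7, income = 1:3, education = 1:4)
  w <- marginals$age_group[grid$age] *
    marginals$household_income[grid$income] *
    marginals$education[grid$education]
  eta <- alpha + logits[["age"]] * grid$age +
    logits[["income"]] * grid$income +
    logits[["education"]] * grid$education
  sum(w * stats::plogis(eta))
}

# Solve (intercept, sex logit) for one risk factor so the implied per-sex
# prevalences hit the targets given the covariate logits.
calibrate_logits <- function(logits, targets, marginals) {
  if (!is.na(logits[["intercept"]]) && !is.na(logits[["sex"]])) return(logits)
  solve_alpha <- function(p) {
    if (p <= 0 || p >= 1) return(stats::qlogis(p))  # forced 0/1 prevalence
    if (all(logits[c("age", "income", "education")] == 0))
      return(stats::qlogis(p))
    stats::uniroot(function(a) expected_prevalence(a, logits, marginals) - p,
                   lower = -30, upper = 30, tol = 1e-12)$root
  }
  a_m <- solve_alpha(targets[["male"]])
  a_f <- solve_alpha(targets[["female"]])
  s <- a_f - a_m
  logits[["intercept"]] <- a_m
  # both sexes forced to the same degenerate prevalence: no sex effect
  logits[["sex"]] <- if (is.nan(s)) 0 else s
  logits
}

sample_levels <- function(levels, probs, n) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

#' Simulate one country's harmonized survey table
#'
#' Demographic variables are drawn independently from the spec's
#' marginals; each of the four cardiometabolic risk factors is then drawn
#' from a logistic model in sex, age score, income score and education
#' score; finally missingness is applied independently per variable at the
#' spec's missing-completely-at-random rates. Identical seeds give
#' bit-identical tables.
#'
#' @param spec A [country_spec()].
#' @param seed Integer RNG seed.
#' @return A validated data.frame matching `spec$schema`, with the row
#'   count `spec$n` and a constant `country` column.
#' @export
simulate_country <- function(spec, seed) {
  stopifnot(inherits(spec, "country_spec"))
  set.seed(seed)
  n <- spec$n
  m <- spec$marginals
  sch <- spec$schema
  df <- data.frame(
    country = rep(spec$name, n),
    sex = sample_levels(sch$sex$levels, m$sex, n),
    age_group = sample_levels(sch$age_group$levels, m$age_group, n),
    stringsAsFactors = FALSE
  )
  age_score <- match(df$age_group, sch$age_group$levels)
  for (nm in c("marital_status", "household_size", "education",
               "household_income", "immigrant"))
    df[[nm]] <- sample_levels(sch[[nm]]$levels, m[[nm]], n)
  inc_score <- match(df$household_income, sch$household_income$levels)
  edu_score <- match(df$education, sch$education$levels)
  female <- as.numeric(df$sex == "female")

  for (rf in risk_factor_names()) {
    lg <- calibrate_logits(spec$effect_logits[[rf]], spec$risk_targets[[rf]], m)
    eta <- lg[["intercept"]] + spec$country_shift + lg[["sex"]] * female +
      lg[["age"]] * age_score + lg[["income"]] * inc_score +
      lg[["education"]] * edu_score
    df[[rf]] <- ifelse(stats::runif(n) < stats::plogis(eta), "yes", "no")
  }

  if (spec$continuous_bmi) {
    lt <- df$bmi_lt25 == "yes"
    bmi <- numeric(n)
    # truncated normals on either side of the 25 kg/m^2 cut
    bmi[lt] <- 25 - abs(stats::rnorm(sum(lt), mean = 2.0, sd = 1.8))
    bmi[!lt] <- 25 + abs(stats::rnorm(sum(!lt), mean = 4.0, sd = 3.5))
    df$bmi <- round(pmax(bmi, 14), 1)
  }

  # risk-factor columns expect 'yes'/'no' strings before reordering
  df <- df[, schema_names(sch)]
  for (nm in names(spec$missing_rates)) {
    r <- spec$missing_rates[[nm]]
    if (r > 0) df[[nm]][stats::runif(n) < r] <- NA
  }
  validate_table(df, sch)
  df
}

#' Modified CANHEART cardiovascular-health index
#'
#' Counts the ideal states among four cardiometabolic metrics: non-smoker,
#' BMI under 25, no diabetes, no hypertension. The score ranges from 0
#' (worst) to 4 (ideal cardiovascular health). Rows with any component
#' missing get `NA` (flagged missing outcome, to be excluded from outcome
#' models) rather than an error.
#'
#' @param table A data.frame with columns `smoking`, `bmi_lt25`,
#'   `diabetes`, `hypertension` (a single row is fine).
#' @return Integer vector in `{0, ..., 4}` with `NA` for incomplete rows.
#' @export
compute_canheart <- function(table) {
  ideal <- cbind(table$smoking == "no",
                 table$bmi_lt25 == "yes",
                 table$diabetes == "no",
                 table$hypertension == "no")
  out <- as.integer(rowSums(ideal))
  out[rowSums(is.na(ideal)) > 0] <- NA_integer_
  out
}

#' Split a table into member and holdout parts
#'
#' A reproducible disjoint row partition whose union is the input table;
#' both parts always contain at least one row.
#'
#' @param table A data.frame.
#' @param fraction Proportion of rows assigned to the member part, in (0, 1).
#' @param seed Integer RNG seed.
#' @return A list with elements `members` and `holdout`.
#' @export
split_members_holdout <- function(table, fraction, seed) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 rows to split")
  set.seed(seed)
  n_mem <- min(max(1L, as.integer(round(fraction * n))), n - 1L)
  idx <- sample.int(n, n_mem)
  list(members = table[idx, , drop = FALSE],
       holdout = table[-idx, , drop = FALSE])
}
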