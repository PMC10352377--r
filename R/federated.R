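#' Code a harmonized survey table for the regression models
#'
#' Produces the numeric analysis variables used by every regression in
#' the package, with codings fixed once here: outcome `canheart` (0-4);
#' `sex_female` (ref: male); marital-status dummies `marital_divwid` and
#' `marital_married` (ref: single); `household_size` as ordinal score 1-5;
#' `education` as ordinal score 1-4; `income_rev` reverse-coded
#' (high = 1, medium = 2, low = 3, so larger values mean lower income);
#' `immigrant_yes` (ref: no); `age` as ordinal score 1-7; `country_at`
#' (ref: CA).
#'
#' @param table A harmonized survey data.frame.
#' @param schema A `survey_schema`.
#' @return A data.frame of numeric analysis columns (missing where source
#'   cells are missing).
#' @export
code_analysis_data <- function(table, schema) {
  sc <- function(v) match(table[[v]], schema[[v]]$levels)
  data.frame(
    canheart = compute_canheart(table),
    sex_female = as.numeric(table$sex == "female"),
    marital_divwid = as.numeric(table$marital_status == "divorced/widowed"),
    marital_married = as.numeric(table$marital_status == "common-law/married"),
    household_size = as.numeric(sc("household_size")),
    education = as.numeric(sc("education")),
    income_rev = 4 - as.numeric(sc("household_income")),
    immigrant_yes = as.numeric(table$immigrant == "yes"),
    age = as.numeric(sc("age_group")),
    country_at = as.numeric(table$country == "AT")
  )
}

#' Regression model formulas for the cardiovascular-health analysis
#'
#' Three analysis layers on the coded data ([code_analysis_data()]):
#' the univariable set (one model per predictor, marital status entering
#' as one model with its two dummies), the multivariable main-effects
#' model, and the multivariable model with every predictor-by-country
#' interaction.
#'
#' @return A list with elements `univariable` (named list of formulas),
#'   `main` and `interaction` (formulas).
#' @export
model_formulas <- function() {
  uni <- list(
    sex = canheart ~ sex_female,
    marital = canheart ~ marital_divwid + marital_married,
    household_size = canheart ~ household_size,
    education = canheart ~ education,
    income = canheart ~ income_rev,
    immigrant = canheart ~ immigrant_yes,
    age = canheart ~ age,
    country = canheart ~ country_at
  )
  main <- canheart ~ sex_female + education + marital_divwid +
    marital_married + household_size + income_rev + immigrant_yes + age +
    country_at
  inter <- canheart ~ (sex_female + education + marital_divwid +
    marital_married + household_size + income_rev + immigrant_yes + age) *
    country_at
  list(univariable = uni, main = main, interaction = inter)
}

#' Node summary: the interim results one site shares
#'
#' Computes, over complete cases only, the aggregate sufficient statistics
#' of a least-squares fit: the predictor cross-product matrix X'X, the
#' predictor-outcome vector X'y, the outcome sum of squares y'y and the
#' row count. No row-level data appears in the output.
#'
#' @param table A harmonized survey data.frame (one site's rows).
#' @param formula A model formula on the coded analysis variables.
#' @param schema A `survey_schema`.
#' @return An object of class `node_summary`.
#' @export
summarize_node <- function(table, formula, schema) {
  coded <- code_analysis_data(table, schema)
  mf <- stats::model.frame(formula, coded, na.action = stats::na.omit)
  if (nrow(mf) == 0L) stop("zero complete cases for this model")
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  structure(
    list(XtX = crossprod(X), Xty = drop(crossprod(X, y)),
         yty = sum(y^2), n = nrow(X), columns = colnames(X)),
    class = "node_summary"
  )
}

#' Solve the pooled least-squares fit from node summaries
#'
#' Sums the sufficient statistics across nodes and solves the normal
#' equations, reproducing exactly the ordinary least-squares fit on the
#' row-concatenated data: coefficient estimates, their variances,
#' residual variance and R-squared. A rank-deficient pooled X'X falls
#' back to the Moore-Penrose pseudo-inverse with a warning naming the
#' aliased columns.
#'
#' @param summaries A list of `node_summary` objects sharing column lists
#'   (a single summary is allowed).
#' @return An object of class `ols_fit` with `coefficients`, `variances`,
#'   `se`, `ci_low`, `ci_high`, `p_value` (large-sample normal), `sigma2`,
#'   `r_squared`, `n`.
#' @export
solve_federated <- function(summaries) {
  if (inherits(summaries, "node_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1L)
  cols <- summaries[[1]]$columns
  for (s in summaries)
    if (!identical(s$columns, cols))
      stop("node summaries disagree on model columns")
  XtX <- Reduce(`+`, lapply(summaries, `[[`, "XtX"))
  Xty <- Reduce(`+`, lapply(summaries, `[[`, "Xty"))
  yty <- sum(vapply(summaries, `[[`, numeric(1), "yty"))
  n <- sum(vapply(summaries, `[[`, numeric(1), "n"))
  p <- length(cols)

  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (!is.null(ch)) {
    inv <- chol2inv(ch)
    beta <- drop(inv %*% Xty)
    rank <- p
  } else {
    sv <- svd(XtX)
    tol <- max(sv$d) * 1e-10
    keep <- sv$d > tol
    warning("rank-deficient pooled cross-product matrix; ",
            "pseudo-inverse used, ", sum(!keep),
            " aliased direction(s) among: ", paste(cols, collapse = ", "))
    inv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    beta <- drop(inv %*% Xty)
    rank <- sum(keep)
  }
  rss <- max(yty - sum(beta * Xty), 0)
  sigma2 <- rss / (n - rank)
  vb <- pmax(sigma2 * diag(inv), 0)
  se <- sqrt(vb)
  has_int <- "(Intercept)" %in% cols
  tss <- if (has_int) yty - Xty[["(Intercept)"]]^2 / n else yty
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  z <- ifelse(se > 0, beta / se, Inf * sign(beta))
  pv <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(vb) <- names(se) <- names(pv) <- cols
  structure(
    list(coefficients = beta, variances = vb, se = se,
         ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
         p_value = pv,
         sigma2 = sigma2, r_squared = min(max(r2, 0), 1), n = n,
         rank = rank, columns = cols),
    class = "ols_fit"
  )
}

#' Fit one pooled regression directly (per-replicate workhorse)
#'
#' Ordinary least squares via [stats::lm()] on the coded analysis data,
#' returning the coefficient vector and its sampling variances in the
#' shape the combining rules expect.
#'
#' @inheritParams summarize_node
#' @return A list with `coefficients`, `variances`, `r_squared`, `n`.
#' @export
fit_pooled_ols <- function(table, formula, schema) {
  coded <- code_analysis_data(table, schema)
  fit <- stats::lm(formula, coded, na.action = stats::na.omit)
  sm <- summary(fit)
  list(coefficients = stats::coef(fit),
       variances = diag(stats::vcov(fit)),
       r_squared = sm$r.squared, n = length(sm$residuals))
}

#' Serialize / read a node summary as JSON
#'
#' The wire format of the "interim results" a node shares: the column
#' list, X'X as a nested array, X'y, y'y and the row count.
#'
#' @param summary A `node_summary`.
#' @param path JSON file path.
#' @return `read_node_summary` returns a `node_summary`.
#' @export
write_node_summary <- function(summary, path) {
  jsonlite::write_json(
    list(columns = as.list(summary$columns),
         XtX = unname(apply(summary$XtX, 1, as.list)),
         Xty = unname(as.numeric(summary$Xty)),
         yty = summary$yty, n = summary$n),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_node_summary
#' @export
read_node_summary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cols <- as.character(obj$columns)
  XtX <- matrix(unlist(obj$XtX), nrow = length(cols), byrow = TRUE,
                dimnames = list(cols, cols))
  structure(list(XtX = XtX, Xty = stats::setNames(as.numeric(obj$Xty), cols),
                 yty = obj$yty, n = obj$n, columns = cols),
            class = "node_summary")
}
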