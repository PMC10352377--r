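#' Configuration for the sequential synthesis engine
#'
#' Controls the gradient-boosted-tree fits, the five-fold cross-validation
#' used for tuning and out-of-fold calibration, and the hyperparameter
#' search. With `tune_trials = 0` every conditional model uses the fixed
#' default hyperparameters; with `tune_trials > 0` each model's
#' hyperparameters are chosen by sequential model-based optimization
#' (Latin-hypercube initial design, then a random-forest surrogate
#' proposing the candidate with the lowest predicted cross-validated loss).
#'
#' @param tune_trials Number of hyperparameter evaluations per conditional
#'   model (0 = use defaults, no search).
#' @param cv_folds Cross-validation folds for tuning and out-of-fold
#'   calibration/residuals.
#' @param min_rows Minimum training rows required per conditional model.
#' @param nrounds,max_depth,eta,min_child_weight Default boosting
#'   hyperparameters (used directly when `tune_trials = 0` and as the
#'   centre of the search space otherwise).
#' @param search_space Named list of `c(lower, upper)` bounds for
#'   `nrounds`, `max_depth`, `eta`, `min_child_weight`; `eta`,
#'   `min_child_weight` and `nrounds` are searched on a log scale.
#' @param tune_init Size of the Latin-hypercube initial design.
#' @param candidate_pool Candidate points scored by the surrogate per
#'   sequential step.
#' @return A list of class `synthesis_config`.
#' @export
synthesis_config <- function(tune_trials = 25, cv_folds = 5, min_rows = 50,
                             nrounds = 60, max_depth = 3, eta = 0.3,
                             min_child_weight = 5,
                             search_space = list(
                               nrounds = c(20, 300),
                               max_depth = c(2, 8),
                               eta = c(0.01, 0.3),
                               min_child_weight = c(1, 50)),
                             tune_init = 8, candidate_pool = 100) {
  stopifnot(tune_trials >= 0, cv_folds >= 2, min_rows >= 2)
  structure(list(tune_trials = tune_trials, cv_folds = cv_folds,
                 min_rows = min_rows,
                 defaults = list(nrounds = nrounds, max_depth = max_depth,
                                 eta = eta, min_child_weight = min_child_weight),
                 search_space = search_space, tune_init = tune_init,
                 candidate_pool = candidate_pool),
            class = "synthesis_config")
}

# deterministic child seed for replicate / stage i; kept under 2^31
child_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) * 69621 + i * 10007
  as.integer(s %% 2147483629) + 1L
}

MISSING_LEVEL <- "(missing)"

# ---- design-matrix encoding -------------------------------------------------

# Freeze, at fit time, how each predictor is turned into numeric features;
# reused verbatim at generation time so feature spaces always line up.
make_encoder <- function(data, vars, defs) {
  enc <- lapply(vars, function(v) {
    d <- defs[[v]]
    x <- data[[v]]
    if (d$kind == "continuous") {
      has_na <- anyNA(x)
      list(name = v, type = "continuous",
           fill = stats::median(x, na.rm = TRUE), has_na = has_na)
    } else {
      lev <- d$levels
      if (anyNA(x) || MISSING_LEVEL %in% x) lev <- c(lev, MISSING_LEVEL)
      list(name = v, type = "onehot", levels = lev)
    }
  })
  names(enc) <- vars
  enc
}

build_design <- function(data, enc) {
  n <- nrow(data)
  cols <- list()
  for (e in enc) {
    x <- data[[e$name]]
    if (e$type == "continuous") {
      miss <- is.na(x)
      v <- x
      v[miss] <- e$fill
      cols[[paste0(e$name, "..value")]] <- v
      if (e$has_na) cols[[paste0(e$name, "..na")]] <- as.numeric(miss)
    } else {
      x <- as.character(x)
      x[is.na(x)] <- MISSING_LEVEL
      for (l in e$levels)
        cols[[paste0(e$name, "..", l)]] <- as.numeric(x == l)
    }
  }
  if (!length(cols)) return(matrix(numeric(0), nrow = n, ncol = 0))
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

# ---- cross-validated boosting -----------------------------------------------

clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

xgb_params <- function(pars, objective, num_class = NULL, seed = 1L) {
  out <- list(objective = objective, max_depth = as.integer(pars$max_depth),
              eta = pars$eta, min_child_weight = pars$min_child_weight,
              nthread = 1, seed = as.integer(seed))
  if (!is.null(num_class)) out$num_class <- num_class
  out
}

train_xgb <- function(X, y, w, pars, kind, num_class, seed) {
  d <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
  obj <- if (kind == "regressor") "reg:squarederror"
         else if (num_class == 2L) "binary:logistic" else "multi:softprob"
  nc <- if (kind == "classifier" && num_class > 2L) num_class else NULL
  xgboost::xgb.train(params = xgb_params(pars, obj, nc, seed), data = d,
                     nrounds = as.integer(pars$nrounds), verbose = 0)
}

predict_probs <- function(booster, X, num_class) {
  p <- predict(booster, X)
  if (num_class == 2L) cbind(1 - p, p) else matrix(p, ncol = num_class)
}

# k-fold CV: returns mean loss (multiclass log-loss or MSE) and the
# out-of-fold predictions (probability matrix or numeric vector)
cv_fit <- function(X, y, w, pars, kind, num_class, folds, seed) {
  n <- length(y)
  oof <- if (kind == "classifier") matrix(NA_real_, n, num_class)
         else rep(NA_real_, n)
  for (k in sort(unique(folds))) {
    te <- folds == k
    b <- train_xgb(X[!te, , drop = FALSE], y[!te], w[!te], pars, kind,
                   num_class, seed + k)
    if (kind == "classifier")
      oof[te, ] <- predict_probs(b, X[te, , drop = FALSE], num_class)
    else oof[te] <- predict(b, X[te, , drop = FALSE])
  }
  loss <- if (kind == "classifier")
    -mean(log(clip_prob(oof[cbind(seq_len(n), y + 1L)])))
  else mean((oof - y)^2)
  list(loss = loss, oof = oof)
}

# sequential model-based hyperparameter search (Latin-hypercube design +
# random-forest surrogate), scored by k-fold CV loss; deterministic in seed
tune_hyperparams <- function(X, y, w, kind, num_class, folds, config, seed) {
  if (config$tune_trials == 0) return(config$defaults)
  sp <- config$search_space
  from_unit <- function(u) list(
    nrounds = round(exp(log(sp$nrounds[1]) +
                          u[1] * diff(log(sp$nrounds)))),
    max_depth = round(sp$max_depth[1] + u[2] * diff(sp$max_depth)),
    eta = exp(log(sp$eta[1]) + u[3] * diff(log(sp$eta))),
    min_child_weight = exp(log(sp$min_child_weight[1]) +
                             u[4] * diff(log(sp$min_child_weight))))
  set.seed(child_seed(seed, 811L))
  n0 <- min(config$tune_init, config$tune_trials)
  U <- lhs::randomLHS(n0, 4)
  evals <- data.frame(u1 = U[, 1], u2 = U[, 2], u3 = U[, 3], u4 = U[, 4],
                      loss = NA_real_)
  for (i in seq_len(n0))
    evals$loss[i] <- cv_fit(X, y, w, from_unit(as.numeric(U[i, ])), kind,
                            num_class, folds, child_seed(seed, i))$loss
  extra <- config$tune_trials - n0
  for (j in seq_len(max(0L, extra))) {
    set.seed(child_seed(seed, 900L + j))
    cand <- lhs::randomLHS(config$candidate_pool, 4)
    rf <- ranger::ranger(loss ~ ., data = evals, num.trees = 100,
                         seed = child_seed(seed, 950L + j))
    pred <- predict(rf, data.frame(u1 = cand[, 1], u2 = cand[, 2],
                                   u3 = cand[, 3], u4 = cand[, 4]))$predictions
    u <- as.numeric(cand[which.min(pred), ])
    loss <- cv_fit(X, y, w, from_unit(u), kind, num_class, folds,
                   child_seed(seed, n0 + j))$loss
    evals <- rbind(evals, data.frame(u1 = u[1], u2 = u[2], u3 = u[3],
                                     u4 = u[4], loss = loss))
  }
  best <- as.numeric(evals[which.min(evals$loss), 1:4])
  from_unit(best)
}

# ---- conditional models -----------------------------------------------------

#' Fit one conditional model of the synthesis sequence
#'
#' Fits a gradient-boosted-tree model of `target` given `predictors`.
#' Categorical targets are fitted as (multi)classifiers with class weights
#' inversely proportional to class frequency and carry one-vs-rest beta
#' calibration maps fitted on out-of-fold predictions; continuous targets
#' are fitted on their normal scores and carry the pool of out-of-fold
#' residuals used to inject sampling noise at generation time.
#' Hyperparameters are tuned per [synthesis_config()].
#'
#' @param data Training data.frame (categorical missingness already coded
#'   as an explicit level where applicable).
#' @param target Target variable name.
#' @param predictors Character vector of predictor names (may be empty).
#' @param defs Internal variable definitions (a `survey_schema` or
#'   compatible list).
#' @param config A [synthesis_config()].
#' @param seed Integer seed; fixes folds, tuning and tree fits.
#' @return An object of class `conditional_model`.
#' @export
fit_conditional <- function(data, target, predictors, defs, config, seed) {
  d <- defs[[target]]
  kind <- if (d$kind == "continuous") "regressor" else "classifier"
  x_t <- data[[target]]
  use <- if (kind == "regressor") !is.na(x_t) else rep(TRUE, nrow(data))
  dat <- data[use, , drop = FALSE]
  if (nrow(dat) < config$min_rows)
    stop("too few rows (", nrow(dat), ") to fit model for '", target, "'")
  enc <- make_encoder(dat, predictors, defs)
  X <- build_design(dat, enc)
  out <- list(target = target, predictors = predictors, kind = kind,
              encoder = enc)

  if (kind == "classifier") {
    xs <- as.character(dat[[target]])
    xs[is.na(xs)] <- MISSING_LEVEL
    lev <- intersect(c(d$levels, MISSING_LEVEL), unique(xs))
    if (length(lev) == 1L) {
      out$kind <- "constant"
      out$value <- lev
      return(structure(out, class = "conditional_model"))
    }
    y <- match(xs, lev) - 1L
    cnt <- tabulate(y + 1L, nbins = length(lev))
    w <- (length(y) / (length(lev) * cnt))[y + 1L]  # inverse-frequency weights
    set.seed(child_seed(seed, 1L))
    folds <- sample(rep_len(seq_len(config$cv_folds), length(y)))
    pars <- tune_hyperparams(X, y, w, "classifier", length(lev), folds,
                             config, child_seed(seed, 2L))
    cvr <- cv_fit(X, y, w, pars, "classifier", length(lev), folds,
                  child_seed(seed, 3L))
    maps <- lapply(seq_along(lev), function(k)
      fit_beta_calibration(cvr$oof[, k], as.numeric(y == k - 1L)))
    booster <- train_xgb(X, y, w, pars, "classifier", length(lev),
                         child_seed(seed, 4L))
    out <- c(out, list(levels = lev, params = pars, cv_loss = cvr$loss,
                       calibration = maps,
                       booster_raw = xgboost::xgb.save.raw(booster)))
  } else {
    tr <- normal_score_fit(dat[[target]])
    y <- normal_score_forward(dat[[target]], tr)
    w <- rep(1, length(y))
    set.seed(child_seed(seed, 1L))
    folds <- sample(rep_len(seq_len(config$cv_folds), length(y)))
    pars <- tune_hyperparams(X, y, w, "regressor", 0L, folds, config,
                             child_seed(seed, 2L))
    cvr <- cv_fit(X, y, w, pars, "regressor", 0L, folds, child_seed(seed, 3L))
    booster <- train_xgb(X, y, w, pars, "regressor", 0L, child_seed(seed, 4L))
    out <- c(out, list(transform = tr, params = pars, cv_loss = cvr$loss,
                       residuals = y - cvr$oof,
                       booster_raw = xgboost::xgb.save.raw(booster)))
  }
  structure(out, class = "conditional_model")
}

# calibrated class-probability matrix for new data
conditional_class_probs <- function(cm, newdata) {
  X <- build_design(newdata, cm$encoder)
  booster <- xgboost::xgb.load.raw(cm$booster_raw)
  raw <- predict_probs(booster, X, length(cm$levels))
  apply_calibration(cm$calibration, raw)
}

# ---- the sequential model ---------------------------------------------------

# internal variable definitions: schema plus one yes/no missingness
# indicator per continuous variable that has missing values in training
internal_plan <- function(data, schema, order) {
  defs <- as.list(schema)
  internal <- character()
  for (v in order) {
    d <- schema[[v]]
    if (d$kind == "continuous" && anyNA(data[[v]])) {
      aux <- paste0(v, "__missing")
      defs[[aux]] <- variable_schema(aux, "categorical",
                                     c("observed", "missing"))
      internal <- c(internal, aux, v)
    } else internal <- c(internal, v)
  }
  list(defs = defs, order = internal)
}

#' Fit the full sequential generative model
#'
#' Variables are synthesized one at a time in `order`: the first variable
#' is stored as its empirical marginal; every later variable gets a
#' [fit_conditional()] model using all variables earlier in the sequence
#' as predictors. Categorical missingness is modelled as an explicit extra
#' level; continuous missingness via a synthesized indicator plus a value
#' model trained on the observed rows. Continuous variables are modelled
#' on their normal scores.
#'
#' @param data Training data.frame matching `schema`.
#' @param schema A `survey_schema`.
#' @param order Character vector, a permutation of the columns of `data`;
#'   default is schema order. Use `order = "auto"` for the opt-in greedy
#'   predictability ordering (most predictable next, by CV loss reduction).
#' @param config A [synthesis_config()].
#' @param seed Integer seed.
#' @return An object of class `synthesis_model`.
#' @export
fit_sequential <- function(data, schema, order = NULL,
                           config = synthesis_config(), seed = 1L) {
  validate_table(data, schema)
  vars <- intersect(schema_names(schema), names(data))
  auto <- identical(order, "auto")
  if (is.null(order) || auto) order <- vars
  if (!setequal(order, vars) || anyDuplicated(order))
    stop("order must be a permutation of the table's variables")
  if (auto) order <- greedy_order(data, schema, config, seed)
  plan <- internal_plan(data, schema, order)
  defs <- plan$defs

  # working copy with explicit missing levels / indicators
  work <- data
  for (v in order) {
    d <- schema[[v]]
    if (d$kind == "continuous") {
      aux <- paste0(v, "__missing")
      if (aux %in% plan$order)
        work[[aux]] <- ifelse(is.na(work[[v]]), "missing", "observed")
    } else {
      x <- as.character(work[[v]])
      x[is.na(x)] <- MISSING_LEVEL
      work[[v]] <- x
    }
  }

  models <- vector("list", length(plan$order))
  names(models) <- plan$order
  for (i in seq_along(plan$order)) {
    v <- plan$order[i]
    if (i == 1L) {
      if (defs[[v]]$kind == "continuous")
        stop("first variable in the order must be categorical/ordinal ",
             "(its marginal is stored directly)")
      tab <- table(work[[v]])
      models[[v]] <- structure(
        list(target = v, kind = "empirical",
             levels = names(tab), probs = as.numeric(tab) / sum(tab)),
        class = "conditional_model")
    } else {
      models[[v]] <- fit_conditional(work, v, plan$order[seq_len(i - 1L)],
                                     defs, config, child_seed(seed, 100L + i))
    }
  }
  structure(list(order = order, internal_order = plan$order, defs = defs,
                 schema = schema, models = models, n_train = nrow(data),
                 config = config),
            class = "synthesis_model")
}

# opt-in ordering heuristic: place the most predictable remaining variable
# next, measured by CV loss of a default-parameter model on the already
# placed variables; messaged so a chosen order is always visible in logs
greedy_order <- function(data, schema, config, seed) {
  vars <- intersect(schema_names(schema), names(data))
  cfg0 <- config
  cfg0$tune_trials <- 0
  work <- data
  for (v in vars) if (schema[[v]]$kind != "continuous") {
    x <- as.character(work[[v]])
    x[is.na(x)] <- MISSING_LEVEL
    work[[v]] <- x
  }
  # start from the lowest-entropy categorical variable
  ent <- vapply(vars, function(v) {
    if (schema[[v]]$kind == "continuous") return(Inf)
    p <- prop.table(table(work[[v]]))
    -sum(p * log(p))
  }, numeric(1))
  placed <- vars[which.min(ent)]
  remaining <- setdiff(vars, placed)
  while (length(remaining)) {
    score <- vapply(remaining, function(v) {
      cm <- try(fit_conditional(work, v, placed, as.list(schema), cfg0,
                                child_seed(seed, 500L + length(placed))),
                silent = TRUE)
      if (inherits(cm, "try-error") || is.null(cm$cv_loss)) Inf else cm$cv_loss
    }, numeric(1))
    nxt <- remaining[which.min(score)]
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  message("greedy synthesis order: ", paste(placed, collapse = " -> "))
  placed
}

#' Sample synthetic replicate datasets from a fitted model
#'
#' Each replicate is generated sequentially: the first variable is drawn
#' from the stored empirical marginal; each later categorical variable is
#' drawn from its calibrated class probabilities given the
#' already-synthesized predecessors; each continuous variable is the
#' boosted-tree point prediction on the normal scale plus a residual drawn
#' with replacement from the out-of-fold residual pool, back-transformed
#' to the original scale. Replicate `i` uses a deterministic child seed
#' derived from `(seed, i)`.
#'
#' @param model A [fit_sequential()] model.
#' @param n Rows per replicate.
#' @param m Number of replicates.
#' @param seed Integer seed.
#' @return An object of class `synthetic_replicates`: a list with `m` and
#'   `tables` (list of data.frames matching the training schema).
#' @export
generate_replicates <- function(model, n, m, seed = 1L) {
  stopifnot(inherits(model, "synthesis_model"), n >= 1, m >= 1)
  tables <- lapply(seq_len(m), function(i)
    generate_one(model, n, child_seed(seed, i)))
  structure(list(m = m, tables = tables), class = "synthetic_replicates")
}

generate_one <- function(model, n, seed) {
  set.seed(seed)
  out <- list()
  for (v in model$internal_order) {
    cm <- model$models[[v]]
    d <- model$defs[[v]]
    if (cm$kind == "empirical") {
      out[[v]] <- cm$levels[sample.int(length(cm$levels), n, replace = TRUE,
                                       prob = cm$probs)]
    } else if (cm$kind == "constant") {
      out[[v]] <- rep(cm$value, n)
    } else if (cm$kind == "classifier") {
      P <- conditional_class_probs(cm, as.data.frame(out,
                                                     stringsAsFactors = FALSE))
      cs <- P
      for (k in seq_len(ncol(P))[-1]) cs[, k] <- cs[, k - 1] + cs[, k]
      u <- stats::runif(n)
      idx <- rowSums(cs < u) + 1L
      out[[v]] <- cm$levels[pmin(idx, length(cm$levels))]
    } else {  # regressor
      X <- build_design(as.data.frame(out, stringsAsFactors = FALSE),
                        cm$encoder)
      booster <- xgboost::xgb.load.raw(cm$booster_raw)
      z <- predict(booster, X) +
        sample(cm$residuals, n, replace = TRUE)
      out[[v]] <- normal_score_inverse(z, cm$transform)
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  # restore missingness conventions
  for (v in model$order) {
    d <- model$schema[[v]]
    aux <- paste0(v, "__missing")
    if (d$kind == "continuous" && aux %in% names(df)) {
      df[[v]][df[[aux]] == "missing"] <- NA_real_
    } else if (d$kind != "continuous") {
      df[[v]][df[[v]] == MISSING_LEVEL] <- NA_character_
    }
  }
  df <- df[, model$order, drop = FALSE]
  validate_table(df, model$schema[model$order])
  df
}
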