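#' Save / load a fitted synthesis model
#'
#' The archive is a single JSON file: all metadata (order, variable
#' definitions, hyperparameters, calibration triples, normal-score
#' transforms, residual pools) as plain JSON, with each boosted-tree
#' ensemble embedded as a base64-encoded blob. A reloaded model samples
#' bit-identically to the original given equal seeds.
#'
#' @param model A `synthesis_model`.
#' @param path Archive file path.
#' @return `load_synthesis_model` returns the reconstructed
#'   `synthesis_model`.
#' @export
save_synthesis_model <- function(model, path) {
  ser_def <- function(v) list(name = v$name, kind = v$kind,
                              levels = as.list(v$levels),
                              codes = as.list(v$codes),
                              missing_allowed = v$missing_allowed)
  ser_cm <- function(cm) {
    out <- list(target = cm$target, kind = cm$kind)
    if (!is.null(cm$predictors)) out$predictors <- as.list(cm$predictors)
    if (!is.null(cm$encoder)) out$encoder <- lapply(cm$encoder, unclass)
    if (cm$kind == "empirical") {
      out$levels <- as.list(cm$levels); out$probs <- cm$probs
    } else if (cm$kind == "constant") {
      out$value <- cm$value
    } else if (cm$kind == "classifier") {
      out$levels <- as.list(cm$levels)
      out$params <- cm$params
      out$calibration <- lapply(cm$calibration, function(mp)
        list(a = mp$a, b = mp$b, c = mp$c))
      out$booster <- jsonlite::base64_enc(cm$booster_raw)
    } else {
      out$params <- cm$params
      out$residuals <- cm$residuals
      out$transform <- list(support = cm$transform$support,
                            probs = cm$transform$probs,
                            n = cm$transform$n, range = cm$transform$range)
      out$booster <- jsonlite::base64_enc(cm$booster_raw)
    }
    out
  }
  obj <- list(order = as.list(model$order),
              internal_order = as.list(model$internal_order),
              n_train = model$n_train,
              config = unclass(model$config),
              defs = lapply(model$defs, ser_def),
              schema_vars = as.list(schema_names(model$schema)),
              models = lapply(model$models, ser_cm))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_synthesis_model
#' @export
load_synthesis_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) as.character(unlist(x))
  num <- function(x) as.numeric(unlist(x))
  de_def <- function(v)
    variable_schema(v$name, v$kind, levels = chr(v$levels),
                    codes = if (length(v$codes)) num(v$codes) else NULL,
                    missing_allowed = isTRUE(v$missing_allowed))
  de_enc <- function(e) {
    out <- list(name = e$name, type = e$type)
    if (e$type == "continuous") {
      out$fill <- e$fill; out$has_na <- isTRUE(e$has_na)
    } else out$levels <- chr(e$levels)
    out
  }
  de_cm <- function(cm) {
    out <- list(target = cm$target, kind = cm$kind)
    if (!is.null(cm$predictors)) out$predictors <- chr(cm$predictors)
    if (!is.null(cm$encoder)) {
      out$encoder <- lapply(cm$encoder, de_enc)
      names(out$encoder) <- out$predictors
    }
    if (cm$kind == "empirical") {
      out$levels <- chr(cm$levels); out$probs <- num(cm$probs)
    } else if (cm$kind == "constant") {
      out$value <- cm$value
    } else if (cm$kind == "classifier") {
      out$levels <- chr(cm$levels)
      out$params <- lapply(cm$params, function(x) x)
      out$calibration <- lapply(cm$calibration, function(mp)
        structure(list(a = mp$a, b = mp$b, c = mp$c),
                  class = "beta_calibration_map"))
      out$booster_raw <- jsonlite::base64_dec(cm$booster)
    } else {
      out$params <- lapply(cm$params, function(x) x)
      out$residuals <- num(cm$residuals)
      tr <- cm$transform
      out$transform <- structure(
        list(support = num(tr$support), probs = num(tr$probs),
             n = tr$n, range = num(tr$range)),
        class = "normal_score_transform")
      out$booster_raw <- jsonlite::base64_dec(cm$booster)
    }
    structure(out, class = "conditional_model")
  }
  defs <- lapply(obj$defs, de_def)
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  schema <- structure(defs[chr(obj$schema_vars)], class = "survey_schema")
  models <- lapply(obj$models, de_cm)
  names(models) <- chr(obj$internal_order)
  structure(list(order = chr(obj$order),
                 internal_order = chr(obj$internal_order),
                 defs = defs, schema = schema, models = models,
                 n_train = obj$n_train,
                 config = do.call(synthesis_config,
                                  obj$config[c("tune_trials", "cv_folds",
                                               "min_rows")])),
            class = "synthesis_model")
}
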