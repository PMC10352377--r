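#' Configuration of a full pooling study
#'
#' Bundles everything [run_study()] needs: the two country specifications
#' (the first is the country whose data gets synthesized, the second
#' stays "real"), the synthesis settings, the number of synthetic
#' replicates m, which regression layers to fit, the privacy-attack
#' configuration, and the master seed.
#'
#' @param synth_spec [country_spec()] of the country to synthesize.
#' @param real_spec [country_spec()] of the partner country whose real
#'   data is pooled with the synthetic replicates.
#' @param m Number of synthetic replicates (>= 2 so the combining rules
#'   have a between-replicate variance).
#' @param synthesis A [synthesis_config()]; the desk-scale default uses
#'   the fixed documented hyperparameters (`tune_trials = 0`).
#' @param order Synthesis order passed to [fit_sequential()].
#' @param models Which regression layers to fit: any of `"univariable"`,
#'   `"main"`, `"interaction"`.
#' @param attack An [attack_config()], or `NULL` to skip the privacy
#'   stage.
#' @param attack_targets Total number of attack targets (members plus
#'   non-members, split by the attack's `mix`).
#' @param fail_on_privacy Optional threshold: abort the study when the
#'   mean relative F1 exceeds it (by default the privacy gate is reported,
#'   not enforced).
#' @param seed Master seed; every stage derives a deterministic child
#'   seed from it.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return A list of class `study_config`.
#' @export
study_config <- function(synth_spec = canada_like_spec(),
                         real_spec = austria_like_spec(),
                         m = 5,
                         synthesis = synthesis_config(tune_trials = 0),
                         order = NULL,
                         models = c("univariable", "main", "interaction"),
                         attack = attack_config(),
                         attack_targets = 1000,
                         fail_on_privacy = NULL,
                         seed = 1L, out_dir = NULL) {
  stopifnot(inherits(synth_spec, "country_spec"),
            inherits(real_spec, "country_spec"), m >= 2)
  models <- match.arg(models, several.ok = TRUE)
  structure(list(synth_spec = synth_spec, real_spec = real_spec, m = m,
                 synthesis = synthesis, order = order, models = models,
                 attack = attack, attack_targets = attack_targets,
                 fail_on_privacy = fail_on_privacy,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "study_config")
}

# per-replicate fits -> combined table + oracle + concordance for one formula
analyze_formula <- function(formula, pooled_tables, real_a, real_b, schema) {
  fits <- lapply(pooled_tables, function(tab)
    fit_pooled_ols(tab, formula, schema))
  est <- t(vapply(fits, `[[`, fits[[1]]$coefficients, "coefficients"))
  var <- t(vapply(fits, `[[`, fits[[1]]$variances, "variances"))
  colnames(est) <- colnames(var) <- names(fits[[1]]$coefficients)
  combined <- combine_model(est, var)
  oracle <- solve_federated(list(summarize_node(real_a, formula, schema),
                                 summarize_node(real_b, formula, schema)))
  list(combined = combined, oracle = oracle,
       comparison = compare_fits(oracle, combined),
       r_squared = c(oracle = oracle$r_squared,
                     pooled = mean(vapply(fits, `[[`, numeric(1),
                                          "r_squared"))))
}

#' Run the full synthesize-pool-analyze-compare study
#'
#' Executes the whole workflow from one configuration: simulate both
#' countries; fit the sequential generative model on the first country's
#' table; generate m synthetic replicates; run the membership-disclosure
#' attack on them (reported, and optionally enforced via
#' `fail_on_privacy`); pool each replicate with the second country's real
#' table and fit the requested regression layers per replicate; combine
#' across replicates with the partial-synthesis rules; fit the federated
#' oracle on the two real tables; and emit the SMD balance report and
#' per-model concordance reports. Every artifact is reproducible from
#' `(config, seed)`.
#'
#' @param cfg A [study_config()].
#' @return A list of class `study_report` with elements `privacy`
#'   (`membership_attack_result` or `NULL`), `smd` (`smd_report`),
#'   `models` (per layer: `combined`, `oracle`, `comparison`,
#'   `r_squared`), `synthesis_model`, `replicates`, `real_a`, `real_b`,
#'   and `seed`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  seed <- cfg$seed
  schema <- cfg$synth_spec$schema
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("study stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  real_a <- stage("simulate_synth_country",
                  simulate_country(cfg$synth_spec, child_seed(seed, 1L)))
  real_b <- stage("simulate_real_country",
                  simulate_country(cfg$real_spec, child_seed(seed, 2L)))
  model <- stage("fit_sequential",
                 fit_sequential(real_a, schema, order = cfg$order,
                                config = cfg$synthesis,
                                seed = child_seed(seed, 3L)))
  reps <- stage("generate_replicates",
                generate_replicates(model, n = nrow(real_a), m = cfg$m,
                                    seed = child_seed(seed, 4L)))

  privacy <- NULL
  if (!is.null(cfg$attack)) {
    privacy <- stage("membership_attack", {
      n_mem <- max(1L, round(cfg$attack_targets * cfg$attack$mix))
      n_non <- max(1L, cfg$attack_targets - n_mem)
      set.seed(child_seed(seed, 5L))
      members <- real_a[sample.int(nrow(real_a), min(n_mem, nrow(real_a))), ,
                        drop = FALSE]
      pop_spec <- cfg$synth_spec
      pop_spec$n <- as.integer(n_non)
      non_members <- simulate_country(pop_spec, child_seed(seed, 6L))
      membership_attack(members, non_members, reps, cfg$attack, schema)
    })
    if (!is.null(cfg$fail_on_privacy) &&
        privacy$relative_f1 > cfg$fail_on_privacy)
      stop("privacy gate failed: relative F1 ",
           format(privacy$relative_f1, digits = 3), " exceeds ",
           cfg$fail_on_privacy)
  }

  pooled <- lapply(reps$tables, function(tab) rbind(tab, real_b))
  gt_pooled <- rbind(real_a, real_b)
  fml <- model_formulas()
  results <- list()
  if ("univariable" %in% cfg$models)
    results$univariable <- stage("univariable_models",
      lapply(fml$univariable, analyze_formula, pooled_tables = pooled,
             real_a = real_a, real_b = real_b, schema = schema))
  if ("main" %in% cfg$models)
    results$main <- stage("main_effects_model",
      analyze_formula(fml$main, pooled, real_a, real_b, schema))
  if ("interaction" %in% cfg$models)
    results$interaction <- stage("interaction_model",
      analyze_formula(fml$interaction, pooled, real_a, real_b, schema))

  smd_rep <- stage("smd_report",
                   smd_report(gt_pooled, pooled, schema, strata = "sex"))

  report <- structure(
    list(privacy = privacy, smd = smd_rep, models = results,
         synthesis_model = model, replicates = reps,
         real_a = real_a, real_b = real_b, seed = seed),
    class = "study_report")
  if (!is.null(cfg$out_dir)) stage("write_outputs",
                                   write_study_outputs(report, cfg$out_dir))
  report
}

write_study_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(report$replicates$tables))
    write_survey_csv(report$replicates$tables[[i]],
                     file.path(dir, sprintf("synthetic_%02d.csv", i)))
  write_survey_csv(report$real_b, file.path(dir, "real_partner.csv"))
  utils::write.csv(report$smd$table, file.path(dir, "smd_report.csv"),
                   row.names = FALSE)
  flat <- function(res, nm) {
    utils::write.csv(res$combined,
                     file.path(dir, paste0("combined_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(res$comparison$table,
                     file.path(dir, paste0("comparison_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$models$main)) flat(report$models$main, "main")
  if (!is.null(report$models$interaction))
    flat(report$models$interaction, "interaction")
  if (!is.null(report$models$univariable))
    for (nm in names(report$models$univariable))
      flat(report$models$univariable[[nm]], paste0("uni_", nm))
  if (!is.null(report$privacy))
    jsonlite::write_json(
      list(precision = report$privacy$precision,
           recall = report$privacy$recall, f1 = report$privacy$f1,
           naive_f1 = report$privacy$naive_f1,
           relative_f1 = report$privacy$relative_f1,
           per_replicate = report$privacy$per_replicate),
      file.path(dir, "privacy.json"), auto_unbox = TRUE, digits = NA)
  save_synthesis_model(report$synthesis_model,
                       file.path(dir, "synthesis_model.json"))
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Pooling study report (seed ", x$seed, ")\n", sep = "")
  cat("  training rows:", nrow(x$real_a), " partner rows:", nrow(x$real_b),
      " replicates:", x$replicates$m, "\n")
  if (!is.null(x$privacy))
    cat(sprintf("  privacy: relative membership F1 = %.4f (naive F1 %.3f)\n",
                x$privacy$relative_f1, x$privacy$naive_f1))
  cat(sprintf("  balance: max mean SMD = %.4f (threshold %.2f, %d flagged)\n",
              max(x$smd$table$mean_smd), x$smd$threshold,
              sum(x$smd$table$flagged)))
  for (nm in names(x$models)) {
    if (nm == "univariable") {
      s <- Reduce(`+`, lapply(x$models$univariable,
                              function(r) r$comparison$summary))
    } else s <- x$models[[nm]]$comparison$summary
    cat(sprintf("  %s: sign agreement %d/%d, significance %d/%d\n",
                nm, s[["sign_agree"]], s[["n_coefficients"]],
                s[["significance_agree"]], s[["n_coefficients"]]))
  }
  invisible(x)
}

#' @export
print.membership_attack_result <- function(x, ...) {
  cat(sprintf(paste0("Membership-disclosure attack (h = %g, %d QIs, ",
                     "%d members / %d non-members)\n"),
              x$h, length(x$quasi_identifiers), x$n_members,
              x$n_non_members))
  cat(sprintf("  precision %.3f, recall %.3f, F1 %.3f, naive F1 %.3f\n",
              x$precision, x$recall, x$f1, x$naive_f1))
  cat(sprintf("  relative F1 = %.4f\n", x$relative_f1))
  invisible(x)
}

#' @export
print.combined_estimate <- function(x, ...) {
  cat(sprintf("Combined estimate over m = %d replicates\n", x$m))
  cat(sprintf("  q_bar %.5g  (95%% CI %.5g, %.5g), p = %.3g\n",
              x$q_bar, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  v_bar %.5g  b_m %.5g  T_p %.5g\n", x$v_bar, x$b_m, x$T_p))
  invisible(x)
}
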