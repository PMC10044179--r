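#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `generator` (a [generator_config()] for a synthetic cohort)
#' or `cohort` (a data frame, or path to a cohort CSV) must be supplied. The
#' master `seed` drives every stochastic stage through [stage_seed()], so a
#' rerun with the same configuration reproduces every number.
#'
#' @param generator a [generator_config()], or `NULL`.
#' @param cohort a cohort data frame or CSV path, or `NULL`.
#' @param seed master seed.
#' @param ratio train fraction for the train/test split.
#' @param n_trees trees per imputation forest.
#' @param max_iter maximum imputation sweeps.
#' @param balance_threshold SMD balance threshold.
#' @param include_dose_in_prediction include the number of appointments in
#'   the prediction (interaction) model as well as the treatment model.
#' @param lower_q,upper_q PAI quantile bounds defining the high-PAI set.
#' @param mcid_table absolute-MCID band table ([default_mcid_table()]), or
#'   `NULL` to skip that metric.
#' @param out_dir optional directory for stage artifacts (CSV/JSON plus a
#'   hash manifest).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, cohort = NULL, seed = 1L,
                            ratio = 0.75, n_trees = 500L, max_iter = 10L,
                            balance_threshold = 0.1,
                            include_dose_in_prediction = FALSE,
                            lower_q = 0.25, upper_q = 0.75,
                            mcid_table = default_mcid_table(),
                            out_dir = NULL) {
  if (is.null(generator) == is.null(cohort))
    stop("configuration error: supply exactly one of `generator` or `cohort`",
         call. = FALSE)
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_config"))
  assert_number(seed, "seed")
  assert_number(ratio, "ratio")
  structure(list(generator = generator, cohort = cohort, seed = as.integer(seed),
                 ratio = ratio, n_trees = n_trees, max_iter = max_iter,
                 balance_threshold = balance_threshold,
                 include_dose_in_prediction = include_dose_in_prediction,
                 lower_q = lower_q, upper_q = upper_q,
                 mcid_table = mcid_table, out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full allocation-evaluation pipeline
#'
#' Executes, in order: cohort acquisition (synthetic generation or CSV load),
#' selection filters, 3:1 train/test split with SMD balance check,
#' random-forest imputation separately per partition, propensity estimation
#' on the training sample, main-effects and interaction outcome models on the
#' training sample, counterfactual prediction / PAI scoring / allocation
#' classification on the held-out test sample, and clinically-thresholded
#' evaluation of the optimal-vs-suboptimal contrast.
#'
#' @param config a [pipeline_config()].
#' @return A `pai_pipeline` list with every stage's outputs: `cohort`,
#'   `filter_log`, `partition`, `balance`, `imputation_reports`,
#'   `propensity`, `main_effects_fit`, `interaction_fit`, `pai_results`,
#'   `allocation_summary`, `mcid`, `evaluation`, `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  cohort <- run_stage("acquire", {
    if (!is.null(config$generator)) generate_cohort(config$generator)
    else if (is.character(config$cohort)) read_cohort(config$cohort)
    else config$cohort
  })

  filtered <- run_stage("filter", apply_selection_filters(cohort))
  selected <- filtered$cohort

  partition <- run_stage("split",
                         split_train_test(selected, ratio = config$ratio,
                                          seed = stage_seed(seed, 11L)))
  balance <- run_stage("balance",
                       check_balance(selected, partition,
                                     threshold = config$balance_threshold))
  if (!attr(balance, "pass"))
    warning("run_pipeline: train/test partition failed the SMD balance check (max |SMD| = ",
            format(attr(balance, "max_smd"), digits = 3), ")", call. = FALSE)

  train <- selected[partition == "train", , drop = FALSE]
  test <- selected[partition == "test", , drop = FALSE]

  imp_train <- run_stage("impute_train",
                         impute(train, n_trees = config$n_trees,
                                max_iter = config$max_iter,
                                seed = stage_seed(seed, 12L)))
  imp_test <- run_stage("impute_test",
                        impute(test, n_trees = config$n_trees,
                               max_iter = config$max_iter,
                               seed = stage_seed(seed, 13L)))
  train <- imp_train$cohort; test <- imp_test$cohort

  prop <- run_stage("propensity", fit_propensity(train))
  train_scores <- run_stage("propensity", propensity_scores(prop, train))
  test_scores <- run_stage("propensity", propensity_scores(prop, test))

  main_fit <- run_stage("treatment_model",
                        fit_main_effects_model(train, train_scores))
  int_fit <- run_stage("prediction_model",
                       fit_interaction_model(train, train_scores,
                                             include_dose = config$include_dose_in_prediction))

  pai_results <- run_stage("pai", {
    preds <- predict_counterfactuals(int_fit, test, scores = test_scores)
    preds <- compute_pai(preds)
    preds <- classify_allocation(preds, config$lower_q, config$upper_q)
    preds$phq9_baseline <- test$phq9_baseline
    preds$phq9_post <- test$phq9_post
    preds
  })
  allocation_summary <- run_stage("pai", summarize_allocation(pai_results))
  mcid <- run_stage("pai", mcid_exceedance(pai_results$pai, pai_results$phq9_baseline))

  evaluation <- run_stage("evaluate",
                          evaluate_allocation(pai_results, config$mcid_table))

  result <- structure(list(
    cohort = selected, filter_log = filtered$log, partition = partition,
    balance = balance,
    imputation_reports = list(train = imp_train$report, test = imp_test$report),
    propensity = prop, main_effects_fit = main_fit, interaction_fit = int_fit,
    pai_results = pai_results, allocation_summary = allocation_summary,
    mcid = mcid, evaluation = evaluation, seed = seed, config = config
  ), class = "pai_pipeline")

  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pai_pipeline <- function(x, ...) {
  cat("PAI allocation pipeline (seed ", x$seed, ")\n", sep = "")
  cat("  cohort after selection: ", nrow(x$cohort), " records (train ",
      sum(x$partition == "train"), " / test ", sum(x$partition == "test"), ")\n", sep = "")
  cat("  balance: max |SMD| = ", format(attr(x$balance, "max_smd"), digits = 3),
      if (attr(x$balance, "pass")) " (balanced)\n" else " (IMBALANCED)\n", sep = "")
  tr <- x$main_effects_fit$coefficients
  tr <- tr[tr$term == "treatmentCBT", ]
  cat(sprintf("  adjusted treatment effect: %.2f (95%% CI %.2f to %.2f)\n",
              tr$estimate, tr$ci_lower, tr$ci_upper))
  s <- x$allocation_summary
  cat(sprintf("  median PAI %.2f (IQR %.2f to %.2f); high-PAI set %d of %d\n",
              s$median_pai, s$iqr_pai[1], s$iqr_pai[2], s$n_high_pai, s$n))
  print(x$evaluation)
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort(result$cohort, p("cohort_selected.csv"))
  utils::write.csv(data.frame(partition = result$partition), p("partition.csv"),
                   row.names = FALSE)
  write_cohort(result$pai_results, p("pai_results.csv"))
  jsonlite::write_json(list(
    seed = result$seed,
    filter_log = result$filter_log,
    balance = list(max_smd = attr(result$balance, "max_smd"),
                   pass = attr(result$balance, "pass"),
                   smd = result$balance),
    imputation = lapply(result$imputation_reports, function(r)
      r[c("nrmse", "pfc", "n_trees", "iterations")]),
    propensity_coefficients = as.list(stats::coef(result$propensity)),
    main_effects = result$main_effects_fit$coefficients,
    interaction = result$interaction_fit$coefficients,
    allocation_summary = lapply(result$allocation_summary, function(v)
      if (inherits(v, "table")) as.list(v) else v),
    mcid = result$mcid[c("count", "fraction")],
    evaluation = list(metrics = result$evaluation$metrics,
                      mean_difference = result$evaluation$mean_difference,
                      group_summary = result$evaluation$group_summary)
  ), p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(out_dir, full.names = TRUE), p("manifest.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Replicated simulation study over generator scenarios
#'
#' Runs the core pipeline (selection, split, propensity, interaction model,
#' PAI classification, optimal-vs-suboptimal contrast) on freshly generated
#' cohorts for each scenario, and summarises benefit estimates against the
#' generator's ground truth: the observed mean difference, its Monte-Carlo
#' error against the oracle expectation (computed from the generating
#' coefficients on the integer instrument scale), confidence-interval
#' coverage of zero and of the oracle value, and the rejection rate of the
#' joint treatment-interaction likelihood ratio test.
#'
#' @param scenarios named list; each element a list of [generator_config()]
#'   argument overrides (e.g. `beta_interaction`, `noise_sd`).
#' @param n_replicates replicates per scenario.
#' @param n cohort size per replicate.
#' @param seed master seed; replicate seeds derive from it.
#' @param alpha LRT significance level.
#' @return A `simulation_study` list with a per-scenario `summary` data frame
#'   and the per-replicate `details`.
#' @export
simulation_study <- function(scenarios, n_replicates = 100L, n = 2000L,
                             seed = 1L, alpha = 0.05) {
  stopifnot(length(scenarios) >= 1L)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  details <- list(); summaries <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    rows <- vector("list", n_replicates)
    failures <- 0L
    for (r in seq_len(n_replicates)) {
      rep_seed <- stage_seed(seed, 1000L * si + r)
      args <- utils::modifyList(
        list(n = n, seed = rep_seed, missingness_rates = numeric(0)), sc)
      cfg <- do.call(generator_config, args)
      rows[[r]] <- tryCatch(simulate_one_replicate(cfg, rep_seed, alpha),
                            error = function(e) {
                              failures <<- failures + 1L
                              NULL
                            })
    }
    det <- do.call(rbind, rows)
    details[[names(scenarios)[si]]] <- det
    summaries[[si]] <- data.frame(
      scenario = names(scenarios)[si],
      n_replicates = n_replicates,
      failures = failures,
      mean_difference = mean(det$difference),
      mean_oracle = mean(det$oracle),
      mc_se_vs_oracle = stats::sd(det$difference - det$oracle) / sqrt(nrow(det)),
      coverage_zero = mean(det$ci_lower <= 0 & det$ci_upper >= 0),
      coverage_oracle = mean(det$ci_lower <= det$oracle & det$ci_upper >= det$oracle),
      lrt_rejection_rate = mean(det$lrt_p < alpha),
      stringsAsFactors = FALSE
    )
  }
  structure(list(summary = do.call(rbind, summaries), details = details),
            class = "simulation_study")
}

simulate_one_replicate <- function(cfg, rep_seed, alpha) {
  cohort <- generate_cohort(cfg)
  selected <- apply_selection_filters(cohort)$cohort
  partition <- split_train_test(selected, seed = stage_seed(rep_seed, 21L))
  train <- selected[partition == "train", , drop = FALSE]
  test <- selected[partition == "test", , drop = FALSE]
  prop <- fit_propensity(train)
  int_fit <- fit_interaction_model(train, propensity_scores(prop, train))
  null_fit <- fit_main_effects_model(train, propensity_scores(prop, train),
                                     include_dose = FALSE)
  lrt <- lrt_moderator(int_fit, null_fit)
  preds <- compute_pai(predict_counterfactuals(int_fit, test,
                                               scores = propensity_scores(prop, test)))
  preds <- classify_allocation(preds)
  opt <- preds$group == "optimal"; sub <- preds$group == "suboptimal"
  cmp <- compare_groups_continuous(test$phq9_post[opt], test$phq9_post[sub])
  mu <- expected_outcome(test, cfg$beta_main, cfg$beta_treatment,
                         cfg$beta_interaction, cfg$noise_sd,
                         integer_scale = cfg$round_outcomes)
  data.frame(difference = cmp$difference, ci_lower = cmp$ci_lower,
             ci_upper = cmp$ci_upper,
             oracle = mean(mu[opt]) - mean(mu[sub]),
             n_optimal = sum(opt), n_suboptimal = sum(sub),
             lrt_p = lrt$p_value)
}

#' @export
print.simulation_study <- function(x, ...) {
  cat("Simulation study (", nrow(x$summary), " scenario(s))\n", sep = "")
  print.data.frame(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
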