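# Fixture factories: every test cohort is generated in code.

# complete cohort (no missingness), integer outcome scale by default
complete_config <- function(n, seed, ...) {
  args <- utils::modifyList(
    list(n = n, seed = seed, missingness_rates = numeric(0)),
    list(...))
  do.call(generator_config, args)
}

# cohort with no confounding and no treatment effect or moderation
null_config <- function(n, seed, ...) {
  complete_config(n, seed,
                  propensity_coefs = c("(Intercept)" = 0),
                  beta_treatment = 0,
                  beta_interaction = numeric(0), ...)
}

# generated cohort fitted end-to-end up to PAI classification, no imputation
run_pai_lite <- function(cfg, split_seed = 99L) {
  cohort <- generate_cohort(cfg)
  selected <- apply_selection_filters(cohort)$cohort
  partition <- split_train_test(selected, seed = split_seed)
  train <- selected[partition == "train", , drop = FALSE]
  test <- selected[partition == "test", , drop = FALSE]
  prop <- fit_propensity(train)
  fit <- fit_interaction_model(train, propensity_scores(prop, train))
  preds <- compute_pai(predict_counterfactuals(fit, test,
                                               scores = propensity_scores(prop, test)))
  list(train = train, test = test, fit = fit, prop = prop, preds = preds)
}
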