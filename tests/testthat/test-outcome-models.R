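test_that("with no covariates the treatment coefficient is the mean difference", {
  co <- generate_cohort(complete_config(400, seed = 3))
  fit <- fit_main_effects_model(co, covariates = character(0),
                                include_propensity = FALSE,
                                include_context = FALSE, include_dose = FALSE)
  est <- fit$coefficients$estimate[fit$coefficients$term == "treatmentCBT"]
  expect_equal(est,
               mean(co$phq9_post[co$treatment == "CBT"]) -
                 mean(co$phq9_post[co$treatment == "CFD"]),
               tolerance = 1e-12)
})

test_that("the adjusted treatment effect is recovered within 3 SEs", {
  cfg <- complete_config(5000, seed = 5, beta_treatment = -2,
                         beta_interaction = numeric(0))
  co <- generate_cohort(cfg)
  sel <- apply_selection_filters(co)$cohort
  prop <- fit_propensity(sel)
  fit <- fit_main_effects_model(sel, propensity_scores(prop, sel))
  tr <- fit$coefficients[fit$coefficients$term == "treatmentCBT", ]
  expect_lt(abs(tr$estimate - (-2)), 3 * tr$se)
})

test_that("the null treatment effect is covered by the 95% CI in >= 90% of replicates", {
  hits <- 0L
  for (r in 1:100) {
    cfg <- complete_config(1000, seed = 3000 + r, beta_treatment = 0,
                           beta_interaction = numeric(0),
                           propensity_coefs = c("(Intercept)" = 0))
    co <- apply_selection_filters(generate_cohort(cfg))$cohort
    prop <- fit_propensity(co)
    fit <- fit_main_effects_model(co, propensity_scores(prop, co))
    tr <- fit$coefficients[fit$coefficients$term == "treatmentCBT", ]
    if (tr$ci_lower <= 0 && tr$ci_upper >= 0) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("interaction coefficients are recovered and identified exactly without noise", {
  cfg <- complete_config(4000, seed = 7,
                         beta_interaction = c(medication = 1.5))
  co <- apply_selection_filters(generate_cohort(cfg))$cohort
  prop <- fit_propensity(co)
  fit <- fit_interaction_model(co, propensity_scores(prop, co))
  cc <- fit$coefficients
  int <- cc[cc$term == "treatmentCBT:medication", ]
  expect_lt(abs(int$estimate - 1.5), 3 * int$se)

  # exact identification on the continuous latent outcome with no noise
  cfg0 <- complete_config(3000, seed = 9, noise_sd = 0, round_outcomes = FALSE)
  co0 <- apply_selection_filters(generate_cohort(cfg0))$cohort
  prop0 <- fit_propensity(co0)
  fit0 <- fit_interaction_model(co0, propensity_scores(prop0, co0))
  b <- coef(fit0)
  expect_equal(b[["treatmentCBT"]], cfg0$beta_treatment, tolerance = 1e-6)
  expect_equal(b[["treatmentCBT:medication"]],
               unname(cfg0$beta_interaction[["medication"]]), tolerance = 1e-6)
  expect_equal(b[["phq9_baseline"]],
               unname(default_outcome_coefs()[["phq9_baseline"]]), tolerance = 1e-6)
  expect_equal(b[["propensity"]], 0, tolerance = 1e-6)
  # interactions absent from the generator come back as zero
  expect_equal(b[["treatmentCBT:age"]], 0, tolerance = 1e-6)
})

test_that("the interaction model nests the main-effects model", {
  co <- generate_cohort(complete_config(1500, seed = 11))
  sel <- apply_selection_filters(co)$cohort
  prop <- fit_propensity(sel)
  sc <- propensity_scores(prop, sel)
  main <- fit_main_effects_model(sel, sc, include_dose = FALSE)
  int <- fit_interaction_model(sel, sc)
  expect_gte(int$log_likelihood, main$log_likelihood)
  lrt <- lrt_moderator(int, main)
  expect_gte(lrt$statistic, 0)
  expect_gt(lrt$df, 0)
  # identical designs: zero statistic, p = 1
  same <- lrt_moderator(main, main)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # reversing full and reduced is not a nested comparison
  expect_error(lrt_moderator(main, int), "not nested")
})

test_that("joint interaction LRT holds its size under the null", {
  rejections <- 0L
  for (r in 1:100) {
    cfg <- complete_config(1000, seed = 5000 + r, beta_interaction = numeric(0),
                           propensity_coefs = c("(Intercept)" = 0))
    co <- apply_selection_filters(generate_cohort(cfg))$cohort
    prop <- fit_propensity(co)
    sc <- propensity_scores(prop, co)
    lrt <- lrt_moderator(fit_interaction_model(co, sc),
                         fit_main_effects_model(co, sc, include_dose = FALSE))
    if (lrt$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 10L)
})

test_that("a strong three-level moderator is detected by the LRT", {
  detections <- 0L
  for (r in 1:100) {
    cfg <- complete_config(1000, seed = 7000 + r,
                           propensity_coefs = c("(Intercept)" = 0),
                           beta_interaction = c(employmentnot_working = 3,
                                                employmentother = 3))
    co <- apply_selection_filters(generate_cohort(cfg))$cohort
    prop <- fit_propensity(co)
    fit <- fit_interaction_model(co, propensity_scores(prop, co))
    if (test_moderator(fit, "employment")$p_value < 0.05)
      detections <- detections + 1L
  }
  expect_gte(detections, 90L)
})

test_that("moderator profiles isolate the injected effect modification", {
  cfg <- complete_config(2500, seed = 13, noise_sd = 0, round_outcomes = FALSE,
                         beta_interaction = c(employmentnot_working = 1.2,
                                              employmentother = -0.7))
  co <- apply_selection_filters(generate_cohort(cfg))$cohort
  prop <- fit_propensity(co)
  fit <- fit_interaction_model(co, propensity_scores(prop, co))
  prof <- moderator_profile(fit, "employment")
  expect_equal(prof$difference, prof$pred_cbt - prof$pred_cfd)
  # differences across levels shift by exactly the injected coefficients
  base_diff <- prof$difference[prof$level == "employed"]
  expect_equal(prof$difference[prof$level == "not_working"] - base_diff, 1.2,
               tolerance = 1e-6)
  expect_equal(prof$difference[prof$level == "other"] - base_diff, -0.7,
               tolerance = 1e-6)
  # a variable with no interaction shows a constant difference
  prof_age <- moderator_profile(fit, "age")
  expect_equal(diff(range(prof_age$difference)), 0, tolerance = 1e-6)
  # internal consistency with direct counterfactual prediction
  row <- co[5, ]
  row$propensity <- propensity_scores(prop, row)
  expect_equal(predict(fit, row, treatment = "CBT") - predict(fit, row, treatment = "CFD"),
               -compute_pai(predict(fit, row, treatment = "CBT"),
                            predict(fit, row, treatment = "CFD")))
  expect_error(moderator_profile(fit, "shoe_size"), "unknown variable")
})

test_that("predictions are invariant to the categorical reference level", {
  co <- apply_selection_filters(generate_cohort(complete_config(800, seed = 15)))$cohort
  prop <- fit_propensity(co)
  sc <- propensity_scores(prop, co)
  fit1 <- fit_interaction_model(co, sc)
  flipped <- co
  flipped$gender <- stats::relevel(flipped$gender, "male")
  fit2 <- fit_interaction_model(flipped, sc)
  p1 <- predict(fit1, transform(co, propensity = sc))
  p2 <- predict(fit2, transform(flipped, propensity = sc))
  expect_equal(p1, p2, tolerance = 1e-8)
})
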