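test_that("generator configuration rejects invalid settings", {
  expect_error(generator_config(n = 0), "n.*must be >= 1")
  expect_error(generator_config(n = 10, noise_sd = -1), "noise_sd")
  expect_error(generator_config(n = 10, missingness_rates = c(imd = 1.2)), "\\[0, 1\\]")
  expect_error(generator_config(n = 10, missingness_rates = c(phq9_post = 0.1)),
               "non-baseline")
  expect_error(generate_cohort(generator_config(
    n = 10, covariate_distributions = utils::modifyList(
      default_covariate_distributions(), list(gender = c(female = 0.5, male = 0.6, other = 0.2))))),
    "sum to 1")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- generator_config(n = 500, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("generated scores respect instrument ranges and marginals", {
  co <- generate_cohort(complete_config(10000, seed = 11))
  expect_true(all(co$phq9_baseline >= 0 & co$phq9_baseline <= 27))
  expect_true(all(co$gad7_baseline >= 0 & co$gad7_baseline <= 21))
  expect_true(all(co$wsas_baseline >= 0 & co$wsas_baseline <= 40))
  expect_true(all(co$phq9_post >= 0 & co$phq9_post <= 27))
  expect_true(all(co$referral_number >= 1))
  expect_true(all(co$n_appointments >= 1))
  # law of large numbers: sample mean within 3 SEs of the configured mean
  expect_lt(abs(mean(co$phq9_baseline) - 18), 3 * 4 / sqrt(10000))
})

test_that("null propensity assigns treatments as a fair coin", {
  co <- generate_baseline(generator_config(n = 10000, seed = 3))
  co <- assign_treatment(co, c("(Intercept)" = 0), seed = 5)
  expect_lt(abs(mean(co$treatment == "CBT") - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("propensity coefficients shift assignment as configured", {
  co <- generate_baseline(generator_config(n = 5000, seed = 3))
  # severity-driven allocation: CBT arm should carry higher baseline PHQ-9
  co2 <- assign_treatment(co, c("(Intercept)" = -3.6, phq9_baseline = 0.2), seed = 5)
  expect_gt(mean(co2$phq9_baseline[co2$treatment == "CBT"]),
            mean(co2$phq9_baseline[co2$treatment == "CFD"]))
  # saturating intercept: everyone receives CBT
  co3 <- assign_treatment(co, c("(Intercept)" = 50), seed = 5)
  expect_true(all(co3$treatment == "CBT"))
  expect_error(assign_treatment(co, c(not_a_column = 1)), "configuration error")
})

test_that("noise-free outcomes equal the linear predictor by construction", {
  co <- generate_baseline(generator_config(n = 50, seed = 2))
  co <- assign_treatment(co, c("(Intercept)" = 0), seed = 4)
  flat <- simulate_outcomes(co, beta_main = c("(Intercept)" = 10),
                            beta_treatment = 0, beta_interaction = NULL,
                            noise_sd = 0)
  expect_true(all(flat$phq9_post == 10))
  # pure treatment effect: arms differ by exactly the configured effect
  eff <- simulate_outcomes(co, beta_main = c("(Intercept)" = 12),
                           beta_treatment = -2, beta_interaction = NULL,
                           noise_sd = 0)
  expect_true(all(eff$phq9_post[eff$treatment == "CBT"] == 10))
  expect_true(all(eff$phq9_post[eff$treatment == "CFD"] == 12))
  expect_error(simulate_outcomes(generate_baseline(generator_config(n = 5)),
                                 noise_sd = 0), "treatment")
})

test_that("true_pai matches the counterfactual-simulation oracle", {
  cfg <- complete_config(400, seed = 9, round_outcomes = FALSE)
  co <- generate_cohort(cfg)
  # oracle: simulate noise-free outcomes under both labels and difference them
  as_cbt <- co; as_cbt$treatment <- factor(rep("CBT", nrow(co)), levels = c("CFD", "CBT"))
  as_cfd <- co; as_cfd$treatment <- factor(rep("CFD", nrow(co)), levels = c("CFD", "CBT"))
  mu_cbt <- simulate_outcomes(as_cbt, cfg$beta_main, cfg$beta_treatment,
                              cfg$beta_interaction, noise_sd = 0,
                              round_outcomes = FALSE)$phq9_post
  mu_cfd <- simulate_outcomes(as_cfd, cfg$beta_main, cfg$beta_treatment,
                              cfg$beta_interaction, noise_sd = 0,
                              round_outcomes = FALSE)$phq9_post
  expect_equal(true_pai(co, cfg$beta_treatment, cfg$beta_interaction),
               mu_cfd - mu_cbt, tolerance = 1e-12)
  # sign convention: a pure negative treatment effect favours CBT by +|effect|
  expect_equal(true_pai(co, beta_treatment = -1), rep(1, nrow(co)))
  expect_equal(true_pai(co, beta_treatment = 0), rep(0, nrow(co)))
  # no moderation implies zero PAI variance
  expect_equal(var(true_pai(co, beta_treatment = -2)), 0)
})

test_that("missingness injection honours rates and never touches outcomes", {
  co <- generate_cohort(complete_config(10000, seed = 13))
  same <- inject_missingness(co, c(imd = 0), seed = 1)
  expect_identical(same, co)
  hit <- inject_missingness(co, c(imd = 0.2), seed = 1)
  expect_lt(abs(mean(is.na(hit$imd)) - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  expect_false(anyNA(hit$phq9_post))
  expect_false(anyNA(hit$treatment))
  gone <- inject_missingness(co, c(wsas_baseline = 1), seed = 1)
  expect_true(all(is.na(gone$wsas_baseline)))
  expect_error(inject_missingness(co, c(imd = -0.1)), "\\[0, 1\\]")
  expect_error(inject_missingness(co, c(phq9_post = 0.1)), "configuration error")
})

test_that("expected_outcome matches the Monte-Carlo mean on the integer scale", {
  cfg <- complete_config(30, seed = 21)
  co <- generate_cohort(cfg)
  mu <- expected_outcome(co, cfg$beta_main, cfg$beta_treatment,
                         cfg$beta_interaction, noise_sd = cfg$noise_sd)
  # brute-force oracle: average many noisy integer outcomes per patient
  set.seed(42)
  sims <- replicate(4000, simulate_outcomes(co, cfg$beta_main, cfg$beta_treatment,
                                            cfg$beta_interaction,
                                            noise_sd = cfg$noise_sd)$phq9_post)
  mc <- rowMeans(sims)
  expect_lt(max(abs(mu - mc)), 4 * cfg$noise_sd / sqrt(4000) * 3)
})
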