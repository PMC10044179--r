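#' Baseline covariates used throughout the pipeline
#'
#' The sixteen pre-treatment patient characteristics recorded at referral or
#' assessment: sociodemographics (age, gender, ethnicity, employment, sexual
#' orientation, area deprivation), clinical status (disability, long-term
#' condition, diagnosis, PHQ-9, GAD-7, WSAS, psychotropic medication) and
#' service-use history (referral source, prior low-intensity therapy, referral
#' number). Service and referral year are handled separately as context
#' variables.
#'
#' @return Character vector of column names.
#' @export
baseline_covariates <- function() {
  c("age", "gender", "ethnicity", "employment", "sexual_orientation", "imd",
    "disability", "long_term_condition", "diagnosis",
    "phq9_baseline", "gad7_baseline", "wsas_baseline",
    "medication", "referral_source", "prior_lit", "referral_number")
}

#' Canonical factor levels for categorical cohort columns
#'
#' The first level of each set is the modelling reference level, chosen as the
#' most frequent category under the default generator.
#'
#' @param n_services number of service identifiers.
#' @return Named list of level vectors.
#' @export
cohort_levels <- function(n_services = 10L) {
  list(
    gender = c("female", "male", "other"),
    ethnicity = c("white", "minority"),
    employment = c("employed", "not_working", "other"),
    sexual_orientation = c("heterosexual", "not_heterosexual"),
    diagnosis = c("depressive_episode", "recurrent_depression", "other"),
    referral_source = c("primary_care", "self", "other"),
    service = sprintf("service_%02d", seq_len(n_services)),
    treatment = c("CFD", "CBT")
  )
}

categorical_covariates <- function() {
  c("gender", "ethnicity", "employment", "sexual_orientation", "diagnosis",
    "referral_source")
}

binary_covariates <- function() {
  c("disability", "long_term_condition", "medication", "prior_lit")
}

#' Default covariate sampling distributions
#'
#' Marginals emulate a primary-care psychological-therapy cohort with clinical
#' depression: mean age 40, 67% female, ~80% White, moderately severe
#' depression (mean PHQ-9 18), moderate anxiety (mean GAD-7 14) and
#' moderately severe functional impairment (mean WSAS 23). Covariates are
#' sampled independently; only marginal distributions are specified.
#'
#' @return Named list understood by [generate_baseline()].
#' @export
default_covariate_distributions <- function() {
  list(
    age = list(mean = 40, sd = 13, min = 18, max = 90, round = FALSE),
    gender = c(female = 0.67, male = 0.31, other = 0.02),
    ethnicity = c(white = 0.799, minority = 0.201),
    employment = c(employed = 0.55, not_working = 0.30, other = 0.15),
    sexual_orientation = c(heterosexual = 0.92, not_heterosexual = 0.08),
    imd = list(mean = 21, sd = 6, min = 1, max = 60, round = FALSE),
    disability = 0.20,
    long_term_condition = 0.35,
    diagnosis = c(depressive_episode = 0.60, recurrent_depression = 0.30, other = 0.10),
    phq9_baseline = list(mean = 18, sd = 4, min = 0, max = 27, round = TRUE),
    gad7_baseline = list(mean = 14, sd = 4, min = 0, max = 21, round = TRUE),
    wsas_baseline = list(mean = 23, sd = 8, min = 0, max = 40, round = TRUE),
    medication = 0.45,
    referral_source = c(primary_care = 0.50, self = 0.35, other = 0.15),
    prior_lit = 0.35
  )
}

#' Default propensity (treatment-assignment) coefficients
#'
#' Log-odds of receiving CBT rather than CFD. Names refer to columns of the
#' baseline design matrix (see [cohort_design()]). Defaults reproduce the
#' confounding pattern seen in routine services: more severe, medicated,
#' self-referring patients with prior low-intensity therapy are likelier to
#' receive CBT, with roughly three quarters of the cohort in the CBT arm.
#'
#' @return Named numeric vector.
#' @export
default_propensity_coefs <- function() {
  c("(Intercept)" = -0.4, phq9_baseline = 0.04, wsas_baseline = 0.01,
    medication = 0.3, prior_lit = 0.3, referral_sourceself = 0.4,
    referral_number = 0.15)
}

#' Default outcome main-effect coefficients
#'
#' Linear predictor of post-treatment PHQ-9 on the baseline design matrix.
#' Directions follow the established prognostic pattern: higher baseline
#' severity (PHQ-9, GAD-7, WSAS), deprivation, disability, long-term illness,
#' medication, not working, non-self referral and repeat referrals predict
#' worse outcomes; older age predicts better outcomes.
#'
#' @return Named numeric vector.
#' @export
default_outcome_coefs <- function() {
  c("(Intercept)" = 0.5, phq9_baseline = 0.45, gad7_baseline = 0.10,
    wsas_baseline = 0.05, age = -0.03, imd = 0.04,
    disability = 0.7, long_term_condition = 0.5, medication = 0.7,
    employmentnot_working = 0.9, referral_sourceself = -0.4,
    referral_number = 0.3)
}

#' Default treatment-by-covariate interaction coefficients
#'
#' Effect-modification on post-treatment PHQ-9 for the CBT arm relative to
#' CFD. Defaults encode the two moderators with any empirical support in this
#' literature: patients on psychotropic medication do better in CBT (negative
#' interaction, i.e. lower post-treatment score under CBT), patients not in
#' employment do better in counselling.
#'
#' @return Named numeric vector (may be empty for a no-moderation scenario).
#' @export
default_interaction_coefs <- function() {
  c(medication = -0.8, employmentnot_working = 0.8)
}

#' Default baseline missingness rates
#'
#' Missing-completely-at-random cell rates for a subset of baseline
#' covariates, mimicking the uneven completeness of routinely collected
#' records (demographics recorded less reliably than symptom scores).
#'
#' @return Named numeric vector of per-column missing fractions.
#' @export
default_missingness_rates <- function() {
  c(imd = 0.10, sexual_orientation = 0.15, employment = 0.06,
    ethnicity = 0.05, wsas_baseline = 0.08, gad7_baseline = 0.03)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles the ground truth of a simulated cohort: covariate marginals, the
#' treatment-assignment (propensity) coefficients, the linear outcome model
#' (main effects, treatment effect, treatment-by-covariate interactions),
#' residual noise, and missingness. Every downstream stage can be validated
#' against these known quantities.
#'
#' @param n cohort size (>= 1).
#' @param seed integer seed; generation is fully reproducible given the seed.
#' @param covariate_distributions see [default_covariate_distributions()].
#' @param propensity_coefs named log-odds coefficients for CBT assignment.
#' @param beta_main named main-effect coefficients on post-treatment PHQ-9.
#' @param beta_treatment scalar CBT main effect (PHQ-9 points; negative means
#'   CBT lowers post-treatment scores).
#' @param beta_interaction named treatment-by-covariate interaction
#'   coefficients; may be `NULL` or empty.
#' @param noise_sd residual standard deviation of the outcome (>= 0).
#' @param missingness_rates named per-column missing fractions in `[0, 1]`
#'   for baseline covariates; treatment and outcome are never made missing.
#' @param outcome_missing_rate fraction of post-treatment scores set missing
#'   (an exclusion downstream, never an imputation target).
#' @param n_services number of service identifiers.
#' @param years calendar years sampled for the referral.
#' @param appointments_lambda Poisson mean of appointments beyond the minimum
#'   of two needed for a pre and a post measure.
#' @param referral_lambda Poisson mean of referrals beyond the first.
#' @param round_outcomes if `TRUE` (default) post-treatment PHQ-9 is rounded
#'   and clipped to the 0-27 instrument range after noise is added; `FALSE`
#'   keeps the latent continuous outcome (useful for exact-identification
#'   studies).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n,
                             seed = 1L,
                             covariate_distributions = default_covariate_distributions(),
                             propensity_coefs = default_propensity_coefs(),
                             beta_main = default_outcome_coefs(),
                             beta_treatment = -0.1,
                             beta_interaction = default_interaction_coefs(),
                             noise_sd = 5.5,
                             missingness_rates = default_missingness_rates(),
                             outcome_missing_rate = 0,
                             n_services = 10L,
                             years = 2012:2019,
                             appointments_lambda = 7,
                             referral_lambda = 0.25,
                             round_outcomes = TRUE) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("configuration error: cohort size `n` must be >= 1", call. = FALSE)
  assert_number(seed, "seed")
  assert_number(beta_treatment, "beta_treatment")
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(outcome_missing_rate, "outcome_missing_rate", lower = 0, upper = 1)
  if (length(missingness_rates)) {
    if (is.null(names(missingness_rates)) || any(!nzchar(names(missingness_rates))))
      stop("configuration error: missingness_rates must be named", call. = FALSE)
    if (any(is.na(missingness_rates)) || any(missingness_rates < 0 | missingness_rates > 1))
      stop("configuration error: missingness rates must lie in [0, 1]", call. = FALSE)
    unknown <- setdiff(names(missingness_rates), baseline_covariates())
    if (length(unknown))
      stop("configuration error: missingness_rates name non-baseline column(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (v in c(categorical_covariates())) {
    p <- covariate_distributions[[v]]
    if (!is.null(p) && (any(p < 0) || abs(sum(p) - 1) > 1e-8))
      stop("configuration error: probabilities for `", v, "` must be non-negative and sum to 1",
           call. = FALSE)
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    covariate_distributions = covariate_distributions,
    propensity_coefs = propensity_coefs,
    beta_main = beta_main, beta_treatment = beta_treatment,
    beta_interaction = beta_interaction %||% numeric(0),
    noise_sd = noise_sd,
    missingness_rates = missingness_rates,
    outcome_missing_rate = outcome_missing_rate,
    n_services = as.integer(n_services), years = as.integer(years),
    appointments_lambda = appointments_lambda, referral_lambda = referral_lambda,
    round_outcomes = round_outcomes
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat("  n:", x$n, " seed:", x$seed, "\n")
  cat("  treatment effect (CBT):", x$beta_treatment, "PHQ-9 points\n")
  cat("  interactions:", if (length(x$beta_interaction))
    paste(names(x$beta_interaction), "=", x$beta_interaction, collapse = ", ") else "none", "\n")
  cat("  noise sd:", x$noise_sd,
      " outcome scale:", if (x$round_outcomes) "integer 0-27" else "continuous latent", "\n")
  invisible(x)
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

sample_numeric <- function(n, spec) {
  x <- stats::rnorm(n, spec$mean, spec$sd)
  x <- clip(x, spec$min, spec$max)
  if (isTRUE(spec$round)) x <- round(x)
  x
}

#' Generate baseline records for a synthetic cohort
#'
#' Samples patient identifiers, covariates, service, referral year and the
#' number of attended appointments. Treatment and outcomes are added by
#' [assign_treatment()] and [simulate_outcomes()]. Instrument scores are
#' rounded and clipped into their ranges (PHQ-9 0-27, GAD-7 0-21, WSAS 0-40).
#'
#' @param config a [generator_config()].
#' @return A data frame with one row per patient.
#' @export
generate_baseline <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n
  dist <- config$covariate_distributions
  lev <- cohort_levels(config$n_services)
  draw_cat <- function(p, levels) {
    if (is.null(names(p)) || !setequal(names(p), levels))
      stop("configuration error: category probabilities must name every level: ",
           paste(levels, collapse = ", "), call. = FALSE)
    factor(sample(levels, n, replace = TRUE, prob = p[levels]), levels = levels)
  }
  out <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = sample_numeric(n, dist$age),
    gender = draw_cat(dist$gender, lev$gender),
    ethnicity = draw_cat(dist$ethnicity, lev$ethnicity),
    employment = draw_cat(dist$employment, lev$employment),
    sexual_orientation = draw_cat(dist$sexual_orientation, lev$sexual_orientation),
    imd = sample_numeric(n, dist$imd),
    disability = stats::rbinom(n, 1L, dist$disability),
    long_term_condition = stats::rbinom(n, 1L, dist$long_term_condition),
    diagnosis = draw_cat(dist$diagnosis, lev$diagnosis),
    phq9_baseline = sample_numeric(n, dist$phq9_baseline),
    gad7_baseline = sample_numeric(n, dist$gad7_baseline),
    wsas_baseline = sample_numeric(n, dist$wsas_baseline),
    medication = stats::rbinom(n, 1L, dist$medication),
    referral_source = draw_cat(dist$referral_source, lev$referral_source),
    prior_lit = stats::rbinom(n, 1L, dist$prior_lit %||% 0.35),
    referral_number = 1L + stats::rpois(n, config$referral_lambda),
    service = factor(sample(lev$service, n, replace = TRUE), levels = lev$service),
    year = sample(config$years, n, replace = TRUE),
    n_appointments = 2L + stats::rpois(n, config$appointments_lambda),
    stringsAsFactors = FALSE
  )
  out
}

#' Design matrix over baseline covariates (and optionally service/year)
#'
#' Standard treatment-coded model matrix used both by the generator (to apply
#' named ground-truth coefficients) and by tests that need hand-computed
#' linear predictors. Categorical variables expand to dummies named
#' `<variable><level>` relative to the canonical reference level.
#'
#' @param cohort cohort data frame with complete covariates.
#' @param covariates covariate columns to include.
#' @param include_context include `service` and `year`.
#' @return Numeric matrix with an `(Intercept)` column.
#' @export
cohort_design <- function(cohort, covariates = baseline_covariates(),
                          include_context = TRUE) {
  vars <- c(covariates, if (include_context) intersect(c("service", "year"), names(cohort)))
  require_columns(cohort, vars, "cohort_design")
  mf <- cohort[vars]
  if (anyNA(mf))
    stop("cohort_design: covariates contain missing values; impute or complete them first",
         call. = FALSE)
  stats::model.matrix(~ ., data = mf)
}

# linear predictor from a named coefficient vector matched against design columns
linear_predictor <- function(X, coefs) {
  coefs <- unlist(coefs)
  if (!length(coefs)) return(rep(0, nrow(X)))
  unknown <- setdiff(names(coefs), colnames(X))
  if (length(unknown))
    stop("configuration error: coefficient name(s) not in design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  unname(drop(X[, names(coefs), drop = FALSE] %*% coefs))
}

#' Assign treatment by a logistic propensity model
#'
#' Draws each patient's treatment (CBT vs CFD) as a Bernoulli variable with
#' probability `plogis(x' propensity_coefs)`, emulating non-random allocation
#' in routine care. With all coefficients zero the assignment probability is
#' 0.5 for everyone. High-intensity session counts are recorded consistently
#' with the assigned arm.
#'
#' @param cohort baseline cohort with complete covariates.
#' @param propensity_coefs named log-odds coefficients (see [cohort_design()]
#'   for naming); unspecified columns contribute zero.
#' @param seed integer seed.
#' @return The cohort with `treatment` (factor, reference CFD) and per-arm
#'   session-count columns.
#' @export
assign_treatment <- function(cohort, propensity_coefs = default_propensity_coefs(),
                             seed = NULL) {
  X <- cohort_design(cohort)
  p <- stats::plogis(linear_predictor(X, propensity_coefs))
  if (!is.null(seed)) set.seed(seed)
  cbt <- stats::runif(nrow(cohort)) < p
  cohort$treatment <- factor(ifelse(cbt, "CBT", "CFD"), levels = c("CFD", "CBT"))
  napp <- cohort$n_appointments %||% rep(2L, nrow(cohort))
  cohort$n_cbt_sessions <- ifelse(cbt, napp, 0L)
  cohort$n_cfd_sessions <- ifelse(cbt, 0L, napp)
  cohort$n_other_hit_sessions <- 0L
  cohort
}

#' Simulate post-treatment PHQ-9 outcomes
#'
#' The outcome follows a linear model: main effects of the baseline design,
#' plus for the CBT arm the treatment effect and any treatment-by-covariate
#' interactions, plus Gaussian noise. With `round_outcomes = TRUE` scores are
#' rounded and clipped to the 0-27 instrument range after the noise is added;
#' with `noise_sd = 0` the outcome is the deterministic linear predictor.
#'
#' @param cohort cohort with assigned treatment.
#' @param beta_main,beta_treatment,beta_interaction generating coefficients.
#' @param noise_sd residual standard deviation (>= 0).
#' @param seed integer seed.
#' @param round_outcomes round/clip to the integer instrument scale.
#' @return The cohort with a `phq9_post` column.
#' @export
simulate_outcomes <- function(cohort, beta_main = default_outcome_coefs(),
                              beta_treatment = -0.1,
                              beta_interaction = default_interaction_coefs(),
                              noise_sd = 5.5, seed = NULL,
                              round_outcomes = TRUE) {
  if (is.null(cohort$treatment) || anyNA(cohort$treatment))
    stop("simulate_outcomes: treatment must be assigned before outcomes are simulated",
         call. = FALSE)
  assert_number(noise_sd, "noise_sd", lower = 0)
  X <- cohort_design(cohort)
  ind <- as.numeric(cohort$treatment == "CBT")
  mu <- linear_predictor(X, beta_main) +
    ind * (beta_treatment + linear_predictor(X, beta_interaction %||% numeric(0)))
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd > 0) stats::rnorm(nrow(cohort), 0, noise_sd) else 0
  post <- mu + eps
  cohort$phq9_post <- if (round_outcomes) clip(round(post), 0, 27) else post
  cohort
}

#' Ground-truth Personalised Advantage Index
#'
#' The noise-free difference in expected post-treatment PHQ-9 under CFD minus
#' under CBT, computed in closed form from the generating coefficients.
#' Positive values mean CBT is truly the better (lower-scoring) treatment.
#' With no interactions the PAI is the constant `-beta_treatment`.
#'
#' @param cohort records with complete covariates.
#' @param beta_treatment scalar CBT main effect.
#' @param beta_interaction named interaction coefficients (may be empty).
#' @return Numeric vector of signed PHQ-9 point differences.
#' @export
true_pai <- function(cohort, beta_treatment, beta_interaction = NULL) {
  X <- cohort_design(cohort)
  -(beta_treatment + linear_predictor(X, beta_interaction %||% numeric(0)))
}

#' Expected observed outcome under the generating model
#'
#' Expected value of the recorded post-treatment PHQ-9 for each patient under
#' a given (or the received) treatment. On the integer instrument scale the
#' expectation accounts for the rounding and clipping of the noisy latent
#' outcome, summing `k * P(round(clip(mu + eps)) = k)` over the 0-27 grid
#' using Gaussian cell probabilities; on the latent scale it is the linear
#' predictor itself.
#'
#' @param cohort records with complete covariates (and `treatment` unless
#'   `treatment` is supplied).
#' @param beta_main,beta_treatment,beta_interaction generating coefficients.
#' @param noise_sd residual standard deviation used in generation.
#' @param treatment optional single label ("CBT" or "CFD") overriding the
#'   received treatment.
#' @param integer_scale account for rounding/clipping to 0-27.
#' @return Numeric vector of expected outcomes.
#' @export
expected_outcome <- function(cohort, beta_main = default_outcome_coefs(),
                             beta_treatment = -0.1,
                             beta_interaction = default_interaction_coefs(),
                             noise_sd = 5.5, treatment = NULL,
                             integer_scale = TRUE) {
  X <- cohort_design(cohort)
  ind <- if (is.null(treatment)) {
    if (is.null(cohort$treatment)) stop("expected_outcome: no treatment available", call. = FALSE)
    as.numeric(cohort$treatment == "CBT")
  } else rep(as.numeric(match.arg(treatment, c("CBT", "CFD")) == "CBT"), nrow(X))
  mu <- linear_predictor(X, beta_main) +
    ind * (beta_treatment + linear_predictor(X, beta_interaction %||% numeric(0)))
  if (!integer_scale) return(mu)
  if (noise_sd == 0) return(clip(round(mu), 0, 27))
  # exact expectation over the rounded, clipped integer grid
  cuts <- c(-Inf, seq(0.5, 26.5, by = 1), Inf) # boundaries for k = 0..27
  probs <- vapply(seq_len(28), function(k) {
    stats::pnorm(cuts[k + 1L], mean = mu, sd = noise_sd) -
      stats::pnorm(cuts[k], mean = mu, sd = noise_sd)
  }, numeric(length(mu)))
  drop(if (is.matrix(probs)) probs %*% (0:27) else sum(probs * (0:27)))
}

#' Inject missingness into baseline covariates
#'
#' Sets baseline covariate cells missing, by default completely at random at
#' the stated per-column rates. Treatment and the post-treatment outcome are
#' never made missing here: missing outcomes are an exclusion criterion, not
#' an imputation target. An optional missing-at-random hook tilts each cell's
#' missingness probability by a (complete) driver covariate.
#'
#' @param cohort cohort data frame.
#' @param missingness_rates named rates in `[0, 1]` over baseline covariates.
#' @param seed integer seed.
#' @param mar optional list `list(driver = <column>, strength = <log-odds per
#'   SD>)` making missingness depend on the standardised driver.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, missingness_rates = default_missingness_rates(),
                               seed = NULL, mar = NULL) {
  if (!length(missingness_rates)) return(cohort)
  if (any(is.na(missingness_rates)) || any(missingness_rates < 0 | missingness_rates > 1))
    stop("configuration error: missingness rates must lie in [0, 1]", call. = FALSE)
  bad <- setdiff(names(missingness_rates), baseline_covariates())
  if (length(bad))
    stop("configuration error: cannot inject missingness into: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tilt <- 0
  if (!is.null(mar)) {
    driver <- cohort[[mar$driver]]
    if (is.null(driver) || anyNA(driver) || !is.numeric(driver))
      stop("configuration error: MAR driver must be a complete numeric column", call. = FALSE)
    z <- (driver - mean(driver)) / stats::sd(driver)
    tilt <- mar$strength * z
  }
  for (v in names(missingness_rates)) {
    r <- missingness_rates[[v]]
    if (r == 0) next
    p <- if (identical(tilt, 0)) rep(r, nrow(cohort)) else stats::plogis(stats::qlogis(r) + tilt)
    cohort[[v]][stats::runif(nrow(cohort)) < p] <- NA
  }
  cohort
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generator: baseline covariates, propensity-driven treatment
#' assignment, linear-model outcomes with interactions and noise, optional
#' missing outcomes, and baseline missingness. All stages derive their seeds
#' from `config$seed` via [stage_seed()], so generation is bit-reproducible.
#'
#' @param config a [generator_config()].
#' @return Cohort data frame with the generating config attached as attribute
#'   `"generator_config"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cohort <- generate_baseline(config)
  cohort <- assign_treatment(cohort, config$propensity_coefs,
                             seed = stage_seed(config$seed, 1L))
  cohort <- simulate_outcomes(cohort, config$beta_main, config$beta_treatment,
                              config$beta_interaction, config$noise_sd,
                              seed = stage_seed(config$seed, 2L),
                              round_outcomes = config$round_outcomes)
  if (config$outcome_missing_rate > 0) {
    set.seed(stage_seed(config$seed, 3L))
    drop_idx <- stats::runif(nrow(cohort)) < config$outcome_missing_rate
    cohort$phq9_post[drop_idx] <- NA
  }
  cohort <- inject_missingness(cohort, config$missingness_rates,
                               seed = stage_seed(config$seed, 4L))
  attr(cohort, "generator_config") <- config
  cohort
}
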