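outcome_formula <- function(covariates, interactions, include_propensity,
                            include_context, include_dose) {
  rhs <- character(0)
  if (length(covariates)) {
    block <- paste(covariates, collapse = " + ")
    rhs <- c(rhs, if (interactions) paste0("treatment * (", block, ")")
             else paste("treatment +", block))
  } else rhs <- c(rhs, "treatment")
  if (include_propensity) rhs <- c(rhs, "propensity")
  if (include_dose) rhs <- c(rhs, "n_appointments")
  if (include_context) rhs <- c(rhs, "service", "year")
  stats::as.formula(paste("phq9_post ~", paste(rhs, collapse = " + ")))
}

fit_outcome_model <- function(train, scores, type, covariates, include_propensity,
                              include_context, include_dose) {
  require_columns(train, c(covariates, "treatment", "phq9_post"), "outcome model")
  d <- train
  if (include_propensity) {
    if (is.null(scores)) stop("outcome model: propensity scores are required", call. = FALSE)
    stopifnot(length(scores) == nrow(train))
    d$propensity <- scores
  }
  vars_used <- c(covariates, "treatment", "phq9_post",
                 if (include_propensity) "propensity",
                 if (include_dose) "n_appointments",
                 if (include_context) intersect(c("service", "year"), names(d)))
  if (anyNA(d[intersect(vars_used, names(d))]))
    stop("outcome model: design variables contain missing values; impute first", call. = FALSE)
  f <- outcome_formula(covariates, interactions = (type == "interaction"),
                       include_propensity = include_propensity,
                       include_context = include_context && all(c("service", "year") %in% names(d)),
                       include_dose = include_dose)
  fit <- withCallingHandlers(
    stats::lm(f, data = d),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased))
    stop("outcome model: rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  fit_summary <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sm <- fit_summary$coefficients
  ll <- stats::logLik(fit)
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                      ci_lower = sm[, 1L] - 1.96 * sm[, 2L],
                      ci_upper = sm[, 1L] + 1.96 * sm[, 2L],
                      p_value = sm[, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
  num <- vars_used[vapply(d[intersect(vars_used, names(d))], is.numeric, logical(1))]
  num <- setdiff(num, "phq9_post")
  fac <- intersect(vars_used, names(which(vapply(d, is.factor, logical(1)))))
  center <- list(
    means = vapply(num, function(v) mean(d[[v]]), numeric(1)),
    sds = vapply(num, function(v) stats::sd(d[[v]]), numeric(1)),
    modes = lapply(d[fac], stat_mode)
  )
  structure(list(model = fit, type = type, formula = f, covariates = covariates,
                 include_propensity = include_propensity,
                 include_context = include_context, include_dose = include_dose,
                 coefficients = coefs, log_likelihood = as.numeric(ll),
                 df = attr(ll, "df"), sigma = fit_summary$sigma,
                 n = stats::nobs(fit), center = center,
                 training_levels = factor_levels_of(d[fac]),
                 data = d),
            class = "outcome_fit")
}

#' Fit the main-effects treatment model
#'
#' Linear regression of post-treatment PHQ-9 on treatment, all baseline
#' covariates, the propensity score, the number of attended appointments
#' (treatment dose), service and referral year. Its adjusted treatment
#' coefficient is the average CBT-vs-CFD effect used to assess whether the
#' two therapies are, on average, equivalent.
#'
#' @param train imputed training cohort.
#' @param scores propensity scores aligned with `train` (from
#'   [propensity_scores()]); ignored when `include_propensity = FALSE`.
#' @param covariates baseline covariates in the design.
#' @param include_propensity,include_context,include_dose design switches;
#'   the treatment model includes the dose by default.
#' @return An `outcome_fit`.
#' @export
fit_main_effects_model <- function(train, scores = NULL,
                                   covariates = baseline_covariates(),
                                   include_propensity = TRUE,
                                   include_context = TRUE,
                                   include_dose = TRUE) {
  fit_outcome_model(train, scores, type = "main_effects", covariates = covariates,
                    include_propensity = include_propensity,
                    include_context = include_context, include_dose = include_dose)
}

#' Fit the treatment-interaction prediction model
#'
#' Linear regression of post-treatment PHQ-9 with every baseline covariate
#' entering both as a main effect and in interaction with treatment
#' (moderation), while service, referral year and the propensity score enter
#' as main effects only. This is the model used for factual/counterfactual
#' prediction and PAI scoring. Treatment dose is excluded by default because
#' the number of appointments is unknown at allocation time; set
#' `include_dose = TRUE` to add it as a main effect.
#'
#' @inheritParams fit_main_effects_model
#' @return An `outcome_fit`.
#' @export
fit_interaction_model <- function(train, scores = NULL,
                                  covariates = baseline_covariates(),
                                  include_propensity = TRUE,
                                  include_context = TRUE,
                                  include_dose = FALSE) {
  fit_outcome_model(train, scores, type = "interaction", covariates = covariates,
                    include_propensity = include_propensity,
                    include_context = include_context, include_dose = include_dose)
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("Outcome model (", x$type, "): ", deparse(x$formula), "\n", sep = "")
  cat("  n =", x$n, " logLik =", format(x$log_likelihood, digits = 6),
      " residual sd =", format(x$sigma, digits = 3), "\n")
  tr <- x$coefficients[x$coefficients$term == "treatmentCBT", , drop = FALSE]
  if (nrow(tr))
    cat("  treatment (CBT) effect: ", format(tr$estimate, digits = 3),
        " (95% CI ", format(tr$ci_lower, digits = 3), " to ",
        format(tr$ci_upper, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.outcome_fit <- function(object, ...) stats::coef(object$model)

#' @export
logLik.outcome_fit <- function(object, ...) stats::logLik(object$model)

#' Coefficient table of an outcome model
#'
#' @param fit an `outcome_fit`.
#' @return Data frame with estimate, standard error, normal-approximation
#'   95% CI (estimate +/- 1.96 SE) and p-value per term.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "outcome_fit"))
  fit$coefficients
}

#' Predict post-treatment PHQ-9 from an outcome model
#'
#' @param object an `outcome_fit`.
#' @param newdata records sharing the training schema; must carry a
#'   `propensity` column (or pass `propensity`) when the model includes one.
#' @param treatment optional single label "CBT"/"CFD" overriding the
#'   recorded treatment for counterfactual prediction.
#' @param propensity optional vector of propensity scores for `newdata`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.outcome_fit <- function(object, newdata, treatment = NULL,
                                propensity = NULL, ...) {
  d <- newdata
  if (!is.null(propensity)) d$propensity <- propensity
  if (object$include_propensity && is.null(d$propensity))
    stop("predict.outcome_fit: propensity scores required (column `propensity`)",
         call. = FALSE)
  if (!is.null(treatment)) {
    treatment <- match.arg(treatment, c("CBT", "CFD"))
    d$treatment <- factor(rep(treatment, nrow(d)), levels = c("CFD", "CBT"))
  }
  d <- conform_levels(d, object$training_levels)
  as.numeric(stats::predict(object$model, newdata = d))
}

lik_and_df <- function(fit) {
  ll <- if (inherits(fit, "outcome_fit")) stats::logLik(fit$model) else stats::logLik(fit)
  list(ll = as.numeric(ll), df = attr(ll, "df"),
       n = if (inherits(fit, "outcome_fit")) fit$n else stats::nobs(fit),
       terms = attr(stats::terms(if (inherits(fit, "outcome_fit")) fit$model else fit),
                    "term.labels"))
}

#' Likelihood ratio test between nested outcome models
#'
#' Statistic `2 * (logLik_full - logLik_reduced)` referred to the chi-square
#' upper tail with degrees of freedom equal to the difference in parameter
#' counts. Used to test moderators: for a categorical variable with more than
#' two levels the test pools its treatment-interaction dummies. The models
#' must be fitted to the same data and the reduced design must nest in the
#' full design.
#'
#' @param fit_full,fit_reduced `outcome_fit` (or `lm`) objects.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lrt_moderator <- function(fit_full, fit_reduced) {
  a <- lik_and_df(fit_full); b <- lik_and_df(fit_reduced)
  if (a$n != b$n)
    stop("lrt_moderator: models were fitted to different data", call. = FALSE)
  if (length(setdiff(b$terms, a$terms)) || a$df < b$df)
    stop("lrt_moderator: designs are not nested", call. = FALSE)
  stat <- max(0, 2 * (a$ll - b$ll))
  df <- a$df - b$df
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Test one moderator by likelihood ratio
#'
#' Refits the interaction model without the treatment-by-`variable`
#' interaction (keeping the variable's main effect) and compares by LRT.
#'
#' @param fit an interaction `outcome_fit`.
#' @param variable one of the model's baseline covariates.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
test_moderator <- function(fit, variable) {
  stopifnot(inherits(fit, "outcome_fit"))
  if (fit$type != "interaction")
    stop("test_moderator: requires an interaction model", call. = FALSE)
  if (!variable %in% fit$covariates)
    stop("test_moderator: unknown variable `", variable, "`", call. = FALSE)
  others <- setdiff(fit$covariates, variable)
  rhs <- c(if (length(others)) paste0("treatment * (", paste(others, collapse = " + "), ")")
           else "treatment",
           variable,
           if (fit$include_propensity) "propensity",
           if (fit$include_dose) "n_appointments",
           if (fit$include_context && all(c("service", "year") %in% names(fit$data)))
             c("service", "year"))
  reduced <- stats::lm(stats::as.formula(paste("phq9_post ~", paste(rhs, collapse = " + "))),
                       data = fit$data)
  lrt_moderator(fit$model, reduced)
}

#' Moderator profile: predicted outcomes by treatment across one variable
#'
#' Illustrates effect modification: predicted post-treatment PHQ-9 under CBT
#' and under CFD across the levels of one covariate, with every other
#' covariate held constant at the training mean (continuous) or most frequent
#' level (categorical). Continuous moderators are profiled at the mean and
#' mean +/- 1 SD.
#'
#' @param fit a fitted interaction `outcome_fit`.
#' @param variable covariate to vary.
#' @return A `moderator_profile` data frame with columns `level`,
#'   `pred_cbt`, `pred_cfd` and `difference` (CBT minus CFD).
#' @export
moderator_profile <- function(fit, variable) {
  stopifnot(inherits(fit, "outcome_fit"))
  if (fit$type != "interaction")
    stop("moderator_profile: requires an interaction model", call. = FALSE)
  d <- fit$data
  model_vars <- setdiff(all.vars(fit$formula), "phq9_post")
  if (!variable %in% model_vars)
    stop("moderator_profile: unknown variable `", variable, "`", call. = FALSE)
  base <- d[1L, model_vars, drop = FALSE]
  for (v in model_vars) {
    if (v %in% names(fit$center$means)) base[[v]] <- fit$center$means[[v]]
    else if (v %in% names(fit$center$modes)) base[[v]] <- fit$center$modes[[v]]
  }
  if (is.factor(d[[variable]])) {
    grid_vals <- levels(d[[variable]])
    rows <- base[rep(1L, length(grid_vals)), , drop = FALSE]
    rows[[variable]] <- factor(grid_vals, levels = levels(d[[variable]]))
    level_lab <- grid_vals
  } else if (all(d[[variable]] %in% c(0, 1))) {
    grid_vals <- c(0, 1)
    rows <- base[rep(1L, 2L), , drop = FALSE]
    rows[[variable]] <- grid_vals
    level_lab <- c("no", "yes")
  } else {
    m <- fit$center$means[[variable]]; s <- fit$center$sds[[variable]]
    grid_vals <- c(m - s, m, m + s)
    rows <- base[rep(1L, 3L), , drop = FALSE]
    rows[[variable]] <- grid_vals
    level_lab <- c("mean - 1 SD", "mean", "mean + 1 SD")
  }
  pred_cbt <- predict(fit, rows, treatment = "CBT")
  pred_cfd <- predict(fit, rows, treatment = "CFD")
  out <- data.frame(variable = variable, level = level_lab, value = grid_vals,
                    pred_cbt = pred_cbt, pred_cfd = pred_cfd,
                    difference = pred_cbt - pred_cfd,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("moderator_profile", "data.frame")
  out
}
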