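factor_levels_of <- function(data) {
  fac <- vapply(data, is.factor, logical(1))
  lapply(data[fac], levels)
}

# map unseen categorical levels in new data to the training reference level
conform_levels <- function(records, training_levels, warn = TRUE) {
  for (v in names(training_levels)) {
    if (is.null(records[[v]])) next
    x <- as.character(records[[v]])
    known <- training_levels[[v]]
    unseen <- setdiff(unique(x[!is.na(x)]), known)
    if (length(unseen)) {
      if (warn)
        warning("unseen level(s) in `", v, "` mapped to reference level `", known[1L],
                "`: ", paste(unseen, collapse = ", "), call. = FALSE)
      x[x %in% unseen] <- known[1L]
    }
    records[[v]] <- factor(x, levels = known)
  }
  records
}

#' Fit the propensity model for treatment assignment
#'
#' Logistic regression of the treatment indicator (CBT = 1, CFD = 0) on all
#' baseline covariates plus service and referral year. Because allocation in
#' routine care is not random, the fitted probability of receiving CBT is
#' carried forward as a covariate in every subsequent outcome model in
#' addition to regression adjustment -- a doubly robust design. No trimming or
#' weighting is applied.
#'
#' @param train imputed (complete) training cohort containing both treatments.
#' @param covariates baseline covariates to include.
#' @param include_context include service and year.
#' @return A `propensity_model` (fitted glm plus training level metadata).
#' @export
fit_propensity <- function(train, covariates = baseline_covariates(),
                           include_context = TRUE) {
  require_columns(train, c(covariates, "treatment"), "fit_propensity")
  if (length(unique(stats::na.omit(train$treatment))) < 2L)
    stop("fit_propensity: both treatments must be present in the training cohort",
         call. = FALSE)
  vars <- c(covariates, if (include_context) intersect(c("service", "year"), names(train)))
  if (anyNA(train[vars]))
    stop("fit_propensity: covariates contain missing values; impute first", call. = FALSE)
  d <- train[vars]
  d$.cbt <- as.numeric(train$treatment == "CBT")
  f <- stats::as.formula(paste(".cbt ~", paste(vars, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (separated || !fit$converged)
    stop("fit_propensity: (quasi-)separation or non-convergence detected; ",
         "review the covariates for levels perfectly predicting treatment",
         call. = FALSE)
  p <- stats::fitted(fit)
  if (any(p <= 0) || any(p >= 1))
    stop("fit_propensity: fitted probabilities must lie strictly in (0, 1)", call. = FALSE)
  structure(list(fit = fit, variables = vars,
                 training_levels = factor_levels_of(d[vars])),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model: P(CBT | baseline covariates, service, year)\n")
  cat("  n =", length(stats::fitted(x$fit)),
      " mean score =", format(mean(stats::fitted(x$fit)), digits = 3), "\n")
  invisible(x)
}

#' @export
coef.propensity_model <- function(object, ...) stats::coef(object$fit)

#' Propensity scores for new or training records
#'
#' Deterministic fitted probabilities of receiving CBT, usable on both the
#' training sample and held-out records. Categorical levels unseen during
#' training are mapped to the training reference level with a warning rather
#' than dropping records.
#'
#' @param model a `propensity_model`.
#' @param records cohort records sharing the training schema (complete
#'   covariates).
#' @return Numeric vector of probabilities strictly in (0, 1).
#' @export
propensity_scores <- function(model, records) {
  stopifnot(inherits(model, "propensity_model"))
  require_columns(records, model$variables, "propensity_scores")
  if (anyNA(records[model$variables]))
    stop("propensity_scores: records contain missing covariates; impute first", call. = FALSE)
  newdata <- conform_levels(records[model$variables], model$training_levels)
  as.numeric(stats::predict(model$fit, newdata = newdata, type = "response"))
}

#' @export
predict.propensity_model <- function(object, newdata, ...) {
  propensity_scores(object, newdata)
}
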