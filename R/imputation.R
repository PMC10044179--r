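impute_init <- function(col) {
  if (is.numeric(col)) {
    if (all(is.na(col))) 0 else mean(col, na.rm = TRUE)
  } else {
    if (all(is.na(col))) levels(col)[1L] else as.character(stat_mode(col))
  }
}

fit_and_predict <- function(v, data, obs, n_trees, seed) {
  p <- ncol(data) - 1L
  # canonical forest defaults: p/3 candidate predictors for regression
  # targets, sqrt(p) for classification targets
  mtry <- if (is.numeric(data[[v]])) max(1L, floor(p / 3)) else
    max(1L, floor(sqrt(p)))
  rf <- ranger::ranger(
    dependent.variable.name = v,
    data = data[obs, , drop = FALSE],
    num.trees = n_trees,
    mtry = mtry,
    respect.unordered.factors = "order",
    num.threads = 1L,
    seed = seed
  )
  stats::predict(rf, data = data[!obs, , drop = FALSE],
                 num.threads = 1L)$predictions
}

#' Iterative random-forest imputation with error reporting
#'
#' Chained random-forest imputation for mixed-type baseline covariates.
#' Missing cells are initialised with the column mean (continuous) or mode
#' (categorical); columns are then cycled in order of increasing missingness,
#' each refitted as a forest of `n_trees` trees on the rows where it is
#' observed (service and year, when present, always enter as predictors), and
#' its missing cells re-predicted. Iteration stops when the column-wise
#' change in imputed values increases for both the continuous and the
#' categorical set (the values from the previous iteration are kept), or
#' after `max_iter` sweeps.
#'
#' Imputation error is estimated by mask-and-score: a random fraction
#' (`mask_fraction`) of observed cells in each imputable column is hidden,
#' imputed alongside the genuinely missing cells, scored, and then restored.
#' Continuous error is reported as NRMSE,
#' `sqrt(mean((imputed - true)^2) / var(true))` over masked cells (an
#' uninformative imputation tends to NRMSE 1); categorical error as PFC, the
#' proportion of falsely classified masked cells.
#'
#' Observed cells are never altered, and imputed categorical cells only ever
#' take levels observed in the data. Outcomes and treatment are not handled
#' here: records with missing outcomes are excluded upstream, never imputed.
#'
#' @param cohort cohort data frame (one partition; impute train and test
#'   separately).
#' @param variables columns eligible for imputation (baseline covariates
#'   present in the cohort by default).
#' @param n_trees trees per forest (default 500).
#' @param max_iter maximum sweeps over the columns (default 10).
#' @param seed integer seed controlling masking and the forests.
#' @param evaluate_error run the mask-and-score error estimate.
#' @param mask_fraction fraction of observed cells masked per column.
#' @return A list with `cohort` (completed data) and `report` (an
#'   `imputation_report`: global `nrmse` and `pfc`, `n_trees`, `iterations`,
#'   and a `per_variable` table).
#' @export
impute <- function(cohort, variables = intersect(baseline_covariates(), names(cohort)),
                   n_trees = 500L, max_iter = 10L, seed = NULL,
                   evaluate_error = TRUE, mask_fraction = 0.1) {
  require_columns(cohort, variables, "impute")
  if (!is.null(seed)) set.seed(seed)
  context <- intersect(c("service", "year"), names(cohort))
  work <- cohort[c(variables, context)]
  n <- nrow(work)

  # 0/1 indicator columns are imputed as two-level classification targets so
  # imputed cells only ever take observed values
  binary <- vapply(work[variables], function(col)
    is.numeric(col) && all(stats::na.omit(col) %in% c(0, 1)) && any(!is.na(col)),
    logical(1))
  for (v in variables[binary])
    work[[v]] <- factor(work[[v]], levels = c(0, 1))

  miss0 <- vapply(work[variables], is.na, logical(n))
  if (!is.matrix(miss0)) miss0 <- matrix(miss0, nrow = n, dimnames = list(NULL, variables))
  if (!any(miss0)) {
    report <- new_imputation_report(nrmse = 0, pfc = 0, n_trees = n_trees, iterations = 0L,
                                    per_variable = empty_per_variable(variables))
    return(list(cohort = cohort, report = report))
  }
  if (all(miss0))
    stop("imputation error: every imputable cell is missing", call. = FALSE)

  # mask a held-out fraction of observed cells for error scoring
  truth <- list()
  masked <- matrix(FALSE, n, length(variables), dimnames = list(NULL, variables))
  if (evaluate_error) {
    # score only the columns actually being imputed; fully observed columns
    # stay intact as clean predictors
    for (v in variables[colSums(miss0) > 0]) {
      obs_idx <- which(!miss0[, v])
      m <- floor(mask_fraction * length(obs_idx))
      if (m < 1L) next
      sel <- sort(sample(obs_idx, m))
      truth[[v]] <- work[[v]][sel]
      masked[sel, v] <- TRUE
      work[[v]][sel] <- NA
    }
  }

  miss <- vapply(work[variables], is.na, logical(n))
  if (!is.matrix(miss)) miss <- matrix(miss, nrow = n, dimnames = list(NULL, variables))
  if (all(miss)) stop("imputation error: every imputable cell is missing", call. = FALSE)

  is_cont <- vapply(work[variables], is.numeric, logical(1))
  for (v in variables) {
    fill <- impute_init(work[[v]])
    if (all(is.na(work[[v]])))
      warning("impute: column `", v, "` has no observed values; filled with a constant",
              call. = FALSE)
    work[[v]][miss[, v]] <- fill
  }

  to_impute <- variables[colSums(miss) > 0 & colSums(!miss) > 0]
  to_impute <- to_impute[order(colSums(miss)[to_impute])]

  prev_vals <- lapply(variables, function(v) work[[v]][miss[, v]])
  names(prev_vals) <- variables
  snapshot <- work
  prev_dc <- Inf; prev_df <- Inf
  iterations <- 0L
  fit_counter <- 0L

  for (iter in seq_len(max_iter)) {
    for (v in to_impute) {
      fit_counter <- fit_counter + 1L
      pred <- fit_and_predict(v, work, obs = !miss[, v], n_trees = n_trees,
                              seed = stage_seed(seed %||% 0L, 100L + fit_counter))
      work[[v]][miss[, v]] <- pred
    }
    cur_vals <- lapply(variables, function(v) work[[v]][miss[, v]])
    names(cur_vals) <- variables
    dc_num <- 0; dc_den <- 0; df_num <- 0; df_den <- 0
    for (v in to_impute) {
      if (is_cont[[v]]) {
        dc_num <- dc_num + sum((as.numeric(cur_vals[[v]]) - as.numeric(prev_vals[[v]]))^2)
        dc_den <- dc_den + sum(as.numeric(cur_vals[[v]])^2)
      } else {
        df_num <- df_num + sum(cur_vals[[v]] != prev_vals[[v]])
        df_den <- df_den + length(cur_vals[[v]])
      }
    }
    dc <- if (dc_den > 0) dc_num / dc_den else NA_real_
    df_ <- if (df_den > 0) df_num / df_den else NA_real_
    worse_cont <- is.na(dc) || dc >= prev_dc
    worse_cat <- is.na(df_) || df_ >= prev_df
    if (iter > 1L && worse_cont && worse_cat) {
      work <- snapshot # keep the previous, better sweep
      break
    }
    iterations <- iter
    snapshot <- work
    prev_vals <- cur_vals
    prev_dc <- if (!is.na(dc)) dc else prev_dc
    prev_df <- if (!is.na(df_)) df_ else prev_df
    if ((is.na(dc) || dc == 0) && (is.na(df_) || df_ == 0)) break
  }

  per_var <- empty_per_variable(variables)
  cont_err2 <- numeric(0); cont_truth <- numeric(0)
  cat_wrong <- 0L; cat_total <- 0L
  for (i in seq_along(variables)) {
    v <- variables[i]
    sel <- masked[, v]
    per_var$n_missing[i] <- sum(miss0[, v])
    per_var$n_masked[i] <- sum(sel)
    if (!any(sel)) next
    imp <- work[[v]][sel]; tru <- truth[[v]]
    if (is_cont[[v]]) {
      err2 <- (as.numeric(imp) - as.numeric(tru))^2
      vt <- stats::var(as.numeric(tru))
      per_var$nrmse[i] <- if (isTRUE(vt > 0)) sqrt(mean(err2) / vt) else sqrt(mean(err2))
      cont_err2 <- c(cont_err2, err2); cont_truth <- c(cont_truth, as.numeric(tru))
    } else {
      wrong <- sum(as.character(imp) != as.character(tru))
      per_var$pfc[i] <- wrong / length(tru)
      cat_wrong <- cat_wrong + wrong; cat_total <- cat_total + length(tru)
    }
  }
  gvar <- if (length(cont_truth) > 1L) stats::var(cont_truth) else NA_real_
  nrmse <- if (length(cont_err2)) {
    if (isTRUE(gvar > 0)) sqrt(mean(cont_err2) / gvar) else sqrt(mean(cont_err2))
  } else 0
  pfc <- if (cat_total > 0L) cat_wrong / cat_total else 0

  # restore masked observed cells to their true values
  for (v in names(truth)) work[[v]][masked[, v]] <- truth[[v]]

  completed <- cohort
  for (v in variables) {
    col <- work[[v]]
    if (binary[[v]]) col <- as.integer(as.character(col))
    if (!any(miss[, v])) col <- cohort[[v]] # untouched column keeps its type
    completed[[v]] <- col
  }

  report <- new_imputation_report(nrmse = nrmse, pfc = pfc, n_trees = n_trees,
                                  iterations = iterations, per_variable = per_var)
  list(cohort = completed, report = report)
}

empty_per_variable <- function(variables) {
  data.frame(variable = variables, n_missing = 0L, n_masked = 0L,
             nrmse = NA_real_, pfc = NA_real_, stringsAsFactors = FALSE)
}

new_imputation_report <- function(nrmse, pfc, n_trees, iterations, per_variable) {
  structure(list(nrmse = nrmse, pfc = pfc, n_trees = as.integer(n_trees),
                 iterations = as.integer(iterations), per_variable = per_variable),
            class = "imputation_report")
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("Random-forest imputation (", x$n_trees, " trees, ", x$iterations,
      " iteration(s))\n", sep = "")
  cat("  NRMSE (continuous): ", format(x$nrmse, digits = 3),
      "   PFC (categorical): ", format(x$pfc, digits = 3), "\n", sep = "")
  invisible(x)
}
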