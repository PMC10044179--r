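#' Factual and counterfactual predictions on held-out records
#'
#' Scores each record twice with the fitted interaction model: once under
#' CBT and once under CFD, all other inputs unchanged. The factual prediction
#' corresponds to the treatment the patient actually received; the other is
#' the counterfactual.
#'
#' @param fit fitted interaction `outcome_fit`.
#' @param records imputed test records with a `treatment` column; propensity
#'   scores via a `propensity` column or the `scores` argument.
#' @param scores optional propensity scores aligned with `records`.
#' @return Data frame with `patient_id`, `pred_cbt`, `pred_cfd`, `received`
#'   and `factual`.
#' @export
predict_counterfactuals <- function(fit, records, scores = NULL) {
  stopifnot(inherits(fit, "outcome_fit"))
  require_columns(records, c("treatment"), "predict_counterfactuals")
  pred_cbt <- predict(fit, records, treatment = "CBT", propensity = scores)
  pred_cfd <- predict(fit, records, treatment = "CFD", propensity = scores)
  received <- factor(as.character(records$treatment), levels = c("CFD", "CBT"))
  data.frame(
    patient_id = records$patient_id %||% sprintf("R%06d", seq_len(nrow(records))),
    pred_cbt = pred_cbt, pred_cfd = pred_cfd, received = received,
    factual = ifelse(received == "CBT", pred_cbt, pred_cfd),
    stringsAsFactors = FALSE
  )
}

#' Personalised Advantage Index
#'
#' The signed difference between the two counterfactual predictions,
#' `pai = pred_cfd - pred_cbt` in PHQ-9 points. Positive values favour CBT
#' (its predicted post-treatment score is lower); negative values favour
#' CFD; the magnitude is the predicted benefit of the favoured treatment.
#' The index is antisymmetric under swapping the treatment labels.
#'
#' Given two numeric vectors it returns the PAI values; given the prediction
#' table from [predict_counterfactuals()] it returns the table augmented with
#' `pai` and `indicated_optimal` (the treatment with the lower prediction, or
#' `"none"` on an exact tie).
#'
#' @param pred_cbt predicted outcome under CBT, or a prediction data frame.
#' @param pred_cfd predicted outcome under CFD (ignored in data-frame form).
#' @return Numeric vector, or augmented data frame.
#' @export
compute_pai <- function(pred_cbt, pred_cfd = NULL) {
  if (is.data.frame(pred_cbt)) {
    preds <- pred_cbt
    require_columns(preds, c("pred_cbt", "pred_cfd"), "compute_pai")
    preds$pai <- preds$pred_cfd - preds$pred_cbt
    preds$indicated_optimal <- factor(
      ifelse(preds$pai > 0, "CBT", ifelse(preds$pai < 0, "CFD", "none")),
      levels = c("CFD", "CBT", "none"))
    return(preds)
  }
  pred_cfd - pred_cbt
}

#' Classify patients into allocation groups by PAI quartiles
#'
#' Patients with a high PAI -- beyond the first or third quartile of the
#' test-set PAI distribution (linear-interpolation sample quantiles) -- are
#' the half of the sample for whom the model indicates a preference. Within
#' this high-PAI set, patients who received their model-indicated optimal
#' treatment form the `optimal` group and the rest the `suboptimal` group;
#' patients between the quartiles (boundary ties included) form the
#' `no_preference` group, as do exact PAI ties of zero.
#'
#' @param results data frame with `pai`, `indicated_optimal` and `received`
#'   (from [compute_pai()]); at least 4 records.
#' @param lower_q,upper_q quantile bounds defining the high-PAI set.
#' @return The data frame with a `group` factor
#'   (optimal/suboptimal/no_preference) and attribute `quartiles`.
#' @export
classify_allocation <- function(results, lower_q = 0.25, upper_q = 0.75) {
  require_columns(results, c("pai", "indicated_optimal", "received"),
                  "classify_allocation")
  if (nrow(results) < 4L)
    stop("classify_allocation: at least 4 records are needed for quartiles",
         call. = FALSE)
  q <- stats::quantile(results$pai, c(lower_q, upper_q), type = 7, names = FALSE)
  high <- results$pai < q[1L] | results$pai > q[2L]
  grp <- ifelse(!high | results$indicated_optimal == "none", "no_preference",
                ifelse(as.character(results$received) ==
                         as.character(results$indicated_optimal),
                       "optimal", "suboptimal"))
  results$group <- factor(grp, levels = c("optimal", "suboptimal", "no_preference"))
  attr(results, "quartiles") <- q
  results
}

#' Summarise a classified PAI table
#'
#' @param results classified PAI results from [classify_allocation()].
#' @return List with the median PAI and interquartile range, group sizes, the
#'   high-PAI set size, the fraction of high-PAI patients who received their
#'   indicated optimal treatment, and that fraction split by indicated arm.
#' @export
summarize_allocation <- function(results) {
  require_columns(results, c("pai", "group", "received", "indicated_optimal"),
                  "summarize_allocation")
  high <- results[results$group != "no_preference", , drop = FALSE]
  frac_arm <- function(arm) {
    sel <- high[high$indicated_optimal == arm, , drop = FALSE]
    if (!nrow(sel)) return(NA_real_)
    mean(as.character(sel$received) == arm)
  }
  list(
    n = nrow(results),
    median_pai = stats::median(results$pai),
    iqr_pai = unname(stats::quantile(results$pai, c(0.25, 0.75))),
    group_sizes = table(results$group),
    n_high_pai = nrow(high),
    prop_received_optimal = if (nrow(high)) mean(high$group == "optimal") else NA_real_,
    prop_received_cbt_when_indicated = frac_arm("CBT"),
    prop_received_cfd_when_indicated = frac_arm("CFD")
  )
}

#' Patients whose PAI reaches the percent-MCID threshold
#'
#' Flags patients whose predicted between-treatment difference is at least as
#' large as the percent minimal clinically important difference, a 20%
#' reduction from their baseline PHQ-9 (`|pai| >= 0.2 * baseline`,
#' boundary inclusive).
#'
#' @param pai PAI values.
#' @param phq9_baseline baseline PHQ-9 scores.
#' @param fraction MCID fraction of baseline (default 0.2).
#' @return List with per-record `flag`, and aggregate `count` and `fraction`.
#' @export
mcid_exceedance <- function(pai, phq9_baseline, fraction = 0.2) {
  stopifnot(length(pai) == length(phq9_baseline))
  flag <- abs(pai) >= fraction * phq9_baseline
  list(flag = flag, count = sum(flag), fraction = mean(flag))
}
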