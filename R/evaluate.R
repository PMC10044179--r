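validate_phq9 <- function(pre, post) {
  assert_scores(pre, "pre", 0, 27)
  assert_scores(post, "post", 0, 27)
  stopifnot(length(pre) == length(post))
  invisible(NULL)
}

#' Recovery (depression-only adaptation)
#'
#' The PHQ-9 clinical cut-off for caseness is a score of 10 or more. A
#' patient above the cut-off at baseline has recovered when their
#' post-treatment score falls below it (`post < 10`). This is the
#' depression-only adaptation of the IAPT recovery definition; the combined
#' depression-plus-anxiety definition is not implemented.
#'
#' @param pre,post baseline and post-treatment PHQ-9 scores (0-27).
#' @return Logical vector.
#' @export
recovery <- function(pre, post) {
  validate_phq9(pre, post)
  post < 10
}

#' Reliable change classification
#'
#' Pre-post change exceeding the PHQ-9 measurement error, with a reliable
#' change threshold of 6 points (boundary inclusive): `improved` when
#' `pre - post >= 6`, `deteriorated` when `post - pre >= 6`, otherwise
#' `none`. Improvement and deterioration are mutually exclusive.
#'
#' @param pre,post baseline and post-treatment PHQ-9 scores (0-27).
#' @param threshold reliable change threshold (default 6 points).
#' @return Character vector in `{improved, none, deteriorated}`.
#' @export
reliable_change <- function(pre, post, threshold = 6) {
  validate_phq9(pre, post)
  ifelse(pre - post >= threshold, "improved",
         ifelse(post - pre >= threshold, "deteriorated", "none"))
}

#' Reliable recovery
#'
#' A change that exceeds measurement error together with scores falling below
#' the clinical cut-off: reliable improvement and recovery combined.
#'
#' @inheritParams reliable_change
#' @return Logical vector.
#' @export
reliable_recovery <- function(pre, post, threshold = 6) {
  reliable_change(pre, post, threshold) == "improved" & recovery(pre, post)
}

#' Percent minimal clinically important difference
#'
#' A reduction of at least 20% from the baseline PHQ-9 score
#' (`(pre - post) / pre >= 0.20`, boundary inclusive).
#'
#' @param pre,post baseline and post-treatment PHQ-9 scores; `pre` must be
#'   positive.
#' @param fraction MCID fraction (default 0.2).
#' @return Logical vector.
#' @export
percent_mcid <- function(pre, post, fraction = 0.2) {
  validate_phq9(pre, post)
  if (any(pre <= 0))
    stop("percent_mcid: baseline scores must be positive", call. = FALSE)
  (pre - post) / pre >= fraction
}

#' Default absolute-MCID band table
#'
#' Severity-band-specific absolute PHQ-9 point thresholds: 3 points for
#' baseline scores 10-14 and 5 points for 15-27. These defaults are
#' package-chosen, clinically plausible values covering the eligible baseline
#' range; published band tables vary, so supply your own where one is
#' mandated.
#'
#' @return Data frame with columns `lower`, `upper`, `threshold`.
#' @export
default_mcid_table <- function() {
  data.frame(lower = c(10, 15), upper = c(14, 27), threshold = c(3, 5))
}

#' Absolute minimal clinically important difference
#'
#' The pre-post improvement must reach the point threshold of the patient's
#' baseline severity band, `pre - post >= threshold[band(pre)]`.
#'
#' @param pre,post baseline and post-treatment PHQ-9 scores.
#' @param table band table (`lower`, `upper`, `threshold`); bands must cover
#'   every observed baseline score.
#' @return Logical vector.
#' @export
absolute_mcid <- function(pre, post, table = default_mcid_table()) {
  validate_phq9(pre, post)
  require_columns(table, c("lower", "upper", "threshold"), "absolute_mcid")
  band <- vapply(pre, function(p) {
    hit <- which(table$lower <= p & p <= table$upper)
    if (!length(hit)) NA_integer_ else hit[1L]
  }, integer(1))
  if (anyNA(band))
    stop("configuration error: MCID table does not cover baseline score(s): ",
         paste(unique(pre[is.na(band)]), collapse = ", "), call. = FALSE)
  (pre - post) >= table$threshold[band]
}

#' Odds ratio from two proportions
#'
#' Closed-form cross-product odds ratio
#' `(p1 / (1 - p1)) / (p2 / (1 - p2))`; the verification oracle for
#' [compare_groups_binary()], to which simple logistic regression is
#' algebraically identical.
#'
#' @param p1,p2 proportions strictly inside (0, 1).
#' @return Scalar odds ratio.
#' @export
odds_ratio_from_proportions <- function(p1, p2) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1))
    stop("odds_ratio_from_proportions: proportions must lie strictly in (0, 1)",
         call. = FALSE)
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' Compare a binary outcome between allocation groups
#'
#' Logistic regression of the outcome flag on a group indicator
#' (optimal vs suboptimal). The fitted odds ratio equals the 2x2
#' cross-product odds ratio to numerical tolerance. A zero cell is flagged in
#' the result -- no continuity correction is applied silently.
#'
#' @param optimal,suboptimal logical outcome flags for the two groups.
#' @return List with `or`, Wald `ci_lower`/`ci_upper`, `p_value`, per-group
#'   `proportions` and sizes, and `zero_cell`.
#' @export
compare_groups_binary <- function(optimal, suboptimal) {
  optimal <- as.logical(optimal); suboptimal <- as.logical(suboptimal)
  if (!length(optimal) || !length(suboptimal))
    stop("compare_groups_binary: both groups must be non-empty", call. = FALSE)
  flags <- c(optimal, suboptimal)
  if (!any(flags) || all(flags))
    stop("compare_groups_binary: need at least one event and one non-event overall",
         call. = FALSE)
  grp <- factor(rep(c("optimal", "suboptimal"), c(length(optimal), length(suboptimal))),
                levels = c("suboptimal", "optimal"))
  zero_cell <- any(table(grp, flags) == 0)
  if (zero_cell)
    warning("compare_groups_binary: a zero cell was found; the odds ratio is degenerate ",
            "and no continuity correction has been applied", call. = FALSE)
  fit <- suppressWarnings(stats::glm(flags ~ grp, family = stats::binomial()))
  b <- summary(fit)$coefficients["grpoptimal", ]
  list(or = exp(b[["Estimate"]]),
       ci_lower = exp(b[["Estimate"]] - 1.96 * b[["Std. Error"]]),
       ci_upper = exp(b[["Estimate"]] + 1.96 * b[["Std. Error"]]),
       p_value = b[["Pr(>|z|)"]],
       proportions = c(optimal = mean(optimal), suboptimal = mean(suboptimal)),
       n = c(optimal = length(optimal), suboptimal = length(suboptimal)),
       zero_cell = zero_cell)
}

#' Compare mean post-treatment scores between allocation groups
#'
#' Simple linear regression of the post-treatment PHQ-9 on a group indicator;
#' the coefficient equals the difference in group means (optimal minus
#' suboptimal) exactly.
#'
#' @param optimal,suboptimal post-treatment scores in the two groups.
#' @return List with `difference`, t-based `ci_lower`/`ci_upper`, `p_value`
#'   and per-group means/SDs/sizes. With a group of size 1 the CI and p-value
#'   are `NA` with a warning.
#' @export
compare_groups_continuous <- function(optimal, suboptimal) {
  if (!length(optimal) || !length(suboptimal))
    stop("compare_groups_continuous: both groups must be non-empty", call. = FALSE)
  y <- c(optimal, suboptimal)
  grp <- factor(rep(c("optimal", "suboptimal"), c(length(optimal), length(suboptimal))),
                levels = c("suboptimal", "optimal"))
  est <- mean(optimal) - mean(suboptimal)
  if (length(optimal) < 2L || length(suboptimal) < 2L) {
    warning("compare_groups_continuous: a group has fewer than 2 records; ",
            "point estimate only", call. = FALSE)
    ci <- c(NA_real_, NA_real_); p <- NA_real_
  } else {
    fit <- stats::lm(y ~ grp)
    b <- summary(fit)$coefficients["grpoptimal", ]
    tq <- stats::qt(0.975, df = fit$df.residual)
    ci <- b[["Estimate"]] + c(-1, 1) * tq * b[["Std. Error"]]
    p <- b[["Pr(>|t|)"]]
    est <- b[["Estimate"]]
  }
  list(difference = est, ci_lower = ci[1L], ci_upper = ci[2L], p_value = p,
       means = c(optimal = mean(optimal), suboptimal = mean(suboptimal)),
       sds = c(optimal = stats::sd(optimal), suboptimal = stats::sd(suboptimal)),
       n = c(optimal = length(optimal), suboptimal = length(suboptimal)))
}

#' Evaluate a data-driven allocation in the held-out sample
#'
#' Applies the clinically-thresholded outcome definitions (recovery, reliable
#' change, reliable recovery, percent MCID, absolute MCID) and compares
#' patients who received their model-indicated optimal treatment against
#' those who received their suboptimal treatment: proportions and odds ratio
#' per metric, and mean post-treatment PHQ-9 difference. Patients with no
#' indicated preference are excluded from the contrasts.
#'
#' @param results classified PAI table joined with observed scores: columns
#'   `group`, `phq9_baseline`, `phq9_post`.
#' @param mcid_table absolute-MCID band table, or `NULL` to skip that metric
#'   with a warning.
#' @return An `evaluation_report`: `metrics` data frame, `mean_difference`
#'   list and `group_summary` data frame.
#' @export
evaluate_allocation <- function(results, mcid_table = default_mcid_table()) {
  require_columns(results, c("group", "phq9_baseline", "phq9_post"),
                  "evaluate_allocation")
  opt <- results[results$group == "optimal", , drop = FALSE]
  sub <- results[results$group == "suboptimal", , drop = FALSE]
  if (!nrow(opt) || !nrow(sub))
    stop("evaluate_allocation: both the optimal and suboptimal groups must be non-empty",
         call. = FALSE)
  metric_flags <- function(df) {
    out <- list(
      recovery = recovery(df$phq9_baseline, df$phq9_post),
      reliable_change = reliable_change(df$phq9_baseline, df$phq9_post) == "improved",
      reliable_recovery = reliable_recovery(df$phq9_baseline, df$phq9_post),
      percent_mcid = percent_mcid(df$phq9_baseline, df$phq9_post)
    )
    if (!is.null(mcid_table))
      out$absolute_mcid <- absolute_mcid(df$phq9_baseline, df$phq9_post, mcid_table)
    out
  }
  if (is.null(mcid_table))
    warning("evaluate_allocation: no MCID band table supplied; the absolute-MCID ",
            "metric is skipped", call. = FALSE)
  fo <- metric_flags(opt); fs <- metric_flags(sub)
  rows <- lapply(names(fo), function(m) {
    cmp <- tryCatch(compare_groups_binary(fo[[m]], fs[[m]]),
                    error = function(e) NULL)
    data.frame(metric = m,
               n_optimal = length(fo[[m]]), prop_optimal = mean(fo[[m]]),
               n_suboptimal = length(fs[[m]]), prop_suboptimal = mean(fs[[m]]),
               odds_ratio = cmp$or %||% NA_real_,
               ci_lower = cmp$ci_lower %||% NA_real_,
               ci_upper = cmp$ci_upper %||% NA_real_,
               p_value = cmp$p_value %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  md <- compare_groups_continuous(opt$phq9_post, sub$phq9_post)
  group_summary <- data.frame(
    group = c("optimal", "suboptimal"),
    n = c(nrow(opt), nrow(sub)),
    mean_phq9_post = c(mean(opt$phq9_post), mean(sub$phq9_post)),
    sd_phq9_post = c(stats::sd(opt$phq9_post), stats::sd(sub$phq9_post)),
    stringsAsFactors = FALSE
  )
  structure(list(metrics = metrics, mean_difference = md,
                 group_summary = group_summary),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation of data-driven treatment allocation (held-out sample)\n\n")
  gs <- x$group_summary
  for (i in seq_len(nrow(gs)))
    cat(sprintf("  %-11s n = %4d  post-treatment PHQ-9 %.2f (s.d. %.2f)\n",
                gs$group[i], gs$n[i], gs$mean_phq9_post[i], gs$sd_phq9_post[i]))
  md <- x$mean_difference
  cat(sprintf("\n  Mean difference (optimal - suboptimal): %.2f (95%% CI %.2f to %.2f, p = %.3g)\n\n",
              md$difference, md$ci_lower, md$ci_upper, md$p_value))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-18s %5.1f%% vs %5.1f%%   OR %.2f (95%% CI %.2f to %.2f, p = %.3g)\n",
                m$metric[i], 100 * m$prop_optimal[i], 100 * m$prop_suboptimal[i],
                m$odds_ratio[i], m$ci_lower[i], m$ci_upper[i], m$p_value[i]))
  invisible(x)
}
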