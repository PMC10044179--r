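#' Apply the cohort selection filters
#'
#' Reproduces the routine-care cohort definition for the CBT-vs-CFD
#' comparison, applying five rules in a fixed order and logging attrition per
#' rule:
#' \enumerate{
#'   \item baseline PHQ-9 at or above the clinical threshold of 10 (records
#'     with a missing baseline score cannot meet the threshold and are
#'     removed here);
#'   \item the majority high-intensity treatment (most sessions among
#'     `n_cbt_sessions`, `n_cfd_sessions`, `n_other_hit_sessions`) is CBT or
#'     CFD, with exact ties between two arms excluded; the `treatment` label
#'     is (re)derived from the majority arm;
#'   \item at least two attended appointments (a pre and a post measure);
#'   \item only the most recent referral per patient (highest
#'     `referral_number`, ties broken by `year`);
#'   \item a non-missing post-treatment PHQ-9 at the last attended
#'     appointment.
#' }
#' The rule order affects per-rule attrition counts only, not the final
#' cohort. Applying the filters twice gives the same cohort as applying them
#' once.
#'
#' @param records cohort data frame.
#' @return A list with `cohort` (the retained records, with `treatment` set
#'   to the majority arm) and `log` (a `filter_log` data frame with columns
#'   `rule`, `n_in`, `n_removed`, `n_out`).
#' @export
apply_selection_filters <- function(records) {
  required <- c("patient_id", "phq9_baseline", "n_cbt_sessions", "n_cfd_sessions",
                "n_other_hit_sessions", "n_appointments", "referral_number",
                "phq9_post")
  require_columns(records, required, "apply_selection_filters")

  log_rows <- list()
  keep_step <- function(df, keep, rule) {
    keep[is.na(keep)] <- FALSE
    log_rows[[rule]] <<- data.frame(rule = rule, n_in = nrow(df),
                                    n_removed = sum(!keep), n_out = sum(keep))
    df[keep, , drop = FALSE]
  }

  out <- keep_step(records, records$phq9_baseline >= 10, "phq9_baseline_ge_10")

  sessions <- cbind(CBT = out$n_cbt_sessions, CFD = out$n_cfd_sessions,
                    other = out$n_other_hit_sessions)
  if (nrow(out)) {
    top <- apply(sessions, 1L, max)
    tie <- rowSums(sessions == top) > 1L
    majority <- colnames(sessions)[apply(sessions, 1L, which.max)]
    keep <- !tie & majority %in% c("CBT", "CFD")
    out$treatment <- factor(majority, levels = c("CFD", "CBT"))
    out <- keep_step(out, keep, "majority_hit_cbt_or_cfd")
  } else {
    out$treatment <- factor(character(0), levels = c("CFD", "CBT"))
    out <- keep_step(out, logical(0), "majority_hit_cbt_or_cfd")
  }

  out <- keep_step(out, out$n_appointments >= 2, "min_two_appointments")

  if (nrow(out)) {
    ord <- order(out$referral_number, if (!is.null(out$year)) out$year else out$referral_number)
    ranked <- out[ord, , drop = FALSE]
    latest_row <- !duplicated(ranked$patient_id, fromLast = TRUE)
    keep <- rep(FALSE, nrow(out)); keep[ord] <- latest_row
  } else keep <- logical(0)
  out <- keep_step(out, keep, "most_recent_referral")

  out <- keep_step(out, !is.na(out$phq9_post), "outcome_present")

  log_df <- do.call(rbind, log_rows)
  rownames(log_df) <- NULL
  class(log_df) <- c("filter_log", "data.frame")
  list(cohort = out, log = log_df)
}

#' @export
print.filter_log <- function(x, ...) {
  cat("Cohort selection attrition (", x$n_in[1L], " -> ", x$n_out[nrow(x)], " records)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Randomly partition a cohort into training and test samples
#'
#' Simple random split at a train:test ratio (default 3:1), performed before
#' any analysis so the test sample stays a held-out validation set. The
#' training size is `round(n * ratio)`, so sizes are within one record of the
#' exact ratio; e.g. n = 7 at ratio 0.75 gives a 5/2 split.
#'
#' @param cohort non-empty cohort data frame.
#' @param ratio train fraction in (0, 1); default 0.75.
#' @param seed integer seed.
#' @return Factor of partition labels (`"train"`/`"test"`), one per record.
#' @export
split_train_test <- function(cohort, ratio = 0.75, seed = NULL) {
  n <- nrow(cohort)
  if (n < 1L) stop("split_train_test: cohort is empty", call. = FALSE)
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio <= 0 || ratio >= 1)
    stop("configuration error: `ratio` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_train <- round(n * ratio)
  labels <- rep("test", n)
  labels[sample.int(n, n_train)] <- "train"
  factor(labels, levels = c("train", "test"))
}

smd_binary <- function(p1, p2) {
  denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  num <- abs(p1 - p2)
  if (denom == 0) return(if (num < 1e-12) 0 else Inf)
  num / denom
}

#' Standardised mean difference between two groups
#'
#' Covariate-balance statistic. For a continuous variable,
#' `|mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)`; for a binary variable (two
#' observed values, or a two-level factor), `|p1 - p2| /
#' sqrt((p1(1-p1) + p2(1-p2)) / 2)`; for a categorical variable with more
#' than two levels, the maximum over one-vs-rest binary SMDs (a conservative
#' reduction against a balance threshold). Zero pooled variance yields 0 when
#' the group means agree and `Inf` otherwise. Missing values are dropped
#' within each group. The statistic is symmetric in its two arguments.
#'
#' @param x,y the variable's values in the two groups.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
compute_smd <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("compute_smd: both groups must be non-empty", call. = FALSE)
  if (is.character(x) || is.character(y) || is.logical(x) || is.logical(y)) {
    x <- factor(x); y <- factor(y)
  }
  if (is.factor(x) || is.factor(y)) {
    levs <- union(levels(factor(x)), levels(factor(y)))
    if (length(levs) <= 2L) {
      target <- levs[length(levs)]
      return(smd_binary(mean(x == target), mean(y == target)))
    }
    return(max(vapply(levs, function(l) smd_binary(mean(x == l), mean(y == l)),
                      numeric(1))))
  }
  vals <- unique(c(x, y))
  if (all(vals %in% c(0, 1)))
    return(smd_binary(mean(x), mean(y)))
  denom <- sqrt((stats::var(x) + stats::var(y)) / 2)
  if (is.na(denom)) denom <- 0
  num <- abs(mean(x) - mean(y))
  if (denom == 0) return(if (num < 1e-12) 0 else Inf)
  num / denom
}

default_balance_variables <- function(cohort) {
  intersect(c(baseline_covariates(), "service", "year", "n_appointments", "treatment"),
            names(cohort))
}

#' Check covariate balance of a train/test partition
#'
#' Computes the SMD between the training and test samples for every modelled
#' variable (baseline covariates plus service, referral year, appointments
#' and treatment by default) and compares the largest against a conservative
#' balance threshold (default 0.1).
#'
#' @param cohort cohort data frame.
#' @param partition factor of `"train"`/`"test"` labels from
#'   [split_train_test()].
#' @param variables variables to assess.
#' @param threshold balance threshold on each |SMD|.
#' @return A `balance_report`: data frame of per-variable SMDs with
#'   attributes `max_smd`, `threshold` and `pass`.
#' @export
check_balance <- function(cohort, partition, variables = default_balance_variables(cohort),
                          threshold = 0.1) {
  stopifnot(length(partition) == nrow(cohort))
  a <- cohort[partition == "train", , drop = FALSE]
  b <- cohort[partition == "test", , drop = FALSE]
  smds <- vapply(variables, function(v) compute_smd(a[[v]], b[[v]]), numeric(1))
  rep <- data.frame(variable = variables, smd = unname(smds), stringsAsFactors = FALSE)
  attr(rep, "max_smd") <- max(smds)
  attr(rep, "threshold") <- threshold
  attr(rep, "pass") <- all(smds < threshold)
  class(rep) <- c("balance_report", "data.frame")
  rep
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Train/test covariate balance: max |SMD| =",
      format(attr(x, "max_smd"), digits = 3),
      if (attr(x, "pass")) "(balanced," else "(IMBALANCED,",
      "threshold", attr(x, "threshold"), ")\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
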