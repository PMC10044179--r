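#' Write a cohort to CSV
#'
#' Plain-text round-trip: factors are written as their labels and restored by
#' [read_cohort()] against the canonical level sets.
#'
#' @param cohort cohort data frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Restores the canonical factor levels for the categorical columns
#' (appending, with a warning, any values outside the canonical sets) and a
#' `CFD`-referenced treatment factor.
#'
#' @param path CSV file written by [write_cohort()] or matching its header.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lev <- cohort_levels(n_services = 99L)
  lev$service <- NULL
  for (v in names(lev)) {
    if (is.null(df[[v]])) next
    extra <- setdiff(unique(stats::na.omit(df[[v]])), lev[[v]])
    if (length(extra))
      warning("read_cohort: non-canonical level(s) in `", v, "`: ",
              paste(extra, collapse = ", "), call. = FALSE)
    df[[v]] <- factor(df[[v]], levels = c(lev[[v]], extra))
  }
  if (!is.null(df$service)) df$service <- factor(df$service)
  df
}
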