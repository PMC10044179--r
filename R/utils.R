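`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Deterministic counter scheme: every stochastic stage of the pipeline draws
#' its own seed from the master seed and a stage counter, so that reruns with
#' the same master seed are bit-identical and stages remain independent.
#'
#' @param master integer master seed.
#' @param stage non-negative integer stage counter.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, length(stage) == 1L, is.finite(master), is.finite(stage))
  as.integer((as.double(master) + 1009 * as.double(stage)) %% 2147483646)
}

# most frequent value; for factors returns a level, ties broken by level order
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NULL)
  tab <- sort(table(x), decreasing = TRUE)
  val <- names(tab)[1L]
  if (is.factor(x)) factor(val, levels = levels(x)) else
    if (is.numeric(x)) as.numeric(val) else val
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stop("`", name, "` must be TRUE or FALSE", call. = FALSE)
  invisible(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop("`", name, "` must be a number in [", lower, ", ", upper, "]", call. = FALSE)
  invisible(x)
}

# validates instrument scores, vectorised; NA allowed when na_ok
assert_scores <- function(x, name, lower, upper, na_ok = FALSE) {
  bad <- if (na_ok) !is.na(x) & (x < lower | x > upper) else is.na(x) | x < lower | x > upper
  if (any(bad))
    stop("`", name, "` contains values outside [", lower, ", ", upper, "]", call. = FALSE)
  invisible(x)
}

require_columns <- function(df, cols, where) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(where, ": required field(s) missing from records: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  invisible(df)
}
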