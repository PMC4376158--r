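# Observer-reliability analysis: single-measure intraclass correlation
# coefficients from the two-way items x raters ANOVA layout, plus median
# observer differences. Intra-observer reliability uses the two-way mixed
# consistency form, inter-observer the two-way random absolute-agreement
# form (Shrout-Fleiss single measures); all forms are selectable.

.validate_ratings <- function(table) {
  table <- as.matrix(table)
  if (!is.numeric(table))
    stop("ratings table must be numeric", call. = FALSE)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("ratings table needs at least 2 items and 2 rating columns", call. = FALSE)
  if (any(!is.finite(table)))
    stop("ratings table must be complete (all values finite)", call. = FALSE)
  if (is.null(colnames(table)))
    colnames(table) <- paste0("R", seq_len(ncol(table)))
  if (anyDuplicated(colnames(table)))
    stop("rating column labels must be unique", call. = FALSE)
  table
}

#' Intraclass correlation coefficient (single measures)
#'
#' Computes the single-measure ICC for an items x raters table from the
#' two-way ANOVA mean squares. Models: `"oneway"` (raters nested in items),
#' `"twoway_random_absolute"` (absolute agreement, raters a random sample)
#' and `"twoway_mixed_consistency"` (consistency, raters fixed). Negative
#' estimates are returned as computed and flagged, never truncated.
#'
#' @param table Numeric matrix, items in rows, rating columns (raters or
#'   sessions) in columns; complete, >= 2 x 2.
#' @param model ICC model (see Details).
#' @param conf_level Confidence level for the F-based two-sided interval.
#' @return An object of class `uka_icc`: `value`, `model`,
#'   `variance_components` (item, rater, residual), `n_items`, `n_raters`,
#'   `negative_estimate`, `ci_lower`, `ci_upper`, `grade`.
#' @examples
#' m <- cbind(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8))
#' icc(m, "twoway_mixed_consistency")$value
#' @export
icc <- function(table,
                model = c("oneway", "twoway_random_absolute",
                          "twoway_mixed_consistency"),
                conf_level = 0.95) {
  model <- match.arg(model)
  x <- .validate_ratings(table)
  n <- nrow(x); k <- ncol(x)
  if (stats::var(as.vector(x)) == 0)
    stop("all ratings identical: total variance is zero, ICC undefined",
         call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)                  # between items
  msc <- n * sum((col_m - grand)^2) / (k - 1)                  # between raters
  mse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  msw <- sum((x - row_m)^2) / (n * (k - 1))                    # within items

  value <- switch(model,
    oneway = (msr - msw) / (msr + (k - 1) * msw),
    twoway_random_absolute =
      (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    twoway_mixed_consistency = (msr - mse) / (msr + (k - 1) * mse))

  ci <- .icc_ci(model, value, msr, msc, mse, msw, n, k, conf_level)
  vc <- if (model == "oneway")
    c(item = (msr - msw) / k, rater = NA_real_, residual = msw)
  else
    c(item = (msr - mse) / k, rater = (msc - mse) / n, residual = mse)

  structure(list(value = value, model = model, variance_components = vc,
                 n_items = n, n_raters = k,
                 negative_estimate = is.finite(value) && value < 0,
                 ci_lower = ci[1], ci_upper = ci[2],
                 grade = icc_grade(value)),
            class = "uka_icc")
}

# F-based two-sided CI (Shrout-Fleiss); NA when mean squares degenerate.
.icc_ci <- function(model, value, msr, msc, mse, msw, n, k, conf_level) {
  alpha <- 1 - conf_level
  out <- c(NA_real_, NA_real_)
  if (model == "oneway") {
    if (msw <= 0) return(out)
    f <- msr / msw
    fl <- f / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    out <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else if (model == "twoway_mixed_consistency") {
    if (mse <= 0) return(out)
    f <- msr / mse
    fl <- f / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    out <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    if (mse <= 0 || !is.finite(value) || value >= 1) return(out)
    a <- (k * value) / (n * (1 - value))
    b <- 1 + (k * value * (n - 1)) / (n * (1 - value))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    if (!is.finite(v) || v <= 0) return(out)
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    out <- c(lower, upper)
  }
  out
}

#' Grade an ICC value on the conventional reliability bands
#'
#' Values of 0.81-1 are graded "very good", 0.61-0.80 "good", anything
#' lower "below good".
#'
#' @param value ICC estimate.
#' @return Character grade.
#' @export
icc_grade <- function(value) {
  if (!is.finite(value)) return(NA_character_)
  if (value >= 0.81) "very good" else if (value >= 0.61) "good" else "below good"
}

#' @export
print.uka_icc <- function(x, ...) {
  cat(sprintf("<ICC %s, single measures>\n", x$model))
  cat(sprintf("  value: %.4f (%s)%s\n", x$value, x$grade,
              if (isTRUE(x$negative_estimate)) "  [negative estimate]" else ""))
  if (is.finite(x$ci_lower))
    cat(sprintf("  95%% CI: [%.4f, %.4f]\n", x$ci_lower, x$ci_upper))
  cat(sprintf("  items: %d, rating columns: %d\n", x$n_items, x$n_raters))
  invisible(x)
}

#' Intra-observer (test-retest) reliability
#'
#' ICC of one observer's two reading sessions, two-way mixed consistency
#' model with single measures: systematic between-session shifts do not
#' count against reliability.
#'
#' @param readings Numeric matrix: items in rows, exactly the observer's
#'   two session columns.
#' @param observer Optional observer label recorded on the result.
#' @return A `uka_icc` with an `observer` field.
#' @export
intra_observer <- function(readings, observer = NULL) {
  readings <- .validate_ratings(readings)
  if (ncol(readings) != 2L)
    stop("intra-observer reliability needs exactly two session columns",
         call. = FALSE)
  res <- icc(readings, "twoway_mixed_consistency")
  res$observer <- observer
  res
}

#' Inter-observer reliability
#'
#' ICC across observers, two-way random absolute-agreement model with
#' single measures: systematic between-observer shifts do count against
#' reliability. Column names must be `observer:session`; the session policy
#' selects one column per observer (`"first_session"`) or averages each
#' observer's sessions (`"mean_of_sessions"`).
#'
#' @param readings Numeric matrix, items x (observer, session) columns with
#'   `observer:session` column names.
#' @param session_policy `"first_session"` or `"mean_of_sessions"`.
#' @return A `uka_icc`.
#' @export
inter_observer <- function(readings,
                           session_policy = c("first_session",
                                              "mean_of_sessions")) {
  session_policy <- match.arg(session_policy)
  readings <- .validate_ratings(readings)
  parts <- strsplit(colnames(readings), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("inter_observer column names must have the form 'observer:session'",
         call. = FALSE)
  observer <- vapply(parts, `[`, "", 1L)
  session <- vapply(parts, `[`, "", 2L)
  obs_levels <- unique(observer)
  if (length(obs_levels) < 2L)
    stop("inter-observer reliability needs at least two observers", call. = FALSE)
  per_obs <- vapply(obs_levels, function(o) {
    cols <- which(observer == o)
    if (session_policy == "first_session")
      readings[, cols[order(session[cols])][1L]]
    else
      rowMeans(readings[, cols, drop = FALSE])
  }, numeric(nrow(readings)))
  colnames(per_obs) <- obs_levels
  icc(per_obs, "twoway_random_absolute")
}

#' Median signed and absolute paired differences
#'
#' For paired readings `a` and `b` (same items, same order), the median of
#' `a - b` and the median of `|a - b|`, in the units of the input. Medians
#' of even-length vectors are the midpoint of the two central order
#' statistics.
#'
#' @param a,b Equal-length numeric vectors of paired readings.
#' @return List with `median_signed` and `median_absolute`.
#' @export
median_difference <- function(a, b) {
  if (length(a) != length(b))
    stop("paired readings must have equal length", call. = FALSE)
  if (length(a) < 1L)
    stop("paired readings must be non-empty", call. = FALSE)
  d <- a - b
  list(median_signed = stats::median(d), median_absolute = stats::median(abs(d)))
}

#' Reliability report from tidy observer ratings
#'
#' Takes tidy ratings (`item`, `observer`, `session`, `variable`, `value`)
#' and, per variable, computes each observer's intra-observer ICC and the
#' inter-observer ICC, mirroring a per-region/per-angle reliability table.
#'
#' @param ratings Data.frame with columns `item`, `observer`, `session`,
#'   `variable`, `value`.
#' @param session_policy Passed to [inter_observer()].
#' @return Data.frame: one row per (variable, observer) intra result plus
#'   one inter row per variable, with columns `variable`, `measure`,
#'   `observer`, `model`, `icc`, `grade`.
#' @export
reliability_report <- function(ratings,
                               session_policy = c("first_session",
                                                  "mean_of_sessions")) {
  session_policy <- match.arg(session_policy)
  needed <- c("item", "observer", "session", "variable", "value")
  missing <- setdiff(needed, names(ratings))
  if (length(missing))
    stop(sprintf("ratings missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  rows <- list()
  for (v in unique(ratings$variable)) {
    sub <- ratings[ratings$variable == v, , drop = FALSE]
    wide <- ratings_matrix(sub)
    parts <- strsplit(colnames(wide), ":", fixed = TRUE)
    observer <- vapply(parts, `[`, "", 1L)
    for (o in unique(observer)) {
      cols <- which(observer == o)
      if (length(cols) == 2L) {
        res <- intra_observer(wide[, cols, drop = FALSE], observer = o)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, measure = "intra", observer = o, model = res$model,
          icc = res$value, grade = res$grade, stringsAsFactors = FALSE)
      }
    }
    if (length(unique(observer)) >= 2L) {
      res <- inter_observer(wide, session_policy)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, measure = "inter", observer = paste(unique(observer),
                                                          collapse = "-"),
        model = res$model, icc = res$value, grade = res$grade,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pivot tidy ratings into an items x (observer, session) matrix
#'
#' @param ratings Tidy data.frame with columns `item`, `observer`,
#'   `session`, `value` (a single variable).
#' @return Numeric matrix with `observer:session` column names, items in
#'   rows; errors on duplicated or missing cells.
#' @export
ratings_matrix <- function(ratings) {
  needed <- c("item", "observer", "session", "value")
  missing <- setdiff(needed, names(ratings))
  if (length(missing))
    stop(sprintf("ratings missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  col <- paste(ratings$observer, ratings$session, sep = ":")
  items <- unique(as.character(ratings$item))
  cols <- unique(col)
  m <- matrix(NA_real_, length(items), length(cols),
              dimnames = list(items, cols))
  idx <- cbind(match(as.character(ratings$item), items), match(col, cols))
  if (anyDuplicated(idx))
    stop("duplicated (item, observer, session) cells in ratings", call. = FALSE)
  m[idx] <- ratings$value
  if (any(is.na(m)))
    stop("incomplete ratings: every item needs a value in every column",
         call. = FALSE)
  m
}
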