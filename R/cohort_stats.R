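# Two-group descriptive and inferential statistics used to summarize a
# cohort: median/IQR descriptives, rank and exact/chi-square tests, and an
# intraclass correlation for observer agreement. Quartiles use linear
# interpolation (the default, type-7 convention).

#' Median and interquartile range
#'
#' @param values non-empty numeric vector.
#' @return list with `median`, `q1`, `q3` (linear-interpolation quartiles).
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))  # 3 (2-4)
#' @export
median_iqr <- function(values) {
  if (!length(values) || anyNA(values)) {
    stop_invalid("values", "must be non-empty and free of missing values")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Mann-Whitney U test for two independent groups
#'
#' The U statistic is computed from midranks (ties get half credit). The
#' p-value is exact (null-distribution enumeration) when the samples are
#' tie-free and `n1 * n2 <= 400`; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used. Two samples
#' with no variation at all are reported as `p = 1` with a zero-variance
#' flag.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `U` (for the first sample), `p` (two-sided), `method`,
#'   and `zero_variance`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y) || anyNA(x) || anyNA(y)) {
    stop_invalid("x/y", "must be non-empty and free of missing values")
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = U, p = 1, method = "degenerate", zero_variance = TRUE))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !has_ties && n1 * n2 <= 400
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = U, p = res$p.value,
       method = if (exact) "exact" else "normal approximation",
       zero_variance = FALSE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the total hypergeometric probability of all tables
#' at most as probable as the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2))  # 1/3
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(dim(table) != 2L) || any(table < 0) || any(table != round(table))) {
    stop_invalid("table", "must be a 2x2 matrix of non-negative integer counts")
  }
  stats::fisher.test(table)$p.value
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Uncorrected Pearson statistic referred to a chi-square distribution with
#' `(r-1)(c-1)` degrees of freedom. A warning flag is raised when any
#' expected count is below 5 (Fisher's exact test is preferable there).
#'
#' @param table r x c matrix of non-negative counts; no zero margins.
#' @return list with `statistic`, `df`, `p`, and `low_expected`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop_invalid("table", "counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: every row and column must have a positive total",
         call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  low <- any(expected < 5)
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (low) {
    warning("some expected counts are below 5; consider fisher_exact()",
            call. = FALSE)
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, low_expected = low)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the mean squares of the two-way (subject x rater) decomposition:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` subjects and `k` raters. Because this is the absolute-agreement
#' form, a constant offset between raters lowers the coefficient.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns; at
#'   least 2 of each, no missing cells.
#' @return list with `icc`, the mean squares (`ms_rows`, `ms_cols`,
#'   `ms_error`) and `zero_between_subject` (when subjects do not vary the
#'   ICC is reported as 0 with this flag set).
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L || anyNA(ratings)) {
    stop_invalid("ratings", "needs >= 2 subjects, >= 2 raters, no missing cells")
  }
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n
  if (ss_rows <= .Machine$double.eps * max(1, ss_total) || denom <= 0) {
    return(list(icc = 0, ms_rows = ms_rows, ms_cols = ms_cols,
                ms_error = ms_err, zero_between_subject = TRUE))
  }
  list(icc = (ms_rows - ms_err) / denom, ms_rows = ms_rows,
       ms_cols = ms_cols, ms_error = ms_err, zero_between_subject = FALSE)
}

format_median_iqr <- function(values) {
  m <- median_iqr(values)
  sprintf("%g (%g-%g)", signif(m$median, 4), signif(m$q1, 4), signif(m$q3, 4))
}

format_count_pct <- function(flags) {
  sprintf("%d (%.0f%%)", sum(flags), 100 * mean(flags))
}

#' Two-group comparison table for a cohort
#'
#' Builds a per-variable comparison of the conservative-management and
#' treated groups: continuous variables are summarized as median (IQR) and
#' compared with the Mann-Whitney U test; binary indicators as count (%)
#' with Fisher's exact test; other categorical variables with the Pearson
#' chi-square test. A variable with no variation in either group is reported
#' with `p = 1`.
#'
#' @param cohort cohort data frame with a `group` column (`"CM"` / `"IBT"`).
#' @param variables character vector of cohort columns to compare; defaults
#'   to every column except identifiers and the group label.
#' @return data frame with columns `variable`, `cm_summary`, `ibt_summary`,
#'   `test`, `p_value`.
#' @export
group_comparison_table <- function(cohort, variables = NULL) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  if (!all(c("CM", "IBT") %in% cohort$group)) {
    stop_invalid("cohort", "needs both CM and IBT groups")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(cohort), c("infant_id", "group"))
  }
  cm <- cohort[cohort$group == "CM", , drop = FALSE]
  ibt <- cohort[cohort$group == "IBT", , drop = FALSE]
  rows <- lapply(variables, function(v) {
    x <- cm[[v]]; y <- ibt[[v]]
    if (is.numeric(x) && !all(x %in% c(0, 1) & y %in% c(0, 1))) {
      res <- mann_whitney(y, x)
      data.frame(variable = v, cm_summary = format_median_iqr(x),
                 ibt_summary = format_median_iqr(y), test = "mann-whitney",
                 p_value = res$p, stringsAsFactors = FALSE)
    } else if (is.numeric(x)) {
      tab <- rbind(c(sum(x == 1), sum(x == 0)), c(sum(y == 1), sum(y == 0)))
      p <- if (any(colSums(tab) == 0)) 1 else fisher_exact(tab)
      data.frame(variable = v, cm_summary = format_count_pct(x == 1),
                 ibt_summary = format_count_pct(y == 1), test = "fisher",
                 p_value = p, stringsAsFactors = FALSE)
    } else {
      lev <- sort(unique(c(as.character(x), as.character(y))))
      tab <- rbind(table(factor(x, lev)), table(factor(y, lev)))
      keep <- colSums(tab) > 0
      tab <- tab[, keep, drop = FALSE]
      p <- if (ncol(tab) < 2L) 1 else chi_square(tab)$p
      top <- lev[keep][which.max(colSums(tab))]
      data.frame(variable = v,
                 cm_summary = format_count_pct(as.character(x) == top),
                 ibt_summary = format_count_pct(as.character(y) == top),
                 test = "chi-square", p_value = p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
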