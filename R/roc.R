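# Empirical ROC analysis for the staging score. Orientation convention: the
# positive class is the treated (hemodynamically significant PDA) group and a
# test-positive is a score *above* the cut-off. This is the orientation under
# which the four screening performance figures (sens 0.90, spec 0.86,
# PPV 0.76, NPV 0.95) are jointly consistent with 21 treated / 42 observed
# infants; results can always be re-phrased as "score below the cut-off
# predicts early spontaneous closure".

#' Empirical ROC curve
#'
#' Sweeps every candidate threshold (midpoints between adjacent distinct
#' score values, plus infinite sentinels) and records sensitivity and
#' specificity; the AUC is the trapezoidal area under the resulting curve.
#'
#' @param scores numeric classifier scores.
#' @param labels binary class labels (0/1 or logical); 1 = positive class.
#' @param positive_high if `TRUE` (default) higher scores indicate the
#'   positive class and a test-positive is `score > threshold`; if `FALSE`
#'   the orientation is reversed.
#' @return an object of class `roc_result`: `points` (data frame of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `positive_high`,
#'   and the class counts `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(3, 5, 1, 4), c(1, 1, 0, 0))$auc  # 0.75
#' @export
roc_curve <- function(scores, labels, positive_high = TRUE) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop_invalid("scores/labels", "must be equal-length and free of missing values")
  }
  if (!all(labels %in% c(0, 1))) stop_invalid("labels", "must be binary (0/1)")
  if (length(unique(labels)) < 2L) {
    stop("degenerate input: both classes must be present", call. = FALSE)
  }
  s <- if (positive_high) scores else -scores
  uniq <- sort(unique(s))
  mids <- if (length(uniq) > 1L) (uniq[-1] + uniq[-length(uniq)]) / 2 else numeric(0)
  thr <- c(-Inf, mids, Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(s > t & labels == 1) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(s <= t & labels == 0) / n_neg, numeric(1))
  fpr <- 1 - spec
  # thresholds ascend, so fpr descends 1 -> 0; trapezoid over (fpr, sens)
  k <- length(thr)
  auc <- sum((fpr[-k] - fpr[-1]) * (sens[-k] + sens[-1]) / 2)
  points <- data.frame(threshold = if (positive_high) thr else -thr,
                       sensitivity = sens, specificity = spec)
  structure(list(points = points, auc = auc, positive_high = positive_high,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f over %d thresholds (%d positives, %d negatives)\n",
              x$auc, nrow(x$points), x$n_pos, x$n_neg))
  invisible(x)
}

#' Mann-Whitney estimate of the AUC
#'
#' Computes `P(score_pos > score_neg) + 0.5 * P(tie)` over all
#' positive-negative pairs via midranks. This rank statistic is
#' algebraically identical to the trapezoidal area under the empirical ROC
#' curve, which the test suite asserts to within 1e-12.
#'
#' @inheritParams roc_curve
#' @return the AUC as a single number in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels, positive_high = TRUE) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop_invalid("labels", "must be binary (0/1)")
  if (length(unique(labels)) < 2L) {
    stop("degenerate input: both classes must be present", call. = FALSE)
  }
  s <- if (positive_high) scores else -scores
  r <- rank(s)  # midranks
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal cut-off
#'
#' Selects the threshold maximizing the Youden index
#' `J = sensitivity + specificity - 1`. Ties are broken toward higher
#' sensitivity, then toward the lower threshold.
#'
#' @param roc a `roc_result` from [roc_curve()].
#' @return list with `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  pts <- roc$points
  J <- pts$sensitivity + pts$specificity - 1
  ord <- order(-J, -pts$sensitivity, pts$threshold)
  best <- ord[1L]
  list(threshold = pts$threshold[best], J = J[best],
       sensitivity = pts$sensitivity[best],
       specificity = pts$specificity[best])
}

#' Wilson score interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials; must be positive.
#' @param confidence confidence level, default 0.95.
#' @return numeric vector `c(low, high)`, always inside `[0, 1]` and always
#'   containing `k/n`.
#' @export
wilson_ci <- function(k, n, confidence = 0.95) {
  if (n <= 0 || k < 0 || k > n) stop_invalid("k/n", "need 0 <= k <= n, n > 0")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  ph <- k / n
  centre <- ph + z^2 / (2 * n)
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))
  ci <- c(low = centre - half, high = centre + half) / (1 + z^2 / n)
  # guard floating-point drift at the boundaries
  ci["low"] <- min(max(ci[["low"]], 0), ph)
  ci["high"] <- max(min(ci[["high"]], 1), ph)
  ci
}

perf_row <- function(num, den, confidence) {
  if (den == 0) {
    return(list(estimate = NA_real_, low = NA_real_, high = NA_real_,
                defined = FALSE))
  }
  ci <- wilson_ci(num, den, confidence)
  list(estimate = num / den, low = unname(ci["low"]), high = unname(ci["high"]),
       defined = TRUE)
}

#' Diagnostic performance from 2x2 counts
#'
#' @param tp,fp,fn,tn non-negative integer cell counts of the 2x2
#'   classification table.
#' @param confidence confidence level of the Wilson score intervals.
#' @return an object of class `diagnostic_performance`: the counts, and a
#'   `metrics` data frame (`metric`, `estimate`, `ci_low`, `ci_high`,
#'   `defined`) over sensitivity, specificity, PPV and NPV. A metric whose
#'   denominator margin is empty is flagged `defined = FALSE` rather than
#'   silently set to 0.
#' @examples
#' performance_from_counts(19, 6, 2, 36)
#' @export
performance_from_counts <- function(tp, fp, fn, tn, confidence = 0.95) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts", "must be non-negative integers")
  }
  rows <- list(sensitivity = perf_row(tp, tp + fn, confidence),
               specificity = perf_row(tn, tn + fp, confidence),
               ppv = perf_row(tp, tp + fp, confidence),
               npv = perf_row(tn, tn + fn, confidence))
  metrics <- data.frame(metric = names(rows),
                        estimate = vapply(rows, `[[`, numeric(1), "estimate"),
                        ci_low = vapply(rows, `[[`, numeric(1), "low"),
                        ci_high = vapply(rows, `[[`, numeric(1), "high"),
                        defined = vapply(rows, `[[`, logical(1), "defined"),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(counts = counts, metrics = metrics, confidence = confidence),
            class = "diagnostic_performance")
}

#' Diagnostic performance of a score at a cut-off
#'
#' Dichotomizes the scores at `cutoff` (test-positive = score above the
#' cut-off when `positive_high`) and summarizes the resulting 2x2 table as
#' sensitivity, specificity, PPV and NPV with Wilson score intervals.
#'
#' @inheritParams roc_curve
#' @param cutoff decision threshold on the score scale.
#' @param confidence confidence level of the Wilson intervals.
#' @return a `diagnostic_performance` object; see
#'   [performance_from_counts()].
#' @export
diagnostic_performance <- function(scores, labels, cutoff,
                                   positive_high = TRUE, confidence = 0.95) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop_invalid("labels", "must be binary (0/1)")
  test_pos <- if (positive_high) scores > cutoff else scores < cutoff
  performance_from_counts(tp = sum(test_pos & labels == 1),
                          fp = sum(test_pos & labels == 0),
                          fn = sum(!test_pos & labels == 1),
                          tn = sum(!test_pos & labels == 0),
                          confidence = confidence)
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf("2x2 counts: tp=%d fp=%d fn=%d tn=%d\n",
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"]))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (m$defined[i]) {
      cat(sprintf("  %-11s %.3f (%d%% CI %.3f-%.3f)\n", m$metric[i],
                  m$estimate[i], round(100 * x$confidence), m$ci_low[i],
                  m$ci_high[i]))
    } else {
      cat(sprintf("  %-11s undefined (empty margin)\n", m$metric[i]))
    }
  }
  invisible(x)
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Bayes' rule for the positive and negative predictive values, used as a
#' consistency check on reported screening metrics.
#'
#' @param sensitivity,specificity,prevalence proportions in `[0, 1]`.
#' @return list with `ppv` and `npv`; a value whose denominator is zero is
#'   `NA` with `defined = FALSE` flags.
#' @examples
#' predictive_values_from_rates(0.90, 0.86, 21 / 63)
#' @export
predictive_values_from_rates <- function(sensitivity, specificity, prevalence) {
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  check_prob(prevalence, "prevalence")
  d_ppv <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  d_npv <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  list(ppv = if (d_ppv > 0) sensitivity * prevalence / d_ppv else NA_real_,
       npv = if (d_npv > 0) specificity * (1 - prevalence) / d_npv else NA_real_,
       ppv_defined = d_ppv > 0, npv_defined = d_npv > 0)
}

#' Compare staging schemes on one cohort
#'
#' Scores the cohort under each scheme, computes the ROC against the
#' management-group label (treated = positive class), picks the Youden
#' cut-off and evaluates diagnostic performance there — one summary row per
#' scheme.
#'
#' @param cohort cohort data frame with a `group` column (`"IBT"` treated /
#'   `"CM"` conservative) and the staged measurement columns.
#' @param schemes a list of `staging_scheme` objects (a single scheme is
#'   also accepted).
#' @return data frame with columns `scheme`, `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
compare_schemes <- function(cohort, schemes) {
  if (inherits(schemes, "staging_scheme")) schemes <- list(schemes)
  stopifnot(length(schemes) >= 1L)
  labels <- as.numeric(cohort$group == "IBT")
  rows <- lapply(schemes, function(sch) {
    scored <- score_cohort(cohort, sch)
    roc <- roc_curve(scored$pda_score, labels)
    cut <- youden_cutoff(roc)
    perf <- diagnostic_performance(scored$pda_score, labels, cut$threshold)
    m <- stats::setNames(perf$metrics$estimate, perf$metrics$metric)
    data.frame(scheme = sch$name, auc = roc$auc, cutoff = cut$threshold,
               sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
               ppv = m[["ppv"]], npv = m[["npv"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write ROC operating points as CSV
#'
#' @param roc a `roc_result`.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  utils::write.csv(roc$points, path, row.names = FALSE)
  invisible(path)
}
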