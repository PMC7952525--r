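# Maximum-likelihood logistic fitting and Wald-driven backward elimination.
# Fitting is delegated to stats::glm (iteratively reweighted least squares)
# with a tight convergence control; the covariance is the inverse observed
# information. Covariates are used unstandardized so that fitted coefficients
# live on the same scale as the published model; standardization is applied
# only internally to flag (quasi-)complete separation.

#' Fit a logistic regression by maximum likelihood
#'
#' @param design data frame (or matrix) of numeric covariates; may have zero
#'   columns for an intercept-only fit.
#' @param outcome binary vector (0/1 or logical) of the same length.
#' @return a `logistic_model` with covariance and `fit_info` (`converged`,
#'   `iterations`, `log_likelihood`, `separation`).
#' @details (Quasi-)complete separation is flagged — not errored — when any
#'   internally standardized coefficient exceeds 30 in absolute value; the
#'   flag is stored in `fit_info$separation`. A rank-deficient design is an
#'   error.
#' @examples
#' set.seed(1)
#' x <- data.frame(x1 = rnorm(200))
#' y <- rbinom(200, 1, plogis(-0.5 + x$x1))
#' fit_logistic(x, y)
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.data.frame(design)
  outcome <- as.numeric(outcome)
  if (anyNA(design) || anyNA(outcome)) {
    stop_invalid("design/outcome", "missing values are not allowed")
  }
  if (!all(outcome %in% c(0, 1))) {
    stop_invalid("outcome", "must be binary (0/1)")
  }
  if (nrow(design) != length(outcome)) {
    stop_invalid("outcome", "length must match the design rows")
  }
  if (nrow(design) < ncol(design) + 1L) {
    stop_invalid("design", "needs at least one more row than covariates")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: covariates are linearly dependent",
         call. = FALSE)
  }
  dat <- cbind(design, .outcome = outcome)
  form <- if (ncol(design)) {
    stats::reformulate(colnames(design), response = ".outcome")
  } else {
    .outcome ~ 1
  }
  fit <- stats::glm(form, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  beta <- stats::coef(fit)
  # separation check on the standardized coefficient scale
  sds <- if (ncol(design)) vapply(design, stats::sd, numeric(1)) else numeric(0)
  separation <- any(abs(beta[-1] * sds) > 30, na.rm = TRUE) || !fit$converged
  info <- list(converged = fit$converged, iterations = fit$iter,
               log_likelihood = as.numeric(stats::logLik(fit)),
               separation = separation)
  logistic_model(intercept = unname(beta[1L]),
                 coefficients = if (ncol(design)) beta[-1L] else
                   stats::setNames(numeric(0), character(0)),
                 covariance = stats::vcov(fit),
                 fit_info = info,
                 name = "fitted_model")
}

#' Wald test of one coefficient
#'
#' Tests `beta = 0` with the statistic `(beta/SE)^2` referred to a chi-square
#' distribution with one degree of freedom.
#'
#' @param model a `logistic_model` with covariance.
#' @param covariate name of one model covariate.
#' @return list with `statistic` and `p`.
#' @export
wald_test <- function(model, covariate) {
  stopifnot(inherits(model, "logistic_model"))
  if (is.null(model$covariance)) {
    stop("missing covariance: Wald test unavailable", call. = FALSE)
  }
  if (!covariate %in% names(model$coefficients)) {
    stop(sprintf("unknown covariate `%s`", covariate), call. = FALSE)
  }
  beta <- model$coefficients[[covariate]]
  se <- sqrt(model$covariance[covariate, covariate])
  stat <- (beta / se)^2
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Backward elimination by Wald p-value
#'
#' Starts from the full model over all candidate covariates and repeatedly
#' removes the single covariate with the largest Wald p-value, refitting
#' after every removal, until every remaining covariate has `p <
#' alpha_stay` or only the intercept remains. Ties in the largest p are
#' broken by the smaller absolute Wald statistic, then lexicographically, so
#' traces are deterministic.
#'
#' @param design data frame of numeric covariates.
#' @param outcome binary outcome vector.
#' @param candidates character vector of design columns to consider; default
#'   all columns.
#' @param alpha_stay covariates stay while their Wald p is below this
#'   threshold (default 0.05).
#' @return an object of class `elimination_trace`: `steps` (data frame with
#'   `step`, `removed`, `wald_p`, `log_likelihood` after the removal) and
#'   `final_model` (a `logistic_model`).
#' @export
backward_eliminate <- function(design, outcome, candidates = colnames(design),
                               alpha_stay = 0.05) {
  design <- as.data.frame(design)
  if (!all(candidates %in% colnames(design))) {
    stop_invalid("candidates", "must be a subset of the design columns")
  }
  current <- candidates
  model <- fit_logistic(design[, current, drop = FALSE], outcome)
  steps <- data.frame(step = integer(0), removed = character(0),
                      wald_p = numeric(0), log_likelihood = numeric(0),
                      stringsAsFactors = FALSE)
  while (length(current)) {
    tests <- lapply(current, function(v) wald_test(model, v))
    p <- vapply(tests, `[[`, numeric(1), "p")
    stat <- vapply(tests, `[[`, numeric(1), "statistic")
    ord <- order(-p, stat, current)
    worst <- ord[1L]
    if (p[worst] < alpha_stay) break
    removed <- current[worst]
    current <- setdiff(current, removed)
    model <- fit_logistic(design[, current, drop = FALSE], outcome)
    steps <- rbind(steps, data.frame(
      step = nrow(steps) + 1L, removed = removed, wald_p = p[worst],
      log_likelihood = model$fit_info$log_likelihood,
      stringsAsFactors = FALSE))
  }
  structure(list(steps = steps, final_model = model),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat("Backward elimination trace\n")
  if (nrow(x$steps)) {
    print(x$steps, row.names = FALSE)
  } else {
    cat("  no covariate removed\n")
  }
  cat(sprintf("Final model retains: %s\n",
              if (length(x$final_model$coefficients)) {
                paste(names(x$final_model$coefficients), collapse = ", ")
              } else "(intercept only)"))
  invisible(x)
}

#' Export an elimination trace as a plain-text table
#'
#' @param trace an `elimination_trace`.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "elimination_trace"))
  utils::write.csv(trace$steps, path, row.names = FALSE)
  invisible(path)
}
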