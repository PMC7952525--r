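# The logistic prediction layer. A `logistic_model` is a plain container for
# an intercept, named coefficients and (optionally) their covariance, so that
# a model refit from data and the fixed published screening model share one
# representation and one serialization format.

#' Construct a logistic model object
#'
#' @param intercept intercept on the logit scale.
#' @param coefficients named numeric vector of covariate coefficients.
#' @param covariance optional symmetric covariance matrix of
#'   `c("(Intercept)", names(coefficients))`, in that order.
#' @param fit_info optional list of fit metadata (`converged`, `iterations`,
#'   `log_likelihood`, `separation`).
#' @param name model label used in printing and serialization.
#' @return an object of class `logistic_model`.
#' @export
logistic_model <- function(intercept, coefficients, covariance = NULL,
                           fit_info = NULL, name = "model") {
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients))) {
    stop_invalid("coefficients", "must have unique names")
  }
  if (!is.null(covariance)) {
    p <- length(coefficients) + 1L
    if (!is.matrix(covariance) || any(dim(covariance) != p)) {
      stop_invalid("covariance", sprintf("must be a %d x %d matrix", p, p))
    }
    if (max(abs(covariance - t(covariance))) > 1e-8) {
      stop_invalid("covariance", "must be symmetric")
    }
    dimnames(covariance) <- rep(list(c("(Intercept)", names(coefficients))), 2)
  }
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 covariance = covariance,
                 fit_info = fit_info,
                 name = name),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic model `%s`\n", x$name))
  cat(sprintf("  logit(p) = %.4f %s\n", x$intercept,
              paste(sprintf("%+.4f*%s", x$coefficients, names(x$coefficients)),
                    collapse = " ")))
  if (!is.null(x$fit_info)) {
    cat(sprintf("  converged: %s after %d iterations, logLik %.4f\n",
                x$fit_info$converged, x$fit_info$iterations,
                x$fit_info$log_likelihood))
    if (isTRUE(x$fit_info$separation)) {
      cat("  warning: possible (quasi-)complete separation\n")
    }
  }
  invisible(x)
}

#' The published screening model for early spontaneous PDA closure
#'
#' Returns the fixed logistic model
#' \deqn{\mathrm{logit}(p) = -28.41 + 1.23\,GA - 0.87\,score}
#' where `p` is the probability of early spontaneous ductal closure, `GA` is
#' gestational age in (possibly fractional) weeks and `score` is the 0-11
#' screening staging score of [model5_scheme()]. The published model carries
#' no covariance, so confidence-interval queries are unavailable for it.
#'
#' @return a `logistic_model` with coefficients `gestational_age_weeks`
#'   (1.23) and `pda_score` (-0.87) and intercept -28.41.
#' @export
published_model <- function() {
  logistic_model(intercept = -28.41,
                 coefficients = c(gestational_age_weeks = 1.23,
                                  pda_score = -0.87),
                 name = "published_screening_model")
}

model_linear_predictor <- function(model, covariates) {
  covariates <- as.list(covariates)
  x <- vapply(names(model$coefficients), function(nm) {
    v <- resolve_cohort_column(covariates, nm)
    if (is.null(v)) {
      stop(sprintf("missing covariate: %s", nm), call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1))
  model$intercept + sum(model$coefficients * x)
}

#' Predicted probability of early spontaneous closure
#'
#' Evaluates a logistic model at one infant's covariates and classifies the
#' result against a probability threshold.
#'
#' @param model a `logistic_model`.
#' @param covariates named list or vector supplying every model covariate
#'   (for the published model: `gestational_age_weeks` and `pda_score`).
#' @param threshold classification threshold on the probability scale,
#'   default 0.5.
#' @return an object of class `closure_prediction`: `logit`, `probability`
#'   and `classification` (`"likely-early-closure"` when the probability is
#'   at or above the threshold, `"likely-hsPDA"` otherwise).
#' @examples
#' closure_probability(published_model(),
#'                     c(gestational_age_weeks = 26, pda_score = 3))
#' @export
closure_probability <- function(model, covariates, threshold = 0.5) {
  stopifnot(inherits(model, "logistic_model"))
  check_prob(threshold, "threshold")
  lp <- model_linear_predictor(model, covariates)
  p <- stats::plogis(lp)
  structure(list(logit = lp, probability = p,
                 classification = classify(p, threshold)),
            class = "closure_prediction")
}

#' @export
print.closure_prediction <- function(x, ...) {
  cat(sprintf("P(early spontaneous closure) = %.3f (logit %.3f) -> %s\n",
              x$probability, x$logit, x$classification))
  invisible(x)
}

#' Classify a closure probability against a threshold
#'
#' @param probability predicted probability of early spontaneous closure.
#' @param threshold decision threshold in `[0, 1]`; a probability at or above
#'   it is classified as likely early closure.
#' @return `"likely-early-closure"` or `"likely-hsPDA"`.
#' @export
classify <- function(probability, threshold = 0.5) {
  check_prob(probability, "probability")
  check_prob(threshold, "threshold")
  ifelse(probability >= threshold, "likely-early-closure", "likely-hsPDA")
}

#' Odds ratios of a logistic model
#'
#' Per-unit odds ratios `exp(beta)` for every covariate, with Wald confidence
#' intervals `exp(beta +/- z * SE)` when the model carries a covariance.
#'
#' @param model a `logistic_model`.
#' @param confidence confidence level for the intervals, default 0.95. Only
#'   used when a covariance is present; requesting intervals from a model
#'   without covariance (such as [published_model()]) is an error, so set
#'   `ci = FALSE` for such models.
#' @param ci logical; compute Wald confidence intervals.
#' @return a data frame with columns `covariate`, `or` and, when `ci`,
#'   `ci_low`, `ci_high`.
#' @examples
#' odds_ratios(published_model(), ci = FALSE)  # 3.42 per GA week, 0.42 per point
#' @export
odds_ratios <- function(model, confidence = 0.95, ci = !is.null(model$covariance)) {
  stopifnot(inherits(model, "logistic_model"))
  out <- data.frame(covariate = names(model$coefficients),
                    or = exp(unname(model$coefficients)),
                    stringsAsFactors = FALSE)
  if (ci) {
    if (is.null(model$covariance)) {
      stop("missing covariance: confidence intervals are unavailable for this model",
           call. = FALSE)
    }
    z <- stats::qnorm(1 - (1 - confidence) / 2)
    se <- sqrt(diag(model$covariance))[out$covariate]
    out$ci_low <- exp(unname(model$coefficients) - z * se)
    out$ci_high <- exp(unname(model$coefficients) + z * se)
  }
  out
}

#' Plain-language effect of one covariate on the odds of closure
#'
#' Expresses a coefficient as the per-unit change in the odds of early
#' spontaneous closure: a percent decrease for a negative coefficient
#' (one staging point lowers the odds by 58% under the published model) or a
#' fold increase for a positive one (each gestational week multiplies them
#' by 3.4).
#'
#' @param model a `logistic_model`.
#' @param covariate name of one model covariate.
#' @return a list with `covariate`, `direction` (`"decrease"`, `"increase"`
#'   or `"none"`), `value` (percent decrease, or fold change), and a
#'   formatted `statement`.
#' @export
effect_statement <- function(model, covariate) {
  stopifnot(inherits(model, "logistic_model"))
  if (!covariate %in% names(model$coefficients)) {
    stop(sprintf("unknown covariate `%s`", covariate), call. = FALSE)
  }
  beta <- model$coefficients[[covariate]]
  if (beta < 0) {
    val <- (1 - exp(beta)) * 100
    list(covariate = covariate, direction = "decrease", value = val,
         statement = sprintf("each unit of %s decreases the odds of early spontaneous closure by %.0f%%",
                             covariate, val))
  } else if (beta > 0) {
    val <- exp(beta)
    list(covariate = covariate, direction = "increase", value = val,
         statement = sprintf("each unit of %s increases the odds of early spontaneous closure %.1f-fold",
                             covariate, val))
  } else {
    list(covariate = covariate, direction = "none", value = 0,
         statement = sprintf("%s does not change the odds", covariate))
  }
}

#' Write or read a logistic model as JSON
#'
#' Fitted and published models share one JSON-compatible text format:
#' `name`, `intercept`, `coefficients` and an optional `covariance` stored
#' by rows.
#'
#' @param model a `logistic_model`.
#' @param path file path.
#' @return `read_model` returns a `logistic_model`; `write_model` invisibly
#'   returns `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "logistic_model"))
  obj <- list(name = model$name, intercept = model$intercept,
              coefficients = as.list(model$coefficients))
  if (!is.null(model$covariance)) {
    obj$covariance <- apply(model$covariance, 1, as.list, simplify = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  coefs <- vapply(obj$coefficients, as.numeric, numeric(1))
  names(coefs) <- names(obj$coefficients)
  covariance <- NULL
  if (!is.null(obj$covariance)) {
    covariance <- do.call(rbind, lapply(obj$covariance, function(r) {
      vapply(r, as.numeric, numeric(1))
    }))
  }
  logistic_model(intercept = as.numeric(obj$intercept), coefficients = coefs,
                 covariance = covariance,
                 name = if (is.null(obj$name)) "model" else obj$name)
}
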