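test_that("intercept-only fit recovers the sample log-odds", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logistic(data.frame(row.names = seq_along(y)), y)
  expect_equal(fit$intercept, log(30 / 70), tolerance = 1e-6)
  expect_length(fit$coefficients, 0)
  expect_true(fit$fit_info$converged)
})

test_that("a covariate independent of the outcome gets a near-zero coefficient", {
  set.seed(7)
  X <- data.frame(noise = rnorm(400))
  y <- rbinom(400, 1, 0.5)
  fit <- fit_logistic(X, y)
  se <- sqrt(fit$covariance["noise", "noise"])
  expect_lt(abs(fit$coefficients[["noise"]]), 3 * se)
})

test_that("the IRLS fit matches a direct likelihood-maximization oracle", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(60:120, 1)
    k <- sample(1:3, 1)
    X <- as.data.frame(matrix(rnorm(n * k), n, k))
    names(X) <- paste0("x", seq_len(k))
    b_true <- runif(k + 1, -1, 1)
    y <- rbinom(n, 1, plogis(cbind(1, as.matrix(X)) %*% b_true))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(X, y)
    oracle <- optim_logistic_oracle(X, y)
    expect_equal(unname(c(fit$intercept, fit$coefficients)), oracle,
                 tolerance = 1e-6)
  }
})

test_that("refits on outcomes simulated from the published model recover its coefficients", {
  truth <- c(-28.41, 1.23, -0.87)
  joint <- logical(20)
  for (r in 1:20) {
    cfg <- cohort_config(n_conservative = 1000, n_treated = 1000,
                         seed = 1000 + r)
    co <- generate_cohort(cfg)
    y <- simulate_outcomes_from_model(co, published_model(), seed = 2000 + r)
    fit <- fit_logistic(data.frame(gestational_age_weeks = co$ga_weeks,
                                   pda_score = co$pda_score), y)
    b <- c(fit$intercept, fit$coefficients)
    se <- sqrt(diag(fit$covariance))
    joint[r] <- all(abs(b - truth) <= stats::qnorm(0.975) * se)
  }
  expect_gte(mean(joint), 0.9)
})

test_that("Wald statistics map to chi-square tail probabilities", {
  cov <- diag(c(1, 0.5, 1, 4))  # intercept first
  m <- logistic_model(0, c(a = 0, b = 1.96, c = 6), covariance = cov)
  wa <- wald_test(m, "a")
  expect_equal(wa$statistic, 0)
  expect_equal(wa$p, 1)
  wb <- wald_test(m, "b")  # z = 1.96
  expect_equal(wb$statistic, 3.8416, tolerance = 1e-4)
  expect_equal(round(wb$p, 3), 0.05)
  wc <- wald_test(m, "c")  # z = 3
  expect_equal(wc$p, 0.0027, tolerance = 1e-2)
  expect_equal(wc$p, 2 * stats::pnorm(-3), tolerance = 1e-12)
  expect_error(wald_test(m, "zzz"), "unknown covariate")
  expect_error(wald_test(published_model(), "pda_score"), "covariance")
})

test_that("backward elimination handles the degenerate and the clean case", {
  set.seed(17)
  X <- data.frame(x = rnorm(60))
  y <- rbinom(60, 1, 0.5)
  tr <- backward_eliminate(X, y, candidates = character(0))
  expect_length(tr$final_model$coefficients, 0)
  expect_equal(nrow(tr$steps), 0)

  kept_strong <- logical(20)
  for (r in 1:20) {
    set.seed(3000 + r)
    X <- data.frame(s = rnorm(500), n1 = rnorm(500), n2 = rnorm(500),
                    n3 = rnorm(500))
    y <- rbinom(500, 1, plogis(2 * X$s))
    tr <- backward_eliminate(X, y)
    kept_strong[r] <- "s" %in% names(tr$final_model$coefficients)
    # log-likelihood can only fall as covariates leave (nesting)
    if (nrow(tr$steps) > 1) expect_true(all(diff(tr$steps$log_likelihood) <= 1e-8))
    # every removal happened at or above the stay threshold
    if (nrow(tr$steps) > 0) expect_true(all(tr$steps$wald_p >= 0.05))
  }
  # the informative covariate always survives; pure-noise covariates are
  # retained at roughly the nominal 5% rate each, so an occasional extra
  # survivor is expected behaviour, not an error
  expect_true(all(kept_strong))
})

test_that("elimination on a synthetic cohort keeps gestational age and the score", {
  co <- generate_cohort(cohort_config(n_conservative = 200, n_treated = 100,
                                      seed = 1))
  y <- as.numeric(co$group == "CM")  # early spontaneous closure
  tr <- backward_eliminate(data.frame(ga_weeks = co$ga_weeks,
                                      pda_score = co$pda_score,
                                      birth_weight_g = co$birth_weight_g), y)
  expect_setequal(names(tr$final_model$coefficients),
                  c("ga_weeks", "pda_score"))
  expect_equal(tr$steps$removed, "birth_weight_g")
  expect_lt(tr$final_model$coefficients[["pda_score"]], 0)
  expect_gt(tr$final_model$coefficients[["ga_weeks"]], 0)
  # the fitted model explains more than the null
  null_ll <- sum(stats::dbinom(y, 1, mean(y), log = TRUE))
  expect_gte(tr$final_model$fit_info$log_likelihood, null_ll)
})

test_that("pathological designs are flagged", {
  set.seed(23)
  x <- rnorm(40)
  expect_error(fit_logistic(data.frame(a = x, b = 2 * x), rbinom(40, 1, 0.5)),
               "rank-deficient")
  # complete separation
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  fit <- suppressWarnings(fit_logistic(data.frame(x = xs), ys))
  expect_true(fit$fit_info$separation)
  expect_error(fit_logistic(data.frame(x = 1:5), c(0, 1, 2, 0, 1)), "binary")
})
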