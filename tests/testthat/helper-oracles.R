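# Independent oracles used across the suite.

# Brute-force AUC: explicit enumeration of all positive-negative pairs with
# half credit for ties.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Literal re-reading of the printed staging table, written as nested
# conditionals independent of the package's bin machinery. Boundary values
# belong to the closed middle range.
table_score_oracle <- function(td, vmax, lpa, dao) {
  s_td <- if (td == 0) 0 else if (td < 1.5) 1 else if (td <= 3) 2 else 3
  s_vm <- if (vmax == 0) 0 else if (vmax < 1.5) 1 else if (vmax <= 2) 2 else 3
  s_lpa <- if (lpa == 0) 0 else if (lpa < 30) 1 else if (lpa <= 50) 2 else 3
  s_dao <- c(forward = 0, absent = 1, reverse = 2)[[dao]]
  s_td + s_vm + s_lpa + s_dao
}

# Direct numerical maximization of the Bernoulli log-likelihood, as an
# oracle for the IRLS-based fit.
optim_logistic_oracle <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  nll <- function(b) {
    eta <- as.vector(Xd %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(Xd)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# A full-schema one-row cohort table for CLI round-trips.
one_row_cohort <- function(ga = 24, score = 5) {
  data.frame(infant_id = "P001", group = "unknown", ga_weeks = ga,
             birth_weight_g = 800, apgar5 = 7, cord_ph = 7.3,
             advanced_resuscitation = 0, td_mm = 2.2, vmax_vmin = 1.6,
             lpa_cms = 35, dao_direction = "reverse", la_ao = 1.6,
             lvo_mlkgmin = 200, svc_mlkgmin = 80, ea_ratio = 0.8,
             pda_score = score, postnatal_age_h = 45,
             stringsAsFactors = FALSE)
}
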