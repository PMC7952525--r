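---
title: "Methods behind pdaclose: staging, prediction and simulation of early ductal closure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind pdaclose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdaclose)
```

## The clinical problem and the model

In infants born before 29 completed weeks of gestation, the arterial duct
frequently remains patent after birth. A majority of these ducts close
spontaneously during the first two weeks of life; the rest sustain a
left-to-right shunt that over-circulates the lungs and steals flow from the
systemic circulation, and are candidates for ibuprofen treatment. The
package implements a screening-based decision chain: a bedside
echocardiogram between 18 and 72 hours of life is staged with an ordinal
ductal disease score, and the score is combined with gestational age in a
logistic model of the probability of early spontaneous closure,

$$\mathrm{logit}(p) = -28.41 + 1.23\,\mathrm{GA} - 0.87\,\mathrm{score},$$

with GA in continuous weeks (an infant at 27 weeks and 3 days enters as
27.43). The model's structure encodes two clinical facts: maturity strongly
favours spontaneous closure (each week multiplies the odds of closure by
$e^{1.23} \approx 3.4$), and a more severe ductal pattern argues against it
(each staging point multiplies the odds by $e^{-0.87} \approx 0.42$, a 58%
reduction). `published_model()` returns this fixed equation; because no
coefficient covariance is published for it, confidence-interval queries are
deliberately disabled for that object rather than reconstructed from
rounded odds-ratio bounds, which are not mutually consistent with
$\exp(\beta \pm z\,SE)$ at the printed precision. (The printed odds ratio
for gestational age, 3.44, likewise differs in the third digit from
$e^{1.23} = 3.42$, presumably because the unrounded coefficient was
slightly larger; the package always reports transforms of its own
coefficients.)

## The staging score

The built-in scheme (`model5_scheme()`) stages four Doppler findings:

| component | 0 | 1 | 2 | 3 |
|---|---|---|---|---|
| transductal diameter, mm | 0 | <1.5 | 1.5–3 | >3 |
| ductal Vmax/Vmin ratio | 0 | <1.5 | 1.5–2 | >2 |
| antegrade LPA diastolic velocity, cm/s | 0 | <30 | 30–50 | >50 |
| descending-aorta diastolic flow | forward | absent | reverse | — |

The total ranges from 0 to 11. Three conventions are worth stating
explicitly because the printed ranges alone do not fix them:

* **Boundary convention.** The middle ranges are closed on both ends, the
  outer bins open, so a measurement on a shared edge belongs to the closed
  middle bin; where two closed bins would meet in a user-defined scheme,
  the milder (lower-score) bin wins. A diameter of exactly 1.5 mm scores 2;
  a diameter of exactly 3 mm also scores 2.
* **The exact-zero bin.** Zero means "no measurable signal" and scores 0 on
  every numeric component. A closed duct (diameter 0) must also have a
  zero velocity ratio; the exam constructor enforces this equivalence. It
  does not force the descending-aorta direction to be forward for a closed
  duct — that is expected physiologically but remains the sonographer's
  reading.
* **Missing measurements raise errors.** A patent duct whose velocity
  ratio was not recorded is not imputed; scoring stops with an error naming
  the missing field.

Alternative schemes (e.g. candidate score models with different components
or thresholds) are loaded from a JSON description by `load_scheme()`,
which validates that the bins of each numeric component start at zero,
chain without gaps or overlaps, end unbounded, and carry non-decreasing
scores. Velocity units are cm/s throughout the staging layer; the cohort
reader accepts an `lpa_units = "ms"` flag because published tables record
the LPA diastolic velocity in m/s (values around 0.1–0.45) while the
staging thresholds are printed in cm/s.

## Fitting and selection

`fit_logistic()` maximizes the Bernoulli likelihood by iteratively
reweighted least squares (via `stats::glm`, relative-deviance convergence
at $10^{-10}$, at most 50 iterations) and returns the coefficient
covariance as the inverse observed information. Covariates are used
unstandardized so fitted coefficients are directly comparable with the
published equation; standardization is applied only internally to flag
likely (quasi-)complete separation, reported as a flag in `fit_info`
rather than an error because separated fits can still be inspected.
The test suite verifies the fit against a direct numerical maximizer of
the same likelihood to $10^{-6}$.

`backward_eliminate()` starts from the full candidate model and repeatedly
removes the covariate with the largest Wald p-value
($p = P(\chi^2_1 > (\beta/SE)^2)$), refitting after each removal, until all
remaining p-values fall below `alpha_stay`. The default `alpha_stay = 0.05`
matches the analysis's global significance level; the removal threshold
and the single-covariate removal rule are package decisions, as is the
deterministic tie-break (largest p, then smaller Wald statistic, then
name). One statistical consequence worth knowing: with $k$ pure-noise
candidates, at least one of them survives elimination with probability
roughly $1 - 0.95^k$ (about 14% for $k = 3$), which is nominal behaviour
of the procedure, not a defect.

## ROC analysis and diagnostic performance

The positive class is the treated (hemodynamically significant) group and
a test-positive is a score **above** the cut-off. This orientation is the
one under which the four screening performance figures — sensitivity 0.90,
specificity 0.86, PPV 0.76, NPV 0.95 — are simultaneously consistent with
21 treated and 42 observed infants (counts 19/2/6/36); results are
re-expressed in closure terms by noting that a score below the cut-off
predicts early spontaneous closure. Candidate thresholds are midpoints
between adjacent distinct scores (plus infinite sentinels), so reported
cut-offs for an integer score are half-integers such as 4.5. The AUC is
computed both as the trapezoidal area and as the tie-corrected rank
statistic $P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)$; the two are
algebraically identical and the suite asserts their equality to
$10^{-12}$, with `pROC` as an independent cross-check.

Proportion confidence intervals use the Wilson score interval, which
reproduces the published sensitivity and specificity intervals exactly at
two decimals when reconstructed from 19/21 and 36/42. (The published PPV
interval is not reproduced by any binomial method applied to 19/25; it was
evidently computed differently, and the package makes no attempt to match
it.) An AUC confidence interval is deliberately not reported: the method
behind the published interval is unstated, and the package does not guess.
Empty 2×2 margins flag the affected predictive value as undefined instead
of silently reporting zero.

## Cohort statistics

Quartiles use linear interpolation (R's default type 7); the printed
medians and IQRs cannot discriminate between quartile conventions, so the
most common one is used. The Mann-Whitney U statistic is computed from
midranks; p-values are exact when the data are tie-free and
$n_1 n_2 \le 400$, and otherwise use the normal approximation with
tie-corrected variance and continuity correction (an exact null
distribution under heavy ties is not available in closed form, and the
two approaches agree within 0.02 by group sizes of 15). Fisher's exact
test sums hypergeometric probabilities at most that of the observed table;
the chi-square test is the uncorrected Pearson statistic, with a warning
when any expected count falls below 5. Observer agreement uses ICC(2,1) —
two-way random effects, absolute agreement, single measurement — the
standard reliability form when raters are considered exchangeable; the
published analysis does not state which ICC form it used, so this choice
is flagged to users. Kruskal-Wallis is omitted because only two groups are
ever compared in this design.

## The synthetic cohort generator

No patient-level data are deposited, so the package ships a generator
whose defaults are the study conditions: 42 conservatively managed (CM)
and 21 ibuprofen-treated (IBT) infants, with per-group medians, IQRs and
prevalences of the perinatal and screening-echo variables matching the
published group summaries.

Each infant carries a latent severity $z \sim N(0,1)$. Every variable is a
monotone transform of a Gaussian-copula coordinate
$w = s\rho z + \sqrt{1-\rho^2}\,\varepsilon$, where $s = +1$ for severity
markers (ductal measurements, reverse aortic flow, resuscitation), $-1$
for maturity markers (gestational age, birth weight, Apgar), and $0$ for
unlinked variables. The default loading $\rho = 0.6$ induces realistic
co-movement of diameter, velocity ratio and LPA flow; it is a free
calibration knob, not an estimate of anything.

Marginals use a **two-piece (split) normal** quantile transform that hits
the target $(q_1, \mathrm{median}, q_3)$ exactly, clamped at physiologic
bounds (GA in [23, 29] weeks per the eligibility window, diameters
non-negative, Apgar integers in [0, 10]). A symmetric truncated normal
with $\sigma = IQR/1.349$ was considered and rejected: several published
summaries are strongly asymmetric (the CM birth-weight IQR's upper bound
coincides with its median), and a symmetric family cannot reproduce all
three quartiles within tolerance.

Two structural features make the CM group's printed summaries mutually
consistent:

* **A closed-duct point mass.** The CM median transductal diameter of 0
  requires at least half the group to have no visible duct (all ductal
  measurements exactly zero). The mixing weight, 0.60, is set so that the
  staged-score median lands on the published CM value of 1; the open-duct
  diameter and velocity-ratio distributions are then solved so the overall
  group quartiles still match the printed 0 (0–1.5) and 0 (0–1.4). Because
  "open" is a selection on the correlated diameter latent, the velocity
  ratio of open ducts is mapped through its conditional rank within the
  open subgroup, which keeps its marginal on target.
* **A zero-inflated LPA velocity.** The CM group's printed LPA IQR
  (q1 = 8 cm/s) is compatible with up to a quarter of infants having no
  measurable diastolic LPA flow. The generator gives exactly 25% of CM
  infants a velocity of zero with a detection floor at 8 cm/s for the
  rest; this is what lets closed-duct infants reach a staged score of 0
  and the group score median reach 1, while the group's velocity quartiles
  stay at the printed 10 (8–18).

`calibration_report()` audits a generated cohort against every target:
continuous statistics pass within 15% of the target IQR width, the integer
score within one point, prevalences within 0.10. At 5,000 infants per
group all 70 audited statistics pass; at the study's own n = 63 the score
distributions yield a Mann-Whitney AUC with median 0.91 across 20 seeds
(within the published interval of 0.88–0.99) and a median Youden cut-off
of 4.5, matching the reported screening cut-off.

What the generator does **not** emulate: longitudinal (serial) scans and
treatment response; time-to-closure beyond a single screening snapshot;
the excluded infants with pulmonary hypertension; and any real-data
pathologies such as measurement rounding habits, informative missingness,
or clinician-driven treatment decisions beyond the group label itself.
Group membership stands in for the closure outcome, mirroring the study's
operational definition, so passing tests demonstrate internal consistency
of the analysis chain under the published summary statistics — not
external validity on real cohorts.

## Problem sizes and numerical choices

The shipped tests use the sizes at which the relevant behaviour is
measurable while staying quick: calibration audits at 5,000 infants per
group; parameter recovery of the published coefficients from cohorts of
2,000 with Bernoulli outcomes drawn from the published equation (joint
95% Wald coverage ≈ 0.95 across replicates); discrimination and cut-off
checks at the study's own 42/21 split over 20 fixed seeds; and the
score-bounds property over $10^5$ random exams. Logistic fits converge by
relative deviance at $10^{-10}$; ROC and rank AUC agree to $10^{-12}$;
Wilson bounds are clamped against floating-point drift at 0 and 1.

## Limitations

The published model is retrospective and single-centre; the package
reproduces its analysis surface, not its evidence. The staging boundary
convention and the cut-off midpoint convention are reconstructions
consistent with the printed tables but not uniquely determined by them.
Backward elimination by Wald p-values is implemented as specified even
though likelihood-ratio-based selection has better small-sample behaviour;
neither Firth correction nor shrinkage is provided, and separation is
flagged rather than penalized.
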