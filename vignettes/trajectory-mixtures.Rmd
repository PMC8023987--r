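---
title: "Latent-class trajectories of disease activity: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class trajectories of disease activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

trajmix analyses longitudinal disease-activity scores in juvenile
dermatomyositis (JDM) cohorts: the physician's global assessment (PGA,
0–10) and the cutaneous modified Disease Activity Score (modified DAS,
0–5). Patients attend clinic roughly twice a year for up to a decade, their
scores decline at very different rates, and the clinical question is
whether a small group with persistently active disease can be told apart
early. The package answers this with a growth mixture model for the
trajectories, a GEE diagnostic for visit-level missingness, and a
posterior-probability-weighted lasso that screens baseline features for
association with the persistent class — exercised end to end on simulated
cohorts, since no patient-level data ship with the package.

## The growth mixture model

For patient $i$ with visits at times $t_{ij}$ (years since diagnosis) and
transformed outcome $y^*_{ij}$, each latent class $g \in \{1,\dots,G\}$ has
its own polynomial mean, shared covariate effects, and Gaussian
patient-level deviations:

$$y^*_{ij} \mid (c_i = g) \;=\; \beta_{g0} + \beta_{g1} t_{ij} +
  \beta_{g2} t_{ij}^2 + \beta_{g3} t_{ij}^3 + w_i^\top\gamma +
  b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},$$

with $(b_{0i}, b_{1i}) \sim N(0, D)$, $\varepsilon_{ij} \sim N(0,
\sigma^2)$, and $P(c_i = g) = \pi_g$ via multinomial-logit intercepts. The
marginal likelihood integrates the random effects analytically — each
patient contributes a $G$-term mixture of multivariate normal densities
with covariance $Z_i D Z_i^\top + \sigma^2 I$ — and is maximised directly.

Key choices, and why:

* **Square-root transform, cubic time** (defaults). The activity scores are
  bounded, right-skewed, and fall steeply early on; the square-root scale
  makes residuals approximately Gaussian and the cubic captures the early
  drop with a late plateau. `fit_range()` treats both as empirical
  questions: it fits every candidate (transform, degree) single-class model
  and keeps the BIC-best. Because the candidates put the outcome on
  different scales, these comparison log-likelihoods include the
  log-Jacobian of the transform, with exact zeros floored at 0.05 (half the
  finest plausible score increment) so the Jacobian stays finite.
* **Direct quasi-Newton rather than EM.** The likelihood is optimised by
  BFGS with an analytic gradient over an unconstrained parameterisation
  (logit class intercepts, Cholesky factor of $D$ with log diagonal, log
  $\sigma$). Mixture likelihoods are multimodal, so `fit_gmm()` runs a
  multistart (default 30): one start from k-means on per-patient OLS
  intercept/slope summaries, the rest random perturbations of a
  single-class fit. BFGS can meet its relative-objective tolerance while
  the gradient is still large in flat directions; each start is therefore
  "polished" by restarting the optimiser (which resets its Hessian
  approximation) until the objective stops improving, and a fit is declared
  converged when the gradient is small (below $10^{-3} n$) or stationarity
  is reached.
* **Centre as a common covariate.** The recruiting centre predicts whether
  PGA is recorded, so keeping it in the mean model makes the missingness
  ignorable under MAR. Its effect is common to classes by default (a
  class-specific variant would double-count the small centre signal given
  only two centres' worth of contrast); the covariate set is configurable.
* **Random intercept + slope** by default, with an intercept-only switch:
  trajectories differ in both level and rate, and the slope variance is
  what lets long-followed patients diverge from their class mean without
  being re-assigned.
* **Label switching** is resolved by relabelling classes in order of
  decreasing $\pi_g$ after every fit, so "class 2" is always the smaller,
  persistently active class.
* **BIC with patients (not visits) as the sample size**, $\mathrm{BIC} =
  -2\ell + k\ln n$: patients are the independent units. Entropy is the
  standard relative form $1 - \sum_{ig}(-p_{ig}\ln p_{ig})/(n\ln G)$; the
  mean posterior probability per modal class is reported alongside, since
  "how well are individuals allocated" is sometimes read either way.
  `select_model()` takes BIC as primary and reports (never silently
  resolves) a conflict with the entropy ranking.
* **Numerical guards**: mixture sums in the log domain via log-sum-exp;
  marginal-covariance Cholesky failures retried with escalating diagonal
  jitter ($10^{-8}$ to $10^{-2}$ of the diagonal scale); objective clamped
  to a large finite value outside the feasible region so line searches
  survive excursions.
* **Confidence bands** for predicted class trajectories use a parametric
  bootstrap (500 draws from the asymptotic normal of the packed parameters,
  Hessian by central differences on the analytic gradient) with a
  delta-method alternative; the class median on the original scale is the
  back-transformed mean because the transform is monotone.

Patients whose outcome is never recorded cannot contribute and are excluded
with a logged count; visits with a missing outcome are simply dropped from
that patient's likelihood (valid under MAR given the covariates in the
model).

## Missingness diagnostic

`fit_gee_missingness()` models the indicator "PGA missing at this visit" by
logistic GEE with patients as clusters, an exchangeable working correlation
(moment estimator with the $N_{\text{pairs}} - p$ denominator correction)
and robust sandwich standard errors. It is a diagnostic, not a correction:
its role is to identify which covariates (baseline severity, centre) drive
missingness and therefore belong in the trajectory model's mean. With the
correlation fixed at zero it reduces exactly to ordinary logistic ML, which
is how the implementation is tested.

## Imputation and the weighted lasso

Baseline clinical features carry 0–34% missingness, so the predictive stage
first runs chained-equations imputation (`impute_baseline()`): predictive
mean matching with 5 donors for numeric columns (draws are always observed
values, so ranges are preserved by construction), approximate-Bayesian
logistic draws for binaries, multinomial draws for categoricals; 10 sweeps,
10 completed tables, one independent RNG stream per table. The class label
is deliberately *not* an imputation predictor by default — using the
outcome of the analysis to fill its own predictors is anti-conservative —
though a flag allows it. For the multinomial draw the parameter uncertainty
is not redrawn (the categorical columns here are complete by default, so
this path is rarely exercised).

Class membership is not observed, only estimated, so the lasso stage
propagates that uncertainty: each patient enters twice, once as a
"member" row ($y = 1$, weight $p_{i2}$) and once as a "non-member" row
($y = 0$, weight $1 - p_{i2}$). With one-hot posteriors this collapses to
modal-class regression; a modal single-row scheme is available via the
weighting argument of the task builder. The penalised objective is the
weighted logistic deviance plus $\lambda\lVert\beta\rVert_1$ with an
unpenalised intercept and predictors standardised by weighted mean/SD,
solved by coordinate descent on the IRLS quadratic with warm starts along
100 log-spaced penalties from $\lambda_{\max}$ down to
$10^{-3}\lambda_{\max}$; KKT conditions are verified at every reported
solution. Cross-validation uses 10 folds that partition *patients*
(both rows of a patient travel together), stratified by modal class;
the loss is $1 - \mathrm{AUC}$ by default with weighted deviance and
misclassification as alternatives; the selected penalty is the loss
minimiser, with exact ties resolved toward the sparser model — the
1-standard-error rule is deliberately not used. One consequence worth
knowing: on pure-noise predictors the minimiser is rarely the exactly
empty model (the reference coordinate-descent implementation behaves the
same way); nullity shows up instead as near-chance out-of-fold AUC and
near-zero coefficients.

Across imputations, a predictor is *retained* when non-zero in more than
half of the completed datasets, its pooled coefficient is the mean over the
datasets where it is non-zero, and the pooled odds ratio its exponential.
No standard errors are attached — they are unreliable for penalised
estimates. When at least two predictors are retained the model is re-run
with all their pairwise interactions. `predicted_probability_grid()`
evaluates the pooled model over combinations of the retained binaries with
continuous covariates held at weighted medians.

## What the simulator emulates — and what it does not

`default_sim_spec()` encodes the reference cohort the analysis assumes:
519 patients, 46.4% at Centre A, recruitment delay log-normal with median
0.2 years (shifted upward in the persistent class), follow-up log-normal
with median 5.1 years clipped to 0.2–23.4, Gamma inter-visit gaps averaging
half a year. PGA has two classes (89%/11%): the majority declines from
about PGA 3.2 to low-grade activity, the minority starts near 4.8 and stays
active; on the square-root scale these are cubic curves with intercepts
1.80 and 2.20. Modified DAS has three classes (16%/12%/72%):
high-slow-improving, high-persistent and low-fast-improving. Variance
components (random intercept SD 0.30, slope SD 0.03, residual SD 0.28 on
the transformed scale) were chosen to give clear but imperfect
classification — entropy around 0.8, matching a confidently selected
two-class solution. Visit-level PGA missingness is logistic in true
baseline severity and centre with the intercept calibrated so the overall
rate is about 13%; baseline features are MCAR-masked at the cohort's
documented completeness rates. Binary baseline features are drawn with
marginal prevalences 24.4/9.2/11.7/6.3/12.5% and log odds ratios
$\ln 1.91$ (abnormal respiration) and $\ln 1.92$ (lipodystrophy) for
membership of the persistent class, the rest null.

Deliberate non-features, which bound what passing tests demonstrate:

* **No remission pile-up at zero.** Real activity scores have a point mass
  at 0 that a Gaussian mixture on the square-root scale does not model;
  during design we found that floor clipping at realistic rates biases the
  estimated mixture proportion downward by several points. The generator
  therefore keeps class trajectories in the interior of the scale (clipping
  to the instrument range remains, as a guard, affecting well under 2% of
  observations). Tests passing on these cohorts show the estimator works
  when its model holds — not that boundary pile-up is handled.
* **Independent latent classes for PGA and DAS** in the joint simulator:
  the observed association between the two classifications is an empirical
  finding, not a generator target, so the simulated cross-tabulation is
  near-independent by construction.
* **No feature–feature correlation** in the baseline generator (a
  Gaussian-copula knob is the natural extension), no medication exposure,
  no calendar-time effects, no informative visit process.
* Even with everything correctly specified, the MLE of a small mixture
  weight carries a finite-sample shrinkage of about $-0.02$ at $n = 519$
  and entropy 0.8 (verified during design against heavy multistarts and
  with masking disabled); recovery checks therefore compare against the
  generating value within three binomial standard errors rather than
  expecting exact unbiasedness.
* At the reference size, the two rare binary features (prevalence 9.2% and
  6.3%, odds ratios near 1.9) sit at the edge of what the weighted lasso
  can retain: their realised single-cohort log odds ratios scatter with SE
  around 0.4–0.45, so retention is seed-dependent and pooled odds ratios
  are summarised across replicate cohorts where retained.

## Problem sizes used by the tests and scripts

The unit suite exercises the models on simulated cohorts of 80–300
patients; recovery checks run 20 replicate cohorts at the reference size
n = 519 with class counts 1–3 and a reduced multistart (the k-means start
is reliable for well-separated two-class data); the acceptance script fits
class counts 1–4 with 12 starts, 10 imputations and 10-fold
cross-validation, and summarises the rare-feature pooled odds ratios over
20 replicate cohorts because single-cohort retention is seed-dependent.
These sizes are the package's choices for routine verification; all of
them scale up by argument.

## Known limitations

Ordered-logistic mixtures for categorical outcomes, time-varying
covariates, joint multivariate (PGA + DAS) mixtures and medication
modelling are out of scope. The bootstrap confidence bands treat the
asymptotic normal of the packed parameters as exact and ignore model
selection; the imputation's multinomial draw ignores parameter uncertainty;
the GEE assumes a common exchangeable correlation across clusters. The
modified-DAS component weighting (1, 1, 1, 2 by default) is configurable
because only the 0–5 total is standardised.
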