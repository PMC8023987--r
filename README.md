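# trajmix

Growth mixture models and baseline prediction of severe disease-activity
trajectories in juvenile dermatomyositis (JDM) cohorts.

JDM is a rare paediatric autoimmune disease. In registry cohorts, patients
attend clinic roughly twice a year and each visit records activity scores:
the physician's global assessment (PGA, 0–10) and the cutaneous modified
Disease Activity Score (modified DAS, 0–5). Most children improve; a
minority stay persistently active for years. trajmix is for
biostatisticians and clinical researchers who want to (1) separate these
trajectory patterns into latent classes, (2) diagnose whether missing
scores distort the model, and (3) ask which features at first presentation
predict membership of the persistently active class.

## The model

For patient $i$ at time $t_{ij}$ (years since diagnosis), with latent class
$c_i = g$ and transformed outcome $y^*_{ij}$ (square root of PGA or DAS by
default):

$$y^*_{ij} = \beta_{g0} + \beta_{g1} t_{ij} + \beta_{g2} t_{ij}^2 +
  \beta_{g3} t_{ij}^3 + w_i^\top\gamma + b_{0i} + b_{1i} t_{ij} +
  \varepsilon_{ij},$$

with class probabilities $\pi_g$, random intercept/slope
$(b_{0i}, b_{1i}) \sim N(0, D)$ and residual
$\varepsilon_{ij} \sim N(0, \sigma^2)$. The marginal likelihood integrates
the random effects analytically and is maximised directly by multistart
BFGS with an analytic gradient (compiled in C++). The number of classes is
chosen by fitting $G = 1 \ldots G_{\max}$ and taking the lowest BIC
($-2\ell + k\ln n$, $n$ = patients), with relative entropy as the secondary
criterion. Around the mixture sit: a logistic GEE (exchangeable working
correlation, sandwich SEs) for visit-level outcome missingness;
chained-equations multiple imputation of baseline features; and an
L1-penalised logistic regression for class-2 membership in which each
patient enters weighted by their posterior class probabilities, with the
penalty chosen by 10-fold cross-validated AUC and coefficients pooled
across imputations by a majority rule.

No patient data ship with the package: a seeded simulator
(`default_sim_spec()`, `simulate_cohort()`) generates cohorts with the
statistical structure the analysis assumes (519 patients, two PGA classes
89%/11%, three DAS classes 16%/12%/72%, ~13% MAR visit missingness driven
by baseline severity and centre, class-associated rare baseline features),
so every stage runs end to end. See `vignettes/trajectory-mixtures.Rmd`
for the modelling choices and what the simulator does and does not
emulate.

## Worked example

```r
library(trajmix)

sim <- simulate_cohort(default_sim_spec("pga", 300), seed = 42)
co  <- truncate_followup(sim$cohort, 10)   # closed 10-year horizon
co
#> <cohort> 300 patients, 3526 visits, follow-up 0.0-10.0 y
#>   PGA observed at 3065 visits, modified DAS at 0

fit <- fit_gmm(co, gmm_spec(2, outcome = "pga"), n_starts = 10, seed = 1)
fit
#> <gmm_fit> pga, G=2, degree 3, sqrt transform
#>   n=300 patients (0 excluded, no usable outcome)
#>   loglik -902.20, k=14, BIC 1884.2, entropy 0.829, converged TRUE
#>   class proportions: 0.868 0.132
```

The fitted class proportions track the generating 89%/11% split; entropy
0.83 says patients are assigned with reasonable confidence. Class 2 — the
smaller class, always ordered second — is the persistently active one; its
predicted median PGA barely falls over a decade:

```r
predict_trajectory(fit, class = 2, c(0, 2, 5, 10), ci = "delta")
#>    t median lower upper
#> 1  0   4.66  3.82  5.59
#> 2  2   4.13  3.62  4.68
#> 3  5   3.88  3.33  4.46
#> 4 10   4.25  3.15  5.51

fit_gee_missingness(co)
#> <gee_result> logistic GEE, exchangeable alpha = 0.0006, 266 clusters
#>                     estimate  robust_se      z        p
#> (Intercept)        -2.645      0.207    -12.75  3.1e-37
#> sexM               -0.019      0.117     -0.16  0.87
#> age_at_diagnosis    0.019      0.014      1.37  0.17
#> t                  -0.013      0.019     -0.69  0.49
#> pga0                0.112      0.030      3.70  2.1e-04
#> centreA             0.520      0.109      4.77  1.8e-06
```

The GEE finds exactly the missingness drivers the simulator planted —
baseline PGA and centre — which is why centre sits in the mixture model's
mean (missingness then ignorable under MAR). The remaining stages:

```r
imp <- impute_baseline(co$baseline, m = 10, seed = 3)   # chained equations
lr  <- lasso_predict(fit, imp, seed = 4)                # weighted lasso
run_pipeline(pipeline_config(seed = 1))                 # everything, with artifacts
```

`run_pipeline()` writes per-stage CSV/JSON artifacts and a `manifest.json`
to its output directory. A thin command-line wrapper is provided at
`inst/cli/trajmix.R` (`Rscript trajmix.R run --seed 1 --out dir`).

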