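# brainAGE: lifestyle risk and the brain-age gap

Structural brain aging varies widely between people of the same
chronological age. The **Brain Age Gap Estimation (BrainAGE)** framework
quantifies this variability by training a machine-learning model to
predict age from gray-matter (GM) morphology and reading the signed
prediction gap,

```
BrainAGE = estimated age − chronological age,
```

as a biomarker: positive values mean a brain that looks older than its
years (accelerated aging), negative values a younger-looking brain. This
package implements, end to end, an epidemiological analysis linking a
**combined lifestyle risk score** — smoking, alcohol consumption, social
integration and physical activity folded into one number — to BrainAGE in
an older adult cohort, together with a calibrated synthetic cohort
generator so that the entire pipeline is testable without access to any
cohort data. It is aimed at researchers in imaging epidemiology and
biostatistics who want a reproducible, tested reference implementation of
this analysis style.

## What the package computes

**Lifestyle exposures** (`computePackYears`, `computeAlcoholGramsPerMonth`,
`computeSocialIndex`, `computeMetScore`): pack-years = years smoked ×
cigarettes/day ÷ 20; pure alcohol in g/month from beverage volumes and
ethanol fractions (789 g/L); a Berkman-style social integration index
(partnership + close ties + memberships); MET-hours of sportive activity.

**Combined lifestyle risk score** (`combinedRiskScore`): each exposure is
z-scored, protective behaviors (social integration, activity) are
sign-reversed, and each variable is shifted so risk components are
non-negative (z − min z) and protective components non-positive; the sum
is the combined score — higher is riskier, zero is a balanced profile.
Transform constants are stored so the fitted scorer applies to new
subjects without refitting (`applyRiskScore`).

**Brain-age estimation** (`fitPCA`, `fitRVR`, `leaveKOutEstimate`): GM
probability features are reduced by PCA, then a **relevance vector
regression** (sparse Bayesian learning with per-weight precision
hyperparameters α and noise precision β, tuned by evidence maximization
with pruning) maps reduced features to age. Estimation is cross-validated
with a sex-split leave-10-out scheme — every subject is predicted by a
model that never saw them, trained only on same-sex subjects — and the
raw gaps are detrended by least squares on {1, age, age²}
(`detrendQuadratic`), which removes the regression-to-the-mean age bias
and centers BrainAGE at zero.

**Inference** (`fitLifestyleModel`, `quantifyMonths`,
`testSexInteraction`, `compareLinearQuadratic`, `smokerGroupAnalysis`,
`computePower`): multiple regressions of BrainAGE on lifestyle under
three age-handling approaches (1: age as covariate; 2: age omitted;
3: age regressed out of BrainAGE first), standardized β, ΔR² of the
lifestyle term, residual MAE, a 3-SD outlier rule, Bonferroni correction
at α/15, effect sizes converted to months of brain age per exposure unit
(b₃ × 12), sex-interaction and stratified ANCOVAs, linear-vs-quadratic
curve comparison, age-matched never/moderate/severe smoker contrasts, and
noncentral-F power analysis (λ = f²·n).

## Worked example

```r
library(brainAGE)

cfg    <- simulationConfig(nSubjects = 400, seed = 42)
cohort <- simulateCohort(cfg)

rs <- combinedRiskScore(phenotypes(cohort))
rs
#> RiskScore: 400 subjects; mean combined score -1.012

est    <- leaveKOutEstimate(cohort, k = 10, sexSplit = TRUE, seed = 42)
result <- brainAgeResult(cohort, est)
result
#> BrainAgeResult: 400 subjects
#>   mean raw gap 0.006 y; detrended BrainAGE mean -1.07e-16, SD 5.18 y
#>   removed trend: 14.324 + -0.5304 age + 0.004285 age^2

ph <- phenotypes(cohort)
performanceReport(ph$age, brainAgeTable(result)$estimated_age,
                  brainAGE(result), ph$sex)
#> PerformanceReport
#>  stratum  mae r_est     r_gap    r2   n
#>      all 4.05 0.960  1.45e-17 0.922 400
#>     male 3.99 0.959  1.46e-02 0.919 237
#>   female 4.13 0.962 -1.84e-02 0.925 163

ph$risk_score <- riskScores(rs)
ph$brainage   <- brainAGE(result)
fit <- fitLifestyleModel(ph, lifestyle = "risk_score", approach = 1,
                         covariates = "sex")
fit
#> RegressionFit (approach 1, all, n = 400): F = 1.610, p = 0.187
#>   R2 = 0.0120 (lifestyle dR2 = 0.0120), residual MAE 4.04 y
#>        term         b    beta       t      p
#>     sexmale 0.1101000 0.01050 0.20880 0.8350
#>         age 0.0007802 0.00302 0.06045 0.9520
#>  risk_score 0.2790000 0.11000 2.19600 0.0287
```

Reading the output: the mean combined risk score of −1.01 says this
synthetic cohort leans protective overall. The estimator reaches a mean
absolute error of ~4 years with r ≈ 0.96 between chronological and
estimated age, and the detrended BrainAGE is centered at zero by
construction. In the regression, one unit of combined lifestyle risk
predicts b = 0.28 years of additional BrainAGE —
`quantifyMonths(0.279)` ≈ 3.3 months of apparent brain aging per unit of
risk — adjusted for sex and age; at n = 400 and this effect size the
association does not clear conventional significance, which is what the
power analysis predicts for small samples:

```r
computePower(f2 = 0.05, n = 622, alpha = 0.003, nPredictors = 5)
#> PowerResult: power 0.9952 (lambda 31.10, F crit 8.878 on 1, 616 df)
```

`runPipeline()` chains all of the above (simulate or load → score →
estimate → analyze → report) and writes tidy CSV/JSON outputs with a
provenance block (configuration hash, seed, package version).

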