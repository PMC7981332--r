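---
title: "Brain-age gap estimation and lifestyle risk: models and methods"
author: "brainAGE package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age gap estimation and lifestyle risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and the design decisions taken where the problem was genuinely
open. The companion README shows a worked run; here we explain *why* the
pieces look the way they do.

## The brain-age model

Brain age estimation treats chronological age as a supervised learning
target: gray-matter (GM) probability features $x_i \in [0,1]^p$ predict
age $a_i$, and the signed residual of that prediction on held-out
subjects,
$$\mathrm{BrainAGE}_i = \hat a_i - a_i,$$
is read as a biomarker of accelerated ($>0$) or decelerated ($<0$)
structural aging. Three ingredients matter.

**Dimension reduction.** Neighboring GM features are strongly
correlated, so a PCA (`fitPCA`) is fitted *within each training set* and
held-out subjects are projected onto it — refitting inside every fold is
what keeps the cross-validation leak-free. The default retains the
components explaining 95% of training variance, capped at the training
rank; the cap matters because the synthetic features have an (almost)
rank-one age signal, so very few components carry information.

**Relevance vector regression.** The age model is Tipping-style sparse
Bayesian regression: $y = \Phi w + \varepsilon$ with
$\varepsilon \sim N(0, \beta^{-1})$ and independent priors
$w_j \sim N(0, \alpha_j^{-1})$. The kernel basis is
$\Phi = [\mathbf 1, K]$ with $K_{nm} = x_n^\top x_m$ (linear kernel, the
standard choice in the brain-age literature; an RBF kernel is available
via `kernel = "rbf"`). Hyperparameters maximize the marginal likelihood
through the classic fixed-point sweeps
$$\gamma_j = 1 - \alpha_j \Sigma_{jj}, \qquad
  \alpha_j \leftarrow \gamma_j / \mu_j^2, \qquad
  \beta \leftarrow (N - \textstyle\sum_j \gamma_j) / \lVert y - \Phi\mu \rVert^2,$$
pruning basis functions whose precision exceeds `pruneThreshold = 1e9`.
Convergence requires the largest relative change in the retained
$\alpha_j$ to fall below `tol = 1e-6` *and* a stable $\beta$; at most
`maxIter = 1000` sweeps are run, after which the best-evidence iterate is
returned and flagged in the model (`@converged`). These are conventional
settings and all are exposed.

*Numerical form.* For the linear kernel, $\Phi = C D$ with
$C = [\mathbf 1, X]$ of rank $r = k+1 \ll N$, and the posterior is
evaluated through the push-through identity
$\mu = \beta A^{-1} D^\top (I_r + \beta G P)^{-1} C^\top y$ with
$G = C^\top C$, $P = D A^{-1} D^\top$, and
$\gamma_j = \beta\, d_j^\top (I_r + \beta G P)^{-1} G\, d_j / \alpha_j$.
This is algebraically identical to the dense computation (a test asserts
agreement of the log evidence to $10^{-6}$) but is free of the
large-$\beta$ cancellation that a naive Woodbury evaluation suffers when
the fit is near-exact, and it makes a 1000-subject leave-10-out run a
matter of seconds. The noise precision is capped at $10^{10}$ so that
noise-free inputs (a legitimate test condition) stay finite. The evidence
itself is computed via the stable decomposition
$y^\top C_y^{-1} y = \beta \lVert y - \Phi\mu \rVert^2 + \mu^\top A \mu$.
A unit test checks the converged evidence against brute-force
maximization by an independent multi-start optimizer on a five-function
basis.

**Cross-validation and detrending.** Estimation uses a sex-split
leave-$k$-out scheme (`leaveKOutEstimate`, $k = 10$ by default): within
each sex, subjects are shuffled once with the given seed and chunked into
consecutive folds of $k$ (the remainder forms a smaller final fold); each
fold is predicted by a model trained on the rest of its stratum only.
Separate male/female models reflect known sex differences in GM
architecture and aging trajectories. Raw gaps show the well-known
regression-to-the-mean age bias — young subjects over-, old subjects
under-estimated, with curvature — so the gaps are detrended by OLS on
$\{1, a, a^2\}$ (`detrendQuadratic`). The residuals are exactly
orthogonal to that design, hence mean BrainAGE is 0.00 by construction;
detrending is done once on the pooled cohort (whether the original
framework detrended per sex is not documented; pooled is the default
here) and the coefficients are returned so subsamples inherit the same
correction.

## The combined lifestyle risk score

Four exposures enter: pack-years of smoking (years × cigarettes/day ÷
20 — the standard pack-year; the literal years × cigarettes product is
available behind `perPack = FALSE` but is 20× too large to match
published descriptive ranges), pure alcohol in g/month (serving volume ×
ethanol volume fraction × 789 g/L × servings/month, with conventional
fractions beer 0.048, wine 0.11, spirits 0.33 — configurable, since the
source instrument does not publish them), a Berkman-style social
integration index (2 for partnered + children + close relatives +
friends + active memberships, uncapped), and MET-hours of sportive
activity (≤ 4 activities; the reporting window is treated as-is, since
the instrument's month/week phrasing is ambiguous).

Each variable is z-scored on the fitting cohort; protective variables
are sign-reversed; risk components are shifted by their minimum
($z - \min z \ge 0$) and protective components by their maximum
($-z - \max(-z) \le 0$); the combined score is the sum. The shift
direction is a deliberate correction: shifting risk z-scores by *adding*
a (negative) minimum cannot produce non-negative components, whereas the
subtractive form does, and its closed-form cohort mean
$-\min z_{smoke} - \min z_{alc} + \min z_{MET} + \min z_{social}
\approx -1.05$ under the default calibration is consistent with
published summaries of this score construction (≈ −1.0 in comparable
cohorts), while the additive reading lands near −3.4. Transform
constants are persisted in the `RiskScore` object and re-applied to new
subjects without refitting.

## The synthetic cohort generator

`simulateCohort` exists so every downstream stage is testable with known
ground truth. It emulates:

- **Ages** uniform on 18.5–87 y (population-based adult cohorts are
  roughly flat over the adult span; the exact histogram of any real
  cohort is not published), sex Bernoulli with 55.3% male.
- **Lifestyle exposures** from *truncated-normal mixtures*: a point mass
  at the variable's minimum plus a doubly truncated normal. The mixture
  is needed, not cosmetic: the published descriptives for pack-years
  (mean 13.61, SD 21.73, min 0) imply a coefficient of variation of 1.6,
  which no lower-truncated normal can reach (its CV is bounded by 1, the
  exponential limit). A large never-smoker mass is also what real
  cohorts show. `solveTruncnorm` finds the smallest feasible point mass
  and then moment-matches $(\mu, \sigma)$ so the mixture reproduces the
  target mean and SD essentially exactly — this is the "truncation
  adjustment" behind the calibration tests. Variables are drawn
  independently by default; inter-correlations of the exposures are not
  published, and independence is the conservative default.
- **A latent brain-age offset**
  $o_i = \sum_v \frac{m_v}{12}(x_{iv} - \bar x_v) + N(0, \sigma_o^2)$,
  with defaults $m = (+0.6, 0, -0.55, 0)$ months per unit for
  (pack-years, alcohol, MET, social) and $\sigma_o = 5$ y — effect sizes
  and gap dispersion of the magnitude reported for older adult cohorts.
- **GM features**
  $f_{ij} = \mathrm{clip}_{[0,1]}(b_j + L_j\, g(a_i + o_i) +
  \epsilon_{ij})$ with $g(a) = c_1 (a - 50) + c_2 (a-50)^2$, defaults
  $c_1 = -4\times10^{-3}$/y, $c_2 = -2\times10^{-5}$/y² (decline
  accelerating with age, strictly monotone over the configured range),
  loadings $L_j \in [0.5, 1.5]$ and baselines $b_j \in [0.55, 0.8]$
  drawn once from the seed, and feature noise SD 0.02. Crucially the
  offset enters *only through effective age*: the estimator can recover
  it solely from anatomy, which is the causal reading the analysis
  assumes. The clipping rate is logged in the cohort metadata.

What the generator does **not** emulate: voxel topology and spatial
autocorrelation beyond a single shared aging factor, scanner/site
effects, non-Gaussian feature noise, exposure inter-correlations, and
any real cohort's age histogram. Passing tests therefore demonstrate
correctness of the *pipeline machinery and its statistical properties*
(calibration, no leakage, type-I error, parameter recovery), not
real-data performance.

## The statistical layer

- **Three age-handling approaches** address the circularity of modelling
  an age-derived outcome: (1) age as covariate, (2) age omitted, (3) age
  regressed out of BrainAGE before modelling. Approach 1 forces age into
  the covariate set; 2 and 3 exclude it. When lifestyle is exactly
  orthogonal to age, approaches 1 and 3 give identical lifestyle
  coefficients (Frisch–Waugh–Lovell; asserted to $10^{-8}$ in tests).
- **Standardized β** uses $\beta_j = b_j\, s_{x_j} / s_y$; **ΔR²** is
  the increment over the covariates-only model on identical rows;
  **residual MAE** is the mean absolute OLS residual.
- **Outlier rule**: excluded iff the value lies ≥ 3 *population* SDs
  from the mean, computed once (no iteration). The population estimator
  is deliberate: sample-SD z-scores are bounded by $(n-1)/\sqrt n$, so a
  lone extreme point in a small sample could never be flagged under the
  sample convention.
- **Multiplicity**: the standard analysis family is 15 tests (5
  lifestyle terms × whole sample + two sexes), gated at
  $\alpha/15 \approx 0.003$.
- **Quantification**: months of brain age per exposure unit is
  $b_3 \times 12$.
- **Smoker groups**: never (= 0), moderate (0 < pack-years < 20), severe
  (≥ 20); groups are age-matched within sex by greedy nearest-neighbour
  matching without replacement (caliper 2 y, seeded reference order,
  ties broken by subject id — the matching algorithm itself is not
  documented in the source analyses, so a simple deterministic one was
  chosen), followed by an ANCOVA of BrainAGE on group + sex + age +
  education with adjusted means and pairwise contrasts from estimated
  marginal means (emmeans). Multivariate (Wilks-type) statistics are
  deliberately out of scope; per-outcome univariate F tests are used.
- **Power**: for a tested term with $df_1$ numerator degrees of freedom
  in a $p$-predictor model, $\lambda = f^2 n$, critical
  $F_{1-\alpha}(df_1, n-p-1)$, and power is the noncentral upper tail.
  With $f^2 = 0.05$, $n = 622$, $\alpha = 0.003$, $df_1 = 1$, $p = 5$
  this gives 0.9952 — displayed as 0.99 at two decimals (truncated); a
  Monte-Carlo oracle of $10^5$ simulated regressions agrees. The
  $\lambda = f^2 n$ variant (single tested predictor) is the default;
  the deviation-from-zero variant is available through `testedDf`.
- **Sex coding**: female = 0, male = 1 throughout (F tests are invariant
  to this; coefficients are reported relative to it). Missing data are
  handled by listwise deletion, matching complete-case analysis;
  p-values are two-sided.

## Problem sizes and degenerate inputs

The test suite exercises the pipeline at the sizes the properties
require while staying quick: moment calibration at n = 20 000
(phenotypes only), the detrend-centering run at n = 1000 with the full
sex-split leave-10-out estimator, parameter recovery over 50 seeds at
n = 600 via the generator's ground-truth offsets, type-I error over 500
null replicates at n = 150, and estimator-path effect recovery at
n = 200 over 5 seeds. Degenerate inputs are contracts, not accidents:
zero-variance exposures and collinear designs raise errors naming the
offending variable; zero-variance correlations are flagged undefined
rather than silently 0; all-equal ages make the detrend design collinear
and error; a stratum not exceeding the fold size errors with advice to
disable the sex split or reduce k; constant targets leave the RVR bias
to carry the solution.

## Known limitations

- The GM feature model is a single-factor caricature; estimator accuracy
  on it is better than on real morphology, so absolute MAE values are
  not comparable to real-cohort reports.
- The combined score assumes independent exposures at generation time;
  the scorer itself is agnostic.
- Approach 2's coefficients absorb residual age confounding by design;
  that is a property of the approach, not a bug.
- NIfTI ingestion flattens one 3D GM map per subject behind a mean-mask
  threshold; no registration or smoothing is performed — preprocessing
  is out of scope.
- Feature matrices are exchanged as CSV (HDF5 would be preferable for
  very wide matrices but is not required at the sizes handled here).
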