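#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats coef lm predict pf qf pnorm qnorm dnorm resid sd var
#'   anova as.formula complete.cases cor cor.test median model.matrix
#'   quantile rbinom rnorm runif setNames
NULL

#' Simulation settings for a synthetic brain-aging cohort
#'
#' Holds every knob of the synthetic-data generator: cohort size, the adult
#' age range, the sex split, the four lifestyle exposure distributions
#' (truncated normals with an optional point mass at the minimum), the
#' per-variable brain-age effect in months per exposure unit, and the
#' gray-matter feature model (per-year decline with a quadratic component,
#' feature noise, latent brain-age noise).
#'
#' @slot nSubjects number of subjects to simulate.
#' @slot seed integer seed; the generator is fully reproducible given the
#'   configuration and this seed.
#' @slot ageRange numeric(2), minimum and maximum age in years.
#' @slot propMale fraction of male subjects in `[0, 1]`.
#' @slot lifestyle data.frame with one row per exposure
#'   (`pack_years`, `alcohol_g_month`, `met_score`, `social_index`) and
#'   columns `mean`, `sd`, `min`, `max`, `pMin` (probability of the point
#'   mass at `min`), `effectMonths` (months of brain-age offset per unit),
#'   and the solved underlying truncated-normal parameters `mu`, `sigma`.
#' @slot nFeatures number of gray-matter features (>= 2).
#' @slot featureNoiseSd feature noise SD in GM-probability units.
#' @slot ageTrend numeric(2), linear and quadratic coefficients (per year,
#'   per year squared) of the mean GM decline, centered at 50 years.
#' @slot estimatorNoiseSd SD in years of the latent brain-age offset noise.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nSubjects = "integer",
        seed = "integer",
        ageRange = "numeric",
        propMale = "numeric",
        lifestyle = "data.frame",
        nFeatures = "integer",
        featureNoiseSd = "numeric",
        ageTrend = "numeric",
        estimatorNoiseSd = "numeric"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@ageRange) != 2L || object@ageRange[1] >= object@ageRange[2])
        msg <- c(msg, "ageRange: need age_min < age_max")
    if (object@propMale < 0 || object@propMale > 1)
        msg <- c(msg, "propMale: must lie in [0, 1]")
    if (object@nSubjects < 1L)
        msg <- c(msg, "nSubjects: must be >= 1")
    if (object@nFeatures < 2L)
        msg <- c(msg, "nFeatures: must be >= 2 (PCA undefined otherwise)")
    if (object@featureNoiseSd < 0)
        msg <- c(msg, "featureNoiseSd: must be >= 0")
    if (object@estimatorNoiseSd < 0)
        msg <- c(msg, "estimatorNoiseSd: must be >= 0")
    if (length(object@ageTrend) != 2L)
        msg <- c(msg, "ageTrend: need (linear, quadratic) coefficients")
    ls <- object@lifestyle
    need <- c("mean", "sd", "min", "max", "pMin", "effectMonths")
    if (!all(need %in% colnames(ls))) {
        msg <- c(msg, sprintf("lifestyle: missing columns %s",
            paste(setdiff(need, colnames(ls)), collapse = ", ")))
    } else {
        if (any(ls$sd <= 0))
            msg <- c(msg, sprintf("lifestyle: sd must be > 0 (offending: %s)",
                paste(rownames(ls)[ls$sd <= 0], collapse = ", ")))
        if (any(ls$min >= ls$max))
            msg <- c(msg, "lifestyle: need min < max for every variable")
        if (any(ls$pMin < 0 | ls$pMin >= 1))
            msg <- c(msg, "lifestyle: pMin must lie in [0, 1)")
    }
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort: phenotypes plus gray-matter features
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay `"gm"`
#' holds the gray-matter probability features (features x subjects, values
#' in `[0, 1]`) and whose `colData` holds the per-subject phenotypes:
#' chronological age, sex, education (ISCED level), BMI, DemTect score, the
#' four lifestyle exposures, and -- for simulated cohorts -- the latent
#' ground-truth brain-age offset `true_offset` in years. The configuration
#' used to simulate the cohort, if any, is stored in `metadata(x)$config`.
#'
#' @exportClass BrainAgeCohort
setClass("BrainAgeCohort", contains = "SummarizedExperiment")

setValidity("BrainAgeCohort", function(object) {
    msg <- character()
    if (!"gm" %in% SummarizedExperiment::assayNames(object))
        return("assay 'gm' (gray-matter features) is required")
    gm <- SummarizedExperiment::assay(object, "gm")
    if (anyNA(gm))
        msg <- c(msg, "assay 'gm' must not contain missing values")
    else if (min(gm) < 0 || max(gm) > 1)
        msg <- c(msg, "assay 'gm' must be bounded to [0, 1]")
    if (nrow(object) < 2L)
        msg <- c(msg, "need >= 2 gray-matter features")
    need <- c("age", "sex")
    have <- colnames(SummarizedExperiment::colData(object))
    if (!all(need %in% have))
        msg <- c(msg, sprintf("colData must contain %s",
            paste(setdiff(need, have), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Fitted combined lifestyle risk scorer
#'
#' Stores the per-variable transform constants learned on a fitting cohort
#' (z-score mean and SD, plus the shift constant: the minimum of the
#' z-score for risk variables, the maximum of the sign-reversed z-score for
#' protective variables) together with the per-subject components and the
#' combined score. Applying the scorer to new subjects reuses these
#' constants; there is no silent refit.
#'
#' @slot constants data.frame with one row per lifestyle variable and
#'   columns `mean`, `sd`, `direction` (+1 risk, -1 protective), `shift`.
#' @slot components numeric matrix (subjects x 4) of transformed components;
#'   risk components are >= 0, protective components <= 0 on the fitting
#'   cohort.
#' @slot score numeric vector, combined risk score (the row sums).
#' @exportClass RiskScore
setClass("RiskScore",
    representation(constants = "data.frame", components = "matrix",
        score = "numeric"))

setValidity("RiskScore", function(object) {
    if (!all(c("mean", "sd", "direction", "shift") %in%
            colnames(object@constants)))
        return("constants must have columns mean, sd, direction, shift")
    if (nrow(object@components) != length(object@score))
        return("components and score must describe the same subjects")
    ok <- max(abs(rowSums(object@components) - object@score)) < 1e-8
    if (!ok) return("score must equal the sum of the four components")
    TRUE
})

#' Principal component reduction of gray-matter features
#'
#' @slot center feature means of the training data.
#' @slot rotation orthonormal loadings (features x k).
#' @slot sdev singular-value-derived component SDs (all components).
#' @slot k number of retained components.
#' @slot varianceExplained fraction of variance per retained component.
#' @exportClass PCAModel
setClass("PCAModel",
    representation(center = "numeric", rotation = "matrix", sdev = "numeric",
        k = "integer", varianceExplained = "numeric"))

setValidity("PCAModel", function(object) {
    if (ncol(object@rotation) != object@k)
        return("rotation must have k columns")
    G <- crossprod(object@rotation)
    if (max(abs(G - diag(object@k))) > 1e-8)
        return("loadings must be orthonormal")
    ev <- object@varianceExplained
    if (length(ev) && any(diff(ev) > 1e-12))
        return("explained-variance fractions must be non-increasing")
    TRUE
})

#' Relevance vector regression model
#'
#' Sparse Bayesian regression in the style of Tipping's relevance vector
#' machine: a kernel basis over the training points (plus a bias), a
#' zero-mean Gaussian prior with one precision hyperparameter per weight,
#' and a Gaussian noise model with precision `beta`. Hyperparameters are
#' set by iterative evidence (type-II marginal likelihood) maximization;
#' basis functions whose precision diverges are pruned.
#'
#' @slot kernel kernel specification: `"linear"`, `"rbf"` or
#'   `"precomputed"` (the design matrix was supplied directly).
#' @slot kernelWidth RBF width (ignored otherwise).
#' @slot relevanceVectors training inputs of the retained kernel basis
#'   functions (rows), or a 0-row matrix for `"precomputed"`.
#' @slot weights posterior weight means of the retained basis functions.
#' @slot alpha per-weight precision hyperparameters (retained only).
#' @slot beta noise precision.
#' @slot bias bias term (0 if the bias was pruned).
#' @slot hasBias whether the bias survived pruning.
#' @slot basisIndex indices of retained basis functions into the original
#'   basis (0 denotes the bias).
#' @slot logEvidence log marginal likelihood at convergence.
#' @slot converged logical; `FALSE` means the iteration cap was reached and
#'   the best iterate was returned (also recorded as a warning).
#' @slot iterations number of update sweeps performed.
#' @exportClass RVRModel
setClass("RVRModel",
    representation(kernel = "character", kernelWidth = "numeric",
        relevanceVectors = "matrix", weights = "numeric", alpha = "numeric",
        beta = "numeric", bias = "numeric", hasBias = "logical",
        basisIndex = "integer", logEvidence = "numeric",
        converged = "logical", iterations = "integer"))

setValidity("RVRModel", function(object) {
    msg <- character()
    if (object@beta <= 0) msg <- c(msg, "beta must be > 0")
    if (length(object@weights) != length(object@alpha))
        msg <- c(msg, "weights and alpha must align")
    if (any(!is.finite(object@weights)))
        msg <- c(msg, "weights must be finite")
    if (length(msg)) msg else TRUE
})

#' Per-subject brain-age estimation result
#'
#' @slot table data.frame with columns `subject_id`, `age` (chronological),
#'   `sex`, `estimated_age`, `raw_gap` (estimated minus chronological) and
#'   `brainage` (the quadratically detrended gap).
#' @slot detrendCoef coefficients (intercept, age, age^2) of the removed
#'   quadratic age trend.
#' @slot plan data.frame cross-validation plan: `subject_id`, `stratum`,
#'   `fold`.
#' @exportClass BrainAgeResult
setClass("BrainAgeResult",
    representation(table = "data.frame", detrendCoef = "numeric",
        plan = "data.frame"))

setValidity("BrainAgeResult", function(object) {
    tb <- object@table
    need <- c("subject_id", "age", "estimated_age", "raw_gap", "brainage")
    if (!all(need %in% colnames(tb)))
        return(sprintf("table must contain %s", paste(need, collapse = ", ")))
    if (max(abs(tb$raw_gap - (tb$estimated_age - tb$age))) > 1e-10)
        return("raw_gap must equal estimated_age - age exactly")
    if (abs(mean(tb$brainage)) > 1e-8)
        return("detrended BrainAGE must have mean zero")
    TRUE
})

#' Accuracy report for a brain-age estimation run
#'
#' @slot overall data.frame with `mae` (mean absolute BrainAGE, years),
#'   `r_est` (Pearson r of chronological vs estimated age), `r_gap`
#'   (Pearson r of chronological age vs BrainAGE), `r2` (R squared of the
#'   estimated-on-chronological regression) and `n`.
#' @slot byStratum same columns, one row per stratum.
#' @slot undefined character vector naming statistics that were undefined
#'   (zero-variance input) and therefore reported as `NA`.
#' @exportClass PerformanceReport
setClass("PerformanceReport",
    representation(overall = "data.frame", byStratum = "data.frame",
        undefined = "character"))

#' One fitted lifestyle-to-BrainAGE regression
#'
#' @slot terms data.frame, one row per model term: `term`, `b`
#'   (unstandardized), `beta` (standardized), `t`, `p`.
#' @slot intercept model intercept.
#' @slot fstat overall model F statistic.
#' @slot fp overall model p value.
#' @slot r2 model R squared.
#' @slot deltaR2 increment in R squared attributable to the lifestyle
#'   term(s) over the covariates-only model.
#' @slot residMAE mean absolute residual in years.
#' @slot residSD SD of the absolute residuals.
#' @slot n number of subjects used (after listwise deletion and any
#'   outlier exclusion).
#' @slot approach age-handling approach (1, 2 or 3).
#' @slot stratum `"all"`, `"male"` or `"female"`.
#' @slot lifestyleTerms names of the lifestyle term(s).
#' @exportClass RegressionFit
setClass("RegressionFit",
    representation(terms = "data.frame", intercept = "numeric",
        fstat = "numeric", fp = "numeric", r2 = "numeric",
        deltaR2 = "numeric", residMAE = "numeric", residSD = "numeric",
        n = "integer", approach = "integer", stratum = "character",
        lifestyleTerms = "character"))

setValidity("RegressionFit", function(object) {
    msg <- character()
    if (object@deltaR2 < -1e-10) msg <- c(msg, "deltaR2 must be >= 0")
    if (object@residMAE < 0) msg <- c(msg, "residMAE must be >= 0")
    if (!object@approach %in% 1:3) msg <- c(msg, "approach must be 1, 2 or 3")
    if (length(msg)) msg else TRUE
})

#' Noncentral-F power analysis result
#'
#' @slot power achieved power in `[alpha, 1]`.
#' @slot lambda noncentrality parameter `f2 * n`.
#' @slot critF critical F value at the requested alpha.
#' @slot df1,df2 numerator and denominator degrees of freedom.
#' @exportClass PowerResult
setClass("PowerResult",
    representation(power = "numeric", lambda = "numeric", critF = "numeric",
        df1 = "numeric", df2 = "numeric"))

#' Smoker-group contrast result
#'
#' @slot groups factor per input subject: never / moderate / severe (or NA
#'   when pack-years are missing).
#' @slot matched data.frame of age-matched triplets: `subject_id`, `group`,
#'   `sex`, `age`.
#' @slot adjustedMeans data.frame of covariate-adjusted group means of
#'   BrainAGE (from the ANCOVA on the matched sample).
#' @slot fstat,p ANCOVA F test of the group factor.
#' @slot contrasts data.frame of pairwise group contrasts.
#' @exportClass SmokerGroupResult
setClass("SmokerGroupResult",
    representation(groups = "factor", matched = "data.frame",
        adjustedMeans = "data.frame", fstat = "numeric", p = "numeric",
        contrasts = "data.frame"))

#' End-to-end pipeline output
#'
#' @slot performance a [PerformanceReport-class].
#' @slot brainAge a [BrainAgeResult-class].
#' @slot riskScore the fitted [RiskScore-class].
#' @slot regressions data.frame, one row per term per model per approach
#'   per stratum (tidy layout: term, b, beta, t, p, F, R2, delta_R2, mae,
#'   n, approach, stratum, significant after the configured Bonferroni
#'   correction).
#' @slot power data.frame power table.
#' @slot provenance list with the configuration hash, seed and package
#'   version.
#' @exportClass ReportBundle
setClass("ReportBundle",
    representation(performance = "PerformanceReport",
        brainAge = "BrainAgeResult", riskScore = "RiskScore",
        regressions = "data.frame", power = "data.frame",
        provenance = "list"))
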