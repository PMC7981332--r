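#' Default calibration of the four lifestyle exposures
#'
#' Observed mean, SD, minimum and maximum of pack-years of smoking, pure
#' alcohol in grams per month, MET-hours of physical activity and the
#' social integration index in an older population-based adult cohort,
#' used as the default calibration targets of the generator.
#'
#' @return data.frame with columns `mean`, `sd`, `min`, `max` and one row
#'   per exposure.
#' @export
#' @examples
#' defaultLifestyleTargets()
defaultLifestyleTargets <- function() {
    data.frame(
        mean = c(13.61, 11.25, 14.32, 12.99),
        sd   = c(21.73, 19.87, 20.94, 6.40),
        min  = c(0, 0, 0, 3),
        max  = c(204, 198.5, 196, 53),
        row.names = c("pack_years", "alcohol_g_month", "met_score",
            "social_index"))
}

#' Build a simulation configuration
#'
#' Assembles and validates every setting of the synthetic cohort generator
#' and solves, once, the truncated-normal mixture parameters that reproduce
#' the requested lifestyle means and SDs after truncation. Exposures with a
#' strongly right-skewed target (SD larger than the truncated normal can
#' carry, as for pack-years where a large never-smoker fraction dominates)
#' automatically receive a point mass at the minimum; `pMin` overrides that
#' probability per variable.
#'
#' @param nSubjects cohort size.
#' @param seed integer seed (< 2^31).
#' @param ageRange numeric(2), age span in years.
#' @param propMale fraction of males.
#' @param lifestyleTargets data.frame as [defaultLifestyleTargets()].
#' @param effectMonths named numeric: months of brain-age offset per 1-unit
#'   exposure (positive = accelerating). Defaults inject the effects that
#'   motivate the pipeline: +0.6 months per pack-year and -0.55 months per
#'   MET-hour, none for alcohol and social integration.
#' @param pMin named numeric, point-mass probability at each variable's
#'   minimum; `NA` (default) solves the smallest feasible value.
#' @param nFeatures number of gray-matter features.
#' @param featureNoiseSd feature noise SD (GM-probability units).
#' @param ageTrend numeric(2): linear and quadratic coefficients of the
#'   mean GM decline per year, centered at age 50; both negative by default
#'   so decline accelerates with age.
#' @param estimatorNoiseSd SD (years) of the latent brain-age offset noise.
#' @return a validated [SimulationConfig-class].
#' @export
#' @examples
#' cfg <- simulationConfig(nSubjects = 100, seed = 7)
#' cfg
simulationConfig <- function(nSubjects, seed = 1L,
        ageRange = c(18.5, 87),
        propMale = 0.553,
        lifestyleTargets = defaultLifestyleTargets(),
        effectMonths = c(pack_years = 0.6, alcohol_g_month = 0,
            met_score = -0.55, social_index = 0),
        pMin = NULL,
        nFeatures = 100L,
        featureNoiseSd = 0.02,
        ageTrend = c(linear = -0.004, quadratic = -2e-5),
        estimatorNoiseSd = 5) {
    vars <- rownames(lifestyleTargets)
    ls <- lifestyleTargets
    ls$effectMonths <- 0
    if (!is.null(names(effectMonths)))
        ls[names(effectMonths), "effectMonths"] <- effectMonths
    else ls$effectMonths <- effectMonths
    ls$pMin <- NA_real_
    if (!is.null(pMin)) ls[names(pMin), "pMin"] <- pMin
    ls$mu <- ls$sigma <- NA_real_
    for (v in vars) {
        sol <- solveTruncnorm(ls[v, "mean"], ls[v, "sd"], ls[v, "min"],
            ls[v, "max"], ls[v, "pMin"])
        ls[v, c("mu", "sigma", "pMin")] <- c(sol$mu, sol$sigma, sol$pMin)
    }
    new("SimulationConfig",
        nSubjects = as.integer(nSubjects), seed = as.integer(seed),
        ageRange = as.numeric(ageRange), propMale = propMale,
        lifestyle = ls, nFeatures = as.integer(nFeatures),
        featureNoiseSd = featureNoiseSd, ageTrend = as.numeric(ageTrend),
        estimatorNoiseSd = estimatorNoiseSd)
}

withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
    expr
}

drawLifestyle <- function(n, row) {
    atMin <- runif(n) < row$pMin
    x <- rtruncnormInv(n, row$mu, row$sigma, row$min, row$max)
    x[atMin] <- row$min
    x
}

#' Simulate a synthetic brain-aging cohort
#'
#' Draws per-subject phenotypes (uniform ages, sex by the configured male
#' fraction, education, BMI, DemTect, and the four lifestyle exposures from
#' calibrated truncated-normal mixtures), computes the latent ground-truth
#' brain-age offset
#' \deqn{o_i = \sum_v \frac{m_v}{12}\,(x_{iv} - \bar x_v) + \varepsilon_i,
#'   \quad \varepsilon_i \sim N(0, \sigma_o^2),}
#' with \eqn{m_v} the configured months of offset per exposure unit, and
#' generates gray-matter features through the subject's *effective* brain
#' age (chronological age plus offset), so that downstream estimators can
#' only recover the offset from anatomy.
#'
#' @param config a [SimulationConfig-class].
#' @return a [BrainAgeCohort-class]; the latent offset is in
#'   `colData(x)$true_offset` and the configuration in
#'   `metadata(x)$config`.
#' @export
#' @examples
#' cohort <- simulateCohort(simulationConfig(50, seed = 1))
#' cohort
simulateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    n <- config@nSubjects
    ls <- config@lifestyle
    ph <- withSeed(config@seed, {
        age <- runif(n, config@ageRange[1], config@ageRange[2])
        sex <- factor(ifelse(runif(n) < config@propMale, "male", "female"),
            levels = c("female", "male"))
        education <- pmin(pmax(round(rnorm(n, 5, 2)), 1), 10)
        bmi <- pmin(pmax(rnorm(n, 27.5, 4.2), 16), 45)
        demtect <- pmin(pmax(round(rnorm(n, 14.8, 2.4)), 0), 18)
        expo <- vapply(rownames(ls), function(v) drawLifestyle(n, ls[v, ]),
            numeric(n))
        offset <- as.numeric(expo %*% (ls$effectMonths / 12)) -
            sum(ls$mean * ls$effectMonths / 12) +
            rnorm(n, 0, config@estimatorNoiseSd)
        data.frame(
            subject_id = sprintf("S%04d", seq_len(n)),
            age = age, sex = sex, education = education, bmi = bmi,
            demtect = demtect, expo, true_offset = offset,
            stringsAsFactors = FALSE)
    })
    gm <- generateGMFeatures(ph$age + ph$true_offset, config)
    colnames(gm) <- ph$subject_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(gm = gm),
        colData = S4Vectors::DataFrame(ph, row.names = ph$subject_id),
        metadata = list(config = config,
            clippingRate = attr(gm, "clippingRate")))
    new("BrainAgeCohort", se)
}

#' Generate gray-matter probability features from effective brain ages
#'
#' Each feature j follows
#' \deqn{f_{ij} = \mathrm{clip}_{[0,1]}\big(b_j + L_j\, g(a_i) +
#'   \epsilon_{ij}\big),}
#' where \eqn{g(a) = c_1 (a - 50) + c_2 (a - 50)^2} is the configured
#' linear-plus-quadratic decline, \eqn{L_j > 0} are fixed per-feature
#' loadings and \eqn{b_j} per-feature baselines, both drawn
#' deterministically from the configuration seed. With the default
#' negative coefficients the expectation is strictly decreasing in
#' effective age across the configured age span. The fraction of clipped
#' entries is attached as attribute `clippingRate`.
#'
#' @param effectiveAge numeric vector of effective brain ages (years).
#' @param config a [SimulationConfig-class].
#' @return numeric matrix, features x subjects, values in `[0, 1]`.
#' @export
generateGMFeatures <- function(effectiveAge, config) {
    stopifnot(is(config, "SimulationConfig"))
    if (config@nFeatures < 2L)
        stop("nFeatures must be >= 2 (PCA undefined otherwise)")
    p <- config@nFeatures
    n <- length(effectiveAge)
    featSeed <- (config@seed + 1L) %% .Machine$integer.max
    withSeed(featSeed, {
        base <- runif(p, 0.55, 0.80)
        load <- runif(p, 0.5, 1.5)
        a <- effectiveAge - 50
        g <- config@ageTrend[1] * a + config@ageTrend[2] * a^2
        eps <- matrix(rnorm(p * n, 0, config@featureNoiseSd), p, n)
        f <- base + outer(load, g) + eps
        clipped <- mean(f < 0 | f > 1)
        f <- pmin(pmax(f, 0), 1)
        rownames(f) <- sprintf("gm%04d", seq_len(p))
        attr(f, "clippingRate") <- clipped
        f
    })
}

#' @describeIn BrainAgeCohort per-subject phenotype table as a data.frame.
#' @param x,object a `BrainAgeCohort`.
#' @export
phenotypes <- function(x) {
    as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn BrainAgeCohort subjects x features gray-matter matrix.
#' @export
gmFeatures <- function(x) {
    t(SummarizedExperiment::assay(x, "gm"))
}

#' @describeIn BrainAgeCohort latent ground-truth brain-age offset
#'   (years), or `NULL` for non-simulated cohorts.
#' @export
trueOffset <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("true_offset" %in% colnames(cd)) cd$true_offset else NULL
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nSubjects, "subjects, ages",
        paste(object@ageRange, collapse = "-"), "y, seed",
        object@seed, "\n")
    cat(sprintf("  %d GM features, feature noise %.3g, offset noise %.3g y\n",
        object@nFeatures, object@featureNoiseSd, object@estimatorNoiseSd))
    print(round(object@lifestyle, 3))
})

setMethod("show", "BrainAgeCohort", function(object) {
    cat("BrainAgeCohort:", ncol(object), "subjects,", nrow(object),
        "gray-matter features\n")
    callNextMethod()
})
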