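# End-to-end orchestration: simulate (or load) -> score -> estimate ->
# analyze -> report.

#' Run the full lifestyle/BrainAGE pipeline
#'
#' Sequences the whole analysis: obtain a cohort (simulated from `config`,
#' or loaded from `phenotypePath`/`featurePath`), fit the combined
#' lifestyle risk score, run sex-split leave-k-out brain-age estimation,
#' detrend the gaps, and fit the lifestyle regressions for every requested
#' age-handling approach, lifestyle term and stratum, flagging
#' significance against the Bonferroni-corrected threshold
#' `alpha / family`. A noncentral-F power table is computed for the
#' configured effect sizes at the achieved sample size. All randomness is
#' governed by `seed`.
#'
#' @param config a [SimulationConfig-class] (simulate mode), or `NULL` to
#'   load files.
#' @param phenotypePath,featurePath input CSVs for analyze mode (ignored
#'   when `config` is given).
#' @param outputDir if non-NULL, results are written there (CSV tables,
#'   JSON reports, provenance block).
#' @param k,sexSplit,kernel,varianceTarget estimation settings, see
#'   [leaveKOutEstimate()].
#' @param seed seed for fold construction (defaults to the simulation
#'   seed).
#' @param approaches subset of 1:3.
#' @param covariates covariate set for the regressions.
#' @param strata strata to fit (`"all"`, `"male"`, `"female"`).
#' @param alpha family-wise error level.
#' @param family number of tests in the Bonferroni family (default 15).
#' @param outlierRule `"off"` or `"3SD"`.
#' @param powerEffects named numeric of Cohen's f2 values for the power
#'   table.
#' @param powerPredictors predictor count of the fully adjusted model
#'   used in the power analysis.
#' @return a [ReportBundle-class].
#' @export
#' @examples
#' \donttest{
#' bundle <- runPipeline(simulationConfig(120, seed = 11, nFeatures = 30),
#'     k = 10, sexSplit = FALSE)
#' bundle
#' }
runPipeline <- function(config = NULL, phenotypePath = NULL,
        featurePath = NULL, outputDir = NULL, k = 10L, sexSplit = TRUE,
        kernel = "linear", varianceTarget = 0.95, seed = NULL,
        approaches = 1:3, covariates = "sex",
        strata = c("all", "male", "female"), alpha = 0.05, family = 15L,
        outlierRule = "off",
        powerEffects = c(risk_score = 0.05, pack_years = 0.04,
            met_score = 0.07),
        powerPredictors = 5L) {
    t0 <- Sys.time()
    if (!is.null(config)) {
        if (is.null(seed)) seed <- config@seed
        cohort <- simulateCohort(config)
        message("stage simulate: n = ", ncol(cohort), ", features = ",
            nrow(cohort))
    } else {
        if (is.null(phenotypePath) || is.null(featurePath))
            stop("either a simulation config or both input paths ",
                "are required")
        if (is.null(seed)) seed <- 1L
        cohort <- loadCohort(phenotypePath, featurePath)
        message("stage load: n = ", ncol(cohort), ", features = ",
            nrow(cohort))
    }
    ph <- phenotypes(cohort)

    rs <- combinedRiskScore(ph)
    ph$risk_score <- riskScores(rs)
    message("stage score: mean combined risk ",
        sprintf("%.3f", mean(ph$risk_score)))

    est <- leaveKOutEstimate(cohort, k = k, sexSplit = sexSplit,
        seed = seed, varianceTarget = varianceTarget, kernel = kernel)
    bar <- brainAgeResult(cohort, est)
    perf <- performanceReport(ph$age, brainAgeTable(bar)$estimated_age,
        brainAGE(bar), strata = ph$sex)
    message("stage estimate: MAE ",
        sprintf("%.2f y", perf@overall$mae))

    adat <- cbind(ph, brainage = brainAGE(bar))
    threshold <- bonferroniThreshold(alpha, family)
    lifestyleSets <- as.list(c("risk_score", "pack_years",
        "alcohol_g_month", "met_score", "social_index"))
    rows <- list()
    for (ap in approaches) for (st in strata) for (lv in lifestyleSets) {
        fit <- fitLifestyleModel(adat, lifestyle = lv, approach = ap,
            covariates = covariates, stratum = st,
            outlierRule = outlierRule)
        tr <- coefTable(fit)
        tr <- tr[tr$term %in% lv, , drop = FALSE]
        rows[[length(rows) + 1L]] <- cbind(tr,
            F = fit@fstat, R2 = fit@r2, delta_R2 = fit@deltaR2,
            mae = fit@residMAE, n = fit@n, approach = ap, stratum = st,
            months_per_unit = quantifyMonths(tr$b),
            significant = tr$p < threshold)
    }
    regressions <- do.call(rbind, rows)
    message("stage analyze: ", nrow(regressions), " fitted terms, ",
        sum(regressions$significant), " significant at p < ",
        signif(threshold, 3))

    powerTab <- do.call(rbind, lapply(names(powerEffects), function(v) {
        pr <- computePower(powerEffects[[v]], n = nrow(ph),
            alpha = round(threshold, 3), nPredictors = powerPredictors)
        data.frame(term = v, f2 = powerEffects[[v]], n = nrow(ph),
            alpha = round(threshold, 3), power = pr@power,
            lambda = pr@lambda, stringsAsFactors = FALSE)
    }))

    settings <- list(k = k, sexSplit = sexSplit, kernel = kernel,
        varianceTarget = varianceTarget, seed = seed,
        approaches = approaches, covariates = covariates,
        alpha = alpha, family = family, outlierRule = outlierRule)
    if (!is.null(config)) settings$config <- configAsList(config)
    provenance <- list(
        hash = configHash(jsonlite::toJSON(settings, auto_unbox = TRUE,
            digits = NA)),
        seed = seed,
        version = as.character(utils::packageVersion("brainAGE")),
        elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))

    bundle <- new("ReportBundle", performance = perf, brainAge = bar,
        riskScore = rs, regressions = regressions, power = powerTab,
        provenance = provenance)
    if (!is.null(outputDir)) writeReportBundle(bundle, outputDir)
    bundle
}

#' Write a report bundle to disk
#'
#' @param bundle a [ReportBundle-class].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeReportBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        brainage = file.path(dir, "brainage.csv"),
        regressions = file.path(dir, "regressions.csv"),
        power = file.path(dir, "power.csv"),
        performance = file.path(dir, "performance.json"),
        risk = file.path(dir, "risk_constants.json"),
        provenance = file.path(dir, "provenance.json"))
    utils::write.csv(brainAgeTable(bundle@brainAge), paths["brainage"],
        row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(bundle@regressions, paths["regressions"],
        row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(bundle@power, paths["power"], row.names = FALSE,
        fileEncoding = "UTF-8")
    jsonlite::write_json(performanceTable(bundle@performance),
        paths["performance"], dataframe = "rows", digits = NA)
    jsonlite::write_json(cbind(variable =
            rownames(riskConstants(bundle@riskScore)),
        riskConstants(bundle@riskScore)), paths["risk"],
        dataframe = "rows", digits = NA)
    jsonlite::write_json(bundle@provenance, paths["provenance"],
        auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

setMethod("show", "ReportBundle", function(object) {
    cat("ReportBundle (seed ", object@provenance$seed, ", hash ",
        object@provenance$hash, ")\n", sep = "")
    show(object@performance)
    sig <- object@regressions[object@regressions$significant, , drop = FALSE]
    cat(nrow(object@regressions), "fitted lifestyle terms;",
        nrow(sig), "significant after Bonferroni correction\n")
})
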