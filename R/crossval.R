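# Sex-split leave-k-out brain-age estimation, BrainAGE, detrending,
# and performance measures.

#' Build a leave-k-out cross-validation plan
#'
#' Subjects are shuffled once per stratum with the given seed, then
#' chunked into consecutive groups of `k`; the remainder forms a smaller
#' final fold. Every subject lands in exactly one test fold of its own
#' stratum.
#'
#' @param strata factor (or vector) of stratum labels, one per subject;
#'   use a constant for unstratified folds.
#' @param k fold size (default 10).
#' @param seed integer seed for the per-stratum shuffle.
#' @return data.frame with columns `index`, `stratum`, `fold`.
#' @export
crossValPlan <- function(strata, k = 10L, seed = 1L) {
    strata <- as.factor(strata)
    withSeed(seed, {
        out <- lapply(levels(strata), function(s) {
            idx <- which(strata == s)
            if (length(idx) <= k)
                stop("stratum '", s, "' has ", length(idx),
                    " subjects but fold size k = ", k,
                    "; disable the sex split or reduce k")
            idx <- sample(idx)
            data.frame(index = idx, stratum = s,
                fold = ceiling(seq_along(idx) / k))
        })
        do.call(rbind, out)
    })
}

#' Cross-validated brain-age estimation
#'
#' Estimates every subject's brain age from gray-matter features with a
#' model whose training set excluded that subject: within each stratum
#' (by default the two sexes, trained separately), subjects are split
#' into folds of `k`; for each fold a PCA is fitted on the training
#' subjects only (no leakage), training and test features are projected,
#' a relevance vector regression of chronological age on the reduced
#' features is fitted, and the held-out subjects receive its predictions.
#'
#' @param cohort a [BrainAgeCohort-class].
#' @param k fold size (default 10, the leave-10-out scheme).
#' @param sexSplit train separate models per sex (default `TRUE`).
#' @param seed seed for the fold shuffle.
#' @param varianceTarget PCA variance target (see [fitPCA()]).
#' @param pcaK fixed PCA component count (overrides `varianceTarget`).
#' @param kernel,kernelWidth RVR kernel settings (see [fitRVR()]).
#' @param ... further arguments passed to [fitRVR()].
#' @return list with `estimated` (named numeric vector of estimated ages,
#'   in cohort order) and `plan` (data.frame: `subject_id`, `stratum`,
#'   `fold`).
#' @export
#' @examples
#' cohort <- simulateCohort(simulationConfig(60, seed = 3, nFeatures = 20))
#' est <- leaveKOutEstimate(cohort, k = 10, sexSplit = FALSE, seed = 1)
#' head(est$estimated)
leaveKOutEstimate <- function(cohort, k = 10L, sexSplit = TRUE, seed = 1L,
        varianceTarget = 0.95, pcaK = NULL, kernel = "linear",
        kernelWidth = NULL, ...) {
    stopifnot(is(cohort, "BrainAgeCohort"))
    ph <- phenotypes(cohort)
    feats <- gmFeatures(cohort)
    strata <- if (sexSplit) as.character(ph$sex) else
        rep("all", nrow(ph))
    plan <- crossValPlan(strata, k = k, seed = seed)
    estimated <- rep(NA_real_, nrow(ph))
    notConverged <- 0L
    nFolds <- 0L
    for (s in unique(plan$stratum)) {
        ps <- plan[plan$stratum == s, ]
        for (f in unique(ps$fold)) {
            test <- ps$index[ps$fold == f]
            train <- ps$index[ps$fold != f]
            pca <- fitPCA(feats[train, , drop = FALSE],
                varianceTarget = varianceTarget, k = pcaK)
            Xtr <- projectPCA(pca, feats[train, , drop = FALSE])
            Xte <- projectPCA(pca, feats[test, , drop = FALSE])
            rvr <- withCallingHandlers(
                fitRVR(Xtr, ph$age[train], kernel = kernel,
                    kernelWidth = kernelWidth, ...),
                warning = function(w) {
                    if (grepl("did not converge", conditionMessage(w)))
                        invokeRestart("muffleWarning")
                })
            nFolds <- nFolds + 1L
            if (!rvr@converged) notConverged <- notConverged + 1L
            estimated[test] <- predictRVR(rvr, Xte)
        }
    }
    if (notConverged > 0L)
        message(notConverged, " of ", nFolds, " fold models stopped at ",
            "the iteration cap; best-evidence iterates were used")
    names(estimated) <- ph$subject_id
    plan <- plan[order(plan$index), ]
    list(estimated = estimated,
        plan = data.frame(subject_id = ph$subject_id[plan$index],
            stratum = plan$stratum, fold = plan$fold,
            stringsAsFactors = FALSE))
}

#' Raw brain-age gap
#'
#' @param estimated,chronological aligned age vectors (years).
#' @return `estimated - chronological`, per subject.
#' @export
#' @examples
#' computeBrainAGE(70, 65)   # +5: the brain looks five years older
computeBrainAGE <- function(estimated, chronological) {
    if (length(estimated) != length(chronological))
        stop("estimated and chronological ages must align")
    estimated - chronological
}

#' Remove the quadratic age trend from raw gaps
#'
#' Least-squares fit of the raw gap on `{1, age, age^2}`; the detrended
#' BrainAGE is the residual, so it has mean zero and is exactly orthogonal
#' to age and age squared on the detrending sample. The same coefficients
#' can be applied to subsamples via the returned `coefficients`.
#'
#' @param gaps raw gaps in years.
#' @param ages chronological ages in years.
#' @return list with `brainage` (detrended gaps) and `coefficients`
#'   (intercept, age, age^2).
#' @export
detrendQuadratic <- function(gaps, ages) {
    if (length(gaps) != length(ages)) stop("gaps and ages must align")
    if (length(gaps) < 4L) stop("need at least 4 subjects to detrend")
    if (var(ages) == 0) stop("all ages equal: detrend design is collinear")
    fit <- lm(gaps ~ ages + I(ages^2))
    list(brainage = as.numeric(resid(fit)),
        coefficients = setNames(coef(fit),
            c("intercept", "age", "age2")))
}

#' Assemble a per-subject brain-age result
#'
#' Convenience wrapper chaining [computeBrainAGE()] and
#' [detrendQuadratic()] over a cross-validated estimation run.
#'
#' @param cohort a [BrainAgeCohort-class].
#' @param estimation result of [leaveKOutEstimate()].
#' @return a [BrainAgeResult-class].
#' @export
brainAgeResult <- function(cohort, estimation) {
    ph <- phenotypes(cohort)
    est <- estimation$estimated[ph$subject_id]
    gaps <- computeBrainAGE(est, ph$age)
    dt <- detrendQuadratic(gaps, ph$age)
    tb <- data.frame(subject_id = ph$subject_id, age = ph$age,
        sex = ph$sex, estimated_age = as.numeric(est),
        raw_gap = as.numeric(gaps), brainage = dt$brainage,
        stringsAsFactors = FALSE)
    new("BrainAgeResult", table = tb, detrendCoef = dt$coefficients,
        plan = estimation$plan)
}

#' @describeIn BrainAgeResult per-subject result table.
#' @param object a `BrainAgeResult`.
#' @export
brainAgeTable <- function(object) object@table

#' @describeIn BrainAgeResult detrended BrainAGE values (years).
#' @export
brainAGE <- function(object) object@table$brainage

#' @describeIn BrainAgeResult removed quadratic trend coefficients.
#' @export
detrendCoefficients <- function(object) object@detrendCoef

.safeCor <- function(x, y) {
    if (var(x) == 0 || var(y) == 0) NA_real_ else cor(x, y)
}

#' Performance measures for a brain-age estimation
#'
#' The accuracy summary of the estimation framework: the mean absolute
#' BrainAGE (each detrended gap read as the error of the age estimate),
#' Pearson correlations of chronological age with estimated age and with
#' BrainAGE, and the R squared of the estimated-on-chronological
#' regression -- overall and per stratum. Zero-variance inputs yield `NA`
#' statistics listed in the `undefined` slot rather than silent zeros.
#'
#' @param chronological,estimated,brainage aligned vectors (years).
#' @param strata optional stratum labels (e.g. sex) for the breakdown.
#' @return a [PerformanceReport-class].
#' @export
performanceReport <- function(chronological, estimated, brainage,
        strata = NULL) {
    n <- length(chronological)
    if (length(estimated) != n || length(brainage) != n)
        stop("all input vectors must align")
    one <- function(idx, label) {
        ch <- chronological[idx]; es <- estimated[idx]; bg <- brainage[idx]
        r2 <- if (var(ch) == 0) NA_real_ else
            summary(lm(es ~ ch))$r.squared
        data.frame(stratum = label, mae = mean(abs(bg)),
            r_est = .safeCor(ch, es), r_gap = .safeCor(ch, bg),
            r2 = r2, n = length(idx), stringsAsFactors = FALSE)
    }
    overall <- one(seq_len(n), "all")
    by <- if (is.null(strata)) overall[0, ] else
        do.call(rbind, lapply(unique(as.character(strata)), function(s)
            one(which(strata == s), s)))
    undef <- character()
    for (cn in c("r_est", "r_gap", "r2"))
        if (anyNA(c(overall[[cn]], by[[cn]])))
            undef <- c(undef, cn)
    new("PerformanceReport", overall = overall, byStratum = by,
        undefined = undef)
}

#' @describeIn PerformanceReport one-row overall summary.
#' @param object a `PerformanceReport`.
#' @export
performanceTable <- function(object) rbind(object@overall, object@byStratum)

setMethod("show", "BrainAgeResult", function(object) {
    tb <- object@table
    cat("BrainAgeResult:", nrow(tb), "subjects\n")
    cat(sprintf("  mean raw gap %.3f y; detrended BrainAGE mean %.2e, SD %.2f y\n",
        mean(tb$raw_gap), mean(tb$brainage), sd(tb$brainage)))
    cat(sprintf("  removed trend: %.3f + %.4f age + %.6f age^2\n",
        object@detrendCoef[1], object@detrendCoef[2], object@detrendCoef[3]))
})

setMethod("show", "PerformanceReport", function(object) {
    cat("PerformanceReport\n")
    print(performanceTable(object), row.names = FALSE, digits = 3)
    if (length(object@undefined))
        cat("  undefined (zero-variance):",
            paste(object@undefined, collapse = ", "), "\n")
})
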