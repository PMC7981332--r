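# Statistical layer: lifestyle-to-BrainAGE regressions under three
# age-handling approaches, effect quantification, interaction and
# stratified analyses, curve comparison, outlier rule, smoker groups,
# and power analysis.

#' Three-SD outlier inclusion mask
#'
#' A value is excluded when it lies three or more SDs from the mean, with
#' mean and SD computed once on the full vector (no iteration). The
#' population SD (denominator n) is used: with the sample estimator a
#' single extreme point can never reach three SDs of a small sample, since
#' sample z-scores are bounded by (n-1)/sqrt(n).
#'
#' @param values numeric vector (n >= 3).
#' @return logical mask, `TRUE` = included; always the input length.
#' @export
#' @examples
#' excludeOutliers(c(rep(0, 9), 100))
excludeOutliers <- function(values) {
    if (length(values) < 3L) stop("need at least 3 values")
    n <- length(values)
    s <- sd(values) * sqrt((n - 1) / n)
    if (s == 0) {
        warning("zero SD: no outliers can be identified, all included")
        return(rep(TRUE, length(values)))
    }
    abs(values - mean(values)) < 3 * s
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error level.
#' @param m number of tests in the family (15 in the standard analysis
#'   plan: five lifestyle terms, each in the whole sample and per sex).
#' @return `alpha / m`.
#' @export
#' @examples
#' round(bonferroniThreshold(), 3)   # 0.003
bonferroniThreshold <- function(alpha = 0.05, m = 15L) {
    stopifnot(alpha > 0, alpha < 1, m >= 1)
    alpha / m
}

.checkCollinearity <- function(X, labels) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- labels[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("perfectly collinear model terms: ",
            paste(bad, collapse = ", "))
    }
}

#' Regress BrainAGE on lifestyle under one age-handling approach
#'
#' Ordinary least squares of (detrended) BrainAGE on one or more lifestyle
#' terms plus covariates, under the three ways of handling chronological
#' age: approach 1 includes age as a predictor, approach 2 omits it, and
#' approach 3 first replaces the outcome by the residuals of
#' `BrainAGE ~ age` on the analysis sample and then omits age. Rows with
#' missing values in any used column are dropped (listwise deletion);
#' an optional 3-SD rule additionally excludes subjects extreme on any
#' lifestyle term or on the outcome.
#'
#' @param data data.frame containing a `brainage` column, the lifestyle
#'   term(s) and the covariates; a `sex` column is needed when
#'   `stratum != "all"` or `"sex"` is a covariate.
#' @param lifestyle character, lifestyle term column name(s).
#' @param approach 1, 2 or 3.
#' @param covariates character subset of
#'   `c("sex", "age", "education", "bmi", "demtect")`; age is forced in
#'   under approach 1 and removed under approaches 2 and 3.
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @param outlierRule `"off"` or `"3SD"`.
#' @param outcome outcome column name (default `"brainage"`).
#' @return a [RegressionFit-class].
#' @export
fitLifestyleModel <- function(data, lifestyle = "risk_score",
        approach = 1L, covariates = c("sex"), stratum = "all",
        outlierRule = c("off", "3SD"), outcome = "brainage") {
    outlierRule <- match.arg(outlierRule)
    approach <- as.integer(approach)
    stopifnot(approach %in% 1:3)
    if (approach == 1L) covariates <- union(covariates, "age")
    if (approach != 1L) covariates <- setdiff(covariates, "age")
    if (stratum != "all") {
        data <- data[as.character(data$sex) == stratum, , drop = FALSE]
        covariates <- setdiff(covariates, "sex")
    }
    used <- unique(c(outcome, "age"[approach == 3L], lifestyle, covariates))
    miss <- setdiff(used, colnames(data))
    if (length(miss))
        stop("missing model columns: ", paste(miss, collapse = ", "))
    data <- data[complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
    if (outlierRule == "3SD") {
        keep <- rep(TRUE, nrow(data))
        for (v in c(lifestyle, outcome))
            keep <- keep & excludeOutliers(data[[v]])
        data <- data[keep, , drop = FALSE]
    }
    y <- data[[outcome]]
    if (approach == 3L)
        y <- as.numeric(resid(lm(y ~ age, data = data)))
    predictors <- c(covariates, lifestyle)
    fml <- as.formula(paste("y ~", paste(predictors, collapse = " + ")))
    mf <- cbind(y = y, data[, predictors, drop = FALSE])
    X <- model.matrix(fml, mf)
    .checkCollinearity(X, colnames(X))
    fit <- lm(fml, data = mf)
    sm <- summary(fit)
    cf <- sm$coefficients
    termNames <- rownames(cf)[-1]
    sdy <- sd(y)
    betaStd <- vapply(termNames, function(tn) {
        xcol <- X[, tn]
        cf[tn, 1] * sd(xcol) / sdy
    }, numeric(1))
    terms <- data.frame(term = termNames, b = cf[-1, 1], beta = betaStd,
        t = cf[-1, 3], p = cf[-1, 4], row.names = NULL,
        stringsAsFactors = FALSE)
    r2 <- sm$r.squared
    if (length(covariates)) {
        fml0 <- as.formula(paste("y ~",
            paste(covariates, collapse = " + ")))
        r20 <- summary(lm(fml0, data = mf))$r.squared
    } else {
        r20 <- 0
    }
    fs <- sm$fstatistic
    new("RegressionFit", terms = terms,
        intercept = unname(cf[1, 1]),
        fstat = unname(fs[1]),
        fp = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
        r2 = r2, deltaR2 = max(r2 - r20, 0),
        residMAE = mean(abs(resid(fit))), residSD = sd(abs(resid(fit))),
        n = nrow(mf), approach = approach, stratum = stratum,
        lifestyleTerms = lifestyle)
}

#' @describeIn RegressionFit per-term coefficient table.
#' @param object a `RegressionFit`.
#' @export
coefTable <- function(object) object@terms

#' @describeIn RegressionFit increment in R squared attributable to the
#'   lifestyle term(s).
#' @export
deltaR2 <- function(object) object@deltaR2

setMethod("show", "RegressionFit", function(object) {
    cat(sprintf(
        "RegressionFit (approach %d, %s, n = %d): F = %.3f, p = %.3g\n",
        object@approach, object@stratum, object@n, object@fstat,
        object@fp))
    cat(sprintf("  R2 = %.4f (lifestyle dR2 = %.4f), residual MAE %.2f y\n",
        object@r2, object@deltaR2, object@residMAE))
    print(transform(object@terms, b = signif(b, 4), beta = signif(beta, 3),
        t = signif(t, 4), p = signif(p, 3)), row.names = FALSE)
})

#' Convert a regression slope to months of brain age per exposure unit
#'
#' The slope of BrainAGE (years) on an exposure, times 12, gives the
#' additional months of apparent brain age per one-unit increase in that
#' exposure, already adjusted for the model's covariates.
#'
#' @param b3 unstandardized lifestyle coefficient (years per unit).
#' @return months per unit (signed; take the magnitude to report size).
#' @export
#' @examples
#' quantifyMonths(-0.046)   # -0.552: 0.55 months younger per MET-hour
quantifyMonths <- function(b3) {
    stopifnot(all(is.finite(b3)))
    b3 * 12
}

#' Test whether sex moderates a lifestyle association
#'
#' ANCOVA as OLS with main effects plus sex-by-lifestyle product terms;
#' each interaction term is tested by comparing the full model against the
#' model without that term (partial F). Partial eta squared is reported.
#'
#' @param data data.frame with `brainage`, `sex`, the lifestyle term(s)
#'   and covariates.
#' @param lifestyle character, lifestyle term(s).
#' @param covariates additional covariates (default age and education).
#' @param outcome outcome column.
#' @return data.frame, one row per interaction term: `term`, `F`, `p`,
#'   `partialEta2`.
#' @export
testSexInteraction <- function(data, lifestyle = "risk_score",
        covariates = c("age", "education"), outcome = "brainage") {
    if (length(unique(data$sex)) < 2L)
        stop("both sexes must be present to test an interaction")
    used <- c(outcome, "sex", lifestyle, covariates)
    data <- data[complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
    main <- c("sex", covariates, lifestyle)
    inter <- paste0("sex:", lifestyle)
    full <- lm(as.formula(paste(outcome, "~",
        paste(c(main, inter), collapse = " + "))), data = data)
    rssFull <- sum(resid(full)^2)
    dfFull <- full$df.residual
    out <- lapply(lifestyle, function(v) {
        reduced <- lm(as.formula(paste(outcome, "~",
            paste(c(main, setdiff(inter, paste0("sex:", v))),
                collapse = " + "))), data = data)
        a <- anova(reduced, full)
        ssInt <- a[2, "Sum of Sq"]
        data.frame(term = paste0("sex:", v), F = a[2, "F"],
            p = a[2, "Pr(>F)"],
            partialEta2 = ssInt / (ssInt + rssFull),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Compare linear and quadratic lifestyle fits
#'
#' The lifestyle term is first residualized on the linear effects of the
#' covariates (age, sex, education by default; add BMI where the analysis
#' plan demands); BrainAGE is then regressed on the residualized term
#' linearly and quadratically, and the two nested fits are compared on
#' explained variance, together with the test of the quadratic
#' coefficient.
#'
#' @param data data.frame with `brainage`, the term and covariates.
#' @param lifestyle lifestyle term column name.
#' @param covariates covariates to residualize on.
#' @param outcome outcome column.
#' @return list with `r2Linear`, `r2Quadratic`, `b1l`, `b1q`, `b2q`,
#'   `pQuadratic`.
#' @export
compareLinearQuadratic <- function(data, lifestyle,
        covariates = c("age", "sex", "education"), outcome = "brainage") {
    used <- c(outcome, lifestyle, covariates)
    data <- data[complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
    if (nrow(data) < 5L) stop("need at least 5 subjects")
    r <- as.numeric(resid(lm(as.formula(paste(lifestyle, "~",
        paste(covariates, collapse = " + "))), data = data)))
    y <- data[[outcome]]
    linFit <- lm(y ~ r)
    quadFit <- lm(y ~ r + I(r^2))
    sq <- summary(quadFit)$coefficients
    list(r2Linear = summary(linFit)$r.squared,
        r2Quadratic = summary(quadFit)$r.squared,
        b1l = unname(coef(linFit)[2]),
        b1q = unname(coef(quadFit)[2]),
        b2q = unname(coef(quadFit)[3]),
        pQuadratic = unname(sq["I(r^2)", 4]))
}

#' Classify smokers by pack-years
#'
#' Never: pack-years exactly 0; moderate: 0 < pack-years < 20; severe:
#' pack-years >= 20.
#'
#' @param packYears numeric vector.
#' @return factor with levels never, moderate, severe.
#' @export
#' @examples
#' classifySmokers(c(0, 5, 19.9, 20, 45))
classifySmokers <- function(packYears) {
    g <- ifelse(packYears == 0, "never",
        ifelse(packYears < 20, "moderate", "severe"))
    factor(g, levels = c("never", "moderate", "severe"))
}

# Greedy nearest-neighbour age matching without replacement across the
# three smoker groups, within sex, caliper in years; reference order is
# seeded, ties broken by subject id.
.matchTriplets <- function(df, caliper, seed) {
    withSeed(seed, {
        out <- list()
        for (s in unique(as.character(df$sex))) {
            d <- df[as.character(df$sex) == s, ]
            sizes <- table(d$group)
            refGroup <- names(sizes)[which.min(sizes)]
            others <- setdiff(levels(d$group), refGroup)
            ref <- d[d$group == refGroup, ]
            ref <- ref[sample(nrow(ref)), ]
            pools <- lapply(others, function(g) d[d$group == g, ])
            names(pools) <- others
            for (i in seq_len(nrow(ref))) {
                picks <- list()
                ok <- TRUE
                for (g in others) {
                    pool <- pools[[g]]
                    if (nrow(pool) == 0L) { ok <- FALSE; break }
                    dist <- abs(pool$age - ref$age[i])
                    j <- which(dist == min(dist))
                    if (length(j) > 1L)
                        j <- j[order(pool$subject_id[j])][1]
                    if (dist[j] > caliper) { ok <- FALSE; break }
                    picks[[g]] <- pool[j, ]
                    pools[[g]] <- pool[-j, ]
                }
                if (ok)
                    out[[length(out) + 1L]] <-
                        rbind(ref[i, ], do.call(rbind, picks))
            }
        }
        if (length(out)) do.call(rbind, out) else df[0, ]
    })
}

#' Age-matched smoker-group contrast on BrainAGE
#'
#' Classifies subjects into never / moderate / severe smokers, age-matches
#' the groups within sex (greedy nearest neighbour without replacement,
#' 2-year caliper by default, seeded tie-breaking by subject id), then
#' runs an ANCOVA of BrainAGE on the group factor and sex with age and
#' education as covariates on the matched sample. The group test is the
#' partial F from dropping the factor; adjusted group means and pairwise
#' contrasts come from the estimated marginal means of the fitted model.
#'
#' @param data data.frame with `subject_id`, `brainage`, `pack_years`,
#'   `sex`, `age`, `education`.
#' @param caliper maximum age difference within a matched triplet, years.
#' @param seed matching seed.
#' @return a [SmokerGroupResult-class].
#' @export
smokerGroupAnalysis <- function(data, caliper = 2, seed = 1L) {
    used <- c("subject_id", "brainage", "pack_years", "sex", "age",
        "education")
    miss <- setdiff(used, colnames(data))
    if (length(miss))
        stop("missing columns: ", paste(miss, collapse = ", "))
    data <- data[complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
    groups <- classifySmokers(data$pack_years)
    counts <- table(groups)
    if (any(counts == 0))
        stop("empty smoker group(s): ",
            paste(sprintf("%s = %d", names(counts), counts),
                collapse = ", "))
    df <- cbind(data, group = groups)
    matched <- .matchTriplets(df, caliper = caliper, seed = seed)
    if (nrow(matched) < 9L)
        stop("age matching retained fewer than 3 triplets; ",
            "widen the caliper or check group overlap in age")
    full <- lm(brainage ~ group + sex + age + education, data = matched)
    reduced <- lm(brainage ~ sex + age + education, data = matched)
    a <- anova(reduced, full)
    emm <- emmeans::emmeans(full, "group")
    adj <- as.data.frame(emm)
    class(adj) <- "data.frame"
    ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise"))
    class(ctr) <- "data.frame"
    new("SmokerGroupResult", groups = groups,
        matched = matched[, c("subject_id", "group", "sex", "age")],
        adjustedMeans = adj, fstat = a[2, "F"], p = a[2, "Pr(>F)"],
        contrasts = ctr)
}

setMethod("show", "SmokerGroupResult", function(object) {
    cat(sprintf(
        "SmokerGroupResult: %d matched subjects; group F = %.3f, p = %.3g\n",
        nrow(object@matched), object@fstat, object@p))
    print(object@adjustedMeans, digits = 3)
})

#' Power of a regression F test from the noncentral F distribution
#'
#' For a multiple regression with `nPredictors` predictors and a tested
#' subset with `testedDf` numerator degrees of freedom, the noncentrality
#' is `lambda = f2 * n` (Cohen's f squared times the sample size) and
#' power is the upper-tail probability of the noncentral F at the central
#' critical value.
#'
#' @param f2 Cohen's f squared effect size (>= 0).
#' @param n sample size (must exceed `nPredictors + 1`).
#' @param alpha significance level.
#' @param nPredictors total predictors in the model.
#' @param testedDf numerator degrees of freedom of the tested term(s);
#'   1 for a single lifestyle predictor.
#' @return a [PowerResult-class].
#' @export
#' @examples
#' computePower(f2 = 0.05, n = 622, alpha = 0.003, nPredictors = 5)
computePower <- function(f2, n, alpha = 0.05, nPredictors, testedDf = 1) {
    stopifnot(f2 >= 0, alpha > 0, alpha < 1)
    if (n <= nPredictors + 1)
        stop("n must exceed the number of predictors + 1")
    df2 <- n - nPredictors - 1
    lambda <- f2 * n
    critF <- qf(1 - alpha, testedDf, df2)
    power <- pf(critF, testedDf, df2, ncp = lambda, lower.tail = FALSE)
    new("PowerResult", power = power, lambda = lambda, critF = critF,
        df1 = testedDf, df2 = df2)
}

#' @describeIn PowerResult achieved power.
#' @param object a `PowerResult`.
#' @export
powerValue <- function(object) object@power

setMethod("show", "PowerResult", function(object) {
    cat(sprintf(
        "PowerResult: power %.4f (lambda %.2f, F crit %.3f on %g, %g df)\n",
        object@power, object@lambda, object@critF, object@df1,
        object@df2))
})

.corMatWithP <- function(x, method) {
    p <- ncol(x)
    r <- pv <- matrix(NA_real_, p, p, dimnames = list(colnames(x),
        colnames(x)))
    diag(r) <- 1
    undef <- character()
    for (i in seq_len(p)) for (j in seq_len(p)) {
        if (j <= i) next
        xi <- x[, i]; xj <- x[, j]
        ok <- complete.cases(xi, xj)
        if (sd(xi[ok]) == 0 || sd(xj[ok]) == 0) {
            undef <- c(undef,
                paste(colnames(x)[c(i, j)], collapse = ":"))
            next
        }
        ct <- suppressWarnings(cor.test(xi[ok], xj[ok], method = method,
            exact = FALSE))
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        pv[i, j] <- pv[j, i] <- ct$p.value
    }
    list(r = r, p = pv, undefined = unique(undef))
}

#' Descriptive statistics and correlation matrices
#'
#' Per-stratum means, SDs, minima and maxima of the numeric columns, plus
#' Pearson and Spearman correlation matrices with p values. Spearman uses
#' average ranks so ties are handled by the standard tie correction; pairs
#' with zero variance are flagged as undefined rather than reported as 0.
#'
#' @param data data.frame of numeric columns (plus an optional stratum
#'   column).
#' @param strataCol name of the stratum column, or `NULL`.
#' @return list with `summary` (data.frame), `pearson`, `spearman` (each
#'   a list `r`, `p`, `undefined`).
#' @export
descriptives <- function(data, strataCol = NULL) {
    num <- data[, vapply(data, is.numeric, logical(1)), drop = FALSE]
    strat <- if (is.null(strataCol)) rep("all", nrow(data)) else
        as.character(data[[strataCol]])
    summ <- do.call(rbind, lapply(unique(c("all", strat)), function(s) {
        idx <- if (s == "all") seq_len(nrow(num)) else which(strat == s)
        do.call(rbind, lapply(colnames(num), function(v) {
            x <- num[idx, v]; x <- x[is.finite(x)]
            data.frame(stratum = s, variable = v, mean = mean(x),
                sd = sd(x), min = min(x), max = max(x), n = length(x),
                stringsAsFactors = FALSE)
        }))
    }))
    list(summary = summ,
        pearson = .corMatWithP(as.matrix(num), "pearson"),
        spearman = .corMatWithP(as.matrix(num), "spearman"))
}
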