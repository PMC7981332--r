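test_that("the 3-SD rule excludes exactly the extreme values, once", {
    set.seed(20)
    x <- rnorm(100)
    sPop <- sd(x) * sqrt(99 / 100)
    x <- x[abs(x - mean(x)) < 2.9 * sPop]
    expect_true(all(excludeOutliers(x)))
    v <- c(rep(0, 9), 100)
    mask <- excludeOutliers(v)
    expect_length(mask, 10)
    expect_identical(which(!mask), 10L)
    expect_warning(m0 <- excludeOutliers(rep(1, 5)), "zero SD")
    expect_true(all(m0))
})

test_that("the Bonferroni gate uses alpha over the family size", {
    expect_equal(bonferroniThreshold(0.05, 15), 0.05 / 15)
    expect_equal(round(bonferroniThreshold(0.05, 15), 3), 0.003)
})

test_that("approaches 1 and 3 agree when lifestyle is orthogonal to age", {
    ph <- groundTruthBrainage(makeCohort(500, seed = 23, nFeatures = 2))
    # construct an exposure exactly orthogonal to age (and the intercept)
    set.seed(1)
    raw <- rnorm(nrow(ph))
    ph$ortho <- as.numeric(resid(lm(raw ~ age, data = ph)))
    f1 <- fitLifestyleModel(ph, lifestyle = "ortho", approach = 1,
        covariates = character())
    f3 <- fitLifestyleModel(ph, lifestyle = "ortho", approach = 3,
        covariates = character())
    b1 <- coefTable(f1)$b[coefTable(f1)$term == "ortho"]
    b3 <- coefTable(f3)$b[coefTable(f3)$term == "ortho"]
    expect_equal(b1, b3, tolerance = 1e-8)
})

test_that("standardized coefficients satisfy the scaling identity", {
    ph <- groundTruthBrainage(makeCohort(300, seed = 29, nFeatures = 2))
    fit <- fitLifestyleModel(ph, lifestyle = "pack_years", approach = 1,
        covariates = c("sex", "education"))
    tb <- coefTable(fit)
    y <- ph$brainage[complete.cases(ph)]
    for (v in c("pack_years", "education")) {
        row <- tb[tb$term == v, ]
        expect_equal(row$beta, row$b * sd(ph[[v]]) / sd(ph$brainage),
            tolerance = 1e-10)
    }
    expect_gte(deltaR2(fit), 0)
})

test_that("an injected smoking effect is recovered from ground-truth BrainAGE", {
    cfg <- simulationConfig(600, seed = 31, nFeatures = 2,
        effectMonths = c(pack_years = 6, alcohol_g_month = 0,
            met_score = 0, social_index = 0))
    ph <- groundTruthBrainage(simulateCohort(cfg))
    fit <- fitLifestyleModel(ph, lifestyle = "pack_years", approach = 1,
        covariates = "sex")
    row <- coefTable(fit)
    b <- row$b[row$term == "pack_years"]
    se <- abs(b / row$t[row$term == "pack_years"])
    expect_lt(abs(b - 0.5), 2 * se)
})

test_that("collinear lifestyle terms are rejected by name", {
    ph <- groundTruthBrainage(makeCohort(100, seed = 37, nFeatures = 2))
    ph$copy_age <- ph$age
    expect_error(fitLifestyleModel(ph, lifestyle = "copy_age",
        approach = 1, covariates = character()), "collinear")
    expect_error(fitLifestyleModel(ph, lifestyle = "nope", approach = 1),
        "missing model columns")
})

test_that("slope-to-months conversion reproduces the reported magnitudes", {
    expect_equal(quantifyMonths(-0.046), -0.552)
    expect_equal(round(abs(quantifyMonths(-0.046)), 2), 0.55)
    expect_equal(round(abs(quantifyMonths(-0.058)), 2), 0.70)
    expect_equal(round(abs(quantifyMonths(-0.029)), 2), 0.35)
    expect_equal(quantifyMonths(0), 0)
})

test_that("sex interaction test is invariant to sex coding and detects slope differences", {
    set.seed(41)
    n <- 600
    sexNum <- rbinom(n, 1, 0.5)
    x <- rnorm(n)
    # slopes differ by 1 SD-unit between the sexes
    y <- 0.5 * x + 1 * x * sexNum + rnorm(n)
    d <- data.frame(brainage = y, sex = sexNum, ls = x,
        age = runif(n, 55, 85), education = sample(1:10, n, TRUE))
    it <- testSexInteraction(d, "ls")
    expect_lt(it$p, 0.001)
    d2 <- d
    d2$sex <- d$sex + 1   # {0,1} -> {1,2}
    it2 <- testSexInteraction(d2, "ls")
    expect_equal(it$F, it2$F, tolerance = 1e-8)
    expect_error(testSexInteraction(d[d$sex == 0, ], "ls"),
        "both sexes")
})

test_that("sex interaction false-positive rate is near the nominal level", {
    set.seed(43)
    hits <- vapply(1:200, function(i) {
        n <- 200
        d <- data.frame(brainage = rnorm(n), sex = rbinom(n, 1, 0.5),
            ls = rnorm(n), age = runif(n, 55, 85),
            education = sample(1:10, n, TRUE))
        testSexInteraction(d, "ls")$p < 0.05
    }, logical(1))
    expect_gt(mean(hits), 0.01)
    expect_lt(mean(hits), 0.10)
})

test_that("curve comparison prefers the quadratic exactly when it should", {
    set.seed(47)
    n <- 400
    d <- data.frame(age = runif(n, 55, 85), sex = rbinom(n, 1, 0.5),
        education = sample(1:10, n, TRUE), ls = rnorm(n))
    # outcome an exact parabola in the residualized term
    r <- resid(lm(ls ~ age + sex + education, data = d))
    d$brainage <- 2 + r - 3 * r^2
    cmp <- suppressWarnings(compareLinearQuadratic(d, "ls"))
    expect_gt(cmp$r2Quadratic, 0.999)
    expect_gt(cmp$r2Quadratic, cmp$r2Linear)
    expect_lt(cmp$pQuadratic, 1e-10)

    # nested models: quadratic R2 never below linear R2
    for (i in 1:10) {
        d$brainage <- rnorm(n)
        cm <- compareLinearQuadratic(d, "ls")
        expect_gte(cm$r2Quadratic, cm$r2Linear)
    }
    expect_error(compareLinearQuadratic(d[1:4, ], "ls"), "at least 5")
})

test_that("a purely linear signal keeps the quadratic term at the nominal rate", {
    set.seed(53)
    hits <- vapply(1:200, function(i) {
        n <- 300
        d <- data.frame(age = runif(n, 55, 85), sex = rbinom(n, 1, 0.5),
            education = sample(1:10, n, TRUE), ls = rnorm(n))
        d$brainage <- 0.4 * d$ls + rnorm(n)
        compareLinearQuadratic(d, "ls")$pQuadratic < 0.05
    }, logical(1))
    expect_gt(mean(hits), 0.01)
    expect_lt(mean(hits), 0.10)
})

test_that("smokers are classified by the pack-year thresholds", {
    g <- classifySmokers(c(0, 5, 19.9, 20, 45))
    expect_equal(as.character(g),
        c("never", "moderate", "moderate", "severe", "severe"))
})

test_that("a constructed severe-smoker offset is detected after age matching", {
    cfg <- simulationConfig(450, seed = 59, nFeatures = 2,
        estimatorNoiseSd = 2.5,
        effectMonths = c(pack_years = 0, alcohol_g_month = 0,
            met_score = 0, social_index = 0))
    ph <- phenotypes(simulateCohort(cfg))
    off <- ph$true_offset + ifelse(ph$pack_years >= 20, 2, 0)
    ph$brainage <- detrendQuadratic(off, ph$age)$brainage
    sg <- smokerGroupAnalysis(ph)
    expect_lt(sg@p, 0.01)
    am <- sg@adjustedMeans
    sev <- am$emmean[am$group == "severe"]
    expect_equal(sev - am$emmean[am$group == "never"], 2, tolerance = 0.9)
    expect_equal(sev - am$emmean[am$group == "moderate"], 2,
        tolerance = 0.9)
    # matched triplets respect the caliper within sex
    mt <- sg@matched
    expect_equal(nrow(mt) %% 3, 0)
    expect_error(smokerGroupAnalysis(ph[ph$pack_years == 0, ]),
        "empty smoker group")
})

test_that("identical group distributions keep the group test near alpha", {
    set.seed(61)
    hits <- vapply(1:100, function(i) {
        cfg <- simulationConfig(240, seed = 1000 + i, nFeatures = 2,
            effectMonths = c(pack_years = 0, alcohol_g_month = 0,
                met_score = 0, social_index = 0))
        ph <- phenotypes(simulateCohort(cfg))
        ph$brainage <- detrendQuadratic(ph$true_offset, ph$age)$brainage
        smokerGroupAnalysis(ph)@p < 0.05
    }, logical(1))
    expect_lt(mean(hits), 0.12)
})

test_that("noncentral-F power behaves as the theory demands", {
    # zero effect size: power equals alpha exactly (central F)
    p0 <- computePower(0, n = 100, alpha = 0.05, nPredictors = 5)
    expect_equal(powerValue(p0), 0.05, tolerance = 1e-12)
    # strictly increasing in n and in f2
    pw <- function(f2, n) powerValue(computePower(f2, n, 0.05, 5))
    ns <- c(50, 100, 200, 400)
    expect_true(all(diff(vapply(ns, function(n) pw(0.05, n),
        numeric(1))) > 0))
    f2s <- c(0.01, 0.03, 0.05, 0.1)
    expect_true(all(diff(vapply(f2s, function(f) pw(f, 200),
        numeric(1))) > 0))
    expect_error(computePower(0.05, n = 6, alpha = 0.05, nPredictors = 5),
        "exceed")
})

test_that("descriptive correlations match closed forms and a rank oracle", {
    x <- seq(1, 10)
    d <- data.frame(a = x, b = exp(x), c = 3 * x - 2)
    ds <- descriptives(d)
    expect_equal(ds$spearman$r["a", "b"], 1)   # monotone transform
    expect_equal(ds$pearson$r["a", "c"], 1)    # exact linear relation

    # tie-laden vectors against a brute-force average-rank computation
    tx <- c(1, 2, 2, 3, 3, 3, 4, 10)
    ty <- c(5, 5, 7, 8, 8, 2, 2, 9)
    dt <- descriptives(data.frame(x = tx, y = ty))
    expect_equal(dt$spearman$r["x", "y"],
        pearsonBySums(bruteAvgRank(tx), bruteAvgRank(ty)),
        tolerance = 1e-10)
    expect_equal(dt$spearman$r["x", "y"], 0.243769045201,
        tolerance = 1e-8)

    # zero variance is flagged undefined, not reported as zero
    dz <- descriptives(data.frame(x = tx, z = rep(1, 8)))
    expect_true("x:z" %in% dz$spearman$undefined)
    expect_true(is.na(dz$pearson$r["x", "z"]))
})
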