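test_that("cross-validation plans partition each stratum into folds of k", {
    plan <- crossValPlan(rep("all", 20), k = 10, seed = 1)
    expect_equal(sort(unique(plan$fold)), 1:2)
    expect_equal(sort(plan$index), 1:20)
    expect_equal(unname(table(plan$fold)), c(10L, 10L),
        ignore_attr = TRUE)

    # remainder forms a smaller final fold
    plan2 <- crossValPlan(rep("all", 23), k = 10, seed = 1)
    expect_equal(unname(table(plan2$fold)), c(10L, 10L, 3L),
        ignore_attr = TRUE)

    expect_error(crossValPlan(c(rep("f", 5), rep("m", 30)), k = 10),
        "disable the sex split or reduce k")
})

test_that("sex-split training sets never contain opposite-sex subjects", {
    co <- makeCohort(60, seed = 2, nFeatures = 10)
    est <- leaveKOutEstimate(co, k = 10, sexSplit = TRUE, seed = 4)
    ph <- phenotypes(co)
    # the plan assigns each subject to a fold within its own sex stratum,
    # so any fold's training set (same stratum, other folds) is single-sex
    expect_identical(est$plan$stratum, as.character(ph$sex))
    expect_true(all(!is.na(est$estimated)))
    expect_identical(names(est$estimated), ph$subject_id)
})

test_that("held-out subjects cannot influence each other's estimates", {
    cfg <- simulationConfig(40, seed = 6, nFeatures = 10)
    co <- simulateCohort(cfg)
    est <- leaveKOutEstimate(co, k = 10, sexSplit = FALSE, seed = 9)
    fold1 <- est$plan$subject_id[est$plan$fold == 1]
    # corrupt one held-out subject's features; same-fold estimates of the
    # others must be unchanged (the fold model never saw any of them)
    gm <- SummarizedExperiment::assay(co, "gm")
    gm[, fold1[1]] <- rev(gm[, fold1[1]])
    co2 <- co
    SummarizedExperiment::assay(co2, "gm") <- gm
    est2 <- leaveKOutEstimate(co2, k = 10, sexSplit = FALSE, seed = 9)
    others <- setdiff(fold1, fold1[1])
    expect_equal(est2$estimated[others], est$estimated[others])
    expect_false(isTRUE(all.equal(est2$estimated[fold1[1]],
        est$estimated[fold1[1]])))
})

test_that("a noise-free monotone cohort is estimated within a year", {
    cfg <- simulationConfig(300, seed = 14, nFeatures = 30,
        featureNoiseSd = 0, estimatorNoiseSd = 0,
        ageTrend = c(-0.004, 0),
        effectMonths = c(pack_years = 0, alcohol_g_month = 0,
            met_score = 0, social_index = 0))
    co <- simulateCohort(cfg)
    est <- leaveKOutEstimate(co, k = 10, sexSplit = TRUE, seed = 3)
    mae <- mean(abs(est$estimated - phenotypes(co)$age))
    expect_lt(mae, 1)
})

test_that("cross-validated BrainAGE recovers an injected exposure effect", {
    # the offset enters the features only through effective age, so a
    # positive smoking effect must re-emerge in the estimated gaps
    for (s in 1:5) {
        cfg <- simulationConfig(200, seed = 100 + s, nFeatures = 30,
            effectMonths = c(pack_years = 6, alcohol_g_month = 0,
                met_score = 0, social_index = 0))
        co <- simulateCohort(cfg)
        est <- suppressMessages(leaveKOutEstimate(co, k = 10,
            sexSplit = FALSE, seed = s))
        bg <- brainAGE(brainAgeResult(co, est))
        ct <- cor.test(bg, phenotypes(co)$pack_years,
            alternative = "greater")
        expect_lt(ct$p.value, 0.01)
    }
})

test_that("raw gaps are the exact difference of estimated and chronological age", {
    expect_equal(computeBrainAGE(70, 65), 5)
    expect_equal(computeBrainAGE(c(60.5, 70), c(63, 70)), c(-2.5, 0))
    expect_error(computeBrainAGE(1:3, 1:2), "align")
})

test_that("quadratic detrending matches the normal-equation solution and centers", {
    ages <- c(20, 30, 40, 55, 65, 80)
    gaps <- c(1.2, -0.5, 0.3, 2.0, -1.1, 0.6)
    dt <- detrendQuadratic(gaps, ages)
    # hand-solved 3x3 normal equations (frozen oracle values)
    expect_equal(unname(dt$coefficients),
        c(1.168123146126, -0.029377315645, 0.000242337321),
        tolerance = 1e-8)
    expect_lt(abs(mean(dt$brainage)), 1e-10)

    # an exact quadratic detrends to zero
    g2 <- 1 + 0.2 * ages - 0.003 * ages^2
    expect_equal(detrendQuadratic(g2, ages)$brainage, rep(0, 6),
        tolerance = 1e-10)

    # residuals are orthogonal to the quadratic age design
    set.seed(10)
    a <- runif(50, 20, 80); g <- rnorm(50)
    r <- detrendQuadratic(g, a)$brainage
    expect_lt(abs(sum(r)), 1e-8)
    expect_lt(abs(cor(r, a)), 1e-8)
    expect_lt(abs(cor(r, a^2)), 1e-8)

    expect_error(detrendQuadratic(c(1, 2, 3, 4), rep(5, 4)), "collinear")
    expect_error(detrendQuadratic(1:3, 1:3), "at least 4")
})

test_that("performance measures match hand arithmetic and handle degeneracy", {
    ch <- c(60, 65, 70, 75, 80)
    es <- c(62, 64, 73, 74, 78)
    bg <- c(2, -1, 3, -1, -2)
    pr <- performanceReport(ch, es, bg)
    expect_equal(pr@overall$mae, 1.8)
    expect_equal(pr@overall$r_est, 0.9666033488, tolerance = 1e-8)
    expect_equal(pr@overall$r_gap, -0.5834599660, tolerance = 1e-8)
    expect_equal(pr@overall$r2, 0.9343220339, tolerance = 1e-8)

    perfect <- suppressWarnings(performanceReport(ch, ch, rep(0, 5)))
    expect_equal(perfect@overall$mae, 0)
    expect_equal(perfect@overall$r_est, 1)
    expect_equal(perfect@overall$r2, 1)

    expect_equal(performanceReport(c(-2, 2), c(0, 0), c(-2, 2))@overall$mae, 2)

    flat <- suppressWarnings(performanceReport(ch, rep(70, 5), bg))
    expect_true(is.na(flat@overall$r_est))
    expect_true("r_est" %in% flat@undefined)
})

test_that("brainAgeResult assembles a consistent per-subject table", {
    co <- makeCohort(80, seed = 16, nFeatures = 10)
    est <- leaveKOutEstimate(co, k = 10, sexSplit = FALSE, seed = 2)
    bar <- brainAgeResult(co, est)
    tb <- brainAgeTable(bar)
    expect_equal(tb$raw_gap, tb$estimated_age - tb$age)
    expect_lt(abs(mean(brainAGE(bar))), 1e-8)
    expect_length(detrendCoefficients(bar), 3)
})
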