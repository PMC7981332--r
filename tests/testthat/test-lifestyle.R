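test_that("pack-years follow the standard packs-per-day definition", {
    expect_equal(computePackYears(10, 20), 10)
    expect_equal(computePackYears(37, 0), 0)
    # heaviest plausible exposure: 51 years at 80 cigarettes a day
    expect_equal(computePackYears(51, 80), 204)
    # the literal years-times-cigarettes product is 20x larger
    expect_equal(computePackYears(10, 20, perPack = FALSE), 200)
    expect_error(computePackYears(-1, 10), "yearsSmoked")
    expect_error(computePackYears(10, NA), "finite")
})

test_that("alcohol intake sums to grams of pure ethanol per month", {
    expect_equal(computeAlcoholGramsPerMonth(list()), 0)
    beer <- beverageIntake("beer", 30)
    expect_equal(round(computeAlcoholGramsPerMonth(list(beer)), 1), 227.2)
    wine <- beverageIntake("red_wine", 10)
    expect_equal(round(computeAlcoholGramsPerMonth(list(wine)), 1), 173.6)
    both <- computeAlcoholGramsPerMonth(list(beer, wine))
    expect_equal(both, 0.2 * 0.048 * 789 * 30 + 0.2 * 0.11 * 789 * 10)
    expect_error(beverageIntake("mead", 5), "unknown beverage")
    custom <- beverageIntake("mead", 5, servingVolume = 0.25,
        alcoholFraction = 0.08)
    expect_equal(computeAlcoholGramsPerMonth(list(custom)),
        0.25 * 0.08 * 789 * 5)
})

test_that("social integration index sums partnership, close ties and memberships", {
    expect_equal(computeSocialIndex(FALSE), 0)
    expect_equal(computeSocialIndex(TRUE, 2, 3, 5, 1), 13)
    expect_equal(computeSocialIndex(FALSE, nFriends = 1), 1)
    expect_error(computeSocialIndex(TRUE, nChildren = -1), ">= 0")
})

test_that("MET score sums activity dose over at most four records", {
    expect_equal(computeMetScore(), 0)
    expect_equal(computeMetScore(4, 5), 20)
    expect_equal(computeMetScore(c(7, 3.5), c(4, 8)), 56)
    expect_error(computeMetScore(rep(3, 5), rep(1, 5)), "at most 4")
    expect_error(computeMetScore(0.5, 2), ">= 1")
})

test_that("combined risk score components satisfy the sign and sum contracts", {
    ph <- phenotypes(makeCohort(300, seed = 3, nFeatures = 2))
    rs <- combinedRiskScore(ph)
    comp <- riskComponents(rs)
    expect_true(all(comp[, c("pack_years", "alcohol_g_month")] >= 0))
    expect_true(all(comp[, c("met_score", "social_index")] <= 0))
    expect_equal(rowSums(comp), riskScores(rs), tolerance = 1e-12)

    # two identical subjects get identical scores
    ph2 <- ph[c(1, 1, 2:10), ]
    rs2 <- combinedRiskScore(ph2)
    expect_equal(riskScores(rs2)[1], riskScores(rs2)[2])

    # the subject extreme on every variable in the risky direction is the
    # cohort maximum
    worst <- ph[1, ]
    worst$pack_years <- max(ph$pack_years)
    worst$alcohol_g_month <- max(ph$alcohol_g_month)
    worst$met_score <- min(ph$met_score)
    worst$social_index <- min(ph$social_index)
    sW <- riskScores(applyRiskScore(rs, worst))
    expect_gte(sW + 1e-10, max(riskScores(rs)))
})

test_that("risk score is monotone in exposures and invariant to affine rescaling", {
    ph <- phenotypes(makeCohort(200, seed = 7, nFeatures = 2))
    rs <- combinedRiskScore(ph)
    probe <- ph[3, ]
    s0 <- riskScores(applyRiskScore(rs, probe))
    probe$pack_years <- probe$pack_years + 5
    expect_gte(riskScores(applyRiskScore(rs, probe)), s0)
    probe$social_index <- probe$social_index + 5
    expect_lt(riskScores(applyRiskScore(rs, probe)),
        riskScores(applyRiskScore(rs, ph[3, ])) + 1e-10)

    # affine rescaling of a raw variable is absorbed by the z-transform
    ph3 <- ph
    ph3$alcohol_g_month <- ph3$alcohol_g_month / 28 * 7   # per week
    expect_equal(riskScores(combinedRiskScore(ph3)), riskScores(rs),
        tolerance = 1e-10)
})

test_that("sample mean of the combined score equals the closed-form shift sum", {
    # algebraic identity: mean(z - min z) = -min z per risk variable,
    # mean(-z - max(-z)) = min z per protective variable
    ph <- phenotypes(makeCohort(400, seed = 13, nFeatures = 2))
    rs <- combinedRiskScore(ph)
    zmin <- function(v) (min(ph[[v]]) - mean(ph[[v]])) / sd(ph[[v]])
    expected <- -zmin("pack_years") - zmin("alcohol_g_month") +
        zmin("met_score") + zmin("social_index")
    expect_equal(mean(riskScores(rs)), expected, tolerance = 1e-10)
})

test_that("zero-variance exposures are rejected by name", {
    ph <- phenotypes(makeCohort(50, seed = 9, nFeatures = 2))
    ph$met_score <- 1
    expect_error(combinedRiskScore(ph), "met_score")
    expect_error(combinedRiskScore(ph[1, , drop = FALSE]), ">= 2")
})
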