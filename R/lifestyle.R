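# Lifestyle exposure derivation and the combined lifestyle risk score.

#' Pack-years of smoking
#'
#' Lifetime tobacco exposure in pack-years: years smoked times packs (20
#' cigarettes) per day. A flag switches to the literal
#' years-times-cigarettes product, which inflates the unit by a factor 20
#' and is provided for comparison only.
#'
#' @param yearsSmoked years of smoking, >= 0.
#' @param cigarettesPerDay cigarettes smoked per day, >= 0.
#' @param perPack divide by 20 cigarettes per pack (default `TRUE`).
#' @return pack-years (vectorized).
#' @export
#' @examples
#' computePackYears(10, 20)   # one pack a day for a decade -> 10
computePackYears <- function(yearsSmoked, cigarettesPerDay, perPack = TRUE) {
    if (any(!is.finite(yearsSmoked)) || any(!is.finite(cigarettesPerDay)))
        stop("smoking history must be finite")
    if (any(yearsSmoked < 0)) stop("yearsSmoked must be >= 0")
    if (any(cigarettesPerDay < 0)) stop("cigarettesPerDay must be >= 0")
    yearsSmoked * cigarettesPerDay / if (perPack) 20 else 1
}

# Conventional pure-ethanol fractions by volume and serving volumes (litres).
.beverages <- data.frame(
    volume = c(beer = 0.2, red_wine = 0.2, white_wine = 0.2,
        spirits = 0.02),
    fraction = c(beer = 0.048, red_wine = 0.11, white_wine = 0.11,
        spirits = 0.33))

.ethanolDensity <- 789   # g per litre

#' One reported beverage intake
#'
#' @param beverage one of `"beer"`, `"red_wine"`, `"white_wine"`,
#'   `"spirits"`, or any label when both `servingVolume` and
#'   `alcoholFraction` are given explicitly.
#' @param servingsPerMonth servings consumed per month.
#' @param servingVolume serving volume in litres (defaulted per beverage).
#' @param alcoholFraction ethanol volume fraction (defaulted per beverage).
#' @return a `BeverageIntake` list for [computeAlcoholGramsPerMonth()].
#' @export
beverageIntake <- function(beverage, servingsPerMonth, servingVolume = NULL,
        alcoholFraction = NULL) {
    known <- beverage %in% rownames(.beverages)
    if (is.null(servingVolume)) {
        if (!known) stop("unknown beverage '", beverage,
            "': supply servingVolume explicitly")
        servingVolume <- .beverages[beverage, "volume"]
    }
    if (is.null(alcoholFraction)) {
        if (!known) stop("unknown beverage '", beverage,
            "': supply alcoholFraction explicitly")
        alcoholFraction <- .beverages[beverage, "fraction"]
    }
    stopifnot(servingVolume > 0, alcoholFraction > 0, alcoholFraction < 1,
        servingsPerMonth >= 0)
    structure(list(beverage = beverage, servingVolume = servingVolume,
        alcoholFraction = alcoholFraction,
        servingsPerMonth = servingsPerMonth), class = "BeverageIntake")
}

#' Pure alcohol intake in grams per month
#'
#' Sums `servingVolume x alcoholFraction x 789 g/L x servingsPerMonth`
#' over all reported beverages (789 g/L is the density of ethanol).
#'
#' @param intakes list of [beverageIntake()] records (possibly empty).
#' @return grams of pure alcohol per month.
#' @export
#' @examples
#' computeAlcoholGramsPerMonth(list(beverageIntake("beer", 30)))
computeAlcoholGramsPerMonth <- function(intakes) {
    if (length(intakes) == 0L) return(0)
    stopifnot(all(vapply(intakes, inherits, logical(1), "BeverageIntake")))
    sum(vapply(intakes, function(b)
        b$servingVolume * b$alcoholFraction * .ethanolDensity *
            b$servingsPerMonth, numeric(1)))
}

#' Social integration index
#'
#' Berkman-style sum of partnership status (2 points if married or
#' cohabitating), close ties (children + close relatives + friends) and
#' active organizational memberships. No cap is applied to the close-ties
#' sub-score.
#'
#' @param partnered logical.
#' @param nChildren,nCloseRelatives,nFriends,nActiveMemberships
#'   non-negative counts.
#' @return index points (vectorized).
#' @export
#' @examples
#' computeSocialIndex(TRUE, 2, 3, 5, 1)   # 13
computeSocialIndex <- function(partnered, nChildren = 0, nCloseRelatives = 0,
        nFriends = 0, nActiveMemberships = 0) {
    counts <- cbind(nChildren, nCloseRelatives, nFriends, nActiveMemberships)
    if (any(counts < 0)) stop("counts must be >= 0")
    2 * as.numeric(partnered) + nChildren + nCloseRelatives + nFriends +
        nActiveMemberships
}

#' MET-hour physical activity score
#'
#' Sum of MET value times duration in hours over the (at most four)
#' reported sportive activities. The reporting window follows the
#' instrument (hours per month here); the score is treated as MET-hours
#' per reporting window throughout.
#'
#' @param metValues MET value per activity (>= 1, the resting multiple).
#' @param hours duration in hours per activity (>= 0).
#' @return MET-hours per reporting window.
#' @export
#' @examples
#' computeMetScore(c(7, 3.5), c(4, 8))   # 56
computeMetScore <- function(metValues = numeric(), hours = numeric()) {
    if (length(metValues) != length(hours))
        stop("metValues and hours must align")
    if (length(metValues) > 4L)
        stop("at most 4 activity records per subject are supported")
    if (length(metValues) == 0L) return(0)
    if (any(metValues < 1)) stop("MET values must be >= 1")
    if (any(hours < 0)) stop("hours must be >= 0")
    sum(metValues * hours)
}

.riskDirections <- c(pack_years = 1, alcohol_g_month = 1,
    met_score = -1, social_index = -1)

#' Fit the combined lifestyle risk score
#'
#' Each exposure is z-scored on the fitting cohort; protective behaviors
#' (social integration, physical activity) have their sign reversed so
#' that larger always means riskier; each variable is then shifted so that
#' risk components are non-negative (z minus its minimum) and protective
#' components non-positive (reversed z minus its maximum); the combined
#' score is the sum of the four components. The transform constants (mean,
#' SD, direction, shift) are stored so the fitted scorer can be applied to
#' new subjects with [applyRiskScore()].
#'
#' @param exposures data.frame with columns `pack_years`,
#'   `alcohol_g_month`, `met_score`, `social_index` (>= 2 rows, each with
#'   SD > 0).
#' @return a [RiskScore-class].
#' @export
#' @examples
#' cohort <- simulateCohort(simulationConfig(200, seed = 1))
#' rs <- combinedRiskScore(phenotypes(cohort))
#' head(riskScores(rs))
combinedRiskScore <- function(exposures) {
    vars <- names(.riskDirections)
    miss <- setdiff(vars, colnames(exposures))
    if (length(miss))
        stop("exposures: missing columns ", paste(miss, collapse = ", "))
    if (nrow(exposures) < 2L) stop("need >= 2 subjects to fit the scorer")
    const <- data.frame(mean = NA_real_, sd = NA_real_,
        direction = unname(.riskDirections), shift = NA_real_,
        row.names = vars)
    comp <- matrix(NA_real_, nrow(exposures), length(vars),
        dimnames = list(NULL, vars))
    for (v in vars) {
        x <- exposures[[v]]
        m <- mean(x); s <- sd(x)
        if (!is.finite(s) || s == 0)
            stop("zero-variance lifestyle variable: ", v)
        z <- .riskDirections[[v]] * (x - m) / s
        shift <- if (.riskDirections[[v]] > 0) min(z) else max(z)
        const[v, c("mean", "sd", "shift")] <- c(m, s, shift)
        comp[, v] <- z - shift
    }
    new("RiskScore", constants = const, components = comp,
        score = rowSums(comp))
}

#' Apply a fitted risk scorer to new subjects
#'
#' Reuses the transform constants of the fitting cohort (no refit): new
#' exposures are standardized with the stored means/SDs, sign-aligned and
#' shifted with the stored constants, then summed.
#'
#' @param object a fitted [RiskScore-class].
#' @param exposures data.frame with the four exposure columns.
#' @return a [RiskScore-class] for the new subjects (same constants).
#' @export
applyRiskScore <- function(object, exposures) {
    stopifnot(is(object, "RiskScore"))
    const <- object@constants
    vars <- rownames(const)
    miss <- setdiff(vars, colnames(exposures))
    if (length(miss))
        stop("exposures: missing columns ", paste(miss, collapse = ", "))
    comp <- vapply(vars, function(v) {
        z <- const[v, "direction"] *
            (exposures[[v]] - const[v, "mean"]) / const[v, "sd"]
        z - const[v, "shift"]
    }, numeric(nrow(exposures)))
    comp <- matrix(comp, nrow = nrow(exposures),
        dimnames = list(NULL, vars))
    new("RiskScore", constants = const, components = comp,
        score = rowSums(comp))
}

#' @describeIn RiskScore per-subject combined scores.
#' @param object a `RiskScore`.
#' @export
riskScores <- function(object) object@score

#' @describeIn RiskScore transform constants learned on the fitting cohort.
#' @export
riskConstants <- function(object) object@constants

#' @describeIn RiskScore per-subject transformed components.
#' @export
riskComponents <- function(object) object@components

setMethod("show", "RiskScore", function(object) {
    cat("RiskScore:", length(object@score), "subjects; mean combined score",
        sprintf("%.3f\n", mean(object@score)))
    print(round(object@constants, 3))
})
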