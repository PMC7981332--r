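# Doubly truncated normal: moments, sampling, and moment-matching.
#
# The generator draws each lifestyle exposure from a truncated normal on
# [min, max], optionally mixed with a point mass at the minimum (never
# smokers, non-drinkers, inactive subjects). Published cohort tables report
# the observed mean/SD of the mixture, so the underlying (mu, sigma) must be
# solved so that the *truncated mixture* reproduces those moments -- a plain
# truncated normal with the published mean/SD plugged in would be biased
# upward by the truncation.

truncnormMoments <- function(mu, sigma, lo, hi) {
    a <- (lo - mu) / sigma
    b <- (hi - mu) / sigma
    Z <- pnorm(b) - pnorm(a)
    if (Z < 1e-300) return(c(mean = NA_real_, sd = NA_real_))
    da <- dnorm(a); db <- dnorm(b)
    lam <- (da - db) / Z
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + (a * da - b * db) / Z - lam^2)
    c(mean = unname(m), sd = unname(sqrt(max(v, 0))))
}

rtruncnormInv <- function(n, mu, sigma, lo, hi) {
    pa <- pnorm(lo, mu, sigma)
    pb <- pnorm(hi, mu, sigma)
    qnorm(pa + runif(n) * (pb - pa), mu, sigma)
}

# Maximum coefficient of variation (on the lo-shifted scale) a lower-
# truncated normal can attain is 1 (the exponential limit). Mixture targets
# whose continuous part would need more skew get extra mass at the minimum.
.maxFeasibleCV <- 0.95

# Solve the mixture  p * delta(lo) + (1 - p) * TN(mu, sigma; lo, hi)  so
# that its mean and SD match the targets. If pMin is NA, the smallest
# point-mass probability keeping the continuous part feasible is used
# (0 when the targets are already feasible).
solveTruncnorm <- function(mean, sd, lo, hi, pMin = NA_real_) {
    stopifnot(sd > 0, lo < hi)
    contTargets <- function(p) {
        m <- (mean - p * lo) / (1 - p)
        e2 <- (mean^2 + sd^2 - p * lo^2) / (1 - p)
        v <- e2 - m^2
        c(mean = m, sd = sqrt(max(v, 0)))
    }
    cvShift <- function(p) {
        tg <- contTargets(p)
        if (tg["mean"] <= lo || tg["sd"] <= 0) return(Inf)
        tg["sd"] / (tg["mean"] - lo)
    }
    if (is.na(pMin)) {
        pMin <- 0
        if (cvShift(0) > .maxFeasibleCV) {
            # p where the continuous-part variance vanishes bounds the search
            mS <- mean - lo
            pUpper <- 1 - mS^2 / (sd^2 + mS^2)
            f <- function(p) cvShift(p) - .maxFeasibleCV
            pMin <- tryCatch(
                stats::uniroot(f, c(1e-6, pUpper - 1e-9), tol = 1e-10)$root,
                error = function(e) stop(
                    "lifestyle: cannot calibrate a truncated-normal mixture ",
                    "to mean ", mean, ", sd ", sd, " on [", lo, ", ", hi, "]",
                    call. = FALSE))
        }
    } else if (cvShift(pMin) > 1) {
        stop("lifestyle: point mass pMin = ", pMin, " leaves an infeasible ",
            "continuous part (needs coefficient of variation > 1)",
            call. = FALSE)
    }
    tg <- contTargets(pMin)
    obj <- function(par) {
        mo <- truncnormMoments(par[1], exp(par[2]), lo, hi)
        if (anyNA(mo)) return(1e10)
        (mo["mean"] - tg["mean"])^2 + (mo["sd"] - tg["sd"])^2
    }
    start <- c(unname(tg["mean"]), log(unname(tg["sd"])))
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
        control = list(maxit = 5000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
        control = list(maxit = 5000, reltol = 1e-14))
    mo <- truncnormMoments(fit$par[1], exp(fit$par[2]), lo, hi)
    list(mu = unname(fit$par[1]), sigma = unname(exp(fit$par[2])),
        pMin = pMin, achieved = mo,
        residual = sqrt(fit$value))
}

# Polynomial string hash, for provenance blocks (not cryptographic).
configHash <- function(x) {
    bytes <- utf8ToInt(x)
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}
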