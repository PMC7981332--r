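# Shared fixtures and independent oracles, built in code at test time.

# Small cohort with cheap features for inference-layer tests.
makeCohort <- function(n, seed, nFeatures = 20L, ...) {
    simulateCohort(simulationConfig(n, seed = seed,
        nFeatures = nFeatures, ...))
}

# Ground-truth BrainAGE path: the latent offset, quadratically detrended.
# Bypasses the imaging estimator so inference properties are tested
# against the generator's known effects.
groundTruthBrainage <- function(cohort) {
    ph <- phenotypes(cohort)
    ph$brainage <- detrendQuadratic(ph$true_offset, ph$age)$brainage
    ph
}

# Independent marginal-likelihood evaluation for the sparse Bayesian
# regression model, via the dense covariance C = I/beta + Phi A^-1 Phi'.
# Deliberately avoids the package's Woodbury/Cholesky computation path.
evidenceDense <- function(logAlpha, logBeta, Phi, y) {
    N <- length(y)
    a <- pmin(exp(logAlpha), 1e12)
    b <- min(exp(logBeta), 1e12)
    C <- diag(N) / b + Phi %*% (t(Phi) / a)
    out <- tryCatch(
        -0.5 * (N * log(2 * pi) + as.numeric(determinant(C)$modulus) +
            sum(y * solve(C, y))),
        error = function(e) -1e10)
    if (!is.finite(out)) -1e10 else out
}

# Brute-force evidence maximization: multi-start Nelder-Mead over
# (log alpha_1..M, log beta) on the dense evidence above.
evidenceOracleMax <- function(Phi, y, nStarts = 40, seed = 99) {
    M <- ncol(Phi)
    obj <- function(p) -evidenceDense(p[seq_len(M)], p[M + 1], Phi, y)
    best <- Inf
    withr::with_seed(seed, {
        for (i in seq_len(nStarts)) {
            st <- c(runif(M, -5, 12), runif(1, -3, 6))
            o <- optim(st, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
            o <- optim(o$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
            if (o$value < best) best <- o$value
        }
    })
    -best
}

# Average-rank computation by explicit position enumeration (Spearman
# tie-correction oracle).
bruteAvgRank <- function(v) {
    vapply(v, function(vi) mean(which(sort(v) == vi)), numeric(1))
}

pearsonBySums <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
        sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}
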