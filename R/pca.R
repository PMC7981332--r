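# Principal component reduction of the gray-matter feature space.

#' Fit a principal component reduction
#'
#' Thin wrapper around [stats::prcomp()] (no scaling: features share the
#' GM-probability unit) retaining either a fixed number of components or
#' the smallest number explaining at least `varianceTarget` of the total
#' variance; in both cases k is capped at the rank of the centered data
#' (at most training-set size minus one).
#'
#' @param x subjects x features matrix.
#' @param varianceTarget fraction of variance to retain, in `(0, 1]`.
#' @param k fixed component count (overrides `varianceTarget`).
#' @return a [PCAModel-class].
#' @export
#' @examples
#' m <- fitPCA(matrix(rnorm(50), 10, 5), k = 2)
#' m
fitPCA <- function(x, varianceTarget = 0.95, k = NULL) {
    x <- as.matrix(x)
    if (nrow(x) < 2L) stop("need >= 2 subjects to fit a PCA")
    if (is.null(k) && (varianceTarget <= 0 || varianceTarget > 1))
        stop("varianceTarget must lie in (0, 1]")
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    rank <- sum(ev > max(ev) * 1e-12)
    frac <- ev / sum(ev)
    if (is.null(k)) {
        k <- which(cumsum(frac) >= varianceTarget - 1e-12)[1]
        if (is.na(k)) k <- rank
    }
    k <- min(k, rank)
    new("PCAModel", center = pc$center,
        rotation = pc$rotation[, seq_len(k), drop = FALSE],
        sdev = pc$sdev, k = as.integer(k),
        varianceExplained = frac[seq_len(k)])
}

#' Project features onto a fitted reduction
#'
#' @param model a [PCAModel-class].
#' @param x subjects x features matrix with the training feature
#'   dimension.
#' @return subjects x k score matrix.
#' @export
projectPCA <- function(model, x) {
    stopifnot(is(model, "PCAModel"))
    x <- as.matrix(x)
    if (ncol(x) != length(model@center))
        stop("feature dimension mismatch: model has ",
            length(model@center), ", data has ", ncol(x))
    sweep(x, 2, model@center) %*% model@rotation
}

setMethod("show", "PCAModel", function(object) {
    cat(sprintf(
        "PCAModel: %d features -> %d components (%.1f%% variance)\n",
        length(object@center), object@k,
        100 * sum(object@varianceExplained)))
})
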