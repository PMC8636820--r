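# Core sparse k-means machinery. The alternation follows the lasso-weighted
# scheme: (a) k-means in the sqrt(w)-scaled feature space, (b) exact weight
# update maximizing sum(w * bcss) under ||w||_2 <= 1, ||w||_1 <= s, w >= 0.
# The robust variant trims the ceiling(alpha * n) samples farthest from their
# centers (union of weighted- and unweighted-space distances) from center and
# weight updates, then reinserts them by nearest weighted center.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, code) {
    if (is.null(seed))
        return(code)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    code
}

.asMatrix <- function(data) {
    if (is(data, "LifespanExperiment")) exprValues(data) else as.matrix(data)
}

# z-score columns; zero-variance columns are centered but left unscaled
.standardizeColumns <- function(X) {
    mu <- colMeans(X)
    sdev <- apply(X, 2, sd)
    sdev[sdev == 0] <- 1
    sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
}

# squared Euclidean distances from every row of X to every row of centers
.dist2 <- function(X, centers) {
    d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
        2 * X %*% t(centers) +
        outer(rep(1, nrow(X)), rowSums(centers^2))
    d2[d2 < 0] <- 0
    d2
}

# per-feature between-cluster sum of squares (over clusters present in
# `labels`)
.bcssPerFeature <- function(X, labels) {
    k <- max(labels)
    sizes <- tabulate(labels, k)
    present <- which(sizes > 0L)
    mu <- colMeans(X)
    centers <- rowsum(X, labels, reorder = TRUE) / sizes[present]
    bcss <- colSums(sizes[present] * sweep(centers, 2, mu, "-")^2)
    bcss[bcss < 0] <- 0
    bcss
}

.wssPerFeature <- function(X, labels) {
    tss <- colSums(sweep(X, 2, colMeans(X), "-")^2)
    pmax(tss - .bcssPerFeature(X, labels), 0)
}

#' Optimal lasso-bounded feature weights for given between-cluster scores
#'
#' Maximizes \eqn{\sum_j w_j b_j} over \eqn{w \ge 0} subject to
#' \eqn{\|w\|_2 \le 1} and \eqn{\|w\|_1 \le s}. The solution soft-thresholds
#' the scores at \eqn{\Delta} and L2-normalizes, with \eqn{\Delta} found by
#' bisection so that the L1 constraint holds with equality (or
#' \eqn{\Delta = 0} when it is slack).
#'
#' @param bcss non-negative per-feature between-cluster sums of squares.
#' @param l1Bound the L1 bound \eqn{s}, with \eqn{1 < s \le \sqrt{p}}.
#' @return numeric weight vector satisfying both norm constraints to 1e-8.
#' @examples
#' updateWeights(c(4, 1), l1Bound = 1.1)
#' updateWeights(rep(2, 4), l1Bound = 2)  # symmetric: all 1/2
#' @export
updateWeights <- function(bcss, l1Bound) {
    p <- length(bcss)
    if (l1Bound <= 1 || l1Bound > sqrt(p) + 1e-8)
        stop("'l1Bound' must lie in (1, sqrt(p)]")
    bcss <- pmax(bcss, 0)
    if (all(bcss <= 0))
        stop("all between-cluster sums of squares are zero; weights undefined")
    l1At <- function(delta) {
        u <- bcss - delta
        u[u < 0] <- 0
        sum(u) / sqrt(sum(u * u))
    }
    w0 <- bcss / sqrt(sum(bcss * bcss))
    if (sum(w0) <= l1Bound + 1e-12)
        return(w0)
    lo <- 0
    hi <- max(bcss)
    for (i in seq_len(50L)) {
        mid <- (lo + hi) / 2
        if (l1At(mid) > l1Bound) lo <- mid else hi <- mid
    }
    u <- bcss - (lo + hi) / 2
    u[u < 0] <- 0
    u / sqrt(sum(u * u))
}

.checkClusterInputs <- function(X, k, l1Bound, alpha) {
    n <- nrow(X)
    p <- ncol(X)
    if (k < 2 || k > n)
        stop("'k' must satisfy 2 <= k <= n (n = ", n, ")")
    if (l1Bound <= 1 || l1Bound > sqrt(p) + 1e-8)
        stop("'l1Bound' must lie in (1, sqrt(p)]")
    if (alpha < 0 || alpha >= 0.5)
        stop("'alpha' must lie in [0, 0.5)")
    tss <- sum(sweep(X, 2, colMeans(X), "-")^2)
    if (tss <= 0)
        stop("constant expression matrix: total dispersion is zero")
    invisible(TRUE)
}

.defaultL1Bound <- function(p) min(1 + sqrt(p) / 8, sqrt(p))

#' Robust sparse k-means clustering
#'
#' Partitions samples into \code{k} clusters while adaptively reweighting
#' features under a lasso (L1) bound, with optional trimming that makes the
#' fit robust to outlier samples. Each weight alternation (i) runs k-means on
#' the \eqn{\sqrt{w}}-scaled data, (ii) trims the \eqn{\lceil \alpha n
#' \rceil} samples farthest from their cluster centers in weighted space and,
#' separately, in the original unweighted space (the union is excluded), and
#' (iii) refits the weights from the per-feature between-cluster sums of
#' squares of the retained samples. After convergence every sample, trimmed
#' ones included, is assigned to its nearest center in weighted space;
#' trimmed samples are flagged as outliers.
#'
#' With \code{alpha = 0} the fit reduces exactly to plain sparse k-means.
#'
#' @param data a \linkS4class{LifespanExperiment} or a numeric
#'   samples-by-features matrix.
#' @param k number of clusters, \code{2 <= k <= n}.
#' @param l1Bound L1 bound on the weights, in \code{(1, sqrt(p)]}; default
#'   \code{min(1 + sqrt(p)/8, sqrt(p))}, a sparse setting suited to panels
#'   where a minority of features carries the stage signal (tune with
#'   \code{\link{selectL1Bound}}).
#' @param alpha trim fraction in \code{[0, 0.5)}; default 0.1.
#' @param nStarts number of k-means++ restarts; the best restart by the
#'   weighted between-cluster objective is returned.
#' @param seed optional integer seed; the global RNG state is restored on
#'   exit.
#' @param standardize z-score features before clustering (default
#'   \code{TRUE}).
#' @param refineScale for robust fits (\code{alpha > 0}) with
#'   \code{standardize = TRUE}: after a first pass, re-estimate the feature
#'   means and SDs from the samples not flagged as outliers and refit
#'   (default \code{TRUE}). Outlier samples inflate classical SDs and can
#'   mask the informative features; the two-pass fit restores them.
#' @param maxAlt maximum weight alternations (default 20).
#' @param tol relative L1 change in the weights declaring convergence
#'   (default 1e-4).
#' @param nInnerStarts k-means++ seedings tried within each weight
#'   alternation (the warm start from the previous alternation is always
#'   kept as a candidate), compared by trimmed weighted within-cluster SS
#'   (default 4).
#' @return a \linkS4class{SparseKMeansFit}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(50), 10), matrix(rnorm(50, 4), 10))
#' fit <- robustSparseKMeans(x, k = 2, alpha = 0, seed = 1)
#' clusterAssignments(fit)
#' @seealso \code{\link{sparseKMeans}}, \code{\link{updateWeights}},
#'   \code{\link{wwss}}
#' @export
robustSparseKMeans <- function(data, k, l1Bound = NULL, alpha = 0.1,
                               nStarts = 10L, seed = NULL,
                               standardize = TRUE, refineScale = TRUE,
                               maxAlt = 20L, tol = 1e-4,
                               nInnerStarts = 4L) {
    X0 <- .asMatrix(data)
    p <- ncol(X0)
    if (is.null(l1Bound))
        l1Bound <- .defaultL1Bound(p)
    .checkClusterInputs(X0, k, l1Bound, alpha)
    X <- if (standardize) .standardizeColumns(X0) else X0
    best <- .withSeed(seed, {
        fit1 <- .rskcFit(X, as.integer(k), l1Bound, alpha,
                         as.integer(nStarts), as.integer(maxAlt), tol, 50L,
                         as.integer(nInnerStarts))
        if (alpha > 0 && standardize && refineScale && any(fit1$flags)) {
            # second pass: outlier samples inflate per-feature SDs and can
            # crush the informative signal, so re-standardize from the
            # samples not flagged in the first pass and refit
            clean <- X0[!fit1$flags, , drop = FALSE]
            mu <- colMeans(clean)
            sdev <- apply(clean, 2, sd)
            sdev[sdev == 0] <- 1
            X <- sweep(sweep(X0, 2, mu, "-"), 2, sdev, "/")
            .rskcFit(X, as.integer(k), l1Bound, alpha, as.integer(nStarts),
                     as.integer(maxAlt), tol, 50L, as.integer(nInnerStarts))
        } else fit1
    })
    labels <- best$labels + 1L
    ww <- sum(best$weights * .wssPerFeature(X, labels))
    new("SparseKMeansFit",
        assignments = as.integer(labels),
        weights = best$weights,
        outlierFlags = best$flags,
        wwss = ww,
        objective = best$objective,
        objectiveTrace = best$trace,
        l1Bound = l1Bound,
        alpha = alpha,
        k = as.integer(k),
        nIterRun = best$nIter,
        converged = best$converged,
        standardized = standardize)
}

#' Sparse k-means clustering
#'
#' Lasso-weighted k-means without trimming: identical to
#' \code{\link{robustSparseKMeans}} with \code{alpha = 0} (and produces
#' bit-identical results at equal seed).
#'
#' @inheritParams robustSparseKMeans
#' @return a \linkS4class{SparseKMeansFit} with \code{alpha = 0} and no
#'   outlier flags set.
#' @examples
#' set.seed(2)
#' x <- rbind(matrix(rnorm(60), 12), matrix(rnorm(60, 3), 12))
#' sparseKMeans(x, k = 2, seed = 7)
#' @export
sparseKMeans <- function(data, k, l1Bound = NULL, nStarts = 10L, seed = NULL,
                         standardize = TRUE, maxAlt = 20L, tol = 1e-4,
                         nInnerStarts = 4L) {
    robustSparseKMeans(data, k, l1Bound = l1Bound, alpha = 0,
                       nStarts = nStarts, seed = seed,
                       standardize = standardize, maxAlt = maxAlt, tol = tol,
                       nInnerStarts = nInnerStarts)
}

#' Weighted within-cluster sum of squares
#'
#' \eqn{\mathrm{WWSS} = \sum_j w_j \sum_c \sum_{i \in c} (x_{ij} -
#' \bar{x}_{cj})^2}: the within-cluster dispersion with each feature scaled
#' by its weight. This is the quantity whose elbow over \code{k} guides model
#' selection.
#'
#' @param data a \linkS4class{LifespanExperiment} or samples-by-features
#'   matrix.
#' @param assignments integer cluster labels in \code{1..k}.
#' @param weights non-negative feature weights, length \code{p}.
#' @return a non-negative scalar.
#' @examples
#' x <- matrix(rnorm(12), 6, 2)
#' wwss(x, rep(1:2, each = 3), c(0.8, 0.6))
#' @export
wwss <- function(data, assignments, weights) {
    X <- .asMatrix(data)
    assignments <- as.integer(assignments)
    if (length(assignments) != nrow(X))
        stop("'assignments' must have one label per sample")
    k <- max(assignments)
    if (any(assignments < 1L))
        stop("cluster labels must lie in 1..k")
    if (length(weights) != ncol(X))
        stop("'weights' must have one entry per feature")
    if (any(weights < 0))
        stop("'weights' must be non-negative")
    sum(weights * .wssPerFeature(X, assignments))
}

#' Scale each feature by its clustering weight
#'
#' Multiplies column \code{j} of the expression matrix by \code{weights[j]};
#' the transformed matrix is the usual input for low-dimensional embeddings
#' that emphasize the features driving the clustering.
#'
#' @param data a \linkS4class{LifespanExperiment} or samples-by-features
#'   matrix.
#' @param weights numeric vector of length \code{p}.
#' @return a samples-by-features matrix.
#' @examples
#' weightTransform(matrix(1, 2, 3), c(1, 0, 2))
#' @export
weightTransform <- function(data, weights) {
    X <- .asMatrix(data)
    if (length(weights) != ncol(X))
        stop("'weights' must have one entry per feature (",
             ncol(X), ")")
    sweep(X, 2, weights, "*")
}
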