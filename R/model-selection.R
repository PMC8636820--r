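# Choice of k (elbow of the weighted within-cluster dispersion with
# log-scale curvature detection) and of the L1 weight bound (permutation gap
# statistic).

#' Locate the elbow of a dispersion-versus-k curve
#'
#' Takes the (averaged) dispersion values over increasing \code{k},
#' monotonizes them with a cumulative minimum (the optimal dispersion is
#' non-increasing in \code{k}; upward jitter is Monte-Carlo noise), moves to
#' the log scale — where both the pre-elbow and post-elbow regimes of a
#' clustering dispersion curve decay near-linearly, so the elbow is a convex
#' kink — optionally smooths with a Savitzky-Golay filter, and returns the
#' interior \code{k} maximizing the signed discrete second difference. Ties
#' resolve to the smaller \code{k}.
#'
#' @param values positive dispersion values, one per \code{kValues}.
#' @param kValues increasing integers (at least 4).
#' @param sgWindow Savitzky-Golay window length; 0 (default) disables
#'   smoothing, which is appropriate when \code{values} are already averages
#'   over many runs.
#' @param sgOrder Savitzky-Golay polynomial order (default 2).
#' @return a list with \code{chosenK}, \code{curvature} (signed second
#'   differences, NA at the endpoints) and \code{smoothed} (the log-scale
#'   curve used).
#' @examples
#' elbowFromCurve(c(40, 20, 10, 9.5, 9, 8.8), 2:7)$chosenK  # kink at k = 4
#' @export
elbowFromCurve <- function(values, kValues, sgWindow = 0L, sgOrder = 2L) {
    kValues <- as.integer(kValues)
    m <- length(values)
    if (length(kValues) != m)
        stop("'values' and 'kValues' must have equal length")
    if (m < 4L)
        stop("at least 4 k values are required")
    if (any(values <= 0))
        stop("dispersion values must be positive")
    y <- log(cummin(values))
    if (sgWindow > 0L) {
        if (sgWindow %% 2L == 0L || sgWindow < 3L)
            stop("'sgWindow' must be an odd number >= 3")
        if (m < sgWindow)
            stop("curve is shorter than the Savitzky-Golay window (",
                 sgWindow, ")")
        y <- as.numeric(signal::sgolayfilt(y, p = sgOrder, n = sgWindow))
    }
    curv <- rep(NA_real_, m)
    curv[2:(m - 1L)] <- y[3:m] - 2 * y[2:(m - 1L)] + y[1:(m - 2L)]
    chosen <- kValues[which.max(curv)]   # ties: first (= smaller k)
    list(chosenK = chosen, curvature = curv, smoothed = y)
}

#' Choose the number of clusters from the WWSS elbow
#'
#' For each candidate \code{k} the robust sparse fit is run \code{nIter}
#' times with fresh restarts, recording the weighted within-cluster sum of
#' squares (WWSS) and its normalized form, the weighted unexplained-variance
#' fraction \eqn{\mathrm{WWSS} / \sum_j w_j \mathrm{TSS}_j}. The elbow is
#' detected on the mean normalized curve with \code{\link{elbowFromCurve}}:
#' normalization makes the curve comparable across \code{k} (the total
#' weight mass retained by the lasso bound varies with \code{k}), and the
#' log-scale curvature peaks sharply at the planted number of stages on
#' benchmark data.
#'
#' @param data a \linkS4class{LifespanExperiment} or samples-by-features
#'   matrix.
#' @param kRange candidate cluster numbers (at least 4 values; default
#'   \code{2:9}).
#' @param nIter runs averaged per k (default 100).
#' @param alpha trim fraction passed to \code{\link{robustSparseKMeans}}.
#' @param l1Bound L1 weight bound (default as in
#'   \code{\link{robustSparseKMeans}}).
#' @param seed optional integer seed.
#' @param nStarts restarts per run (default 8; thorough per-run optimization
#'   keeps the dispersion curve close to its optimal envelope, which sharpens
#'   the elbow).
#' @param nInnerStarts inner k-means++ seedings per weight alternation
#'   (default 6; see \code{\link{robustSparseKMeans}}).
#' @param refineScale passed to \code{\link{robustSparseKMeans}}; default
#'   \code{FALSE} here so every run measures dispersion on the same fixed
#'   standardization (per-run rescaling would add Monte-Carlo variance to
#'   the curve).
#' @param sgWindow,sgOrder optional Savitzky-Golay smoothing of the curve
#'   before curvature detection (off by default; see
#'   \code{\link{elbowFromCurve}}).
#' @param ... further arguments to \code{\link{robustSparseKMeans}}.
#' @return an \linkS4class{ElbowCurve}.
#' @examples
#' sim <- simulateLifespanData(nSubjects = 24, nStages = 3,
#'                             nNoiseFeatures = 5, seed = 1)
#' elbowK(sim$data, kRange = 2:7, nIter = 2, seed = 1, nStarts = 2)
#' @export
elbowK <- function(data, kRange = 2:9, nIter = 100L, alpha = 0.1,
                   l1Bound = NULL, seed = NULL, nStarts = 8L,
                   nInnerStarts = 6L, refineScale = FALSE,
                   sgWindow = 0L, sgOrder = 2L, ...) {
    kRange <- sort(as.integer(kRange))
    if (length(kRange) < 4L)
        stop("'kRange' must span at least 4 values")
    if (sgWindow > 0L && length(kRange) < sgWindow)
        stop("'kRange' is shorter than the Savitzky-Golay window (",
             sgWindow, ")")
    if (nIter < 1L)
        stop("'nIter' must be at least 1")
    X <- .asMatrix(data)
    n <- nrow(X)
    res <- .withSeed(seed, {
        vapply(kRange, function(k) {
            runs <- vapply(seq_len(nIter), function(i) {
                fit <- robustSparseKMeans(X, k = k, l1Bound = l1Bound,
                                          alpha = alpha, nStarts = nStarts,
                                          nInnerStarts = nInnerStarts,
                                          refineScale = refineScale,
                                          seed = NULL, ...)
                c(fit@wwss,
                  fit@wwss / (sum(fit@weights) * (n - 1)))
            }, numeric(2))
            rowMeans(runs)
        }, numeric(2))
    })
    meanWWSS <- res[1, ]
    meanFrac <- res[2, ]
    det <- elbowFromCurve(meanFrac, kRange, sgWindow = sgWindow,
                          sgOrder = sgOrder)
    new("ElbowCurve", kValues = kRange, meanWWSS = meanWWSS,
        meanFraction = meanFrac, smoothed = det$smoothed,
        curvature = det$curvature, chosenK = as.integer(det$chosenK))
}

#' Choose the L1 weight bound by a permutation gap statistic
#'
#' For each candidate bound \eqn{s}, computes \eqn{\mathrm{gap}(s) =
#' \log O(s; X) - \overline{\log O(s; X^*)}} where \eqn{O} is the weighted
#' between-cluster objective attained by the sparse fit and \eqn{X^*} are
#' datasets with each feature column independently permuted. The smallest
#' candidate whose gap is within one standard error of the maximum gap is
#' returned (exact ties also resolve to the smallest bound).
#'
#' @param data a \linkS4class{LifespanExperiment} or samples-by-features
#'   matrix.
#' @param k number of clusters.
#' @param candidateBounds numeric candidates in \code{(1, sqrt(p)]}.
#' @param nPerm permuted datasets per candidate (default 5).
#' @param alpha trim fraction (default 0.1).
#' @param seed optional integer seed.
#' @param nStarts restarts per fit (default 5).
#' @param ... further arguments to \code{\link{robustSparseKMeans}}.
#' @return the selected bound (scalar).
#' @examples
#' sim <- simulateLifespanData(nSubjects = 20, nStages = 2,
#'                             nNoiseFeatures = 5, seed = 3)
#' selectL1Bound(sim$data, k = 2, candidateBounds = c(1.5, 2.5),
#'               nPerm = 2, seed = 1, nStarts = 2)
#' @export
selectL1Bound <- function(data, k, candidateBounds, nPerm = 5L, alpha = 0.1,
                          seed = NULL, nStarts = 5L, ...) {
    if (!length(candidateBounds))
        stop("'candidateBounds' must be non-empty")
    candidateBounds <- sort(candidateBounds)
    X <- .asMatrix(data)
    p <- ncol(X)
    if (any(candidateBounds <= 1 | candidateBounds > sqrt(p) + 1e-8))
        stop("candidate bounds must lie in (1, sqrt(p)]")
    if (length(candidateBounds) == 1L)
        return(candidateBounds)
    if (nPerm < 2L)
        stop("'nPerm' must be at least 2")
    .withSeed(seed, {
        perms <- lapply(seq_len(nPerm), function(b)
            apply(X, 2, sample))
        obj <- function(M, s)
            robustSparseKMeans(M, k = k, l1Bound = s, alpha = alpha,
                               nStarts = nStarts, seed = NULL, ...)@objective
        gaps <- vapply(candidateBounds, function(s) {
            o <- log(obj(X, s))
            po <- vapply(perms, function(M) log(obj(M, s)), numeric(1))
            c(gap = o - mean(po), se = sd(po) * sqrt(1 + 1 / nPerm))
        }, numeric(2))
        gap <- gaps["gap", ]
        se <- gaps["se", ]
        top <- which.max(gap)
        eligible <- which(gap >= gap[top] - se[top])
        candidateBounds[min(eligible)]
    })
}
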