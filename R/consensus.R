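# Multi-restart consensus: label alignment by cluster median age,
# co-assignment counts, Jaccard overlap of consensus memberships, averaged
# weights, and the age-randomization null for age progression.

# relabel clusters so median ages are ascending (cluster 1 = youngest);
# ties broken by original cluster index
.alignByAge <- function(assignments, ages) {
    k <- max(assignments)
    med <- vapply(seq_len(k), function(c)
        median(ages[assignments == c]), numeric(1))
    ord <- order(med, seq_len(k))
    newLab <- integer(k)
    newLab[ord] <- seq_len(k)
    newLab[assignments]
}

#' Relabel clusters by ascending median sample age
#'
#' Returns the same partition with labels permuted so that cluster 1 ("A")
#' has the youngest median age, matching the age-ordered presentation used
#' throughout the workflow. Ties in median age break by original label.
#'
#' @param assignments integer cluster labels in \code{1..k}.
#' @param sampleAges numeric ages, one per sample.
#' @return integer labels in \code{1..k}, age-ordered.
#' @examples
#' alignClustersByAge(c(1, 1, 2, 2), c(50, 60, 1, 2))  # cluster 2 is younger
#' @export
alignClustersByAge <- function(assignments, sampleAges) {
    .alignByAge(as.integer(assignments), sampleAges)
}

#' Consensus of repeated robust sparse k-means runs
#'
#' Runs the clustering \code{nIter} times with fresh random starts. Within
#' each run clusters are relabelled by ascending median sample age (so label
#' 1, "A", is always the youngest cluster), then per-sample co-assignment
#' counts, the per-feature average weight and the Jaccard overlap between
#' consensus memberships are accumulated.
#'
#' @param data a \linkS4class{LifespanExperiment}.
#' @param k number of clusters.
#' @param l1Bound,alpha,nStarts,... passed to
#'   \code{\link{robustSparseKMeans}}.
#' @param nIter number of runs (default 100).
#' @param seed optional integer seed; per-run seeds are derived from it.
#' @param minCount consensus-membership threshold for the Jaccard matrix;
#'   default scales the rule of 10-in-100 to \code{nIter}.
#' @param replicates \code{"keep"} clusters every replicate run;
#'   \code{"average"} first averages replicate runs of the same subject.
#' @return a \linkS4class{ConsensusFit}.
#' @examples
#' sim <- simulateLifespanData(nSubjects = 18, nStages = 3,
#'                             nNoiseFeatures = 5, seed = 4)
#' runConsensus(sim$data, k = 3, nIter = 5, seed = 1, nStarts = 2)
#' @export
runConsensus <- function(data, k, l1Bound = NULL, alpha = 0.1, nIter = 100L,
                         seed = NULL, nStarts = 5L,
                         minCount = NULL,
                         replicates = c("keep", "average"), ...) {
    replicates <- match.arg(replicates)
    if (nIter < 2L)
        stop("'nIter' must be at least 2")
    if (replicates == "average" && is(data, "LifespanExperiment"))
        data <- averageReplicates(data)
    X <- .asMatrix(data)
    sampleAges <- if (is(data, "LifespanExperiment")) ages(data) else
        stop("'data' must be a LifespanExperiment (ages are required)")
    n <- nrow(X)
    if (is.null(minCount))
        minCount <- max(1L, as.integer(round(10 * nIter / 100)))
    counts <- matrix(0L, n, k)
    sumW <- numeric(ncol(X))
    .withSeed(seed, {
        runSeeds <- sample.int(.Machine$integer.max - 1L, nIter)
        for (i in seq_len(nIter)) {
            fit <- robustSparseKMeans(X, k = k, l1Bound = l1Bound,
                                      alpha = alpha, nStarts = nStarts,
                                      seed = runSeeds[i], ...)
            lab <- .alignByAge(fit@assignments, sampleAges)
            counts[cbind(seq_len(n), lab)] <- counts[cbind(seq_len(n), lab)] + 1L
            sumW <- sumW + fit@weights
        }
    })
    # modal assignment; count ties go to the younger-median cluster (lower
    # label, because labels are age-ordered)
    modal <- max.col(counts, ties.method = "first")
    med <- vapply(seq_len(k), function(c) {
        if (any(modal == c)) median(sampleAges[modal == c]) else NA_real_
    }, numeric(1))
    iqr <- vapply(seq_len(k), function(c) {
        if (any(modal == c)) stats::IQR(sampleAges[modal == c]) else NA_real_
    }, numeric(1))
    clusterAges <- data.frame(cluster = LETTERS[seq_len(k)], median = med,
                              iqr = iqr)
    dimnames(counts) <- list(rownames(X) %||% paste0("S", seq_len(n)),
                             LETTERS[seq_len(k)])
    fitObj <- new("ConsensusFit", nIter = as.integer(nIter),
                  countMatrix = counts, modalAssignment = as.integer(modal),
                  meanWeights = sumW / nIter, clusterAges = clusterAges,
                  jaccard = matrix(numeric(0), 0, 0),
                  minCount = as.integer(minCount), k = as.integer(k))
    fitObj@jaccard <- jaccardMatrix(fitObj, minCount)
    validObject(fitObj)
    fitObj
}

#' Jaccard overlap between consensus cluster memberships
#'
#' A sample belongs to a cluster's consensus membership when it was assigned
#' to it at least \code{minCount} times; the Jaccard similarity of clusters
#' \code{a} and \code{b} is then \eqn{|A \cap B| / |A \cup B|} (0 when the
#' union is empty).
#'
#' @param consensus a \linkS4class{ConsensusFit}.
#' @param minCount membership threshold, in \code{1..nIter}.
#' @return a symmetric k x k matrix with entries in \code{[0, 1]}.
#' @examples
#' sim <- simulateLifespanData(nSubjects = 18, nStages = 3,
#'                             nNoiseFeatures = 5, seed = 4)
#' cons <- runConsensus(sim$data, k = 3, nIter = 5, seed = 1, nStarts = 2)
#' jaccardMatrix(cons, minCount = 1)
#' @export
jaccardMatrix <- function(consensus, minCount = NULL) {
    counts <- consensus@countMatrix
    if (is.null(minCount))
        minCount <- consensus@minCount
    if (minCount < 1L || minCount > consensus@nIter)
        stop("'minCount' must lie in 1..nIter")
    k <- ncol(counts)
    member <- counts >= minCount
    J <- matrix(0, k, k, dimnames = list(colnames(counts), colnames(counts)))
    for (a in seq_len(k)) {
        for (b in seq_len(k)) {
            un <- sum(member[, a] | member[, b])
            J[a, b] <- if (un == 0) 0 else
                sum(member[, a] & member[, b]) / un
        }
    }
    J
}

#' Age-randomization null for cluster-age progression
#'
#' Tests whether the observed progression of cluster ages could arise by
#' chance. The progression statistic is the Spearman correlation between each
#' sample's age and the rank of its cluster when clusters are ordered by
#' median age. Observed values come from \code{nIter} runs with the true
#' ages; the null re-runs the clustering with ages permuted across samples on
#' every iteration. Per-cluster age IQRs are recorded for both.
#'
#' @param data a \linkS4class{LifespanExperiment}.
#' @param k number of clusters.
#' @param l1Bound,alpha,nStarts,... passed to
#'   \code{\link{robustSparseKMeans}}.
#' @param nIter null iterations (default 100).
#' @param seed optional integer seed.
#' @return a list with elements \code{observed} (mean observed progression),
#'   \code{observedRuns}, \code{null} (null progression values),
#'   \code{pValue} (empirical, \eqn{(1 + \#\{null \ge obs\}) / (nIter + 1)}),
#'   \code{observedIQR} and \code{nullIQR} (per-cluster age IQR summaries)
#'   and \code{degenerate} (TRUE when \code{nIter} < 2).
#' @examples
#' sim <- simulateLifespanData(nSubjects = 18, nStages = 3,
#'                             nNoiseFeatures = 5, seed = 5)
#' ageRandomizationNull(sim$data, k = 3, nIter = 3, seed = 1, nStarts = 2)$pValue
#' @export
ageRandomizationNull <- function(data, k, l1Bound = NULL, alpha = 0.1,
                                 nIter = 100L, seed = NULL, nStarts = 5L,
                                 ...) {
    X <- .asMatrix(data)
    sampleAges <- ages(data)
    if (length(unique(sampleAges)) < 2L)
        stop("ages are constant; age progression is undefined")
    n <- nrow(X)
    progression <- function(lab, a) {
        aligned <- .alignByAge(lab, a)
        suppressWarnings(cor(aligned, a, method = "spearman"))
    }
    clusterIQR <- function(lab, a) {
        aligned <- .alignByAge(lab, a)
        vapply(seq_len(max(aligned)), function(c)
            stats::IQR(a[aligned == c]), numeric(1))
    }
    .withSeed(seed, {
        runSeeds <- sample.int(.Machine$integer.max - 1L, 2L * nIter)
        obsRuns <- numeric(nIter)
        obsIQR <- matrix(NA_real_, nIter, k)
        nullRuns <- numeric(nIter)
        nullIQR <- matrix(NA_real_, nIter, k)
        for (i in seq_len(nIter)) {
            fit <- robustSparseKMeans(X, k = k, l1Bound = l1Bound,
                                      alpha = alpha, nStarts = nStarts,
                                      seed = runSeeds[i], ...)
            obsRuns[i] <- progression(fit@assignments, sampleAges)
            obsIQR[i, ] <- clusterIQR(fit@assignments, sampleAges)
            permAges <- sample(sampleAges)
            fitP <- robustSparseKMeans(X, k = k, l1Bound = l1Bound,
                                       alpha = alpha, nStarts = nStarts,
                                       seed = runSeeds[nIter + i], ...)
            nullRuns[i] <- progression(fitP@assignments, permAges)
            nullIQR[i, ] <- clusterIQR(fitP@assignments, permAges)
        }
        observed <- mean(obsRuns)
        pValue <- (1 + sum(nullRuns >= observed)) / (nIter + 1)
        list(observed = observed,
             observedRuns = obsRuns,
             null = nullRuns,
             pValue = pValue,
             observedIQR = colMeans(obsIQR),
             nullIQR = colMeans(nullIQR),
             degenerate = nIter < 2L)
    })
}

#' Average replicate runs of each subject
#'
#' Collapses samples sharing a subject id to their mean expression (ages and
#' annotations are taken from the first replicate).
#'
#' @param data a \linkS4class{LifespanExperiment} with a \code{subject}
#'   column in its colData.
#' @return a \linkS4class{LifespanExperiment} with one sample per subject.
#' @examples
#' x <- matrix(rnorm(16), nrow = 4)
#' le <- LifespanExperiment(x, ages = c(1, 1, 5, 9),
#'                          subject = c("a", "a", "b", "c"))
#' averageReplicates(le)
#' @export
averageReplicates <- function(data) {
    subj <- subjectIds(data)
    X <- exprValues(data)
    a <- ages(data)
    first <- !duplicated(subj)
    M <- rowsum(X, subj, reorder = FALSE) / as.vector(table(
        factor(subj, levels = unique(subj))))
    LifespanExperiment(M, ages = a[first], sampleIds = unique(subj),
                       featureNames = colnames(X))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return a scalar.
#' @examples
#' ariScore(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition, relabelled
#' @export
ariScore <- function(a, b) {
    if (length(a) != length(b))
        stop("partitions must have equal length")
    tab <- table(a, b)
    n <- length(a)
    sumIJ <- sum(choose(tab, 2))
    sumI <- sum(choose(rowSums(tab), 2))
    sumJ <- sum(choose(colSums(tab), 2))
    expIdx <- sumI * sumJ / choose(n, 2)
    maxIdx <- (sumI + sumJ) / 2
    if (maxIdx == expIdx) return(1)
    (sumIJ - expIdx) / (maxIdx - expIdx)
}
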