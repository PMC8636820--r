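#' @import methods
#' @importFrom stats quantile median sd cor var rnorm runif qnorm qt pt
#'   prcomp loess predict kmeans cor.test p.adjust setNames
#' @importFrom utils head read.table write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom Rcpp evalCpp
#' @useDynLib sparseStages, .registration = TRUE
NULL

#' LifespanExperiment: an expression matrix with sample ages
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a numeric
#' expression matrix (features in rows, samples in columns, following the
#' Bioconductor convention) together with the per-sample annotations that the
#' lifespan-clustering workflow needs: age in years (required), and optional
#' subject identifiers for replicate runs, sex and post-mortem interval.
#'
#' Most workflow functions consume the matrix in samples-by-features
#' orientation (the \code{n x p} layout conventional for clustering); use
#' \code{\link{exprValues}} to obtain it.
#'
#' @slot .Data inherited SummarizedExperiment machinery.
#' @name LifespanExperiment-class
#' @aliases LifespanExperiment-class
#' @exportClass LifespanExperiment
setClass("LifespanExperiment", contains = "SummarizedExperiment")

setValidity("LifespanExperiment", function(object) {
    msg <- character()
    if (!"expression" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'expression' is required")
    else {
        m <- SummarizedExperiment::assay(object, "expression")
        if (!is.numeric(m))
            msg <- c(msg, "expression values must be numeric")
        if (anyNA(m))
            msg <- c(msg, "expression values must not contain missing values")
    }
    if (nrow(object) < 2L)
        msg <- c(msg, "at least 2 features are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature names must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"age" %in% colnames(cd))
        msg <- c(msg, "colData must contain an 'age' column (years)")
    else {
        a <- cd$age
        if (!is.numeric(a) || anyNA(a) || any(a < 0))
            msg <- c(msg, "ages must be non-negative numbers with no missing values")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a LifespanExperiment
#'
#' @param values numeric matrix of expression, samples in rows and features in
#'   columns (\code{n x p}). A features-by-samples matrix is also accepted when
#'   \code{byRow = FALSE}.
#' @param ages numeric vector of sample ages in years, length \code{n}.
#' @param sampleIds,featureNames optional character vectors; defaults are taken
#'   from dimnames or generated.
#' @param subject optional character vector mapping each sample (replicate run)
#'   to a subject.
#' @param sex,pmi optional per-sample annotations.
#' @param byRow logical; if \code{TRUE} (default) \code{values} is
#'   samples-by-features.
#' @return a \linkS4class{LifespanExperiment}.
#' @examples
#' x <- matrix(rnorm(20), nrow = 5)
#' le <- LifespanExperiment(x, ages = c(0.5, 2, 9, 30, 70))
#' exprValues(le)[1:2, 1:2]
#' @export
LifespanExperiment <- function(values, ages, sampleIds = NULL,
                               featureNames = NULL, subject = NULL,
                               sex = NULL, pmi = NULL, byRow = TRUE) {
    values <- as.matrix(values)
    if (byRow) values <- t(values)          # store features x samples
    n <- ncol(values)
    p <- nrow(values)
    if (is.null(sampleIds))
        sampleIds <- colnames(values) %||% paste0("S", seq_len(n))
    if (is.null(featureNames))
        featureNames <- rownames(values) %||% paste0("F", seq_len(p))
    dimnames(values) <- list(featureNames, sampleIds)
    if (length(ages) != n)
        stop("'ages' must have one entry per sample (", n, ")")
    cd <- S4Vectors::DataFrame(age = as.numeric(ages), row.names = sampleIds)
    if (!is.null(subject)) cd$subject <- as.character(subject)
    if (!is.null(sex)) cd$sex <- sex
    if (!is.null(pmi)) cd$pmi <- pmi
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expression = values), colData = cd)
    new("LifespanExperiment", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One sparse (optionally robust) k-means fit
#'
#' Holds the cluster assignments, the non-negative feature weight vector
#' \eqn{w} (unit L2 norm, L1 norm bounded by \code{l1Bound}), outlier flags
#' from trimming, the weighted within-cluster sum of squares (WWSS) and the
#' maximized weighted between-cluster objective.
#'
#' @slot assignments integer cluster labels in \code{1..k}, one per sample.
#' @slot weights numeric feature weights, length \code{p}.
#' @slot outlierFlags logical, \code{TRUE} for samples trimmed in the final
#'   iteration (always all \code{FALSE} when \code{alpha = 0}).
#' @slot wwss numeric, weighted within-cluster sum of squares.
#' @slot objective numeric, weighted between-cluster sum of squares attained.
#' @slot objectiveTrace numeric, objective after each weight update of the
#'   winning restart (non-decreasing).
#' @slot l1Bound,alpha,k tuning parameters of the run.
#' @slot nIterRun integer, alternations run in the winning restart.
#' @slot converged logical.
#' @slot standardized logical, whether features were z-scored before fitting.
#' @exportClass SparseKMeansFit
setClass("SparseKMeansFit", representation(
    assignments = "integer",
    weights = "numeric",
    outlierFlags = "logical",
    wwss = "numeric",
    objective = "numeric",
    objectiveTrace = "numeric",
    l1Bound = "numeric",
    alpha = "numeric",
    k = "integer",
    nIterRun = "integer",
    converged = "logical",
    standardized = "logical"))

setValidity("SparseKMeansFit", function(object) {
    msg <- character()
    w <- object@weights
    if (any(w < -1e-12))
        msg <- c(msg, "weights must be non-negative")
    if (abs(sqrt(sum(w^2)) - 1) > 1e-8)
        msg <- c(msg, "weights must have unit L2 norm")
    if (sum(abs(w)) > object@l1Bound + 1e-8)
        msg <- c(msg, "weights violate the L1 bound")
    k <- object@k
    a <- object@assignments
    if (length(a) && (any(a < 1L) || any(a > k)))
        msg <- c(msg, "assignments must lie in 1..k")
    if (length(a) && length(unique(a)) < k)
        msg <- c(msg, "no cluster may be empty")
    if (length(object@outlierFlags) != length(a))
        msg <- c(msg, "outlierFlags must match assignments in length")
    if (object@wwss < -1e-8)
        msg <- c(msg, "wwss must be non-negative")
    if (length(msg)) msg else TRUE
})

#' WWSS elbow curve over a range of k
#'
#' @slot kValues strictly increasing integers.
#' @slot meanWWSS mean weighted within-cluster sum of squares per k.
#' @slot meanFraction mean weighted unexplained-variance fraction (WWSS over
#'   weighted total SS) per k; the curve the elbow is detected on.
#' @slot smoothed the log-scale (optionally Savitzky-Golay smoothed) curve
#'   used for curvature.
#' @slot curvature absolute second difference of \code{smoothed} (NA at the
#'   endpoints).
#' @slot chosenK the k at maximum curvature.
#' @exportClass ElbowCurve
setClass("ElbowCurve", representation(
    kValues = "integer",
    meanWWSS = "numeric",
    meanFraction = "numeric",
    smoothed = "numeric",
    curvature = "numeric",
    chosenK = "integer"))

setValidity("ElbowCurve", function(object) {
    msg <- character()
    if (any(diff(object@kValues) <= 0))
        msg <- c(msg, "kValues must be strictly increasing")
    if (!all(is.finite(object@meanWWSS)))
        msg <- c(msg, "meanWWSS must be finite")
    if (!(object@chosenK %in% object@kValues))
        msg <- c(msg, "chosenK must be one of kValues")
    if (length(msg)) msg else TRUE
})

#' Consensus over repeated clustering runs
#'
#' Cluster labels are aligned across runs by ascending median sample age, so
#' cluster 1 ("A") is always the youngest.
#'
#' @slot nIter number of runs.
#' @slot countMatrix samples x k integer co-assignment counts; each row sums
#'   to \code{nIter}.
#' @slot modalAssignment per-sample most frequent cluster (ties go to the
#'   younger cluster).
#' @slot meanWeights per-feature weights averaged over runs.
#' @slot clusterAges data.frame of per-cluster age median and IQR (from the
#'   modal assignment).
#' @slot jaccard k x k Jaccard similarity of consensus memberships.
#' @slot minCount membership threshold used for \code{jaccard}.
#' @slot k number of clusters.
#' @exportClass ConsensusFit
setClass("ConsensusFit", representation(
    nIter = "integer",
    countMatrix = "matrix",
    modalAssignment = "integer",
    meanWeights = "numeric",
    clusterAges = "data.frame",
    jaccard = "matrix",
    minCount = "integer",
    k = "integer"))

setValidity("ConsensusFit", function(object) {
    msg <- character()
    if (!all(rowSums(object@countMatrix) == object@nIter))
        msg <- c(msg, "each count row must sum to nIter")
    J <- object@jaccard
    if (nrow(J) && (max(abs(J - t(J))) > 1e-12 || any(J < 0) || any(J > 1)))
        msg <- c(msg, "jaccard must be symmetric with entries in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Over/under-representation calls per (feature, cluster)
#'
#' @slot calls character matrix, features x clusters, entries in
#'   \code{c("over", "under", "neutral")}.
#' @slot upperCut,lowerCut per-feature null distribution cutoffs.
#' @slot nSim simulation size (0 in analytic mode).
#' @slot analytic logical, whether exact normal quantiles were used.
#' @slot nullQuantiles the two null quantiles (default 0.05, 0.95).
#' @slot clusterQuantiles the two cluster quantiles compared against them
#'   (default 0.25, 0.75).
#' @exportClass ORATable
setClass("ORATable", representation(
    calls = "matrix",
    upperCut = "numeric",
    lowerCut = "numeric",
    nSim = "integer",
    analytic = "logical",
    nullQuantiles = "numeric",
    clusterQuantiles = "numeric"))

setValidity("ORATable", function(object) {
    msg <- character()
    ok <- object@calls %in% c("over", "under", "neutral")
    if (!all(ok))
        msg <- c(msg, "calls must be 'over', 'under' or 'neutral'")
    bad <- is.finite(object@upperCut) & is.finite(object@lowerCut) &
        object@upperCut <= object@lowerCut
    if (any(bad))
        msg <- c(msg, "upperCut must exceed lowerCut for non-degenerate features")
    if (length(msg)) msg else TRUE
})

#' PCA with per-feature quality of representation (cos2)
#'
#' @slot basisVectors p x d loadings (unit-norm basis vectors).
#' @slot scores n x d sample coordinates.
#' @slot varianceFraction fraction of total variance per dimension.
#' @slot cos2 p x d squared normalized feature coordinates; each feature's
#'   cos2 over all dimensions of the decomposition sums to 1.
#' @slot cos2Sum per-feature cos2 summed over the first \code{nDims}
#'   dimensions.
#' @slot nDims number of reported dimensions.
#' @exportClass PCARepresentation
setClass("PCARepresentation", representation(
    basisVectors = "matrix",
    scores = "matrix",
    varianceFraction = "numeric",
    cos2 = "matrix",
    cos2Sum = "numeric",
    nDims = "integer"))

setValidity("PCARepresentation", function(object) {
    msg <- character()
    vf <- object@varianceFraction
    if (any(diff(vf) > 1e-8))
        msg <- c(msg, "varianceFraction must be non-increasing")
    if (sum(vf) > 1 + 1e-8)
        msg <- c(msg, "varianceFraction must sum to at most 1")
    if (length(msg)) msg else TRUE
})

#' A composite phenotype feature: protein sum or contrast index
#'
#' A \code{sum} feature adds the expression of its members; an \code{index}
#' feature is the bounded contrast \eqn{(A - B) / (A + B)} between the summed
#' expression of two member sets.
#'
#' @slot name feature name.
#' @slot kind \code{"sum"} or \code{"index"}.
#' @slot membersA member feature names (the numerator-favoured side for an
#'   index).
#' @slot membersB second side of an index; empty for a sum.
#' @slot sourceDim PCA dimension the candidate came from (NA if user-defined).
#' @exportClass CandidateFeature
setClass("CandidateFeature", representation(
    name = "character",
    kind = "character",
    membersA = "character",
    membersB = "character",
    sourceDim = "integer"))

setValidity("CandidateFeature", function(object) {
    msg <- character()
    if (!object@kind %in% c("sum", "index"))
        msg <- c(msg, "kind must be 'sum' or 'index'")
    if (object@kind == "sum" && length(object@membersB))
        msg <- c(msg, "a sum feature must have empty membersB")
    if (object@kind == "index" &&
        (!length(object@membersA) || !length(object@membersB)))
        msg <- c(msg, "an index feature needs members on both sides")
    if (!length(object@membersA))
        msg <- c(msg, "membersA must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Create a CandidateFeature
#'
#' @param name feature name.
#' @param kind \code{"sum"} or \code{"index"}.
#' @param membersA,membersB member feature names (see
#'   \linkS4class{CandidateFeature}).
#' @param sourceDim originating PCA dimension (optional).
#' @return a \linkS4class{CandidateFeature}.
#' @examples
#' CandidateFeature("PGSS", "sum",
#'                  c("Synapsin", "Synaptophysin", "PSD95", "Gephyrin"))
#' @export
CandidateFeature <- function(name, kind = c("sum", "index"), membersA,
                             membersB = character(), sourceDim = NA_integer_) {
    kind <- match.arg(kind)
    new("CandidateFeature", name = name, kind = kind,
        membersA = as.character(membersA), membersB = as.character(membersB),
        sourceDim = as.integer(sourceDim))
}

#' Cluster-by-feature phenotype table
#'
#' Median composite-feature values per age-ordered cluster, with the scale
#' each row is drawn on (sums map to [0, global max sum]; indices to [-1, 1])
#' and over/under-representation flags.
#'
#' @slot medians features x clusters matrix of medians, rows ordered by
#'   hierarchical clustering of the feature correlation matrix.
#' @slot scaleKind \code{"sum"} or \code{"index"} per row.
#' @slot sumMax the shared anchor for all sum scales.
#' @slot flags character matrix of ORA calls aligned with \code{medians}.
#' @exportClass PhenotypeTable
setClass("PhenotypeTable", representation(
    medians = "matrix",
    scaleKind = "character",
    sumMax = "numeric",
    flags = "matrix"))

setValidity("PhenotypeTable", function(object) {
    msg <- character()
    if (length(object@scaleKind) != nrow(object@medians))
        msg <- c(msg, "scaleKind must have one entry per feature row")
    idx <- object@scaleKind == "index"
    if (any(idx)) {
        v <- object@medians[idx, , drop = FALSE]
        if (any(v < -1 - 1e-8 | v > 1 + 1e-8, na.rm = TRUE))
            msg <- c(msg, "index medians must lie in [-1, 1]")
    }
    if (length(msg)) msg else TRUE
})
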