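# PCA quality-of-representation (cos2), agreement of clustering weights with
# cos2, candidate composite features from basis vectors, their validation
# against PC scores, and the phenotype table.

#' PCA with per-feature cos2 quality of representation
#'
#' Decomposes the (by default z-scored) expression matrix by PCA and scores
#' each feature's quality of representation on each dimension as
#' \eqn{\cos^2_{jd} = c_{jd}^2 / \sum_{d'} c_{jd'}^2}, where \eqn{c_{jd}} is
#' the feature's coordinate (loading times the dimension's singular
#' standard deviation). Each feature's cos2 over all dimensions sums to 1.
#'
#' @param data a \linkS4class{LifespanExperiment} or samples-by-features
#'   matrix.
#' @param nDims number of reported dimensions (default 3); must not exceed
#'   the rank of the centered matrix.
#' @param standardize z-score features first (default \code{TRUE}).
#' @return a \linkS4class{PCARepresentation}; \code{cos2Sum} holds each
#'   feature's cos2 summed over the first \code{nDims} dimensions.
#' @examples
#' x <- matrix(rnorm(40), nrow = 8)
#' pcaCos2(x, nDims = 2)
#' @export
pcaCos2 <- function(data, nDims = 3L, standardize = TRUE) {
    X <- .asMatrix(data)
    if (standardize)
        X <- .standardizeColumns(X)
    else
        X <- sweep(X, 2, colMeans(X), "-")
    pc <- prcomp(X, center = FALSE, scale. = FALSE)
    keep <- pc$sdev > max(pc$sdev) * 1e-10
    rank <- sum(keep)
    if (nDims > rank)
        stop("'nDims' (", nDims, ") exceeds the rank of the data (", rank,
             ")")
    load <- pc$rotation[, keep, drop = FALSE]
    sdev <- pc$sdev[keep]
    coord <- sweep(load, 2, sdev, "*")
    cos2 <- coord^2 / rowSums(coord^2)
    varFrac <- sdev^2 / sum(pc$sdev^2)
    new("PCARepresentation",
        basisVectors = load[, seq_len(nDims), drop = FALSE],
        scores = pc$x[, seq_len(nDims), drop = FALSE],
        varianceFraction = varFrac[seq_len(nDims)],
        cos2 = cos2,
        cos2Sum = rowSums(cos2[, seq_len(nDims), drop = FALSE]),
        nDims = as.integer(nDims))
}

#' Agreement between clustering weights and PCA cos2
#'
#' Reports the Spearman rank correlation of the two per-feature measures,
#' then a Bland-Altman analysis of their differences after normalizing each
#' vector by its maximum: the mean difference (bias) with its 95% CI, the
#' limits of agreement (mean +/- 1.96 SD) with their 95% CIs, and the
#' features falling outside the limits.
#'
#' @param meanWeights per-feature clustering weights (e.g.
#'   \code{featureWeights} of a \linkS4class{ConsensusFit}).
#' @param cos2Sum per-feature cos2 summed over the leading dimensions (same
#'   feature order).
#' @return a list with \code{rho}, \code{differences}, \code{bias},
#'   \code{biasCI}, \code{loa} (lower/upper limits), \code{loaCI} (2 x 2
#'   matrix), and \code{outside} (feature indices or names beyond the
#'   limits).
#' @examples
#' w <- c(0.9, 0.5, 0.1, 0.4, 0.2, 0.8)
#' weightCos2Agreement(w, w)$rho  # identical measures: rho = 1
#' @export
weightCos2Agreement <- function(meanWeights, cos2Sum) {
    if (length(meanWeights) != length(cos2Sum))
        stop("the two vectors must have the same feature order and length")
    p <- length(meanWeights)
    if (p < 3L)
        stop("at least 3 features are required")
    if (sd(meanWeights) == 0 || sd(cos2Sum) == 0)
        stop("constant vector: rank correlation is undefined")
    rho <- cor(meanWeights, cos2Sum, method = "spearman")
    a <- meanWeights / max(meanWeights)
    b <- cos2Sum / max(cos2Sum)
    d <- a - b
    bias <- mean(d)
    sdd <- sd(d)
    tq <- qt(0.975, p - 1)
    biasCI <- bias + c(-1, 1) * tq * sdd / sqrt(p)
    loa <- bias + c(-1.96, 1.96) * sdd
    seLoa <- sdd * sqrt(1 / p + 1.96^2 / (2 * (p - 1)))
    loaCI <- rbind(lower = loa[1] + c(-1, 1) * tq * seLoa,
                   upper = loa[2] + c(-1, 1) * tq * seLoa)
    nm <- names(meanWeights) %||% seq_len(p)
    outside <- nm[d < loa[1] | d > loa[2]]
    list(rho = rho, differences = setNames(d, nm), bias = bias,
         biasCI = biasCI, loa = setNames(loa, c("lower", "upper")),
         loaCI = loaCI, outside = outside)
}

#' Propose composite features from PCA basis vectors
#'
#' Screens features by their summed cos2 over the reported dimensions
#' (eligibility cutoff, default 0.5), then inspects each basis vector:
#' same-signed features with amplitude at or above the within-dimension
#' quantile are combined into a sum candidate; high-amplitude features of
#' opposite sign are paired (in descending amplitude order) into two-sided
#' contrast index candidates. Domain-motivated pairs can be pinned through
#' \code{pairingRules}, mirroring the semi-supervised use of prior knowledge.
#'
#' @param pca a \linkS4class{PCARepresentation}.
#' @param cos2Cutoff eligibility cutoff on summed cos2 (default 0.5).
#' @param amplitudeQuantile quantile of |amplitude| within each dimension
#'   that a feature must reach (default 0.7).
#' @param pairingRules optional list of \linkS4class{CandidateFeature}
#'   objects to pin (returned first, deduplicated by name).
#' @return a list of \linkS4class{CandidateFeature}; empty (with a warning)
#'   when no feature passes the cos2 cutoff.
#' @examples
#' x <- matrix(rnorm(60), nrow = 10)
#' colnames(x) <- paste0("P", 1:6)
#' proposeCandidateFeatures(pcaCos2(x, 2), cos2Cutoff = 0.1)
#' @export
proposeCandidateFeatures <- function(pca, cos2Cutoff = 0.5,
                                     amplitudeQuantile = 0.7,
                                     pairingRules = list()) {
    if (cos2Cutoff <= 0 || cos2Cutoff >= 1)
        stop("'cos2Cutoff' must lie in (0, 1)")
    eligible <- pca@cos2Sum > cos2Cutoff
    feats <- rownames(pca@basisVectors) %||%
        paste0("F", seq_len(nrow(pca@basisVectors)))
    out <- list()
    for (f in pairingRules)
        out[[f@name]] <- f
    if (!any(eligible)) {
        if (!length(out))
            warning("no feature passes the cos2 cutoff; returning no candidates")
        return(out)
    }
    for (d in seq_len(pca@nDims)) {
        amp <- pca@basisVectors[eligible, d]
        nmE <- feats[eligible]
        cut <- quantile(abs(amp), amplitudeQuantile, names = FALSE)
        high <- abs(amp) >= cut
        pos <- nmE[high & amp > 0]
        neg <- nmE[high & amp < 0]
        posOrd <- pos[order(-amp[match(pos, nmE)])]
        negOrd <- neg[order(amp[match(neg, nmE)])]
        if (length(pos) >= 2L) {
            nm <- paste0("sum_dim", d, "_pos")
            out[[nm]] <- out[[nm]] %||%
                CandidateFeature(nm, "sum", posOrd, sourceDim = d)
        }
        if (length(neg) >= 2L) {
            nm <- paste0("sum_dim", d, "_neg")
            out[[nm]] <- out[[nm]] %||%
                CandidateFeature(nm, "sum", negOrd, sourceDim = d)
        }
        nPair <- min(length(posOrd), length(negOrd))
        for (i in seq_len(nPair)) {
            nm <- paste0(posOrd[i], ":", negOrd[i])
            out[[nm]] <- out[[nm]] %||%
                CandidateFeature(nm, "index", posOrd[i], negOrd[i],
                                 sourceDim = d)
        }
    }
    unname(out)
}

#' Evaluate a composite feature on every sample
#'
#' A \code{sum} feature is the per-sample sum of its members' expression. An
#' \code{index} feature is \eqn{(A - B) / (A + B)} with \eqn{A} and \eqn{B}
#' the summed expression of the two sides; it lies in \code{[-1, 1]} for
#' non-negative expression and is \code{NA} where \eqn{A + B = 0}.
#'
#' @param data a \linkS4class{LifespanExperiment} or samples-by-features
#'   matrix with named columns.
#' @param feature a \linkS4class{CandidateFeature}.
#' @return numeric vector, one value per sample.
#' @examples
#' x <- cbind(a = c(1, 2), b = c(1, 0))
#' computeFeatureValues(x, CandidateFeature("a:b", "index", "a", "b"))
#' @export
computeFeatureValues <- function(data, feature) {
    X <- .asMatrix(data)
    missing <- setdiff(c(feature@membersA, feature@membersB), colnames(X))
    if (length(missing))
        stop("member feature(s) not in data: ",
             paste(missing, collapse = ", "))
    A <- rowSums(X[, feature@membersA, drop = FALSE])
    if (feature@kind == "sum")
        return(A)
    B <- rowSums(X[, feature@membersB, drop = FALSE])
    tot <- A + B
    out <- ifelse(tot == 0, NA_real_, (A - B) / tot)
    as.numeric(out)
}

#' Validate composite features against PC scores
#'
#' Pearson-correlates each feature's per-sample values with each of the first
#' three PC score vectors and applies a Bonferroni correction over all
#' (feature, dimension) tests at family level \code{alpha}. A feature is
#' retained when it is significant on at least one dimension.
#'
#' @param data data the features are evaluated on (see
#'   \code{\link{computeFeatureValues}}).
#' @param features list of \linkS4class{CandidateFeature}.
#' @param pca a \linkS4class{PCARepresentation} with at least 3 dimensions.
#' @param alpha family-wise error level (default 0.05).
#' @return a list with \code{retained} (the validated features),
#'   \code{correlations} and \code{pAdjusted} (features x 3 matrices).
#' @examples
#' x <- matrix(rnorm(80), nrow = 16)
#' colnames(x) <- paste0("P", 1:5)
#' pca <- pcaCos2(x, 3)
#' f <- CandidateFeature("s", "sum", c("P1", "P2"))
#' validateFeatures(x, list(f), pca)$pAdjusted
#' @export
validateFeatures <- function(data, features, pca, alpha = 0.05) {
    if (!length(features))
        stop("'features' must be non-empty")
    X <- .asMatrix(data)
    if (nrow(X) < 4L)
        stop("at least 4 samples are required for correlation tests")
    if (pca@nDims < 3L)
        stop("'pca' must carry at least 3 dimensions")
    nf <- length(features)
    nms <- vapply(features, function(f) f@name, character(1))
    r <- matrix(NA_real_, nf, 3L, dimnames = list(nms, paste0("PC", 1:3)))
    pv <- r
    for (i in seq_len(nf)) {
        v <- computeFeatureValues(X, features[[i]])
        for (d in 1:3) {
            ok <- is.finite(v)
            ct <- cor.test(v[ok], pca@scores[ok, d])
            r[i, d] <- unname(ct$estimate)
            pv[i, d] <- ct$p.value
        }
    }
    padj <- matrix(pmin(1, pv * (nf * 3L)), nf, 3L, dimnames = dimnames(pv))
    keep <- apply(padj <= alpha, 1, any)
    list(retained = features[keep], correlations = r, pAdjusted = padj)
}

#' Phenotype table of median composite-feature values per cluster
#'
#' Evaluates every feature on every sample, takes medians within each
#' (age-ordered) cluster and attaches over/under-representation flags from
#' \code{\link{oraClassify}} run on the feature values. Rows are ordered by
#' average-linkage hierarchical clustering of the feature-feature Pearson
#' correlation (distance \code{1 - r}). Sum rows share the scale
#' \code{[0, max median over all sum features]}; index rows live on
#' \code{[-1, 1]}.
#'
#' @param data a \linkS4class{LifespanExperiment} or samples-by-features
#'   matrix.
#' @param assignments cluster labels in \code{1..k} (1 = youngest cluster).
#' @param features list of validated \linkS4class{CandidateFeature}.
#' @param ora optional precomputed \linkS4class{ORATable} on the feature
#'   values; computed analytically when \code{NULL}.
#' @return a \linkS4class{PhenotypeTable}.
#' @examples
#' x <- matrix(abs(rnorm(60)), nrow = 10)
#' colnames(x) <- paste0("P", 1:6)
#' f <- list(CandidateFeature("s", "sum", c("P1", "P2")),
#'           CandidateFeature("i", "index", "P3", "P4"))
#' phenotypeTable(x, rep(1:2, each = 5), f)
#' @export
phenotypeTable <- function(data, assignments, features, ora = NULL) {
    X <- .asMatrix(data)
    assignments <- as.integer(assignments)
    k <- max(assignments)
    if (any(tabulate(assignments, k) == 0L))
        stop("empty cluster in 'assignments'")
    if (!length(features))
        stop("'features' must be non-empty")
    nms <- vapply(features, function(f) f@name, character(1))
    vals <- vapply(features, function(f) computeFeatureValues(X, f),
                   numeric(nrow(X)))
    colnames(vals) <- nms
    med <- matrix(NA_real_, length(features), k,
                  dimnames = list(nms, LETTERS[seq_len(k)]))
    for (c in seq_len(k))
        med[, c] <- apply(vals[assignments == c, , drop = FALSE], 2, median,
                          na.rm = TRUE)
    kind <- vapply(features, function(f) f@kind, character(1))
    # row order from the feature correlation structure
    ordNames <- nms
    if (length(features) > 2L) {
        cc <- suppressWarnings(cor(vals, use = "pairwise.complete.obs"))
        cc[!is.finite(cc)] <- 0
        hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
        ordNames <- nms[hc$order]
    }
    if (is.null(ora))
        ora <- oraClassify(vals, assignments, analytic = TRUE)
    flags <- ora@calls[nms, , drop = FALSE]
    med <- med[ordNames, , drop = FALSE]
    flags <- flags[ordNames, , drop = FALSE]
    kind <- kind[match(ordNames, nms)]
    sumMax <- if (any(kind == "sum"))
        max(med[kind == "sum", , drop = FALSE], na.rm = TRUE) else NA_real_
    new("PhenotypeTable", medians = med, scaleKind = kind,
        sumMax = sumMax, flags = flags)
}
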