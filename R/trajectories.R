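# LOESS lifespan trajectories and the age-binned cross-omics pair
# correlation procedure, plus probe-to-gene summarization for exon-array
# tables.

#' The six lifespan age bins
#'
#' Default bin edges partition the positive age axis into <1, 1-5, 5-12,
#' 12-20, 20-55 and >55 years. Bins are right-open at the printed
#' boundaries (\code{[1, 5)} etc.).
#'
#' @param edges interior bin edges in years (strictly increasing).
#' @return an object of class \code{ageBins}: the full break vector with bin
#'   labels.
#' @examples
#' binAges(c(0.5, 3, 10, 15, 40, 70))
#' @export
ageBins <- function(edges = c(1, 5, 12, 20, 55)) {
    if (any(diff(edges) <= 0) || any(edges <= 0))
        stop("'edges' must be positive and strictly increasing")
    breaks <- c(0, edges, Inf)
    labels <- c(paste0("<", edges[1]),
                paste0(edges[-length(edges)], "-", edges[-1]),
                paste0(">", edges[length(edges)]))
    structure(list(breaks = breaks, labels = labels), class = "ageBins")
}

#' Assign ages to bins
#'
#' @param ages numeric ages in years.
#' @param bins an \code{\link{ageBins}} object (default: the six lifespan
#'   bins).
#' @return a factor with one level per bin.
#' @rdname ageBins
#' @export
binAges <- function(ages, bins = ageBins()) {
    cut(ages, breaks = bins$breaks, labels = bins$labels, right = FALSE,
        include.lowest = TRUE)
}

#' LOESS lifespan trajectory with a 95% confidence band
#'
#' Fits a locally weighted regression of expression on age and evaluates the
#' fitted curve and a pointwise 95% band (fit +/- t * SE) on an age grid.
#'
#' @param values numeric expression values, one per sample.
#' @param ages sample ages in years (strictly positive).
#' @param span LOESS span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param gridLength number of grid points (default 100), spaced uniformly
#'   on the observed age range.
#' @return a data.frame with columns \code{age}, \code{fit}, \code{lower},
#'   \code{upper}.
#' @examples
#' a <- seq(0.1, 70, length.out = 30)
#' head(loessTrajectory(2 * a + 1, a))
#' @export
loessTrajectory <- function(values, ages, span = 0.75, degree = 2,
                            gridLength = 100L) {
    if (length(values) != length(ages))
        stop("'values' and 'ages' must have equal length")
    if (length(values) < 10L)
        stop("at least 10 samples are required for a LOESS trajectory")
    if (any(ages <= 0))
        stop("ages must be strictly positive")
    if (span * length(values) < degree + 1)
        stop("'span' too small for local neighborhoods at this sample size")
    fit <- loess(values ~ ages, span = span, degree = degree,
                 control = stats::loess.control(surface = "direct"))
    grid <- seq(min(ages), max(ages), length.out = gridLength)
    pr <- predict(fit, newdata = data.frame(ages = grid), se = TRUE)
    tq <- qt(0.975, pr$df)
    data.frame(age = grid, fit = as.numeric(pr$fit),
               lower = as.numeric(pr$fit - tq * pr$se.fit),
               upper = as.numeric(pr$fit + tq * pr$se.fit))
}

#' Age-binned correlation of paired features across two datasets
#'
#' Implements the cross-omics pair procedure: expression in each dataset is
#' z-scored per feature, samples are partitioned into the six lifespan age
#' bins, per-bin means are taken, and each pair is Pearson-correlated across
#' the binned means. The summary reports the mean and median pair correlation
#' and a percentile bootstrap 95% CI of the median.
#'
#' @param proteinData,geneData \linkS4class{LifespanExperiment} objects (the
#'   two datasets may have different samples).
#' @param pairs data.frame with columns \code{protein} and \code{gene} naming
#'   the paired features in the two datasets.
#' @param bins an \code{\link{ageBins}} object.
#' @param nBoot bootstrap resamples for the median CI (default 10000).
#' @param seed optional integer seed for the bootstrap.
#' @return a list with \code{perPair} (data.frame of pair correlations),
#'   \code{meanR}, \code{medianR} and \code{medianCI}.
#' @examples
#' sim <- simulateLifespanData(nSubjects = 30, nStages = 3, seed = 1)
#' paired <- generatePairedOmics(sim, targetR = 1, seed = 2,
#'                               sameSubjects = TRUE)
#' prs <- data.frame(protein = colnames(exprValues(sim$data)),
#'                   gene = colnames(exprValues(paired$data)))
#' pairCorrelations(sim$data, paired$data, prs, nBoot = 100)$medianR
#' @export
pairCorrelations <- function(proteinData, geneData, pairs, bins = ageBins(),
                             nBoot = 10000L, seed = NULL) {
    stopifnot(all(c("protein", "gene") %in% colnames(pairs)))
    zP <- .standardizeColumns(exprValues(proteinData))
    zG <- .standardizeColumns(exprValues(geneData))
    missP <- setdiff(pairs$protein, colnames(zP))
    missG <- setdiff(pairs$gene, colnames(zG))
    if (length(missP) || length(missG))
        stop("unresolvable pair member(s): ",
             paste(c(missP, missG), collapse = ", "))
    bP <- binAges(ages(proteinData), bins)
    bG <- binAges(ages(geneData), bins)
    for (lv in levels(bP)) {
        if (!any(bP == lv))
            stop("age bin '", lv, "' is empty in the first dataset")
        if (!any(bG == lv))
            stop("age bin '", lv, "' is empty in the second dataset")
    }
    binMeans <- function(Z, b)
        apply(Z, 2, function(v) tapply(v, b, mean))
    mP <- binMeans(zP, bP)
    mG <- binMeans(zG, bG)
    r <- vapply(seq_len(nrow(pairs)), function(i)
        cor(mP[, pairs$protein[i]], mG[, pairs$gene[i]]), numeric(1))
    perPair <- data.frame(protein = pairs$protein, gene = pairs$gene, r = r)
    medCI <- .withSeed(seed, {
        boot <- vapply(seq_len(nBoot), function(b)
            median(sample(r, replace = TRUE)), numeric(1))
        quantile(boot, c(0.025, 0.975), names = FALSE)
    })
    list(perPair = perPair, meanR = mean(r), medianR = median(r),
         medianCI = medCI)
}

#' Summarize an exon-array probe table to genes
#'
#' Probes mapping to the same gene are averaged when all of their pairwise
#' Pearson correlations reach \code{rThreshold}; single-probe genes pass
#' through. Genes whose probes fail the rule are represented by the
#' highest-variance probe (\code{fallback = "representative"}, the default)
#' or keep all probes tagged by probe id (\code{fallback = "keep"}).
#' Unmapped probes are dropped with a warning.
#'
#' @param exonTable numeric probes-by-samples matrix with probe row names.
#' @param probeGeneMap data.frame with columns \code{probe} and \code{gene}.
#' @param rThreshold correlation needed for averaging, in \code{(0, 1]}
#'   (default 0.9).
#' @param fallback what to do with probe sets failing the rule.
#' @return a genes-by-samples matrix (rows tagged \code{gene.probe} for kept
#'   multi-probe genes under \code{fallback = "keep"}).
#' @examples
#' m <- rbind(p1 = 1:4, p2 = c(1, 2, 3, 4.2), p3 = rnorm(4))
#' map <- data.frame(probe = c("p1", "p2", "p3"),
#'                   gene = c("g1", "g1", "g2"))
#' probeToGene(m, map)
#' @export
probeToGene <- function(exonTable, probeGeneMap, rThreshold = 0.9,
                        fallback = c("representative", "keep")) {
    fallback <- match.arg(fallback)
    if (rThreshold <= 0 || rThreshold > 1)
        stop("'rThreshold' must lie in (0, 1]")
    exonTable <- as.matrix(exonTable)
    probes <- rownames(exonTable)
    if (is.null(probes))
        stop("'exonTable' must have probe row names")
    unmapped <- setdiff(probes, probeGeneMap$probe)
    if (length(unmapped)) {
        warning("dropping ", length(unmapped), " unmapped probe(s): ",
                paste(head(unmapped, 5), collapse = ", "))
        exonTable <- exonTable[setdiff(probes, unmapped), , drop = FALSE]
        probes <- rownames(exonTable)
    }
    geneOf <- probeGeneMap$gene[match(probes, probeGeneMap$probe)]
    rows <- list()
    for (g in unique(geneOf)) {
        idx <- which(geneOf == g)
        if (length(idx) == 1L) {
            rows[[g]] <- exonTable[idx, ]
            next
        }
        cc <- cor(t(exonTable[idx, , drop = FALSE]))
        ok <- all(cc[upper.tri(cc)] >= rThreshold)
        if (ok) {
            rows[[g]] <- colMeans(exonTable[idx, , drop = FALSE])
        } else if (fallback == "representative") {
            vars <- apply(exonTable[idx, , drop = FALSE], 1, var)
            rows[[g]] <- exonTable[idx[which.max(vars)], ]
        } else {
            for (i in idx)
                rows[[paste0(g, ".", probes[i])]] <- exonTable[i, ]
        }
    }
    do.call(rbind, rows)
}
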