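#' @rdname LifespanExperiment-class
#' @param x a \linkS4class{LifespanExperiment}.
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname LifespanExperiment-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname LifespanExperiment-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname LifespanExperiment-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname SparseKMeansFit-class
#' @param object a fit object.
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))

#' @rdname SparseKMeansFit-class
#' @export
setGeneric("featureWeights", function(object) standardGeneric("featureWeights"))

#' @rdname SparseKMeansFit-class
#' @export
setGeneric("outlierFlags", function(object) standardGeneric("outlierFlags"))

#' @rdname ConsensusFit-class
#' @param object a \linkS4class{ConsensusFit}.
#' @export
setGeneric("countMatrix", function(object) standardGeneric("countMatrix"))

#' Ages of the samples
#' @param x a \linkS4class{LifespanExperiment}.
#' @return numeric vector of ages in years.
#' @rdname LifespanExperiment-class
#' @export
setMethod("ages", "LifespanExperiment", function(x)
    SummarizedExperiment::colData(x)$age)

#' @rdname LifespanExperiment-class
#' @export
setMethod("exprValues", "LifespanExperiment", function(x)
    t(SummarizedExperiment::assay(x, "expression")))

#' @rdname LifespanExperiment-class
#' @export
setMethod("sampleIds", "LifespanExperiment", function(x) colnames(x))

#' @rdname LifespanExperiment-class
#' @export
setMethod("subjectIds", "LifespanExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("subject" %in% colnames(cd)) cd$subject else colnames(x)
})

setMethod("show", "LifespanExperiment", function(object) {
    a <- ages(object)
    cat("LifespanExperiment:", ncol(object), "samples x", nrow(object),
        "features\n")
    cat("  ages (years): ", signif(min(a), 3), "-", signif(max(a), 3), "\n",
        sep = "")
    extra <- setdiff(colnames(SummarizedExperiment::colData(object)), "age")
    if (length(extra))
        cat("  sample annotations:", paste(extra, collapse = ", "), "\n")
})

#' @rdname SparseKMeansFit-class
#' @export
setMethod("clusterAssignments", "SparseKMeansFit", function(object)
    object@assignments)

#' @rdname SparseKMeansFit-class
#' @export
setMethod("featureWeights", "SparseKMeansFit", function(object)
    object@weights)

#' @rdname SparseKMeansFit-class
#' @export
setMethod("outlierFlags", "SparseKMeansFit", function(object)
    object@outlierFlags)

setMethod("show", "SparseKMeansFit", function(object) {
    cat("SparseKMeansFit: k =", object@k,
        "| l1 bound =", signif(object@l1Bound, 4),
        "| alpha =", object@alpha, "\n")
    cat("  WWSS =", signif(object@wwss, 6),
        "| objective =", signif(object@objective, 6), "\n")
    cat("  non-zero weights:", sum(object@weights > 1e-10), "/",
        length(object@weights),
        "| outliers flagged:", sum(object@outlierFlags), "\n")
    cat("  converged:", object@converged, "after", object@nIterRun,
        "alternations\n")
})

setMethod("show", "ElbowCurve", function(object) {
    cat("ElbowCurve over k =", paste(range(object@kValues), collapse = ".."),
        "| chosen k =", object@chosenK, "\n")
})

#' @rdname ConsensusFit-class
#' @export
setMethod("countMatrix", "ConsensusFit", function(object) object@countMatrix)

#' @rdname ConsensusFit-class
#' @export
setMethod("clusterAssignments", "ConsensusFit", function(object)
    object@modalAssignment)

#' @rdname ConsensusFit-class
#' @export
setMethod("featureWeights", "ConsensusFit", function(object)
    object@meanWeights)

setMethod("show", "ConsensusFit", function(object) {
    cat("ConsensusFit:", object@nIter, "runs | k =", object@k, "\n")
    cat("  cluster age medians:",
        paste(signif(object@clusterAges$median, 3), collapse = ", "), "\n")
    offdiag <- object@jaccard[upper.tri(object@jaccard)]
    if (length(offdiag))
        cat("  Jaccard overlap range:",
            paste(signif(range(offdiag), 3), collapse = " - "), "\n")
})

setMethod("show", "ORATable", function(object) {
    tab <- table(factor(object@calls, c("over", "under", "neutral")))
    cat("ORATable:", nrow(object@calls), "features x", ncol(object@calls),
        "clusters (", if (object@analytic) "analytic" else
            paste0("n_sim = ", object@nSim), ")\n")
    cat("  over:", tab["over"], "| under:", tab["under"],
        "| neutral:", tab["neutral"], "\n")
})

setMethod("show", "PCARepresentation", function(object) {
    cat("PCARepresentation:", nrow(object@basisVectors), "features,",
        object@nDims, "reported dimensions\n")
    cat("  variance captured:",
        paste0(round(100 * cumsum(object@varianceFraction)[object@nDims], 1),
               "%"), "\n")
})

setMethod("show", "CandidateFeature", function(object) {
    if (object@kind == "sum")
        cat("CandidateFeature (sum):", object@name, "=",
            paste(object@membersA, collapse = " + "), "\n")
    else
        cat("CandidateFeature (index):", object@name, "= (A - B)/(A + B), A =",
            paste(object@membersA, collapse = "+"), ", B =",
            paste(object@membersB, collapse = "+"), "\n")
})

setMethod("show", "PhenotypeTable", function(object) {
    cat("PhenotypeTable:", nrow(object@medians), "features x",
        ncol(object@medians), "clusters |", sum(object@scaleKind == "sum"),
        "sums,", sum(object@scaleKind == "index"), "indices\n")
})
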