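test_that("cos2 is a normalized quality of representation", {
    # rows sum to 1 over all dimensions, for any input
    set.seed(2)
    for (i in 1:5) {
        x <- matrix(rnorm(15 * sample(4:8, 1)), 15)
        pca <- pcaCos2(x, nDims = 2)
        expect_lt(max(abs(rowSums(pca@cos2) - 1)), 1e-8)
    }
    # a feature varying only along the first principal direction
    set.seed(3)
    t1 <- rnorm(30, sd = 4)
    x <- cbind(t1, t1 * 0.9 + rnorm(30, 0, 1e-4), rnorm(30, sd = 0.1))
    pca <- pcaCos2(x, nDims = 2, standardize = FALSE)
    expect_gt(pca@cos2[1, 1], 0.999)
    expect_error(pcaCos2(matrix(rnorm(12), 4, 3), nDims = 4), "rank|nDims")
})

test_that("cos2 matches an independently coded eigendecomposition", {
    x <- matrix(c(2, 4, 1, 7, 5,
                  3, 1, 6, 2, 8,
                  9, 2, 4, 4, 1,
                  1, 5, 5, 3, 2), 5, 4)
    pca <- pcaCos2(x, nDims = 3, standardize = TRUE)
    # oracle: eigendecomposition of the correlation-scaled cross-product
    z <- scale(x)
    z[is.na(z)] <- 0
    ev <- eigen(crossprod(z) / 1)          # unnormalized; ratios matter only
    coord2 <- (ev$vectors %*% diag(sqrt(pmax(ev$values, 0))))^2
    cos2oracle <- coord2 / rowSums(coord2)
    keep <- ev$values > max(ev$values) * 1e-10
    expect_equal(unname(pca@cos2), cos2oracle[, keep, drop = FALSE],
                 tolerance = 1e-8)
    expect_equal(pca@cos2Sum, rowSums(pca@cos2[, 1:3]), ignore_attr = TRUE)
})

test_that("weight/cos2 agreement reports rank correlation and
           Bland-Altman limits", {
    w <- c(0.9, 0.5, 0.1, 0.4, 0.2, 0.8)
    same <- weightCos2Agreement(w, w)
    expect_equal(same$rho, 1)
    expect_equal(same$bias, 0)
    expect_length(same$outside, 0)
    rev <- weightCos2Agreement(w, max(w) + min(w) - w)
    expect_equal(rev$rho, -1)
    # hand-computed oracle on a 6-feature toy
    a <- c(0.2, 0.9, 0.4, 0.7, 0.1, 0.5)
    b <- c(0.3, 0.8, 0.2, 0.9, 0.2, 0.4)
    rep <- weightCos2Agreement(a, b)
    d <- a / max(a) - b / max(b)
    expect_equal(rep$bias, mean(d))
    expect_equal(unname(rep$loa), mean(d) + c(-1.96, 1.96) * sd(d))
    expect_equal(rep$rho, cor(a, b, method = "spearman"))
    expect_error(weightCos2Agreement(a, b[-1]), "length")
    expect_error(weightCos2Agreement(rep(1, 5), b[-1]), "constant")
})

test_that("candidate features follow sign and amplitude on the basis
           vectors", {
    # planted decomposition: four strong positive features on dim 1, an
    # opposite-sign pair on dim 2
    load <- matrix(0, 6, 2,
                   dimnames = list(paste0("P", 1:6), NULL))
    load[1:4, 1] <- c(0.6, 0.55, 0.5, 0.45)
    load[5, 2] <- 0.7
    load[6, 2] <- -0.7
    pca <- new("PCARepresentation", basisVectors = load,
               scores = matrix(0, 10, 2), varianceFraction = c(0.5, 0.3),
               cos2 = matrix(0.5, 6, 2), cos2Sum = rep(0.9, 6), nDims = 2L)
    feats <- proposeCandidateFeatures(pca, cos2Cutoff = 0.5,
                                      amplitudeQuantile = 0.3)
    kinds <- vapply(feats, function(f) f@kind, character(1))
    sums <- feats[kinds == "sum"]
    expect_true(any(vapply(sums, function(f)
        setequal(f@membersA, c("P1", "P2", "P3", "P4")), logical(1))))
    idx <- feats[kinds == "index"]
    expect_true(any(vapply(idx, function(f)
        f@membersA == "P5" && f@membersB == "P6", logical(1))))
    # all features below the cos2 cutoff: empty with a warning
    pcaLow <- pca
    pcaLow@cos2Sum <- rep(0.1, 6)
    expect_warning(none <- proposeCandidateFeatures(pcaLow), "no feature")
    expect_length(none, 0)
    # pinned domain pairs survive regardless
    pin <- CandidateFeature("GFAP:Integrin", "index", "P1", "P2")
    withPin <- suppressWarnings(
        proposeCandidateFeatures(pcaLow, pairingRules = list(pin)))
    expect_equal(withPin[[1]]@name, "GFAP:Integrin")
})

test_that("composite feature values follow the sum and contrast
           formulas", {
    x <- cbind(a = c(1, 2, 3), b = c(1, 0, 3), c = c(2, 2, 2))
    sumF <- CandidateFeature("s", "sum", c("a", "c"))
    expect_equal(computeFeatureValues(x, sumF), x[, "a"] + x[, "c"])
    idxF <- CandidateFeature("i", "index", "a", "b")
    expect_equal(computeFeatureValues(x, idxF),
                 c(0, 1, 0))                 # balance, extreme, balance
    x0 <- cbind(a = c(0, 1), b = c(0, 1))
    expect_true(is.na(computeFeatureValues(x0,
                                           CandidateFeature("i", "index",
                                                            "a", "b"))[1]))
    expect_error(computeFeatureValues(x, CandidateFeature("z", "sum", "q")),
                 "not in data")
    # indices bounded for non-negative expression
    set.seed(10)
    xp <- matrix(abs(rnorm(60)), 20, 3, dimnames = list(NULL, c("a","b","c")))
    v <- computeFeatureValues(xp, CandidateFeature("i", "index", "a",
                                                   c("b", "c")))
    expect_true(all(v >= -1 & v <= 1))
})

test_that("features validate against PC scores with Bonferroni control", {
    set.seed(12)
    x <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("P", 1:6)))
    pca <- pcaCos2(x, nDims = 3)
    # a feature reproducing PC1 must be retained with r near 1
    x2 <- cbind(x, pc1like = pca@scores[, 1] + 10)
    pca2 <- pcaCos2(x2, nDims = 3)
    f <- CandidateFeature("pc1like", "sum", "pc1like")
    val <- validateFeatures(x2, list(f), pca2)
    expect_length(val$retained, 1)
    expect_gt(abs(val$correlations[1, 1]), 0.99)
    expect_error(validateFeatures(x[1:3, ], list(f), pca), "4 samples")
    # type-I control: pure-noise features are rarely retained
    set.seed(13)
    hits <- 0L
    base <- matrix(rnorm(20 * 6), 20, 6,
                   dimnames = list(NULL, paste0("P", 1:6)))
    nzSim <- 200L
    for (i in seq_len(nzSim)) {
        noisy <- cbind(base, nf = rnorm(20))
        pcaN <- pcaCos2(base, nDims = 3)
        v <- validateFeatures(noisy, list(CandidateFeature("nf", "sum",
                                                           "nf")), pcaN)
        hits <- hits + length(v$retained)
    }
    alpha <- 0.05
    bound <- alpha + 2 * sqrt(alpha * (1 - alpha) / nzSim)
    expect_lte(hits / nzSim, bound)
})

test_that("the phenotype table reports per-cluster medians on the right
           scales", {
    x <- cbind(a = c(1, 1, 5, 5), b = c(2, 2, 2, 2),
               c = c(1, 1, 0, 0), d = c(0, 0, 1, 1))
    lab <- c(1, 1, 2, 2)
    feats <- list(CandidateFeature("sumAB", "sum", c("a", "b")),
                  CandidateFeature("cd", "index", "c", "d"))
    pt <- phenotypeTable(x, lab, feats)
    expect_equal(pt@medians["sumAB", ], c(A = 3, B = 7))
    expect_equal(pt@medians["cd", ], c(A = 1, B = -1))  # index endpoints
    expect_equal(pt@sumMax, 7)
    expect_equal(sort(pt@scaleKind), c("index", "sum"))
    expect_error(phenotypeTable(x, c(1, 1, 1, 3), feats), "empty cluster")
    # a constant feature gives identical mid-scale bands with neutral flags
    x2 <- cbind(x, e = rep(4, 4))
    ptc <- suppressWarnings(   # constant feature: zero-SD ORA warning
        phenotypeTable(x2, lab,
                       c(feats, list(CandidateFeature("e", "sum", "e")))))
    expect_equal(unname(diff(ptc@medians["e", ])), 0)
})
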