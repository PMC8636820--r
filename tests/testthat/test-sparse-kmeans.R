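test_that("updateWeights matches a brute-force grid maximizer and handles
           symmetric and degenerate inputs", {
    # symmetry: equal scores, generous bound -> equal weights
    expect_equal(updateWeights(rep(2, 4), 2), rep(0.5, 4))
    # single informative feature
    expect_equal(updateWeights(c(1, 0, 0), 1.2), c(1, 0, 0))
    # grid oracle on 2 features, binding L1 constraint
    w <- updateWeights(c(4, 1), 1.1)
    wg <- gridMaxWeights2(c(4, 1), 1.1)
    expect_lt(max(abs(w - wg)), 1e-3)
    # another instance, slack constraint
    w2 <- updateWeights(c(3, 2), 1.41)
    wg2 <- gridMaxWeights2(c(3, 2), 1.41)
    expect_lt(max(abs(w2 - wg2)), 1e-3)
    expect_error(updateWeights(c(0, 0), 1.2), "zero")
    expect_error(updateWeights(c(1, 2), 0.9), "l1Bound")
})

test_that("updateWeights always satisfies both norm constraints", {
    set.seed(11)
    for (i in 1:50) {
        p <- sample(3:40, 1)
        bcss <- rexp(p)
        s <- runif(1, 1.05, sqrt(p))
        w <- updateWeights(bcss, s)
        expect_true(all(w >= 0))
        expect_lt(abs(sqrt(sum(w^2)) - 1), 1e-8)
        expect_lte(sum(w), s + 1e-8)
    }
})

test_that("sparse k-means isolates the informative feature on a
           two-cluster toy", {
    toy <- twoClusterToy()
    fit <- sparseKMeans(toy$x, k = 2, l1Bound = 1.5, seed = 1,
                        standardize = FALSE)
    expect_gt(featureWeights(fit)[1], 0.9)
    expect_equal(ariScore(clusterAssignments(fit), toy$truth), 1)
    # the returned weights are the exact optimum for the returned partition
    bcss <- vapply(seq_len(ncol(toy$x)), function(j) {
        mu <- mean(toy$x[, j])
        sum(vapply(1:2, function(c) {
            v <- toy$x[clusterAssignments(fit) == c, j]
            length(v) * (mean(v) - mu)^2
        }, numeric(1)))
    }, numeric(1))
    expect_equal(featureWeights(fit), updateWeights(bcss, 1.5),
                 tolerance = 1e-6)
})

test_that("an inactive L1 penalty reproduces standard k-means", {
    toy <- twoClusterToy(n = 16, pNoise = 3)
    p <- ncol(toy$x)
    fit <- sparseKMeans(toy$x, k = 2, l1Bound = sqrt(p), seed = 3,
                        standardize = FALSE)
    expect_equal(featureWeights(fit), rep(1 / sqrt(p), p), tolerance = 1e-8)
    km <- kmeans(toy$x, 2, nstart = 20)
    expect_equal(ariScore(clusterAssignments(fit), km$cluster), 1)
})

test_that("k = n gives singleton clusters and zero WWSS", {
    set.seed(5)
    x <- matrix(rnorm(8 * 3), 8, 3)
    fit <- sparseKMeans(x, k = 8, l1Bound = 1.5, seed = 1,
                        standardize = FALSE)
    expect_equal(sort(clusterAssignments(fit)), 1:8)
    expect_equal(fit@wwss, 0, tolerance = 1e-10)
})

test_that("the weighted between-cluster objective ascends within a
           restart", {
    for (s in 1:5) {
        sim <- simulateLifespanData(nSubjects = 20, nStages = 4, seed = s)
        fit <- sparseKMeans(sim$data, k = 4, seed = s, nStarts = 1)
        expect_true(all(diff(fit@objectiveTrace) > -1e-8))
    }
})

test_that("sparsity decreases monotonically with a tighter L1 bound", {
    set.seed(21)
    bcss <- rexp(30)
    bounds <- c(1.2, 1.8, 2.5, 3.5, 4.5, sqrt(30))
    zeros <- vapply(bounds, function(s) sum(updateWeights(bcss, s) == 0),
                    numeric(1))
    expect_true(all(diff(zeros) <= 0))
    # at the fit level, on a stable well-separated toy
    toy <- twoClusterToy()
    nz <- vapply(c(1.2, 1.8, 2.5), function(s)
        sum(featureWeights(sparseKMeans(toy$x, 2, l1Bound = s, seed = 2,
                                        standardize = FALSE)) == 0),
        numeric(1))
    expect_true(all(diff(nz) <= 0))
})

test_that("sparse k-means attains the exhaustive-partition optimum on a
           small instance", {
    set.seed(31)
    x <- rbind(matrix(rnorm(4 * 3, 0, 0.5), 4),
               matrix(rnorm(4 * 3, 3, 0.5), 4))
    l1 <- 1.4
    parts <- allTwoPartitions(8)
    objs <- vapply(parts, function(lab) partitionObjective(x, lab, l1),
                   numeric(1))
    fit <- sparseKMeans(x, k = 2, l1Bound = l1, nStarts = 30, seed = 7,
                        standardize = FALSE)
    found <- partitionObjective(x, clusterAssignments(fit), l1)
    expect_equal(found, max(objs), tolerance = 1e-8)
})

test_that("wwss matches direct summation and validates its inputs", {
    x <- matrix(c(1, 2, 3, 10, 11, 12,
                  5, 5, 6, 6, 7, 7), 6, 2)
    lab <- rep(1:2, each = 3)
    w <- c(0.8, 0.6)
    direct <- 0
    for (j in 1:2) for (c in 1:2) {
        v <- x[lab == c, j]
        direct <- direct + w[j] * sum((v - mean(v))^2)
    }
    expect_equal(wwss(x, lab, w), direct)
    # one cluster, uniform weights: weighted total dispersion
    expect_equal(wwss(x, rep(1, 6), c(1, 1)),
                 sum(sweep(x, 2, colMeans(x))^2))
    expect_error(wwss(x, c(0, 1, 1, 2, 2, 2), w), "1..k")
    expect_error(wwss(x, lab, c(0.5)), "feature")
})

test_that("weightTransform scales columns and validates lengths", {
    x <- matrix(rnorm(12), 4, 3)
    expect_equal(weightTransform(x, rep(1, 3)), x)
    expect_equal(weightTransform(x, c(1, 0, 2))[, 2], rep(0, 4))
    w <- runif(3)
    expect_equal(weightTransform(x, w), sweep(x, 2, w, "*"))
    expect_error(weightTransform(x, c(1, 2)), "feature")
})

test_that("degenerate and invalid inputs are rejected", {
    const <- matrix(1, 10, 4)
    expect_error(sparseKMeans(const, k = 2, seed = 1), "dispersion")
    x <- matrix(rnorm(20), 10, 2)
    expect_error(sparseKMeans(x, k = 11, seed = 1), "k")
    expect_error(sparseKMeans(x, k = 2, l1Bound = 5, seed = 1), "l1Bound")
})
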