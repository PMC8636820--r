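test_that("perfectly separated clusters give a one-hot count matrix", {
    sim <- simulateLifespanData(nSubjects = 18, nStages = 3,
                                nNoiseFeatures = 5, stageSeparation = 8,
                                noiseSd = 0.1, seed = 5)
    cons <- runConsensus(sim$data, k = 3, nIter = 6, seed = 1, nStarts = 5)
    counts <- countMatrix(cons)
    expect_true(all(rowSums(counts) == 6L))
    expect_true(all(apply(counts, 1, max) == 6L))
    expect_equal(ariScore(clusterAssignments(cons), sim$truth$stages), 1)
})

test_that("co-assignment counts are conserved for every sample", {
    sim <- simulateLifespanData(nSubjects = 16, nStages = 3,
                                nNoiseFeatures = 10, seed = 9)
    cons <- runConsensus(sim$data, k = 4, nIter = 7, seed = 2, nStarts = 3)
    expect_true(all(rowSums(countMatrix(cons)) == 7L))
    expect_error(runConsensus(sim$data, k = 3, nIter = 1), "at least 2")
})

test_that("clusters are relabelled so median ages ascend", {
    set.seed(33)
    for (i in 1:20) {
        n <- sample(10:40, 1)
        k <- sample(2:5, 1)
        lab <- sample(seq_len(k), n, replace = TRUE)
        lab[seq_len(k)] <- seq_len(k)   # every cluster non-empty
        agesV <- runif(n, 0, 80)
        aligned <- alignClustersByAge(lab, agesV)
        med <- vapply(seq_len(k), function(c)
            median(agesV[aligned == c]), numeric(1))
        expect_true(all(diff(med) >= 0))
        expect_equal(ariScore(aligned, lab), 1)  # same partition
    }
})

test_that("Jaccard similarity matches hand-computed set overlaps", {
    # memberships at threshold 10: A = {1,2,3,4}, B = {3,4,5}
    counts <- rbind(c(15L, 5L), c(15L, 5L), c(10L, 10L), c(10L, 10L),
                    c(5L, 15L))
    cons <- new("ConsensusFit", nIter = 20L, countMatrix = counts,
                modalAssignment = as.integer(max.col(counts)),
                meanWeights = numeric(0), clusterAges = data.frame(),
                jaccard = matrix(0, 0, 0), minCount = 10L, k = 2L)
    J <- jaccardMatrix(cons, minCount = 10)
    expect_equal(J[1, 2], 0.4)   # |{3,4}| / |{1,2,3,4,5}|
    expect_equal(J[1, 1], 1)
    expect_equal(J[2, 1], J[1, 2])
    # identical and disjoint memberships
    c2 <- matrix(c(10L, 10L, 0L, 0L, 0L, 0L, 10L, 10L), 4, 2)
    cons2 <- new("ConsensusFit", nIter = 10L, countMatrix = c2,
                 modalAssignment = c(1L, 1L, 2L, 2L),
                 meanWeights = numeric(0), clusterAges = data.frame(),
                 jaccard = matrix(0, 0, 0), minCount = 10L, k = 2L)
    J2 <- jaccardMatrix(cons2, minCount = 10)
    expect_equal(J2[1, 2], 0)
    expect_equal(diag(J2), c(A = 1, B = 1), ignore_attr = TRUE)
    expect_error(jaccardMatrix(cons2, minCount = 0), "minCount")
})

test_that("boundary samples split their consensus counts while interior
           samples stay stable", {
    # two tight clusters on one feature with two samples planted midway
    set.seed(44)
    n <- 20
    v <- c(rnorm(9, 0, 0.05), rnorm(9, 6, 0.05), 2.9, 3.1)
    x <- cbind(v, matrix(rnorm(n * 3, 0, 0.1), n))
    colnames(x) <- paste0("f", 1:4)
    agesV <- c(rep(2, 9), rep(50, 9), 25, 26)
    le <- LifespanExperiment(x, ages = agesV)
    cons <- runConsensus(le, k = 2, l1Bound = 1.5, alpha = 0, nIter = 20,
                         seed = 3, nStarts = 5, nInnerStarts = 4,
                         standardize = FALSE)
    counts <- countMatrix(cons)
    purity <- apply(counts, 1, max) / 20
    expect_true(all(purity[1:18] == 1))
})

test_that("the age-randomization null separates planted age structure from
           independence", {
    sim <- simulateLifespanData(nSubjects = 20, nStages = 4, seed = 13)
    nl <- ageRandomizationNull(sim$data, k = 4, nIter = 9, seed = 1,
                               nStarts = 4)
    expect_lte(nl$pValue, 1 / 10)
    expect_false(nl$degenerate)
    # independence: same expression, shuffled ages
    le <- sim$data
    set.seed(99)
    SummarizedExperiment::colData(le)$age <- sample(ages(le))
    nl2 <- ageRandomizationNull(le, k = 4, nIter = 9, seed = 2, nStarts = 4)
    expect_gt(nl2$pValue, 1 / 10)
    # degenerate null flagged; constant ages rejected
    nl3 <- ageRandomizationNull(sim$data, k = 4, nIter = 1, seed = 3,
                                nStarts = 2)
    expect_true(nl3$degenerate)
    lec <- LifespanExperiment(exprValues(sim$data), ages = rep(5, 20))
    expect_error(ageRandomizationNull(lec, k = 4), "constant")
})

test_that("replicate runs can be averaged per subject", {
    sim <- simulateLifespanData(nSubjects = 10, nStages = 3,
                                nReplicates = 3, seed = 21)
    expect_equal(nrow(exprValues(sim$data)), 30)
    avg <- averageReplicates(sim$data)
    expect_equal(nrow(exprValues(avg)), 10)
    subj <- subjectIds(sim$data)
    expect_equal(exprValues(avg)[1, ],
                 colMeans(exprValues(sim$data)[subj == subj[1], ]))
    cons <- runConsensus(sim$data, k = 3, nIter = 3, seed = 1, nStarts = 2,
                         replicates = "average")
    expect_equal(nrow(countMatrix(cons)), 10)
})
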