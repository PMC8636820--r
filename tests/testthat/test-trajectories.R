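test_that("LOESS trajectories reproduce polynomials and flag bad inputs", {
    a <- seq(0.1, 70, length.out = 40)
    tr <- loessTrajectory(2 * a + 1, a)
    expect_lt(max(abs(tr$fit - (2 * tr$age + 1))), 1e-6)
    # constant values: flat curve, positive band width
    trc <- loessTrajectory(rep(3, 40) + rnorm(40, 0, 1e-12), a)
    expect_lt(max(abs(trc$fit - 3)), 1e-6)
    expect_true(all(trc$upper >= trc$lower))
    expect_error(loessTrajectory(rnorm(5), 1:5), "10 samples")
    expect_error(loessTrajectory(rnorm(12), c(-1, 2:12)), "positive")
    expect_error(loessTrajectory(rnorm(12), 1:12, span = 0.01), "span")
})

test_that("the fitted peak of a noisy inverted-U lands near the planted
           peak", {
    hits <- 0L
    for (s in 1:20) {
        set.seed(400 + s)
        a <- runif(60, 0.1, 40)
        v <- 2 * exp(-(a - 10)^2 / (2 * 5^2)) + rnorm(60, 0, 0.15)
        tr <- loessTrajectory(v, a, span = 0.5, gridLength = 600)
        peak <- tr$age[which.max(tr$fit)]
        if (abs(peak - 10) <= 1) hits <- hits + 1L   # within 10% of 10 y
    }
    expect_gte(hits, 16L)
})

test_that("the six lifespan age bins partition all positive ages", {
    b <- ageBins()
    f <- binAges(c(0.5, 1, 4.9, 5, 11, 12, 19, 20, 54, 55, 79))
    expect_equal(as.character(f),
                 c("<1", "1-5", "1-5", "5-12", "5-12", "12-20", "12-20",
                   "20-55", "20-55", ">55", ">55"))
    expect_false(anyNA(binAges(runif(100, 0.01, 120))))
    expect_error(ageBins(c(5, 2)), "increasing")
})

test_that("pair correlations are exact for identical trajectories and
           invariant to affine transforms", {
    sim <- simulateLifespanData(nSubjects = 48, seed = 31)
    paired <- generatePairedOmics(sim, targetR = 1, sameSubjects = TRUE,
                                  seed = 1)
    pc <- pairCorrelations(sim$data, sim$data,
                           data.frame(protein = "inc1", gene = "inc1"),
                           nBoot = 100, seed = 1)
    expect_equal(pc$perPair$r, 1)
    # affine transform of one dataset leaves binned z-score correlations
    # unchanged
    shifted <- LifespanExperiment(exprValues(sim$data) * 7 + 100,
                                  ages = ages(sim$data))
    pc2 <- pairCorrelations(shifted, sim$data,
                            data.frame(protein = "inc1", gene = "inc1"),
                            nBoot = 100, seed = 1)
    expect_equal(pc2$perPair$r, 1)
    # the bootstrap CI brackets the sample median
    prs <- data.frame(protein = colnames(exprValues(sim$data)),
                      gene = colnames(exprValues(sim$data)))
    pc3 <- pairCorrelations(sim$data, shifted, prs, nBoot = 500, seed = 2)
    expect_gte(pc3$medianR, pc3$medianCI[1])
    expect_lte(pc3$medianR, pc3$medianCI[2])
})

test_that("empty age bins are reported by name", {
    sim <- simulateLifespanData(nSubjects = 20, nStages = 4, seed = 3)
    young <- LifespanExperiment(exprValues(sim$data),
                                ages = runif(20, 0.1, 0.9))
    expect_error(pairCorrelations(young, sim$data,
                                  data.frame(protein = "inc1",
                                             gene = "inc1"), nBoot = 10),
                 "bin '1-5'")
})

test_that("probe-to-gene summarization follows the correlation rule", {
    set.seed(71)
    samples <- 6
    base <- rnorm(samples)
    tab <- rbind(p1 = base, p2 = base + rnorm(samples, 0, 1e-3),
                 p3 = rnorm(samples), p4 = rnorm(samples),
                 p5 = 5 * rnorm(samples))
    map <- data.frame(probe = c("p1", "p2", "p3", "p4", "p5"),
                      gene = c("g1", "g1", "g2", "g3", "g3"))
    # identical rows averaged: result equals either row
    out <- probeToGene(tab, map)
    expect_equal(out["g1", ], colMeans(tab[c("p1", "p2"), ]),
                 ignore_attr = TRUE)
    # g3 probes are uncorrelated: the higher-variance probe represents it
    expect_equal(out["g3", ], tab["p5", ], ignore_attr = TRUE)
    expect_equal(nrow(out), 3)               # hand count of genes
    # keep mode retains both probes tagged by probe id
    keep <- probeToGene(tab, map, fallback = "keep")
    expect_true(all(c("g3.p4", "g3.p5") %in% rownames(keep)))
    expect_equal(nrow(keep), 4)
    # unmapped probes are dropped with a warning
    expect_warning(dropped <- probeToGene(tab, map[-3, ]), "unmapped")
    expect_false("g2" %in% rownames(dropped))
})
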