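test_that("over-, under- and neutral calls follow the simulated normal
           null", {
    set.seed(3)
    n <- 40
    base <- rnorm(n)
    sdv <- sd(base)
    x <- cbind(over = base, under = base, neutral = base)
    lab <- rep(1:8, each = 5)
    # the shifted cluster itself inflates the overall SD, so the shift must
    # be large (and the cluster small) for its quartile to clear the
    # simulated 95th percentile
    x[lab == 1, "over"] <- mean(base) + 30 * sdv + rnorm(5, 0, 0.01)
    x[lab == 1, "under"] <- mean(base) - 30 * sdv + rnorm(5, 0, 0.01)
    x[lab == 1, "neutral"] <- mean(x[lab != 1, "neutral"])
    ora <- oraClassify(x, lab, nSim = 5000, seed = 1)
    expect_equal(ora@calls["over", "A"], "over")
    expect_equal(ora@calls["under", "A"], "under")
    expect_equal(ora@calls["neutral", "A"], "neutral")
    expect_true(all(ora@upperCut > ora@lowerCut))
    # analytic mode agrees on the same construction
    oa <- oraClassify(x, lab, analytic = TRUE)
    expect_equal(oa@calls["over", "A"], "over")
    expect_equal(oa@calls["under", "A"], "under")
})

test_that("simulated cutoffs converge to the analytic normal quantiles", {
    set.seed(7)
    x <- matrix(rnorm(60 * 4, mean = 5, sd = 2), 60, 4)
    lab <- rep(1:3, each = 20)
    sim <- oraClassify(x, lab, nSim = 1e5, seed = 11)
    mu <- colMeans(x)
    sdv <- apply(x, 2, sd)
    expect_true(all(abs(sim@upperCut - (mu + qnorm(0.95) * sdv)) <
                        0.02 * sdv))
    expect_true(all(abs(sim@lowerCut - (mu - qnorm(0.95) * sdv)) <
                        0.02 * sdv))
    ana <- oraClassify(x, lab, analytic = TRUE)
    expect_equal(ana@upperCut, mu + qnorm(0.95) * sdv, ignore_attr = TRUE)
})

test_that("a cluster quartile just across the cutoff flips the call", {
    # analytic mode: the call boundary is exactly mean + 1.6449 sd of the
    # full column. Solve for the fixed point where a constant cluster sits
    # exactly on the cutoff, then nudge either side.
    lab <- rep(1:6, each = 5)
    others <- rep(c(-1, 0, 1), length.out = 25)
    column <- function(c1) c(rep(c1, 5), others)
    gap <- function(c1) {
        v <- column(c1)
        c1 - (mean(v) + qnorm(0.95) * sd(v))
    }
    cstar <- uniroot(gap, c(1, 1000), tol = 1e-12)$root
    flip <- function(eps) {
        m <- matrix(column(cstar + eps), ncol = 1,
                    dimnames = list(NULL, "f"))
        oraClassify(m, lab, analytic = TRUE)@calls["f", "A"]
    }
    expect_equal(flip(1e-6), "over")
    expect_equal(flip(-1e-6), "neutral")
    # Monte-Carlo mode approaches the same boundary at large nSim
    mcFlip <- oraClassify(matrix(column(cstar * 1.05), ncol = 1,
                                 dimnames = list(NULL, "f")),
                          lab, nSim = 1e5, seed = 8)@calls["f", "A"]
    expect_equal(mcFlip, "over")
})

test_that("stricter cutoffs call a subset of the default calls", {
    # features with cluster shifts of graded size produce a mix of calls
    set.seed(19)
    lab <- rep(1:5, each = 6)
    shifts <- seq(0, 60, length.out = 12)
    x <- sapply(seq_along(shifts), function(j) {
        v <- rnorm(30)
        cl <- (j %% 5) + 1
        v[lab == cl] <- v[lab == cl] + sample(c(-1, 1), 1) * shifts[j]
        v
    })
    colnames(x) <- paste0("f", 1:12)
    def <- oraClassify(x, lab, nSim = 5000, seed = 42)
    strict <- oraClassify(x, lab, nSim = 5000, seed = 42,
                          nullQuantiles = c(0.01, 0.99))
    # every non-neutral strict call must agree with the default call
    expect_true(all(strict@calls == "neutral" | strict@calls == def@calls))
    expect_gt(sum(def@calls != "neutral"), 0)
})

test_that("zero-SD features yield all-neutral calls with a warning", {
    x <- cbind(flat = rep(3, 20), ok = rnorm(20))
    expect_warning(ora <- oraClassify(x, rep(1:2, each = 10), nSim = 1000,
                                      seed = 1), "zero SD")
    expect_true(all(ora@calls["flat", ] == "neutral"))
})

test_that("inputs are validated and the table serializes", {
    x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
    expect_error(oraClassify(x, c(rep(1, 9), 2), nSim = 1000), "2 samples")
    expect_error(oraClassify(x, rep(1:2, each = 5), nSim = 10), "1000")
    ora <- oraClassify(x, rep(1:2, each = 5), analytic = TRUE)
    df <- oraTable(ora)
    expect_equal(nrow(df), 4)
    expect_setequal(df$feature, c("a", "b"))
    f <- tempfile(fileext = ".csv")
    oraTable(ora, f)
    expect_true(file.exists(f))
})
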