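# Small constructed datasets used across tests. Everything is generated in
# code; no files.

# two well-separated Gaussian clusters on feature 1, plus pure-noise features
twoClusterToy <- function(n = 20, pNoise = 9, gap = 6, seed = 101) {
    set.seed(seed)
    half <- n / 2
    x <- cbind(c(rnorm(half, 0), rnorm(half, gap)),
               matrix(rnorm(n * pNoise), n))
    list(x = x, truth = rep(1:2, each = half))
}

# three planted Gaussian clusters on two features + noise features, with
# optional extreme outlier samples appended
plantedThree <- function(nPer = 10, pNoise = 8, shift = 5, nOut = 0,
                         seed = 202) {
    set.seed(seed)
    centers <- rbind(c(0, 0), c(shift, 0), c(0, shift))
    x <- do.call(rbind, lapply(1:3, function(c)
        cbind(rnorm(nPer, centers[c, 1], 0.4),
              rnorm(nPer, centers[c, 2], 0.4))))
    x <- cbind(x, matrix(rnorm(nrow(x) * pNoise), nrow(x)))
    truth <- rep(1:3, each = nPer)
    outIdx <- integer(0)
    if (nOut > 0) {
        out <- matrix(rnorm(nOut * ncol(x)), nOut)
        out[, 1:2] <- out[, 1:2] + 40
        x <- rbind(x, out)
        outIdx <- nrow(x) - nOut + seq_len(nOut)
        truth <- c(truth, rep(NA_integer_, nOut))
    }
    list(x = x, truth = truth, outliers = outIdx)
}

# brute-force maximum of sum(w * bcss) over the constraint set, on a fine
# grid; independent of the bisection implementation. 2 features only.
gridMaxWeights2 <- function(bcss, s, step = 1e-4) {
    w1 <- seq(0, 1, by = step)
    w2 <- pmin(sqrt(pmax(1 - w1^2, 0)), pmax(s - w1, 0))
    obj <- bcss[1] * w1 + bcss[2] * w2
    i <- which.max(obj)
    c(w1[i], w2[i])
}

# all partitions of n items into exactly 2 non-empty unlabeled groups
allTwoPartitions <- function(n) {
    out <- list()
    for (code in 1:(2^(n - 1) - 1)) {
        bits <- as.integer(intToBits(code))[seq_len(n)]
        out[[length(out) + 1]] <- bits + 1L
    }
    out
}

# weighted between-cluster objective of a partition with its optimal weights
partitionObjective <- function(X, labels, l1Bound) {
    bcss <- vapply(seq_len(ncol(X)), function(j) {
        mu <- mean(X[, j])
        sum(vapply(unique(labels), function(c) {
            v <- X[labels == c, j]
            length(v) * (mean(v) - mu)^2
        }, numeric(1)))
    }, numeric(1))
    if (all(bcss <= 0))
        return(0)
    w <- updateWeights(bcss, l1Bound)
    sum(w * bcss)
}
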