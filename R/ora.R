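# Over/under-representation calls: each (feature, cluster) cell is compared
# against a normal null simulated from the feature's overall mean and SD.

#' Over-representation calls against a simulated normal null
#'
#' For each feature a normal distribution is simulated with the mean and
#' standard deviation of that feature over all samples. A cluster is called
#' \emph{over}-represented when its 25th percentile exceeds the null's 95th
#' percentile, \emph{under}-represented when its 75th percentile falls below
#' the null's 5th percentile, and \emph{neutral} otherwise. All four
#' quantiles are configurable; linear-interpolation quantiles (R type 7) are
#' used throughout. Features with zero SD yield all-neutral calls with a
#' warning.
#'
#' @param data a \linkS4class{LifespanExperiment} or samples-by-features
#'   matrix.
#' @param assignments integer cluster labels in \code{1..k}.
#' @param nSim null simulation size per feature (default 10000; at least
#'   1000).
#' @param seed optional integer seed.
#' @param analytic if \code{TRUE}, exact normal quantiles replace the
#'   simulation (a faster, deterministic equivalent).
#' @param nullQuantiles lower/upper null percentiles (default
#'   \code{c(0.05, 0.95)}).
#' @param clusterQuantiles cluster percentiles compared against them
#'   (default \code{c(0.25, 0.75)}).
#' @return an \linkS4class{ORATable}.
#' @examples
#' x <- cbind(a = c(0, 0, 10, 10), b = rnorm(4))
#' oraClassify(x, c(1, 1, 2, 2), analytic = TRUE)
#' @export
oraClassify <- function(data, assignments, nSim = 10000L, seed = NULL,
                        analytic = FALSE,
                        nullQuantiles = c(0.05, 0.95),
                        clusterQuantiles = c(0.25, 0.75)) {
    X <- .asMatrix(data)
    assignments <- as.integer(assignments)
    if (length(assignments) != nrow(X))
        stop("'assignments' must have one label per sample")
    k <- max(assignments)
    if (any(tabulate(assignments, k) < 2L))
        stop("every cluster needs at least 2 samples for percentiles")
    if (!analytic && nSim < 1000L)
        stop("'nSim' must be at least 1000")
    p <- ncol(X)
    featNames <- colnames(X) %||% paste0("F", seq_len(p))
    calls <- matrix("neutral", p, k,
                    dimnames = list(featNames, LETTERS[seq_len(k)]))
    upper <- lower <- rep(NA_real_, p)
    .withSeed(seed, {
        for (j in seq_len(p)) {
            v <- X[, j]
            mu <- mean(v)
            sdev <- sd(v)
            if (sdev == 0) {
                warning("feature '", featNames[j],
                        "' has zero SD; calls set to neutral")
                next
            }
            if (analytic) {
                lower[j] <- qnorm(nullQuantiles[1], mu, sdev)
                upper[j] <- qnorm(nullQuantiles[2], mu, sdev)
            } else {
                sim <- rnorm(nSim, mu, sdev)
                qq <- quantile(sim, nullQuantiles, names = FALSE, type = 7)
                lower[j] <- qq[1]
                upper[j] <- qq[2]
            }
            for (c in seq_len(k)) {
                cv <- v[assignments == c]
                q <- quantile(cv, clusterQuantiles, names = FALSE, type = 7)
                if (q[1] > upper[j])
                    calls[j, c] <- "over"
                else if (q[2] < lower[j])
                    calls[j, c] <- "under"
            }
        }
    })
    new("ORATable", calls = calls, upperCut = upper, lowerCut = lower,
        nSim = if (analytic) 0L else as.integer(nSim),
        analytic = analytic, nullQuantiles = nullQuantiles,
        clusterQuantiles = clusterQuantiles)
}

#' Serialize an ORATable to a data.frame / CSV
#'
#' @param ora an \linkS4class{ORATable}.
#' @param path optional file; when given, the long-format table is written as
#'   CSV.
#' @return (invisibly, when writing) a long-format data.frame with columns
#'   feature, cluster, call, lowerCut, upperCut.
#' @examples
#' x <- cbind(a = c(0, 0, 10, 10), b = rnorm(4))
#' head(oraTable(oraClassify(x, c(1, 1, 2, 2), analytic = TRUE)))
#' @export
oraTable <- function(ora, path = NULL) {
    df <- data.frame(
        feature = rep(rownames(ora@calls), ncol(ora@calls)),
        cluster = rep(colnames(ora@calls), each = nrow(ora@calls)),
        call = as.vector(ora@calls),
        lowerCut = rep(ora@lowerCut, ncol(ora@calls)),
        upperCut = rep(ora@upperCut, ncol(ora@calls)))
    if (!is.null(path)) {
        write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
        return(invisible(df))
    }
    df
}
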