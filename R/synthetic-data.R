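# Synthetic lifespan expression generator. Emulates the structure of
# postmortem developmental panels: log-uniform ages from infancy to old age,
# informative features following canonical lifespan trajectory shapes
# (monotone up/down, inverted-U, undulating, flat), planted stage structure
# as piecewise shifts at boundary ages, age-independent noise features,
# optional replicate runs per subject and planted extreme outliers, plus a
# paired-omics generator with controlled per-feature trajectory correlation.

#' Specify one lifespan trajectory shape
#'
#' @param shape one of \code{"increase"}, \code{"decrease"},
#'   \code{"inverted_u"}, \code{"undulating"}, \code{"flat"}.
#' @param amplitude peak-to-trough amplitude of the smooth trajectory
#'   (expression units); must be 0 for \code{"flat"}.
#' @param peakAge age in years of the inverted-U peak (default 10).
#' @param period cycles of the undulating shape across the (log) lifespan
#'   (default 2).
#' @param noiseSd SD of the additive Gaussian measurement noise (default
#'   0.25).
#' @return a \code{trajectorySpec} list.
#' @examples
#' trajectorySpec("inverted_u", amplitude = 1.5, peakAge = 8)
#' @export
trajectorySpec <- function(shape = c("increase", "decrease", "inverted_u",
                                     "undulating", "flat"),
                           amplitude = 1, peakAge = 10, period = 2,
                           noiseSd = 0.25) {
    shape <- match.arg(shape)
    if (amplitude < 0 || noiseSd < 0)
        stop("'amplitude' and 'noiseSd' must be non-negative")
    if (shape == "flat" && amplitude > 0)
        stop("contradictory spec: a flat trajectory cannot have amplitude > 0")
    structure(list(shape = shape, amplitude = amplitude, peakAge = peakAge,
                   period = period, noiseSd = noiseSd),
              class = "trajectorySpec")
}

# evaluate a shape on the normalized log-age axis x in [0, 1]
.shapeValue <- function(spec, x, ageRange) {
    switch(spec$shape,
           increase = spec$amplitude * x,
           decrease = spec$amplitude * (1 - x),
           inverted_u = {
               pk <- (log(spec$peakAge) - log(ageRange[1])) /
                   (log(ageRange[2]) - log(ageRange[1]))
               spec$amplitude * exp(-(x - pk)^2 / (2 * 0.18^2))
           },
           undulating = spec$amplitude *
               (0.5 + 0.5 * sin(2 * pi * spec$period * x - pi / 2)),
           flat = rep(0, length(x)))
}

# all permutations of 1..n (n <= 6 in practice)
.permutations <- function(n) {
    if (n == 1L)
        return(matrix(1L, 1, 1))
    sub <- .permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i)
        cbind(i, sub + (sub >= i))))
}

# Balanced stage-shift design: each feature's profile is a permutation of
# equispaced centered levels (range 1). Monotone shapes take the sorted
# permutation (ascending/descending), flat shapes a zero profile, and the
# remaining shapes greedily receive the permutation that makes the stage
# centroids most nearly equidistant (minimum relative variance of pairwise
# squared distances). The design is deterministic: identical for every
# dataset with the same specs and stage count, so the planted k is equally
# well defined across seeds.
.stageDesign <- function(specs, nStages, stageJitter = 0) {
    nInf <- length(specs)
    base <- seq(0, 1, length.out = nStages) - 0.5
    L <- matrix(0, nStages, nInf)
    free <- integer(0)
    for (j in seq_len(nInf)) {
        L[, j] <- switch(specs[[j]]$shape,
                         increase = base,
                         decrease = rev(base),
                         flat = rep(0, nStages),
                         base)
        if (!specs[[j]]$shape %in% c("increase", "decrease", "flat"))
            free <- c(free, j)
    }
    if (length(free)) {
        cand <- if (nStages <= 6L) .permutations(nStages) else
            .withSeed(20240601L,
                      t(replicate(720, sample.int(nStages))))
        score <- function(M) {
            d2 <- as.vector(dist(M))^2
            stats::var(d2) / mean(d2)^2
        }
        for (j in free) {
            best <- Inf
            bestLev <- L[, j]
            for (r in seq_len(nrow(cand))) {
                L[, j] <- base[cand[r, ]]
                sc <- score(L[, seq_len(j), drop = FALSE])
                if (sc < best - 1e-12) {
                    best <- sc
                    bestLev <- L[, j]
                }
            }
            L[, j] <- bestLev
        }
    }
    if (stageJitter > 0) {
        for (j in seq_len(nInf)) {
            if (specs[[j]]$shape == "flat")
                next
            jit <- runif(nStages, -stageJitter, stageJitter)
            lev <- L[, j] + jit
            if (specs[[j]]$shape == "increase")
                lev <- sort(lev)
            if (specs[[j]]$shape == "decrease")
                lev <- sort(lev, decreasing = TRUE)
            L[, j] <- lev
        }
    }
    L
}

.defaultSpecs <- function(n = 5L) {
    base <- list(trajectorySpec("increase", amplitude = 0.5),
                 trajectorySpec("decrease", amplitude = 0.5),
                 trajectorySpec("inverted_u", amplitude = 0.7, peakAge = 8),
                 trajectorySpec("undulating", amplitude = 0.5, period = 2),
                 trajectorySpec("undulating", amplitude = 0.5, period = 1.2))
    rep(base, length.out = n)
}

#' Named dataset presets
#'
#' \code{"small7"} (7 features: 5 informative + 2 noise), \code{"full23"}
#' (5 informative + 18 noise) and \code{"wide95"} (5 informative + 90 noise)
#' mirror the feature counts of typical developmental protein panels; all use
#' 31 subjects and 6 planted stages.
#'
#' @param name preset name.
#' @return a list of arguments for \code{\link{simulateLifespanData}}.
#' @examples
#' lifespanPreset("full23")$nNoiseFeatures
#' @export
lifespanPreset <- function(name = c("full23", "small7", "wide95")) {
    name <- match.arg(name)
    switch(name,
           small7 = list(nSubjects = 31L, nNoiseFeatures = 2L,
                         trajectorySpecs = .defaultSpecs(5L), nStages = 6L),
           full23 = list(nSubjects = 31L, nNoiseFeatures = 18L,
                         trajectorySpecs = .defaultSpecs(5L), nStages = 6L),
           wide95 = list(nSubjects = 31L, nNoiseFeatures = 90L,
                         trajectorySpecs = .defaultSpecs(5L), nStages = 6L))
}

#' Simulate a lifespan expression dataset with planted structure
#'
#' Ages are drawn log-uniformly over \code{ageRange}, mimicking the age
#' density of postmortem brain banks. Each informative feature follows its
#' trajectory shape over (log) age; stage structure is induced by piecewise
#' shifts at planted boundary ages (boundaries at empirical log-age
#' quantiles, so stages are balanced in size). The shift profiles form a
#' balanced design: permutations of equispaced levels, sorted for monotone
#' shapes and chosen to keep the stage centroids near-equidistant otherwise,
#' so every pair of stages is separated on every informative feature and the
#' planted number of stages is well defined. Noise features are
#' age-independent Gaussian. Planted outlier subjects receive shifts of at
#' least 5 feature-SDs on a random subset of features.
#'
#' @param nSubjects number of subjects (default 31).
#' @param ageRange age range in years (default \code{c(0.05, 80)}).
#' @param trajectorySpecs list of \code{\link{trajectorySpec}} for the
#'   informative features (default: five canonical shapes).
#' @param nNoiseFeatures age-independent features to append (default 45).
#' @param nOutliers planted outlier subjects (default 0).
#' @param nStages planted stages (default 6); requires
#'   \code{nSubjects >= 2 * nStages}.
#' @param stageSeparation scale of the between-stage shifts in expression
#'   units (default 4).
#' @param stageJitter optional uniform half-width of per-(stage, feature)
#'   perturbation of the balanced shift profiles (default 0: the design is
#'   deterministic); jittered levels stay sorted for monotone shapes so
#'   monotonicity in age is preserved.
#' @param nReplicates replicate runs per subject (default 1); replicates
#'   share the subject's signal and differ by measurement noise.
#' @param noiseSd if non-NULL, overrides every spec's measurement noise SD.
#' @param baseline additive constant keeping expression positive (default 5).
#' @param seed optional integer seed; identical seeds give identical
#'   datasets.
#' @return a list with \code{data} (a \linkS4class{LifespanExperiment}) and
#'   \code{truth}: planted stage labels and boundary ages, the informative
#'   feature set, outlier sample ids, the noiseless signal matrix and the
#'   generator parameters.
#' @examples
#' sim <- simulateLifespanData(nSubjects = 20, nStages = 4, seed = 1)
#' table(sim$truth$stages)
#' @export
simulateLifespanData <- function(nSubjects = 31L,
                                 ageRange = c(0.05, 80),
                                 trajectorySpecs = .defaultSpecs(),
                                 nNoiseFeatures = 45L,
                                 nOutliers = 0L,
                                 nStages = 6L,
                                 stageSeparation = 4,
                                 stageJitter = 0,
                                 nReplicates = 1L,
                                 noiseSd = NULL,
                                 baseline = 5,
                                 seed = NULL) {
    if (nSubjects < 2L * nStages)
        stop("'nSubjects' must be at least twice the number of stages")
    if (nOutliers >= nSubjects / 2)
        stop("'nOutliers' must be fewer than half the subjects")
    specs <- lapply(trajectorySpecs, function(sp) {
        if (!inherits(sp, "trajectorySpec"))
            sp <- do.call(trajectorySpec, sp)
        if (!is.null(noiseSd))
            sp$noiseSd <- noiseSd
        sp
    })
    nInf <- length(specs)
    p <- nInf + nNoiseFeatures
    .withSeed(seed, {
        subjAges <- exp(runif(nSubjects, log(ageRange[1]), log(ageRange[2])))
        subjAges <- sort(subjAges)
        x01 <- (log(subjAges) - log(ageRange[1])) /
            (log(ageRange[2]) - log(ageRange[1]))
        # balanced planted stages: boundaries at empirical log-age quantiles
        qs <- quantile(x01, probs = seq_len(nStages - 1L) / nStages,
                       names = FALSE)
        stage <- findInterval(x01, qs) + 1L
        bounds01 <- c(0, qs, 1)
        mids01 <- (bounds01[-1] + bounds01[-(nStages + 1L)]) / 2
        boundaryAges <- exp(log(ageRange[1]) +
            qs * (log(ageRange[2]) - log(ageRange[1])))
        # replicate expansion
        subj <- rep(seq_len(nSubjects), each = nReplicates)
        n <- length(subj)
        agesAll <- subjAges[subj]
        stageAll <- stage[subj]
        x01All <- x01[subj]
        infNames <- vapply(seq_len(nInf), function(j)
            paste0(substr(specs[[j]]$shape, 1, 3), j), character(1))
        noiseNames <- if (nNoiseFeatures > 0)
            paste0("noise", seq_len(nNoiseFeatures)) else character(0)
        signal <- matrix(0, n, p,
                         dimnames = list(NULL, c(infNames, noiseNames)))
        stageLevels <- .stageDesign(specs, nStages, stageJitter)
        for (j in seq_len(nInf)) {
            sp <- specs[[j]]
            signal[, j] <- baseline + .shapeValue(sp, x01All, ageRange) +
                stageSeparation * stageLevels[stageAll, j]
        }
        if (nNoiseFeatures > 0)
            signal[, nInf + seq_len(nNoiseFeatures)] <- baseline
        noiseSds <- c(vapply(specs, `[[`, numeric(1), "noiseSd"),
                      rep(if (is.null(noiseSd)) 0.25 else noiseSd,
                          nNoiseFeatures))
        values <- signal + matrix(rnorm(n * p), n, p) %*% diag(noiseSds, p)
        # planted outliers: subjects shifted >= 5 SD on a random feature set
        outlierSubj <- if (nOutliers > 0)
            sample(seq_len(nSubjects), nOutliers) else integer(0)
        sds <- pmax(apply(values, 2, sd), 1e-8)
        for (s in outlierSubj) {
            nShift <- max(2L, ceiling(0.15 * p))
            featIdx <- sample(seq_len(p), nShift)
            shift <- sample(c(-6, 6), nShift, replace = TRUE) * sds[featIdx]
            rows <- which(subj == s)
            values[rows, featIdx] <- values[rows, featIdx] +
                rep(shift, each = length(rows))
        }
        sampleIds <- if (nReplicates > 1L)
            paste0("S", sprintf("%02d", subj), "_r",
                   sequence(rep(nReplicates, nSubjects)))
        else paste0("S", sprintf("%02d", subj))
        data <- LifespanExperiment(values, ages = agesAll,
                                   sampleIds = sampleIds,
                                   featureNames = colnames(signal),
                                   subject = paste0("S",
                                                    sprintf("%02d", subj)))
        truth <- list(stages = stageAll,
                      stageBoundaryAges = boundaryAges,
                      informative = infNames,
                      outlierSubjects = outlierSubj,
                      outlierSamples = sampleIds[subj %in% outlierSubj],
                      signal = signal,
                      specs = specs,
                      stageLevels = stageLevels,
                      x01 = x01All,
                      ageRange = ageRange,
                      stageMids01 = mids01,
                      stageSeparation = stageSeparation,
                      baseline = baseline)
        list(data = data, truth = truth)
    })
}

# noiseless trajectory value (smooth shape + stage shifts) for feature j of a
# simulated dataset, at normalized log-ages x01
.plantedSignal <- function(truth, j, x01) {
    sp <- truth$specs[[j]]
    levels <- truth$stageLevels[, j]
    # recover boundaries from the stored boundary ages
    q01 <- (log(truth$stageBoundaryAges) - log(truth$ageRange[1])) /
        (log(truth$ageRange[2]) - log(truth$ageRange[1]))
    st <- findInterval(x01, q01) + 1L
    .shapeValue(sp, x01, truth$ageRange) + truth$stageSeparation * levels[st]
}

#' Simulate a paired omics dataset with controlled trajectory correlation
#'
#' Builds a companion dataset (e.g. gene expression paired with a protein
#' panel) in which each feature's lifespan trajectory is a
#' \code{targetR}-correlated mixture of the base feature's planted trajectory
#' and an independent smooth age function: \eqn{r f + \sqrt{1 - r^2} g},
#' with \eqn{g} orthogonalized against \eqn{f} across the sampled subjects.
#' By default the paired dataset uses an independent subject set.
#'
#' @param baseSim the list returned by \code{\link{simulateLifespanData}}.
#' @param targetR target per-feature correlation in \code{[-1, 1]}.
#' @param nSubjects subjects in the paired dataset (default 48).
#' @param sameSubjects reuse the base subjects and ages (then
#'   \code{targetR = 1} reproduces the base z-scored trajectories exactly).
#' @param seed optional integer seed.
#' @return a list with \code{data} (\linkS4class{LifespanExperiment}; feature
#'   \code{g_<name>} pairs with base feature \code{<name>}) and \code{pairs}
#'   (a data.frame ready for \code{\link{pairCorrelations}}).
#' @examples
#' sim <- simulateLifespanData(nSubjects = 20, nStages = 4, seed = 1)
#' paired <- generatePairedOmics(sim, targetR = 0.2, seed = 2)
#' head(paired$pairs)
#' @export
generatePairedOmics <- function(baseSim, targetR, nSubjects = 48L,
                                sameSubjects = FALSE, seed = NULL) {
    if (targetR < -1 || targetR > 1)
        stop("'targetR' must lie in [-1, 1]")
    truth <- baseSim$truth
    p <- ncol(truth$signal)
    featNames <- colnames(truth$signal)
    nInf <- length(truth$informative)
    .withSeed(seed, {
        if (sameSubjects) {
            x01 <- truth$x01
            agesNew <- ages(baseSim$data)
        } else {
            agesNew <- exp(runif(nSubjects, log(truth$ageRange[1]),
                                 log(truth$ageRange[2])))
            agesNew <- sort(agesNew)
            x01 <- (log(agesNew) - log(truth$ageRange[1])) /
                (log(truth$ageRange[2]) - log(truth$ageRange[1]))
        }
        n <- length(x01)
        zscore <- function(v) {
            s <- sd(v)
            if (s == 0) rep(0, n) else (v - mean(v)) / s
        }
        vals <- matrix(0, n, p, dimnames = list(NULL,
                                                paste0("g_", featNames)))
        for (j in seq_len(p)) {
            f <- if (j <= nInf) .plantedSignal(truth, j, x01) else rep(0, n)
            fz <- zscore(f)
            # independent smooth age function plus sample-level noise
            g <- runif(1, -1, 1) * x01 + runif(1, -1, 1) * x01^2 +
                runif(1, -1, 1) * sin(2 * pi * runif(1, 1, 3) * x01 +
                                          runif(1, 0, 2 * pi)) +
                rnorm(n, 0, 0.3)
            if (sd(fz) > 0)
                g <- g - sum(g * fz) / sum(fz^2) * fz
            gz <- zscore(g)
            vals[, j] <- truth$baseline + targetR * fz +
                sqrt(1 - targetR^2) * gz
        }
        data <- LifespanExperiment(vals, ages = agesNew,
                                   sampleIds = paste0("G",
                                                      sprintf("%02d",
                                                              seq_len(n))))
        pairs <- data.frame(protein = featNames,
                            gene = paste0("g_", featNames))
        list(data = data, pairs = pairs, targetR = targetR)
    })
}
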