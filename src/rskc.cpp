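// Core fitting loop for (robust) sparse k-means: k-means++ seeding, trimmed
// Lloyd iterations in sqrt(w)-scaled space, union trimming in weighted and
// unweighted space, and the exact lasso-bounded weight update. Randomness
// comes from R's RNG so results are reproducible from a single seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// squared distances: n x k
static arma::mat dist2(const arma::mat& X, const arma::mat& centers) {
    arma::mat d2 = arma::repmat(arma::sum(arma::square(X), 1), 1,
                                centers.n_rows)
        - 2.0 * X * centers.t()
        + arma::repmat(arma::sum(arma::square(centers), 1).t(), X.n_rows, 1);
    d2.clamp(0.0, arma::datum::inf);
    return d2;
}

// weighted draw in [0, n) with weights w (uses R RNG)
static int drawWeighted(const arma::vec& w) {
    double tot = arma::accu(w);
    if (tot <= 0.0)
        return (int) std::floor(unif_rand() * w.n_elem);
    double u = unif_rand() * tot, acc = 0.0;
    for (arma::uword i = 0; i < w.n_elem; ++i) {
        acc += w(i);
        if (u <= acc) return (int) i;
    }
    return (int) (w.n_elem - 1);
}

// uniform seeding without replacement (robust fits: d^2-weighted seeding
// would preferentially pick outliers as centers)
static arma::mat uniformSeed(const arma::mat& X, int k) {
    int n = X.n_rows;
    arma::uvec idx = arma::regspace<arma::uvec>(0, n - 1);
    // partial Fisher-Yates with R RNG
    for (int j = 0; j < k; ++j) {
        int r = j + (int) std::floor(unif_rand() * (n - j));
        if (r >= n) r = n - 1;
        std::swap(idx(j), idx(r));
    }
    arma::mat centers(k, X.n_cols);
    for (int j = 0; j < k; ++j)
        centers.row(j) = X.row(idx(j));
    return centers;
}

// k-means++ seeding over a candidate subset of rows
static arma::mat kmeansPPsub(const arma::mat& X, int k,
                             const arma::uvec& cand) {
    arma::mat Xc = X.rows(cand);
    int n = Xc.n_rows;
    arma::mat centers(k, X.n_cols);
    int first = (int) std::floor(unif_rand() * n);
    if (first == n) first = n - 1;
    centers.row(0) = Xc.row(first);
    arma::vec closest = dist2(Xc, centers.rows(0, 0)).col(0);
    for (int j = 1; j < k; ++j) {
        int idx = drawWeighted(closest);
        centers.row(j) = Xc.row(idx);
        arma::vec d = dist2(Xc, centers.rows(j, j)).col(0);
        closest = arma::min(closest, d);
    }
    return centers;
}

static arma::mat kmeansPP(const arma::mat& X, int k) {
    return kmeansPPsub(X, k, arma::regspace<arma::uvec>(0, X.n_rows - 1));
}

// centroids with sentinel rows for empty clusters
static arma::mat centroids(const arma::mat& X, const arma::ivec& labels,
                           const arma::uvec& keep, int k) {
    arma::mat M(k, X.n_cols, arma::fill::value(1e15));
    arma::vec cnt(k, arma::fill::zeros);
    arma::mat S(k, X.n_cols, arma::fill::zeros);
    for (arma::uword ii = 0; ii < keep.n_elem; ++ii) {
        int i = keep(ii);
        int c = labels(i);
        S.row(c) += X.row(i);
        cnt(c) += 1.0;
    }
    for (int c = 0; c < k; ++c)
        if (cnt(c) > 0) M.row(c) = S.row(c) / cnt(c);
    return M;
}

// exact weight update: soft-threshold + L2 normalize, bisection on delta
static arma::vec updateW(const arma::vec& bcss, double s) {
    arma::vec b = arma::clamp(bcss, 0.0, arma::datum::inf);
    arma::vec w = b / arma::norm(b, 2);
    if (arma::accu(w) <= s + 1e-12) return w;
    double lo = 0.0, hi = b.max();
    for (int it = 0; it < 50; ++it) {
        double mid = 0.5 * (lo + hi);
        arma::vec u = arma::clamp(b - mid, 0.0, arma::datum::inf);
        if (arma::accu(u) / arma::norm(u, 2) > s) lo = mid; else hi = mid;
    }
    arma::vec u = arma::clamp(b - 0.5 * (lo + hi), 0.0, arma::datum::inf);
    return u / arma::norm(u, 2);
}

static arma::vec bcssPerFeature(const arma::mat& X, const arma::ivec& labels,
                                const arma::uvec& keep, int k) {
    arma::mat S(k, X.n_cols, arma::fill::zeros);
    arma::vec cnt(k, arma::fill::zeros);
    arma::rowvec mu(X.n_cols, arma::fill::zeros);
    for (arma::uword ii = 0; ii < keep.n_elem; ++ii) {
        int i = keep(ii);
        S.row(labels(i)) += X.row(i);
        cnt(labels(i)) += 1.0;
        mu += X.row(i);
    }
    mu /= (double) keep.n_elem;
    arma::rowvec bcss(X.n_cols, arma::fill::zeros);
    for (int c = 0; c < k; ++c)
        if (cnt(c) > 0) {
            arma::rowvec d = S.row(c) / cnt(c) - mu;
            bcss += cnt(c) * arma::square(d);
        }
    bcss.clamp(0.0, arma::datum::inf);
    return bcss.t();
}

// order(d, decreasing = TRUE)[1:nTrim]
static arma::uvec topIdx(const arma::vec& d, int nTrim) {
    arma::uvec ord = arma::sort_index(d, "descend");
    return ord.head(nTrim);
}

struct LloydResult {
    arma::ivec labels;
    arma::uvec trimmed;
    double wss;
};

static LloydResult trimmedLloyd(const arma::mat& X, int k, arma::mat centers,
                                int nTrim, int maxIter) {
    int n = X.n_rows;
    arma::ivec labels(n, arma::fill::value(-1));
    arma::uvec trimmed;
    for (int iter = 0; iter < maxIter; ++iter) {
        arma::mat d2 = dist2(X, centers);
        arma::ivec newLabels(n);
        arma::vec dOwn(n);
        for (int i = 0; i < n; ++i) {
            arma::uword c;
            dOwn(i) = d2.row(i).min(c);   // ties: lowest index
            newLabels(i) = (int) c;
        }
        trimmed = (nTrim > 0) ? topIdx(dOwn, nTrim) : arma::uvec();
        arma::uvec isTrim(n, arma::fill::zeros);
        for (arma::uword t = 0; t < trimmed.n_elem; ++t)
            isTrim(trimmed(t)) = 1;
        arma::uvec keep = arma::find(isTrim == 0);
        // re-seed clusters emptied among kept samples
        arma::vec cnt(k, arma::fill::zeros);
        for (arma::uword ii = 0; ii < keep.n_elem; ++ii)
            cnt(newLabels(keep(ii))) += 1.0;
        for (int c = 0; c < k; ++c) {
            if (cnt(c) == 0) {
                double worst = -1.0;
                int far = -1;
                for (arma::uword ii = 0; ii < keep.n_elem; ++ii) {
                    int i = keep(ii);
                    if (cnt(newLabels(i)) > 1 && dOwn(i) > worst) {
                        worst = dOwn(i);
                        far = i;
                    }
                }
                if (far >= 0) {
                    cnt(newLabels(far)) -= 1.0;
                    newLabels(far) = c;
                    cnt(c) += 1.0;
                    dOwn(far) = 0.0;
                }
            }
        }
        centers = centroids(X, newLabels, keep, k);
        bool same = true;
        for (int i = 0; i < n; ++i)
            if (newLabels(i) != labels(i)) { same = false; break; }
        labels = newLabels;
        if (same) break;
    }
    LloydResult res;
    res.labels = labels;
    res.trimmed = trimmed;
    // trimmed within-cluster SS in this (weighted) space
    arma::uvec isTrim(n, arma::fill::zeros);
    for (arma::uword t = 0; t < trimmed.n_elem; ++t) isTrim(trimmed(t)) = 1;
    arma::uvec keep = arma::find(isTrim == 0);
    arma::mat d2f = dist2(X, centroids(X, labels, keep, (int) centers.n_rows));
    double wss = 0.0;
    for (arma::uword ii = 0; ii < keep.n_elem; ++ii)
        wss += d2f(keep(ii), labels(keep(ii)));
    res.wss = wss;
    return res;
}

// best-of-several Lloyd runs for fixed weights: warm start (when given)
// plus fresh k-means++ seedings, compared by trimmed within-cluster SS
static LloydResult bestLloyd(const arma::mat& Xw, int k, bool haveWarm,
                             const arma::mat& warmInit, int nTrim,
                             int maxIter, int nInnerStarts) {
    LloydResult best;
    bool first = true;
    if (haveWarm) {
        best = trimmedLloyd(Xw, k, warmInit, nTrim, maxIter);
        first = false;
    }
    arma::uvec candSet;
    if (nTrim > 0) {
        // robust seeding pool: exclude the nTrim samples farthest from the
        // grand mean, so extreme outliers cannot be picked as centers while
        // seeding still favours spread-out structure
        arma::rowvec mu = arma::mean(Xw, 0);
        arma::vec d(Xw.n_rows);
        for (arma::uword i = 0; i < Xw.n_rows; ++i) {
            arma::rowvec dd = Xw.row(i) - mu;
            d(i) = arma::dot(dd, dd);
        }
        arma::uvec ord = arma::sort_index(d, "ascend");
        candSet = arma::sort(ord.head(Xw.n_rows - nTrim));
    } else {
        candSet = arma::regspace<arma::uvec>(0, Xw.n_rows - 1);
    }
    for (int s = 0; s < nInnerStarts; ++s) {
        LloydResult cand = trimmedLloyd(Xw, k, kmeansPPsub(Xw, k, candSet),
                                        nTrim, maxIter);
        if (first || cand.wss < best.wss) {
            best = cand;
            first = false;
        }
    }
    return best;
}

// one restart; consumes R RNG
static List fitOnce(const arma::mat& X, int k, double l1Bound, double alpha,
                    int maxAlt, double tol, int kmeansMaxIter,
                    int nInnerStarts) {
    int n = X.n_rows, p = X.n_cols;
    int nTrim = (int) std::ceil(alpha * n);
    if (nTrim >= n - k) nTrim = std::max(0, n - k - 1);
    arma::vec w(p, arma::fill::value(1.0 / std::sqrt((double) p)));
    std::vector<double> trace;
    arma::ivec labels;
    bool haveLabels = false, converged = false;
    arma::uvec trimmedIdx;
    int nAlt = 0;
    arma::uvec allIdx = arma::regspace<arma::uvec>(0, n - 1);
    for (int alt = 0; alt < maxAlt; ++alt) {
        nAlt = alt + 1;
        arma::mat Xw = X * arma::diagmat(arma::sqrt(w));
        arma::mat warmInit;
        if (haveLabels)
            warmInit = centroids(Xw, labels, allIdx, k);
        // fresh seedings explore in the first alternations; later
        // alternations refine from the warm start only
        int fresh = haveLabels ? ((alt < 3) ? nInnerStarts - 1 : 0)
                               : nInnerStarts;
        LloydResult fit = bestLloyd(Xw, k, haveLabels, warmInit, nTrim,
                                    kmeansMaxIter, fresh);
        labels = fit.labels;
        haveLabels = true;
        if (nTrim > 0) {
            arma::uvec isTrim(n, arma::fill::zeros);
            for (arma::uword t = 0; t < fit.trimmed.n_elem; ++t)
                isTrim(fit.trimmed(t)) = 1;
            arma::uvec keepW = arma::find(isTrim == 0);
            arma::mat centersU = centroids(X, labels, keepW, k);
            arma::vec dU(n);
            for (int i = 0; i < n; ++i) {
                arma::rowvec d = X.row(i) - centersU.row(labels(i));
                dU(i) = arma::dot(d, d);
            }
            arma::uvec trimU = topIdx(dU, nTrim);
            for (arma::uword t = 0; t < trimU.n_elem; ++t)
                isTrim(trimU(t)) = 1;
            trimmedIdx = arma::find(isTrim == 1);
        } else {
            trimmedIdx.reset();
        }
        arma::uvec isOut(n, arma::fill::zeros);
        for (arma::uword t = 0; t < trimmedIdx.n_elem; ++t)
            isOut(trimmedIdx(t)) = 1;
        arma::uvec keep = arma::find(isOut == 0);
        arma::vec bcss = bcssPerFeature(X, labels, keep, k);
        if (bcss.max() <= 0.0)
            stop("zero between-cluster dispersion; input is degenerate");
        // at the maximal bound the lasso penalty is inactive by design:
        // weights stay uniform and the fit is standard (trimmed) k-means
        bool inactive = l1Bound >= std::sqrt((double) p) * (1.0 - 1e-12);
        arma::vec wNew = inactive ? w : updateW(bcss, l1Bound);
        trace.push_back(arma::dot(wNew, bcss));
        double delta = arma::accu(arma::abs(wNew - w)) /
            arma::accu(arma::abs(w));
        w = wNew;
        if (delta < tol) {
            converged = true;
            break;
        }
    }
    // final reinsertion: assign everyone to nearest weighted center
    arma::mat Xw = X * arma::diagmat(arma::sqrt(w));
    arma::uvec isOut(n, arma::fill::zeros);
    for (arma::uword t = 0; t < trimmedIdx.n_elem; ++t)
        isOut(trimmedIdx(t)) = 1;
    arma::uvec keep = arma::find(isOut == 0);
    arma::mat centersW = centroids(Xw, labels, keep, k);
    arma::mat d2 = dist2(Xw, centersW);
    arma::ivec finalLabels(n);
    for (int i = 0; i < n; ++i) {
        arma::uword c;
        d2.row(i).min(c);
        finalLabels(i) = (int) c;
    }
    // guard the no-empty-cluster invariant
    arma::vec cnt(k, arma::fill::zeros);
    for (int i = 0; i < n; ++i) cnt(finalLabels(i)) += 1.0;
    for (int c = 0; c < k; ++c) {
        if (cnt(c) == 0) {
            double worst = -1.0;
            int far = -1;
            for (int i = 0; i < n; ++i) {
                if (cnt(finalLabels(i)) > 1 &&
                    d2(i, finalLabels(i)) > worst) {
                    worst = d2(i, finalLabels(i));
                    far = i;
                }
            }
            cnt(finalLabels(far)) -= 1.0;
            finalLabels(far) = c;
            cnt(c) += 1.0;
        }
    }
    arma::vec bcssKeep = bcssPerFeature(X, labels, keep, k);
    // does any cluster consist of a single kept sample? (its between-SS
    // contribution is untrustworthy — typically an outlier holding a center)
    arma::vec cntKept(k, arma::fill::zeros);
    for (arma::uword ii = 0; ii < keep.n_elem; ++ii)
        cntKept(labels(keep(ii))) += 1.0;
    bool keptSingleton = arma::any(cntKept == 1.0);
    // weighted within-cluster SS over kept samples (trimmed k-means
    // objective; used to pick among robust restarts)
    arma::mat centersK(k, p, arma::fill::zeros);
    arma::vec cntK(k, arma::fill::zeros);
    for (arma::uword ii = 0; ii < keep.n_elem; ++ii) {
        centersK.row(labels(keep(ii))) += X.row(keep(ii));
        cntK(labels(keep(ii))) += 1.0;
    }
    for (int c = 0; c < k; ++c)
        if (cntK(c) > 0) centersK.row(c) /= cntK(c);
    double wssKept = 0.0;
    for (arma::uword ii = 0; ii < keep.n_elem; ++ii) {
        arma::rowvec d = X.row(keep(ii)) - centersK.row(labels(keep(ii)));
        wssKept += arma::dot(arma::square(d), w);
    }
    // weighted total SS over kept samples, for the scale-free fraction
    arma::rowvec muK(p, arma::fill::zeros);
    for (arma::uword ii = 0; ii < keep.n_elem; ++ii)
        muK += X.row(keep(ii));
    muK /= (double) keep.n_elem;
    double tssKept = 0.0;
    for (arma::uword ii = 0; ii < keep.n_elem; ++ii) {
        arma::rowvec d = X.row(keep(ii)) - muK;
        tssKept += arma::dot(arma::square(d), w);
    }
    LogicalVector flags(n, false);
    for (arma::uword t = 0; t < trimmedIdx.n_elem; ++t)
        flags(trimmedIdx(t)) = true;
    return List::create(
        Named("labels") = IntegerVector(finalLabels.begin(),
                                        finalLabels.end()),
        Named("weights") = NumericVector(w.begin(), w.end()),
        Named("flags") = flags,
        Named("objective") = arma::dot(w, bcssKeep),
        Named("wssKept") = wssKept,
        Named("wssFracKept") = (tssKept > 0.0) ? wssKept / tssKept : 1.0,
        Named("keptSingleton") = keptSingleton,
        Named("trace") = NumericVector(trace.begin(), trace.end()),
        Named("nIter") = nAlt,
        Named("converged") = converged);
}

// [[Rcpp::export(name = ".rskcFit")]]
List rskcFit(const arma::mat& X, int k, double l1Bound, double alpha,
             int nStarts, int maxAlt, double tol, int kmeansMaxIter,
             int nInnerStarts) {
    RNGScope scope;
    int nTrim = (int) std::ceil(alpha * X.n_rows);
    List best;
    double bestObj = 0.0;
    for (int s = 0; s < nStarts; ++s) {
        List fit = fitOnce(X, k, l1Bound, alpha, maxAlt, tol, kmeansMaxIter,
                           nInnerStarts);
        // Sparse fits: best restart by the weighted between-cluster
        // objective. Robust fits: by the trimmed weighted unexplained
        // variance fraction (scale-free across weight vectors), with
        // restarts whose kept samples contain a singleton cluster
        // deprioritized — a far-away sample holding its own center defeats
        // the purpose of trimming.
        double score;
        if (nTrim > 0) {
            score = -as<double>(fit["wssFracKept"]);
            if (as<bool>(fit["keptSingleton"])) score -= 100.0;
        } else {
            score = as<double>(fit["objective"]);
        }

        if (s == 0 || score > bestObj) {
            bestObj = score;
            best = fit;
        }
    }
    return best;
}
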