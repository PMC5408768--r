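#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// streaming log(exp(a) + exp(b)); beyond 40 nats the correction is
// below double precision (log1p(exp(-40)) ~ 4e-18), so skip it
static inline double logadd(double a, double b) {
    if (a == NEG_INF) return b;
    if (b == NEG_INF) return a;
    double m, d;
    if (a > b) { m = a; d = a - b; } else { m = b; d = b - a; }
    if (d > 40.0) return m;
    return m + std::log1p(std::exp(-d));
}

// Log-space forward-backward over the truncated sparse successor table.
// logemit: S x n (state-major, one contiguous column per event);
// nbr: S x M 0-based successor indices (-1 padding); nbr_logp: matching
// log transition probabilities; frac0/1/2: per-edge shift-class mass
// fractions. Returns total log-likelihood, n x S state posteriors and
// expected transition mass per shift class.
// [[Rcpp::export]]
List fb_core(NumericMatrix logemit, IntegerMatrix nbr,
             NumericMatrix nbr_logp, NumericMatrix frac0,
             NumericMatrix frac1, NumericMatrix frac2) {
    const int S = logemit.nrow(), n = logemit.ncol(), M = nbr.ncol();
    const double *em = REAL(logemit);
    const int *nb = INTEGER(nbr);
    const double *lp = REAL(nbr_logp);
    const double *f0 = REAL(frac0), *f1 = REAL(frac1), *f2 = REAL(frac2);
    std::vector<double> alpha((size_t) S * n), beta((size_t) S * n);
    const double log_unif = -std::log((double) S);

    for (int j = 0; j < S; ++j) alpha[j] = log_unif + em[j];
    for (int t = 1; t < n; ++t) {
        double *cur = &alpha[(size_t) S * t];
        const double *prev = &alpha[(size_t) S * (t - 1)];
        const double *emt = em + (size_t) S * t;
        for (int j = 0; j < S; ++j) cur[j] = NEG_INF;
        for (int m = 0; m < M; ++m) {
            const int *nbc = nb + (size_t) S * m;
            const double *lpc = lp + (size_t) S * m;
            for (int i = 0; i < S; ++i) {
                int j = nbc[i];
                if (j < 0 || prev[i] == NEG_INF) continue;
                cur[j] = logadd(cur[j], prev[i] + lpc[i]);
            }
        }
        bool any_finite = false;
        for (int j = 0; j < S; ++j) {
            cur[j] += emt[j];
            if (cur[j] != NEG_INF) any_finite = true;
        }
        if (!any_finite)
            stop("numerical underflow in forward pass at event %d", t + 1);
    }
    double loglik = NEG_INF;
    {
        const double *last = &alpha[(size_t) S * (n - 1)];
        for (int j = 0; j < S; ++j) loglik = logadd(loglik, last[j]);
    }
    if (!R_finite(loglik)) stop("non-finite forward log-likelihood");

    for (int j = 0; j < S; ++j) beta[(size_t) S * (n - 1) + j] = 0.0;
    for (int t = n - 2; t >= 0; --t) {
        double *cur = &beta[(size_t) S * t];
        const double *nxt = &beta[(size_t) S * (t + 1)];
        const double *emt = em + (size_t) S * (t + 1);
        for (int i = 0; i < S; ++i) cur[i] = NEG_INF;
        for (int m = 0; m < M; ++m) {
            const int *nbc = nb + (size_t) S * m;
            const double *lpc = lp + (size_t) S * m;
            for (int i = 0; i < S; ++i) {
                int j = nbc[i];
                if (j < 0) continue;
                cur[i] = logadd(cur[i], lpc[i] + emt[j] + nxt[j]);
            }
        }
    }

    // posterior returned event-major (n x S) for direct use from R
    NumericMatrix post(n, S);
    double *po = REAL(post);
    for (int t = 0; t < n; ++t) {
        const double *a = &alpha[(size_t) S * t];
        const double *b = &beta[(size_t) S * t];
        for (int j = 0; j < S; ++j)
            po[(size_t) n * j + t] = std::exp(a[j] + b[j] - loglik);
    }

    NumericVector mass(3);
    double m0 = 0, m1 = 0, m2 = 0;
    for (int t = 0; t < n - 1; ++t) {
        const double *a = &alpha[(size_t) S * t];
        const double *nxt = &beta[(size_t) S * (t + 1)];
        const double *emt = em + (size_t) S * (t + 1);
        for (int m = 0; m < M; ++m) {
            const int *nbc = nb + (size_t) S * m;
            const double *lpc = lp + (size_t) S * m;
            const double *g0 = f0 + (size_t) S * m;
            const double *g1 = f1 + (size_t) S * m;
            const double *g2 = f2 + (size_t) S * m;
            for (int i = 0; i < S; ++i) {
                int j = nbc[i];
                if (j < 0 || a[i] == NEG_INF) continue;
                double lx = a[i] + lpc[i] + emt[j] + nxt[j] - loglik;
                if (lx < -40.0) continue;   // below double resolution
                double xi = std::exp(lx);
                m0 += xi * g0[i];
                m1 += xi * g1[i];
                m2 += xi * g2[i];
            }
        }
    }
    mass[0] = m0; mass[1] = m1; mass[2] = m2;

    return List::create(_["loglik"] = loglik, _["posterior"] = post,
                        _["shift_mass"] = mass);
}

// Forward pass only: total log-likelihood without posteriors, for cheap
// likelihood scoring (e.g. choosing an EM starting point). logemit S x n.
// [[Rcpp::export]]
double forward_loglik_core(NumericMatrix logemit, IntegerMatrix nbr,
                           NumericMatrix nbr_logp) {
    const int S = logemit.nrow(), n = logemit.ncol(), M = nbr.ncol();
    const double *em = REAL(logemit);
    const int *nb = INTEGER(nbr);
    const double *lp = REAL(nbr_logp);
    std::vector<double> prev(S), cur(S);
    const double log_unif = -std::log((double) S);

    for (int j = 0; j < S; ++j) prev[j] = log_unif + em[j];
    for (int t = 1; t < n; ++t) {
        const double *emt = em + (size_t) S * t;
        for (int j = 0; j < S; ++j) cur[j] = NEG_INF;
        for (int m = 0; m < M; ++m) {
            const int *nbc = nb + (size_t) S * m;
            const double *lpc = lp + (size_t) S * m;
            for (int i = 0; i < S; ++i) {
                int j = nbc[i];
                if (j < 0 || prev[i] == NEG_INF) continue;
                cur[j] = logadd(cur[j], prev[i] + lpc[i]);
            }
        }
        bool any_finite = false;
        for (int j = 0; j < S; ++j) {
            prev[j] = cur[j] + emt[j];
            if (prev[j] != NEG_INF) any_finite = true;
        }
        if (!any_finite)
            stop("numerical underflow in forward pass at event %d", t + 1);
    }
    double loglik = NEG_INF;
    for (int j = 0; j < S; ++j) loglik = logadd(loglik, prev[j]);
    return loglik;
}

// Max-product Viterbi over the same sparse structure; logemit is S x n.
// Ties are broken toward the numerically smallest predecessor state
// (predecessors are scanned in ascending order with strict improvement).
// Returns the 0-based state path and the joint log-probability from the
// last DP column.
// [[Rcpp::export]]
List viterbi_core(NumericMatrix logemit, IntegerMatrix nbr,
                  NumericMatrix nbr_logp) {
    const int S = logemit.nrow(), n = logemit.ncol(), M = nbr.ncol();
    const double *em = REAL(logemit);
    const int *nb = INTEGER(nbr);
    const double *lp = REAL(nbr_logp);
    std::vector<double> prev(S), cur(S);
    std::vector<int> bp((size_t) S * n, -1);
    const double log_unif = -std::log((double) S);

    for (int j = 0; j < S; ++j) prev[j] = log_unif + em[j];
    for (int t = 1; t < n; ++t) {
        const double *emt = em + (size_t) S * t;
        int *bpt = &bp[(size_t) S * t];
        for (int j = 0; j < S; ++j) cur[j] = NEG_INF;
        for (int i = 0; i < S; ++i) {
            if (prev[i] == NEG_INF) continue;
            const double base = prev[i];
            for (int m = 0; m < M; ++m) {
                int j = nb[(size_t) S * m + i];
                if (j < 0) continue;
                double v = base + lp[(size_t) S * m + i];
                if (v > cur[j]) { cur[j] = v; bpt[j] = i; }
            }
        }
        bool any_finite = false;
        for (int j = 0; j < S; ++j) {
            cur[j] += emt[j];
            if (cur[j] != NEG_INF) any_finite = true;
            prev[j] = cur[j];
        }
        if (!any_finite)
            stop("numerical underflow in Viterbi at event %d", t + 1);
    }

    int best = 0;
    for (int j = 1; j < S; ++j)
        if (prev[j] > prev[best]) best = j;
    IntegerVector path(n);
    path[n - 1] = best;
    for (int t = n - 1; t > 0; --t) path[t - 1] = bp[(size_t) S * t + path[t]];

    return List::create(_["path"] = path, _["logp"] = prev[best]);
}
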