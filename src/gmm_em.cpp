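#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093453;
static const double SD_FLOOR = 1e-10;

struct Em2State {
    double m1, m2, s1, s2, w1, w2;
    double ll;
    bool collapsed;
    bool converged;
};

// Run EM for a 1-D two-component Gaussian mixture from the given state for
// at most `iters` iterations. Convergence: either the per-iteration
// log-likelihood gain falls below `tol`, or the Aitken-accelerated estimate
// of the remaining asymptotic gain does (plain increments crawl when the
// two components overlap).
static void em2Run(const NumericVector& x, std::vector<double>& g,
                   Em2State& st, int iters, double tol) {
    const int n = x.size();
    double ll = st.ll, llPrev1 = R_NegInf, llPrev2 = R_NegInf;
    for (int it = 0; it < iters; ++it) {
        double llNew = 0.0, n1 = 0.0, sum1 = 0.0, sum2 = 0.0;
        const double c1 = std::log(st.w1) - std::log(st.s1) - 0.5 * LOG_2PI;
        const double c2 = std::log(st.w2) - std::log(st.s2) - 0.5 * LOG_2PI;
        const double i1 = 1.0 / st.s1, i2 = 1.0 / st.s2;
        for (int i = 0; i < n; ++i) {
            const double z1 = (x[i] - st.m1) * i1;
            const double z2 = (x[i] - st.m2) * i2;
            const double l1 = c1 - 0.5 * z1 * z1;
            const double l2 = c2 - 0.5 * z2 * z2;
            double gi;
            if (l1 > l2) {
                const double e = std::exp(l2 - l1);
                gi = 1.0 / (1.0 + e);
                llNew += l1 + std::log1p(e);
            } else {
                const double e = std::exp(l1 - l2);
                gi = e / (1.0 + e);
                llNew += l2 + std::log1p(e);
            }
            g[i] = gi;
            n1 += gi;
            sum1 += gi * x[i];
            sum2 += (1.0 - gi) * x[i];
        }
        const double n2 = n - n1;
        if (n1 < 1e-8 || n2 < 1e-8) { st.collapsed = true; break; }
        st.m1 = sum1 / n1;
        st.m2 = sum2 / n2;
        double v1 = 0.0, v2 = 0.0;
        for (int i = 0; i < n; ++i) {
            const double d1 = x[i] - st.m1, d2 = x[i] - st.m2;
            v1 += g[i] * d1 * d1;
            v2 += (1.0 - g[i]) * d2 * d2;
        }
        st.s1 = std::max(std::sqrt(v1 / n1), SD_FLOOR);
        st.s2 = std::max(std::sqrt(v2 / n2), SD_FLOOR);
        st.w1 = n1 / n;
        st.w2 = n2 / n;
        llPrev2 = llPrev1;
        llPrev1 = ll;
        ll = llNew;
        if (R_finite(llPrev1) && ll - llPrev1 < tol) {
            st.converged = true;
            break;
        }
        if (R_finite(llPrev2)) {
            const double d1 = llPrev1 - llPrev2, d2 = ll - llPrev1;
            if (d1 > 0.0) {
                const double a = d2 / d1;
                if (a < 1.0 && d2 * a / (1.0 - a) < tol) {
                    st.converged = true;
                    break;
                }
            }
        }
    }
    st.ll = ll;
}

// Best-of-several-starts EM ("small-EM" initialization): every start is
// burnt in for a few iterations, then only the most promising one is run
// to convergence. Collapsed solutions (a component shrinking onto a point,
// driving the likelihood unbounded) are rejected.
// [[Rcpp::export(name = ".em2Best")]]
List em2Best(NumericVector x, NumericMatrix mu0, NumericMatrix sd0,
             NumericMatrix w0, double tol, int maxIter, int burnIn = 50) {
    const int nStarts = mu0.ncol();
    std::vector<double> g(x.size());
    std::vector<Em2State> states(nStarts);
    for (int r = 0; r < nStarts; ++r) {
        Em2State st = {mu0(0, r), mu0(1, r),
                       std::max(sd0(0, r), SD_FLOOR),
                       std::max(sd0(1, r), SD_FLOOR),
                       w0(0, r), w0(1, r), R_NegInf, false, false};
        em2Run(x, g, st, std::min(burnIn, maxIter), tol);
        states[r] = st;
    }
    // continue the best surviving start; fall back to the next best if the
    // continuation collapses
    std::vector<int> order;
    for (int r = 0; r < nStarts; ++r)
        if (!states[r].collapsed) order.push_back(r);
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return states[a].ll > states[b].ll; });
    for (int idx : order) {
        Em2State st = states[idx];
        if (!st.converged)
            em2Run(x, g, st, maxIter - std::min(burnIn, maxIter), tol);
        if (st.collapsed || st.s1 <= 1e-9 || st.s2 <= 1e-9 ||
            !R_finite(st.ll))
            continue;
        return List::create(_["ok"] = true,
            _["weights"] = NumericVector::create(st.w1, st.w2),
            _["means"] = NumericVector::create(st.m1, st.m2),
            _["sds"] = NumericVector::create(st.s1, st.s2),
            _["loglik"] = st.ll);
    }
    return List::create(_["ok"] = false);
}
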