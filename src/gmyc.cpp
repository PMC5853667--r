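// Single-threshold GMYC mixed-model likelihood and profile optimizer.
//
// The tree's n-1 node ages are ordered (descending); the K = n-2
// inter-event intervals each end with a branching event.  With a threshold
// age T, every branch is classified by the age of its subtending (parent)
// node: older than T -> diversification (Yule-like) class, younger ->
// coalescent class inside its cluster.  During interval i the total
// branching rate is
//   b_i = lam_div * A_i^p_div + lam_coal * sum_j (c_ij (c_ij - 1))^p_coal
// where A_i counts diversification-class branches and c_ij counts sampled
// branches inside cluster j.  logL = sum_i [log b_i - b_i * x_i]; zero
// length intervals (tied node ages) contribute only the log-rate term.
//
// R precomputes, per candidate threshold, A (length K), the unique positive
// values ug of c(c-1) and the multiplicity matrix M (K x length(ug)); the
// profile over thresholds and the bounded 4-parameter optimization run here.

#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <cmath>

using namespace Rcpp;

static const double L_LO = 1e-8, L_HI = 1e3;  // rate bounds
static const double P_LO = 0.0, P_HI = 3.0;   // scaling-exponent bounds
// (the single-class null needs exponents above 2 to track coalescent
// n(n-1) growth; capping at 2 handicaps the null and inflates the LR)
static const double BIG = 1e10;

static inline double sig(double u) { return 1.0 / (1.0 + std::exp(-u)); }
static inline double box(double u, double lo, double hi) {
    return lo + (hi - lo) * sig(u);
}
static inline double lbox(double u, double lo, double hi) {
    return std::exp(std::log(lo) + (std::log(hi) - std::log(lo)) * sig(u));
}
static inline double unbox(double x, double lo, double hi) {
    double p = (x - lo) / (hi - lo);
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    return std::log(p / (1.0 - p));
}
static inline double unlbox(double x, double lo, double hi) {
    if (x < lo) x = lo;
    if (x > hi) x = hi;
    double p = (std::log(x) - std::log(lo)) / (std::log(hi) - std::log(lo));
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    return std::log(p / (1.0 - p));
}

struct GmycCtx {
    const double* x;    // interval durations, length K
    const double* A;    // diversification-class counts, length K
    const double* M;    // K x U multiplicities (column-major)
    const double* ug;   // unique c(c-1) values, length U
    int K, U;
    std::vector<double> powu;  // scratch, length U
};

static double gmyc_loglik_raw(GmycCtx* c, double ld, double pd,
                              double lc, double pc) {
    for (int u = 0; u < c->U; ++u) c->powu[u] = std::pow(c->ug[u], pc);
    double ll = 0.0;
    for (int i = 0; i < c->K; ++i) {
        double coal = 0.0;
        for (int u = 0; u < c->U; ++u) coal += c->M[i + (size_t)c->K * u] * c->powu[u];
        double div = (c->A[i] > 0.0) ? std::pow(c->A[i], pd) : 0.0;
        double b = ld * div + lc * coal;
        if (!(b > 0.0)) return R_NegInf;
        ll += std::log(b) - b * c->x[i];
    }
    return ll;
}

static double gmyc_obj(int np, double* u, void* ex) {
    GmycCtx* c = (GmycCtx*)ex;
    double ll = gmyc_loglik_raw(c, lbox(u[0], L_LO, L_HI), box(u[1], P_LO, P_HI),
                                lbox(u[2], L_LO, L_HI), box(u[3], P_LO, P_HI));
    if (!R_finite(ll)) return BIG;
    return -ll;
}

// [[Rcpp::export]]
double cpp_gmyc_loglik(NumericVector x, NumericVector A, NumericMatrix M,
                       NumericVector ug, double lam_div, double p_div,
                       double lam_coal, double p_coal) {
    GmycCtx c;
    c.x = x.begin(); c.A = A.begin(); c.M = M.begin(); c.ug = ug.begin();
    c.K = x.size(); c.U = ug.size();
    c.powu.resize(c.U);
    return gmyc_loglik_raw(&c, lam_div, p_div, lam_coal, p_coal);
}

// Profile fit over candidate thresholds.  thr_data is a list with one
// element per candidate: list(A = numeric(K), M = matrix(K x U), ug =
// numeric(U)).  det_start: c(lam, p) from the null single-process fit, used
// as the deterministic collapse start.  Returns nT x 5 matrix:
// logL, lam_div, p_div, lam_coal, p_coal.
// [[Rcpp::export]]
NumericMatrix cpp_gmyc_profile(NumericVector x, List thr_data,
                               NumericVector det_start, int n_starts,
                               int maxit) {
    int nT = thr_data.size();
    int K = x.size();
    NumericMatrix out(nT, 5);
    double u_det[4] = { unlbox(det_start[0], L_LO, L_HI),
                        unbox(det_start[1], P_LO, P_HI),
                        unlbox(det_start[0], L_LO, L_HI),
                        unbox(det_start[1], P_LO, P_HI) };
    std::vector<double> warm(4);
    bool have_warm = false;
    for (int t = 0; t < nT; ++t) {
        List td = thr_data[t];
        NumericVector A = td["A"];
        NumericMatrix M = td["M"];
        NumericVector ug = td["ug"];
        GmycCtx c;
        c.x = x.begin(); c.A = A.begin(); c.M = M.begin(); c.ug = ug.begin();
        c.K = K; c.U = ug.size();
        c.powu.resize(c.U);

        double best = BIG, bu[4];
        std::vector<std::vector<double> > starts;
        starts.push_back(std::vector<double>(u_det, u_det + 4));
        if (have_warm) starts.push_back(warm);
        while ((int)starts.size() < n_starts)
            { std::vector<double> r(4); for (int j = 0; j < 4; ++j) r[j] = R::runif(-3.0, 3.0); starts.push_back(r); }
        std::vector<double> xout(4);
        for (size_t s = 0; s < starts.size(); ++s) {
            std::vector<double> xin(starts[s]);
            double f0 = gmyc_obj(4, &xin[0], &c);
            if (f0 < best) { best = f0; for (int j = 0; j < 4; ++j) bu[j] = xin[j]; }
            double fmin; int fail = 0, fncount = 0;
            nmmin(4, &xin[0], &xout[0], &fmin, gmyc_obj, &fail, -BIG, 1e-10,
                  &c, 1.0, 0.5, 2.0, 0, &fncount, maxit);
            if (fmin < best) { best = fmin; for (int j = 0; j < 4; ++j) bu[j] = xout[j]; }
        }
        warm.assign(bu, bu + 4);
        have_warm = true;
        out(t, 0) = -best;
        out(t, 1) = lbox(bu[0], L_LO, L_HI);
        out(t, 2) = box(bu[1], P_LO, P_HI);
        out(t, 3) = lbox(bu[2], L_LO, L_HI);
        out(t, 4) = box(bu[3], P_LO, P_HI);
        if ((t & 15) == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
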