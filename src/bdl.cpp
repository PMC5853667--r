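// Birth-death likelihood (BDL) machinery on branching times.
//
// Conventions (shared by every model, the fitters, the null simulator and
// the R-level oracles used in the tests):
//  * branching times b[0] >= b[1] >= ... >= b[m-1] are ages (Ma before
//    present) of the m = n-1 internal nodes of the crown group; b[0] is the
//    crown age.
//  * all likelihoods are conditioned on the crown age; models with
//    extinction are additionally conditioned on survival of both crown
//    lineages to the present (the reconstructed-process form).  For the
//    pure-birth class this reduces to the product of inter-event
//    waiting-time densities with total rate R_k while k lineages are
//    extant, times the terminal no-event (survival) factor exp(-R_n * b[m-1]).
//  * rates are events per lineage per Myr; time-varying rates are functions
//    of forward time t since the crown (t = crown_age - age).

#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <cmath>
#include <cfloat>

using namespace Rcpp;

static const double RATE_LO = 1e-6, RATE_HI = 10.0;
static const double A_LO = 0.0, A_HI = 0.99;
static const double EXP_LO = 0.0, EXP_HI = 5.0;
static const double MU_LO = 0.0, MU_HI = 10.0;
static const double BIG = 1e10;

// ---- bounded transforms (unconstrained u <-> box (lo,hi)) ----------------
static inline double sig(double u) { return 1.0 / (1.0 + std::exp(-u)); }
static inline double box(double u, double lo, double hi) {
    return lo + (hi - lo) * sig(u);
}
static inline double unbox(double x, double lo, double hi) {
    double p = (x - lo) / (hi - lo);
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    return std::log(p / (1.0 - p));
}
// log-scale box for rates spanning orders of magnitude
static inline double lbox(double u, double lo, double hi) {
    return std::exp(std::log(lo) + (std::log(hi) - std::log(lo)) * sig(u));
}
static inline double unlbox(double x, double lo, double hi) {
    if (x < lo) x = lo;
    if (x > hi) x = hi;
    double p = (std::log(x) - std::log(lo)) / (std::log(hi) - std::log(lo));
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    return std::log(p / (1.0 - p));
}
static inline double clip(double x, double lo, double hi) {
    return x < lo ? lo : (x > hi ? hi : x);
}

// self-contained Brent minimizer on [ax, bx]
static double brent_min(double ax, double bx, double (*f)(double, void*),
                        void* info, double tol) {
    const double c = 0.5 * (3.0 - std::sqrt(5.0));
    double a = ax, b = bx;
    double x = a + c * (b - a), w = x, v = x;
    double fx = f(x, info), fw = fx, fv = fx;
    double d = 0.0, e = 0.0;
    for (int iter = 0; iter < 200; ++iter) {
        double xm = 0.5 * (a + b);
        double tol1 = tol * std::fabs(x) + 1e-12;
        double tol2 = 2.0 * tol1;
        if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
        double p = 0.0, q = 0.0, r = 0.0;
        bool golden = true;
        if (std::fabs(e) > tol1) {
            r = (x - w) * (fx - fv);
            q = (x - v) * (fx - fw);
            p = (x - v) * q - (x - w) * r;
            q = 2.0 * (q - r);
            if (q > 0.0) p = -p;
            q = std::fabs(q);
            if (std::fabs(p) < std::fabs(0.5 * q * e) && p > q * (a - x) &&
                p < q * (b - x)) {
                e = d; d = p / q;
                double u = x + d;
                if (u - a < tol2 || b - u < tol2) d = (xm > x) ? tol1 : -tol1;
                golden = false;
            }
        }
        if (golden) { e = (x < xm) ? b - x : a - x; d = c * e; }
        double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0.0) ? tol1 : -tol1);
        double fu = f(u, info);
        if (fu <= fx) {
            if (u < x) b = x; else a = x;
            v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
        } else {
            if (u < x) a = u; else b = u;
            if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
            else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
        }
    }
    return x;
}

// ---- pure birth ----------------------------------------------------------
// total lineage-Myr weighted exposure S = sum_k k * w_k (k = 2..n, terminal
// included); telescopes to b[0] + sum(b).
static double exposure_sum(const double* b, int m) {
    double S = b[0];
    for (int i = 0; i < m; ++i) S += b[i];
    return S;
}

static double loglik_pb(const double* b, int m, double r) {
    int n = m + 1;
    return std::lgamma((double)n) + (n - 2) * std::log(r) - r * exposure_sum(b, m);
}

// ---- constant birth-death (Nee et al. reconstructed process) -------------
static double loglik_bd(const double* b, int m, double r, double a) {
    int n = m + 1;
    double ll = std::lgamma((double)n) + (n - 2) * std::log(r) + n * std::log1p(-a);
    for (int i = 1; i < m; ++i) ll += r * b[i];
    for (int i = 0; i < m; ++i) {
        // log(exp(r*b) - a) computed stably as r*b + log1p(-a*exp(-r*b))
        ll -= 2.0 * (r * b[i] + std::log1p(-a * std::exp(-r * b[i])));
    }
    return ll;
}

struct BdCtx { const double* b; int m; };
static double bd_obj(int np, double* u, void* ex) {
    BdCtx* c = (BdCtx*)ex;
    double r = lbox(u[0], RATE_LO, RATE_HI);
    double a = box(u[1], A_LO, A_HI);
    double ll = loglik_bd(c->b, c->m, r, a);
    if (!R_finite(ll)) return BIG;
    return -ll;
}

// ---- yule2rate: pure birth with one rate shift at age st -----------------
// r1 applies to ages > st, r2 to ages < st; closed-form profile MLEs for
// (r1, r2) given st.
static double y2r_profile(const double* b, int m, double st,
                          double* r1o, double* r2o) {
    int n = m + 1;
    double E1 = 0.0, E2 = 0.0;
    for (int k = 2; k <= n; ++k) {
        double hi = b[k - 2];
        double lo = (k == n) ? 0.0 : b[k - 1];
        double older = hi - std::max(lo, st);
        if (older < 0.0) older = 0.0;
        double younger = (hi - lo) - older;
        E1 += k * older;
        E2 += k * younger;
    }
    int m1 = 0;
    for (int i = 1; i < m; ++i) if (b[i] > st) ++m1;
    int m2 = (n - 2) - m1;
    double r1 = (E1 > 0.0 && m1 > 0) ? clip(m1 / E1, RATE_LO, RATE_HI) : RATE_LO;
    double r2 = (E2 > 0.0 && m2 > 0) ? clip(m2 / E2, RATE_LO, RATE_HI) : RATE_LO;
    double ll = std::lgamma((double)n) + m1 * std::log(r1) + m2 * std::log(r2)
        - r1 * E1 - r2 * E2;
    *r1o = r1; *r2o = r2;
    return ll;
}

static double loglik_y2r(const double* b, int m, double r1, double r2, double st) {
    int n = m + 1;
    double E1 = 0.0, E2 = 0.0;
    for (int k = 2; k <= n; ++k) {
        double hi = b[k - 2];
        double lo = (k == n) ? 0.0 : b[k - 1];
        double older = hi - std::max(lo, st);
        if (older < 0.0) older = 0.0;
        E1 += k * older;
        E2 += k * ((hi - lo) - older);
    }
    int m1 = 0;
    for (int i = 1; i < m; ++i) if (b[i] > st) ++m1;
    int m2 = (n - 2) - m1;
    return std::lgamma((double)n) + m1 * std::log(r1) + m2 * std::log(r2)
        - r1 * E1 - r2 * E2;
}

// shift-time candidate grid: interior branching times (two oldest and the
// single youngest event excluded) plus midpoints of consecutive candidates.
static std::vector<double> y2r_grid(const double* b, int m) {
    std::vector<double> g;
    for (int i = 2; i < m - 1; ++i) {  // b[2] .. b[m-2]
        g.push_back(b[i]);
        if (i + 1 < m - 1) g.push_back(0.5 * (b[i] + b[i + 1]));
    }
    return g;
}

// ---- density-dependent: DDL (linear) and DDX (exponential) ---------------
// DDL: per-lineage rate r1*(1 - k/kappa); DDX: r1*k^(-x).  Total rate while
// k lineages extant is k * per-lineage rate.  Closed-form r1 given shape.
static double ddl_profile(const double* b, int m, double kappa, double* r1o) {
    int n = m + 1;
    if (kappa <= n) { *r1o = NA_REAL; return -BIG; }
    double S = 0.0, C = 0.0;
    for (int k = 2; k <= n; ++k) {
        double hi = b[k - 2];
        double lo = (k == n) ? 0.0 : b[k - 1];
        S += k * (1.0 - k / kappa) * (hi - lo);
        if (k <= n - 1) C += std::log(k * (1.0 - k / kappa));
    }
    double r1 = clip((n - 2) / S, RATE_LO, RATE_HI);
    *r1o = r1;
    return C + (n - 2) * std::log(r1) - r1 * S;
}

static double loglik_ddl(const double* b, int m, double r1, double kappa) {
    int n = m + 1;
    double S = 0.0, C = 0.0;
    for (int k = 2; k <= n; ++k) {
        double rate = 1.0 - k / kappa;
        if (rate <= 0.0) return R_NegInf;
        double hi = b[k - 2];
        double lo = (k == n) ? 0.0 : b[k - 1];
        S += k * rate * (hi - lo);
        if (k <= n - 1) C += std::log(k * rate);
    }
    return C + (n - 2) * std::log(r1) - r1 * S;
}

static double ddx_profile(const double* b, int m, double x, double* r1o) {
    int n = m + 1;
    double S = 0.0;
    for (int k = 2; k <= n; ++k) {
        double hi = b[k - 2];
        double lo = (k == n) ? 0.0 : b[k - 1];
        S += std::pow((double)k, 1.0 - x) * (hi - lo);
    }
    double r1 = clip((n - 2) / S, RATE_LO, RATE_HI);
    *r1o = r1;
    return (1.0 - x) * std::lgamma((double)n) + (n - 2) * std::log(r1) - r1 * S;
}

static double loglik_ddx(const double* b, int m, double r1, double x) {
    int n = m + 1;
    double S = 0.0;
    for (int k = 2; k <= n; ++k) {
        double hi = b[k - 2];
        double lo = (k == n) ? 0.0 : b[k - 1];
        S += std::pow((double)k, 1.0 - x) * (hi - lo);
    }
    return (1.0 - x) * std::lgamma((double)n) + (n - 2) * std::log(r1) - r1 * S;
}

struct Dd1Ctx { const double* b; int m; };
static double ddl_obj1(double u, void* ex) {
    Dd1Ctx* c = (Dd1Ctx*)ex;
    double kappa = (c->m + 1) + std::exp(u);
    double r1;
    return -ddl_profile(c->b, c->m, kappa, &r1);
}
static double ddx_obj1(double x, void* ex) {
    Dd1Ctx* c = (Dd1Ctx*)ex;
    double r1;
    return -ddx_profile(c->b, c->m, x, &r1);
}

// ---- time-varying rates: SPVAR / EXVAR / BOTHVAR -------------------------
// lambda(t) = lam0 * exp(-k*t);  mu(t) = muf * (1 - exp(-z*t))  (t forward
// from the crown; SPVAR uses constant mu = muf, EXVAR constant lambda).
// Generalized reconstructed-process (Nee-type) likelihood:
//   rho(x)  = int_0^x (mu - lambda) over ages
//   F(x)    = exp(-rho(x)) + int_0^x mu(a) exp(-rho(a)) da
//   logL    = lgamma(n) + sum_{non-crown} [log lambda(b_i) - rho(b_i)]
//             - 2 * sum_{all ages} log F(b_i)
// The F integral is evaluated by composite Gauss-Legendre quadrature on the
// inter-age segments (nsub subdivisions per segment).

enum TvVariant { SPVAR = 1, EXVAR = 2, BOTHVAR = 3 };

struct TvPar {
    double lam0, k, muf, z, T;
    int variant;
    double lam_age(double x) const {  // lambda at age x
        double t = T - x;
        return (variant == EXVAR) ? lam0 : lam0 * std::exp(-k * t);
    }
    double mu_age(double x) const {
        double t = T - x;
        if (variant == SPVAR) return muf;
        return muf * (1.0 - std::exp(-z * t));
    }
    double Lam(double x) const {  // int_0^x lambda over ages
        if (variant == EXVAR || k < 1e-12) return lam0 * x;
        return lam0 * std::exp(-k * T) * (std::exp(k * x) - 1.0) / k;
    }
    double Mint(double x) const {  // int_0^x mu over ages
        if (variant == SPVAR) return muf * x;
        if (z < 1e-12) return 0.0;
        return muf * (x - std::exp(-z * T) * (std::exp(z * x) - 1.0) / z);
    }
    double rho(double x) const { return Mint(x) - Lam(x); }
};

// 5-point Gauss-Legendre nodes/weights on [-1, 1]
static const int GL_N = 5;
static const double GL_X[5] = {
    -0.9061798459386640, -0.5384693101056831, 0.0,
    0.5384693101056831, 0.9061798459386640 };
static const double GL_W[5] = {
    0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
    0.4786286704993665, 0.2369268850561891 };

static double loglik_tv(const double* b, int m, const TvPar& p, int nsub) {
    int n = m + 1;
    // ascending ages with 0 prepended
    std::vector<double> asc(m + 1);
    asc[0] = 0.0;
    for (int i = 0; i < m; ++i) asc[i + 1] = b[m - 1 - i];
    // cumulative G(x) = int_0^x mu(a) exp(-rho(a)) da at each asc[i]
    std::vector<double> G(m + 1, 0.0);
    bool has_mu = (p.muf > 0.0) && !(p.variant != SPVAR && p.z < 1e-12);
    if (has_mu) {
        double acc = 0.0;
        for (int i = 1; i <= m; ++i) {
            double lo = asc[i - 1], hi = asc[i];
            double seg = (hi - lo) / nsub;
            for (int s = 0; s < nsub; ++s) {
                double a0 = lo + s * seg, a1 = a0 + seg;
                double c = 0.5 * (a0 + a1), h = 0.5 * (a1 - a0);
                double val = 0.0;
                for (int q = 0; q < GL_N; ++q) {
                    double x = c + h * GL_X[q];
                    double e = -p.rho(x);
                    if (e > 700.0) return R_NegInf;  // overflow guard
                    val += GL_W[q] * p.mu_age(x) * std::exp(e);
                }
                acc += h * val;
            }
            G[i] = acc;
        }
    }
    double ll = std::lgamma((double)n);
    for (int i = 0; i <= m; ++i) {
        if (i >= 1) {  // an actual branching age asc[i] = some b_j
            double x = asc[i];
            double e = -p.rho(x);
            if (e > 700.0) return R_NegInf;
            double F = std::exp(e) + G[i];
            if (!(F > 0.0)) return R_NegInf;
            ll -= 2.0 * std::log(F);
            if (x < b[0] || (x == b[0] && i < m)) {
                // non-crown node (the crown age appears once, as asc[m])
                double lam = p.lam_age(x);
                if (!(lam > 0.0)) return R_NegInf;
                ll += std::log(lam) - p.rho(x);
            }
        }
    }
    return ll;
}

struct TvCtx { const double* b; int m; int variant; double T; int nsub; };
static double tv_obj(int np, double* u, void* ex) {
    TvCtx* c = (TvCtx*)ex;
    TvPar p;
    p.T = c->T; p.variant = c->variant;
    if (c->variant == SPVAR) {
        p.lam0 = lbox(u[0], RATE_LO, RATE_HI);
        p.k = box(u[1], EXP_LO, EXP_HI);
        p.muf = box(u[2], MU_LO, MU_HI);
        p.z = 0.0;
    } else if (c->variant == EXVAR) {
        p.lam0 = lbox(u[0], RATE_LO, RATE_HI);
        p.muf = box(u[1], MU_LO, MU_HI);
        p.z = box(u[2], EXP_LO, EXP_HI);
        p.k = 0.0;
    } else {
        p.lam0 = lbox(u[0], RATE_LO, RATE_HI);
        p.k = box(u[1], EXP_LO, EXP_HI);
        p.muf = box(u[2], MU_LO, MU_HI);
        p.z = box(u[3], EXP_LO, EXP_HI);
    }
    double ll = loglik_tv(c->b, c->m, p, c->nsub);
    if (!R_finite(ll)) return BIG;
    return -ll;
}

// ---- generic Nelder-Mead driver over multiple starts ---------------------
static double nm_multistart(int np, optimfn fn, void* ex,
                            const std::vector<std::vector<double> >& starts,
                            double* best_u, int maxit) {
    double best = BIG;
    std::vector<double> xout(np);
    for (size_t s = 0; s < starts.size(); ++s) {
        std::vector<double> xin(starts[s]);
        double f0 = fn(np, &xin[0], ex);
        if (f0 < best) { best = f0; for (int j = 0; j < np; ++j) best_u[j] = xin[j]; }
        double fmin; int fail = 0, fncount = 0;
        nmmin(np, &xin[0], &xout[0], &fmin, fn, &fail, -BIG, 1e-9, ex,
              1.0, 0.5, 2.0, 0, &fncount, maxit);
        if (fmin < best) { best = fmin; for (int j = 0; j < np; ++j) best_u[j] = xout[j]; }
    }
    return best;
}

static std::vector<double> rand_start(int np) {
    std::vector<double> u(np);
    for (int j = 0; j < np; ++j) u[j] = R::runif(-3.0, 3.0);
    return u;
}

// ---- model fits ----------------------------------------------------------
struct Fit {
    double logL, aic;
    double par[4];  // meaning depends on model
    int npar;
};

static Fit fit_pb(const double* b, int m) {
    int n = m + 1;
    double S = exposure_sum(b, m);
    double r = clip((n - 2) / S, RATE_LO, RATE_HI);
    Fit f; f.logL = loglik_pb(b, m, r); f.npar = 1;
    f.aic = 2.0 * f.npar - 2.0 * f.logL;
    f.par[0] = r;
    return f;
}

static Fit fit_bd(const double* b, int m, int n_starts, int maxit) {
    int n = m + 1;
    double rpb = clip((n - 2) / exposure_sum(b, m), RATE_LO, RATE_HI);
    BdCtx ctx = { b, m };
    std::vector<std::vector<double> > starts;
    std::vector<double> s0(2);
    s0[0] = unlbox(rpb, RATE_LO, RATE_HI); s0[1] = unbox(1e-8, A_LO, A_HI);
    starts.push_back(s0);
    s0[1] = unbox(0.5, A_LO, A_HI);
    starts.push_back(s0);
    while ((int)starts.size() < n_starts) starts.push_back(rand_start(2));
    if ((int)starts.size() > std::max(n_starts, 1))
        starts.resize(std::max(n_starts, 1));
    double u[2];
    double nll = nm_multistart(2, bd_obj, &ctx, starts, u, maxit);
    Fit f; f.logL = -nll; f.npar = 2;
    f.aic = 2.0 * f.npar - 2.0 * f.logL;
    f.par[0] = lbox(u[0], RATE_LO, RATE_HI);
    f.par[1] = box(u[1], A_LO, A_HI);
    return f;
}

static Fit fit_y2r(const double* b, int m) {
    std::vector<double> grid = y2r_grid(b, m);
    Fit f; f.npar = 3;
    f.logL = R_NegInf; f.par[0] = f.par[1] = f.par[2] = NA_REAL;
    for (size_t i = 0; i < grid.size(); ++i) {
        double r1, r2;
        double ll = y2r_profile(b, m, grid[i], &r1, &r2);
        if (ll > f.logL) { f.logL = ll; f.par[0] = r1; f.par[1] = r2; f.par[2] = grid[i]; }
    }
    f.aic = 2.0 * f.npar - 2.0 * f.logL;
    return f;
}

static Fit fit_ddl(const double* b, int m) {
    Dd1Ctx ctx = { b, m };
    double u = brent_min(std::log(1e-6), std::log(1e9), ddl_obj1, &ctx, 1e-10);
    double kappa = (m + 1) + std::exp(u), r1;
    double ll = ddl_profile(b, m, kappa, &r1);
    // check the pure-birth boundary (kappa -> inf) explicitly
    Fit f; f.npar = 2;
    f.logL = ll; f.par[0] = r1; f.par[1] = kappa;
    double r1b;
    double llb = ddl_profile(b, m, 1e12, &r1b);
    if (llb > ll) { f.logL = llb; f.par[0] = r1b; f.par[1] = 1e12; }
    f.aic = 2.0 * f.npar - 2.0 * f.logL;
    return f;
}

static Fit fit_ddx(const double* b, int m) {
    Dd1Ctx ctx = { b, m };
    double x = brent_min(EXP_LO, EXP_HI, ddx_obj1, &ctx, 1e-10);
    double r1;
    double ll = ddx_profile(b, m, x, &r1);
    double r0;
    double ll0 = ddx_profile(b, m, 0.0, &r0);  // boundary x = 0
    Fit f; f.npar = 2;
    if (ll0 > ll) { f.logL = ll0; f.par[0] = r0; f.par[1] = 0.0; }
    else { f.logL = ll; f.par[0] = r1; f.par[1] = x; }
    f.aic = 2.0 * f.npar - 2.0 * f.logL;
    return f;
}

static Fit fit_tv(const double* b, int m, int variant, int n_starts, int maxit,
                  int nsub, const Fit& bd, const Fit* spvar, const Fit* exvar) {
    TvCtx ctx = { b, m, variant, b[0], nsub };
    double lam_bd = bd.par[0] / (1.0 - bd.par[1]);  // lambda = r/(1-a)
    double mu_bd = lam_bd * bd.par[1];
    int np = (variant == BOTHVAR) ? 4 : 3;
    std::vector<std::vector<double> > starts;
    std::vector<double> s0(np);
    if (variant == SPVAR) {
        s0[0] = unlbox(lam_bd, RATE_LO, RATE_HI);
        s0[1] = unbox(1e-4, EXP_LO, EXP_HI);
        s0[2] = unbox(std::max(mu_bd, 1e-8), MU_LO, MU_HI);
        starts.push_back(s0);
        s0[1] = unbox(0.2, EXP_LO, EXP_HI);
        starts.push_back(s0);
    } else if (variant == EXVAR) {
        s0[0] = unlbox(lam_bd, RATE_LO, RATE_HI);
        s0[1] = unbox(std::max(mu_bd, 1e-8), MU_LO, MU_HI);
        s0[2] = unbox(1e-4, EXP_LO, EXP_HI);
        starts.push_back(s0);
        s0[1] = unbox(std::max(2.0 * mu_bd, 0.05), MU_LO, MU_HI);
        s0[2] = unbox(0.5, EXP_LO, EXP_HI);
        starts.push_back(s0);
    } else {
        // warm start from the better of SPVAR / EXVAR
        if (spvar && exvar) {
            if (spvar->logL >= exvar->logL) {
                // near-constant extinction: z at its upper bound rises to
                // muf almost immediately, approximating SPVAR's constant mu
                s0[0] = unlbox(spvar->par[0], RATE_LO, RATE_HI);
                s0[1] = unbox(spvar->par[1], EXP_LO, EXP_HI);
                s0[2] = unbox(spvar->par[2], MU_LO, MU_HI);
                s0[3] = unbox(EXP_HI - 1e-6, EXP_LO, EXP_HI);
            } else {
                s0[0] = unlbox(exvar->par[0], RATE_LO, RATE_HI);
                s0[1] = unbox(1e-4, EXP_LO, EXP_HI);
                s0[2] = unbox(exvar->par[1], MU_LO, MU_HI);
                s0[3] = unbox(exvar->par[2], EXP_LO, EXP_HI);
            }
            starts.push_back(s0);
        }
        s0[0] = unlbox(lam_bd, RATE_LO, RATE_HI);
        s0[1] = unbox(1e-4, EXP_LO, EXP_HI);
        s0[2] = unbox(std::max(mu_bd, 1e-8), MU_LO, MU_HI);
        s0[3] = unbox(1e-4, EXP_LO, EXP_HI);
        starts.push_back(s0);
    }
    while ((int)starts.size() < n_starts) starts.push_back(rand_start(np));
    if ((int)starts.size() > std::max(n_starts, 1))
        starts.resize(std::max(n_starts, 1));
    std::vector<double> u(np);
    double nll = nm_multistart(np, tv_obj, &ctx, starts, &u[0], maxit);
    Fit f; f.npar = np; f.logL = -nll;
    f.aic = 2.0 * f.npar - 2.0 * f.logL;
    if (variant == SPVAR) {
        f.par[0] = lbox(u[0], RATE_LO, RATE_HI);
        f.par[1] = box(u[1], EXP_LO, EXP_HI);
        f.par[2] = box(u[2], MU_LO, MU_HI);
    } else if (variant == EXVAR) {
        f.par[0] = lbox(u[0], RATE_LO, RATE_HI);
        f.par[1] = box(u[1], MU_LO, MU_HI);
        f.par[2] = box(u[2], EXP_LO, EXP_HI);
    } else {
        f.par[0] = lbox(u[0], RATE_LO, RATE_HI);
        f.par[1] = box(u[1], EXP_LO, EXP_HI);
        f.par[2] = box(u[2], MU_LO, MU_HI);
        f.par[3] = box(u[3], EXP_LO, EXP_HI);
    }
    return f;
}

// fit all eight models; returns 8 x 8 matrix (rows: models in canonical
// order; cols: logL, aic, npar, p1..p4, na-fill)
static void fit_all(const double* b, int m, int n_starts, int maxit, int nsub,
                    Fit out[8]) {
    out[0] = fit_pb(b, m);
    out[1] = fit_bd(b, m, n_starts, maxit);
    out[2] = fit_y2r(b, m);
    out[3] = fit_ddl(b, m);
    out[4] = fit_ddx(b, m);
    out[5] = fit_tv(b, m, SPVAR, n_starts, maxit, nsub, out[1], 0, 0);
    out[6] = fit_tv(b, m, EXVAR, n_starts, maxit, nsub, out[1], 0, 0);
    out[7] = fit_tv(b, m, BOTHVAR, n_starts, maxit, nsub, out[1], &out[5], &out[6]);
}

// ---- exported likelihood evaluators --------------------------------------

// [[Rcpp::export]]
double cpp_loglik_constant(NumericVector b, double r, double a) {
    if (a == 0.0) return loglik_pb(b.begin(), b.size(), r);
    return loglik_bd(b.begin(), b.size(), r, a);
}

// [[Rcpp::export]]
double cpp_loglik_yule2rate(NumericVector b, double r1, double r2, double st) {
    return loglik_y2r(b.begin(), b.size(), r1, r2, st);
}

// [[Rcpp::export]]
double cpp_loglik_ddl(NumericVector b, double r1, double kappa) {
    return loglik_ddl(b.begin(), b.size(), r1, kappa);
}

// [[Rcpp::export]]
double cpp_loglik_ddx(NumericVector b, double r1, double x) {
    return loglik_ddx(b.begin(), b.size(), r1, x);
}

// [[Rcpp::export]]
double cpp_loglik_tv(NumericVector b, double lam0, double k, double muf,
                     double z, int variant, int nsub) {
    TvPar p;
    p.lam0 = lam0; p.k = k; p.muf = muf; p.z = z;
    p.T = b[0]; p.variant = variant;
    return loglik_tv(b.begin(), b.size(), p, nsub);
}

// [[Rcpp::export]]
NumericMatrix cpp_fit_all(NumericVector b, int n_starts, int maxit, int nsub) {
    Fit f[8];
    fit_all(b.begin(), b.size(), n_starts, maxit, nsub, f);
    NumericMatrix out(8, 7);
    for (int i = 0; i < 8; ++i) {
        out(i, 0) = f[i].logL;
        out(i, 1) = f[i].aic;
        out(i, 2) = f[i].npar;
        for (int j = 0; j < 4; ++j)
            out(i, 3 + j) = (j < ((i == 0) ? 1 : f[i].npar)) ? f[i].par[j] : NA_REAL;
    }
    return out;
}

// ---- conditioned branching-age sampler -----------------------------------
// Reconstructed constant-rate birth-death process conditioned on age T:
// branching ages are iid with CDF Q(x)/Q(T), Q(x) = (1-exp(-r x)) /
// (lam - mu exp(-r x)) (stem conditioning: all n-1 ages; crown
// conditioning: the n-2 non-crown ages).
static double q_inv(double q, double T, double lam, double mu) {
    double r = lam - mu;
    double QT = (1.0 - std::exp(-r * T)) / (lam - mu * std::exp(-r * T));
    double w = q * QT;
    double y = (1.0 - w * lam) / (1.0 - w * mu);  // y = exp(-r x)
    if (y < DBL_MIN) y = DBL_MIN;
    return -std::log(y) / r;
}

// [[Rcpp::export]]
NumericVector cpp_rcond_ages(int nev, double T, double lam, double mu) {
    NumericVector out(nev);
    for (int i = 0; i < nev; ++i) out[i] = q_inv(R::unif_rand(), T, lam, mu);
    return out;
}

// ---- delta-AIC_RC and its simulated null ---------------------------------
static double daic_rc(const Fit f[8]) {
    double rc = std::min(f[0].aic, f[1].aic);
    double rv = f[2].aic;
    for (int i = 3; i < 8; ++i) rv = std::min(rv, f[i].aic);
    return rc - rv;
}

// [[Rcpp::export]]
double cpp_daic_rc(NumericVector b, int n_starts, int maxit, int nsub) {
    Fit f[8];
    fit_all(b.begin(), b.size(), n_starts, maxit, nsub, f);
    return daic_rc(f);
}

// null distribution: nsim trees with n tips, crown age T, simulated under
// the constant-rate birth-death reconstructed process at (lam, mu); each
// null tree is refitted with all eight models.
// [[Rcpp::export]]
NumericVector cpp_daic_null(int nsim, int n, double T, double lam, double mu,
                            int n_starts, int maxit, int nsub) {
    NumericVector out(nsim);
    int m = n - 1;
    std::vector<double> b(m);
    for (int s = 0; s < nsim; ++s) {
        b[0] = T;
        for (int i = 1; i < m; ++i) b[i] = q_inv(R::unif_rand(), T, lam, mu);
        std::sort(b.begin() + 1, b.end(), std::greater<double>());
        Fit f[8];
        fit_all(&b[0], m, n_starts, maxit, nsub, f);
        out[s] = daic_rc(f);
        if ((s & 63) == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
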