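// Pairwise-interaction core: 3x3x2 contingency counting via 64-bit
// genotype bit-planes (popcounts of conjunctions), plus the three
// per-table interaction statistics (BOOST homogeneous-model LRT via
// iterative proportional fitting, additive logistic interaction LRT via
// Newton on the 18 weighted cells, and the joint-effects delta-method
// quadratic form). Cell index convention matches R's array(dim=c(3,3,2)):
// counts[g1 + 3*g2 + 9*status], status 0 = control, 1 = case.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int pcount(uint64_t x) { return __builtin_popcountll(x); }

// ---- small dense solver (Gaussian elimination, partial pivoting) ------
static bool solve_sym(int k, double A[], double b[], double x[]) {
    double M[5][6];
    for (int i = 0; i < k; ++i) {
        for (int j = 0; j < k; ++j) M[i][j] = A[i * k + j];
        M[i][k] = b[i];
    }
    for (int c = 0; c < k; ++c) {
        int piv = c;
        for (int r = c + 1; r < k; ++r)
            if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
        if (std::fabs(M[piv][c]) < 1e-12) return false;
        if (piv != c)
            for (int j = 0; j <= k; ++j) std::swap(M[c][j], M[piv][j]);
        for (int r = 0; r < k; ++r) {
            if (r == c) continue;
            double f = M[r][c] / M[c][c];
            for (int j = c; j <= k; ++j) M[r][j] -= f * M[c][j];
        }
    }
    for (int i = 0; i < k; ++i) x[i] = M[i][k] / M[i][i];
    return true;
}

// ---- BOOST: saturated vs homogeneous-association log-linear model ----
// IPF over the three two-way margins (g1xg2, g1xstatus, g2xstatus);
// statistic = 2 * sum n*log(n/m) on a chi-square with 4 df.
static double boost_stat_core(const double n[18], double tol,
                              int max_sweeps, bool &converged, int &iters) {
    double m[18];
    double tot = 0.0;
    for (int i = 0; i < 18; ++i) tot += n[i];
    for (int i = 0; i < 18; ++i) m[i] = tot / 18.0;
    converged = false;
    iters = 0;
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
        double delta = 0.0;
        // margin g1 x g2
        for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b) {
                double no = n[a + 3 * b] + n[a + 3 * b + 9];
                double mo = m[a + 3 * b] + m[a + 3 * b + 9];
                for (int s = 0; s < 2; ++s) {
                    int i = a + 3 * b + 9 * s;
                    double nv = (mo > 0.0) ? m[i] * no / mo : 0.0;
                    delta = std::max(delta, std::fabs(nv - m[i]));
                    m[i] = nv;
                }
            }
        // margin g1 x status
        for (int a = 0; a < 3; ++a)
            for (int s = 0; s < 2; ++s) {
                double no = 0.0, mo = 0.0;
                for (int b = 0; b < 3; ++b) {
                    no += n[a + 3 * b + 9 * s];
                    mo += m[a + 3 * b + 9 * s];
                }
                for (int b = 0; b < 3; ++b) {
                    int i = a + 3 * b + 9 * s;
                    double nv = (mo > 0.0) ? m[i] * no / mo : 0.0;
                    delta = std::max(delta, std::fabs(nv - m[i]));
                    m[i] = nv;
                }
            }
        // margin g2 x status
        for (int b = 0; b < 3; ++b)
            for (int s = 0; s < 2; ++s) {
                double no = 0.0, mo = 0.0;
                for (int a = 0; a < 3; ++a) {
                    no += n[a + 3 * b + 9 * s];
                    mo += m[a + 3 * b + 9 * s];
                }
                for (int a = 0; a < 3; ++a) {
                    int i = a + 3 * b + 9 * s;
                    double nv = (mo > 0.0) ? m[i] * no / mo : 0.0;
                    delta = std::max(delta, std::fabs(nv - m[i]));
                    m[i] = nv;
                }
            }
        ++iters;
        if (delta < tol) { converged = true; break; }
    }
    double stat = 0.0;
    for (int i = 0; i < 18; ++i)
        if (n[i] > 0.0 && m[i] > 0.0) stat += n[i] * std::log(n[i] / m[i]);
    return 2.0 * stat;
}

// [[Rcpp::export(name = ".boost_stat_cpp")]]
List boost_stat_cpp(NumericVector counts, double tol = 1e-8,
                    int max_sweeps = 10000) {
    if (counts.size() != 18) stop("counts must have length 18");
    bool conv; int iters;
    double s = boost_stat_core(REAL(counts), tol, max_sweeps, conv, iters);
    return List::create(_["stat"] = s, _["converged"] = conv,
                        _["iters"] = iters);
}

// ---- additive-coding logistic interaction LRT ------------------------
// logit P(case | g1,g2) = b0 + b1*g1 + b2*g2 [+ b3*g1*g2], fitted on the
// 9 genotype cells with binomial weights; 1-df LRT for the product term.
static bool logistic_fit(const double n[18], int k, double &ll,
                         double beta_out[4]) {
    // design rows: the 9 cells
    double X[9][4];
    double y[9], tot[9];
    for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
            int r = a + 3 * b;
            X[r][0] = 1.0; X[r][1] = a; X[r][2] = b; X[r][3] = a * b;
            y[r] = n[r + 9];
            tot[r] = n[r] + n[r + 9];
        }
    double beta[4] = {0, 0, 0, 0};
    for (int it = 0; it < 200; ++it) {
        double grad[4] = {0, 0, 0, 0};
        double H[16] = {0};
        for (int r = 0; r < 9; ++r) {
            if (tot[r] <= 0.0) continue;
            double eta = 0.0;
            for (int j = 0; j < k; ++j) eta += X[r][j] * beta[j];
            double p = 1.0 / (1.0 + std::exp(-eta));
            double w = tot[r] * p * (1.0 - p);
            double resid = y[r] - tot[r] * p;
            for (int j = 0; j < k; ++j) {
                grad[j] += X[r][j] * resid;
                for (int l = 0; l < k; ++l)
                    H[j * k + l] += w * X[r][j] * X[r][l];
            }
        }
        double step[4];
        if (!solve_sym(k, H, grad, step)) return false;
        double mx = 0.0;
        for (int j = 0; j < k; ++j) {
            beta[j] += step[j];
            mx = std::max(mx, std::fabs(step[j]));
        }
        if (mx < 1e-10) {
            ll = 0.0;
            for (int r = 0; r < 9; ++r) {
                if (tot[r] <= 0.0) continue;
                double eta = 0.0;
                for (int j = 0; j < k; ++j) eta += X[r][j] * beta[j];
                // log-likelihood up to the binomial-coefficient constant
                ll += y[r] * eta - tot[r] * std::log1p(std::exp(eta));
            }
            for (int j = 0; j < 4; ++j) beta_out[j] = (j < k) ? beta[j] : 0.0;
            return true;
        }
        if (std::fabs(beta[0]) > 50.0 || std::fabs(beta[1]) > 50.0 ||
            std::fabs(beta[2]) > 50.0 || std::fabs(beta[3]) > 50.0)
            return false;                        // separation guard
    }
    return false;
}

// [[Rcpp::export(name = ".logistic_lrt_cpp")]]
List logistic_lrt_cpp(NumericVector counts) {
    if (counts.size() != 18) stop("counts must have length 18");
    double ll_full, ll_red, beta[4];
    bool ok_full = logistic_fit(REAL(counts), 4, ll_full, beta);
    double beta_int = beta[3];
    bool ok_red = logistic_fit(REAL(counts), 3, ll_red, beta);
    if (!ok_full || !ok_red)
        return List::create(_["stat"] = NA_REAL, _["converged"] = false,
                            _["beta_int"] = NA_REAL);
    return List::create(_["stat"] = 2.0 * (ll_full - ll_red),
                        _["converged"] = true, _["beta_int"] = beta_int);
}

// ---- joint-effects statistic -----------------------------------------
// Four log-ORs of the 2x2 subtables anchored at genotype cell (0,0),
// computed in cases and controls; delta-method covariance; quadratic
// form on chi-square 4 df.
static bool joint_core(const double n[18], double d[4], double V[16]) {
    double lam[2][4], Vs[2][16];
    for (int s = 0; s < 2; ++s) {
        const double *c = n + 9 * s;
        double c00 = c[0];
        if (c00 <= 0.0) return false;
        int idx = 0;
        double a_[4], b_[4];
        for (int a = 1; a <= 2; ++a)
            for (int b = 1; b <= 2; ++b) {
                double cab = c[a + 3 * b], ca0 = c[a], c0b = c[3 * b];
                if (cab <= 0.0 || ca0 <= 0.0 || c0b <= 0.0) return false;
                lam[s][idx] = std::log(cab) - std::log(ca0) -
                              std::log(c0b) + std::log(c00);
                a_[idx] = a; b_[idx] = b;
                ++idx;
            }
        for (int i = 0; i < 4; ++i)
            for (int j = 0; j < 4; ++j) {
                double v = 1.0 / c00;
                if (a_[i] == a_[j]) v += 1.0 / c[(int)a_[i]];
                if (b_[i] == b_[j]) v += 1.0 / c[3 * (int)b_[i]];
                if (a_[i] == a_[j] && b_[i] == b_[j])
                    v += 1.0 / c[(int)a_[i] + 3 * (int)b_[i]];
                Vs[s][4 * i + j] = v;
            }
    }
    for (int i = 0; i < 4; ++i) d[i] = lam[1][i] - lam[0][i];
    for (int i = 0; i < 16; ++i) V[i] = Vs[0][i] + Vs[1][i];
    return true;
}

// [[Rcpp::export(name = ".joint_stat_cpp")]]
List joint_stat_cpp(NumericVector counts, bool haldane = false) {
    if (counts.size() != 18) stop("counts must have length 18");
    double n[18];
    for (int i = 0; i < 18; ++i)
        n[i] = counts[i] + (haldane ? 0.5 : 0.0);
    double d[4], V[16], x[4];
    if (!joint_core(n, d, V))
        return List::create(_["stat"] = NA_REAL, _["ok"] = false,
                            _["reason"] = "zero anchored cell");
    if (!solve_sym(4, V, d, x))
        return List::create(_["stat"] = NA_REAL, _["ok"] = false,
                            _["reason"] = "singular covariance");
    double s = 0.0;
    for (int i = 0; i < 4; ++i) s += d[i] * x[i];
    return List::create(_["stat"] = s, _["ok"] = true, _["reason"] = "");
}

// ---- bit-plane encoding ----------------------------------------------
struct BitPlanes {
    int nw;
    std::vector<uint64_t> p;                    // [snp][geno][word]
    std::vector<uint64_t> status[2];            // control / case masks
    int m;
    uint64_t *plane(int snp, int g) { return &p[(3 * snp + g) * (size_t)nw]; }
};

static void build_planes(const IntegerMatrix &calls,
                         const IntegerVector &status, BitPlanes &bp) {
    int m = calls.nrow(), n = calls.ncol();
    bp.m = m;
    bp.nw = (n + 63) / 64;
    bp.p.assign((size_t)3 * m * bp.nw, 0ULL);
    bp.status[0].assign(bp.nw, 0ULL);
    bp.status[1].assign(bp.nw, 0ULL);
    for (int j = 0; j < n; ++j) {
        int st = status[j];
        if (st == NA_INTEGER || (st != 0 && st != 1)) continue;
        bp.status[st][j / 64] |= (1ULL << (j % 64));
    }
    for (int s = 0; s < m; ++s)
        for (int j = 0; j < n; ++j) {
            int g = calls(s, j);
            if (g == NA_INTEGER) continue;
            bp.plane(s, g)[j / 64] |= (1ULL << (j % 64));
        }
}

static void count_pair(BitPlanes &bp, int a, int b, double out[18]) {
    for (int ga = 0; ga < 3; ++ga) {
        const uint64_t *pa = bp.plane(a, ga);
        for (int gb = 0; gb < 3; ++gb) {
            const uint64_t *pb = bp.plane(b, gb);
            int c0 = 0, c1 = 0;
            for (int w = 0; w < bp.nw; ++w) {
                uint64_t both = pa[w] & pb[w];
                c0 += pcount(both & bp.status[0][w]);
                c1 += pcount(both & bp.status[1][w]);
            }
            out[ga + 3 * gb] = c0;
            out[ga + 3 * gb + 9] = c1;
        }
    }
}

// [[Rcpp::export(name = ".joint_table_cpp")]]
NumericVector joint_table_cpp(IntegerMatrix calls, IntegerVector status,
                              int a, int b) {
    BitPlanes bp;
    build_planes(calls, status, bp);
    NumericVector out(18);
    double buf[18];
    count_pair(bp, a - 1, b - 1, buf);
    for (int i = 0; i < 18; ++i) out[i] = buf[i];
    return out;
}

// ---- all-pairs screen -------------------------------------------------
// Returns one row per unordered SNP pair: indices, minimum cell count,
// and the requested statistics (NaN where skipped or non-converged).
// [[Rcpp::export(name = ".screen_pairs_cpp")]]
NumericMatrix screen_pairs_cpp(IntegerMatrix calls, IntegerVector status,
                               int min_cell, bool do_logistic,
                               bool do_boost, bool do_joint,
                               double boost_tol = 1e-8,
                               int boost_max_sweeps = 10000) {
    BitPlanes bp;
    build_planes(calls, status, bp);
    int m = calls.nrow();
    R_xlen_t npair = (R_xlen_t)m * (m - 1) / 2;
    NumericMatrix res(npair, 6);
    colnames(res) = CharacterVector::create("a", "b", "min_cell",
                                            "stat_logistic", "stat_boost",
                                            "stat_joint");
    double n[18], d[4], V[16], x[4], beta[4];
    R_xlen_t row = 0;
    for (int a = 0; a < m; ++a) {
        for (int b = a + 1; b < m; ++b, ++row) {
            count_pair(bp, a, b, n);
            double mc = n[0];
            for (int i = 1; i < 18; ++i) mc = std::min(mc, n[i]);
            res(row, 0) = a + 1;
            res(row, 1) = b + 1;
            res(row, 2) = mc;
            double sl = NA_REAL, sb = NA_REAL, sj = NA_REAL;
            if (mc >= min_cell) {
                if (do_logistic) {
                    double llf, llr;
                    if (logistic_fit(n, 4, llf, beta) &&
                        logistic_fit(n, 3, llr, beta))
                        sl = 2.0 * (llf - llr);
                }
                if (do_boost) {
                    bool conv; int iters;
                    double s = boost_stat_core(n, boost_tol,
                                               boost_max_sweeps, conv, iters);
                    if (conv) sb = s;
                }
                if (do_joint) {
                    if (joint_core(n, d, V) && solve_sym(4, V, d, x)) {
                        sj = 0.0;
                        for (int i = 0; i < 4; ++i) sj += d[i] * x[i];
                    }
                }
            }
            res(row, 3) = sl;
            res(row, 4) = sb;
            res(row, 5) = sj;
        }
        Rcpp::checkUserInterrupt();
    }
    return res;
}
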