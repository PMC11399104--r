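#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Levenberg-Marquardt least-squares fitting of k (1..3) pixel-integrated
// symmetric 2D Gaussians sharing one width, plus a constant background, to
// a square fitting window. Parameter layout: [sigma, bg, (x, y, flux) * k];
// x/y in window-local px (pixel j spans [j, j+1)), flux in integrated
// counts. Model selection across k is by BIC on the window residual.

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;
static const int PMAX = 11;  // 2 + 3*3

static inline double Phi(double z) { return 0.5 * erfc(-z * INV_SQRT2); }
static inline double phi(double z) { return INV_SQRT2PI * std::exp(-0.5 * z * z); }

// solve p x p linear system with partial pivoting; false if singular
static bool solveP(int p, double A[PMAX][PMAX], double b[PMAX], double x[PMAX]) {
    int idx[PMAX];
    for (int i = 0; i < p; ++i) idx[i] = i;
    for (int c = 0; c < p; ++c) {
        int piv = c;
        for (int r = c + 1; r < p; ++r)
            if (std::fabs(A[idx[r]][c]) > std::fabs(A[idx[piv]][c])) piv = r;
        std::swap(idx[c], idx[piv]);
        double d = A[idx[c]][c];
        if (std::fabs(d) < 1e-300) return false;
        for (int r = c + 1; r < p; ++r) {
            double f = A[idx[r]][c] / d;
            for (int k = c; k < p; ++k) A[idx[r]][k] -= f * A[idx[c]][k];
            b[idx[r]] -= f * b[idx[c]];
        }
    }
    for (int c = p - 1; c >= 0; --c) {
        double s = b[idx[c]];
        for (int k = c + 1; k < p; ++k) s -= A[idx[c]][k] * x[k];
        x[c] = s / A[idx[c]][c];
    }
    return true;
}

struct KFit {
    int w, k, np;
    std::vector<double> gx, gy, dgx_dx, dgy_dy, dgx_ds, dgy_ds;  // per emitter, length k*w

    KFit(int w_, int k_) : w(w_), k(k_), np(2 + 3 * k_),
        gx(k_ * w_), gy(k_ * w_), dgx_dx(k_ * w_), dgy_dy(k_ * w_),
        dgx_ds(k_ * w_), dgy_ds(k_ * w_) {}

    void axes(const double* th) {
        double s = th[0];
        for (int e = 0; e < k; ++e) {
            double x0 = th[2 + 3 * e], y0 = th[3 + 3 * e];
            for (int j = 0; j < w; ++j) {
                double zl = (j - x0) / s, zh = (j + 1 - x0) / s;
                gx[e * w + j] = Phi(zh) - Phi(zl);
                double pl = phi(zl), ph = phi(zh);
                dgx_dx[e * w + j] = -(ph - pl) / s;
                dgx_ds[e * w + j] = -(zh * ph - zl * pl) / s;
                zl = (j - y0) / s; zh = (j + 1 - y0) / s;
                gy[e * w + j] = Phi(zh) - Phi(zl);
                pl = phi(zl); ph = phi(zh);
                dgy_dy[e * w + j] = -(ph - pl) / s;
                dgy_ds[e * w + j] = -(zh * ph - zl * pl) / s;
            }
        }
    }

    double evaluate(const double* win, const double* th, bool withJ,
                    double JtJ[PMAX][PMAX], double Jtr[PMAX]) {
        axes(th);
        double b = th[1];
        double rss = 0.0;
        if (withJ) {
            for (int a = 0; a < np; ++a) {
                Jtr[a] = 0;
                for (int b2 = 0; b2 < np; ++b2) JtJ[a][b2] = 0;
            }
        }
        double J[PMAX];
        for (int r = 0; r < w; ++r) {
            for (int c = 0; c < w; ++c) {
                double model = b;
                for (int e = 0; e < k; ++e)
                    model += th[4 + 3 * e] * gx[e * w + c] * gy[e * w + r];
                double res = win[r + c * w] - model;
                rss += res * res;
                if (withJ) {
                    J[0] = 0;
                    for (int e = 0; e < k; ++e)
                        J[0] += th[4 + 3 * e] * (dgx_ds[e * w + c] * gy[e * w + r] +
                                                 gx[e * w + c] * dgy_ds[e * w + r]);
                    J[1] = 1.0;
                    for (int e = 0; e < k; ++e) {
                        J[2 + 3 * e] = th[4 + 3 * e] * dgx_dx[e * w + c] * gy[e * w + r];
                        J[3 + 3 * e] = th[4 + 3 * e] * gx[e * w + c] * dgy_dy[e * w + r];
                        J[4 + 3 * e] = gx[e * w + c] * gy[e * w + r];
                    }
                    for (int a = 0; a < np; ++a) {
                        Jtr[a] += J[a] * res;
                        for (int b2 = a; b2 < np; ++b2) JtJ[a][b2] += J[a] * J[b2];
                    }
                }
            }
        }
        if (withJ)
            for (int a = 0; a < np; ++a)
                for (int b2 = 0; b2 < a; ++b2) JtJ[a][b2] = JtJ[b2][a];
        return rss;
    }

    void clamp(double* th) const {
        if (th[0] < 0.25) th[0] = 0.25;
        if (th[0] > 2.0 * w) th[0] = 2.0 * w;
        for (int e = 0; e < k; ++e) {
            double* xe = th + 2 + 3 * e;
            if (xe[0] < -2.0) xe[0] = -2.0;
            if (xe[0] > w + 2.0) xe[0] = w + 2.0;
            if (xe[1] < -2.0) xe[1] = -2.0;
            if (xe[1] > w + 2.0) xe[1] = w + 2.0;
            if (xe[2] < 1e-8) xe[2] = 1e-8;
        }
    }

    double lm(const double* win, double* th) {
        double JtJ[PMAX][PMAX], Jtr[PMAX];
        clamp(th);
        double rss = evaluate(win, th, true, JtJ, Jtr);
        double lambda = 1e-3;
        bool done = false;
        for (int iter = 0; iter < 80 && !done; ++iter) {
            double A[PMAX][PMAX], bvec[PMAX], delta[PMAX], trial[PMAX];
            bool stepped = false;
            for (int tries = 0; tries < 12 && !stepped; ++tries) {
                for (int a = 0; a < np; ++a) {
                    for (int b2 = 0; b2 < np; ++b2) A[a][b2] = JtJ[a][b2];
                    A[a][a] *= (1.0 + lambda);
                    if (A[a][a] < 1e-12) A[a][a] = 1e-12;
                    bvec[a] = Jtr[a];
                }
                if (!solveP(np, A, bvec, delta)) { lambda *= 10; continue; }
                for (int a = 0; a < np; ++a) trial[a] = th[a] + delta[a];
                clamp(trial);
                double rssTrial = evaluate(win, trial, false, NULL, NULL);
                if (rssTrial <= rss) {
                    double shift = 0;
                    for (int a = 0; a < np; ++a) shift += std::fabs(trial[a] - th[a]);
                    double rel = (rss - rssTrial) / (rss + 1e-300);
                    for (int a = 0; a < np; ++a) th[a] = trial[a];
                    rss = rssTrial;
                    lambda = std::max(lambda / 5.0, 1e-9);
                    stepped = true;
                    if (shift < 1e-7 && rel < 1e-10) done = true;
                } else {
                    lambda *= 10;
                }
            }
            if (!stepped) done = true;  // cannot improve further
            if (!done) rss = evaluate(win, th, true, JtJ, Jtr);
        }
        return rss;
    }
};

struct Emitter { int cand; double x, y, sigma, flux, bg; };

// Fit all candidate windows. Single-emitter fits first; windows whose
// residual is an outlier (rss > 3x median) or whose width is inflated
// (> 1.35x the modal width or > 1.25x the expected PSF width) are re-fit
// with up to max_emitters Gaussians, keeping the lowest-BIC model.
// Returns one row per accepted emitter:
// cand, x_px, y_px, sigma_px, flux, bg (positions in image px, 0-based
// origin) plus the count of dropped windows as attribute "n_dropped".
// [[Rcpp::export]]
NumericMatrix cpp_fit_spots(NumericMatrix img, IntegerMatrix peaks, int win,
                            double sigma0, int max_emitters = 1) {
    int npk = peaks.nrow();
    int nr = img.nrow(), nc = img.ncol();
    int h = win / 2, n = win * win;
    std::vector<double> w(n);
    std::vector<double> th1(npk * 5, NA_REAL);  // sigma, bg, x, y, F
    std::vector<double> rss1(npk, NA_REAL);
    std::vector<char> ok1(npk, 0);
    KFit fit1(win, 1);
    int n_dropped = 0;

    std::vector<std::vector<double> > windows(npk);
    for (int p = 0; p < npk; ++p) {
        int pr = peaks(p, 0) - 1, pc = peaks(p, 1) - 1;
        int r0 = pr - h, c0 = pc - h;
        if (r0 < 0 || c0 < 0 || r0 + win > nr || c0 + win > nc) {
            ++n_dropped;
            continue;
        }
        windows[p].resize(n);
        double lo = R_PosInf, tot = 0.0;
        for (int c = 0; c < win; ++c)
            for (int r = 0; r < win; ++r) {
                double v = img(r0 + r, c0 + c);
                windows[p][r + c * win] = v;
                if (v < lo) lo = v;
                tot += v;
            }
        double th[PMAX];
        th[0] = sigma0; th[1] = lo;
        th[2] = h + 0.5; th[3] = h + 0.5;
        th[4] = std::max(tot - lo * n, 1.0);
        rss1[p] = fit1.lm(&windows[p][0], th);
        bool ok = th[4] > 1e-6 && th[2] > -1 && th[2] < win + 1 &&
                  th[3] > -1 && th[3] < win + 1 && th[0] > 0.26 &&
                  th[0] < 1.9 * win;
        if (!ok) { ++n_dropped; continue; }
        ok1[p] = 1;
        for (int a = 0; a < 5; ++a) th1[p * 5 + a] = th[a];
    }

    // robust medians of rss and sigma over single-emitter fits
    std::vector<double> tmp;
    for (int p = 0; p < npk; ++p) if (ok1[p]) tmp.push_back(rss1[p]);
    double med_rss = R_PosInf;
    if (!tmp.empty()) {
        std::sort(tmp.begin(), tmp.end());
        med_rss = tmp[tmp.size() / 2];
    }
    tmp.clear();
    for (int p = 0; p < npk; ++p) if (ok1[p]) tmp.push_back(th1[p * 5 + 0]);
    double med_sigma = sigma0;
    if (!tmp.empty()) {
        std::sort(tmp.begin(), tmp.end());
        med_sigma = tmp[tmp.size() / 2];
    }

    std::vector<Emitter> out;
    for (int p = 0; p < npk; ++p) {
        if (!ok1[p]) continue;
        int pr = peaks(p, 0) - 1, pc = peaks(p, 1) - 1;
        int r0 = pr - h, c0 = pc - h;
        double sig = th1[p * 5 + 0];
        bool crowded = rss1[p] > 3.0 * med_rss || sig > 1.35 * med_sigma ||
                       sig > 1.25 * sigma0;
        int kbest = 1;
        double best[PMAX];
        for (int a = 0; a < 5; ++a) best[a] = th1[p * 5 + a];
        double bestRss = rss1[p];
        double bestBic = n * std::log(std::max(bestRss, 1e-12) / n) +
                         5 * std::log((double)n);
        if (max_emitters > 1 && crowded) {
            for (int k = 2; k <= max_emitters; ++k) {
                // init: previous model + one emitter at the residual peak
                KFit fitp(win, kbest);
                double resmax = -R_PosInf;
                int rbest = h, cbest = h;
                fitp.axes(best);
                for (int r = 0; r < win; ++r)
                    for (int c = 0; c < win; ++c) {
                        double model = best[1];
                        for (int e = 0; e < kbest; ++e)
                            model += best[4 + 3 * e] * fitp.gx[e * win + c] *
                                     fitp.gy[e * win + r];
                        double res = windows[p][r + c * win] - model;
                        if (res > resmax) { resmax = res; rbest = r; cbest = c; }
                    }
                double th[PMAX];
                th[0] = best[0]; th[1] = best[1];
                for (int e = 0; e < kbest; ++e)
                    for (int a = 0; a < 3; ++a)
                        th[2 + 3 * e + a] = best[2 + 3 * e + a];
                th[2 + 3 * kbest] = cbest + 0.5;
                th[3 + 3 * kbest] = rbest + 0.5;
                th[4 + 3 * kbest] = std::max(resmax * 6.28 * th[0] * th[0], 10.0);
                if (k != kbest + 1) break;  // only grow one at a time
                KFit fitk(win, k);
                double rss = fitk.lm(&windows[p][0], th);
                double bic = n * std::log(std::max(rss, 1e-12) / n) +
                             (2 + 3 * k) * std::log((double)n);
                if (bic < bestBic) {
                    kbest = k; bestRss = rss; bestBic = bic;
                    for (int a = 0; a < 2 + 3 * k; ++a) best[a] = th[a];
                } else break;
            }
        }
        for (int e = 0; e < kbest; ++e) {
            double x = best[2 + 3 * e], y = best[3 + 3 * e], F = best[4 + 3 * e];
            if (x < -0.5 || x > win + 0.5 || y < -0.5 || y > win + 0.5 ||
                F <= 1e-6)
                continue;
            Emitter em;
            em.cand = p + 1;
            em.x = c0 + x; em.y = r0 + y;
            em.sigma = best[0]; em.flux = F; em.bg = best[1];
            out.push_back(em);
        }
    }

    NumericMatrix res(out.size(), 6);
    colnames(res) = CharacterVector::create("cand", "x_px", "y_px",
                                            "sigma_px", "flux", "bg");
    for (size_t i = 0; i < out.size(); ++i) {
        res(i, 0) = out[i].cand;
        res(i, 1) = out[i].x;
        res(i, 2) = out[i].y;
        res(i, 3) = out[i].sigma;
        res(i, 4) = out[i].flux;
        res(i, 5) = out[i].bg;
    }
    res.attr("n_dropped") = n_dropped;
    return res;
}
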