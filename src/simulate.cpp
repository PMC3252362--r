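#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "adi.h"

using namespace Rcpp;

// Euler-Maruyama increment for the fate variable:
// f <- f + (B + chi (1/2 - s) f - nu f^3) dt + sqrt(2 delta) dW,  dW ~ N(0, dt)
static inline double fate_increment(double f, double s, double B,
                                    double chi, double nu, double delta,
                                    double dt, double dW) {
    return (B + chi * (0.5 - s) * f - nu * f * f * f) * dt
         + std::sqrt(2.0 * delta) * dW;
}

static void check_finite(double v, int cell, int step) {
    if (!R_finite(v))
        stop("non-finite fate value for cell %d at step %d", cell + 1, step + 1);
}

// snapshot bookkeeping shared by both mechanisms
struct SnapshotStore {
    std::vector<int> steps;   // 1-based step indices after which to record
    List out;
    SnapshotStore(IntegerVector s) : out(s.size()) {
        for (int i = 0; i < s.size(); ++i) steps.push_back(s[i]);
    }
    bool wants(int step1) const {
        for (size_t i = 0; i < steps.size(); ++i) if (steps[i] == step1) return true;
        return false;
    }
    void record(int step1, double dt, const std::vector<double>& s,
                const std::vector<double>& f) {
        for (size_t i = 0; i < steps.size(); ++i)
            if (steps[i] == step1)
                out[i] = List::create(_["step"] = step1, _["t"] = step1 * dt,
                                      _["s"] = wrap(s), _["f"] = wrap(f));
    }
};

// [[Rcpp::export]]
List simulate_diffusive_cpp(NumericMatrix pos, double L, int Ms,
                            double Da, double Db,
                            double lambda_a, double lambda_b,
                            double alpha, double Sdiff,
                            double chi, double nu, double delta,
                            double dt, int nsteps,
                            IntegerVector snapshot_steps,
                            Nullable<NumericMatrix> noise) {
    const int N = pos.nrow();
    const double h = L / Ms;
    const double inv_h2 = 1.0 / (h * h);
    if (Ms < 3) stop("grid must be at least 3 x 3");

    // grid square of each (static) cell centre: half-open [(j-1)h, jh)
    std::vector<size_t> cell_idx(N);
    for (int n = 0; n < N; ++n) {
        int jx = (int)std::floor(pos(n, 0) / h); if (jx >= Ms) jx = Ms - 1; if (jx < 0) jx = 0;
        int jy = (int)std::floor(pos(n, 1) / h); if (jy >= Ms) jy = Ms - 1; if (jy < 0) jy = 0;
        cell_idx[n] = (size_t)jx + (size_t)Ms * jy;
    }

    std::vector<double> a((size_t)Ms * Ms, 0.0), b((size_t)Ms * Ms, 0.0);
    std::vector<double> src_a(a.size()), src_b(b.size());
    std::vector<double> work(3 * (size_t)Ms * Ms + 2 * Ms);
    double beta_a = Da * dt / (2.0 * h * h), beta_b = Db * dt / (2.0 * h * h);
    CyclicTridiag fac_a, fac_b;
    fac_a.init(Ms, 1.0 + 2.0 * beta_a + 0.25 * dt * lambda_a, -beta_a);
    fac_b.init(Ms, 1.0 + 2.0 * beta_b + 0.25 * dt * lambda_b, -beta_b);

    std::vector<double> s(N, 1.0), f(N, 0.0), B(N, 0.0);
    bool have_noise = noise.isNotNull();
    NumericMatrix noise_m;
    if (have_noise) {
        noise_m = NumericMatrix(noise);
        if (noise_m.nrow() != nsteps || noise_m.ncol() != N)
            stop("noise matrix must be nsteps x N");
    }
    const double sqdt = std::sqrt(dt);
    SnapshotStore snaps(snapshot_steps);
    double min_a = 0.0, min_b = 0.0;

    for (int step = 0; step < nsteps; ++step) {
        // morphogen production from the start-of-step cell states
        std::fill(src_a.begin(), src_a.end(), 0.0);
        std::fill(src_b.begin(), src_b.end(), 0.0);
        for (int n = 0; n < N; ++n) {
            if (f[n] > 0.0)      src_a[cell_idx[n]] += alpha * (1.0 - s[n]) * inv_h2;
            else if (f[n] < 0.0) src_b[cell_idx[n]] += alpha * (1.0 - s[n]) * inv_h2;
        }
        adi_step_core(a.data(), src_a.data(), Ms, lambda_a, dt, fac_a, beta_a, work.data());
        adi_step_core(b.data(), src_b.data(), Ms, lambda_b, dt, fac_b, beta_b, work.data());

        // bias from the just-updated fields, then synchronous cell updates
        for (int n = 0; n < N; ++n) {
            B[n] = Sdiff * (a[cell_idx[n]] - b[cell_idx[n]]);
            double dW = have_noise ? noise_m(step, n) * sqdt : norm_rand() * sqdt;
            double fn = f[n] + fate_increment(f[n], s[n], B[n], chi, nu, delta, dt, dW);
            check_finite(fn, n, step);
            f[n] = fn;
        }
        for (int n = 0; n < N; ++n) s[n] *= (1.0 - dt);

        if (snaps.wants(step + 1)) {
            snaps.record(step + 1, dt, s, f);
            for (size_t i = 0; i < a.size(); ++i) {
                if (a[i] < min_a) min_a = a[i];
                if (b[i] < min_b) min_b = b[i];
            }
        }
    }
    for (size_t i = 0; i < a.size(); ++i) {
        if (a[i] < min_a) min_a = a[i];
        if (b[i] < min_b) min_b = b[i];
    }
    NumericMatrix am(Ms, Ms), bm(Ms, Ms);
    std::copy(a.begin(), a.end(), am.begin());
    std::copy(b.begin(), b.end(), bm.begin());
    return List::create(_["s"] = wrap(s), _["f"] = wrap(f), _["bias"] = wrap(B),
                        _["a"] = am, _["b"] = bm,
                        _["min_field"] = NumericVector::create(min_a, min_b),
                        _["snapshots"] = snaps.out);
}

// [[Rcpp::export]]
List simulate_juxtacrine_cpp(int N,
                             IntegerVector pair_i, IntegerVector pair_j,
                             NumericVector pair_d,
                             double Sjuxt, double rc, double beta_lig,
                             double chi, double nu, double delta,
                             double dt, int nsteps,
                             IntegerVector snapshot_steps,
                             Nullable<NumericMatrix> noise) {
    const int P = pair_i.size();
    std::vector<double> w(P);
    for (int p = 0; p < P; ++p) {
        if (pair_d[p] <= 0) stop("non-positive neighbour distance");
        w[p] = 2.0 * rc / pair_d[p];
    }
    std::vector<double> s(N, 1.0), f(N, 0.0), B(N, 0.0), sig(N);
    bool have_noise = noise.isNotNull();
    NumericMatrix noise_m;
    if (have_noise) {
        noise_m = NumericMatrix(noise);
        if (noise_m.nrow() != nsteps || noise_m.ncol() != N)
            stop("noise matrix must be nsteps x N");
    }
    const double sqdt = std::sqrt(dt);
    SnapshotStore snaps(snapshot_steps);

    for (int step = 0; step < nsteps; ++step) {
        // ligand signal beta_a - beta_b of each cell at the start of the step
        for (int n = 0; n < N; ++n) {
            double sgn = (f[n] > 0.0) ? 1.0 : ((f[n] < 0.0) ? -1.0 : 0.0);
            sig[n] = beta_lig * (1.0 - s[n]) * sgn;
        }
        std::fill(B.begin(), B.end(), 0.0);
        for (int p = 0; p < P; ++p) {
            int i = pair_i[p] - 1, j = pair_j[p] - 1;
            B[i] += Sjuxt * w[p] * sig[j];
            B[j] += Sjuxt * w[p] * sig[i];
        }
        for (int n = 0; n < N; ++n) {
            double dW = have_noise ? noise_m(step, n) * sqdt : norm_rand() * sqdt;
            double fn = f[n] + fate_increment(f[n], s[n], B[n], chi, nu, delta, dt, dW);
            check_finite(fn, n, step);
            f[n] = fn;
        }
        for (int n = 0; n < N; ++n) s[n] *= (1.0 - dt);
        if (snaps.wants(step + 1)) snaps.record(step + 1, dt, s, f);
    }
    return List::create(_["s"] = wrap(s), _["f"] = wrap(f), _["bias"] = wrap(B),
                        _["snapshots"] = snaps.out);
}
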