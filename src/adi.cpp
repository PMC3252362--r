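#include <Rcpp.h>
#include <cmath>
#include "adi.h"

using namespace Rcpp;

void CyclicTridiag::init(int n_, double ad_, double ao_) {
    n = n_; ad = ad_; ao = ao_;
    double gamma = -ad;
    vfac = ao / gamma;
    d.assign(n, ad);
    d[0] = ad - gamma;              // 2 ad
    d[n - 1] = ad - ao * ao / gamma;
    cp.assign(n, 0.0);
    cp[0] = ao / d[0];
    for (int i = 1; i < n; ++i) cp[i] = ao / (d[i] - ao * cp[i - 1]);
    // z = A'^{-1} u with u = (gamma, 0, ..., 0, ao)
    z.assign(n, 0.0);
    z[0] = gamma; z[n - 1] = ao;
    std::vector<double> y(n);
    // plain Thomas on z (cannot call solve(): correction not yet set up)
    y[0] = z[0] / d[0];
    for (int i = 1; i < n; ++i)
        y[i] = (z[i] - ao * y[i - 1]) / (d[i] - ao * cp[i - 1]);
    z[n - 1] = y[n - 1];
    for (int i = n - 2; i >= 0; --i) z[i] = y[i] - cp[i] * z[i + 1];
    corr_den = 1.0 + z[0] + vfac * z[n - 1];
}

void CyclicTridiag::solve(double* rhs, double* y) const {
    y[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
        y[i] = (rhs[i] - ao * y[i - 1]) / (d[i] - ao * cp[i - 1]);
    rhs[n - 1] = y[n - 1];
    for (int i = n - 2; i >= 0; --i) rhs[i] = y[i] - cp[i] * rhs[i + 1];
    double f = (rhs[0] + vfac * rhs[n - 1]) / corr_den;
    for (int i = 0; i < n; ++i) rhs[i] -= f * z[i];
}

// Douglas splitting of du/dt = A1 u + A2 u + src with
// A1 = D d2/dx2 - lambda/2, A2 = D d2/dy2 - lambda/2:
//   (I - dt/2 A1) u*     = (I + dt/2 A1 + dt A2) u^n + dt src
//   (I - dt/2 A2) u^{n+1} = u* - dt/2 A2 u^n
// Second-order in dt; the uniform mode decays by exp(-lambda dt) + O(dt^3).
void adi_step_core(double* u, const double* src, int M,
                   double lambda, double dt,
                   const CyclicTridiag& fac, double beta, double* work) {
    double* rhs = work;                 // M*M, becomes u*
    double* rhs2 = work + (size_t)M * M; // M*M
    double* line = work + 2 * (size_t)M * M; // M
    double* y = line + M;                // M
    const double qlam = 0.25 * dt * lambda;
    const double hlam = 0.5 * dt * lambda;

    for (int k = 0; k < M; ++k) {
        int km = (k == 0) ? M - 1 : k - 1;
        int kp = (k == M - 1) ? 0 : k + 1;
        const double* uc = u + (size_t)M * k;
        const double* um = u + (size_t)M * km;
        const double* up = u + (size_t)M * kp;
        double* r = rhs + (size_t)M * k;
        for (int j = 0; j < M; ++j) {
            int jm = (j == 0) ? M - 1 : j - 1;
            int jp = (j == M - 1) ? 0 : j + 1;
            double dxx = uc[jm] - 2.0 * uc[j] + uc[jp];
            double dyy = um[j] - 2.0 * uc[j] + up[j];
            r[j] = uc[j] + beta * dxx - qlam * uc[j]
                 + 2.0 * beta * dyy - hlam * uc[j]
                 + dt * src[j + (size_t)M * k];
        }
    }
    // x-sweep: columns are contiguous
    for (int k = 0; k < M; ++k) fac.solve(rhs + (size_t)M * k, y);

    // rhs2 = u* - dt/2 A2 u^n
    for (int k = 0; k < M; ++k) {
        int km = (k == 0) ? M - 1 : k - 1;
        int kp = (k == M - 1) ? 0 : k + 1;
        const double* uc = u + (size_t)M * k;
        const double* um = u + (size_t)M * km;
        const double* up = u + (size_t)M * kp;
        double* r2 = rhs2 + (size_t)M * k;
        const double* us = rhs + (size_t)M * k;
        for (int j = 0; j < M; ++j) {
            double dyy = um[j] - 2.0 * uc[j] + up[j];
            r2[j] = us[j] - (beta * dyy - qlam * uc[j]);
        }
    }
    // y-sweep: gather strided rows
    for (int j = 0; j < M; ++j) {
        for (int k = 0; k < M; ++k) line[k] = rhs2[j + (size_t)M * k];
        fac.solve(line, y);
        for (int k = 0; k < M; ++k) u[j + (size_t)M * k] = line[k];
    }
}

// [[Rcpp::export]]
NumericMatrix adi_step_cpp(NumericMatrix field, NumericMatrix source,
                           double D, double lambda, double dt, double h) {
    int M = field.nrow();
    if (field.ncol() != M || source.nrow() != M || source.ncol() != M)
        stop("field and source must be square matrices of equal size");
    if (M < 3) stop("grid must be at least 3 x 3");
    NumericMatrix out = clone(field);
    double beta = D * dt / (2.0 * h * h);
    CyclicTridiag fac;
    fac.init(M, 1.0 + 2.0 * beta + 0.25 * dt * lambda, -beta);
    std::vector<double> work(3 * (size_t)M * M + 2 * M);
    adi_step_core(REAL(out), REAL(source), M, lambda, dt, fac, beta, work.data());
    for (R_xlen_t i = 0; i < out.size(); ++i)
        if (!R_finite(out[i])) stop("ADI step produced non-finite values");
    return out;
}
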