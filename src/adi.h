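#ifndef STEMPATTERNS_ADI_H
#define STEMPATTERNS_ADI_H

#include <vector>

// Constant-coefficient symmetric cyclic tridiagonal solver (Sherman-Morrison
// corner correction) with precomputed Thomas elimination factors.
struct CyclicTridiag {
    int n;
    double ad, ao;              // diagonal / off-diagonal entries
    std::vector<double> cp;     // precomputed elimination multipliers
    std::vector<double> d;      // modified diagonal (first/last entries differ)
    std::vector<double> z;      // A'^{-1} u for the rank-one correction
    double corr_den;            // 1 + v.z
    double vfac;                // ao / gamma
    CyclicTridiag() : n(0) {}
    void init(int n_, double ad_, double ao_);
    // solve in place; y is scratch of length n
    void solve(double* rhs, double* y) const;
};

// One Douglas ADI step of du/dt = D lap(u) - lambda u + src on an M x M
// periodic grid with spacing h; u is column-major (x index fastest), src is
// the instantaneous source density.  work must hold >= 3*M*M + 2*M doubles.
void adi_step_core(double* u, const double* src, int M,
                   double lambda, double dt,
                   const CyclicTridiag& fac, double beta, double* work);

#endif
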