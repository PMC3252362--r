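#include <Rcpp.h>
#include <vector>
#include "torus.h"

using namespace Rcpp;

// Pairwise speed v(r): singular repulsion below 2 r_c, adhesion out to the
// cut-off R_v, zero beyond.  Positive values push a pair apart.
static inline double pair_speed(double r, double A, double rc, double Rv) {
    if (r >= Rv) return 0.0;
    return A * rc * rc * (2.0 * rc - r) / (r * r * r);
}

struct CellGrid {
    int nb;          // bins per side
    double w;        // bin width (>= cutoff)
    std::vector<std::vector<int> > bins;
    CellGrid(const NumericMatrix& pos, double L, double cutoff) {
        nb = (int)std::floor(L / cutoff);
        if (nb < 1) nb = 1;
        w = L / nb;
        bins.assign((size_t)nb * nb, std::vector<int>());
        for (int i = 0; i < pos.nrow(); ++i) {
            int bx = (int)std::floor(pos(i, 0) / w); if (bx >= nb) bx = nb - 1;
            int by = (int)std::floor(pos(i, 1) / w); if (by >= nb) by = nb - 1;
            bins[(size_t)bx * nb + by].push_back(i);
        }
    }
};

// accumulate pair displacements for one Euler step into vel (N x 2)
static void accumulate_velocities(const NumericMatrix& pos, double L,
                                  double A, double rc, double Rv,
                                  bool use_grid, NumericMatrix& vel) {
    const int N = pos.nrow();
    const double floor_d = 1e-9 * rc;
    if (use_grid && std::floor(L / Rv) < 3) use_grid = false;  // 3x3 stencil needs >= 3 bins
    if (!use_grid || N < 2) {
        for (int i = 0; i < N; ++i) {
            for (int j = i + 1; j < N; ++j) {
                double dx = torus_delta(pos(i, 0) - pos(j, 0), L);
                double dy = torus_delta(pos(i, 1) - pos(j, 1), L);
                double r = std::sqrt(dx * dx + dy * dy);
                if (r >= Rv) continue;
                if (r < floor_d)
                    stop("coincident cells %d and %d (separation %g)", i + 1, j + 1, r);
                double v = pair_speed(r, A, rc, Rv);
                double ux = v * dx / r, uy = v * dy / r;
                vel(i, 0) += ux; vel(i, 1) += uy;
                vel(j, 0) -= ux; vel(j, 1) -= uy;
            }
        }
        return;
    }
    CellGrid grid(pos, L, Rv);
    int nb = grid.nb;
    for (int bx = 0; bx < nb; ++bx) {
        for (int by = 0; by < nb; ++by) {
            const std::vector<int>& me = grid.bins[(size_t)bx * nb + by];
            if (me.empty()) continue;
            for (int ox = -1; ox <= 1; ++ox) {
                for (int oy = -1; oy <= 1; ++oy) {
                    int cx = (bx + ox + nb) % nb, cy = (by + oy + nb) % nb;
                    const std::vector<int>& other = grid.bins[(size_t)cx * nb + cy];
                    for (size_t a = 0; a < me.size(); ++a) {
                        int i = me[a];
                        for (size_t b = 0; b < other.size(); ++b) {
                            int j = other[b];
                            if (j <= i) continue;  // each pair once
                            double dx = torus_delta(pos(i, 0) - pos(j, 0), L);
                            double dy = torus_delta(pos(i, 1) - pos(j, 1), L);
                            double r = std::sqrt(dx * dx + dy * dy);
                            if (r >= Rv) continue;
                            if (r < floor_d)
                                stop("coincident cells %d and %d (separation %g)",
                                     i + 1, j + 1, r);
                            double v = pair_speed(r, A, rc, Rv);
                            double ux = v * dx / r, uy = v * dy / r;
                            vel(i, 0) += ux; vel(i, 1) += uy;
                            vel(j, 0) -= ux; vel(j, 1) -= uy;
                        }
                    }
                }
            }
        }
    }
}

// [[Rcpp::export]]
NumericMatrix relax_positions_cpp(NumericMatrix positions, double L,
                                  double A, double rc, double Rv,
                                  double dt, int nsteps, bool use_grid) {
    NumericMatrix pos = clone(positions);
    const int N = pos.nrow();
    NumericMatrix vel(N, 2);
    for (int step = 0; step < nsteps; ++step) {
        std::fill(vel.begin(), vel.end(), 0.0);
        accumulate_velocities(pos, L, A, rc, Rv, use_grid, vel);
        for (int i = 0; i < N; ++i) {
            double x = pos(i, 0) + dt * vel(i, 0);
            double y = pos(i, 1) + dt * vel(i, 1);
            if (!R_finite(x) || !R_finite(y))
                stop("non-finite position for cell %d at relaxation step %d",
                     i + 1, step + 1);
            pos(i, 0) = torus_wrap(x, L);
            pos(i, 1) = torus_wrap(y, L);
        }
    }
    return pos;
}

// All pairs with minimum-image distance strictly below cutoff.
// Returns 1-based index pairs (i < j) and distances.
// [[Rcpp::export]]
List neighbour_pairs_cpp(NumericMatrix pos, double L, double cutoff,
                         bool use_grid) {
    const int N = pos.nrow();
    std::vector<int> pi, pj;
    std::vector<double> pd;
    const double floor_d = 1e-9;
    if (use_grid && std::floor(L / cutoff) < 3) use_grid = false;
    if (!use_grid || N < 2) {
        for (int i = 0; i < N; ++i)
            for (int j = i + 1; j < N; ++j) {
                double r = torus_dist(pos(i, 0), pos(i, 1), pos(j, 0), pos(j, 1), L);
                if (r < cutoff) {
                    if (r < floor_d)
                        stop("coincident cells %d and %d", i + 1, j + 1);
                    pi.push_back(i + 1); pj.push_back(j + 1); pd.push_back(r);
                }
            }
    } else {
        CellGrid grid(pos, L, cutoff);
        int nb = grid.nb;
        for (int bx = 0; bx < nb; ++bx)
            for (int by = 0; by < nb; ++by) {
                const std::vector<int>& me = grid.bins[(size_t)bx * nb + by];
                if (me.empty()) continue;
                for (int ox = -1; ox <= 1; ++ox)
                    for (int oy = -1; oy <= 1; ++oy) {
                        int cx = (bx + ox + nb) % nb, cy = (by + oy + nb) % nb;
                        const std::vector<int>& other = grid.bins[(size_t)cx * nb + cy];
                        for (size_t a = 0; a < me.size(); ++a) {
                            int i = me[a];
                            for (size_t b = 0; b < other.size(); ++b) {
                                int j = other[b];
                                if (j <= i) continue;
                                double r = torus_dist(pos(i, 0), pos(i, 1),
                                                      pos(j, 0), pos(j, 1), L);
                                if (r < cutoff) {
                                    if (r < floor_d)
                                        stop("coincident cells %d and %d", i + 1, j + 1);
                                    pi.push_back(i + 1); pj.push_back(j + 1);
                                    pd.push_back(r);
                                }
                            }
                        }
                    }
            }
    }
    return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj), _["d"] = wrap(pd));
}
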