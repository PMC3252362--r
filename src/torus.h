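#ifndef STEMPATTERNS_TORUS_H
#define STEMPATTERNS_TORUS_H

#include <cmath>

// Doubly periodic square [0, L) x [0, L).

// wrap a coordinate into [0, L); same convention as R's x %% L
inline double torus_wrap(double x, double L) {
    double y = x - L * std::floor(x / L);
    if (y >= L) y = 0.0;  // guard against rounding at the seam
    if (y < 0.0) y = 0.0;
    return y;
}

// map a coordinate difference into (-L/2, L/2]
inline double torus_delta(double d, double L) {
    d -= L * std::floor(d / L);   // now in [0, L)
    if (d > 0.5 * L) d -= L;
    return d;
}

inline double torus_dist(double x1, double y1, double x2, double y2, double L) {
    double dx = torus_delta(x1 - x2, L);
    double dy = torus_delta(y1 - y2, L);
    return std::sqrt(dx * dx + dy * dy);
}

#endif
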