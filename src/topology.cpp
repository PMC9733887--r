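#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum-image displacement on a periodic interval of length L.
static inline double min_image(double d, double L) {
    return d - L * std::round(d / L);
}

// Distance-thresholded connectivity with Gaussian distance-decaying,
// per-source normalized weights. Targets are sorted ascending by periodic
// distance, ties broken by neuron index (a total order is required by the
// coalescence fallback during simulation).
//
// Returns CSR-like arrays: ptr (length N+1, 0-based offsets), targets
// (1-based neuron indices) and weights (sum to 1 per source).
// [[Rcpp::export]]
List buildConnectivityCpp(NumericMatrix pos, double L, double dmax,
                          double sigma) {
    const int n = pos.nrow();
    if (dmax >= L / 2)
        stop("d_max must be < L/2 for the minimum-image convention");

    // cell list: cell edge >= dmax so 3x3 neighborhoods cover the cutoff
    int ncell = std::max(1, (int)std::floor(L / dmax));
    const double cell = L / ncell;
    std::vector<std::vector<int> > cells(ncell * ncell);
    std::vector<int> cx(n), cy(n);
    for (int i = 0; i < n; ++i) {
        int ix = (int)std::floor(pos(i, 0) / cell);
        int iy = (int)std::floor(pos(i, 1) / cell);
        if (ix >= ncell) ix = ncell - 1;
        if (iy >= ncell) iy = ncell - 1;
        cx[i] = ix;
        cy[i] = iy;
        cells[ix + ncell * iy].push_back(i);
    }

    const double d2max = dmax * dmax;
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

    std::vector<int> ptr(n + 1, 0);
    std::vector<int> targets;
    std::vector<double> weights;
    targets.reserve((size_t)n * 64);
    weights.reserve((size_t)n * 64);

    std::vector<std::pair<double, int> > cand;
    for (int i = 0; i < n; ++i) {
        cand.clear();
        const double xi = pos(i, 0), yi = pos(i, 1);
        for (int dxc = -1; dxc <= 1; ++dxc) {
            for (int dyc = -1; dyc <= 1; ++dyc) {
                int jx = (cx[i] + dxc + ncell) % ncell;
                int jy = (cy[i] + dyc + ncell) % ncell;
                // ncell < 3 would revisit cells; dedupe via the flat index
                if (ncell < 3) {
                    bool dup = false;
                    for (int ax = -1; ax < dxc; ++ax)
                        for (int ay = -1; ay <= 1; ++ay)
                            if ((cx[i] + ax + ncell) % ncell == jx &&
                                (cy[i] + ay + ncell) % ncell == jy &&
                                (ax < dxc || ay < dyc))
                                dup = true;
                    if (dup) continue;
                }
                const std::vector<int>& bucket = cells[jx + ncell * jy];
                for (size_t b = 0; b < bucket.size(); ++b) {
                    const int j = bucket[b];
                    if (j == i) continue;
                    const double dx = min_image(pos(j, 0) - xi, L);
                    const double dy = min_image(pos(j, 1) - yi, L);
                    const double d2 = dx * dx + dy * dy;
                    if (d2 <= d2max) cand.push_back(std::make_pair(d2, j));
                }
            }
        }
        std::sort(cand.begin(), cand.end());
        double omega = 0.0;
        const size_t k0 = weights.size();
        for (size_t c = 0; c < cand.size(); ++c) {
            const double w = std::exp(-cand[c].first * inv2s2);
            targets.push_back(cand[c].second + 1);
            weights.push_back(w);
            omega += w;
        }
        if (omega > 0)
            for (size_t c = k0; c < weights.size(); ++c) weights[c] /= omega;
        ptr[i + 1] = (int)targets.size();
    }

    return List::create(_["ptr"] = wrap(ptr), _["targets"] = wrap(targets),
                        _["weights"] = wrap(weights));
}

// Periodic minimum-image distances from each of n points to each of m
// reference points (e.g. neurons to electrodes). Returns n x m matrix.
// [[Rcpp::export]]
NumericMatrix periodicDistanceCpp(NumericMatrix a, NumericMatrix b,
                                  double L) {
    const int n = a.nrow(), m = b.nrow();
    NumericMatrix out(n, m);
    for (int j = 0; j < m; ++j) {
        const double xj = b(j, 0), yj = b(j, 1);
        for (int i = 0; i < n; ++i) {
            const double dx = min_image(a(i, 0) - xj, L);
            const double dy = min_image(a(i, 1) - yj, L);
            out(i, j) = std::sqrt(dx * dx + dy * dy);
        }
    }
    return out;
}
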