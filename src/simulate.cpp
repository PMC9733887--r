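#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include "rng.h"
using namespace Rcpp;

// Binomial(n, p) by inversion; counts the spontaneously driven neurons per
// step. Per-step means are small (N*h ~ 2-320), so the linear search is
// cheap and exact.
static int rbinom_inv(Xoshiro256pp& rng, int n, double p) {
    if (p <= 0.0) return 0;
    if (p >= 1.0) return n;
    const double u = rng.unif();
    double f = std::exp(n * std::log1p(-p));  // P(X = 0)
    double cdf = f;
    const double odds = p / (1.0 - p);
    int k = 0;
    while (u > cdf && k < n) {
        f *= odds * (double)(n - k) / (double)(k + 1);
        cdf += f;
        ++k;
    }
    return k;
}

// Driven branching process with coalescence compensation on a fixed
// topology (CSR arrays; targets sorted by distance, i.e. weight-descending).
//
// Per step: every active neuron i attempts each listed connection j with
// success probability m*w_ij; a success on a target already marked for the
// next step is redirected to the next quiescent entry of i's distance-sorted
// list (wrapping to the head; dropped if none). Afterwards every neuron
// spikes spontaneously with probability h. method = "skip" draws successes
// by exact geometric-skip thinning over the weight-descending list
// (equivalent in law to per-target Bernoulli draws); "naive" loops all
// targets.
// [[Rcpp::export]]
List simulateBranchingCpp(IntegerVector ptr, IntegerVector targets,
                          NumericVector weights, int nNeurons, double m,
                          double h, int nSteps, double seed, bool compensate,
                          std::string method, IntegerVector initActive) {
    const int n = nNeurons;
    const bool skip = (method == "skip");
    Xoshiro256pp rng((uint64_t)seed);

    std::vector<int> stamp(n, -1);       // step for which neuron is marked
    std::vector<int> spont_stamp(n, -1); // spontaneous draw bookkeeping
    std::vector<int> cur, nxt;
    cur.reserve(1024);
    nxt.reserve(1024);

    for (int k = 0; k < initActive.size(); ++k)
        cur.push_back(initActive[k] - 1);
    std::sort(cur.begin(), cur.end());

    IntegerVector activity(nSteps);
    std::vector<int> rStep, rNeuron;
    int saturated = 0, dropped = 0;

    for (int t = 0; t < nSteps; ++t) {
        nxt.clear();

        if (m > 0.0) {
            for (size_t a = 0; a < cur.size(); ++a) {
                const int i = cur[a];
                const int lo = ptr[i], hi = ptr[i + 1];
                for (int j = lo; j < hi; ++j) {
                    double pj = m * weights[j];
                    if (skip) {
                        // envelope = current entry (list is weight-sorted)
                        if (pj <= 0.0) break;
                        if (pj < 1.0) {
                            const double g = std::floor(
                                std::log1p(-rng.unif()) / std::log1p(-pj));
                            if (g > (double)(hi - 1 - j)) break;
                            const int jn = j + (int)g;
                            // accept candidate with true/envelope ratio
                            if (m * weights[jn] < pj * rng.unif()) {
                                j = jn;
                                continue;
                            }
                            j = jn;
                        }
                    } else {
                        if (rng.unif() >= pj) continue;
                    }
                    // successful activation at list position j
                    int tgt = targets[j] - 1;
                    if (stamp[tgt] == t) {
                        if (!compensate) continue;
                        tgt = -1;
                        for (int w = j + 1; w < hi; ++w) {
                            const int c = targets[w] - 1;
                            if (stamp[c] != t) { tgt = c; break; }
                        }
                        if (tgt < 0) {
                            for (int w = lo; w < j; ++w) {
                                const int c = targets[w] - 1;
                                if (stamp[c] != t) { tgt = c; break; }
                            }
                        }
                        if (tgt < 0) { ++dropped; continue; }
                    }
                    stamp[tgt] = t;
                    nxt.push_back(tgt);
                }
            }
        }

        // spontaneous drive: a uniform subset of size Binomial(N, h)
        const int k = rbinom_inv(rng, n, h);
        for (int c = 0; c < k; ++c) {
            int idx;
            do {
                idx = rng.below(n);
            } while (spont_stamp[idx] == t);
            spont_stamp[idx] = t;
            if (stamp[idx] != t) {
                stamp[idx] = t;
                nxt.push_back(idx);
            }
        }

        std::sort(nxt.begin(), nxt.end());
        activity[t] = (int)nxt.size();
        if ((int)nxt.size() == n) ++saturated;
        for (size_t a = 0; a < nxt.size(); ++a) {
            rStep.push_back(t + 1);
            rNeuron.push_back(nxt[a] + 1);
        }
        cur.swap(nxt);
    }

    return List::create(_["step"] = wrap(rStep), _["neuron"] = wrap(rNeuron),
                        _["activity"] = activity,
                        _["saturatedSteps"] = saturated,
                        _["droppedActivations"] = dropped);
}
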