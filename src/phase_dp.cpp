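#include <Rcpp.h>
using namespace Rcpp;

// Exact minimum-recombination chain phasing by DP over meiosis states.
// t: heterozygous-marker x meiosis matrix of transmitted alleles (0/1,
// NA = undetermined). State = bit vector of current transmitted-haplotype
// indicators, one bit per meiosis. At each marker the phase choice forces
// the bits of the meioses informative there (z = t XOR phi); one event is
// charged per forced bit change, via a Hamming-penalized minimum over
// predecessor states computed by per-bit relaxation. Returns the phase
// vector phi (0/1 per marker); ties take the lowest state index.
// [[Rcpp::export(name = ".phaseDPCpp")]]
IntegerVector phase_dp_cpp(IntegerMatrix t) {
    const int nh = t.nrow(), noff = t.ncol();
    IntegerVector phi(nh);
    if (nh == 0) return phi;
    if (noff > 24) stop("too many meioses for exact DP");
    const int S = 1 << noff;
    const double INF = 1e18;

    std::vector<double> cost(S, 0.0), rel(S), nxt(S);
    // per-marker: informative mask, forced-bit patterns under phi = 0/1
    std::vector<int> maskJ(nh), m0J(nh), m1J(nh);
    std::vector<double> costMat((size_t)(nh + 1) * S);

    for (int j = 0; j < nh; ++j) {
        std::copy(cost.begin(), cost.end(),
                  costMat.begin() + (size_t)j * S);
        int mask = 0, m0 = 0;
        for (int o = 0; o < noff; ++o) {
            int v = t(j, o);
            if (v == NA_INTEGER) continue;
            mask |= (1 << o);
            if (v & 1) m0 |= (1 << o);
        }
        maskJ[j] = mask; m0J[j] = m0; m1J[j] = m0 ^ mask;
        if (mask == 0) { phi[j] = 0; continue; }
        rel = cost;
        for (int o = 0; o < noff; ++o) {
            if (!(mask & (1 << o))) continue;
            const int b = 1 << o;
            for (int s = 0; s < S; ++s) {
                double alt = rel[s ^ b] + 1.0;
                if (alt < rel[s]) rel[s] = alt;
            }
        }
        const int m0j = m0J[j], m1j = m1J[j];
        for (int s = 0; s < S; ++s) {
            int ib = s & mask;
            cost[s] = (ib == m0j || ib == m1j) ? rel[s] : INF;
        }
    }
    std::copy(cost.begin(), cost.end(), costMat.begin() + (size_t)nh * S);

    // backtrack: pick the best final state, then the Hamming-penalized
    // minimum predecessor within the forced-bit subcube of each marker
    int s = 0;
    {
        double best = cost[0];
        for (int k = 1; k < S; ++k)
            if (cost[k] < best) { best = cost[k]; s = k; }
    }
    for (int j = nh - 1; j >= 0; --j) {
        const int mask = maskJ[j];
        if (mask == 0) { phi[j] = 0; continue; }
        phi[j] = ((s & mask) == m0J[j]) ? 0 : 1;
        const double *prev = &costMat[(size_t)j * S];
        const int base = s & ~mask;
        const int forced = s & mask;
        // enumerate subcube: predecessor inf bits = forced ^ c, c subset
        int bestState = base | forced;
        double bestVal = INF;
        for (int c = mask;; c = (c - 1) & mask) {
            int p = base | (forced ^ c);
            double v = prev[p] + __builtin_popcount(c);
            if (v < bestVal - 1e-12 ||
                (v < bestVal + 1e-12 && p < bestState)) {
                bestVal = v; bestState = p;
            }
            if (c == 0) break;
        }
        s = bestState;
    }
    return phi;
}
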