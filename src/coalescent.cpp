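#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <set>
using namespace Rcpp;

// Structured coalescent for one non-recombining block.
//
// Lineages coalesce within populations at rate choose(k,2)/(2N) per
// generation (N diploid). Backward-time events: size changes, merges
// (forward-time splits) and migration pulses. Mutations are dropped on the
// resulting genealogy under the infinite-sites model, one biallelic SNP per
// mutation, positions uniform on the block.
//
// Uses R's RNG so set.seed() in R gives reproducible output.

struct Demog {
    std::vector<double> time;   // ascending, > 0 (generations)
    std::vector<int> type;      // 0 = size change, 1 = merge, 2 = pulse
    std::vector<int> pop;       // affected pop (child/source for merge/pulse)
    std::vector<int> dest;      // destination pop for merge/pulse, else -1
    std::vector<double> value;  // new diploid size, or pulse probability
};

static void simulate_tree(const std::vector<int>& nPerPop,
                          const std::vector<double>& popSize0,
                          const Demog& dg,
                          std::vector<int>& parent,
                          std::vector<double>& ntime) {
    const int nPops = popSize0.size();
    int nLeaves = 0;
    for (int p = 0; p < nPops; ++p) nLeaves += nPerPop[p];
    const int maxNodes = 2 * nLeaves - 1;
    parent.assign(maxNodes, -1);
    ntime.assign(maxNodes, 0.0);

    std::vector<int> pop(maxNodes, 0);
    std::vector<int> active;
    active.reserve(nLeaves);
    {
        int id = 0;
        for (int p = 0; p < nPops; ++p)
            for (int i = 0; i < nPerPop[p]; ++i) { pop[id] = p; active.push_back(id); ++id; }
    }
    std::vector<double> N = popSize0;
    double t = 0.0;
    size_t evIdx = 0;
    int nextNode = nLeaves;

    while ((int)active.size() > 1) {
        // per-population lineage counts and coalescent rates
        std::vector<int> k(nPops, 0);
        for (int id : active) k[pop[id]]++;
        double rate = 0.0;
        std::vector<double> prate(nPops, 0.0);
        for (int p = 0; p < nPops; ++p) {
            if (k[p] >= 2) {
                prate[p] = (double)k[p] * (k[p] - 1) / (4.0 * N[p]);
                rate += prate[p];
            }
        }
        double nextEv = (evIdx < dg.time.size()) ? dg.time[evIdx] : R_PosInf;
        if (rate <= 0.0) {
            if (!R_FINITE(nextEv))
                stop("demographic model leaves lineages in separate populations forever (no common ancestor)");
            t = nextEv;
        } else {
            double dt = R::rexp(1.0 / rate);
            if (t + dt >= nextEv) {
                t = nextEv;
            } else {
                t += dt;
                // choose population, then an unordered lineage pair within it
                double u = unif_rand() * rate, acc = 0.0;
                int chosen = nPops - 1;
                for (int p = 0; p < nPops; ++p) { acc += prate[p]; if (u <= acc) { chosen = p; break; } }
                std::vector<int> idx;
                for (size_t i = 0; i < active.size(); ++i)
                    if (pop[active[i]] == chosen) idx.push_back(i);
                int a = (int)(unif_rand() * idx.size()); if (a >= (int)idx.size()) a = idx.size() - 1;
                int b = (int)(unif_rand() * (idx.size() - 1)); if (b >= (int)idx.size() - 1) b = idx.size() - 2;
                if (b >= a) ++b;
                int ia = idx[a], ib = idx[b];
                int na = active[ia], nb = active[ib];
                parent[na] = nextNode; parent[nb] = nextNode;
                ntime[nextNode] = t; pop[nextNode] = chosen;
                // replace the two with the new node (order-stable removal)
                if (ia > ib) std::swap(ia, ib);
                active[ia] = nextNode;
                active.erase(active.begin() + ib);
                ++nextNode;
                continue;
            }
        }
        // apply all events scheduled at time t
        while (evIdx < dg.time.size() && dg.time[evIdx] <= t) {
            int ty = dg.type[evIdx], p = dg.pop[evIdx];
            if (ty == 0) {
                N[p] = dg.value[evIdx];
            } else if (ty == 1) {
                for (size_t i = 0; i < active.size(); ++i)
                    if (pop[active[i]] == p) pop[active[i]] = dg.dest[evIdx];
            } else { // pulse
                for (size_t i = 0; i < active.size(); ++i)
                    if (pop[active[i]] == p && unif_rand() < dg.value[evIdx])
                        pop[active[i]] = dg.dest[evIdx];
            }
            ++evIdx;
        }
    }
}

// [[Rcpp::export(name = ".simBlocksCpp")]]
List sim_blocks_cpp(IntegerVector nPerPop, NumericVector popSize0,
                    NumericVector evTime, IntegerVector evType,
                    IntegerVector evPop, IntegerVector evDest,
                    NumericVector evValue,
                    double chromLen, double blockLen, double mu) {
    Demog dg;
    dg.time = as<std::vector<double> >(evTime);
    dg.type = as<std::vector<int> >(evType);
    dg.pop = as<std::vector<int> >(evPop);
    dg.dest = as<std::vector<int> >(evDest);
    dg.value = as<std::vector<double> >(evValue);
    std::vector<int> npp = as<std::vector<int> >(nPerPop);
    std::vector<double> ps0 = as<std::vector<double> >(popSize0);

    int nLeaves = 0;
    for (size_t i = 0; i < npp.size(); ++i) nLeaves += npp[i];
    if (nLeaves < 2) stop("need at least two sampled chromosomes");

    std::vector<int> positions;
    std::vector<std::vector<char> > haps; // per site, length nLeaves

    std::vector<int> parent;
    std::vector<double> ntime;
    int nBlocks = (int)std::ceil(chromLen / blockLen);
    for (int b = 0; b < nBlocks; ++b) {
        double bstart = (double)b * blockLen;
        double blen = std::min(blockLen, chromLen - bstart);
        simulate_tree(npp, ps0, dg, parent, ntime);
        int nNodes = 2 * nLeaves - 1;
        // total branch length
        double L = 0.0;
        for (int i = 0; i < nNodes - 1; ++i) L += ntime[parent[i]] - ntime[i];
        int nmut = (int)R::rpois(mu * blen * L);
        if (nmut == 0) continue;
        // children lists for carrier lookup
        std::vector<std::vector<int> > children(nNodes);
        for (int i = 0; i < nNodes - 1; ++i) children[parent[i]].push_back(i);
        std::set<int> used;
        for (int m = 0; m < nmut; ++m) {
            // branch proportional to length
            double u = unif_rand() * L, acc = 0.0;
            int br = nNodes - 2;
            for (int i = 0; i < nNodes - 1; ++i) {
                acc += ntime[parent[i]] - ntime[i];
                if (u <= acc) { br = i; break; }
            }
            // unique integer position within the block
            int posn = 0; int tries = 0;
            do {
                posn = (int)(bstart + unif_rand() * blen) + 1; // 1-based bp
                ++tries;
            } while (used.count(posn) && tries < 100);
            if (used.count(posn)) continue;
            used.insert(posn);
            // carriers = leaf descendants of br
            std::vector<char> row(nLeaves, 0);
            std::vector<int> stack; stack.push_back(br);
            while (!stack.empty()) {
                int nd = stack.back(); stack.pop_back();
                if (nd < nLeaves) row[nd] = 1;
                else for (int c : children[nd]) stack.push_back(c);
            }
            positions.push_back(posn);
            haps.push_back(row);
        }
    }
    // sort by position
    int nSites = positions.size();
    std::vector<int> ord(nSites);
    for (int i = 0; i < nSites; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return positions[a] < positions[b]; });
    IntegerVector pos(nSites);
    IntegerMatrix geno(nSites, nLeaves);
    for (int i = 0; i < nSites; ++i) {
        pos[i] = positions[ord[i]];
        const std::vector<char>& row = haps[ord[i]];
        for (int j = 0; j < nLeaves; ++j) geno(i, j) = row[j];
    }
    return List::create(_["pos"] = pos, _["haplotypes"] = geno);
}
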