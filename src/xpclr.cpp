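#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// XP-CLR grid scoring.
//
// Neutral model: object (dog) allele frequency p drifts from the reference
// (wolf) frequency p2 as a truncated Gaussian with variance omega*p2*(1-p2);
// probability mass pushed past 0 or 1 is absorbed as fixation. The observed
// alt count k out of nChrom object chromosomes is binomial given p.
//
// Sweep model at a grid point: a lineage at recombination distance r (M)
// from the swept site escapes the sweep with probability c = 1 - exp(-r/s),
// where s is the selection scale (M) maximised over a grid. With probability
// p2 the swept haplotype carries the alt allele, mapping the pre-sweep
// frequency x to (1-c) + c*x; otherwise to c*x. s = 0 is defined as c = 1
// (pure neutrality), so the likelihood-ratio score is >= 0 by construction.

static inline double binom_pmf(double lcoef, int k, int n, double p) {
    if (p <= 0.0) return (k == 0) ? 1.0 : 0.0;
    if (p >= 1.0) return (k == n) ? 1.0 : 0.0;
    return std::exp(lcoef + k * std::log(p) + (n - k) * std::log1p(-p));
}

// [[Rcpp::export(name = ".xpclrGridCpp")]]
NumericMatrix xpclr_grid_cpp(IntegerVector k1, int nChrom,
                             NumericVector p2, NumericVector posBp,
                             NumericVector posM, NumericVector gridBp,
                             NumericVector gridM, NumericVector sGrid,
                             double omega, NumericVector qx, NumericVector qw,
                             double halfWinBp, int maxSnps) {
    const int nSnp = k1.size(), nGrid = gridBp.size();
    const int nq = qx.size(), nS = sGrid.size();

    // per-SNP quantities independent of the grid point
    std::vector<double> lcoef(nSnp), m0(nSnp), m1(nSnp);
    std::vector<std::vector<double> > wphi(nSnp, std::vector<double>(nq));
    for (int i = 0; i < nSnp; ++i) {
        lcoef[i] = R::lchoose((double)nChrom, (double)k1[i]);
        double pc = p2[i];
        double sig = std::sqrt(omega * pc * (1.0 - pc));
        if (sig < 1e-8) sig = 1e-8;
        m0[i] = R::pnorm(0.0, pc, sig, 1, 0);
        m1[i] = R::pnorm(1.0, pc, sig, 0, 0);
        for (int j = 0; j < nq; ++j)
            wphi[i][j] = qw[j] * R::dnorm(qx[j], pc, sig, 0);
    }

    NumericMatrix out(nGrid, 2); // score, nSnps used
    int lo = 0, hi = 0;
    for (int g = 0; g < nGrid; ++g) {
        double centre = gridBp[g];
        while (lo < nSnp && posBp[lo] < centre - halfWinBp) ++lo;
        if (hi < lo) hi = lo;
        while (hi < nSnp && posBp[hi] <= centre + halfWinBp) ++hi;
        int nUse = hi - lo;
        if (nUse < 1) { out(g, 0) = NA_REAL; out(g, 1) = 0; continue; }
        int step = 1;
        if (maxSnps > 0 && nUse > maxSnps) step = (nUse + maxSnps - 1) / maxSnps;

        std::vector<double> ll(nS, 0.0);
        int used = 0;
        for (int i = lo; i < hi; i += step) {
            ++used;
            double pc = p2[i];
            double r = std::fabs(posM[i] - gridM[g]);
            for (int si = 0; si < nS; ++si) {
                double s = sGrid[si];
                double c = (s <= 0.0) ? 1.0 : (1.0 - std::exp(-r / s));
                double Lsw = 0.0, Lesc = 0.0;
                for (int j = 0; j < nq; ++j) {
                    double w = wphi[i][j];
                    Lsw  += w * binom_pmf(lcoef[i], k1[i], nChrom, (1.0 - c) + c * qx[j]);
                    Lesc += w * binom_pmf(lcoef[i], k1[i], nChrom, c * qx[j]);
                }
                Lsw  += m0[i] * binom_pmf(lcoef[i], k1[i], nChrom, 1.0 - c)
                      + m1[i] * binom_pmf(lcoef[i], k1[i], nChrom, 1.0);
                Lesc += m0[i] * binom_pmf(lcoef[i], k1[i], nChrom, 0.0)
                      + m1[i] * binom_pmf(lcoef[i], k1[i], nChrom, c);
                double L = pc * Lsw + (1.0 - pc) * Lesc;
                if (L < 1e-300) L = 1e-300;
                ll[si] += std::log(L);
            }
        }
        double best = ll[0];
        for (int si = 1; si < nS; ++si) if (ll[si] > best) best = ll[si];
        double score = 2.0 * (best - ll[0]);
        if (score < 0.0) score = 0.0;
        out(g, 0) = score;
        out(g, 1) = used;
    }
    return out;
}
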