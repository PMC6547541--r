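#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Empirical two-sided p of an absolute log-fold-change within a bin:
// (1 + #{null |lfc| >= obs}) / (N + 1), null values sorted ascending.
static inline double tail_p(double alfc, const double* nb, int nlen) {
  if (nlen == 0) return 1.0;
  const double* lo = std::lower_bound(nb, nb + nlen, alfc);
  int ge = nlen - (int)(lo - nb);
  return (1.0 + ge) / (nlen + 1.0);
}

struct NoiseModel {
  NumericVector breaks;   // inner bin breaks on log2 mean (length nbins - 1)
  NumericVector nulls;    // concatenated sorted |lfc| per bin
  IntegerVector offsets;  // length nbins + 1, start of each bin in nulls
  double pc;              // pseudocount
  int nbins;

  inline int bin_of(double logmean) const {
    const double* b = breaks.begin();
    return (int)(std::upper_bound(b, b + (nbins - 1), logmean) - b);
  }
  // signed score for one ordered pair of log2-transformed values
  inline double score_log(double la, double lb) const {
    if (la == lb) return 0.0;
    double lfc = la - lb;
    int k = bin_of(0.5 * (la + lb));
    double p = tail_p(std::fabs(lfc),
                      nulls.begin() + offsets[k], offsets[k + 1] - offsets[k]);
    double s = -std::log10(p);
    return lfc > 0 ? s : -s;
  }
};

// Raw DE scores for one cluster-pair comparison, exploiting sparsity.
// xa, xb: cells-x-genes CsparseMatrix slots for groups A and B (only the
// per-gene non-zero VALUES are used). Algebraically identical to enumerating
// all n1 x n2 cell pairs: zero-zero pairs score 0, zero-nonzero pairs are
// weighted by the zero count of the opposite group.
// [[Rcpp::export]]
List raw_score_sparse(NumericVector xa_x, IntegerVector xa_p, int n1,
                      NumericVector xb_x, IntegerVector xb_p, int n2,
                      int n_genes,
                      NumericVector breaks, NumericVector nulls,
                      IntegerVector offsets, double pc) {
  NoiseModel nm{breaks, nulls, offsets, pc, (int)offsets.size() - 1};
  NumericVector raw(n_genes), eff(n_genes);
  const double l0 = std::log2(pc);
  std::vector<double> la, lb;

  for (int g = 0; g < n_genes; ++g) {
    int a0 = xa_p[g], a1 = xa_p[g + 1];
    int b0 = xb_p[g], b1 = xb_p[g + 1];
    la.clear(); lb.clear();
    for (int i = a0; i < a1; ++i)
      if (xa_x[i] != 0.0) la.push_back(std::log2(xa_x[i] + pc));
    for (int j = b0; j < b1; ++j)
      if (xb_x[j] != 0.0) lb.push_back(std::log2(xb_x[j] + pc));
    int nza = n1 - (int)la.size();   // zero cells in A (incl. stored zeros)
    int nzb = n2 - (int)lb.size();
    double s = 0.0;
    for (double va : la) {
      if (nzb > 0) s += nzb * nm.score_log(va, l0);
      for (double vb : lb) s += nm.score_log(va, vb);
    }
    if (nza > 0)
      for (double vb : lb) s += nza * nm.score_log(l0, vb);
    raw[g] = s;
    eff[g] = (double)n1 * n2 - (double)nza * nzb;
  }
  return List::create(_["raw"] = raw, _["eff"] = eff);
}
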