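#include <Rcpp.h>
using namespace Rcpp;

// One-directional iHH accumulation from a core site over a pooled
// haplotype matrix. Haplotypes are grouped by identity over the growing
// span; extension stops at the last site before pooled EHH first drops
// below `cutoff`, at the data edge, or at a gap wider than `max_gap`
// (edge flag). The focal / non-focal EHH curves are integrated by
// trapezoids against physical position as the span grows.
//
// Returns c(ihh_focal, ihh_ref, edge_flag, truncated_at_core).
// `core` is a 0-based column index; `dir` is +1 (right) or -1 (left).
// [[Rcpp::export]]
NumericVector cpp_ihh_dir(const IntegerMatrix& A, const NumericVector& pos,
                          int core, int dir, double cutoff, double max_gap,
                          const LogicalVector& focal) {
  const int n = A.nrow(), m = A.ncol();
  const int* a = INTEGER(A);
  std::vector<char> isf(n);
  int nf = 0;
  for (int i = 0; i < n; ++i) {
    isf[i] = focal[i] ? 1 : 0;
    if (isf[i]) ++nf;
  }
  const int nr = n - nf;
  const double denom_p = (double)n * (n - 1);
  const double denom_f = (nf > 1) ? (double)nf * (nf - 1) : 1.0;
  const double denom_r = (nr > 1) ? (double)nr * (nr - 1) : 1.0;

  std::vector<int> g(n), g2(n);
  std::vector<int> cnt, cntf, cnt2, cntf2, remap;
  cnt.assign(2, 0); cntf.assign(2, 0);
  int ng = 2;
  {
    const int* col = a + (size_t)core * n;
    for (int i = 0; i < n; ++i) {
      g[i] = col[i];
      cnt[g[i]]++;
      if (isf[i]) cntf[g[i]]++;
    }
  }
  double sp = 0, sf = 0, sr = 0;
  for (int k = 0; k < ng; ++k) {
    sp += (double)cnt[k] * (cnt[k] - 1);
    sf += (double)cntf[k] * (cntf[k] - 1);
    int cr = cnt[k] - cntf[k];
    sr += (double)cr * (cr - 1);
  }
  if (sp / denom_p < cutoff)
    return NumericVector::create(0.0, 0.0, 0.0, 1.0);
  double ef = (nf > 1) ? sf / denom_f : 0.0;
  double er = (nr > 1) ? sr / denom_r : 0.0;

  double ihhf = 0, ihhr = 0, edge = 0;
  int j = core;
  for (;;) {
    int nxt = j + dir;
    if (nxt < 0 || nxt >= m) { edge = 1; break; }
    if (std::abs(pos[nxt] - pos[j]) > max_gap) { edge = 1; break; }
    remap.assign(2 * ng + 2, -1);
    cnt2.clear(); cntf2.clear();
    int ng2 = 0;
    const int* col = a + (size_t)nxt * n;
    for (int i = 0; i < n; ++i) {
      int key = g[i] * 2 + col[i];
      int t = remap[key];
      if (t < 0) {
        t = ng2++;
        remap[key] = t;
        cnt2.push_back(0);
        cntf2.push_back(0);
      }
      g2[i] = t;
      cnt2[t]++;
      if (isf[i]) cntf2[t]++;
    }
    sp = sf = sr = 0;
    for (int k = 0; k < ng2; ++k) {
      sp += (double)cnt2[k] * (cnt2[k] - 1);
      sf += (double)cntf2[k] * (cntf2[k] - 1);
      int cr = cnt2[k] - cntf2[k];
      sr += (double)cr * (cr - 1);
    }
    if (sp / denom_p < cutoff) break;  // nxt not retained
    double ef2 = (nf > 1) ? sf / denom_f : 0.0;
    double er2 = (nr > 1) ? sr / denom_r : 0.0;
    double d = std::abs(pos[nxt] - pos[j]);
    ihhf += d * (ef + ef2) / 2.0;
    ihhr += d * (er + er2) / 2.0;
    g.swap(g2);
    cnt.swap(cnt2);
    cntf.swap(cntf2);
    ng = ng2;
    ef = ef2; er = er2; j = nxt;
  }
  return NumericVector::create(ihhf, ihhr, edge, 0.0);
}
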