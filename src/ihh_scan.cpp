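#include <Rcpp.h>
using namespace Rcpp;

// Integrated EHH (both directions summed) for every core site of one
// population on one chromosome.  H: haplotypes x sites (0/1 alleles),
// pos: ascending bp positions.  EHH at distance 0 is 1 by definition;
// extension stops at the first site whose EHH falls below `truncation`,
// and that below-threshold point is excluded from the trapezoidal
// integral (so a curve that collapses immediately integrates to 0).
// [[Rcpp::export]]
NumericVector ihh_scan_cpp(IntegerMatrix H, NumericVector pos,
                           double truncation) {
  const int n = H.nrow(), S = H.ncol();
  if (n < 2) stop("need at least 2 haplotypes");
  NumericVector out(S);
  const double denom = (double)n * (n - 1) / 2.0;
  std::vector<int> g(n), g2(n), relab(2 * n + 2), cnt(n);

  for (int core = 0; core < S; ++core) {
    double area = 0.0;
    for (int dir = 0; dir < 2; ++dir) {
      std::fill(g.begin(), g.end(), 0);
      int ng = 1;
      double prev_e = 1.0, prev_d = 0.0;
      int j = core;
      while (true) {
        j += (dir == 0) ? -1 : 1;
        if (j < 0 || j >= S) break;
        int lim = 2 * ng + 2;
        std::fill(relab.begin(), relab.begin() + lim, -1);
        int newng = 0;
        for (int h = 0; h < n; ++h) {
          int key = g[h] * 2 + H(h, j);
          if (relab[key] < 0) relab[key] = newng++;
          g2[h] = relab[key];
        }
        std::fill(cnt.begin(), cnt.begin() + newng, 0);
        for (int h = 0; h < n; ++h) cnt[g2[h]]++;
        double hom = 0.0;
        for (int k = 0; k < newng; ++k)
          hom += (double)cnt[k] * (cnt[k] - 1) / 2.0;
        double e = hom / denom;
        double d = std::abs(pos[j] - pos[core]);
        if (e < truncation) break;
        area += (d - prev_d) * (e + prev_e) / 2.0;
        prev_e = e;
        prev_d = d;
        std::swap(g, g2);
        ng = newng;
        if (e <= 0.0) break;
      }
    }
    out[core] = area;
  }
  return out;
}
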