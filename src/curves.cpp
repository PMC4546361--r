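#include <Rcpp.h>
using namespace Rcpp;

// Coancestry-curve accumulator. Chunks (one row per copied segment across
// all sampled copy-paths) are compared between designated pairs of paths;
// each same-chromosome chunk pair contributes the product of the two
// (capped) cM sizes to the 0.1 cM bin of their midpoint separation,
// credited to the (donor group, donor group) cell.

// [[Rcpp::export]]
List accumulate_curves_cpp(const IntegerVector& path_of,   // chunk -> path id (1-based)
                           const IntegerVector& chrom,     // chunk chromosome id
                           const NumericVector& mid_cm,
                           const NumericVector& size_capped,
                           const IntegerVector& grp,       // 1-based donor group
                           int S,
                           const IntegerMatrix& pairs,     // P x 2 path ids
                           double bin_cm, double max_cm) {
  const int n = path_of.size();
  const int nbin = (int)std::lround(max_cm / bin_cm);
  NumericVector wt(S * S * nbin);
  NumericVector cnt(S * S * nbin);

  // index chunks by path id
  int maxp = 0;
  for (int i = 0; i < n; ++i) maxp = std::max(maxp, path_of[i]);
  std::vector<std::vector<int>> by_path(maxp + 1);
  for (int i = 0; i < n; ++i) by_path[path_of[i]].push_back(i);

  for (int p = 0; p < pairs.nrow(); ++p) {
    const std::vector<int>& A = by_path[pairs(p, 0)];
    const std::vector<int>& B = by_path[pairs(p, 1)];
    for (size_t a = 0; a < A.size(); ++a) {
      const int i = A[a];
      for (size_t b = 0; b < B.size(); ++b) {
        const int j = B[b];
        if (chrom[i] != chrom[j]) continue;
        double d = std::fabs(mid_cm[i] - mid_cm[j]);
        int bi = (int)std::lround(d / bin_cm);  // bin centred at bi*bin_cm
        if (bi < 1 || bi > nbin) continue;
        double w = size_capped[i] * size_capped[j];
        int g1 = grp[i] - 1, g2 = grp[j] - 1;
        int idx = (bi - 1) * S * S + g2 * S + g1;
        wt[idx] += w; cnt[idx] += 1.0;
        if (g1 != g2) {
          int idx2 = (bi - 1) * S * S + g1 * S + g2;
          wt[idx2] += w; cnt[idx2] += 1.0;
        }
      }
    }
  }
  wt.attr("dim") = IntegerVector::create(S, S, nbin);
  cnt.attr("dim") = IntegerVector::create(S, S, nbin);
  return List::create(_["weight"] = wt, _["count"] = cnt);
}
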