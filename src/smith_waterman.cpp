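#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment score (Smith-Waterman / Gotoh).
// A gap of length L costs gap_open + L * gap_extend (both negative).
// Bases are encoded 0..3 = A,C,G,T; 4 = N. N never matches (scores as
// mismatch against everything, including N).
// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(IntegerVector a, IntegerVector b,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e18;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;       // H[i-1][0]
    double F = NEG;          // gap in b (vertical), recomputed per row
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1] && a[i - 1] != 4) ? match : mismatch;
      // E[j]: gap consuming a (H[j] still holds row i-1 at this point);
      // F: gap consuming b (H[j-1] already updated to row i)
      E[j] = std::max(H[j] + gap_open + gap_extend, E[j] + gap_extend);
      F    = std::max(H[j - 1] + gap_open + gap_extend, F + gap_extend);
      double h = std::max(std::max(diag + s, 0.0), std::max(E[j], F));
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}
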