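#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps.
// A gap of length L costs gap_open + (L - 1) * gap_extend (both given as
// positive penalties). Traceback preference is fixed (diagonal, then gap in
// read, then gap in reference) so the result is deterministic; callers
// left-normalise gap placement afterwards.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string ref, std::string read,
                  double match = 2.0, double mismatch = -4.0,
                  double gap_open = 12.0, double gap_extend = 1.0) {
  const int n = ref.size(), m = read.size();
  const double NEG = -1e18;
  // M: ref[i] aligned to read[j]; X: gap in read (deletion);
  // Y: gap in ref (insertion). Indexed (n+1) x (m+1), row-major.
  std::vector<double> M((n + 1) * (m + 1), NEG), X = M, Y = M;
  std::vector<unsigned char> tbM(M.size()), tbX(M.size()), tbY(M.size());
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(gap_open + (i - 1) * gap_extend);
    tbX[at(i, 0)] = (i == 1) ? 0 : 1; // from M / from X
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(gap_open + (j - 1) * gap_extend);
    tbY[at(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (ref[i - 1] == read[j - 1]) ? match : mismatch;
      double dm = M[at(i - 1, j - 1)], dx = X[at(i - 1, j - 1)],
             dy = Y[at(i - 1, j - 1)];
      double best = dm; unsigned char tb = 0;
      if (dx > best) { best = dx; tb = 1; }
      if (dy > best) { best = dy; tb = 2; }
      M[at(i, j)] = best + s; tbM[at(i, j)] = tb;

      double xm = M[at(i - 1, j)] - gap_open,
             xx = X[at(i - 1, j)] - gap_extend;
      if (xm >= xx) { X[at(i, j)] = xm; tbX[at(i, j)] = 0; }
      else          { X[at(i, j)] = xx; tbX[at(i, j)] = 1; }

      double ym = M[at(i, j - 1)] - gap_open,
             yy = Y[at(i, j - 1)] - gap_extend;
      if (ym >= yy) { Y[at(i, j)] = ym; tbY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = yy; tbY[at(i, j)] = 1; }
    }
  }
  // Endpoint: best of the three states at (n, m).
  double score = M[at(n, m)]; int state = 0;
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::string ar, aq; // aligned ref / read, built backwards
  ar.reserve(n + m); aq.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char tb = tbM[at(i, j)];
      ar.push_back(ref[i - 1]); aq.push_back(read[j - 1]);
      --i; --j; state = tb;
    } else if (state == 1) {
      unsigned char tb = tbX[at(i, j)];
      ar.push_back(ref[i - 1]); aq.push_back('-');
      --i; state = (tb == 0) ? 0 : 1;
    } else {
      unsigned char tb = tbY[at(i, j)];
      ar.push_back('-'); aq.push_back(read[j - 1]);
      --j; state = (tb == 0) ? 0 : 2;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(aq.begin(), aq.end());
  return List::create(_["ref_aln"] = ar, _["read_aln"] = aq,
                      _["score"] = score);
}
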