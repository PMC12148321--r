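#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Needleman-Wunsch-Gotoh global alignment with affine gaps.
// A gap of length L costs gap_open + gap_extend * (L - 1); end gaps are
// penalized (true global alignment). Traceback ties are broken in the
// fixed order diagonal > up (gap in seq2) > left (gap in seq1).
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string s1, std::string s2, double match,
                 double mismatch, double gap_open, double gap_extend) {
  const int n = s1.size(), m = s2.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // M: s1[i] aligned to s2[j]; X: gap in s2 (consume s1, "up");
  // Y: gap in s1 (consume s2, "left")
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[at(i, 0)] = -gap_open - gap_extend * (i - 1);
  for (int j = 1; j <= m; ++j)
    Y[at(0, j)] = -gap_open - gap_extend * (j - 1);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (s1[i - 1] == s2[j - 1]) ? match : mismatch;
      double d = std::max(M[at(i - 1, j - 1)],
                          std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      if (d > NEG) M[at(i, j)] = d + s;
      double x = std::max(M[at(i - 1, j)] - gap_open,
                          std::max(X[at(i - 1, j)] - gap_extend,
                                   Y[at(i - 1, j)] - gap_open));
      X[at(i, j)] = x;
      double y = std::max(M[at(i, j - 1)] - gap_open,
                          std::max(X[at(i, j - 1)] - gap_open,
                                   Y[at(i, j - 1)] - gap_extend));
      Y[at(i, j)] = y;
    }
  }

  // traceback: state 0 = M, 1 = X (up), 2 = Y (left); tie order M > X > Y
  int i = n, j = m, state;
  double best = M[at(n, m)];
  state = 0;
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; state = 2; }
  const double eps = 1e-9;
  std::string a1, a2;
  a1.reserve(n + m); a2.reserve(n + m);
  while (i > 0 || j > 0) {
    if (state == 0) {
      a1.push_back(s1[i - 1]); a2.push_back(s2[j - 1]);
      double target = M[at(i, j)] -
        ((s1[i - 1] == s2[j - 1]) ? match : mismatch);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[at(i, j)] - target) < eps) state = 0;
      else if (std::abs(X[at(i, j)] - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      a1.push_back(s1[i - 1]); a2.push_back('-');
      double target = X[at(i, j)];
      --i;
      if (std::abs(M[at(i, j)] - gap_open - target) < eps) state = 0;
      else if (std::abs(X[at(i, j)] - gap_extend - target) < eps) state = 1;
      else state = 2;
      if (i == 0 && j == 0) break;
    } else {
      a1.push_back('-'); a2.push_back(s2[j - 1]);
      double target = Y[at(i, j)];
      --j;
      if (std::abs(M[at(i, j)] - gap_open - target) < eps) state = 0;
      else if (std::abs(X[at(i, j)] - gap_open - target) < eps) state = 1;
      else state = 2;
      if (i == 0 && j == 0) break;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  return List::create(_["aligned1"] = a1, _["aligned2"] = a2,
                      _["score"] = best);
}
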