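// Profile-profile global alignment with affine gaps (Gotoh), used by the
// progressive small-set aligner. Profiles are 4 x L base-frequency
// matrices (rows A,C,G,T); gap/N mass is simply absent, so columns rich in
// gaps contribute proportionally less substitution score. A gap run of
// length k costs open + k * extend. Tie-break order: diagonal, then gap in
// the second profile, then gap in the first (deterministic).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B, double match,
                       double mismatch, double gap_open, double gap_extend) {
  const int la = A.ncol(), lb = B.ncol();
  if ((double)(la + 1) * (double)(lb + 1) > 6.4e7)
    stop("profiles too long for exact alignment (", la, " x ", lb, ")");
  const double NEG = -1e30;
  // column sums and pairwise match dot products
  std::vector<double> sa(la), sb(lb);
  for (int i = 0; i < la; ++i)
    sa[i] = A(0, i) + A(1, i) + A(2, i) + A(3, i);
  for (int j = 0; j < lb; ++j)
    sb[j] = B(0, j) + B(1, j) + B(2, j) + B(3, j);
  auto colscore = [&](int i, int j) {
    double dot = A(0, i) * B(0, j) + A(1, i) * B(1, j) +
                 A(2, i) * B(2, j) + A(3, i) * B(3, j);
    return match * dot + mismatch * (sa[i] * sb[j] - dot);
  };
  const size_t W = (size_t)lb + 1;
  std::vector<double> Mprev(W), Xprev(W), Yprev(W), Mcur(W), Xcur(W), Ycur(W);
  // traceback: 0 from M, 1 from X, 2 from Y
  std::vector<uint8_t> tbM((size_t)(la + 1) * W), tbX((size_t)(la + 1) * W),
      tbY((size_t)(la + 1) * W);
  Mprev[0] = 0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= lb; ++j) {
    Mprev[j] = NEG; Xprev[j] = NEG;
    Yprev[j] = gap_open + j * gap_extend;
    tbY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= la; ++i) {
    Mcur[0] = NEG; Ycur[0] = NEG;
    Xcur[0] = gap_open + i * gap_extend;
    tbX[(size_t)i * W] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= lb; ++j) {
      // M: consume a column from each
      double m0 = Mprev[j - 1], m1 = Xprev[j - 1], m2 = Yprev[j - 1];
      uint8_t tm = 0; double mv = m0;
      if (m1 > mv) { mv = m1; tm = 1; }
      if (m2 > mv) { mv = m2; tm = 2; }
      Mcur[j] = colscore(i - 1, j - 1) + mv;
      tbM[(size_t)i * W + j] = tm;
      // X: consume a column of A against a gap
      double x0 = Mprev[j] + gap_open + gap_extend;
      double x1 = Xprev[j] + gap_extend;
      double x2 = Yprev[j] + gap_open + gap_extend;
      uint8_t tx = 0; double xv = x0;
      if (x1 > xv) { xv = x1; tx = 1; }
      if (x2 > xv) { xv = x2; tx = 2; }
      Xcur[j] = xv;
      tbX[(size_t)i * W + j] = tx;
      // Y: consume a column of B against a gap
      double y0 = Mcur[j - 1] + gap_open + gap_extend;
      double y1 = Xcur[j - 1] + gap_open + gap_extend;
      double y2 = Ycur[j - 1] + gap_extend;
      uint8_t ty = 0; double yv = y0;
      if (y1 > yv) { yv = y1; ty = 1; }
      if (y2 > yv) { yv = y2; ty = 2; }
      Ycur[j] = yv;
      tbY[(size_t)i * W + j] = ty;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  double score = Mprev[lb]; int state = 0;
  if (Xprev[lb] > score) { score = Xprev[lb]; state = 1; }
  if (Yprev[lb] > score) { score = Yprev[lb]; state = 2; }
  // traceback
  std::vector<int> ai, bi;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      uint8_t t = tbM[(size_t)i * W + j];
      ai.push_back(i); bi.push_back(j); --i; --j; state = t;
    } else if (state == 1) {
      uint8_t t = tbX[(size_t)i * W + j];
      ai.push_back(i); bi.push_back(0); --i; state = t;
    } else {
      uint8_t t = tbY[(size_t)i * W + j];
      ai.push_back(0); bi.push_back(j); --j; state = t;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score, _["ai"] = wrap(ai),
                      _["bi"] = wrap(bi));
}
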