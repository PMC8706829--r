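// Banded global alignment with affine gap penalties, for high-identity
// mitogenome sequences. The DP is restricted to a diagonal band wide enough
// to absorb the cumulative indel offset; the caller doubles the band when
// the optimal path touches its edge.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string a, std::string b, int band,
                      double gap_open, double gap_ext,
                      double match, double mismatch) {
  const int n = a.size(), m = b.size();
  // diagonal d = j - i, constrained to [lo, hi]
  const int lo = std::min(0, m - n) - band;
  const int hi = std::max(0, m - n) + band;
  const int w = hi - lo + 1;
  const double gopen = gap_open + gap_ext;  // cost of a gap of length 1

  // three layers: M (a_i ~ b_j), X (gap in b, vertical), Y (gap in a, horiz)
  const size_t sz = (size_t)(n + 1) * w;
  std::vector<double> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  std::vector<unsigned char> tbM(sz, 0), tbX(sz, 0), tbY(sz, 0);

  auto idx = [&](int i, int d) { return (size_t)i * w + (d - lo); };

  M[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m && j <= hi; ++j) {
    Y[idx(0, j)] = -(gap_open + gap_ext * j);
    tbY[idx(0, j)] = (j == 1) ? 0 : 2;  // from M at start else extend Y
  }
  for (int i = 1; i <= n && -i >= lo; ++i) {
    X[idx(i, -i)] = -(gap_open + gap_ext * i);
    tbX[idx(i, -i)] = (i == 1) ? 0 : 1;
  }

  for (int i = 1; i <= n; ++i) {
    const int jmin = std::max(1, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      const int d = j - i;
      // M: diagonal move from (i-1, j-1), same d
      {
        double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
        double vM = M[idx(i - 1, d)], vX = X[idx(i - 1, d)],
               vY = Y[idx(i - 1, d)];
        double best = vM; unsigned char tb = 0;
        if (vX > best) { best = vX; tb = 1; }
        if (vY > best) { best = vY; tb = 2; }
        M[idx(i, d)] = (best == NEG_INF) ? NEG_INF : best + s;
        tbM[idx(i, d)] = tb;
      }
      // X: vertical move from (i-1, j): d+1
      if (d + 1 <= hi) {
        double vM = M[idx(i - 1, d + 1)], vX = X[idx(i - 1, d + 1)],
               vY = Y[idx(i - 1, d + 1)];
        double best = vM - gopen; unsigned char tb = 0;
        if (vX - gap_ext > best) { best = vX - gap_ext; tb = 1; }
        if (vY - gopen > best) { best = vY - gopen; tb = 2; }
        X[idx(i, d)] = best;
        tbX[idx(i, d)] = tb;
      }
      // Y: horizontal move from (i, j-1): d-1
      if (d - 1 >= lo) {
        double vM = M[idx(i, d - 1)], vX = X[idx(i, d - 1)],
               vY = Y[idx(i, d - 1)];
        double best = vM - gopen; unsigned char tb = 0;
        if (vX - gopen > best) { best = vX - gopen; tb = 1; }
        if (vY - gap_ext > best) { best = vY - gap_ext; tb = 2; }
        Y[idx(i, d)] = best;
        tbY[idx(i, d)] = tb;
      }
    }
  }

  const int dend = m - n;
  double sM = M[idx(n, dend)], sX = X[idx(n, dend)], sY = Y[idx(n, dend)];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }
  if (score == NEG_INF) stop("band too narrow: no path within band");

  // traceback
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  bool band_hit = false;
  while (i > 0 || j > 0) {
    const int d = j - i;
    if (d == lo || d == hi) band_hit = true;
    unsigned char tb;
    if (state == 0) {
      tb = tbM[idx(i, d)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      tb = tbX[idx(i, d)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
    } else {
      tb = tbY[idx(i, d)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
    }
    state = tb;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score, _["band_hit"] = band_hit);
}
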