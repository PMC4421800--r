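#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Interval dynamic program over hairpin-class structures: base pairs form a
// single strictly nested chain (stem-loop with bulges / internal loops, no
// multiloops). V(i,j) = best energy of a chain whose outermost pair is
// (i,j); transitions are restricted to at most max_loop_side unpaired bases
// per side. All penalty values are precomputed in R and passed in, so the
// arithmetic is bit-identical to the R scoring route.

static inline int pair_type(int a, int b) {
  // bases: A=0, C=1, G=2, T=3 ; pair codes 1..6 = AT,TA,CG,GC,GT,TG
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 1) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seq, NumericMatrix stack,
                  NumericVector hairpin, NumericVector bulge,
                  NumericMatrix internal_pen, int min_hairpin,
                  int max_loop_side) {
  const int n = seq.size();
  const double INF = std::numeric_limits<double>::infinity();
  if (n < min_hairpin + 2) {
    return List::create(_["pairs"] = IntegerVector(0), _["energy"] = 0.0);
  }

  std::vector<std::vector<int> > pt(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pt[i][j] = pair_type(seq[i], seq[j]);

  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  // traceback: inner pair (c,d), or (-1,-1) for hairpin closure
  std::vector<std::vector<int> > tc(n, std::vector<int>(n, -2));
  std::vector<std::vector<int> > td(n, std::vector<int>(n, -2));

  for (int span = min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (pt[i][j] == 0) continue;
      double best = INF;
      int bc = -2, bd = -2;
      int loop = j - i - 1;
      if (loop >= min_hairpin) {
        best = hairpin[loop - 1];  // hairpin[] is 1-indexed by loop size
        bc = -1; bd = -1;
      }
      int cmax = std::min(i + 1 + max_loop_side, j - 1);
      for (int c = i + 1; c <= cmax; ++c) {
        int a = c - i - 1;
        int dmin = std::max(c + 1, j - 1 - max_loop_side);
        for (int d = j - 1; d >= dmin; --d) {
          int b = j - d - 1;
          if (pt[c][d] == 0 || V[c][d] == INF) continue;
          double t;
          if (a == 0 && b == 0)
            t = stack(pt[i][j] - 1, pt[c][d] - 1);
          else if (a == 0 || b == 0)
            t = bulge[a + b - 1];
          else
            t = internal_pen(a - 1, b - 1);
          double e = t + V[c][d];
          if (e < best) { best = e; bc = c; bd = d; }
        }
      }
      V[i][j] = best;
      tc[i][j] = bc;
      td[i][j] = bd;
    }
  }

  double mfe = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (V[i][j] < mfe) { mfe = V[i][j]; bi = i; bj = j; }

  std::vector<int> pi, pj;
  if (bi >= 0) {
    int i = bi, j = bj;
    while (i >= 0) {
      pi.push_back(i + 1);  // 1-based for R
      pj.push_back(j + 1);
      int c = tc[i][j], d = td[i][j];
      i = c; j = d;
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    pairs(r, 0) = pi[r];
    pairs(r, 1) = pj[r];
  }
  return List::create(_["pairs"] = pairs, _["energy"] = mfe);
}
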