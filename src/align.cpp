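#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap global alignment over a precomputed column-score matrix.
//
// `scores(i, j)` is the substitution score for aligning column i of profile A
// with column j of profile B (profiles reduce to sequences when each column
// is a single residue).  Gap costs are signed contributions: opening a run
// costs `open + extend` for its first element and `extend` for each further
// element.  With `free_ends` leading and trailing gap runs cost nothing
// (the "global with free end gaps" policy).
//
// Returns the optimal score and the aligned path as two 1-based index
// vectors (0 marks a gap in that profile).

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix scores, double open, double extend,
                 bool free_ends) {
  const int la = scores.nrow(), lb = scores.ncol();
  if (la == 0 || lb == 0) stop("empty profile");

  // rolling rows for scores, full byte matrices for traceback
  std::vector<double> Mprev(lb + 1), Xprev(lb + 1), Yprev(lb + 1);
  std::vector<double> Mcur(lb + 1), Xcur(lb + 1), Ycur(lb + 1);
  // traceback codes: predecessor state 0=M, 1=X, 2=Y
  std::vector<unsigned char> tbM((la + 1) * (lb + 1));
  std::vector<unsigned char> tbX((la + 1) * (lb + 1));
  std::vector<unsigned char> tbY((la + 1) * (lb + 1));
  auto idx = [lb](int i, int j) { return i * (lb + 1) + j; };

  Mprev[0] = 0.0;
  Xprev[0] = NEG_INF;
  Yprev[0] = NEG_INF;
  for (int j = 1; j <= lb; ++j) {
    Mprev[j] = NEG_INF;
    Xprev[j] = NEG_INF;
    Yprev[j] = free_ends ? 0.0 : open + j * extend;
    tbY[idx(0, j)] = 2;
  }

  double best = NEG_INF;
  int best_i = la, best_j = lb, best_s = 0;
  if (free_ends) {
    // degenerate endpoint: the profiles may not overlap at all
    best = 0.0;
    best_i = 0;
    best_j = lb;
    best_s = 2;
  }

  for (int i = 1; i <= la; ++i) {
    Mcur[0] = NEG_INF;
    Ycur[0] = NEG_INF;
    Xcur[0] = free_ends ? 0.0 : open + i * extend;
    tbX[idx(i, 0)] = 1;
    for (int j = 1; j <= lb; ++j) {
      // match state
      double m = Mprev[j - 1], x = Xprev[j - 1], y = Yprev[j - 1];
      unsigned char c = 0;
      double v = m;
      if (x > v) { v = x; c = 1; }
      if (y > v) { v = y; c = 2; }
      Mcur[j] = v + scores(i - 1, j - 1);
      tbM[idx(i, j)] = c;

      // X: consume A column, gap in B
      double xo = Mprev[j] + open + extend;
      double xx = Xprev[j] + extend;
      double xy = Yprev[j] + open + extend;
      c = 0; v = xo;
      if (xx > v) { v = xx; c = 1; }
      if (xy > v) { v = xy; c = 2; }
      Xcur[j] = v;
      tbX[idx(i, j)] = c;

      // Y: consume B column, gap in A
      double yo = Mcur[j - 1] + open + extend;
      double yy = Ycur[j - 1] + extend;
      double yx = Xcur[j - 1] + open + extend;
      c = 0; v = yo;
      if (yy > v) { v = yy; c = 2; }
      if (yx > v) { v = yx; c = 1; }
      Ycur[j] = v;
      tbY[idx(i, j)] = c;
    }
    if (free_ends) {
      // candidate endpoints along the last column
      for (int s = 0; s < 3; ++s) {
        double v = s == 0 ? Mcur[lb] : (s == 1 ? Xcur[lb] : Ycur[lb]);
        if (i < la) {
          if (v > best) { best = v; best_i = i; best_j = lb; best_s = s; }
        }
      }
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  // final row (i == la): all cells are endpoint candidates under free ends
  if (free_ends) {
    // recompute is unnecessary: Mprev now holds row la
    for (int j = 1; j <= lb; ++j) {
      // endpoints in last row
      // note j == lb also covered here
      double vals[3] = { Mprev[j], Xprev[j], Yprev[j] };
      for (int s = 0; s < 3; ++s)
        if (vals[s] > best) { best = vals[s]; best_i = la; best_j = j; best_s = s; }
    }
  } else {
    double vals[3] = { Mprev[lb], Xprev[lb], Yprev[lb] };
    best = vals[0]; best_s = 0;
    if (vals[1] > best) { best = vals[1]; best_s = 1; }
    if (vals[2] > best) { best = vals[2]; best_s = 2; }
    best_i = la; best_j = lb;
  }

  // Traceback needs the per-cell state values only through the stored
  // predecessor codes, so it can run on the byte matrices alone.
  std::vector<int> ai, bi;
  ai.reserve(la + lb);
  bi.reserve(la + lb);
  // free-end tail gaps
  for (int i = la; i > best_i; --i) { ai.push_back(i); bi.push_back(0); }
  for (int j = lb; j > best_j; --j) { ai.push_back(0); bi.push_back(j); }

  int i = best_i, j = best_j, s = best_s;
  while (i > 0 || j > 0) {
    if (i == 0) { ai.push_back(0); bi.push_back(j); --j; continue; }
    if (j == 0) { ai.push_back(i); bi.push_back(0); --i; continue; }
    if (s == 0) {
      int prev = tbM[idx(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j; s = prev;
    } else if (s == 1) {
      int prev = tbX[idx(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i; s = prev;
    } else {
      int prev = tbY[idx(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j; s = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = best,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}
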