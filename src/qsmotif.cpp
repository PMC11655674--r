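#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sum of per-position values over all sliding windows of width ncol(mat).
// seq holds integer base codes 0..3 (A,C,G,T); negative codes mark ambiguous
// bases and poison every window that covers them (score NA).
// [[Rcpp::export]]
NumericVector window_scores_cpp(IntegerVector seq, NumericMatrix mat) {
  const int L = seq.size(), w = mat.ncol();
  if (L < w) return NumericVector(0);
  NumericVector out(L - w + 1);
  for (int o = 0; o <= L - w; ++o) {
    double s = 0.0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      const int b = seq[o + j];
      if (b < 0) { ok = false; break; }
      s += mat(b, j);
    }
    out[o] = ok ? s : NA_REAL;
  }
  return out;
}

// Posterior-weighted base counts for the motif M-step: z[o] is the weight of
// the window starting at o; returns a 4 x w count matrix. NA/zero weights
// contribute nothing.
// [[Rcpp::export]]
NumericMatrix weighted_counts_cpp(IntegerVector seq, NumericVector z, int w) {
  const int L = seq.size();
  NumericMatrix out(4, w);
  const int nw = L - w + 1;
  for (int o = 0; o < nw; ++o) {
    const double zz = z[o];
    if (!(zz > 0)) continue;  // also skips NA
    for (int j = 0; j < w; ++j) {
      const int b = seq[o + j];
      if (b >= 0) out(b, j) += zz;
    }
  }
  return out;
}

// Gotoh local alignment with affine gaps. a and b are 0-based indices into
// submat. A gap of length k costs gap_open + k * gap_extend (BLAST-style
// existence/extension). Returns the optimal score plus the statistics of one
// optimal alignment (deterministic traceback: match state preferred, and the
// first best-scoring cell in row-major order).
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if ((double)n * (double)m > 2.5e7)
    stop("sequences too long for the dense aligner");
  const double gi = gap_open + gap_extend;
  const double NEG = -1e30;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, 0.0), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int id = i * W + j, up = (i - 1) * W + j, lf = i * W + (j - 1),
                dg = (i - 1) * W + (j - 1);
      double x = std::max(M[up] - gi, X[up] - gap_extend);
      double y = std::max(M[lf] - gi, Y[lf] - gap_extend);
      double diag = std::max(M[dg], std::max(X[dg], Y[dg]));
      double mm = diag + submat(a[i - 1], b[j - 1]);
      if (mm < 0.0) mm = 0.0;
      M[id] = mm;
      X[id] = x;
      Y[id] = y;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["matches"] = 0, _["columns"] = 0,
                        _["qstart"] = NA_INTEGER, _["qend"] = NA_INTEGER,
                        _["sstart"] = NA_INTEGER, _["send"] = NA_INTEGER);
  // traceback
  const double tol = 1e-9;
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = X (gap in b), 2 = Y (gap in a)
  int matches = 0, cols = 0;
  bool done = false;
  while (!done) {
    if (state == 0) {
      const double val = M[i * W + j];
      const double s = submat(a[i - 1], b[j - 1]);
      ++cols;
      if (a[i - 1] == b[j - 1]) ++matches;
      const double need = val - s;
      const int dg = (i - 1) * W + (j - 1);
      --i; --j;
      if (need <= tol) done = true;  // local alignment starts here
      else if (std::fabs(M[dg] - need) <= tol) state = 0;
      else if (std::fabs(X[dg] - need) <= tol) state = 1;
      else state = 2;
    } else if (state == 1) {
      const double val = X[i * W + j];
      ++cols;
      const int up = (i - 1) * W + j;
      --i;
      state = (std::fabs(M[up] - gi - val) <= tol) ? 0 : 1;
    } else {
      const double val = Y[i * W + j];
      ++cols;
      const int lf = i * W + (j - 1);
      --j;
      state = (std::fabs(M[lf] - gi - val) <= tol) ? 0 : 2;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = cols, _["qstart"] = i + 1,
                      _["qend"] = bi, _["sstart"] = j + 1, _["send"] = bj);
}
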