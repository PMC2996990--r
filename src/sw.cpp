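#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
//
// Sequences arrive as 1-based integer codes into the rows/columns of the
// substitution matrix. A gap run of length k costs gap_open + k * gap_ext
// (BLAST convention), so the first gapped position costs gap_open + gap_ext.

namespace {

struct Cells {
  std::vector<double> H, E, F;
};

// Score-only DP, two rolling rows.
double sw_score(const IntegerVector& a, const IntegerVector& b,
                const NumericMatrix& mat, double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  const double ninf = -std::numeric_limits<double>::infinity();
  std::vector<double> H(m + 1, 0.0), E(m + 1, ninf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = H[0];  // H[i-1][0]
    double F = ninf;
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j - 1] - gap_open - gap_ext, E[j] - gap_ext);
      F = std::max(H[j] - gap_open - gap_ext, F - gap_ext);
      double h = diag + mat(a[i - 1] - 1, b[j - 1] - 1);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".sw_score")]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                    double gap_open, double gap_ext) {
  return sw_score(a, b, mat, gap_open, gap_ext);
}

// Full DP with traceback: returns score, matches, alignment columns and the
// aligned spans on both sequences.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                  double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["matches"] = 0, _["columns"] = 0,
                        _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER);
  const double ninf = -std::numeric_limits<double>::infinity();
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, ninf),
      F((n + 1) * W, ninf);
  // traceback states: H: 0 stop, 1 diag, 2 from E (gap in a), 3 from F.
  //                   E/F: 0 opened from H, 1 extended.
  std::vector<unsigned char> tH((n + 1) * W, 0), tE((n + 1) * W, 0),
      tF((n + 1) * W, 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = i * W + j;
      double e_open = H[k - 1] - gap_open - gap_ext;
      double e_ext = E[k - 1] - gap_ext;
      E[k] = std::max(e_open, e_ext);
      tE[k] = e_ext > e_open ? 1 : 0;
      double f_open = H[k - W] - gap_open - gap_ext;
      double f_ext = F[k - W] - gap_ext;
      F[k] = std::max(f_open, f_ext);
      tF[k] = f_ext > f_open ? 1 : 0;
      double d = H[k - W - 1] + mat(a[i - 1] - 1, b[j - 1] - 1);
      double h = 0.0;
      unsigned char s = 0;
      if (d > h) { h = d; s = 1; }
      if (E[k] > h) { h = E[k]; s = 2; }
      if (F[k] > h) { h = F[k]; s = 3; }
      H[k] = h;
      tH[k] = s;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  int matches = 0, columns = 0;
  int i = bi, j = bj;
  int a_end = bi, b_end = bj;
  char layer = 'H';
  while (i > 0 && j > 0) {
    const int k = i * W + j;
    if (layer == 'H') {
      unsigned char s = tH[k];
      if (s == 0) break;
      if (s == 1) {
        ++columns;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (s == 2) {
        layer = 'E';
      } else {
        layer = 'F';
      }
    } else if (layer == 'E') {
      ++columns;
      unsigned char s = tE[k];
      --j;
      if (s == 0) layer = 'H';
    } else {  // F
      ++columns;
      unsigned char s = tF[k];
      --i;
      if (s == 0) layer = 'H';
    }
  }
  int a_start = i + 1, b_start = j + 1;
  if (best == 0.0)
    return List::create(_["score"] = 0.0, _["matches"] = 0, _["columns"] = 0,
                        _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER);
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = columns, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end);
}

// All-vs-all score matrix between two lists of encoded sequences.
// [[Rcpp::export(name = ".sw_score_matrix")]]
NumericMatrix sw_score_matrix_cpp(List A, List B, NumericMatrix mat,
                                  double gap_open, double gap_ext) {
  const int nA = A.size(), nB = B.size();
  NumericMatrix out(nA, nB);
  for (int i = 0; i < nA; ++i) {
    IntegerVector a = A[i];
    for (int j = 0; j < nB; ++j) {
      IntegerVector b = B[j];
      out(i, j) = sw_score(a, b, mat, gap_open, gap_ext);
    }
  }
  return out;
}
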