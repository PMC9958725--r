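#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh global alignment with affine gap penalties.
//
// A gap run of length L costs gap_open + L * gap_extend (so a single
// isolated gap costs gap_open + gap_extend).  Scores are maximised.
//
// Traceback is deterministic: on score ties the move priority is
// substitution (diagonal), then gap-in-query (a reference residue over a
// gap, i.e. a deletion from the reference), then gap-in-reference
// (an insertion).  Within a gap state, extending the existing run is
// preferred over opening a fresh one.  Traceback runs from the alignment
// end, so tied gap runs settle as late as possible in the reference,
// which matches the reference-numbered naming convention used for
// variant edit lists.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  NumericMatrix submat, CharacterVector sub_rows,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("both sequences must be non-empty");

  // residue -> submat index
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < sub_rows.size(); ++i) {
    std::string r = as<std::string>(sub_rows[i]);
    if (r.size() == 1) idx[(unsigned char)r[0]] = i;
  }
  for (int i = 0; i < n; ++i)
    if (idx[(unsigned char)a[i]] < 0)
      stop("invalid residue symbol '%s' in first sequence",
           std::string(1, a[i]).c_str());
  for (int j = 0; j < m; ++j)
    if (idx[(unsigned char)b[j]] < 0)
      stop("invalid residue symbol '%s' in second sequence",
           std::string(1, b[j]).c_str());

  const double open1 = gap_open + gap_extend;  // cost of a length-1 gap

  // DP matrices: M substitution end, X gap in query (consumes a),
  // Y gap in reference (consumes b).  (n+1) x (m+1), row-major.
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback pointers: which predecessor state fed this cell
  std::vector<char> pM((n + 1) * (m + 1), 0);
  std::vector<char> pX((n + 1) * (m + 1), 0);
  std::vector<char> pY((n + 1) * (m + 1), 0);
  const int W = m + 1;

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + i * gap_extend);
    pX[i * W] = (i == 1) ? 'M' : 'X';
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + j * gap_extend);
    pY[j] = (j == 1) ? 'M' : 'Y';
  }

  for (int i = 1; i <= n; ++i) {
    const int ia = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, up = (i - 1) * W + j,
                left = i * W + (j - 1), diag = (i - 1) * W + (j - 1);
      // M: diagonal move; predecessor preference M > X > Y on ties
      double s = submat(ia, idx[(unsigned char)b[j - 1]]);
      double best = M[diag]; char ptr = 'M';
      if (X[diag] > best) { best = X[diag]; ptr = 'X'; }
      if (Y[diag] > best) { best = Y[diag]; ptr = 'Y'; }
      M[c] = best + s; pM[c] = ptr;
      // X: gap in query; prefer extension over opening
      best = X[up] - gap_extend; ptr = 'X';
      if (M[up] - open1 > best) { best = M[up] - open1; ptr = 'M'; }
      if (Y[up] - open1 > best) { best = Y[up] - open1; ptr = 'Y'; }
      X[c] = best; pX[c] = ptr;
      // Y: gap in reference; prefer extension over opening
      best = Y[left] - gap_extend; ptr = 'Y';
      if (M[left] - open1 > best) { best = M[left] - open1; ptr = 'M'; }
      if (X[left] - open1 > best) { best = X[left] - open1; ptr = 'X'; }
      Y[c] = best; pY[c] = ptr;
    }
  }

  const int end = n * W + m;
  double score = M[end]; char state = 'M';
  if (X[end] > score) { score = X[end]; state = 'X'; }
  if (Y[end] > score) { score = Y[end]; state = 'Y'; }

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 'M') {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = pM[c]; --i; --j;
    } else if (state == 'X') {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = pX[c]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = pY[c]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_ref"] = ra, _["aligned_query"] = rb,
                      _["score"] = score);
}
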