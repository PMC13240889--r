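#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch edit distance for categorical state sequences:
// insert/delete at cost `indel`, substitute x_i -> y_j at cost sub(x_i, y_j).
// States are 1-based alphabet indices.
static double om_dist_core(const int* x, int nx, const int* y, int ny,
                           const NumericMatrix& sub, double indel,
                           std::vector<double>& prev,
                           std::vector<double>& curr) {
  prev.resize(ny + 1);
  curr.resize(ny + 1);
  for (int j = 0; j <= ny; ++j) prev[j] = j * indel;
  for (int i = 1; i <= nx; ++i) {
    curr[0] = i * indel;
    int xi = x[i - 1] - 1;
    for (int j = 1; j <= ny; ++j) {
      double d = prev[j - 1] + sub(xi, y[j - 1] - 1);
      double del = prev[j] + indel;
      double ins = curr[j - 1] + indel;
      if (del < d) d = del;
      if (ins < d) d = ins;
      curr[j] = d;
    }
    prev.swap(curr);
  }
  return prev[ny];
}

// [[Rcpp::export]]
double om_dist_cpp(IntegerVector x, IntegerVector y,
                   NumericMatrix sub, double indel) {
  std::vector<double> prev, curr;
  return om_dist_core(x.begin(), x.size(), y.begin(), y.size(),
                      sub, indel, prev, curr);
}

// [[Rcpp::export]]
NumericMatrix om_pairwise_cpp(IntegerMatrix seqs, NumericMatrix sub,
                              double indel) {
  int n = seqs.nrow(), L = seqs.ncol();
  NumericMatrix out(n, n);
  std::vector<int> rows(n * L);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < L; ++t)
      rows[i * L + t] = seqs(i, t);
  std::vector<double> prev, curr;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = om_dist_core(&rows[i * L], L, &rows[j * L], L,
                              sub, indel, prev, curr);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
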