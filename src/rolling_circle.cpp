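#include <Rcpp.h>
using namespace Rcpp;

// Grayscale opening of y with structuring function elem (length 2w+1,
// apex at index w). Circle centers range over the extended index set
// [-w, n-1+w] so that circles centered beyond the recorded range can
// still support the envelope near the edges; the "below the spectrum"
// constraint applies only where the spectrum is defined.
//
// erosion:  e[c] = min_{j : 0 <= c+j-w < n} y[c+j-w] - elem[j]
// dilation: b[i] = max_{c : |i-c| <= w}     e[c] + elem[i-c+w]
// [[Rcpp::export]]
NumericVector rc_open(NumericVector y, NumericVector elem) {
  const int n = y.size();
  const int m = elem.size();
  const int w = (m - 1) / 2;
  if (m % 2 == 0) stop("structuring element must have odd length");
  const int nc = n + 2 * w;            // centers -w .. n-1+w
  std::vector<double> ero(nc);
  for (int c = -w; c <= n - 1 + w; ++c) {
    double mn = R_PosInf;
    int jlo = std::max(0, w - c);          // c + j - w >= 0
    int jhi = std::min(m - 1, n - 1 + w - c);
    for (int j = jlo; j <= jhi; ++j) {
      double v = y[c + j - w] - elem[j];
      if (v < mn) mn = v;
    }
    ero[c + w] = mn;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double mx = R_NegInf;
    for (int c = i - w; c <= i + w; ++c) {
      double v = ero[c + w] + elem[i - c + w];
      if (v > mx) mx = v;
    }
    out[i] = mx;
  }
  return out;
}
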