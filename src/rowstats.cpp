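#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of a scratch buffer; buffer is reordered in place
static double med_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// [[Rcpp::export]]
NumericVector row_medians(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) buf[j] = x(i, j);
    out[i] = med_inplace(buf);
    buf.resize(p);
  }
  return out;
}

// unscaled MAD per row: median(|x - median(x)|)
// [[Rcpp::export]]
NumericVector row_mads(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(p), dev(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) buf[j] = x(i, j);
    double m = med_inplace(buf);
    for (int j = 0; j < p; ++j) dev[j] = std::fabs(x(i, j) - m);
    out[i] = med_inplace(dev);
    buf.resize(p);
    dev.resize(p);
  }
  return out;
}
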