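#include <Rcpp.h>
using namespace Rcpp;

// Multichannel IIR filter (direct-form II transposed) along the rows of a
// channels x samples matrix. Filter state zi (channels x order) is taken as
// the entry state and the exit state is returned alongside the output, so
// chunked (streaming) filtering reproduces one-shot filtering bit-for-bit.
// [[Rcpp::export(name = ".iir_chunk_cpp")]]
List iir_chunk_cpp(NumericVector b, NumericVector a, NumericMatrix x,
                   NumericMatrix zi) {
  const int nb = b.size(), na = a.size();
  const int k = std::max(nb, na) - 1;
  const int nch = x.nrow(), n = x.ncol();
  if (k < 1) stop("filter must have order >= 1");
  if (zi.nrow() != nch || zi.ncol() != k)
    stop("filter state must be %d x %d", nch, k);
  const double a0 = a[0];
  std::vector<double> bb(k + 1, 0.0), aa(k + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;

  NumericMatrix y(nch, n);
  NumericMatrix zf(clone(zi));
  std::vector<double> z(k);
  for (int c = 0; c < nch; ++c) {
    for (int j = 0; j < k; ++j) z[j] = zf(c, j);
    for (int t = 0; t < n; ++t) {
      const double xt = x(c, t);
      const double yt = bb[0] * xt + z[0];
      for (int j = 0; j < k - 1; ++j)
        z[j] = bb[j + 1] * xt + z[j + 1] - aa[j + 1] * yt;
      z[k - 1] = bb[k] * xt - aa[k] * yt;
      y(c, t) = yt;
    }
    for (int j = 0; j < k; ++j) zf(c, j) = z[j];
  }
  return List::create(_["y"] = y, _["zf"] = zf);
}
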