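#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase (forward-backward) cascade of IIR sections applied to every
// column of a time x channels matrix, with odd-reflection padding of
// `pad` samples at both ends.  Sections are given as two matrices of
// numerator/denominator coefficients, one section per row, padded with
// zeros to a common order; a0 is assumed normalized to 1.
// [[Rcpp::export(name = ".filtfilt_cascade_cpp")]]
NumericMatrix filtfilt_cascade_cpp(NumericMatrix bmat, NumericMatrix amat,
                                   NumericMatrix x, int pad) {
  const int n = x.nrow(), nch = x.ncol();
  const int ns = bmat.nrow();
  const int nw = bmat.ncol() - 1;            // filter state size
  const int m = n + 2 * pad;
  NumericMatrix y(n, nch);
  std::vector<double> buf(m), w(nw);

  for (int ch = 0; ch < nch; ++ch) {
    const double* xc = &x(0, ch);
    // odd reflection: 2*x[0] - x[pad..1], data, 2*x[n-1] - x[n-2..]
    for (int i = 0; i < pad; ++i) buf[i] = 2.0 * xc[0] - xc[pad - i];
    std::copy(xc, xc + n, buf.begin() + pad);
    for (int i = 0; i < pad; ++i)
      buf[pad + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];

    for (int dir = 0; dir < 2; ++dir) {
      for (int s = 0; s < ns; ++s) {
        const double* b = &bmat(s, 0);
        const double* a = &amat(s, 0);
        // strided row access: Rcpp matrices are column-major
        std::vector<double> bs(nw + 1), as(nw + 1);
        for (int k = 0; k <= nw; ++k) { bs[k] = bmat(s, k); as[k] = amat(s, k); }
        (void)b; (void)a;
        std::fill(w.begin(), w.end(), 0.0);
        for (int t = 0; t < m; ++t) {
          const double xt = buf[t];
          const double yt = bs[0] * xt + w[0];
          for (int k = 0; k < nw - 1; ++k)
            w[k] = w[k + 1] + bs[k + 1] * xt - as[k + 1] * yt;
          w[nw - 1] = bs[nw] * xt - as[nw] * yt;
          buf[t] = yt;
        }
      }
      std::reverse(buf.begin(), buf.end());
    }
    std::copy(buf.begin() + pad, buf.begin() + pad + n, &y(0, ch));
  }
  return y;
}
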