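#include <Rcpp.h>
using namespace Rcpp;

// Accumulate shifted [-win, 0] windows over trials for every surrogate draw.
// d: samples x trials x channels array (column-major, sample-major for cache
// locality); onsetIdx: trials x draws matrix of 1-based sample indices of
// each draw's t = 0 sample. Returns an nwin x draws x channels array of
// per-draw trial sums.
// [[Rcpp::export(name = ".shiftedAccumulate")]]
NumericVector shifted_accumulate(NumericVector d, IntegerVector dims,
                                 IntegerMatrix onsetIdx, int nwin) {
  const int nS = dims[0], nTr = dims[1], nC = dims[2];
  const int nD = onsetIdx.ncol();
  NumericVector out(static_cast<R_xlen_t>(nwin) * nD * nC);
  const double *pd = REAL(d);
  double *po = REAL(out);
  for (int c = 0; c < nC; ++c) {
    for (int i = 0; i < nTr; ++i) {
      const double *base = pd + static_cast<R_xlen_t>(nS) * (i + static_cast<R_xlen_t>(nTr) * c);
      for (int k = 0; k < nD; ++k) {
        const int s0 = onsetIdx(i, k) - nwin;  // 0-based first window sample
        double *acc = po + (static_cast<R_xlen_t>(c) * nD + k) * nwin;
        const double *src = base + s0;
        for (int w = 0; w < nwin; ++w) acc[w] += src[w];
      }
    }
  }
  return out;
}

// Row-wise medians of an n x m matrix (median over columns per row).
// [[Rcpp::export(name = ".rowMediansC")]]
NumericVector row_medians(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) buf[j] = x(i, j);
    const int h = m / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double v = buf[h];
    if (m % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      v = (v + lo) / 2.0;
    }
    out[i] = v;
  }
  return out;
}

// Shape a white-noise matrix (n x m, column-major) to ~1/f ("pink") noise in
// place with a 3-pole / 3-zero IIR cascade; columns are independent.
// [[Rcpp::export(name = ".pinkShape")]]
NumericMatrix pink_shape(NumericMatrix w) {
  const int n = w.nrow(), m = w.ncol();
  const double b0 = 0.049922035, b1 = -0.095993537, b2 = 0.050612699,
               b3 = -0.004408786;
  const double a1 = 2.494956002, a2 = -2.017265875, a3 = 0.522189400;
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double *x = &w(0, j);
    double *y = &out(0, j);
    double x1 = 0, x2 = 0, x3 = 0, y1 = 0, y2 = 0, y3 = 0;
    double s = 0, ss = 0;
    for (int i = 0; i < n; ++i) {
      double v = b0 * x[i] + b1 * x1 + b2 * x2 + b3 * x3
                 + a1 * y1 + a2 * y2 + a3 * y3;
      x3 = x2; x2 = x1; x1 = x[i];
      y3 = y2; y2 = y1; y1 = v;
      y[i] = v;
      s += v; ss += v * v;
    }
    double mu = s / n;
    double sd = std::sqrt(ss / n - mu * mu);
    if (sd <= 0) sd = 1;
    for (int i = 0; i < n; ++i) y[i] /= sd;
  }
  return out;
}
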