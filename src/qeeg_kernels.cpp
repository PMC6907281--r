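#include <Rcpp.h>
using namespace Rcpp;

// One IIR pass (direct form II transposed) over a signal, in place.
static void iir_pass(std::vector<double>& x, const NumericVector& b,
                     const NumericVector& a) {
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int k = 1; k < nz; ++k)
      z[k - 1] = (k < nb ? b[k] * xi : 0.0) + z[k] - (k < na ? a[k] * yi : 0.0);
    z[nz - 1] = (nz < nb ? b[nz] * xi : 0.0) - (nz < na ? a[nz] * yi : 0.0);
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering of each row of X, with
// odd-reflection padding of `pad` samples at both ends to suppress edge
// transients.  b, a: transfer-function coefficients (a[0] == 1).
// [[Rcpp::export]]
NumericMatrix filtfilt_rows(NumericVector b, NumericVector a,
                            NumericMatrix X, int pad = 2560) {
  const int nr = X.nrow(), nc = X.ncol();
  if (pad >= nc) pad = nc - 1;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  for (int r = 0; r < nr; ++r) {
    buf.assign(nc + 2 * pad, 0.0);
    for (int i = 0; i < pad; ++i)
      buf[i] = 2.0 * X(r, 0) - X(r, pad - i);
    for (int i = 0; i < nc; ++i) buf[pad + i] = X(r, i);
    for (int i = 0; i < pad; ++i)
      buf[pad + nc + i] = 2.0 * X(r, nc - 1) - X(r, nc - 2 - i);
    iir_pass(buf, b, a);
    std::reverse(buf.begin(), buf.end());
    iir_pass(buf, b, a);
    std::reverse(buf.begin(), buf.end());
    for (int i = 0; i < nc; ++i) out(r, i) = buf[pad + i];
  }
  return out;
}

// Mean magnitude-squared coherence over all unordered channel pairs.
// fr, fi: real/imaginary segment spectra, dim (nf, nseg, nd) flattened
// column-major; segok: nseg x nd validity (int); returns the MSC averaged
// over frequencies and valid pairs (NA when no pair has >= 2 segments).
// [[Rcpp::export]]
NumericVector msc_mean_pairs(NumericVector fr, NumericVector fi,
                             IntegerMatrix segok, int nf, int nseg, int nd) {
  const double* FR = fr.begin();
  const double* FI = fi.begin();
  std::vector<double> sxyr(nf), sxyi(nf), sxx(nf), syy(nf);
  double acc = 0.0;
  long npair = 0;
  for (int i = 0; i < nd - 1; ++i) {
    for (int j = i + 1; j < nd; ++j) {
      std::fill(sxyr.begin(), sxyr.end(), 0.0);
      std::fill(sxyi.begin(), sxyi.end(), 0.0);
      std::fill(sxx.begin(), sxx.end(), 0.0);
      std::fill(syy.begin(), syy.end(), 0.0);
      int nseg_used = 0;
      for (int s = 0; s < nseg; ++s) {
        if (!segok(s, i) || !segok(s, j)) continue;
        ++nseg_used;
        const double* xr = FR + (size_t)nf * (s + (size_t)nseg * i);
        const double* xi = FI + (size_t)nf * (s + (size_t)nseg * i);
        const double* yr = FR + (size_t)nf * (s + (size_t)nseg * j);
        const double* yi = FI + (size_t)nf * (s + (size_t)nseg * j);
        for (int f = 0; f < nf; ++f) {
          // x * conj(y)
          sxyr[f] += xr[f] * yr[f] + xi[f] * yi[f];
          sxyi[f] += xi[f] * yr[f] - xr[f] * yi[f];
          sxx[f] += xr[f] * xr[f] + xi[f] * xi[f];
          syy[f] += yr[f] * yr[f] + yi[f] * yi[f];
        }
      }
      if (nseg_used < 2) continue;
      double m = 0.0;
      for (int f = 0; f < nf; ++f)
        m += (sxyr[f] * sxyr[f] + sxyi[f] * sxyi[f]) / (sxx[f] * syy[f]);
      acc += m / nf;
      ++npair;
    }
  }
  if (npair == 0) return NumericVector::create(NA_REAL);
  return NumericVector::create(acc / npair);
}

// Demeaned, tapered analysis segments of every row of X, batched into one
// seg_len x (length(starts) * nrow(X)) matrix (columns: segment s of row
// d at column (d-1)*ns + s).
// [[Rcpp::export]]
NumericMatrix segment_matrix(NumericMatrix X, IntegerVector starts,
                             int seg_len, NumericVector taper) {
  const int nr = X.nrow(), ns = starts.size();
  NumericMatrix out(seg_len, ns * nr);
  for (int d = 0; d < nr; ++d) {
    for (int s = 0; s < ns; ++s) {
      const int c0 = starts[s] - 1;
      double* col = &out(0, d * ns + s);
      double mu = 0.0;
      for (int i = 0; i < seg_len; ++i) mu += X(d, c0 + i);
      mu /= seg_len;
      for (int i = 0; i < seg_len; ++i)
        col[i] = (X(d, c0 + i) - mu) * taper[i];
    }
  }
  return out;
}

// Per-epoch sample standard deviation (n-1 denominator) of each row of X:
// returns an n_epochs x nrow(X) matrix.
// [[Rcpp::export]]
NumericMatrix epoch_sd(NumericMatrix X, int ep_len, int n_ep) {
  const int nr = X.nrow();
  NumericMatrix out(n_ep, nr);
  for (int d = 0; d < nr; ++d) {
    for (int e = 0; e < n_ep; ++e) {
      double s = 0.0, s2 = 0.0;
      const int c0 = e * ep_len;
      for (int i = 0; i < ep_len; ++i) {
        double v = X(d, c0 + i);
        s += v; s2 += v * v;
      }
      double var = (s2 - s * s / ep_len) / (ep_len - 1);
      out(e, d) = var > 0 ? std::sqrt(var) : 0.0;
    }
  }
  return out;
}
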