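#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel (i, j) (0-based here) has its center at ((j + 0.5) * px, (i + 0.5) * px):
// origin top-left, x rightward along columns, y downward along rows.

// Deposit unit-amplitude d x d nm squares at continuous emitter positions.
// A pixel is covered when its center lies in [x - d/2, x + d/2) x
// [y - d/2, y + d/2): a center exactly on the low-coordinate edge is in, on the
// high edge it is out. Footprints are clipped at the image border. When the
// square straddles pixel centers without containing any (possible for d < px),
// the emitter collapses to a single deposit at its containing pixel.
// [[Rcpp::export]]
NumericMatrix render_square_cpp(NumericVector x, NumericVector y,
                                int nrow, int ncol, double px, double d) {
  NumericMatrix out(nrow, ncol);
  const double h = d / 2.0;
  const R_xlen_t n = x.size();
  for (R_xlen_t e = 0; e < n; ++e) {
    long jlo = (long)std::ceil((x[e] - h) / px - 0.5);
    long jhi = (long)std::ceil((x[e] + h) / px - 0.5) - 1;
    long ilo = (long)std::ceil((y[e] - h) / px - 0.5);
    long ihi = (long)std::ceil((y[e] + h) / px - 0.5) - 1;
    if (jhi < jlo || ihi < ilo) {
      // degenerate footprint: single-pixel deposit at the containing pixel
      long j = (long)std::floor(x[e] / px);
      long i = (long)std::floor(y[e] / px);
      if (j >= 0 && j < ncol && i >= 0 && i < nrow) out(i, j) += 1.0;
      continue;
    }
    if (jlo < 0) jlo = 0;
    if (ilo < 0) ilo = 0;
    if (jhi > ncol - 1) jhi = ncol - 1;
    if (ihi > nrow - 1) ihi = nrow - 1;
    for (long j = jlo; j <= jhi; ++j)
      for (long i = ilo; i <= ihi; ++i)
        out(i, j) += 1.0;
  }
  return out;
}

// Deposit isotropic Gaussians of peak amplitude 1 and deviation sigma,
// sampled at pixel centers and truncated to the |dx| <= 3 sigma,
// |dy| <= 3 sigma box (separable truncation keeps the deposited mass within
// erf(3/sqrt(2))^2 ~ 99.5% of the full integral 2*pi*sigma^2 / px^2).
// [[Rcpp::export]]
NumericMatrix render_gaussian_cpp(NumericVector x, NumericVector y,
                                  int nrow, int ncol, double px, double sigma) {
  NumericMatrix out(nrow, ncol);
  const double r = 3.0 * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const R_xlen_t n = x.size();
  std::vector<double> wx, wy;
  for (R_xlen_t e = 0; e < n; ++e) {
    long jlo = (long)std::ceil((x[e] - r) / px - 0.5);
    long jhi = (long)std::floor((x[e] + r) / px - 0.5);
    long ilo = (long)std::ceil((y[e] - r) / px - 0.5);
    long ihi = (long)std::floor((y[e] + r) / px - 0.5);
    if (jhi < jlo || ihi < ilo) {
      long j = (long)std::floor(x[e] / px);
      long i = (long)std::floor(y[e] / px);
      if (j >= 0 && j < ncol && i >= 0 && i < nrow) out(i, j) += 1.0;
      continue;
    }
    if (jlo < 0) jlo = 0;
    if (ilo < 0) ilo = 0;
    if (jhi > ncol - 1) jhi = ncol - 1;
    if (ihi > nrow - 1) ihi = nrow - 1;
    if (jhi < jlo || ihi < ilo) continue;  // footprint entirely outside
    wx.assign(jhi - jlo + 1, 0.0);
    wy.assign(ihi - ilo + 1, 0.0);
    for (long j = jlo; j <= jhi; ++j) {
      double dx = (j + 0.5) * px - x[e];
      wx[j - jlo] = std::exp(-dx * dx * inv2s2);
    }
    for (long i = ilo; i <= ihi; ++i) {
      double dy = (i + 0.5) * px - y[e];
      wy[i - ilo] = std::exp(-dy * dy * inv2s2);
    }
    for (long j = jlo; j <= jhi; ++j)
      for (long i = ilo; i <= ihi; ++i)
        out(i, j) += wx[j - jlo] * wy[i - ilo];
  }
  return out;
}
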