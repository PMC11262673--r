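#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 2D parallel-beam projection operators.
//
// Coordinates: pixel (row r, col c) of an N x N image sits at
// x = c - (N-1)/2, y = r - (N-1)/2 (row index increasing "downwards" is
// immaterial as long as forward and back projection agree). Detector bins
// use the same unit spacing and centring: bin k is at s = k - (Nd-1)/2.
// For angle theta (radians), a point (x, y) projects to
// s = x*cos(theta) + y*sin(theta); the ray direction is (-sin, cos).

// [[Rcpp::export]]
NumericMatrix forward_project_cpp(NumericMatrix image, NumericVector theta,
                                  int n_det, double step) {
  const int n = image.nrow();
  if (image.ncol() != n) stop("image must be square");
  const int na = theta.size();
  const double c0 = (n - 1) / 2.0;
  const double d0 = (n_det - 1) / 2.0;
  NumericMatrix sino(na, n_det);

  // integrate along the ray with sampling interval `step` (pixel units),
  // bilinear interpolation, zero outside the image
  const double tmax = n / 2.0 * 1.42; // a bit over half-diagonal/[-1,1] span
  const int nsamp = (int)std::ceil(2.0 * tmax / step);

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(theta[a]);
    const double st = std::sin(theta[a]);
    for (int k = 0; k < n_det; ++k) {
      const double s = k - d0;
      double acc = 0.0;
      for (int m = 0; m <= nsamp; ++m) {
        const double t = -tmax + m * step;
        const double x = s * ct - t * st;
        const double y = s * st + t * ct;
        const double fc = x + c0; // column coordinate
        const double fr = y + c0; // row coordinate
        if (fc < 0 || fr < 0 || fc > n - 1 || fr > n - 1) continue;
        const int c1 = (int)std::floor(fc);
        const int r1 = (int)std::floor(fr);
        const int c2 = c1 + 1 < n ? c1 + 1 : c1;
        const int r2 = r1 + 1 < n ? r1 + 1 : r1;
        const double wc = fc - c1;
        const double wr = fr - r1;
        acc += (1 - wr) * ((1 - wc) * image(r1, c1) + wc * image(r1, c2)) +
               wr * ((1 - wc) * image(r2, c1) + wc * image(r2, c2));
      }
      sino(a, k) = acc * step;
    }
  }
  return sino;
}

// Backproject one detector profile (already filtered or not) at one angle
// into an n x n image, linear interpolation on the detector.
// [[Rcpp::export]]
NumericMatrix backproject_one_cpp(NumericVector profile, double theta,
                                  int n) {
  const int n_det = profile.size();
  const double c0 = (n - 1) / 2.0;
  const double d0 = (n_det - 1) / 2.0;
  const double ct = std::cos(theta);
  const double st = std::sin(theta);
  NumericMatrix img(n, n);
  for (int r = 0; r < n; ++r) {
    const double y = r - c0;
    for (int c = 0; c < n; ++c) {
      const double x = c - c0;
      const double s = x * ct + y * st + d0;
      if (s < 0 || s > n_det - 1) continue;
      const int k = (int)std::floor(s);
      const int k2 = k + 1 < n_det ? k + 1 : k;
      const double w = s - k;
      img(r, c) = (1 - w) * profile[k] + w * profile[k2];
    }
  }
  return img;
}

// Accumulate backprojections of several profiles (rows of `profiles`) at
// matching angles into one running sum; used by the batch path.
// [[Rcpp::export]]
NumericMatrix backproject_sum_cpp(NumericMatrix profiles,
                                  NumericVector theta, int n) {
  const int na = profiles.nrow();
  const int n_det = profiles.ncol();
  const double c0 = (n - 1) / 2.0;
  const double d0 = (n_det - 1) / 2.0;
  NumericMatrix img(n, n);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(theta[a]);
    const double st = std::sin(theta[a]);
    for (int r = 0; r < n; ++r) {
      const double y = r - c0;
      for (int c = 0; c < n; ++c) {
        const double x = c - c0;
        const double s = x * ct + y * st + d0;
        if (s < 0 || s > n_det - 1) continue;
        const int k = (int)std::floor(s);
        const int k2 = k + 1 < n_det ? k + 1 : k;
        const double w = s - k;
        img(r, c) += (1 - w) * profiles(a, k) + w * profiles(a, k2);
      }
    }
  }
  return img;
}
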