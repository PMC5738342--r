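// Pixel-grid ellipse geometry: interior support (mean map value),
// pairwise interior overlap area and IoU by unit-grid sampling.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline bool insideE(double x, double y, double cx, double cy,
                           double a, double b, double ct, double st) {
  double dx = x - cx, dy = y - cy;
  double u = (dx * ct + dy * st) / a;
  double v = (-dx * st + dy * ct) / b;
  return u * u + v * v <= 1.0;
}

// mean of `probs` over interior pixel centres; NA when empty
// [[Rcpp::export(name = ".ellipseSupportC")]]
double ellipse_support_cpp(NumericMatrix probs, double cx, double cy,
                           double a, double b, double theta) {
  const int h = probs.nrow(), w = probs.ncol();
  int x0 = std::max(0, (int)std::floor(cx - a));
  int x1 = std::min(w - 1, (int)std::ceil(cx + a));
  int y0 = std::max(0, (int)std::floor(cy - a));
  int y1 = std::min(h - 1, (int)std::ceil(cy + a));
  if (x1 < x0 || y1 < y0) return NA_REAL;
  double ct = std::cos(theta), st = std::sin(theta);
  double sum = 0.0;
  long n = 0;
  for (int x = x0; x <= x1; ++x) {
    for (int y = y0; y <= y1; ++y) {
      if (insideE(x, y, cx, cy, a, b, ct, st)) {
        sum += probs(y, x);
        ++n;
      }
    }
  }
  if (n == 0) return NA_REAL;
  return sum / (double)n;
}

// overlap area (px^2) of two ellipse interiors by grid sampling
// [[Rcpp::export(name = ".ellipseOverlapC")]]
double ellipse_overlap_cpp(NumericVector e1, NumericVector e2, double step) {
  double d2 = (e1[0] - e2[0]) * (e1[0] - e2[0]) +
              (e1[1] - e2[1]) * (e1[1] - e2[1]);
  double rs = e1[2] + e2[2];
  if (d2 > rs * rs) return 0.0;
  double x0 = std::max(e1[0] - e1[2], e2[0] - e2[2]);
  double x1 = std::min(e1[0] + e1[2], e2[0] + e2[2]);
  double y0 = std::max(e1[1] - e1[2], e2[1] - e2[2]);
  double y1 = std::min(e1[1] + e1[2], e2[1] + e2[2]);
  if (x1 < x0 || y1 < y0) return 0.0;
  double c1 = std::cos(e1[4]), s1 = std::sin(e1[4]);
  double c2 = std::cos(e2[4]), s2 = std::sin(e2[4]);
  long n = 0;
  for (double x = std::floor(x0); x <= std::ceil(x1); x += step)
    for (double y = std::floor(y0); y <= std::ceil(y1); y += step)
      if (insideE(x, y, e1[0], e1[1], e1[2], e1[3], c1, s1) &&
          insideE(x, y, e2[0], e2[1], e2[2], e2[3], c2, s2))
        ++n;
  return (double)n * step * step;
}

// intersection-over-union of two ellipse interiors by grid sampling
// [[Rcpp::export(name = ".ellipseIoUC")]]
double ellipse_iou_cpp(NumericVector e1, NumericVector e2, double step) {
  double d2 = (e1[0] - e2[0]) * (e1[0] - e2[0]) +
              (e1[1] - e2[1]) * (e1[1] - e2[1]);
  double rs = e1[2] + e2[2];
  if (d2 > rs * rs) return 0.0;
  double x0 = std::min(e1[0] - e1[2], e2[0] - e2[2]);
  double x1 = std::max(e1[0] + e1[2], e2[0] + e2[2]);
  double y0 = std::min(e1[1] - e1[2], e2[1] - e2[2]);
  double y1 = std::max(e1[1] + e1[2], e2[1] + e2[2]);
  double c1 = std::cos(e1[4]), s1 = std::sin(e1[4]);
  double c2 = std::cos(e2[4]), s2 = std::sin(e2[4]);
  long ni = 0, nu = 0;
  for (double x = std::floor(x0); x <= std::ceil(x1); x += step)
    for (double y = std::floor(y0); y <= std::ceil(y1); y += step) {
      bool i1 = insideE(x, y, e1[0], e1[1], e1[2], e1[3], c1, s1);
      bool i2 = insideE(x, y, e2[0], e2[1], e2[2], e2[3], c2, s2);
      if (i1 && i2) ++ni;
      if (i1 || i2) ++nu;
    }
  if (nu == 0) return 0.0;
  return (double)ni / (double)nu;
}

// probability-weighted centroid of the interior; returns (wx, wy, support)
// [[Rcpp::export(name = ".ellipseCentroidC")]]
NumericVector ellipse_centroid_cpp(NumericMatrix probs, double cx, double cy,
                                   double a, double b, double theta) {
  const int h = probs.nrow(), w = probs.ncol();
  int x0 = std::max(0, (int)std::floor(cx - a));
  int x1 = std::min(w - 1, (int)std::ceil(cx + a));
  int y0 = std::max(0, (int)std::floor(cy - a));
  int y1 = std::min(h - 1, (int)std::ceil(cy + a));
  NumericVector out = NumericVector::create(NA_REAL, NA_REAL, NA_REAL);
  if (x1 < x0 || y1 < y0) return out;
  double ct = std::cos(theta), st = std::sin(theta);
  double sw = 0.0, sx = 0.0, sy = 0.0;
  long n = 0;
  for (int x = x0; x <= x1; ++x)
    for (int y = y0; y <= y1; ++y)
      if (insideE(x, y, cx, cy, a, b, ct, st)) {
        double p = probs(y, x);
        sw += p; sx += p * x; sy += p * y;
        ++n;
      }
  if (n == 0 || sw <= 0) return out;
  out[0] = sx / sw; out[1] = sy / sw; out[2] = sw / (double)n;
  return out;
}
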