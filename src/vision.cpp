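#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary raster.
// fg: integer matrix, nonzero = foreground.  connectivity: 4 or 8.
// Labels are assigned in raster-scan (row-major, top-left origin)
// first-encounter order, starting at 1.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& fg, int connectivity) {
  const int h = fg.nrow(), w = fg.ncol();
  IntegerMatrix lab(h, w);
  std::vector<std::pair<int,int> > stack;
  stack.reserve(1024);
  const int dr8[8] = { 0, 0, -1, 1, -1, -1, 1, 1 };
  const int dc8[8] = { -1, 1, 0, 0, -1, 1, -1, 1 };
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      if (fg(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr8[k], cc = p.second + dc8[k];
          if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
          if (fg(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation with a square (2*radius+1) structuring element,
// computed separably as a horizontal then vertical running maximum.
// [[Rcpp::export(name = ".dilate_square")]]
IntegerMatrix dilate_square(const IntegerMatrix& fg, int radius) {
  const int h = fg.nrow(), w = fg.ncol();
  IntegerMatrix tmp(h, w), out(h, w);
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      int v = 0;
      int lo = std::max(0, c - radius), hi = std::min(w - 1, c + radius);
      for (int k = lo; k <= hi && !v; ++k) v = (fg(r, k) != 0);
      tmp(r, c) = v;
    }
  }
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      int v = 0;
      int lo = std::max(0, r - radius), hi = std::min(h - 1, r + radius);
      for (int k = lo; k <= hi && !v; ++k) v = (tmp(k, c) != 0);
      out(r, c) = v;
    }
  }
  return out;
}

// Separable convolution with an odd-length kernel; image edges are
// handled by clamping (replicating the border sample).
// [[Rcpp::export(name = ".convolve_sep")]]
NumericMatrix convolve_sep(const NumericMatrix& img, const NumericVector& kernel) {
  const int h = img.nrow(), w = img.ncol();
  const int kn = kernel.size(), half = kn / 2;
  NumericMatrix tmp(h, w), out(h, w);
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      double s = 0.0;
      for (int k = 0; k < kn; ++k) {
        int cc = c + k - half;
        if (cc < 0) cc = 0;
        if (cc >= w) cc = w - 1;
        s += img(r, cc) * kernel[k];
      }
      tmp(r, c) = s;
    }
  }
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      double s = 0.0;
      for (int k = 0; k < kn; ++k) {
        int rr = r + k - half;
        if (rr < 0) rr = 0;
        if (rr >= h) rr = h - 1;
        s += tmp(rr, c) * kernel[k];
      }
      out(r, c) = s;
    }
  }
  return out;
}
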