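// Low-level raster operations shared by the simulator, segmentation and
// patch-preparation code. Conventions: images are R matrices indexed
// [row, col] = [y + 1, x + 1]; pixel centers sit at integer (x, y)
// coordinates, 0-based.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Separable Gaussian blur. The kernel is truncated at 3*sigma and
// renormalized at the borders, so a constant image is mapped to itself
// exactly (no energy leaks out of the field of view).
// [[Rcpp::export(name = ".cpp_gauss_blur")]]
arma::mat cpp_gauss_blur(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  int rad = (int)std::ceil(3.0 * sigma);
  arma::vec k(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i)
    k(i + rad) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  k /= arma::accu(k);
  int H = img.n_rows, W = img.n_cols;
  arma::mat tmp(H, W), out(H, W);
  // rows direction (y)
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double s = 0.0, wsum = 0.0;
      int lo = std::max(0, y - rad), hi = std::min(H - 1, y + rad);
      for (int yy = lo; yy <= hi; ++yy) {
        double w = k(yy - y + rad);
        s += w * img(yy, x);
        wsum += w;
      }
      tmp(y, x) = s / wsum;
    }
  }
  // cols direction (x)
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double s = 0.0, wsum = 0.0;
      int lo = std::max(0, x - rad), hi = std::min(W - 1, x + rad);
      for (int xx = lo; xx <= hi; ++xx) {
        double w = k(xx - x + rad);
        s += w * tmp(y, xx);
        wsum += w;
      }
      out(y, x) = s / wsum;
    }
  }
  return out;
}

// Bilinear resampling to an arbitrary output size. Output pixel i (0-based)
// maps to source coordinate (i + 0.5) * src/out - 0.5 (pixel-center
// convention); source coordinates outside the grid are clamped.
// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
arma::mat cpp_resize_bilinear(const arma::mat& img, int out_h, int out_w) {
  int H = img.n_rows, W = img.n_cols;
  arma::mat out(out_h, out_w);
  double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int oy = 0; oy < out_h; ++oy) {
    double fy = (oy + 0.5) * sy - 0.5;
    if (fy < 0) fy = 0;
    if (fy > H - 1) fy = H - 1;
    int y0 = (int)std::floor(fy);
    int y1 = std::min(y0 + 1, H - 1);
    double wy = fy - y0;
    for (int ox = 0; ox < out_w; ++ox) {
      double fx = (ox + 0.5) * sx - 0.5;
      if (fx < 0) fx = 0;
      if (fx > W - 1) fx = W - 1;
      int x0 = (int)std::floor(fx);
      int x1 = std::min(x0 + 1, W - 1);
      double wx = fx - x0;
      out(oy, ox) =
        (1 - wy) * ((1 - wx) * img(y0, x0) + wx * img(y0, x1)) +
        wy * ((1 - wx) * img(y1, x0) + wx * img(y1, x1));
    }
  }
  return out;
}

// Affine patch transform used by training-set augmentation: scale about the
// patch center, then shift by (dx, dy) px. Out-of-view source samples fill
// with `fill`. Inverse-mapped bilinear interpolation.
// [[Rcpp::export(name = ".cpp_scale_shift")]]
arma::mat cpp_scale_shift(const arma::mat& img, double scale, double dx,
                          double dy, double fill) {
  int H = img.n_rows, W = img.n_cols;
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  arma::mat out(H, W);
  for (int oy = 0; oy < H; ++oy) {
    for (int ox = 0; ox < W; ++ox) {
      // inverse map: undo shift, undo scale about center
      double sy = (oy - dy - cy) / scale + cy;
      double sx = (ox - dx - cx) / scale + cx;
      if (sy < 0 || sy > H - 1 || sx < 0 || sx > W - 1) {
        out(oy, ox) = fill;
        continue;
      }
      int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
      double wy = sy - y0, wx = sx - x0;
      out(oy, ox) =
        (1 - wy) * ((1 - wx) * img(y0, x0) + wx * img(y0, x1)) +
        wy * ((1 - wx) * img(y1, x0) + wx * img(y1, x1));
    }
  }
  return out;
}
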