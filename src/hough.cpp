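// Two-stage circular Hough transform.
//
// Stage 1 votes circle centers: every edge pixel (Sobel gradient magnitude
// above a fraction of the image maximum) casts votes along +/- its gradient
// direction at every radius in [rmin, rmax]; peaks of the smoothed
// accumulator are candidate centers. Stage 2 estimates, for each candidate,
// the radius as the peak of the radial mean-intensity profile (the rim of a
// fluorescent shell is an intensity maximum, which is unbiased even when
// the edge map carries the two borders of a thick thresholded band), and
// scores the circle by angular coverage: the fraction of angular sectors
// containing an edge pixel near the fitted radius. Circles are kept when
// score >= 1 - sensitivity, so raising the sensitivity only admits more
// circles; overlapping candidates are resolved by keeping the higher score
// (non-maximum suppression on center distance).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// remove connected components (8-connectivity) smaller than min_area from
// a binary image; suppresses noise speckle surviving the threshold
static void drop_small_components(arma::mat& m, int min_area) {
  const int H = m.n_rows, W = m.n_cols;
  arma::Mat<int> lab(H, W, arma::fill::zeros);
  std::vector<std::pair<int,int>> stack, comp;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (m(y, x) <= 0 || lab(y, x)) continue;
      stack.clear(); comp.clear();
      stack.push_back({x, y});
      lab(y, x) = 1;
      while (!stack.empty()) {
        auto p = stack.back(); stack.pop_back();
        comp.push_back(p);
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nx = p.first + dx, ny = p.second + dy;
            if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
            if (m(ny, nx) > 0 && !lab(ny, nx)) {
              lab(ny, nx) = 1;
              stack.push_back({nx, ny});
            }
          }
      }
      if ((int)comp.size() < min_area)
        for (auto& p : comp) m(p.second, p.first) = 0;
    }
}

// fill background holes smaller than min_area: a patchy bright interior
// (intensity hovering at the threshold) otherwise leaves a swiss-cheese
// mask whose internal edges flood the vote space
static void fill_small_holes(arma::mat& m, int min_area) {
  arma::mat inv(m.n_rows, m.n_cols);
  for (arma::uword i = 0; i < m.n_elem; ++i) inv(i) = m(i) > 0 ? 0.0 : 1.0;
  drop_small_components(inv, min_area);
  // pixels that were background but sat in a dropped (small) component
  for (arma::uword i = 0; i < m.n_elem; ++i)
    if (m(i) <= 0 && inv(i) <= 0) m(i) = 1.0;
}

// [[Rcpp::export(name = ".cpp_cht_detect")]]
DataFrame cpp_cht_detect(const arma::mat& img, const arma::mat& intensity,
                         int rmin, int rmax, double sensitivity,
                         double edge_frac, int max_peaks, bool is_mask,
                         int min_component, int min_hole) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat edge_img = img;
  if (is_mask && min_component > 0)
    drop_small_components(edge_img, min_component);
  if (is_mask && min_hole > 0)
    fill_small_holes(edge_img, min_hole);

  // Edge pixels: strong intensity-gradient pixels within the (dilated)
  // cleaned mask. The mask confines voting to real structures (the paper's
  // rationale for masking at low SNR); the intensity gradient supplies
  // magnitude and an accurate direction — pixels at the mask border sit on
  // the shallow tail of the rim profile where the local direction is
  // noise-dominated, while the steep rim slopes vote precisely.
  auto sobel = [&](const arma::mat& m, arma::mat& gx, arma::mat& gy) {
    gx.zeros(H, W); gy.zeros(H, W);
    for (int y = 1; y < H - 1; ++y)
      for (int x = 1; x < W - 1; ++x) {
        gx(y, x) = (m(y - 1, x + 1) + 2 * m(y, x + 1) + m(y + 1, x + 1)) -
                   (m(y - 1, x - 1) + 2 * m(y, x - 1) + m(y + 1, x - 1));
        gy(y, x) = (m(y + 1, x - 1) + 2 * m(y + 1, x) + m(y + 1, x + 1)) -
                   (m(y - 1, x - 1) + 2 * m(y - 1, x) + m(y - 1, x + 1));
      }
  };
  arma::mat igx, igy;
  sobel(intensity, igx, igy);
  arma::mat imag = arma::sqrt(igx % igx + igy % igy);
  // dilate the mask so the slope pixels flanking a thin (1 px) rim count
  arma::mat dmask = edge_img;
  for (int it = 0; it < 2; ++it) {
    arma::mat nd = dmask;
    for (int y = 1; y < H - 1; ++y)
      for (int x = 1; x < W - 1; ++x)
        if (dmask(y, x) <= 0) {
          double mx = 0;
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx)
              mx = std::max(mx, dmask(y + dy, x + dx));
          nd(y, x) = mx;
        }
    dmask = nd;
  }
  double mmax = 0;
  for (int y = 1; y < H - 1; ++y)
    for (int x = 1; x < W - 1; ++x)
      if (dmask(y, x) > 0) mmax = std::max(mmax, imag(y, x));
  if (mmax <= 0) {
    return DataFrame::create(_["cx"] = NumericVector(0),
                             _["cy"] = NumericVector(0),
                             _["r"] = NumericVector(0),
                             _["score"] = NumericVector(0));
  }
  double ethr = edge_frac * mmax;

  std::vector<int> ex, ey;
  std::vector<double> eux, euy, ew;
  for (int y = 1; y < H - 1; ++y)
    for (int x = 1; x < W - 1; ++x)
      if (dmask(y, x) > 0 && imag(y, x) > ethr) {
        ex.push_back(x); ey.push_back(y);
        eux.push_back(igx(y, x) / imag(y, x));
        euy.push_back(igy(y, x) / imag(y, x));
        ew.push_back(imag(y, x));
      }
  const int nE = (int)ex.size();
  // votes weighted by gradient magnitude: pixels on a real rim slope aim
  // accurately and dominate; pixels whose local gradient is noise-driven
  // (e.g. the faint outer apron of a dim vesicle) contribute little
  double wnorm = 0;
  for (int i = 0; i < nE; ++i) wnorm = std::max(wnorm, ew[i]);
  if (wnorm <= 0) wnorm = 1.0;

  // Stage 1: center accumulator
  arma::mat acc(H, W, arma::fill::zeros);
  for (int i = 0; i < nE; ++i) {
    double w = ew[i] / wnorm;
    for (int r = rmin; r <= rmax; ++r) {
      for (int s = -1; s <= 1; s += 2) {
        int cx = (int)std::lround(ex[i] + s * r * eux[i]);
        int cy = (int)std::lround(ey[i] + s * r * euy[i]);
        if (cx >= 0 && cx < W && cy >= 0 && cy < H) acc(cy, cx) += w;
      }
    }
  }
  // 3x3 box smoothing keeps votes split over neighboring bins together
  arma::mat accs(H, W, arma::fill::zeros);
  for (int y = 1; y < H - 1; ++y)
    for (int x = 1; x < W - 1; ++x)
      accs(y, x) = arma::accu(acc.submat(y - 1, x - 1, y + 1, x + 1)) / 9.0;

  // local maxima above a gate relative to the strongest peak (final
  // acceptance is decided by the coverage score, not here)
  const double gate = std::max(4.0, 0.15 * accs.max());
  std::vector<std::pair<double, std::pair<int,int>>> peaks;
  for (int y = 2; y < H - 2; ++y) {
    for (int x = 2; x < W - 2; ++x) {
      double v = accs(y, x);
      if (v < gate) continue;
      bool ismax = true;
      for (int dy = -1; dy <= 1 && ismax; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0) continue;
          if (accs(y + dy, x + dx) > v ||
              (accs(y + dy, x + dx) == v && (dy < 0 || (dy == 0 && dx < 0)))) {
            ismax = false; break;
          }
        }
      if (ismax) peaks.push_back({v, {x, y}});
    }
  }
  std::sort(peaks.begin(), peaks.end(),
            [](const std::pair<double, std::pair<int,int>>& a,
               const std::pair<double, std::pair<int,int>>& b) {
              return a.first > b.first;
            });
  // suppress near-coincident accumulator peaks (same center, split votes)
  std::vector<std::pair<int,int>> cand;
  for (auto& p : peaks) {
    bool dup = false;
    for (auto& c : cand) {
      double d = std::hypot((double)(p.second.first - c.first),
                            (double)(p.second.second - c.second));
      if (d < 3.0) { dup = true; break; }
    }
    if (!dup) cand.push_back(p.second);
    if ((int)cand.size() >= max_peaks) break;
  }

  // Stage 2: per-candidate radius estimation + scoring
  std::vector<double> out_cx, out_cy, out_r, out_score;
  const double thr_score = 1.0 - sensitivity;
  const int nsect = 48;
  for (auto& c : cand) {
    // sub-pixel center: centroid of the 5x5 accumulator neighborhood
    // (above half the peak, so a plateau does not drag the centroid)
    double peak = accs(c.second, c.first);
    double sw = 0, sx = 0, sy = 0;
    for (int dy = -2; dy <= 2; ++dy)
      for (int dx = -2; dx <= 2; ++dx) {
        int yy = c.second + dy, xx = c.first + dx;
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        double w = accs(yy, xx);
        if (w < 0.5 * peak) continue;
        sw += w; sx += w * xx; sy += w * yy;
      }
    double cx = sw > 0 ? sx / sw : c.first;
    double cy = sw > 0 ? sy / sw : c.second;

    // radial mean-intensity profile, 1 px bins over [0, rmax+2]
    int nb = rmax + 3;
    arma::vec psum(nb, arma::fill::zeros), pcnt(nb, arma::fill::zeros);
    int x0 = std::max(0, (int)std::floor(cx) - rmax - 2);
    int x1 = std::min(W - 1, (int)std::ceil(cx) + rmax + 2);
    int y0 = std::max(0, (int)std::floor(cy) - rmax - 2);
    int y1 = std::min(H - 1, (int)std::ceil(cy) + rmax + 2);
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        int b = (int)std::lround(std::hypot(x - cx, y - cy));
        if (b < nb) { psum(b) += intensity(y, x); pcnt(b) += 1.0; }
      }
    arma::vec prof(nb, arma::fill::zeros);
    for (int b = 0; b < nb; ++b)
      if (pcnt(b) > 0) prof(b) = psum(b) / pcnt(b);
    arma::vec ps = prof;
    for (int b = 1; b < nb - 1; ++b)
      ps(b) = 0.25 * prof(b - 1) + 0.5 * prof(b) + 0.25 * prof(b + 1);
    // peak restricted to the admissible radius range
    int bbest = rmin;
    for (int b = rmin; b <= rmax; ++b)
      if (ps(b) > ps(bbest)) bbest = b;
    // sub-bin refinement: intensity-weighted centroid around the peak
    double rs = 0, rw = 0;
    int blo = std::max(0, bbest - 2), bhi = std::min(nb - 1, bbest + 2);
    double base = ps.subvec(blo, bhi).min();
    for (int b = blo; b <= bhi; ++b) {
      double w = ps(b) - base;
      rs += w * b; rw += w;
    }
    double r = rw > 0 ? rs / rw : (double)bbest;
    if (r < rmin || r > rmax) continue;

    // Angular coverage of edge support. The edge map of a thresholded
    // blurred rim carries the two borders of the band, so support is
    // measured tightly (+/- 2.5 px) around the one or two modes of the
    // radial edge-distance histogram; a mode must also sit near the
    // intensity-profile radius, otherwise the candidate does not describe
    // a rim at all. Tight tolerances keep off-center candidates (which
    // spread edge distances over a wide range) from scoring.
    double wmax = std::max(9.0, 0.25 * r);
    int nbh = rmax + 3;
    arma::vec ehist(nbh, arma::fill::zeros);
    for (int i = 0; i < nE; ++i) {
      int b = (int)std::lround(std::hypot(ex[i] - cx, ey[i] - cy));
      if (b < nbh) ehist(b) += 1.0;
    }
    arma::vec ehs = ehist;
    for (int b = 1; b < nbh - 1; ++b)
      ehs(b) = 0.25 * ehist(b - 1) + 0.5 * ehist(b) + 0.25 * ehist(b + 1);
    arma::uword m1;
    double h1 = ehs.max(m1);
    if (h1 <= 0) continue;
    std::vector<double> modes{(double)m1};
    arma::vec eh2 = ehs;
    int zlo = std::max(0, (int)m1 - 3), zhi = std::min(nbh - 1, (int)m1 + 3);
    for (int b = zlo; b <= zhi; ++b) eh2(b) = 0;
    arma::uword m2;
    double h2 = eh2.max(m2);
    if (h2 >= 0.4 * h1) modes.push_back((double)m2);
    double moddev = wmax + 1;
    for (double m : modes) moddev = std::min(moddev, std::abs(m - r));
    if (moddev > wmax) continue;
    std::vector<bool> covered(nsect, false);
    for (int i = 0; i < nE; ++i) {
      double d = std::hypot(ex[i] - cx, ey[i] - cy);
      bool near = false;
      for (double m : modes)
        if (std::abs(d - m) <= 2.5) { near = true; break; }
      if (near) {
        double a = std::atan2(ey[i] - cy, ex[i] - cx);
        int sct = (int)std::floor((a + M_PI) / (2 * M_PI) * nsect);
        if (sct < 0) sct = 0;
        if (sct >= nsect) sct = nsect - 1;
        covered[sct] = true;
      }
    }
    int ncov = 0;
    for (int sct = 0; sct < nsect; ++sct) if (covered[sct]) ++ncov;
    double score = (double)ncov / nsect;
    if (score >= thr_score) {
      out_cx.push_back(cx); out_cy.push_back(cy);
      out_r.push_back(r); out_score.push_back(score);
    }
  }

  // sort by descending score; non-maximum suppression: drop a circle whose
  // center lies within 0.75*rmin of a stronger one (covers the <2 px / <2
  // px duplicate rule as a special case)
  std::vector<int> ord(out_cx.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return out_score[a] > out_score[b];
  });
  const double nms_dist = 0.75 * rmin;
  std::vector<double> fx, fy, fr, fs;
  for (int i : ord) {
    bool dup = false;
    for (size_t j = 0; j < fx.size(); ++j) {
      double dc = std::hypot(out_cx[i] - fx[j], out_cy[i] - fy[j]);
      double dr = std::abs(out_r[i] - fr[j]);
      if ((dc < 2.0 && dr < 2.0) || dc < nms_dist) { dup = true; break; }
    }
    if (!dup) {
      fx.push_back(out_cx[i]); fy.push_back(out_cy[i]);
      fr.push_back(out_r[i]); fs.push_back(out_score[i]);
    }
  }
  return DataFrame::create(_["cx"] = wrap(fx), _["cy"] = wrap(fy),
                           _["r"] = wrap(fr), _["score"] = wrap(fs));
}
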