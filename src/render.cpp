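// Image kernels: reverse-skeletonization patch warping, worm outline mask,
// normalized cross-correlation template matching, and the procedural
// fixture-frame renderer. Skeleton coordinates are passed in R convention
// (x = column, y = row, 1-based, y increasing downward) and converted to
// 0-based here. Images are (row, col) matrices with values in [0, 1].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using arma::mat;
using arma::vec;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double bilinear(const mat& img, double y, double x) {
  int H = img.n_rows, W = img.n_cols;
  x = clampd(x, 0.0, W - 1.000001);
  y = clampd(y, 0.0, H - 1.000001);
  int x0 = (int)x, y0 = (int)y;
  double fx = x - x0, fy = y - y0;
  int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  return img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x1) * fx * (1 - fy) +
         img(y1, x0) * (1 - fx) * fy + img(y1, x1) * fx * fy;
}

// ---- outline mask: per-segment convex quadrilaterals + end caps ------------

static void fill_quad(arma::imat& mask, const double qx[4], const double qy[4],
                      int L) {
  double xmin = qx[0], xmax = qx[0], ymin = qy[0], ymax = qy[0];
  for (int j = 1; j < 4; ++j) {
    xmin = std::min(xmin, qx[j]); xmax = std::max(xmax, qx[j]);
    ymin = std::min(ymin, qy[j]); ymax = std::max(ymax, qy[j]);
  }
  int x0 = std::max(0, (int)std::floor(xmin)), x1 = std::min(L - 1, (int)std::ceil(xmax));
  int y0 = std::max(0, (int)std::floor(ymin)), y1 = std::min(L - 1, (int)std::ceil(ymax));
  for (int x = x0; x <= x1; ++x)
    for (int y = y0; y <= y1; ++y) {
      bool inside = true;
      for (int j = 0; j < 4 && inside; ++j) {
        int k = (j + 1) % 4;
        double cx = (qx[k] - qx[j]) * (y - qy[j]) - (qy[k] - qy[j]) * (x - qx[j]);
        if (cx < 0) inside = false;
      }
      if (inside) mask(y, x) = 1;
    }
}

static void fill_disc(arma::imat& mask, double cx, double cy, double r, int L) {
  int x0 = std::max(0, (int)std::floor(cx - r)), x1 = std::min(L - 1, (int)std::ceil(cx + r));
  int y0 = std::max(0, (int)std::floor(cy - r)), y1 = std::min(L - 1, (int)std::ceil(cy + r));
  for (int x = x0; x <= x1; ++x)
    for (int y = y0; y <= y1; ++y)
      if ((x - cx) * (x - cx) + (y - cy) * (y - cy) <= r * r) mask(y, x) = 1;
}

static arma::imat outline_mask(const mat& skel, const vec& ww, int L) {
  // skel: n x 2 (x, y), 0-based
  int n = skel.n_rows;
  arma::imat mask(L, L, arma::fill::zeros);
  for (int i = 0; i + 1 < n; ++i) {
    double dx = skel(i + 1, 0) - skel(i, 0), dy = skel(i + 1, 1) - skel(i, 1);
    double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-12) continue;
    double nx = -dy / len, ny = dx / len;
    double r0 = ww(i) / 2.0, r1 = ww(i + 1) / 2.0;
    // counter-clockwise in (x, y with y down) == consistent sign order
    double qx[4] = {skel(i, 0) + nx * r0, skel(i + 1, 0) + nx * r1,
                    skel(i + 1, 0) - nx * r1, skel(i, 0) - nx * r0};
    double qy[4] = {skel(i, 1) + ny * r0, skel(i + 1, 1) + ny * r1,
                    skel(i + 1, 1) - ny * r1, skel(i, 1) - ny * r0};
    // ensure orientation for the inside test
    double area2 = 0;
    for (int j = 0; j < 4; ++j) {
      int k = (j + 1) % 4;
      area2 += qx[j] * qy[k] - qx[k] * qy[j];
    }
    if (area2 < 0) {
      std::swap(qx[1], qx[3]);
      std::swap(qy[1], qy[3]);
    }
    fill_quad(mask, qx, qy, L);
    // rounded joints keep bent segments connected
    fill_disc(mask, skel(i + 1, 0), skel(i + 1, 1), std::max(r1, 0.5), L);
  }
  fill_disc(mask, skel(0, 0), skel(0, 1), ww(0) / 2.0, L);
  fill_disc(mask, skel(n - 1, 0), skel(n - 1, 1), ww(n - 1) / 2.0, L);
  return mask;
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_outline_mask(Rcpp::NumericMatrix skel,
                                     Rcpp::NumericVector widths, int L) {
  int n = skel.nrow();
  mat s(n, 2);
  vec w(n);
  for (int i = 0; i < n; ++i) {
    s(i, 0) = skel(i, 0) - 1.0;
    s(i, 1) = skel(i, 1) - 1.0;
    w(i) = widths[i];
  }
  arma::imat m = outline_mask(s, w, L);
  Rcpp::IntegerMatrix out(L, L);
  for (int x = 0; x < L; ++x)
    for (int y = 0; y < L; ++y) out(y, x) = (int)m(y, x);
  return out;
}

// ---- synthetic rendering ---------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_render_synth(Rcpp::NumericMatrix ref_img,
                            Rcpp::NumericMatrix ref_skel,
                            Rcpp::NumericMatrix tgt_skel,
                            Rcpp::NumericVector widths,
                            double w_multiplier, int step,
                            int L, double background,
                            bool head_last, double mask_pad) {
  int n = ref_skel.nrow();
  mat ref(ref_img.nrow(), ref_img.ncol());
  for (int j = 0; j < ref_img.ncol(); ++j)
    for (int i = 0; i < ref_img.nrow(); ++i) ref(i, j) = ref_img(i, j);
  mat rs(n, 2), ts(n, 2);
  vec ww(n);
  for (int i = 0; i < n; ++i) {
    rs(i, 0) = ref_skel(i, 0) - 1.0; rs(i, 1) = ref_skel(i, 1) - 1.0;
    ts(i, 0) = tgt_skel(i, 0) - 1.0; ts(i, 1) = tgt_skel(i, 1) - 1.0;
    ww(i) = widths[i];
  }
  mat canvas(L, L, arma::fill::zeros);
  arma::imat cover(L, L, arma::fill::zeros);

  // patch start indices tiling the skeleton; drawn tail-first by default so
  // the head patches land on top
  std::vector<int> starts;
  for (int i = 0; i + step < n; i += step) starts.push_back(i);
  if (!starts.empty() && starts.back() + step < n - 1) starts.push_back(n - 1 - step);
  if (head_last) std::reverse(starts.begin(), starts.end());

  for (int idx : starts) {
    int i0 = idx, i1 = idx + step;
    double rcx = (rs(i0, 0) + rs(i1, 0)) / 2, rcy = (rs(i0, 1) + rs(i1, 1)) / 2;
    double tcx = (ts(i0, 0) + ts(i1, 0)) / 2, tcy = (ts(i0, 1) + ts(i1, 1)) / 2;
    double rux = rs(i1, 0) - rs(i0, 0), ruy = rs(i1, 1) - rs(i0, 1);
    double tux = ts(i1, 0) - ts(i0, 0), tuy = ts(i1, 1) - ts(i0, 1);
    double rlen = std::sqrt(rux * rux + ruy * ruy);
    double tlen = std::sqrt(tux * tux + tuy * tuy);
    if (rlen < 1e-9 || tlen < 1e-9) continue;
    rux /= rlen; ruy /= rlen; tux /= tlen; tuy /= tlen;
    double rnx = -ruy, rny = rux, tnx = -tuy, tny = tux;
    int imid = (i0 + i1) / 2;
    double hw = w_multiplier * ww(imid) / 2.0;
    double rhl = rlen / 2.0 + 0.5, thl = tlen / 2.0 + 0.5; // slight overlap
    // bounding box of the target rectangle
    double ex = std::abs(tux) * thl + std::abs(tnx) * hw;
    double ey = std::abs(tuy) * thl + std::abs(tny) * hw;
    int x0 = std::max(0, (int)std::floor(tcx - ex)), x1 = std::min(L - 1, (int)std::ceil(tcx + ex));
    int y0 = std::max(0, (int)std::floor(tcy - ey)), y1 = std::min(L - 1, (int)std::ceil(tcy + ey));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y) {
        double dx = x - tcx, dy = y - tcy;
        double a = dx * tux + dy * tuy;      // along-axis coordinate
        double c = dx * tnx + dy * tny;      // across-axis coordinate
        if (std::abs(a) > thl || std::abs(c) > hw) continue;
        double srcx = rcx + (a / thl) * rhl * rux + c * rnx;
        double srcy = rcy + (a / thl) * rhl * ruy + c * rny;
        double val = bilinear(ref, srcy, srcx);
        if (cover(y, x) == 0) canvas(y, x) = val;
        else canvas(y, x) = 0.5 * canvas(y, x) + 0.5 * val;
        cover(y, x) += 1;
      }
  }

  // mask protrusions with the expected worm outline (actual width plus a
  // small pad so the copied halo keeps its soft edge)
  arma::imat mask = outline_mask(ts, ww + 2.0 * mask_pad, L);
  for (int x = 0; x < L; ++x)
    for (int y = 0; y < L; ++y)
      if (!mask(y, x) || cover(y, x) == 0) canvas(y, x) = background;

  // 3x3 median filter restricted to the worm region
  mat out = canvas;
  double win[9];
  for (int x = 0; x < L; ++x)
    for (int y = 0; y < L; ++y) {
      if (!mask(y, x)) continue;
      int m = 0;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          int xx = x + dx, yy = y + dy;
          win[m++] = (xx >= 0 && xx < L && yy >= 0 && yy < L)
                         ? canvas(yy, xx) : background;
        }
      std::nth_element(win, win + 4, win + 9);
      out(y, x) = win[4];
    }

  Rcpp::NumericMatrix res(L, L);
  Rcpp::LogicalMatrix msk(L, L);
  for (int x = 0; x < L; ++x)
    for (int y = 0; y < L; ++y) {
      res(y, x) = out(y, x);
      msk(y, x) = mask(y, x) != 0;
    }
  return Rcpp::List::create(Rcpp::Named("image") = res,
                            Rcpp::Named("mask") = msk);
}

// ---- template matching (normalized correlation coefficient) ---------------

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_ncc_map(Rcpp::NumericMatrix source,
                                Rcpp::NumericMatrix templ) {
  int Hs = source.nrow(), Ws = source.ncol();
  int Ht = templ.nrow(), Wt = templ.ncol();
  if (Ht > Hs || Wt > Ws)
    Rcpp::stop("template is larger than the source image");
  int Ho = Hs - Ht + 1, Wo = Ws - Wt + 1;
  double npix = (double)Ht * Wt;
  double tmean = 0;
  for (int j = 0; j < Wt; ++j)
    for (int i = 0; i < Ht; ++i) tmean += templ(i, j);
  tmean /= npix;
  mat T(Ht, Wt);
  double tss = 0;
  for (int j = 0; j < Wt; ++j)
    for (int i = 0; i < Ht; ++i) {
      T(i, j) = templ(i, j) - tmean;
      tss += T(i, j) * T(i, j);
    }
  Rcpp::NumericMatrix out(Ho, Wo);
  for (int xo = 0; xo < Wo; ++xo)
    for (int yo = 0; yo < Ho; ++yo) {
      double smean = 0;
      for (int j = 0; j < Wt; ++j)
        for (int i = 0; i < Ht; ++i) smean += source(yo + i, xo + j);
      smean /= npix;
      double num = 0, sss = 0;
      for (int j = 0; j < Wt; ++j)
        for (int i = 0; i < Ht; ++i) {
          double sv = source(yo + i, xo + j) - smean;
          num += sv * T(i, j);
          sss += sv * sv;
        }
      double den = std::sqrt(sss * tss);
      out(yo, xo) = den > 1e-12 ? num / den : 0.0;
    }
  return out;
}

// ---- gaussian blur ---------------------------------------------------------

static mat gauss_blur(const mat& img, double sigma) {
  if (sigma <= 0) return img;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  vec k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k(i + r);
  }
  k /= s;
  int H = img.n_rows, W = img.n_cols;
  mat tmp(H, W), out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int yy = std::min(std::max(y + i, 0), H - 1);
        acc += k(i + r) * img(yy, x);
      }
      tmp(y, x) = acc;
    }
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int xx = std::min(std::max(x + i, 0), W - 1);
        acc += k(i + r) * tmp(y, xx);
      }
      out(y, x) = acc;
    }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_gauss_blur(Rcpp::NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  mat x(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) x(i, j) = img(i, j);
  mat y = gauss_blur(x, sigma);
  Rcpp::NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = y(i, j);
  return out;
}

// ---- procedural fixture frame ---------------------------------------------
// Draws a smooth dark worm body on a light background with a radial shading
// profile, longitudinal texture, sensor noise and optical blur.

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_fixture_frame(Rcpp::NumericMatrix skel,
                                      Rcpp::NumericVector widths, int L,
                                      double background, double body_dark,
                                      double texture_amp, double texture_freq,
                                      double noise_sd, double blur_sigma,
                                      int seed) {
  int n = skel.nrow();
  mat s(n, 2);
  vec w(n);
  for (int i = 0; i < n; ++i) {
    s(i, 0) = skel(i, 0) - 1.0;
    s(i, 1) = skel(i, 1) - 1.0;
    w(i) = widths[i];
  }
  mat dist(L, L);
  dist.fill(1e9);
  mat frac(L, L, arma::fill::zeros);  // arc-length fraction of nearest point
  mat wloc(L, L, arma::fill::zeros);  // local width at nearest point
  double wmax = w.max();
  for (int i = 0; i + 1 < n; ++i) {
    double ax = s(i, 0), ay = s(i, 1);
    double bx = s(i + 1, 0), by = s(i + 1, 1);
    double dx = bx - ax, dy = by - ay;
    double l2 = dx * dx + dy * dy;
    double pad = wmax / 2.0 + 2.0;
    int x0 = std::max(0, (int)std::floor(std::min(ax, bx) - pad));
    int x1 = std::min(L - 1, (int)std::ceil(std::max(ax, bx) + pad));
    int y0 = std::max(0, (int)std::floor(std::min(ay, by) - pad));
    int y1 = std::min(L - 1, (int)std::ceil(std::max(ay, by) + pad));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y) {
        double t = l2 > 1e-12
                       ? clampd(((x - ax) * dx + (y - ay) * dy) / l2, 0.0, 1.0)
                       : 0.0;
        double px = ax + t * dx, py = ay + t * dy;
        double d = std::sqrt((x - px) * (x - px) + (y - py) * (y - py));
        if (d < dist(y, x)) {
          dist(y, x) = d;
          frac(y, x) = (i + t) / (n - 1.0);
          wloc(y, x) = w(i) * (1 - t) + w(i + 1) * t;
        }
      }
  }
  mat img(L, L);
  img.fill(background);
  for (int x = 0; x < L; ++x)
    for (int y = 0; y < L; ++y) {
      double r = wloc(y, x) / 2.0;
      if (dist(y, x) >= r + 1.0 || r <= 0) continue;
      double rel = dist(y, x) / std::max(r, 1e-9);
      // darker core, lighter rim, soft 1-px anti-aliased edge
      double body = body_dark + (background - body_dark) * 0.35 * rel * rel;
      body += texture_amp * std::sin(2.0 * M_PI * texture_freq * frac(y, x));
      if (dist(y, x) <= r) img(y, x) = body;
      else {
        double edge = dist(y, x) - r; // in (0, 1)
        img(y, x) = body * (1 - edge) + background * edge;
      }
    }
  if (noise_sd > 0) {
    std::mt19937 rng((unsigned int)seed);
    std::normal_distribution<double> gauss(0.0, noise_sd);
    for (int x = 0; x < L; ++x)
      for (int y = 0; y < L; ++y) img(y, x) += gauss(rng);
  }
  if (blur_sigma > 0) img = gauss_blur(img, blur_sigma);
  Rcpp::NumericMatrix out(L, L);
  for (int x = 0; x < L; ++x)
    for (int y = 0; y < L; ++y) out(y, x) = clampd(img(y, x), 0.0, 1.0);
  return out;
}
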