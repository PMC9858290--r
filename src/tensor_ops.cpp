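// Low-level numerical kernels for the convolutional networks.
//
// Feature stacks use the R array layout H x W x C (column-major), batches
// H x W x C x N. Convolutions are same-padded cross-correlations computed
// by im2col + GEMM; kernels are stored kh x kw x Cin x Cout as in the R
// weight arrays, so no reordering happens at the interface.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) { H = d[0]; W = d[1]; C = d[2]; N = 1; }
  else if (d.size() == 4) { H = d[0]; W = d[1]; C = d[2]; N = d[3]; }
  else stop("expected a 3-d or 4-d array");
}

// Build the patch rows for one sample into a (possibly grouped) patch
// matrix with leading dimension `ld`; column r = i + k*j + k*k*c holds
// the pixel shifted by the kernel offset (i, j) in channel c, rows
// [row_off, row_off + H*W).
static void im2col_same(const double* x, int H, int W, int C, int k,
                        double* colbase, size_t ld, size_t row_off) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      const int dx = j - p;
      for (int i = 0; i < k; ++i) {
        const int dy = i - p;
        double* dst = colbase + (size_t)(i + k * j + k * k * c) * ld + row_off;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dx;
          double* d = dst + (size_t)w * H;
          if (sw < 0 || sw >= W) {
            std::fill(d, d + H, 0.0);
            continue;
          }
          const double* s = xc + (size_t)sw * H;
          const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          for (int h = 0; h < h0; ++h) d[h] = 0.0;
          for (int h = h0; h < h1; ++h) d[h] = s[h + dy];
          for (int h = h1; h < H; ++h) d[h] = 0.0;
        }
      }
    }
  }
}

// Scatter-add of a patch-matrix gradient back onto the input gradient.
static void col2im_same(const double* colbase, size_t ld, size_t row_off,
                        int H, int W, int C, int k, double* gx) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      const int dx = j - p;
      for (int i = 0; i < k; ++i) {
        const int dy = i - p;
        const double* src = colbase + (size_t)(i + k * j + k * k * c) * ld + row_off;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dx;
          if (sw < 0 || sw >= W) continue;
          const double* s = src + (size_t)w * H;
          double* d = xc + (size_t)sw * H;
          const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          for (int h = h0; h < h1; ++h) d[h + dy] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("kernel must be a 4-d array (kh, kw, in, out)");
  const int k = wd[0], Cin = wd[2], F = wd[3];
  if (wd[1] != k) stop("only square kernels are supported");
  if (Cin != C)
    stop("kernel depth (" + std::to_string(Cin) + ") does not match input depth (" +
         std::to_string(C) + ")");
  if (b.size() != F) stop("bias length must equal the number of filters");

  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, F, false, true);
  NumericVector out((size_t)H * W * F * N);
  out.attr("dim") = IntegerVector::create(H, W, F, N);

  // group samples into one GEMM; cap the patch-matrix working set
  const size_t col_bytes = (size_t)H * W * k * k * C * sizeof(double);
  int group = (int)std::max((size_t)1,
                            (size_t)(64u << 20) / std::max(col_bytes, (size_t)1));
  group = std::min(group, N);

  arma::mat col((size_t)H * W * group, (size_t)k * k * C);
  for (int n0 = 0; n0 < N; n0 += group) {
    const int g = std::min(group, N - n0);
    const size_t rows = (size_t)H * W * g;
    for (int j = 0; j < g; ++j)
      im2col_same(x.begin() + (size_t)(n0 + j) * H * W * C, H, W, C, k,
                  col.memptr(), col.n_rows, (size_t)j * H * W);
    arma::mat o;
    if ((size_t)g == (size_t)group) {
      o = col * Wm;
    } else {
      o = col.rows(0, rows - 1) * Wm;
    }
    for (int j = 0; j < g; ++j) {
      arma::mat dst(out.begin() + (size_t)(n0 + j) * H * W * F,
                    (size_t)H * W, F, false, true);
      dst = o.rows((size_t)j * H * W, (size_t)(j + 1) * H * W - 1);
      for (int f = 0; f < F; ++f) dst.col(f) += b[f];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    bool need_gx) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], F = wd[3];

  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, F, false, true);
  arma::mat gw((size_t)k * k * C, F, arma::fill::zeros);
  arma::vec gb(F, arma::fill::zeros);

  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }

  const size_t col_bytes = (size_t)H * W * k * k * C * sizeof(double);
  int group = (int)std::max((size_t)1,
                            (size_t)(48u << 20) / std::max(col_bytes, (size_t)1));
  group = std::min(group, N);

  arma::mat col((size_t)H * W * group, (size_t)k * k * C);
  arma::mat gym((size_t)H * W * group, F);
  arma::mat gcol;
  for (int n0 = 0; n0 < N; n0 += group) {
    const int g = std::min(group, N - n0);
    const size_t rows = (size_t)H * W * g;
    for (int j = 0; j < g; ++j) {
      im2col_same(x.begin() + (size_t)(n0 + j) * H * W * C, H, W, C, k,
                  col.memptr(), col.n_rows, (size_t)j * H * W);
      const arma::mat gsub(const_cast<double*>(gy.begin()) +
                             (size_t)(n0 + j) * H * W * F,
                           (size_t)H * W, F, false, true);
      gym.rows((size_t)j * H * W, (size_t)(j + 1) * H * W - 1) = gsub;
    }
    if (rows == col.n_rows) {
      gw += col.t() * gym;
      gb += arma::sum(gym, 0).t();
      if (need_gx) {
        gcol = gym * Wm.t();
        for (int j = 0; j < g; ++j)
          col2im_same(gcol.memptr(), gcol.n_rows, (size_t)j * H * W,
                      H, W, C, k, gx.begin() + (size_t)(n0 + j) * H * W * C);
      }
    } else {
      const arma::mat cpart = col.rows(0, rows - 1);
      const arma::mat gpart = gym.rows(0, rows - 1);
      gw += cpart.t() * gpart;
      gb += arma::sum(gpart, 0).t();
      if (need_gx) {
        gcol = gpart * Wm.t();
        for (int j = 0; j < g; ++j)
          col2im_same(gcol.memptr(), gcol.n_rows, (size_t)j * H * W,
                      H, W, C, k, gx.begin() + (size_t)(n0 + j) * H * W * C);
      }
    }
  }

  NumericVector gwr(gw.begin(), gw.end());
  gwr.attr("dim") = IntegerVector::create(k, k, C, F);
  List res = List::create(_["gw"] = gwr, _["gb"] = NumericVector(gb.begin(), gb.end()));
  if (need_gx) res["gx"] = gx;
  return res;
}

// 2x2 max pooling with stride 2 (floor on odd sizes); records argmax
// positions for the backward pass.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd_cpp(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("input too small to pool");
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h = 2 * ho, w = 2 * wo;
          size_t best = base + (size_t)w * H + h;
          double bv = xp[best];
          const size_t cand[3] = { base + (size_t)w * H + h + 1,
                                   base + (size_t)(w + 1) * H + h,
                                   base + (size_t)(w + 1) * H + h + 1 };
          for (int q = 0; q < 3; ++q)
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
          *yp++ = bv;
          *ip++ = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd_cpp(NumericVector gy, IntegerVector idx, IntegerVector in_dim) {
  size_t len = 1;
  for (int i = 0; i < in_dim.size(); ++i) len *= (size_t)in_dim[i];
  NumericVector gx(len);
  gx.attr("dim") = in_dim;
  const double* g = gy.begin();
  const int* ip = idx.begin();
  double* o = gx.begin();
  const size_t m = gy.size();
  for (size_t i = 0; i < m; ++i) o[ip[i]] += g[i];
  return gx;
}

// Nearest-neighbour 2x upsampling and its adjoint (block sum).
// [[Rcpp::export(name = ".upsample_fwd")]]
NumericVector upsample_fwd_cpp(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = xp + s * H * W;
    double* ys = yp + s * Ho * Wo;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double v = xs[(size_t)w * H + h];
        double* d = ys + (size_t)(2 * w) * Ho + 2 * h;
        d[0] = v; d[1] = v; d[Ho] = v; d[Ho + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample_bwd")]]
NumericVector upsample_bwd_cpp(NumericVector gy) {
  int Ho, Wo, C, N;
  dims4(gy, Ho, Wo, C, N);
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* g = gy.begin();
  double* o = gx.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* gs = g + s * Ho * Wo;
    double* os = o + s * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* p = gs + (size_t)(2 * w) * Ho + 2 * h;
        os[(size_t)w * H + h] = p[0] + p[1] + p[Ho] + p[Ho + 1];
      }
    }
  }
  return gx;
}

static inline double bilinear_at(const double* ch, int H, int W,
                                 double sy, double sx, double fill) {
  if (sy < -0.5 || sy > H - 0.5 || sx < -0.5 || sx > W - 0.5) return fill;
  const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
  const double fy = sy - y0, fx = sx - x0;
  double v = 0.0;
  for (int dy = 0; dy <= 1; ++dy) {
    for (int dx = 0; dx <= 1; ++dx) {
      const int yy = y0 + dy, xx = x0 + dx;
      const double wgt = (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
      if (wgt == 0.0) continue;
      double pv = fill;
      if (yy >= 0 && yy < H && xx >= 0 && xx < W) pv = ch[(size_t)xx * H + yy];
      v += wgt * pv;
    }
  }
  return v;
}

// Rotate about the image centre by `angle` degrees (counter-clockwise in
// standard x/y convention), bilinear sampling, out-of-frame -> fill[c].
// [[Rcpp::export(name = ".rotate_bilinear")]]
NumericVector rotate_bilinear_cpp(NumericVector x, double angle, NumericVector fill) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  if (N != 1) stop("rotate expects a single image");
  if (fill.size() != C) stop("fill must have one value per channel");
  const double th = angle * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  NumericVector y((size_t)H * W * C);
  y.attr("dim") = IntegerVector::create(H, W, C);
  for (int c = 0; c < C; ++c) {
    const double* ch = x.begin() + (size_t)c * H * W;
    double* oc = y.begin() + (size_t)c * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        // inverse rotation of the destination coordinate
        const double dy = h - cy, dx = w - cx;
        const double sy = ct * dy + st * dx + cy;
        const double sx = -st * dy + ct * dx + cx;
        oc[(size_t)w * H + h] = bilinear_at(ch, H, W, sy, sx, fill[c]);
      }
    }
  }
  return y;
}

// Bilinear resize with half-pixel centre alignment.
// [[Rcpp::export(name = ".resize_bilinear")]]
NumericVector resize_bilinear_cpp(NumericVector x, int out_h, int out_w) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  if (N != 1) stop("resize expects a single image");
  NumericVector y((size_t)out_h * out_w * C);
  y.attr("dim") = IntegerVector::create(out_h, out_w, C);
  const double ry = (double)H / out_h, rx = (double)W / out_w;
  for (int c = 0; c < C; ++c) {
    const double* ch = x.begin() + (size_t)c * H * W;
    double* oc = y.begin() + (size_t)c * out_h * out_w;
    for (int w = 0; w < out_w; ++w) {
      const double sx = std::min(std::max((w + 0.5) * rx - 0.5, 0.0), W - 1.0);
      for (int h = 0; h < out_h; ++h) {
        const double sy = std::min(std::max((h + 0.5) * ry - 0.5, 0.0), H - 1.0);
        oc[(size_t)w * out_h + h] = bilinear_at(ch, H, W, sy, sx, 0.0);
      }
    }
  }
  return y;
}
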