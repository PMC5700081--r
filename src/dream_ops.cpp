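#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Low-level kernels shared by the toy network, the dream loop and the
// optical-flow stage. Arrays follow R's column-major layout: an H x W x C
// array indexes as y + H*x + H*W*c (0-based).

static inline int wrap_idx(int i, int n) {
  i %= n;
  if (i < 0) i += n;
  return i;
}

static inline int clamp_idx(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// 2-D cross-correlation ("conv layer" convention), stride 1, same padding.
// pad_mode: 0 = zero padding, 1 = circular (periodic) padding.
// weights: kh x kw x Cin x Cout.
// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector input, IntegerVector in_dim,
                                 NumericVector w, IntegerVector w_dim,
                                 NumericVector bias, int pad_mode) {
  const int H = in_dim[0], W = in_dim[1], Cin = in_dim[2];
  const int kh = w_dim[0], kw = w_dim[1], Cout = w_dim[3];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector out(static_cast<R_xlen_t>(H) * W * Cout);
  for (int oc = 0; oc < Cout; ++oc) {
    const double b = bias[oc];
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        double acc = b;
        for (int ic = 0; ic < Cin; ++ic) {
          for (int kx = 0; kx < kw; ++kx) {
            int xx = x + kx - pw;
            if (pad_mode == 1) xx = wrap_idx(xx, W);
            else if (xx < 0 || xx >= W) continue;
            const double *icol = &input[H * xx + H * W * ic];
            const double *wcol = &w[kh * kx + kh * kw * ic + kh * kw * Cin * oc];
            for (int ky = 0; ky < kh; ++ky) {
              int yy = y + ky - ph;
              if (pad_mode == 1) yy = wrap_idx(yy, H);
              else if (yy < 0 || yy >= H) continue;
              acc += icol[yy] * wcol[ky];
            }
          }
        }
        out[y + H * x + static_cast<R_xlen_t>(H) * W * oc] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// Gradient of conv2d_forward_cpp with respect to its input (weights fixed).
// grad_out: H x W x Cout  ->  returns H x W x Cin.
// [[Rcpp::export]]
NumericVector conv2d_backward_cpp(NumericVector grad_out, IntegerVector out_dim,
                                  NumericVector w, IntegerVector w_dim,
                                  int pad_mode) {
  const int H = out_dim[0], W = out_dim[1], Cout = out_dim[2];
  const int kh = w_dim[0], kw = w_dim[1], Cin = w_dim[2];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector gin(static_cast<R_xlen_t>(H) * W * Cin);
  for (int ic = 0; ic < Cin; ++ic) {
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        double acc = 0.0;
        for (int oc = 0; oc < Cout; ++oc) {
          for (int kx = 0; kx < kw; ++kx) {
            int xo = x - kx + pw;
            if (pad_mode == 1) xo = wrap_idx(xo, W);
            else if (xo < 0 || xo >= W) continue;
            const double *gcol = &grad_out[H * xo + static_cast<R_xlen_t>(H) * W * oc];
            const double *wcol = &w[kh * kx + kh * kw * ic + kh * kw * Cin * oc];
            for (int ky = 0; ky < kh; ++ky) {
              int yo = y - ky + ph;
              if (pad_mode == 1) yo = wrap_idx(yo, H);
              else if (yo < 0 || yo >= H) continue;
              acc += gcol[yo] * wcol[ky];
            }
          }
        }
        gin[y + H * x + static_cast<R_xlen_t>(H) * W * ic] = acc;
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(H, W, Cin);
  return gin;
}

// Bilinear resize with half-pixel-centre sampling and edge clamping.
// Identity when output dims equal input dims.
// [[Rcpp::export]]
NumericVector bilinear_resize_cpp(NumericVector img, IntegerVector in_dim,
                                  int out_h, int out_w) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2];
  const double sy = static_cast<double>(H) / out_h;
  const double sx = static_cast<double>(W) / out_w;
  NumericVector out(static_cast<R_xlen_t>(out_h) * out_w * C);
  for (int x = 0; x < out_w; ++x) {
    double fx = (x + 0.5) * sx - 0.5;
    if (fx < 0) fx = 0;
    if (fx > W - 1) fx = W - 1;
    const int x0 = static_cast<int>(std::floor(fx));
    const int x1 = clamp_idx(x0 + 1, W);
    const double wx = fx - x0;
    for (int y = 0; y < out_h; ++y) {
      double fy = (y + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0;
      if (fy > H - 1) fy = H - 1;
      const int y0 = static_cast<int>(std::floor(fy));
      const int y1 = clamp_idx(y0 + 1, H);
      const double wy = fy - y0;
      for (int c = 0; c < C; ++c) {
        const double *p = &img[static_cast<R_xlen_t>(H) * W * c];
        const double v =
          (1 - wy) * ((1 - wx) * p[y0 + H * x0] + wx * p[y0 + H * x1]) +
          wy * ((1 - wx) * p[y1 + H * x0] + wx * p[y1 + H * x1]);
        out[y + out_h * x + static_cast<R_xlen_t>(out_h) * out_w * c] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  return out;
}

// Backward warp: out(y, x) = img(y - v(y,x), x - u(y,x)), bilinear sampling.
// Out-of-bounds samples clamp to the nearest edge; with wrap_x the x axis
// wraps (equirectangular seams).
// [[Rcpp::export]]
NumericVector bilinear_warp_cpp(NumericVector img, IntegerVector in_dim,
                                NumericVector flow_u, NumericVector flow_v,
                                int wrap_x) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2];
  NumericVector out(static_cast<R_xlen_t>(H) * W * C);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double fx = x - flow_u[y + H * x];
      double fy = y - flow_v[y + H * x];
      if (fy < 0) fy = 0;
      if (fy > H - 1) fy = H - 1;
      int x0, x1;
      double wx;
      if (wrap_x) {
        fx -= W * std::floor(fx / W);
        if (fx < 0 || fx >= W) fx = 0;  // guard rounding at the seam
        x0 = static_cast<int>(std::floor(fx));
        wx = fx - x0;
        x0 = wrap_idx(x0, W);
        x1 = wrap_idx(x0 + 1, W);
      } else {
        if (fx < 0) fx = 0;
        if (fx > W - 1) fx = W - 1;
        x0 = static_cast<int>(std::floor(fx));
        x1 = clamp_idx(x0 + 1, W);
        wx = fx - x0;
      }
      const int y0 = static_cast<int>(std::floor(fy));
      const int y1 = clamp_idx(y0 + 1, H);
      const double wy = fy - y0;
      for (int c = 0; c < C; ++c) {
        const double *p = &img[static_cast<R_xlen_t>(H) * W * c];
        out[y + H * x + static_cast<R_xlen_t>(H) * W * c] =
          (1 - wy) * ((1 - wx) * p[y0 + H * x0] + wx * p[y0 + H * x1]) +
          wy * ((1 - wx) * p[y1 + H * x0] + wx * p[y1 + H * x1]);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// Separable Gaussian blur of a single-channel image, edge-clamped.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, static_cast<int>(std::ceil(3.0 * sigma)));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * img(clamp_idx(y + i, H), x);
      tmp(y, x) = acc;
    }
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(y, clamp_idx(x + i, W));
      out(y, x) = acc;
    }
  return out;
}
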