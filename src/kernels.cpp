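// Dense rank-4 tensor kernels. Layout convention throughout: R arrays with
// dim (B, C, H, W), column-major, so the linear index of (b, c, h, w)
// (0-based) is b + B*(c + C*(h + H*w)).
//
// Convolutions use im2col + BLAS GEMM. The im2col column order is
// j = c*k*k + (kh + k*kw): channel-major so that channel groups occupy
// contiguous column blocks; within a channel the (kh, kw) order matches the
// column-major layout of an (C_out, C_g, k, k) weight array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a rank-4 array");
  return d;
}

static inline int out_size(int H, int k, int stride, int pad, int dil) {
  return (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Fill the im2col matrix: rows n = b + B*(ho + Ho*wo), cols j as above.
// pad_mode 0 = zero padding, 1 = replicate (clamped) padding.
static void im2col_fill(const double* x, arma::mat& cols,
                        int B, int C, int H, int W,
                        int k, int stride, int pad, int dil,
                        int Ho, int Wo, int pad_mode) {
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int j = c * k * k + kh + k * kw;
        double* col = cols.colptr(j);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw * dil;
          if (pad_mode == 1) wi = std::min(std::max(wi, 0), W - 1);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh * dil;
            if (pad_mode == 1) hi = std::min(std::max(hi, 0), H - 1);
            const int n0 = B * (ho + Ho * wo);
            if (hi < 0 || hi >= H || wi < 0 || wi >= W) {
              for (int b = 0; b < B; ++b) col[n0 + b] = 0.0;
            } else {
              const double* src = x + B * (c + C * (hi + H * wi));
              for (int b = 0; b < B; ++b) col[n0 + b] = src[b];
            }
          }
        }
      }
    }
  }
}

// Scatter-add of an im2col-shaped gradient back onto the input.
static void col2im_acc(const arma::mat& cols, double* gx,
                       int B, int C, int H, int W,
                       int k, int stride, int pad, int dil,
                       int Ho, int Wo, int pad_mode) {
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int j = c * k * k + kh + k * kw;
        const double* col = cols.colptr(j);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw * dil;
          if (pad_mode == 1) wi = std::min(std::max(wi, 0), W - 1);
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh * dil;
            if (pad_mode == 1) hi = std::min(std::max(hi, 0), H - 1);
            if (hi < 0 || hi >= H) continue;
            double* dst = gx + B * (c + C * (hi + H * wi));
            const int n0 = B * (ho + Ho * wo);
            for (int b = 0; b < B; ++b) dst[b] += col[n0 + b];
          }
        }
      }
    }
  }
}

// Weight array w has dim (C_out, C_g, k, k); build the (C_g*k*k, C_outg)
// matrix for group g matching the im2col column order.
static arma::mat weight_mat(const NumericVector& w, int Cout, int Cg, int k,
                            int g, int Coutg) {
  arma::mat W(Cg * k * k, Coutg);
  const double* wp = w.begin();
  for (int co = 0; co < Coutg; ++co) {
    const int cog = g * Coutg + co;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int cg = 0; cg < Cg; ++cg)
          W(cg * k * k + kh + k * kw, co) =
            wp[cog + Cout * (cg + Cg * (kh + k * kw))];
  }
  return W;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int dilation, int groups,
                             int pad_mode) {
  IntegerVector xd = dims4(x);
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weight must be rank-4 (C_out, C_g, k, k)");
  const int Cout = wd[0], Cg = wd[1], k = wd[2];
  if (wd[3] != k) stop("non-square kernels unsupported");
  if (C / groups != Cg) stop("weight/group mismatch");
  const int Ho = out_size(H, k, stride, pad, dilation);
  const int Wo = out_size(W, k, stride, pad, dilation);
  if (Ho < 1 || Wo < 1) stop("non-positive output size");
  const int N = B * Ho * Wo, Coutg = Cout / groups;

  arma::mat cols(N, C * k * k);
  im2col_fill(x.begin(), cols, B, C, H, W, k, stride, pad, dilation, Ho, Wo,
              pad_mode);

  NumericVector y(N * Cout);
  y.attr("dim") = IntegerVector::create(B, Cout, Ho, Wo);
  double* yp = y.begin();

  for (int g = 0; g < groups; ++g) {
    arma::mat Wg = weight_mat(w, Cout, Cg, k, g, Coutg);
    arma::mat Yg = cols.cols(g * Cg * k * k, (g + 1) * Cg * k * k - 1) * Wg;
    for (int co = 0; co < Coutg; ++co) {
      const int cog = g * Coutg + co;
      const double* src = Yg.colptr(co);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double* dst = yp + B * (cog + Cout * (ho + Ho * wo));
          const double* s = src + B * (ho + Ho * wo);
          for (int b = 0; b < B; ++b) dst[b] = s[b];
        }
    }
  }
  if (bias.isNotNull()) {
    NumericVector bv(bias);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int co = 0; co < Cout; ++co) {
          double* dst = yp + B * (co + Cout * (ho + Ho * wo));
          for (int b = 0; b < B; ++b) dst[b] += bv[co];
        }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int dilation, int groups,
                    bool need_gx, bool has_bias, int pad_mode) {
  IntegerVector xd = dims4(x);
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[0], Cg = wd[1], k = wd[2];
  IntegerVector gd = dims4(gy);
  const int Ho = gd[2], Wo = gd[3];
  if (gd[0] != B || gd[1] != Cout) stop("grad shape mismatch");
  const int N = B * Ho * Wo, Coutg = Cout / groups;

  arma::mat cols(N, C * k * k);
  im2col_fill(x.begin(), cols, B, C, H, W, k, stride, pad, dilation, Ho, Wo,
              pad_mode);

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector(x.size());
    gx.attr("dim") = xd;
  }
  NumericVector gb;
  if (has_bias) gb = NumericVector(Cout);

  const double* gyp = gy.begin();
  arma::mat gcols;
  if (need_gx) gcols.set_size(N, C * k * k);

  for (int g = 0; g < groups; ++g) {
    // gather grad for this group's output channels: (N, Coutg)
    arma::mat G(N, Coutg);
    for (int co = 0; co < Coutg; ++co) {
      const int cog = g * Coutg + co;
      double* dst = G.colptr(co);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double* src = gyp + B * (cog + Cout * (ho + Ho * wo));
          double* d = dst + B * (ho + Ho * wo);
          for (int b = 0; b < B; ++b) d[b] = src[b];
        }
    }
    arma::mat colsg = cols.cols(g * Cg * k * k, (g + 1) * Cg * k * k - 1);
    arma::mat GW = colsg.t() * G;  // (Cg*k*k, Coutg)
    double* gwp = gw.begin();
    for (int co = 0; co < Coutg; ++co) {
      const int cog = g * Coutg + co;
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          for (int cg = 0; cg < Cg; ++cg)
            gwp[cog + Cout * (cg + Cg * (kh + k * kw))] =
              GW(cg * k * k + kh + k * kw, co);
    }
    if (need_gx) {
      arma::mat Wg = weight_mat(w, Cout, Cg, k, g, Coutg);
      gcols.cols(g * Cg * k * k, (g + 1) * Cg * k * k - 1) = G * Wg.t();
    }
    if (has_bias) {
      for (int co = 0; co < Coutg; ++co)
        gb[g * Coutg + co] = arma::accu(G.col(co));
    }
  }
  if (need_gx)
    col2im_acc(gcols, gx.begin(), B, C, H, W, k, stride, pad, dilation,
               Ho, Wo, pad_mode);

  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gw,
                      _["gb"] = has_bias ? (SEXP)gb : R_NilValue);
}

// Average pooling. count_include_pad = false divides each window by its
// number of valid taps, so a constant map pools to the same constant at the
// borders (constant-preserving padding).
// [[Rcpp::export]]
NumericVector avgpool2d_fwd_cpp(NumericVector x, int k, int stride, int pad,
                                bool include_pad) {
  IntegerVector xd = dims4(x);
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Ho = out_size(H, k, stride, pad, 1);
  const int Wo = out_size(W, k, stride, pad, 1);
  NumericVector y((double)B * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(B, C, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      int h1 = std::max(h0, 0), w1 = std::max(w0, 0);
      int h2 = std::min(h0 + k, H), w2 = std::min(w0 + k, W);
      double cnt = include_pad ? (double)(k * k)
                               : (double)((h2 - h1) * (w2 - w1));
      for (int c = 0; c < C; ++c) {
        double* dst = yp + B * (c + C * (ho + Ho * wo));
        for (int b = 0; b < B; ++b) {
          double s = 0.0;
          for (int wi = w1; wi < w2; ++wi)
            for (int hi = h1; hi < h2; ++hi)
              s += xp[b + B * (c + C * (hi + H * wi))];
          dst[b] = s / cnt;
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2d_bwd_cpp(NumericVector gy, int H, int W, int k,
                                int stride, int pad, bool include_pad) {
  IntegerVector gd = dims4(gy);
  const int B = gd[0], C = gd[1], Ho = gd[2], Wo = gd[3];
  NumericVector gx((double)B * C * H * W);
  gx.attr("dim") = IntegerVector::create(B, C, H, W);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      int h1 = std::max(h0, 0), w1 = std::max(w0, 0);
      int h2 = std::min(h0 + k, H), w2 = std::min(w0 + k, W);
      double cnt = include_pad ? (double)(k * k)
                               : (double)((h2 - h1) * (w2 - w1));
      for (int c = 0; c < C; ++c) {
        const double* src = gp + B * (c + C * (ho + Ho * wo));
        for (int b = 0; b < B; ++b) {
          double g = src[b] / cnt;
          for (int wi = w1; wi < w2; ++wi)
            for (int hi = h1; hi < h2; ++hi)
              xp[b + B * (c + C * (hi + H * wi))] += g;
        }
      }
    }
  return gx;
}

// [[Rcpp::export]]
List maxpool2d_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = dims4(x);
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Ho = out_size(H, k, stride, pad, 1);
  const int Wo = out_size(W, k, stride, pad, 1);
  NumericVector y((double)B * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(B, C, Ho, Wo);
  IntegerVector arg(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      int h1 = std::max(h0, 0), w1 = std::max(w0, 0);
      int h2 = std::min(h0 + k, H), w2 = std::min(w0 + k, W);
      for (int c = 0; c < C; ++c) {
        const R_xlen_t oidx = B * (c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * wo));
        for (int b = 0; b < B; ++b) {
          double best = R_NegInf;
          int besti = -1;
          for (int wi = w1; wi < w2; ++wi)
            for (int hi = h1; hi < h2; ++hi) {
              int idx = b + B * (c + C * (hi + H * wi));
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          yp[oidx + b] = best;
          ap[oidx + b] = besti;
        }
      }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bwd_cpp(NumericVector gy, IntegerVector argmax,
                                IntegerVector xdim) {
  NumericVector gx((double)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double* xp = gx.begin();
  const double* gp = gy.begin();
  const int* ap = argmax.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) xp[ap[i]] += gp[i];
  return gx;
}

// Adaptive average pooling with floor/ceil bin edges.
// [[Rcpp::export]]
NumericVector adaptive_avgpool_fwd_cpp(NumericVector x, int oh, int ow) {
  IntegerVector xd = dims4(x);
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y((double)B * C * oh * ow);
  y.attr("dim") = IntegerVector::create(B, C, oh, ow);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int wo = 0; wo < ow; ++wo) {
    int w1 = (int)std::floor((double)wo * W / ow);
    int w2 = (int)std::ceil((double)(wo + 1) * W / ow);
    for (int ho = 0; ho < oh; ++ho) {
      int h1 = (int)std::floor((double)ho * H / oh);
      int h2 = (int)std::ceil((double)(ho + 1) * H / oh);
      double cnt = (double)((h2 - h1) * (w2 - w1));
      for (int c = 0; c < C; ++c) {
        double* dst = yp + B * (c + C * (ho + oh * wo));
        for (int b = 0; b < B; ++b) {
          double s = 0.0;
          for (int wi = w1; wi < w2; ++wi)
            for (int hi = h1; hi < h2; ++hi)
              s += xp[b + B * (c + C * (hi + H * wi))];
          dst[b] = s / cnt;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector adaptive_avgpool_bwd_cpp(NumericVector gy, int H, int W) {
  IntegerVector gd = dims4(gy);
  const int B = gd[0], C = gd[1], oh = gd[2], ow = gd[3];
  NumericVector gx((double)B * C * H * W);
  gx.attr("dim") = IntegerVector::create(B, C, H, W);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int wo = 0; wo < ow; ++wo) {
    int w1 = (int)std::floor((double)wo * W / ow);
    int w2 = (int)std::ceil((double)(wo + 1) * W / ow);
    for (int ho = 0; ho < oh; ++ho) {
      int h1 = (int)std::floor((double)ho * H / oh);
      int h2 = (int)std::ceil((double)(ho + 1) * H / oh);
      double cnt = (double)((h2 - h1) * (w2 - w1));
      for (int c = 0; c < C; ++c) {
        const double* src = gp + B * (c + C * (ho + oh * wo));
        for (int b = 0; b < B; ++b) {
          double g = src[b] / cnt;
          for (int wi = w1; wi < w2; ++wi)
            for (int hi = h1; hi < h2; ++hi)
              xp[b + B * (c + C * (hi + H * wi))] += g;
        }
      }
    }
  }
  return gx;
}

// Bilinear resize without corner alignment (half-pixel centers).
static inline void bilin_coef(int o, int O, int I, int& i0, int& i1,
                              double& w0, double& w1) {
  double src = ((double)o + 0.5) * I / O - 0.5;
  if (src < 0) src = 0;
  if (src > I - 1) src = I - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, I - 1);
  w1 = src - i0;
  w0 = 1.0 - w1;
}

// [[Rcpp::export]]
NumericVector bilinear_fwd_cpp(NumericVector x, int oh, int ow) {
  IntegerVector xd = dims4(x);
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y((double)B * C * oh * ow);
  y.attr("dim") = IntegerVector::create(B, C, oh, ow);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int wo = 0; wo < ow; ++wo) {
    int wA, wB2; double ww0, ww1;
    bilin_coef(wo, ow, W, wA, wB2, ww0, ww1);
    for (int ho = 0; ho < oh; ++ho) {
      int hA, hB2; double hw0, hw1;
      bilin_coef(ho, oh, H, hA, hB2, hw0, hw1);
      for (int c = 0; c < C; ++c) {
        double* dst = yp + B * (c + C * (ho + oh * wo));
        const double* p00 = xp + B * (c + C * (hA + H * wA));
        const double* p10 = xp + B * (c + C * (hB2 + H * wA));
        const double* p01 = xp + B * (c + C * (hA + H * wB2));
        const double* p11 = xp + B * (c + C * (hB2 + H * wB2));
        for (int b = 0; b < B; ++b)
          dst[b] = hw0 * ww0 * p00[b] + hw1 * ww0 * p10[b] +
                   hw0 * ww1 * p01[b] + hw1 * ww1 * p11[b];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_bwd_cpp(NumericVector gy, int H, int W) {
  IntegerVector gd = dims4(gy);
  const int B = gd[0], C = gd[1], oh = gd[2], ow = gd[3];
  NumericVector gx((double)B * C * H * W);
  gx.attr("dim") = IntegerVector::create(B, C, H, W);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int wo = 0; wo < ow; ++wo) {
    int wA, wB2; double ww0, ww1;
    bilin_coef(wo, ow, W, wA, wB2, ww0, ww1);
    for (int ho = 0; ho < oh; ++ho) {
      int hA, hB2; double hw0, hw1;
      bilin_coef(ho, oh, H, hA, hB2, hw0, hw1);
      for (int c = 0; c < C; ++c) {
        const double* src = gp + B * (c + C * (ho + oh * wo));
        double* p00 = xp + B * (c + C * (hA + H * wA));
        double* p10 = xp + B * (c + C * (hB2 + H * wA));
        double* p01 = xp + B * (c + C * (hA + H * wB2));
        double* p11 = xp + B * (c + C * (hB2 + H * wB2));
        for (int b = 0; b < B; ++b) {
          double g = src[b];
          p00[b] += hw0 * ww0 * g;
          p10[b] += hw1 * ww0 * g;
          p01[b] += hw0 * ww1 * g;
          p11[b] += hw1 * ww1 * g;
        }
      }
    }
  }
  return gx;
}

// Exact 3x3 high-pass response: for each position the mean over valid taps
// of (center - tap). Algebraically equal to x - AvgPool3x3(x) with
// valid-tap border averaging, but a constant map yields exact zeros.
// [[Rcpp::export]]
NumericVector highpass3_cpp(NumericVector x) {
  IntegerVector xd = dims4(x);
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int wo = 0; wo < W; ++wo)
    for (int ho = 0; ho < H; ++ho) {
      int h1 = std::max(ho - 1, 0), w1 = std::max(wo - 1, 0);
      int h2 = std::min(ho + 2, H), w2 = std::min(wo + 2, W);
      double cnt = (double)((h2 - h1) * (w2 - w1));
      for (int c = 0; c < C; ++c) {
        const R_xlen_t base = B * (c + (R_xlen_t)C * (ho + (R_xlen_t)H * wo));
        for (int b = 0; b < B; ++b) {
          double ctr = xp[b + B * (c + C * (ho + H * wo))];
          double s = 0.0;
          for (int wi = w1; wi < w2; ++wi)
            for (int hi = h1; hi < h2; ++hi)
              s += ctr - xp[b + B * (c + C * (hi + H * wi))];
          yp[base + b] = s / cnt;
        }
      }
    }
  return y;
}
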