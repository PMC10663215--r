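// Dense tensor kernels for the segmentation network.
//
// Tensors are R numeric arrays with dim = c(H, W, C, N) in R's column-major
// order, i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)) (0-based),
// so each channel image is a contiguous H*W block — the layout the
// convolution loops stream over. Convolution weights have
// dim = c(Cout, Cin_per_group, kh, kw). Convolutions are im2col + GEMM
// (Armadillo); backward passes recompute the column matrix rather than
// caching it, trading FLOPs for memory.

#include <RcppArmadillo.h>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_size(int in, int k, int s, int p, int d) {
  return (in + 2 * p - d * (k - 1) - 1) / s + 1;
}

// col: (Cg*kh*kw) x (Ho*Wo); row = ci*kh*kw + j*kh + i; opix = oh + Ho*ow
static void im2col(const double* x, int H, int W, int C, int n,
                   int c0, int Cg, int kh, int kw,
                   int sh, int sw, int ph, int pw, int dh, int dw,
                   int Ho, int Wo, arma::mat& col) {
  for (int ci = 0; ci < Cg; ++ci) {
    const double* xc = x + (std::size_t)H * W * (c0 + ci + (std::size_t)C * n);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = ci * kh * kw + j * kh + i;
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * sw - pw + j * dw;
          double* dst = col.memptr() +
            (std::size_t)col.n_rows * (Ho * (std::size_t)ow) + row;
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < Ho; ++oh, dst += col.n_rows) *dst = 0.0;
            continue;
          }
          const double* xcw = xc + (std::size_t)H * iw;
          for (int oh = 0; oh < Ho; ++oh, dst += col.n_rows) {
            int ih = oh * sh - ph + i * dh;
            *dst = (ih < 0 || ih >= H) ? 0.0 : xcw[ih];
          }
        }
      }
    }
  }
}

static void col2im_add(double* dx, int H, int W, int C, int n,
                       int c0, int Cg, int kh, int kw,
                       int sh, int sw, int ph, int pw, int dh, int dw,
                       int Ho, int Wo, const arma::mat& col) {
  for (int ci = 0; ci < Cg; ++ci) {
    double* xc = dx + (std::size_t)H * W * (c0 + ci + (std::size_t)C * n);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = ci * kh * kw + j * kh + i;
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * sw - pw + j * dw;
          if (iw < 0 || iw >= W) continue;
          double* xcw = xc + (std::size_t)H * iw;
          const double* src = col.memptr() +
            (std::size_t)col.n_rows * (Ho * (std::size_t)ow) + row;
          for (int oh = 0; oh < Ho; ++oh, src += col.n_rows) {
            int ih = oh * sh - ph + i * dh;
            if (ih >= 0 && ih < H) xcw[ih] += *src;
          }
        }
      }
    }
  }
}

static arma::mat weight_matrix(const NumericVector& w, int Cout, int Cg,
                               int kh, int kw, int g, int Cout_g) {
  // rows: local output channel; cols: ci*kh*kw + j*kh + i
  arma::mat Wm(Cout_g, Cg * kh * kw);
  for (int col = 0; col < Cout_g; ++col) {
    int co = g * Cout_g + col;
    for (int ci = 0; ci < Cg; ++ci)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          Wm(col, ci * kh * kw + j * kh + i) =
            w[co + (std::size_t)Cout * (ci + (std::size_t)Cg * (i + (std::size_t)kh * j))];
  }
  return Wm;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias,
                                 int sh, int sw, int ph, int pw,
                                 int dh, int dw, int groups) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Cout = wdim[0], Cg = wdim[1], kh = wdim[2], kw = wdim[3];
  if (C != Cg * groups) stop("conv2d: channel/group mismatch");
  int Ho = conv_out_size(H, kh, sh, ph, dh);
  int Wo = conv_out_size(W, kw, sw, pw, dw);
  if (Ho < 1 || Wo < 1) stop("conv2d: non-positive output size");
  int Cout_g = Cout / groups;
  NumericVector y((std::size_t)N * Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(Cg * kh * kw, (std::size_t)Ho * Wo);
  bool has_bias = bias.size() == Cout;
  std::vector<arma::mat> Wms;
  for (int g = 0; g < groups; ++g)
    Wms.push_back(weight_matrix(w, Cout, Cg, kh, kw, g, Cout_g));
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, C, n, g * Cg, Cg, kh, kw,
             sh, sw, ph, pw, dh, dw, Ho, Wo, col);
      arma::mat out = Wms[g] * col; // Cout_g x (Ho*Wo)
      for (int cl = 0; cl < Cout_g; ++cl) {
        int co = g * Cout_g + cl;
        double b = has_bias ? bias[co] : 0.0;
        double* dst = y.begin() + (std::size_t)Ho * Wo * (co + (std::size_t)Cout * n);
        const double* src = out.memptr() + cl;
        for (std::size_t p = 0; p < (std::size_t)Ho * Wo; ++p, src += Cout_g)
          dst[p] = *src + b;
      }
    }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector dout,
                         int sh, int sw, int ph, int pw,
                         int dh, int dw, int groups, bool has_bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Cout = wdim[0], Cg = wdim[1], kh = wdim[2], kw = wdim[3];
  int Ho = conv_out_size(H, kh, sh, ph, dh);
  int Wo = conv_out_size(W, kw, sw, pw, dw);
  int Cout_g = Cout / groups;
  NumericVector grad_x((std::size_t)N * C * H * W);
  grad_x.attr("dim") = xdim;
  NumericVector grad_w((std::size_t)Cout * Cg * kh * kw);
  grad_w.attr("dim") = wdim;
  NumericVector grad_b(has_bias ? Cout : 0);
  arma::mat col(Cg * kh * kw, (std::size_t)Ho * Wo);
  arma::mat doutm(Cout_g, (std::size_t)Ho * Wo);
  std::vector<arma::mat> Wms, dWms;
  for (int g = 0; g < groups; ++g) {
    Wms.push_back(weight_matrix(w, Cout, Cg, kh, kw, g, Cout_g));
    dWms.push_back(arma::mat(Cout_g, Cg * kh * kw, arma::fill::zeros));
  }
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      for (int cl = 0; cl < Cout_g; ++cl) {
        int co = g * Cout_g + cl;
        const double* src = dout.begin() +
          (std::size_t)Ho * Wo * (co + (std::size_t)Cout * n);
        double* dst = doutm.memptr() + cl;
        double acc = 0.0;
        for (std::size_t p = 0; p < (std::size_t)Ho * Wo; ++p, dst += Cout_g) {
          *dst = src[p];
          acc += src[p];
        }
        if (has_bias) grad_b[co] += acc;
      }
      im2col(x.begin(), H, W, C, n, g * Cg, Cg, kh, kw,
             sh, sw, ph, pw, dh, dw, Ho, Wo, col);
      dWms[g] += doutm * col.t();
      arma::mat dcol = Wms[g].t() * doutm;
      col2im_add(grad_x.begin(), H, W, C, n, g * Cg, Cg, kh, kw,
                 sh, sw, ph, pw, dh, dw, Ho, Wo, dcol);
    }
  }
  for (int g = 0; g < groups; ++g) {
    for (int cl = 0; cl < Cout_g; ++cl) {
      int co = g * Cout_g + cl;
      for (int ci = 0; ci < Cg; ++ci)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i)
            grad_w[co + (std::size_t)Cout * (ci + (std::size_t)Cg * (i + (std::size_t)kh * j))] =
              dWms[g](cl, ci * kh * kw + j * kh + i);
    }
  }
  return List::create(_["dx"] = grad_x, _["dw"] = grad_w, _["db"] = grad_b);
}

// [[Rcpp::export(rng = false)]]
List cpp_bn_forward(NumericVector x, IntegerVector xdim,
                    NumericVector gamma, NumericVector beta,
                    double eps, bool training,
                    NumericVector rmean, NumericVector rvar, int act) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  std::size_t hw = (std::size_t)H * W;
  std::size_t m = hw * N;
  NumericVector y(x.size());
  y.attr("dim") = xdim;
  NumericVector mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + hw * (c + (std::size_t)C * n);
        for (std::size_t k = 0; k < hw; ++k) { s += p[k]; s2 += p[k] * p[k]; }
      }
      mu[c] = s / m;
      var[c] = s2 / m - mu[c] * mu[c];
      if (var[c] < 0) var[c] = 0;
    }
  } else {
    mu = clone(rmean);
    var = clone(rvar);
  }
  double hi = act == 2 ? 6.0 : std::numeric_limits<double>::infinity();
  for (int c = 0; c < C; ++c) {
    double inv = gamma[c] / std::sqrt(var[c] + eps);
    double b = beta[c] - mu[c] * inv;
    for (int n = 0; n < N; ++n) {
      std::size_t off = hw * (c + (std::size_t)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      if (act == 0) {
        for (std::size_t k = 0; k < hw; ++k) q[k] = p[k] * inv + b;
      } else {
        for (std::size_t k = 0; k < hw; ++k) {
          double v = p[k] * inv + b;
          q[k] = v < 0.0 ? 0.0 : (v > hi ? hi : v);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export(rng = false)]]
List cpp_bn_backward(NumericVector x, IntegerVector xdim,
                     NumericVector gamma, NumericVector mu, NumericVector var,
                     NumericVector dout, double eps, int act,
                     NumericVector y) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  std::size_t hw = (std::size_t)H * W;
  std::size_t m = hw * N;
  NumericVector dx(x.size());
  dx.attr("dim") = xdim;
  NumericVector dgamma(C), dbeta(C);
  double hi = act == 2 ? 6.0 : std::numeric_limits<double>::infinity();
  for (int c = 0; c < C; ++c) {
    double istd = 1.0 / std::sqrt(var[c] + eps);
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      std::size_t off = hw * (c + (std::size_t)C * n);
      const double* xp = x.begin() + off;
      const double* gp = dout.begin() + off;
      const double* yp = act ? y.begin() + off : nullptr;
      for (std::size_t k = 0; k < hw; ++k) {
        double g = gp[k];
        if (act && (yp[k] <= 0.0 || yp[k] >= hi)) g = 0.0;
        sg += g * (xp[k] - mu[c]) * istd;
        sb += g;
      }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    double kk = gamma[c] * istd;
    double mb = sb / m, mg = sg / m;
    for (int n = 0; n < N; ++n) {
      std::size_t off = hw * (c + (std::size_t)C * n);
      const double* xp = x.begin() + off;
      const double* gp = dout.begin() + off;
      const double* yp = act ? y.begin() + off : nullptr;
      double* dp = dx.begin() + off;
      for (std::size_t k = 0; k < hw; ++k) {
        double g = gp[k];
        if (act && (yp[k] <= 0.0 || yp[k] >= hi)) g = 0.0;
        double xh = (xp[k] - mu[c]) * istd;
        dp[k] = kk * (g - mb - xh * mg);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

struct BilinearCoef {
  int lo, hi;
  double wlo, whi;
};

static std::vector<BilinearCoef> bilinear_coefs(int in, int out) {
  std::vector<BilinearCoef> cs(out);
  double scale = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, in - 1);
    double fr = src - lo;
    cs[o] = {lo, hi, 1.0 - fr, fr};
  }
  return cs;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_bilinear_forward(NumericVector x, IntegerVector xdim,
                                   int Ho, int Wo) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  auto ch = bilinear_coefs(H, Ho), cw = bilinear_coefs(W, Wo);
  NumericVector y((std::size_t)N * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      double* ys = y.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        const double* cl = xs + (std::size_t)H * cw[ow].lo;
        const double* cr = xs + (std::size_t)H * cw[ow].hi;
        double* yc = ys + (std::size_t)Ho * ow;
        for (int oh = 0; oh < Ho; ++oh) {
          yc[oh] =
            cw[ow].wlo * (ch[oh].wlo * cl[ch[oh].lo] + ch[oh].whi * cl[ch[oh].hi]) +
            cw[ow].whi * (ch[oh].wlo * cr[ch[oh].lo] + ch[oh].whi * cr[ch[oh].hi]);
        }
      }
    }
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_bilinear_backward(NumericVector dout, IntegerVector odim,
                                    int H, int W) {
  int Ho = odim[0], Wo = odim[1], C = odim[2], N = odim[3];
  auto ch = bilinear_coefs(H, Ho), cw = bilinear_coefs(W, Wo);
  NumericVector dx((std::size_t)N * C * H * W);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xs = dx.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      const double* ys = dout.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        double* cl = xs + (std::size_t)H * cw[ow].lo;
        double* cr = xs + (std::size_t)H * cw[ow].hi;
        const double* yc = ys + (std::size_t)Ho * ow;
        for (int oh = 0; oh < Ho; ++oh) {
          double g = yc[oh];
          cl[ch[oh].lo] += cw[ow].wlo * ch[oh].wlo * g;
          cl[ch[oh].hi] += cw[ow].wlo * ch[oh].whi * g;
          cr[ch[oh].lo] += cw[ow].whi * ch[oh].wlo * g;
          cr[ch[oh].hi] += cw[ow].whi * ch[oh].whi * g;
        }
      }
    }
  return dx;
}


// Direct depthwise convolution (groups == C, one filter per channel).
// Weight dim = c(C, 1, kh, kw).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_dwconv_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 int sh, int sw, int ph, int pw,
                                 int dh, int dw_) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = wdim[2], kw = wdim[3];
  int Ho = conv_out_size(H, kh, sh, ph, dh);
  int Wo = conv_out_size(W, kw, sw, pw, dw_);
  if (Ho < 1 || Wo < 1) stop("dwconv: non-positive output size");
  NumericVector y((std::size_t)N * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<double> ker(kh * kw);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      double* ys = y.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          ker[j * kh + i] = w[c + (std::size_t)wdim[0] * (0 + (std::size_t)1 * (i + (std::size_t)kh * j))];
      for (int ow = 0; ow < Wo; ++ow) {
        double* yc = ys + (std::size_t)Ho * ow;
        for (int oh = 0; oh < Ho; ++oh) yc[oh] = 0.0;
        for (int j = 0; j < kw; ++j) {
          int iw = ow * sw - pw + j * dw_;
          if (iw < 0 || iw >= W) continue;
          const double* xc = xs + (std::size_t)H * iw;
          for (int i = 0; i < kh; ++i) {
            double kv = ker[j * kh + i];
            int ib = -ph + i * dh;
            // oh range with ih = oh*sh + ib inside [0, H)
            int oh0 = ib < 0 ? ((-ib + sh - 1) / sh) : 0;
            int oh1 = Ho - 1;
            if (ib + oh1 * sh >= H) oh1 = (H - 1 - ib) / sh;
            const double* xi = xc + ib;
            for (int oh = oh0; oh <= oh1; ++oh)
              yc[oh] += kv * xi[(std::size_t)oh * sh];
          }
        }
      }
    }
  return y;
}

// [[Rcpp::export(rng = false)]]
List cpp_dwconv_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector dout,
                         int sh, int sw, int ph, int pw,
                         int dh, int dw_) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = wdim[2], kw = wdim[3];
  int Ho = conv_out_size(H, kh, sh, ph, dh);
  int Wo = conv_out_size(W, kw, sw, pw, dw_);
  NumericVector gx((std::size_t)N * C * H * W);
  gx.attr("dim") = xdim;
  NumericVector gw((std::size_t)wdim[0] * wdim[1] * kh * kw);
  gw.attr("dim") = wdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      double* gxs = gx.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      const double* gys = dout.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          double kv = w[c + (std::size_t)wdim[0] * (i + (std::size_t)kh * j)];
          double acc = 0.0;
          int ib = -ph + i * dh;
          for (int ow = 0; ow < Wo; ++ow) {
            int iw = ow * sw - pw + j * dw_;
            if (iw < 0 || iw >= W) continue;
            const double* xc = xs + (std::size_t)H * iw + ib;
            double* gxc = gxs + (std::size_t)H * iw + ib;
            const double* gyc = gys + (std::size_t)Ho * ow;
            int oh0 = ib < 0 ? ((-ib + sh - 1) / sh) : 0;
            int oh1 = Ho - 1;
            if (ib + oh1 * sh >= H) oh1 = (H - 1 - ib) / sh;
            for (int oh = oh0; oh <= oh1; ++oh) {
              double g = gyc[oh];
              acc += g * xc[(std::size_t)oh * sh];
              gxc[(std::size_t)oh * sh] += kv * g;
            }
          }
          gw[c + (std::size_t)wdim[0] * (i + (std::size_t)kh * j)] += acc;
        }
    }
  return List::create(_["dx"] = gx, _["dw"] = gw);
}

// clamp activation (relu: lo=0, hi=Inf; relu6: lo=0, hi=6)
// [[Rcpp::export(rng = false)]]
NumericVector cpp_clamp_forward(NumericVector x, double lo, double hi) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    y[i] = v < lo ? lo : (v > hi ? hi : v);
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_clamp_backward(NumericVector x, NumericVector g,
                                 double lo, double hi) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    dx[i] = (x[i] > lo && x[i] < hi) ? g[i] : 0.0;
  }
  return dx;
}
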