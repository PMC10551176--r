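#include <Rcpp.h>
using namespace Rcpp;

// Tensors are column-major (H, W, C, N): idx = h + H*(w + W*(c + C*n)).
// padmode: 0 = zero padding, 1 = replicate (edge-clamp) padding.

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Unfold conv patches into a (Hout*Wout*N) x (k*k*C) matrix whose row order
// is (ho, wo, n) with ho fastest, and whose column order (ki, kj, c) matches
// the column-major flattening of a (k, k, C) kernel.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad, int padmode) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Hout * Wout * N, k * k * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * (kj + k * c);
        double *pcol = &out(0, col);
        for (int n = 0; n < N; ++n) {
          const double *base = px + (size_t)(c + (size_t)C * n) * H * W;
          for (int wo = 0; wo < Wout; ++wo) {
            int wi = wo * stride - pad + kj;
            bool win = (wi >= 0 && wi < W);
            int wic = clampi(wi, 0, W - 1);
            size_t rbase = (size_t)Hout * (wo + (size_t)Wout * n);
            for (int ho = 0; ho < Hout; ++ho) {
              int hi = ho * stride - pad + ki;
              double v = 0.0;
              if (padmode == 1) {
                v = base[clampi(hi, 0, H - 1) + (size_t)H * wic];
              } else if (win && hi >= 0 && hi < H) {
                v = base[hi + (size_t)H * wi];
              }
              pcol[rbase + ho] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch-gradient columns back onto the
// input tensor. With replicate padding the gradient accumulates on the
// clamped edge pixels.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad, int padmode) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((size_t)H * W * C * N);
  double *pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * (kj + k * c);
        const double *pcol = &cols(0, col);
        for (int n = 0; n < N; ++n) {
          double *base = pdx + (size_t)(c + (size_t)C * n) * H * W;
          for (int wo = 0; wo < Wout; ++wo) {
            int wi = wo * stride - pad + kj;
            bool win = (wi >= 0 && wi < W);
            if (padmode == 0 && !win) continue;
            int wic = clampi(wi, 0, W - 1);
            size_t rbase = (size_t)Hout * (wo + (size_t)Wout * n);
            for (int ho = 0; ho < Hout; ++ho) {
              int hi = ho * stride - pad + ki;
              if (padmode == 1) {
                base[clampi(hi, 0, H - 1) + (size_t)H * wic] += pcol[rbase + ho];
              } else if (hi >= 0 && hi < H) {
                base[hi + (size_t)H * wi] += pcol[rbase + ho];
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// Depthwise convolution, stride 1, odd k, "same" zero padding.
// K is (k, k, C) column-major; bias has length C.
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                             NumericVector K, int k, NumericVector bias) {
  const int pad = (k - 1) / 2;
  NumericVector out((size_t)H * W * C * N);
  const double *px = x.begin();
  const double *pK = K.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xb = px + (size_t)(c + (size_t)C * n) * H * W;
      double *ob = po + (size_t)(c + (size_t)C * n) * H * W;
      const double *Kb = pK + (size_t)c * k * k;
      const double b = bias[c];
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          double acc = b;
          for (int kj = 0; kj < k; ++kj) {
            int wi = w - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = h - pad + ki;
              if (hi < 0 || hi >= H) continue;
              acc += xb[hi + (size_t)H * wi] * Kb[ki + k * kj];
            }
          }
          ob[h + (size_t)H * w] = acc;
        }
      }
    }
  }
  return out;
}

// Gradients of the depthwise convolution w.r.t. input, kernel and bias.
// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector K, NumericVector dout,
                    int H, int W, int C, int N, int k) {
  const int pad = (k - 1) / 2;
  NumericVector dx((size_t)H * W * C * N);
  NumericVector dK((size_t)k * k * C);
  NumericVector db(C);
  const double *px = x.begin(), *pK = K.begin(), *pd = dout.begin();
  double *pdx = dx.begin(), *pdK = dK.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xb = px + (size_t)(c + (size_t)C * n) * H * W;
      const double *db_ = pd + (size_t)(c + (size_t)C * n) * H * W;
      double *dxb = pdx + (size_t)(c + (size_t)C * n) * H * W;
      const double *Kb = pK + (size_t)c * k * k;
      double *dKb = pdK + (size_t)c * k * k;
      double accb = 0.0;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          const double g = db_[h + (size_t)H * w];
          accb += g;
          for (int kj = 0; kj < k; ++kj) {
            int wi = w - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = h - pad + ki;
              if (hi < 0 || hi >= H) continue;
              dxb[hi + (size_t)H * wi] += g * Kb[ki + k * kj];
              dKb[ki + k * kj] += g * xb[hi + (size_t)H * wi];
            }
          }
        }
      }
      db[c] += accb;
    }
  }
  return List::create(_["dx"] = dx, _["dK"] = dK, _["db"] = db);
}

// Max pooling over k x k windows; out-of-range positions are simply excluded
// from the window (equivalent to replicate padding for the max). Returns the
// pooled tensor and the 0-based flat argmax index into the input.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                     int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)Hout * Wout * C * N);
  IntegerVector arg((size_t)Hout * Wout * C * N);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t xoff = (size_t)(c + (size_t)C * n) * H * W;
      const size_t ooff = (size_t)(c + (size_t)C * n) * Hout * Wout;
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho) {
          double best = R_NegInf;
          int bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              double v = px[xoff + hi + (size_t)H * wi];
              if (v > best) { best = v; bidx = hi + H * wi; }
            }
          }
          out[ooff + ho + (size_t)Hout * wo] = best;
          arg[ooff + ho + (size_t)Hout * wo] = (int)(xoff + bidx);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector argmax,
                              double inlen) {
  NumericVector dx((size_t)inlen);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i]] += dout[i];
  return dx;
}

// Exact GELU, x * Phi(x), with Phi the standard normal CDF via erf.
// [[Rcpp::export]]
NumericVector gelu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size());
  const double s = M_SQRT1_2;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] * 0.5 * (1.0 + std::erf(x[i] * s));
  return out;
}

// d/dx [x * Phi(x)] = Phi(x) + x * phi(x), times the upstream gradient.
// [[Rcpp::export]]
NumericVector gelu_bwd_cpp(NumericVector x, NumericVector dout) {
  NumericVector out(x.size());
  const double s = M_SQRT1_2;
  const double inv_sqrt2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double Phi = 0.5 * (1.0 + std::erf(x[i] * s));
    double phi = inv_sqrt2pi * std::exp(-0.5 * x[i] * x[i]);
    out[i] = dout[i] * (Phi + x[i] * phi);
  }
  return out;
}
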