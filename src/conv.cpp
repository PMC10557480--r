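// Grouped 2-D convolution forward/backward on NCHW tensors via im2col + gemm.
// Tensors arrive as flat numeric vectors with explicit dims; R arrays are
// column-major, so for dim = c(N, C, H, W) the offset of (n, c, h, w)
// (0-based) is n + N*(c + C*(h + H*w)).  Weights use dim
// c(C_out, C_in/g, K, K) with the output channel fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the per-group weight matrix (Cout_g x Cin_g*K*K); column index
// r = i + Cin_g*(kh + K*kw) matches the im2col row layout below.
static arma::mat weight_matrix(const NumericVector& w, int Cout, int Cin_g,
                               int K, int g, int Cout_g) {
  arma::mat W(Cout_g, Cin_g * K * K);
  for (int r = 0; r < Cin_g * K * K; ++r)
    for (int o = 0; o < Cout_g; ++o)
      W(o, r) = w[(g * Cout_g + o) + (R_xlen_t)Cout * r];
  return W;
}

static void im2col(const double* x, int N, int C, int H, int Wd,
                   int n, int c0, int Cin_g, int K, int stride, int pad,
                   int Ho, int Wo, arma::mat& A) {
  // A is (Cin_g*K*K) x (Ho*Wo); column j = oh + Ho*ow.
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      int j = oh + Ho * ow;
      for (int kw = 0; kw < K; ++kw) {
        int wi = ow * stride - pad + kw;
        for (int kh = 0; kh < K; ++kh) {
          int hi = oh * stride - pad + kh;
          for (int i = 0; i < Cin_g; ++i) {
            int r = i + Cin_g * (kh + K * kw);
            if (hi >= 0 && hi < H && wi >= 0 && wi < Wd) {
              int c = c0 + i;
              A(r, j) = x[n + (R_xlen_t)N * (c + (R_xlen_t)C * (hi + (R_xlen_t)H * wi))];
            } else {
              A(r, j) = 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias, int stride, int pad,
                                 int groups) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], Wd = xdim[3];
  const int Cout = wdim[0], Cin_g = wdim[1], K = wdim[2];
  const int Ho = out_size(H, K, stride, pad), Wo = out_size(Wd, K, stride, pad);
  const int Cout_g = Cout / groups;
  const bool has_bias = bias.size() > 0;

  NumericVector y((R_xlen_t)N * Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, Cout, Ho, Wo);

  std::vector<arma::mat> Wg(groups);
  for (int g = 0; g < groups; ++g)
    Wg[g] = weight_matrix(w, Cout, Cin_g, K, g, Cout_g);

  arma::mat A(Cin_g * K * K, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), N, C, H, Wd, n, g * Cin_g, Cin_g, K, stride, pad, Ho, Wo, A);
      arma::mat Y = Wg[g] * A;  // Cout_g x Ho*Wo
      for (int j = 0; j < Ho * Wo; ++j) {
        int oh = j % Ho, ow = j / Ho;
        for (int o = 0; o < Cout_g; ++o) {
          int oc = g * Cout_g + o;
          double v = Y(o, j) + (has_bias ? bias[oc] : 0.0);
          y[n + (R_xlen_t)N * (oc + (R_xlen_t)Cout * (oh + (R_xlen_t)Ho * ow))] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector gy, int stride, int pad,
                         int groups, bool has_bias) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], Wd = xdim[3];
  const int Cout = wdim[0], Cin_g = wdim[1], K = wdim[2];
  const int Ho = out_size(H, K, stride, pad), Wo = out_size(Wd, K, stride, pad);
  const int Cout_g = Cout / groups;

  NumericVector gx((R_xlen_t)N * C * H * Wd);
  gx.attr("dim") = IntegerVector::create(N, C, H, Wd);
  NumericVector gw((R_xlen_t)Cout * Cin_g * K * K);
  gw.attr("dim") = IntegerVector::create(Cout, Cin_g, K, K);
  NumericVector gb(has_bias ? Cout : 0);

  std::vector<arma::mat> Wg(groups), GW(groups);
  for (int g = 0; g < groups; ++g) {
    Wg[g] = weight_matrix(w, Cout, Cin_g, K, g, Cout_g);
    GW[g] = arma::zeros<arma::mat>(Cout_g, Cin_g * K * K);
  }

  arma::mat A(Cin_g * K * K, Ho * Wo);
  arma::mat GY(Cout_g, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), N, C, H, Wd, n, g * Cin_g, Cin_g, K, stride, pad, Ho, Wo, A);
      for (int j = 0; j < Ho * Wo; ++j) {
        int oh = j % Ho, ow = j / Ho;
        for (int o = 0; o < Cout_g; ++o) {
          int oc = g * Cout_g + o;
          double v = gy[n + (R_xlen_t)N * (oc + (R_xlen_t)Cout * (oh + (R_xlen_t)Ho * ow))];
          GY(o, j) = v;
          if (has_bias) gb[oc] += v;
        }
      }
      GW[g] += GY * A.t();
      arma::mat GA = Wg[g].t() * GY;  // col2im accumulate
      for (int j = 0; j < Ho * Wo; ++j) {
        int oh = j % Ho, ow = j / Ho;
        for (int kw = 0; kw < K; ++kw) {
          int wi = ow * stride - pad + kw;
          if (wi < 0 || wi >= Wd) continue;
          for (int kh = 0; kh < K; ++kh) {
            int hi = oh * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            for (int i = 0; i < Cin_g; ++i) {
              int r = i + Cin_g * (kh + K * kw);
              int c = g * Cin_g + i;
              gx[n + (R_xlen_t)N * (c + (R_xlen_t)C * (hi + (R_xlen_t)H * wi))] += GA(r, j);
            }
          }
        }
      }
    }
  }
  for (int g = 0; g < groups; ++g)
    for (int r = 0; r < Cin_g * K * K; ++r)
      for (int o = 0; o < Cout_g; ++o)
        gw[(g * Cout_g + o) + (R_xlen_t)Cout * r] = GW[g](o, r);

  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
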