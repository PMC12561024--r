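// Numeric kernels for the network, losses and image utilities.
// Tensor layout everywhere: (H, W, C, N), column-major (R array order).
// Conv weights: (kh, kw, Cin, Cout); depthwise weights: (kh, kw, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static NumericVector make4(int H, int W, int C, int N) {
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// ---------------------------------------------------------------- im2col ---

// Fill M (P x K) with patches of sample n; P = Ho*Wo, K = kh*kw*Cin.
static void im2col(const double* xp, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& M) {
  M.zeros();
  for (int ci = 0; ci < Cin; ci++) {
    const double* xc = xp + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; kj++) {
      for (int ki = 0; ki < kh; ki++) {
        int q = ki + kh * (kj + kw * ci);
        double* Mq = M.colptr(q);
        for (int wo = 0; wo < Wo; wo++) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)H * wi;
          double* Mcol = Mq + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ho++) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            Mcol[ho] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add M (P x K) back into gx for sample n (col2im).
static void col2im(const arma::mat& M, double* gxp, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int ci = 0; ci < Cin; ci++) {
    double* xc = gxp + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; kj++) {
      for (int ki = 0; ki < kh; ki++) {
        int q = ki + kh * (kj + kw * ci);
        const double* Mq = M.colptr(q);
        for (int wo = 0; wo < Wo; wo++) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)H * wi;
          const double* Mcol = Mq + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ho++) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += Mcol[ho];
          }
        }
      }
    }
  }
}

// ------------------------------------------------------------------- conv ---

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  int H, W, C, N; get4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector y = make4(Ho, Wo, Cout, N);
  arma::mat M(P, K);
  for (int n = 0; n < N; n++) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, Cin, kh, kw, stride, pad, Ho, Wo, M);
    arma::mat O = M * Wm;
    O.each_row() += bv;
    std::copy(O.begin(), O.end(), y.begin() + (size_t)P * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  int H, W, C, N; get4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1];
  int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector gx = make4(H, W, C, N);
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), K, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat M(P, K);
  for (int n = 0; n < N; n++) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, Cin, kh, kw, stride, pad, Ho, Wo, M);
    arma::mat G(const_cast<double*>(gy.begin()) + (size_t)P * Cout * n, P, Cout, false, true);
    gWm += M.t() * G;
    gbv += arma::sum(G, 0).t();
    arma::mat gM = G * Wm.t();
    col2im(gM, gx.begin() + (size_t)H * W * C * n, H, W, Cin, kh, kw, stride, pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// -------------------------------------------------------- depthwise conv ---

// 3x3, stride 1, pad 1, one filter per channel. w: (3,3,C), b: C.
// [[Rcpp::export]]
NumericVector cpp_dwconv3(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N; get4(x, H, W, C, N);
  NumericVector y = make4(H, W, C, N);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + 9 * (size_t)c;
      double* yc = y.begin() + (size_t)H * W * (c + (size_t)C * n);
      double bc = b[c];
      for (int j = 0; j < W; j++)
        for (int i = 0; i < H; i++) {
          double acc = bc;
          for (int kj = 0; kj < 3; kj++) {
            int wj = j + kj - 1;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < 3; ki++) {
              int wi = i + ki - 1;
              if (wi < 0 || wi >= H) continue;
              acc += wc[ki + 3 * kj] * xc[wi + (size_t)H * wj];
            }
          }
          yc[i + (size_t)H * j] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv3_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, C, N; get4(x, H, W, C, N);
  NumericVector gx = make4(H, W, C, N);
  NumericVector gw(w.size()); gw.attr("dim") = w.attr("dim");
  NumericVector gb(C);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* gc = gy.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + 9 * (size_t)c;
      double* gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* gwc = gw.begin() + 9 * (size_t)c;
      double gbc = 0.0;
      for (int j = 0; j < W; j++)
        for (int i = 0; i < H; i++) {
          double g = gc[i + (size_t)H * j];
          gbc += g;
          for (int kj = 0; kj < 3; kj++) {
            int wj = j + kj - 1;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < 3; ki++) {
              int wi = i + ki - 1;
              if (wi < 0 || wi >= H) continue;
              gwc[ki + 3 * kj] += g * xc[wi + (size_t)H * wj];
              gxc[wi + (size_t)H * wj] += g * wc[ki + 3 * kj];
            }
          }
        }
      gb[c] += gbc;
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ------------------------------------------------------------- batch norm ---

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  int H, W, C, N; get4(x, H, W, C, N);
  NumericVector y = make4(H, W, C, N);
  NumericVector mean(C), var(C), invstd(C);
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  for (int c = 0; c < C; c++) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; n++) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; i++) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    double mu = s / m, v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu; var[c] = v; invstd[c] = 1.0 / std::sqrt(v + eps);
    double g = gamma[c], b = beta[c], is = invstd[c];
    for (int n = 0; n < N; n++) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; i++) yc[i] = g * (xc[i] - mu) * is + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
                NumericVector invstd, NumericVector gy) {
  int H, W, C, N; get4(x, H, W, C, N);
  NumericVector gx = make4(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  for (int c = 0; c < C; c++) {
    double mu = mean[c], is = invstd[c], g = gamma[c];
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; n++) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = gy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; i++) {
        double xh = (xc[i] - mu) * is;
        sg += gc[i]; sgx += gc[i] * xh;
      }
    }
    gbeta[c] = sg; ggamma[c] = sgx;
    double mg = sg / m, mgx = sgx / m;
    for (int n = 0; n < N; n++) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = gy.begin() + plane * (c + (size_t)C * n);
      double* gxc = gx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; i++) {
        double xh = (xc[i] - mu) * is;
        gxc[i] = g * is * (gc[i] - mg - xh * mgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector cpp_bn_eval(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector rmean,
                          NumericVector rvar, double eps) {
  int H, W, C, N; get4(x, H, W, C, N);
  NumericVector y = make4(H, W, C, N);
  size_t plane = (size_t)H * W;
  for (int c = 0; c < C; c++) {
    double is = 1.0 / std::sqrt(rvar[c] + eps);
    double g = gamma[c], b = beta[c], mu = rmean[c];
    for (int n = 0; n < N; n++) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; i++) yc[i] = g * (xc[i] - mu) * is + b;
    }
  }
  return y;
}

// ------------------------------------------------------------- layer norm ---

// Normalize across channels at every (h, w, n) location (token LayerNorm).
// [[Rcpp::export]]
List cpp_ln_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  int H, W, C, N; get4(x, H, W, C, N);
  NumericVector y = make4(H, W, C, N);
  size_t plane = (size_t)H * W;
  NumericVector mean((R_xlen_t)plane * N), invstd((R_xlen_t)plane * N);
  for (int n = 0; n < N; n++) {
    const double* xn = x.begin() + plane * (size_t)C * n;
    double* yn = y.begin() + plane * (size_t)C * n;
    for (size_t p = 0; p < plane; p++) {
      double s = 0, s2 = 0;
      for (int c = 0; c < C; c++) {
        double v = xn[p + plane * c]; s += v; s2 += v * v;
      }
      double mu = s / C, v = s2 / C - mu * mu;
      if (v < 0) v = 0;
      double is = 1.0 / std::sqrt(v + eps);
      mean[p + plane * n] = mu; invstd[p + plane * n] = is;
      for (int c = 0; c < C; c++)
        yn[p + plane * c] = gamma[c] * (xn[p + plane * c] - mu) * is + beta[c];
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_ln_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
                NumericVector invstd, NumericVector gy) {
  int H, W, C, N; get4(x, H, W, C, N);
  NumericVector gx = make4(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  size_t plane = (size_t)H * W;
  for (int n = 0; n < N; n++) {
    const double* xn = x.begin() + plane * (size_t)C * n;
    const double* gn = gy.begin() + plane * (size_t)C * n;
    double* gxn = gx.begin() + plane * (size_t)C * n;
    for (size_t p = 0; p < plane; p++) {
      double mu = mean[p + plane * n], is = invstd[p + plane * n];
      double sg = 0, sgx = 0;
      for (int c = 0; c < C; c++) {
        double xh = (xn[p + plane * c] - mu) * is;
        double gh = gn[p + plane * c] * gamma[c];
        sg += gh; sgx += gh * xh;
        ggamma[c] += gn[p + plane * c] * xh;
        gbeta[c] += gn[p + plane * c];
      }
      double mg = sg / C, mgx = sgx / C;
      for (int c = 0; c < C; c++) {
        double xh = (xn[p + plane * c] - mu) * is;
        double gh = gn[p + plane * c] * gamma[c];
        gxn[p + plane * c] = is * (gh - mg - xh * mgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---------------------------------------------------------------- pooling ---

// 2x2 max pool, stride 2 (H, W even). idx holds 0-based argmax into x.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  int H, W, C, N; get4(x, H, W, C, N);
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  size_t o = 0;
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; wo++)
        for (int ho = 0; ho < Ho; ho++) {
          double best = -1e300; size_t bi = 0;
          for (int dj = 0; dj < 2; dj++)
            for (int di = 0; di < 2; di++) {
              size_t ii = base + (2 * ho + di) + (size_t)H * (2 * wo + dj);
              if (x[ii] > best) { best = x[ii]; bi = ii; }
            }
          // y index must follow (Ho,Wo,C,N) order:
          size_t yi = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          y[yi] = best; idx[yi] = (int)bi;
          (void)o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector gy,
                              int H, int W, int C, int N) {
  NumericVector gx = make4(H, W, C, N);
  for (R_xlen_t i = 0; i < gy.size(); i++) gx[idx[i]] += gy[i];
  return gx;
}

// Generic kh x kw max/min pool, stride 1, same padding (for soft skeletons).
// mode: 0 = max, 1 = min.
// [[Rcpp::export]]
List cpp_pool_same(NumericVector x, int kh, int kw, int mode) {
  int H, W, C, N; get4(x, H, W, C, N);
  NumericVector y = make4(H, W, C, N);
  IntegerVector idx((R_xlen_t)H * W * C * N);
  int ph = kh / 2, pw = kw / 2;
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < W; j++)
        for (int i = 0; i < H; i++) {
          double best = (mode == 0) ? -1e300 : 1e300;
          size_t bi = base + i + (size_t)H * j;
          for (int kjj = 0; kjj < kw; kjj++) {
            int wj = j + kjj - pw;
            if (wj < 0 || wj >= W) continue;
            for (int kii = 0; kii < kh; kii++) {
              int wi = i + kii - ph;
              if (wi < 0 || wi >= H) continue;
              size_t ii = base + wi + (size_t)H * wj;
              double v = x[ii];
              if ((mode == 0 && v > best) || (mode == 1 && v < best)) {
                best = v; bi = ii;
              }
            }
          }
          size_t yi = base + i + (size_t)H * j;
          y[yi] = best; idx[yi] = (int)bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_scatter_bw(IntegerVector idx, NumericVector gy,
                             int H, int W, int C, int N) {
  NumericVector gx = make4(H, W, C, N);
  for (R_xlen_t i = 0; i < gy.size(); i++) gx[idx[i]] += gy[i];
  return gx;
}

// ---------------------------------------------------- bilinear upsampling ---

// Factor-2 bilinear upsampling, align_corners = FALSE convention.
// [[Rcpp::export]]
NumericVector cpp_up2(NumericVector x) {
  int H, W, C, N; get4(x, H, W, C, N);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make4(Ho, Wo, C, N);
  std::vector<int> i0(Ho), i1(Ho); std::vector<double> wi(Ho);
  for (int i = 0; i < Ho; i++) {
    double s = (i + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(s);
    double t = s - f;
    i0[i] = std::min(std::max(f, 0), H - 1);
    i1[i] = std::min(std::max(f + 1, 0), H - 1);
    wi[i] = t;
  }
  std::vector<int> j0(Wo), j1(Wo); std::vector<double> wj(Wo);
  for (int j = 0; j < Wo; j++) {
    double s = (j + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(s);
    double t = s - f;
    j0[j] = std::min(std::max(f, 0), W - 1);
    j1[j] = std::min(std::max(f + 1, 0), W - 1);
    wj[j] = t;
  }
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < Wo; j++)
        for (int i = 0; i < Ho; i++) {
          double a = xc[i0[i] + (size_t)H * j0[j]];
          double b = xc[i1[i] + (size_t)H * j0[j]];
          double cc = xc[i0[i] + (size_t)H * j1[j]];
          double d = xc[i1[i] + (size_t)H * j1[j]];
          double top = a * (1 - wi[i]) + b * wi[i];
          double bot = cc * (1 - wi[i]) + d * wi[i];
          yc[i + (size_t)Ho * j] = top * (1 - wj[j]) + bot * wj[j];
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_up2_bw(NumericVector gy, int H, int W) {
  int Ho, Wo, C, N; get4(gy, Ho, Wo, C, N);
  NumericVector gx = make4(H, W, C, N);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double* gc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* xc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; j++) {
        double sj = (j + 0.5) / 2.0 - 0.5;
        int jf = (int)std::floor(sj);
        double tj = sj - jf;
        int J0 = std::min(std::max(jf, 0), W - 1);
        int J1 = std::min(std::max(jf + 1, 0), W - 1);
        for (int i = 0; i < Ho; i++) {
          double si = (i + 0.5) / 2.0 - 0.5;
          int fi = (int)std::floor(si);
          double ti = si - fi;
          int I0 = std::min(std::max(fi, 0), H - 1);
          int I1 = std::min(std::max(fi + 1, 0), H - 1);
          double g = gc[i + (size_t)Ho * j];
          xc[I0 + (size_t)H * J0] += g * (1 - ti) * (1 - tj);
          xc[I1 + (size_t)H * J0] += g * ti * (1 - tj);
          xc[I0 + (size_t)H * J1] += g * (1 - ti) * tj;
          xc[I1 + (size_t)H * J1] += g * ti * tj;
        }
      }
    }
  return gx;
}

// ------------------------------------------------------------ token shift ---

// Shift each channel c by shifts[c] pixels along an axis (0 = rows/depth,
// 1 = cols), zero-filling vacated pixels. Backward = negated shifts.
// [[Rcpp::export]]
NumericVector cpp_shift(NumericVector x, int axis, IntegerVector shifts) {
  int H, W, C, N; get4(x, H, W, C, N);
  NumericVector y = make4(H, W, C, N);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      int s = shifts[c];
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < W; j++)
        for (int i = 0; i < H; i++) {
          int si = i, sj = j;
          if (axis == 0) si = i - s; else sj = j - s;
          if (si < 0 || si >= H || sj < 0 || sj >= W) continue;
          yc[i + (size_t)H * j] = xc[si + (size_t)H * sj];
        }
    }
  return y;
}

// ------------------------------------------------------------ activations ---

// [[Rcpp::export]]
NumericVector cpp_gelu(NumericVector x) {
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  const double isq2 = 0.7071067811865476;
  for (R_xlen_t i = 0; i < x.size(); i++)
    y[i] = 0.5 * x[i] * (1.0 + std::erf(x[i] * isq2));
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_bw(NumericVector x, NumericVector gy) {
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  const double isq2 = 0.7071067811865476;
  const double isq2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < x.size(); i++) {
    double Phi = 0.5 * (1.0 + std::erf(x[i] * isq2));
    double phi = isq2pi * std::exp(-0.5 * x[i] * x[i]);
    gx[i] = gy[i] * (Phi + x[i] * phi);
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid(NumericVector x) {
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); i++) {
    double z = x[i];
    y[i] = (z >= 0) ? 1.0 / (1.0 + std::exp(-z))
                    : std::exp(z) / (1.0 + std::exp(z));
  }
  return y;
}

// ----------------------------------------------------------- weighted BCE ---

// Numerically stable weighted BCE on logits, mean reduction.
// Returns the scalar loss and d(loss)/d(logits).
// [[Rcpp::export]]
List cpp_wbce(NumericVector z, NumericVector y, double pos_weight) {
  if (z.size() != y.size()) stop("wbce: shape mismatch");
  double loss = 0.0;
  NumericVector gz(z.size()); gz.attr("dim") = z.attr("dim");
  double m = (double)z.size();
  for (R_xlen_t i = 0; i < z.size(); i++) {
    double zi = z[i], yi = y[i];
    double sp_nz = (zi > 0) ? std::log1p(std::exp(-zi)) : -zi + std::log1p(std::exp(zi));
    double sp_z = zi + sp_nz;  // softplus(z)
    loss += pos_weight * yi * sp_nz + (1.0 - yi) * sp_z;
    double s = (zi >= 0) ? 1.0 / (1.0 + std::exp(-zi))
                         : std::exp(zi) / (1.0 + std::exp(zi));
    gz[i] = (-pos_weight * yi * (1.0 - s) + (1.0 - yi) * s) / m;
  }
  return List::create(_["loss"] = loss / m, _["gz"] = gz);
}

// -------------------------------------------------------- image utilities ---

// Bilinear resize of a single-channel matrix (align_corners = FALSE).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int oh, int ow) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  double fy = (double)H / oh, fx = (double)W / ow;
  for (int j = 0; j < ow; j++) {
    double sx = (j + 0.5) * fx - 0.5;
    int x0 = (int)std::floor(sx);
    double tx = sx - x0;
    int X0 = std::min(std::max(x0, 0), W - 1);
    int X1 = std::min(std::max(x0 + 1, 0), W - 1);
    for (int i = 0; i < oh; i++) {
      double sy = (i + 0.5) * fy - 0.5;
      int y0 = (int)std::floor(sy);
      double ty = sy - y0;
      int Y0 = std::min(std::max(y0, 0), H - 1);
      int Y1 = std::min(std::max(y0 + 1, 0), H - 1);
      double top = img(Y0, X0) * (1 - tx) + img(Y0, X1) * tx;
      double bot = img(Y1, X0) * (1 - tx) + img(Y1, X1) * tx;
      out(i, j) = top * (1 - ty) + bot * ty;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(NumericMatrix img, int oh, int ow) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  double fy = (double)H / oh, fx = (double)W / ow;
  for (int j = 0; j < ow; j++) {
    int sj = std::min((int)std::floor((j + 0.5) * fx), W - 1);
    for (int i = 0; i < oh; i++) {
      int si = std::min((int)std::floor((i + 0.5) * fy), H - 1);
      out(i, j) = img(si, sj);
    }
  }
  return out;
}

// Inverse-mapped affine warp about the image centre. A is the 2x2 matrix and
// t the offset mapping OUTPUT (row,col) to INPUT coords, both centred.
// interp: 0 = bilinear, 1 = nearest. Outside pixels are zero.
// [[Rcpp::export]]
NumericMatrix cpp_affine_warp(NumericMatrix img, NumericMatrix A,
                              NumericVector t, int interp) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double yo = i - cy, xo = j - cx;
      double yi = A(0, 0) * yo + A(0, 1) * xo + t[0] + cy;
      double xi = A(1, 0) * yo + A(1, 1) * xo + t[1] + cx;
      if (interp == 1) {
        int ri = (int)std::lround(yi), rj = (int)std::lround(xi);
        if (ri >= 0 && ri < H && rj >= 0 && rj < W) out(i, j) = img(ri, rj);
      } else {
        int y0 = (int)std::floor(yi), x0 = (int)std::floor(xi);
        double ty = yi - y0, tx = xi - x0;
        double acc = 0.0;
        for (int dj = 0; dj < 2; dj++)
          for (int di = 0; di < 2; di++) {
            int rr = y0 + di, cc = x0 + dj;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            double wgt = (di ? ty : 1 - ty) * (dj ? tx : 1 - tx);
            acc += wgt * img(rr, cc);
          }
        out(i, j) = acc;
      }
    }
  return out;
}

// Separable Gaussian blur with reflect padding.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double acc = 0.0;
      for (int d = -r; d <= r; d++) acc += k[d + r] * img(reflect(i + d, H), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double acc = 0.0;
      for (int d = -r; d <= r; d++) acc += k[d + r] * tmp(i, reflect(j + d, W));
      out(i, j) = acc;
    }
  return out;
}

// --------------------------------------------------- Zhang-Suen thinning ---

// Morphological thinning of a binary mask to a 1-px-wide skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix m(clone(mask));
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return m(i, j) != 0 ? 1 : 0;
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; pass++) {
      kill.clear();
      for (int i = 0; i < H; i++)
        for (int j = 0; j < W; j++) {
          if (!m(i, j)) continue;
          // neighbours p2..p9 clockwise from north
          int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
              p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
              p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int q = 0; q < 8; q++) if (seq[q] == 0 && seq[q + 1] == 1) A++;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({i, j});
        }
      if (!kill.empty()) changed = true;
      for (auto& pr : kill) m(pr.first, pr.second) = 0;
    }
  }
  return m;
}

// Pairwise minimum distances: for each point in L (rows), min Euclidean
// distance to any point in P, in physical units.
// pts are 2-col matrices (row, col) in px; sp = (row_mm, col_mm) spacing.
// [[Rcpp::export]]
List cpp_min_dists(NumericMatrix L, NumericMatrix P, NumericVector sp) {
  int nl = L.nrow(), np = P.nrow();
  NumericVector d(nl); IntegerVector which(nl);
  for (int i = 0; i < nl; i++) {
    double best = R_PosInf; int bj = -1;
    for (int j = 0; j < np; j++) {
      double dy = (L(i, 0) - P(j, 0)) * sp[0];
      double dx = (L(i, 1) - P(j, 1)) * sp[1];
      double dd = dy * dy + dx * dx;
      if (dd < best) { best = dd; bj = j; }
    }
    d[i] = std::sqrt(best); which[i] = bj + 1;
  }
  return List::create(_["dist"] = d, _["which"] = which);
}
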