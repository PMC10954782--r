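// 3D convolution, batch normalization and max-pooling kernels for the
// volumetric CNN. Activations are laid out as column-major R arrays
// (D, H, W, C, B); convolution is realised as batched im2col + BLAS GEMM
// via Armadillo.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Convolution arithmetic runs in single precision: activations and
// gradients are cast to float for the im2col buffers and GEMMs (the usual
// precision for neural-network training) and results are returned as
// doubles. This halves memory traffic and roughly doubles GEMM throughput.

// patch matrix over the whole batch: row (s*V + v), column (c, kx, ky, kz)
static arma::fmat im2col3d_batch(const double* x, int D, int H, int W, int Cin,
                                 int B, int K, int pad, int Do, int Ho, int Wo) {
  size_t V = static_cast<size_t>(Do) * Ho * Wo;
  size_t vx = static_cast<size_t>(D) * H * W * Cin;
  arma::fmat P(V * B, static_cast<size_t>(K) * K * K * Cin);
  size_t col = 0;
  for (int c = 0; c < Cin; ++c)
    for (int kx = 0; kx < K; ++kx)
      for (int ky = 0; ky < K; ++ky)
        for (int kz = 0; kz < K; ++kz, ++col) {
          float* pcol = P.colptr(col);
          for (int s = 0; s < B; ++s) {
            const double* xc = x + s * vx + static_cast<size_t>(c) * D * H * W;
            float* pc = pcol + s * V;
            size_t v = 0;
            for (int xo = 0; xo < Wo; ++xo) {
              int xi = xo - pad + kx;
              for (int yo = 0; yo < Ho; ++yo) {
                int yi = yo - pad + ky;
                bool ok_xy = xi >= 0 && xi < W && yi >= 0 && yi < H;
                const double* base =
                    ok_xy ? xc + (static_cast<size_t>(xi) * H + yi) * D : nullptr;
                for (int zo = 0; zo < Do; ++zo, ++v) {
                  int zi = zo - pad + kz;
                  pc[v] = (ok_xy && zi >= 0 && zi < D)
                              ? static_cast<float>(base[zi]) : 0.0f;
                }
              }
            }
          }
        }
  return P;
}

// scatter-add of one sample's patch-gradient rows back onto its input grid
static void col2im3d(const arma::fmat& G, size_t row0, double* dx, int D, int H,
                     int W, int Cin, int K, int pad, int Do, int Ho, int Wo) {
  size_t col = 0;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + static_cast<size_t>(c) * D * H * W;
    for (int kx = 0; kx < K; ++kx)
      for (int ky = 0; ky < K; ++ky)
        for (int kz = 0; kz < K; ++kz, ++col) {
          const float* pc = G.colptr(col) + row0;
          size_t v = 0;
          for (int xo = 0; xo < Wo; ++xo) {
            int xi = xo - pad + kx;
            for (int yo = 0; yo < Ho; ++yo) {
              int yi = yo - pad + ky;
              bool ok_xy = xi >= 0 && xi < W && yi >= 0 && yi < H;
              double* base =
                  ok_xy ? xc + (static_cast<size_t>(xi) * H + yi) * D : nullptr;
              for (int zo = 0; zo < Do; ++zo, ++v) {
                int zi = zo - pad + kz;
                if (ok_xy && zi >= 0 && zi < D) base[zi] += pc[v];
              }
            }
          }
        }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, NumericVector w, NumericVector b,
                             int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3], B = xd[4];
  int K = wd[0], Cout = wd[4];
  int Do = D + 2 * pad - K + 1, Ho = H + 2 * pad - K + 1, Wo = W + 2 * pad - K + 1;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("conv3d: input smaller than kernel");
  arma::mat Wd(w.begin(), static_cast<size_t>(K) * K * K * Cin, Cout, false);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(Wd);
  size_t V = static_cast<size_t>(Do) * Ho * Wo;
  arma::fmat P = im2col3d_batch(x.begin(), D, H, W, Cin, B, K, pad, Do, Ho, Wo);
  arma::fmat O = P * Wm;
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(
      arma::rowvec(b.begin(), Cout));
  O.each_row() += bf;
  NumericVector out(static_cast<R_xlen_t>(V) * Cout * B);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout, B);
  // O rows are (sample-block, voxel); output blocks are (voxel, channel) per sample
  for (int s = 0; s < B; ++s) {
    double* op = out.begin() + s * V * Cout;
    for (int c = 0; c < Cout; ++c) {
      const float* src = O.colptr(c) + s * V;
      for (size_t v = 0; v < V; ++v) op[c * V + v] = src[v];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward(NumericVector x, NumericVector w, NumericVector gout,
                     int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3], B = xd[4];
  int K = wd[0], Cout = wd[4];
  int Do = gd[0], Ho = gd[1], Wo = gd[2];
  arma::mat Wd(w.begin(), static_cast<size_t>(K) * K * K * Cin, Cout, false);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(Wd);
  size_t V = static_cast<size_t>(Do) * Ho * Wo;
  size_t vx = static_cast<size_t>(D) * H * W * Cin;
  arma::fmat G(V * B, Cout);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < Cout; ++c) {
      const double* src = gout.begin() + (static_cast<size_t>(s) * Cout + c) * V;
      float* dst = G.colptr(c) + s * V;
      for (size_t v = 0; v < V; ++v) dst[v] = static_cast<float>(src[v]);
    }
  arma::fmat P = im2col3d_batch(x.begin(), D, H, W, Cin, B, K, pad, Do, Ho, Wo);
  arma::fmat dW = P.t() * G;
  arma::frowvec db = arma::sum(G, 0);
  arma::fmat GP = G * Wm.t();
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  for (int s = 0; s < B; ++s) {
    col2im3d(GP, s * V, dx.begin() + s * vx, D, H, W, Cin, K, pad, Do, Ho, Wo);
  }
  NumericVector dWr(wd[0] * wd[1] * wd[2] * wd[3] * wd[4]);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  dWr.attr("dim") = wd;
  NumericVector dbr(Cout);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr);
}

// Ceil-mode max pooling, stride = window: trailing partial windows are kept,
// so a 32-voxel axis survives the (2, 3, 2, 3) pooling schedule (16, 6, 3, 1).
// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward(NumericVector x, int win) {
  IntegerVector xd = x.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3], B = xd[4];
  int Dc = (D + win - 1) / win, Hc = (H + win - 1) / win, Wc = (W + win - 1) / win;
  R_xlen_t n_out = static_cast<R_xlen_t>(Dc) * Hc * Wc * C * B;
  NumericVector out(n_out);
  IntegerVector idx(n_out);  // flat index into x of the winning element
  out.attr("dim") = IntegerVector::create(Dc, Hc, Wc, C, B);
  const double* xp = x.begin();
  R_xlen_t o = 0;
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      size_t base_cb = (static_cast<size_t>(s) * C + c) * D * H * W;
      for (int xo = 0; xo < Wc; ++xo)
        for (int yo = 0; yo < Hc; ++yo)
          for (int zo = 0; zo < Dc; ++zo, ++o) {
            double best = -HUGE_VAL;
            size_t best_i = 0;
            int x1 = xo * win, y1 = yo * win, z1 = zo * win;
            int x2 = std::min(x1 + win, W), y2 = std::min(y1 + win, H),
                z2 = std::min(z1 + win, D);
            for (int xi = x1; xi < x2; ++xi)
              for (int yi = y1; yi < y2; ++yi) {
                size_t row = base_cb + (static_cast<size_t>(xi) * H + yi) * D;
                for (int zi = z1; zi < z2; ++zi) {
                  double v = xp[row + zi];
                  if (v > best) { best = v; best_i = row + zi; }
                }
              }
            out[o] = best;
            idx[o] = static_cast<int>(best_i);
          }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward(NumericVector gout, IntegerVector idx,
                                 IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t o = 0; o < gout.size(); ++o) dx[idx[o]] += gout[o];
  return dx;
}

// Batch normalization over (spatial x batch) per channel, layout (D,H,W,C,B),
// with the ReLU fused into the output. Returns the rectified output plus the
// caches the backward pass needs (normalized activations and the ReLU mask).
// [[Rcpp::export(name = ".bn_relu_forward")]]
List bn_relu_forward(NumericVector z, NumericVector gamma, NumericVector beta,
                     NumericVector rmean, NumericVector rvar, bool training,
                     double momentum, double eps) {
  IntegerVector zd = z.attr("dim");
  int C = zd[3], B = zd[4];
  size_t V = static_cast<size_t>(zd[0]) * zd[1] * zd[2];
  double n = static_cast<double>(V) * B;
  NumericVector mu(C), va(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const double* p = z.begin() + (static_cast<size_t>(b) * C + c) * V;
        for (size_t v = 0; v < V; ++v) { s += p[v]; s2 += p[v] * p[v]; }
      }
      mu[c] = s / n;
      va[c] = std::max(s2 / n - mu[c] * mu[c], 0.0);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rmean[c];
      va[c] = std::max(rvar[c], 0.0);  // guard against corrupted statistics
    }
  }
  NumericVector out(z.size()), xhat(z.size());
  LogicalVector mask(z.size());
  NumericVector istd(C);
  out.attr("dim") = zd;
  for (int c = 0; c < C; ++c) istd[c] = 1.0 / std::sqrt(va[c] + eps);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      size_t off = (static_cast<size_t>(b) * C + c) * V;
      const double* p = z.begin() + off;
      double* xh = xhat.begin() + off;
      double* o = out.begin() + off;
      int* mk = mask.begin() + off;
      double m = mu[c], is = istd[c], g = gamma[c], bt = beta[c];
      for (size_t v = 0; v < V; ++v) {
        xh[v] = (p[v] - m) * is;
        double y = xh[v] * g + bt;
        if (y > 0) { o[v] = y; mk[v] = 1; } else { o[v] = 0; mk[v] = 0; }
      }
    }
  NumericVector nrm(C), nrv(C);
  if (training) {
    double ub = n > 1 ? n / (n - 1) : 1.0;
    for (int c = 0; c < C; ++c) {
      nrm[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      nrv[c] = (1 - momentum) * rvar[c] + momentum * va[c] * ub;
    }
  } else { nrm = rmean; nrv = rvar; }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["istd"] = istd,
                      _["mask"] = mask, _["rmean"] = nrm, _["rvar"] = nrv);
}

// backward through BN (ReLU mask applied to the incoming gradient first)
// [[Rcpp::export(name = ".bn_relu_backward")]]
List bn_relu_backward(NumericVector dout, LogicalVector mask, NumericVector xhat,
                      NumericVector istd, NumericVector gamma) {
  IntegerVector zd = dout.attr("dim");
  int C = zd[3], B = zd[4];
  size_t V = static_cast<size_t>(zd[0]) * zd[1] * zd[2];
  double n = static_cast<double>(V) * B;
  NumericVector dgamma(C), dbeta(C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      size_t off = (static_cast<size_t>(b) * C + c) * V;
      const double* dy = dout.begin() + off;
      const int* mk = mask.begin() + off;
      const double* xh = xhat.begin() + off;
      double sg = 0, sb = 0;
      for (size_t v = 0; v < V; ++v) {
        if (mk[v]) { sg += dy[v] * xh[v]; sb += dy[v]; }
      }
      dgamma[c] += sg; dbeta[c] += sb;
    }
  NumericVector dx(dout.size());
  dx.attr("dim") = zd;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      size_t off = (static_cast<size_t>(b) * C + c) * V;
      const double* dy = dout.begin() + off;
      const int* mk = mask.begin() + off;
      const double* xh = xhat.begin() + off;
      double* d = dx.begin() + off;
      double k = gamma[c] * istd[c] / n, dg = dgamma[c], db = dbeta[c];
      for (size_t v = 0; v < V; ++v) {
        double g = mk[v] ? dy[v] : 0.0;
        d[v] = k * (n * g - db - xh[v] * dg);
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
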