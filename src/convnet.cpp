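// Convolutional forward/backward kernels for the placement regressor.
//
// Activations are passed between R and C++ as cubes of shape
// (channels, height*width, batch) with spatial index s = h + H*w (0-based,
// column-major within a slice). Conv weights are matrices of shape
// (out_channels, in_channels*k*k) with row index r = (c*k + kw)*k + kh.
// The im2col matrices of all batch items are concatenated column-wise so
// each layer runs as one large GEMM per minibatch.
//
// The architecture table `arch` has one row per conv layer with columns:
//   0: k  1: stride  2: pad  3: H_in  4: W_in  5: oH  6: oW
//   7: pool flag (0/1)  8: pH  9: pW
// Pooling is always max-pool 3x3 stride 2. All dimensions are computed on
// the R side (conv_arch) and passed in, so the two sides cannot diverge.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_one(const double* A, int C, int H, int W, int k,
                       int stride, int pad, int oH, int oW, arma::mat& col,
                       std::size_t col_offset) {
  for (int ow = 0; ow < oW; ++ow) {
    const int wbase = ow * stride - pad;
    for (int oh = 0; oh < oH; ++oh) {
      const int hbase = oh * stride - pad;
      double* dst = col.colptr(col_offset + (std::size_t)ow * oH + oh);
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int w = wbase + kw;
          const bool win = (w >= 0 && w < W);
          const double* src = A + (std::size_t)C * H * w + c;
          double* d = dst + (std::size_t)(c * k + kw) * k;
          for (int kh = 0; kh < k; ++kh) {
            const int h = hbase + kh;
            d[kh] = (win && h >= 0 && h < H) ? src[(std::size_t)C * h] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& dcol, std::size_t col_offset,
                       double* dA, int C, int H, int W, int k, int stride,
                       int pad, int oH, int oW) {
  for (int ow = 0; ow < oW; ++ow) {
    const int wbase = ow * stride - pad;
    for (int oh = 0; oh < oH; ++oh) {
      const int hbase = oh * stride - pad;
      const double* src = dcol.colptr(col_offset + (std::size_t)ow * oH + oh);
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int w = wbase + kw;
          if (w < 0 || w >= W) continue;
          double* dst = dA + (std::size_t)C * H * w + c;
          const double* s = src + (std::size_t)(c * k + kw) * k;
          for (int kh = 0; kh < k; ++kh) {
            const int h = hbase + kh;
            if (h < 0 || h >= H) continue;
            dst[(std::size_t)C * h] += s[kh];
          }
        }
      }
    }
  }
}

// Max-pool 3x3 stride 2; records the argmax input spatial index per output.
static void maxpool_fwd(const arma::mat& Z, int H, int W, int pH, int pW,
                        arma::mat& P, arma::umat& idx) {
  const int C = Z.n_rows;
  for (int pw = 0; pw < pW; ++pw) {
    for (int ph = 0; ph < pH; ++ph) {
      const int ocol = pw * pH + ph;
      const int h0 = ph * 2, w0 = pw * 2;
      const int h1 = std::min(h0 + 3, H), w1 = std::min(w0 + 3, W);
      for (int c = 0; c < C; ++c) {
        double best = -std::numeric_limits<double>::infinity();
        std::size_t besti = 0;
        for (int w = w0; w < w1; ++w) {
          for (int h = h0; h < h1; ++h) {
            const std::size_t s = (std::size_t)w * H + h;
            const double v = Z(c, s);
            if (v > best) { best = v; besti = s; }
          }
        }
        P(c, ocol) = best;
        idx(c, ocol) = besti;
      }
    }
  }
}

// [[Rcpp::export]]
List conv_stack_forward(const arma::cube& x, List Ws, List bs,
                        const IntegerMatrix& arch) {
  const int L = arch.nrow();
  const int N = x.n_slices;
  List acts(L);      // post-ReLU conv outputs (pre-pool), per layer
  List pooled(L);    // layer outputs after optional pooling
  List poolidx(L);   // argmax indices where pooled
  arma::cube cur = x;

  for (int l = 0; l < L; ++l) {
    const int k = arch(l, 0), stride = arch(l, 1), pad = arch(l, 2);
    const int H = arch(l, 3), W = arch(l, 4), oH = arch(l, 5), oW = arch(l, 6);
    const bool pool = arch(l, 7) != 0;
    const int pH = arch(l, 8), pW = arch(l, 9);
    const arma::mat Wm = as<arma::mat>(Ws[l]);
    const arma::vec bv = as<arma::vec>(bs[l]);
    const int C = cur.n_rows;
    const int outC = Wm.n_rows;
    const std::size_t opix = (std::size_t)oH * oW;

    arma::mat col(C * k * k, opix * N);
    for (int n = 0; n < N; ++n) {
      im2col_one(cur.slice(n).memptr(), C, H, W, k, stride, pad, oH, oW,
                 col, opix * n);
    }
    arma::mat out = Wm * col;            // one GEMM for the whole batch
    out.each_col() += bv;
    out.clamp(0.0, arma::datum::inf);    // ReLU
    arma::cube Z(out.memptr(), outC, opix, N); // copies into cube layout
    acts[l] = Z;

    if (pool) {
      arma::cube P(outC, (std::size_t)pH * pW, N);
      arma::ucube I(outC, (std::size_t)pH * pW, N);
      for (int n = 0; n < N; ++n) {
        arma::mat Ps(outC, (std::size_t)pH * pW);
        arma::umat Is(outC, (std::size_t)pH * pW);
        maxpool_fwd(Z.slice(n), oH, oW, pH, pW, Ps, Is);
        P.slice(n) = Ps;
        I.slice(n) = Is;
      }
      poolidx[l] = I;
      pooled[l] = P;
      cur = P;
    } else {
      poolidx[l] = R_NilValue;
      pooled[l] = Z;
      cur = Z;
    }
  }

  // Flatten final activation to (features x N) for the FC head.
  const std::size_t flat = cur.n_rows * cur.n_cols;
  arma::mat feat(flat, N);
  for (int n = 0; n < N; ++n) {
    feat.col(n) = arma::vectorise(cur.slice(n));
  }
  return List::create(_["feat"] = feat, _["acts"] = acts,
                      _["pooled"] = pooled, _["poolidx"] = poolidx);
}

// [[Rcpp::export]]
List conv_stack_backward(const arma::mat& dfeat, const arma::cube& x,
                         List acts, List pooled, List poolidx, List Ws,
                         const IntegerMatrix& arch) {
  const int L = arch.nrow();
  const int N = x.n_slices;
  List dWs(L), dbs(L);

  // Reshape dfeat into the final layer's output cube.
  const arma::cube lastout = as<arma::cube>(pooled[L - 1]);
  arma::cube dcur(lastout.n_rows, lastout.n_cols, N);
  for (int n = 0; n < N; ++n) {
    dcur.slice(n) = arma::reshape(dfeat.col(n), lastout.n_rows, lastout.n_cols);
  }

  for (int l = L - 1; l >= 0; --l) {
    const int k = arch(l, 0), stride = arch(l, 1), pad = arch(l, 2);
    const int H = arch(l, 3), W = arch(l, 4), oH = arch(l, 5), oW = arch(l, 6);
    const bool pool = arch(l, 7) != 0;
    const arma::mat Wm = as<arma::mat>(Ws[l]);
    const arma::cube Z = as<arma::cube>(acts[l]);
    const arma::cube Ain = (l == 0) ? x : as<arma::cube>(pooled[l - 1]);
    const int C = Ain.n_rows;
    const int outC = Z.n_rows;
    const std::size_t opix = (std::size_t)oH * oW;

    // Gradient w.r.t. the post-ReLU conv output, batch-concatenated.
    arma::mat dZ(outC, opix * N, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      arma::mat dZn(dZ.memptr() + (std::size_t)outC * opix * n, outC, opix,
                    false, true);
      if (pool) {
        const arma::ucube I = as<arma::ucube>(poolidx[l]);
        const arma::mat dP = dcur.slice(n);
        const arma::umat In = I.slice(n);
        for (std::size_t j = 0; j < dP.n_cols; ++j) {
          for (std::size_t c = 0; c < dP.n_rows; ++c) {
            dZn(c, In(c, j)) += dP(c, j);
          }
        }
      } else {
        dZn = dcur.slice(n);
      }
      // ReLU gate
      const arma::mat& Zn = Z.slice(n);
      for (std::size_t j = 0; j < opix; ++j) {
        for (int c = 0; c < outC; ++c) {
          if (Zn(c, j) <= 0) dZn(c, j) = 0;
        }
      }
    }

    arma::mat col(C * k * k, opix * N);
    for (int n = 0; n < N; ++n) {
      im2col_one(Ain.slice(n).memptr(), C, H, W, k, stride, pad, oH, oW,
                 col, opix * n);
    }
    dWs[l] = arma::mat(dZ * col.t());        // one GEMM
    dbs[l] = arma::vec(arma::sum(dZ, 1));

    if (l > 0) {
      arma::mat dcol = Wm.t() * dZ;          // one GEMM
      arma::cube dAin(C, (std::size_t)H * W, N, arma::fill::zeros);
      for (int n = 0; n < N; ++n) {
        col2im_one(dcol, opix * n, dAin.slice(n).memptr(), C, H, W, k,
                   stride, pad, oH, oW);
      }
      dcur = dAin;
    }
  }
  return List::create(_["dWs"] = dWs, _["dbs"] = dbs);
}

// Fused RMSprop step: one pass over the parameter array, returning the
// updated parameters and squared-gradient cache.
// [[Rcpp::export]]
List rmsprop_step(NumericVector p, NumericVector g, NumericVector c,
                  double lr, double rho, double eps) {
  const R_xlen_t n = p.size();
  NumericVector pn(n), cn(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double ci = rho * c[i] + (1.0 - rho) * g[i] * g[i];
    cn[i] = ci;
    pn[i] = p[i] - lr * g[i] / (std::sqrt(ci) + eps);
  }
  pn.attr("dim") = p.attr("dim");
  return List::create(_["p"] = pn, _["c"] = cn);
}
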