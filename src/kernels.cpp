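// Hot kernels for the small conv autoencoder: direct 3x3 same-padding
// convolution (forward and backward), 2x2 max pooling and
// nearest-neighbour x2 upsampling. Activations are C x (H*W*B) matrices,
// columns ordered position-fast (row-major spatial order) within each
// sample, so one spatial position is one contiguous column of channels.
// At these channel counts (1..32) direct loops beat im2col+GEMM because
// the 9x im2col blow-up is pure memory traffic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// weight layout: W_ is Cout x (9*C); column block k*C..k*C+C-1 holds the
// kernel tap k = 3*(dr+1) + (dc+1) for all input channels.
__attribute__((target_clones("avx2", "default")))
// [[Rcpp::export]]
arma::mat conv3_fwd(const arma::mat& A, const arma::mat& W_,
                    const arma::vec& b, int C, int H, int W, int B) {
  const int HW = H * W;
  const int Cout = W_.n_rows;
  arma::mat out(Cout, (size_t)HW * B);
  const double* bp = b.memptr();
  for (int bb = 0; bb < B; ++bb) {
    const size_t o = (size_t)bb * HW;
    for (int r = 0; r < H; ++r) {
      for (int c0 = 0; c0 < W; ++c0) {
        double* op = out.colptr(o + r * W + c0);
        for (int co = 0; co < Cout; ++co) op[co] = bp[co];
        for (int k = 0; k < 9; ++k) {
          const int sr = r + k / 3 - 1, sc = c0 + k % 3 - 1;
          if (sr < 0 || sr >= H || sc < 0 || sc >= W) continue;
          const double* ap = A.colptr(o + sr * W + sc);
          const double* wp = W_.colptr((size_t)k * C);
          for (int ci = 0; ci < C; ++ci) {
            const double va = ap[ci];
            const double* wc = wp + (size_t)ci * Cout;
            for (int co = 0; co < Cout; ++co) op[co] += wc[co] * va;
          }
        }
      }
    }
  }
  return out;
}

// returns dW (Cout x 9C) and dA (C x HW*B); db is computed in R
__attribute__((target_clones("avx2", "default")))
// [[Rcpp::export]]
List conv3_bwd(const arma::mat& A, const arma::mat& W_, const arma::mat& dY,
               int C, int H, int W, int B) {
  const int HW = H * W;
  const int Cout = W_.n_rows;
  arma::mat dW(Cout, 9 * C, arma::fill::zeros);
  arma::mat dA(C, (size_t)HW * B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    const size_t o = (size_t)bb * HW;
    for (int r = 0; r < H; ++r) {
      for (int c0 = 0; c0 < W; ++c0) {
        const double* dyp = dY.colptr(o + r * W + c0);
        for (int k = 0; k < 9; ++k) {
          const int sr = r + k / 3 - 1, sc = c0 + k % 3 - 1;
          if (sr < 0 || sr >= H || sc < 0 || sc >= W) continue;
          const size_t scol = o + sr * W + sc;
          const double* ap = A.colptr(scol);
          double* dap = dA.colptr(scol);
          const double* wp = W_.colptr((size_t)k * C);
          double* dwp = dW.colptr((size_t)k * C);
          for (int ci = 0; ci < C; ++ci) {
            const double va = ap[ci];
            const double* wc = wp + (size_t)ci * Cout;
            double* dwc = dwp + (size_t)ci * Cout;
            double s = 0.0;
            for (int co = 0; co < Cout; ++co) {
              const double dyv = dyp[co];
              s += wc[co] * dyv;
              dwc[co] += dyv * va;
            }
            dap[ci] += s;
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["dA"] = dA);
}

// 2x2 max pool; returns pooled values and 0-based linear argmax into A
// (ties routed to the first element in scan order, deterministically)
// [[Rcpp::export]]
List pool2_fwd(const arma::mat& A, int C, int H, int W, int B) {
  const int HW = H * W, oH = H / 2, oW = W / 2, oHW = oH * oW;
  arma::mat out(C, (size_t)oHW * B);
  IntegerMatrix arg(C, oHW * B);
  int* argp = arg.begin();
  for (int b = 0; b < B; ++b) {
    for (int orr = 0; orr < oH; ++orr) {
      for (int oc = 0; oc < oW; ++oc) {
        const size_t ocol = (size_t)b * oHW + orr * oW + oc;
        const size_t c00 = (size_t)b * HW + (2 * orr) * W + 2 * oc;
        const double* p0 = A.colptr(c00);
        const double* p1 = A.colptr(c00 + 1);
        const double* p2 = A.colptr(c00 + W);
        const double* p3 = A.colptr(c00 + W + 1);
        double* op = out.colptr(ocol);
        int* ap = argp + ocol * C;
        for (int i = 0; i < C; ++i) {
          double best = p0[i];
          size_t bj = c00;
          if (p1[i] > best) { best = p1[i]; bj = c00 + 1; }
          if (p2[i] > best) { best = p2[i]; bj = c00 + W; }
          if (p3[i] > best) { best = p3[i]; bj = c00 + W + 1; }
          op[i] = best;
          ap[i] = (int)(bj * C + i);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::mat pool2_bwd(const arma::mat& dY, const IntegerMatrix& arg,
                    int C, int n_in_cols) {
  arma::mat out(C, (size_t)n_in_cols, arma::fill::zeros);
  const double* dy = dY.memptr();
  const int* ap = arg.begin();
  double* o = out.memptr();
  const size_t n = dY.n_elem;
  for (size_t i = 0; i < n; ++i) o[ap[i]] += dy[i];
  return out;
}

// [[Rcpp::export]]
arma::mat up2_fwd(const arma::mat& A, int C, int H, int W, int B) {
  const int HW = H * W, oW = 2 * W, oHW = 4 * HW;
  arma::mat out(C, (size_t)oHW * B);
  for (int b = 0; b < B; ++b) {
    for (int r = 0; r < 2 * H; ++r) {
      for (int c0 = 0; c0 < oW; ++c0) {
        const double* s = A.colptr((size_t)b * HW + (r / 2) * W + c0 / 2);
        double* d = out.colptr((size_t)b * oHW + r * oW + c0);
        for (int i = 0; i < C; ++i) d[i] = s[i];
      }
    }
  }
  return out;
}

// H, W are the *input* (pre-upsampling) dims
// [[Rcpp::export]]
arma::mat up2_bwd(const arma::mat& dY, int C, int H, int W, int B) {
  const int HW = H * W, oW = 2 * W, oHW = 4 * HW;
  arma::mat out(C, (size_t)HW * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int r = 0; r < 2 * H; ++r) {
      for (int c0 = 0; c0 < oW; ++c0) {
        const double* s = dY.colptr((size_t)b * oHW + r * oW + c0);
        double* d = out.colptr((size_t)b * HW + (r / 2) * W + c0 / 2);
        for (int i = 0; i < C; ++i) d[i] += s[i];
      }
    }
  }
  return out;
}
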