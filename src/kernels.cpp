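#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, C, N), column-major.
// im2col lays out patches so that convolution becomes one GEMM done in R
// with the BLAS; col2im is its adjoint and accumulates overlapping writes.

static inline double at4(const NumericVector& x, int H, int W, int C,
                         int i, int j, int c, int n) {
  return x[i + (double)H * (j + (double)W * (c + (double)C * n))];
}

// [[Rcpp::export(name = ".cpp_im2col")]]
NumericMatrix cpp_im2col(NumericVector x, int kh, int kw, int padh, int padw) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int K = kh * kw * C;
  NumericMatrix out(K, (double)H * W * N);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const R_xlen_t col = i + (R_xlen_t)H * j + (R_xlen_t)H * W * n;
        R_xlen_t row = 0;
        for (int c = 0; c < C; ++c) {
          for (int dj = 0; dj < kw; ++dj) {
            const int jj = j + dj - padw;
            for (int di = 0; di < kh; ++di, ++row) {
              const int ii = i + di - padh;
              out[row + (R_xlen_t)K * col] =
                (ii >= 0 && ii < H && jj >= 0 && jj < W)
                  ? at4(x, H, W, C, ii, jj, c, n) : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_col2im")]]
NumericVector cpp_col2im(NumericMatrix dk, int H, int W, int C, int N,
                         int kh, int kw, int padh, int padw) {
  const int K = kh * kw * C;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const R_xlen_t col = i + (R_xlen_t)H * j + (R_xlen_t)H * W * n;
        R_xlen_t row = 0;
        for (int c = 0; c < C; ++c) {
          for (int dj = 0; dj < kw; ++dj) {
            const int jj = j + dj - padw;
            for (int di = 0; di < kh; ++di, ++row) {
              const int ii = i + di - padh;
              if (ii >= 0 && ii < H && jj >= 0 && jj < W)
                dx[ii + (R_xlen_t)H * (jj + (R_xlen_t)W * (c + (R_xlen_t)C * n))] +=
                  dk[row + (R_xlen_t)K * col];
            }
          }
        }
      }
    }
  }
  return dx;
}

// 2x2 max pooling with stride 2; ties go to the first element scanned
// (top-left), which keeps backward deterministic.
// [[Rcpp::export(name = ".cpp_maxpool_fw")]]
List cpp_maxpool_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);  // 0-based linear index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++p) {
          double best = R_NegInf; R_xlen_t bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const R_xlen_t q = (2 * i + di) +
                (R_xlen_t)H * ((2 * j + dj) + (R_xlen_t)W * (c + (R_xlen_t)C * n));
              if (x[q] > best) { best = x[q]; bi = q; }
            }
          y[i + (R_xlen_t)Ho * (j + (R_xlen_t)Wo * (c + (R_xlen_t)C * n))] = best;
          idx[i + (R_xlen_t)Ho * (j + (R_xlen_t)Wo * (c + (R_xlen_t)C * n))] = (int)bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bw")]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx,
                             int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t p = 0; p < dy.size(); ++p) dx[idx[p]] += dy[p];
  return dx;
}

// 8-connected component labelling of a binary matrix (BFS), labels 1..k.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second; q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
      }
    }
  return lab;
}
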