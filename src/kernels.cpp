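// Low-level numeric kernels for the 3D convolutional engine and the
// detection utilities.
//
// Array layout convention (shared with the R side): a multi-channel volume
// is a numeric vector representing an array of dim (C, D, H, W) in R's
// column-major order, i.e. element (c, z, y, x) lives at linear index
//   c + C*(z + D*(y + H*x))          (all indices 0-based here).
// Single-channel volumes use dim (D, H, W): z + D*(y + H*x).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outDim(int n, int stride) {
  // kernel 3, pad 1
  return (n + 2 - 3) / stride + 1;
}

// Unfold x (C,D,H,W) into a (C*27) x (Do*Ho*Wo) matrix for a 3x3x3 kernel
// with padding 1 and the given stride. Row order: c fastest, then kz, ky, kx.
static arma::mat im2col3(const double* x, int C, int D, int H, int W,
                         int stride, int Do, int Ho, int Wo) {
  const int K = C * 27;
  const int N = Do * Ho * Wo;
  arma::mat col(K, N, arma::fill::zeros);
  for (int xo = 0; xo < Wo; ++xo) {
    for (int yo = 0; yo < Ho; ++yo) {
      for (int zo = 0; zo < Do; ++zo) {
        const int n = zo + Do * (yo + Ho * xo);
        double* cptr = col.colptr(n);
        for (int kx = 0; kx < 3; ++kx) {
          const int xi = xo * stride + kx - 1;
          if (xi < 0 || xi >= W) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int yi = yo * stride + ky - 1;
            if (yi < 0 || yi >= H) continue;
            for (int kz = 0; kz < 3; ++kz) {
              const int zi = zo * stride + kz - 1;
              if (zi < 0 || zi >= D) continue;
              const double* src = x + C * (zi + D * (yi + H * xi));
              double* dst = cptr + C * (kz + 3 * (ky + 3 * kx));
              std::copy(src, src + C, dst);
            }
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add a (C*27) x N column matrix back onto a (C,D,H,W) volume.
static void col2im3(const arma::mat& col, double* dx, int C, int D, int H,
                    int W, int stride, int Do, int Ho, int Wo) {
  for (int xo = 0; xo < Wo; ++xo) {
    for (int yo = 0; yo < Ho; ++yo) {
      for (int zo = 0; zo < Do; ++zo) {
        const int n = zo + Do * (yo + Ho * xo);
        const double* cptr = col.colptr(n);
        for (int kx = 0; kx < 3; ++kx) {
          const int xi = xo * stride + kx - 1;
          if (xi < 0 || xi >= W) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int yi = yo * stride + ky - 1;
            if (yi < 0 || yi >= H) continue;
            for (int kz = 0; kz < 3; ++kz) {
              const int zi = zo * stride + kz - 1;
              if (zi < 0 || zi >= D) continue;
              double* dst = dx + C * (zi + D * (yi + H * xi));
              const double* src = cptr + C * (kz + 3 * (ky + 3 * kx));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// 3x3x3 convolution, padding 1. w is (Cout) x (Cin*27); b length Cout.
// [[Rcpp::export(name = ".conv3Forward")]]
NumericVector conv3Forward(NumericVector x, IntegerVector dims,
                           NumericMatrix w, NumericVector b, int stride) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int Cout = w.nrow();
  if (w.ncol() != C * 27) stop("weight/input channel mismatch");
  const int Do = outDim(D, stride), Ho = outDim(H, stride),
            Wo = outDim(W, stride);
  arma::mat col = im2col3(x.begin(), C, D, H, W, stride, Do, Ho, Wo);
  arma::mat wm(w.begin(), Cout, C * 27, false);
  arma::mat y = wm * col;
  y.each_col() += arma::vec(b.begin(), Cout);
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Cout, Do, Ho, Wo);
  return out;
}

// Gradients of conv3Forward. dy has dim (Cout, Do, Ho, Wo).
// For stride 1 the input gradient is itself a 3x3x3 correlation of dy with
// the channel-transposed, spatially flipped kernel, so it runs through
// im2col + GEMM instead of a scatter-add; the strided case falls back to
// col2im.
// [[Rcpp::export(name = ".conv3Backward")]]
List conv3Backward(NumericVector x, IntegerVector dims, NumericMatrix w,
                   NumericVector dy, int stride) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int Cout = w.nrow();
  const int Do = outDim(D, stride), Ho = outDim(H, stride),
            Wo = outDim(W, stride);
  const int N = Do * Ho * Wo;
  arma::mat col = im2col3(x.begin(), C, D, H, W, stride, Do, Ho, Wo);
  arma::mat dym(dy.begin(), Cout, N, false);
  arma::mat wm(w.begin(), Cout, C * 27, false);
  arma::mat dW = dym * col.t();
  arma::vec db = arma::sum(dym, 1);
  NumericVector dx(x.size());
  if (stride == 1) {
    // wt[(ci), (co, 26-k)] = w[co, (ci, k)]
    arma::mat wt(C, Cout * 27);
    for (int k = 0; k < 27; ++k) {
      for (int ci = 0; ci < C; ++ci) {
        for (int co = 0; co < Cout; ++co) {
          wt(ci, co + Cout * (26 - k)) = wm(co, ci + C * k);
        }
      }
    }
    arma::mat dycol = im2col3(dy.begin(), Cout, Do, Ho, Wo, 1, Do, Ho, Wo);
    arma::mat dxm = wt * dycol;
    std::copy(dxm.begin(), dxm.end(), dx.begin());
  } else {
    arma::mat dcol = wm.t() * dym;
    col2im3(dcol, dx.begin(), C, D, H, W, stride, Do, Ho, Wo);
  }
  dx.attr("dim") = dims;
  NumericMatrix dWout(Cout, C * 27, dW.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution, kernel 2, stride 2 (exact x2 upsampling).
// w is (Cout*8) x (Cin), row order: cout fastest, then kz, ky, kx.
// [[Rcpp::export(name = ".tconv2Forward")]]
NumericVector tconv2Forward(NumericVector x, IntegerVector dims,
                            NumericMatrix w, NumericVector b) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int Cout = w.nrow() / 8;
  if (w.ncol() != C) stop("weight/input channel mismatch");
  const int N = D * H * W;
  arma::mat xm(x.begin(), C, N, false);
  arma::mat wm(w.begin(), Cout * 8, C, false);
  arma::mat ym = wm * xm;  // (Cout*8) x N
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector out(Cout * Do * Ho * Wo);
  double* o = out.begin();
  for (int xi = 0; xi < W; ++xi) {
    for (int yi = 0; yi < H; ++yi) {
      for (int zi = 0; zi < D; ++zi) {
        const int n = zi + D * (yi + H * xi);
        const double* yc = ym.colptr(n);
        for (int kx = 0; kx < 2; ++kx) {
          for (int ky = 0; ky < 2; ++ky) {
            for (int kz = 0; kz < 2; ++kz) {
              double* dst = o + Cout * ((2 * zi + kz) +
                            Do * ((2 * yi + ky) + Ho * (2 * xi + kx)));
              const double* src = yc + Cout * (kz + 2 * (ky + 2 * kx));
              for (int c = 0; c < Cout; ++c) dst[c] = src[c] + b[c];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Cout, Do, Ho, Wo);
  return out;
}

// [[Rcpp::export(name = ".tconv2Backward")]]
List tconv2Backward(NumericVector x, IntegerVector dims, NumericMatrix w,
                    NumericVector dy) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int Cout = w.nrow() / 8;
  const int N = D * H * W;
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  arma::mat dym(Cout * 8, N);
  const double* dyp = dy.begin();
  arma::vec db(Cout, arma::fill::zeros);
  for (int xi = 0; xi < W; ++xi) {
    for (int yi = 0; yi < H; ++yi) {
      for (int zi = 0; zi < D; ++zi) {
        const int n = zi + D * (yi + H * xi);
        double* yc = dym.colptr(n);
        for (int kx = 0; kx < 2; ++kx) {
          for (int ky = 0; ky < 2; ++ky) {
            for (int kz = 0; kz < 2; ++kz) {
              const double* src = dyp + Cout * ((2 * zi + kz) +
                                  Do * ((2 * yi + ky) + Ho * (2 * xi + kx)));
              double* dst = yc + Cout * (kz + 2 * (ky + 2 * kx));
              for (int c = 0; c < Cout; ++c) {
                dst[c] = src[c];
                db[c] += src[c];
              }
            }
          }
        }
      }
    }
  }
  arma::mat xm(x.begin(), C, N, false);
  arma::mat wm(w.begin(), Cout * 8, C, false);
  arma::mat dW = dym * xm.t();
  arma::mat dxm = wm.t() * dym;
  NumericVector dx(dxm.begin(), dxm.end());
  dx.attr("dim") = dims;
  NumericMatrix dWout(Cout * 8, C, dW.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Strict local maxima over the 26-neighborhood of a (D,H,W) volume.
// A voxel qualifies when its value is strictly greater than every in-bounds
// neighbor and >= minScore. Returns 1-based (z,y,x) coords and scores,
// unsorted.
// [[Rcpp::export(name = ".localMaxima26")]]
List localMaxima26(NumericVector x, IntegerVector dims, double minScore) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const double* p = x.begin();
  std::vector<int> zs, ys, xs;
  std::vector<double> sc;
  for (int xi = 0; xi < W; ++xi) {
    for (int yi = 0; yi < H; ++yi) {
      for (int zi = 0; zi < D; ++zi) {
        const double v = p[zi + D * (yi + H * xi)];
        if (v < minScore) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx) {
          const int xn = xi + dx;
          if (xn < 0 || xn >= W) continue;
          for (int dy = -1; dy <= 1 && ismax; ++dy) {
            const int yn = yi + dy;
            if (yn < 0 || yn >= H) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int zn = zi + dz;
              if (zn < 0 || zn >= D) continue;
              if (p[zn + D * (yn + H * xn)] >= v) { ismax = false; break; }
            }
          }
        }
        if (ismax) {
          zs.push_back(zi + 1); ys.push_back(yi + 1); xs.push_back(xi + 1);
          sc.push_back(v);
        }
      }
    }
  }
  return List::create(_["z"] = wrap(zs), _["y"] = wrap(ys), _["x"] = wrap(xs),
                      _["score"] = wrap(sc));
}

// 26-connected component labelling of a binary (D,H,W) volume.
// Returns an integer volume: 0 background, 1..n component ids.
// [[Rcpp::export(name = ".labelComponents26")]]
IntegerVector labelComponents26(IntegerVector mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int n = D * H * W;
  IntegerVector lab(n, 0);
  const int* m = mask.begin();
  int nextLab = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (m[i] == 0 || lab[i] != 0) continue;
    ++nextLab;
    stack.push_back(i);
    lab[i] = nextLab;
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int zi = cur % D;
      const int yi = (cur / D) % H;
      const int xi = cur / (D * H);
      for (int dx = -1; dx <= 1; ++dx) {
        const int xn = xi + dx;
        if (xn < 0 || xn >= W) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yn = yi + dy;
          if (yn < 0 || yn >= H) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            const int zn = zi + dz;
            if (zn < 0 || zn >= D) continue;
            const int j = zn + D * (yn + H * xn);
            if (m[j] != 0 && lab[j] == 0) {
              lab[j] = nextLab;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
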