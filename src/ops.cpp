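// Network primitives. Activations live as float32 tensors owned by C++
// (handed through R as external pointers) so the hot path never converts
// to double; parameters are double on the R side with float mirrors.
// Convolutions use im2col + GEMM on the system BLAS, batched over images.
// Tensor layout is (H, W, C, N) column-major.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Buffer recycling: tensor sizes repeat every training iteration, so both
// the result tensors and the GEMM workspaces come from size-keyed pools to
// avoid continual large-allocation page faults.
static std::multimap<size_t, arma::fvec>& tensor_pool() {
  static std::multimap<size_t, arma::fvec> pool;
  return pool;
}
static size_t pool_bytes = 0;
static const size_t POOL_CAP = (size_t)1 << 30;

static void pool_return(arma::fvec&& v) {
  size_t bytes = v.n_elem * sizeof(float);
  if (bytes == 0 || pool_bytes + bytes > POOL_CAP) return;
  pool_bytes += bytes;
  tensor_pool().insert(std::make_pair(v.n_elem, std::move(v)));
}

static arma::fvec pool_take(size_t n) {
  auto& pool = tensor_pool();
  auto it = pool.find(n);
  if (it != pool.end()) {
    arma::fvec out = std::move(it->second);
    pool_bytes -= n * sizeof(float);
    pool.erase(it);
    return out;
  }
  return arma::fvec(n, arma::fill::none);
}

struct FTensor {
  arma::fvec data;
  int d[4];
  size_t numel() const { return (size_t)d[0] * d[1] * d[2] * d[3]; }
  ~FTensor() { pool_return(std::move(data)); }
};

typedef XPtr<FTensor> FT;

static FT make_ft(int h, int w, int c, int n, bool zero = false) {
  FTensor* t = new FTensor();
  t->d[0] = h; t->d[1] = w; t->d[2] = c; t->d[3] = n;
  t->data = pool_take((size_t)h * w * c * n);
  if (zero) t->data.zeros();
  return FT(t, true);
}

// persistent GEMM workspaces (single-threaded R); callers wrap the raw
// buffer in a non-owning arma::fmat view of the shape they need
static float* scratch_buf(int which, size_t n) {
  static arma::fvec bufs[3];
  if (bufs[which].n_elem < n) bufs[which].set_size(n);
  return bufs[which].memptr();
}

// [[Rcpp::export]]
SEXP ft_upload(NumericVector x) {
  IntegerVector d0 = x.hasAttribute("dim") ? as<IntegerVector>(x.attr("dim"))
                                           : IntegerVector::create((int)x.size());
  int d[4] = {1, 1, 1, 1};
  for (int i = 0; i < d0.size() && i < 4; ++i) d[i] = d0[i];
  FT t = make_ft(d[0], d[1], d[2], d[3]);
  const double* xp = REAL(x);
  float* f = t->data.memptr();
  size_t n = t->numel();
  for (size_t i = 0; i < n; ++i) f[i] = (float)xp[i];
  return t;
}

// [[Rcpp::export]]
NumericVector ft_download(SEXP xp) {
  FT t(xp);
  size_t n = t->numel();
  NumericVector out(n);
  const float* f = t->data.memptr();
  double* o = REAL(out);
  for (size_t i = 0; i < n; ++i) o[i] = (double)f[i];
  out.attr("dim") = IntegerVector::create(t->d[0], t->d[1], t->d[2], t->d[3]);
  return out;
}

// [[Rcpp::export]]
IntegerVector ft_dim(SEXP xp) {
  FT t(xp);
  return IntegerVector::create(t->d[0], t->d[1], t->d[2], t->d[3]);
}

// [[Rcpp::export]]
SEXP ft_add(SEXP ap, SEXP bp) {
  FT a(ap), b(bp);
  FT y = make_ft(a->d[0], a->d[1], a->d[2], a->d[3]);
  y->data = a->data + b->data;
  return y;
}

// [[Rcpp::export]]
SEXP ft_concat(SEXP ap, SEXP bp) {
  FT a(ap), b(bp);
  int H = a->d[0], W = a->d[1], Ca = a->d[2], N = a->d[3], Cb = b->d[2];
  FT y = make_ft(H, W, Ca + Cb, N);
  size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    std::copy(a->data.memptr() + hw * Ca * n, a->data.memptr() + hw * Ca * (n + 1),
              y->data.memptr() + hw * (Ca + Cb) * n);
    std::copy(b->data.memptr() + hw * Cb * n, b->data.memptr() + hw * Cb * (n + 1),
              y->data.memptr() + hw * (Ca + Cb) * n + hw * Ca);
  }
  return y;
}

// [[Rcpp::export]]
List ft_split(SEXP gp, int ca) {
  FT g(gp);
  int H = g->d[0], W = g->d[1], C = g->d[2], N = g->d[3], cb = C - ca;
  FT ga = make_ft(H, W, ca, N), gb = make_ft(H, W, cb, N);
  size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    std::copy(g->data.memptr() + hw * C * n, g->data.memptr() + hw * C * n + hw * ca,
              ga->data.memptr() + hw * ca * n);
    std::copy(g->data.memptr() + hw * C * n + hw * ca,
              g->data.memptr() + hw * C * (n + 1),
              gb->data.memptr() + hw * cb * n);
  }
  return List::create(_["a"] = (SEXP)ga, _["b"] = (SEXP)gb);
}

// Fill one image's rows of the im2col matrix, laid out (N*Ho*Wo x K*K*Cin).
// Every entry of the slab is written exactly once (padding written as 0).
static void im2col(const float* x, int H, int W, int Cin, int K, int stride,
                   int padT, int padL, int Ho, int Wo, arma::fmat& cols,
                   size_t row0) {
  for (int ci = 0; ci < Cin; ++ci) {
    const float* xc = x + (size_t)H * W * ci;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        float* col = cols.colptr(ki + K * (kj + K * ci)) + row0;
        for (int jo = 0; jo < Wo; ++jo) {
          float* dst = col + (size_t)Ho * jo;
          int jj = jo * stride - padL + kj;
          if (jj < 0 || jj >= W) { std::fill(dst, dst + Ho, 0.0f); continue; }
          const float* xcol = xc + (size_t)H * jj;
          int io0 = 0, io1 = Ho;
          while (io0 < Ho && io0 * stride - padT + ki < 0) ++io0;
          while (io1 > io0 && (io1 - 1) * stride - padT + ki >= H) --io1;
          std::fill(dst, dst + io0, 0.0f);
          for (int io = io0; io < io1; ++io)
            dst[io] = xcol[io * stride - padT + ki];
          std::fill(dst + io1, dst + Ho, 0.0f);
        }
      }
    }
  }
}

static void col2im(const arma::fmat& cols, int H, int W, int Cin, int K,
                   int stride, int padT, int padL, int Ho, int Wo, float* gx,
                   size_t row0) {
  for (int ci = 0; ci < Cin; ++ci) {
    float* xc = gx + (size_t)H * W * ci;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const float* col = cols.colptr(ki + K * (kj + K * ci)) + row0;
        for (int jo = 0; jo < Wo; ++jo) {
          int jj = jo * stride - padL + kj;
          if (jj < 0 || jj >= W) continue;
          float* xcol = xc + (size_t)H * jj;
          const float* src = col + (size_t)Ho * jo;
          int io0 = 0, io1 = Ho;
          while (io0 < Ho && io0 * stride - padT + ki < 0) ++io0;
          while (io1 > io0 && (io1 - 1) * stride - padT + ki >= H) --io1;
          for (int io = io0; io < io1; ++io)
            xcol[io * stride - padT + ki] += src[io];
        }
      }
    }
  }
}

// [[Rcpp::export]]
SEXP ft_conv_fwd(SEXP xp, SEXP wfp, NumericVector b, int stride,
                 int padT, int padB, int padL, int padR) {
  FT x(xp), wf(wfp);
  int H = x->d[0], W = x->d[1], Cin = x->d[2], N = x->d[3];
  int K = wf->d[0], Cout = wf->d[3];
  if (wf->d[2] != Cin) stop("conv: weight/input channel mismatch");
  int Ho = (H + padT + padB - K) / stride + 1;
  int Wo = (W + padL + padR - K) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv: output size would be empty");
  size_t hw = (size_t)Ho * Wo;

  arma::fmat Wmat(wf->data.memptr(), (size_t)K * K * Cin, Cout, false);
  size_t kkc = (size_t)K * K * Cin;
  arma::fmat cols(scratch_buf(0, hw * N * kkc), hw * N, kkc, false, true);
  for (int n = 0; n < N; ++n)
    im2col(x->data.memptr() + (size_t)H * W * Cin * n, H, W, Cin, K, stride,
           padT, padL, Ho, Wo, cols, hw * n);
  arma::fmat Yall(scratch_buf(1, hw * N * Cout), hw * N, Cout, false, true);
  Yall = cols * Wmat;
  FT y = make_ft(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const float* src = Yall.colptr(co) + hw * n;
      float* dst = y->data.memptr() + hw * Cout * n + hw * co;
      float bias = (float)b[co];
      for (size_t q = 0; q < hw; ++q) dst[q] = src[q] + bias;
    }
  return y;
}

// [[Rcpp::export]]
List ft_conv_bwd(SEXP xp, SEXP wfp, SEXP gyp, int stride,
                 int padT, int padB, int padL, int padR,
                 bool need_gx, bool need_gw) {
  FT x(xp), wf(wfp), gy(gyp);
  int H = x->d[0], W = x->d[1], Cin = x->d[2], N = x->d[3];
  int K = wf->d[0], Cout = wf->d[3];
  int Ho = gy->d[0], Wo = gy->d[1];
  size_t hw = (size_t)Ho * Wo;
  arma::fmat Wmat(wf->data.memptr(), (size_t)K * K * Cin, Cout, false);

  arma::fmat Gall(scratch_buf(2, hw * N * Cout), hw * N, Cout, false, true);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      std::copy(gy->data.memptr() + hw * Cout * n + hw * co,
                gy->data.memptr() + hw * Cout * n + hw * (co + 1),
                Gall.colptr(co) + hw * n);

  List out = List::create(_["gw"] = R_NilValue, _["gb"] = R_NilValue,
                          _["gx"] = R_NilValue);
  size_t kkc = (size_t)K * K * Cin;
  if (need_gw) {
    arma::fmat cols(scratch_buf(0, hw * N * kkc), hw * N, kkc, false, true);
    for (int n = 0; n < N; ++n)
      im2col(x->data.memptr() + (size_t)H * W * Cin * n, H, W, Cin, K, stride,
             padT, padL, Ho, Wo, cols, hw * n);
    arma::fmat gW = cols.t() * Gall;
    arma::frowvec gbf = arma::sum(Gall, 0);
    NumericVector gw((R_xlen_t)((size_t)K * K * Cin * Cout));
    double* gwp = REAL(gw);
    const float* gf = gW.memptr();
    for (size_t i = 0; i < gW.n_elem; ++i) gwp[i] = (double)gf[i];
    gw.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
    NumericVector gb(Cout);
    for (int co = 0; co < Cout; ++co) gb[co] = (double)gbf[co];
    out["gw"] = gw; out["gb"] = gb;
  }
  if (need_gx) {
    FT gx = make_ft(H, W, Cin, N, true);
    arma::fmat gcols(scratch_buf(0, hw * N * kkc), hw * N, kkc, false, true);
    gcols = Gall * Wmat.t();
    for (int n = 0; n < N; ++n)
      col2im(gcols, H, W, Cin, K, stride, padT, padL, Ho, Wo,
             gx->data.memptr() + (size_t)H * W * Cin * n, hw * n);
    out["gx"] = (SEXP)gx;
  }
  return out;
}

// Transpose convolution, kernel 2x2, stride 2. Weight layout
// (2, 2, Cin, Cout): y(2i+a, 2j+b, co) = sum_ci x(i, j, ci) w(a, b, ci, co).
static arma::fmat tconv_wmat(const FTensor* wf) {
  int Cin = wf->d[2], Cout = wf->d[3];
  arma::fmat Wmat2(Cin, 4 * Cout);
  const float* w = wf->data.memptr();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int bb = 0; bb < 2; ++bb)
        for (int aa = 0; aa < 2; ++aa)
          Wmat2(ci, aa + 2 * bb + 4 * co) =
            w[aa + 2 * (bb + 2 * ((size_t)ci + (size_t)Cin * co))];
  return Wmat2;
}

// [[Rcpp::export]]
SEXP ft_tconv_fwd(SEXP xp, SEXP wfp, NumericVector b) {
  FT x(xp), wf(wfp);
  int H = x->d[0], W = x->d[1], Cin = x->d[2], N = x->d[3], Cout = wf->d[3];
  arma::fmat Wmat2 = tconv_wmat(wf);
  int H2 = 2 * H, W2 = 2 * W;
  FT y = make_ft(H2, W2, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::fmat Xn(x->data.memptr() + (size_t)H * W * Cin * n,
                  (size_t)H * W, Cin, false);
    arma::fmat Yn = Xn * Wmat2;
    float* yp = y->data.memptr() + (size_t)H2 * W2 * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      float bias = (float)b[co];
      for (int bb = 0; bb < 2; ++bb)
        for (int aa = 0; aa < 2; ++aa) {
          const float* yn = Yn.colptr(aa + 2 * bb + 4 * co);
          for (int j = 0; j < W; ++j) {
            float* dst = yp + (size_t)H2 * W2 * co + (size_t)H2 * (2 * j + bb) + aa;
            const float* src = yn + (size_t)H * j;
            for (int i = 0; i < H; ++i) dst[2 * i] = src[i] + bias;
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List ft_tconv_bwd(SEXP xp, SEXP wfp, SEXP gyp, bool need_gx) {
  FT x(xp), wf(wfp), gy(gyp);
  int H = x->d[0], W = x->d[1], Cin = x->d[2], N = x->d[3], Cout = wf->d[3];
  int H2 = 2 * H, W2 = 2 * W, K = 2;
  arma::fmat Wmat2 = tconv_wmat(wf);
  arma::fmat gWmat2(Cin, 4 * Cout, arma::fill::zeros);
  arma::fvec gbf(Cout, arma::fill::zeros);
  FT gx(new FTensor(), true);
  if (need_gx) {
    gx->d[0] = H; gx->d[1] = W; gx->d[2] = Cin; gx->d[3] = N;
    gx->data.set_size((size_t)H * W * Cin * N);
  }
  arma::fmat G4((size_t)H * W, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const float* gp = gy->data.memptr() + (size_t)H2 * W2 * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      for (int bb = 0; bb < 2; ++bb)
        for (int aa = 0; aa < 2; ++aa) {
          float* g4 = G4.colptr(aa + 2 * bb + 4 * co);
          for (int j = 0; j < W; ++j) {
            const float* src = gp + (size_t)H2 * W2 * co + (size_t)H2 * (2 * j + bb) + aa;
            float* dst = g4 + (size_t)H * j;
            for (int i = 0; i < H; ++i) dst[i] = src[2 * i];
          }
        }
      gbf[co] += arma::accu(G4.cols(4 * co, 4 * co + 3));
    }
    arma::fmat Xn(x->data.memptr() + (size_t)H * W * Cin * n,
                  (size_t)H * W, Cin, false);
    gWmat2 += Xn.t() * G4;
    if (need_gx) {
      arma::fmat GXn(gx->data.memptr() + (size_t)H * W * Cin * n,
                     (size_t)H * W, Cin, false, true);
      GXn = G4 * Wmat2.t();
    }
  }
  NumericVector gw((R_xlen_t)((size_t)K * K * Cin * Cout));
  double* gwp = REAL(gw);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int bb = 0; bb < 2; ++bb)
        for (int aa = 0; aa < 2; ++aa)
          gwp[aa + 2 * (bb + 2 * ((size_t)ci + (size_t)Cin * co))] =
            (double)gWmat2(ci, aa + 2 * bb + 4 * co);
  gw.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) gb[co] = (double)gbf[co];
  List out = List::create(_["gw"] = gw, _["gb"] = gb, _["gx"] = R_NilValue);
  if (need_gx) out["gx"] = (SEXP)gx;
  return out;
}

// [[Rcpp::export]]
List ft_maxpool_fwd(SEXP xp) {
  FT x(xp);
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  if (H % 2 || W % 2) stop("maxpool: spatial dims must be even");
  int Ho = H / 2, Wo = W / 2;
  FT y = make_ft(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)((size_t)Ho * Wo * C * N));
  const float* xp_ = x->data.memptr();
  float* yp = y->data.memptr();
  int* ip = INTEGER(idx);
  size_t q = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const float* xc = xp_ + (size_t)H * W * cn;
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io, ++q) {
        float best = -HUGE_VALF; int barg = 0;
        for (int bb = 0; bb < 2; ++bb)
          for (int aa = 0; aa < 2; ++aa) {
            float v = xc[(2 * io + aa) + (size_t)H * (2 * jo + bb)];
            if (v > best) { best = v; barg = aa + 2 * bb; }
          }
        yp[q] = best; ip[q] = barg;
      }
  }
  return List::create(_["y"] = (SEXP)y, _["idx"] = idx);
}

// [[Rcpp::export]]
SEXP ft_maxpool_bwd(SEXP gyp, IntegerVector idx) {
  FT gy(gyp);
  int Ho = gy->d[0], Wo = gy->d[1], C = gy->d[2], N = gy->d[3];
  int H = 2 * Ho, W = 2 * Wo;
  FT gx = make_ft(H, W, C, N, true);
  const float* gp = gy->data.memptr();
  const int* ip = INTEGER(idx);
  float* xp = gx->data.memptr();
  size_t q = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    float* xc = xp + (size_t)H * W * cn;
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io, ++q)
        xc[(2 * io + ip[q] % 2) + (size_t)H * (2 * jo + ip[q] / 2)] += gp[q];
  }
  return gx;
}

// Fused batchnorm + (leaky) ReLU forward. slope < 0 means "no activation".
// Training mode uses batch statistics and updates the double running
// stats in place; eval mode reads them. Statistics accumulate in double.
// [[Rcpp::export]]
List ft_bnact_fwd(SEXP xp, NumericVector gamma, NumericVector beta,
                  NumericVector rmean, NumericVector rvar, double momentum,
                  double eps, bool train, double slope) {
  FT x(xp);
  int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  size_t hw = (size_t)H * W;
  double m = (double)hw * N;
  const float* xf = x->data.memptr();
  std::vector<double> mu(C), va(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (int n = 0; n < N; ++n) {
        const float* p = xf + hw * (c + (size_t)C * n);
        for (size_t q = 0; q < hw; ++q) s += p[q];
      }
      mu[c] = s / m;
    }
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (int n = 0; n < N; ++n) {
        const float* p = xf + hw * (c + (size_t)C * n);
        for (size_t q = 0; q < hw; ++q) {
          double u = p[q] - mu[c]; s += u * u;
        }
      }
      va[c] = s / m;
      rmean[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      rvar[c] = (1 - momentum) * rvar[c] + momentum * va[c];
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = rmean[c]; va[c] = rvar[c]; }
  }
  FT out = make_ft(H, W, C, N);
  FT xhat = make_ft(H, W, C, N);
  NumericVector invstd(C);
  float* op = out->data.memptr();
  float* xh = xhat->data.memptr();
  bool act = slope >= 0;
  float sl = (float)slope;
  for (int c = 0; c < C; ++c) {
    double is = 1.0 / std::sqrt(va[c] + eps);
    invstd[c] = is;
    float isf = (float)is, g = (float)gamma[c], b = (float)beta[c],
          mc = (float)mu[c];
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)C * n);
      for (size_t q = 0; q < hw; ++q) {
        float u = (xf[off + q] - mc) * isf;
        xh[off + q] = u;
        float v = g * u + b;
        if (act && v < 0) v *= sl;
        op[off + q] = v;
      }
    }
  }
  return List::create(_["out"] = (SEXP)out, _["xhat"] = (SEXP)xhat,
                      _["invstd"] = invstd);
}

// Fused backward of (leaky) ReLU + batchnorm. `out` is the forward
// activation output (its sign gives the ReLU mask, valid for any positive
// slope); slope < 0 means no activation was applied.
// [[Rcpp::export]]
List ft_bnact_bwd(SEXP outp, SEXP xhatp, NumericVector invstd,
                  NumericVector gamma, SEXP gyp, double slope, bool train) {
  FT out(outp), xhat(xhatp), gy(gyp);
  int H = gy->d[0], W = gy->d[1], C = gy->d[2], N = gy->d[3];
  size_t hw = (size_t)H * W;
  double m = (double)hw * N;
  const float* op = out->data.memptr();
  const float* xh = xhat->data.memptr();
  const float* gp = gy->data.memptr();
  FT gx = make_ft(H, W, C, N);
  float* gxp = gx->data.memptr();
  NumericVector ggamma(C), gbeta(C);
  bool act = slope >= 0;
  float sl = (float)slope;
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)C * n);
      for (size_t q = 0; q < hw; ++q) {
        float g = gp[off + q];
        if (act && op[off + q] <= 0) g *= sl;
        gxp[off + q] = g;  // stash the post-activation gradient
        s1 += g; s2 += (double)g * xh[off + q];
      }
    }
    gbeta[c] = s1; ggamma[c] = s2;
    double gis = gamma[c] * invstd[c];
    if (train) {
      float a1 = (float)gis, a2 = (float)(gis / m);
      float f1 = (float)s1, f2 = (float)s2;
      for (int n = 0; n < N; ++n) {
        size_t off = hw * (c + (size_t)C * n);
        for (size_t q = 0; q < hw; ++q)
          gxp[off + q] = a1 * gxp[off + q] - a2 * (f1 + xh[off + q] * f2);
      }
    } else {
      float a1 = (float)gis;
      for (int n = 0; n < N; ++n) {
        size_t off = hw * (c + (size_t)C * n);
        for (size_t q = 0; q < hw; ++q) gxp[off + q] *= a1;
      }
    }
  }
  return List::create(_["gx"] = (SEXP)gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// Standalone (leaky) ReLU for layers without normalization.
// [[Rcpp::export]]
SEXP ft_act_fwd(SEXP xp, double slope) {
  FT x(xp);
  FT y = make_ft(x->d[0], x->d[1], x->d[2], x->d[3]);
  const float* a = x->data.memptr();
  float* b = y->data.memptr();
  float sl = (float)slope;
  size_t n = x->numel();
  for (size_t i = 0; i < n; ++i) b[i] = a[i] > 0 ? a[i] : sl * a[i];
  return y;
}

// [[Rcpp::export]]
SEXP ft_act_bwd(SEXP prep, SEXP gyp, double slope) {
  FT pre(prep), gy(gyp);
  FT g = make_ft(gy->d[0], gy->d[1], gy->d[2], gy->d[3]);
  const float* p = pre->data.memptr();
  const float* gp = gy->data.memptr();
  float* go = g->data.memptr();
  float sl = (float)slope;
  size_t n = gy->numel();
  for (size_t i = 0; i < n; ++i) go[i] = p[i] > 0 ? gp[i] : sl * gp[i];
  return g;
}

// In-place Adam update on double vectors (par, m, v modified).
// [[Rcpp::export]]
void cpp_adam_step(NumericVector par, NumericVector g, NumericVector m,
                   NumericVector v, int t, double lr, double beta1,
                   double beta2, double eps) {
  double* p = REAL(par); const double* gp = REAL(g);
  double* mp = REAL(m); double* vp = REAL(v);
  double bc1 = 1.0 - std::pow(beta1, (double)t);
  double bc2 = 1.0 - std::pow(beta2, (double)t);
  R_xlen_t n = par.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
    p[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}
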