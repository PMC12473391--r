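// Hot numerical kernels for the batched network engine: fused 1D
// convolution + batch norm + ReLU (shifted-GEMM accumulation over kernel
// taps, float32 internals - the customary deep-learning precision), max
// pooling, and batched scaled dot-product attention. Tensors arrive as
// (L*B x C) matrices, samples stacked along rows with the time index
// fastest (column-major R layout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

extern "C" {
  void sgemm_(const char* transa, const char* transb, const int* m,
              const int* n, const int* k, const float* alpha,
              const float* a, const int* lda, const float* b,
              const int* ldb, const float* beta, float* c, const int* ldc);
}

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

// copy (L*B x C) sample-stacked matrix into per-sample zero-padded layout
// (Lp*B x C), data at offset `at` within each padded block, Lp = L + k - 1
static arma::fmat padSamples(const arma::fmat& X, int L, int B, int k,
                             int at) {
  const int Lp = L + k - 1, C = X.n_cols;
  arma::fmat Xp((size_t) Lp * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    float* dst = Xp.colptr(c);
    for (int b = 0; b < B; ++b)
      std::copy(src + (size_t) b * L, src + (size_t) (b + 1) * L,
                dst + (size_t) b * Lp + at);
  }
  return Xp;
}

// kernel array arrives as (k*cin x cout) with tap fastest (R array
// (k, cin, cout)); rearrange to k stacked (cin x cout) blocks so block o
// is addressable as pointer offset o*cin with column stride k*cin
static arma::fmat rearrangeW(const arma::mat& Win, int k, int cin,
                             int cout) {
  arma::fmat W((size_t) k * cin, cout);
  for (int c = 0; c < cout; ++c)
    for (int ci = 0; ci < cin; ++ci)
      for (int o = 0; o < k; ++o)
        W((size_t) o * cin + ci, c) = (float) Win((size_t) ci * k + o, c);
  return W;
}

// [[Rcpp::export(name = ".convBnReluForwardC")]]
List convBnReluForwardC(const arma::mat& Xin, const arma::mat& Win,
                        const arma::vec& b, const arma::vec& gamma,
                        const arma::vec& beta, const arma::vec& runMean,
                        const arma::vec& runVar, int L, int B, int k,
                        int padL, bool training, double count,
                        double eps, bool wantCache) {
  const int cin = Xin.n_cols, cout = Win.n_cols;
  const arma::fmat X = arma::conv_to<arma::fmat>::from(Xin);
  const arma::fmat W = rearrangeW(Win, k, cin, cout);
  const arma::fmat Xp = padSamples(X, L, B, k, padL);
  const int Lp = L + k - 1;
  const int LpB = Lp * B, kcin = k * cin;
  const int nv = LpB - (k - 1);
  const int N = L * B;

  // per-offset accumulation: Ybig(r) += Xp(r + o) * W_o, no copies
  arma::fmat Ybig(LpB, cout, arma::fill::zeros);
  for (int o = 0; o < k; ++o)
    sgemm('N', 'N', nv, cout, cin, 1.0f,
          Xp.memptr() + o, LpB, W.memptr() + (size_t) o * cin, kcin,
          1.0f, Ybig.memptr(), LpB);

  arma::fmat Y(N, cout);
  for (int c = 0; c < cout; ++c) {
    const float* src = Ybig.colptr(c);
    float* dst = Y.colptr(c);
    for (int s = 0; s < B; ++s)
      std::copy(src + (size_t) s * Lp, src + (size_t) s * Lp + L,
                dst + (size_t) s * L);
  }

  arma::vec mu(cout), var(cout), newMean(cout), newVar(cout);
  if (training) {
    for (int c = 0; c < cout; ++c) {
      const float* y = Y.colptr(c);
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += y[i];
      double m = s / N + b(c);
      double s2 = 0.0;
      for (int i = 0; i < N; ++i) {
        double d = y[i] + b(c) - m;
        s2 += d * d;
      }
      mu(c) = m;
      var(c) = s2 / N;
      // cumulative average of batch statistics: exact after any number of
      // updates, unlike a fixed-momentum EMA that needs hundreds of batches
      newMean(c) = (runMean(c) * count + mu(c)) / (count + 1);
      newVar(c) = (runVar(c) * count + var(c)) / (count + 1);
    }
  } else {
    mu = runMean; var = runVar; newMean = runMean; newVar = runVar;
  }
  arma::vec invstd = 1.0 / arma::sqrt(var + eps);
  arma::fmat xhat(wantCache ? N : 0, wantCache ? cout : 0);
  arma::fmat act(N, cout);
  for (int c = 0; c < cout; ++c) {
    const float bc = (float) b(c), m = (float) mu(c);
    const float is = (float) invstd(c);
    const float g = (float) gamma(c), be = (float) beta(c);
    const float* y = Y.colptr(c);
    float* a = act.colptr(c);
    if (wantCache) {
      float* xh = xhat.colptr(c);
      for (int i = 0; i < N; ++i) {
        xh[i] = (y[i] + bc - m) * is;
        float v = g * xh[i] + be;
        a[i] = v > 0.0f ? v : 0.0f;
      }
    } else {
      for (int i = 0; i < N; ++i) {
        float v = g * (y[i] + bc - m) * is + be;
        a[i] = v > 0.0f ? v : 0.0f;
      }
    }
  }
  return List::create(
    _["act"] = act, _["xhat"] = xhat, _["invstd"] = invstd,
    _["newMean"] = newMean, _["newVar"] = newVar);
}

// [[Rcpp::export(name = ".convBnReluBackwardC")]]
List convBnReluBackwardC(const arma::mat& dYin, const arma::mat& actIn,
                         const arma::mat& xhatIn,
                         const arma::vec& invstd, const arma::vec& gamma,
                         const arma::mat& Xin, const arma::mat& Win,
                         int L, int B, int k, int padL, bool training) {
  const arma::fmat act = arma::conv_to<arma::fmat>::from(actIn);
  const arma::fmat xhat = arma::conv_to<arma::fmat>::from(xhatIn);
  const arma::fmat X = arma::conv_to<arma::fmat>::from(Xin);
  const int cin = Xin.n_cols, cout = Win.n_cols;
  const arma::fmat W = rearrangeW(Win, k, cin, cout);
  arma::fmat dA = arma::conv_to<arma::fmat>::from(dYin);
  const int N = L * B;

  // ReLU and batch-norm backward, fused per channel
  arma::vec dGamma(cout), dBeta(cout);
  arma::fmat dYm(N, cout);
  for (int c = 0; c < cout; ++c) {
    float* da = dA.colptr(c);
    const float* a = act.colptr(c);
    const float* xh = xhat.colptr(c);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < N; ++i) {
      if (a[i] <= 0.0f) da[i] = 0.0f;
      sg += (double) da[i] * xh[i];
      sb += da[i];
    }
    dGamma(c) = sg; dBeta(c) = sb;
    const float g = (float) gamma(c), is = (float) invstd(c);
    float* dy = dYm.colptr(c);
    if (training) {
      const float mg = (float) (sb / N) * g;
      const float mgx = (float) (sg / N) * g;
      for (int i = 0; i < N; ++i)
        dy[i] = is * (g * da[i] - mg - xh[i] * mgx);
    } else {
      for (int i = 0; i < N; ++i) dy[i] = is * g * da[i];
    }
  }

  // padded layouts; zero pad rows make cross-sample contributions vanish
  const int Lp = L + k - 1;
  const int LpB = Lp * B, kcin = k * cin;
  const int nv = LpB - (k - 1);
  const arma::fmat Xp = padSamples(X, L, B, k, padL);
  const arma::fmat dYp = padSamples(dYm, L, B, k, padL);

  // dXbig(o + r) += dYp(padL + r) * W_o'   and
  // dW_o += Xp(o + r)' * dYp(padL + r), accumulated over r in [0, nv)
  arma::fmat dXbig(LpB, cin, arma::fill::zeros);
  arma::fmat dWr((size_t) k * cin, cout, arma::fill::zeros);
  for (int o = 0; o < k; ++o) {
    sgemm('N', 'T', nv, cin, cout, 1.0f,
          dYp.memptr() + padL, LpB, W.memptr() + (size_t) o * cin, kcin,
          1.0f, dXbig.memptr() + o, LpB);
    sgemm('T', 'N', cin, cout, nv, 1.0f,
          Xp.memptr() + o, LpB, dYp.memptr() + padL, LpB,
          1.0f, dWr.memptr() + (size_t) o * cin, kcin);
  }
  arma::fmat dX(N, cin);
  for (int c = 0; c < cin; ++c) {
    const float* src = dXbig.colptr(c);
    float* dst = dX.colptr(c);
    for (int s = 0; s < B; ++s)
      std::copy(src + (size_t) s * Lp + padL,
                src + (size_t) s * Lp + padL + L, dst + (size_t) s * L);
  }
  // un-rearrange dW back to the R kernel-array layout (tap fastest)
  arma::mat dWout((size_t) k * cin, cout);
  for (int c = 0; c < cout; ++c)
    for (int ci = 0; ci < cin; ++ci)
      for (int o = 0; o < k; ++o)
        dWout((size_t) ci * k + o, c) = dWr((size_t) o * cin + ci, c);
  arma::frowvec db = arma::sum(dYm, 0);
  return List::create(
    _["dX"] = arma::conv_to<arma::mat>::from(dX),
    _["dW"] = dWout,
    _["db"] = arma::conv_to<arma::rowvec>::from(db),
    _["dGamma"] = dGamma, _["dBeta"] = dBeta);
}

// [[Rcpp::export(name = ".maxPoolForwardC")]]
List maxPoolForwardC(const arma::mat& X, int L, int B, int pool) {
  const int C = X.n_cols, Lo = L / pool;
  arma::mat Y(Lo * B, C);
  arma::imat arg(Lo * B, C);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    arma::sword* ag = arg.colptr(c);
    for (int s = 0; s < B; ++s) {
      const int ibase = s * L, obase = s * Lo;
      for (int j = 0; j < Lo; ++j) {
        int best = ibase + j * pool;
        double bv = x[best];
        for (int o = 1; o < pool; ++o) {
          if (x[ibase + j * pool + o] > bv) {
            bv = x[ibase + j * pool + o];
            best = ibase + j * pool + o;
          }
        }
        y[obase + j] = bv;
        ag[obase + j] = best;        // 0-based absolute row in X
      }
    }
  }
  return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxPoolBackwardC")]]
arma::mat maxPoolBackwardC(const arma::mat& dY, const arma::imat& arg,
                           int L, int B) {
  const int C = dY.n_cols;
  arma::mat dX(L * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.colptr(c);
    const arma::sword* ag = arg.colptr(c);
    double* dx = dX.colptr(c);
    for (arma::uword i = 0; i < dY.n_rows; ++i) dx[ag[i]] += dy[i];
  }
  return dX;
}

// [[Rcpp::export(name = ".sdpaForwardC")]]
List sdpaForwardC(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  int L, int B, bool keepA) {
  const int dk = Q.n_cols, dv = V.n_cols;
  const double scale = 1.0 / std::sqrt((double) dk);
  arma::mat O(L * B, dv);
  arma::cube A(L, L, keepA ? B : 0);
  arma::mat S(L, L);
  for (int s = 0; s < B; ++s) {
    const int r0 = s * L, r1 = s * L + L - 1;
    S = Q.rows(r0, r1) * K.rows(r0, r1).t();
    S *= scale;
    // row-wise stabilized softmax, in place
    for (int i = 0; i < L; ++i) {
      double mx = S(i, 0);
      for (int j = 1; j < L; ++j) if (S(i, j) > mx) mx = S(i, j);
      double sum = 0.0;
      for (int j = 0; j < L; ++j) { S(i, j) = std::exp(S(i, j) - mx); sum += S(i, j); }
      const double inv = 1.0 / sum;
      for (int j = 0; j < L; ++j) S(i, j) *= inv;
    }
    if (keepA) A.slice(s) = S;
    O.rows(r0, r1) = S * V.rows(r0, r1);
  }
  return List::create(_["O"] = O, _["A"] = A);
}

// [[Rcpp::export(name = ".sdpaBackwardC")]]
List sdpaBackwardC(const arma::mat& dO, const arma::mat& Q, const arma::mat& K,
                   const arma::mat& V, const arma::cube& A, int L, int B) {
  const int dk = Q.n_cols;
  const double scale = 1.0 / std::sqrt((double) dk);
  arma::mat dQ(arma::size(Q)), dK(arma::size(K)), dV(arma::size(V));
  arma::mat dA(L, L), dS(L, L);
  for (int s = 0; s < B; ++s) {
    const int r0 = s * L, r1 = s * L + L - 1;
    const arma::mat& Ab = A.slice(s);
    dA = dO.rows(r0, r1) * V.rows(r0, r1).t();
    dV.rows(r0, r1) = Ab.t() * dO.rows(r0, r1);
    for (int i = 0; i < L; ++i) {
      double rd = 0.0;
      for (int j = 0; j < L; ++j) rd += Ab(i, j) * dA(i, j);
      for (int j = 0; j < L; ++j) dS(i, j) = Ab(i, j) * (dA(i, j) - rd);
    }
    dQ.rows(r0, r1) = dS * K.rows(r0, r1) * scale;
    dK.rows(r0, r1) = dS.t() * Q.rows(r0, r1) * scale;
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// [[Rcpp::export(name = ".lnForwardC")]]
List lnForwardC(const arma::mat& X, const arma::vec& gamma,
                const arma::vec& beta, double eps, bool wantCache) {
  const int n = X.n_rows, d = X.n_cols;
  arma::mat out(n, d);
  arma::mat xhat(wantCache ? n : 0, wantCache ? d : 0);
  arma::vec invstd(wantCache ? n : 0);
  std::vector<double> mu(n), is(n);
  for (int i = 0; i < n; ++i) mu[i] = 0.0;
  for (int c = 0; c < d; ++c) {
    const double* x = X.colptr(c);
    for (int i = 0; i < n; ++i) mu[i] += x[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= d;
  for (int i = 0; i < n; ++i) is[i] = 0.0;
  for (int c = 0; c < d; ++c) {
    const double* x = X.colptr(c);
    for (int i = 0; i < n; ++i) {
      const double dd = x[i] - mu[i];
      is[i] += dd * dd;
    }
  }
  for (int i = 0; i < n; ++i) is[i] = 1.0 / std::sqrt(is[i] / d + eps);
  if (wantCache) for (int i = 0; i < n; ++i) invstd(i) = is[i];
  for (int c = 0; c < d; ++c) {
    const double* x = X.colptr(c);
    double* o = out.colptr(c);
    const double g = gamma(c), be = beta(c);
    if (wantCache) {
      double* xh = xhat.colptr(c);
      for (int i = 0; i < n; ++i) {
        xh[i] = (x[i] - mu[i]) * is[i];
        o[i] = g * xh[i] + be;
      }
    } else {
      for (int i = 0; i < n; ++i)
        o[i] = g * (x[i] - mu[i]) * is[i] + be;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".lnBackwardC")]]
List lnBackwardC(const arma::mat& dY, const arma::vec& gamma,
                 const arma::mat& xhat, const arma::vec& invstd) {
  const int n = dY.n_rows, d = dY.n_cols;
  arma::vec dGamma(d), dBeta(d);
  std::vector<double> m1(n, 0.0), m2(n, 0.0);
  for (int c = 0; c < d; ++c) {
    const double* dy = dY.colptr(c);
    const double* xh = xhat.colptr(c);
    const double g = gamma(c);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dxh = dy[i] * g;
      m1[i] += dxh;
      m2[i] += dxh * xh[i];
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dGamma(c) = sg; dBeta(c) = sb;
  }
  for (int i = 0; i < n; ++i) { m1[i] /= d; m2[i] /= d; }
  arma::mat dX(n, d);
  for (int c = 0; c < d; ++c) {
    const double* dy = dY.colptr(c);
    const double* xh = xhat.colptr(c);
    double* dx = dX.colptr(c);
    const double g = gamma(c);
    for (int i = 0; i < n; ++i)
      dx[i] = (dy[i] * g - m1[i] - xh[i] * m2[i]) * invstd(i);
  }
  return List::create(_["dX"] = dX, _["dGamma"] = dGamma,
                      _["dBeta"] = dBeta);
}

// [[Rcpp::export(name = ".biasReluC")]]
List biasReluC(const arma::mat& X, const arma::vec& b) {
  const int n = X.n_rows, d = X.n_cols;
  arma::mat out(n, d);
  for (int c = 0; c < d; ++c) {
    const double* x = X.colptr(c);
    double* o = out.colptr(c);
    const double bc = b(c);
    for (int i = 0; i < n; ++i) {
      const double v = x[i] + bc;
      o[i] = v > 0.0 ? v : 0.0;
    }
  }
  return List::create(_["out"] = out);
}

// [[Rcpp::export(name = ".colAddC")]]
arma::mat colAddC(const arma::mat& X, const arma::vec& a) {
  arma::mat out = X;
  for (arma::uword c = 0; c < out.n_cols; ++c) out.col(c) += a(c);
  return out;
}
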