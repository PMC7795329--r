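// Hot inner contractions of the network layers. The surrounding layer
// logic (and its gradients) lives in R; these kernels only remove R-level
// allocation overhead from the per-frame attention products and the
// temporal-convolution gather/scatter.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// E[(j,i), f] = sum_d K(j, f, d) * Q(i, f, d)
// qa, ka: (V, Fr, d) cubes
// [[Rcpp::export]]
arma::mat qk_logits(const arma::cube& qa, const arma::cube& ka) {
  const arma::uword V = qa.n_rows, Fr = qa.n_cols, D = qa.n_slices;
  arma::mat E(V * V, Fr, arma::fill::zeros);
  for (arma::uword f = 0; f < Fr; ++f) {
    for (arma::uword d = 0; d < D; ++d) {
      const double* q = &qa(0, f, d);
      const double* k = &ka(0, f, d);
      double* e = E.colptr(f);
      for (arma::uword i = 0; i < V; ++i) {
        const double qi = q[i];
        double* ei = e + i * V;
        for (arma::uword j = 0; j < V; ++j) ei[j] += k[j] * qi;
      }
    }
  }
  return E;
}

// S[(i,f), d] = sum_j alpha(j, (i,f)) * va(j, f, d)
// alpha: (V, V*Fr) with columns ordered (i, f); va: (V, Fr, dv)
// [[Rcpp::export]]
arma::mat attn_weighted_values(const arma::mat& alpha, const arma::cube& va) {
  const arma::uword V = va.n_rows, Fr = va.n_cols, D = va.n_slices;
  arma::mat S(V * Fr, D, arma::fill::zeros);
  for (arma::uword d = 0; d < D; ++d) {
    double* s = S.colptr(d);
    for (arma::uword f = 0; f < Fr; ++f) {
      const double* v = &va(0, f, d);
      for (arma::uword i = 0; i < V; ++i) {
        const double* a = alpha.colptr(f * V + i);
        double acc = 0.0;
        for (arma::uword j = 0; j < V; ++j) acc += a[j] * v[j];
        s[f * V + i] = acc;
      }
    }
  }
  return S;
}

// gradients through the weighted sum:
//   dAlpha(j, (i,f)) = sum_d va(j, f, d) * dS((i,f), d)
//   dV((j,f), d)     = sum_i alpha(j, (i,f)) * dS((i,f), d)
// [[Rcpp::export]]
List attn_values_bwd(const arma::mat& alpha, const arma::cube& va,
                     const arma::mat& dS) {
  const arma::uword V = va.n_rows, Fr = va.n_cols, D = va.n_slices;
  arma::mat dAlpha(V, V * Fr, arma::fill::zeros);
  arma::mat dV(V * Fr, D, arma::fill::zeros);
  for (arma::uword d = 0; d < D; ++d) {
    const double* ds = dS.colptr(d);
    double* dv = dV.colptr(d);
    for (arma::uword f = 0; f < Fr; ++f) {
      const double* v = &va(0, f, d);
      for (arma::uword i = 0; i < V; ++i) {
        const double g = ds[f * V + i];
        if (g == 0.0) continue;
        double* da = dAlpha.colptr(f * V + i);
        const double* a = alpha.colptr(f * V + i);
        for (arma::uword j = 0; j < V; ++j) {
          da[j] += v[j] * g;
          dv[f * V + j] += a[j] * g;
        }
      }
    }
  }
  return List::create(Named("dAlpha") = dAlpha, Named("dV") = dV);
}

// gradients through the scaled dot product:
//   dQ((i,f), d) = sum_j dE(j, (i,f)) * ka(j, f, d)
//   dK((j,f), d) = sum_i dE(j, (i,f)) * qa(i, f, d)
// [[Rcpp::export]]
List qk_bwd(const arma::mat& dE, const arma::cube& qa,
            const arma::cube& ka) {
  const arma::uword V = qa.n_rows, Fr = qa.n_cols, D = qa.n_slices;
  arma::mat dQ(V * Fr, D, arma::fill::zeros);
  arma::mat dK(V * Fr, D, arma::fill::zeros);
  for (arma::uword d = 0; d < D; ++d) {
    double* dq = dQ.colptr(d);
    double* dk = dK.colptr(d);
    for (arma::uword f = 0; f < Fr; ++f) {
      const double* k = &ka(0, f, d);
      const double* q = &qa(0, f, d);
      for (arma::uword i = 0; i < V; ++i) {
        const double* de = dE.colptr(f * V + i);
        const double qi = q[i];
        double acc = 0.0;
        for (arma::uword j = 0; j < V; ++j) {
          acc += de[j] * k[j];
          dk[f * V + j] += de[j] * qi;
        }
        dq[f * V + i] = acc;
      }
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK);
}

// column-wise softmax of an (V, m) matrix, in place semantics avoided
// [[Rcpp::export]]
arma::mat softmax_columns(const arma::mat& E) {
  arma::mat A(E.n_rows, E.n_cols);
  for (arma::uword c = 0; c < E.n_cols; ++c) {
    const double mx = E.col(c).max();
    arma::vec e = arma::exp(E.col(c) - mx);
    A.col(c) = e / arma::accu(e);
  }
  return A;
}

// softmax backward over columns: dE = A % (dA - colsum(A % dA))
// [[Rcpp::export]]
arma::mat softmax_columns_bwd(const arma::mat& A, const arma::mat& dA) {
  arma::mat dE(A.n_rows, A.n_cols);
  for (arma::uword c = 0; c < A.n_cols; ++c) {
    const double s = arma::dot(A.col(c), dA.col(c));
    dE.col(c) = A.col(c) % (dA.col(c) - s);
  }
  return dE;
}

// temporal convolution forward.
// x: (C, T, V, N) passed as vector with dims; W: (Co, C, Kt); stride s;
// symmetric zero padding (Kt-1)/2. Returns (Co, To, V, N).
// [[Rcpp::export]]
NumericVector tconv_forward(const NumericVector& x, const IntegerVector& xd,
                            const arma::cube& W, const arma::vec& b,
                            const int stride) {
  const int C = xd[0], T = xd[1], V = xd[2], N = xd[3];
  const int Co = W.n_rows, Kt = W.n_slices;
  const int pad = (Kt - 1) / 2;
  const int To = (T + 2 * pad - Kt) / stride + 1;
  // im2col: columns are (t', v, n), rows (c, kt)
  arma::mat cols(C * Kt, (arma::uword)To * V * N, arma::fill::zeros);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int v = 0; v < V; ++v) {
      const double* xs = xp + ((size_t)n * V + v) * T * C;
      for (int to = 0; to < To; ++to) {
        double* cp = cols.colptr(((size_t)n * V + v) * To + to);
        for (int kt = 0; kt < Kt; ++kt) {
          const int t = to * stride + kt - pad;
          if (t < 0 || t >= T) continue;
          const double* src = xs + (size_t)t * C;
          double* dst = cp + kt * C;
          for (int c = 0; c < C; ++c) dst[c] = src[c];
        }
      }
    }
  }
  arma::mat W2(Co, C * Kt);
  for (int kt = 0; kt < Kt; ++kt) {
    W2.cols(kt * C, kt * C + C - 1) = W.slice(kt);
  }
  arma::mat out = W2 * cols;              // (Co, To*V*N)
  out.each_col() += b;
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Co, To, V, N);
  return res;
}

// temporal convolution backward: returns dx, dW, db
// [[Rcpp::export]]
List tconv_backward(const NumericVector& x, const IntegerVector& xd,
                    const arma::cube& W, const int stride,
                    const NumericVector& dout) {
  const int C = xd[0], T = xd[1], V = xd[2], N = xd[3];
  const int Co = W.n_rows, Kt = W.n_slices;
  const int pad = (Kt - 1) / 2;
  const int To = (T + 2 * pad - Kt) / stride + 1;
  // rebuild im2col (cheaper than caching it across the R boundary)
  arma::mat cols(C * Kt, (arma::uword)To * V * N, arma::fill::zeros);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int v = 0; v < V; ++v) {
      const double* xs = xp + ((size_t)n * V + v) * T * C;
      for (int to = 0; to < To; ++to) {
        double* cp = cols.colptr(((size_t)n * V + v) * To + to);
        for (int kt = 0; kt < Kt; ++kt) {
          const int t = to * stride + kt - pad;
          if (t < 0 || t >= T) continue;
          const double* src = xs + (size_t)t * C;
          double* dst = cp + kt * C;
          for (int c = 0; c < C; ++c) dst[c] = src[c];
        }
      }
    }
  }
  const arma::mat dY(const_cast<double*>(dout.begin()), Co,
                     (arma::uword)To * V * N, false, true);
  arma::mat dW2 = dY * cols.t();          // (Co, C*Kt)
  arma::vec db = arma::sum(dY, 1);
  arma::mat W2(Co, C * Kt);
  for (int kt = 0; kt < Kt; ++kt) {
    W2.cols(kt * C, kt * C + C - 1) = W.slice(kt);
  }
  arma::mat dcols = W2.t() * dY;          // (C*Kt, To*V*N)
  NumericVector dx((size_t)C * T * V * N);
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int v = 0; v < V; ++v) {
      double* xs = dxp + ((size_t)n * V + v) * T * C;
      for (int to = 0; to < To; ++to) {
        const double* cp = dcols.colptr(((size_t)n * V + v) * To + to);
        for (int kt = 0; kt < Kt; ++kt) {
          const int t = to * stride + kt - pad;
          if (t < 0 || t >= T) continue;
          double* dst = xs + (size_t)t * C;
          const double* src = cp + kt * C;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  dx.attr("dim") = xd;
  arma::cube dW(Co, C, Kt);
  for (int kt = 0; kt < Kt; ++kt) {
    dW.slice(kt) = dW2.cols(kt * C, kt * C + C - 1);
  }
  return List::create(Named("dx") = dx, Named("dW") = dW,
                      Named("db") = NumericVector(db.begin(), db.end()));
}
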