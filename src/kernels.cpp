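// Numerical layers for the MF-Net encoder-decoder: dilated conv2d,
// deformable conv2d, batch-norm, 2x max-pool, 2x bilinear upsample,
// each with its backward pass.
//
// Tensor layout: R double arrays of dim (h, w, c, n), column-major.
// Conv weights: (kh, kw, cin, cout); "same" padding = dilation*(kh-1)/2.
// The large conv GEMMs run in single precision (float32) for CPU speed;
// everything else accumulates in double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (h,w,c,n) array");
  return d;
}

// ---------------------------------------------------------------------------
// im2col (transposed layout): colT is P x K with P = h*w positions (i fastest)
// and K = kh*kw*cin taps ordered (ki fastest, then kj, then c) to match the
// column-major flattening of a (kh,kw,cin,cout) weight array.
// ---------------------------------------------------------------------------
template <typename MT, typename ET>
static void im2colT(const double* x, int h, int w, int cin,
                    int kh, int dil, MT& colT) {
  const int ctr = (kh - 1) / 2;
  const int P = h * w;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (size_t)c * h * w;
    for (int kj = 0; kj < kh; ++kj) {
      const int dj = (kj - ctr) * dil;
      for (int ki = 0; ki < kh; ++ki) {
        const int di = (ki - ctr) * dil;
        ET* col = colT.colptr(ki + kh * (kj + kh * c));
        for (int j = 0; j < w; ++j) {
          const int jj = j + dj;
          ET* dst = col + (size_t)j * h;
          if (jj < 0 || jj >= w) {
            std::fill(dst, dst + h, (ET)0);
            continue;
          }
          const double* src = xc + (size_t)jj * h;
          int i0 = std::min(h, std::max(0, -di));
          int i1 = std::max(i0, std::min(h, h - di));
          for (int i = 0; i < i0; ++i) dst[i] = (ET)0;
          for (int i = i0; i < i1; ++i) dst[i] = (ET)src[i + di];
          for (int i = i1; i < h; ++i) dst[i] = (ET)0;
        }
      }
    }
  }
  (void)P;
}

// scatter-add transpose of im2colT
template <typename MT, typename ET>
static void col2imT(const MT& dcolT, int h, int w, int cin,
                    int kh, int dil, double* dx) {
  const int ctr = (kh - 1) / 2;
  for (int c = 0; c < cin; ++c) {
    double* xc = dx + (size_t)c * h * w;
    for (int kj = 0; kj < kh; ++kj) {
      const int dj = (kj - ctr) * dil;
      for (int ki = 0; ki < kh; ++ki) {
        const int di = (ki - ctr) * dil;
        const ET* col = dcolT.colptr(ki + kh * (kj + kh * c));
        for (int j = 0; j < w; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= w) continue;
          const ET* src = col + (size_t)j * h;
          double* dst = xc + (size_t)jj * h;
          int i0 = std::min(h, std::max(0, -di));
          int i1 = std::max(i0, std::min(h, h - di));
          for (int i = i0; i < i1; ++i) dst[i + di] += (double)src[i];
        }
      }
    }
  }
}

template <typename MT, typename RT, typename ET>
static NumericVector conv2d_fwd_impl(const NumericVector& x,
                                     const NumericVector& W,
                                     const NumericVector& b, int dilation) {
  IntegerVector xd = dims4(x), wd = W.attr("dim");
  const int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  const int kh = wd[0], cout = wd[3];
  if (wd[1] != kh || wd[2] != cin) stop("weight dims do not match input");
  const int P = h * w, K = kh * kh * cin;
  MT Wf(K, cout);
  for (int k = 0; k < K * cout; ++k) Wf[k] = (ET)W[k];
  RT bf(cout);
  for (int c = 0; c < cout; ++c) bf[c] = (ET)b[c];

  NumericVector y((size_t)P * cout * n);
  y.attr("dim") = IntegerVector::create(h, w, cout, n);
  MT colT(P, K);
  for (int s = 0; s < n; ++s) {
    im2colT<MT, ET>(&x[0] + (size_t)s * P * cin, h, w, cin, kh, dilation,
                    colT);
    MT ymat = colT * Wf;          // P x cout
    ymat.each_row() += bf;
    double* yp = &y[0] + (size_t)s * P * cout;
    const ET* sp = ymat.memptr();
    for (size_t k = 0; k < (size_t)P * cout; ++k) yp[k] = (double)sp[k];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector W,
                             NumericVector b, int dilation,
                             bool dbl = false) {
  if (dbl)
    return conv2d_fwd_impl<arma::mat, arma::rowvec, double>(x, W, b,
                                                            dilation);
  return conv2d_fwd_impl<arma::fmat, arma::frowvec, float>(x, W, b,
                                                           dilation);
}

template <typename MT, typename ET>
static List conv2d_bwd_impl(const NumericVector& x, const NumericVector& W,
                            const NumericVector& dy, int dilation) {
  IntegerVector xd = dims4(x), wd = W.attr("dim");
  const int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  const int kh = wd[0], cout = wd[3];
  const int P = h * w, K = kh * kh * cin;
  MT Wf(K, cout);
  for (int k = 0; k < K * cout; ++k) Wf[k] = (ET)W[k];

  NumericVector dx((size_t)P * cin * n);
  dx.attr("dim") = xd;
  arma::mat dWacc(K, cout, arma::fill::zeros);
  arma::vec dbacc(cout, arma::fill::zeros);
  MT colT(P, K), dymat(P, cout);

  for (int s = 0; s < n; ++s) {
    const double* dyp = &dy[0] + (size_t)s * P * cout;
    ET* dmp = dymat.memptr();
    for (size_t k = 0; k < (size_t)P * cout; ++k) dmp[k] = (ET)dyp[k];
    im2colT<MT, ET>(&x[0] + (size_t)s * P * cin, h, w, cin, kh, dilation,
                    colT);
    MT dW1 = colT.t() * dymat;    // K x cout
    dWacc += arma::conv_to<arma::mat>::from(dW1);
    dbacc += arma::conv_to<arma::mat>::from(arma::sum(dymat, 0)).t();
    MT dcolT = dymat * Wf.t();    // P x K
    col2imT<MT, ET>(dcolT, h, w, cin, kh, dilation,
                    &dx[0] + (size_t)s * P * cin);
  }
  NumericVector dW(K * cout);
  dW.attr("dim") = wd;
  std::copy(dWacc.memptr(), dWacc.memptr() + (size_t)K * cout, dW.begin());
  NumericVector db(cout);
  std::copy(dbacc.memptr(), dbacc.memptr() + cout, db.begin());
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector W, NumericVector dy,
                    int dilation, bool dbl = false) {
  if (dbl) return conv2d_bwd_impl<arma::mat, double>(x, W, dy, dilation);
  return conv2d_bwd_impl<arma::fmat, float>(x, W, dy, dilation);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2 (h, w even)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  if (h % 2 || w % 2) stop("max-pool input dims must be even");
  const int ho = h / 2, wo = w / 2;
  NumericVector y((size_t)ho * wo * c * n);
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  IntegerVector idx(y.size());
  double* yp = &y[0];
  int* ip = &idx[0];
  size_t q = 0;
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* xs = &x[0] + ((size_t)s * c + cc) * h * w;
      for (int j = 0; j < wo; ++j)
        for (int i = 0; i < ho; ++i) {
          const size_t base = (size_t)(2 * j) * h + 2 * i;
          const size_t cand[4] = {base, base + 1, base + h, base + h + 1};
          int best = 0;
          double bv = xs[cand[0]];
          for (int k = 1; k < 4; ++k)
            if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = k; }
          yp[q] = bv;
          ip[q] = (int)cand[best];
          ++q;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx,
                               int h, int w) {
  IntegerVector yd = dims4(dy);
  const int ho = yd[0], wo = yd[1], c = yd[2], n = yd[3];
  NumericVector dx((size_t)h * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  const double* dyp = &dy[0];
  const int* ip = &idx[0];
  size_t q = 0;
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      double* xs = &dx[0] + ((size_t)s * c + cc) * h * w;
      for (size_t k = 0; k < (size_t)ho * wo; ++k, ++q) xs[ip[q]] += dyp[q];
    }
  return dx;
}

// ---------------------------------------------------------------------------
// bilinear 2x upsample (align_corners = FALSE convention)
// ---------------------------------------------------------------------------
static void up2_weights(int ho, int hin, std::vector<int>& i0,
                        std::vector<double>& wi) {
  i0.resize(ho); wi.resize(ho);
  for (int i = 0; i < ho; ++i) {
    double src = (i + 0.5) / 2.0 - 0.5;
    if (src < 0) src = 0;
    if (src > hin - 1) src = hin - 1;
    int a = (int)std::floor(src);
    if (a > hin - 2) a = hin - 2;
    if (a < 0) a = 0;
    i0[i] = a;
    wi[i] = src - a;  // weight of i0+1
    if (hin == 1) { i0[i] = 0; wi[i] = 0.0; }
  }
}

// [[Rcpp::export(name = ".cpp_upsample2_fwd")]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  const int ho = 2 * h, wo = 2 * w;
  std::vector<int> i0, j0;
  std::vector<double> wi, wj;
  up2_weights(ho, h, i0, wi);
  up2_weights(wo, w, j0, wj);
  NumericVector y((size_t)ho * wo * c * n);
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  double* yp = &y[0];
  std::vector<int> i1v(ho);
  std::vector<double> w0(ho), w1(ho);
  for (int i = 0; i < ho; ++i) {
    i1v[i] = std::min(i0[i] + 1, h - 1);
    w1[i] = wi[i];
    w0[i] = 1 - wi[i];
  }
  size_t q = 0;
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      const double* xs = &x[0] + ((size_t)s * c + cc) * h * w;
      for (int j = 0; j < wo; ++j) {
        const double* c0 = xs + (size_t)j0[j] * h;
        const double* c1 = xs + (size_t)std::min(j0[j] + 1, w - 1) * h;
        const double b = wj[j], b0 = 1 - b;
        for (int i = 0; i < ho; ++i, ++q) {
          yp[q] = b0 * (w0[i] * c0[i0[i]] + w1[i] * c0[i1v[i]]) +
                  b * (w0[i] * c1[i0[i]] + w1[i] * c1[i1v[i]]);
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2_bwd")]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dims4(dy);
  const int ho = yd[0], wo = yd[1], c = yd[2], n = yd[3];
  const int h = ho / 2, w = wo / 2;
  std::vector<int> i0, j0;
  std::vector<double> wi, wj;
  up2_weights(ho, h, i0, wi);
  up2_weights(wo, w, j0, wj);
  NumericVector dx((size_t)h * w * c * n);
  dx.attr("dim") = IntegerVector::create(h, w, c, n);
  const double* dyp = &dy[0];
  size_t q = 0;
  for (int s = 0; s < n; ++s)
    for (int cc = 0; cc < c; ++cc) {
      double* xs = &dx[0] + ((size_t)s * c + cc) * h * w;
      for (int j = 0; j < wo; ++j) {
        double* c0 = xs + (size_t)j0[j] * h;
        double* c1 = xs + (size_t)std::min(j0[j] + 1, w - 1) * h;
        const double b = wj[j];
        for (int i = 0; i < ho; ++i, ++q) {
          const int a0 = i0[i], a1 = std::min(i0[i] + 1, h - 1);
          const double a = wi[i], g = dyp[q];
          c0[a0] += (1 - b) * (1 - a) * g;
          c0[a1] += (1 - b) * a * g;
          c1[a0] += b * (1 - a) * g;
          c1[a1] += b * a * g;
        }
      }
    }
  return dx;
}

// ---------------------------------------------------------------------------
// batch normalization over (h, w, n) per channel
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_bn_fwd")]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, double eps,
                double momentum, bool training) {
  IntegerVector xd = dims4(x);
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  const size_t hw = (size_t)h * w, N = hw * n;
  NumericVector y(x.size()), xhat(training ? x.size() : 0);
  y.attr("dim") = xd;
  if (training) xhat.attr("dim") = xd;
  NumericVector invstd(c), nmean(clone(rmean)), nvar(clone(rvar));
  for (int cc = 0; cc < c; ++cc) {
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int ss = 0; ss < n; ++ss) {
        const double* xs = &x[0] + ((size_t)ss * c + cc) * hw;
        for (size_t k = 0; k < hw; ++k) { s += xs[k]; s2 += xs[k] * xs[k]; }
      }
      mu = s / N;
      var = s2 / N - mu * mu;   // biased, used for normalization
      if (var < 0) var = 0;
      const double ub = (N > 1) ? var * (double)N / (N - 1) : var;
      nmean[cc] = (1 - momentum) * rmean[cc] + momentum * mu;
      nvar[cc] = (1 - momentum) * rvar[cc] + momentum * ub;
    } else {
      mu = rmean[cc];
      var = rvar[cc];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[cc] = is;
    const double g = gamma[cc], bb = beta[cc];
    for (int ss = 0; ss < n; ++ss) {
      const size_t off = ((size_t)ss * c + cc) * hw;
      const double* xs = &x[0] + off;
      double* ys = &y[0] + off;
      if (training) {
        double* xh = &xhat[0] + off;
        for (size_t k = 0; k < hw; ++k) {
          xh[k] = (xs[k] - mu) * is;
          ys[k] = g * xh[k] + bb;
        }
      } else {
        for (size_t k = 0; k < hw; ++k) ys[k] = g * (xs[k] - mu) * is + bb;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = nmean, _["rvar"] = nvar);
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector invstd,
                NumericVector gamma) {
  IntegerVector xd = dims4(dy);
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  const size_t hw = (size_t)h * w, N = hw * n;
  NumericVector dx(dy.size()), dgamma(c), dbeta(c);
  dx.attr("dim") = xd;
  for (int cc = 0; cc < c; ++cc) {
    double sdy = 0, sdyx = 0;
    for (int ss = 0; ss < n; ++ss) {
      const size_t off = ((size_t)ss * c + cc) * hw;
      const double* d = &dy[0] + off;
      const double* xh = &xhat[0] + off;
      for (size_t k = 0; k < hw; ++k) { sdy += d[k]; sdyx += d[k] * xh[k]; }
    }
    dgamma[cc] = sdyx;
    dbeta[cc] = sdy;
    const double g = gamma[cc], is = invstd[cc];
    const double m1 = sdy / N, m2 = sdyx / N;
    for (int ss = 0; ss < n; ++ss) {
      const size_t off = ((size_t)ss * c + cc) * hw;
      const double* d = &dy[0] + off;
      const double* xh = &xhat[0] + off;
      double* o = &dx[0] + off;
      for (size_t k = 0; k < hw; ++k)
        o[k] = g * is * (d[k] - m1 - xh[k] * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---------------------------------------------------------------------------
// deformable 3x3 convolution (stride 1, same padding, zero outside).
// offs: (h, w, 18, n); channels ordered (dy_0, dx_0, dy_1, dx_1, ...) with
// tap index k = ki + 3*kj over the 3x3 grid (ki, kj in 0..2, row fastest).
// Sampling position for output (i, j), tap k: (i + ki - 1 + dy_k(i,j),
// j + kj - 1 + dx_k(i,j)), evaluated by bilinear interpolation.
// ---------------------------------------------------------------------------
static inline double bsample(const double* xc, int h, int w, double py,
                             double px) {
  if (py <= -1.0 || py >= (double)h || px <= -1.0 || px >= (double)w)
    return 0.0;
  const int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
  const double fy = py - y0, fx = px - x0;
  double v = 0.0;
  for (int dy = 0; dy < 2; ++dy)
    for (int dx = 0; dx < 2; ++dx) {
      const int yy = y0 + dy, xx = x0 + dx;
      if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
      const double wgt = (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
      v += wgt * xc[(size_t)xx * h + yy];
    }
  return v;
}

// [[Rcpp::export(name = ".cpp_deform_conv_fwd")]]
NumericVector cpp_deform_conv_fwd(NumericVector x, NumericVector offs,
                                  NumericVector W, NumericVector b) {
  IntegerVector xd = dims4(x), wd = W.attr("dim");
  const int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  const int cout = wd[3];
  if (wd[0] != 3 || wd[1] != 3 || wd[2] != cin)
    stop("deformable conv expects a (3,3,cin,cout) kernel");
  const int P = h * w, K = 9 * cin;
  arma::mat Wm(const_cast<double*>(&W[0]), K, cout, false);
  NumericVector y((size_t)P * cout * n);
  y.attr("dim") = IntegerVector::create(h, w, cout, n);
  arma::mat colT(P, K);
  for (int s = 0; s < n; ++s) {
    const double* xs = &x[0] + (size_t)s * P * cin;
    const double* os = &offs[0] + (size_t)s * P * 18;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const int p = i + h * j;
        for (int k = 0; k < 9; ++k) {
          const double py = i + (k % 3) - 1 + os[(size_t)(2 * k) * P + p];
          const double px = j + (k / 3) - 1 + os[(size_t)(2 * k + 1) * P + p];
          for (int c = 0; c < cin; ++c)
            colT(p, k + 9 * c) = bsample(xs + (size_t)c * P, h, w, py, px);
        }
      }
    arma::mat ymat = colT * Wm;
    for (int c = 0; c < cout; ++c) ymat.col(c) += b[c];
    std::copy(ymat.memptr(), ymat.memptr() + (size_t)P * cout,
              &y[0] + (size_t)s * P * cout);
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_deform_conv_bwd")]]
List cpp_deform_conv_bwd(NumericVector x, NumericVector offs, NumericVector W,
                         NumericVector dy) {
  IntegerVector xd = dims4(x), wd = W.attr("dim");
  const int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  const int cout = wd[3];
  const int P = h * w, K = 9 * cin;
  arma::mat Wm(const_cast<double*>(&W[0]), K, cout, false);
  NumericVector dx(x.size()), doffs(offs.size()), dW(W.size()), db(cout);
  dx.attr("dim") = xd;
  doffs.attr("dim") = offs.attr("dim");
  dW.attr("dim") = wd;
  arma::mat dWm(&dW[0], K, cout, false);
  arma::mat colT(P, K);
  for (int s = 0; s < n; ++s) {
    const double* xs = &x[0] + (size_t)s * P * cin;
    const double* os = &offs[0] + (size_t)s * P * 18;
    double* dxs = &dx[0] + (size_t)s * P * cin;
    double* dos = &doffs[0] + (size_t)s * P * 18;
    arma::mat dymat(const_cast<double*>(&dy[0]) + (size_t)s * P * cout,
                    P, cout, false);
    // rebuild sampled columns for dW
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const int p = i + h * j;
        for (int k = 0; k < 9; ++k) {
          const double py = i + (k % 3) - 1 + os[(size_t)(2 * k) * P + p];
          const double px = j + (k / 3) - 1 + os[(size_t)(2 * k + 1) * P + p];
          for (int c = 0; c < cin; ++c)
            colT(p, k + 9 * c) = bsample(xs + (size_t)c * P, h, w, py, px);
        }
      }
    dWm += colT.t() * dymat;
    for (int c = 0; c < cout; ++c) db[c] += arma::accu(dymat.col(c));
    arma::mat dcolT = dymat * Wm.t();  // P x K
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const int p = i + h * j;
        for (int k = 0; k < 9; ++k) {
          const double py = i + (k % 3) - 1 + os[(size_t)(2 * k) * P + p];
          const double px = j + (k / 3) - 1 + os[(size_t)(2 * k + 1) * P + p];
          if (py <= -1.0 || py >= (double)h || px <= -1.0 ||
              px >= (double)w)
            continue;
          const int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
          const double fy = py - y0, fx = px - x0;
          double gpy = 0.0, gpx = 0.0;
          for (int c = 0; c < cin; ++c) {
            const double g = dcolT(p, k + 9 * c);
            if (g == 0.0) continue;
            double* dxc = dxs + (size_t)c * P;
            const double* xc = xs + (size_t)c * P;
            double v[2][2] = {{0, 0}, {0, 0}};
            for (int a = 0; a < 2; ++a)
              for (int bq = 0; bq < 2; ++bq) {
                const int yy = y0 + a, xx = x0 + bq;
                if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
                v[a][bq] = xc[(size_t)xx * h + yy];
                dxc[(size_t)xx * h + yy] +=
                    g * (a ? fy : 1 - fy) * (bq ? fx : 1 - fx);
              }
            gpy += g * ((1 - fx) * (v[1][0] - v[0][0]) +
                        fx * (v[1][1] - v[0][1]));
            gpx += g * ((1 - fy) * (v[0][1] - v[0][0]) +
                        fy * (v[1][1] - v[1][0]));
          }
          dos[(size_t)(2 * k) * P + p] += gpy;
          dos[(size_t)(2 * k + 1) * P + p] += gpx;
        }
      }
  }
  return List::create(_["dx"] = dx, _["doffs"] = doffs, _["dW"] = dW,
                      _["db"] = db);
}
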