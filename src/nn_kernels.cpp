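// Numerical kernels: grouped 3D convolution (forward/backward, im2col +
// BLAS gemm), separable Gaussian blur, and binary ball morphology.
// Array layout everywhere is R column-major with dims (X, Y, Z, C, N) for
// feature maps and (k, k, k, Cin/groups, Cout) for convolution weights.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int conv_out(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill `col` (rows = k^3 * cin_g, cols = OX*OY*OZ) for sample n, group g.
static void im2col_group(const double* x, arma::mat& col,
                         int X, int Y, int Z, int Cin,
                         int k, int s, int p,
                         int cin_g, int g, int n,
                         int OX, int OY, int OZ) {
  const long sampOff = (long)X * Y * Z * Cin * n;
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const long pcol = (long)ox + (long)OX * (oy + (long)OY * oz);
        int r = 0;
        for (int ci = 0; ci < cin_g; ++ci) {
          const int c = g * cin_g + ci;
          const long chanOff = sampOff + (long)X * Y * Z * c;
          for (int kz = 0; kz < k; ++kz) {
            const int iz = oz * s - p + kz;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = oy * s - p + ky;
              for (int kx = 0; kx < k; ++kx, ++r) {
                const int ix = ox * s - p + kx;
                col(r, pcol) =
                  (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 && iz < Z)
                  ? x[chanOff + ix + (long)X * (iy + (long)Y * iz)]
                  : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// Weight matrix for group g: (cout_g x k^3*cin_g), row-order matching im2col.
static arma::mat weight_mat(const double* w, int k, int cin_g, int cout_g,
                            int g) {
  const long k3 = (long)k * k * k;
  arma::mat W(cout_g, k3 * cin_g);
  for (int co = 0; co < cout_g; ++co) {
    const int coG = g * cout_g + co;
    for (int ci = 0; ci < cin_g; ++ci)
      for (long t = 0; t < k3; ++t)
        W(co, (long)ci * k3 + t) = w[t + k3 * (ci + (long)cin_g * coG)];
  }
  return W;
}

// Pointwise (1x1x1, stride 1, ungrouped) convolution as a plain gemm per
// sample: y[S x Cout] = x[S x Cin] * W^T.
static NumericVector conv1_fw(NumericVector x, NumericVector w,
                              NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3], N = xd[4];
  const int Cout = wd[4];
  const long S = (long)X * Y * Z;
  NumericVector y(S * Cout * N);
  y.attr("dim") = IntegerVector::create(X, Y, Z, Cout, N);
  arma::mat W(const_cast<double*>(w.begin()), Cin, Cout, false);  // k3=1
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + S * Cin * n, S, Cin,
                 false);
    arma::mat Ym(y.begin() + S * Cout * n, S, Cout, false, true);
    Ym = Xm * W;
    if (bias.size() == Cout)
      for (int co = 0; co < Cout; ++co) Ym.col(co) += bias[co];
  }
  return y;
}

static List conv1_bw(NumericVector x, NumericVector w, NumericVector gy,
                     bool hasBias, bool needGx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3], N = xd[4];
  const int Cout = wd[4];
  const long S = (long)X * Y * Z;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(hasBias ? Cout : 0);
  arma::mat W(const_cast<double*>(w.begin()), Cin, Cout, false);
  arma::mat GW(gw.begin(), Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + S * Cin * n, S, Cin,
                 false);
    arma::mat Gy(const_cast<double*>(gy.begin()) + S * Cout * n, S, Cout,
                 false);
    arma::mat Gx(gx.begin() + S * Cin * n, S, Cin, false, true);
    GW += Xm.t() * Gy;
    if (needGx) Gx = Gy * W.t();
    if (hasBias)
      for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(Gy.col(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector bias,
                        int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3], N = xd[4];
  const int k = wd[0], cin_g = wd[3], Cout = wd[4];
  if (Cin % groups != 0 || Cout % groups != 0 || Cin / groups != cin_g)
    stop("conv3d_fw: channel/group mismatch");
  if (k == 1 && stride == 1 && pad == 0 && groups == 1)
    return conv1_fw(x, w, bias);
  const int cout_g = Cout / groups;
  const int OX = conv_out(X, k, stride, pad), OY = conv_out(Y, k, stride, pad),
            OZ = conv_out(Z, k, stride, pad);
  const long P = (long)OX * OY * OZ;
  NumericVector y((long)P * Cout * N);
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, Cout, N);
  const bool hasBias = bias.size() == Cout;
  arma::mat col((long)k * k * k * cin_g, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col_group(x.begin(), col, X, Y, Z, Cin, k, stride, pad,
                   cin_g, g, n, OX, OY, OZ);
      arma::mat W = weight_mat(w.begin(), k, cin_g, cout_g, g);
      arma::mat Yg = W * col;  // cout_g x P
      for (int co = 0; co < cout_g; ++co) {
        const int coG = g * cout_g + co;
        double* dst = y.begin() + P * (coG + (long)Cout * n);
        const double b = hasBias ? bias[coG] : 0.0;
        for (long pidx = 0; pidx < P; ++pidx) dst[pidx] = Yg(co, pidx) + b;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad, int groups, bool hasBias,
               bool needGx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3], N = xd[4];
  const int k = wd[0], cin_g = wd[3], Cout = wd[4];
  if (k == 1 && stride == 1 && pad == 0 && groups == 1)
    return conv1_bw(x, w, gy, hasBias, needGx);
  const int cout_g = Cout / groups;
  const int OX = conv_out(X, k, stride, pad), OY = conv_out(Y, k, stride, pad),
            OZ = conv_out(Z, k, stride, pad);
  const long P = (long)OX * OY * OZ, k3 = (long)k * k * k;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(hasBias ? Cout : 0);

  arma::mat col(k3 * cin_g, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col_group(x.begin(), col, X, Y, Z, Cin, k, stride, pad,
                   cin_g, g, n, OX, OY, OZ);
      arma::mat Gy(cout_g, P);
      for (int co = 0; co < cout_g; ++co) {
        const int coG = g * cout_g + co;
        const double* src = gy.begin() + P * (coG + (long)Cout * n);
        for (long pidx = 0; pidx < P; ++pidx) Gy(co, pidx) = src[pidx];
        if (hasBias) gb[coG] += arma::accu(Gy.row(co));
      }
      arma::mat GW = Gy * col.t();  // cout_g x k3*cin_g
      for (int co = 0; co < cout_g; ++co) {
        const int coG = g * cout_g + co;
        for (int ci = 0; ci < cin_g; ++ci)
          for (long t = 0; t < k3; ++t)
            gw[t + k3 * (ci + (long)cin_g * coG)] += GW(co, (long)ci * k3 + t);
      }
      if (!needGx) continue;
      arma::mat W = weight_mat(w.begin(), k, cin_g, cout_g, g);
      arma::mat Gcol = W.t() * Gy;  // k3*cin_g x P, scatter-add (col2im)
      double* gxp = gx.begin();
      const long sampOff = (long)X * Y * Z * Cin * n;
      for (int oz = 0; oz < OZ; ++oz)
        for (int oy = 0; oy < OY; ++oy)
          for (int ox = 0; ox < OX; ++ox) {
            const long pcol = (long)ox + (long)OX * (oy + (long)OY * oz);
            int r = 0;
            for (int ci = 0; ci < cin_g; ++ci) {
              const int c = g * cin_g + ci;
              const long chanOff = sampOff + (long)X * Y * Z * c;
              for (int kz = 0; kz < k; ++kz) {
                const int iz = oz * stride - pad + kz;
                for (int ky = 0; ky < k; ++ky) {
                  const int iy = oy * stride - pad + ky;
                  for (int kx = 0; kx < k; ++kx, ++r) {
                    const int ix = ox * stride - pad + kx;
                    if (ix >= 0 && ix < X && iy >= 0 && iy < Y &&
                        iz >= 0 && iz < Z)
                      gxp[chanOff + ix + (long)X * (iy + (long)Y * iz)] +=
                        Gcol(r, pcol);
                  }
                }
              }
            }
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Separable Gaussian blur of a 3D array, reflecting borders.
// [[Rcpp::export]]
NumericVector gaussian_blur3d(NumericVector x, double sigma) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  if (sigma <= 0) return clone(x);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (auto& v : ker) v /= s;
  NumericVector a = clone(x), b(x.size());
  b.attr("dim") = xd;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int axis = 0; axis < 3; ++axis) {
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y)
        for (int xi = 0; xi < X; ++xi) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int xx = xi, yy = y, zz = z;
            if (axis == 0) xx = reflect(xi + t, X);
            else if (axis == 1) yy = reflect(y + t, Y);
            else zz = reflect(z + t, Z);
            acc += ker[t + rad] * a[xx + (long)X * (yy + (long)Y * zz)];
          }
          b[xi + (long)X * (y + (long)Y * z)] = acc;
        }
    std::swap(a, b);
  }
  a.attr("dim") = xd;
  return a;
}

// Binary dilation (dilate=true) or erosion with a ball of given radius.
// [[Rcpp::export]]
IntegerVector ball_morph3d(IntegerVector x, int radius, bool dilate) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  IntegerVector out(x.size());
  out.attr("dim") = xd;
  std::vector<std::array<int, 3>> off;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          off.push_back({dx, dy, dz});
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xi = 0; xi < X; ++xi) {
        int hit = dilate ? 0 : 1;
        for (const auto& o : off) {
          const int ax = xi + o[0], ay = y + o[1], az = z + o[2];
          int v = 0;  // outside treated as background
          if (ax >= 0 && ax < X && ay >= 0 && ay < Y && az >= 0 && az < Z)
            v = x[ax + (long)X * (ay + (long)Y * az)];
          if (dilate && v) { hit = 1; break; }
          if (!dilate && !v) { hit = 0; break; }
        }
        out[xi + (long)X * (y + (long)Y * z)] = hit;
      }
  return out;
}

// ---- batch-norm helpers --------------------------------------------------
// Layout: x flat with channel index (i / S) % C, i.e. dims (S..., C, N).

// [[Rcpp::export]]
List bn_stats(NumericVector x, long S, int C, int N) {
  NumericVector mu(C), m2(C);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* q = p + S * (c + (long)C * n);
      double s = 0, s2 = 0;
      for (long i = 0; i < S; ++i) { s += q[i]; s2 += q[i] * q[i]; }
      mu[c] += s; m2[c] += s2;
    }
  const double m = (double)S * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    m2[c] = std::max(m2[c] / m - mu[c] * mu[c], 0.0);
  }
  return List::create(_["mean"] = mu, _["var"] = m2);
}

// [[Rcpp::export]]
List bn_apply(NumericVector x, NumericVector mu, NumericVector inv,
              NumericVector gamma, NumericVector beta, long S, int C,
              int N, bool want_xhat) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector xhat;
  if (want_xhat) { xhat = NumericVector(x.size()); }
  const double* p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = S * (c + (long)C * n);
      const double m = mu[c], iv = inv[c], g = gamma[c], b = beta[c];
      for (long i = 0; i < S; ++i) {
        const double xh = (p[off + i] - m) * iv;
        if (want_xhat) xhat[off + i] = xh;
        y[off + i] = g * xh + b;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Per-channel sums of gy and gy*xhat (batch-norm backward reductions).
// [[Rcpp::export]]
List bn_bw_sums(NumericVector gy, NumericVector xhat, long S, int C, int N) {
  NumericVector dbeta(C), dgamma(C);
  const double* g = gy.begin();
  const double* xh = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = S * (c + (long)C * n);
      double sb = 0, sg = 0;
      for (long i = 0; i < S; ++i) {
        sb += g[off + i];
        sg += g[off + i] * xh[off + i];
      }
      dbeta[c] += sb; dgamma[c] += sg;
    }
  return List::create(_["dbeta"] = dbeta, _["dgamma"] = dgamma);
}

// [[Rcpp::export]]
NumericVector bn_bw_gx(NumericVector gy, NumericVector xhat,
                       NumericVector gamma, NumericVector inv,
                       NumericVector mean_dy, NumericVector mean_dyx,
                       long S, int C, int N, bool training) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double* g = gy.begin();
  const double* xh = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = S * (c + (long)C * n);
      const double sc = gamma[c] * inv[c];
      if (training) {
        const double md = mean_dy[c], mdx = mean_dyx[c];
        for (long i = 0; i < S; ++i)
          gx[off + i] = sc * (g[off + i] - md - xh[off + i] * mdx);
      } else {
        for (long i = 0; i < S; ++i) gx[off + i] = sc * g[off + i];
      }
    }
  return gx;
}
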