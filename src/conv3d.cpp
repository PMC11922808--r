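// Dense 3D compute kernels for the volumetric CNN: im2col + BLAS GEMM
// convolution (forward/backward), max-pooling with argmax bookkeeping,
// and trilinear resampling (resize, rotation) for augmentation.
//
// Tensor layouts (R column-major):
//   activations : (X, Y, Z, C, N)
//   conv weights: (k, k, k, Cin, Cout)  -> flattens to a (k^3*Cin x Cout) matrix
// im2col columns use the matching row order (kx fastest, then ky, kz, ci),
// so the GEMM needs no transposition fix-ups. Columns are processed in
// bounded chunks so peak memory stays modest even for 61^3 inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int n, int k, int s) {
  return (n - k) / s + 1;
}

// fill columns [p0, p1) of the im2col buffer for one sample
static void im2col_chunk(const double* xs, int X, int Y, int Z, int Cin,
                         int k, int OX, int OY, int p0, int p1,
                         arma::mat& Xc) {
  const int XY = X * Y, XYZ = X * Y * Z;
  for (int p = p0; p < p1; ++p) {
    const int ox = p % OX;
    const int oy = (p / OX) % OY;
    const int oz = p / (OX * OY);
    double* col = Xc.colptr(p - p0);
    int r = 0;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xs + (size_t)ci * XYZ;
      for (int kz = 0; kz < k; ++kz) {
        const int z = oz + kz;
        for (int ky = 0; ky < k; ++ky) {
          const int y = oy + ky;
          const double* src = xc + (size_t)z * XY + (size_t)y * X + ox;
          std::memcpy(col + r, src, k * sizeof(double));
          r += k;
        }
      }
    }
  }
}

static int chunk_cols(int K) {
  // cap im2col buffer around 32 MB
  int c = (int)(4000000 / (size_t)K);
  if (c < 64) c = 64;
  return c;
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3], N = xd[4];
  const int k = wd[0], Cout = wd[4];
  if (wd[3] != Cin) stop("conv3d: weight Cin %d != input Cin %d", wd[3], Cin);
  const int OX = out_len(X, k, 1), OY = out_len(Y, k, 1), OZ = out_len(Z, k, 1);
  if (OX < 1 || OY < 1 || OZ < 1)
    stop("conv3d: kernel %d does not fit input %dx%dx%d", k, X, Y, Z);
  const int K = k * k * k * Cin;
  const size_t OP = (size_t)OX * OY * OZ;

  const arma::mat W(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector out((size_t)OP * Cout * N);
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, Cout, N);

  const int CH = chunk_cols(K);
  arma::mat Xc(K, std::min<int>(CH, (int)OP));
  const size_t xstride = (size_t)X * Y * Z * Cin;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * xstride;
    double* os = out.begin() + n * OP * Cout;
    for (int p0 = 0; p0 < (int)OP; p0 += CH) {
      const int p1 = std::min<int>(p0 + CH, (int)OP);
      const int pc = p1 - p0;
      if (Xc.n_cols != (size_t)pc) Xc.set_size(K, pc);
      im2col_chunk(xs, X, Y, Z, Cin, k, OX, OY, p0, p1, Xc);
      arma::mat Yc = Xc.t() * W;  // pc x Cout
      for (int co = 0; co < Cout; ++co) {
        double* dst = os + (size_t)co * OP + p0;
        const double* srcc = Yc.colptr(co);
        const double bb = bias[co];
        for (int p = 0; p < pc; ++p) dst[p] = srcc[p] + bb;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3], N = xd[4];
  const int k = wd[0], Cout = wd[4];
  const int OX = out_len(X, k, 1), OY = out_len(Y, k, 1), OZ = out_len(Z, k, 1);
  const int K = k * k * k * Cin;
  const size_t OP = (size_t)OX * OY * OZ;
  const int XY = X * Y, XYZ = X * Y * Z;

  const arma::mat W(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx(need_dx ? (size_t)XYZ * Cin * N : 1);
  if (need_dx) dx.attr("dim") = xd;
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  const int CH = chunk_cols(K);
  arma::mat Xc(K, std::min<int>(CH, (int)OP));
  const size_t xstride = (size_t)XYZ * Cin;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * xstride;
    const double* dys = dy.begin() + n * OP * Cout;
    double* dxs = need_dx ? dx.begin() + n * xstride : nullptr;
    for (int p0 = 0; p0 < (int)OP; p0 += CH) {
      const int p1 = std::min<int>(p0 + CH, (int)OP);
      const int pc = p1 - p0;
      if (Xc.n_cols != (size_t)pc) Xc.set_size(K, pc);
      im2col_chunk(xs, X, Y, Z, Cin, k, OX, OY, p0, p1, Xc);
      arma::mat dYc(pc, Cout);
      for (int co = 0; co < Cout; ++co) {
        const double* srcc = dys + (size_t)co * OP + p0;
        std::memcpy(dYc.colptr(co), srcc, pc * sizeof(double));
      }
      dW += Xc * dYc;
      db += arma::sum(dYc, 0).t();
      if (!need_dx) continue;
      arma::mat dXc = W * dYc.t();  // K x pc
      for (int p = p0; p < p1; ++p) {
        const int ox = p % OX;
        const int oy = (p / OX) % OY;
        const int oz = p / (OX * OY);
        const double* col = dXc.colptr(p - p0);
        int r = 0;
        for (int ci = 0; ci < Cin; ++ci) {
          double* xc = dxs + (size_t)ci * XYZ;
          for (int kz = 0; kz < k; ++kz) {
            const int z = oz + kz;
            for (int ky = 0; ky < k; ++ky) {
              double* dst = xc + (size_t)z * XY + (size_t)(oy + ky) * X + ox;
              for (int kx = 0; kx < k; ++kx) dst[kx] += col[r + kx];
              r += k;
            }
          }
        }
      }
    }
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool3d_forward_cpp(NumericVector x, int k, int s) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3], N = xd[4];
  const int OX = out_len(X, k, s), OY = out_len(Y, k, s), OZ = out_len(Z, k, s);
  if (OX < 1 || OY < 1 || OZ < 1)
    stop("maxpool3d: kernel %d does not fit input %dx%dx%d", k, X, Y, Z);
  const int XY = X * Y;
  const size_t XYZ = (size_t)X * Y * Z, OP = (size_t)OX * OY * OZ;
  NumericVector y(OP * C * N);
  IntegerVector am(OP * C * N);
  IntegerVector od = IntegerVector::create(OX, OY, OZ, C, N);
  y.attr("dim") = od;
  am.attr("dim") = od;

  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + n * XYZ * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + c * XYZ;
      for (int oz = 0; oz < OZ; ++oz)
        for (int oy = 0; oy < OY; ++oy)
          for (int ox = 0; ox < OX; ++ox, ++o) {
            const int x0 = ox * s, y0 = oy * s, z0 = oz * s;
            double best = -std::numeric_limits<double>::infinity();
            int besti = 0;
            for (int kz = 0; kz < k; ++kz)
              for (int ky = 0; ky < k; ++ky) {
                const double* row = xc + (size_t)(z0 + kz) * XY +
                                    (size_t)(y0 + ky) * X + x0;
                for (int kx = 0; kx < k; ++kx)
                  if (row[kx] > best) {
                    best = row[kx];
                    besti = (x0 + kx) + (y0 + ky) * X + (z0 + kz) * XY;
                  }
              }
            y[o] = best;
            am[o] = besti;
          }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool3d_backward_cpp(NumericVector dy, IntegerVector am,
                                     IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const size_t XYZ = (size_t)X * Y * Z;
  IntegerVector od = dy.attr("dim");
  const size_t OP = (size_t)od[0] * od[1] * od[2];
  NumericVector dx(XYZ * C * N);
  dx.attr("dim") = xdim;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + n * XYZ * C + c * XYZ;
      for (size_t p = 0; p < OP; ++p, ++o) dxc[am[o]] += dy[o];
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector trilinear_resize_cpp(NumericVector x, IntegerVector odim) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int OX = odim[0], OY = odim[1], OZ = odim[2];
  NumericVector out((size_t)OX * OY * OZ);
  out.attr("dim") = odim;
  const double rx = (double)X / OX, ry = (double)Y / OY, rz = (double)Z / OZ;
  const int XY = X * Y;
  size_t o = 0;
  for (int oz = 0; oz < OZ; ++oz) {
    double sz = (oz + 0.5) * rz - 0.5;
    sz = std::min(std::max(sz, 0.0), (double)(Z - 1));
    const int z0 = std::min((int)std::floor(sz), Z - 2 >= 0 ? Z - 2 : 0);
    const double fz = Z > 1 ? sz - z0 : 0.0;
    for (int oy = 0; oy < OY; ++oy) {
      double sy = (oy + 0.5) * ry - 0.5;
      sy = std::min(std::max(sy, 0.0), (double)(Y - 1));
      const int y0 = std::min((int)std::floor(sy), Y - 2 >= 0 ? Y - 2 : 0);
      const double fy = Y > 1 ? sy - y0 : 0.0;
      for (int ox = 0; ox < OX; ++ox, ++o) {
        double sx = (ox + 0.5) * rx - 0.5;
        sx = std::min(std::max(sx, 0.0), (double)(X - 1));
        const int x0 = std::min((int)std::floor(sx), X - 2 >= 0 ? X - 2 : 0);
        const double fx = X > 1 ? sx - x0 : 0.0;
        const double* base = x.begin() + (size_t)z0 * XY + (size_t)y0 * X + x0;
        const int dxs = (X > 1) ? 1 : 0, dys = (Y > 1) ? X : 0,
                  dzs = (Z > 1) ? XY : 0;
        const double c000 = base[0], c100 = base[dxs];
        const double c010 = base[dys], c110 = base[dys + dxs];
        const double c001 = base[dzs], c101 = base[dzs + dxs];
        const double c011 = base[dzs + dys], c111 = base[dzs + dys + dxs];
        const double c00 = c000 + fx * (c100 - c000);
        const double c10 = c010 + fx * (c110 - c010);
        const double c01 = c001 + fx * (c101 - c001);
        const double c11 = c011 + fx * (c111 - c011);
        const double c0 = c00 + fy * (c10 - c00);
        const double c1 = c01 + fy * (c11 - c01);
        out[o] = c0 + fz * (c1 - c0);
      }
    }
  }
  return out;
}

// rotate a single 3D volume by `deg` degrees about spatial axis `axis`
// (1 = x, 2 = y, 3 = z), about the volume center, trilinear interpolation;
// voxels sampled outside the input get `fill`.
// [[Rcpp::export]]
NumericVector rotate3d_cpp(NumericVector x, int axis, double deg,
                           double fill) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int XY = X * Y;
  NumericVector out((size_t)X * Y * Z);
  out.attr("dim") = xd;
  const double th = deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cx = (X - 1) / 2.0, cy = (Y - 1) / 2.0, cz = (Z - 1) / 2.0;
  size_t o = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xi = 0; xi < X; ++xi, ++o) {
        const double ux = xi - cx, uy = y - cy, uz = z - cz;
        double sx, sy, szz;  // inverse rotation of output coords
        if (axis == 1) {
          sx = ux;
          sy = ct * uy + st * uz;
          szz = -st * uy + ct * uz;
        } else if (axis == 2) {
          sx = ct * ux - st * uz;
          sy = uy;
          szz = st * ux + ct * uz;
        } else {
          sx = ct * ux + st * uy;
          sy = -st * ux + ct * uy;
          szz = uz;
        }
        sx += cx;
        sy += cy;
        szz += cz;
        if (sx < 0 || sx > X - 1 || sy < 0 || sy > Y - 1 || szz < 0 ||
            szz > Z - 1) {
          out[o] = fill;
          continue;
        }
        int x0 = std::min((int)std::floor(sx), X - 2 >= 0 ? X - 2 : 0);
        int y0 = std::min((int)std::floor(sy), Y - 2 >= 0 ? Y - 2 : 0);
        int z0 = std::min((int)std::floor(szz), Z - 2 >= 0 ? Z - 2 : 0);
        const double fx = sx - x0, fy = sy - y0, fz = szz - z0;
        const double* base = x.begin() + (size_t)z0 * XY + (size_t)y0 * X + x0;
        const int dxs = (X > 1) ? 1 : 0, dys = (Y > 1) ? X : 0,
                  dzs = (Z > 1) ? XY : 0;
        const double c000 = base[0], c100 = base[dxs];
        const double c010 = base[dys], c110 = base[dys + dxs];
        const double c001 = base[dzs], c101 = base[dzs + dxs];
        const double c011 = base[dzs + dys], c111 = base[dzs + dys + dxs];
        const double c00 = c000 + fx * (c100 - c000);
        const double c10 = c010 + fx * (c110 - c010);
        const double c01 = c001 + fx * (c101 - c001);
        const double c11 = c011 + fx * (c111 - c011);
        const double c0 = c00 + fy * (c10 - c00);
        const double c1 = c01 + fy * (c11 - c01);
        out[o] = c0 + fz * (c1 - c0);
      }
  return out;
}
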