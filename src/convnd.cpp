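// Minimal n-d convolution engine: im2col + GEMM forward, GEMM backward.
// Tensors are R arrays in column-major layout (nx, ny, nz, channels);
// 2-d feature maps are handled as (nx, ny, 1, channels) with kz = 1.
// Chunked over the z axis so the im2col buffer stays small.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill im2col block for output z-range [z0, z1): K is (kx*ky*kz*ci) x (ox*oy*(z1-z0))
static void im2col_block(const double* x, int nx, int ny, int nz, int ci,
                         int kx, int ky, int kz, int sx, int sy, int sz,
                         int px, int py, int pz, int ox, int oy,
                         int z0, int z1, arma::mat& K) {
  K.zeros();
  const int rowsPerC = kx * ky * kz;
  for (int oz = z0; oz < z1; ++oz) {
    for (int oyi = 0; oyi < oy; ++oyi) {
      for (int oxi = 0; oxi < ox; ++oxi) {
        const int col = oxi + ox * (oyi + oy * (oz - z0));
        const int ix0 = oxi * sx - px, iy0 = oyi * sy - py, iz0 = oz * sz - pz;
        for (int c = 0; c < ci; ++c) {
          for (int dz = 0; dz < kz; ++dz) {
            const int iz = iz0 + dz;
            if (iz < 0 || iz >= nz) continue;
            for (int dy = 0; dy < ky; ++dy) {
              const int iy = iy0 + dy;
              if (iy < 0 || iy >= ny) continue;
              const double* xp = x + (size_t)nx * (iy + (size_t)ny * (iz + (size_t)nz * c));
              double* kp = K.colptr(col) + c * rowsPerC + kx * (dy + ky * dz);
              const int dlo = std::max(0, -ix0), dhi = std::min(kx, nx - ix0);
              for (int dx = dlo; dx < dhi; ++dx) kp[dx] = xp[ix0 + dx];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector convnd_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b, IntegerVector stride,
                            IntegerVector pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], co = wdim[4];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int ox = out_dim(nx, kx, sx, px), oy = out_dim(ny, ky, sy, py),
            oz = out_dim(nz, kz, sz, pz);
  const int R = kx * ky * kz * ci;

  NumericVector y((size_t)ox * oy * oz * co);
  arma::mat W(const_cast<double*>(w.begin()), R, co, false, true);

  int zb = std::max(1, (int)(8e6 / ((double)R * ox * oy * sizeof(double))));
  arma::mat K(R, (size_t)ox * oy * zb);
  for (int z0 = 0; z0 < oz; z0 += zb) {
    const int z1 = std::min(oz, z0 + zb);
    const int ncol = ox * oy * (z1 - z0);
    arma::mat Kv(K.memptr(), R, ncol, false, true);
    im2col_block(x.begin(), nx, ny, nz, ci, kx, ky, kz, sx, sy, sz,
                 px, py, pz, ox, oy, z0, z1, Kv);
    arma::mat Y = W.t() * Kv;  // co x ncol
    for (int c = 0; c < co; ++c) {
      double* yp = y.begin() + (size_t)ox * oy * z0 + (size_t)ox * oy * oz * c;
      const double bc = b[c];
      for (int j = 0; j < ncol; ++j) yp[j] = Y(c, j) + bc;
    }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, co);
  return y;
}

// [[Rcpp::export]]
List convnd_bw_cpp(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector gy, IntegerVector stride, IntegerVector pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], co = wdim[4];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int ox = out_dim(nx, kx, sx, px), oy = out_dim(ny, ky, sy, py),
            oz = out_dim(nz, kz, sz, pz);
  const int R = kx * ky * kz * ci;

  NumericVector gx((size_t)nx * ny * nz * ci);
  arma::mat W(const_cast<double*>(w.begin()), R, co, false, true);
  arma::mat gW(R, co, arma::fill::zeros);
  arma::vec gb(co, arma::fill::zeros);

  int zb = std::max(1, (int)(8e6 / ((double)R * ox * oy * sizeof(double))));
  arma::mat K(R, (size_t)ox * oy * zb);
  for (int z0 = 0; z0 < oz; z0 += zb) {
    const int z1 = std::min(oz, z0 + zb);
    const int ncol = ox * oy * (z1 - z0);
    arma::mat Kv(K.memptr(), R, ncol, false, true);
    im2col_block(x.begin(), nx, ny, nz, ci, kx, ky, kz, sx, sy, sz,
                 px, py, pz, ox, oy, z0, z1, Kv);
    arma::mat G(co, ncol);
    for (int c = 0; c < co; ++c) {
      const double* gp = gy.begin() + (size_t)ox * oy * z0 + (size_t)ox * oy * oz * c;
      double acc = 0.0;
      for (int j = 0; j < ncol; ++j) { G(c, j) = gp[j]; acc += gp[j]; }
      gb[c] += acc;
    }
    gW += Kv * G.t();
    arma::mat GX = W * G;  // R x ncol, scatter-add (col2im)
    const int rowsPerC = kx * ky * kz;
    for (int ozi = z0; ozi < z1; ++ozi) {
      for (int oyi = 0; oyi < oy; ++oyi) {
        for (int oxi = 0; oxi < ox; ++oxi) {
          const int col = oxi + ox * (oyi + oy * (ozi - z0));
          const int ix0 = oxi * sx - px, iy0 = oyi * sy - py, iz0 = ozi * sz - pz;
          const double* gcol = GX.colptr(col);
          for (int c = 0; c < ci; ++c) {
            for (int dz = 0; dz < kz; ++dz) {
              const int iz = iz0 + dz;
              if (iz < 0 || iz >= nz) continue;
              for (int dy = 0; dy < ky; ++dy) {
                const int iy = iy0 + dy;
                if (iy < 0 || iy >= ny) continue;
                double* xp = gx.begin() + (size_t)nx * (iy + (size_t)ny * (iz + (size_t)nz * c));
                const double* kp = gcol + c * rowsPerC + kx * (dy + ky * dz);
                const int dlo = std::max(0, -ix0), dhi = std::min(kx, nx - ix0);
                for (int dx = dlo; dx < dhi; ++dx) xp[ix0 + dx] += kp[dx];
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  NumericVector gwOut(w.size());
  std::copy(gW.begin(), gW.end(), gwOut.begin());
  gwOut.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gwOut,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Nearest-neighbour upsampling by integer factors along the three spatial axes.
// [[Rcpp::export]]
NumericVector upsample_nn_fw_cpp(NumericVector x, IntegerVector xdim,
                                 IntegerVector f) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], nc = xdim[3];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int ox = nx * fx, oy = ny * fy, oz = nz * fz;
  NumericVector y((size_t)ox * oy * oz * nc);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z)
      for (int j = 0; j < oy; ++j) {
        const double* xp = x.begin() +
          (size_t)nx * ((j / fy) + (size_t)ny * ((z / fz) + (size_t)nz * c));
        double* yp = y.begin() + (size_t)ox * (j + (size_t)oy * (z + (size_t)oz * c));
        for (int i = 0; i < ox; ++i) yp[i] = xp[i / fx];
      }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_nn_bw_cpp(NumericVector gy, IntegerVector ydim,
                                 IntegerVector f) {
  const int ox = ydim[0], oy = ydim[1], oz = ydim[2], nc = ydim[3];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int nx = ox / fx, ny = oy / fy, nz = oz / fz;
  NumericVector gx((size_t)nx * ny * nz * nc);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z)
      for (int j = 0; j < oy; ++j) {
        double* xp = gx.begin() +
          (size_t)nx * ((j / fy) + (size_t)ny * ((z / fz) + (size_t)nz * c));
        const double* gp = gy.begin() + (size_t)ox * (j + (size_t)oy * (z + (size_t)oz * c));
        for (int i = 0; i < ox; ++i) xp[i / fx] += gp[i];
      }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return gx;
}

// Fused instance-norm + leaky-ReLU, one pass per channel; backward recovers
// the activation mask from the sign of the cached normalised tensor.
// [[Rcpp::export]]
List in_act_fw_cpp(NumericVector x, int nspatial, int nc, double eps,
                   double slope) {
  NumericVector y(x.size()), xh(x.size()), sd(nc);
  for (int c = 0; c < nc; ++c) {
    const double* xp = x.begin() + (size_t)nspatial * c;
    double* yp = y.begin() + (size_t)nspatial * c;
    double* hp = xh.begin() + (size_t)nspatial * c;
    double mu = 0.0;
    for (int i = 0; i < nspatial; ++i) mu += xp[i];
    mu /= nspatial;
    double var = 0.0;
    for (int i = 0; i < nspatial; ++i) {
      const double d = xp[i] - mu;
      var += d * d;
    }
    const double s = std::sqrt(var / nspatial + eps);
    sd[c] = s;
    for (int i = 0; i < nspatial; ++i) {
      const double h = (xp[i] - mu) / s;
      hp[i] = h;
      yp[i] = h > 0 ? h : slope * h;
    }
  }
  return List::create(_["y"] = y, _["xh"] = xh, _["sd"] = sd);
}

// [[Rcpp::export]]
NumericVector in_act_bw_cpp(NumericVector xh, NumericVector sd,
                            NumericVector gy, int nspatial, int nc,
                            double slope) {
  NumericVector gx(gy.size());
  for (int c = 0; c < nc; ++c) {
    const double* hp = xh.begin() + (size_t)nspatial * c;
    const double* gp = gy.begin() + (size_t)nspatial * c;
    double* op = gx.begin() + (size_t)nspatial * c;
    double mg = 0.0, mgh = 0.0;
    for (int i = 0; i < nspatial; ++i) {
      const double g = hp[i] > 0 ? gp[i] : slope * gp[i];
      op[i] = g;  // stash lrelu-backward value
      mg += g;
      mgh += g * hp[i];
    }
    mg /= nspatial;
    mgh /= nspatial;
    const double s = sd[c];
    for (int i = 0; i < nspatial; ++i)
      op[i] = (op[i] - mg - hp[i] * mgh) / s;
  }
  return gx;
}
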