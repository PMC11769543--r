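#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel order throughout: column-major over (x, y, z), 0-based,
// linear index = x + nx * (y + ny * z). Feature maps are C x N matrices.

static inline int conv_out_extent(int d, int k, int pad, int stride) {
  return (d + 2 * pad - k) / stride + 1;
}

// Lower a C x N feature map to a (C*k^3) x Nout patch matrix so that a
// 3D convolution becomes a single GEMM. Out-of-bounds taps are zero.
// Row layout: c + C * (kx + k * (ky + k * kz)).
// [[Rcpp::export(name = ".im2col3d")]]
NumericMatrix im2col3d(const NumericMatrix& x, const IntegerVector& dims,
                       int k, int pad, int stride) {
  const int C = x.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = conv_out_extent(nx, k, pad, stride);
  const int oy = conv_out_extent(ny, k, pad, stride);
  const int oz = conv_out_extent(nz, k, pad, stride);
  const int Nout = ox * oy * oz;
  NumericMatrix out(C * k * k * k, Nout);
  const double* xp = x.begin();
  double* op = out.begin();
  const int rows = C * k * k * k;
  for (int zo = 0; zo < oz; ++zo) {
    for (int yo = 0; yo < oy; ++yo) {
      for (int xo = 0; xo < ox; ++xo) {
        const int col = xo + ox * (yo + (long)oy * zo);
        double* ocol = op + (long)col * rows;
        for (int kz = 0; kz < k; ++kz) {
          const int zi = zo * stride - pad + kz;
          for (int ky = 0; ky < k; ++ky) {
            const int yi = yo * stride - pad + ky;
            for (int kx = 0; kx < k; ++kx) {
              const int xi = xo * stride - pad + kx;
              double* dst = ocol + (long)C * (kx + k * (ky + k * kz));
              if (xi < 0 || xi >= nx || yi < 0 || yi >= ny ||
                  zi < 0 || zi >= nz) {
                for (int c = 0; c < C; ++c) dst[c] = 0.0;
              } else {
                const double* src = xp + (long)C * (xi + nx * (yi + (long)ny * zi));
                for (int c = 0; c < C; ++c) dst[c] = src[c];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3d: scatter-add patch columns back onto the input grid.
// [[Rcpp::export(name = ".col2im3d")]]
NumericMatrix col2im3d(const NumericMatrix& cols, const IntegerVector& dims,
                       int C, int k, int pad, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = conv_out_extent(nx, k, pad, stride);
  const int oy = conv_out_extent(ny, k, pad, stride);
  const int oz = conv_out_extent(nz, k, pad, stride);
  NumericMatrix out(C, (long)nx * ny * nz);
  const double* cp = cols.begin();
  double* op = out.begin();
  const int rows = C * k * k * k;
  for (int zo = 0; zo < oz; ++zo) {
    for (int yo = 0; yo < oy; ++yo) {
      for (int xo = 0; xo < ox; ++xo) {
        const int col = xo + ox * (yo + (long)oy * zo);
        const double* ccol = cp + (long)col * rows;
        for (int kz = 0; kz < k; ++kz) {
          const int zi = zo * stride - pad + kz;
          if (zi < 0 || zi >= nz) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int yi = yo * stride - pad + ky;
            if (yi < 0 || yi >= ny) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int xi = xo * stride - pad + kx;
              if (xi < 0 || xi >= nx) continue;
              const double* src = ccol + (long)C * (kx + k * (ky + k * kz));
              double* dst = op + (long)C * (xi + nx * (yi + (long)ny * zi));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Resample a scalar 3D array through an affine map from output voxel index
// to continuous input voxel coordinates: in = A %*% c(out_idx, 1).
// mode 0 = trilinear, 1 = nearest neighbour. Points whose continuous
// coordinate falls outside [-0.5, d-0.5] get `fill`.
// [[Rcpp::export(name = ".resampleAffine3d")]]
NumericVector resample_affine3d(const NumericVector& x,
                                const IntegerVector& in_dims,
                                const NumericMatrix& A,
                                const IntegerVector& out_dims,
                                int mode, double fill) {
  const int nx = in_dims[0], ny = in_dims[1], nz = in_dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((long)ox * oy * oz);
  const double* xp = x.begin();
  double* op = out.begin();
  const double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2), a03 = A(0,3);
  const double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2), a13 = A(1,3);
  const double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2), a23 = A(2,3);
  long idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i, ++idx) {
        const double u = a00 * i + a01 * j + a02 * k + a03;
        const double v = a10 * i + a11 * j + a12 * k + a13;
        const double w = a20 * i + a21 * j + a22 * k + a23;
        if (u < -0.5 || u > nx - 0.5 || v < -0.5 || v > ny - 0.5 ||
            w < -0.5 || w > nz - 0.5) {
          op[idx] = fill;
          continue;
        }
        if (mode == 1) {
          int ui = (int)std::lround(u), vi = (int)std::lround(v),
              wi = (int)std::lround(w);
          if (ui < 0) ui = 0; if (ui >= nx) ui = nx - 1;
          if (vi < 0) vi = 0; if (vi >= ny) vi = ny - 1;
          if (wi < 0) wi = 0; if (wi >= nz) wi = nz - 1;
          op[idx] = xp[ui + (long)nx * (vi + (long)ny * wi)];
        } else {
          const double uf = std::floor(u), vf = std::floor(v), wf = std::floor(w);
          const double du = u - uf, dv = v - vf, dw = w - wf;
          int u0 = (int)uf, v0 = (int)vf, w0 = (int)wf;
          int u1 = u0 + 1, v1 = v0 + 1, w1 = w0 + 1;
          // clamp taps at the border (coordinate itself is in-bounds)
          if (u0 < 0) u0 = 0; if (v0 < 0) v0 = 0; if (w0 < 0) w0 = 0;
          if (u1 >= nx) u1 = nx - 1; if (v1 >= ny) v1 = ny - 1;
          if (w1 >= nz) w1 = nz - 1;
          const long s00 = (long)nx * (v0 + (long)ny * w0);
          const long s10 = (long)nx * (v1 + (long)ny * w0);
          const long s01 = (long)nx * (v0 + (long)ny * w1);
          const long s11 = (long)nx * (v1 + (long)ny * w1);
          const double c000 = xp[u0 + s00], c100 = xp[u1 + s00];
          const double c010 = xp[u0 + s10], c110 = xp[u1 + s10];
          const double c001 = xp[u0 + s01], c101 = xp[u1 + s01];
          const double c011 = xp[u0 + s11], c111 = xp[u1 + s11];
          const double c00 = c000 * (1 - du) + c100 * du;
          const double c10 = c010 * (1 - du) + c110 * du;
          const double c01 = c001 * (1 - du) + c101 * du;
          const double c11 = c011 * (1 - du) + c111 * du;
          const double c0 = c00 * (1 - dv) + c10 * dv;
          const double c1 = c01 * (1 - dv) + c11 * dv;
          op[idx] = c0 * (1 - dw) + c1 * dw;
        }
      }
    }
  }
  return out;
}

// 26-connected component labelling of a binary 3D field. Labels are
// assigned in raster-scan order of each component's first voxel, so the
// labelling is deterministic.
// [[Rcpp::export(name = ".labelComponents26")]]
IntegerVector label_components26(const IntegerVector& mask,
                                 const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector labels(n);
  const int* mp = mask.begin();
  int* lp = labels.begin();
  std::vector<long> stack;
  int next = 0;
  for (long s = 0; s < n; ++s) {
    if (mp[s] == 0 || lp[s] != 0) continue;
    ++next;
    lp[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const long cur = stack.back();
      stack.pop_back();
      const int cx = (int)(cur % nx);
      const int cy = (int)((cur / nx) % ny);
      const int cz = (int)(cur / ((long)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        const int z2 = cz + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y2 = cy + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int x2 = cx + dx;
            if (x2 < 0 || x2 >= nx) continue;
            const long t = x2 + (long)nx * (y2 + (long)ny * z2);
            if (mp[t] != 0 && lp[t] == 0) {
              lp[t] = next;
              stack.push_back(t);
            }
          }
        }
      }
    }
  }
  return labels;
}

#include <R_ext/BLAS.h>

// Fused 3D convolution forward: tiles the output voxels, lowers each tile
// with im2col into a small workspace and multiplies through dgemm. Avoids
// materialising the full patch matrix.
// [[Rcpp::export(name = ".conv3dForward")]]
NumericMatrix conv3d_forward(const NumericMatrix& x, const IntegerVector& dims,
                             const NumericMatrix& W, const NumericVector& b,
                             int k, int pad, int stride) {
  const int C = x.nrow();
  const int Cout = W.nrow();
  const int kk = k * k * k;
  const int rows = C * kk;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = conv_out_extent(nx, k, pad, stride);
  const int oy = conv_out_extent(ny, k, pad, stride);
  const int oz = conv_out_extent(nz, k, pad, stride);
  const long Nout = (long)ox * oy * oz;
  NumericMatrix y(Cout, Nout);
  const double* xp = x.begin();
  double* yp = y.begin();
  const int tile = std::max(1, (int)std::min<long>(Nout, 16384 / (rows / 64 + 1) * 64));
  std::vector<double> col((size_t)rows * tile);
  const double one = 1.0, zero = 0.0;
  for (long t0 = 0; t0 < Nout; t0 += tile) {
    const int tn = (int)std::min<long>(tile, Nout - t0);
    for (int t = 0; t < tn; ++t) {
      const long o = t0 + t;
      const int xo = (int)(o % ox);
      const int yo = (int)((o / ox) % oy);
      const int zo = (int)(o / ((long)ox * oy));
      double* ocol = col.data() + (size_t)t * rows;
      for (int kz = 0; kz < k; ++kz) {
        const int zi = zo * stride - pad + kz;
        for (int ky = 0; ky < k; ++ky) {
          const int yi = yo * stride - pad + ky;
          for (int kx = 0; kx < k; ++kx) {
            const int xi = xo * stride - pad + kx;
            double* dst = ocol + (long)C * (kx + k * (ky + k * kz));
            if (xi < 0 || xi >= nx || yi < 0 || yi >= ny ||
                zi < 0 || zi >= nz) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double* src = xp + (long)C * (xi + nx * (yi + (long)ny * zi));
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
    // y_tile (Cout x tn) = W (Cout x rows) * col (rows x tn)
    F77_CALL(dgemm)("N", "N", &Cout, &tn, &rows, &one, W.begin(), &Cout,
                    col.data(), &rows, &zero, yp + (size_t)t0 * Cout, &Cout
                    FCONE FCONE);
  }
  if (b.size() == Cout) {
    for (long o = 0; o < Nout; ++o) {
      double* yc = yp + (size_t)o * Cout;
      for (int c = 0; c < Cout; ++c) yc[c] += b[c];
    }
  }
  return y;
}

// Fused backward: returns dx (C x N), dW (Cout x C*k^3), db (Cout).
// [[Rcpp::export(name = ".conv3dBackward")]]
List conv3d_backward(const NumericMatrix& g, const NumericMatrix& x,
                     const IntegerVector& dims, const NumericMatrix& W,
                     int k, int pad, int stride) {
  const int C = x.nrow();
  const int Cout = W.nrow();
  const int kk = k * k * k;
  const int rows = C * kk;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = conv_out_extent(nx, k, pad, stride);
  const int oy = conv_out_extent(ny, k, pad, stride);
  const int oz = conv_out_extent(nz, k, pad, stride);
  const long Nout = (long)ox * oy * oz;
  NumericMatrix dx(C, x.ncol());
  NumericMatrix dW(Cout, rows);
  NumericVector db(Cout);
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* dxp = dx.begin();
  const int tile = std::max(1, (int)std::min<long>(Nout, 16384 / (rows / 64 + 1) * 64));
  std::vector<double> col((size_t)rows * tile);
  std::vector<double> dcol((size_t)rows * tile);
  const double one = 1.0, zero = 0.0;
  for (long t0 = 0; t0 < Nout; t0 += tile) {
    const int tn = (int)std::min<long>(tile, Nout - t0);
    for (int t = 0; t < tn; ++t) {
      const long o = t0 + t;
      const int xo = (int)(o % ox);
      const int yo = (int)((o / ox) % oy);
      const int zo = (int)(o / ((long)ox * oy));
      double* ocol = col.data() + (size_t)t * rows;
      for (int kz = 0; kz < k; ++kz) {
        const int zi = zo * stride - pad + kz;
        for (int ky = 0; ky < k; ++ky) {
          const int yi = yo * stride - pad + ky;
          for (int kx = 0; kx < k; ++kx) {
            const int xi = xo * stride - pad + kx;
            double* dst = ocol + (long)C * (kx + k * (ky + k * kz));
            if (xi < 0 || xi >= nx || yi < 0 || yi >= ny ||
                zi < 0 || zi >= nz) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double* src = xp + (long)C * (xi + nx * (yi + (long)ny * zi));
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
    const double* gt = gp + (size_t)t0 * Cout;
    // dW += g_tile * col^T : (Cout x tn)(tn x rows)
    F77_CALL(dgemm)("N", "T", &Cout, &rows, &tn, &one, gt, &Cout,
                    col.data(), &rows, &one, dW.begin(), &Cout FCONE FCONE);
    // dcol = W^T * g_tile : (rows x Cout)(Cout x tn)
    F77_CALL(dgemm)("T", "N", &rows, &tn, &Cout, &one, W.begin(), &Cout,
                    gt, &Cout, &zero, dcol.data(), &rows FCONE FCONE);
    for (int t = 0; t < tn; ++t) {
      const long o = t0 + t;
      const int xo = (int)(o % ox);
      const int yo = (int)((o / ox) % oy);
      const int zo = (int)(o / ((long)ox * oy));
      const double* ocol = dcol.data() + (size_t)t * rows;
      for (int kz = 0; kz < k; ++kz) {
        const int zi = zo * stride - pad + kz;
        if (zi < 0 || zi >= nz) continue;
        for (int ky = 0; ky < k; ++ky) {
          const int yi = yo * stride - pad + ky;
          if (yi < 0 || yi >= ny) continue;
          for (int kx = 0; kx < k; ++kx) {
            const int xi = xo * stride - pad + kx;
            if (xi < 0 || xi >= nx) continue;
            const double* src = ocol + (long)C * (kx + k * (ky + k * kz));
            double* dst = dxp + (long)C * (xi + nx * (yi + (long)ny * zi));
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
    for (int t = 0; t < tn; ++t) {
      const double* gc = gt + (size_t)t * Cout;
      for (int c = 0; c < Cout; ++c) db[c] += gc[c];
    }
  }
  return List::create(Named("dx") = dx, Named("dW") = dW,
                      Named("db") = db);
}
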