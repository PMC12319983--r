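#include <Rcpp.h>
using namespace Rcpp;

// Keys for the interpolation argument: 0 = nearest, 1 = trilinear, 3 = cubic
// (Catmull-Rom, interpolating). Out-of-field samples evaluate to 0.

static inline double at(const double* v, int nx, int ny, int nz,
                        int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

// Resample a 3D volume under an affine map given in voxel coordinates:
// for each output voxel (0-based index x), sample the input at M * [x, 1].
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dim,
                                  NumericMatrix M, int interp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* o = out.begin();

  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      // start of row: x = 0
      double sx = m01 * j + m02 * k + m03;
      double sy = m11 * j + m12 * k + m13;
      double sz = m21 * j + m22 * k + m23;
      for (int i = 0; i < nx; ++i, ++idx, sx += m00, sy += m10, sz += m20) {
        if (interp == 0) {
          int ii = (int)std::lround(sx), jj = (int)std::lround(sy),
              kk = (int)std::lround(sz);
          o[idx] = at(v, nx, ny, nz, ii, jj, kk);
        } else if (interp == 1) {
          double fx = std::floor(sx), fy = std::floor(sy), fz = std::floor(sz);
          int i0 = (int)fx, j0 = (int)fy, k0 = (int)fz;
          double tx = sx - fx, ty = sy - fy, tz = sz - fz;
          if (i0 < -1 || j0 < -1 || k0 < -1 ||
              i0 > nx - 1 || j0 > ny - 1 || k0 > nz - 1) {
            o[idx] = 0.0;
            continue;
          }
          if (i0 >= 0 && j0 >= 0 && k0 >= 0 &&
              i0 < nx - 1 && j0 < ny - 1 && k0 < nz - 1) {
            const double* p =
              v + i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0);
            const R_xlen_t sj = nx, sk = (R_xlen_t)nx * ny;
            double c00 = p[0] * (1 - tx) + p[1] * tx;
            double c10 = p[sj] * (1 - tx) + p[sj + 1] * tx;
            double c01 = p[sk] * (1 - tx) + p[sk + 1] * tx;
            double c11 = p[sk + sj] * (1 - tx) + p[sk + sj + 1] * tx;
            o[idx] = (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
                     (c01 * (1 - ty) + c11 * ty) * tz;
          } else {
            double c00 = at(v, nx, ny, nz, i0, j0, k0) * (1 - tx) +
                         at(v, nx, ny, nz, i0 + 1, j0, k0) * tx;
            double c10 = at(v, nx, ny, nz, i0, j0 + 1, k0) * (1 - tx) +
                         at(v, nx, ny, nz, i0 + 1, j0 + 1, k0) * tx;
            double c01 = at(v, nx, ny, nz, i0, j0, k0 + 1) * (1 - tx) +
                         at(v, nx, ny, nz, i0 + 1, j0, k0 + 1) * tx;
            double c11 = at(v, nx, ny, nz, i0, j0 + 1, k0 + 1) * (1 - tx) +
                         at(v, nx, ny, nz, i0 + 1, j0 + 1, k0 + 1) * tx;
            o[idx] = (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
                     (c01 * (1 - ty) + c11 * ty) * tz;
          }
        } else {
          double fx = std::floor(sx), fy = std::floor(sy), fz = std::floor(sz);
          int i0 = (int)fx, j0 = (int)fy, k0 = (int)fz;
          double tx = sx - fx, ty = sy - fy, tz = sz - fz;
          if (i0 < -2 || j0 < -2 || k0 < -2 ||
              i0 > nx || j0 > ny || k0 > nz) {
            o[idx] = 0.0;
            continue;
          }
          double wx[4], wy[4], wz[4];
          // Catmull-Rom tap weights per axis
          for (int a = 0; a < 4; ++a) {
            wx[a] = wy[a] = wz[a] = 0.0;
          }
          {
            double t = tx, t2 = tx * tx, t3 = t2 * tx;
            wx[0] = 0.5 * (-t3 + 2 * t2 - t);
            wx[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
            wx[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
            wx[3] = 0.5 * (t3 - t2);
            t = ty; t2 = t * t; t3 = t2 * t;
            wy[0] = 0.5 * (-t3 + 2 * t2 - t);
            wy[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
            wy[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
            wy[3] = 0.5 * (t3 - t2);
            t = tz; t2 = t * t; t3 = t2 * t;
            wz[0] = 0.5 * (-t3 + 2 * t2 - t);
            wz[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
            wz[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
            wz[3] = 0.5 * (t3 - t2);
          }
          double acc = 0.0;
          if (i0 >= 1 && j0 >= 1 && k0 >= 1 &&
              i0 < nx - 2 && j0 < ny - 2 && k0 < nz - 2) {
            const R_xlen_t sj = nx, sk = (R_xlen_t)nx * ny;
            const double* base =
              v + (i0 - 1) + (R_xlen_t)nx * ((j0 - 1) + (R_xlen_t)ny * (k0 - 1));
            for (int dk = 0; dk < 4; ++dk) {
              const double* pk = base + dk * sk;
              double accj = 0.0;
              for (int dj = 0; dj < 4; ++dj) {
                const double* pj = pk + dj * sj;
                accj += wy[dj] * (wx[0] * pj[0] + wx[1] * pj[1] +
                                  wx[2] * pj[2] + wx[3] * pj[3]);
              }
              acc += wz[dk] * accj;
            }
          } else {
            for (int dk = 0; dk < 4; ++dk) {
              double accj = 0.0;
              for (int dj = 0; dj < 4; ++dj) {
                double acci = 0.0;
                for (int di = 0; di < 4; ++di)
                  acci += wx[di] * at(v, nx, ny, nz, i0 - 1 + di,
                                      j0 - 1 + dj, k0 - 1 + dk);
                accj += wy[dj] * acci;
              }
              acc += wz[dk] * accj;
            }
          }
          o[idx] = acc;
        }
      }
    }
  }
  return out;
}
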