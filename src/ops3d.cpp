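// Low-level 3D array kernels: convolution, average pooling and resampling.
// Arrays follow R's column-major layout. Spatial tensors are stored as
// (x, y, z, channel); convolution weights as (kx, ky, kz, c_in, c_out).
// All accumulation is in double precision.

#include <Rcpp.h>
using namespace Rcpp;

// "same"-style padding: output size depends only on the stride,
// pad_total = max((out - 1) * stride + k - in, 0), split floor-first.
static inline void same_pad(int in, int k, int s, int& out, int& pad) {
  out = (in + s - 1) / s;
  int tot = (out - 1) * s + k - in;
  if (tot < 0) tot = 0;
  pad = tot / 2;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, NumericVector w, NumericVector bias,
                         IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd.size() != 4) stop("input must be a 4D (x, y, z, channel) array");
  if (wd.size() != 5) stop("weights must be a 5D (kx, ky, kz, c_in, c_out) array");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int KX = wd[0], KY = wd[1], KZ = wd[2], CI = wd[3], CO = wd[4];
  if (CI != C)
    stop("channel mismatch: input has %d channels, weights expect %d", C, CI);
  if (bias.size() != CO) stop("bias length must equal the output channel count");
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  if (sx < 1 || sy < 1 || sz < 1) stop("strides must be positive");

  int XO, YO, ZO, px, py, pz;
  same_pad(X, KX, sx, XO, px);
  same_pad(Y, KY, sy, YO, py);
  same_pad(Z, KZ, sz, ZO, pz);

  NumericVector out(R_xlen_t(XO) * YO * ZO * CO);
  out.attr("dim") = IntegerVector::create(XO, YO, ZO, CO);
  double* o = out.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();

  for (int co = 0; co < CO; ++co) {
    const double b = bias[co];
    double* oc = o + R_xlen_t(co) * XO * YO * ZO;
    for (R_xlen_t i = 0, nvox = R_xlen_t(XO) * YO * ZO; i < nvox; ++i) oc[i] = b;

    for (int ci = 0; ci < C; ++ci) {
      const double* xc = xp + R_xlen_t(ci) * X * Y * Z;
      for (int kz = 0; kz < KZ; ++kz) {
        // valid output range along z: 0 <= oz*sz + kz - pz < Z
        int lo = pz - kz;
        int oz0 = lo <= 0 ? 0 : (lo + sz - 1) / sz;
        int oz1 = (Z - 1 + pz - kz);
        if (oz1 < 0) continue;
        oz1 = std::min(ZO - 1, oz1 / sz);
        for (int ky = 0; ky < KY; ++ky) {
          int loy = py - ky;
          int oy0 = loy <= 0 ? 0 : (loy + sy - 1) / sy;
          int oy1 = (Y - 1 + py - ky);
          if (oy1 < 0) continue;
          oy1 = std::min(YO - 1, oy1 / sy);
          for (int kx = 0; kx < KX; ++kx) {
            const double wv =
              wp[kx + KX * (ky + KY * (kz + R_xlen_t(KZ) * (ci + R_xlen_t(CI) * co)))];
            if (wv == 0.0) continue;
            int lox = px - kx;
            int ox0 = lox <= 0 ? 0 : (lox + sx - 1) / sx;
            int ox1 = (X - 1 + px - kx);
            if (ox1 < 0) continue;
            ox1 = std::min(XO - 1, ox1 / sx);
            for (int oz = oz0; oz <= oz1; ++oz) {
              const int iz = oz * sz + kz - pz;
              for (int oy = oy0; oy <= oy1; ++oy) {
                const int iy = oy * sy + ky - py;
                const double* xrow = xc + R_xlen_t(X) * (iy + R_xlen_t(Y) * iz);
                double* orow = oc + R_xlen_t(XO) * (oy + R_xlen_t(YO) * oz);
                int ix = ox0 * sx + kx - px;
                for (int ox = ox0; ox <= ox1; ++ox, ix += sx)
                  orow[ox] += wv * xrow[ix];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Average pooling with "same" padding; padded voxels are excluded from the
// mean (divisor = number of in-bounds voxels), so constants are preserved.
// [[Rcpp::export]]
NumericVector cpp_avgpool3d(NumericVector x, IntegerVector kernel,
                            IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("input must be a 4D (x, y, z, channel) array");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int KX = kernel[0], KY = kernel[1], KZ = kernel[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  int XO, YO, ZO, px, py, pz;
  same_pad(X, KX, sx, XO, px);
  same_pad(Y, KY, sy, YO, py);
  same_pad(Z, KZ, sz, ZO, pz);

  NumericVector out(R_xlen_t(XO) * YO * ZO * C);
  out.attr("dim") = IntegerVector::create(XO, YO, ZO, C);
  double* o = out.begin();
  const double* xp = x.begin();

  for (int c = 0; c < C; ++c) {
    const double* xc = xp + R_xlen_t(c) * X * Y * Z;
    double* oc = o + R_xlen_t(c) * XO * YO * ZO;
    for (int oz = 0; oz < ZO; ++oz) {
      const int z0 = std::max(0, oz * sz - pz);
      const int z1 = std::min(Z, oz * sz - pz + KZ);
      for (int oy = 0; oy < YO; ++oy) {
        const int y0 = std::max(0, oy * sy - py);
        const int y1 = std::min(Y, oy * sy - py + KY);
        for (int ox = 0; ox < XO; ++ox) {
          const int x0 = std::max(0, ox * sx - px);
          const int x1 = std::min(X, ox * sx - px + KX);
          double acc = 0.0;
          for (int iz = z0; iz < z1; ++iz)
            for (int iy = y0; iy < y1; ++iy) {
              const double* xrow = xc + R_xlen_t(X) * (iy + R_xlen_t(Y) * iz);
              for (int ix = x0; ix < x1; ++ix) acc += xrow[ix];
            }
          const int cnt = (z1 - z0) * (y1 - y0) * (x1 - x0);
          oc[ox + R_xlen_t(XO) * (oy + R_xlen_t(YO) * oz)] =
            cnt > 0 ? acc / cnt : 0.0;
        }
      }
    }
  }
  return out;
}

// Resample a 3D grid to new dimensions. Voxel centers are aligned:
// in_coord = (out_index + 0.5) * scale - 0.5 (0-based), edge-clamped.
// method 0 = trilinear, 1 = nearest neighbour.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector out_dim,
                             NumericVector scale, int method) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("input must be a 3D array");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int XO = out_dim[0], YO = out_dim[1], ZO = out_dim[2];
  if (XO < 1 || YO < 1 || ZO < 1) stop("degenerate output shape");
  const double ax = scale[0], ay = scale[1], az = scale[2];
  NumericVector out(R_xlen_t(XO) * YO * ZO);
  out.attr("dim") = IntegerVector::create(XO, YO, ZO);
  const double* xp = x.begin();
  double* o = out.begin();

  for (int oz = 0; oz < ZO; ++oz) {
    double cz = (oz + 0.5) * az - 0.5;
    for (int oy = 0; oy < YO; ++oy) {
      double cy = (oy + 0.5) * ay - 0.5;
      for (int ox = 0; ox < XO; ++ox) {
        double cx = (ox + 0.5) * ax - 0.5;
        double v;
        if (method == 1) {
          int ix = std::min(X - 1, std::max(0, (int)std::lround(cx)));
          int iy = std::min(Y - 1, std::max(0, (int)std::lround(cy)));
          int iz = std::min(Z - 1, std::max(0, (int)std::lround(cz)));
          v = xp[ix + R_xlen_t(X) * (iy + R_xlen_t(Y) * iz)];
        } else {
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
              z0 = (int)std::floor(cz);
          double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          int x0c = std::min(X - 1, std::max(0, x0));
          int x1c = std::min(X - 1, std::max(0, x0 + 1));
          int y0c = std::min(Y - 1, std::max(0, y0));
          int y1c = std::min(Y - 1, std::max(0, y0 + 1));
          int z0c = std::min(Z - 1, std::max(0, z0));
          int z1c = std::min(Z - 1, std::max(0, z0 + 1));
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            int iz = dz ? z1c : z0c;
            double wz = dz ? fz : 1.0 - fz;
            if (wz == 0.0) continue;
            for (int dy = 0; dy < 2; ++dy) {
              int iy = dy ? y1c : y0c;
              double wy = dy ? fy : 1.0 - fy;
              if (wy == 0.0) continue;
              for (int dx = 0; dx < 2; ++dx) {
                int ix = dx ? x1c : x0c;
                double wx = dx ? fx : 1.0 - fx;
                if (wx == 0.0) continue;
                acc += wz * wy * wx *
                       xp[ix + R_xlen_t(X) * (iy + R_xlen_t(Y) * iz)];
              }
            }
          }
          v = acc;
        }
        o[ox + R_xlen_t(XO) * (oy + R_xlen_t(YO) * oz)] = v;
      }
    }
  }
  return out;
}
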