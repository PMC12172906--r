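#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Affine resampling of a 3D volume.
//
// `vmat` is a 4x4 voxel-to-voxel map taking 0-based target voxel indices
// (i,j,k) to continuous 0-based source voxel coordinates.  Samples whose
// continuous coordinate falls outside the source index box [0, dim-1] are
// filled with 0 and flagged out-of-bounds; for the interpolating kernels a
// sample is in-bounds when its *center* is inside the box, and neighbour
// taps outside the box contribute 0 (the volume is treated as zero-padded).
//
// method: 0 = nearest neighbour, 1 = trilinear, 2 = Hann-windowed sinc
// (radius 4, separable, weights renormalized to unit sum so constants are
// reproduced exactly away from the boundary).

// Hann-windowed sinc, radius 4: sinc(x) * 0.5 * (1 + cos(pi x / 4)).
// The Hann window is chosen over sharper windows (e.g. Lanczos) for its
// low sidelobes: overshoot rings around high-contrast lesion edges would
// otherwise masquerade as opposite-signed activity in the subtraction.
static inline double wsinc4(double x) {
  const double a = 4.0;
  if (x == 0.0) return 1.0;
  if (std::fabs(x) >= a) return 0.0;
  double px = M_PI * x;
  return (std::sin(px) / px) * 0.5 * (1.0 + std::cos(px / a));
}

// [[Rcpp::export(name = ".c_resample")]]
List c_resample(NumericVector src, IntegerVector sdim,
                NumericMatrix vmat, IntegerVector tdim, int method) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  const R_xlen_t n = (R_xlen_t)tx * ty * tz;
  NumericVector out(n);
  LogicalVector inb(n);

  const double m00 = vmat(0,0), m01 = vmat(0,1), m02 = vmat(0,2), m03 = vmat(0,3);
  const double m10 = vmat(1,0), m11 = vmat(1,1), m12 = vmat(1,2), m13 = vmat(1,3);
  const double m20 = vmat(2,0), m21 = vmat(2,1), m22 = vmat(2,2), m23 = vmat(2,3);

  const double *s = src.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      // start of the row at i = 0
      double x = m01*j + m02*k + m03;
      double y = m11*j + m12*k + m13;
      double z = m21*j + m22*k + m23;
      for (int i = 0; i < tx; ++i, ++idx, x += m00, y += m10, z += m20) {
        bool inside = (x >= 0.0 && x <= sx - 1.0 &&
                       y >= 0.0 && y <= sy - 1.0 &&
                       z >= 0.0 && z <= sz - 1.0);
        inb[idx] = inside;
        if (!inside && method != 2) { out[idx] = 0.0; continue; }

        if (method == 0) {            // nearest neighbour
          int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
          out[idx] = s[(R_xlen_t)xi + sx * ((R_xlen_t)yi + (R_xlen_t)sy * zi)];
        } else if (method == 1) {     // trilinear, zero-padded taps
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
          double fx = x - x0, fy = y - y0, fz = z - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz) {
            int zz = z0 + dz; if (zz < 0 || zz >= sz) continue;
            double wz = dz ? fz : 1.0 - fz; if (wz == 0.0) continue;
            for (int dy = 0; dy <= 1; ++dy) {
              int yy = y0 + dy; if (yy < 0 || yy >= sy) continue;
              double wy = dy ? fy : 1.0 - fy; if (wy == 0.0) continue;
              double wzy = wz * wy;
              for (int dx = 0; dx <= 1; ++dx) {
                int xx = x0 + dx; if (xx < 0 || xx >= sx) continue;
                double wx = dx ? fx : 1.0 - fx; if (wx == 0.0) continue;
                acc += wzy * wx * s[(R_xlen_t)xx + sx * ((R_xlen_t)yy + (R_xlen_t)sy * zz)];
              }
            }
          }
          out[idx] = acc;
        } else {                      // Hann-windowed sinc, radius 4
          if (!inside) { out[idx] = 0.0; continue; }
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
          double wxv[8], wyv[8], wzv[8];
          double swx = 0.0, swy = 0.0, swz = 0.0;
          for (int t = 0; t < 8; ++t) {
            int off = t - 3;
            wxv[t] = wsinc4(x - (x0 + off)); swx += wxv[t];
            wyv[t] = wsinc4(y - (y0 + off)); swy += wyv[t];
            wzv[t] = wsinc4(z - (z0 + off)); swz += wzv[t];
          }
          double norm = swx * swy * swz;
          double acc = 0.0;
          for (int dz = 0; dz < 8; ++dz) {
            int zz = z0 + dz - 3; if (zz < 0 || zz >= sz || wzv[dz] == 0.0) continue;
            for (int dy = 0; dy < 8; ++dy) {
              int yy = y0 + dy - 3; if (yy < 0 || yy >= sy || wyv[dy] == 0.0) continue;
              double wzy = wzv[dz] * wyv[dy];
              const double *row = s + sx * ((R_xlen_t)yy + (R_xlen_t)sy * zz);
              for (int dx = 0; dx < 8; ++dx) {
                int xx = x0 + dx - 3; if (xx < 0 || xx >= sx) continue;
                acc += wzy * wxv[dx] * row[xx];
              }
            }
          }
          out[idx] = acc / norm;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(tx, ty, tz);
  inb.attr("dim") = IntegerVector::create(tx, ty, tz);
  return List::create(_["values"] = out, _["inbounds"] = inb);
}

// Registration metric evaluated over a precomputed set of fixed-image
// sample points (within-mask voxels only).  The moving image is sampled
// by trilinear interpolation through `vmat` (fixed voxel -> moving voxel
// continuous coordinates); out-of-bounds samples are dropped and reported
// through the returned mass fraction.
//
// metric 0: normalized mutual information (Studholme), joint histogram of
//   the precomputed fixed-intensity bins `fbin` (1..nbf) against moving
//   bins over [mlo, mhi].
// metric 1: correlation ratio eta^2 of the moving intensities given the
//   fixed bins, with voxel weights `w`.
// interp 1: trilinear; interp 2: Hann-windowed sinc of radius 2 (used for
//   the final refinement pass, where trilinear interpolation error would
//   bias the metric optimum).

static inline double wsinc2(double x) {
  const double a = 2.0;
  if (x == 0.0) return 1.0;
  if (std::fabs(x) >= a) return 0.0;
  double px = M_PI * x;
  return (std::sin(px) / px) * 0.5 * (1.0 + std::cos(px / a));
}

// [[Rcpp::export(name = ".c_metric")]]
List c_metric(NumericVector src, IntegerVector sdim, NumericMatrix vmat,
              NumericMatrix pts, IntegerVector fbin, NumericVector w,
              int nbf, int nbm, double mlo, double mhi, int metric,
              int interp = 1) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const R_xlen_t n = pts.nrow();
  const double m00 = vmat(0,0), m01 = vmat(0,1), m02 = vmat(0,2), m03 = vmat(0,3);
  const double m10 = vmat(1,0), m11 = vmat(1,1), m12 = vmat(1,2), m13 = vmat(1,3);
  const double m20 = vmat(2,0), m21 = vmat(2,1), m22 = vmat(2,2), m23 = vmat(2,3);
  const double *s = src.begin();
  const double *px = &pts(0,0), *py = &pts(0,1), *pz = &pts(0,2);

  std::vector<double> joint;
  std::vector<double> sw, sm, sm2;
  if (metric == 0) joint.assign((size_t)nbf * nbm, 0.0);
  else { sw.assign(nbf, 0.0); sm.assign(nbf, 0.0); sm2.assign(nbf, 0.0); }

  double mass = 0.0, total = 0.0;
  const double mscale = nbm / (mhi - mlo);
  for (R_xlen_t q = 0; q < n; ++q) {
    double wq = w[q];
    total += wq;
    double x = m00*px[q] + m01*py[q] + m02*pz[q] + m03;
    double y = m10*px[q] + m11*py[q] + m12*pz[q] + m13;
    double z = m20*px[q] + m21*py[q] + m22*pz[q] + m23;
    if (x < 0.0 || x > sx - 1.0 || y < 0.0 || y > sy - 1.0 ||
        z < 0.0 || z > sz - 1.0) continue;
    mass += wq;
    int x0 = (int)x, y0 = (int)y, z0 = (int)z;
    if (x0 == sx - 1) --x0;
    if (y0 == sy - 1) --y0;
    if (z0 == sz - 1) --z0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double m;
    if (interp == 1) {
      const double *base = s + (R_xlen_t)x0 + sx * ((R_xlen_t)y0 + (R_xlen_t)sy * z0);
      const R_xlen_t dyo = sx, dzo = (R_xlen_t)sx * sy;
      double c00 = base[0]   * (1-fx) + base[1]       * fx;
      double c10 = base[dyo] * (1-fx) + base[dyo + 1] * fx;
      double c01 = base[dzo] * (1-fx) + base[dzo + 1] * fx;
      double c11 = base[dzo + dyo] * (1-fx) + base[dzo + dyo + 1] * fx;
      m = ((c00 * (1-fy) + c10 * fy) * (1-fz) +
           (c01 * (1-fy) + c11 * fy) * fz);
    } else {
      double wxv[4], wyv[4], wzv[4];
      double swx = 0.0, swy = 0.0, swz = 0.0;
      for (int t = 0; t < 4; ++t) {
        int off = t - 1;
        wxv[t] = wsinc2(fx - off); swx += wxv[t];
        wyv[t] = wsinc2(fy - off); swy += wyv[t];
        wzv[t] = wsinc2(fz - off); swz += wzv[t];
      }
      double acc = 0.0;
      for (int dz = 0; dz < 4; ++dz) {
        int zz = z0 + dz - 1; if (zz < 0) zz = 0; if (zz >= sz) zz = sz - 1;
        for (int dy = 0; dy < 4; ++dy) {
          int yy = y0 + dy - 1; if (yy < 0) yy = 0; if (yy >= sy) yy = sy - 1;
          double wzy = wzv[dz] * wyv[dy];
          const double *row = s + sx * ((R_xlen_t)yy + (R_xlen_t)sy * zz);
          for (int dx = 0; dx < 4; ++dx) {
            int xx = x0 + dx - 1; if (xx < 0) xx = 0; if (xx >= sx) xx = sx - 1;
            acc += wzy * wxv[dx] * row[xx];
          }
        }
      }
      m = acc / (swx * swy * swz);
    }
    if (metric == 0) {
      int bm = (int)((m - mlo) * mscale);
      if (bm < 0) bm = 0; if (bm >= nbm) bm = nbm - 1;
      joint[(size_t)(fbin[q] - 1) + (size_t)nbf * bm] += wq;
    } else {
      int b = fbin[q] - 1;
      sw[b] += wq; sm[b] += wq * m; sm2[b] += wq * m * m;
    }
  }
  double value = NA_REAL;
  if (mass > 0) {
    if (metric == 0) {
      std::vector<double> pf(nbf, 0.0), pm(nbm, 0.0);
      double hj = 0.0;
      for (int bm = 0; bm < nbm; ++bm)
        for (int bf = 0; bf < nbf; ++bf) {
          double p = joint[(size_t)bf + (size_t)nbf * bm] / mass;
          if (p > 0) { hj -= p * std::log(p); pf[bf] += p; pm[bm] += p; }
        }
      double hf = 0.0, hm = 0.0;
      for (int bf = 0; bf < nbf; ++bf) if (pf[bf] > 0) hf -= pf[bf] * std::log(pf[bf]);
      for (int bm = 0; bm < nbm; ++bm) if (pm[bm] > 0) hm -= pm[bm] * std::log(pm[bm]);
      value = (hj > 0) ? (hf + hm) / hj : NA_REAL;
    } else {
      double stot = 0.0, stot2 = 0.0, vwithin = 0.0;
      for (int b = 0; b < nbf; ++b) {
        stot += sm[b]; stot2 += sm2[b];
        if (sw[b] > 0) vwithin += sm2[b] - sm[b] * sm[b] / sw[b];
      }
      double mu = stot / mass;
      double vtot = stot2 / mass - mu * mu;
      value = (vtot > 0) ? 1.0 - (vwithin / mass) / vtot : 0.0;
    }
  }
  return List::create(_["value"] = value,
                      _["massFraction"] = total > 0 ? mass / total : 0.0);
}
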