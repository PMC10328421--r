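#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear resampling of a 3D volume. `map` is a 4x4 matrix sending
// 0-based target voxel indices to 0-based source voxel coordinates.
// Target voxels mapping outside the source grid get NA.
// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector src, IntegerVector dims,
                                     NumericMatrix map) {
  IntegerVector sdim = src.attr("dim");
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = dims[0], ty = dims[1], tz = dims[2];
  NumericVector out(static_cast<R_xlen_t>(tx) * ty * tz, NA_REAL);
  out.attr("dim") = dims;
  const double *m = REAL(map);  // column-major 4x4
  const double *s = REAL(src);
  double *o = REAL(out);
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      for (int i = 0; i < tx; ++i) {
        double xs = m[0] * i + m[4] * j + m[8] * k + m[12];
        double ys = m[1] * i + m[5] * j + m[9] * k + m[13];
        double zs = m[2] * i + m[6] * j + m[10] * k + m[14];
        if (xs < 0 || ys < 0 || zs < 0 ||
            xs > sx - 1 || ys > sy - 1 || zs > sz - 1) continue;
        int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys), z0 = (int)std::floor(zs);
        if (x0 == sx - 1) x0--;
        if (y0 == sy - 1) y0--;
        if (z0 == sz - 1) z0--;
        if (sx == 1) x0 = 0;
        if (sy == 1) y0 = 0;
        if (sz == 1) z0 = 0;
        double fx = xs - x0, fy = ys - y0, fz = zs - z0;
        int x1 = std::min(x0 + 1, sx - 1);
        int y1 = std::min(y0 + 1, sy - 1);
        int z1 = std::min(z0 + 1, sz - 1);
        #define V(a, b, c) s[(a) + sx * ((b) + (R_xlen_t)sy * (c))]
        double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
        double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
        double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
        double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
        #undef V
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        o[i + tx * ((R_xlen_t)j + (R_xlen_t)ty * k)] = c0 * (1 - fz) + c1 * fz;
      }
    }
  }
  return out;
}

// Per-slice (2D) non-local-means filtering. The similarity weight combines
// (a) the mean squared patch difference with the expected noise
// contribution 2*sigma^2 subtracted, so flat regions average aggressively,
// and (b) a centre-difference guard that only activates when the two
// centre pixels differ by more than ~2 sigma, which protects single-voxel
// structures (whose centre contrast is their defining feature) without
// introducing centre-selection bias in flat regions.
// The guard is gated on `zsupport`: it only engages where the adjacent
// slab shows local contrast too (a through-plane tubular structure
// continues across slabs; an isolated noise spike does not).
// [[Rcpp::export]]
NumericVector nlm2d_cpp(NumericVector vol, int patch_radius, int search_radius,
                        double h, double sigma,
                        double guard_beta, double guard_h,
                        NumericVector zsupport, double z_thresh) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  out.attr("dim") = dim;
  const double *v = REAL(vol);
  double *o = REAL(out);
  const double h2 = h * h;
  const double two_s2 = 2.0 * sigma * sigma;
  const double beta_s2 = guard_beta * sigma * sigma;
  const double gh2 = guard_h * guard_h;
  const double *zs = REAL(zsupport);
  for (int k = 0; k < nz; ++k) {
    const double *sl = v + (R_xlen_t)nx * ny * k;
    double *os = o + (R_xlen_t)nx * ny * k;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double wsum = 0.0, acc = 0.0;
        for (int dj = -search_radius; dj <= search_radius; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -search_radius; di <= search_radius; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            double d2 = 0.0;
            int npx = 0;
            for (int pj = -patch_radius; pj <= patch_radius; ++pj) {
              for (int pi = -patch_radius; pi <= patch_radius; ++pi) {
                int ai = i + pi, aj = j + pj;
                int bi = ii + pi, bj = jj + pj;
                if (ai < 0 || ai >= nx || aj < 0 || aj >= ny) continue;
                if (bi < 0 || bi >= nx || bj < 0 || bj >= ny) continue;
                double d = sl[ai + (R_xlen_t)nx * aj] - sl[bi + (R_xlen_t)nx * bj];
                d2 += d * d;
                npx++;
              }
            }
            if (npx == 0) continue;
            d2 /= npx;
            double dd = d2 - two_s2;
            if (dd < 0) dd = 0;
            double w = std::exp(-dd / h2);
            if (zs[(R_xlen_t)nx * ny * k + i + (R_xlen_t)nx * j] > z_thresh) {
              double dc = sl[i + (R_xlen_t)nx * j] - sl[ii + (R_xlen_t)nx * jj];
              double gg = dc * dc - beta_s2;
              if (gg > 0) w *= std::exp(-gg / gh2);
            }
            wsum += w;
            acc += w * sl[ii + (R_xlen_t)nx * jj];
          }
        }
        os[i + (R_xlen_t)nx * j] = (wsum > 0) ? acc / wsum : sl[i + (R_xlen_t)nx * j];
      }
    }
  }
  return out;
}

// 8-connected component labeling run independently within each slice along
// the third array axis ("edges or corners touch"; clusters never span
// slices). Labels are unique across the whole volume; 0 = background.
// [[Rcpp::export]]
IntegerVector label_slices8_cpp(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dim;
  const int *m = LOGICAL(mask);
  int *L = INTEGER(lab);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; ++k) {
    R_xlen_t off = (R_xlen_t)nx * ny * k;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = off + i + (R_xlen_t)nx * j;
        if (m[idx] != 1 || L[idx] != 0) continue;
        ++next;
        stack.clear();
        stack.push_back(idx);
        L[idx] = next;
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int ci = (int)((cur - off) % nx);
          int cj = (int)((cur - off) / nx);
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0) continue;
              int ni = ci + di, nj = cj + dj;
              if (ni < 0 || ni >= nx || nj < 0 || nj >= ny) continue;
              R_xlen_t nidx = off + ni + (R_xlen_t)nx * nj;
              if (m[nidx] == 1 && L[nidx] == 0) {
                L[nidx] = next;
                stack.push_back(nidx);
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

// 3D 6-connected component labeling (used by the white-matter fallback
// segmentation to keep the largest brain component).
// [[Rcpp::export]]
IntegerVector label3d6_cpp(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dim;
  const int *m = LOGICAL(mask);
  int *L = INTEGER(lab);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t n = mask.size();
  for (R_xlen_t start = 0; start < n; ++start) {
    if (m[start] != 1 || L[start] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(start);
    L[start] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int ci = (int)(cur % nx);
      int cj = (int)((cur / nx) % ny);
      int ck = (int)(cur / ((R_xlen_t)nx * ny));
      const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int q = 0; q < 6; ++q) {
        int ni = ci + d[q][0], nj = cj + d[q][1], nk = ck + d[q][2];
        if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz) continue;
        R_xlen_t nidx = ni + nx * ((R_xlen_t)nj + (R_xlen_t)ny * nk);
        if (m[nidx] == 1 && L[nidx] == 0) {
          L[nidx] = next;
          stack.push_back(nidx);
        }
      }
    }
  }
  return lab;
}

// Minimum distance from each of a set of points to a 3D segment [p0, p1],
// vectorized for phantom tube rendering.
// [[Rcpp::export]]
NumericVector dist_to_segment_cpp(NumericMatrix pts, NumericVector p0,
                                  NumericVector p1) {
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  double dx = p1[0] - p0[0], dy = p1[1] - p0[1], dz = p1[2] - p0[2];
  double len2 = dx * dx + dy * dy + dz * dz;
  for (R_xlen_t i = 0; i < n; ++i) {
    double ax = pts(i, 0) - p0[0], ay = pts(i, 1) - p0[1], az = pts(i, 2) - p0[2];
    double t = len2 > 0 ? (ax * dx + ay * dy + az * dz) / len2 : 0.0;
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    double ex = ax - t * dx, ey = ay - t * dy, ez = az - t * dz;
    out[i] = std::sqrt(ex * ex + ey * ey + ez * ez);
  }
  return out;
}
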