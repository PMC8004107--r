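#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Poisson log-likelihood of ROI data d under mu = b + a*g (factorial terms
// dropped; they cancel in likelihood ratios).
static inline double roi_loglik(const std::vector<double>& d,
                                const std::vector<double>& g,
                                double a, double b) {
  double ll = 0.0;
  const int n = (int)d.size();
  for (int m = 0; m < n; ++m) {
    const double mu = b + a * g[m];
    if (d[m] > 0.0) ll += d[m] * std::log(mu);
    ll -= mu;
  }
  return ll;
}

// Per-voxel generalized likelihood ratio statistic for a fixed-width 3D
// Gaussian spot plus constant background vs background alone, Poisson noise.
// img is an (nz, ny, nx) array (z fastest); gz / gxy are the pixel-integrated
// 1D Gaussian profiles along z and lateral axes. Edge voxels whose ROI leaves
// the image are returned as NA.
// [[Rcpp::export]]
NumericVector glrt_scan_cpp(NumericVector img, IntegerVector dim,
                            NumericVector gz, NumericVector gxy) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int dz = gz.size(), dxy = gxy.size();
  const int hz = (dz - 1) / 2, hxy = (dxy - 1) / 2;
  const int nroi = dz * dxy * dxy;

  // separable template, normalised to sum 1 (amplitude parameter = photons in ROI)
  std::vector<double> g(nroi);
  double gs = 0.0;
  {
    int idx = 0;
    for (int i = 0; i < dxy; ++i)
      for (int j = 0; j < dxy; ++j)
        for (int k = 0; k < dz; ++k) {
          const double v = gz[k] * gxy[j] * gxy[i];
          g[idx++] = v;
          gs += v;
        }
  }
  double g2 = 0.0;
  for (int m = 0; m < nroi; ++m) { g[m] /= gs; g2 += g[m] * g[m]; }

  NumericVector out(nz * ny * nx, NA_REAL);
  out.attr("dim") = dim;
  std::vector<double> d(nroi);
  const double n = (double)nroi;

  for (int x = hxy; x < nx - hxy; ++x) {
    for (int y = hxy; y < ny - hxy; ++y) {
      for (int z = hz; z < nz - hz; ++z) {
        // gather ROI
        int idx = 0;
        double sumd = 0.0, sgd = 0.0;
        for (int i = -hxy; i <= hxy; ++i)
          for (int j = -hxy; j <= hxy; ++j) {
            const R_xlen_t base = (R_xlen_t)(x + i) * ny * nz + (R_xlen_t)(y + j) * nz + z;
            for (int k = -hz; k <= hz; ++k) {
              const double v = img[base + k];
              d[idx] = v;
              sumd += v;
              sgd += g[idx] * v;
              ++idx;
            }
          }
        const R_xlen_t o = (R_xlen_t)x * ny * nz + (R_xlen_t)y * nz + z;
        const double b0 = sumd / n;
        if (b0 <= 0.0) { out[o] = 0.0; continue; }
        // score in the amplitude direction at the H0 fit; non-positive score
        // means the constrained MLE sits on the boundary a = 0 (T = 0 exactly)
        const double score = sgd / b0 - 1.0;
        if (score <= 0.0) { out[o] = 0.0; continue; }
        // Rao score statistic (background profiled): first-order equivalent
        // to the LRT. Far below any usable significance cut-off the score
        // value stands in for T; the exact boundary MLE is only computed
        // where it could matter.
        const double s_stat = score * score * b0 / (g2 - 1.0 / n);
        if (s_stat < 9.0) { out[o] = s_stat; continue; }
        // exact boundary-constrained MLE: step-clamped Newton (no line
        // search on the fast path; a guarded pass below catches the rare
        // non-converged case)
        double a = score * b0 / g2;
        double b = b0 - a / n;
        if (b < 1e-9) b = 1e-9;
        bool converged = false;
        for (int iter = 0; iter < 20; ++iter) {
          double ga = 0, gb = 0, haa = 0, hab = 0, hbb = 0;
          for (int m = 0; m < nroi; ++m) {
            const double inv = 1.0 / (b + a * g[m]);
            const double r = d[m] * inv - 1.0;
            const double w = (r + 1.0) * inv;
            ga += g[m] * r;
            gb += r;
            haa += g[m] * g[m] * w;
            hab += g[m] * w;
            hbb += w;
          }
          const double det = haa * hbb - hab * hab;
          if (!(det > 1e-300)) break;
          double da = (hbb * ga - hab * gb) / det;
          double db = (haa * gb - hab * ga) / det;
          // keep parameters in the feasible region (at most halve towards 0)
          if (a + da < -0.5 * a) da = -0.5 * a;
          if (b + db < 0.5 * b) db = -0.5 * b;
          a += da;
          b += db;
          if (a < 1e-12 && ga <= 0.0) { a = 0.0; b = b0; converged = true; break; }
          if (std::fabs(da) < 1e-8 * (a + 1.0) && std::fabs(db) < 1e-8 * (b + 1.0)) {
            converged = true;
            break;
          }
        }
        double T = 0.0;
        if (converged || a > 0.0) {
          double ll1 = 0.0;
          for (int m = 0; m < nroi; ++m) {
            if (d[m] > 0.0) ll1 += d[m] * std::log((b + a * g[m]) / b0);
          }
          T = 2.0 * (ll1 - (n * b + a - sumd));
        }
        if (!(T >= 0.0) || (!converged && T < s_stat)) {
          // guarded fallback: damped Newton with explicit likelihood ascent
          a = score * b0 / g2;
          b = b0 - a / n;
          if (b < 1e-9) b = 1e-9;
          double ll = roi_loglik(d, g, a, b);
          const double ll0 = sumd * std::log(b0) - n * b0;
          for (int iter = 0; iter < 50; ++iter) {
            double ga = 0, gb = 0, haa = 0, hab = 0, hbb = 0;
            for (int m = 0; m < nroi; ++m) {
              const double inv = 1.0 / (b + a * g[m]);
              const double r = d[m] * inv - 1.0;
              const double w = (r + 1.0) * inv;
              ga += g[m] * r;
              gb += r;
              haa += g[m] * g[m] * w;
              hab += g[m] * w;
              hbb += w;
            }
            const double det = haa * hbb - hab * hab;
            if (!(det > 1e-300)) break;
            const double da = (hbb * ga - hab * gb) / det;
            const double db = (haa * gb - hab * ga) / det;
            double step = 1.0, lln = ll, an = a, bn = b;
            bool ok = false;
            for (int h = 0; h < 25; ++h) {
              an = a + step * da;
              bn = b + step * db;
              if (an < 0.0) an = 0.0;
              if (bn < 1e-12) bn = 1e-12;
              lln = roi_loglik(d, g, an, bn);
              if (lln >= ll - 1e-12) { ok = true; break; }
              step *= 0.5;
            }
            if (!ok) break;
            const double dll = lln - ll;
            a = an; b = bn; ll = lln;
            if (dll < 1e-10 * (std::fabs(ll) + 1.0)) break;
          }
          T = 2.0 * (ll - ll0);
          if (T < 0.0) T = 0.0;
        }
        out[o] = T;
      }
    }
  }
  return out;
}

// Pull-warp of a 3D image under an affine map on 1-based (z, y, x) voxel
// coordinates: output(p) = img(M p + t), trilinear, out-of-bounds -> 0.
// [[Rcpp::export]]
NumericVector warp_affine_cpp(NumericVector img, IntegerVector dim,
                              NumericVector M, NumericVector t) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(nz * ny * nx);
  out.attr("dim") = dim;
  // M row-major rows (z, y, x)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const double pz = z + 1.0, py = y + 1.0, px = x + 1.0;
        const double qz = M[0] * pz + M[1] * py + M[2] * px + t[0] - 1.0;
        const double qy = M[3] * pz + M[4] * py + M[5] * px + t[1] - 1.0;
        const double qx = M[6] * pz + M[7] * py + M[8] * px + t[2] - 1.0;
        const R_xlen_t o = (R_xlen_t)x * ny * nz + (R_xlen_t)y * nz + z;
        if (qz < 0 || qz > nz - 1 || qy < 0 || qy > ny - 1 || qx < 0 || qx > nx - 1) {
          out[o] = 0.0;
          continue;
        }
        int z0 = (int)std::floor(qz), y0 = (int)std::floor(qy), x0 = (int)std::floor(qx);
        if (z0 > nz - 2) z0 = nz - 2 < 0 ? 0 : nz - 2;
        if (y0 > ny - 2) y0 = ny - 2 < 0 ? 0 : ny - 2;
        if (x0 > nx - 2) x0 = nx - 2 < 0 ? 0 : nx - 2;
        const double fz = qz - z0, fy = qy - y0, fx = qx - x0;
        double acc = 0.0;
        for (int cx = 0; cx <= 1; ++cx)
          for (int cy = 0; cy <= 1; ++cy)
            for (int cz = 0; cz <= 1; ++cz) {
              const double w = (cz ? fz : 1 - fz) * (cy ? fy : 1 - fy) * (cx ? fx : 1 - fx);
              if (w == 0.0) continue;
              const R_xlen_t ii = (R_xlen_t)(x0 + cx) * ny * nz + (R_xlen_t)(y0 + cy) * nz + (z0 + cz);
              acc += w * img[ii];
            }
        out[o] = acc;
      }
  return out;
}

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;       // half-sample mirror: -1 -> 0, -2 -> 1
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur of a (ny, nx) matrix, reflective boundaries.
// [[Rcpp::export]]
NumericMatrix gauss_blur2d_cpp(NumericMatrix im, double sigma) {
  const int ny = im.nrow(), nx = im.ncol();
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double ks = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    ks += k[i + r];
  }
  for (auto& v : k) v /= ks;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * im(reflect_idx(y + i, ny), x);
      tmp(y, x) = acc;
    }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(y, reflect_idx(x + i, nx));
      out(y, x) = acc;
    }
  return out;
}

// Rolling-ball background: grayscale opening with a ball-shaped (non-flat)
// structuring element of the given radius. Returns the background estimate.
// [[Rcpp::export]]
NumericMatrix rolling_ball_cpp(NumericMatrix im, double radius) {
  const int ny = im.nrow(), nx = im.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> ox, oy;
  std::vector<double> oh;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      const double d2 = (double)dx * dx + (double)dy * dy;
      if (d2 <= radius * radius) {
        ox.push_back(dx);
        oy.push_back(dy);
        oh.push_back(std::sqrt(radius * radius - d2) - radius); // <= 0, peak 0
      }
    }
  const int no = (int)ox.size();
  NumericMatrix ero(ny, nx), bg(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double mn = R_PosInf;
      for (int m = 0; m < no; ++m) {
        const int yy = y + oy[m], xx = x + ox[m];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        const double v = im(yy, xx) - oh[m];
        if (v < mn) mn = v;
      }
      ero(y, x) = mn;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double mx = R_NegInf;
      for (int m = 0; m < no; ++m) {
        const int yy = y + oy[m], xx = x + ox[m];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        const double v = ero(yy, xx) + oh[m];
        if (v > mx) mx = v;
      }
      bg(y, x) = mx;
    }
  return bg;
}

// Local maxima of the statistic field within an ellipsoidal-cylinder
// neighborhood (lateral radius r_xy, axial radius r_z). Only voxels with
// stat >= floor are considered (others cannot be selected downstream).
// Ties are broken towards the smaller linear index.
// [[Rcpp::export]]
LogicalVector local_max_cpp(NumericVector stat, IntegerVector dim,
                            double r_xy, int r_z, double floor_val) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int rxi = (int)std::floor(r_xy);
  LogicalVector out(nz * ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t o = (R_xlen_t)x * ny * nz + (R_xlen_t)y * nz + z;
        const double v = stat[o];
        if (ISNA(v) || v < floor_val) continue;
        bool is_max = true;
        for (int i = -rxi; i <= rxi && is_max; ++i) {
          const int xx = x + i;
          if (xx < 0 || xx >= nx) continue;
          for (int j = -rxi; j <= rxi && is_max; ++j) {
            const int yy = y + j;
            if (yy < 0 || yy >= ny) continue;
            if ((double)i * i + (double)j * j > r_xy * r_xy) continue;
            for (int k = -r_z; k <= r_z; ++k) {
              const int zz = z + k;
              if (zz < 0 || zz >= nz) continue;
              const R_xlen_t n = (R_xlen_t)xx * ny * nz + (R_xlen_t)yy * nz + zz;
              if (n == o) continue;
              const double w = stat[n];
              if (ISNA(w)) continue;
              if (w > v || (w == v && n < o)) { is_max = false; break; }
            }
          }
        }
        out[o] = is_max;
      }
  return out;
}
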