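#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double DT_INF = 1e18;

// ---------------------------------------------------------------------------
// 1D squared distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher.
// ---------------------------------------------------------------------------
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int q0 = -1;
  for (int q = 0; q < n; q++) if (f[q] < DT_INF) { q0 = q; break; }
  if (q0 < 0) {
    for (int q = 0; q < n; q++) d[q] = DT_INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] >= DT_INF) continue;            // no parabola at q
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    int p = v[k];
    d[q] = (double)(q - p) * (q - p) + f[p];
  }
}

// in-place 3D squared EDT of f (0 at seeds, DT_INF elsewhere)
static void edt3(std::vector<double>& f, int n1, int n2, int n3) {
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> line(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1 (stride 1)
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      double* p = &f[(size_t)n1 * (j + (size_t)n2 * k)];
      dt1d(p, out.data(), n1, v.data(), z.data());
      std::copy(out.begin(), out.begin() + n1, p);
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      size_t base = (size_t)i + (size_t)n1 * n2 * k;
      for (int j = 0; j < n2; j++) line[j] = f[base + (size_t)n1 * j];
      dt1d(line.data(), out.data(), n2, v.data(), z.data());
      for (int j = 0; j < n2; j++) f[base + (size_t)n1 * j] = out[j];
    }
  // axis 3 (stride n1*n2)
  size_t s3 = (size_t)n1 * n2;
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      size_t base = (size_t)i + (size_t)n1 * j;
      for (int k = 0; k < n3; k++) line[k] = f[base + s3 * k];
      dt1d(line.data(), out.data(), n3, v.data(), z.data());
      for (int k = 0; k < n3; k++) f[base + s3 * k] = out[k];
    }
}

// squared EDT of the foreground: distance to the nearest background voxel.
// border_bg: if true the volume border counts as background; if false the
// volume is treated as extending indefinitely (no seeds outside the grid).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         bool border_bg = true) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int pad = border_bg ? 1 : 0;
  int p1 = n1 + 2 * pad, p2 = n2 + 2 * pad, p3 = n3 + 2 * pad;
  std::vector<double> f((size_t)p1 * p2 * p3, 0.0);
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      size_t src = (size_t)n1 * (j + (size_t)n2 * k);
      size_t dst = pad + (size_t)p1 * ((j + pad) + (size_t)p2 * (k + pad));
      for (int i = 0; i < n1; i++)
        f[dst + i] = mask[src + i] ? DT_INF : 0.0;
    }
  edt3(f, p1, p2, p3);
  NumericVector res((size_t)n1 * n2 * n3);
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      size_t src = pad + (size_t)p1 * ((j + pad) + (size_t)p2 * (k + pad));
      size_t dst = (size_t)n1 * (j + (size_t)n2 * k);
      for (int i = 0; i < n1; i++) res[dst + i] = f[src + i];
    }
  res.attr("dim") = dim;
  return res;
}

// distance (squared) from every voxel to the nearest TRUE voxel; no border
// effect (outside the grid there are no seeds).
// [[Rcpp::export]]
NumericVector cpp_dist_sq_to(LogicalVector seeds, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  std::vector<double> f(n);
  for (size_t l = 0; l < n; l++) f[l] = seeds[l] ? 0.0 : DT_INF;
  edt3(f, n1, n2, n3);
  NumericVector res(n);
  std::copy(f.begin(), f.end(), res.begin());
  res.attr("dim") = dim;
  return res;
}

// ---------------------------------------------------------------------------
// Connected component labelling (6 / 18 / 26 connectivity), iterative BFS.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  int maxnorm;
  if (connectivity == 6) maxnorm = 1;
  else if (connectivity == 18) maxnorm = 2;
  else if (connectivity == 26) maxnorm = 3;
  else stop("connectivity must be 6, 18 or 26");
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        int s = a * a + b * b + c * c;
        if (s > 0 && s <= maxnorm) { di.push_back(a); dj.push_back(b); dk.push_back(c); }
      }
  int ndir = (int)di.size();
  IntegerVector labels(n);
  std::vector<double> counts;
  std::vector<size_t> stack;
  int cur = 0;
  size_t s3 = (size_t)n1 * n2;
  for (size_t seed = 0; seed < n; seed++) {
    if (!mask[seed] || labels[seed] != 0) continue;
    cur++;
    double cnt = 0;
    labels[seed] = cur;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      size_t l = stack.back();
      stack.pop_back();
      cnt += 1;
      int k = (int)(l / s3);
      size_t r = l - (size_t)k * s3;
      int j = (int)(r / n1);
      int i = (int)(r - (size_t)j * n1);
      for (int d = 0; d < ndir; d++) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
        size_t ll = (size_t)ii + (size_t)n1 * jj + s3 * kk;
        if (mask[ll] && labels[ll] == 0) {
          labels[ll] = cur;
          stack.push_back(ll);
        }
      }
    }
    counts.push_back(cnt);
  }
  labels.attr("dim") = dim;
  return List::create(_["labels"] = labels,
                      _["counts"] = NumericVector(counts.begin(), counts.end()));
}

// ---------------------------------------------------------------------------
// Local thickness: diameter of the largest inscribed sphere covering each
// foreground voxel, via exact sphere-openings at a descending set of squared
// radii (integer-valued, in voxel units). A sphere of squared radius r2 is
// the strict ball {x : |x - c|^2 <= r2 - 1}; it fits at c iff EDT^2(c) >= r2.
// radii2 must be sorted descending. Returns thickness in voxels (0 on
// background).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim,
                                  NumericVector radii2, bool border_bg = true) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int pad = border_bg ? 1 : 0;
  int p1 = n1 + 2 * pad, p2 = n2 + 2 * pad, p3 = n3 + 2 * pad;
  size_t np = (size_t)p1 * p2 * p3;
  std::vector<double> edt(np, 0.0);
  std::vector<char> fg(np, 0);
  size_t nfg = 0;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      size_t src = (size_t)n1 * (j + (size_t)n2 * k);
      size_t dst = pad + (size_t)p1 * ((j + pad) + (size_t)p2 * (k + pad));
      for (int i = 0; i < n1; i++)
        if (mask[src + i]) { edt[dst + i] = DT_INF; fg[dst + i] = 1; nfg++; }
    }
  edt3(edt, p1, p2, p3);

  std::vector<double> out(np, 0.0), work(np);
  size_t remaining = nfg;
  for (int ri = 0; ri < radii2.size() && remaining > 0; ri++) {
    double r2 = radii2[ri];
    // seeds: erosion by the strict ball of squared radius r2
    bool any = false;
    for (size_t l = 0; l < np; l++) {
      if (fg[l] && edt[l] >= r2) { work[l] = 0.0; any = true; }
      else work[l] = DT_INF;
    }
    if (!any) continue;
    edt3(work, p1, p2, p3);
    double val = 2.0 * std::sqrt(r2);
    for (size_t l = 0; l < np; l++) {
      if (fg[l] && out[l] == 0.0 && work[l] <= r2 - 1.0) {
        out[l] = val;
        remaining--;
      }
    }
  }
  NumericVector res((size_t)n1 * n2 * n3);
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      size_t src = pad + (size_t)p1 * ((j + pad) + (size_t)p2 * (k + pad));
      size_t dst = (size_t)n1 * (j + (size_t)n2 * k);
      for (int i = 0; i < n1; i++) res[dst + i] = out[src + i];
    }
  res.attr("dim") = dim;
  return res;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with mirror boundary handling.
// ---------------------------------------------------------------------------
static void blur_axis(std::vector<double>& f, int n1, int n2, int n3, int axis,
                      const std::vector<double>& kern) {
  int R = (int)(kern.size() - 1) / 2;
  int len = (axis == 1) ? n1 : (axis == 2 ? n2 : n3);
  size_t stride = (axis == 1) ? 1 : (axis == 2 ? (size_t)n1 : (size_t)n1 * n2);
  std::vector<double> line(len), out(len);
  int o1 = (axis == 1) ? n2 : n1;
  for (int b = 0; b < ((axis == 3) ? n2 : n3); b++)
    for (int a = 0; a < o1; a++) {
      size_t base;
      if (axis == 1) base = (size_t)n1 * (a + (size_t)n2 * b);
      else if (axis == 2) base = (size_t)a + (size_t)n1 * n2 * b;
      else base = (size_t)a + (size_t)n1 * b;
      for (int q = 0; q < len; q++) line[q] = f[base + stride * q];
      for (int q = 0; q < len; q++) {
        double acc = 0;
        for (int t = -R; t <= R; t++) {
          int idx = q + t;
          if (idx < 0) idx = -idx - 1;
          if (idx >= len) idx = 2 * len - 1 - idx;
          if (idx < 0) idx = 0;          // very short lines
          if (idx >= len) idx = len - 1;
          acc += kern[t + R] * line[idx];
        }
        out[q] = acc;
      }
      for (int q = 0; q < len; q++) f[base + stride * q] = out[q];
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim, double sigma) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  size_t n = (size_t)n1 * n2 * n3;
  std::vector<double> f(vol.begin(), vol.end());
  int R = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> kern(2 * R + 1);
  double s = 0;
  for (int t = -R; t <= R; t++) {
    kern[t + R] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + R];
  }
  for (auto& w : kern) w /= s;
  blur_axis(f, n1, n2, n3, 1, kern);
  blur_axis(f, n1, n2, n3, 2, kern);
  blur_axis(f, n1, n2, n3, 3, kern);
  NumericVector res(n);
  std::copy(f.begin(), f.end(), res.begin());
  res.attr("dim") = dim;
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector vol, IntegerVector dim, int k) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int m1 = n1 / k, m2 = n2 / k, m3 = n3 / k;
  NumericVector res((size_t)m1 * m2 * m3);
  double inv = 1.0 / ((double)k * k * k);
  for (int c = 0; c < m3; c++)
    for (int b = 0; b < m2; b++)
      for (int a = 0; a < m1; a++) {
        double acc = 0;
        for (int dc = 0; dc < k; dc++)
          for (int db = 0; db < k; db++)
            for (int da = 0; da < k; da++)
              acc += vol[(size_t)(a * k + da) +
                         (size_t)n1 * ((b * k + db) + (size_t)n2 * (c * k + dc))];
        res[(size_t)a + (size_t)m1 * (b + (size_t)m2 * c)] = acc * inv;
      }
  res.attr("dim") = IntegerVector::create(m1, m2, m3);
  return res;
}

// ---------------------------------------------------------------------------
// Phantom rasterizers: accumulate the volume fraction occupied by tilted
// cylinders / arbitrarily oriented ellipsoids into `frac` (modified in
// place), using ss^3 subsamples per voxel. Coordinates are physical (um);
// voxel (i,j,k) spans [i*v,(i+1)*v] x ... along (dim1, dim2, dim3).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
void cpp_add_cylinders(NumericVector frac, IntegerVector dim, double voxel,
                       NumericMatrix cyl, int ss) {
  // cyl columns: x0, y0 (axis position at z = 0), tx, ty (slope per um of z),
  //              radius
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  double w = 1.0 / ((double)ss * ss * ss);
  std::vector<double> off(ss);
  for (int s = 0; s < ss; s++) off[s] = (s + 0.5) / ss * voxel;
  for (int c = 0; c < cyl.nrow(); c++) {
    double x0 = cyl(c, 0), y0 = cyl(c, 1), tx = cyl(c, 2), ty = cyl(c, 3),
           r = cyl(c, 4);
    double un = std::sqrt(1.0 + tx * tx + ty * ty);
    double ux = tx / un, uy = ty / un, uz = 1.0 / un;
    double halo = r * un + 1.5 * voxel;   // window half-width in-plane
    double r2 = r * r;
    for (int k = 0; k < n3; k++) {
      double zlo = k * voxel, zhi = (k + 1) * voxel;
      double cx0 = x0 + tx * zlo, cx1 = x0 + tx * zhi;
      double cy0 = y0 + ty * zlo, cy1 = y0 + ty * zhi;
      int ilo = std::max(0, (int)std::floor((std::min(cx0, cx1) - halo) / voxel));
      int ihi = std::min(n1 - 1, (int)std::ceil((std::max(cx0, cx1) + halo) / voxel));
      int jlo = std::max(0, (int)std::floor((std::min(cy0, cy1) - halo) / voxel));
      int jhi = std::min(n2 - 1, (int)std::ceil((std::max(cy0, cy1) + halo) / voxel));
      for (int j = jlo; j <= jhi; j++)
        for (int i = ilo; i <= ihi; i++) {
          int cnt = 0;
          for (int sk = 0; sk < ss; sk++) {
            double qz = k * voxel + off[sk];
            for (int sj = 0; sj < ss; sj++) {
              double qy = j * voxel + off[sj] - y0 - ty * qz;
              for (int si = 0; si < ss; si++) {
                double qx = i * voxel + off[si] - x0 - tx * qz;
                // distance to line through (x0 + tx*z, y0 + ty*z, z):
                // vector from axis point at height qz is (qx, qy, 0)
                double dot = qx * ux + qy * uy;
                double d2 = qx * qx + qy * qy - dot * dot;
                if (d2 <= r2) cnt++;
              }
            }
          }
          if (cnt > 0)
            frac[(size_t)i + (size_t)n1 * (j + (size_t)n2 * k)] += cnt * w;
        }
    }
  }
}

// [[Rcpp::export]]
void cpp_add_ellipsoids(NumericVector frac, IntegerVector dim, double voxel,
                        NumericMatrix ell, int ss) {
  // ell columns: cx, cy, cz, m11..m33 (row-major world->unit-sphere matrix),
  //              bound (max semi-axis)
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  double w = 1.0 / ((double)ss * ss * ss);
  std::vector<double> off(ss);
  for (int s = 0; s < ss; s++) off[s] = (s + 0.5) / ss * voxel;
  for (int e = 0; e < ell.nrow(); e++) {
    double cx = ell(e, 0), cy = ell(e, 1), cz = ell(e, 2);
    double m11 = ell(e, 3), m12 = ell(e, 4), m13 = ell(e, 5);
    double m21 = ell(e, 6), m22 = ell(e, 7), m23 = ell(e, 8);
    double m31 = ell(e, 9), m32 = ell(e, 10), m33 = ell(e, 11);
    double bound = ell(e, 12) + voxel;
    int ilo = std::max(0, (int)std::floor((cx - bound) / voxel));
    int ihi = std::min(n1 - 1, (int)std::ceil((cx + bound) / voxel));
    int jlo = std::max(0, (int)std::floor((cy - bound) / voxel));
    int jhi = std::min(n2 - 1, (int)std::ceil((cy + bound) / voxel));
    int klo = std::max(0, (int)std::floor((cz - bound) / voxel));
    int khi = std::min(n3 - 1, (int)std::ceil((cz + bound) / voxel));
    for (int k = klo; k <= khi; k++)
      for (int j = jlo; j <= jhi; j++)
        for (int i = ilo; i <= ihi; i++) {
          int cnt = 0;
          for (int sk = 0; sk < ss; sk++) {
            double qz = k * voxel + off[sk] - cz;
            for (int sj = 0; sj < ss; sj++) {
              double qy = j * voxel + off[sj] - cy;
              for (int si = 0; si < ss; si++) {
                double qx = i * voxel + off[si] - cx;
                double a = m11 * qx + m12 * qy + m13 * qz;
                double b = m21 * qx + m22 * qy + m23 * qz;
                double c2 = m31 * qx + m32 * qy + m33 * qz;
                if (a * a + b * b + c2 * c2 <= 1.0) cnt++;
              }
            }
          }
          if (cnt > 0)
            frac[(size_t)i + (size_t)n1 * (j + (size_t)n2 * k)] += cnt * w;
        }
  }
}
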