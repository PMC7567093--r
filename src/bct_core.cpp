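#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Per-label thickness sinogram of a label map, by ray marching with bilinear
// label-indicator weights. Geometry: parallel beam; rotation axis at pixel
// ((n-1)/2, (n-1)/2) (0-based); detector column m maps to signed coordinate
// s = m - det_center (pixel units). For projection angle theta the detector
// axis is (cos t, sin t) and the ray direction (-sin t, cos t) in (x, y) =
// (column, row) coordinates. Output: array [n_det, n_angles, n_labels] of
// path lengths in cm (label 0 = air contributes nothing).
// [[Rcpp::export]]
NumericVector cpp_label_sinogram(IntegerMatrix labels, int n_labels,
                                 NumericVector angles, int n_det,
                                 double det_center, double pixel_cm,
                                 double step_px, double r_max) {
  const int nr = labels.nrow(), nc = labels.ncol(), na = angles.size();
  const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
  NumericVector out(static_cast<R_xlen_t>(n_det) * na * n_labels);
  out.attr("dim") = IntegerVector::create(n_det, na, n_labels);
  std::vector<double> acc(n_labels);

  // clipping to the bounding circle keeps every sample (and its 4 bilinear
  // neighbours) strictly inside the grid provided the non-air content has a
  // >= 2 px margin, which the phantom builders guarantee
  const bool safe = (r_max + 2.0 <= cx) && (r_max + 2.0 <= cy);
  const int *lab_ptr = labels.begin();

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int m = 0; m < n_det; ++m) {
      const double s = m - det_center;
      const double h2 = r_max * r_max - s * s;
      if (h2 <= 0.0) continue;
      const double T = std::sqrt(h2);
      const int nstep = static_cast<int>(std::ceil(2.0 * T / step_px));
      const double dt = 2.0 * T / nstep;
      std::fill(acc.begin(), acc.end(), 0.0);
      double x = cx + s * ct - (-T + 0.5 * dt) * st;
      double y = cy + s * st + (-T + 0.5 * dt) * ct;
      const double dx = -dt * st, dy = dt * ct;
      if (safe) {
        for (int k = 0; k < nstep; ++k, x += dx, y += dy) {
          const int j0 = static_cast<int>(x);
          const int i0 = static_cast<int>(y);
          const int *col = lab_ptr + static_cast<size_t>(j0) * nr + i0;
          const int l00 = col[0], l10 = col[1], l01 = col[nr], l11 = col[nr + 1];
          if (l00 == l10 && l00 == l01 && l00 == l11) {
            if (l00 > 0) acc[l00 - 1] += dt;
            continue;
          }
          const double fx = x - j0, fy = y - i0;
          if (l00 > 0) acc[l00 - 1] += (1 - fx) * (1 - fy) * dt;
          if (l10 > 0) acc[l10 - 1] += (1 - fx) * fy * dt;
          if (l01 > 0) acc[l01 - 1] += fx * (1 - fy) * dt;
          if (l11 > 0) acc[l11 - 1] += fx * fy * dt;
        }
      } else {
        for (int k = 0; k < nstep; ++k, x += dx, y += dy) {
          const int j0 = static_cast<int>(std::floor(x));
          const int i0 = static_cast<int>(std::floor(y));
          if (j0 < -1 || j0 > nc - 1 || i0 < -1 || i0 > nr - 1) continue;
          const double fx = x - j0, fy = y - i0;
          const double w[4] = {(1 - fx) * (1 - fy), fx * (1 - fy),
                               (1 - fx) * fy, fx * fy};
          const int jj[4] = {j0, j0 + 1, j0, j0 + 1};
          const int ii[4] = {i0, i0, i0 + 1, i0 + 1};
          for (int q = 0; q < 4; ++q) {
            if (jj[q] < 0 || jj[q] >= nc || ii[q] < 0 || ii[q] >= nr) continue;
            const int lab = labels(ii[q], jj[q]);
            if (lab > 0) acc[lab - 1] += w[q] * dt;
          }
        }
      }
      for (int l = 0; l < n_labels; ++l)
        out[m + static_cast<R_xlen_t>(n_det) * (a + static_cast<R_xlen_t>(na) * l)] =
            acc[l] * pixel_cm;
    }
  }
  return out;
}

// Per-label path length from each listed pixel back along the incoming beam
// direction to the grid boundary (primary-beam entrance attenuation paths
// for the DgN surrogate). px_row/px_col are 0-based. Output:
// [n_pixels, n_angles, n_labels], lengths in cm.
// [[Rcpp::export]]
NumericVector cpp_entry_integrals(IntegerMatrix labels, int n_labels,
                                  IntegerVector px_row, IntegerVector px_col,
                                  NumericVector angles, double pixel_cm,
                                  double step_px, double r_max) {
  const int nr = labels.nrow(), nc = labels.ncol();
  const int np = px_row.size(), na = angles.size();
  const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
  NumericVector out(static_cast<R_xlen_t>(np) * na * n_labels);
  out.attr("dim") = IntegerVector::create(np, na, n_labels);
  std::vector<double> acc(n_labels);

  for (int a = 0; a < na; ++a) {
    // beam direction (-sin t, cos t); march opposite to it
    const double bx = std::sin(angles[a]), by = -std::cos(angles[a]);
    for (int p = 0; p < np; ++p) {
      const double x0 = px_col[p], y0 = px_row[p];
      std::fill(acc.begin(), acc.end(), 0.0);
      // max path inside the bounding circle from this point
      const double rx = x0 - cx, ry = y0 - cy;
      const double b = rx * bx + ry * by;
      const double c = rx * rx + ry * ry - r_max * r_max;
      double T = b * b - c > 0 ? -b + std::sqrt(b * b - c) : 0.0;
      if (T < 0) T = 0;
      const int nstep = static_cast<int>(std::ceil(T / step_px));
      const double dt = nstep > 0 ? T / nstep : 0.0;
      for (int k = 0; k < nstep; ++k) {
        const double t = (k + 0.5) * dt;
        const double x = x0 + t * bx, y = y0 + t * by;
        const int j0 = static_cast<int>(std::floor(x));
        const int i0 = static_cast<int>(std::floor(y));
        if (j0 < -1 || j0 > nc - 1 || i0 < -1 || i0 > nr - 1) continue;
        const double fx = x - j0, fy = y - i0;
        const double w[4] = {(1 - fx) * (1 - fy), fx * (1 - fy),
                             (1 - fx) * fy, fx * fy};
        const int jj[4] = {j0, j0 + 1, j0, j0 + 1};
        const int ii[4] = {i0, i0, i0 + 1, i0 + 1};
        for (int q = 0; q < 4; ++q) {
          if (jj[q] < 0 || jj[q] >= nc || ii[q] < 0 || ii[q] >= nr) continue;
          const int lab = labels(ii[q], jj[q]);
          if (lab > 0) acc[lab - 1] += w[q] * dt;
        }
      }
      for (int l = 0; l < n_labels; ++l)
        out[p + static_cast<R_xlen_t>(np) * (a + static_cast<R_xlen_t>(na) * l)] =
            acc[l] * pixel_cm;
    }
  }
  return out;
}

// Linear-interpolation backprojection of a filtered sinogram [n_det, n_ang].
// Output image is n x n with the rotation axis at ((n-1)/2, (n-1)/2); pixels
// outside mask_radius (pixel units) are left at 0.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix q, NumericVector angles, int n,
                              double det_center, double dtheta,
                              double mask_radius) {
  const int n_det = q.nrow(), na = angles.size();
  NumericMatrix out(n, n);
  const double c = (n - 1) / 2.0;

  // per-row j range inside the reconstruction circle (branch-free inner loop)
  std::vector<int> jlo(n), jhi(n);
  for (int i = 0; i < n; ++i) {
    const double y = i - c;
    const double h2 = mask_radius * mask_radius - y * y;
    if (h2 <= 0) { jlo[i] = 1; jhi[i] = 0; continue; }
    const double h = std::sqrt(h2);
    jlo[i] = std::max(0, static_cast<int>(std::ceil(c - h)));
    jhi[i] = std::min(n - 1, static_cast<int>(std::floor(c + h)));
  }
  double *o = out.begin();

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    const double *qa = &q(0, a);
    for (int i = 0; i < n; ++i) {
      const double y = i - c;
      double s = (jlo[i] - c) * ct + y * st + det_center;
      double *orow = o + i;
      for (int j = jlo[i]; j <= jhi[i]; ++j, s += ct) {
        // s stays within [0, n_det-1] when the detector spans the circle;
        // clamp defensively at the borders
        double sc = s;
        if (sc < 0) sc = 0;
        if (sc > n_det - 1) sc = n_det - 1;
        const int m = static_cast<int>(sc);
        const double f = sc - m;
        const double v = (m + 1 < n_det) ? qa[m] + f * (qa[m + 1] - qa[m])
                                         : qa[m];
        orow[static_cast<size_t>(j) * n] += v * dtheta;
      }
    }
  }
  return out;
}

// Replace zero counts by the median of the non-zero 3x3 neighbours (computed
// on the original counts); pixels with no non-zero neighbour get `fallback`.
// [[Rcpp::export]]
NumericMatrix cpp_fill_zeros_median3(NumericMatrix counts, double fallback) {
  const int nr = counts.nrow(), nc = counts.ncol();
  NumericMatrix out = clone(counts);
  double buf[8];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (counts(i, j) != 0) continue;
      int nn = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          const double v = counts(ii, jj);
          if (v > 0) buf[nn++] = v;
        }
      }
      if (nn == 0) {
        out(i, j) = fallback;
      } else {
        std::sort(buf, buf + nn);
        out(i, j) = (nn % 2 == 1) ? buf[nn / 2]
                                  : 0.5 * (buf[nn / 2 - 1] + buf[nn / 2]);
      }
    }
  }
  return out;
}

static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Euclidean distance (in pixels) from each true pixel of `mask` to the
// nearest false pixel, with outside-of-grid treated as false (Felzenszwalb
// & Huttenlocher two-pass transform plus an edge-distance cap).
// [[Rcpp::export]]
NumericMatrix cpp_distance_transform(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  std::vector<double> g(static_cast<size_t>(nr) * nc);
  // columns pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? INF : 0.0;
    edt_1d(f, d, nr);
    for (int i = 0; i < nr; ++i) g[static_cast<size_t>(j) * nr + i] = d[i];
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g[static_cast<size_t>(j) * nr + i];
    edt_1d(f, d, nc);
    for (int j = 0; j < nc; ++j) {
      double dist = std::sqrt(d[j]);
      const double edge = 1.0 + std::min(std::min(i, nr - 1 - i),
                                         std::min(j, nc - 1 - j));
      out(i, j) = std::min(dist, edge);
    }
  }
  return out;
}
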