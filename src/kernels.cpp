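#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parallel-beam forward projection of per-material occupancy.
//
// labels: nx*ny*nz integer volume (column-major, axis 3 = vertical rotation
// axis). For each requested label value, binary occupancy is sampled on a
// grid rotated by theta about the vertical axis through the volume centre
// (pixel centres at half-integers) with bilinear interpolation, and summed
// along the ray direction. Output: array (nz, nx, nMat) of thickness in
// voxel units; rows = vertical (slice index), cols = detector column.
// [[Rcpp::export]]
NumericVector cpp_project_labels(IntegerVector labels, int nx, int ny, int nz,
                                 IntegerVector mats, double theta) {
  const int nm = mats.size();
  NumericVector out(Dimension(nz, nx, nm));
  const double cx = nx / 2.0, cy = ny / 2.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  // precompute per-(u,s) sample coordinates
  std::vector<int> ix0(nx * ny), iy0(nx * ny);
  std::vector<double> w00(nx * ny), w10(nx * ny), w01(nx * ny), w11(nx * ny);
  std::vector<bool> ok(nx * ny);
  for (int u = 0; u < nx; ++u) {
    const double du = (u + 0.5) - cx;
    for (int s = 0; s < ny; ++s) {
      const double ds = (s + 0.5) - cy;
      // centre-based coordinates of the sample point
      const double x = cx + du * ct - ds * st;
      const double y = cy + du * st + ds * ct;
      // convert to 0-based voxel indices (centres at half-integers)
      const double xf = x - 0.5, yf = y - 0.5;
      const int i0 = (int)std::floor(xf), j0 = (int)std::floor(yf);
      const int idx = u * ny + s;
      if (i0 < -1 || i0 > nx - 1 || j0 < -1 || j0 > ny - 1) {
        ok[idx] = false;
        continue;
      }
      ok[idx] = true;
      const double fx = xf - i0, fy = yf - j0;
      ix0[idx] = i0; iy0[idx] = j0;
      w00[idx] = (1 - fx) * (1 - fy);
      w10[idx] = fx * (1 - fy);
      w01[idx] = (1 - fx) * fy;
      w11[idx] = fx * fy;
    }
  }
  const int *lab = INTEGER(labels);
  double *o = REAL(out);
  for (int m = 0; m < nm; ++m) {
    const int target = mats[m];
    for (int k = 0; k < nz; ++k) {
      const int *slice = lab + (size_t)k * nx * ny;
      for (int u = 0; u < nx; ++u) {
        double acc = 0.0;
        for (int s = 0; s < ny; ++s) {
          const int idx = u * ny + s;
          if (!ok[idx]) continue;
          const int i0 = ix0[idx], j0 = iy0[idx];
          // bilinear sample of occupancy (outside = 0)
          double v = 0.0;
          if (i0 >= 0 && j0 >= 0 && slice[i0 + nx * j0] == target)
            v += w00[idx];
          if (i0 + 1 < nx && j0 >= 0 && slice[i0 + 1 + nx * j0] == target)
            v += w10[idx];
          if (i0 >= 0 && j0 + 1 < ny && slice[i0 + nx * (j0 + 1)] == target)
            v += w01[idx];
          if (i0 + 1 < nx && j0 + 1 < ny &&
              slice[i0 + 1 + nx * (j0 + 1)] == target)
            v += w11[idx];
          acc += v;
        }
        o[(size_t)m * nz * nx + (size_t)u * nz + k] = acc;
      }
    }
  }
  return out;
}

// Filtered backprojection accumulation for one slice.
// sino: (nAngles x nu) filtered sinogram, thetas in radians, center is the
// 0-based detector coordinate of the rotation axis. Output nx x nx slice in
// the same in-plane coordinates as the phantom volume (pixel centres at
// half-integers, axis at the grid centre). Caller multiplies by pi/nAngles.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector thetas,
                              double center, int nx) {
  const int na = sino.nrow(), nu = sino.ncol();
  NumericMatrix out(nx, nx);
  const double c = nx / 2.0;
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(thetas[a]), st = std::sin(thetas[a]);
    const double *row = &sino(a, 0);
    for (int j = 0; j < nx; ++j) {
      const double dy = (j + 0.5) - c;
      const double base = center + dy * st;
      for (int i = 0; i < nx; ++i) {
        const double dx = (i + 0.5) - c;
        const double u = base + dx * ct;
        const int u0 = (int)std::floor(u);
        if (u0 < 0 || u0 + 1 >= nu) continue;
        const double fu = u - u0;
        out(i, j) += (1 - fu) * row[u0 * na] + fu * row[(u0 + 1) * na];
      }
    }
  }
  return out;
}

// 6-connected components of a logical 3D mask. Returns integer labels
// (0 = background), labelled in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int nx, int ny, int nz) {
  IntegerVector lab(mask.size(), 0);
  const int *m = LOGICAL(mask);
  int *l = INTEGER(lab);
  int next = 0;
  std::vector<size_t> stack;
  const size_t n = (size_t)nx * ny * nz;
  for (size_t start = 0; start < n; ++start) {
    if (m[start] != TRUE || l[start] != 0) continue;
    ++next;
    stack.push_back(start);
    l[start] = next;
    while (!stack.empty()) {
      const size_t p = stack.back();
      stack.pop_back();
      const int i = p % nx, j = (p / nx) % ny, k = p / ((size_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        const int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const size_t q = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (m[q] == TRUE && l[q] == 0) {
          l[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}

// Seeded watershed by priority flooding on a priority image (e.g. gradient
// magnitude): voxels are assigned, in increasing priority order, to the
// label of the already-assigned neighbour that reached them first. Voxels
// outside mask stay 0.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector priority, IntegerVector seeds,
                              LogicalVector mask, int nx, int ny, int nz) {
  typedef std::pair<double, size_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
  IntegerVector lab = clone(seeds);
  int *l = INTEGER(lab);
  const double *pr = REAL(priority);
  const int *mk = LOGICAL(mask);
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> queued(n, 0);
  for (size_t p = 0; p < n; ++p)
    if (l[p] > 0) {
      q.push(QE(pr[p], p));
      queued[p] = 1;
    }
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  while (!q.empty()) {
    const size_t p = q.top().second;
    q.pop();
    const int i = p % nx, j = (p / nx) % ny, k = p / ((size_t)nx * ny);
    for (int d = 0; d < 6; ++d) {
      const int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      const size_t s = ii + (size_t)nx * (jj + (size_t)ny * kk);
      if (mk[s] != TRUE || queued[s]) continue;
      l[s] = l[p];
      queued[s] = 1;
      q.push(QE(pr[s], s));
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}

// Separable 2D convolution with a symmetric 1D kernel, replicated borders.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv2(NumericMatrix x, NumericVector kernel) {
  const int nr = x.nrow(), nc = x.ncol(), kn = kernel.size();
  const int h = kn / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical direction)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = 0; t < kn; ++t) {
        int ii = i + t - h;
        if (ii < 0) ii = 0;
        if (ii >= nr) ii = nr - 1;
        acc += kernel[t] * x(ii, j);
      }
      tmp(i, j) = acc;
    }
  // along columns (horizontal direction)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = 0; t < kn; ++t) {
        int jj = j + t - h;
        if (jj < 0) jj = 0;
        if (jj >= nc) jj = nc - 1;
        acc += kernel[t] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}
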