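// Compiled kernels for 3D morphometry: exact squared Euclidean distance
// transform (separable, Saito-Toriwaki family), local thickness by
// distance-ridge sphere superposition, Crofton 13-direction interface area,
// separable Gaussian smoothing, and implicit-surface curvature from the
// gradient/Hessian of a smoothed indicator.
//
// All arrays are R column-major with dims (n1, n2, n3) = (y, x, z).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double DT_INF = 1e30;

// 1D squared distance transform by lower envelope of parabolas.
// f: input squared distances (0 or DT_INF at seeds/non-seeds, or partial
// results from a previous axis); d: output. Exact in integer arithmetic
// representable in doubles.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * (q - p));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

static void dt_axis(std::vector<double>& g, int n1, int n2, int n3, int axis) {
  int len = (axis == 0) ? n1 : (axis == 1) ? n2 : n3;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)n1
                                                  : (R_xlen_t)n1 * n2;
  std::vector<double> f(len), d(len), z(len + 1);
  std::vector<int> v(len);
  // iterate over all lines perpendicular to `axis`
  int la = (axis == 0) ? n2 : n1;
  int lb = (axis == 2) ? n2 : n3;
  R_xlen_t sa = (axis == 0) ? (R_xlen_t)n1 : 1;
  R_xlen_t sb = (axis == 2) ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2;
  for (int b = 0; b < lb; b++) {
    for (int a = 0; a < la; a++) {
      R_xlen_t base = a * sa + b * sb;
      for (int i = 0; i < len; i++) f[i] = g[base + i * stride];
      dt1d(f, d, v, z, len);
      for (int i = 0; i < len; i++) g[base + i * stride] = d[i];
    }
  }
}

// Exact squared Euclidean distance (voxel units) from every voxel to the
// nearest background (FALSE) voxel. Background voxels get 0. If the volume
// contains no background, all values are >= DT_INF / 2 (mapped to Inf in R).
// [[Rcpp::export]]
NumericVector sqedt_cpp(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? DT_INF : 0.0;
  dt_axis(g, n1, n2, n3, 0);
  dt_axis(g, n1, n2, n3, 1);
  dt_axis(g, n1, n2, n3, 2);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (g[i] >= DT_INF / 2) ? R_PosInf : g[i];
  out.attr("dim") = dim;
  return out;
}

// Local thickness (Hildebrand definition): per foreground voxel, the
// diameter (voxel units) of the largest inscribed sphere containing it.
// Sphere at centre c has squared radius sqEDT(c); it covers v iff
// dist^2(v,c) < sqEDT(c) (exact integer comparison). Redundant centres
// (spheres provably contained in a 26-neighbour's sphere) are pruned; the
// pruning test is the exact containment condition, so coverage is never
// lost.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector fg, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector d2 = sqedt_cpp(fg, dim);
  NumericVector out(n);
  // any unbounded distances (no background at all) -> Inf thickness
  bool has_bg = false;
  for (R_xlen_t i = 0; i < n; i++)
    if (!fg[i]) { has_bg = true; break; }
  if (!has_bg) {
    for (R_xlen_t i = 0; i < n; i++) out[i] = fg[i] ? R_PosInf : 0.0;
    out.attr("dim") = dim;
    return out;
  }
  // 26-neighbourhood offsets
  int offs[26][3];
  double olen[26];
  int no = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dx = -1; dx <= 1; dx++)
      for (int dy = -1; dy <= 1; dy++) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        offs[no][0] = dy; offs[no][1] = dx; offs[no][2] = dz;
        olen[no] = std::sqrt((double)(dy * dy + dx * dx + dz * dz));
        no++;
      }
  std::vector<R_xlen_t> ridge;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t idx = i + (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * k;
        if (!fg[idx]) continue;
        double rc = std::sqrt(d2[idx]);
        bool redundant = false;
        for (int o = 0; o < no; o++) {
          int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
            continue;
          R_xlen_t nb = ii + (R_xlen_t)n1 * jj + (R_xlen_t)n1 * n2 * kk;
          if (d2[nb] <= 0) continue;
          if (std::sqrt(d2[nb]) >= rc + olen[o] - 1e-9) {
            redundant = true;
            break;
          }
        }
        if (!redundant) ridge.push_back(idx);
      }
  // sphere superposition from ridge centres
  for (size_t r = 0; r < ridge.size(); r++) {
    R_xlen_t idx = ridge[r];
    int i = (int)(idx % n1);
    int j = (int)((idx / n1) % n2);
    int k = (int)(idx / ((R_xlen_t)n1 * n2));
    double R2 = d2[idx];
    double diam = 2.0 * std::sqrt(R2);
    int rad = (int)std::floor(std::sqrt(R2 - 1.0 + 1e-9));
    if (R2 <= 1.0) rad = 0;
    for (int dk = -rad; dk <= rad; dk++) {
      int kk = k + dk;
      if (kk < 0 || kk >= n3) continue;
      int rem2k = (int)R2 - 1 - dk * dk;
      if (rem2k < 0) continue;
      int radj = (int)std::floor(std::sqrt((double)rem2k + 1e-9));
      for (int dj = -radj; dj <= radj; dj++) {
        int jj = j + dj;
        if (jj < 0 || jj >= n2) continue;
        int rem2 = rem2k - dj * dj;
        if (rem2 < 0) continue;
        int radi = (int)std::floor(std::sqrt((double)rem2 + 1e-9));
        int i0 = i - radi; if (i0 < 0) i0 = 0;
        int i1 = i + radi; if (i1 >= n1) i1 = n1 - 1;
        R_xlen_t base = (R_xlen_t)n1 * jj + (R_xlen_t)n1 * n2 * kk;
        for (int ii = i0; ii <= i1; ii++) {
          R_xlen_t t = base + ii;
          if (out[t] < diam) out[t] = diam;
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < n; i++)
    if (!fg[i]) out[i] = 0.0;
  out.attr("dim") = dim;
  return out;
}

// Crofton interface area between two disjoint phase masks, in voxel^2
// units, using 13 discrete directions with spherical-Voronoi weights.
// Counts voxel pairs (v, v+d) straddling the a/b interface; the estimate is
// S = 4 * sum_d w_d * n_d / l_d with l_d the lattice step length.
// [[Rcpp::export]]
double crofton_area_cpp(LogicalVector a, LogicalVector b, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  static const int D[13][3] = {
      {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
      {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
      {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
  static const double W[13] = {
      0.04577789120476, 0.04577789120476, 0.04577789120476,
      0.03698062787608, 0.03698062787608, 0.03698062787608,
      0.03698062787608, 0.03698062787608, 0.03698062787608,
      0.03519563978232, 0.03519563978232, 0.03519563978232,
      0.03519563978232};
  double area = 0.0;
  for (int d = 0; d < 13; d++) {
    int dy = D[d][0], dx = D[d][1], dz = D[d][2];
    double len = std::sqrt((double)(dy * dy + dx * dx + dz * dz));
    double cnt = 0.0;
    int i0 = (dy < 0) ? -dy : 0, i1 = (dy > 0) ? n1 - dy : n1;
    int j0 = (dx < 0) ? -dx : 0, j1 = (dx > 0) ? n2 - dx : n2;
    int k0 = (dz < 0) ? -dz : 0, k1 = (dz > 0) ? n3 - dz : n3;
    for (int k = k0; k < k1; k++)
      for (int j = j0; j < j1; j++) {
        R_xlen_t base = (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * k;
        R_xlen_t base2 = (R_xlen_t)n1 * (j + dx) + (R_xlen_t)n1 * n2 * (k + dz);
        for (int i = i0; i < i1; i++) {
          R_xlen_t v = base + i;
          R_xlen_t w = base2 + i + dy;
          if ((a[v] && b[w]) || (b[v] && a[w])) cnt += 1.0;
        }
      }
    area += 4.0 * W[d] * cnt / len;
  }
  return area;
}

static void gauss_axis(std::vector<double>& g, int n1, int n2, int n3,
                       int axis, double sigma) {
  int len = (axis == 0) ? n1 : (axis == 1) ? n2 : n3;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)n1
                                                  : (R_xlen_t)n1 * n2;
  int r = (int)std::ceil(3.5 * sigma);
  if (r < 1) r = 1;
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; i++) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (int i = 0; i < 2 * r + 1; i++) ker[i] /= s;
  int la = (axis == 0) ? n2 : n1;
  int lb = (axis == 2) ? n2 : n3;
  R_xlen_t sa = (axis == 0) ? (R_xlen_t)n1 : 1;
  R_xlen_t sb = (axis == 2) ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2;
  std::vector<double> line(len), outl(len);
  for (int b = 0; b < lb; b++) {
    for (int a = 0; a < la; a++) {
      R_xlen_t base = a * sa + b * sb;
      for (int i = 0; i < len; i++) line[i] = g[base + i * stride];
      for (int i = 0; i < len; i++) {
        double acc = 0.0;
        for (int t = -r; t <= r; t++) {
          int j = i + t;
          // mirror reflection at the faces
          while (j < 0 || j >= len) {
            if (j < 0) j = -j - 1;
            if (j >= len) j = 2 * len - 1 - j;
          }
          acc += ker[t + r] * line[j];
        }
        outl[i] = acc;
      }
      for (int i = 0; i < len; i++) g[base + i * stride] = outl[i];
    }
  }
}

// Separable Gaussian smoothing with mirror boundary conditions.
// [[Rcpp::export]]
NumericVector gauss3_cpp(NumericVector x, IntegerVector dim, double sigma) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = x[i];
  if (sigma > 0) {
    gauss_axis(g, n1, n2, n3, 0, sigma);
    gauss_axis(g, n1, n2, n3, 1, sigma);
    gauss_axis(g, n1, n2, n3, 2, sigma);
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = g[i];
  out.attr("dim") = dim;
  return out;
}

// Level-set curvature of a smooth scalar field phi (high inside the
// foreground). Returns gradient magnitude, mean curvature H and Gaussian
// curvature K per voxel (voxel units; border voxels zeroed). Sign
// convention: H > 0 where the foreground is convex (a foreground ball has
// H = +1/r on its surface).
// [[Rcpp::export]]
List curvature_cpp(NumericVector phi, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector gmag(n), H(n), K(n);
  R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;
  for (int k = 1; k < n3 - 1; k++)
    for (int j = 1; j < n2 - 1; j++)
      for (int i = 1; i < n1 - 1; i++) {
        R_xlen_t c = i + (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * k;
        double gy = 0.5 * (phi[c + s1] - phi[c - s1]);
        double gx = 0.5 * (phi[c + s2] - phi[c - s2]);
        double gz = 0.5 * (phi[c + s3] - phi[c - s3]);
        double g2 = gx * gx + gy * gy + gz * gz;
        double gm = std::sqrt(g2);
        gmag[c] = gm;
        if (gm < 1e-9) continue;
        double hyy = phi[c + s1] - 2.0 * phi[c] + phi[c - s1];
        double hxx = phi[c + s2] - 2.0 * phi[c] + phi[c - s2];
        double hzz = phi[c + s3] - 2.0 * phi[c] + phi[c - s3];
        double hxy = 0.25 * (phi[c + s1 + s2] - phi[c + s1 - s2] -
                             phi[c - s1 + s2] + phi[c - s1 - s2]);
        double hyz = 0.25 * (phi[c + s1 + s3] - phi[c + s1 - s3] -
                             phi[c - s1 + s3] + phi[c - s1 - s3]);
        double hxz = 0.25 * (phi[c + s2 + s3] - phi[c + s2 - s3] -
                             phi[c - s2 + s3] + phi[c - s2 - s3]);
        double tr = hxx + hyy + hzz;
        double gHg = gx * (hxx * gx + hxy * gy + hxz * gz) +
                     gy * (hxy * gx + hyy * gy + hyz * gz) +
                     gz * (hxz * gx + hyz * gy + hzz * gz);
        H[c] = (gHg - g2 * tr) / (2.0 * g2 * gm);
        double axx = hyy * hzz - hyz * hyz;
        double ayy = hxx * hzz - hxz * hxz;
        double azz = hxx * hyy - hxy * hxy;
        double axy = hxz * hyz - hxy * hzz;
        double axz = hxy * hyz - hxz * hyy;
        double ayz = hxy * hxz - hyz * hxx;
        double gAg = gx * (axx * gx + axy * gy + axz * gz) +
                     gy * (axy * gx + ayy * gy + ayz * gz) +
                     gz * (axz * gx + ayz * gy + azz * gz);
        K[c] = gAg / (g2 * g2);
      }
  gmag.attr("dim") = dim;
  H.attr("dim") = dim;
  K.attr("dim") = dim;
  return List::create(Named("gmag") = gmag, Named("H") = H, Named("K") = K);
}
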