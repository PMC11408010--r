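#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher (2012). Values must be finite; binary masks
// use a large sentinel instead of +Inf so the envelope arithmetic stays
// well-defined.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double BIG = 1e30;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
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
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dv = (double)q - v[k];
    d[q] = dv * dv + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every grid point to the
// nearest TRUE voxel, computed separably over up to three dimensions.
// Column-major layout matching R arrays.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  int nd = dims.size();
  int nx = dims[0];
  int ny = nd > 1 ? dims[1] : 1;
  int nz = nd > 2 ? dims[2] : 1;
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  // sentinel larger than any achievable squared distance
  double maxd = (double)nx + ny + nz;
  double sent = 4.0 * maxd * maxd + 1.0;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++)
    out[i] = (mask[i] == TRUE) ? 0.0 : sent;

  std::vector<double> f, d;
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  if (ny > 1) {
    f.resize(ny); d.resize(ny);
    for (int z = 0; z < nz; z++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
        dt1d(f, d, ny);
        for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  if (nz > 1) {
    f.resize(nz); d.resize(nz);
    R_xlen_t plane = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)z * plane];
        dt1d(f, d, nz);
        for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * plane] = d[z];
      }
  }
  return out;
}

// Count exposed faces of a label class: voxel faces where a voxel of
// `code` (or any code in `codes`) touches a voxel of a different class.
// Domain-boundary faces are not counted (no neighbour there).
// Returns c(total_exposed_faces, faces_touching `contact_code`).
// [[Rcpp::export(name = ".face_count_cpp")]]
NumericVector face_count_cpp(IntegerVector labels, IntegerVector dims,
                             IntegerVector codes, int contact_code) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  std::vector<bool> inset(256, false);
  for (int i = 0; i < codes.size(); i++) inset[codes[i]] = true;
  R_xlen_t plane = (R_xlen_t)nx * ny;
  double exposed = 0, contact = 0;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = (R_xlen_t)z * plane + (R_xlen_t)y * nx + x;
        int li = labels[i];
        if (!inset[li]) continue;
        int nb[6];
        int nn = 0;
        if (x > 0)      nb[nn++] = labels[i - 1];
        if (x < nx - 1) nb[nn++] = labels[i + 1];
        if (y > 0)      nb[nn++] = labels[i - nx];
        if (y < ny - 1) nb[nn++] = labels[i + nx];
        if (z > 0)      nb[nn++] = labels[i - plane];
        if (z < nz - 1) nb[nn++] = labels[i + plane];
        for (int j = 0; j < nn; j++) {
          if (!inset[nb[j]]) {
            exposed += 1;
            if (nb[j] == contact_code) contact += 1;
          }
        }
      }
  return NumericVector::create(exposed, contact);
}
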