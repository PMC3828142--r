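#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Quasi-steady-state Gauss-Seidel relaxation of D lap(c) = sink on the voxels
// flagged `occupied`; cell-free voxels are Dirichlet at c_boundary (the medium
// perfuses the space around and inside gaps of the spheroid), as is everything
// beyond the grid faces. Concentrations are clamped at zero; the clamped
// (starved) voxels are reported so unmet demand can be acted on upstream.
// Units: c mM, sink mM/h (per voxel), D um^2/h, h um.
// [[Rcpp::export]]
List cpp_relax_field(NumericVector conc, LogicalVector occupied,
                     NumericVector sink, int nx, int ny, int nz,
                     double D, double h, double c_boundary,
                     int max_sweeps, double tol) {
  NumericVector c = clone(conc);
  double k = h * h / (6.0 * D);
  int sweeps = 0;
  double delta = R_PosInf;
  for (int n = 0; n < nx * ny * nz; ++n) if (!occupied[n]) c[n] = c_boundary;
  while (sweeps < max_sweeps && delta > tol) {
    delta = 0.0;
    ++sweeps;
    for (int kk = 0; kk < nz; ++kk)
      for (int jj = 0; jj < ny; ++jj)
        for (int ii = 0; ii < nx; ++ii) {
          int n = idx3(ii, jj, kk, nx, ny);
          if (!occupied[n]) continue;
          double s = 0.0;
          s += (ii > 0)      ? c[idx3(ii - 1, jj, kk, nx, ny)] : c_boundary;
          s += (ii < nx - 1) ? c[idx3(ii + 1, jj, kk, nx, ny)] : c_boundary;
          s += (jj > 0)      ? c[idx3(ii, jj - 1, kk, nx, ny)] : c_boundary;
          s += (jj < ny - 1) ? c[idx3(ii, jj + 1, kk, nx, ny)] : c_boundary;
          s += (kk > 0)      ? c[idx3(ii, jj, kk - 1, nx, ny)] : c_boundary;
          s += (kk < nz - 1) ? c[idx3(ii, jj, kk + 1, nx, ny)] : c_boundary;
          double cn = s / 6.0 - k * sink[n];
          if (cn < 0.0) cn = 0.0;
          double d = std::fabs(cn - c[n]);
          if (d > delta) delta = d;
          c[n] = cn;
        }
  }
  LogicalVector starved(nx * ny * nz);
  for (int kk = 0; kk < nz; ++kk)
    for (int jj = 0; jj < ny; ++jj)
      for (int ii = 0; ii < nx; ++ii) {
        int n = idx3(ii, jj, kk, nx, ny);
        starved[n] = occupied[n] && c[n] <= 0.0;
      }
  return List::create(_["conc"] = c, _["sweeps"] = sweeps,
                      _["residual"] = delta, _["starved"] = starved);
}

// One explicit Euler step of dc/dt = D lap(c) - sink on occupied voxels
// (cell-free voxels held at c_boundary). dt in hours; caller must respect
// the stability bound dt <= h^2 / (6 D). Returns the updated field plus the
// boundary influx and uptake actually realised, for mass-balance audits.
// [[Rcpp::export]]
List cpp_step_field_explicit(NumericVector conc, LogicalVector occupied,
                             NumericVector sink, int nx, int ny, int nz,
                             double D, double h, double c_boundary, double dt) {
  NumericVector c0 = clone(conc);
  NumericVector c(nx * ny * nz);
  for (int n = 0; n < nx * ny * nz; ++n) if (!occupied[n]) c0[n] = c_boundary;
  double a = D * dt / (h * h);
  double influx = 0.0, uptake = 0.0; // in mM * voxel units
  for (int kk = 0; kk < nz; ++kk)
    for (int jj = 0; jj < ny; ++jj)
      for (int ii = 0; ii < nx; ++ii) {
        int n = idx3(ii, jj, kk, nx, ny);
        if (!occupied[n]) { c[n] = c_boundary; continue; }
        double lap = -6.0 * c0[n];
        lap += (ii > 0)      ? c0[idx3(ii - 1, jj, kk, nx, ny)] : c_boundary;
        lap += (ii < nx - 1) ? c0[idx3(ii + 1, jj, kk, nx, ny)] : c_boundary;
        lap += (jj > 0)      ? c0[idx3(ii, jj - 1, kk, nx, ny)] : c_boundary;
        lap += (jj < ny - 1) ? c0[idx3(ii, jj + 1, kk, nx, ny)] : c_boundary;
        lap += (kk > 0)      ? c0[idx3(ii, jj, kk - 1, nx, ny)] : c_boundary;
        lap += (kk < nz - 1) ? c0[idx3(ii, jj, kk + 1, nx, ny)] : c_boundary;
        double diff = a * lap;
        double cn = c0[n] + diff - sink[n] * dt;
        double up = sink[n] * dt;
        if (cn < 0.0) { up += cn; cn = 0.0; } // unmet demand not consumed
        c[n] = cn;
        influx += diff;
        uptake += up;
      }
  return List::create(_["conc"] = c, _["influx"] = influx, _["uptake"] = uptake);
}

// Trilinear interpolation of a voxel field at arbitrary points. Voxel centres
// sit at corner + (i + 1/2) h; samples outside the grid return c_boundary and
// the interpolation stencil is clamped at the faces.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector conc, int nx, int ny, int nz,
                            double h, double x0, double y0, double z0,
                            NumericVector xs, NumericVector ys,
                            NumericVector zs, double c_boundary) {
  int np = xs.size();
  NumericVector out(np);
  double lx = nx * h, ly = ny * h, lz = nz * h;
  for (int p = 0; p < np; ++p) {
    double x = xs[p] - x0, y = ys[p] - y0, z = zs[p] - z0;
    if (x < 0 || y < 0 || z < 0 || x > lx || y > ly || z > lz) {
      out[p] = c_boundary;
      continue;
    }
    double gx = x / h - 0.5, gy = y / h - 0.5, gz = z / h - 0.5;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    double tx = gx - i0, ty = gy - j0, tz = gz - k0;
    if (i0 < 0) { i0 = 0; tx = 0.0; }
    if (j0 < 0) { j0 = 0; ty = 0.0; }
    if (k0 < 0) { k0 = 0; tz = 0.0; }
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1);
    int k1 = std::min(k0 + 1, nz - 1);
    if (i0 > nx - 1) { i0 = i1 = nx - 1; tx = 0.0; }
    if (j0 > ny - 1) { j0 = j1 = ny - 1; ty = 0.0; }
    if (k0 > nz - 1) { k0 = k1 = nz - 1; tz = 0.0; }
    double c000 = conc[idx3(i0, j0, k0, nx, ny)], c100 = conc[idx3(i1, j0, k0, nx, ny)];
    double c010 = conc[idx3(i0, j1, k0, nx, ny)], c110 = conc[idx3(i1, j1, k0, nx, ny)];
    double c001 = conc[idx3(i0, j0, k1, nx, ny)], c101 = conc[idx3(i1, j0, k1, nx, ny)];
    double c011 = conc[idx3(i0, j1, k1, nx, ny)], c111 = conc[idx3(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - tx) + c100 * tx, c10 = c010 * (1 - tx) + c110 * tx;
    double c01 = c001 * (1 - tx) + c101 * tx, c11 = c011 * (1 - tx) + c111 * tx;
    double c0 = c00 * (1 - ty) + c10 * ty, c1 = c01 * (1 - ty) + c11 * ty;
    double v = c0 * (1 - tz) + c1 * tz;
    out[p] = v < 0.0 ? 0.0 : v;
  }
  return out;
}

// Map points to 1-based voxel indices (0 for points outside the grid).
// [[Rcpp::export]]
IntegerVector cpp_voxel_of(NumericVector xs, NumericVector ys, NumericVector zs,
                           int nx, int ny, int nz, double h,
                           double x0, double y0, double z0) {
  int np = xs.size();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    int i = (int)std::floor((xs[p] - x0) / h);
    int j = (int)std::floor((ys[p] - y0) / h);
    int k = (int)std::floor((zs[p] - z0) / h);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) out[p] = 0;
    else out[p] = 1 + idx3(i, j, k, nx, ny);
  }
  return out;
}
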