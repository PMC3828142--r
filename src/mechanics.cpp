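#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pairwise force law along the centre line, as a function of overlap
// delta = R_i + R_j - d (positive when spheres interpenetrate).
// Repulsion: extended Hertz, F_rep = (4/3) * E_pair * sqrt(R_eff) * delta^{3/2}.
// Adhesion: finite well of depth f_adh = 2*pi*w*R_eff, full strength at contact,
// ramping linearly to zero over a gap of delta_cut beyond touching.
// Lengths enter in metres; the R wrappers work in micrometres.
static inline double force_scalar(double delta_m, double reff_m,
                                  double e_pair, double w_adh,
                                  double delta_cut_m, double f_clamp) {
  double f = 0.0;
  if (delta_m > 0.0) {
    f = (4.0 / 3.0) * e_pair * std::sqrt(reff_m) * delta_m * std::sqrt(delta_m);
    if (f > f_clamp) f = f_clamp;
  }
  double f0 = 2.0 * M_PI * w_adh * reff_m;
  double s;
  if (delta_m >= 0.0) s = 1.0;
  else if (delta_m > -delta_cut_m) s = 1.0 + delta_m / delta_cut_m;
  else s = 0.0;
  return f - f0 * s;   // positive = repulsive (pushes centres apart)
}

// Pair potential consistent with force_scalar (w.r.t. centre distance),
// zero at and beyond the adhesion cutoff. Used by the energy audit.
static inline double pair_potential(double delta_m, double reff_m,
                                    double e_pair, double w_adh,
                                    double delta_cut_m) {
  double u = 0.0;
  if (delta_m > 0.0) {
    u += (8.0 / 15.0) * e_pair * std::sqrt(reff_m) * std::pow(delta_m, 2.5);
  }
  double f0 = 2.0 * M_PI * w_adh * reff_m;
  if (delta_m >= 0.0) {
    u += -f0 * (delta_m + 0.5 * delta_cut_m);
  } else if (delta_m > -delta_cut_m) {
    double t = delta_m + delta_cut_m;
    u += -f0 * t * t / (2.0 * delta_cut_m);
  }
  return u;
}

// Linked-list cell binning: head[bin] -> first cell, nxt[cell] -> next cell.
// Bin edge = 2 rmax + skin, so neighbours are confined to the 27-bin stencil.
struct CellBins {
  double x0, y0, z0, cell;
  int nx, ny, nz;
  std::vector<int> head, nxt;
  CellBins(const double* x, const double* y, const double* z, int n,
           double cell_size) : cell(cell_size), nxt(n) {
    double xmin = 1e300, ymin = 1e300, zmin = 1e300;
    double xmax = -1e300, ymax = -1e300, zmax = -1e300;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = (int)std::floor((xmax - x0) / cell) + 3;
    ny = (int)std::floor((ymax - y0) / cell) + 3;
    nz = (int)std::floor((zmax - z0) / cell) + 3;
    head.assign((size_t)nx * ny * nz, -1);
    for (int i = 0; i < n; ++i) {
      size_t b = bin_of(x[i], y[i], z[i]);
      nxt[i] = head[b];
      head[b] = i;
    }
  }
  inline size_t bin_of(double x, double y, double z) const {
    int ix = (int)std::floor((x - x0) / cell) + 1;
    int iy = (int)std::floor((y - y0) / cell) + 1;
    int iz = (int)std::floor((z - z0) / cell) + 1;
    return (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * (size_t)iz);
  }
};

static void find_pairs(const double* x, const double* y, const double* z,
                       const double* r, int n, double skin,
                       std::vector<int>& ii, std::vector<int>& jj) {
  ii.clear(); jj.clear();
  if (n < 2) return;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  CellBins cb(x, y, z, n, 2.0 * rmax + skin);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor((x[i] - cb.x0) / cb.cell) + 1;
    int iy = (int)std::floor((y[i] - cb.y0) / cb.cell) + 1;
    int iz = (int)std::floor((z[i] - cb.z0) / cb.cell) + 1;
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        size_t b = (size_t)(ix + dx) +
          (size_t)cb.nx * ((size_t)(iy + dy) + (size_t)cb.ny * (size_t)(iz + dz));
        for (int j = cb.head[b]; j >= 0; j = cb.nxt[j]) {
          if (j <= i) continue;
          double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
          double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          double cut = r[i] + r[j] + skin;
          if (d2 < cut * cut) { ii.push_back(i); jj.push_back(j); }
        }
      }
  }
}

// Symmetric contact list: pairs with centre distance < R_i + R_j + skin.
// Coordinates and radii in micrometres; indices 1-based.
// [[Rcpp::export]]
List cpp_build_contacts(NumericVector x, NumericVector y, NumericVector z,
                        NumericVector r, double skin) {
  int n = x.size();
  std::vector<int> ii, jj;
  find_pairs(REAL(x), REAL(y), REAL(z), REAL(r), n, skin, ii, jj);
  int m = ii.size();
  IntegerVector oi(m), oj(m);
  NumericVector ov(m), od(m);
  for (int k = 0; k < m; ++k) {
    int i = ii[k], j = jj[k];
    double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
    double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
    oi[k] = i + 1; oj[k] = j + 1;
    ov[k] = r[i] + r[j] - d; od[k] = d;
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["overlap"] = ov,
                      _["dist"] = od);
}

// Vectorised force law; overlap and radii in micrometres, force in newtons.
// [[Rcpp::export]]
NumericVector cpp_pair_force(NumericVector overlap_um, NumericVector ri_um,
                             NumericVector rj_um, double e_pair, double w_adh,
                             double delta_cut_um, double f_clamp) {
  int n = overlap_um.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double reff = 1e-6 * (ri_um[i] * rj_um[i]) / (ri_um[i] + rj_um[i]);
    out[i] = force_scalar(1e-6 * overlap_um[i], reff, e_pair, w_adh,
                          1e-6 * delta_cut_um, f_clamp);
  }
  return out;
}

// Overdamped relaxation: n_sub substeps of dx = F/gamma * dt, displacement per
// substep capped at cap_frac * rmin; the contact list is rebuilt each substep.
// Coordinates um, dt hours, gamma N s/m. Returns updated positions, per-cell
// pressure (Pa: calibrated compressive contact-force sum over 4 pi R^2),
// pair-potential energy (J) on the first and last substep, and the number of
// capped displacements.
// [[Rcpp::export]]
List cpp_mech_step(NumericVector x, NumericVector y, NumericVector z,
                   NumericVector r, double skin, double e_pair, double w_adh,
                   double delta_cut_um, double f_clamp, double gamma,
                   double dt_h, int n_sub, double cap_frac, double rmin_um,
                   double pressure_calib) {
  int n = x.size();
  NumericVector px = clone(x), py = clone(y), pz = clone(z);
  NumericVector pressure(n);
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<int> ii, jj;
  if (n_sub < 1) n_sub = 1;
  double dt_s = dt_h * 3600.0 / n_sub;
  double cap_um = cap_frac * rmin_um;
  int ncap = 0;
  double energy0 = NA_REAL, energy1 = NA_REAL;
  double dcut_m = 1e-6 * delta_cut_um;

  for (int sub = 0; sub < n_sub; ++sub) {
    find_pairs(REAL(px), REAL(py), REAL(pz), REAL(r), n, skin, ii, jj);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    std::fill(pressure.begin(), pressure.end(), 0.0);
    double energy = 0.0;
    for (size_t k = 0; k < ii.size(); ++k) {
      int i = ii[k], j = jj[k];
      double ddx = px[i] - px[j], ddy = py[i] - py[j], ddz = pz[i] - pz[j];
      double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (d < 1e-9) { // coincident centres: deterministic perturbation
        ddx = 1e-3 * (1 + (i % 7)); ddy = 1e-3 * (1 + (j % 5)); ddz = 1e-3;
        d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      }
      double delta = 1e-6 * (r[i] + r[j] - d);
      double reff = 1e-6 * (r[i] * r[j]) / (r[i] + r[j]);
      double f = force_scalar(delta, reff, e_pair, w_adh, dcut_m, f_clamp);
      energy += pair_potential(delta, reff, e_pair, w_adh, dcut_m);
      double ux = ddx / d, uy = ddy / d, uz = ddz / d;
      fx[i] += f * ux; fy[i] += f * uy; fz[i] += f * uz;
      fx[j] -= f * ux; fy[j] -= f * uy; fz[j] -= f * uz;
      if (f > 0.0) { // compressive normal force contributes to pressure
        pressure[i] += f; pressure[j] += f;
      }
    }
    if (sub == 0) energy0 = energy;
    energy1 = energy;
    if (dt_s > 0.0) {
      for (int i = 0; i < n; ++i) {
        double sx = fx[i] / gamma * dt_s * 1e6; // metres -> micrometres
        double sy = fy[i] / gamma * dt_s * 1e6;
        double sz = fz[i] / gamma * dt_s * 1e6;
        double step = std::sqrt(sx * sx + sy * sy + sz * sz);
        if (step > cap_um) {
          double sc = cap_um / step;
          sx *= sc; sy *= sc; sz *= sc;
          ++ncap;
        }
        px[i] += sx; py[i] += sy; pz[i] += sz;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    double area = 4.0 * M_PI * (1e-6 * r[i]) * (1e-6 * r[i]);
    pressure[i] = pressure_calib * pressure[i] / area;
  }
  return List::create(_["x"] = px, _["y"] = py, _["z"] = pz,
                      _["pressure"] = pressure, _["energy_before"] = energy0,
                      _["energy_after"] = energy1, _["n_capped"] = ncap);
}

// Total pair-potential energy (J) of a configuration; audit helper.
// [[Rcpp::export]]
double cpp_pair_energy(NumericVector x, NumericVector y, NumericVector z,
                       NumericVector r, double skin, double e_pair,
                       double w_adh, double delta_cut_um) {
  int n = x.size();
  std::vector<int> ii, jj;
  find_pairs(REAL(x), REAL(y), REAL(z), REAL(r), n, skin, ii, jj);
  double e = 0.0;
  for (size_t k = 0; k < ii.size(); ++k) {
    int i = ii[k], j = jj[k];
    double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
    double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
    double reff = 1e-6 * (r[i] * r[j]) / (r[i] + r[j]);
    e += pair_potential(1e-6 * (r[i] + r[j] - d), reff, e_pair, w_adh,
                        1e-6 * delta_cut_um);
  }
  return e;
}
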