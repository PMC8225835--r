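// Mechanics kernels for the epidermis model.
//
// All lengths are in micrometres, time in days, damping gamma = 1, so a
// "force" has units of µm/day. Periodic in x and y, open in z. The pair
// potential is piecewise quadratic: linear repulsion below the rest
// separation r_eq, a quadratic attraction well between r_eq and r_cut that
// vanishes at both ends (peak attraction k_adh/4 at the midpoint).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

static inline double pair_force_scalar(double r, double r_eq, double k_rep,
                                       double k_adh, double r_cut) {
  if (r < r_eq) return k_rep * (r_eq - r);
  if (r < r_cut) {
    double W = r_cut - r_eq;
    return -k_adh * (r - r_eq) * (r_cut - r) / (W * W);
  }
  return 0.0;
}

// Potential with U(r_cut) = 0; continuous, minimum at r_eq of depth k_adh*W/6.
static inline double pair_energy_scalar(double r, double r_eq, double k_rep,
                                        double k_adh, double r_cut) {
  double W = r_cut - r_eq;
  double well = k_adh * W / 6.0;
  if (r < r_eq) return 0.5 * k_rep * (r_eq - r) * (r_eq - r) - well;
  if (r < r_cut) {
    double u = r - r_eq;
    return k_adh * (W * u * u / 2.0 - u * u * u / 3.0) / (W * W) - well;
  }
  return 0.0;
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Membrane elastic forces: harmonic springs on edges (rest length l0) and
// hinge bending E = k_bend * (1 - cos theta) per interior edge, theta the
// dihedral deviation from flat. Hinge rows are (a, b, c, d): triangles
// (a,b,c) and (b,a,d) share edge (a,b). Forces are the analytic negative
// gradient; they sum to zero over the four hinge vertices.
static void membrane_elastic(const NumericMatrix& mem, const IntegerMatrix& edges,
                             const NumericVector& l0, const IntegerMatrix& hinges,
                             double k_stretch, double k_bend,
                             double Lx, double Ly,
                             NumericMatrix& f, double* energy) {
  const int ne = edges.nrow();
  for (int e = 0; e < ne; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    double d[3] = {min_image(mem(i, 0) - mem(j, 0), Lx),
                   min_image(mem(i, 1) - mem(j, 1), Ly),
                   mem(i, 2) - mem(j, 2)};
    double r = std::sqrt(dot3(d, d));
    if (r <= 0) stop("membrane edge with coincident endpoints");
    double fm = -k_stretch * (r - l0[e]) / r;
    for (int k = 0; k < 3; ++k) {
      f(i, k) += fm * d[k];
      f(j, k) -= fm * d[k];
    }
    if (energy) *energy += 0.5 * k_stretch * (r - l0[e]) * (r - l0[e]);
  }
  const int nh = hinges.nrow();
  for (int h = 0; h < nh; ++h) {
    int ia = hinges(h, 0) - 1, ib = hinges(h, 1) - 1,
        ic = hinges(h, 2) - 1, id = hinges(h, 3) - 1;
    // coordinates relative to a, minimal image (hinge extent << box/2)
    double xb[3] = {min_image(mem(ib, 0) - mem(ia, 0), Lx),
                    min_image(mem(ib, 1) - mem(ia, 1), Ly),
                    mem(ib, 2) - mem(ia, 2)};
    double xc[3] = {min_image(mem(ic, 0) - mem(ia, 0), Lx),
                    min_image(mem(ic, 1) - mem(ia, 1), Ly),
                    mem(ic, 2) - mem(ia, 2)};
    double xd[3] = {min_image(mem(id, 0) - mem(ia, 0), Lx),
                    min_image(mem(id, 1) - mem(ia, 1), Ly),
                    mem(id, 2) - mem(ia, 2)};
    // n1 = xb x xc, n2 = xd x xb  (both +z for a flat mesh)
    double n1[3], n2[3];
    cross3(xb, xc, n1);
    cross3(xd, xb, n2);
    double m1 = std::sqrt(dot3(n1, n1)), m2 = std::sqrt(dot3(n2, n2));
    if (m1 < 1e-12 || m2 < 1e-12) stop("degenerate membrane triangle");
    double ct = dot3(n1, n2) / (m1 * m2);
    if (energy) *energy += k_bend * (1.0 - ct);
    // ga = d cos / d n1, gb = d cos / d n2
    double ga[3], gb[3];
    for (int k = 0; k < 3; ++k) {
      ga[k] = n2[k] / (m1 * m2) - ct * n1[k] / (m1 * m1);
      gb[k] = n1[k] / (m1 * m2) - ct * n2[k] / (m2 * m2);
    }
    // d cos/d xb = xc x ga + gb x xd ; d cos/d xc = ga x xb ; d cos/d xd = xb x gb
    double t1[3], t2[3], gxb[3], gxc[3], gxd[3];
    cross3(xc, ga, t1);
    cross3(gb, xd, t2);
    for (int k = 0; k < 3; ++k) gxb[k] = t1[k] + t2[k];
    cross3(ga, xb, gxc);
    cross3(xb, gb, gxd);
    // F = -dE/dx = +k_bend * d cos/d x ; a gets minus the sum (translation inv.)
    for (int k = 0; k < 3; ++k) {
      double fb = k_bend * gxb[k], fc = k_bend * gxc[k], fd = k_bend * gxd[k];
      f(ib, k) += fb;
      f(ic, k) += fc;
      f(id, k) += fd;
      f(ia, k) -= fb + fc + fd;
    }
  }
}

// [[Rcpp::export]]
List ep_membrane_forces_cpp(NumericMatrix mem, IntegerMatrix edges,
                            NumericVector l0, IntegerMatrix hinges,
                            double k_stretch, double k_bend,
                            double Lx, double Ly) {
  NumericMatrix f(mem.nrow(), 3);
  double energy = 0.0;
  membrane_elastic(mem, edges, l0, hinges, k_stretch, k_bend, Lx, Ly, f, &energy);
  return List::create(_["force"] = f, _["energy"] = energy);
}

struct Grid {
  int nx, ny, nz;
  double hx, hy, hz, zmin, Lx, Ly;
  std::vector<std::vector<int> > bins;
  bool brute;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double cut, double Lx_, double Ly_) {
    Lx = Lx_; Ly = Ly_;
    nx = (int)std::floor(Lx / cut);
    ny = (int)std::floor(Ly / cut);
    brute = (nx < 3 || ny < 3);
    if (brute) return;
    hx = Lx / nx; hy = Ly / ny;
    double zmax = -1e30; zmin = 1e30;
    for (size_t i = 0; i < z.size(); ++i) {
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    nz = std::max(1, (int)std::floor((zmax - zmin) / cut) + 1);
    hz = (zmax - zmin) / nz + 1e-9;
    if (hz < cut) { nz = std::max(1, (int)((zmax - zmin) / cut)); hz = cut; }
    bins.assign((size_t)nx * ny * nz, std::vector<int>());
    for (size_t i = 0; i < x.size(); ++i) bins[index_of(x[i], y[i], z[i])].push_back((int)i);
  }
  int index_of(double x, double y, double z) const {
    int ix = (int)std::floor(x / hx); ix = ((ix % nx) + nx) % nx;
    int iy = (int)std::floor(y / hy); iy = ((iy % ny) + ny) % ny;
    int iz = (int)std::floor((z - zmin) / hz);
    iz = std::max(0, std::min(nz - 1, iz));
    return (iz * ny + iy) * nx + ix;
  }
};

// [[Rcpp::export]]
List ep_forces_cpp(NumericMatrix derm, LogicalVector derm_mobile,
                   NumericMatrix mem, IntegerMatrix edges, NumericVector l0,
                   IntegerMatrix hinges,
                   NumericMatrix cells, NumericVector cell_a, NumericVector cell_c,
                   LogicalVector attached, LogicalVector is_stem,
                   List par, bool want_energy) {
  const int nd = derm.nrow(), nm = mem.nrow(), nc = cells.nrow();
  const double Lx = par["Lx"], Ly = par["Ly"];
  const double k_rep = par["k_rep"], k_adh_cell = par["k_adh_cell"];
  const double k_adh_derm = par["k_adh_derm_eff"], k_adh_dm = par["k_adh_derm_mem"];
  const double k_stem = par["k_stem"], k_TA = par["k_TA"];
  const double k_stretch = par["k_stretch"], k_bend = par["k_bend"];
  const double derm_req = par["derm_req"], derm_rcut = par["derm_rcut"];
  const double dm_req = par["dm_req"], dm_rcut = par["dm_rcut"];
  const double rcut_factor = par["rcut_factor"];
  const double R = par["R"], derm_radius = par["derm_radius"];

  NumericMatrix f_derm(nd, 3), f_mem(nm, 3), f_cell(nc, 3);
  NumericVector mem_dist(nc, NA_REAL);
  double energy = 0.0;
  double* epen = want_energy ? &energy : (double*)0;

  // combined point set: 0..nd-1 derm, nd..nd+nm-1 mem, then cells
  const int n = nd + nm + nc;
  std::vector<double> X(n), Y(n), Z(n);
  std::vector<int> sp(n), loc(n);
  double amax = R;
  for (int i = 0; i < nc; ++i) amax = std::max(amax, cell_a[i]);
  for (int i = 0; i < nd; ++i) { X[i] = derm(i,0); Y[i] = derm(i,1); Z[i] = derm(i,2); sp[i] = 0; loc[i] = i; }
  for (int i = 0; i < nm; ++i) { int k = nd + i; X[k] = mem(i,0); Y[k] = mem(i,1); Z[k] = mem(i,2); sp[k] = 1; loc[k] = i; }
  for (int i = 0; i < nc; ++i) { int k = nd + nm + i; X[k] = cells(i,0); Y[k] = cells(i,1); Z[k] = cells(i,2); sp[k] = 2; loc[k] = i; }

  double cut = std::max(std::max(derm_rcut, dm_rcut),
                        std::max(rcut_factor * 2.0 * amax, amax + 2.0 * derm_radius));

  std::vector<int> pr_i, pr_j;  // cell neighbour graph (local cell indices)
  pr_i.reserve(16 * nc); pr_j.reserve(16 * nc);

  // pair handler over combined indices; accumulates forces symmetrically
  #define HANDLE_PAIR(gi, gj) do {                                            \
    int a_ = (gi), b_ = (gj);                                                 \
    if (sp[a_] > sp[b_]) std::swap(a_, b_);                                   \
    int si = sp[a_], sj = sp[b_];                                             \
    if (si == 1 && sj == 1) break;                                            \
    double dx = min_image(X[a_] - X[b_], Lx);                                 \
    double dy = min_image(Y[a_] - Y[b_], Ly);                                 \
    double dz = Z[a_] - Z[b_];                                                \
    double r2 = dx*dx + dy*dy + dz*dz;                                        \
    if (r2 > cut * cut) break;                                                \
    double fx = 0, fy = 0, fz = 0;                                            \
    if (si == 0 && sj == 0) {                                                 \
      double r = std::sqrt(r2);                                               \
      if (r < derm_rcut) {                                                    \
        if (r <= 0) stop("coincident dermal particles");                      \
        double fs = pair_force_scalar(r, derm_req, k_rep, k_adh_derm, derm_rcut); \
        fx = fs * dx / r; fy = fs * dy / r; fz = fs * dz / r;                 \
        if (epen) *epen += pair_energy_scalar(r, derm_req, k_rep, k_adh_derm, derm_rcut); \
      }                                                                       \
    } else if (si == 0 && sj == 1) {                                          \
      double r = std::sqrt(r2);                                               \
      if (r < dm_rcut) {                                                      \
        if (r <= 0) stop("coincident dermis/membrane particles");             \
        double fs = pair_force_scalar(r, dm_req, k_rep, k_adh_dm, dm_rcut);   \
        fx = fs * dx / r; fy = fs * dy / r; fz = fs * dz / r;                 \
        if (epen) *epen += pair_energy_scalar(r, dm_req, k_rep, k_adh_dm, dm_rcut); \
      }                                                                       \
    } else if (si == 0 && sj == 2) {                                          \
      int ci = loc[b_];                                                       \
      double req = cell_a[ci] + derm_radius;                                  \
      double r = std::sqrt(r2);                                               \
      if (r < req) {                                                          \
        if (r <= 0) stop("cell coincident with dermal particle");             \
        double fs = k_rep * (req - r);                                        \
        fx = fs * dx / r; fy = fs * dy / r; fz = fs * dz / r;                 \
        if (epen) *epen += 0.5 * k_rep * (req - r) * (req - r);               \
      }                                                                       \
    } else if (si == 1 && sj == 2) {                                          \
      int ci = loc[b_];                                                       \
      double s = 0.5 * (cell_a[ci] / cell_c[ci] + 1.0);                       \
      double reff2 = dx*dx + dy*dy + s*s*dz*dz;                               \
      double req = cell_a[ci];                                                \
      if (reff2 < req * req) {                                                \
        double reff = std::sqrt(reff2);                                       \
        if (reff <= 0) stop("cell coincident with membrane particle");        \
        double fs = k_rep * (req - reff) / reff;                              \
        fx = fs * dx; fy = fs * dy; fz = fs * s * s * dz;                     \
        if (epen) *epen += 0.5 * k_rep * (req - reff) * (req - reff);         \
      }                                                                       \
    } else {                                                                  \
      int ci = loc[a_], cj = loc[b_];                                         \
      double s = 0.5 * (cell_a[ci] / cell_c[ci] + cell_a[cj] / cell_c[cj]);   \
      double reff2 = dx*dx + dy*dy + s*s*dz*dz;                               \
      double req = cell_a[ci] + cell_a[cj];                                   \
      double rc = rcut_factor * req;                                          \
      if (reff2 < rc * rc) {                                                  \
        double reff = std::sqrt(reff2);                                       \
        if (reff <= 0) stop("coincident cells");                              \
        pr_i.push_back(ci); pr_j.push_back(cj);                               \
        double fs = pair_force_scalar(reff, req, k_rep, k_adh_cell, rc) / reff; \
        fx = fs * dx; fy = fs * dy; fz = fs * s * s * dz;                     \
        if (epen) *epen += pair_energy_scalar(reff, req, k_rep, k_adh_cell, rc); \
      }                                                                       \
    }                                                                         \
    if (fx != 0 || fy != 0 || fz != 0) {                                      \
      if (sp[a_] == 0) { f_derm(loc[a_],0) += fx; f_derm(loc[a_],1) += fy; f_derm(loc[a_],2) += fz; } \
      else if (sp[a_] == 1) { f_mem(loc[a_],0) += fx; f_mem(loc[a_],1) += fy; f_mem(loc[a_],2) += fz; } \
      else { f_cell(loc[a_],0) += fx; f_cell(loc[a_],1) += fy; f_cell(loc[a_],2) += fz; } \
      if (sp[b_] == 0) { f_derm(loc[b_],0) -= fx; f_derm(loc[b_],1) -= fy; f_derm(loc[b_],2) -= fz; } \
      else if (sp[b_] == 1) { f_mem(loc[b_],0) -= fx; f_mem(loc[b_],1) -= fy; f_mem(loc[b_],2) -= fz; } \
      else { f_cell(loc[b_],0) -= fx; f_cell(loc[b_],1) -= fy; f_cell(loc[b_],2) -= fz; } \
    }                                                                         \
  } while (0)

  Grid g;
  g.build(X, Y, Z, cut, Lx, Ly);
  if (g.brute) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) HANDLE_PAIR(i, j);
  } else {
    // half-shell neighbour offsets (z not periodic; only upward)
    static const int off[13][3] = {
      {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
      {-1,-1,1}, {0,-1,1}, {1,-1,1}, {-1,0,1}, {0,0,1}, {1,0,1},
      {-1,1,1}, {0,1,1}, {1,1,1}};
    for (int iz = 0; iz < g.nz; ++iz)
      for (int iy = 0; iy < g.ny; ++iy)
        for (int ix = 0; ix < g.nx; ++ix) {
          const std::vector<int>& A = g.bins[((size_t)iz * g.ny + iy) * g.nx + ix];
          if (A.empty()) continue;
          for (size_t u = 0; u < A.size(); ++u)
            for (size_t v = u + 1; v < A.size(); ++v) HANDLE_PAIR(A[u], A[v]);
          for (int o = 0; o < 13; ++o) {
            int jx = ((ix + off[o][0]) % g.nx + g.nx) % g.nx;
            int jy = ((iy + off[o][1]) % g.ny + g.ny) % g.ny;
            int jz = iz + off[o][2];
            if (jz < 0 || jz >= g.nz) continue;
            const std::vector<int>& B = g.bins[((size_t)jz * g.ny + jy) * g.nx + jx];
            for (size_t u = 0; u < A.size(); ++u)
              for (size_t v = 0; v < B.size(); ++v) HANDLE_PAIR(A[u], B[v]);
          }
        }
  }
  #undef HANDLE_PAIR

  // membrane elastic terms
  membrane_elastic(mem, edges, l0, hinges, k_stretch, k_bend, Lx, Ly, f_mem, epen);

  // basal adhesion: pull-only spring from each attached cell to its nearest
  // membrane particle; zero force at contact distance R; reaction applied to
  // the membrane particle. Stems use k_stem, TA cells k_TA.
  for (int ci = 0; ci < nc; ++ci) {
    if (!attached[ci]) continue;
    double best = 1e30; int bj = -1; double bd[3] = {0, 0, 0};
    for (int mj = 0; mj < nm; ++mj) {
      double dx = min_image(cells(ci, 0) - mem(mj, 0), Lx);
      double dy = min_image(cells(ci, 1) - mem(mj, 1), Ly);
      double dz = cells(ci, 2) - mem(mj, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) { best = r2; bj = mj; bd[0] = dx; bd[1] = dy; bd[2] = dz; }
    }
    double d = std::sqrt(best);
    mem_dist[ci] = d;
    if (d > R && bj >= 0) {
      double k = is_stem[ci] ? k_stem : k_TA;
      double fs = -k * (d - R) / d;  // pulls cell toward membrane
      for (int kk = 0; kk < 3; ++kk) {
        f_cell(ci, kk) += fs * bd[kk];
        f_mem(bj, kk) -= fs * bd[kk];
      }
      if (epen) *epen += 0.5 * k * (d - R) * (d - R);
    }
  }

  // immobile dermal particles: zero out so Euler updates leave them fixed
  for (int i = 0; i < nd; ++i)
    if (!derm_mobile[i]) { f_derm(i, 0) = 0; f_derm(i, 1) = 0; f_derm(i, 2) = 0; }

  IntegerMatrix pairs(pr_i.size(), 2);
  for (size_t k = 0; k < pr_i.size(); ++k) {
    pairs(k, 0) = pr_i[k] + 1;
    pairs(k, 1) = pr_j[k] + 1;
  }
  return List::create(_["f_derm"] = f_derm, _["f_mem"] = f_mem,
                      _["f_cell"] = f_cell, _["mem_dist"] = mem_dist,
                      _["pairs"] = pairs, _["energy"] = energy);
}

// Sum over graph neighbours of (v_j - v_i) for every i; pairs are 1-based.
// [[Rcpp::export]]
NumericVector ep_graph_sum_cpp(NumericVector v, IntegerVector pi, IntegerVector pj, int n) {
  NumericVector out(n);
  for (int k = 0; k < pi.size(); ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double d = v[j] - v[i];
    out[i] += d;
    out[j] -= d;
  }
  return out;
}

// Surface exposure for desquamation candidates: a cell is exposed when no
// other cell centre lies above it within one lateral (equatorial) radius.
// [[Rcpp::export]]
LogicalVector ep_exposed_cpp(NumericMatrix cells, NumericVector a,
                             IntegerVector cand, double Lx, double Ly) {
  int n = cells.nrow();
  LogicalVector out(cand.size());
  for (int k = 0; k < cand.size(); ++k) {
    int i = cand[k] - 1;
    bool exposed = true;
    double ai2 = a[i] * a[i];
    for (int j = 0; j < n && exposed; ++j) {
      if (j == i) continue;
      if (cells(j, 2) <= cells(i, 2)) continue;
      double dx = min_image(cells(i, 0) - cells(j, 0), Lx);
      double dy = min_image(cells(i, 1) - cells(j, 1), Ly);
      if (dx * dx + dy * dy < ai2) exposed = false;
    }
    out[k] = exposed;
  }
  return out;
}
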