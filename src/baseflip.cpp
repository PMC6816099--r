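// Core numerical kernels: analytic/coarse-grained force fields, collective
// variables with analytic gradients, the capped adaptive biasing potential,
// and a BAOAB Langevin integrator with pluggable restraint/bias forces.
//
// Units: length Angstrom, energy kJ/mol, time ps, mass amu, temperature K.
// 1 kJ/mol = 100 amu A^2 / ps^2, hence the factor KEFAC in the integrator.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

static const double KB = 0.0083145;   // kJ/mol/K
static const double KEFAC = 100.0;    // (kJ/mol) -> amu A^2/ps^2

// ---------------------------------------------------------------------------
// System representation
// ---------------------------------------------------------------------------

enum SysKind { DOUBLE_WELL, HARMONIC, MULLER_BROWN, COS2D, CG_DUPLEX };

struct Sys {
  int kind;
  int dim;
  NumericVector params;
  // cg_duplex topology (0-based indices)
  NumericMatrix bonds;   // i, j, k, r0
  NumericMatrix angles;  // i, j, k, ktheta, theta0
  NumericMatrix pairs;   // i, j, D, r0, cutoff
  NumericMatrix excl;    // soft-core candidate pairs: i, j
  double sc_eps, sc_rc;
  bool has_topology;
};

static Sys parse_sys(const List& s) {
  Sys sys;
  std::string kind = as<std::string>(s["kind"]);
  sys.dim = as<int>(s["dim"]);
  sys.params = as<NumericVector>(s["params"]);
  sys.has_topology = false;
  if (kind == "double_well") sys.kind = DOUBLE_WELL;
  else if (kind == "harmonic") sys.kind = HARMONIC;
  else if (kind == "muller_brown") sys.kind = MULLER_BROWN;
  else if (kind == "cos2d") sys.kind = COS2D;
  else if (kind == "cg_duplex") {
    sys.kind = CG_DUPLEX;
    sys.bonds = as<NumericMatrix>(s["bonds"]);
    sys.angles = as<NumericMatrix>(s["angles"]);
    sys.pairs = as<NumericMatrix>(s["pairs"]);
    sys.excl = as<NumericMatrix>(s["softcore_pairs"]);
    sys.sc_eps = as<double>(s["sc_eps"]);
    sys.sc_rc = as<double>(s["sc_rc"]);
    sys.has_topology = true;
  } else stop("unknown system kind: %s", kind.c_str());
  return sys;
}

// Muller-Brown canonical constants
static const double MB_A[4]  = {-200.0, -100.0, -170.0, 15.0};
static const double MB_a[4]  = {-1.0, -1.0, -6.5, 0.7};
static const double MB_b[4]  = {0.0, 0.0, 11.0, 0.6};
static const double MB_c[4]  = {-10.0, -10.0, -6.5, 0.7};
static const double MB_x0[4] = {1.0, 0.0, -0.5, -1.0};
static const double MB_y0[4] = {0.0, 0.5, 1.5, 1.0};

// energy; grad accumulated into g (dU/dx)
static double sys_energy_grad(const Sys& sys, const double* x, double* g) {
  const int d = sys.dim;
  for (int i = 0; i < d; ++i) g[i] = 0.0;
  switch (sys.kind) {
  case DOUBLE_WELL: {
    double U0 = sys.params[0], a = sys.params[1];
    double s = x[0] / a, q = s * s - 1.0;
    g[0] = U0 * 2.0 * q * 2.0 * x[0] / (a * a);
    return U0 * q * q;
  }
  case HARMONIC: {
    int nd = (int)sys.params[0];
    double U = 0.0;
    for (int i = 0; i < nd; ++i) {
      double k = sys.params[1 + i], mu = sys.params[1 + nd + i];
      double dx = x[i] - mu;
      U += 0.5 * k * dx * dx;
      g[i] = k * dx;
    }
    return U;
  }
  case MULLER_BROWN: {
    double U = 0.0;
    for (int k = 0; k < 4; ++k) {
      double dx = x[0] - MB_x0[k], dy = x[1] - MB_y0[k];
      double e = MB_A[k] * std::exp(MB_a[k]*dx*dx + MB_b[k]*dx*dy + MB_c[k]*dy*dy);
      U += e;
      g[0] += e * (2.0*MB_a[k]*dx + MB_b[k]*dy);
      g[1] += e * (MB_b[k]*dx + 2.0*MB_c[k]*dy);
    }
    return U;
  }
  case COS2D: {
    double A = sys.params[0], B = sys.params[1];
    g[0] = A * std::sin(x[0]);
    g[1] = B * std::sin(x[1]);
    return A * (1.0 - std::cos(x[0])) + B * (1.0 - std::cos(x[1]));
  }
  case CG_DUPLEX: {
    double U = 0.0;
    // harmonic bonds (includes backbone and stacking terms)
    for (int r = 0; r < sys.bonds.nrow(); ++r) {
      int i = 3 * (int)sys.bonds(r, 0), j = 3 * (int)sys.bonds(r, 1);
      double k = sys.bonds(r, 2), r0 = sys.bonds(r, 3);
      double dx = x[i]-x[j], dy = x[i+1]-x[j+1], dz = x[i+2]-x[j+2];
      double rr = std::sqrt(dx*dx + dy*dy + dz*dz);
      double dl = rr - r0;
      U += 0.5 * k * dl * dl;
      if (rr > 1e-12) {
        double c = k * dl / rr;
        g[i] += c*dx; g[i+1] += c*dy; g[i+2] += c*dz;
        g[j] -= c*dx; g[j+1] -= c*dy; g[j+2] -= c*dz;
      }
    }
    // harmonic angles
    for (int r = 0; r < sys.angles.nrow(); ++r) {
      int i = 3*(int)sys.angles(r,0), j = 3*(int)sys.angles(r,1), k3 = 3*(int)sys.angles(r,2);
      double kt = sys.angles(r,3), th0 = sys.angles(r,4);
      double rij[3] = {x[i]-x[j], x[i+1]-x[j+1], x[i+2]-x[j+2]};
      double rkj[3] = {x[k3]-x[j], x[k3+1]-x[j+1], x[k3+2]-x[j+2]};
      double nij = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
      double nkj = std::sqrt(rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2]);
      if (nij < 1e-12 || nkj < 1e-12) continue;
      double cs = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (nij*nkj);
      cs = std::max(-1.0, std::min(1.0, cs));
      double th = std::acos(cs);
      double dth = th - th0;
      U += 0.5 * kt * dth * dth;
      double sn = std::sqrt(std::max(1e-12, 1.0 - cs*cs));
      double coef = kt * dth / sn;
      for (int m = 0; m < 3; ++m) {
        double di = (rkj[m]/(nij*nkj) - cs*rij[m]/(nij*nij));
        double dk = (rij[m]/(nij*nkj) - cs*rkj[m]/(nkj*nkj));
        // dU/dri = kt*dth * dtheta/dri, dtheta/dri = -di/sin(theta)
        g[i+m]  += -coef * di;
        g[k3+m] += -coef * dk;
        g[j+m]  +=  coef * (di + dk);
      }
    }
    // breakable base-pair bonds: U = -D + 0.5*kp*(r-r0)^2 capped at 0 for r>r0
    for (int r = 0; r < sys.pairs.nrow(); ++r) {
      int i = 3*(int)sys.pairs(r,0), j = 3*(int)sys.pairs(r,1);
      double D = sys.pairs(r,2), r0 = sys.pairs(r,3), rc = sys.pairs(r,4);
      double dmax = rc - r0;
      double kp = 2.0 * D / (dmax*dmax);
      double dx = x[i]-x[j], dy = x[i+1]-x[j+1], dz = x[i+2]-x[j+2];
      double rr = std::sqrt(dx*dx + dy*dy + dz*dz);
      double dl = rr - r0;
      if (dl > dmax) { U += 0.0; continue; }   // broken: flat, zero force
      U += -D + 0.5 * kp * dl * dl;
      if (rr > 1e-12) {
        double c = kp * dl / rr;
        g[i] += c*dx; g[i+1] += c*dy; g[i+2] += c*dz;
        g[j] -= c*dx; g[j+1] -= c*dy; g[j+2] -= c*dz;
      }
    }
    // soft-core excluded volume on listed candidate pairs
    // (per-pair radius and strength)
    for (int r = 0; r < sys.excl.nrow(); ++r) {
      int i = 3*(int)sys.excl(r,0), j = 3*(int)sys.excl(r,1);
      double rc2 = sys.excl(r,2) * sys.excl(r,2);
      double eps = sys.excl(r,3);
      double dx = x[i]-x[j], dy = x[i+1]-x[j+1], dz = x[i+2]-x[j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rc2) continue;
      double q = 1.0 - r2/rc2;
      U += eps * q * q;
      double c = -4.0 * eps * q / rc2;  // dU/dxi = c * dx
      g[i] += c*dx; g[i+1] += c*dy; g[i+2] += c*dz;
      g[j] -= c*dx; g[j+1] -= c*dy; g[j+2] -= c*dz;
    }
    return U;
  }
  }
  return NA_REAL;
}

// ---------------------------------------------------------------------------
// Collective variables
// ---------------------------------------------------------------------------

struct CVDef {
  int type;                 // 0 coord, 1 pseudodihedral
  int idx;                  // coord index
  bool periodic;
  std::vector<int> g[4];    // pdih groups (0-based particle indices)
};

static CVDef parse_cv(const List& cv) {
  CVDef d;
  std::string t = as<std::string>(cv["type"]);
  if (t == "coord") {
    d.type = 0;
    d.idx = as<int>(cv["index"]);
    d.periodic = as<bool>(cv["periodic"]);
  } else if (t == "pdih") {
    d.type = 1;
    d.periodic = true;
    const char* nm[4] = {"g1","g2","g3","g4"};
    for (int k = 0; k < 4; ++k) {
      IntegerVector gi = as<IntegerVector>(cv[nm[k]]);
      d.g[k].assign(gi.begin(), gi.end());
    }
  } else stop("unknown cv type: %s", t.c_str());
  return d;
}

static inline double wrap_pi(double a) {
  while (a <= -M_PI) a += 2.0*M_PI;
  while (a >   M_PI) a -= 2.0*M_PI;
  return a;
}

static inline void cross3(const double* u, const double* v, double* w) {
  w[0] = u[1]*v[2] - u[2]*v[1];
  w[1] = u[2]*v[0] - u[0]*v[2];
  w[2] = u[0]*v[1] - u[1]*v[0];
}
static inline double dot3(const double* u, const double* v) {
  return u[0]*v[0] + u[1]*v[1] + u[2]*v[2];
}

// dihedral of four points; optionally gradient wrt the 12 coordinates
static double dihedral4(const double* p1, const double* p2, const double* p3,
                        const double* p4, double* dg /* 12 or NULL */) {
  double b1[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
  double b2[3] = {p3[0]-p2[0], p3[1]-p2[1], p3[2]-p2[2]};
  double b3[3] = {p4[0]-p3[0], p4[1]-p3[1], p4[2]-p3[2]};
  double n1[3], n2[3], m1[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double lb2 = std::sqrt(dot3(b2, b2));
  double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
  if (lb2 < 1e-10 || n1sq < 1e-16 || n2sq < 1e-16)
    stop("degenerate geometry: collinear or coincident dihedral points");
  cross3(n1, n2, m1);
  double phi = std::atan2(dot3(m1, b2) / lb2, dot3(n1, n2));
  if (dg) {
    // standard analytic dihedral derivatives
    double f1[3], f4[3];
    for (int m = 0; m < 3; ++m) {
      f1[m] = -lb2 / n1sq * n1[m];
      f4[m] =  lb2 / n2sq * n2[m];
    }
    double p = dot3(b1, b2) / (lb2*lb2);
    double q = dot3(b3, b2) / (lb2*lb2);
    for (int m = 0; m < 3; ++m) {
      double f2 = -(1.0 + p) * f1[m] + q * f4[m];
      double f3 = p * f1[m] - (1.0 + q) * f4[m];
      dg[0 + m] = f1[m];
      dg[3 + m] = f2;
      dg[6 + m] = f3;
      dg[9 + m] = f4[m];
    }
  }
  return phi;
}

static void centroid(const double* x, const std::vector<int>& g, double* c) {
  c[0] = c[1] = c[2] = 0.0;
  for (size_t k = 0; k < g.size(); ++k) {
    int i = 3 * g[k];
    c[0] += x[i]; c[1] += x[i+1]; c[2] += x[i+2];
  }
  double n = (double)g.size();
  c[0] /= n; c[1] /= n; c[2] /= n;
}

static double cv_value(const CVDef& cv, const double* x) {
  if (cv.type == 0) {
    double v = x[cv.idx];
    return cv.periodic ? wrap_pi(v) : v;
  }
  double c[4][3];
  for (int k = 0; k < 4; ++k) centroid(x, cv.g[k], c[k]);
  return dihedral4(c[0], c[1], c[2], c[3], NULL);
}

// value + gradient accumulated: grad_out += coef * dcv/dx
static double cv_value_addgrad(const CVDef& cv, const double* x,
                               double coef, double* grad_out) {
  if (cv.type == 0) {
    double v = x[cv.idx];
    grad_out[cv.idx] += coef;
    return cv.periodic ? wrap_pi(v) : v;
  }
  double c[4][3], dg[12];
  for (int k = 0; k < 4; ++k) centroid(x, cv.g[k], c[k]);
  double phi = dihedral4(c[0], c[1], c[2], c[3], dg);
  for (int k = 0; k < 4; ++k) {
    double w = coef / (double)cv.g[k].size();
    for (size_t m = 0; m < cv.g[k].size(); ++m) {
      int i = 3 * cv.g[k][m];
      grad_out[i]   += w * dg[3*k];
      grad_out[i+1] += w * dg[3*k+1];
      grad_out[i+2] += w * dg[3*k+2];
    }
  }
  return phi;
}

// ---------------------------------------------------------------------------
// Adaptive biasing potential state
// ---------------------------------------------------------------------------

struct ABP {
  int ndim;
  int nb[2];
  double lo[2], dx[2];
  bool per[2];
  std::vector<double> visits, bias;
  double c, b, alpha, kT, cap;
  int stride, halfwidth;
};

static ABP parse_abp(const List& a) {
  ABP g;
  g.ndim = as<int>(a["ndim"]);
  IntegerVector nb = as<IntegerVector>(a["nbins"]);
  NumericVector lo = as<NumericVector>(a["lo"]), hi = as<NumericVector>(a["hi"]);
  LogicalVector per = as<LogicalVector>(a["periodic"]);
  for (int d = 0; d < g.ndim; ++d) {
    g.nb[d] = nb[d];
    g.lo[d] = lo[d];
    g.dx[d] = (hi[d] - lo[d]) / nb[d];
    g.per[d] = per[d];
  }
  NumericVector v = as<NumericVector>(a["visits"]), bb = as<NumericVector>(a["bias"]);
  g.visits.assign(v.begin(), v.end());
  g.bias.assign(bb.begin(), bb.end());
  g.c = as<double>(a["c"]);
  g.b = as<double>(a["b"]);
  g.alpha = as<double>(a["alpha"]);
  g.kT = KB * as<double>(a["temperature"]);
  g.cap = g.alpha * g.kT;
  g.stride = as<int>(a["stride"]);
  g.halfwidth = as<int>(a["halfwidth"]);
  return g;
}

// continuous cell-center coordinate; returns false if off-grid (non-periodic)
static bool grid_locate(const ABP& g, int d, double z, int& i0, int& i1, double& f) {
  double u = (z - g.lo[d]) / g.dx[d] - 0.5;
  int n = g.nb[d];
  if (g.per[d]) {
    u -= n * std::floor(u / n);
    i0 = (int)std::floor(u);
    f = u - i0;
    i0 = i0 % n;
    i1 = (i0 + 1) % n;
    return true;
  }
  if (u <= 0.0) { i0 = i1 = 0; f = 0.0; return (z >= g.lo[d] - 1e-12); }
  if (u >= n - 1.0) { i0 = i1 = n - 1; f = 0.0; return (z <= g.lo[d] + n*g.dx[d] + 1e-12); }
  i0 = (int)std::floor(u);
  i1 = i0 + 1;
  f = u - i0;
  return true;
}

static inline int cell_index(const ABP& g, int i, int j) {
  return (g.ndim == 1) ? i : (i + g.nb[0] * j);
}

// central-difference derivative of bias along dim d at cell (i,j)
static double bias_cderiv(const ABP& g, int d, int i, int j) {
  int n = g.nb[d];
  int c = (d == 0) ? i : j;
  int cm = c - 1, cp = c + 1;
  double h = 2.0 * g.dx[d];
  if (g.per[d]) { cm = (cm + n) % n; cp = cp % n; }
  else {
    if (cm < 0) { cm = 0; h = g.dx[d]; }
    if (cp > n - 1) { cp = n - 1; h = (cp == cm) ? 1.0 : g.dx[d]; }
    if (cp == cm) return 0.0;
  }
  int im = (d == 0) ? cell_index(g, cm, j) : cell_index(g, i, cm);
  int ip = (d == 0) ? cell_index(g, cp, j) : cell_index(g, i, cp);
  return (g.bias[ip] - g.bias[im]) / h;
}

// bias energy and dU/dz at z; returns energy (0 off-grid)
static double bias_eval(const ABP& g, const double* z, double* dUdz) {
  int i0[2], i1[2];
  double f[2];
  for (int d = 0; d < g.ndim; ++d) dUdz[d] = 0.0;
  for (int d = 0; d < g.ndim; ++d)
    if (!grid_locate(g, d, z[d], i0[d], i1[d], f[d])) return 0.0;
  if (g.ndim == 1) {
    double E = (1-f[0])*g.bias[i0[0]] + f[0]*g.bias[i1[0]];
    dUdz[0] = (1-f[0])*bias_cderiv(g,0,i0[0],0) + f[0]*bias_cderiv(g,0,i1[0],0);
    return E;
  }
  double w00 = (1-f[0])*(1-f[1]), w10 = f[0]*(1-f[1]);
  double w01 = (1-f[0])*f[1],     w11 = f[0]*f[1];
  int c00 = cell_index(g,i0[0],i0[1]), c10 = cell_index(g,i1[0],i0[1]);
  int c01 = cell_index(g,i0[0],i1[1]), c11 = cell_index(g,i1[0],i1[1]);
  double E = w00*g.bias[c00] + w10*g.bias[c10] + w01*g.bias[c01] + w11*g.bias[c11];
  for (int d = 0; d < 2; ++d) {
    dUdz[d] = w00*bias_cderiv(g,d,i0[0],i0[1]) + w10*bias_cderiv(g,d,i1[0],i0[1])
            + w01*bias_cderiv(g,d,i0[0],i1[1]) + w11*bias_cderiv(g,d,i1[0],i1[1]);
  }
  return E;
}

static void abp_update_cell(ABP& g, int cell, double add) {
  g.visits[cell] += add;
  double bb = (g.kT / g.b) * std::log1p(g.b * g.c * g.visits[cell]);
  g.bias[cell] = std::min(g.cap, bb);
}

// deposit mollified kernel of total mass `mass` centered at z (tempered)
// returns false if z off-grid on a non-periodic dimension
static bool abp_deposit(ABP& g, const double* z, double mass) {
  double dUdz[2];
  double bz = bias_eval(g, z, dUdz);
  double temper = 1.0 - bz / g.cap;
  if (temper <= 0.0) temper = 0.0;
  int w = g.halfwidth;
  int cc[2];
  for (int d = 0; d < g.ndim; ++d) {
    double u = (z[d] - g.lo[d]) / g.dx[d];
    int n = g.nb[d];
    if (g.per[d]) {
      u -= n * std::floor(u / n);
      cc[d] = ((int)std::floor(u)) % n;
    } else {
      if (z[d] < g.lo[d] || z[d] > g.lo[d] + n * g.dx[d]) return false;
      cc[d] = std::min(n - 1, std::max(0, (int)std::floor(u)));
    }
  }
  // kernel weights per offset: raised-cosine bump, support |o| <= w
  std::vector<double> kw(2*w+1);
  for (int o = -w; o <= w; ++o)
    kw[o+w] = 1.0 + std::cos(M_PI * o / (w + 1.0));
  // collect in-grid cells and total weight, then normalize
  std::vector<int> cells;
  std::vector<double> wts;
  double tot = 0.0;
  if (g.ndim == 1) {
    int n = g.nb[0];
    for (int o = -w; o <= w; ++o) {
      int i = cc[0] + o;
      if (g.per[0]) i = ((i % n) + n) % n;
      else if (i < 0 || i >= n) continue;
      cells.push_back(i);
      wts.push_back(kw[o+w]);
      tot += kw[o+w];
    }
  } else {
    int n0 = g.nb[0], n1 = g.nb[1];
    for (int o1 = -w; o1 <= w; ++o1) {
      int j = cc[1] + o1;
      if (g.per[1]) j = ((j % n1) + n1) % n1;
      else if (j < 0 || j >= n1) continue;
      for (int o0 = -w; o0 <= w; ++o0) {
        int i = cc[0] + o0;
        if (g.per[0]) i = ((i % n0) + n0) % n0;
        else if (i < 0 || i >= n0) continue;
        cells.push_back(cell_index(g, i, j));
        double ww = kw[o0+w] * kw[o1+w];
        wts.push_back(ww);
        tot += ww;
      }
    }
  }
  if (tot <= 0.0) return false;
  double scale = mass * temper / tot;
  for (size_t k = 0; k < cells.size(); ++k)
    abp_update_cell(g, cells[k], wts[k] * scale);
  return true;
}

static List abp_to_list(const ABP& g, const List& proto) {
  List out = clone(proto);
  out["visits"] = NumericVector(g.visits.begin(), g.visits.end());
  out["bias"] = NumericVector(g.bias.begin(), g.bias.end());
  return out;
}

// ---------------------------------------------------------------------------
// Restraints
// ---------------------------------------------------------------------------

struct CVRestraint { CVDef cv; double target, k; };

// position restraints: rows (dofbase_idx0 particle, rx, ry, rz, k)
static double restraint_forces(const NumericMatrix& pos,
                               const std::vector<CVRestraint>& cvr,
                               const double* x, double* g, int dim) {
  double U = 0.0;
  for (int r = 0; r < pos.nrow(); ++r) {
    int i = 3 * (int)pos(r, 0);
    double k = pos(r, 4);
    for (int m = 0; m < 3; ++m) {
      double dxm = x[i+m] - pos(r, 1+m);
      U += 0.5 * k * dxm * dxm;
      g[i+m] += k * dxm;
    }
  }
  for (size_t r = 0; r < cvr.size(); ++r) {
    // two-pass: value first (cheap for coord; pdih recomputed with grad)
    std::vector<double> tmp(dim, 0.0);
    double v = cv_value_addgrad(cvr[r].cv, x, 1.0, tmp.data());
    double d = v - cvr[r].target;
    if (cvr[r].cv.periodic) d = wrap_pi(d);
    U += 0.5 * cvr[r].k * d * d;
    double coef = cvr[r].k * d;
    for (int i = 0; i < dim; ++i) g[i] += coef * tmp[i];
  }
  return U;
}

// ---------------------------------------------------------------------------
// Exported primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_force_energy(List sys, NumericVector x) {
  Sys s = parse_sys(sys);
  if ((int)x.size() != s.dim) stop("coordinate length mismatch");
  NumericVector g(s.dim);
  double U = sys_energy_grad(s, x.begin(), g.begin());
  return List::create(_["energy"] = U, _["gradient"] = g);
}

// [[Rcpp::export]]
double cpp_dihedral(NumericVector p1, NumericVector p2,
                    NumericVector p3, NumericVector p4) {
  return dihedral4(p1.begin(), p2.begin(), p3.begin(), p4.begin(), NULL);
}

// [[Rcpp::export]]
NumericVector cpp_cv_values(List cvs, NumericVector x) {
  int n = cvs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    CVDef d = parse_cv(as<List>(cvs[i]));
    out[i] = cv_value(d, x.begin());
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cv_gradient(List cv, NumericVector x) {
  CVDef d = parse_cv(cv);
  NumericVector g(x.size());
  cv_value_addgrad(d, x.begin(), 1.0, g.begin());
  return g;
}

// [[Rcpp::export]]
List cpp_abp_deposit(List state, NumericVector z, double mass) {
  ABP g = parse_abp(state);
  if ((int)z.size() != g.ndim) stop("CV dimension mismatch");
  bool ok = abp_deposit(g, z.begin(), mass);
  if (!ok) stop("deposit outside grid on a non-periodic dimension");
  return abp_to_list(g, state);
}

// [[Rcpp::export]]
NumericVector cpp_abp_eval(List state, NumericVector z) {
  ABP g = parse_abp(state);
  if ((int)z.size() != g.ndim) stop("CV dimension mismatch");
  double dUdz[2];
  double E = bias_eval(g, z.begin(), dUdz);
  NumericVector out(1 + g.ndim);
  out[0] = E;
  for (int d = 0; d < g.ndim; ++d) out[1+d] = dUdz[d];
  return out;
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_langevin(List sys, NumericVector x0, NumericVector mass_dof,
                  double dt, double gamma, double temperature,
                  int n_steps, int record_stride,
                  List cvs, Nullable<List> abp_state, IntegerVector bias_cv,
                  NumericMatrix pos_restraints, List cv_restraints,
                  int frame_stride) {
  RNGScope scope;
  Sys s = parse_sys(sys);
  int dim = s.dim;
  if ((int)x0.size() != dim) stop("start coordinate length mismatch");
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(dim, 0.0), g(dim, 0.0), gr(dim, 0.0);
  double kT = KB * temperature;

  std::vector<CVDef> cvdefs;
  for (int i = 0; i < cvs.size(); ++i) cvdefs.push_back(parse_cv(as<List>(cvs[i])));
  std::vector<CVRestraint> cvr;
  for (int i = 0; i < cv_restraints.size(); ++i) {
    List r = as<List>(cv_restraints[i]);
    CVRestraint c;
    c.cv = parse_cv(as<List>(r["cv"]));
    c.target = as<double>(r["target"]);
    c.k = as<double>(r["k"]);
    cvr.push_back(c);
  }

  bool has_abp = abp_state.isNotNull();
  ABP abp;
  List abp_proto;
  int nbias = 0;
  if (has_abp) {
    abp_proto = as<List>(abp_state);
    abp = parse_abp(abp_proto);
    nbias = bias_cv.size();
    if (nbias != abp.ndim) stop("bias_cv length must equal ABP dimension");
  }

  // Maxwell-Boltzmann start velocities (A/ps): sd = sqrt(kT*KEFAC/m)
  for (int i = 0; i < dim; ++i)
    v[i] = (temperature > 0) ? R::norm_rand() * std::sqrt(kT * KEFAC / mass_dof[i]) : 0.0;

  // OU coefficients
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  int n_rec = n_steps / record_stride;
  int ncv = cvdefs.size();
  NumericMatrix cv_series(n_rec, ncv);
  NumericVector energies(n_rec);
  int n_frames = (frame_stride > 0) ? n_steps / frame_stride : 0;
  NumericMatrix frames(n_frames, (frame_stride > 0) ? dim : 0);

  // total force into gr (as dU/dx; force = -gr)
  auto eval_forces = [&](double& Usys) {
    Usys = sys_energy_grad(s, x.data(), g.data());
    for (int i = 0; i < dim; ++i) gr[i] = g[i];
    restraint_forces(pos_restraints, cvr, x.data(), gr.data(), dim);
    if (has_abp) {
      double z[2], dUdz[2];
      for (int d = 0; d < nbias; ++d) z[d] = cv_value(cvdefs[bias_cv[d]], x.data());
      bias_eval(abp, z, dUdz);
      for (int d = 0; d < nbias; ++d)
        cv_value_addgrad(cvdefs[bias_cv[d]], x.data(), dUdz[d], gr.data());
    }
  };

  double Usys;
  eval_forces(Usys);
  int irec = 0, ifrm = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < dim; ++i) v[i] -= 0.5 * dt * gr[i] * KEFAC / mass_dof[i];
    // A: half drift
    for (int i = 0; i < dim; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (temperature > 0 && gamma > 0) {
      for (int i = 0; i < dim; ++i)
        v[i] = c1 * v[i] + c2 * std::sqrt(kT * KEFAC / mass_dof[i]) * R::norm_rand();
    } else if (gamma > 0) {
      for (int i = 0; i < dim; ++i) v[i] = c1 * v[i];
    }
    // A: half drift
    for (int i = 0; i < dim; ++i) x[i] += 0.5 * dt * v[i];
    // B: half kick with new force
    eval_forces(Usys);
    for (int i = 0; i < dim; ++i) v[i] -= 0.5 * dt * gr[i] * KEFAC / mass_dof[i];

    if (!std::isfinite(Usys) || !std::isfinite(x[0]))
      stop("non-finite energy or coordinates at step %d", step);

    if (has_abp && (step % abp.stride == 0)) {
      double z[2];
      for (int d = 0; d < nbias; ++d) z[d] = cv_value(cvdefs[bias_cv[d]], x.data());
      abp_deposit(abp, z, (double)abp.stride);  // off-grid deposits are skipped
    }

    if (step % record_stride == 0 && irec < n_rec) {
      for (int c = 0; c < ncv; ++c) cv_series(irec, c) = cv_value(cvdefs[c], x.data());
      energies[irec] = Usys;
      ++irec;
    }
    if (frame_stride > 0 && step % frame_stride == 0 && ifrm < n_frames) {
      for (int i = 0; i < dim; ++i) frames(ifrm, i) = x[i];
      ++ifrm;
    }
  }

  List out = List::create(
    _["cv_series"] = cv_series,
    _["energies"] = energies,
    _["final_x"] = NumericVector(x.begin(), x.end()),
    _["frames"] = frames);
  if (has_abp) out["abp"] = abp_to_list(abp, abp_proto);
  return out;
}

// ---------------------------------------------------------------------------
// Steepest descent with backtracking line search
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_minimize(List sys, NumericVector x0, int max_steps, double ftol,
                  LogicalVector fixed, NumericMatrix pos_restraints,
                  List cv_restraints) {
  Sys s = parse_sys(sys);
  int dim = s.dim;
  std::vector<double> x(x0.begin(), x0.end()), g(dim), gr(dim), xt(dim);
  std::vector<CVRestraint> cvr;
  for (int i = 0; i < cv_restraints.size(); ++i) {
    List r = as<List>(cv_restraints[i]);
    CVRestraint c;
    c.cv = parse_cv(as<List>(r["cv"]));
    c.target = as<double>(r["target"]);
    c.k = as<double>(r["k"]);
    cvr.push_back(c);
  }
  auto energy_at = [&](std::vector<double>& xx, std::vector<double>& grad) {
    double U = sys_energy_grad(s, xx.data(), g.data());
    for (int i = 0; i < dim; ++i) grad[i] = g[i];
    U += restraint_forces(pos_restraints, cvr, xx.data(), grad.data(), dim);
    for (int i = 0; i < dim; ++i) if (fixed[i]) grad[i] = 0.0;
    return U;
  };
  double U = energy_at(x, gr);
  double step = 0.05;
  for (int it = 0; it < max_steps; ++it) {
    double gmax = 0.0;
    for (int i = 0; i < dim; ++i) gmax = std::max(gmax, std::fabs(gr[i]));
    if (gmax < ftol) break;
    // backtracking
    bool accepted = false;
    for (int bt = 0; bt < 30; ++bt) {
      for (int i = 0; i < dim; ++i) xt[i] = x[i] - step * gr[i] / std::max(gmax, 1e-12);
      std::vector<double> gt(dim);
      double Ut = energy_at(xt, gt);
      if (std::isfinite(Ut) && Ut < U) {
        x = xt; gr = gt; U = Ut;
        step *= 1.2;
        accepted = true;
        break;
      }
      step *= 0.5;
    }
    if (!accepted) break;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()), _["energy"] = U);
}
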