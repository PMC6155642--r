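// Core molecular-mechanics engine: potential energy decomposition, analytic
// forces, interaction virial, Verlet neighbor lists, and the velocity-Verlet
// MD loop with Berendsen temperature / pressure coupling.
//
// Units: Angstrom, picosecond, amu, kcal/mol, Debye, Kelvin, atm.
// All atom indices arriving from R are 0-based.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>
using namespace Rcpp;

static const double KCAL_AKMA = 418.4;          // kcal/mol -> amu A^2/ps^2
static const double KB = 0.001987204;           // kcal/mol/K
static const double KDIP = 332.06371 * 0.2081943 * 0.2081943;
static const double PCONV = 68568.5;            // kcal/mol/A^3 -> atm

struct Sys {
  int n;
  std::vector<double> mass;
  std::vector<int> cls;
  std::vector<double> lj_rv, lj_eps;
  std::vector<int> b_i, b_j; std::vector<double> b_ks, b_r0;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_kb, a_th;
  std::vector<int> t_i, t_j, t_k, t_l; std::vector<double> t_v1, t_v2, t_v3;
  std::vector<int> d_i, d_j; std::vector<double> d_mu;
  std::unordered_set<long long> excl;       // 1-2 and 1-3 pairs (i<j)
  std::vector<int> mol;
  double dielectric, cut_vdw, cut_dip, taper;
  // precombined LJ tables per class pair
  int ncls;
  std::vector<double> rm_tab, eps_tab;
};

static Sys parse_sys(const List& comp) {
  Sys s;
  s.n = as<int>(comp["n"]);
  s.mass = as<std::vector<double> >(comp["mass"]);
  s.cls = as<std::vector<int> >(comp["cls"]);
  s.lj_rv = as<std::vector<double> >(comp["lj_rv"]);
  s.lj_eps = as<std::vector<double> >(comp["lj_eps"]);
  s.b_i = as<std::vector<int> >(comp["b_i"]);
  s.b_j = as<std::vector<int> >(comp["b_j"]);
  s.b_ks = as<std::vector<double> >(comp["b_ks"]);
  s.b_r0 = as<std::vector<double> >(comp["b_r0"]);
  s.a_i = as<std::vector<int> >(comp["a_i"]);
  s.a_j = as<std::vector<int> >(comp["a_j"]);
  s.a_k = as<std::vector<int> >(comp["a_k"]);
  s.a_kb = as<std::vector<double> >(comp["a_kb"]);
  s.a_th = as<std::vector<double> >(comp["a_th"]);
  s.t_i = as<std::vector<int> >(comp["t_i"]);
  s.t_j = as<std::vector<int> >(comp["t_j"]);
  s.t_k = as<std::vector<int> >(comp["t_k"]);
  s.t_l = as<std::vector<int> >(comp["t_l"]);
  NumericMatrix tv = comp["t_v"];
  for (int i = 0; i < tv.nrow(); i++) {
    s.t_v1.push_back(tv(i, 0));
    s.t_v2.push_back(tv(i, 1));
    s.t_v3.push_back(tv(i, 2));
  }
  s.d_i = as<std::vector<int> >(comp["d_i"]);
  s.d_j = as<std::vector<int> >(comp["d_j"]);
  s.d_mu = as<std::vector<double> >(comp["d_mu"]);
  std::vector<int> ei = as<std::vector<int> >(comp["ex_i"]);
  std::vector<int> ej = as<std::vector<int> >(comp["ex_j"]);
  for (size_t k = 0; k < ei.size(); k++)
    s.excl.insert((long long)ei[k] * s.n + ej[k]);
  s.mol = as<std::vector<int> >(comp["mol"]);
  s.dielectric = as<double>(comp["dielectric"]);
  s.cut_vdw = as<double>(comp["cut_vdw"]);
  s.cut_dip = as<double>(comp["cut_dip"]);
  s.taper = as<double>(comp["taper"]);
  s.ncls = (int)s.lj_rv.size();
  s.rm_tab.resize(s.ncls * s.ncls);
  s.eps_tab.resize(s.ncls * s.ncls);
  for (int a = 0; a < s.ncls; a++)
    for (int b = 0; b < s.ncls; b++) {
      s.rm_tab[a * s.ncls + b] = s.lj_rv[a] + s.lj_rv[b];
      s.eps_tab[a * s.ncls + b] = std::sqrt(s.lj_eps[a] * s.lj_eps[b]);
    }
  return s;
}

static inline bool excluded(const Sys& s, int i, int j) {
  int a = i < j ? i : j, b = i < j ? j : i;
  return s.excl.count((long long)a * s.n + b) > 0;
}

static inline void minimg(double* d, const double* cell) {
  if (cell[0] > 0) {
    for (int k = 0; k < 3; k++) d[k] -= cell[k] * std::nearbyint(d[k] / cell[k]);
  }
}

// C^1 taper and its derivative: 1 below rc - w, 0 at rc
static inline void taper_sd(double r, double rc, double w, double& S,
                            double& dS) {
  double ron = rc - w;
  if (r <= ron) { S = 1.0; dS = 0.0; return; }
  if (r >= rc) { S = 0.0; dS = 0.0; return; }
  double t = (r - ron) / w;
  S = 1.0 - t * t * (3.0 - 2.0 * t);
  dS = -6.0 * t * (1.0 - t) / w;
}

// Pair lists for nonbonded work. Pairs are stored in sweep order so that
// summation order (and hence floating-point results) is reproducible.
struct NList {
  std::vector<std::pair<int,int> > lj;    // atom pairs, exclusions removed
  std::vector<std::pair<int,int> > dip;   // dipole-index pairs
};

static double eff_cut_dip(const Sys& s, const double* cell) {
  double c = s.cut_dip;
  if (cell[0] > 0) {
    double half = 0.5 * std::min(std::min(cell[0], cell[1]), cell[2]);
    if (c > half) c = half * (1.0 - 1e-9);
  }
  return c;
}

static void build_nlist(const Sys& s, const std::vector<double>& x,
                        const double* cell, double skin, NList& nl) {
  nl.lj.clear(); nl.dip.clear();
  double cl = s.cut_vdw + skin; cl *= cl;
  for (int i = 0; i < s.n; i++)
    for (int j = i + 1; j < s.n; j++) {
      double d[3] = { x[3*i] - x[3*j], x[3*i+1] - x[3*j+1],
                      x[3*i+2] - x[3*j+2] };
      minimg(d, cell);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 < cl && !excluded(s, i, j)) nl.lj.push_back(std::make_pair(i, j));
    }
  int nd = (int)s.d_i.size();
  double cd = eff_cut_dip(s, cell) + skin; cd *= cd;
  std::vector<double> mid(3 * nd);
  for (int a = 0; a < nd; a++) {
    int i = s.d_i[a], j = s.d_j[a];
    double u[3] = { x[3*j] - x[3*i], x[3*j+1] - x[3*i+1], x[3*j+2] - x[3*i+2] };
    minimg(u, cell);
    mid[3*a]   = x[3*i]   + 0.5 * u[0];
    mid[3*a+1] = x[3*i+1] + 0.5 * u[1];
    mid[3*a+2] = x[3*i+2] + 0.5 * u[2];
  }
  for (int a = 0; a < nd; a++)
    for (int b = a + 1; b < nd; b++) {
      // dipoles on bonds sharing an atom never interact
      if (s.d_i[a] == s.d_i[b] || s.d_i[a] == s.d_j[b] ||
          s.d_j[a] == s.d_i[b] || s.d_j[a] == s.d_j[b]) continue;
      double d[3] = { mid[3*a] - mid[3*b], mid[3*a+1] - mid[3*b+1],
                      mid[3*a+2] - mid[3*b+2] };
      minimg(d, cell);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 < cd) nl.dip.push_back(std::make_pair(a, b));
    }
}

// decomposition slots
enum { E_STRETCH = 0, E_BEND, E_TORSION, E_LJ, E_DIP, E_WALL, E_NTERM };

// Full energy/force/virial evaluation. `wall` = {cx, cy, cz, R, k}; R < 0
// disables. The wall term is excluded from the virial.
static void compute(const Sys& s, const std::vector<double>& x,
                    const double* cell, const double* wall, const NList& nl,
                    double* e, std::vector<double>* f, double* virial) {
  for (int k = 0; k < E_NTERM; k++) e[k] = 0.0;
  if (f) std::fill(f->begin(), f->end(), 0.0);
  double W = 0.0;

  // bonds
  for (size_t b = 0; b < s.b_i.size(); b++) {
    int i = s.b_i[b], j = s.b_j[b];
    double d[3] = { x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2] };
    minimg(d, cell);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double dr = r - s.b_r0[b];
    e[E_STRETCH] += s.b_ks[b] * dr * dr;
    if (f || virial) {
      double dEdr = 2.0 * s.b_ks[b] * dr;
      double g = -dEdr / r;
      if (f) for (int k = 0; k < 3; k++) {
        (*f)[3*i+k] += g * d[k];
        (*f)[3*j+k] -= g * d[k];
      }
      W += -dEdr * r;
    }
  }

  // angles
  for (size_t a = 0; a < s.a_i.size(); a++) {
    int i = s.a_i[a], j = s.a_j[a], k = s.a_k[a];
    double u[3] = { x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2] };
    double v[3] = { x[3*k] - x[3*j], x[3*k+1] - x[3*j+1], x[3*k+2] - x[3*j+2] };
    minimg(u, cell); minimg(v, cell);
    double nu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
    double nv = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
    double ct = (u[0]*v[0] + u[1]*v[1] + u[2]*v[2]) / (nu * nv);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double dth = th - s.a_th[a];
    e[E_BEND] += s.a_kb[a] * dth * dth;
    if (f || virial) {
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-8) st = 1e-8;           // guard at linear geometries
      double dEdth = 2.0 * s.a_kb[a] * dth;
      double fi[3], fk[3];
      for (int m = 0; m < 3; m++) {
        // dth/dri = (ct*u/nu - v/nv)/(nu*st)
        double gi = (ct * u[m] / nu - v[m] / nv) / (nu * st);
        double gk = (ct * v[m] / nv - u[m] / nu) / (nv * st);
        fi[m] = -dEdth * gi;
        fk[m] = -dEdth * gk;
      }
      if (f) for (int m = 0; m < 3; m++) {
        (*f)[3*i+m] += fi[m];
        (*f)[3*k+m] += fk[m];
        (*f)[3*j+m] -= fi[m] + fk[m];
      }
      W += u[0]*fi[0] + u[1]*fi[1] + u[2]*fi[2] +
           v[0]*fk[0] + v[1]*fk[1] + v[2]*fk[2];
    }
  }

  // torsions: E = V1/2 (1+cos p) + V2/2 (1-cos 2p) + V3/2 (1+cos 3p)
  for (size_t t = 0; t < s.t_i.size(); t++) {
    int i = s.t_i[t], j = s.t_j[t], k = s.t_k[t], l = s.t_l[t];
    double b1[3] = { x[3*j]-x[3*i], x[3*j+1]-x[3*i+1], x[3*j+2]-x[3*i+2] };
    double b2[3] = { x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2] };
    double b3[3] = { x[3*l]-x[3*k], x[3*l+1]-x[3*k+1], x[3*l+2]-x[3*k+2] };
    minimg(b1, cell); minimg(b2, cell); minimg(b3, cell);
    double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                     b1[0]*b2[1]-b1[1]*b2[0] };
    double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                     b2[0]*b3[1]-b2[1]*b3[0] };
    double n1s = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2s = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (n1s < 1e-12 || n2s < 1e-12) continue;  // collinear; torsion undefined
    double m1[3] = { n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                     n1[0]*b2[1]-n1[1]*b2[0] };
    double xdot = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double ydot = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / nb2;
    double phi = std::atan2(ydot, xdot);
    double V1 = s.t_v1[t], V2 = s.t_v2[t], V3 = s.t_v3[t];
    e[E_TORSION] += 0.5 * (V1 * (1 + std::cos(phi)) +
                           V2 * (1 - std::cos(2*phi)) +
                           V3 * (1 + std::cos(3*phi)));
    if (f || virial) {
      double dEdp = 0.5 * (-V1 * std::sin(phi) + 2*V2 * std::sin(2*phi)
                           - 3*V3 * std::sin(3*phi));
      double gi[3], gl[3], gj[3], gk[3];
      double c12 = b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2];
      double c32 = b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2];
      for (int m = 0; m < 3; m++) {
        gi[m] =  nb2 / n1s * n1[m];            // dphi/dri
        gl[m] = -nb2 / n2s * n2[m];            // dphi/drl
        gj[m] = -(1.0 + c12 / (nb2*nb2)) * gi[m] + c32 / (nb2*nb2) * gl[m];
        gk[m] = -(1.0 + c32 / (nb2*nb2)) * gl[m] + c12 / (nb2*nb2) * gi[m];
      }
      double fi[3], fj[3], fk2[3], fl[3];
      for (int m = 0; m < 3; m++) {
        fi[m] = -dEdp * gi[m]; fj[m] = -dEdp * gj[m];
        fk2[m] = -dEdp * gk[m]; fl[m] = -dEdp * gl[m];
      }
      if (f) for (int m = 0; m < 3; m++) {
        (*f)[3*i+m] += fi[m]; (*f)[3*j+m] += fj[m];
        (*f)[3*k+m] += fk2[m]; (*f)[3*l+m] += fl[m];
      }
      // local frame with j at origin: ri = -b1, rk = b2, rl = b2+b3
      for (int m = 0; m < 3; m++)
        W += -b1[m]*fi[m] + b2[m]*fk2[m] + (b2[m]+b3[m])*fl[m];
    }
  }

  // Lennard-Jones over the pair list
  double cv2 = s.cut_vdw * s.cut_vdw;
  for (size_t p = 0; p < nl.lj.size(); p++) {
    int i = nl.lj[p].first, j = nl.lj[p].second;
    double d[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    minimg(d, cell);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    if (r2 >= cv2) continue;
    double r = std::sqrt(r2);
    int ci = s.cls[i], cj = s.cls[j];
    double rm = s.rm_tab[ci * s.ncls + cj];
    double eps = s.eps_tab[ci * s.ncls + cj];
    double x2 = rm * rm / r2, x6 = x2 * x2 * x2, x12 = x6 * x6;
    double e0 = eps * (x12 - 2.0 * x6);
    double S, dS; taper_sd(r, s.cut_vdw, s.taper, S, dS);
    e[E_LJ] += S * e0;
    if (f || virial) {
      double dEdr = S * (-12.0 * eps * (x12 - x6) / r) + dS * e0;
      double g = -dEdr / r;
      if (f) for (int m = 0; m < 3; m++) {
        (*f)[3*i+m] += g * d[m];
        (*f)[3*j+m] -= g * d[m];
      }
      W += -dEdr * r;
    }
  }

  // bond-dipole electrostatics over the dipole pair list; per-dipole
  // geometry (minimum-imaged bond vector, unit axis, midpoint) is computed
  // once per evaluation, not per pair
  double cdip = eff_cut_dip(s, cell);
  double cd2 = cdip * cdip;
  int ndip = (int)s.d_i.size();
  std::vector<double> dU(3 * ndip), dE(3 * ndip), dM(3 * ndip), dN(ndip);
  for (int a = 0; a < ndip; a++) {
    int i = s.d_i[a], j = s.d_j[a];
    double u[3] = { x[3*j]-x[3*i], x[3*j+1]-x[3*i+1], x[3*j+2]-x[3*i+2] };
    minimg(u, cell);
    double nn = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
    dN[a] = nn;
    for (int m = 0; m < 3; m++) {
      dU[3*a+m] = u[m];
      dE[3*a+m] = u[m] / nn;
      dM[3*a+m] = x[3*i+m] + 0.5 * u[m];
    }
  }
  for (size_t p = 0; p < nl.dip.size(); p++) {
    int a = nl.dip[p].first, b = nl.dip[p].second;
    int ia = s.d_i[a], ja = s.d_j[a], ib = s.d_i[b], jb = s.d_j[b];
    double rv[3] = { dM[3*b] - dM[3*a], dM[3*b+1] - dM[3*a+1],
                     dM[3*b+2] - dM[3*a+2] };
    minimg(rv, cell);
    double r2 = rv[0]*rv[0]+rv[1]*rv[1]+rv[2]*rv[2];
    if (r2 >= cd2) continue;
    double r = std::sqrt(r2);
    if (r < 1e-9) stop("singular geometry: coincident dipole midpoints");
    double n1 = dN[a], n2 = dN[b];
    const double *u1 = &dU[3*a], *u2 = &dU[3*b];
    const double *e1 = &dE[3*a], *e2 = &dE[3*b];
    double C = KDIP * s.d_mu[a] * s.d_mu[b] / s.dielectric;
    double c12 = e1[0]*e2[0]+e1[1]*e2[1]+e1[2]*e2[2];
    double c1r = e1[0]*rv[0]+e1[1]*rv[1]+e1[2]*rv[2];
    double c2r = e2[0]*rv[0]+e2[1]*rv[1]+e2[2]*rv[2];
    double ir3 = 1.0 / (r2 * r), ir5 = ir3 / r2, ir7 = ir5 / r2;
    double e0 = C * (c12 * ir3 - 3.0 * c1r * c2r * ir5);
    double S, dS; taper_sd(r, cdip, s.taper, S, dS);
    e[E_DIP] += S * e0;
    if (f || virial) {
      double grv[3], ge1[3], ge2[3];
      for (int m = 0; m < 3; m++) {
        grv[m] = C * (-3.0 * c12 * ir5 * rv[m]
                      - 3.0 * (c2r * e1[m] + c1r * e2[m]) * ir5
                      + 15.0 * c1r * c2r * ir7 * rv[m]);
        ge1[m] = C * (e2[m] * ir3 - 3.0 * c2r * rv[m] * ir5);
        ge2[m] = C * (e1[m] * ir3 - 3.0 * c1r * rv[m] * ir5);
      }
      // taper chain rule into the rv gradient
      for (int m = 0; m < 3; m++)
        grv[m] = S * grv[m] + e0 * dS * rv[m] / r;
      // project unit-vector gradients: (I - e e^T) ge / n
      double p1 = ge1[0]*e1[0]+ge1[1]*e1[1]+ge1[2]*e1[2];
      double p2 = ge2[0]*e2[0]+ge2[1]*e2[1]+ge2[2]*e2[2];
      double q1[3], q2[3];
      for (int m = 0; m < 3; m++) {
        q1[m] = S * (ge1[m] - p1 * e1[m]) / n1;
        q2[m] = S * (ge2[m] - p2 * e2[m]) / n2;
      }
      double fa[3], fb[3], fc[3], fd[3];
      for (int m = 0; m < 3; m++) {
        fa[m] =  q1[m] + 0.5 * grv[m];
        fb[m] = -q1[m] + 0.5 * grv[m];
        fc[m] =  q2[m] - 0.5 * grv[m];
        fd[m] = -q2[m] - 0.5 * grv[m];
      }
      if (f) for (int m = 0; m < 3; m++) {
        (*f)[3*ia+m] += fa[m]; (*f)[3*ja+m] += fb[m];
        (*f)[3*ib+m] += fc[m]; (*f)[3*jb+m] += fd[m];
      }
      // local frame: a at origin, b = u1, c = m2 - u2/2, d = m2 + u2/2,
      // m2 = u1/2 + rv
      for (int m = 0; m < 3; m++) {
        double m2m = 0.5*u1[m] + rv[m];
        W += fb[m]*u1[m] + fc[m]*(m2m - 0.5*u2[m]) + fd[m]*(m2m + 0.5*u2[m]);
      }
    }
  }

  // spherical wall (one-sided harmonic), not part of the virial
  if (wall[3] > 0) {
    double R = wall[3], kw = wall[4];
    for (int i = 0; i < s.n; i++) {
      double d[3] = { x[3*i]-wall[0], x[3*i+1]-wall[1], x[3*i+2]-wall[2] };
      double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
      if (r > R) {
        double dr = r - R;
        e[E_WALL] += kw * dr * dr;
        if (f) {
          double g = -2.0 * kw * dr / r;
          for (int m = 0; m < 3; m++) (*f)[3*i+m] += g * d[m];
        }
      }
    }
  }

  if (virial) *virial = W;
}

static NList full_nlist(const Sys& s) {
  // "everything" pair list used for single-point brute-force evaluation
  NList nl;
  for (int i = 0; i < s.n; i++)
    for (int j = i + 1; j < s.n; j++)
      if (!excluded(s, i, j)) nl.lj.push_back(std::make_pair(i, j));
  int nd = (int)s.d_i.size();
  for (int a = 0; a < nd; a++)
    for (int b = a + 1; b < nd; b++) {
      if (s.d_i[a] == s.d_i[b] || s.d_i[a] == s.d_j[b] ||
          s.d_j[a] == s.d_i[b] || s.d_j[a] == s.d_j[b]) continue;
      nl.dip.push_back(std::make_pair(a, b));
    }
  return nl;
}

static List energy_impl(const Sys& s, NumericMatrix xyz, NumericVector cell,
                        NumericVector wall, bool want_forces,
                        double nlist_skin) {
  int n = s.n;
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; i++)
    for (int m = 0; m < 3; m++) x[3*i+m] = xyz(i, m);
  NList nl;
  if (nlist_skin >= 0) build_nlist(s, x, cell.begin(), nlist_skin, nl);
  else nl = full_nlist(s);
  double e[E_NTERM], W = 0.0;
  std::vector<double> f(3 * n);
  compute(s, x, cell.begin(), wall.begin(), nl, e,
          want_forces ? &f : (std::vector<double>*)0, &W);
  NumericVector dec = NumericVector::create(
    _["stretch"] = e[E_STRETCH], _["bend"] = e[E_BEND],
    _["torsion"] = e[E_TORSION], _["lj"] = e[E_LJ],
    _["dipole"] = e[E_DIP], _["wall"] = e[E_WALL]);
  List out = List::create(_["decomp"] = dec,
                          _["total"] = e[0]+e[1]+e[2]+e[3]+e[4]+e[5],
                          _["virial"] = W);
  if (want_forces) {
    NumericMatrix fm(n, 3);
    for (int i = 0; i < n; i++)
      for (int m = 0; m < 3; m++) fm(i, m) = f[3*i+m];
    out["forces"] = fm;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_energy(List comp, NumericMatrix xyz, NumericVector cell,
                NumericVector wall, bool want_forces, double nlist_skin) {
  Sys s = parse_sys(comp);
  return energy_impl(s, xyz, cell, wall, want_forces, nlist_skin);
}

// persistent engine handle: parse the system once, evaluate many times
// [[Rcpp::export]]
SEXP cpp_make_engine(List comp) {
  return XPtr<Sys>(new Sys(parse_sys(comp)), true);
}

// [[Rcpp::export]]
List cpp_energy_ptr(SEXP ptr, NumericMatrix xyz, NumericVector cell,
                    NumericVector wall, bool want_forces) {
  XPtr<Sys> s(ptr);
  return energy_impl(*s, xyz, cell, wall, want_forces, -1.0);
}

// [[Rcpp::export]]
List cpp_run_md(List comp, NumericMatrix xyz, NumericMatrix vel,
                NumericVector cell0, NumericVector wall, double dt,
                int nsteps, int stride, int frame_stride,
                bool use_thermo, double T0, double tau,
                bool use_baro, double P0, double tauP, double beta,
                int nlist_every, double skin) {
  Sys s = parse_sys(comp);
  int n = s.n;
  std::vector<double> x(3*n), v(3*n), f(3*n);
  for (int i = 0; i < n; i++)
    for (int m = 0; m < 3; m++) { x[3*i+m] = xyz(i, m); v[3*i+m] = vel(i, m); }
  double cell[3] = { cell0[0], cell0[1], cell0[2] };
  bool periodic = cell[0] > 0;
  int ndof = 3 * n - 3;
  if (ndof < 1) ndof = 1;

  NList nl;
  build_nlist(s, x, cell, skin, nl);
  double e[E_NTERM], W = 0.0;
  compute(s, x, cell, wall.begin(), nl, e, &f, &W);

  int nlog = nsteps / stride + 1;
  NumericMatrix scal(nlog, 12);
  CharacterVector cn = CharacterVector::create(
    "time", "U", "stretch", "bend", "torsion", "lj", "dipole", "wall",
    "K", "T", "P", "V");
  colnames(scal) = cn;
  int nframes = frame_stride > 0 ? nsteps / frame_stride + 1 : 0;
  List frames(nframes);
  NumericMatrix fcell(nframes > 0 ? nframes : 1, 3);
  int ilog = 0, ifr = 0;

  for (int step = 0; step <= nsteps; step++) {
    // log current state
    double K = 0.0;
    for (int i = 0; i < n; i++)
      for (int m = 0; m < 3; m++) K += s.mass[i] * v[3*i+m] * v[3*i+m];
    K = 0.5 * K / KCAL_AKMA;                       // kcal/mol
    double Tinst = 2.0 * K / (ndof * KB);
    double V = periodic ? cell[0]*cell[1]*cell[2] : 0.0;
    double Patm = periodic ? (2.0*K + W) / (3.0*V) * PCONV : 0.0;
    if (step % stride == 0 && ilog < nlog) {
      double U = e[0]+e[1]+e[2]+e[3]+e[4]+e[5];
      scal(ilog, 0) = step * dt; scal(ilog, 1) = U;
      scal(ilog, 2) = e[E_STRETCH]; scal(ilog, 3) = e[E_BEND];
      scal(ilog, 4) = e[E_TORSION]; scal(ilog, 5) = e[E_LJ];
      scal(ilog, 6) = e[E_DIP]; scal(ilog, 7) = e[E_WALL];
      scal(ilog, 8) = K; scal(ilog, 9) = Tinst;
      scal(ilog, 10) = Patm; scal(ilog, 11) = V;
      ilog++;
    }
    if (frame_stride > 0 && step % frame_stride == 0 && ifr < nframes) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; i++)
        for (int m = 0; m < 3; m++) fr(i, m) = x[3*i+m];
      frames[ifr] = fr;
      for (int m = 0; m < 3; m++) fcell(ifr, m) = cell[m];
      ifr++;
    }
    if (step == nsteps) break;

    // velocity Verlet: half-kick + drift
    for (int i = 0; i < n; i++) {
      double am = KCAL_AKMA / s.mass[i];
      for (int m = 0; m < 3; m++) {
        v[3*i+m] += 0.5 * dt * f[3*i+m] * am;
        x[3*i+m] += dt * v[3*i+m];
      }
    }
    // Berendsen pressure coupling: isotropic cell-and-coordinate scaling
    // using the virial of the previous force evaluation (weak coupling)
    if (use_baro && periodic) {
      double K2 = 0.0;
      for (int i = 0; i < n; i++)
        for (int m = 0; m < 3; m++) K2 += s.mass[i] * v[3*i+m] * v[3*i+m];
      K2 = 0.5 * K2 / KCAL_AKMA;
      double V = cell[0]*cell[1]*cell[2];
      double Patm = (2.0*K2 + W) / (3.0*V) * PCONV;
      double mu = std::cbrt(1.0 - beta * dt / tauP * (P0 - Patm));
      if (mu < 0.98) mu = 0.98; if (mu > 1.02) mu = 1.02;
      for (size_t q = 0; q < x.size(); q++) x[q] *= mu;
      for (int m = 0; m < 3; m++) cell[m] *= mu;
    }
    if ((step + 1) % nlist_every == 0) build_nlist(s, x, cell, skin, nl);
    compute(s, x, cell, wall.begin(), nl, e, &f, &W);
    for (int i = 0; i < n; i++) {
      double am = KCAL_AKMA / s.mass[i];
      for (int m = 0; m < 3; m++) v[3*i+m] += 0.5 * dt * f[3*i+m] * am;
    }
    for (int i = 0; i < n; i++)
      for (int m = 0; m < 3; m++)
        if (!std::isfinite(x[3*i+m]))
          stop("integration blew up at step %d", step + 1);

    if (use_thermo) {
      double K2 = 0.0;
      for (int i = 0; i < n; i++)
        for (int m = 0; m < 3; m++) K2 += s.mass[i] * v[3*i+m] * v[3*i+m];
      K2 = 0.5 * K2 / KCAL_AKMA;
      double Ti = 2.0 * K2 / (ndof * KB);
      if (Ti > 1e-12) {
        double lam = std::sqrt(1.0 + dt / tau * (T0 / Ti - 1.0));
        if (lam < 0.8) lam = 0.8; if (lam > 1.25) lam = 1.25;
        for (size_t q = 0; q < v.size(); q++) v[q] *= lam;
      }
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; i++)
    for (int m = 0; m < 3; m++) { xout(i, m) = x[3*i+m]; vout(i, m) = v[3*i+m]; }
  return List::create(_["xyz"] = xout, _["vel"] = vout,
                      _["cell"] = NumericVector::create(cell[0], cell[1], cell[2]),
                      _["scalars"] = scal, _["frames"] = frames,
                      _["frame_cell"] = fcell);
}
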