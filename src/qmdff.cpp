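// Compiled core: force-field evaluation, velocity-Verlet dynamics with
// stochastic velocity rescaling and weak-coupling pressure control, and
// pair-distance histogramming.  Units: nm, ps, amu, kJ/mol; internally
// angles are radians.  1 kJ/mol == 1 amu nm^2 ps^-2, so accelerations are
// simply f/m with no conversion factor.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>

using namespace Rcpp;

static const double F_COULOMB = 138.935458;   // kJ mol^-1 nm e^-2
static const double KB = 0.008314462618;      // kJ mol^-1 K^-1
static const double PRESFAC = 16.6054;        // kJ mol^-1 nm^-3 -> bar

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator-(const V3 &a, const V3 &b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator+(const V3 &a, const V3 &b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator*(double s, const V3 &a) { return V3(s*a.x, s*a.y, s*a.z); }
static inline double dot(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm2(const V3 &a) { return dot(a, a); }

// Packed force field unmarshalled from the R side (all indices 0-based).
struct FF {
  int natoms;
  std::vector<int> b_i, b_j;          std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k;     std::vector<double> a_kf, a_t0;
  std::vector<int> d_i, d_j, d_k, d_l; std::vector<double> d_kf, d_p0; // stiff
  std::vector<int> f_i, f_j, f_k, f_l; std::vector<std::vector<double>> f_c; // flexible
  std::vector<int> w_i, w_j, w_k, w_l; std::vector<double> w_p0, w_kf; // one-sided wall
  std::vector<int> p_i, p_j;          std::vector<double> p_eps, p_sig; // explicit intra pairs
  std::vector<double> q, eps, sig;
  std::vector<int> molid, loc, mtyp;
  std::vector<NumericMatrix> sLJ, sQ; // per molecule type, local-index scale tables
  double cutoff;       // <= 0: no cutoff
  int coul_scheme;     // 0 plain cut, 1 cut + potential shift, 2 reaction field (eps_rf = inf)
  bool lj_shift;
  std::vector<std::vector<int>> mols; // atoms per molecule
};

static void unpack_ff(const List &ffl, FF &ff) {
  ff.natoms = as<int>(ffl["natoms"]);
  IntegerMatrix B = ffl["bonds"];
  NumericVector bk = ffl["bond_k"], br = ffl["bond_r0"];
  for (int i = 0; i < B.nrow(); ++i) {
    ff.b_i.push_back(B(i,0)); ff.b_j.push_back(B(i,1));
    ff.b_k.push_back(bk[i]);  ff.b_r0.push_back(br[i]);
  }
  IntegerMatrix A = ffl["angles"];
  NumericVector ak = ffl["ang_k"], at = ffl["ang_t0"];
  for (int i = 0; i < A.nrow(); ++i) {
    ff.a_i.push_back(A(i,0)); ff.a_j.push_back(A(i,1)); ff.a_k.push_back(A(i,2));
    ff.a_kf.push_back(ak[i]); ff.a_t0.push_back(at[i]);
  }
  IntegerMatrix D = ffl["stiff"];
  NumericVector dk = ffl["stiff_k"], dp = ffl["stiff_phi0"];
  for (int i = 0; i < D.nrow(); ++i) {
    ff.d_i.push_back(D(i,0)); ff.d_j.push_back(D(i,1));
    ff.d_k.push_back(D(i,2)); ff.d_l.push_back(D(i,3));
    ff.d_kf.push_back(dk[i]); ff.d_p0.push_back(dp[i]);
  }
  IntegerMatrix Fm = ffl["flex"];
  NumericMatrix fc = ffl["flex_c"];
  for (int i = 0; i < Fm.nrow(); ++i) {
    ff.f_i.push_back(Fm(i,0)); ff.f_j.push_back(Fm(i,1));
    ff.f_k.push_back(Fm(i,2)); ff.f_l.push_back(Fm(i,3));
    std::vector<double> c(fc.ncol());
    for (int j = 0; j < fc.ncol(); ++j) c[j] = fc(i,j);
    ff.f_c.push_back(c);
  }
  IntegerMatrix W = ffl["wall"];
  NumericVector wp = ffl["wall_phi0"], wk = ffl["wall_k"];
  for (int i = 0; i < W.nrow(); ++i) {
    ff.w_i.push_back(W(i,0)); ff.w_j.push_back(W(i,1));
    ff.w_k.push_back(W(i,2)); ff.w_l.push_back(W(i,3));
    ff.w_p0.push_back(wp[i]); ff.w_kf.push_back(wk[i]);
  }
  IntegerMatrix P = ffl["pairs"];
  NumericVector pe = ffl["pair_eps"], ps = ffl["pair_sigma"];
  for (int i = 0; i < P.nrow(); ++i) {
    ff.p_i.push_back(P(i,0)); ff.p_j.push_back(P(i,1));
    ff.p_eps.push_back(pe[i]); ff.p_sig.push_back(ps[i]);
  }
  ff.q   = as<std::vector<double>>(ffl["q"]);
  ff.eps = as<std::vector<double>>(ffl["eps"]);
  ff.sig = as<std::vector<double>>(ffl["sigma"]);
  ff.molid = as<std::vector<int>>(ffl["molid"]);
  ff.loc   = as<std::vector<int>>(ffl["loc"]);
  ff.mtyp  = as<std::vector<int>>(ffl["mtyp"]);
  List sLJ = ffl["sLJ"], sQ = ffl["sQ"];
  for (int i = 0; i < sLJ.size(); ++i) {
    ff.sLJ.push_back(as<NumericMatrix>(sLJ[i]));
    ff.sQ.push_back(as<NumericMatrix>(sQ[i]));
  }
  ff.cutoff = as<double>(ffl["cutoff"]);
  ff.coul_scheme = as<int>(ffl["coul_scheme"]);
  ff.lj_shift = as<bool>(ffl["lj_shift"]);
  int nmol = 0;
  for (size_t i = 0; i < ff.molid.size(); ++i) nmol = std::max(nmol, ff.molid[i] + 1);
  ff.mols.assign(nmol, std::vector<int>());
  for (size_t i = 0; i < ff.molid.size(); ++i) ff.mols[ff.molid[i]].push_back((int)i);
}

static inline void minimg(double &d, double box) {
  if (box > 0) d -= box * std::round(d / box);
}
static inline V3 delta(const std::vector<V3> &x, int i, int j, double box) {
  V3 d = x[i] - x[j];
  minimg(d.x, box); minimg(d.y, box); minimg(d.z, box);
  return d;
}

struct Energies {
  double bond = 0, angle = 0, stiff = 0, flex = 0, wall = 0,
         pair_lj = 0, lj = 0, coul = 0, posres = 0;
  double total() const {
    return bond + angle + stiff + flex + wall + pair_lj + lj + coul + posres;
  }
};

// Signed dihedral (IUPAC, cis = 0) plus optional force accumulation for
// potential derivative dVdphi.  Atom order i-j-k-l; rotation about j-k.
static double dihedral_geom(const std::vector<V3> &x, int i, int j, int k, int l,
                            double dVdphi, std::vector<V3> *f, double *w) {
  V3 rij = x[i] - x[j];
  V3 rkj = x[k] - x[j];
  V3 rkl = x[k] - x[l];
  V3 m = cross(rij, rkj);
  V3 n = cross(rkj, rkl);
  double m2 = norm2(m), n2 = norm2(n);
  double nrkj = std::sqrt(norm2(rkj));
  double phi = std::atan2(dot(rij, n) * nrkj, dot(m, n));
  if (f != nullptr && dVdphi != 0.0) {
    if (m2 < 1e-18 || n2 < 1e-18) return phi; // degenerate, no defined torque
    V3 fi = (-dVdphi * nrkj / m2) * m;
    V3 fl = ( dVdphi * nrkj / n2) * n;
    double p1 = dot(rij, rkj) / (nrkj * nrkj);
    double p2 = dot(rkl, rkj) / (nrkj * nrkj);
    V3 sv = (p1 * fi) - (p2 * fl);
    V3 fj = sv - fi;
    V3 fk = (-1.0 * sv) - fl;
    (*f)[i] = (*f)[i] + fi; (*f)[j] = (*f)[j] + fj;
    (*f)[k] = (*f)[k] + fk; (*f)[l] = (*f)[l] + fl;
    if (w) *w += dot(fi, x[i]) + dot(fj, x[j]) + dot(fk, x[k]) + dot(fl, x[l]);
  }
  return phi;
}

static inline double wrap_pi(double dphi) {
  while (dphi >  M_PI) dphi -= 2.0 * M_PI;
  while (dphi <= -M_PI) dphi += 2.0 * M_PI;
  return dphi;
}

// Full energy/force/virial evaluation.  Forces vector may be null.
static void eval_ff(const FF &ff, const std::vector<V3> &x, double box,
                    Energies &en, std::vector<V3> *f, double *virial,
                    const std::vector<double> *posres_k = nullptr,
                    const std::vector<V3> *posres_ref = nullptr) {
  en = Energies();
  double w = 0;
  if (f) for (auto &v : *f) v = V3();

  // bonds
  for (size_t t = 0; t < ff.b_i.size(); ++t) {
    int i = ff.b_i[t], j = ff.b_j[t];
    V3 d = x[i] - x[j];
    double r = std::sqrt(norm2(d));
    double dr = r - ff.b_r0[t];
    en.bond += 0.5 * ff.b_k[t] * dr * dr;
    if (f && r > 1e-12) {
      double fs = -ff.b_k[t] * dr / r;
      V3 fv = fs * d;
      (*f)[i] = (*f)[i] + fv; (*f)[j] = (*f)[j] - fv;
      w += fs * r * r;
    }
  }
  // angles
  for (size_t t = 0; t < ff.a_i.size(); ++t) {
    int i = ff.a_i[t], j = ff.a_j[t], k = ff.a_k[t];
    V3 u = x[i] - x[j], v = x[k] - x[j];
    double nu = std::sqrt(norm2(u)), nv = std::sqrt(norm2(v));
    double ct = dot(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dt = th - ff.a_t0[t];
    en.angle += 0.5 * ff.a_kf[t] * dt * dt;
    if (f) {
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-8) st = 1e-8;
      double coef = ff.a_kf[t] * dt / st; // = -dV/dcos * ... assembled below
      V3 dci = (1.0 / (nu * nv)) * v - (ct / (nu * nu)) * u;
      V3 dck = (1.0 / (nu * nv)) * u - (ct / (nv * nv)) * v;
      V3 fi = coef * dci;            // F_i = -dV/dth * dth/dri, dth/dri = -dci/st
      V3 fk = coef * dck;
      V3 fj = (-1.0 * fi) - fk;
      (*f)[i] = (*f)[i] + fi; (*f)[j] = (*f)[j] + fj; (*f)[k] = (*f)[k] + fk;
      w += dot(fi, x[i]) + dot(fj, x[j]) + dot(fk, x[k]);
    }
  }
  // stiff dihedrals: 0.5 k (wrap(phi - phi0))^2
  for (size_t t = 0; t < ff.d_i.size(); ++t) {
    double phi = dihedral_geom(x, ff.d_i[t], ff.d_j[t], ff.d_k[t], ff.d_l[t], 0, nullptr, nullptr);
    double dp = wrap_pi(phi - ff.d_p0[t]);
    en.stiff += 0.5 * ff.d_kf[t] * dp * dp;
    if (f) dihedral_geom(x, ff.d_i[t], ff.d_j[t], ff.d_k[t], ff.d_l[t],
                         ff.d_kf[t] * dp, f, &w);
  }
  // flexible dihedrals: sum_j c_j cos(j delta)
  for (size_t t = 0; t < ff.f_i.size(); ++t) {
    double phi = dihedral_geom(x, ff.f_i[t], ff.f_j[t], ff.f_k[t], ff.f_l[t], 0, nullptr, nullptr);
    const std::vector<double> &c = ff.f_c[t];
    double e = 0, dV = 0;
    for (size_t j = 0; j < c.size(); ++j) {
      e  += c[j] * std::cos(j * phi);
      dV -= c[j] * j * std::sin(j * phi);
    }
    en.flex += e;
    if (f) dihedral_geom(x, ff.f_i[t], ff.f_j[t], ff.f_k[t], ff.f_l[t], dV, f, &w);
  }
  // one-sided walls: 0.5 k (phi - phi0)^2 for phi < phi0 (no wrapping:
  // the wall guards a directed rotation away from the Franck-Condon well)
  for (size_t t = 0; t < ff.w_i.size(); ++t) {
    double phi = dihedral_geom(x, ff.w_i[t], ff.w_j[t], ff.w_k[t], ff.w_l[t], 0, nullptr, nullptr);
    double dp = phi - ff.w_p0[t];
    if (dp < 0) {
      en.wall += 0.5 * ff.w_kf[t] * dp * dp;
      if (f) dihedral_geom(x, ff.w_i[t], ff.w_j[t], ff.w_k[t], ff.w_l[t],
                           ff.w_kf[t] * dp, f, &w);
    }
  }
  // explicit intramolecular LJ pairs (always full strength, no cutoff)
  for (size_t t = 0; t < ff.p_i.size(); ++t) {
    int i = ff.p_i[t], j = ff.p_j[t];
    V3 d = x[i] - x[j];
    double r2 = norm2(d);
    double sr2 = ff.p_sig[t] * ff.p_sig[t] / r2;
    double sr6 = sr2 * sr2 * sr2;
    en.pair_lj += 4.0 * ff.p_eps[t] * (sr6 * sr6 - sr6);
    if (f) {
      double fs = 4.0 * ff.p_eps[t] * (12.0 * sr6 * sr6 - 6.0 * sr6) / r2;
      V3 fv = fs * d;
      (*f)[i] = (*f)[i] + fv; (*f)[j] = (*f)[j] - fv;
      w += fs * r2;
    }
  }
  // nonbonded LJ + Coulomb
  double rc = ff.cutoff, rc2 = rc > 0 ? rc * rc : 0;
  double crf = 0, cshift = 0;
  if (rc > 0) {
    if (ff.coul_scheme == 2) crf = 1.0 / (rc2 * rc);            // eps_rf = inf
    if (ff.coul_scheme == 1) cshift = 1.0 / rc;
    if (ff.coul_scheme == 2) cshift = 1.0 / rc + 0.5 * crf * rc2; // zero at rc
  }
  int N = ff.natoms;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double sLJ = 1.0, sQ = 1.0;
      if (ff.molid[i] == ff.molid[j]) {
        const NumericMatrix &ml = ff.sLJ[ff.mtyp[i]];
        const NumericMatrix &mq = ff.sQ[ff.mtyp[i]];
        sLJ = ml(ff.loc[i], ff.loc[j]);
        sQ  = mq(ff.loc[i], ff.loc[j]);
        if (sLJ == 0.0 && sQ == 0.0) continue;
      }
      V3 d = delta(x, i, j, box);
      double r2 = norm2(d);
      if (rc > 0 && r2 > rc2) continue;
      double fs = 0;
      if (sLJ > 0 && ff.eps[i] > 0 && ff.eps[j] > 0) {
        double sgm = 0.5 * (ff.sig[i] + ff.sig[j]);
        double epsij = std::sqrt(ff.eps[i] * ff.eps[j]) * sLJ;
        double sr2 = sgm * sgm / r2;
        double sr6 = sr2 * sr2 * sr2;
        double e = 4.0 * epsij * (sr6 * sr6 - sr6);
        if (ff.lj_shift && rc > 0) {
          double src2 = sgm * sgm / rc2;
          double src6 = src2 * src2 * src2;
          e -= 4.0 * epsij * (src6 * src6 - src6);
        }
        en.lj += e;
        fs += 4.0 * epsij * (12.0 * sr6 * sr6 - 6.0 * sr6) / r2;
      }
      double qq = ff.q[i] * ff.q[j] * sQ;
      if (qq != 0.0) {
        double r = std::sqrt(r2);
        double e, fsc;
        if (ff.coul_scheme == 2 && rc > 0) {
          e = F_COULOMB * qq * (1.0 / r + 0.5 * crf * r2 - cshift);
          fsc = F_COULOMB * qq * (1.0 / (r2 * r) - crf);
        } else {
          e = F_COULOMB * qq * (1.0 / r - cshift);
          fsc = F_COULOMB * qq / (r2 * r);
        }
        en.coul += e;
        fs += fsc;
      }
      if (f && fs != 0.0) {
        V3 fv = fs * d;
        (*f)[i] = (*f)[i] + fv; (*f)[j] = (*f)[j] - fv;
        w += fs * r2;
      }
    }
  }
  // position restraints (equilibration stage 1)
  if (posres_k != nullptr) {
    for (int i = 0; i < N; ++i) {
      double k = (*posres_k)[i];
      if (k <= 0) continue;
      V3 d = x[i] - (*posres_ref)[i];
      en.posres += 0.5 * k * norm2(d);
      if (f) (*f)[i] = (*f)[i] + (-k) * d;
    }
  }
  if (virial) *virial = w;
}

static std::vector<V3> mat_to_vec(const NumericMatrix &m) {
  std::vector<V3> x(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) x[i] = V3(m(i,0), m(i,1), m(i,2));
  return x;
}
static NumericMatrix vec_to_mat(const std::vector<V3> &x) {
  NumericMatrix m(x.size(), 3);
  for (size_t i = 0; i < x.size(); ++i) { m(i,0) = x[i].x; m(i,1) = x[i].y; m(i,2) = x[i].z; }
  return m;
}

// [[Rcpp::export(name = ".ff_eval_cpp")]]
List ff_eval_cpp(NumericMatrix pos, double box, List ffl, bool forces) {
  FF ff; unpack_ff(ffl, ff);
  if ((int)pos.nrow() != ff.natoms) stop("position matrix does not match topology atom count");
  std::vector<V3> x = mat_to_vec(pos);
  Energies en;
  double w = 0;
  if (forces) {
    std::vector<V3> f(ff.natoms);
    eval_ff(ff, x, box, en, &f, &w);
    return List::create(_["terms"] = NumericVector::create(
        _["bond"] = en.bond, _["angle"] = en.angle, _["stiff_dihedral"] = en.stiff,
        _["flexible_dihedral"] = en.flex, _["wall"] = en.wall,
        _["intra_lj_pairs"] = en.pair_lj, _["lj"] = en.lj, _["coulomb"] = en.coul),
      _["forces"] = vec_to_mat(f), _["virial"] = w);
  }
  eval_ff(ff, x, box, en, nullptr, nullptr);
  return List::create(_["terms"] = NumericVector::create(
      _["bond"] = en.bond, _["angle"] = en.angle, _["stiff_dihedral"] = en.stiff,
      _["flexible_dihedral"] = en.flex, _["wall"] = en.wall,
      _["intra_lj_pairs"] = en.pair_lj, _["lj"] = en.lj, _["coulomb"] = en.coul));
}

// [[Rcpp::export(name = ".dihedral_cpp")]]
double dihedral_cpp(NumericMatrix pos, int i, int j, int k, int l) {
  std::vector<V3> x = mat_to_vec(pos);
  V3 rij = x[i] - x[j], rkj = x[k] - x[j], rkl = x[k] - x[l];
  V3 m = cross(rij, rkj), n = cross(rkj, rkl);
  if (norm2(m) < 1e-18 || norm2(n) < 1e-18)
    stop("degenerate geometry: collinear atoms in dihedral");
  return dihedral_geom(x, i, j, k, l, 0, nullptr, nullptr);
}

static void wrap_molecules(const FF &ff, std::vector<V3> &x, double box) {
  if (box <= 0) return;
  for (const auto &mol : ff.mols) {
    V3 c;
    for (int a : mol) c = c + x[a];
    double inv = 1.0 / mol.size();
    c = inv * c;
    V3 sh(-box * std::floor(c.x / box), -box * std::floor(c.y / box),
          -box * std::floor(c.z / box));
    if (sh.x != 0 || sh.y != 0 || sh.z != 0)
      for (int a : mol) x[a] = x[a] + sh;
  }
}

// Stochastic velocity rescaling (canonical sampling through velocity
// rescaling): returns alpha^2 for current kinetic energy K, target K0,
// Nf degrees of freedom, coupling time tau, step dt.
static double vrescale_alpha2(double K, double K0, int Nf, double tau, double dt,
                              std::mt19937_64 &rng) {
  if (tau <= 0) return 1.0;
  double c = std::exp(-dt / tau);
  std::normal_distribution<double> nd(0.0, 1.0);
  double r1 = nd(rng);
  double sum_r2;
  if (Nf - 1 <= 0) {
    sum_r2 = 0.0;
  } else {
    std::gamma_distribution<double> gd((Nf - 1) / 2.0, 2.0); // chi^2_{Nf-1}
    sum_r2 = gd(rng);
  }
  double a2 = c + (1.0 - c) * K0 * (r1 * r1 + sum_r2) / (Nf * K)
            + 2.0 * r1 * std::sqrt(c * (1.0 - c) * K0 / (Nf * K));
  return a2;
}

// [[Rcpp::export(name = ".vrescale_alpha_cpp")]]
double vrescale_alpha_cpp(double K, double K0, int Nf, double tau, double dt, int seed) {
  std::mt19937_64 rng(seed);
  return std::sqrt(vrescale_alpha2(K, K0, Nf, tau, dt, rng));
}

// [[Rcpp::export(name = ".md_run_cpp")]]
List md_run_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                double box0, List ffl, List opts) {
  FF ff; unpack_ff(ffl, ff);
  int N = ff.natoms;
  if ((int)pos0.nrow() != N) stop("positions do not match topology");
  std::vector<V3> x = mat_to_vec(pos0), v = mat_to_vec(vel0);
  std::vector<double> m = as<std::vector<double>>(mass);
  double box = box0;

  double dt = as<double>(opts["dt"]);
  long nsteps = (long)as<double>(opts["nsteps"]);
  int thermostat = as<int>(opts["thermostat"]);
  double ref_T = as<double>(opts["ref_T"]), tau_T = as<double>(opts["tau_T"]);
  int barostat = as<int>(opts["barostat"]);
  double ref_P = as<double>(opts["ref_P"]), tau_P = as<double>(opts["tau_P"]);
  double compress = as<double>(opts["compressibility"]);
  int nstpcouple = as<int>(opts["nstpcouple"]);
  int com_interval = as<int>(opts["com_interval"]);
  int seed = as<int>(opts["seed"]);
  std::vector<long> save_steps;
  {
    NumericVector ss = opts["save_steps"];
    for (double s : ss) save_steps.push_back((long)s);
  }
  int log_interval = as<int>(opts["log_interval"]);
  double t0 = as<double>(opts["time0"]);
  bool remove_com_start = as<bool>(opts["remove_com_start"]);

  std::vector<double> posres_k;
  std::vector<V3> posres_ref;
  bool has_posres = false;
  if (opts.containsElementNamed("posres_k") && !Rf_isNull(opts["posres_k"])) {
    posres_k = as<std::vector<double>>(opts["posres_k"]);
    NumericMatrix pr = opts["posres_ref"];
    posres_ref = mat_to_vec(pr);
    has_posres = true;
  }

  std::mt19937_64 rng((uint64_t)seed * 2654435761u + 1);

  // COM motion removal
  double Mtot = 0; for (double mi : m) Mtot += mi;
  auto remove_com = [&]() {
    V3 p;
    for (int i = 0; i < N; ++i) p = p + m[i] * v[i];
    V3 vc = (1.0 / Mtot) * p;
    for (int i = 0; i < N; ++i) v[i] = v[i] - vc;
  };
  if (remove_com_start) remove_com();
  int Nf = 3 * N - (com_interval > 0 || remove_com_start ? 3 : 0);

  Energies en;
  double virial = 0;
  std::vector<V3> f(N);
  eval_ff(ff, x, box, en, &f, &virial,
          has_posres ? &posres_k : nullptr, has_posres ? &posres_ref : nullptr);

  auto kinetic = [&]() {
    double K = 0;
    for (int i = 0; i < N; ++i) K += 0.5 * m[i] * norm2(v[i]);
    return K;
  };

  size_t save_ptr = 0;
  List fr_pos, fr_vel;
  std::vector<double> fr_time, fr_box;
  std::vector<double> lg_time, lg_epot, lg_ekin, lg_T, lg_P, lg_box;

  auto save_frame = [&](long step) {
    fr_pos.push_back(vec_to_mat(x));
    fr_vel.push_back(vec_to_mat(v));
    fr_time.push_back(t0 + step * dt);
    fr_box.push_back(box);
  };
  auto log_state = [&](long step) {
    double K = kinetic();
    double T = 2.0 * K / (Nf * KB);
    double vol = box > 0 ? box * box * box : NA_REAL;
    double P = box > 0 ? PRESFAC * (2.0 * K + virial) / (3.0 * vol) : NA_REAL;
    lg_time.push_back(t0 + step * dt);
    lg_epot.push_back(en.total());
    lg_ekin.push_back(K);
    lg_T.push_back(T);
    lg_P.push_back(P);
    lg_box.push_back(box);
  };

  while (save_ptr < save_steps.size() && save_steps[save_ptr] == 0) {
    save_frame(0); ++save_ptr;
  }
  if (log_interval > 0) log_state(0);

  for (long step = 1; step <= nsteps; ++step) {
    // velocity Verlet
    for (int i = 0; i < N; ++i) {
      double h = 0.5 * dt / m[i];
      v[i] = v[i] + h * f[i];
      x[i] = x[i] + dt * v[i];
    }
    wrap_molecules(ff, x, box);
    eval_ff(ff, x, box, en, &f, &virial,
            has_posres ? &posres_k : nullptr, has_posres ? &posres_ref : nullptr);
    for (int i = 0; i < N; ++i) v[i] = v[i] + (0.5 * dt / m[i]) * f[i];

    double K = kinetic();
    if (!std::isfinite(K) || !std::isfinite(en.total())) {
      int bad = -1;
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(norm2(x[i])) || !std::isfinite(norm2(v[i]))) { bad = i; break; }
      stop("integration blow-up at step %ld (atom %d)", step, bad + 1);
    }

    if (thermostat == 1 && K > 0) {
      double K0 = 0.5 * Nf * KB * ref_T;
      double a2 = vrescale_alpha2(K, K0, Nf, tau_T, dt, rng);
      double a = std::sqrt(std::max(0.0, a2));
      for (int i = 0; i < N; ++i) v[i] = a * v[i];
      K = a2 * K;
    }

    if (barostat == 1 && box > 0 && step % nstpcouple == 0) {
      double vol = box * box * box;
      double P = PRESFAC * (2.0 * K + virial) / (3.0 * vol);
      double mu = std::cbrt(1.0 - compress * (nstpcouple * dt / tau_P) * (ref_P - P));
      mu = std::max(0.98, std::min(1.02, mu));
      // scale molecule centres, keep internal geometry
      for (const auto &mol : ff.mols) {
        V3 c;
        for (int a : mol) c = c + x[a];
        c = (1.0 / mol.size()) * c;
        V3 sh = (mu - 1.0) * c;
        for (int a : mol) x[a] = x[a] + sh;
      }
      box *= mu;
    }

    if (com_interval > 0 && step % com_interval == 0) remove_com();

    while (save_ptr < save_steps.size() && save_steps[save_ptr] == step) {
      save_frame(step); ++save_ptr;
    }
    if (log_interval > 0 && step % log_interval == 0) log_state(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["pos"] = vec_to_mat(x), _["vel"] = vec_to_mat(v), _["box"] = box,
    _["time"] = t0 + nsteps * dt,
    _["frame_pos"] = fr_pos, _["frame_vel"] = fr_vel,
    _["frame_time"] = NumericVector(fr_time.begin(), fr_time.end()),
    _["frame_box"] = NumericVector(fr_box.begin(), fr_box.end()),
    _["log"] = List::create(
      _["time"] = NumericVector(lg_time.begin(), lg_time.end()),
      _["epot"] = NumericVector(lg_epot.begin(), lg_epot.end()),
      _["ekin"] = NumericVector(lg_ekin.begin(), lg_ekin.end()),
      _["temperature"] = NumericVector(lg_T.begin(), lg_T.end()),
      _["pressure"] = NumericVector(lg_P.begin(), lg_P.end()),
      _["box"] = NumericVector(lg_box.begin(), lg_box.end())));
}

// Histogram of minimum-image distances between two selections, pooled over
// a list of frames.  Returns integer counts per radial bin.
// [[Rcpp::export(name = ".rdf_counts_cpp")]]
NumericVector rdf_counts_cpp(List frames, NumericVector boxes,
                             IntegerVector selA, IntegerVector selB,
                             double rmax, int nbins) {
  NumericVector counts(nbins);
  double dr = rmax / nbins;
  for (int fidx = 0; fidx < frames.size(); ++fidx) {
    NumericMatrix fm = frames[fidx];
    double box = boxes[fidx];
    for (int a = 0; a < selA.size(); ++a) {
      int i = selA[a];
      for (int b = 0; b < selB.size(); ++b) {
        int j = selB[b];
        if (i == j) continue;
        double dx = fm(i,0) - fm(j,0), dy = fm(i,1) - fm(j,1), dz = fm(i,2) - fm(j,2);
        minimg(dx, box); minimg(dy, box); minimg(dz, box);
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r < rmax) counts[(int)(r / dr)] += 1.0;
      }
    }
    if (fidx % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
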