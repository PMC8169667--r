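// Compiled kernels for the coarse-grained bead force field:
//  - pairwise LJ + screened Coulomb with quintic switching to zero at r_cut,
//    harmonic bonds and angles, orthorhombic minimum image,
//  - velocity-Verlet NVT loop with Berendsen velocity rescaling,
//  - FIRE local minimizer,
//  - residue x nucleobase cross-energy accumulation,
//  - rigid-body pose grid scan (oracle-grade brute force).
//
// Units: A, fs, amu, K, kJ/mol, elementary charge.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double KE2KJ = 1.0e4;  // amu*(A/fs)^2 -> kJ/mol  (amu*NA = 1 g/mol)
const double F2A = 1.0e-4;   // (kJ/mol/A)/amu -> A/fs^2

struct Sys {
  int n, ntype;
  bool periodic;
  double box[3];
  std::vector<int> type;                // 0-based type index per bead
  std::vector<double> sig, eps;         // ntype x ntype, column-major
  std::vector<double> q, mass;
  double coulk;                         // prefactor / dielectric
  double rcut, ljs, couls, kB;
  bool hardcore; double r_hc;           // optional unscaled LJ core in DMD mode
  std::vector<int> bi, bj; std::vector<double> br0, bk;
  std::vector<int> ai, aj, ak; std::vector<double> ath0, aka;
  std::unordered_set<long long> excl;   // 1-2 and 1-3 pairs
  std::vector<char> excl_map;           // n*n bitmap when n is small

  long long key(int i, int j) const {
    long long a = i < j ? i : j, b = i < j ? j : i;
    return a * (long long)n + b;
  }
  bool excluded(int i, int j) const {
    if (!excl_map.empty()) return excl_map[(size_t)i * n + j] != 0;
    return excl.count(key(i, j)) > 0;
  }
};

inline void min_image(const Sys& S, double* d) {
  if (!S.periodic) return;
  for (int k = 0; k < 3; ++k) d[k] -= S.box[k] * std::round(d[k] / S.box[k]);
}

Sys unpack(const List& sys) {
  Sys S;
  S.n = as<int>(sys["n"]);
  S.ntype = as<int>(sys["ntype"]);
  NumericVector box = sys["box"];
  S.periodic = box.size() == 3;
  for (int k = 0; k < 3; ++k) S.box[k] = S.periodic ? box[k] : 0.0;
  S.type = as<std::vector<int>>(sys["type"]);
  S.sig = as<std::vector<double>>(sys["sig"]);
  S.eps = as<std::vector<double>>(sys["eps"]);
  S.q = as<std::vector<double>>(sys["q"]);
  S.mass = as<std::vector<double>>(sys["mass"]);
  S.coulk = as<double>(sys["coulk"]);
  S.rcut = as<double>(sys["rcut"]);
  S.ljs = as<double>(sys["ljs"]);
  S.couls = as<double>(sys["couls"]);
  S.kB = as<double>(sys["kB"]);
  S.hardcore = as<bool>(sys["hardcore"]);
  S.r_hc = as<double>(sys["r_hc"]);
  IntegerMatrix bonds = sys["bonds"];
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.bi.push_back(bonds(b, 0)); S.bj.push_back(bonds(b, 1));
  }
  S.br0 = as<std::vector<double>>(sys["bond_r0"]);
  S.bk = as<std::vector<double>>(sys["bond_k"]);
  IntegerMatrix ang = sys["angles"];
  for (int a = 0; a < ang.nrow(); ++a) {
    S.ai.push_back(ang(a, 0)); S.aj.push_back(ang(a, 1)); S.ak.push_back(ang(a, 2));
  }
  S.ath0 = as<std::vector<double>>(sys["angle_th0"]);
  S.aka = as<std::vector<double>>(sys["angle_k"]);
  IntegerMatrix excl = sys["excl"];
  if (S.n <= 2048) {
    S.excl_map.assign((size_t)S.n * S.n, 0);
    for (int e = 0; e < excl.nrow(); ++e) {
      int i = excl(e, 0), j = excl(e, 1);
      S.excl_map[(size_t)i * S.n + j] = 1;
      S.excl_map[(size_t)j * S.n + i] = 1;
    }
  } else {
    for (int e = 0; e < excl.nrow(); ++e)
      S.excl.insert(S.key(excl(e, 0), excl(e, 1)));
  }
  return S;
}

// Verlet neighbor list: exclusion-filtered pairs within rcut + skin
struct NList {
  std::vector<int> pi, pj;
  std::vector<double> x_ref;
  double skin;
  void build(const Sys& S, const double* x) {
    pi.clear(); pj.clear();
    double rl = S.rcut + skin, rl2 = rl * rl;
    for (int i = 0; i < S.n - 1; ++i)
      for (int j = i + 1; j < S.n; ++j) {
        double d[3];
        for (int k = 0; k < 3; ++k) d[k] = x[3 * i + k] - x[3 * j + k];
        min_image(S, d);
        if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < rl2 &&
            !S.excluded(i, j)) {
          pi.push_back(i); pj.push_back(j);
        }
      }
    x_ref.assign(x, x + 3 * S.n);
  }
  bool stale(const Sys& S, const double* x) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < S.n; ++i) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = x[3 * i + k] - x_ref[3 * i + k];
        s += d * d;
      }
      if (s > lim2) return true;
    }
    return false;
  }
};

// quintic switch: S(rs)=1, S(rc)=0, S'=S''=0 at both ends
inline double switch_val(double r, double rs, double rc, double& dS) {
  double t = (r - rs) / (rc - rs);
  double omt = 1.0 - t;
  dS = -30.0 * t * t * omt * omt / (rc - rs);
  return 1.0 - t * t * t * (10.0 - 15.0 * t + 6.0 * t * t);
}

// energy and d(energy)/dr of one nonbonded pair at distance r (< rcut)
inline void pair_nb(const Sys& S, int i, int j, double r, double scale,
                    double& elj, double& ecoul, double& dedr) {
  elj = 0.0; ecoul = 0.0; dedr = 0.0;
  int ti = S.type[i], tj = S.type[j];
  double ep = S.eps[ti * S.ntype + tj];
  if (ep > 0.0) {
    double lj_scale = scale;
    if (S.hardcore && scale < 1.0 && r < S.r_hc) lj_scale = 1.0;
    double s = S.sig[ti * S.ntype + tj];
    double sr2 = s * s / (r * r);
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    double v = 4.0 * ep * (sr12 - sr6);
    double dv = 24.0 * ep * (sr6 - 2.0 * sr12) / r;
    if (S.ljs < S.rcut && r > S.ljs) {
      double dS; double Sw = switch_val(r, S.ljs, S.rcut, dS);
      dv = dv * Sw + v * dS;
      v *= Sw;
    }
    elj = lj_scale * v;
    dedr += lj_scale * dv;
  }
  double qq = S.q[i] * S.q[j];
  if (qq != 0.0) {
    double v = S.coulk * qq / r;
    double dv = -v / r;
    if (S.couls < S.rcut && r > S.couls) {
      double dS; double Sw = switch_val(r, S.couls, S.rcut, dS);
      dv = dv * Sw + v * dS;
      v *= Sw;
    }
    ecoul = scale * v;
    dedr += scale * dv;
  }
}

struct EvalOut { double eb, ea, elj, ec; double total() const { return eb + ea + elj + ec; } };

// f: length 3n force accumulator (or nullptr); bins: nrowb x ncolb column-major
// accumulator of pair energies (or nullptr), driven by rowbin/colbin (1-based, 0 = not in group)
EvalOut compute(const Sys& S, const double* x, double scale,
                const std::vector<char>& inA, const std::vector<char>& inB,
                bool cross_only, double* f,
                double* bins = nullptr, const int* rowbin = nullptr,
                const int* colbin = nullptr, int nrowb = 0,
                const NList* nl = nullptr) {
  EvalOut o; o.eb = o.ea = o.elj = o.ec = 0.0;
  if (f) std::fill(f, f + 3 * S.n, 0.0);
  double rcut2 = S.rcut * S.rcut;

  auto do_pair = [&](int i, int j) {
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = x[3 * i + k] - x[3 * j + k];
    min_image(S, d);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= rcut2) return;
    double r = std::sqrt(r2);
    double elj, ec, dedr;
    pair_nb(S, i, j, r, scale, elj, ec, dedr);
    o.elj += elj; o.ec += ec;
    if (f) {
      double g = -dedr / r;
      for (int k = 0; k < 3; ++k) {
        f[3 * i + k] += g * d[k];
        f[3 * j + k] -= g * d[k];
      }
    }
    if (bins) {
      int rb = 0, cb = 0;
      if (rowbin[i] > 0 && colbin[j] > 0) { rb = rowbin[i]; cb = colbin[j]; }
      else if (rowbin[j] > 0 && colbin[i] > 0) { rb = rowbin[j]; cb = colbin[i]; }
      if (rb > 0) bins[(cb - 1) * nrowb + (rb - 1)] += elj + ec;
    }
  };

  if (nl) {
    for (size_t p = 0; p < nl->pi.size(); ++p) do_pair(nl->pi[p], nl->pj[p]);
  } else {
    for (int i = 0; i < S.n - 1; ++i) {
      for (int j = i + 1; j < S.n; ++j) {
        if (cross_only) {
          bool ab = (inA[i] && inB[j]) || (inA[j] && inB[i]);
          if (!ab) continue;
        }
        if (S.excluded(i, j)) continue;
        do_pair(i, j);
      }
    }
  }

  if (!cross_only) {
    for (size_t b = 0; b < S.bi.size(); ++b) {
      int i = S.bi[b], j = S.bj[b];
      double d[3];
      for (int k = 0; k < 3; ++k) d[k] = x[3 * i + k] - x[3 * j + k];  // never wrapped
      double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      double dr = r - S.br0[b];
      o.eb += 0.5 * S.bk[b] * dr * dr;
      if (f && r > 1e-12) {
        double g = -S.bk[b] * dr / r;
        for (int k = 0; k < 3; ++k) {
          f[3 * i + k] += g * d[k];
          f[3 * j + k] -= g * d[k];
        }
      }
    }
    for (size_t a = 0; a < S.ai.size(); ++a) {
      int i = S.ai[a], j = S.aj[a], k2 = S.ak[a];
      double u[3], w[3];
      for (int k = 0; k < 3; ++k) {
        u[k] = x[3 * i + k] - x[3 * j + k];
        w[k] = x[3 * k2 + k] - x[3 * j + k];
      }
      double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
      if (nu < 1e-12 || nw < 1e-12) continue;
      double c = (u[0] * w[0] + u[1] * w[1] + u[2] * w[2]) / (nu * nw);
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      double dth = th - S.ath0[a];
      o.ea += 0.5 * S.aka[a] * dth * dth;
      if (f) {
        double s = std::sqrt(std::max(1.0 - c * c, 1e-16));
        double coef = S.aka[a] * dth / s;
        for (int k = 0; k < 3; ++k) {
          double fi = coef * (w[k] / nw - c * u[k] / nu) / nu;
          double fk = coef * (u[k] / nu - c * w[k] / nw) / nw;
          f[3 * i + k] += fi;
          f[3 * k2 + k] += fk;
          f[3 * j + k] -= fi + fk;
        }
      }
    }
  }
  return o;
}

// harmonic spherical container: beads beyond radius feel 0.5*k*(d-R)^2
double container(const Sys& S, const double* x, const double* c, double R,
                 double kc, double* f) {
  if (R <= 0.0) return 0.0;
  double e = 0.0;
  for (int i = 0; i < S.n; ++i) {
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = x[3 * i + k] - c[k];
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r > R) {
      double dr = r - R;
      e += 0.5 * kc * dr * dr;
      if (f) {
        double g = -kc * dr / r;
        for (int k = 0; k < 3; ++k) f[3 * i + k] += g * d[k];
      }
    }
  }
  return e;
}

void closest_pair(const Sys& S, const double* x, int& pi, int& pj, double& pr) {
  pr = std::numeric_limits<double>::infinity(); pi = pj = -1;
  for (int i = 0; i < S.n - 1; ++i)
    for (int j = i + 1; j < S.n; ++j) {
      double d[3];
      for (int k = 0; k < 3; ++k) d[k] = x[3 * i + k] - x[3 * j + k];
      min_image(S, d);
      double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (r < pr) { pr = r; pi = i; pj = j; }
    }
}

std::vector<char> mask_from(IntegerVector sel, int n) {
  std::vector<char> m(n, 0);
  for (int i = 0; i < sel.size(); ++i) m[sel[i] - 1] = 1;
  return m;
}

} // namespace

// [[Rcpp::export]]
List cpp_eval(List sys, NumericMatrix coords, double scale,
              IntegerVector selA, IntegerVector selB, bool cross_only,
              bool want_forces) {
  Sys S = unpack(sys);
  std::vector<char> inA = mask_from(selA, S.n), inB = mask_from(selB, S.n);
  std::vector<double> x(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  std::vector<double> f;
  double* fp = nullptr;
  if (want_forces) { f.assign(3 * S.n, 0.0); fp = f.data(); }
  EvalOut o = compute(S, x.data(), scale, inA, inB, cross_only, fp);
  List out = List::create(
      _["energy"] = o.total(), _["e_bond"] = o.eb, _["e_angle"] = o.ea,
      _["e_lj"] = o.elj, _["e_coul"] = o.ec);
  if (want_forces) {
    NumericMatrix F(S.n, 3);
    for (int i = 0; i < S.n; ++i)
      for (int k = 0; k < 3; ++k) F(i, k) = f[3 * i + k];
    out["forces"] = F;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_cross_matrix(List sys, NumericMatrix coords, double scale,
                               IntegerVector rowbin, IntegerVector colbin,
                               int nrow, int ncol) {
  Sys S = unpack(sys);
  std::vector<char> inA(S.n, 0), inB(S.n, 0);
  for (int i = 0; i < S.n; ++i) {
    if (rowbin[i] > 0) inA[i] = 1;
    if (colbin[i] > 0) inB[i] = 1;
  }
  std::vector<double> x(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  NumericMatrix bins(nrow, ncol);
  compute(S, x.data(), scale, inA, inB, true, nullptr,
          bins.begin(), rowbin.begin(), colbin.begin(), nrow);
  return bins;
}

// [[Rcpp::export]]
List cpp_run_nvt(List sys, NumericMatrix coords, NumericMatrix vel, double dt,
                 int nsteps, double Ttarget, double tau, double scale,
                 int sample_every, NumericVector ccenter, double cradius,
                 double ck) {
  Sys S = unpack(sys);
  std::vector<char> inA(S.n, 0), inB(S.n, 0);
  std::vector<double> x(3 * S.n), v(3 * S.n), f(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = coords(i, k);
      v[3 * i + k] = vel(i, k);
    }
  double cc[3] = {0, 0, 0};
  bool has_container = cradius > 0.0 && ccenter.size() == 3;
  if (has_container) for (int k = 0; k < 3; ++k) cc[k] = ccenter[k];

  int dof = S.n > 1 ? 3 * S.n - 3 : 3 * S.n;
  List frames;
  std::vector<double> t_out, epot_out, ekin_out, temp_out;

  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < S.n; ++i)
      for (int k = 0; k < 3; ++k) ke += S.mass[i] * v[3 * i + k] * v[3 * i + k];
    return 0.5 * ke * KE2KJ;
  };
  auto snapshot = [&](int step, double epot) {
    NumericMatrix fr(S.n, 3);
    for (int i = 0; i < S.n; ++i)
      for (int k = 0; k < 3; ++k) fr(i, k) = x[3 * i + k];
    frames.push_back(fr);
    double ke = kinetic();
    t_out.push_back(step * dt);
    epot_out.push_back(epot);
    ekin_out.push_back(ke);
    temp_out.push_back(2.0 * ke / (dof * S.kB));
  };

  NList nlst; nlst.skin = 2.0;
  nlst.build(S, x.data());
  EvalOut o = compute(S, x.data(), scale, inA, inB, false, f.data(),
                      nullptr, nullptr, nullptr, 0, &nlst);
  double epot = o.total();
  if (has_container) epot += container(S, x.data(), cc, cradius, ck, f.data());
  snapshot(0, epot);

  int status = 0, bad_i = -1, bad_j = -1; double bad_r = NA_REAL;
  if (!std::isfinite(epot) || epot > 1e30) {
    closest_pair(S, x.data(), bad_i, bad_j, bad_r);
    status = 1;
  }
  for (int step = 1; status == 0 && step <= nsteps; ++step) {
    for (int i = 0; i < S.n; ++i) {
      double am = 0.5 * dt * F2A / S.mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += am * f[3 * i + k];
    }
    for (int i = 0; i < 3 * S.n; ++i) x[i] += dt * v[i];
    if (nlst.stale(S, x.data())) nlst.build(S, x.data());
    o = compute(S, x.data(), scale, inA, inB, false, f.data(),
                nullptr, nullptr, nullptr, 0, &nlst);
    epot = o.total();
    if (has_container) epot += container(S, x.data(), cc, cradius, ck, f.data());
    for (int i = 0; i < S.n; ++i) {
      double am = 0.5 * dt * F2A / S.mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += am * f[3 * i + k];
    }
    bool exploded = false;
    for (int i = 0; i < 3 * S.n && !exploded; ++i)
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e8) exploded = true;
    if (!std::isfinite(epot) || epot > 1e30 || exploded) {
      closest_pair(S, x.data(), bad_i, bad_j, bad_r);
      status = 1;
      break;
    }
    if (std::isfinite(tau) && tau > 0.0) {
      double ke = kinetic();
      double Tinst = 2.0 * ke / (dof * S.kB);
      if (Tinst > 1e-12) {
        double lam = std::sqrt(1.0 + (dt / tau) * (Ttarget / Tinst - 1.0));
        for (int i = 0; i < 3 * S.n; ++i) v[i] *= lam;
      }
    }
    if (step % sample_every == 0 || step == nsteps) snapshot(step, epot);
  }

  NumericMatrix X(S.n, 3), V(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) {
      X(i, k) = x[3 * i + k];
      V(i, k) = v[3 * i + k];
    }
  return List::create(
      _["frames"] = frames, _["times"] = wrap(t_out), _["epot"] = wrap(epot_out),
      _["ekin"] = wrap(ekin_out), _["temp"] = wrap(temp_out), _["coords"] = X,
      _["vel"] = V, _["status"] = status,
      _["bad_pair"] = IntegerVector::create(bad_i + 1, bad_j + 1),
      _["bad_r"] = bad_r);
}

// [[Rcpp::export]]
List cpp_fire(List sys, NumericMatrix coords, double scale, double ftol,
              int maxit, double dt0, double dtmax, double dmax,
              NumericVector ccenter, double cradius, double ck) {
  Sys S = unpack(sys);
  std::vector<char> inA(S.n, 0), inB(S.n, 0);
  std::vector<double> x(3 * S.n), v(3 * S.n, 0.0), f(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double cc[3] = {0, 0, 0};
  bool has_container = cradius > 0.0 && ccenter.size() == 3;
  if (has_container) for (int k = 0; k < 3; ++k) cc[k] = ccenter[k];

  NList nlst; nlst.skin = 2.0;
  nlst.build(S, x.data());
  auto eval = [&](double* fp) {
    if (nlst.stale(S, x.data())) nlst.build(S, x.data());
    EvalOut o = compute(S, x.data(), scale, inA, inB, false, fp,
                        nullptr, nullptr, nullptr, 0, &nlst);
    double e = o.total();
    if (has_container) e += container(S, x.data(), cc, cradius, ck, fp);
    return e;
  };
  auto fmax_of = [&]() {
    double fm = 0.0;
    for (int i = 0; i < S.n; ++i) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += f[3 * i + k] * f[3 * i + k];
      fm = std::max(fm, std::sqrt(s));
    }
    return fm;
  };

  double dt = dt0, alpha = 0.1;
  int npos = 0;
  const int nmin = 5;
  double e = eval(f.data());
  double best_e = e;
  std::vector<double> best_x = x;
  bool converged = false;
  int it = 0;
  double fm = fmax_of();
  for (it = 0; it < maxit; ++it) {
    if (fm <= ftol) { converged = true; break; }
    double P = 0.0;
    for (int i = 0; i < 3 * S.n; ++i) P += f[i] * v[i];
    if (P > 0.0) {
      if (++npos > nmin) { dt = std::min(dt * 1.1, dtmax); alpha *= 0.99; }
    } else {
      std::fill(v.begin(), v.end(), 0.0);
      dt *= 0.5;
      alpha = 0.1;
      npos = 0;
    }
    for (int i = 0; i < 3 * S.n; ++i) v[i] += dt * f[i];
    double vn = 0.0, fn = 0.0;
    for (int i = 0; i < 3 * S.n; ++i) { vn += v[i] * v[i]; fn += f[i] * f[i]; }
    vn = std::sqrt(vn); fn = std::sqrt(fn);
    if (fn > 1e-300) {
      for (int i = 0; i < 3 * S.n; ++i)
        v[i] = (1.0 - alpha) * v[i] + alpha * vn * f[i] / fn;
    }
    // per-bead displacement cap
    double dispmax = 0.0;
    for (int i = 0; i < S.n; ++i) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += v[3 * i + k] * v[3 * i + k];
      dispmax = std::max(dispmax, dt * std::sqrt(s));
    }
    double cap = dispmax > dmax ? dmax / dispmax : 1.0;
    for (int i = 0; i < 3 * S.n; ++i) x[i] += cap * dt * v[i];
    e = eval(f.data());
    fm = fmax_of();
    if (std::isfinite(e) && e < best_e) { best_e = e; best_x = x; }
    if (!std::isfinite(e)) { x = best_x; e = eval(f.data()); fm = fmax_of(); std::fill(v.begin(), v.end(), 0.0); dt = dt0; }
  }
  if (e > best_e) { x = best_x; e = eval(f.data()); fm = fmax_of(); }
  NumericMatrix X(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) X(i, k) = x[3 * i + k];
  return List::create(_["coords"] = X, _["energy"] = e, _["converged"] = converged,
                      _["iterations"] = it, _["fmax"] = fm);
}

// Rigid-body pose scan used as a brute-force docking oracle. The cross energy
// is computed by an inline LJ + switched-Coulomb kernel on precomputed
// per-pair parameters (independent of the cg_eval path).
// lig is centered on its COM; pose = rot %*% lig + trans.
// [[Rcpp::export]]
List cpp_grid_scan(NumericMatrix rec, NumericMatrix lig, NumericMatrix sigp,
                   NumericMatrix epsp, NumericMatrix qqp, double rcut,
                   double ljs, double couls, NumericMatrix trans,
                   NumericMatrix rots, int topk) {
  int nr = rec.nrow(), nl = lig.nrow(), nt = trans.nrow(), nk = rots.nrow();
  double rcut2 = rcut * rcut;
  // ligand radius for the reach prefilter
  double ligrad = 0.0;
  for (int i = 0; i < nl; ++i) {
    double s = lig(i, 0) * lig(i, 0) + lig(i, 1) * lig(i, 1) + lig(i, 2) * lig(i, 2);
    ligrad = std::max(ligrad, std::sqrt(s));
  }
  double reach = rcut + ligrad;
  double reach2 = reach * reach;

  std::vector<double> best_e(topk, std::numeric_limits<double>::infinity());
  std::vector<int> best_t(topk, -1), best_k(topk, -1);

  std::vector<double> lx(3 * nl);
  for (int k = 0; k < nk; ++k) {
    // row-major 3x3 rotation
    double R[9];
    for (int m = 0; m < 9; ++m) R[m] = rots(k, m);
    for (int i = 0; i < nl; ++i) {
      for (int d = 0; d < 3; ++d)
        lx[3 * i + d] = R[3 * d] * lig(i, 0) + R[3 * d + 1] * lig(i, 1) +
                        R[3 * d + 2] * lig(i, 2);
    }
    for (int t = 0; t < nt; ++t) {
      double tx = trans(t, 0), ty = trans(t, 1), tz = trans(t, 2);
      // prefilter: skip poses whose COM is beyond reach of every receptor bead
      bool near = false;
      for (int j = 0; j < nr; ++j) {
        double dx = tx - rec(j, 0), dy = ty - rec(j, 1), dz = tz - rec(j, 2);
        if (dx * dx + dy * dy + dz * dz < reach2) { near = true; break; }
      }
      if (!near) continue;
      double e = 0.0;
      bool clash = false;
      for (int i = 0; i < nl && !clash; ++i) {
        double xi = lx[3 * i] + tx, yi = lx[3 * i + 1] + ty, zi = lx[3 * i + 2] + tz;
        for (int j = 0; j < nr; ++j) {
          double dx = xi - rec(j, 0), dy = yi - rec(j, 1), dz = zi - rec(j, 2);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= rcut2) continue;
          double s = sigp(i, j);
          if (r2 < 0.36 * s * s) { clash = true; break; }  // r < 0.6 sigma
          double r = std::sqrt(r2);
          double ep = epsp(i, j);
          if (ep > 0.0) {
            double sr2 = s * s / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
            double v = 4.0 * ep * (sr12 - sr6);
            if (ljs < rcut && r > ljs) {
              double tt = (r - ljs) / (rcut - ljs);
              v *= 1.0 - tt * tt * tt * (10.0 - 15.0 * tt + 6.0 * tt * tt);
            }
            e += v;
          }
          double qq = qqp(i, j);
          if (qq != 0.0) {
            double v = qq / r;
            if (couls < rcut && r > couls) {
              double tt = (r - couls) / (rcut - couls);
              v *= 1.0 - tt * tt * tt * (10.0 - 15.0 * tt + 6.0 * tt * tt);
            }
            e += v;
          }
        }
      }
      if (clash) continue;
      // insert into top-k (worst slot)
      int worst = 0;
      for (int m = 1; m < topk; ++m)
        if (best_e[m] > best_e[worst]) worst = m;
      if (e < best_e[worst]) {
        best_e[worst] = e;
        best_t[worst] = t + 1;
        best_k[worst] = k + 1;
      }
    }
  }
  return List::create(_["energy"] = wrap(best_e), _["trans_idx"] = wrap(best_t),
                      _["rot_idx"] = wrap(best_k));
}
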