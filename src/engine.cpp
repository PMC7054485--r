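// Coarse-grained MD engine: harmonic bonds/angles, shifted Lennard-Jones,
// reaction-field Coulomb, BAOAB Langevin integration, constant-volume
// uniaxial box deformation. Units: nm, ps, kJ/mol, g/mol, e.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/mol/K

struct System {
  int n;
  std::vector<double> x, y, z;     // positions
  std::vector<double> q, m;        // charge, mass
  std::vector<int> type;           // 0-based species index
  double box[3];
  // force field
  int ntypes;
  std::vector<double> eps, sig;    // ntypes*ntypes pair tables
  double rc, rc2, coulk;
  // bonded terms (0-based indices)
  std::vector<int> b_i, b_j;       std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k;  std::vector<double> a_kf, a_t0;
  // exclusions: sorted per-particle lists (1-2 and 1-3)
  std::vector<std::vector<int>> excl;
  // neighbour list
  std::vector<int> nb_i, nb_j;
  std::vector<double> ref_x, ref_y, ref_z;
  double skin, drift;
  std::vector<bool> frozen;
};

static inline double mimg(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// single-correction minimum image: valid while |d| < 1.5 L, which holds
// because the integrator keeps positions wrapped at every list rebuild
static inline double pm(double d, double L, double hL) {
  if (d > hL) d -= L; else if (d < -hL) d += L;
  return d;
}

static void build_exclusions(System& S) {
  S.excl.assign(S.n, {});
  auto add = [&](int i, int j) {
    if (i > j) std::swap(i, j);
    S.excl[i].push_back(j);
  };
  for (size_t b = 0; b < S.b_i.size(); ++b) add(S.b_i[b], S.b_j[b]);
  for (size_t a = 0; a < S.a_i.size(); ++a) add(S.a_i[a], S.a_k[a]);
  for (int i = 0; i < S.n; ++i) {
    std::sort(S.excl[i].begin(), S.excl[i].end());
    S.excl[i].erase(std::unique(S.excl[i].begin(), S.excl[i].end()), S.excl[i].end());
  }
}

static inline bool excluded(const System& S, int i, int j) {
  if (i > j) std::swap(i, j);
  const std::vector<int>& e = S.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

// O(n^2) Verlet list rebuild with skin; robust under box deformation.
static void rebuild_list(System& S) {
  // wrap into the primary cell so single-correction min image stays valid
  for (int i = 0; i < S.n; ++i) {
    S.x[i] -= S.box[0] * std::floor(S.x[i] / S.box[0]);
    S.y[i] -= S.box[1] * std::floor(S.y[i] / S.box[1]);
    S.z[i] -= S.box[2] * std::floor(S.z[i] / S.box[2]);
  }
  S.nb_i.clear(); S.nb_j.clear();
  double rl = S.rc + S.skin, rl2 = rl * rl;
  double h0 = 0.5 * S.box[0], h1 = 0.5 * S.box[1], h2 = 0.5 * S.box[2];
  for (int i = 0; i < S.n - 1; ++i) {
    for (int j = i + 1; j < S.n; ++j) {
      double dx = pm(S.x[i] - S.x[j], S.box[0], h0);
      double dy = pm(S.y[i] - S.y[j], S.box[1], h1);
      double dz = pm(S.z[i] - S.z[j], S.box[2], h2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rl2 && !excluded(S, i, j)) { S.nb_i.push_back(i); S.nb_j.push_back(j); }
    }
  }
  S.ref_x = S.x; S.ref_y = S.y; S.ref_z = S.z;
  S.drift = 0.0;
}

static void maybe_rebuild(System& S) {
  double half = 0.5 * S.skin, max2 = 0.0, h2 = half * half;
  for (int i = 0; i < S.n; ++i) {
    double dx = S.x[i] - S.ref_x[i];
    double dy = S.y[i] - S.ref_y[i];
    double dz = S.z[i] - S.ref_z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > max2) max2 = r2;
    if (max2 + S.drift * S.drift > h2) { rebuild_list(S); return; }
  }
  if (std::sqrt(max2) + S.drift > half) rebuild_list(S);
}

struct Energies { double bond = 0, angle = 0, lj = 0, coul = 0;
                  double total() const { return bond + angle + lj + coul; } };

// Forces + energies. fx/fy/fz are overwritten.
static Energies forces(System& S, std::vector<double>& fx, std::vector<double>& fy,
                       std::vector<double>& fz) {
  Energies E;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);

  double hb0 = 0.5 * S.box[0], hb1 = 0.5 * S.box[1], hb2 = 0.5 * S.box[2];

  // bonds: V = 0.5 k (r - r0)^2
  for (size_t b = 0; b < S.b_i.size(); ++b) {
    int i = S.b_i[b], j = S.b_j[b];
    double dx = pm(S.x[i] - S.x[j], S.box[0], hb0);
    double dy = pm(S.y[i] - S.y[j], S.box[1], hb1);
    double dz = pm(S.z[i] - S.z[j], S.box[2], hb2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) stop("bond between particles %d and %d has zero length", i + 1, j + 1);
    double dr = r - S.b_r0[b];
    E.bond += 0.5 * S.b_k[b] * dr * dr;
    double fmag = -S.b_k[b] * dr / r;
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }

  // angles: V = 0.5 k (theta - theta0)^2 over i-j-k with j the vertex
  for (size_t a = 0; a < S.a_i.size(); ++a) {
    int i = S.a_i[a], j = S.a_j[a], k = S.a_k[a];
    double r1x = pm(S.x[i] - S.x[j], S.box[0], hb0);
    double r1y = pm(S.y[i] - S.y[j], S.box[1], hb1);
    double r1z = pm(S.z[i] - S.z[j], S.box[2], hb2);
    double r2x = pm(S.x[k] - S.x[j], S.box[0], hb0);
    double r2y = pm(S.y[k] - S.y[j], S.box[1], hb1);
    double r2z = pm(S.z[k] - S.z[j], S.box[2], hb2);
    double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
    double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
    double ct = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dth = th - S.a_t0[a];
    E.angle += 0.5 * S.a_kf[a] * dth * dth;
    double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
    double dVdth = S.a_kf[a] * dth;
    double c = dVdth / st; // -dV/dcos(theta); pushes theta toward theta0
    // gradient of cos(theta)
    double gix = (r2x / (n1 * n2)) - ct * r1x / (n1 * n1);
    double giy = (r2y / (n1 * n2)) - ct * r1y / (n1 * n1);
    double giz = (r2z / (n1 * n2)) - ct * r1z / (n1 * n1);
    double gkx = (r1x / (n1 * n2)) - ct * r2x / (n2 * n2);
    double gky = (r1y / (n1 * n2)) - ct * r2y / (n2 * n2);
    double gkz = (r1z / (n1 * n2)) - ct * r2z / (n2 * n2);
    fx[i] += c * gix; fy[i] += c * giy; fz[i] += c * giz;
    fx[k] += c * gkx; fy[k] += c * gky; fz[k] += c * gkz;
    fx[j] -= c * (gix + gkx); fy[j] -= c * (giy + gky); fz[j] -= c * (giz + gkz);
  }

  // nonbonded: shifted LJ + reaction-field Coulomb (both -> 0 at rc)
  {
    const double rc = S.rc, rc2 = S.rc2, rc3 = rc * rc * rc;
    const double inv_rc3 = 1.0 / rc3, half_inv_rc3 = 0.5 / rc3,
                 m3_half_inv_rc = -1.5 / rc;
    // per-pair-type tables: 4 eps, sigma^2, potential shift at rc
    const int nt = S.ntypes;
    std::vector<double> eps4(nt * nt), s2(nt * nt), vshift(nt * nt);
    for (int a = 0; a < nt * nt; ++a) {
      eps4[a] = 4.0 * S.eps[a];
      s2[a] = S.sig[a] * S.sig[a];
      double src2 = s2[a] / rc2, src6 = src2 * src2 * src2;
      vshift[a] = eps4[a] * (src6 * src6 - src6);
    }
    for (size_t p = 0; p < S.nb_i.size(); ++p) {
      int i = S.nb_i[p], j = S.nb_j[p];
      double dx = pm(S.x[i] - S.x[j], S.box[0], hb0);
      double dy = pm(S.y[i] - S.y[j], S.box[1], hb1);
      double dz = pm(S.z[i] - S.z[j], S.box[2], hb2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      if (r2 < 1e-12) stop("particles %d and %d at zero distance", i + 1, j + 1);
      int tp = S.type[i] * nt + S.type[j];
      double inv_r2 = 1.0 / r2;
      double fmag = 0.0;
      double e4 = eps4[tp];
      if (e4 > 0) {
        double sr2 = s2[tp] * inv_r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        E.lj += e4 * (sr12 - sr6) - vshift[tp];
        fmag += 6.0 * e4 * (2.0 * sr12 - sr6) * inv_r2;
      }
      double qq = S.q[i] * S.q[j];
      if (qq != 0) {
        double inv_r = std::sqrt(inv_r2);
        E.coul += S.coulk * qq * (inv_r + r2 * half_inv_rc3 + m3_half_inv_rc);
        fmag += S.coulk * qq * (inv_r * inv_r2 - inv_rc3);
      }
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
  }

  for (int i = 0; i < S.n; ++i)
    if (S.frozen[i]) { fx[i] = 0; fy[i] = 0; fz[i] = 0; }
  return E;
}

static System unpack(NumericMatrix pos, NumericVector charge, NumericVector mass,
                     IntegerVector type, int ntypes, NumericMatrix eps, NumericMatrix sig,
                     NumericVector box, double cutoff, double coulk,
                     IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                     IntegerMatrix angles, NumericVector ang_k, NumericVector ang_t0,
                     LogicalVector frozen, double skin) {
  System S;
  S.n = pos.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  for (int i = 0; i < S.n; ++i) { S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2); }
  S.q = as<std::vector<double>>(charge);
  S.m = as<std::vector<double>>(mass);
  S.type = as<std::vector<int>>(type);
  for (int d = 0; d < 3; ++d) S.box[d] = box[d];
  S.ntypes = ntypes;
  S.eps.resize(ntypes * ntypes); S.sig.resize(ntypes * ntypes);
  for (int a = 0; a < ntypes; ++a)
    for (int b = 0; b < ntypes; ++b) { S.eps[a * ntypes + b] = eps(a, b); S.sig[a * ntypes + b] = sig(a, b); }
  S.rc = cutoff; S.rc2 = cutoff * cutoff; S.coulk = coulk;
  for (int b = 0; b < bonds.nrow(); ++b) { S.b_i.push_back(bonds(b, 0)); S.b_j.push_back(bonds(b, 1)); }
  S.b_k = as<std::vector<double>>(bond_k); S.b_r0 = as<std::vector<double>>(bond_r0);
  for (int a = 0; a < angles.nrow(); ++a) {
    S.a_i.push_back(angles(a, 0)); S.a_j.push_back(angles(a, 1)); S.a_k.push_back(angles(a, 2));
  }
  S.a_kf = as<std::vector<double>>(ang_k); S.a_t0 = as<std::vector<double>>(ang_t0);
  S.frozen.resize(S.n);
  for (int i = 0; i < S.n; ++i) S.frozen[i] = frozen[i];
  S.skin = skin; S.drift = 0.0;
  build_exclusions(S);
  rebuild_list(S);
  return S;
}

// [[Rcpp::export]]
List engine_energy(NumericMatrix pos, NumericVector charge, NumericVector mass,
                   IntegerVector type, int ntypes, NumericMatrix eps, NumericMatrix sig,
                   NumericVector box, double cutoff, double coulk,
                   IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                   IntegerMatrix angles, NumericVector ang_k, NumericVector ang_t0,
                   LogicalVector frozen, bool with_forces = false) {
  System S = unpack(pos, charge, mass, type, ntypes, eps, sig, box, cutoff, coulk,
                    bonds, bond_k, bond_r0, angles, ang_k, ang_t0, frozen, 0.0);
  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  Energies E = forces(S, fx, fy, fz);
  List out = List::create(_["bond"] = E.bond, _["angle"] = E.angle, _["lj"] = E.lj,
                          _["coulomb"] = E.coul, _["total"] = E.total());
  if (with_forces) {
    NumericMatrix F(S.n, 3);
    for (int i = 0; i < S.n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
    out["forces"] = F;
  }
  return out;
}

// BAOAB Langevin / velocity-Verlet (gamma = 0) with optional per-step uniaxial
// constant-volume deformation. zscale[s] multiplies Lz at step s; Lx, Ly are
// divided by sqrt(zscale) and coordinates are remapped affinely.
// [[Rcpp::export]]
List engine_run(NumericMatrix pos, NumericMatrix vel, NumericVector charge, NumericVector mass,
                IntegerVector type, int ntypes, NumericMatrix eps, NumericMatrix sig,
                NumericVector box, double cutoff, double coulk,
                IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                IntegerMatrix angles, NumericVector ang_k, NumericVector ang_t0,
                LogicalVector frozen, int nsteps, double dt, double gamma, double tset,
                NumericVector zscale, int stride, int log_stride, double skin,
                double t0, bool record_vel = false) {
  System S = unpack(pos, charge, mass, type, ntypes, eps, sig, box, cutoff, coulk,
                    bonds, bond_k, bond_r0, angles, ang_k, ang_t0, frozen, skin);
  std::vector<double> vx(S.n), vy(S.n), vz(S.n);
  for (int i = 0; i < S.n; ++i) { vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2); }
  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  Energies E = forces(S, fx, fy, fz);

  int nfree = 0;
  for (int i = 0; i < S.n; ++i) if (!S.frozen[i]) ++nfree;
  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  bool deform = zscale.size() > 0;

  std::vector<double> times; std::vector<NumericMatrix> fpos, fvel;
  std::vector<std::vector<double>> fbox;
  std::vector<std::vector<double>> log; // t,Tkin,Eb,Ea,Elj,Ec,Epot,Ekin,Lx,Ly,Lz
  RNGScope rng;

  auto snap = [&](double t) {
    NumericMatrix P(S.n, 3);
    for (int i = 0; i < S.n; ++i) { P(i, 0) = S.x[i]; P(i, 1) = S.y[i]; P(i, 2) = S.z[i]; }
    fpos.push_back(P);
    if (record_vel) {
      NumericMatrix V(S.n, 3);
      for (int i = 0; i < S.n; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
      fvel.push_back(V);
    }
    fbox.push_back({S.box[0], S.box[1], S.box[2]});
    times.push_back(t);
  };
  auto logrow = [&](double t) {
    double ke = 0;
    for (int i = 0; i < S.n; ++i)
      if (!S.frozen[i]) ke += 0.5 * S.m[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    double Tk = (nfree > 0) ? 2.0 * ke / (3.0 * nfree * KB) : 0.0;
    log.push_back({t, Tk, E.bond, E.angle, E.lj, E.coul, E.total(), ke,
                   S.box[0], S.box[1], S.box[2]});
  };

  snap(t0); logrow(t0);
  for (int s = 0; s < nsteps; ++s) {
    if (deform) {
      double zs = zscale[s];
      if (zs != 1.0) {
        double xys = 1.0 / std::sqrt(zs);
        S.box[2] *= zs; S.box[0] *= xys; S.box[1] *= xys;
        for (int i = 0; i < S.n; ++i) { S.z[i] *= zs; S.x[i] *= xys; S.y[i] *= xys; }
        S.drift += (std::fabs(zs - 1.0) + std::fabs(xys - 1.0)) *
                   0.5 * std::max(S.box[2], S.box[0]);
      }
    }
    for (int i = 0; i < S.n; ++i) {
      if (S.frozen[i]) continue;
      double im = 1.0 / S.m[i];
      vx[i] += 0.5 * dt * fx[i] * im; vy[i] += 0.5 * dt * fy[i] * im; vz[i] += 0.5 * dt * fz[i] * im;
      S.x[i] += 0.5 * dt * vx[i]; S.y[i] += 0.5 * dt * vy[i]; S.z[i] += 0.5 * dt * vz[i];
      if (gamma > 0) {
        double sd = std::sqrt(KB * tset * im);
        vx[i] = c1 * vx[i] + c2 * sd * norm_rand();
        vy[i] = c1 * vy[i] + c2 * sd * norm_rand();
        vz[i] = c1 * vz[i] + c2 * sd * norm_rand();
      }
      S.x[i] += 0.5 * dt * vx[i]; S.y[i] += 0.5 * dt * vy[i]; S.z[i] += 0.5 * dt * vz[i];
    }
    maybe_rebuild(S);
    E = forces(S, fx, fy, fz);
    for (int i = 0; i < S.n; ++i) {
      if (S.frozen[i]) continue;
      double im = 1.0 / S.m[i];
      vx[i] += 0.5 * dt * fx[i] * im; vy[i] += 0.5 * dt * fy[i] * im; vz[i] += 0.5 * dt * fz[i] * im;
      if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]) || !std::isfinite(fz[i]))
        stop("non-finite force on particle %d at step %d; try a smaller timestep", i + 1, s + 1);
    }
    double t = t0 + (s + 1) * dt;
    if ((s + 1) % stride == 0 || s == nsteps - 1) snap(t);
    if ((s + 1) % log_stride == 0 || s == nsteps - 1) logrow(t);
  }

  NumericMatrix P(S.n, 3), V(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    P(i, 0) = S.x[i]; P(i, 1) = S.y[i]; P(i, 2) = S.z[i];
    V(i, 0) = vx[i];  V(i, 1) = vy[i];  V(i, 2) = vz[i];
  }
  NumericMatrix L(log.size(), 11);
  for (size_t r = 0; r < log.size(); ++r)
    for (int cidx = 0; cidx < 11; ++cidx) L(r, cidx) = log[r][cidx];
  NumericMatrix B(fbox.size(), 3);
  for (size_t r = 0; r < fbox.size(); ++r)
    for (int d = 0; d < 3; ++d) B(r, d) = fbox[r][d];
  return List::create(_["pos"] = P, _["vel"] = V,
                      _["box"] = NumericVector::create(S.box[0], S.box[1], S.box[2]),
                      _["times"] = wrap(times), _["frame_pos"] = wrap(fpos),
                      _["frame_vel"] = wrap(fvel), _["frame_box"] = B, _["log"] = L);
}

// Steepest descent with adaptive step; returns relaxed positions and energy.
// [[Rcpp::export]]
List engine_minimize(NumericMatrix pos, NumericVector charge, NumericVector mass,
                     IntegerVector type, int ntypes, NumericMatrix eps, NumericMatrix sig,
                     NumericVector box, double cutoff, double coulk,
                     IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                     IntegerMatrix angles, NumericVector ang_k, NumericVector ang_t0,
                     LogicalVector frozen, int max_steps, double step0, double ftol) {
  System S = unpack(pos, charge, mass, type, ntypes, eps, sig, box, cutoff, coulk,
                    bonds, bond_k, bond_r0, angles, ang_k, ang_t0, frozen, 0.3);
  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  Energies E = forces(S, fx, fy, fz);
  double step = step0;
  for (int it = 0; it < max_steps; ++it) {
    double fmax = 0;
    for (int i = 0; i < S.n; ++i) {
      double f2 = fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
      if (f2 > fmax) fmax = f2;
    }
    fmax = std::sqrt(fmax);
    if (fmax < ftol) break;
    double scale = step / std::max(fmax, 1e-12);
    std::vector<double> ox = S.x, oy = S.y, oz = S.z;
    for (int i = 0; i < S.n; ++i) {
      S.x[i] += scale * fx[i]; S.y[i] += scale * fy[i]; S.z[i] += scale * fz[i];
    }
    maybe_rebuild(S);
    std::vector<double> gx(S.n), gy(S.n), gz(S.n);
    Energies E2 = forces(S, gx, gy, gz);
    if (E2.total() < E.total()) {
      E = E2; fx = gx; fy = gy; fz = gz;
      step = std::min(step * 1.2, 0.05);
    } else {
      S.x = ox; S.y = oy; S.z = oz;
      rebuild_list(S);
      step *= 0.5;
      if (step < 1e-8) break;
    }
  }
  NumericMatrix P(S.n, 3);
  for (int i = 0; i < S.n; ++i) { P(i, 0) = S.x[i]; P(i, 1) = S.y[i]; P(i, 2) = S.z[i]; }
  return List::create(_["pos"] = P,
                      _["energy"] = List::create(_["bond"] = E.bond, _["angle"] = E.angle,
                                                 _["lj"] = E.lj, _["coulomb"] = E.coul,
                                                 _["total"] = E.total()));
}
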