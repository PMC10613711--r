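// Coarse-grained one-bead-per-residue MD core.
//
// Units: nm, ps, Da, kJ/mol, K. With these units 1 kJ/mol = 1 Da nm^2 ps^-2,
// so Newton's equations need no conversion factors.
//
// Interactions:
//   bonds          harmonic, consecutive beads within a chain
//   short range    Ashbaugh-Hatch hydropathy-scaled Lennard-Jones,
//                  sigma_ij = (sigma_i+sigma_j)/2, lambda_ij = mean lambda
//   electrostatics Debye-Hueckel screened Coulomb on charged bead pairs
// Bonded (1-2) pairs are excluded from the nonbonded terms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
#include <algorithm>
using namespace Rcpp;

static const double KB = 0.00831446261815324;   // kJ/mol/K
static const double FC = 138.935458;            // kJ mol-1 nm e-2
static const double BAR = 16.6054;              // kJ mol-1 nm-3 -> bar

struct FF {
  double b0, kb, eps, epsr, kappa, cutoff;
};

struct System {
  int n;
  std::vector<double> x, y, z;      // positions
  std::vector<double> q, sig, lam, mass;
  std::vector<int> chain;
  double box;
  bool periodic;
};

static inline double mic(double d, double box) {
  return d - box * std::round(d / box);
}

static inline double wrap0(double u, double box) {
  return u - box * std::floor(u / box);
}

// fast minimum image, valid when |d| < 1.5 box (positions wrapped at list build)
static inline double fmic(double d, double box, double hbox) {
  if (d > hbox) return d - box;
  if (d < -hbox) return d + box;
  return d;
}

static void wrap_system(System& s) {
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = wrap0(s.x[i], s.box);
    s.y[i] = wrap0(s.y[i], s.box);
    s.z[i] = wrap0(s.z[i], s.box);
  }
}

// ---- neighbor list -------------------------------------------------------

struct NeighborList {
  std::vector<std::pair<int, int>> pairs;
  // per-pair precomputed parameters (filled by finalize())
  std::vector<int> pi, pj;
  std::vector<double> sij2, lij, qq;
  bool with_params = false;
  std::vector<double> x0, y0, z0;   // positions at last build
  double skin = 0.2;
  double box_at_build = -1.0;
  void finalize(const System& s) {
    if (!with_params) return;
    pi.clear(); pj.clear(); sij2.clear(); lij.clear(); qq.clear();
    pi.reserve(pairs.size()); pj.reserve(pairs.size());
    sij2.reserve(pairs.size()); lij.reserve(pairs.size()); qq.reserve(pairs.size());
    for (const auto& pr : pairs) {
      int i = pr.first, j = pr.second;
      if (s.chain[i] == s.chain[j] && std::abs(i - j) == 1) continue;  // 1-2 excluded
      pi.push_back(i); pj.push_back(j);
      double sij = 0.5 * (s.sig[i] + s.sig[j]);
      sij2.push_back(sij * sij);
      lij.push_back(0.5 * (s.lam[i] + s.lam[j]));
      qq.push_back(s.q[i] * s.q[j]);
    }
  }
  void build(System& s, double rlist) {
    if (s.periodic) wrap_system(s);
    pairs.clear();
    const int n = s.n;
    x0.assign(s.x.begin(), s.x.end());
    y0.assign(s.y.begin(), s.y.end());
    z0.assign(s.z.begin(), s.z.end());
    box_at_build = s.box;
    double rl2 = rlist * rlist;
    int ncell = s.periodic ? std::max(1, (int)std::floor(s.box / rlist)) : 0;
    // cap the grid so sparse systems in huge boxes stay O(n) in memory
    int cap = std::max(3, (int)std::ceil(std::cbrt(8.0 * n + 64.0)));
    if (ncell > cap) ncell = cap;
    if (!s.periodic || ncell < 3) {
      // O(N^2) fallback (small or non-periodic systems)
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
          if (s.periodic) { dx = mic(dx, s.box); dy = mic(dy, s.box); dz = mic(dz, s.box); }
          if (dx * dx + dy * dy + dz * dz <= rl2) pairs.emplace_back(i, j);
        }
      finalize(s);
      return;
    }
    double cell = s.box / ncell;
    std::vector<std::vector<int>> bins(ncell * ncell * ncell);
    auto binof = [&](double u) {
      int b = (int)std::floor(u / cell) % ncell;
      if (b < 0) b += ncell;
      return b;
    };
    for (int i = 0; i < n; ++i) {
      int bx = binof(s.x[i]), by = binof(s.y[i]), bz = binof(s.z[i]);
      bins[(bx * ncell + by) * ncell + bz].push_back(i);
    }
    for (int bx = 0; bx < ncell; ++bx)
      for (int by = 0; by < ncell; ++by)
        for (int bz = 0; bz < ncell; ++bz) {
          const auto& me = bins[(bx * ncell + by) * ncell + bz];
          if (me.empty()) continue;
          for (int ox = -1; ox <= 1; ++ox)
            for (int oy = -1; oy <= 1; ++oy)
              for (int oz = -1; oz <= 1; ++oz) {
                int nx = (bx + ox + ncell) % ncell;
                int ny = (by + oy + ncell) % ncell;
                int nz = (bz + oz + ncell) % ncell;
                int nid = (nx * ncell + ny) * ncell + nz;
                int mid = (bx * ncell + by) * ncell + bz;
                if (nid < mid) continue;   // visit each cell pair once
                const auto& other = bins[nid];
                for (size_t a = 0; a < me.size(); ++a) {
                  size_t bstart = (nid == mid) ? a + 1 : 0;
                  for (size_t b = bstart; b < other.size(); ++b) {
                    int i = me[a], j = other[b];
                    double dx = mic(s.x[i] - s.x[j], s.box);
                    double dy = mic(s.y[i] - s.y[j], s.box);
                    double dz = mic(s.z[i] - s.z[j], s.box);
                    if (dx * dx + dy * dy + dz * dz <= rl2)
                      pairs.emplace_back(std::min(i, j), std::max(i, j));
                  }
                }
              }
        }
    finalize(s);
  }
  bool needs_rebuild(const System& s) const {
    if (box_at_build > 0 && std::abs(s.box / box_at_build - 1.0) > 0.02) return true;
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < s.n; ++i) {
      double dx = s.x[i] - x0[i], dy = s.y[i] - y0[i], dz = s.z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// ---- forces and energies -------------------------------------------------

struct Energies {
  double bond = 0, elec = 0, sr = 0, virial = 0;
  bool singular = false;
  double total() const { return bond + elec + sr; }
};

static Energies compute_forces(const System& s, const FF& ff,
                               const NeighborList& nl,
                               std::vector<double>& fx,
                               std::vector<double>& fy,
                               std::vector<double>& fz) {
  Energies en;
  const int n = s.n;
  fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
  const double rc2 = ff.cutoff * ff.cutoff;
  const double hbox = 0.5 * s.box;

  // bonds
  for (int i = 0; i + 1 < n; ++i) {
    if (s.chain[i] != s.chain[i + 1]) continue;
    double dx = s.x[i] - s.x[i + 1], dy = s.y[i] - s.y[i + 1], dz = s.z[i] - s.z[i + 1];
    if (s.periodic) {
      dx = fmic(dx, s.box, hbox); dy = fmic(dy, s.box, hbox); dz = fmic(dz, s.box, hbox);
    }
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-9) { en.singular = true; continue; }
    double dr = r - ff.b0;
    en.bond += 0.5 * ff.kb * dr * dr;
    double fmag = -ff.kb * dr / r;   // dE/dr * (-1/r) applied to dvec
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[i + 1] -= fmag * dx; fy[i + 1] -= fmag * dy; fz[i + 1] -= fmag * dz;
    en.virial += fmag * (dx * dx + dy * dy + dz * dz);
  }

  // nonbonded from neighbor list (bonded pairs removed at build)
  const double two13 = std::cbrt(2.0);
  const size_t np = nl.pi.size();
  const bool per = s.periodic;
  for (size_t k = 0; k < np; ++k) {
    const int i = nl.pi[k], j = nl.pj[k];
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    if (per) {
      dx = fmic(dx, s.box, hbox); dy = fmic(dy, s.box, hbox); dz = fmic(dz, s.box, hbox);
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > rc2) continue;
    if (r2 < 1e-16) { en.singular = true; continue; }
    double fmag = 0.0;   // force coefficient: F = fmag * dvec

    // Ashbaugh-Hatch
    const double s2 = nl.sij2[k] / r2;
    const double s6 = s2 * s2 * s2;
    const double s12 = s6 * s6;
    const double elj = 4.0 * ff.eps * (s12 - s6);
    const double flj = 24.0 * ff.eps * (2.0 * s12 - s6) / r2;  // -dE/dr / r
    const double l = nl.lij[k];
    if (r2 <= two13 * nl.sij2[k]) {      // r <= 2^(1/6) sigma
      en.sr += elj + (1.0 - l) * ff.eps;
      fmag += flj;
    } else {
      en.sr += l * elj;
      fmag += l * flj;
    }

    // Debye-Hueckel
    if (nl.qq[k] != 0.0) {
      double r = std::sqrt(r2);
      double ee = FC * nl.qq[k] * std::exp(-ff.kappa * r) / (ff.epsr * r);
      en.elec += ee;
      fmag += ee * (ff.kappa + 1.0 / r) / r;
    }

    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    en.virial += fmag * r2;
  }
  return en;
}

static System make_system(NumericMatrix pos, IntegerVector chain,
                          NumericVector q, NumericVector sig, NumericVector lam,
                          NumericVector mass, double box, bool periodic) {
  System s;
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) { s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2); }
  s.q.assign(q.begin(), q.end());
  s.sig.assign(sig.begin(), sig.end());
  s.lam.assign(lam.begin(), lam.end());
  s.mass.assign(mass.begin(), mass.end());
  s.chain.assign(chain.begin(), chain.end());
  s.box = box;
  s.periodic = periodic;
  return s;
}

static NumericMatrix pos_matrix(const System& s) {
  NumericMatrix m(s.n, 3);
  for (int i = 0; i < s.n; ++i) { m(i, 0) = s.x[i]; m(i, 1) = s.y[i]; m(i, 2) = s.z[i]; }
  return m;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix pos, IntegerVector chain, NumericVector q,
                NumericVector sig, NumericVector lam, NumericVector mass,
                double box, bool periodic,
                double b0, double kb, double eps, double epsr, double kappa,
                double cutoff) {
  System s = make_system(pos, chain, q, sig, lam, mass, box, periodic);
  FF ff{b0, kb, eps, epsr, kappa, cutoff};
  NeighborList nl;
  nl.with_params = true;
  nl.build(s, cutoff + nl.skin);
  std::vector<double> fx, fy, fz;
  Energies en = compute_forces(s, ff, nl, fx, fy, fz);
  NumericMatrix fm(s.n, 3);
  for (int i = 0; i < s.n; ++i) { fm(i, 0) = fx[i]; fm(i, 1) = fy[i]; fm(i, 2) = fz[i]; }
  return List::create(_["bond"] = en.bond, _["electrostatic"] = en.elec,
                      _["short_range"] = en.sr, _["total"] = en.total(),
                      _["virial"] = en.virial, _["forces"] = fm,
                      _["singular"] = en.singular);
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, IntegerVector chain, NumericVector q,
                  NumericVector sig, NumericVector lam, NumericVector mass,
                  double box, bool periodic,
                  double b0, double kb, double eps, double epsr, double kappa,
                  double cutoff, double tol, int max_iter) {
  System s = make_system(pos, chain, q, sig, lam, mass, box, periodic);
  FF ff{b0, kb, eps, epsr, kappa, cutoff};
  NeighborList nl;
  nl.with_params = true;
  double rlist = cutoff + nl.skin;
  nl.build(s, rlist);
  std::vector<double> fx, fy, fz;
  Energies en = compute_forces(s, ff, nl, fx, fy, fz);
  if (en.singular) stop("singular pair (r = 0) in starting configuration");
  double e = en.total();

  // FIRE descent with a strict energy guard: any step that would raise the
  // energy is reverted (velocities zeroed, timestep halved), so energy is
  // non-increasing across accepted steps.
  const int n = s.n;
  std::vector<double> vx(n, 0.0), vy(n, 0.0), vz(n, 0.0);
  double dtf = 0.002, dtmax = 0.05, alpha = 0.1;
  int n_pos = 0;
  int it = 0;
  double fmax = 0.0;
  System saved = s;
  for (it = 0; it < max_iter; ++it) {
    fmax = 0.0;
    for (int i = 0; i < n; ++i) {
      fmax = std::max({fmax, std::abs(fx[i]), std::abs(fy[i]), std::abs(fz[i])});
    }
    if (fmax <= tol) break;
    double P = 0, vnorm = 0, fnorm = 0;
    for (int i = 0; i < n; ++i) {
      P += vx[i] * fx[i] + vy[i] * fy[i] + vz[i] * fz[i];
      vnorm += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      fnorm += fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
    }
    vnorm = std::sqrt(vnorm); fnorm = std::sqrt(fnorm);
    if (P > 0) {
      double mix = (fnorm > 0) ? alpha * vnorm / fnorm : 0.0;
      for (int i = 0; i < n; ++i) {
        vx[i] = (1 - alpha) * vx[i] + mix * fx[i];
        vy[i] = (1 - alpha) * vy[i] + mix * fy[i];
        vz[i] = (1 - alpha) * vz[i] + mix * fz[i];
      }
      if (++n_pos > 5) { dtf = std::min(dtf * 1.1, dtmax); alpha *= 0.99; }
    } else {
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
      std::fill(vz.begin(), vz.end(), 0.0);
      dtf *= 0.5; alpha = 0.1; n_pos = 0;
    }
    // unit-mass Euler step with displacement clamp
    double dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      vx[i] += dtf * fx[i]; vy[i] += dtf * fy[i]; vz[i] += dtf * fz[i];
      double d2 = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      dmax = std::max(dmax, d2);
    }
    double scale = 1.0;
    dmax = std::sqrt(dmax) * dtf;
    if (dmax > 0.1) scale = 0.1 / dmax;   // cap per-step displacement, nm
    saved = s;
    for (int i = 0; i < n; ++i) {
      s.x[i] += scale * dtf * vx[i];
      s.y[i] += scale * dtf * vy[i];
      s.z[i] += scale * dtf * vz[i];
    }
    if (nl.needs_rebuild(s)) nl.build(s, rlist);
    std::vector<double> tfx, tfy, tfz;
    Energies ten = compute_forces(s, ff, nl, tfx, tfy, tfz);
    if (ten.total() <= e && !ten.singular) {
      e = ten.total();
      fx.swap(tfx); fy.swap(tfy); fz.swap(tfz);
    } else {
      s = saved;
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
      std::fill(vz.begin(), vz.end(), 0.0);
      dtf *= 0.5; alpha = 0.1; n_pos = 0;
      if (dtf < 1e-12) break;
      if (nl.needs_rebuild(s)) nl.build(s, rlist);
    }
  }
  {
    std::vector<double> tfx, tfy, tfz;
    Energies fin = compute_forces(s, ff, nl, tfx, tfy, tfz);
    e = fin.total();
    fmax = 0.0;
    for (int i = 0; i < n; ++i) {
      fmax = std::max({fmax, std::abs(tfx[i]), std::abs(tfy[i]), std::abs(tfz[i])});
    }
  }
  return List::create(_["pos"] = pos_matrix(s), _["energy"] = e,
                      _["max_force"] = fmax, _["iterations"] = it,
                      _["converged"] = fmax <= tol);
}

// Langevin BAOAB integrator with optional Berendsen barostat.
// [[Rcpp::export]]
List cpp_md(NumericMatrix pos, NumericMatrix vel, IntegerVector chain,
            NumericVector q, NumericVector sig, NumericVector lam,
            NumericVector mass, double box, bool periodic,
            double b0, double kb, double eps, double epsr, double kappa,
            double cutoff,
            int n_steps, double dt, double T_ref, double gamma,
            bool barostat, double tau_p, double p_ref, double compress,
            int sample_every, bool include_initial, int seed,
            int temp_every) {
  System s = make_system(pos, chain, q, sig, lam, mass, box, periodic);
  FF ff{b0, kb, eps, epsr, kappa, cutoff};
  const int n = s.n;
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) { vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2); }

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);

  NeighborList nl;
  nl.with_params = true;
  double rlist = cutoff + nl.skin;
  nl.build(s, rlist);
  std::vector<double> fx, fy, fz;
  Energies en = compute_forces(s, ff, nl, fx, fy, fz);
  if (en.singular) stop("singular pair (r = 0) in starting configuration");

  const double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 = (gamma > 0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  std::vector<double> inv2m(n), sd_noise(n);
  for (int i = 0; i < n; ++i) {
    inv2m[i] = 0.5 * dt / s.mass[i];
    sd_noise[i] = std::sqrt(KB * T_ref / s.mass[i]);
  }

  int n_frames = (sample_every > 0) ? n_steps / sample_every : 0;
  List frames(n_frames + (include_initial ? 1 : 0));
  NumericVector frame_times(n_frames + (include_initial ? 1 : 0));
  NumericVector frame_boxes(n_frames + (include_initial ? 1 : 0));
  int fidx = 0;
  if (include_initial) {
    frames[fidx] = pos_matrix(s);
    frame_times[fidx] = 0.0;
    frame_boxes[fidx] = s.box;
    ++fidx;
  }
  std::vector<double> temps;
  std::vector<double> energies;

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      vx[i] += inv2m[i] * fx[i]; vy[i] += inv2m[i] * fy[i]; vz[i] += inv2m[i] * fz[i];
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      s.x[i] += 0.5 * dt * vx[i]; s.y[i] += 0.5 * dt * vy[i]; s.z[i] += 0.5 * dt * vz[i];
    }
    // O: Ornstein-Uhlenbeck
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        const double csd = c2 * sd_noise[i];
        vx[i] = c1 * vx[i] + csd * gauss(rng);
        vy[i] = c1 * vy[i] + csd * gauss(rng);
        vz[i] = c1 * vz[i] + csd * gauss(rng);
      }
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      s.x[i] += 0.5 * dt * vx[i]; s.y[i] += 0.5 * dt * vy[i]; s.z[i] += 0.5 * dt * vz[i];
    }
    if (nl.needs_rebuild(s)) nl.build(s, rlist);
    en = compute_forces(s, ff, nl, fx, fy, fz);
    if (en.singular) stop("singular pair encountered at step %d", step);
    // B: half kick
    for (int i = 0; i < n; ++i) {
      vx[i] += inv2m[i] * fx[i]; vy[i] += inv2m[i] * fy[i]; vz[i] += inv2m[i] * fz[i];
    }

    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      ke += 0.5 * s.mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    }
    double tkin = 2.0 * ke / (3.0 * n * KB);

    if (barostat && compress > 0) {
      double vol = s.box * s.box * s.box;
      double p_inst = (2.0 * ke / 3.0 + en.virial / 3.0) / vol * BAR;  // bar
      double mu3 = 1.0 - (dt / tau_p) * compress * (p_ref - p_inst);
      double mu = std::cbrt(std::max(0.9, std::min(1.1, mu3)));
      // clamp per-step scaling for stability
      mu = std::max(0.98, std::min(1.02, mu));
      s.box *= mu;
      if (s.box <= 0) stop("barostat collapsed the box");
      for (int i = 0; i < n; ++i) { s.x[i] *= mu; s.y[i] *= mu; s.z[i] *= mu; }
      // keep the stale-list reference frame consistent under the rescaling;
      // the 2% box-drift criterion in needs_rebuild bounds the error
      for (int i = 0; i < n; ++i) { nl.x0[i] *= mu; nl.y0[i] *= mu; nl.z0[i] *= mu; }
    }

    if (temp_every > 0 && step % temp_every == 0) {
      temps.push_back(tkin);
      energies.push_back(en.total() + ke);
    }
    bool bad = false;
    for (int i = 0; i < n && !bad; ++i) {
      if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]) || !std::isfinite(s.z[i])) bad = true;
    }
    if (bad) stop("non-finite coordinates at step %d (integration blow-up)", step);

    if (sample_every > 0 && step % sample_every == 0) {
      frames[fidx] = pos_matrix(s);
      frame_times[fidx] = step * dt;
      frame_boxes[fidx] = s.box;
      ++fidx;
    }
  }

  NumericMatrix vout(n, 3);
  for (int i = 0; i < n; ++i) { vout(i, 0) = vx[i]; vout(i, 1) = vy[i]; vout(i, 2) = vz[i]; }
  return List::create(_["frames"] = frames, _["times"] = frame_times,
                      _["boxes"] = frame_boxes,
                      _["final_pos"] = pos_matrix(s), _["final_vel"] = vout,
                      _["final_box"] = s.box,
                      _["temperature"] = NumericVector(temps.begin(), temps.end()),
                      _["total_energy"] = NumericVector(energies.begin(), energies.end()));
}

// Intermolecular contact pairs (bead indices, 1-based) at cutoff rc.
// [[Rcpp::export]]
IntegerMatrix cpp_contacts(NumericMatrix pos, IntegerVector chain, double box,
                           bool periodic, double rc) {
  System s;
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) { s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2); }
  s.chain.assign(chain.begin(), chain.end());
  s.box = box;
  s.periodic = periodic;
  NeighborList nl;
  nl.skin = 0.0;
  nl.build(s, rc);
  std::vector<int> ai, aj;
  double rc2 = rc * rc;
  for (const auto& pr : nl.pairs) {
    int i = pr.first, j = pr.second;
    if (s.chain[i] == s.chain[j]) continue;
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    if (periodic) { dx = mic(dx, box); dy = mic(dy, box); dz = mic(dz, box); }
    if (dx * dx + dy * dy + dz * dz <= rc2) { ai.push_back(i + 1); aj.push_back(j + 1); }
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) { out(k, 0) = ai[k]; out(k, 1) = aj[k]; }
  return out;
}

// Histogram of all pairwise distances of one conformer (open boundaries).
// [[Rcpp::export]]
NumericVector cpp_pair_hist(NumericMatrix pos, double bin_width, int n_bins) {
  int n = pos.nrow();
  NumericVector h(n_bins);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(r / bin_width);
      if (b >= 0 && b < n_bins) h[b] += 1.0;
    }
  }
  return h;
}
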