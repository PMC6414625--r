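// Dissipative particle dynamics engine for a sticky block copolymer near an
// attractive wall, with reversible saturating bonds.
//
// Groot-Warren DPD: soft conservative repulsion a(1 - r/rc), dissipative
// force -gamma w(r)^2 (rhat.v) rhat with w(r) = 1 - r/rc, and a random force
// sigma w(r) xi rhat / sqrt(dt), sigma^2 = 2 gamma kT.  Modified
// velocity-Verlet (lambda = 1/2).  Cell lists, periodic x/y; z is periodic
// for solvent and reflecting for chain particles when a wall is present.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro-style splitmix / PCG-light generator: fast, reproducible across
// platforms, independent of R's RNG.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform on [-sqrt(3), sqrt(3)]: zero mean, unit variance
  double xi() { return (2.0 * unif() - 1.0) * 1.7320508075688772; }
  double normal() {  // Box-Muller (used only at initialisation)
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  int below(int n) { return (int)(unif() * n) % n; }
};

enum PType { SOLVENT = 0, INACTIVE = 1, ACTIVE = 2, WALL = 3 };

struct Sim {
  double Lx, Ly, Lz;
  bool wall;            // wall particles at z=0, z reflecting for chain
  bool zper;            // z periodic for pair interactions (no wall)
  double a_rep, fric, sigma, kT, rc, dt, spring_k;
  int n;                // total particles
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<int> type;
  std::vector<int> partner;      // reversible bond partner (-1 none)
  std::vector<int> chain_next;   // backbone neighbour (+1 index or -1)
  int n_chain;
  // cell list
  int ncx, ncy, ncz;
  std::vector<int> head, nxt;
  std::vector<double> vtx, vty, vtz, fox, foy, foz;   // integrator scratch
  Rng rng;

  Sim(uint64_t seed) : rng(seed) {}

  inline double wrap(double d, double L) const {
    if (d > 0.5 * L) return d - L;
    if (d < -0.5 * L) return d + L;
    return d;
  }

  void build_cells() {
    ncx = std::max(1, (int)std::floor(Lx / rc));
    ncy = std::max(1, (int)std::floor(Ly / rc));
    ncz = std::max(1, (int)std::floor(Lz / rc));
    head.assign(ncx * ncy * ncz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(x[i] / Lx * ncx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
      int cy = (int)(y[i] / Ly * ncy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
      int cz = (int)(z[i] / Lz * ncz); if (cz >= ncz) cz = ncz - 1; if (cz < 0) cz = 0;
      int c = (cz * ncy + cy) * ncx + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  inline void pair_force(int i, int j) {
    if (type[i] == WALL && type[j] == WALL) return;
    // solvent crosses the z boundary periodically and must not feel the
    // wall, or the one-sided repulsion pumps energy around the cycle
    if ((type[i] == WALL && type[j] == SOLVENT) ||
        (type[j] == WALL && type[i] == SOLVENT)) return;
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    dx = wrap(dx, Lx); dy = wrap(dy, Ly);
    // z minimum image for solvent-solvent pairs even with a wall present:
    // solvent wraps in z, and dropping its cross-boundary interactions
    // teleports wrapped particles into overlaps and heats the box
    if (zper || (type[i] == SOLVENT && type[j] == SOLVENT))
      dz = wrap(dz, Lz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc * rc || r2 < 1e-12) return;
    double r = std::sqrt(r2);
    double w = 1.0 - r / rc;
    double inv_r = 1.0 / r;
    double ex = dx * inv_r, ey = dy * inv_r, ez = dz * inv_r;
    double fc = a_rep * w;
    double f = fc;
    // wall particles are a geometric boundary, not a thermostat: coupling
    // the immobile layer dissipatively creates a friction gradient whose
    // uncorrected spurious drift piles chain particles onto the wall
    if (type[i] != WALL && type[j] != WALL) {
      double dvx = vx[i] - vx[j], dvy = vy[i] - vy[j], dvz = vz[i] - vz[j];
      double rv = ex * dvx + ey * dvy + ez * dvz;
      double fd = -fric * w * w * rv;
      double fr = sigma * w * rng.xi() / std::sqrt(dt);
      f += fd + fr;
    }
    fx[i] += f * ex; fy[i] += f * ey; fz[i] += f * ez;
    fx[j] -= f * ex; fy[j] -= f * ey; fz[j] -= f * ez;
  }

  inline void spring(int i, int j) {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    dx = wrap(dx, Lx); dy = wrap(dy, Ly); if (zper) dz = wrap(dz, Lz);
    fx[i] -= spring_k * dx; fy[i] -= spring_k * dy; fz[i] -= spring_k * dz;
    fx[j] += spring_k * dx; fy[j] += spring_k * dy; fz[j] += spring_k * dz;
  }

  void forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    build_cells();
    // half-neighbour stencil (13 offsets) + same cell
    static const int off[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c = (cz * ncy + cy) * ncx + cx;
          for (int i = head[c]; i >= 0; i = nxt[i])
            for (int j = nxt[i]; j >= 0; j = nxt[j]) pair_force(i, j);
          for (int k = 0; k < 13; ++k) {
            int ax = (cx + off[k][0] + ncx) % ncx;
            int ay = (cy + off[k][1] + ncy) % ncy;
            int az = cz + off[k][2];
            if (ncz > 1) az = (az + ncz) % ncz;
            if (az < 0 || az >= ncz) continue;
            int c2 = (az * ncy + ay) * ncx + ax;
            if (c2 == c) continue;
            for (int i = head[c]; i >= 0; i = nxt[i])
              for (int j = head[c2]; j >= 0; j = nxt[j]) pair_force(i, j);
          }
        }
    // backbone springs
    for (int i = 0; i < n_chain; ++i)
      if (chain_next[i] >= 0) spring(i, chain_next[i]);
    // reversible bonds (stored on the inactive side; pp bonds once via i<j)
    for (int i = 0; i < n_chain; ++i) {
      int p = partner[i];
      if (p < 0) continue;
      if (type[p] == INACTIVE && p < i) continue;
      spring(i, p);
    }
  }

  void step() {
    double lam = 0.5;
    int nm = n;  // wall particles never move (type check below)
    if ((int)vtx.size() != nm) {
      vtx.resize(nm); vty.resize(nm); vtz.resize(nm);
      fox.resize(nm); foy.resize(nm); foz.resize(nm);
    }
    for (int i = 0; i < nm; ++i) {
      if (type[i] == WALL) continue;
      x[i] += dt * vx[i] + 0.5 * dt * dt * fx[i];
      y[i] += dt * vy[i] + 0.5 * dt * dt * fy[i];
      z[i] += dt * vz[i] + 0.5 * dt * dt * fz[i];
      vtx[i] = vx[i]; vty[i] = vy[i]; vtz[i] = vz[i];
      fox[i] = fx[i]; foy[i] = fy[i]; foz[i] = fz[i];
      vx[i] += lam * dt * fx[i];
      vy[i] += lam * dt * fy[i];
      vz[i] += lam * dt * fz[i];
      apply_bc(i);
    }
    forces();
    for (int i = 0; i < nm; ++i) {
      if (type[i] == WALL) continue;
      vx[i] = vtx[i] + 0.5 * dt * (fox[i] + fx[i]);
      vy[i] = vty[i] + 0.5 * dt * (foy[i] + fy[i]);
      vz[i] = vtz[i] + 0.5 * dt * (foz[i] + fz[i]);
    }
  }

  inline void apply_bc(int i) {
    // periodic x, y always
    if (x[i] >= Lx) x[i] -= Lx; else if (x[i] < 0) x[i] += Lx;
    if (y[i] >= Ly) y[i] -= Ly; else if (y[i] < 0) y[i] += Ly;
    bool reflect = wall && type[i] != SOLVENT;
    if (reflect) {
      // specular reflection = mirror transform; it must hit the whole
      // per-particle integrator state (position, current velocity, and the
      // stored half-step velocity and old force), or the second velocity
      // half-kick silently undoes the bounce
      if (z[i] < 0) {
        z[i] = -z[i];
        vz[i] = -vz[i]; vtz[i] = -vtz[i]; foz[i] = -foz[i];
      }
      if (z[i] >= Lz) {
        z[i] = 2 * Lz - z[i];
        vz[i] = -vz[i]; vtz[i] = -vtz[i]; foz[i] = -foz[i];
      }
      if (z[i] < 0) z[i] = 0;           // pathological overshoot
      if (z[i] >= Lz) z[i] = Lz * (1 - 1e-12);
    } else {
      if (z[i] >= Lz) z[i] -= Lz; else if (z[i] < 0) z[i] += Lz;
    }
  }

  // One reversible-bond update sweep: break pass then creation pass in
  // randomised particle order. Each association is checked once per sweep:
  // after a creation attempt both the chooser and the chosen inactive
  // partner forfeit their own turn, so an isolated pair forms a bond with
  // probability exactly p_pp per check (two-state Markov chain with rates
  // p_pp / p_break). Saturation (<= 1 bond per inactive particle) holds by
  // construction.
  void bond_update(double p_pp, double p_ps, double p_break) {
    // break pass
    for (int i = 0; i < n_chain; ++i) {
      int p = partner[i];
      if (p < 0) continue;
      if (type[p] == INACTIVE && p < i) continue;  // visit each pp bond once
      if (rng.unif() < p_break) {
        partner[i] = -1;
        if (type[p] == INACTIVE) partner[p] = -1;
      }
    }
    // creation pass over unbonded inactive chain particles, random order
    std::vector<int> cand;
    cand.reserve(n_chain);
    for (int i = 0; i < n_chain; ++i)
      if (type[i] == INACTIVE && partner[i] < 0) cand.push_back(i);
    for (int k = (int)cand.size() - 1; k > 0; --k)
      std::swap(cand[k], cand[rng.below(k + 1)]);
    build_cells();
    std::vector<int> elig;
    std::vector<char> attempted(n, 0);
    for (int idx : cand) {
      int i = idx;
      if (partner[i] >= 0) continue;   // bonded earlier in this sweep
      if (attempted[i]) continue;      // already checked as a partner
      elig.clear();
      int cx = (int)(x[i] / Lx * ncx); if (cx >= ncx) cx = ncx - 1;
      int cy = (int)(y[i] / Ly * ncy); if (cy >= ncy) cy = ncy - 1;
      int cz = (int)(z[i] / Lz * ncz); if (cz >= ncz) cz = ncz - 1;
      for (int dz = -1; dz <= 1; ++dz) {
        int az = cz + dz;
        if (zper && ncz > 1) az = (az + ncz) % ncz;
        if (az < 0 || az >= ncz) continue;
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx2 = -1; dx2 <= 1; ++dx2) {
            int ax = (cx + dx2 + ncx) % ncx, ay = (cy + dy + ncy) % ncy;
            int c2 = (az * ncy + ay) * ncx + ax;
            for (int j = head[c2]; j >= 0; j = nxt[j]) {
              if (j == i) continue;
              bool ok = (type[j] == WALL) ||
                        (type[j] == INACTIVE && partner[j] < 0 && !attempted[j]);
              if (!ok) continue;
              double ddx = wrap(x[i] - x[j], Lx), ddy = wrap(y[i] - y[j], Ly),
                     ddz = z[i] - z[j];
              if (zper) ddz = wrap(ddz, Lz);
              if (ddx * ddx + ddy * ddy + ddz * ddz < rc * rc)
                elig.push_back(j);
            }
          }
      }
      if (elig.empty()) continue;
      int j = elig[rng.below((int)elig.size())];
      double p = (type[j] == WALL) ? p_ps : p_pp;
      attempted[i] = 1;
      if (type[j] == INACTIVE) attempted[j] = 1;
      if (rng.unif() < p) {
        partner[i] = j;
        if (type[j] == INACTIVE) partner[j] = i;
      }
    }
  }

  double kinetic_T() const {
    double s = 0; int m = 0;
    for (int i = 0; i < n; ++i) {
      if (type[i] == WALL) continue;
      s += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      ++m;
    }
    return s / (3.0 * m);
  }
};

void init_sim(Sim &S, List params, uint64_t seed) {
  NumericVector box = params["box"];
  S.Lx = box[0]; S.Ly = box[1]; S.Lz = box[2];
  S.wall = as<bool>(params["wall"]);
  S.zper = !S.wall;
  S.a_rep = as<double>(params["a_rep"]);
  S.fric = as<double>(params["friction_gamma"]);
  S.kT = as<double>(params["kT"]);
  S.sigma = std::sqrt(2.0 * S.fric * S.kT);
  S.rc = as<double>(params["r_cut"]);
  S.dt = as<double>(params["dt"]);
  S.spring_k = as<double>(params["spring_k"]);
  double density = as<double>(params["density"]);
  int n_blocks = as<int>(params["n_blocks"]);
  int ipb = as<int>(params["inactive_per_block"]);
  int apb = as<int>(params["active_per_block"]);

  int n_chain = n_blocks * (ipb + apb);
  // wall lattice
  std::vector<double> wx, wy;
  if (S.wall) {
    double a = 1.0, dy = a * std::sqrt(3.0) / 2.0;
    int nrow = (int)std::floor(S.Ly / dy);
    double dyy = S.Ly / std::max(1, nrow);
    for (int r = 0; r < nrow; ++r) {
      int ncol = (int)std::floor(S.Lx / a);
      double dxx = S.Lx / std::max(1, ncol);
      for (int cc = 0; cc < ncol; ++cc) {
        wx.push_back(dxx * cc + (r % 2 ? dxx / 2 : 0.0));
        wy.push_back(dyy * r);
      }
    }
  }
  int n_wall = (int)wx.size();
  int n_total = (int)std::llround(density * S.Lx * S.Ly * S.Lz);
  int n_solvent = n_total - n_chain - n_wall;
  bool no_solvent = as<bool>(params["no_solvent"]);
  if (no_solvent) { n_solvent = 0; n_total = n_chain + n_wall; }
  if (n_solvent < 0) stop("box too small for chain at this density");
  S.n = n_total;
  S.n_chain = n_chain;
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.vx.assign(S.n, 0.0); S.vy.assign(S.n, 0.0); S.vz.assign(S.n, 0.0);
  S.fx.assign(S.n, 0.0); S.fy.assign(S.n, 0.0); S.fz.assign(S.n, 0.0);
  S.type.resize(S.n);
  S.partner.assign(S.n, -1);
  S.chain_next.assign(S.n, -1);

  // chain: random walk, step 0.7, kept off the walls. With a wall present
  // and init_near_wall set, the chain starts in the wall-adjacent half of
  // the box so the surface is within diffusive reach of every block on
  // desk-scale time scales (the published-scale chain is macroscopic and
  // always contacts the surface); a neutral full-height start is used for
  // null controls.
  bool near_wall = as<bool>(params["init_near_wall"]);
  double zmin = S.wall ? 1.0 : 0.0;
  double zmax = S.wall ? S.Lz - 1.0 : S.Lz;
  if (S.wall && near_wall) {
    zmax = std::max(4.0, 0.5 * S.Lz);
  } else if (S.wall) {
    // neutral start for null controls: central slab, clear of both walls,
    // so the fold-back walk does not compress blocks against a boundary
    zmin = S.Lz / 3.0;
    zmax = 2.0 * S.Lz / 3.0;
  }
  double px = S.rng.unif() * S.Lx, py = S.rng.unif() * S.Ly,
         pz = zmin + S.rng.unif() * (zmax - zmin);
  for (int i = 0; i < n_chain; ++i) {
    S.x[i] = px; S.y[i] = py; S.z[i] = pz;
    int in_block = i % (ipb + apb);
    S.type[i] = in_block < ipb ? INACTIVE : ACTIVE;
    if (i + 1 < n_chain) S.chain_next[i] = i + 1;
    // next bead: random-walk step, folded back at the z margins
    double th = std::acos(2 * S.rng.unif() - 1), ph = 6.283185307179586 * S.rng.unif();
    double qx = px + 0.7 * std::sin(th) * std::cos(ph);
    double qy = py + 0.7 * std::sin(th) * std::sin(ph);
    double qz = pz + 0.7 * std::cos(th);
    if (qx < 0) qx += S.Lx;
    if (qx >= S.Lx) qx -= S.Lx;
    if (qy < 0) qy += S.Ly;
    if (qy >= S.Ly) qy -= S.Ly;
    if (qz < zmin) qz = 2 * zmin - qz;
    if (qz > zmax) qz = 2 * zmax - qz;
    if (qz < zmin || qz > zmax) qz = 0.5 * (zmin + zmax);
    px = qx; py = qy; pz = qz;
  }
  // wall particles
  for (int w = 0; w < n_wall; ++w) {
    int i = n_chain + w;
    S.x[i] = wx[w]; S.y[i] = wy[w]; S.z[i] = 0.0;
    S.type[i] = WALL;
  }
  // solvent
  for (int sI = 0; sI < n_solvent; ++sI) {
    int i = n_chain + n_wall + sI;
    S.x[i] = S.rng.unif() * S.Lx;
    S.y[i] = S.rng.unif() * S.Ly;
    S.z[i] = S.rng.unif() * S.Lz;
    S.type[i] = SOLVENT;
  }
  // thermal velocities, zero net momentum over mobile particles
  double sx = 0, sy = 0, sz = 0; int m = 0;
  for (int i = 0; i < S.n; ++i) {
    if (S.type[i] == WALL) continue;
    S.vx[i] = S.rng.normal() * std::sqrt(S.kT);
    S.vy[i] = S.rng.normal() * std::sqrt(S.kT);
    S.vz[i] = S.rng.normal() * std::sqrt(S.kT);
    sx += S.vx[i]; sy += S.vy[i]; sz += S.vz[i]; ++m;
  }
  for (int i = 0; i < S.n; ++i) {
    if (S.type[i] == WALL) continue;
    S.vx[i] -= sx / m; S.vy[i] -= sy / m; S.vz[i] -= sz / m;
  }
}

} // namespace

// [[Rcpp::export]]
List dpd_engine(List params, int n_steps, double seed) {
  Sim S((uint64_t)seed * 2654435761ULL + 1ULL);
  init_sim(S, params, (uint64_t)seed);
  double p_pp = as<double>(params["p_bond_pp"]);
  double p_ps = as<double>(params["p_bond_ps"]);
  double p_break = as<double>(params["p_break"]);
  int check_interval = as<int>(params["check_interval"]);
  int snapshot_interval = as<int>(params["snapshot_interval"]);
  bool track_momentum = as<bool>(params["track_momentum"]);

  std::vector<NumericMatrix> snaps;
  std::vector<int> snap_steps;
  std::vector<double> temps;
  std::vector<int> n_pp, n_ps;
  double max_mom = 0.0;

  S.forces();
  for (int step = 1; step <= n_steps; ++step) {
    S.step();
    // stability guard
    if (step % 100 == 0) {
      double vmax = 0; int imax = 0;
      for (int i = 0; i < S.n; ++i) {
        double v2 = S.vx[i]*S.vx[i] + S.vy[i]*S.vy[i] + S.vz[i]*S.vz[i];
        if (v2 > vmax) { vmax = v2; imax = i; }
      }
      if (std::sqrt(vmax) * S.dt > S.rc)
        stop("integration unstable at step %d: particle %d (type %d) at z=%.3f has speed %.1f; reduce dt",
             step, imax, S.type[imax], S.z[imax], std::sqrt(vmax));
    }
    if (track_momentum) {
      double sx = 0, sy = 0, sz = 0;
      for (int i = 0; i < S.n; ++i) { sx += S.vx[i]; sy += S.vy[i]; sz += S.vz[i]; }
      double mom = std::sqrt(sx * sx + sy * sy + sz * sz);
      if (mom > max_mom) max_mom = mom;
    }
    if (check_interval > 0 && step % check_interval == 0) {
      S.bond_update(p_pp, p_ps, p_break);
      int cpp = 0, cps = 0;
      for (int i = 0; i < S.n_chain; ++i) {
        if (S.partner[i] < 0) continue;
        if (S.type[S.partner[i]] == WALL) ++cps;
        else if (S.partner[i] > i) ++cpp;
      }
      n_pp.push_back(cpp); n_ps.push_back(cps);
    }
    if (snapshot_interval > 0 && step % snapshot_interval == 0) {
      NumericMatrix m(S.n_chain, 3);
      for (int i = 0; i < S.n_chain; ++i) {
        m(i, 0) = S.x[i]; m(i, 1) = S.y[i]; m(i, 2) = S.z[i];
      }
      snaps.push_back(m);
      snap_steps.push_back(step);
      temps.push_back(S.kinetic_T());
    }
  }
  if (n_steps == 0) {
    NumericMatrix m(S.n_chain, 3);
    for (int i = 0; i < S.n_chain; ++i) {
      m(i, 0) = S.x[i]; m(i, 1) = S.y[i]; m(i, 2) = S.z[i];
    }
    snaps.push_back(m);
    snap_steps.push_back(0);
    temps.push_back(S.kinetic_T());
  }
  IntegerVector types(S.n_chain);
  for (int i = 0; i < S.n_chain; ++i) types[i] = S.type[i];
  return List::create(
    _["snapshots"] = wrap(snaps),
    _["snap_steps"] = wrap(snap_steps),
    _["temps"] = wrap(temps),
    _["chain_types"] = types,
    _["n_particles"] = S.n,
    _["bonds_pp"] = wrap(n_pp),
    _["bonds_ps"] = wrap(n_ps),
    _["max_momentum"] = max_mom,
    _["final_temp"] = S.kinetic_T());
}

// Two isolated inactive particles held at fixed separation inside r_cut:
// repeated bond_update sweeps through the real engine code path. Returns the
// per-check bonded indicator, whose mean approaches p_on / (p_on + p_off).
// [[Rcpp::export]]
IntegerVector bond_kinetics_toy(double p_on, double p_off, int n_checks,
                                double seed) {
  Sim S((uint64_t)seed * 2654435761ULL + 17ULL);
  S.Lx = S.Ly = S.Lz = 5.0; S.wall = false; S.zper = true;
  S.a_rep = 0; S.fric = 0; S.kT = 1; S.sigma = 0; S.rc = 1.0; S.dt = 0.01;
  S.spring_k = 0;
  S.n = 2; S.n_chain = 2;
  S.x = {1.0, 1.5}; S.y = {1.0, 1.0}; S.z = {1.0, 1.0};
  S.vx.assign(2, 0); S.vy.assign(2, 0); S.vz.assign(2, 0);
  S.fx.assign(2, 0); S.fy.assign(2, 0); S.fz.assign(2, 0);
  S.type = {INACTIVE, INACTIVE};
  S.partner.assign(2, -1);
  S.chain_next.assign(2, -1);
  IntegerVector bonded(n_checks);
  for (int c = 0; c < n_checks; ++c) {
    S.bond_update(p_on, p_on, p_off);
    bonded[c] = S.partner[0] >= 0 ? 1 : 0;
  }
  return bonded;
}
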