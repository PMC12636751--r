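// Core force field and overdamped integrator for the 2-D bead-spring cell.
//
// Conventions shared with the R side:
//   roles:      0 = membrane, 1 = nuclear, 2 = actin_shaft, 3 = actin_head
//   bond kinds: 0 = membrane, 1 = nuclear, 2 = filament, 3 = anchor
//   indices arriving from R are 0-based (converted in the R wrappers).
//
// Pair interactions:
//   membrane x actin pairs: WCA core (eps_rep) + attractive tail of depth U3,
//     flat below 2^(1/6) sigma, shifted Lennard-Jones up to r_cut_attr,
//     shifted so the energy is continuous (zero) at the cutoff.
//   all other non-bonded pairs: WCA (eps_rep).
//   directly bonded pairs are excluded from non-bonded terms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double TWO_SIXTH = 1.1224620483093730;  // 2^(1/6)

// ---- internal RNG ----------------------------------------------------------
// xoshiro256++ seeded via splitmix64 from the user seed.  The dynamics loop
// owns its generator state so trajectories are a pure function of the seed,
// independent of R's global RNG, and replicates never share a stream.

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    have_spare = false;
    spare = 0.0;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare;
  double spare;
  inline double rnorm() {  // Box-Muller with cached spare
    if (have_spare) { have_spare = false; return spare; }
    double u1 = runif(), u2 = runif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// WCA repulsion: energy and force factor ff such that F_on_i = ff * (ri - rj)
static inline void wca_ef(double r2, double sigma, double eps,
                          double &e, double &ff) {
  double rc = TWO_SIXTH * sigma;
  if (r2 >= rc * rc) { e = 0.0; ff = 0.0; return; }
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  e = 4.0 * eps * (s12 - s6) + eps;
  ff = 24.0 * eps * (2.0 * s12 - s6) / r2;
}

// Attractive tail of depth U3 (LJ beyond the minimum, flat below), shifted to
// vanish at r_cut. Returns energy and force factor as above.
static inline void attr_tail_ef(double r2, double sigma, double U3,
                                double r_cut, double &e, double &ff) {
  if (r2 >= r_cut * r_cut) { e = 0.0; ff = 0.0; return; }
  double sc2 = sigma * sigma / (r_cut * r_cut);
  double sc6 = sc2 * sc2 * sc2;
  double vshift = 4.0 * U3 * (sc6 * sc6 - sc6);  // LJ value at the cutoff
  double rmin = TWO_SIXTH * sigma;
  if (r2 < rmin * rmin) {
    e = -U3 - vshift;
    ff = 0.0;
    return;
  }
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  e = 4.0 * U3 * (s12 - s6) - vshift;
  ff = 24.0 * U3 * (2.0 * s12 - s6) / r2;
}

struct Topo {
  int n;
  std::vector<int> role;
  std::vector<int> bi, bj, bkind;
  std::vector<double> br0, bk;
  std::vector<int> ai, aj, ak;
  std::vector<double> atheta0, akap, ac0, as0;  // cos/sin of theta0 cached
  // sorted adjacency for bonded-pair exclusion
  std::vector<std::vector<int>> excl;
  void build_excl() {
    excl.assign(n, {});
    for (size_t b = 0; b < bi.size(); ++b) {
      excl[bi[b]].push_back(bj[b]);
      excl[bj[b]].push_back(bi[b]);
    }
    for (int i = 0; i < n; ++i) std::sort(excl[i].begin(), excl[i].end());
  }
  bool excluded(int i, int j) const {
    const std::vector<int> &e = excl[i];
    return std::binary_search(e.begin(), e.end(), j);
  }
};

struct PairPars {
  double sigma, eps_rep, U3, r_cut;
  bool heads_only;
};

static inline bool is_attract_pair(int ri, int rj, bool heads_only) {
  int actin_min = heads_only ? 3 : 2;
  if (ri == 0 && rj >= actin_min) return true;
  if (rj == 0 && ri >= actin_min) return true;
  return false;
}

// ---- neighbor list ---------------------------------------------------------

struct NeighborList {
  std::vector<int> pi, pj;     // candidate pairs within r_list at build time
  std::vector<char> pattr;     // 1 if the pair takes the attraction potential
  std::vector<double> x0, y0;  // positions at build time
  double r_list;
  bool heads_only = false;

  // Two-tier candidate list: attraction-capable pairs are kept out to
  // rl (attraction cutoff + skin); all other pairs only need the WCA
  // contact distance + skin (rl_rep).  Cells are sized by the larger tier.
  void build_cells(const std::vector<double> &x, const std::vector<double> &y,
                   const Topo &topo, double rl, double rl_rep) {
    r_list = rl;
    int n = topo.n;
    pi.clear(); pj.clear(); pattr.clear();
    x0.assign(x.begin(), x.end());
    y0.assign(y.begin(), y.end());
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    if (!std::isfinite(xmin) || !std::isfinite(xmax) ||
        !std::isfinite(ymin) || !std::isfinite(ymax))
      stop("numerical instability: non-finite positions while building neighbor list");
    double cl = rl;
    // cells narrower than the list radius would break the 9-cell scan, so
    // widths are >= rl; the count cap only widens cells further (still safe)
    int ncx = std::max(1, std::min(2048, (int)std::floor((xmax - xmin) / cl)));
    int ncy = std::max(1, std::min(2048, (int)std::floor((ymax - ymin) / cl)));
    double wx = (xmax - xmin) / ncx + 1e-12, wy = (ymax - ymin) / ncy + 1e-12;
    std::vector<int> head(ncx * ncy, -1), nxt(n, -1), cellof(n);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(ncx - 1, std::max(0, (int)((x[i] - xmin) / wx)));
      int cy = std::min(ncy - 1, std::max(0, (int)((y[i] - ymin) / wy)));
      int c = cy * ncx + cx;
      cellof[i] = c;
      nxt[i] = head[c];
      head[c] = i;
    }
    double rl2 = rl * rl, rr2 = rl_rep * rl_rep;
    for (int cy = 0; cy < ncy; ++cy) {
      for (int cx = 0; cx < ncx; ++cx) {
        for (int i = head[cy * ncx + cx]; i != -1; i = nxt[i]) {
          for (int dy = -1; dy <= 1; ++dy) {
            int oy = cy + dy;
            if (oy < 0 || oy >= ncy) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int ox = cx + dx;
              if (ox < 0 || ox >= ncx) continue;
              for (int j = head[oy * ncx + ox]; j != -1; j = nxt[j]) {
                if (j <= i) continue;
                double ddx = x[i] - x[j], ddy = y[i] - y[j];
                double d2 = ddx * ddx + ddy * ddy;
                if (d2 >= rl2) continue;
                bool attr = is_attract_pair(topo.role[i], topo.role[j],
                                            heads_only);
                if (!attr && d2 >= rr2) continue;
                if (topo.excluded(i, j)) continue;
                pi.push_back(i); pj.push_back(j);
                pattr.push_back(attr);
              }
            }
          }
        }
      }
    }
  }

  void build_brute(const std::vector<double> &x, const std::vector<double> &y,
                   const Topo &topo, double rl) {
    r_list = rl;
    int n = topo.n;
    pi.clear(); pj.clear(); pattr.clear();
    x0.assign(x.begin(), x.end());
    y0.assign(y.begin(), y.end());
    double rl2 = rl * rl;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double ddx = x[i] - x[j], ddy = y[i] - y[j];
        if (ddx * ddx + ddy * ddy >= rl2) continue;
        if (topo.excluded(i, j)) continue;
        pi.push_back(i); pj.push_back(j);
        pattr.push_back(is_attract_pair(topo.role[i], topo.role[j],
                                        heads_only));
      }
  }

  double max_disp2(const std::vector<double> &x,
                   const std::vector<double> &y) const {
    double m = 0.0;
    for (size_t i = 0; i < x.size(); ++i) {
      double dx = x[i] - x0[i], dy = y[i] - y0[i];
      m = std::max(m, dx * dx + dy * dy);
    }
    return m;
  }
};

// ---- force/energy evaluation ----------------------------------------------

// Accumulates forces and the energy breakdown
// e[0]=spring e[1]=bending e[2]=attraction e[3]=excluded_volume
static void eval_forces(const std::vector<double> &x,
                        const std::vector<double> &y, const Topo &topo,
                        const PairPars &pp, const NeighborList &nl,
                        std::vector<double> &fx, std::vector<double> &fy,
                        double e[4]) {
  int n = topo.n;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  e[0] = e[1] = e[2] = e[3] = 0.0;

  // bonds
  for (size_t b = 0; b < topo.bi.size(); ++b) {
    int i = topo.bi[b], j = topo.bj[b];
    double dx = x[i] - x[j], dy = y[i] - y[j];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < 1e-12)
      stop("degenerate geometry: coincident bonded beads %d and %d", i + 1, j + 1);
    double d = r - topo.br0[b];
    e[0] += 0.5 * topo.bk[b] * d * d;
    double ff = -topo.bk[b] * d / r;
    fx[i] += ff * dx; fy[i] += ff * dy;
    fx[j] -= ff * dx; fy[j] -= ff * dy;
  }

  // angles: theta = signed angle from u = ri - rj to v = rk - rj
  for (size_t a = 0; a < topo.ai.size(); ++a) {
    int i = topo.ai[a], j = topo.aj[a], k = topo.ak[a];
    double ux = x[i] - x[j], uy = y[i] - y[j];
    double vx = x[k] - x[j], vy = y[k] - y[j];
    double u2 = ux * ux + uy * uy, v2 = vx * vx + vy * vy;
    if (u2 < 1e-24 || v2 < 1e-24)
      stop("degenerate geometry: coincident beads in angle at bead %d", j + 1);
    double cross = ux * vy - uy * vx, dot = ux * vx + uy * vy;
    // sin/cos of the vertex angle without atan2; theta0 terms are cached
    double inv = 1.0 / std::sqrt(u2 * v2);
    double sth = cross * inv, cth = dot * inv;
    double kap = topo.akap[a];
    e[1] += kap * (1.0 - (cth * topo.ac0[a] + sth * topo.as0[a]));
    double dEdth = kap * (sth * topo.ac0[a] - cth * topo.as0[a]);
    // theta = phi_v - phi_u; F_a = -dE/dtheta * dtheta/dr_a
    double gix = -dEdth * uy / u2, giy = dEdth * ux / u2;
    double gkx = dEdth * vy / v2, gky = -dEdth * vx / v2;
    fx[i] += gix; fy[i] += giy;
    fx[k] += gkx; fy[k] += gky;
    fx[j] -= gix + gkx; fy[j] -= giy + gky;
  }

  // non-bonded pairs
  double rcut2 = pp.r_cut * pp.r_cut;
  double rwca = TWO_SIXTH * pp.sigma;
  double rwca2 = rwca * rwca;
  for (size_t p = 0; p < nl.pi.size(); ++p) {
    int i = nl.pi[p], j = nl.pj[p];
    double dx = x[i] - x[j], dy = y[i] - y[j];
    double r2 = dx * dx + dy * dy;
    bool attr = nl.pattr[p];
    if (attr) {
      if (r2 >= rcut2) continue;
      if (r2 < 1e-24)
        stop("degenerate geometry: coincident beads %d and %d", i + 1, j + 1);
      double ew, fw, et, ft;
      wca_ef(r2, pp.sigma, pp.eps_rep, ew, fw);
      attr_tail_ef(r2, pp.sigma, pp.U3, pp.r_cut, et, ft);
      e[2] += ew + et;
      double ff = fw + ft;
      fx[i] += ff * dx; fy[i] += ff * dy;
      fx[j] -= ff * dx; fy[j] -= ff * dy;
    } else {
      if (r2 >= rwca2) continue;
      if (r2 < 1e-24)
        stop("degenerate geometry: coincident beads %d and %d", i + 1, j + 1);
      double ew, fw;
      wca_ef(r2, pp.sigma, pp.eps_rep, ew, fw);
      e[3] += ew;
      fx[i] += fw * dx; fy[i] += fw * dy;
      fx[j] -= fw * dx; fy[j] -= fw * dy;
    }
  }
  (void)n;
}

// ---- R interface helpers ---------------------------------------------------

static Topo topo_from_r(int n, IntegerVector roles, List bonds, List angles) {
  Topo t;
  t.n = n;
  t.role.assign(roles.begin(), roles.end());
  IntegerVector bi = bonds["i"], bj = bonds["j"], bkind = bonds["kind"];
  NumericVector br0 = bonds["rest_length"], bk = bonds["stiffness"];
  t.bi.assign(bi.begin(), bi.end());
  t.bj.assign(bj.begin(), bj.end());
  t.bkind.assign(bkind.begin(), bkind.end());
  t.br0.assign(br0.begin(), br0.end());
  t.bk.assign(bk.begin(), bk.end());
  IntegerVector ai = angles["i"], aj = angles["j"], ak = angles["k"];
  NumericVector ath0 = angles["theta0"], akap = angles["stiffness"];
  t.ai.assign(ai.begin(), ai.end());
  t.aj.assign(aj.begin(), aj.end());
  t.ak.assign(ak.begin(), ak.end());
  t.atheta0.assign(ath0.begin(), ath0.end());
  t.akap.assign(akap.begin(), akap.end());
  t.ac0.resize(t.atheta0.size());
  t.as0.resize(t.atheta0.size());
  for (size_t a = 0; a < t.atheta0.size(); ++a) {
    t.ac0[a] = std::cos(t.atheta0[a]);
    t.as0[a] = std::sin(t.atheta0[a]);
  }
  t.build_excl();
  return t;
}

static PairPars pairpars_from_r(List pp) {
  PairPars p;
  p.sigma = as<double>(pp["sigma"]);
  p.eps_rep = as<double>(pp["eps_rep"]);
  p.U3 = as<double>(pp["U3"]);
  p.r_cut = as<double>(pp["r_cut_attr"]);
  p.heads_only = as<bool>(pp["attract_heads_only"]);
  return p;
}

// [[Rcpp::export]]
List forces_energy_cpp(NumericMatrix pos, IntegerVector roles, List bonds,
                       List angles, List pairpars, bool brute) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  Topo topo = topo_from_r(n, roles, bonds, angles);
  PairPars pp = pairpars_from_r(pairpars);
  NeighborList nl;
  nl.heads_only = pp.heads_only;
  double rl = std::max(pp.r_cut, TWO_SIXTH * pp.sigma);
  if (brute)
    nl.build_brute(x, y, topo, rl);
  else
    nl.build_cells(x, y, topo, rl, TWO_SIXTH * pp.sigma);
  std::vector<double> fx(n), fy(n);
  double e[4];
  eval_forces(x, y, topo, pp, nl, fx, fy, e);
  NumericMatrix F(n, 2);
  for (int i = 0; i < n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; }
  return List::create(_["forces"] = F, _["spring"] = e[0], _["bending"] = e[1],
                      _["attraction"] = e[2], _["excluded_volume"] = e[3],
                      _["total"] = e[0] + e[1] + e[2] + e[3],
                      _["n_pairs"] = (int)nl.pi.size());
}

// [[Rcpp::export]]
List run_dynamics_cpp(NumericMatrix pos, IntegerVector roles, List bonds,
                      List angles, List pairpars,
                      IntegerVector filament_terminal_bond,  // 0-based bond index per filament
                      NumericVector terminal_rest_cap,       // max rest length per terminal bond
                      int n_steps, double dt, double kT, double gamma,
                      int record_every, double growth_rate,
                      double growth_increment, double skin, int check_every,
                      int seed) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  Topo topo = topo_from_r(n, roles, bonds, angles);
  PairPars pp = pairpars_from_r(pairpars);
  int n_fil = filament_terminal_bond.size();
  Xoshiro rng((uint64_t)(unsigned int)seed);

  double rl = std::max(pp.r_cut, TWO_SIXTH * pp.sigma) + skin;
  double rl_rep = TWO_SIXTH * pp.sigma + skin;
  NeighborList nl;
  nl.heads_only = pp.heads_only;
  nl.build_cells(x, y, topo, rl, rl_rep);

  std::vector<double> fx(n), fy(n);
  double e[4];
  double mob = dt / gamma;
  double noise_amp = (kT > 0.0) ? std::sqrt(2.0 * kT * dt / gamma) : 0.0;
  double half_skin2 = 0.25 * skin * skin;

  int n_frames = n_steps / record_every + 1;
  List frames_pos(n_frames), frames_r0(n_frames);
  NumericVector frame_time(n_frames);
  NumericMatrix frame_energy(n_frames, 5);
  int frame = 0;

  auto record = [&](double t_now) {
    eval_forces(x, y, topo, pp, nl, fx, fy, e);
    NumericMatrix P(n, 2);
    for (int i = 0; i < n; ++i) { P(i, 0) = x[i]; P(i, 1) = y[i]; }
    frames_pos[frame] = P;
    frames_r0[frame] = NumericVector(topo.br0.begin(), topo.br0.end());
    frame_time[frame] = t_now;
    frame_energy(frame, 0) = e[0]; frame_energy(frame, 1) = e[1];
    frame_energy(frame, 2) = e[2]; frame_energy(frame, 3) = e[3];
    frame_energy(frame, 4) = e[0] + e[1] + e[2] + e[3];
    ++frame;
  };

  auto integrity_check = [&](int step) {
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]))
        stop("numerical instability at step %d: non-finite position of bead %d",
             step, i + 1);
    for (size_t b = 0; b < topo.bi.size(); ++b) {
      if (topo.bkind[b] != 0) continue;  // membrane bonds only
      int i = topo.bi[b], j = topo.bj[b];
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double r2 = dx * dx + dy * dy;
      double lim = 3.0 * topo.br0[b];
      if (r2 > lim * lim)
        stop("numerical instability at step %d: membrane bond %d-%d exceeds 3x rest length",
             step, i + 1, j + 1);
    }
  };

  record(0.0);
  for (int step = 1; step <= n_steps; ++step) {
    if (nl.max_disp2(x, y) > half_skin2) nl.build_cells(x, y, topo, rl, rl_rep);
    eval_forces(x, y, topo, pp, nl, fx, fy, e);
    if (noise_amp > 0.0) {
      for (int i = 0; i < n; ++i) {
        x[i] += fx[i] * mob + noise_amp * rng.rnorm();
        y[i] += fy[i] * mob + noise_amp * rng.rnorm();
      }
    } else {
      for (int i = 0; i < n; ++i) {
        x[i] += fx[i] * mob;
        y[i] += fy[i] * mob;
      }
    }
    if (growth_rate > 0.0) {
      for (int f = 0; f < n_fil; ++f) {
        if (rng.runif() < growth_rate) {
          int b = filament_terminal_bond[f];
          if (topo.br0[b] + growth_increment <= terminal_rest_cap[f])
            topo.br0[b] += growth_increment;
        }
      }
    }
    if (step % check_every == 0) integrity_check(step);
    if (step % record_every == 0) {
      integrity_check(step);
      if (nl.max_disp2(x, y) > half_skin2) nl.build_cells(x, y, topo, rl, rl_rep);
      record(step * dt);
    }
  }

  return List::create(_["positions"] = frames_pos, _["rest_lengths"] = frames_r0,
                      _["times"] = frame_time, _["energies"] = frame_energy);
}
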