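// Compiled cores: lattice Monte Carlo gating model, backward-Euler cable
// integrator with Hines elimination, and the bidirectional coupling loop.
#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double KB_EV = 8.617333262e-5;   // Boltzmann constant, eV/K
static const double T_REF_K = 303.15;         // reference temperature for energy units
// e0 * 1 mV expressed in units of k_B * T_ref
static const double FV_PER_MV = 1e-3 / (KB_EV * T_REF_K);

// [[Rcpp::export]]
double cpp_fv_per_mv() { return FV_PER_MV; }

// ------------------------------------------------------------------ RNG ----
// PCG32: small, fast, reproducible across platforms; state is carried in the
// patch object so every stochastic operation draws from the patch's own stream.
struct Pcg32 {
  uint64_t state = 0, inc = 1;
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xs >> rot) | (xs << ((-rot) & 31u));
  }
  void seed(uint64_t s, uint64_t seq) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += s; next();
  }
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  int below(int n) { return (int)(unif() * n); }
};

static IntegerVector pack_rng(const Pcg32& r) {
  IntegerVector out(4);
  std::memcpy(&out[0], &r.state, 8);
  std::memcpy(&out[2], &r.inc, 8);
  return out;
}
static Pcg32 unpack_rng(const IntegerVector& v) {
  Pcg32 r;
  std::memcpy(&r.state, &v[0], 8);
  std::memcpy(&r.inc, &v[2], 8);
  return r;
}

// [[Rcpp::export]]
IntegerVector cpp_rng_init(int seed) {
  Pcg32 r;
  r.seed((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 1442695040888963407ULL,
         (uint64_t)(uint32_t)seed);
  return pack_rng(r);
}

// ----------------------------------------------------------- MC lattice ----
// Grid codes: 0 = saturated lipid, 1 = unsaturated lipid, k+2 = channel k
// (0-based). Directions: 0:+x, 1:+y, 2:-x, 3:-y; sensor s of a channel with
// orientation o faces direction (s + o) mod 4.
struct MCParams {
  double eps[2], q[2];      // per selectivity (0 = Na, 1 = K)
  double jl[2][2];          // lipid-lipid coupling
  double jsl[2][2];         // [sensor state][lipid species]
  double jss;               // sensor-sensor coupling within a channel
  double beta;              // T_ref / T_abs
  double vm;                // mV
  double gamma[2], erev[2]; // pS, mV
  double mix[4];            // move mix: sensor, swap, translate, rotate
};

static MCParams parse_mc_params(const List& par) {
  MCParams p;
  NumericVector eps = par["eps_g"], q = par["q_gate"],
                gamma = par["gamma"], erev = par["e_rev"], mix = par["move_mix"];
  NumericMatrix jl = par["j_lipid"], jsl = par["j_sensor_lipid"];
  for (int i = 0; i < 2; ++i) {
    p.eps[i] = eps[i]; p.q[i] = q[i]; p.gamma[i] = gamma[i]; p.erev[i] = erev[i];
    for (int j = 0; j < 2; ++j) { p.jl[i][j] = jl(i, j); p.jsl[i][j] = jsl(i, j); }
  }
  p.jss = as<double>(par["j_sensor_sensor"]);
  p.beta = T_REF_K / (as<double>(par["temperature_c"]) + 273.15);
  p.vm = as<double>(par["v_m"]);
  for (int i = 0; i < 4; ++i) p.mix[i] = mix[i];
  return p;
}

struct MCState {
  int L = 0, ncha = 0;
  std::vector<int> grid;              // L*L site codes
  std::vector<int> sel, cx, cy, ori;  // per channel
  std::vector<int> sens;              // ncha x 4, row-major
  Pcg32 rng;
  double H = 0.0;                     // incrementally tracked energy

  int idx(int x, int y) const { return x + y * L; }
  void nbr(int x, int y, int d, int& nx, int& ny) const {
    nx = x; ny = y;
    switch (d) {
      case 0: nx = (x + 1) % L; break;
      case 1: ny = (y + 1) % L; break;
      case 2: nx = (x + L - 1) % L; break;
      default: ny = (y + L - 1) % L; break;
    }
  }
};

static MCState parse_mc_state(const IntegerMatrix& grid, const List& channels,
                              const IntegerVector& rng) {
  MCState s;
  s.L = grid.nrow();
  if (grid.ncol() != s.L) stop("grid must be square");
  s.grid.assign(grid.begin(), grid.end()); // column-major: idx = row + col*L
  IntegerVector sel = channels["sel"], cx = channels["x"], cy = channels["y"],
                ori = channels["orient"];
  IntegerMatrix sen = channels["sensors"];
  s.ncha = sel.size();
  s.sel.assign(sel.begin(), sel.end());
  s.cx.assign(cx.begin(), cx.end());
  s.cy.assign(cy.begin(), cy.end());
  s.ori.assign(ori.begin(), ori.end());
  s.sens.resize(s.ncha * 4);
  for (int c = 0; c < s.ncha; ++c)
    for (int k = 0; k < 4; ++k) s.sens[c * 4 + k] = sen(c, k);
  s.rng = unpack_rng(rng);
  return s;
}

// energy of the unordered bond between site (x,y) and its neighbour in
// direction d (counted once)
static double bond_energy(const MCState& s, const MCParams& p, int x, int y, int d) {
  int nx, ny; s.nbr(x, y, d, nx, ny);
  int c1 = s.grid[s.idx(x, y)], c2 = s.grid[s.idx(nx, ny)];
  bool ch1 = c1 >= 2, ch2 = c2 >= 2;
  if (ch1 && ch2) return 0.0;
  if (!ch1 && !ch2) return p.jl[c1][c2];
  if (ch1) {
    int ci = c1 - 2;
    int sidx = ((d - s.ori[ci]) % 4 + 4) % 4;
    return p.jsl[s.sens[ci * 4 + sidx]][c2];
  }
  int ci = c2 - 2;
  int dback = (d + 2) % 4;
  int sidx = ((dback - s.ori[ci]) % 4 + 4) % 4;
  return p.jsl[s.sens[ci * 4 + sidx]][c1];
}

static double gating_energy_channel(const MCState& s, const MCParams& p, int c) {
  int nact = 0;
  for (int k = 0; k < 4; ++k) nact += s.sens[c * 4 + k];
  double h = nact * (p.eps[s.sel[c]] - p.q[s.sel[c]] * p.vm * FV_PER_MV);
  h += p.jss * 0.5 * nact * (nact - 1);
  return h;
}

static double mc_total_energy(const MCState& s, const MCParams& p) {
  double H = 0.0;
  for (int y = 0; y < s.L; ++y)
    for (int x = 0; x < s.L; ++x) {
      H += bond_energy(s, p, x, y, 0);
      H += bond_energy(s, p, x, y, 1);
    }
  for (int c = 0; c < s.ncha; ++c) H += gating_energy_channel(s, p, c);
  return H;
}

// sum of the (up to 4) bond energies touching a site
static double site_bonds(const MCState& s, const MCParams& p, int x, int y) {
  double h = 0.0;
  for (int d = 0; d < 4; ++d) h += bond_energy(s, p, x, y, d);
  return h;
}

// bonds touching either of two adjacent sites, shared bond counted once
static double pair_bonds(const MCState& s, const MCParams& p,
                         int xa, int ya, int dab) {
  int xb, yb; s.nbr(xa, ya, dab, xb, yb);
  return site_bonds(s, p, xa, ya) + site_bonds(s, p, xb, yb)
       - bond_energy(s, p, xa, ya, dab);
}

static bool metropolis(Pcg32& rng, double dE, double beta) {
  if (dE <= 0.0) return true;
  return rng.unif() < std::exp(-dE * beta);
}

// one sweep: L^2 attempted moves
static void mc_sweep_core(MCState& s, const MCParams& p) {
  int nAttempt = s.L * s.L;
  double c0 = p.mix[0], c1 = c0 + p.mix[1], c2 = c1 + p.mix[2];
  for (int a = 0; a < nAttempt; ++a) {
    double u = s.rng.unif();
    if (u < c0) { // ---- sensor flip
      if (s.ncha == 0) continue;
      int ci = s.rng.below(s.ncha), k = s.rng.below(4);
      int old = s.sens[ci * 4 + k], nw = 1 - old;
      int nact_others = 0;
      for (int j = 0; j < 4; ++j) if (j != k) nact_others += s.sens[ci * 4 + j];
      double dE = (nw - old) * (p.eps[s.sel[ci]] - p.q[s.sel[ci]] * p.vm * FV_PER_MV)
                + p.jss * nact_others * (nw - old);
      int d = (k + s.ori[ci]) % 4;
      int nx, ny; s.nbr(s.cx[ci], s.cy[ci], d, nx, ny);
      int cn = s.grid[s.idx(nx, ny)];
      if (cn < 2) dE += p.jsl[nw][cn] - p.jsl[old][cn];
      if (metropolis(s.rng, dE, p.beta)) {
        s.sens[ci * 4 + k] = nw;
        s.H += dE;
      }
    } else if (u < c1) { // ---- lipid swap (Kawasaki)
      int x = s.rng.below(s.L), y = s.rng.below(s.L), d = s.rng.below(4);
      int nx, ny; s.nbr(x, y, d, nx, ny);
      int ca = s.grid[s.idx(x, y)], cb = s.grid[s.idx(nx, ny)];
      if (ca >= 2 || cb >= 2 || ca == cb) continue; // reject / no-op
      double before = pair_bonds(s, p, x, y, d);
      s.grid[s.idx(x, y)] = cb; s.grid[s.idx(nx, ny)] = ca;
      double after = pair_bonds(s, p, x, y, d);
      if (metropolis(s.rng, after - before, p.beta)) {
        s.H += after - before;
      } else {
        s.grid[s.idx(x, y)] = ca; s.grid[s.idx(nx, ny)] = cb;
      }
    } else if (u < c2) { // ---- channel translate
      if (s.ncha == 0) continue;
      int ci = s.rng.below(s.ncha), d = s.rng.below(4);
      int x = s.cx[ci], y = s.cy[ci];
      int nx, ny; s.nbr(x, y, d, nx, ny);
      int cb = s.grid[s.idx(nx, ny)];
      if (cb >= 2) continue; // channel-channel: rejected outright
      double before = pair_bonds(s, p, x, y, d);
      s.grid[s.idx(nx, ny)] = ci + 2; s.grid[s.idx(x, y)] = cb;
      s.cx[ci] = nx; s.cy[ci] = ny;
      double after = pair_bonds(s, p, x, y, d);
      if (metropolis(s.rng, after - before, p.beta)) {
        s.H += after - before;
      } else {
        s.grid[s.idx(x, y)] = ci + 2; s.grid[s.idx(nx, ny)] = cb;
        s.cx[ci] = x; s.cy[ci] = y;
      }
    } else { // ---- channel rotate +/-90
      if (s.ncha == 0) continue;
      int ci = s.rng.below(s.ncha);
      int dr = (s.rng.unif() < 0.5) ? 1 : 3;
      double before = site_bonds(s, p, s.cx[ci], s.cy[ci]);
      int oo = s.ori[ci];
      s.ori[ci] = (oo + dr) % 4;
      double after = site_bonds(s, p, s.cx[ci], s.cy[ci]);
      if (metropolis(s.rng, after - before, p.beta)) {
        s.H += after - before;
      } else {
        s.ori[ci] = oo;
      }
    }
  }
}

static void mc_count_open(const MCState& s, int& nNa, int& nK) {
  nNa = 0; nK = 0;
  for (int c = 0; c < s.ncha; ++c) {
    int na = s.sens[c * 4] + s.sens[c * 4 + 1] + s.sens[c * 4 + 2] + s.sens[c * 4 + 3];
    if (na == 4) { if (s.sel[c] == 0) ++nNa; else ++nK; }
  }
}

static double mc_current_pA(const MCState& s, const MCParams& p) {
  int nNa, nK; mc_count_open(s, nNa, nK);
  return (nNa * p.gamma[0] * (p.vm - p.erev[0])
        + nK  * p.gamma[1] * (p.vm - p.erev[1])) * 1e-3;
}

static List mc_state_out(const MCState& s) {
  IntegerMatrix grid(s.L, s.L);
  std::copy(s.grid.begin(), s.grid.end(), grid.begin());
  IntegerMatrix sen(s.ncha, 4);
  for (int c = 0; c < s.ncha; ++c)
    for (int k = 0; k < 4; ++k) sen(c, k) = s.sens[c * 4 + k];
  List channels = List::create(
    _["sel"] = IntegerVector(s.sel.begin(), s.sel.end()),
    _["x"] = IntegerVector(s.cx.begin(), s.cx.end()),
    _["y"] = IntegerVector(s.cy.begin(), s.cy.end()),
    _["orient"] = IntegerVector(s.ori.begin(), s.ori.end()),
    _["sensors"] = sen);
  return List::create(_["grid"] = grid, _["channels"] = channels,
                      _["rng"] = pack_rng(s.rng), _["energy"] = s.H);
}

// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix grid, List channels, IntegerVector rng,
                        List par) {
  MCState s = parse_mc_state(grid, channels, rng);
  return mc_total_energy(s, parse_mc_params(par));
}

// [[Rcpp::export]]
List cpp_mc_run(IntegerMatrix grid, List channels, IntegerVector rng, List par,
                int n_sweeps, int record_every, bool record_sensors) {
  MCState s = parse_mc_state(grid, channels, rng);
  MCParams p = parse_mc_params(par);
  s.H = mc_total_energy(s, p);
  int nrec = (record_every > 0) ? n_sweeps / record_every : 0;
  int ncol = record_sensors ? 7 : 6;
  NumericMatrix obs(nrec, ncol);
  int row = 0;
  for (int sw = 1; sw <= n_sweeps; ++sw) {
    mc_sweep_core(s, p);
    if (record_every > 0 && sw % record_every == 0 && row < nrec) {
      int nNa, nK; mc_count_open(s, nNa, nK);
      int nact = 0;
      for (size_t i = 0; i < s.sens.size(); ++i) nact += s.sens[i];
      obs(row, 0) = sw;
      obs(row, 1) = nNa;
      obs(row, 2) = nK;
      obs(row, 3) = mc_current_pA(s, p);
      obs(row, 4) = s.H;
      obs(row, 5) = nact;
      if (record_sensors) {
        int mask = 0; // sensor bitmask of channel 0 (exact-enumeration tests)
        if (s.ncha > 0)
          for (int k = 0; k < 4; ++k) mask |= s.sens[k] << k;
        obs(row, 6) = mask;
      }
      ++row;
    }
  }
  List out = mc_state_out(s);
  out["obs"] = obs;
  return out;
}

// ------------------------------------------------------------ cable HH -----
// Units: mV, ms, nA, uS, nF. Classic squid HH rate functions on the modern
// (-65 mV rest) voltage scale; rates scaled by phi = q10^((T - T_base)/10).
static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1), guarded near x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - 0.5 * x / y);
  return x / (std::exp(x / y) - 1.0);
}
static inline void hh_rates(double v, double* a, double* b) {
  a[0] = 0.1 * vtrap(-(v + 40.0), 10.0);          // m
  b[0] = 4.0 * std::exp(-(v + 65.0) / 18.0);
  a[1] = 0.07 * std::exp(-(v + 65.0) / 20.0);     // h
  b[1] = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  a[2] = 0.01 * vtrap(-(v + 55.0), 10.0);         // n
  b[2] = 0.125 * std::exp(-(v + 65.0) / 80.0);
}

struct Clamp { int comp; double amp, on, off; };
struct Series { int comp; double t0, dt; std::vector<double> val; };
struct StaticG { int comp; double g, er; };
struct Syn {
  int comp; double er, gpk, tr, td, norm;
  std::vector<double> ev; size_t ptr = 0;
  double A = 0.0, B = 0.0, fr = 0.0, fd = 0.0;
};

struct CableModel {
  int n = 0;
  std::vector<int> parent;
  std::vector<double> cap, gl, el, gna, gk, gax;
  double ena = 50.0, ek = -77.0, phi = 1.0;
  std::vector<Clamp> clamps;
  std::vector<Series> series;
  std::vector<StaticG> statics;
  std::vector<Syn> syns;
};

struct CableState {
  std::vector<double> v, m, h, nn;
  double t = 0.0;
};

static CableModel parse_cable(const List& grid, const List& stim) {
  CableModel M;
  IntegerVector parent = grid["parent"];
  NumericVector cap = grid["cap_nF"], gl = grid["g_leak_uS"], el = grid["e_leak"],
                gna = grid["g_na_uS"], gk = grid["g_k_uS"], gax = grid["g_ax_uS"];
  M.n = parent.size();
  M.parent.assign(parent.begin(), parent.end());
  M.cap.assign(cap.begin(), cap.end());
  M.gl.assign(gl.begin(), gl.end());
  M.el.assign(el.begin(), el.end());
  M.gna.assign(gna.begin(), gna.end());
  M.gk.assign(gk.begin(), gk.end());
  M.gax.assign(gax.begin(), gax.end());
  M.ena = as<double>(grid["e_na"]);
  M.ek = as<double>(grid["e_k"]);
  M.phi = as<double>(grid["phi"]);
  List cl = stim["clamps"], se = stim["series"], st = stim["statics"],
       sy = stim["synapses"];
  for (int i = 0; i < cl.size(); ++i) {
    List x = cl[i];
    M.clamps.push_back({as<int>(x["comp"]), as<double>(x["amp_nA"]),
                        as<double>(x["onset"]), as<double>(x["offset"])});
  }
  for (int i = 0; i < se.size(); ++i) {
    List x = se[i];
    Series srs;
    srs.comp = as<int>(x["comp"]); srs.t0 = as<double>(x["t0"]);
    srs.dt = as<double>(x["dt"]);
    NumericVector v = x["values_nA"];
    srs.val.assign(v.begin(), v.end());
    M.series.push_back(srs);
  }
  for (int i = 0; i < st.size(); ++i) {
    List x = st[i];
    M.statics.push_back({as<int>(x["comp"]), as<double>(x["g_uS"]),
                         as<double>(x["e_rev"])});
  }
  for (int i = 0; i < sy.size(); ++i) {
    List x = sy[i];
    Syn s;
    s.comp = as<int>(x["comp"]); s.er = as<double>(x["e_rev"]);
    s.gpk = as<double>(x["g_peak_uS"]);
    s.tr = as<double>(x["tau_rise"]); s.td = as<double>(x["tau_decay"]);
    double tp = s.tr * s.td / (s.td - s.tr) * std::log(s.td / s.tr);
    s.norm = 1.0 / (std::exp(-tp / s.td) - std::exp(-tp / s.tr));
    NumericVector ev = x["events"];
    s.ev.assign(ev.begin(), ev.end());
    M.syns.push_back(s);
  }
  return M;
}

static CableState cable_init(const CableModel& M, double v_init) {
  CableState S;
  S.v.assign(M.n, v_init);
  S.m.resize(M.n); S.h.resize(M.n); S.nn.resize(M.n);
  double a[3], b[3];
  hh_rates(v_init, a, b);
  for (int i = 0; i < M.n; ++i) {
    S.m[i] = a[0] / (a[0] + b[0]);
    S.h[i] = a[1] / (a[1] + b[1]);
    S.nn[i] = a[2] / (a[2] + b[2]);
  }
  return S;
}

// one backward-Euler step; extra_inj: additional injected current (nA) per
// compartment (may be empty)
static void cable_step_core(CableModel& M, CableState& S, double dt,
                            const std::vector<double>& extra_inj) {
  const int n = M.n;
  double tn = S.t + dt;
  // gate update (exponential integrator at the current voltage)
  double a[3], b[3];
  for (int i = 0; i < n; ++i) {
    if (M.gna[i] > 0.0 || M.gk[i] > 0.0) {
      hh_rates(S.v[i], a, b);
      for (int g = 0; g < 3; ++g) {
        double s = M.phi * (a[g] + b[g]);
        double inf = a[g] / (a[g] + b[g]);
        double* gv = (g == 0) ? &S.m[i] : (g == 1) ? &S.h[i] : &S.nn[i];
        *gv = inf + (*gv - inf) * std::exp(-dt * s);
      }
    }
  }
  std::vector<double> diag(n), rhs(n);
  for (int i = 0; i < n; ++i) {
    double cdt = M.cap[i] / dt;
    double gna = M.gna[i] * S.m[i] * S.m[i] * S.m[i] * S.h[i];
    double gk = M.gk[i] * S.nn[i] * S.nn[i] * S.nn[i] * S.nn[i];
    diag[i] = cdt + M.gl[i] + gna + gk;
    rhs[i] = cdt * S.v[i] + M.gl[i] * M.el[i] + gna * M.ena + gk * M.ek;
  }
  for (auto& s : M.statics) { diag[s.comp] += s.g; rhs[s.comp] += s.g * s.er; }
  for (auto& s : M.syns) {
    s.A *= s.fr; s.B *= s.fd;
    while (s.ptr < s.ev.size() && s.ev[s.ptr] <= tn + 1e-9) {
      s.A += 1.0; s.B += 1.0; ++s.ptr;
    }
    double g = s.gpk * s.norm * (s.B - s.A);
    if (g < 0.0) g = 0.0;
    diag[s.comp] += g; rhs[s.comp] += g * s.er;
  }
  for (auto& c : M.clamps)
    if (tn > c.on + 1e-9 && tn <= c.off + 1e-9) rhs[c.comp] += c.amp;
  for (auto& sr : M.series) {
    double pos = (tn - sr.t0) / sr.dt;
    if (pos >= 0.0) {
      size_t k = (size_t)pos;
      if (k < sr.val.size()) rhs[sr.comp] += sr.val[k];
    }
  }
  if (!extra_inj.empty())
    for (int i = 0; i < n; ++i) rhs[i] += extra_inj[i];
  // axial terms + Hines elimination (compartments ordered parents-first)
  for (int i = 1; i < n; ++i) {
    diag[i] += M.gax[i];
    diag[M.parent[i]] += M.gax[i];
  }
  for (int i = n - 1; i >= 1; --i) {
    double f = M.gax[i] / diag[i];
    diag[M.parent[i]] -= f * M.gax[i];
    rhs[M.parent[i]] += f * rhs[i];
  }
  S.v[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i)
    S.v[i] = (rhs[i] + M.gax[i] * S.v[M.parent[i]]) / diag[i];
  S.t = tn;
}

static void syn_prepare(CableModel& M, double dt) {
  for (auto& s : M.syns) {
    s.fr = std::exp(-dt / s.tr);
    s.fd = std::exp(-dt / s.td);
  }
}

static void check_finite(const CableState& S) {
  for (size_t i = 0; i < S.v.size(); ++i)
    if (!std::isfinite(S.v[i]))
      stop("numerical divergence: non-finite voltage in compartment %d",
           (int)i + 1);
}

// [[Rcpp::export]]
List cpp_cable_run(List grid, List stim, double v_init, double dt, int n_steps,
                   IntegerVector record, int record_every) {
  CableModel M = parse_cable(grid, stim);
  syn_prepare(M, dt);
  CableState S = cable_init(M, v_init);
  int nrec = n_steps / std::max(record_every, 1) + 1;
  NumericMatrix vout(nrec, record.size());
  NumericVector times(nrec);
  int row = 0;
  times[row] = 0.0;
  for (int j = 0; j < record.size(); ++j) vout(row, j) = S.v[record[j]];
  ++row;
  std::vector<double> no_inj;
  for (int k = 1; k <= n_steps; ++k) {
    cable_step_core(M, S, dt, no_inj);
    if (k % 2048 == 0) check_finite(S);
    if (k % std::max(record_every, 1) == 0 && row < nrec) {
      times[row] = S.t;
      for (int j = 0; j < record.size(); ++j) vout(row, j) = S.v[record[j]];
      ++row;
    }
  }
  check_finite(S);
  return List::create(
    _["times"] = times, _["v"] = vout,
    _["v_final"] = NumericVector(S.v.begin(), S.v.end()),
    _["m"] = NumericVector(S.m.begin(), S.m.end()),
    _["h"] = NumericVector(S.h.begin(), S.h.end()),
    _["n"] = NumericVector(S.nn.begin(), S.nn.end()));
}

// ------------------------------------------------------- coupled loop ------
// Alternates: (a) sweeps_per_window MC sweeps at the current somatic voltage;
// (b) window-mean patch current (x area_scale, sign-flipped to injection
// convention) into the soma while the solver advances steps_per_window steps.
// [[Rcpp::export]]
List cpp_coupled_run(IntegerMatrix mc_grid, List mc_channels, IntegerVector mc_rng,
                     List mc_par, List grid, List stim, double v_init, double dt,
                     int n_windows, double sweeps_per_window, int steps_per_window,
                     double area_scale, int soma_comp) {
  MCState s = parse_mc_state(mc_grid, mc_channels, mc_rng);
  MCParams p = parse_mc_params(mc_par);
  s.H = mc_total_energy(s, p);
  CableModel M = parse_cable(grid, stim);
  syn_prepare(M, dt);
  CableState S = cable_init(M, v_init);

  int n_samples = n_windows * steps_per_window + 1;
  NumericVector times(n_samples), vsoma(n_samples);
  NumericVector win_current(n_windows);
  IntegerVector win_open_na(n_windows), win_open_k(n_windows);
  times[0] = 0.0; vsoma[0] = S.v[soma_comp];
  std::vector<double> inj(M.n, 0.0);
  int row = 1;
  // fractional sweeps per window are carried across windows so halving the
  // exchange interval preserves the overall Monte Carlo kinetic rate
  double sweep_accum = 0.0;
  for (int w = 0; w < n_windows; ++w) {
    p.vm = S.v[soma_comp];
    sweep_accum += sweeps_per_window;
    int nsw = (int)sweep_accum;
    sweep_accum -= nsw;
    double isum = 0.0;
    for (int sw = 0; sw < nsw; ++sw) {
      mc_sweep_core(s, p);
      isum += mc_current_pA(s, p);
    }
    // with no sweep this window the current is re-evaluated at the new v_m
    double imean = (nsw > 0) ? isum / nsw : mc_current_pA(s, p);
    win_current[w] = imean;
    int nNa, nK; mc_count_open(s, nNa, nK);
    win_open_na[w] = nNa; win_open_k[w] = nK;
    inj[soma_comp] = -imean * area_scale * 1e-3; // pA (membrane) -> nA injected
    for (int k = 0; k < steps_per_window; ++k) {
      cable_step_core(M, S, dt, inj);
      times[row] = S.t; vsoma[row] = S.v[soma_comp];
      ++row;
    }
    if ((w & 255) == 0) check_finite(S);
  }
  check_finite(S);
  List out = mc_state_out(s);
  out["times"] = times;
  out["v_soma"] = vsoma;
  out["window_current_pA"] = win_current;
  out["window_open_na"] = win_open_na;
  out["window_open_k"] = win_open_k;
  return out;
}
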