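// Metropolis Monte Carlo engine for a self-avoiding 50-monomer lattice
// polymer with compartment-score-weighted contact (A-A, B-B) and
// convex-hull-surface (A-S, B-S) interaction terms.
//
// The "printed" energy is
//   E = sum_{AA contacts} gAA S_i S_j + sum_{BB contacts} gBB S_p S_q
//     + sum_{A on surface} gAS (S_m - mean S_A)
//     + sum_{B on surface} gBS (mean S_B - S_n)
// with contacts = same-compartment pairs at Euclidean distance < 2 lattice
// units (squared distance 1, 2 or 3) and surface membership = vertex of the
// convex hull of all monomers. In the default "attractive" convention the
// objective minimised by Metropolis is -E; "as_printed" minimises +E.

#include <Rcpp.h>
#include "hull.h"
#include <unordered_set>
#include <cstdint>
#include <cmath>
using namespace Rcpp;
using nucleome::Vec3;
using nucleome::Hull;

static inline int64_t pack_key(int x, int y, int z) {
  const int64_t B = 1 << 20;
  return ((x + B) << 42) | (static_cast<int64_t>(y + B) << 21) |
         static_cast<int64_t>(z + B);
}

struct LatticeState {
  int n;
  std::vector<int> x, y, z;
  std::vector<double> s;      // compartment scores
  std::vector<char> isA;      // s > 0
  double gAA, gBB, gAS, gBS;
  double sbarA, sbarB;
  std::unordered_set<int64_t> occ;

  bool surface_needed() const { return gAS != 0.0 || gBS != 0.0; }

  int sqdist(int i, int j) const {
    int dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    return dx * dx + dy * dy + dz * dz;
  }

  double pair_energy() const {
    double e = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (isA[i] != isA[j]) continue;
        if (sqdist(i, j) >= 4) continue;
        e += (isA[i] ? gAA : gBB) * s[i] * s[j];
      }
    return e;
  }

  // pair-energy change if monomer k moves to (nx,ny,nz)
  double pair_delta(int k, int nx, int ny, int nz) const {
    double d = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == k || isA[j] != isA[k]) continue;
      int odx = x[k] - x[j], ody = y[k] - y[j], odz = z[k] - z[j];
      int ndx = nx - x[j], ndy = ny - y[j], ndz = nz - z[j];
      bool oc = (odx * odx + ody * ody + odz * odz) < 4;
      bool nc = (ndx * ndx + ndy * ndy + ndz * ndz) < 4;
      if (oc == nc) continue;
      double term = (isA[k] ? gAA : gBB) * s[k] * s[j];
      d += nc ? term : -term;
    }
    return d;
  }

  // surface term for an arbitrary coordinate set (k moved to nx,ny,nz when
  // k >= 0). A degenerate (coplanar) conformation counts every monomer as
  // surface-exposed.
  double surface_energy(int k, int nx, int ny, int nz) const {
    if (!surface_needed()) return 0.0;
    static thread_local std::vector<Vec3> pts;
    pts.resize(n);
    for (int i = 0; i < n; ++i) {
      if (i == k)
        pts[i] = {static_cast<double>(nx), static_cast<double>(ny),
                  static_cast<double>(nz)};
      else
        pts[i] = {static_cast<double>(x[i]), static_cast<double>(y[i]),
                  static_cast<double>(z[i])};
    }
    static thread_local Hull h;
    bool ok = nucleome::build_hull(pts, h);
    double e = 0.0;
    for (int i = 0; i < n; ++i) {
      bool on_surface = ok ? (h.is_vertex[i] != 0) : true;
      if (!on_surface) continue;
      e += isA[i] ? gAS * (s[i] - sbarA) : gBS * (sbarB - s[i]);
    }
    return e;
  }

  double printed_energy() const { return pair_energy() + surface_energy(-1, 0, 0, 0); }

  bool adjacency_ok(int k, int nx, int ny, int nz) const {
    for (int j : {k - 1, k + 1}) {
      if (j < 0 || j >= n) continue;
      int dx = nx - x[j], dy = ny - y[j], dz = nz - z[j];
      int sq = dx * dx + dy * dy + dz * dz;
      if (sq < 1 || sq > 16) return false;
    }
    return true;
  }

  void check_invariants() const {
    if (occ.size() != static_cast<size_t>(n))
      stop("self-avoidance violated");
    for (int i = 0; i + 1 < n; ++i) {
      int sq = sqdist(i, i + 1);
      if (sq < 1 || sq > 16) stop("adjacency bound violated");
    }
  }
};

static LatticeState make_state(const IntegerMatrix& conf,
                               const NumericVector& scores, double gAA,
                               double gBB, double gAS, double gBS) {
  LatticeState st;
  st.n = conf.nrow();
  if (scores.size() != st.n) stop("scores length must equal monomer count");
  st.x.resize(st.n); st.y.resize(st.n); st.z.resize(st.n);
  st.s.assign(scores.begin(), scores.end());
  st.isA.resize(st.n);
  st.gAA = gAA; st.gBB = gBB; st.gAS = gAS; st.gBS = gBS;
  double sumA = 0, sumB = 0; int nA = 0, nB = 0;
  for (int i = 0; i < st.n; ++i) {
    st.x[i] = conf(i, 0); st.y[i] = conf(i, 1); st.z[i] = conf(i, 2);
    st.isA[i] = st.s[i] > 0;
    if (st.isA[i]) { sumA += st.s[i]; ++nA; } else { sumB += st.s[i]; ++nB; }
    if (!st.occ.insert(pack_key(st.x[i], st.y[i], st.z[i])).second)
      stop("initial conformation is not self-avoiding");
  }
  if (st.surface_needed() && (nA == 0 || nB == 0))
    stop("surface terms undefined: need at least one A and one B monomer");
  st.sbarA = nA ? sumA / nA : 0.0;
  st.sbarB = nB ? sumB / nB : 0.0;
  for (int i = 0; i + 1 < st.n; ++i) {
    int sq = st.sqdist(i, i + 1);
    if (sq < 1 || sq > 16) stop("initial conformation violates adjacency bound");
  }
  return st;
}

// [[Rcpp::export]]
List cpp_lattice_energy(IntegerMatrix conf, NumericVector scores, double gAA,
                        double gBB, double gAS, double gBS) {
  LatticeState st = make_state(conf, scores, gAA, gBB, gAS, gBS);
  double pe = st.pair_energy();
  double se = st.surface_energy(-1, 0, 0, 0);
  return List::create(_["printed_energy"] = pe + se, _["pair_term"] = pe,
                      _["surface_term"] = se);
}

// [[Rcpp::export]]
List cpp_mc_run(IntegerMatrix conf, NumericVector scores, double gAA,
                double gBB, double gAS, double gBS, bool attractive,
                int n_accepted, double max_attempt_factor) {
  LatticeState st = make_state(conf, scores, gAA, gBB, gAS, gBS);
  const int n = st.n;
  double e_pair = st.pair_energy();
  double e_surf = st.surface_energy(-1, 0, 0, 0);
  NumericVector trace(n_accepted);
  const int dx6[6] = {1, -1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, 1, -1, 0, 0};
  const int dz6[6] = {0, 0, 0, 0, 1, -1};
  long long attempts = 0, evaluated = 0;
  const long long max_attempts =
      static_cast<long long>(max_attempt_factor) * n_accepted + 1000000LL;

  int accepted = 0;
  while (accepted < n_accepted) {
    if (++attempts > max_attempts)
      stop("no legal move found within the attempt budget (frozen chain)");
    int k = static_cast<int>(unif_rand() * n);
    if (k == n) k = n - 1;
    int d = static_cast<int>(unif_rand() * 6);
    if (d == 6) d = 5;
    int nx = st.x[k] + dx6[d], ny = st.y[k] + dy6[d], nz = st.z[k] + dz6[d];
    if (st.occ.count(pack_key(nx, ny, nz))) continue;       // occupied
    if (!st.adjacency_ok(k, nx, ny, nz)) continue;           // bond violated
    ++evaluated;
    double d_pair = st.pair_delta(k, nx, ny, nz);
    double new_surf = st.surface_energy(k, nx, ny, nz);
    // printed-energy difference E_new - E_now
    double dE = d_pair + (new_surf - e_surf);
    // attractive convention minimises -E_printed
    double arg = attractive ? dE : -dE;
    bool accept = arg >= 0.0 || unif_rand() < std::exp(arg);
    if (!accept) continue;
    st.occ.erase(pack_key(st.x[k], st.y[k], st.z[k]));
    st.occ.insert(pack_key(nx, ny, nz));
    st.x[k] = nx; st.y[k] = ny; st.z[k] = nz;
    e_pair += d_pair;
    e_surf = new_surf;
    trace[accepted] = e_pair + e_surf;
    ++accepted;
    if (accepted % 1000 == 0) st.check_invariants();
  }

  st.check_invariants();
  double full_pair = st.pair_energy();
  if (std::fabs(full_pair - e_pair) > 1e-6)
    stop("incremental pair-energy bookkeeping diverged from full recomputation");

  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = st.x[i]; out(i, 1) = st.y[i]; out(i, 2) = st.z[i];
  }
  return List::create(_["conformation"] = out, _["energy_trace"] = trace,
                      _["attempts"] = static_cast<double>(attempts),
                      _["evaluated"] = static_cast<double>(evaluated));
}

// Random self-avoiding chain with the bond-length bound (1 <= |step| <= 4).
// [[Rcpp::export]]
IntegerMatrix cpp_random_saw(int n, int max_restarts) {
  if (n < 2) stop("need at least 2 monomers");
  // all integer offsets with squared length in [1, 16]
  std::vector<std::array<int, 3>> offs;
  for (int dx = -4; dx <= 4; ++dx)
    for (int dy = -4; dy <= 4; ++dy)
      for (int dz = -4; dz <= 4; ++dz) {
        int sq = dx * dx + dy * dy + dz * dz;
        if (sq >= 1 && sq <= 16) offs.push_back({dx, dy, dz});
      }
  const int m = static_cast<int>(offs.size());
  for (int restart = 0; restart < max_restarts; ++restart) {
    std::vector<std::array<int, 3>> pos;
    std::unordered_set<int64_t> occ;
    pos.push_back({0, 0, 0});
    occ.insert(pack_key(0, 0, 0));
    bool dead = false;
    while (static_cast<int>(pos.size()) < n && !dead) {
      bool placed = false;
      for (int attempt = 0; attempt < 100; ++attempt) {
        int o = static_cast<int>(unif_rand() * m);
        if (o == m) o = m - 1;
        int nx = pos.back()[0] + offs[o][0];
        int ny = pos.back()[1] + offs[o][1];
        int nz = pos.back()[2] + offs[o][2];
        if (occ.count(pack_key(nx, ny, nz))) continue;
        pos.push_back({nx, ny, nz});
        occ.insert(pack_key(nx, ny, nz));
        placed = true;
        break;
      }
      if (!placed) dead = true;
    }
    if (!dead) {
      IntegerMatrix out(n, 3);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) out(i, k) = pos[i][k];
      return out;
    }
  }
  stop("failed to construct a self-avoiding chain");
}
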