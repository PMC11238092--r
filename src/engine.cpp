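// Brownian-dynamics engine for the coarse-grained chromatin/BRD4/Corelet model.
// Units: kT = 1 (energy), nm (length), tau_d (time; Corelet self-diffusion time).
// Pair interactions: WCA sterics + Flory-Krigbaum (Gaussian) attraction between
// selected polymer-blob species pairs, truncated and shifted where |U| < 1e-4 kT.
// Bonds: FENE. Integration: overdamped (first-order) Langevin with per-particle
// friction; optional Berendsen-style lateral (x-y) pressure coupling, z fixed.
//
// Pair evaluation uses Verlet neighbour lists rebuilt on displacement
// (half-skin criterion), with a second long-cutoff list for species pairs
// whose Flory-Krigbaum range far exceeds the steric range (in practice the
// BRD4 C-blob self-attraction).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// xoshiro256++ PRNG seeded via splitmix64; Marsaglia polar normals.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x1ULL;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double m = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * m;
    have_spare = true;
    return u * m;
  }
};

inline double wrap1(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}

inline double mindelta(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// ---------------------------------------------------------------------------
// Pair parameter tables, indexed by species pair (ns x ns, row-major).
// ---------------------------------------------------------------------------
struct PairTables {
  int ns;
  std::vector<double> sig2, wcaCut2, fkEps, fkAlpha, fkCut2, fkShift;
  std::vector<double> fullCut2, shortCut2;
  std::vector<char> isLong;
  std::vector<char> speciesLong;  // species participates in a long pair
  double epsRep;
  double rcShort, rcLong;  // list cutoffs (no skin)
  inline int at(int s, int t) const { return s * ns + t; }
};

PairTables makeTables(const List &tab) {
  PairTables pt;
  NumericMatrix sig2 = tab["sig2"], wcaCut2 = tab["wca_cut2"],
                fkEps = tab["fk_eps"], fkAlpha = tab["fk_alpha"],
                fkCut2 = tab["fk_cut2"], fkShift = tab["fk_shift"];
  pt.ns = sig2.nrow();
  pt.epsRep = as<double>(tab["eps_rep"]);
  int n2 = pt.ns * pt.ns;
  pt.sig2.resize(n2); pt.wcaCut2.resize(n2); pt.fkEps.resize(n2);
  pt.fkAlpha.resize(n2); pt.fkCut2.resize(n2); pt.fkShift.resize(n2);
  pt.fullCut2.resize(n2); pt.shortCut2.resize(n2);
  pt.isLong.assign(n2, 0);
  pt.speciesLong.assign(pt.ns, 0);
  double full2max = 0.0;
  for (int k = 0; k < n2; ++k) {
    int s = k / pt.ns, t = k % pt.ns;
    pt.sig2[k] = sig2(s, t); pt.wcaCut2[k] = wcaCut2(s, t);
    pt.fkEps[k] = fkEps(s, t); pt.fkAlpha[k] = fkAlpha(s, t);
    pt.fkCut2[k] = fkCut2(s, t); pt.fkShift[k] = fkShift(s, t);
    pt.fullCut2[k] = std::max(pt.wcaCut2[k], pt.fkCut2[k]);
    full2max = std::max(full2max, pt.fullCut2[k]);
  }
  // route pairs whose range is > 70% of the global maximum (and beyond the
  // steric range) through the long list
  double rcShort2 = 0.0;
  for (int k = 0; k < n2; ++k) {
    bool lng = pt.fkCut2[k] > 0.49 * full2max &&
               pt.fkCut2[k] > 1.5 * pt.wcaCut2[k];
    pt.isLong[k] = lng ? 1 : 0;
    pt.shortCut2[k] = lng ? pt.wcaCut2[k] : pt.fullCut2[k];
    if (lng) {
      pt.speciesLong[k / pt.ns] = 1;
      pt.speciesLong[k % pt.ns] = 1;
    }
    rcShort2 = std::max(rcShort2, pt.shortCut2[k]);
  }
  pt.rcShort = std::sqrt(rcShort2);
  pt.rcLong = std::sqrt(full2max);
  return pt;
}

// ---------------------------------------------------------------------------
// Cell grid for neighbour-list builds (deduplicated neighbour cells so that
// boxes only 1-2 cells wide remain correct).
// ---------------------------------------------------------------------------
struct CellGrid {
  int nc[3];
  std::vector<int> head, nxt;
  std::vector<std::vector<int>> nbr;

  void build(const double *x, const std::vector<int> &ids, const double *L,
             double cell) {
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor(L[d] / cell));
      if (nc[d] > 64) nc[d] = 64;
    }
    int ncell = nc[0] * nc[1] * nc[2];
    head.assign(ncell, -1);
    nxt.assign(ids.size(), -1);
    for (size_t a = 0; a < ids.size(); ++a) {
      int i = ids[a];
      int cx = (int)(wrap1(x[3 * i], L[0]) / L[0] * nc[0]); if (cx >= nc[0]) cx = nc[0] - 1;
      int cy = (int)(wrap1(x[3 * i + 1], L[1]) / L[1] * nc[1]); if (cy >= nc[1]) cy = nc[1] - 1;
      int cz = (int)(wrap1(x[3 * i + 2], L[2]) / L[2] * nc[2]); if (cz >= nc[2]) cz = nc[2] - 1;
      int c = (cz * nc[1] + cy) * nc[0] + cx;
      nxt[a] = head[c];
      head[c] = (int)a;
    }
    nbr.assign(ncell, {});
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c = (cz * nc[1] + cy) * nc[0] + cx;
          std::vector<int> &v = nbr[c];
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ox = (cx + dx + nc[0]) % nc[0];
                int oy = (cy + dy + nc[1]) % nc[1];
                int oz = (cz + dz + nc[2]) % nc[2];
                int cn = (oz * nc[1] + oy) * nc[0] + ox;
                if (std::find(v.begin(), v.end(), cn) == v.end()) v.push_back(cn);
              }
        }
  }
};

struct ForceResult {
  double eWca = 0, eFk = 0, eFene = 0;
  double wLat = 0;
  double minRatio2 = 1e300;
};

// Verlet pair lists (short/standard + long FK) with half-skin rebuilds.
struct NeighborEngine {
  const PairTables *pt;
  double skin = 4.0;
  std::vector<int> ai, aj, ak;  // short list (+ species-pair index)
  std::vector<int> bi, bj, bk;  // long (FK-only) list
  std::vector<double> shortList2, longList2;  // (cutoff + skin)^2 per pair
  std::vector<double> xref;
  std::vector<int> allIds, longIds;
  int n = 0;

  void init(int n_, const int *sp, const PairTables *pt_) {
    pt = pt_;
    n = n_;
    allIds.resize(n);
    for (int i = 0; i < n; ++i) allIds[i] = i;
    longIds.clear();
    for (int i = 0; i < n; ++i)
      if (pt->speciesLong[sp[i]]) longIds.push_back(i);
    xref.assign(3 * n, 1e30);
  }

  bool needRebuild(const double *x, const double *L) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = mindelta(x[3 * i] - xref[3 * i], L[0]);
      double dy = mindelta(x[3 * i + 1] - xref[3 * i + 1], L[1]);
      double dz = mindelta(x[3 * i + 2] - xref[3 * i + 2], L[2]);
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void build(const double *x, const int *sp, const double *L) {
    const PairTables &t = *pt;
    ai.clear(); aj.clear(); ak.clear(); bi.clear(); bj.clear(); bk.clear();
    // per-pair list radii squared, computed once
    if (shortList2.empty()) {
      int n2 = t.ns * t.ns;
      shortList2.resize(n2);
      longList2.resize(n2);
      for (int k = 0; k < n2; ++k) {
        double rs = std::sqrt(t.shortCut2[k]) + skin;
        shortList2[k] = rs * rs;
        double rl = std::sqrt(t.fkCut2[k]) + skin;
        longList2[k] = rl * rl;
      }
    }
    CellGrid g;
    double cellA = t.rcShort + skin;
    g.build(x, allIds, L, cellA);
    int ncell = g.nc[0] * g.nc[1] * g.nc[2];
    for (int c = 0; c < ncell; ++c) {
      for (int a = g.head[c]; a >= 0; a = g.nxt[a]) {
        int i = allIds[a];
        double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
        int si = sp[i];
        for (int cn : g.nbr[c]) {
          for (int b = g.head[cn]; b >= 0; b = g.nxt[b]) {
            int j = allIds[b];
            if (j <= i) continue;
            double dx = mindelta(xi - x[3 * j], L[0]);
            double dy = mindelta(yi - x[3 * j + 1], L[1]);
            double dz = mindelta(zi - x[3 * j + 2], L[2]);
            double r2 = dx * dx + dy * dy + dz * dz;
            int k = si * t.ns + sp[j];
            if (r2 < shortList2[k]) {
              ai.push_back(i); aj.push_back(j); ak.push_back(k);
            }
          }
        }
      }
    }
    if (!longIds.empty()) {
      CellGrid g2;
      g2.build(x, longIds, L, t.rcLong + skin);
      int ncell2 = g2.nc[0] * g2.nc[1] * g2.nc[2];
      for (int c = 0; c < ncell2; ++c) {
        for (int a = g2.head[c]; a >= 0; a = g2.nxt[a]) {
          int i = longIds[a];
          double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
          int si = sp[i];
          for (int cn : g2.nbr[c]) {
            for (int b = g2.head[cn]; b >= 0; b = g2.nxt[b]) {
              int j = longIds[b];
              if (j <= i) continue;
              int k = si * t.ns + sp[j];
              if (!t.isLong[k]) continue;
              double dx = mindelta(xi - x[3 * j], L[0]);
              double dy = mindelta(yi - x[3 * j + 1], L[1]);
              double dz = mindelta(zi - x[3 * j + 2], L[2]);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < longList2[k]) {
                bi.push_back(i); bj.push_back(j); bk.push_back(k);
              }
            }
          }
        }
      }
    }
    std::copy(x, x + 3 * n, xref.begin());
  }

  void ensure(const double *x, const int *sp, const double *L) {
    if (xref[0] > 1e29 || needRebuild(x, L)) build(x, sp, L);
  }

  void forces(const double *x, const int *sp, const double *L, double *f,
              ForceResult &fr) const {
    const PairTables &t = *pt;
    const int ns = t.ns;
    const size_t na = ai.size();
    for (size_t p = 0; p < na; ++p) {
      int i = ai[p], j = aj[p];
      double dx = mindelta(x[3 * i] - x[3 * j], L[0]);
      double dy = mindelta(x[3 * i + 1] - x[3 * j + 1], L[1]);
      double dz = mindelta(x[3 * i + 2] - x[3 * j + 2], L[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      int k = ak[p];
      double cfac = 0.0;
      if (r2 < t.wcaCut2[k]) {
        if (r2 <= 0)
          stop("singular separation: particles %d and %d coincide", i + 1, j + 1);
        double s2 = t.sig2[k] / r2;
        double s6 = s2 * s2 * s2;
        fr.eWca += 4.0 * t.epsRep * (s6 * s6 - s6) + t.epsRep;
        cfac += 24.0 * t.epsRep * (2.0 * s6 * s6 - s6) / r2;
        double ratio2 = r2 / t.sig2[k];
        if (ratio2 < fr.minRatio2) fr.minRatio2 = ratio2;
      }
      if (!t.isLong[k] && t.fkEps[k] > 0 && r2 < t.fkCut2[k]) {
        double e = t.fkEps[k] * std::exp(-t.fkAlpha[k] * r2);
        fr.eFk += -e + t.fkShift[k];
        cfac += -2.0 * t.fkAlpha[k] * e;
      }
      if (cfac != 0.0) {
        double fx = cfac * dx, fy = cfac * dy, fz = cfac * dz;
        f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
        f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
        fr.wLat += fx * dx + fy * dy;
      }
    }
    const size_t nb = bi.size();
    for (size_t p = 0; p < nb; ++p) {
      int i = bi[p], j = bj[p];
      double dx = mindelta(x[3 * i] - x[3 * j], L[0]);
      double dy = mindelta(x[3 * i + 1] - x[3 * j + 1], L[1]);
      double dz = mindelta(x[3 * i + 2] - x[3 * j + 2], L[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      int k = bk[p];
      if (r2 < t.fkCut2[k]) {
        double e = t.fkEps[k] * std::exp(-t.fkAlpha[k] * r2);
        fr.eFk += -e + t.fkShift[k];
        double cfac = -2.0 * t.fkAlpha[k] * e;
        double fx = cfac * dx, fy = cfac * dy, fz = cfac * dz;
        f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
        f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
        fr.wLat += fx * dx + fy * dy;
      }
    }
  }
};

// Trial-move guard: first bond whose length exceeds frac2 * R0^2, or -1.
// Keeping trial states below 0.92 R0 (a region with FENE energies of tens
// of kT, never sampled thermally) prevents mechanical deadlocks where
// steric compression forces a bond past its divergence.
int bondOverLimit(const double *x, const double *L, const int *bi,
                  const int *bj, const double *bR02, int nb, double frac2) {
  for (int b = 0; b < nb; ++b) {
    int i = bi[b], j = bj[b];
    double dx = mindelta(x[3 * i] - x[3 * j], L[0]);
    double dy = mindelta(x[3 * i + 1] - x[3 * j + 1], L[1]);
    double dz = mindelta(x[3 * i + 2] - x[3 * j + 2], L[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= frac2 * bR02[b]) return b;
  }
  return -1;
}

// Returns first overstretched bond (r >= R0) or -1; when fr != NULL also
// accumulates FENE energy/forces.
int bondForces(const double *x, const double *L, const int *bi, const int *bj,
               const double *bK, const double *bR02, int nb, double *f,
               ForceResult *fr) {
  for (int b = 0; b < nb; ++b) {
    int i = bi[b], j = bj[b];
    double dx = mindelta(x[3 * i] - x[3 * j], L[0]);
    double dy = mindelta(x[3 * i + 1] - x[3 * j + 1], L[1]);
    double dz = mindelta(x[3 * i + 2] - x[3 * j + 2], L[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= bR02[b]) return b;
    if (fr) {
      double frac = 1.0 - r2 / bR02[b];
      fr->eFene += -0.5 * bK[b] * bR02[b] * std::log(frac);
      double cfac = -bK[b] / frac;
      double fx = cfac * dx, fy = cfac * dy, fz = cfac * dz;
      f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
      f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
      fr->wLat += fx * dx + fy * dy;
    }
  }
  return -1;
}

struct UF {
  std::vector<int> p;
  explicit UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int i) { while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; } return i; }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) p[std::max(a, b)] = std::min(a, b);
  }
};

int largestClusterSize(const double *x, const std::vector<int> &ref,
                       const double *L, double rc2) {
  int m = (int)ref.size();
  if (m == 0) return 0;
  UF uf(m);
  for (int a = 0; a < m; ++a) {
    int i = ref[a];
    for (int b = a + 1; b < m; ++b) {
      int j = ref[b];
      double dx = mindelta(x[3 * i] - x[3 * j], L[0]);
      double dy = mindelta(x[3 * i + 1] - x[3 * j + 1], L[1]);
      double dz = mindelta(x[3 * i + 2] - x[3 * j + 2], L[2]);
      if (dx * dx + dy * dy + dz * dz < rc2) uf.unite(a, b);
    }
  }
  std::vector<int> cnt(m, 0);
  int best = 0;
  for (int a = 0; a < m; ++a) {
    int r = uf.find(a);
    if (++cnt[r] > best) best = cnt[r];
  }
  return best;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_total_forces(NumericMatrix pos, IntegerVector species, List tables,
                      IntegerVector bond_i, IntegerVector bond_j,
                      NumericVector bond_k, NumericVector bond_r02,
                      NumericVector box) {
  int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  PairTables pt = makeTables(tables);
  double L[3] = {box[0], box[1], box[2]};
  NeighborEngine ne;
  ne.init(n, INTEGER(species), &pt);
  ne.build(x.data(), INTEGER(species), L);
  std::vector<double> f(3 * n, 0.0);
  ForceResult fr;
  ne.forces(x.data(), INTEGER(species), L, f.data(), fr);
  int ov = bondForces(x.data(), L, INTEGER(bond_i), INTEGER(bond_j),
                      REAL(bond_k), REAL(bond_r02), bond_i.size(), f.data(), &fr);
  if (ov >= 0)
    stop("overstretched bond %d (r >= R0): particles %d and %d", ov + 1,
         bond_i[ov] + 1, bond_j[ov] + 1);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fm(i, d) = f[3 * i + d];
  return List::create(_["forces"] = fm,
                      _["energy"] = NumericVector::create(
                          _["WCA"] = fr.eWca, _["FK"] = fr.eFk, _["FENE"] = fr.eFene),
                      _["lateral_virial"] = fr.wLat,
                      _["min_sep_ratio"] = std::sqrt(std::min(fr.minRatio2, 1e300)));
}

// [[Rcpp::export]]
List cpp_run_bd(NumericMatrix pos, IntegerVector species, List tables,
                IntegerVector bond_i, IntegerVector bond_j,
                NumericVector bond_k, NumericVector bond_r02,
                NumericVector gamma, NumericVector box, double dt, int n_steps,
                int output_every, double seed1, double seed2, int npxy,
                double p_target, double tau_p,
                IntegerVector stop_ref, double stop_rclust, int stop_size,
                int check_every, int post_steps, double temperature,
                double max_disp) {
  int n = pos.nrow();
  int nb = bond_i.size();
  std::vector<double> x(3 * n), f(3 * n, 0.0), xt(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  PairTables pt = makeTables(tables);
  double L[3] = {box[0], box[1], box[2]};
  uint64_t seed = ((uint64_t)(uint32_t)seed1 << 32) | (uint64_t)(uint32_t)seed2;
  Xoshiro rng(seed);
  const int *sp = INTEGER(species);

  NeighborEngine ne;
  ne.init(n, sp, &pt);

  std::vector<int> ref(stop_ref.begin(), stop_ref.end());
  bool doStop = !ref.empty() && stop_size > 0;
  double rc2 = stop_rclust * stop_rclust;

  const int *bi = INTEGER(bond_i), *bj = INTEGER(bond_j);
  const double *bK = REAL(bond_k), *bR02 = REAL(bond_r02);
  const double *gam = REAL(gamma);

  // precompute mobilities and noise amplitudes for the nominal dt
  std::vector<double> mob0(n), amp0(n);
  for (int i = 0; i < n; ++i) {
    mob0[i] = dt / gam[i];
    amp0[i] = std::sqrt(2.0 * temperature * dt / gam[i]);
  }

  List frames;
  std::vector<double> times, eW, eF, eB, bLx, bLy, pLat;
  double minRatio = 1e300;
  long long nEmergency = 0;
  int stoppedAt = -1;
  long long stepsRemainingAfterStop = -1;

  auto snapshot = [&](double tnow, double plat) {
    NumericMatrix fm(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) fm(i, d) = x[3 * i + d];
    frames.push_back(fm);
    times.push_back(tnow);
    bLx.push_back(L[0]); bLy.push_back(L[1]); pLat.push_back(plat);
  };

  double tnow = 0.0;
  ForceResult fr;
  ne.ensure(x.data(), sp, L);
  ne.forces(x.data(), sp, L, f.data(), fr);
  int ov = bondForces(x.data(), L, bi, bj, bK, bR02, nb, f.data(), &fr);
  if (ov >= 0) stop("initial configuration has overstretched bond %d", ov + 1);
  double V = L[0] * L[1] * L[2];
  double plat = (n * temperature + 0.5 * fr.wLat) / V;
  snapshot(0.0, plat);
  eW.push_back(fr.eWca); eF.push_back(fr.eFk); eB.push_back(fr.eFene);

  for (long long step = 1; step <= (long long)n_steps; ++step) {
    bool accepted = false;
    double dt_used = dt;
    double cap2 = max_disp * max_disp;
    for (int attempt = 0; attempt <= 8 && !accepted; ++attempt) {
      double scale = 1.0 / (double)(1 << attempt);
      dt_used = dt * scale;
      double sqs = std::sqrt(scale);
      bool capped = false;
      for (int i = 0; i < n; ++i) {
        double mob = mob0[i] * scale;
        double amp = amp0[i] * sqs;
        double d0 = f[3 * i] * mob + amp * rng.norm();
        double d1 = f[3 * i + 1] * mob + amp * rng.norm();
        double d2 = f[3 * i + 2] * mob + amp * rng.norm();
        if (d0 * d0 + d1 * d1 + d2 * d2 > cap2) capped = true;
        xt[3 * i] = x[3 * i] + d0;
        xt[3 * i + 1] = x[3 * i + 1] + d1;
        xt[3 * i + 2] = x[3 * i + 2] + d2;
      }
      if (!capped &&
          bondOverLimit(xt.data(), L, bi, bj, bR02, nb, 0.8464) < 0)
        accepted = true;
    }
    if (!accepted) {
      // Emergency valve (rare, counted): a steric jam can push a bond
      // outward with forces no time-step reduction overcomes. Take the
      // smallest-dt trial with per-particle displacements clamped to the
      // cap, then project overstretched bonds back inside 0.95 R0.
      ++nEmergency;
      for (int i = 0; i < n; ++i) {
        double d0 = xt[3 * i] - x[3 * i];
        double d1 = xt[3 * i + 1] - x[3 * i + 1];
        double d2 = xt[3 * i + 2] - x[3 * i + 2];
        double dn2 = d0 * d0 + d1 * d1 + d2 * d2;
        if (dn2 > cap2) {
          double sc = max_disp / std::sqrt(dn2);
          xt[3 * i] = x[3 * i] + d0 * sc;
          xt[3 * i + 1] = x[3 * i + 1] + d1 * sc;
          xt[3 * i + 2] = x[3 * i + 2] + d2 * sc;
        }
      }
      for (int pass = 0; pass < 20; ++pass) {
        int b = bondOverLimit(xt.data(), L, bi, bj, bR02, nb, 0.9025);
        if (b < 0) break;
        int i = bi[b], j = bj[b];
        double dx = mindelta(xt[3 * i] - xt[3 * j], L[0]);
        double dy = mindelta(xt[3 * i + 1] - xt[3 * j + 1], L[1]);
        double dz = mindelta(xt[3 * i + 2] - xt[3 * j + 2], L[2]);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double target = 0.95 * std::sqrt(bR02[b]);
        double shrink = 0.5 * (1.0 - target / r);
        xt[3 * i] -= shrink * dx; xt[3 * i + 1] -= shrink * dy;
        xt[3 * i + 2] -= shrink * dz;
        xt[3 * j] += shrink * dx; xt[3 * j + 1] += shrink * dy;
        xt[3 * j + 2] += shrink * dz;
      }
    }
    std::swap(x, xt);
    for (int i = 0; i < n; ++i) {
      x[3 * i] = wrap1(x[3 * i], L[0]);
      x[3 * i + 1] = wrap1(x[3 * i + 1], L[1]);
      x[3 * i + 2] = wrap1(x[3 * i + 2], L[2]);
    }
    tnow += dt_used;

    std::fill(f.begin(), f.end(), 0.0);
    ForceResult fr2;
    ne.ensure(x.data(), sp, L);
    ne.forces(x.data(), sp, L, f.data(), fr2);
    ov = bondForces(x.data(), L, bi, bj, bK, bR02, nb, f.data(), &fr2);
    if (ov >= 0) stop("overstretched bond %d after accepted step %lld", ov + 1, step);
    if (fr2.minRatio2 < minRatio) minRatio = fr2.minRatio2;
    V = L[0] * L[1] * L[2];
    plat = (n * temperature + 0.5 * fr2.wLat) / V;

    if (npxy) {
      double lam = 1.0 + (dt / tau_p) * (plat - p_target);
      if (lam < 0.98) lam = 0.98;
      if (lam > 1.02) lam = 1.02;
      double mu = std::sqrt(lam);
      L[0] *= mu; L[1] *= mu;
      for (int i = 0; i < n; ++i) { x[3 * i] *= mu; x[3 * i + 1] *= mu; }
    }

    if (step % output_every == 0 || step == (long long)n_steps) {
      snapshot(tnow, plat);
      eW.push_back(fr2.eWca); eF.push_back(fr2.eFk); eB.push_back(fr2.eFene);
    }

    if (doStop && stoppedAt < 0 && step % check_every == 0) {
      int ncs = largestClusterSize(x.data(), ref, L, rc2);
      if (ncs >= stop_size) {
        stoppedAt = (int)step;
        stepsRemainingAfterStop = post_steps;
      }
    }
    if (stoppedAt >= 0) {
      if (stepsRemainingAfterStop-- <= 0) break;
    }
    if (step % 4000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fin(i, d) = x[3 * i + d];
  return List::create(
      _["frames"] = frames, _["times"] = NumericVector(times.begin(), times.end()),
      _["Lx"] = NumericVector(bLx.begin(), bLx.end()),
      _["Ly"] = NumericVector(bLy.begin(), bLy.end()),
      _["Lz"] = box[2],
      _["energy_wca"] = NumericVector(eW.begin(), eW.end()),
      _["energy_fk"] = NumericVector(eF.begin(), eF.end()),
      _["energy_fene"] = NumericVector(eB.begin(), eB.end()),
      _["lateral_pressure"] = NumericVector(pLat.begin(), pLat.end()),
      _["final"] = fin, _["min_sep_ratio"] = std::sqrt(std::min(minRatio, 1e300)),
      _["stopped_at_step"] = stoppedAt,
      _["n_emergency"] = (double)nEmergency);
}

// [[Rcpp::export]]
NumericMatrix cpp_minimize(NumericMatrix pos, IntegerVector species, List tables,
                           IntegerVector bond_i, IntegerVector bond_j,
                           NumericVector bond_k, NumericVector bond_r02,
                           NumericVector box, int n_steps, double max_disp) {
  int n = pos.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  PairTables pt = makeTables(tables);
  double L[3] = {box[0], box[1], box[2]};
  const int *sp = INTEGER(species);
  NeighborEngine ne;
  ne.init(n, sp, &pt);
  for (int it = 0; it < n_steps; ++it) {
    std::fill(f.begin(), f.end(), 0.0);
    ForceResult fr;
    ne.ensure(x.data(), sp, L);
    ne.forces(x.data(), sp, L, f.data(), fr);
    // FENE forces, tolerating overstretch by clamping the extension term
    for (int b = 0; b < bond_i.size(); ++b) {
      int i = bond_i[b], j = bond_j[b];
      double dx = mindelta(x[3 * i] - x[3 * j], L[0]);
      double dy = mindelta(x[3 * i + 1] - x[3 * j + 1], L[1]);
      double dz = mindelta(x[3 * i + 2] - x[3 * j + 2], L[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      double frac = 1.0 - r2 / bond_r02[b];
      if (frac < 0.05) frac = 0.05;
      double cfac = -bond_k[b] / frac;
      f[3 * i] += cfac * dx; f[3 * i + 1] += cfac * dy; f[3 * i + 2] += cfac * dz;
      f[3 * j] -= cfac * dx; f[3 * j + 1] -= cfac * dy; f[3 * j + 2] -= cfac * dz;
    }
    double fmax = 0.0;
    for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::fabs(f[i]));
    if (fmax < 1e-6) break;
    double h = max_disp / fmax;
    for (int i = 0; i < 3 * n; ++i) x[i] += h * f[i];
    for (int i = 0; i < n; ++i) {
      x[3 * i] = wrap1(x[3 * i], L[0]);
      x[3 * i + 1] = wrap1(x[3 * i + 1], L[1]);
      x[3 * i + 2] = wrap1(x[3 * i + 2], L[2]);
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3 * i + d];
  return out;
}

// Single-linkage clustering of reference points under minimum image.
// Returns 1-based component labels; each component is labelled by the
// smallest (1-based) member index.
// [[Rcpp::export]]
IntegerVector cpp_cluster(NumericMatrix pts, NumericVector box, double rcut) {
  int m = pts.nrow();
  IntegerVector lab(m);
  if (m == 0) return lab;
  double L[3] = {box[0], box[1], box[2]};
  double rc2 = rcut * rcut;
  UF uf(m);
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      double dx = mindelta(pts(a, 0) - pts(b, 0), L[0]);
      double dy = mindelta(pts(a, 1) - pts(b, 1), L[1]);
      double dz = mindelta(pts(a, 2) - pts(b, 2), L[2]);
      if (dx * dx + dy * dy + dz * dz <= rc2) uf.unite(a, b);
    }
  for (int a = 0; a < m; ++a) lab[a] = uf.find(a) + 1;
  return lab;
}

// Count rows of B within rcut (minimum image) of any row of A.
// [[Rcpp::export]]
int cpp_count_within(NumericMatrix A, NumericMatrix B, NumericVector box,
                     double rcut) {
  double L[3] = {box[0], box[1], box[2]};
  double rc2 = rcut * rcut;
  int count = 0;
  for (int b = 0; b < B.nrow(); ++b) {
    for (int a = 0; a < A.nrow(); ++a) {
      double dx = mindelta(A(a, 0) - B(b, 0), L[0]);
      double dy = mindelta(A(a, 1) - B(b, 1), L[1]);
      double dz = mindelta(A(a, 2) - B(b, 2), L[2]);
      if (dx * dx + dy * dy + dz * dz <= rc2) { ++count; break; }
    }
  }
  return count;
}

// 8-connected component labelling of a binary mask (union-find).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  UF uf(nr * nc);
  auto idx = [&](int r, int c) { return c * nr + r; };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      const int dr[4] = {-1, -1, -1, 0};
      const int dc[4] = {-1, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (mask(rr, cc)) uf.unite(idx(r, c), idx(rr, cc));
      }
    }
  IntegerMatrix lab(nr, nc);
  std::vector<int> remap(nr * nc, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) { lab(r, c) = 0; continue; }
      int root = uf.find(idx(r, c));
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  return lab;
}

// Deterministic seed splitting (splitmix64 -> positive 31-bit integer).
// [[Rcpp::export]]
int cpp_split_seed(int seed, int index) {
  uint64_t x = ((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)(uint32_t)index;
  uint64_t z = Xoshiro::splitmix64(x);
  return (int)(z % 2147483646ULL) + 1;
}
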