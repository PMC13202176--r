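// Coarse-grained chromatin Langevin engine.
//
// Internal units: length in Angstrom, energy in kcal/mol, mass = 1 per bead.
// The internal time unit is t* = sqrt(mass * A^2 / (kcal/mol)); the mapping to
// physical time (ns per timestep) is metadata handled on the R side.
//
// Single-threaded and fully deterministic for a given seed: each bead owns an
// independent counter-based RNG substream derived from (seed, bead index), so
// trajectories do not depend on how work would be scheduled.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256+ substream per bead, Box-Muller gaussians.
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct BeadRng {
  uint64_t s[4];
  bool has_spare;
  double spare;
  void seed(uint64_t run_seed, uint64_t bead) {
    uint64_t x = run_seed * 0x9E3779B97f4A7C15ULL + (bead + 1) * 0xD1342543DE82EF95ULL;
    for (int k = 0; k < 4; ++k) s[k] = splitmix64(x);
    has_spare = false;
    spare = 0.0;
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {
    // 53-bit mantissa uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// Model containers
// ---------------------------------------------------------------------------
struct Bond { int i, j; double r0, k; };
struct Morse { int i, j; double de, a, r0; };
struct Angle { int i, j, k; double th0, kth; };

struct Params {
  int n;
  std::vector<int> cls;        // 0-based class index per bead
  std::vector<double> charge;
  std::vector<double> eps;     // nclass x nclass, row-major
  int nclass;
  double sigma;
  double rc_lj, rc_dh;
  double kappa, coul_pref;     // coul_pref = 332.0637 / dielectric
  bool softcore;
  double rcap;                 // soft-core capping radius
  // boundary: 0 none, 1 sphere, 2 periodic box
  int boundary;
  double wall_R, wall_eps;
  double box[3];
  // restraint on centroid distance of two groups
  bool restrain;
  double restr_c, restr_k;
  std::vector<int> grp1, grp2;
  // nematic axis-alignment restraint: U = k_o (1 - (u.v)^2), with u and v the
  // unit vectors between the centroids of (a_top, a_bot) and (b_top, b_bot)
  bool orient;
  double orient_k;
  std::vector<int> a_top, a_bot, b_top, b_bot;
  // coaxiality restraint: U = k_c (1 - (u.w)^2) with w the unit
  // centroid-centroid vector of grp1/grp2 and u the body-A axis
  bool coax;
  double coax_k;
  std::vector<Bond> bonds;
  std::vector<Morse> morses;
  std::vector<Angle> angles;
  // exclusions: per-bead sorted lists (only j > i stored both ways for lookup)
  std::vector<std::vector<int>> excl;
};

static inline bool is_excluded(const Params &P, int i, int j) {
  const std::vector<int> &e = P.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

static inline void min_image(const Params &P, double &dx, double &dy, double &dz) {
  if (P.boundary == 2) {
    dx -= P.box[0] * std::nearbyint(dx / P.box[0]);
    dy -= P.box[1] * std::nearbyint(dy / P.box[1]);
    dz -= P.box[2] * std::nearbyint(dz / P.box[2]);
  }
}

// LJ evaluated from the squared distance (no sqrt on the standard path);
// energy shifted to zero at the cutoff via a precomputed per-strength shift.
// for_r = (dU/dr)/r with sign such that the force on i is -for_r * dr_vec.
static inline void lj_pair(double eps, double sigma2, double uc, double r2,
                           bool softcore, double rcap,
                           double &u, double &for_r) {
  if (softcore && r2 < rcap * rcap) {
    // constant-force linear continuation below rcap
    double r = std::sqrt(r2);
    double sr2 = sigma2 / (rcap * rcap);
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    double f = 24.0 * eps * (2.0 * sr12 - sr6) / rcap; // -dU/dr at rcap
    u = 4.0 * eps * (sr12 - sr6) + f * (rcap - r) - uc;
    for_r = -f / r;
    return;
  }
  double sr2 = sigma2 / r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  u = 4.0 * eps * (sr12 - sr6) - uc;
  for_r = -24.0 * eps * (2.0 * sr12 - sr6) / r2;
}

static inline void dh_pair(double pref_qq, double kappa, double r2, double rc,
                           double &u, double &for_r) {
  double r = std::sqrt(r2);
  if (r >= rc) { u = 0.0; for_r = 0.0; return; }
  double uc = pref_qq * std::exp(-kappa * rc) / rc;
  double e = pref_qq * std::exp(-kappa * r) / r;
  u = e - uc;
  double f = e * (1.0 / r + kappa);           // -dU/dr
  for_r = -f / r;
}

// ---------------------------------------------------------------------------
// Neighbor list (cell-binned Verlet list, displacement-criterion rebuild)
// ---------------------------------------------------------------------------
struct NeighborList {
  double rlist, skin;
  std::vector<std::pair<int, int>> pairs;
  std::vector<double> xref;

  void build(const Params &P, const std::vector<double> &x) {
    pairs.clear();
    xref = x;
    int n = P.n;
    double lo[3], hi[3], L[3];
    if (P.boundary == 2) {
      for (int d = 0; d < 3; ++d) { lo[d] = 0.0; L[d] = P.box[d]; }
    } else {
      for (int d = 0; d < 3; ++d) { lo[d] = 1e30; hi[d] = -1e30; }
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          lo[d] = std::min(lo[d], x[3 * i + d]);
          hi[d] = std::max(hi[d], x[3 * i + d]);
        }
      for (int d = 0; d < 3; ++d) L[d] = std::max(hi[d] - lo[d], 1e-6) + 1e-6;
    }
    int nc[3];
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor(L[d] / rlist));
      if (P.boundary == 2 && nc[d] < 3) nc[d] = 1; // too few cells to wrap safely
    }
    long ncell = (long)nc[0] * nc[1] * nc[2];
    bool brute = (ncell <= 8) || (n < 64);
    double r2max = rlist * rlist;
    if (brute) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = x[3 * i] - x[3 * j];
          double dy = x[3 * i + 1] - x[3 * j + 1];
          double dz = x[3 * i + 2] - x[3 * j + 2];
          min_image(P, dx, dy, dz);
          if (dx * dx + dy * dy + dz * dz < r2max && !is_excluded(P, i, j))
            pairs.push_back({i, j});
        }
      return;
    }
    std::vector<int> head(ncell, -1), nxt(n, -1), cellof(n);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        double u = (x[3 * i + d] - lo[d]) / L[d];
        if (P.boundary == 2) u -= std::floor(u);
        int ci = (int)(u * nc[d]);
        if (ci >= nc[d]) ci = nc[d] - 1;
        if (ci < 0) ci = 0;
        c[d] = ci;
      }
      long idx = (long)c[0] + nc[0] * ((long)c[1] + nc[1] * (long)c[2]);
      cellof[i] = (int)idx;
      nxt[i] = head[idx];
      head[idx] = i;
    }
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          long c0 = (long)cx + nc[0] * ((long)cy + nc[1] * (long)cz);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx2 = -1; dx2 <= 1; ++dx2) {
                int ax = cx + dx2, ay = cy + dy, az = cz + dz;
                if (P.boundary == 2) {
                  ax = (ax + nc[0]) % nc[0];
                  ay = (ay + nc[1]) % nc[1];
                  az = (az + nc[2]) % nc[2];
                } else if (ax < 0 || ay < 0 || az < 0 ||
                           ax >= nc[0] || ay >= nc[1] || az >= nc[2]) {
                  continue;
                }
                long c1 = (long)ax + nc[0] * ((long)ay + nc[1] * (long)az);
                if (c1 < c0) continue;
                for (int i = head[c0]; i != -1; i = nxt[i])
                  for (int j = (c1 == c0 ? nxt[i] : head[c1]); j != -1; j = nxt[j]) {
                    double ddx = x[3 * i] - x[3 * j];
                    double ddy = x[3 * i + 1] - x[3 * j + 1];
                    double ddz = x[3 * i + 2] - x[3 * j + 2];
                    min_image(P, ddx, ddy, ddz);
                    if (ddx * ddx + ddy * ddy + ddz * ddz < r2max &&
                        !is_excluded(P, std::min(i, j), std::max(i, j)))
                      pairs.push_back({std::min(i, j), std::max(i, j)});
                  }
              }
        }
  }

  bool needs_rebuild(const Params &P, const std::vector<double> &x) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < P.n; ++i) {
      double dx = x[3 * i] - xref[3 * i];
      double dy = x[3 * i + 1] - xref[3 * i + 1];
      double dz = x[3 * i + 2] - xref[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------------------
// Forces and potential energy
// ---------------------------------------------------------------------------
struct EnergyBreakdown {
  double lj = 0, dh = 0, bond = 0, morse = 0, angle = 0, wall = 0, restraint = 0;
  double total() const { return lj + dh + bond + morse + angle + wall + restraint; }
};

static EnergyBreakdown compute_forces(const Params &P,
                                      const std::vector<double> &x,
                                      const NeighborList &nl,
                                      std::vector<double> &f) {
  EnergyBreakdown E;
  std::fill(f.begin(), f.end(), 0.0);
  double rc_lj2 = P.rc_lj * P.rc_lj;
  double rc_dh2 = P.rc_dh * P.rc_dh;
  double rcmax2 = std::max(rc_lj2, rc_dh2);
  double sigma2 = P.sigma * P.sigma;
  // per-strength cutoff shift: uc = 4 eps (s12 - s6) at rc
  double s2c = sigma2 / rc_lj2, s6c = s2c * s2c * s2c;
  double uc_unit = 4.0 * (s6c * s6c - s6c); // times eps

  for (const auto &pr : nl.pairs) {
    int i = pr.first, j = pr.second;
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    min_image(P, dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rcmax2) continue;
    double eps = P.eps[P.cls[i] * P.nclass + P.cls[j]];
    double u, fr, ftot = 0.0;
    if (eps > 0.0 && r2 < rc_lj2) {
      lj_pair(eps, sigma2, eps * uc_unit, r2, P.softcore, P.rcap, u, fr);
      E.lj += u;
      ftot += fr;
    }
    double qq = P.charge[i] * P.charge[j];
    if (qq != 0.0 && r2 < rc_dh2) {
      dh_pair(P.coul_pref * qq, P.kappa, r2, P.rc_dh, u, fr);
      E.dh += u;
      ftot += fr;
    }
    if (ftot != 0.0) {
      f[3 * i] -= ftot * dx; f[3 * i + 1] -= ftot * dy; f[3 * i + 2] -= ftot * dz;
      f[3 * j] += ftot * dx; f[3 * j + 1] += ftot * dy; f[3 * j + 2] += ftot * dz;
    }
  }

  for (const auto &b : P.bonds) {
    double dx = x[3 * b.i] - x[3 * b.j];
    double dy = x[3 * b.i + 1] - x[3 * b.j + 1];
    double dz = x[3 * b.i + 2] - x[3 * b.j + 2];
    min_image(P, dx, dy, dz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - b.r0;
    E.bond += b.k * dr * dr;
    double fr = 2.0 * b.k * dr / std::max(r, 1e-12); // (dU/dr)/r
    f[3 * b.i] -= fr * dx; f[3 * b.i + 1] -= fr * dy; f[3 * b.i + 2] -= fr * dz;
    f[3 * b.j] += fr * dx; f[3 * b.j + 1] += fr * dy; f[3 * b.j + 2] += fr * dz;
  }

  for (const auto &m : P.morses) {
    double dx = x[3 * m.i] - x[3 * m.j];
    double dy = x[3 * m.i + 1] - x[3 * m.j + 1];
    double dz = x[3 * m.i + 2] - x[3 * m.j + 2];
    min_image(P, dx, dy, dz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ex = std::exp(-m.a * (r - m.r0));
    double omx = 1.0 - ex;
    E.morse += m.de * omx * omx;
    double dudr = 2.0 * m.de * m.a * ex * omx;
    double fr = dudr / std::max(r, 1e-12);
    f[3 * m.i] -= fr * dx; f[3 * m.i + 1] -= fr * dy; f[3 * m.i + 2] -= fr * dz;
    f[3 * m.j] += fr * dx; f[3 * m.j + 1] += fr * dy; f[3 * m.j + 2] += fr * dz;
  }

  for (const auto &a : P.angles) {
    // U = kth * (theta - th0)^2, vertex at j
    double r1x = x[3 * a.i] - x[3 * a.j], r1y = x[3 * a.i + 1] - x[3 * a.j + 1],
           r1z = x[3 * a.i + 2] - x[3 * a.j + 2];
    double r2x = x[3 * a.k] - x[3 * a.j], r2y = x[3 * a.k + 1] - x[3 * a.j + 1],
           r2z = x[3 * a.k + 2] - x[3 * a.j + 2];
    min_image(P, r1x, r1y, r1z);
    min_image(P, r2x, r2y, r2z);
    double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
    double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
    double c = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - a.th0;
    E.angle += a.kth * dth * dth;
    double s = std::sqrt(std::max(1.0 - c * c, 1e-10));
    double coef = 2.0 * a.kth * dth / s; // dU/d(cos theta) * (-1) handled below
    // dcos/dri and dcos/drk
    double gx1 = (r2x / (n1 * n2)) - c * r1x / (n1 * n1);
    double gy1 = (r2y / (n1 * n2)) - c * r1y / (n1 * n1);
    double gz1 = (r2z / (n1 * n2)) - c * r1z / (n1 * n1);
    double gx2 = (r1x / (n1 * n2)) - c * r2x / (n2 * n2);
    double gy2 = (r1y / (n1 * n2)) - c * r2y / (n2 * n2);
    double gz2 = (r1z / (n1 * n2)) - c * r2z / (n2 * n2);
    // F_i = -dU/dri = -dU/dth * dth/dcos * dcos/dri = coef * dcos/dri
    f[3 * a.i] += coef * gx1; f[3 * a.i + 1] += coef * gy1; f[3 * a.i + 2] += coef * gz1;
    f[3 * a.k] += coef * gx2; f[3 * a.k + 1] += coef * gy2; f[3 * a.k + 2] += coef * gz2;
    f[3 * a.j] -= coef * (gx1 + gx2);
    f[3 * a.j + 1] -= coef * (gy1 + gy2);
    f[3 * a.j + 2] -= coef * (gz1 + gz2);
  }

  if (P.boundary == 1) {
    // purely repulsive (WCA) wall acting inward from the sphere surface
    double wca_cut = P.sigma * 1.122462048309373;
    for (int i = 0; i < P.n; ++i) {
      double r = std::sqrt(x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                           x[3 * i + 2] * x[3 * i + 2]);
      double d = P.wall_R - r;
      if (d >= wca_cut) continue;
      double dd = std::max(d, 0.5); // clamp to keep the force finite
      double sr2 = (P.sigma * P.sigma) / (dd * dd);
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      E.wall += 4.0 * P.wall_eps * (sr12 - sr6) + P.wall_eps;
      double fmag = 24.0 * P.wall_eps * (2.0 * sr12 - sr6) / dd; // -dU/dd, pushes inward
      if (r > 1e-9) {
        double fr = -fmag / r;
        f[3 * i] += fr * x[3 * i];
        f[3 * i + 1] += fr * x[3 * i + 1];
        f[3 * i + 2] += fr * x[3 * i + 2];
      }
    }
  }

  if (P.orient) {
    auto centroid = [&](const std::vector<int> &g, double *c) {
      c[0] = c[1] = c[2] = 0;
      for (int i : g) for (int d = 0; d < 3; ++d) c[d] += x[3 * i + d];
      for (int d = 0; d < 3; ++d) c[d] /= g.size();
    };
    double cat[3], cab[3], cbt[3], cbb[3];
    centroid(P.a_top, cat); centroid(P.a_bot, cab);
    centroid(P.b_top, cbt); centroid(P.b_bot, cbb);
    double a[3], b[3];
    for (int d = 0; d < 3; ++d) { a[d] = cat[d] - cab[d]; b[d] = cbt[d] - cbb[d]; }
    double na = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
    double nb = std::sqrt(b[0]*b[0] + b[1]*b[1] + b[2]*b[2]);
    if (na > 1e-9 && nb > 1e-9) {
      double u[3], v[3];
      for (int d = 0; d < 3; ++d) { u[d] = a[d] / na; v[d] = b[d] / nb; }
      double s = u[0]*v[0] + u[1]*v[1] + u[2]*v[2];
      E.restraint += P.orient_k * (1.0 - s * s);
      // dU/da = -2 k s (v - s u)/na ; dU/db = -2 k s (u - s v)/nb
      double ga[3], gb[3];
      for (int d = 0; d < 3; ++d) {
        ga[d] = -2.0 * P.orient_k * s * (v[d] - s * u[d]) / na;
        gb[d] = -2.0 * P.orient_k * s * (u[d] - s * v[d]) / nb;
      }
      double wat = 1.0 / P.a_top.size(), wab = 1.0 / P.a_bot.size();
      double wbt = 1.0 / P.b_top.size(), wbb = 1.0 / P.b_bot.size();
      for (int i : P.a_top) for (int d = 0; d < 3; ++d) f[3*i+d] -= ga[d] * wat;
      for (int i : P.a_bot) for (int d = 0; d < 3; ++d) f[3*i+d] += ga[d] * wab;
      for (int i : P.b_top) for (int d = 0; d < 3; ++d) f[3*i+d] -= gb[d] * wbt;
      for (int i : P.b_bot) for (int d = 0; d < 3; ++d) f[3*i+d] += gb[d] * wbb;
    }
  }

  if (P.coax) {
    auto centroid = [&](const std::vector<int> &g, double *c) {
      c[0] = c[1] = c[2] = 0;
      for (int i : g) for (int d = 0; d < 3; ++d) c[d] += x[3 * i + d];
      for (int d = 0; d < 3; ++d) c[d] /= g.size();
    };
    double cat[3], cab[3], c1[3], c2[3];
    centroid(P.a_top, cat); centroid(P.a_bot, cab);
    centroid(P.grp1, c1); centroid(P.grp2, c2);
    double a[3], dvec[3];
    for (int d = 0; d < 3; ++d) { a[d] = cat[d] - cab[d]; dvec[d] = c2[d] - c1[d]; }
    double na = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
    double nd = std::sqrt(dvec[0]*dvec[0] + dvec[1]*dvec[1] + dvec[2]*dvec[2]);
    if (na > 1e-9 && nd > 1e-9) {
      double u[3], w[3];
      for (int d = 0; d < 3; ++d) { u[d] = a[d] / na; w[d] = dvec[d] / nd; }
      double s = u[0]*w[0] + u[1]*w[1] + u[2]*w[2];
      E.restraint += P.coax_k * (1.0 - s * s);
      double ga[3], gd[3];
      for (int d = 0; d < 3; ++d) {
        ga[d] = -2.0 * P.coax_k * s * (w[d] - s * u[d]) / na; // dU/da
        gd[d] = -2.0 * P.coax_k * s * (u[d] - s * w[d]) / nd; // dU/d(c2-c1)
      }
      double wat = 1.0 / P.a_top.size(), wab = 1.0 / P.a_bot.size();
      double w1 = 1.0 / P.grp1.size(), w2 = 1.0 / P.grp2.size();
      for (int i : P.a_top) for (int d = 0; d < 3; ++d) f[3*i+d] -= ga[d] * wat;
      for (int i : P.a_bot) for (int d = 0; d < 3; ++d) f[3*i+d] += ga[d] * wab;
      for (int i : P.grp2) for (int d = 0; d < 3; ++d) f[3*i+d] -= gd[d] * w2;
      for (int i : P.grp1) for (int d = 0; d < 3; ++d) f[3*i+d] += gd[d] * w1;
    }
  }

  if (P.restrain) {
    double c1[3] = {0, 0, 0}, c2[3] = {0, 0, 0};
    for (int i : P.grp1) for (int d = 0; d < 3; ++d) c1[d] += x[3 * i + d];
    for (int i : P.grp2) for (int d = 0; d < 3; ++d) c2[d] += x[3 * i + d];
    for (int d = 0; d < 3; ++d) { c1[d] /= P.grp1.size(); c2[d] /= P.grp2.size(); }
    double dx = c1[0] - c2[0], dy = c1[1] - c2[1], dz = c1[2] - c2[2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - P.restr_c;
    E.restraint += P.restr_k * dr * dr;
    double fmag = 2.0 * P.restr_k * dr / std::max(r, 1e-12);
    double f1 = -fmag / (double)P.grp1.size();
    double f2 = fmag / (double)P.grp2.size();
    for (int i : P.grp1) {
      f[3 * i] += f1 * dx; f[3 * i + 1] += f1 * dy; f[3 * i + 2] += f1 * dz;
    }
    for (int i : P.grp2) {
      f[3 * i] += f2 * dx; f[3 * i + 1] += f2 * dy; f[3 * i + 2] += f2 * dz;
    }
  }

  return E;
}

// ---------------------------------------------------------------------------
// Parameter unpacking from R
// ---------------------------------------------------------------------------
static Params unpack(const NumericMatrix &pos, const List &model) {
  Params P;
  P.n = pos.nrow();
  IntegerVector cls = model["class_id"]; // 1-based classes
  NumericVector charge = model["charge"];
  NumericMatrix eps = model["eps_matrix"];
  P.nclass = eps.nrow();
  P.cls.resize(P.n);
  P.charge.resize(P.n);
  for (int i = 0; i < P.n; ++i) {
    P.cls[i] = cls[i] - 1;
    P.charge[i] = charge[i];
  }
  P.eps.assign(P.nclass * P.nclass, 0.0);
  for (int a = 0; a < P.nclass; ++a)
    for (int b = 0; b < P.nclass; ++b)
      P.eps[a * P.nclass + b] = eps(a, b);
  P.sigma = as<double>(model["sigma"]);
  P.rc_lj = as<double>(model["rc_lj"]);
  P.rc_dh = as<double>(model["rc_dh"]);
  P.kappa = as<double>(model["kappa"]);
  P.coul_pref = as<double>(model["coul_pref"]);
  P.softcore = as<bool>(model["softcore"]);
  P.rcap = as<double>(model["rcap"]);
  P.boundary = as<int>(model["boundary"]);
  P.wall_R = as<double>(model["wall_radius"]);
  P.wall_eps = as<double>(model["wall_eps"]);
  NumericVector box = model["box"];
  for (int d = 0; d < 3; ++d) P.box[d] = box[d];
  P.restrain = as<bool>(model["restrain"]);
  P.restr_c = as<double>(model["restraint_center"]);
  P.restr_k = as<double>(model["restraint_k"]);
  IntegerVector g1 = model["group1"], g2 = model["group2"];
  for (int i = 0; i < g1.size(); ++i) P.grp1.push_back(g1[i] - 1);
  for (int i = 0; i < g2.size(); ++i) P.grp2.push_back(g2[i] - 1);
  P.orient = as<bool>(model["orient"]);
  P.orient_k = as<double>(model["orient_k"]);
  P.coax = as<bool>(model["coax"]);
  P.coax_k = as<double>(model["coax_k"]);
  IntegerVector at = model["a_top"], ab = model["a_bot"],
                bt = model["b_top"], bb = model["b_bot"];
  for (int i = 0; i < at.size(); ++i) P.a_top.push_back(at[i] - 1);
  for (int i = 0; i < ab.size(); ++i) P.a_bot.push_back(ab[i] - 1);
  for (int i = 0; i < bt.size(); ++i) P.b_top.push_back(bt[i] - 1);
  for (int i = 0; i < bb.size(); ++i) P.b_bot.push_back(bb[i] - 1);

  NumericMatrix B = model["bonds"];   // i j r0 k (1-based)
  for (int r = 0; r < B.nrow(); ++r)
    P.bonds.push_back({(int)B(r, 0) - 1, (int)B(r, 1) - 1, B(r, 2), B(r, 3)});
  NumericMatrix M = model["morse"];   // i j de a r0
  for (int r = 0; r < M.nrow(); ++r)
    P.morses.push_back({(int)M(r, 0) - 1, (int)M(r, 1) - 1, M(r, 2), M(r, 3), M(r, 4)});
  NumericMatrix A = model["angles"];  // i j k th0 kth
  for (int r = 0; r < A.nrow(); ++r)
    P.angles.push_back({(int)A(r, 0) - 1, (int)A(r, 1) - 1, (int)A(r, 2) - 1,
                        A(r, 3), A(r, 4)});
  IntegerMatrix X = model["exclusions"]; // i j (1-based, i < j)
  P.excl.assign(P.n, {});
  for (int r = 0; r < X.nrow(); ++r) {
    int i = X(r, 0) - 1, j = X(r, 1) - 1;
    P.excl[std::min(i, j)].push_back(std::max(i, j));
  }
  // bonded pairs are always excluded from nonbonded interactions
  for (const auto &b : P.bonds)
    P.excl[std::min(b.i, b.j)].push_back(std::max(b.i, b.j));
  for (const auto &m : P.morses)
    P.excl[std::min(m.i, m.j)].push_back(std::max(m.i, m.j));
  for (auto &e : P.excl) {
    std::sort(e.begin(), e.end());
    e.erase(std::unique(e.begin(), e.end()), e.end());
  }
  return P;
}

// [[Rcpp::export(name = ".cg_energy")]]
List cg_energy(NumericMatrix pos, List model) {
  Params P = unpack(pos, model);
  std::vector<double> x(3 * P.n), f(3 * P.n);
  for (int i = 0; i < P.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  NeighborList nl;
  nl.skin = 0.3 * P.sigma;
  nl.rlist = std::max(P.rc_lj, P.rc_dh) + nl.skin;
  nl.build(P, x);
  EnergyBreakdown E = compute_forces(P, x, nl, f);
  NumericMatrix force(P.n, 3);
  for (int i = 0; i < P.n; ++i)
    for (int d = 0; d < 3; ++d) force(i, d) = f[3 * i + d];
  return List::create(
      _["total"] = E.total(), _["lj"] = E.lj, _["dh"] = E.dh, _["bond"] = E.bond,
      _["morse"] = E.morse, _["angle"] = E.angle, _["wall"] = E.wall,
      _["restraint"] = E.restraint, _["forces"] = force);
}

// Group-level contacts: two groups (e.g. nucleosomes) are in contact when
// their minimum inter-bead distance is below the cutoff. `group` is 1-based;
// beads with group 0 are ignored. Returns the per-frame-accumulated count
// matrix (frames x upper triangle handled symmetrically).
// [[Rcpp::export(name = ".cg_contact_counts")]]
NumericMatrix cg_contact_counts(NumericMatrix frames, IntegerVector group,
                                int ngroups, double cutoff,
                                NumericVector box) {
  int nf = frames.nrow();
  int n = group.size();
  bool pbc = box.size() == 3 && box[0] > 0;
  NumericMatrix counts(ngroups, ngroups);
  std::vector<char> seen((size_t)ngroups * ngroups);
  double c2 = cutoff * cutoff;
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) if (group[i] > 0) keep.push_back(i);
  int m = keep.size();
  std::vector<double> x(3 * m);
  for (int f = 0; f < nf; ++f) {
    for (int a = 0; a < m; ++a)
      for (int d = 0; d < 3; ++d) x[3 * a + d] = frames(f, 3 * keep[a] + d);
    std::fill(seen.begin(), seen.end(), 0);
    // cell binning
    double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
    for (int a = 0; a < m; ++a)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], x[3 * a + d]);
        hi[d] = std::max(hi[d], x[3 * a + d]);
      }
    int nc[3];
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)((hi[d] - lo[d]) / cutoff) + 1);
      // cap the table for tiny cutoffs; out-of-range indices clamp into the
      // last cell, which only adds extra (correct) pair checks
      if (nc[d] > 128) nc[d] = 128;
    }
    long ncell = (long)nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(m, -1);
    auto cellidx = [&](int a) {
      long c[3];
      for (int d = 0; d < 3; ++d) {
        c[d] = (long)((x[3 * a + d] - lo[d]) / cutoff);
        if (c[d] >= nc[d]) c[d] = nc[d] - 1;
      }
      return c[0] + nc[0] * (c[1] + nc[1] * c[2]);
    };
    for (int a = 0; a < m; ++a) {
      long ci = cellidx(a);
      nxt[a] = head[ci];
      head[ci] = a;
    }
    for (int a = 0; a < m; ++a) {
      long cx = (long)((x[3 * a] - lo[0]) / cutoff);
      long cy = (long)((x[3 * a + 1] - lo[1]) / cutoff);
      long cz = (long)((x[3 * a + 2] - lo[2]) / cutoff);
      if (cx >= nc[0]) cx = nc[0] - 1;
      if (cy >= nc[1]) cy = nc[1] - 1;
      if (cz >= nc[2]) cz = nc[2] - 1;
      for (long dx = -1; dx <= 1; ++dx)
        for (long dy = -1; dy <= 1; ++dy)
          for (long dz = -1; dz <= 1; ++dz) {
            long ax = cx + dx, ay = cy + dy, az = cz + dz;
            if (ax < 0 || ay < 0 || az < 0 ||
                ax >= nc[0] || ay >= nc[1] || az >= nc[2]) continue;
            for (int b = head[ax + nc[0] * (ay + nc[1] * az)]; b != -1;
                 b = nxt[b]) {
              if (b <= a) continue;
              int ga = group[keep[a]], gb = group[keep[b]];
              double ddx = x[3 * a] - x[3 * b];
              double ddy = x[3 * a + 1] - x[3 * b + 1];
              double ddz = x[3 * a + 2] - x[3 * b + 2];
              if (pbc) {
                ddx -= box[0] * std::nearbyint(ddx / box[0]);
                ddy -= box[1] * std::nearbyint(ddy / box[1]);
                ddz -= box[2] * std::nearbyint(ddz / box[2]);
              }
              if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
                int g1 = std::min(ga, gb) - 1, g2 = std::max(ga, gb) - 1;
                seen[(size_t)g1 * ngroups + g2] = 1;
              }
            }
          }
    }
    for (int g1 = 0; g1 < ngroups; ++g1)
      for (int g2 = g1; g2 < ngroups; ++g2)
        if (seen[(size_t)g1 * ngroups + g2]) {
          counts(g1, g2) += 1;
          if (g2 != g1) counts(g2, g1) += 1;
        }
  }
  return counts;
}

// Contact pair list for a single configuration (same contact definition).
// [[Rcpp::export(name = ".cg_contact_pairs")]]
IntegerMatrix cg_contact_pairs(NumericMatrix pos, IntegerVector group,
                               int ngroups, double cutoff, NumericVector box) {
  NumericMatrix fr(1, 3 * pos.nrow());
  for (int i = 0; i < pos.nrow(); ++i)
    for (int d = 0; d < 3; ++d) fr(0, 3 * i + d) = pos(i, d);
  NumericMatrix counts = cg_contact_counts(fr, group, ngroups, cutoff, box);
  std::vector<std::pair<int, int>> prs;
  for (int a = 0; a < ngroups; ++a)
    for (int b = a + 1; b < ngroups; ++b)
      if (counts(a, b) > 0) prs.push_back({a + 1, b + 1});
  IntegerMatrix out(prs.size(), 2);
  for (size_t k = 0; k < prs.size(); ++k) {
    out(k, 0) = prs[k].first;
    out(k, 1) = prs[k].second;
  }
  return out;
}

// [[Rcpp::export(name = ".cg_min_nonbonded")]]
List cg_min_nonbonded(NumericMatrix pos, List model) {
  Params P = unpack(pos, model);
  std::vector<double> x(3 * P.n);
  for (int i = 0; i < P.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  NeighborList nl;
  nl.skin = 0.3 * P.sigma;
  nl.rlist = std::max(P.rc_lj, P.rc_dh) + nl.skin;
  nl.build(P, x);
  double best = 1e30;
  int bi = -1, bj = -1;
  for (const auto &pr : nl.pairs) {
    double dx = x[3 * pr.first] - x[3 * pr.second];
    double dy = x[3 * pr.first + 1] - x[3 * pr.second + 1];
    double dz = x[3 * pr.first + 2] - x[3 * pr.second + 2];
    min_image(P, dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < best) { best = r2; bi = pr.first; bj = pr.second; }
  }
  return List::create(_["min_dist"] = (bi < 0) ? R_PosInf : std::sqrt(best),
                      _["i"] = bi + 1, _["j"] = bj + 1);
}

// [[Rcpp::export(name = ".cg_run")]]
List cg_run(NumericMatrix pos, List model, List run) {
  Params P = unpack(pos, model);
  int n = P.n;
  double dt = as<double>(run["dt"]);
  double damp = as<double>(run["damp"]);       // Langevin damping time, internal units
  double kBT = as<double>(run["kBT"]);
  long nsteps = (long)as<double>(run["n_steps"]);
  long dump_every = (long)as<double>(run["dump_every"]);
  long cv_every = (long)as<double>(run["colvar_every"]); // 0 = off
  uint64_t seed = (uint64_t)as<double>(run["seed"]);
  double fmax = as<double>(run["force_max"]);
  bool zero_temperature = as<bool>(run["quench"]);       // damped descent, no noise

  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);

  NumericMatrix v0m = run["velocities"];
  bool have_v0 = v0m.nrow() == n;
  std::vector<BeadRng> rng(n);
  for (int i = 0; i < n; ++i) rng[i].seed(seed, i);
  if (have_v0) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] = v0m(i, d);
  } else if (!zero_temperature) {
    double sv = std::sqrt(kBT);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] = sv * rng[i].gauss();
  }

  NeighborList nl;
  nl.skin = 0.3 * P.sigma;
  nl.rlist = std::max(P.rc_lj, P.rc_dh) + nl.skin;
  nl.build(P, x);

  double c1 = std::exp(-dt / damp);
  double c2 = std::sqrt(kBT * (1.0 - c1 * c1));

  long nframes = (dump_every > 0) ? nsteps / dump_every : 0;
  NumericMatrix frames(std::max(nframes, (long)0), (nframes > 0) ? 3 * n : 0);
  NumericVector frame_step(std::max(nframes, (long)0));
  NumericVector pe_series(std::max(nframes, (long)0));
  NumericVector ke_series(std::max(nframes, (long)0));
  long ncv = (cv_every > 0) ? nsteps / cv_every : 0;
  NumericVector colvar(std::max(ncv, (long)0));

  EnergyBreakdown E = compute_forces(P, x, nl, f);
  long iframe = 0, icv = 0;

  // damped-descent speed clamp: steep excluded-volume walls must not cause
  // overshoot during quenches
  double vmax = 0.05 * P.sigma / dt;
  auto clamp_v = [&]() {
    for (int i = 0; i < n; ++i) {
      double sp = std::sqrt(v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                            v[3 * i + 2] * v[3 * i + 2]);
      if (sp > vmax) {
        double s = vmax / sp;
        v[3 * i] *= s; v[3 * i + 1] *= s; v[3 * i + 2] *= s;
      }
    }
  };

  for (long step = 1; step <= nsteps; ++step) {
    // B
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];
    if (zero_temperature) clamp_v();
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (zero_temperature) {
      for (int i = 0; i < 3 * n; ++i) v[i] *= c1;
    } else {
      for (int i = 0; i < n; ++i) {
        v[3 * i] = c1 * v[3 * i] + c2 * rng[i].gauss();
        v[3 * i + 1] = c1 * v[3 * i + 1] + c2 * rng[i].gauss();
        v[3 * i + 2] = c1 * v[3 * i + 2] + c2 * rng[i].gauss();
      }
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // forces, then B
    if (nl.needs_rebuild(P, x)) nl.build(P, x);
    E = compute_forces(P, x, nl, f);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];
    if (zero_temperature) clamp_v();

    if (!zero_temperature && step % 1000 == 0) {
      for (int i = 0; i < n; ++i) {
        double fm = std::fabs(f[3 * i]) + std::fabs(f[3 * i + 1]) + std::fabs(f[3 * i + 2]);
        if (fm > fmax || !std::isfinite(fm))
          stop("force blow-up on bead %d at step %ld (|F| = %g kcal/mol/A)",
               i + 1, step, fm);
      }
    }

    if (cv_every > 0 && step % cv_every == 0 && icv < ncv) {
      double cc1[3] = {0, 0, 0}, cc2[3] = {0, 0, 0};
      for (int i : P.grp1) for (int d = 0; d < 3; ++d) cc1[d] += x[3 * i + d];
      for (int i : P.grp2) for (int d = 0; d < 3; ++d) cc2[d] += x[3 * i + d];
      for (int d = 0; d < 3; ++d) { cc1[d] /= P.grp1.size(); cc2[d] /= P.grp2.size(); }
      double dx = cc1[0] - cc2[0], dy = cc1[1] - cc2[1], dz = cc1[2] - cc2[2];
      colvar[icv++] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }

    if (dump_every > 0 && step % dump_every == 0 && iframe < nframes) {
      double ke = 0.0;
      for (int i = 0; i < 3 * n; ++i) ke += 0.5 * v[i] * v[i];
      for (int i = 0; i < 3 * n; ++i) frames(iframe, i) = x[i];
      frame_step[iframe] = (double)step;
      pe_series[iframe] = E.total();
      ke_series[iframe] = ke;
      ++iframe;
    }
  }

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xf(i, d) = x[3 * i + d];
      vf(i, d) = v[3 * i + d];
    }
  return List::create(
      _["frames"] = frames, _["frame_step"] = frame_step,
      _["potential"] = pe_series, _["kinetic"] = ke_series,
      _["colvar"] = colvar, _["final_positions"] = xf,
      _["final_velocities"] = vf, _["n_pairs_last"] = (double)nl.pairs.size());
}
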