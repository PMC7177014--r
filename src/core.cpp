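// Coarse-grained membrane engine: implicit-solvent lipid model
// (soft-core WCA repulsion for all pairs, smoothly truncated cosine^2
// attraction between selected bead classes, harmonic bonds, cosine angle
// stiffness), the zone-scaled thinning field, Langevin (BAOAB) dynamics,
// and the grid scanner for solvent-exposed tail patches.
//
// Units: nm, ps, kJ/mol, K, amu. Periodic in x and y; open in z.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// wrap into [0, L); floor-based to stay independent of libm's fmod variants
static inline double wrap0(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  if (x < 0) x = 0;
  return x;
}

static inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// deterministic gaussian stream seeded from R's RNG (keeps set.seed control
// without paying the per-call cost of R's generator in the O-step)
struct GaussRNG {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0;
  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = runif(), u2 = runif();
    double m = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = m * std::sin(a);
    have_spare = true;
    return m * std::cos(a);
  }
};

struct FieldSpec {
  bool on;
  double k, D;           // force constant, minimal-thickness parameter
  double Xbox, Athin, Abuffer, xc;
};

// zone scaling C(x): 1 in thin zone, linear ramp over buffers, 0 in normal
static inline double zone_C(double x, const FieldSpec& f) {
  double dx = wrap0(x - f.xc, f.Xbox);
  if (dx > 0.5 * f.Xbox) dx -= f.Xbox;
  double c = 1.0 - (std::fabs(dx) - 0.5 * f.Athin) / f.Abuffer;
  if (c > 1.0) c = 1.0;
  if (c < 0.0) c = 0.0;
  return c;
}

struct System {
  int n;
  std::vector<double> x, y, z;
  std::vector<double> sigma;      // per-bead WCA diameter
  std::vector<int> att;           // 0 none, 1 head, 2 tail, 3 probe-hydrophobic
  std::vector<double> eps;        // per-bead attraction scale
  std::vector<double> se;         // sqrt(eps), precomputed
  std::vector<double> sh;         // sigma/2, precomputed
  std::vector<char> tail;        // thinning field targets
  std::vector<char> lipid;       // beads entering the midplane average
  std::vector<int> mol;          // molecule id; intramolecular pairs are excluded
  double Lx, Ly, Lz;
  // bonded terms
  std::vector<int> b_i, b_j; std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_kk;
  // exclusions (directly bonded pairs)
  std::vector<std::vector<int>> excl;
  double eps_rep, wc;
  // tabulated cosine^2 attraction: U factor and dU/dr factor on u = (r-rc)/wc
  std::vector<double> tabU, tabF;
  // neighbor list
  std::vector<int> nl_start, nl_idx;
  std::vector<double> ref_x, ref_y, ref_z;
  double rlist;
  bool have_list = false;
};

static bool attract_pair(int a, int b) {
  // tail-tail, head-head and probe(hydrophobic)-tail pairs attract
  if (a == 2 && b == 2) return true;
  if (a == 1 && b == 1) return true;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return true;
  return false;
}

static void build_neighbor_list(System& S) {
  const double L = S.rlist;
  int ncx = std::max(1, (int)std::floor(S.Lx / L));
  int ncy = std::max(1, (int)std::floor(S.Ly / L));
  // z extent from current coordinates (open dimension)
  double zmin = S.z[0], zmax = S.z[0];
  for (int i = 1; i < S.n; ++i) { zmin = std::min(zmin, S.z[i]); zmax = std::max(zmax, S.z[i]); }
  int ncz = std::max(1, (int)std::floor((zmax - zmin + 1e-9) / L) + 1);
  double cx = S.Lx / ncx, cy = S.Ly / ncy;
  std::vector<std::vector<int>> cells((size_t)ncx * ncy * ncz);
  auto cell_of = [&](int i) {
    double xx = wrap0(S.x[i], S.Lx);
    double yy = wrap0(S.y[i], S.Ly);
    int ix = std::min(ncx - 1, (int)(xx / cx));
    int iy = std::min(ncy - 1, (int)(yy / cy));
    int iz = std::min(ncz - 1, (int)((S.z[i] - zmin) / L));
    if (iz < 0) iz = 0;
    return (ix * ncy + iy) * ncz + iz;
  };
  for (int i = 0; i < S.n; ++i) cells[cell_of(i)].push_back(i);

  const double r2max = L * L;
  const double c6b = std::pow(2.0, 1.0 / 6.0);
  const double skin_pad = S.rlist - (c6b * 0.5 * (*std::max_element(S.sigma.begin(), S.sigma.end()) + *std::max_element(S.sigma.begin(), S.sigma.end())) + S.wc);
  S.nl_start.assign(S.n + 1, 0);
  std::vector<std::vector<int>> per(S.n);
  std::vector<size_t> nbr;
  for (int ix = 0; ix < ncx; ++ix) for (int iy = 0; iy < ncy; ++iy) for (int iz = 0; iz < ncz; ++iz) {
    const std::vector<int>& ci = cells[((size_t)ix * ncy + iy) * ncz + iz];
    if (ci.empty()) continue;
    // unique neighbour cells: small boxes (< 3 cells in a direction) would
    // otherwise be enumerated repeatedly through the periodic wrap
    nbr.clear();
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) for (int dz = -1; dz <= 1; ++dz) {
      int jx = ((ix + dx) % ncx + ncx) % ncx;
      int jy = ((iy + dy) % ncy + ncy) % ncy;
      int jz = iz + dz;
      if (jz < 0 || jz >= ncz) continue;
      nbr.push_back(((size_t)jx * ncy + jy) * ncz + jz);
    }
    std::sort(nbr.begin(), nbr.end());
    nbr.erase(std::unique(nbr.begin(), nbr.end()), nbr.end());
    for (size_t cidx : nbr) {
      const std::vector<int>& cj = cells[cidx];
      for (int a : ci) for (int b : cj) {
        if (b <= a) continue;
        double ddx = min_image(S.x[a] - S.x[b], S.Lx);
        double ddy = min_image(S.y[a] - S.y[b], S.Ly);
        double ddz = S.z[a] - S.z[b];
        double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (r2 > r2max) continue;
        if (S.mol[a] != 0 && S.mol[a] == S.mol[b]) continue;
        double pc = c6b * 0.5 * (S.sigma[a] + S.sigma[b]);
        if (attract_pair(S.att[a], S.att[b]) && S.eps[a] * S.eps[b] > 0)
          pc += S.wc;
        pc += skin_pad;
        if (r2 > pc * pc) continue;
        bool skip = false;
        for (int e : S.excl[a]) if (e == b) { skip = true; break; }
        if (!skip) per[a].push_back(b);
      }
    }
  }
  S.nl_idx.clear();
  for (int i = 0; i < S.n; ++i) {
    std::sort(per[i].begin(), per[i].end());
    S.nl_start[i] = (int)S.nl_idx.size();
    for (int j : per[i]) S.nl_idx.push_back(j);
  }
  S.nl_start[S.n] = (int)S.nl_idx.size();
  S.ref_x = S.x; S.ref_y = S.y; S.ref_z = S.z;
  S.have_list = true;
}

static bool list_stale(const System& S, double skin) {
  if (!S.have_list) return true;
  double lim2 = 0.25 * skin * skin;
  for (int i = 0; i < S.n; ++i) {
    double dx = min_image(S.x[i] - S.ref_x[i], S.Lx);
    double dy = min_image(S.y[i] - S.ref_y[i], S.Ly);
    double dz = S.z[i] - S.ref_z[i];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

struct ForceOut {
  std::vector<double> fx, fy, fz;      // internal forces
  std::vector<double> ex, ey, ez;      // external (field + restraint)
  double pe = 0.0;                     // internal potential energy
  double Wxx = 0, Wyy = 0, Wzz = 0;    // internal virial (pairwise decomposition)
  double midplane = 0.0;
  double com_x = NA_REAL;              // probe COM x, if restrained/probed
};

// full force evaluation; virial from pairwise/relative-vector decomposition
static void compute_forces(System& S, const FieldSpec& field,
                           const std::vector<int>& probe, double ku, double ucenter,
                           ForceOut& out, double skin) {
  const int n = S.n;
  out.fx.assign(n, 0.0); out.fy.assign(n, 0.0); out.fz.assign(n, 0.0);
  out.ex.assign(n, 0.0); out.ey.assign(n, 0.0); out.ez.assign(n, 0.0);
  out.pe = 0; out.Wxx = out.Wyy = out.Wzz = 0;

  if (list_stale(S, skin)) build_neighbor_list(S);

  const double c6 = std::pow(2.0, 1.0 / 6.0);
  // nonbonded
  for (int i = 0; i < n; ++i) {
    const double xi = S.x[i], yi = S.y[i], zi = S.z[i];
    const double shi = S.sh[i], sei = S.se[i];
    const int ai = S.att[i];
    for (int t = S.nl_start[i]; t < S.nl_start[i + 1]; ++t) {
      int j = S.nl_idx[t];
      double dx = min_image(xi - S.x[j], S.Lx);
      double dy = min_image(yi - S.y[j], S.Ly);
      double dz = zi - S.z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      double b = shi + S.sh[j];
      double rc = c6 * b;
      double e = attract_pair(ai, S.att[j]) ? sei * S.se[j] : 0.0;
      double cut = e > 0 ? (rc + S.wc) : rc;
      if (r2 >= cut * cut) continue;
      double fmag = 0.0;   // dU/dr with sign: force on i along +rij is -dU/dr
      if (r2 < rc * rc) {
        // WCA repulsion, shifted so U(rc) = 0
        double r = std::sqrt(r2);
        double sr2 = (b * b) / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        out.pe += 4.0 * S.eps_rep * (sr12 - sr6) + S.eps_rep - e;
        fmag += 24.0 * S.eps_rep * (2.0 * sr12 - sr6) / r;   // repulsive -> positive
        double fr = fmag / r;
        double fxx = fr * dx, fyy = fr * dy, fzz = fr * dz;
        out.fx[i] += fxx; out.fy[i] += fyy; out.fz[i] += fzz;
        out.fx[j] -= fxx; out.fy[j] -= fyy; out.fz[j] -= fzz;
        out.Wxx += fxx * dx; out.Wyy += fyy * dy; out.Wzz += fzz * dz;
        continue;
      } else if (e > 0) {
        // tabulated cos^2 well: U = -e cos^2(pi u / 2), u = (r - rc)/wc
        double r = std::sqrt(r2);
        double u = (r - rc) / S.wc * 2048.0;
        int ti = (int)u;
        double fr = u - ti;
        out.pe += -e * (S.tabU[ti] * (1 - fr) + S.tabU[ti + 1] * fr);
        fmag += -e * (S.tabF[ti] * (1 - fr) + S.tabF[ti + 1] * fr);
        double fscale = fmag / r;
        double fxx = fscale * dx, fyy = fscale * dy, fzz = fscale * dz;
        out.fx[i] += fxx; out.fy[i] += fyy; out.fz[i] += fzz;
        out.fx[j] -= fxx; out.fy[j] -= fyy; out.fz[j] -= fzz;
        out.Wxx += fxx * dx; out.Wyy += fyy * dy; out.Wzz += fzz * dz;
        continue;
      }
    }
  }
  // bonds
  for (size_t t = 0; t < S.b_i.size(); ++t) {
    int i = S.b_i[t], j = S.b_j[t];
    double dx = min_image(S.x[i] - S.x[j], S.Lx);
    double dy = min_image(S.y[i] - S.y[j], S.Ly);
    double dz = S.z[i] - S.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - S.b_r0[t];
    out.pe += 0.5 * S.b_k[t] * dr * dr;
    double fr = -S.b_k[t] * dr / r;    // force on i
    double fxx = fr * dx, fyy = fr * dy, fzz = fr * dz;
    out.fx[i] += fxx; out.fy[i] += fyy; out.fz[i] += fzz;
    out.fx[j] -= fxx; out.fy[j] -= fyy; out.fz[j] -= fzz;
    out.Wxx += fxx * dx; out.Wyy += fyy * dy; out.Wzz += fzz * dz;
  }
  // angles: U = k (1 + cos theta), minimum at straight chains
  for (size_t t = 0; t < S.a_i.size(); ++t) {
    int i = S.a_i[t], j = S.a_j[t], k = S.a_k[t];
    double ax = min_image(S.x[i] - S.x[j], S.Lx);
    double ay = min_image(S.y[i] - S.y[j], S.Ly);
    double az = S.z[i] - S.z[j];
    double bx = min_image(S.x[k] - S.x[j], S.Lx);
    double by = min_image(S.y[k] - S.y[j], S.Ly);
    double bz = S.z[k] - S.z[j];
    double ra2 = ax * ax + ay * ay + az * az, rb2 = bx * bx + by * by + bz * bz;
    double ra = std::sqrt(ra2), rb = std::sqrt(rb2);
    double ct = (ax * bx + ay * by + az * bz) / (ra * rb);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double kk = S.a_kk[t];
    out.pe += kk * (1.0 + ct);
    // dU/dcos = kk ; F_m = -kk * d(cos)/d r_m
    double fix = -kk * (bx / (ra * rb) - ct * ax / ra2);
    double fiy = -kk * (by / (ra * rb) - ct * ay / ra2);
    double fiz = -kk * (bz / (ra * rb) - ct * az / ra2);
    double fkx = -kk * (ax / (ra * rb) - ct * bx / rb2);
    double fky = -kk * (ay / (ra * rb) - ct * by / rb2);
    double fkz = -kk * (az / (ra * rb) - ct * bz / rb2);
    out.fx[i] += fix; out.fy[i] += fiy; out.fz[i] += fiz;
    out.fx[k] += fkx; out.fy[k] += fky; out.fz[k] += fkz;
    out.fx[j] -= fix + fkx; out.fy[j] -= fiy + fky; out.fz[j] -= fiz + fkz;
    out.Wxx += fix * ax + fkx * bx; out.Wyy += fiy * ay + fky * by; out.Wzz += fiz * az + fkz * bz;
  }
  // bilayer midplane: mean z of all lipid beads
  double zsum = 0; int nz = 0;
  for (int i = 0; i < n; ++i) if (S.lipid[i]) { zsum += S.z[i]; ++nz; }
  out.midplane = nz > 0 ? zsum / nz : 0.0;
  // thinning field on tail beads (external; excluded from pe and virial)
  if (field.on && field.k > 0) {
    for (int i = 0; i < n; ++i) {
      if (!S.tail[i]) continue;
      double zz = S.z[i] - out.midplane;
      int d = zz > 0.5 * field.D ? 1 : (zz < -0.5 * field.D ? -1 : 0);
      if (d == 0) continue;
      double C = zone_C(S.x[i], field);
      if (C <= 0) continue;
      out.ez[i] += d * C * field.k * (0.5 * field.D - std::fabs(zz));
    }
  }
  // umbrella restraint on probe COM x (mass-weighted; equal masses)
  if (!probe.empty()) {
    double ref = S.x[probe[0]];
    double s = 0;
    for (int i : probe) s += ref + min_image(S.x[i] - ref, S.Lx);
    double com = s / probe.size();
    double cw = wrap0(com, S.Lx);
    out.com_x = cw;
    if (ku > 0) {
      double delta = min_image(com - ucenter, S.Lx);
      double f = -ku * delta / probe.size();
      for (int i : probe) out.ex[i] += f;
    }
  }
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(out.fx[i]) || !std::isfinite(out.fy[i]) || !std::isfinite(out.fz[i]))
      stop("non-finite force on bead %d (1-based)", i + 1);
  }
}

static System make_system(NumericMatrix pos, NumericVector sigma, IntegerVector att,
                          NumericVector eps, LogicalVector is_tail, LogicalVector is_lipid,
                          IntegerVector mol, IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                          IntegerMatrix angles, NumericVector angle_k,
                          NumericVector box, double eps_rep, double wc, double skin) {
  System S;
  S.n = pos.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  for (int i = 0; i < S.n; ++i) { S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2); }
  S.sigma = as<std::vector<double>>(sigma);
  S.att = as<std::vector<int>>(att);
  S.eps = as<std::vector<double>>(eps);
  S.tail.resize(S.n); S.lipid.resize(S.n);
  for (int i = 0; i < S.n; ++i) { S.tail[i] = is_tail[i]; S.lipid[i] = is_lipid[i]; }
  S.mol = as<std::vector<int>>(mol);
  S.se.resize(S.n); S.sh.resize(S.n);
  for (int i = 0; i < S.n; ++i) { S.se[i] = std::sqrt(S.eps[i]); S.sh[i] = 0.5 * S.sigma[i]; }
  S.Lx = box[0]; S.Ly = box[1]; S.Lz = box[2];
  S.excl.assign(S.n, {});
  std::vector<std::vector<int>> adj(S.n);
  for (int t = 0; t < bonds.nrow(); ++t) {
    int i = bonds(t, 0), j = bonds(t, 1);
    S.b_i.push_back(i); S.b_j.push_back(j);
    S.b_k.push_back(bond_k[t]); S.b_r0.push_back(bond_r0[t]);
    adj[i].push_back(j); adj[j].push_back(i);
  }
  // exclude 1-2 and 1-3 topological neighbours from nonbonded terms
  for (int i = 0; i < S.n; ++i) {
    std::vector<int> ex;
    for (int j : adj[i]) {
      ex.push_back(j);
      for (int k : adj[j]) if (k != i) ex.push_back(k);
    }
    std::sort(ex.begin(), ex.end());
    ex.erase(std::unique(ex.begin(), ex.end()), ex.end());
    S.excl[i] = ex;
  }
  for (int t = 0; t < angles.nrow(); ++t) {
    S.a_i.push_back(angles(t, 0)); S.a_j.push_back(angles(t, 1));
    S.a_k.push_back(angles(t, 2)); S.a_kk.push_back(angle_k[t]);
  }
  S.eps_rep = eps_rep; S.wc = wc;
  double smax = 0; for (int i = 0; i < S.n; ++i) smax = std::max(smax, S.sigma[i]);
  S.rlist = std::pow(2.0, 1.0 / 6.0) * smax + wc + skin;
  const int NTAB = 2048;
  S.tabU.resize(NTAB + 2); S.tabF.resize(NTAB + 2);
  for (int t = 0; t <= NTAB + 1; ++t) {
    double u = std::min(1.0, (double)t / NTAB);
    double ca = std::cos(M_PI * u / 2.0);
    S.tabU[t] = ca * ca;
    S.tabF[t] = std::sin(M_PI * u) * M_PI / (2.0 * wc);
  }
  return S;
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericVector sigma, IntegerVector att,
                        NumericVector eps, LogicalVector is_tail, LogicalVector is_lipid,
                        IntegerVector mol, IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                        IntegerMatrix angles, NumericVector angle_k,
                        NumericVector box, double eps_rep, double wc, double skin,
                        bool field_on, double fk, double fD,
                        double Athin, double Abuffer,
                        IntegerVector probe, double ku, double ucenter) {
  System S = make_system(pos, sigma, att, eps, is_tail, is_lipid, mol, bonds, bond_k, bond_r0,
                         angles, angle_k, box, eps_rep, wc, skin);
  FieldSpec field{field_on, fk, fD, box[0], Athin, Abuffer, box[0] / 2.0};
  std::vector<int> pr = as<std::vector<int>>(probe);
  ForceOut out;
  compute_forces(S, field, pr, ku, ucenter, out, skin);
  int n = S.n;
  NumericMatrix Fi(n, 3), Fe(n, 3);
  for (int i = 0; i < n; ++i) {
    Fi(i, 0) = out.fx[i]; Fi(i, 1) = out.fy[i]; Fi(i, 2) = out.fz[i];
    Fe(i, 0) = out.ex[i]; Fe(i, 1) = out.ey[i]; Fe(i, 2) = out.ez[i];
  }
  return List::create(_["force"] = Fi, _["force_external"] = Fe,
                      _["pe"] = out.pe,
                      _["virial"] = NumericVector::create(out.Wxx, out.Wyy, out.Wzz),
                      _["midplane"] = out.midplane,
                      _["com_x"] = out.com_x);
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel,
                NumericVector sigma, IntegerVector att, NumericVector eps,
                LogicalVector is_tail, LogicalVector is_lipid,
                IntegerVector mol, IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                IntegerMatrix angles, NumericVector angle_k,
                NumericVector box, double eps_rep, double wc, double skin,
                bool field_on, double fk, double fD,
                double Athin, double Abuffer,
                IntegerVector probe, double ku, double ucenter,
                double dt, double T, double gamma, double mass,
                int n_steps, int frame_stride, int log_stride) {
  System S = make_system(pos, sigma, att, eps, is_tail, is_lipid, mol, bonds, bond_k, bond_r0,
                         angles, angle_k, box, eps_rep, wc, skin);
  FieldSpec field{field_on, fk, fD, box[0], Athin, Abuffer, box[0] / 2.0};
  std::vector<int> pr = as<std::vector<int>>(probe);
  const int n = S.n;
  const double kB = 8.31446261815324e-3;
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) { vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2); }

  ForceOut F;
  compute_forces(S, field, pr, ku, ucenter, F, skin);

  GaussRNG rng;
  rng.seed_from_R();

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * std::sqrt(kB * T / mass);
  double hdt = 0.5 * dt, hdtm = 0.5 * dt / mass;

  List frames;
  std::vector<double> log_rows;
  int n_log = 0;
  const int LOGC = 12;  // step,time,KE,PE,Tinst,Kxx,Kyy,Kzz,Wxx,Wyy,Wzz,com_x
  const double max_disp = 0.5;

  auto log_state = [&](int step) {
    double KE = 0, Kxx = 0, Kyy = 0, Kzz = 0;
    for (int i = 0; i < n; ++i) {
      Kxx += mass * vx[i] * vx[i]; Kyy += mass * vy[i] * vy[i]; Kzz += mass * vz[i] * vz[i];
    }
    KE = 0.5 * (Kxx + Kyy + Kzz);
    double Ti = 2.0 * KE / (3.0 * n * kB);
    log_rows.insert(log_rows.end(), {(double)step, step * dt, KE, F.pe, Ti,
                                     Kxx, Kyy, Kzz, F.Wxx, F.Wyy, F.Wzz, F.com_x});
    ++n_log;
  };
  log_state(0);
  if (frame_stride > 0) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i) { fr(i, 0) = S.x[i]; fr(i, 1) = S.y[i]; fr(i, 2) = S.z[i]; }
    frames.push_back(fr);
  }

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      vx[i] += hdtm * (F.fx[i] + F.ex[i]);
      vy[i] += hdtm * (F.fy[i] + F.ey[i]);
      vz[i] += hdtm * (F.fz[i] + F.ez[i]);
    }
    // A
    for (int i = 0; i < n; ++i) { S.x[i] += hdt * vx[i]; S.y[i] += hdt * vy[i]; S.z[i] += hdt * vz[i]; }
    // O
    if (gamma > 0 && T > 0) {
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * rng.rnorm();
        vy[i] = c1 * vy[i] + c2 * rng.rnorm();
        vz[i] = c1 * vz[i] + c2 * rng.rnorm();
      }
    } else if (gamma > 0) {
      for (int i = 0; i < n; ++i) { vx[i] *= c1; vy[i] *= c1; vz[i] *= c1; }
    }
    // A
    double md2 = 0;
    for (int i = 0; i < n; ++i) {
      S.x[i] += hdt * vx[i]; S.y[i] += hdt * vy[i]; S.z[i] += hdt * vz[i];
      double d2 = dt * dt * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      if (d2 > md2) md2 = d2;
    }
    if (md2 > max_disp * max_disp)
      stop("blow-up: displacement exceeded %g nm at step %d", max_disp, step);
    // B
    compute_forces(S, field, pr, ku, ucenter, F, skin);
    for (int i = 0; i < n; ++i) {
      vx[i] += hdtm * (F.fx[i] + F.ex[i]);
      vy[i] += hdtm * (F.fy[i] + F.ey[i]);
      vz[i] += hdtm * (F.fz[i] + F.ez[i]);
    }
    if (log_stride > 0 && step % log_stride == 0) log_state(step);
    if (frame_stride > 0 && step % frame_stride == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) {
        double xx = wrap0(S.x[i], S.Lx);
        double yy = wrap0(S.y[i], S.Ly);
        fr(i, 0) = xx; fr(i, 1) = yy; fr(i, 2) = S.z[i];
      }
      frames.push_back(fr);
    }
  }

  NumericMatrix P(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i) {
    double xx = wrap0(S.x[i], S.Lx);
    double yy = wrap0(S.y[i], S.Ly);
    P(i, 0) = xx; P(i, 1) = yy; P(i, 2) = S.z[i];
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  NumericMatrix logm(n_log, LOGC);
  for (int r = 0; r < n_log; ++r) for (int c = 0; c < LOGC; ++c) logm(r, c) = log_rows[(size_t)r * LOGC + c];
  colnames(logm) = CharacterVector::create("step", "time", "KE", "PE", "T_inst",
                                           "Kxx", "Kyy", "Kzz", "Wxx", "Wyy", "Wzz", "com_x");
  return List::create(_["pos"] = P, _["vel"] = V, _["frames"] = frames, _["log"] = logm);
}

// steepest-descent energy minimization with displacement-capped steps
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos,
                  NumericVector sigma, IntegerVector att, NumericVector eps,
                  LogicalVector is_tail, LogicalVector is_lipid,
                  IntegerVector mol, IntegerMatrix bonds, NumericVector bond_k,
                  NumericVector bond_r0, IntegerMatrix angles,
                  NumericVector angle_k, NumericVector box,
                  double eps_rep, double wc, double skin,
                  int max_steps, double fmax_tol, double max_disp) {
  System S = make_system(pos, sigma, att, eps, is_tail, is_lipid, mol, bonds,
                         bond_k, bond_r0, angles, angle_k, box, eps_rep, wc,
                         skin);
  FieldSpec field{false, 0, 1, box[0], 1, 1, box[0] / 2.0};
  std::vector<int> pr;
  ForceOut F;
  int it = 0;
  double fmax = 0;
  for (it = 0; it < max_steps; ++it) {
    build_neighbor_list(S);           // configurations change a lot per step
    compute_forces(S, field, pr, 0, 0, F, skin);
    fmax = 0;
    for (int i = 0; i < S.n; ++i) {
      double f = std::sqrt(F.fx[i] * F.fx[i] + F.fy[i] * F.fy[i] +
                           F.fz[i] * F.fz[i]);
      if (f > fmax) fmax = f;
    }
    if (fmax < fmax_tol) break;
    double alpha = max_disp / fmax;
    for (int i = 0; i < S.n; ++i) {
      S.x[i] += alpha * F.fx[i];
      S.y[i] += alpha * F.fy[i];
      S.z[i] += alpha * F.fz[i];
    }
  }
  NumericMatrix P(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    P(i, 0) = wrap0(S.x[i], S.Lx);
    P(i, 1) = wrap0(S.y[i], S.Ly);
    P(i, 2) = S.z[i];
  }
  return List::create(_["pos"] = P, _["pe"] = F.pe, _["fmax"] = fmax,
                      _["n_steps"] = it);
}

// [[Rcpp::export]]
double cpp_min_distance(NumericMatrix pos, NumericVector box) {
  int n = pos.nrow();
  double Lx = box[0], Ly = box[1];
  double cell = 0.8;
  int ncx = std::max(1, (int)std::floor(Lx / cell));
  int ncy = std::max(1, (int)std::floor(Ly / cell));
  double zmin = pos(0, 2), zmax = pos(0, 2);
  for (int i = 1; i < n; ++i) { zmin = std::min(zmin, pos(i, 2)); zmax = std::max(zmax, pos(i, 2)); }
  int ncz = std::max(1, (int)std::floor((zmax - zmin + 1e-9) / cell) + 1);
  std::vector<std::vector<int>> cells((size_t)ncx * ncy * ncz);
  for (int i = 0; i < n; ++i) {
    double xx = wrap0(pos(i, 0), Lx);
    double yy = wrap0(pos(i, 1), Ly);
    int ix = std::min(ncx - 1, (int)(xx / (Lx / ncx)));
    int iy = std::min(ncy - 1, (int)(yy / (Ly / ncy)));
    int iz = std::min(ncz - 1, (int)((pos(i, 2) - zmin) / cell));
    cells[((size_t)ix * ncy + iy) * ncz + iz].push_back(i);
  }
  double best = R_PosInf;
  for (int ix = 0; ix < ncx; ++ix) for (int iy = 0; iy < ncy; ++iy) for (int iz = 0; iz < ncz; ++iz) {
    const std::vector<int>& ci = cells[((size_t)ix * ncy + iy) * ncz + iz];
    if (ci.empty()) continue;
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) for (int dz = -1; dz <= 1; ++dz) {
      int jz = iz + dz;
      if (jz < 0 || jz >= ncz) continue;
      int jx = ((ix + dx) % ncx + ncx) % ncx;
      int jy = ((iy + dy) % ncy + ncy) % ncy;
      const std::vector<int>& cj = cells[((size_t)jx * ncy + jy) * ncz + jz];
      for (int a : ci) for (int b : cj) {
        if (b <= a) continue;
        double ddx = min_image(pos(a, 0) - pos(b, 0), Lx);
        double ddy = min_image(pos(a, 1) - pos(b, 1), Ly);
        double ddz = pos(a, 2) - pos(b, 2);
        double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (r2 < best) best = r2;
      }
    }
  }
  return std::sqrt(best);
}

// Grid scan for solvent-exposed tail patches on one leaflet of one zone.
// For every cell of an xy grid, beads are scanned from the solvent side
// toward the midplane; the first bead whose projected disc covers the cell
// center decides: tail bead (or nothing) -> defect cell, head bead ->
// covered. 4-connected defect cells are clustered.
// [[Rcpp::export]]
List cpp_detect_defects(NumericMatrix pos, NumericVector radius, LogicalVector consider,
                        LogicalVector tail_like, int leaflet, double midplane,
                        double x0, double width, double Lx, double Ly,
                        double spacing, bool wrap_x, bool return_mask) {
  int n = pos.nrow();
  int nx = std::max(1, (int)std::lround(width / spacing));
  int ny = std::max(1, (int)std::lround(Ly / spacing));
  double hx = width / nx, hy = Ly / ny;
  std::vector<double> topz((size_t)nx * ny, NA_REAL);
  std::vector<char> def((size_t)nx * ny, 1);   // uncovered (bare) counts as defect

  for (int i = 0; i < n; ++i) {
    if (!consider[i]) continue;
    double z = pos(i, 2) - midplane;
    if (leaflet > 0 ? (z < 0) : (z > 0)) continue;   // wrong side of the midplane
    double r = radius[i];
    // map the bead into the zone frame: wrap relative to the zone start so
    // zones spanning the periodic x boundary are handled transparently
    double xb = wrap0(pos(i, 0) - x0, Lx);
    if (!wrap_x) {
      if (xb > Lx - r) xb -= Lx;     // bead just left of the zone start
      if (xb < -r || xb > width + r) continue;
    }
    double yb = wrap0(pos(i, 1), Ly);
    int ix0 = (int)std::floor((xb - r) / hx), ix1 = (int)std::floor((xb + r) / hx);
    int iy0 = (int)std::floor((yb - r) / hy), iy1 = (int)std::floor((yb + r) / hy);
    for (int ix = ix0; ix <= ix1; ++ix) {
      int cx = ix;
      if (wrap_x) { cx = ((ix % nx) + nx) % nx; }
      else if (ix < 0 || ix >= nx) continue;
      double xc = (cx + 0.5) * hx;
      double dx = wrap_x ? min_image(xb - xc, width) : (xb - xc);
      for (int iy = iy0; iy <= iy1; ++iy) {
        int cy = ((iy % ny) + ny) % ny;
        double yc = (cy + 0.5) * hy;
        double dy = min_image(yb - yc, Ly);
        if (dx * dx + dy * dy > r * r) continue;
        size_t cell = (size_t)cx * ny + cy;
        double zz = pos(i, 2);
        bool better = ISNA(topz[cell]) || (leaflet > 0 ? zz > topz[cell] : zz < topz[cell]);
        if (better) { topz[cell] = zz; def[cell] = tail_like[i] ? 1 : 0; }
      }
    }
  }

  // union-find clustering, 4-connectivity; y periodic, x periodic iff wrap_x
  std::vector<int> parent((size_t)nx * ny);
  for (size_t i = 0; i < parent.size(); ++i) parent[i] = (int)i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b); if (a != b) parent[b] = a;
  };
  for (int ix = 0; ix < nx; ++ix) for (int iy = 0; iy < ny; ++iy) {
    size_t c = (size_t)ix * ny + iy;
    if (!def[c]) continue;
    int iyn = (iy + 1) % ny;
    if (def[(size_t)ix * ny + iyn]) unite((int)c, ix * ny + iyn);
    int ixn = ix + 1;
    if (ixn >= nx) { if (wrap_x) ixn = 0; else ixn = -1; }
    if (ixn >= 0 && def[(size_t)ixn * ny + iy]) unite((int)c, ixn * ny + iy);
  }
  std::map<int, int> counts;
  for (int ix = 0; ix < nx; ++ix) for (int iy = 0; iy < ny; ++iy) {
    size_t c = (size_t)ix * ny + iy;
    if (def[c]) counts[find((int)c)]++;
  }
  NumericVector areas(counts.size());
  int t = 0;
  double cell_A2 = hx * hy * 100.0;   // nm^2 -> Angstrom^2
  for (auto& kv : counts) areas[t++] = kv.second * cell_A2;

  int n_def = 0;
  for (char c : def) n_def += c;
  List res = List::create(_["areas"] = areas,
                          _["n_cells"] = nx * ny,
                          _["n_defect_cells"] = n_def,
                          _["cell_area"] = cell_A2);
  if (return_mask) {
    IntegerMatrix m(nx, ny);
    for (int ix = 0; ix < nx; ++ix) for (int iy = 0; iy < ny; ++iy)
      m(ix, iy) = def[(size_t)ix * ny + iy] ? 1 : 0;
    res["mask"] = m;
  }
  return res;
}
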