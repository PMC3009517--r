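// Simulated-annealing sampler over per-helix placement parameters
// (sequence shift s, axis rotation theta, axis translation t).
//
// The R layer precomputes, per skeleton: the placement basis for the
// assigned direction, the local-frame backbone coordinates of the ideal
// helix, and for every candidate shift s the residue classes and
// local-frame side-chain centroids of the assigned window. The annealing
// state only moves rigid-placement parameters, so a theta/t move re-places
// one helix and an s move merely swaps that helix's class/centroid data.
//
// Determinism contract: each run r of topology i under master seed q uses
// an RNG seeded by a fixed mix of (q, i, r), so results do not depend on
// how topologies are distributed over workers.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64: small, fast, deterministic across platforms.
struct Rng {
  uint64_t state;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  double gauss() {  // Box-Muller with spare caching
    if (has_spare) { has_spare = false; return spare; }
    double u1 = 0.0, u2;
    while (u1 <= 0.0) u1 = unif();
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

uint64_t mix64(uint64_t x) {
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Vec3 { double x, y, z; };

struct Helix {
  double B[9];                 // placement basis columns x', y', z'
  Vec3 u, center;              // axis direction and midpoint
  int m;                       // residues
  std::vector<Vec3> local_bb;  // 4*m local backbone coords
  // per shift-grid index: residue classes (0-based) and local centroids
  std::vector<std::vector<int> > cls;
  std::vector<std::vector<Vec3> > cent;
  std::vector<bool> svalid;
  std::vector<int> win_start, win_end;  // sequence window per shift index
  // world-frame caches for the current state
  std::vector<Vec3> wbb, wcent;
};

struct EnergyPar {
  double r_core2, r0, r1, r2, e_clash, shallow;
  double eps[9];  // 3x3 row-major
};

inline double d2(const Vec3& a, const Vec3& b) {
  double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
  return dx * dx + dy * dy + dz * dz;
}

// re-place helix world coordinates for (theta, t); s only swaps centroids
void place(Helix& h, double theta_deg, double t, int sidx) {
  double th = theta_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  // M = B * Rz(theta), columns of B are x', y', z'
  const double* B = h.B;
  double M[9] = {
    B[0] * ct + B[3] * st, B[3] * ct - B[0] * st, B[6],
    B[1] * ct + B[4] * st, B[4] * ct - B[1] * st, B[7],
    B[2] * ct + B[5] * st, B[5] * ct - B[2] * st, B[8]};
  Vec3 c = {h.center.x + t * h.u.x, h.center.y + t * h.u.y,
            h.center.z + t * h.u.z};
  size_t nb = h.local_bb.size();
  h.wbb.resize(nb);
  for (size_t i = 0; i < nb; ++i) {
    const Vec3& p = h.local_bb[i];
    h.wbb[i].x = M[0] * p.x + M[1] * p.y + M[2] * p.z + c.x;
    h.wbb[i].y = M[3] * p.x + M[4] * p.y + M[5] * p.z + c.y;
    h.wbb[i].z = M[6] * p.x + M[7] * p.y + M[8] * p.z + c.z;
  }
  const std::vector<Vec3>& ce = h.cent[sidx];
  h.wcent.resize(ce.size());
  for (size_t i = 0; i < ce.size(); ++i) {
    const Vec3& p = ce[i];
    h.wcent[i].x = M[0] * p.x + M[1] * p.y + M[2] * p.z + c.x;
    h.wcent[i].y = M[3] * p.x + M[4] * p.y + M[5] * p.z + c.y;
    h.wcent[i].z = M[6] * p.x + M[7] * p.y + M[8] * p.z + c.z;
  }
}

double pair_energy(const Helix& A, const Helix& B,
                   const std::vector<int>& clsA,
                   const std::vector<int>& clsB, const EnergyPar& ep) {
  double total = 0.0;
  double skip2 = (ep.r2 + 12.0) * (ep.r2 + 12.0);
  for (int i = 0; i < A.m; ++i) {
    const Vec3& cai = A.wbb[4 * i + 1];
    for (int j = 0; j < B.m; ++j) {
      const Vec3& caj = B.wbb[4 * j + 1];
      if (d2(cai, caj) > skip2) continue;
      bool clash = false;
      for (int a = 0; a < 4 && !clash; ++a)
        for (int b = 0; b < 4; ++b)
          if (d2(A.wbb[4 * i + a], B.wbb[4 * j + b]) < ep.r_core2) {
            clash = true;
            break;
          }
      if (clash) {
        total += ep.e_clash;
        continue;
      }
      double dc = std::sqrt(d2(A.wcent[i], B.wcent[j]));
      if (dc >= ep.r0 && dc < ep.r2) {
        double depth = ep.eps[3 * clsA[i] + clsB[j]];
        total -= (dc < ep.r1) ? depth : ep.shallow * depth;
      }
    }
  }
  return total;
}

}  // namespace

// [[Rcpp::export]]
List anneal_topology_cpp(List helices, List sched, List epar,
                         int n_samples, double seed, int topo_index) {
  int K = helices.size();
  std::vector<Helix> H(K);
  for (int k = 0; k < K; ++k) {
    List hk = helices[k];
    NumericMatrix B = hk["B"];
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) H[k].B[3 * c + r] = B(r, c);
    NumericVector u = hk["u"], cen = hk["center"];
    H[k].u = {u[0], u[1], u[2]};
    H[k].center = {cen[0], cen[1], cen[2]};
    H[k].m = as<int>(hk["m"]);
    NumericMatrix bb = hk["bb"];
    H[k].local_bb.resize(bb.nrow());
    for (int i = 0; i < bb.nrow(); ++i)
      H[k].local_bb[i] = {bb(i, 0), bb(i, 1), bb(i, 2)};
    List cls = hk["cls"], cent = hk["cent"];
    LogicalVector sv = hk["svalid"];
    IntegerVector ws = hk["win_start"], we = hk["win_end"];
    H[k].win_start.assign(ws.begin(), ws.end());
    H[k].win_end.assign(we.begin(), we.end());
    int ns = sv.size();
    H[k].cls.resize(ns);
    H[k].cent.resize(ns);
    H[k].svalid.resize(ns);
    for (int si = 0; si < ns; ++si) {
      H[k].svalid[si] = sv[si];
      if (!sv[si]) continue;
      IntegerVector cv = cls[si];
      H[k].cls[si].assign(cv.begin(), cv.end());
      for (int i = 0; i < cv.size(); ++i) H[k].cls[si][i] -= 1;  // 0-based
      NumericMatrix cm = cent[si];
      H[k].cent[si].resize(cm.nrow());
      for (int i = 0; i < cm.nrow(); ++i)
        H[k].cent[si][i] = {cm(i, 0), cm(i, 1), cm(i, 2)};
    }
  }

  double T0 = as<double>(sched["T0"]);
  double alpha = as<double>(sched["alpha"]);
  int steps_per_T = as<int>(sched["steps_per_T"]);
  double T_min = as<double>(sched["T_min"]);
  double sigma_theta = as<double>(sched["sigma_theta"]);
  double sigma_t = as<double>(sched["sigma_t"]);
  double t_max = as<double>(sched["t_max"]);
  bool t_enabled = as<bool>(sched["t_enabled"]);

  EnergyPar ep;
  double rc = as<double>(epar["r_core"]);
  ep.r_core2 = rc * rc;
  ep.r0 = as<double>(epar["r0"]);
  ep.r1 = as<double>(epar["r1"]);
  ep.r2 = as<double>(epar["r2"]);
  ep.e_clash = as<double>(epar["e_clash"]);
  ep.shallow = as<double>(epar["shallow_factor"]);
  NumericMatrix eps = epar["eps"];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) ep.eps[3 * i + j] = eps(i, j);

  int ns_grid = H[0].svalid.size();
  std::vector<int> valid_idx0;  // reused buffer
  IntegerMatrix outS(n_samples, K);
  NumericMatrix outTheta(n_samples, K), outT(n_samples, K);
  NumericVector outE(n_samples), outE0(n_samples);

  uint64_t base = mix64(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                        static_cast<uint64_t>(topo_index));

  std::vector<int> sidx(K);
  std::vector<double> theta(K), tt(K);
  std::vector<std::vector<double> > pe(K, std::vector<double>(K, 0.0));

  // windows of two helices must not claim the same sequence residue;
  // count overlapping pairs for a candidate shift assignment
  auto overlap_pairs = [&](const std::vector<int>& s) {
    int o = 0;
    for (int a = 0; a < K; ++a)
      for (int b = a + 1; b < K; ++b)
        if (H[a].win_start[s[a]] <= H[b].win_end[s[b]] &&
            H[b].win_start[s[b]] <= H[a].win_end[s[a]])
          ++o;
    return o;
  };

  for (int run = 0; run < n_samples; ++run) {
    Rng rng(mix64(base + static_cast<uint64_t>(run) * 0xBF58476D1CE4E5B9ULL));

    // initial state: uniform valid shift, uniform theta, t = 0
    for (int k = 0; k < K; ++k) {
      valid_idx0.clear();
      for (int si = 0; si < ns_grid; ++si)
        if (H[k].svalid[si]) valid_idx0.push_back(si);
      sidx[k] = valid_idx0[static_cast<int>(rng.unif() * valid_idx0.size())];
      theta[k] = rng.unif() * 360.0;
      tt[k] = 0.0;
    }
    if (overlap_pairs(sidx) > 0) {
      // fall back to the least-shifted valid windows
      for (int k = 0; k < K; ++k) {
        int bestsi = -1, bestd = ns_grid + 1;
        for (int si = 0; si < ns_grid; ++si)
          if (H[k].svalid[si] && std::abs(si - ns_grid / 2) < bestd) {
            bestd = std::abs(si - ns_grid / 2);
            bestsi = si;
          }
        sidx[k] = bestsi;
      }
    }
    for (int k = 0; k < K; ++k) place(H[k], theta[k], tt[k], sidx[k]);
    double E = 0.0;
    for (int a = 0; a < K; ++a)
      for (int b = a + 1; b < K; ++b) {
        pe[a][b] = pair_energy(H[a], H[b], H[a].cls[sidx[a]],
                               H[b].cls[sidx[b]], ep);
        E += pe[a][b];
      }
    outE0[run] = E;

    for (double T = T0; T >= T_min; T *= alpha) {
      for (int step = 0; step < steps_per_T; ++step) {
        int k = static_cast<int>(rng.unif() * K);
        int which = static_cast<int>(rng.unif() * (t_enabled ? 3 : 2));
        int old_sidx = sidx[k];
        double old_theta = theta[k], old_t = tt[k];
        if (which == 0) {  // shift +-1 on the grid
          int delta = rng.unif() < 0.5 ? -1 : 1;
          int cand = sidx[k] + delta;
          if (cand < 0 || cand >= ns_grid || !H[k].svalid[cand]) continue;
          int o_cur = overlap_pairs(sidx);
          sidx[k] = cand;
          if (overlap_pairs(sidx) > o_cur) {  // never grow window overlap
            sidx[k] = old_sidx;
            continue;
          }
        } else if (which == 1) {
          double v = theta[k] + rng.gauss() * sigma_theta;
          v -= 360.0 * std::floor(v / 360.0);  // wrap to [0, 360)
          theta[k] = v;
        } else {
          double cand = tt[k] + rng.gauss() * sigma_t;
          if (std::abs(cand) > t_max) continue;
          tt[k] = cand;
        }
        place(H[k], theta[k], tt[k], sidx[k]);
        double dE = 0.0;
        std::vector<double> newpe(K);
        for (int o = 0; o < K; ++o) {
          if (o == k) continue;
          int a = o < k ? o : k, b = o < k ? k : o;
          newpe[o] = pair_energy(H[a], H[b], H[a].cls[sidx[a]],
                                 H[b].cls[sidx[b]], ep);
          dE += newpe[o] - pe[a][b];
        }
        bool accept = dE <= 0.0 || rng.unif() < std::exp(-dE / T);
        if (accept) {
          for (int o = 0; o < K; ++o) {
            if (o == k) continue;
            int a = o < k ? o : k, b = o < k ? k : o;
            pe[a][b] = newpe[o];
          }
          E += dE;
        } else {
          sidx[k] = old_sidx;
          theta[k] = old_theta;
          tt[k] = old_t;
          place(H[k], theta[k], tt[k], sidx[k]);
        }
      }
    }

    for (int k = 0; k < K; ++k) {
      outS(run, k) = sidx[k];  // grid index; R converts to shift value
      outTheta(run, k) = theta[k];
      outT(run, k) = tt[k];
    }
    outE[run] = E;
  }

  return List::create(_["s_index"] = outS, _["theta"] = outTheta,
                      _["t"] = outT, _["energy"] = outE,
                      _["energy0"] = outE0);
}
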