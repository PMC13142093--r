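// Compiled kernels: pairwise forces on a uniform grid, FIRE minimisation,
// overdamped Brownian dynamics, voxelised contact detection, partitioning.
// Units: nm, kBT, seconds. All bead indices entering these functions are
// 0-based; index-valued outputs are 1-based (R convention).
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  double x0, y0, z0, cell;
  int nx, ny, nz;
  std::vector<int> head, nxt;

  Grid(const NumericMatrix& pos, double cell_size) {
    int n = pos.nrow();
    cell = cell_size;
    double xmax = -1e300, ymax = -1e300, zmax = -1e300;
    x0 = y0 = z0 = 1e300;
    for (int i = 0; i < n; ++i) {
      x0 = std::min(x0, pos(i, 0)); xmax = std::max(xmax, pos(i, 0));
      y0 = std::min(y0, pos(i, 1)); ymax = std::max(ymax, pos(i, 1));
      z0 = std::min(z0, pos(i, 2)); zmax = std::max(zmax, pos(i, 2));
    }
    // cap the grid at ~2M cells; a coarser grid stays exact, just slower
    for (;;) {
      nx = std::max(1, (int)std::floor((xmax - x0) / cell) + 1);
      ny = std::max(1, (int)std::floor((ymax - y0) / cell) + 1);
      nz = std::max(1, (int)std::floor((zmax - z0) / cell) + 1);
      double tot = (double)nx * ny * nz;
      if (tot <= 2e6) break;
      cell *= 1.5;
    }
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(pos(i, 0), pos(i, 1), pos(i, 2));
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }
  inline int cell_of(double x, double y, double z) const {
    int cx = clampi((int)std::floor((x - x0) / cell), nx);
    int cy = clampi((int)std::floor((y - y0) / cell), ny);
    int cz = clampi((int)std::floor((z - z0) / cell), nz);
    return (cz * ny + cy) * nx + cx;
  }
};

struct ForceField {
  // 3x3 pair-class tables (0 = DNA, 1 = ribosome, 2 = boundary)
  double pairA[3][3], pairRc[3][3];
  double max_rc;
  const int* pclass;     // length n
  // bonds
  int nb; const int* bi; const int* bj;
  const double* bk; const double* br0;
  // angles (center bead second)
  int na; const int* ai; const int* aj; const int* ak;
  double kappa_b;
  std::unordered_set<long long> excl;
  int n;

  bool excluded(int i, int j) const {
    if (excl.empty()) return false;
    long long a = i < j ? i : j, b = i < j ? j : i;
    return excl.count(a * (long long)n + b) > 0;
  }
};

ForceField make_ff(int n, const IntegerVector& pclass,
                   const NumericMatrix& pairA, const NumericMatrix& pairRc,
                   const IntegerMatrix& bonds, const NumericVector& bond_k,
                   const NumericVector& bond_r0, const IntegerMatrix& angles,
                   double kappa_b, const IntegerMatrix& excl_pairs) {
  ForceField ff;
  ff.n = n;
  ff.max_rc = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      ff.pairA[a][b] = pairA(a, b);
      ff.pairRc[a][b] = pairRc(a, b);
      if (pairA(a, b) != 0.0) ff.max_rc = std::max(ff.max_rc, pairRc(a, b));
    }
  ff.pclass = pclass.begin();
  ff.nb = bonds.nrow();
  ff.bi = ff.nb ? &bonds(0, 0) : nullptr;
  ff.bj = ff.nb ? &bonds(0, 1) : nullptr;
  ff.bk = bond_k.begin();
  ff.br0 = bond_r0.begin();
  ff.na = angles.nrow();
  ff.ai = ff.na ? &angles(0, 0) : nullptr;
  ff.aj = ff.na ? &angles(0, 1) : nullptr;
  ff.ak = ff.na ? &angles(0, 2) : nullptr;
  ff.kappa_b = kappa_b;
  for (int e = 0; e < excl_pairs.nrow(); ++e) {
    int i = excl_pairs(e, 0), j = excl_pairs(e, 1);
    long long a = i < j ? i : j, b = i < j ? j : i;
    ff.excl.insert(a * (long long)n + b);
  }
  return ff;
}

// Total energy and accumulated forces (-grad U). forces must be zeroed by caller.
double compute_forces(const NumericMatrix& pos, const ForceField& ff,
                      NumericMatrix& forces, bool use_grid = true) {
  const int n = pos.nrow();
  double energy = 0.0;

  // bonds: U = k (r - r0)^2
  for (int b = 0; b < ff.nb; ++b) {
    int i = ff.bi[b], j = ff.bj[b];
    double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
           dz = pos(i, 2) - pos(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - ff.br0[b];
    energy += ff.bk[b] * dr * dr;
    if (r > 1e-12) {
      double f = -2.0 * ff.bk[b] * dr / r;  // along r_ij on bead i
      forces(i, 0) += f * dx; forces(i, 1) += f * dy; forces(i, 2) += f * dz;
      forces(j, 0) -= f * dx; forces(j, 1) -= f * dy; forces(j, 2) -= f * dz;
    }
  }

  // angles: U = kappa_b (1 - cos(pi - theta)) = kappa_b (1 + cos theta)
  for (int a = 0; a < ff.na; ++a) {
    int i = ff.ai[a], j = ff.aj[a], k = ff.ak[a];
    double ux = pos(i, 0) - pos(j, 0), uy = pos(i, 1) - pos(j, 1),
           uz = pos(i, 2) - pos(j, 2);
    double vx = pos(k, 0) - pos(j, 0), vy = pos(k, 1) - pos(j, 1),
           vz = pos(k, 2) - pos(j, 2);
    double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double lv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (lu < 1e-12 || lv < 1e-12) continue;
    double c = (ux * vx + uy * vy + uz * vz) / (lu * lv);
    c = std::max(-1.0, std::min(1.0, c));
    energy += ff.kappa_b * (1.0 + c);
    // F_i = -kappa * d(cos)/dr_i = -(kappa/|u|) (v_hat - cos * u_hat)
    double fi_x = -(ff.kappa_b / lu) * (vx / lv - c * ux / lu);
    double fi_y = -(ff.kappa_b / lu) * (vy / lv - c * uy / lu);
    double fi_z = -(ff.kappa_b / lu) * (vz / lv - c * uz / lu);
    double fk_x = -(ff.kappa_b / lv) * (ux / lu - c * vx / lv);
    double fk_y = -(ff.kappa_b / lv) * (uy / lu - c * vy / lv);
    double fk_z = -(ff.kappa_b / lv) * (uz / lu - c * vz / lv);
    forces(i, 0) += fi_x; forces(i, 1) += fi_y; forces(i, 2) += fi_z;
    forces(k, 0) += fk_x; forces(k, 1) += fk_y; forces(k, 2) += fk_z;
    forces(j, 0) -= fi_x + fk_x; forces(j, 1) -= fi_y + fk_y; forces(j, 2) -= fi_z + fk_z;
  }

  // soft pairs: U = A (1 + cos(pi r / rc)) for r < rc
  if (ff.max_rc > 0.0) {
    auto pair_term = [&](int i, int j) {
      int ci = ff.pclass[i], cj = ff.pclass[j];
      double A = ff.pairA[ci][cj];
      if (A == 0.0) return;
      double rc = ff.pairRc[ci][cj];
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc * rc) return;
      if (ff.excluded(i, j)) return;
      double r = std::sqrt(r2);
      energy += A * (1.0 + std::cos(M_PI * r / rc));
      if (r > 1e-12) {
        double f = A * M_PI / rc * std::sin(M_PI * r / rc) / r;  // repulsive
        forces(i, 0) += f * dx; forces(i, 1) += f * dy; forces(i, 2) += f * dz;
        forces(j, 0) -= f * dx; forces(j, 1) -= f * dy; forces(j, 2) -= f * dz;
      }
    };
    if (use_grid && n > 32) {
      // Cell edge follows the largest cutoff involving the dominant class
      // (DNA); classes needing a longer reach (e.g. ribosome-boundary)
      // scan a wider cell neighbourhood. A pair is processed from the side
      // with the larger scan radius (ties: j > i), so each pair is seen
      // exactly once and the scan always covers its cutoff.
      double edge = 0.0;
      for (int b = 0; b < 3; ++b)
        if (ff.pairA[0][b] != 0.0) edge = std::max(edge, ff.pairRc[0][b]);
      if (edge <= 0.0) edge = ff.max_rc;
      double need[3] = {0.0, 0.0, 0.0};
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          if (ff.pairA[a][b] != 0.0) need[a] = std::max(need[a], ff.pairRc[a][b]);
      Grid g(pos, edge);
      int rad[3];
      for (int c = 0; c < 3; ++c)
        rad[c] = std::max(1, (int)std::ceil(need[c] / g.cell));
      for (int i = 0; i < n; ++i) {
        int ri = rad[ff.pclass[i]];
        int cx = g.clampi((int)std::floor((pos(i, 0) - g.x0) / g.cell), g.nx);
        int cy = g.clampi((int)std::floor((pos(i, 1) - g.y0) / g.cell), g.ny);
        int cz = g.clampi((int)std::floor((pos(i, 2) - g.z0) / g.cell), g.nz);
        for (int dz = -ri; dz <= ri; ++dz) {
          int zz = cz + dz; if (zz < 0 || zz >= g.nz) continue;
          for (int dy = -ri; dy <= ri; ++dy) {
            int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
            for (int dx = -ri; dx <= ri; ++dx) {
              int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
              for (int j = g.head[(zz * g.ny + yy) * g.nx + xx]; j >= 0; j = g.nxt[j]) {
                int rj = rad[ff.pclass[j]];
                if (rj > ri || (rj == ri && j <= i)) continue;
                pair_term(i, j);
              }
            }
          }
        }
      }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) pair_term(i, j);
    }
  }
  return energy;
}

double max_bead_force(const NumericMatrix& f, const LogicalVector& mobile) {
  double m = 0.0;
  for (int i = 0; i < f.nrow(); ++i) {
    if (!mobile[i]) continue;
    double s = f(i, 0) * f(i, 0) + f(i, 1) * f(i, 1) + f(i, 2) * f(i, 2);
    if (s > m) m = s;
  }
  return std::sqrt(m);
}

}  // namespace

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, IntegerVector pclass,
                       NumericMatrix pairA, NumericMatrix pairRc,
                       IntegerMatrix bonds, NumericVector bond_k,
                       NumericVector bond_r0, IntegerMatrix angles,
                       double kappa_b, IntegerMatrix excl_pairs,
                       bool use_grid = true) {
  int n = pos.nrow();
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      if (!R_finite(pos(i, d))) stop("non-finite bead position");
  ForceField ff = make_ff(n, pclass, pairA, pairRc, bonds, bond_k, bond_r0,
                          angles, kappa_b, excl_pairs);
  NumericMatrix forces(n, 3);
  double e = compute_forces(pos, ff, forces, use_grid);
  return List::create(_["energy"] = e, _["forces"] = forces);
}

// FIRE descent with an explicit energy guard: trial steps that would raise the
// energy are rejected (velocity reset, step halved), so accepted iterations
// are monotone non-increasing in energy.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, LogicalVector mobile, IntegerVector pclass,
                  NumericMatrix pairA, NumericMatrix pairRc,
                  IntegerMatrix bonds, NumericVector bond_k,
                  NumericVector bond_r0, IntegerMatrix angles, double kappa_b,
                  IntegerMatrix excl_pairs, double tol = 1e-3,
                  int max_iter = 10000) {
  const int n = pos.nrow();
  ForceField ff = make_ff(n, pclass, pairA, pairRc, bonds, bond_k, bond_r0,
                          angles, kappa_b, excl_pairs);
  NumericMatrix x = clone(pos);
  NumericMatrix F(n, 3), Ftrial(n, 3);
  std::vector<double> v(3 * (size_t)n, 0.0);
  double E = compute_forces(x, ff, F);

  const double f_inc = 1.1, f_dec = 0.5, alpha0 = 0.1, f_alpha = 0.99;
  const int n_min = 5;
  double dt = 0.01, dt_max = 0.1, alpha = alpha0;
  int n_pos = 0, iter = 0;
  bool converged = max_bead_force(F, mobile) < tol;

  NumericMatrix xtrial(n, 3);
  while (!converged && iter < max_iter) {
    ++iter;
    double P = 0.0, vnorm2 = 0.0, fnorm2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int d = 0; d < 3; ++d) {
        P += F(i, d) * v[3 * (size_t)i + d];
        vnorm2 += v[3 * (size_t)i + d] * v[3 * (size_t)i + d];
        fnorm2 += F(i, d) * F(i, d);
      }
    }
    if (P > 0) {
      if (++n_pos > n_min) { dt = std::min(dt * f_inc, dt_max); alpha *= f_alpha; }
    } else {
      n_pos = 0; dt *= f_dec; alpha = alpha0;
      std::fill(v.begin(), v.end(), 0.0);
    }
    double mix = fnorm2 > 0 ? std::sqrt(vnorm2 / fnorm2) : 0.0;
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int d = 0; d < 3; ++d) {
        double vi = (1.0 - alpha) * v[3 * (size_t)i + d] + alpha * mix * F(i, d);
        vi += F(i, d) * dt;
        v[3 * (size_t)i + d] = vi;
        xtrial(i, d) = x(i, d) + vi * dt;
      }
      // clamp per-iteration displacement to keep bonded terms stable
      double dx = xtrial(i, 0) - x(i, 0), dy = xtrial(i, 1) - x(i, 1),
             dz = xtrial(i, 2) - x(i, 2);
      double disp = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (disp > 1.0) {
        double s = 1.0 / disp;
        xtrial(i, 0) = x(i, 0) + dx * s;
        xtrial(i, 1) = x(i, 1) + dy * s;
        xtrial(i, 2) = x(i, 2) + dz * s;
      }
    }
    for (int i = 0; i < n; ++i)
      if (!mobile[i]) for (int d = 0; d < 3; ++d) xtrial(i, d) = x(i, d);
    std::fill(Ftrial.begin(), Ftrial.end(), 0.0);
    double Etrial = compute_forces(xtrial, ff, Ftrial);
    if (Etrial <= E + 1e-10 * (std::fabs(E) + 1.0)) {
      std::copy(xtrial.begin(), xtrial.end(), x.begin());
      std::copy(Ftrial.begin(), Ftrial.end(), F.begin());
      E = Etrial;
      converged = max_bead_force(F, mobile) < tol;
    } else {
      std::fill(v.begin(), v.end(), 0.0);
      dt *= f_dec; n_pos = 0;
      if (dt < 1e-12) break;  // stuck at machine precision: treat as done
    }
  }
  return List::create(_["pos"] = x, _["energy"] = E, _["iterations"] = iter,
                      _["converged"] = converged,
                      _["max_force"] = max_bead_force(F, mobile));
}

// Overdamped Euler-Maruyama: dr = F * mobility * dt + sqrt(2 kT mobility dt) xi.
// mobility = 1/gamma in nm^2 / (kBT s). Uses R's RNG (respects set.seed()).
// [[Rcpp::export]]
List cpp_bd(NumericMatrix pos, LogicalVector mobile, NumericVector mobility,
            IntegerVector pclass, NumericMatrix pairA, NumericMatrix pairRc,
            IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
            IntegerMatrix angles, double kappa_b, IntegerMatrix excl_pairs,
            double dt, double kT, int n_steps, int save_every = 0) {
  const int n = pos.nrow();
  ForceField ff = make_ff(n, pclass, pairA, pairRc, bonds, bond_k, bond_r0,
                          angles, kappa_b, excl_pairs);
  NumericMatrix x = clone(pos);
  NumericMatrix F(n, 3);
  std::vector<double> c1(n), c2(n);
  for (int i = 0; i < n; ++i) {
    c1[i] = mobility[i] * dt;
    c2[i] = std::sqrt(2.0 * kT * mobility[i] * dt);
  }
  int n_big = 0;
  const double sigma_dna = 3.4;
  List snaps;
  RNGScope rng;
  for (int s = 0; s < n_steps; ++s) {
    std::fill(F.begin(), F.end(), 0.0);
    compute_forces(x, ff, F);
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      double dx = F(i, 0) * c1[i] + c2[i] * norm_rand();
      double dy = F(i, 1) * c1[i] + c2[i] * norm_rand();
      double dz = F(i, 2) * c1[i] + c2[i] * norm_rand();
      if (dx * dx + dy * dy + dz * dz > sigma_dna * sigma_dna) ++n_big;
      x(i, 0) += dx; x(i, 1) += dy; x(i, 2) += dz;
    }
    if (save_every > 0 && (s + 1) % save_every == 0) snaps.push_back(clone(x));
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["pos"] = x, _["n_large_steps"] = n_big,
                      _["snapshots"] = snaps);
}

// Unique segment pairs (1-based, i <= j) with any bead-bead distance < cutoff,
// detected on a voxel grid with edge = cutoff and 27-cell neighbourhoods.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, IntegerVector seg,
                                double cutoff) {
  const int n = pos.nrow();
  std::unordered_set<long long> found;
  long long nseg = 0;
  for (int i = 0; i < n; ++i) nseg = std::max(nseg, (long long)seg[i] + 1);
  double c2 = cutoff * cutoff;
  if (n > 0) {
    Grid g(pos, cutoff);
    for (int i = 0; i < n; ++i) {
      int cx = g.clampi((int)std::floor((pos(i, 0) - g.x0) / g.cell), g.nx);
      int cy = g.clampi((int)std::floor((pos(i, 1) - g.y0) / g.cell), g.ny);
      int cz = g.clampi((int)std::floor((pos(i, 2) - g.z0) / g.cell), g.nz);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = cz + dz; if (zz < 0 || zz >= g.nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
            for (int j = g.head[(zz * g.ny + yy) * g.nx + xx]; j >= 0; j = g.nxt[j]) {
              if (j <= i) continue;
              double ddx = pos(i, 0) - pos(j, 0), ddy = pos(i, 1) - pos(j, 1),
                     ddz = pos(i, 2) - pos(j, 2);
              if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
                long long a = std::min(seg[i], seg[j]);
                long long b = std::max(seg[i], seg[j]);
                found.insert(a * nseg + b);
              }
            }
          }
        }
      }
    }
  }
  IntegerMatrix out(found.size(), 2);
  int r = 0;
  for (long long key : found) {
    out(r, 0) = (int)(key / nseg) + 1;
    out(r, 1) = (int)(key % nseg) + 1;
    ++r;
  }
  return out;
}

// TRUE for each bead in A with no bead of B within `radius` (exact, grid).
// [[Rcpp::export]]
LogicalVector cpp_unmixed_flags(NumericMatrix posA, NumericMatrix posB,
                                double radius) {
  const int nA = posA.nrow();
  LogicalVector out(nA, true);
  if (posB.nrow() == 0 || nA == 0) return out;
  Grid g(posB, radius);
  double r2 = radius * radius;
  for (int i = 0; i < nA; ++i) {
    int cx = g.clampi((int)std::floor((posA(i, 0) - g.x0) / g.cell), g.nx);
    int cy = g.clampi((int)std::floor((posA(i, 1) - g.y0) / g.cell), g.ny);
    int cz = g.clampi((int)std::floor((posA(i, 2) - g.z0) / g.cell), g.nz);
    bool clear = true;
    for (int dz = -1; dz <= 1 && clear; ++dz) {
      int zz = cz + dz; if (zz < 0 || zz >= g.nz) continue;
      for (int dy = -1; dy <= 1 && clear; ++dy) {
        int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
        for (int dx = -1; dx <= 1 && clear; ++dx) {
          int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
          for (int j = g.head[(zz * g.ny + yy) * g.nx + xx]; j >= 0; j = g.nxt[j]) {
            double ddx = posA(i, 0) - posB(j, 0), ddy = posA(i, 1) - posB(j, 1),
                   ddz = posA(i, 2) - posB(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < r2) { clear = false; break; }
          }
        }
      }
    }
    // note: bead of A exactly on grid-boundary of B box is still checked,
    // because Grid clamps coordinates into the box and cell edge >= radius
    out[i] = clear;
  }
  return out;
}

// All bead pairs (1-based) closer than cutoff; helper for generators/tests.
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  std::vector<std::pair<int, int>> pairs;
  if (n > 1) {
    Grid g(pos, cutoff);
    double c2 = cutoff * cutoff;
    for (int i = 0; i < n; ++i) {
      int cx = g.clampi((int)std::floor((pos(i, 0) - g.x0) / g.cell), g.nx);
      int cy = g.clampi((int)std::floor((pos(i, 1) - g.y0) / g.cell), g.ny);
      int cz = g.clampi((int)std::floor((pos(i, 2) - g.z0) / g.cell), g.nz);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = cz + dz; if (zz < 0 || zz >= g.nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
            for (int j = g.head[(zz * g.ny + yy) * g.nx + xx]; j >= 0; j = g.nxt[j]) {
              if (j <= i) continue;
              double ddx = pos(i, 0) - pos(j, 0), ddy = pos(i, 1) - pos(j, 1),
                     ddz = pos(i, 2) - pos(j, 2);
              if (ddx * ddx + ddy * ddy + ddz * ddz < c2)
                pairs.emplace_back(i + 1, j + 1);
            }
          }
        }
      }
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}
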