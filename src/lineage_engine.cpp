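// Hybrid lattice engine: stochastic cell events on an n x n grid coupled to
// deterministic per-patch mediator fields (production / decay / Moore-neighbour
// hopping).  Sites are indexed column-major (site = row + col * n) to match R.
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
#include <cmath>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

namespace {

struct Grid {
  int n, N;
  std::vector<int> start;  // CSR offsets, length N + 1
  std::vector<int> nbr;    // concatenated Moore neighbours
  std::vector<int> deg;    // m_i in {3, 5, 8}
  explicit Grid(int n_) : n(n_), N(n_ * n_) {
    start.resize(N + 1);
    deg.resize(N);
    nbr.reserve(8 * N);
    for (int col = 0; col < n; col++) {
      for (int row = 0; row < n; row++) {
        int i = row + col * n;
        start[i] = (int)nbr.size();
        for (int dc = -1; dc <= 1; dc++) {
          for (int dr = -1; dr <= 1; dr++) {
            if (dr == 0 && dc == 0) continue;
            int r2 = row + dr, c2 = col + dc;
            if (r2 < 0 || r2 >= n || c2 < 0 || c2 >= n) continue;
            nbr.push_back(r2 + c2 * n);
          }
        }
        deg[i] = (int)nbr.size() - start[i];
      }
    }
    start[N] = (int)nbr.size();
  }
};

// Deterministic linear patch dynamics dz_i/dt = c*1[producer] - b z_i
// - m_i g z_i + g * sum_{j ~ i} z_j, advanced with a frozen producer mask.
// Non-stiff parameter sets use classical RK4 with dt*(b+16g) <= 1.2 (stability
// limit ~2.78, positivity retained in practice); stiff sets (b + 16g > 480)
// use implicit Euler with a banded Cholesky factorisation computed once.
struct FieldSolver {
  const Grid* G;
  double c, b, g;
  bool use_implicit;
  int sub_per_unit;        // substeps per unit time
  // implicit machinery
  double dt_imp;
  int kd, ldab;
  std::vector<double> band;
  // RK4 scratch
  std::vector<double> k1, k2, k3, k4, zt;

  FieldSolver(const Grid* G_, double c_, double b_, double g_, int force_rk4_sub)
      : G(G_), c(c_), b(b_), g(g_) {
    double stiff = b + 16.0 * g;
    if (force_rk4_sub > 0) {
      use_implicit = false;
      sub_per_unit = force_rk4_sub;
    } else if (stiff > 480.0) {
      use_implicit = true;
      sub_per_unit = (int)std::ceil(std::max(10.0, 2.5 * b));
    } else {
      use_implicit = false;
      sub_per_unit = std::max(1, (int)std::ceil(stiff / 1.2));
    }
    if (use_implicit) {
      dt_imp = 1.0 / sub_per_unit;
      factor();
    } else {
      k1.resize(G->N); k2.resize(G->N); k3.resize(G->N); k4.resize(G->N);
      zt.resize(G->N);
    }
  }

  void factor() {
    int n = G->n, N = G->N;
    kd = n + 1;
    ldab = kd + 1;
    band.assign((size_t)ldab * N, 0.0);
    for (int j = 0; j < N; j++) {
      band[(size_t)j * ldab + kd] = 1.0 + dt_imp * (b + g * G->deg[j]);
      for (int k = G->start[j]; k < G->start[j + 1]; k++) {
        int i = G->nbr[k];
        if (i < j) band[(size_t)j * ldab + (kd + i - j)] = -dt_imp * g;
      }
    }
    int info = 0;
    F77_CALL(dpbtrf)("U", &N, &kd, band.data(), &ldab, &info FCONE);
    if (info != 0) stop("banded Cholesky factorisation failed (info=%d)", info);
  }

  // direct column-stream stencil (equivalent to the CSR form, but cheap)
  void rhs(const std::vector<double>& z, const std::vector<unsigned char>& mask,
           std::vector<double>& out) const {
    const int n = G->n;
    for (int col = 0; col < n; col++) {
      const double* zc = &z[(size_t)col * n];
      const double* zl = col > 0 ? &z[(size_t)(col - 1) * n] : NULL;
      const double* zr = col < n - 1 ? &z[(size_t)(col + 1) * n] : NULL;
      const unsigned char* mk = &mask[(size_t)col * n];
      double* o = &out[(size_t)col * n];
      const double mMid = 2 + (zl ? 3 : 0) + (zr ? 3 : 0);
      // top row
      {
        double s = zc[1];
        double m = 1 + (zl ? 2 : 0) + (zr ? 2 : 0);
        if (zl) s += zl[0] + zl[1];
        if (zr) s += zr[0] + zr[1];
        o[0] = (mk[0] ? c : 0.0) - (b + g * m) * zc[0] + g * s;
      }
      if (zl && zr) {
        for (int r = 1; r < n - 1; r++) {
          double s = zc[r - 1] + zc[r + 1] + zl[r - 1] + zl[r] + zl[r + 1] +
                     zr[r - 1] + zr[r] + zr[r + 1];
          o[r] = (mk[r] ? c : 0.0) - (b + g * mMid) * zc[r] + g * s;
        }
      } else {
        const double* zs = zl ? zl : zr;
        for (int r = 1; r < n - 1; r++) {
          double s = zc[r - 1] + zc[r + 1] + zs[r - 1] + zs[r] + zs[r + 1];
          o[r] = (mk[r] ? c : 0.0) - (b + g * mMid) * zc[r] + g * s;
        }
      }
      // bottom row
      {
        int r = n - 1;
        double s = zc[r - 1];
        double m = 1 + (zl ? 2 : 0) + (zr ? 2 : 0);
        if (zl) s += zl[r] + zl[r - 1];
        if (zr) s += zr[r] + zr[r - 1];
        o[r] = (mk[r] ? c : 0.0) - (b + g * m) * zc[r] + g * s;
      }
    }
  }

  void advance(std::vector<double>& z, const std::vector<unsigned char>& mask,
               double duration) {
    const int N = G->N;
    if (use_implicit) {
      int nsub = std::max(1, (int)std::ceil(duration * sub_per_unit));
      // dt must equal the factored dt; adjust nsub so nsub * dt_imp == duration
      // (duration is an integer number of units in the driver; for general
      // durations refactor if needed)
      double dt = duration / nsub;
      if (std::abs(dt - dt_imp) > 1e-12 * dt_imp) { dt_imp = dt; factor(); }
      std::vector<double> v(N);
      int info = 0, nrhs = 1;
      for (int s = 0; s < nsub; s++) {
        for (int i = 0; i < N; i++) v[i] = z[i] + dt_imp * (mask[i] ? c : 0.0);
        F77_CALL(dpbtrs)("U", &N, &kd, &nrhs, band.data(), &ldab, v.data(), &N,
                         &info FCONE);
        if (info != 0) stop("banded solve failed");
        z.swap(v);
      }
    } else {
      int nsub = std::max(1, (int)std::ceil(duration * sub_per_unit));
      double dt = duration / nsub;
      for (int s = 0; s < nsub; s++) {
        rhs(z, mask, k1);
        for (int i = 0; i < N; i++) zt[i] = z[i] + 0.5 * dt * k1[i];
        rhs(zt, mask, k2);
        for (int i = 0; i < N; i++) zt[i] = z[i] + 0.5 * dt * k2[i];
        rhs(zt, mask, k3);
        for (int i = 0; i < N; i++) zt[i] = z[i] + dt * k3[i];
        rhs(zt, mask, k4);
        for (int i = 0; i < N; i++)
          z[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      }
    }
    // positivity guard: clamp roundoff, abort on real violations
    for (int i = 0; i < N; i++) {
      if (z[i] < 0.0) {
        if (z[i] < -1e-8) stop("field integration produced negative concentration");
        z[i] = 0.0;
      }
    }
  }
};

inline int runif_int(int m) {
  int k = (int)(unif_rand() * m);
  return k >= m ? m - 1 : k;
}

}  // namespace

// Standalone field advance (R-level advanceField)
// [[Rcpp::export]]
NumericMatrix cpp_advance_field(NumericMatrix conc, LogicalMatrix producers,
                                double c, double b, double g, double duration,
                                int substeps) {
  int n = conc.nrow();
  Grid G(n);
  FieldSolver solver(&G, c, b, g, substeps);
  std::vector<double> z(conc.begin(), conc.end());
  std::vector<unsigned char> mask(G.N);
  for (int i = 0; i < G.N; i++) mask[i] = producers[i] ? 1 : 0;
  solver.advance(z, mask, duration);
  NumericMatrix out(n, n);
  std::copy(z.begin(), z.end(), out.begin());
  return out;
}

// Cell state codes: 0 empty, 1 stem, 2 transit-amplifying, 3 differentiated.
// One time step = N samplings of the occupied-site list (N = cell count at the
// start of the step, occupancy evolves during the step), then the field layer
// advances one time unit with producer masks from the post-update occupancy
// (z: differentiated cells, w: stem cells).
// [[Rcpp::export]]
List cpp_run_lineage(IntegerMatrix lattice0, NumericMatrix z0, NumericMatrix w0,
                     double pDiv, double p0Self, double pSDeath, double pDDeath,
                     double pMig, double qDiv, double qTDeath,
                     double cz, double bz, double gz, double hz, bool useZ,
                     double cw, double bw, double gw, double hw, bool useW,
                     bool feedforward, int steps, int snapshotEvery,
                     bool earlyStopExtinct) {
  const int n = lattice0.nrow();
  Grid G(n);
  const int N2 = G.N;

  std::vector<int> lat(lattice0.begin(), lattice0.end());
  std::vector<double> z, w;
  std::vector<unsigned char> mask(N2);
  FieldSolver *fz = NULL, *fw = NULL;
  if (useZ) { z.assign(z0.begin(), z0.end()); fz = new FieldSolver(&G, cz, bz, gz, -1); }
  if (useW) { w.assign(w0.begin(), w0.end()); fw = new FieldSolver(&G, cw, bw, gw, -1); }

  // occupancy bookkeeping
  std::vector<int> occ;  occ.reserve(N2);
  std::vector<int> pos(N2, -1);
  int nS = 0, nT = 0, nD = 0;
  for (int i = 0; i < N2; i++) {
    if (lat[i] != 0) {
      pos[i] = (int)occ.size();
      occ.push_back(i);
      if (lat[i] == 1) nS++; else if (lat[i] == 2) nT++; else nD++;
    }
  }

  IntegerMatrix counts(steps + 1, 3);
  counts(0, 0) = nS; counts(0, 1) = nT; counts(0, 2) = nD;
  List snapshots;
  IntegerVector snapTimes;

  RNGScope rng;

  auto addCell = [&](int site, int kind) {
    lat[site] = kind;
    pos[site] = (int)occ.size();
    occ.push_back(site);
    if (kind == 1) nS++; else if (kind == 2) nT++; else nD++;
  };
  auto removeCell = [&](int site) {
    int kind = lat[site];
    if (kind == 1) nS--; else if (kind == 2) nT--; else nD--;
    lat[site] = 0;
    int p = pos[site], last = (int)occ.size() - 1;
    if (p != last) { occ[p] = occ[last]; pos[occ[p]] = p; }
    occ.pop_back();
    pos[site] = -1;
  };
  auto convert = [&](int site, int kind) {
    int old = lat[site];
    if (old == 1) nS--; else if (old == 2) nT--; else nD--;
    lat[site] = kind;
    if (kind == 1) nS++; else if (kind == 2) nT++; else nD++;
  };
  auto moveCell = [&](int from, int to) {
    lat[to] = lat[from];
    lat[from] = 0;
    int p = pos[from];
    occ[p] = to;
    pos[to] = p;
    pos[from] = -1;
  };
  auto tryMigrate = [&](int site) {
    if (pMig <= 0.0) return;
    if (unif_rand() >= pMig) return;
    int m = G.deg[site];
    int t = G.nbr[G.start[site] + runif_int(m)];
    if (lat[t] == 0) moveCell(site, t);
  };

  for (int step = 1; step <= steps; step++) {
    // canonical (scan-order) occupancy at the start of each step: the sampled
    // set is the same, but this makes trajectories independent of how the run
    // is chunked into engine calls
    occ.clear();
    for (int i = 0; i < N2; i++) {
      if (lat[i] != 0) { pos[i] = (int)occ.size(); occ.push_back(i); }
    }
    int Nsamp = (int)occ.size();
    for (int s = 0; s < Nsamp; s++) {
      if (occ.empty()) break;
      int i = occ[runif_int((int)occ.size())];
      int kind = lat[i];
      if (kind == 1) {  // stem
        if (pDiv > 0.0 && unif_rand() < pDiv) {
          int m = G.deg[i];
          int t = G.nbr[G.start[i] + runif_int(m)];
          if (lat[t] == 0) {  // otherwise the division aborts
            double ps = useZ ? p0Self / (1.0 + hz * z[i]) : p0Self;
            if (unif_rand() < ps) {
              addCell(t, 1);  // self-renewal: two stem daughters
            } else if (feedforward) {
              addCell(t, 2);  // differentiation: two TA daughters
              convert(i, 2);
            } else {
              addCell(t, 3);  // differentiation: two differentiated daughters
              convert(i, 3);
            }
          }
        }
        if (lat[i] == 1 && pSDeath > 0.0 && unif_rand() < pSDeath) removeCell(i);
        if (lat[i] != 0) tryMigrate(i);
      } else if (kind == 2) {  // transit-amplifying
        if (qDiv > 0.0 && unif_rand() < qDiv) {
          int m = G.deg[i];
          int t = G.nbr[G.start[i] + runif_int(m)];
          if (lat[t] == 0) {
            double qs = useW ? 1.0 - 1.0 / (1.0 + hw * w[i]) : 0.0;
            if (unif_rand() < qs) {
              addCell(t, 2);
            } else {
              addCell(t, 3);
              convert(i, 3);
            }
          }
        }
        if (lat[i] == 2 && qTDeath > 0.0 && unif_rand() < qTDeath) removeCell(i);
        if (lat[i] != 0) tryMigrate(i);
      } else {  // differentiated
        if (pDDeath > 0.0 && unif_rand() < pDDeath) {
          removeCell(i);
        } else {
          tryMigrate(i);
        }
      }
    }

    if (useZ) {
      for (int i = 0; i < N2; i++) mask[i] = (lat[i] == 3);
      fz->advance(z, mask, 1.0);
    }
    if (useW) {
      for (int i = 0; i < N2; i++) mask[i] = (lat[i] == 1);
      fw->advance(w, mask, 1.0);
    }

    counts(step, 0) = nS; counts(step, 1) = nT; counts(step, 2) = nD;

    if (snapshotEvery > 0 && step % snapshotEvery == 0) {
      IntegerMatrix snap(n, n);
      std::copy(lat.begin(), lat.end(), snap.begin());
      snapshots.push_back(snap);
      snapTimes.push_back(step);
    }

    if (earlyStopExtinct && occ.empty()) {
      double tot = 0.0;
      if (useZ) for (int i = 0; i < N2; i++) tot += z[i];
      if (useW) for (int i = 0; i < N2; i++) tot += w[i];
      if (tot < 1e-14) {
        for (int s2 = step + 1; s2 <= steps; s2++) {
          counts(s2, 0) = 0; counts(s2, 1) = 0; counts(s2, 2) = 0;
        }
        break;
      }
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix latOut(n, n);
  std::copy(lat.begin(), lat.end(), latOut.begin());
  NumericMatrix zOut(n, n), wOut(n, n);
  if (useZ) std::copy(z.begin(), z.end(), zOut.begin());
  if (useW) std::copy(w.begin(), w.end(), wOut.begin());
  delete fz;
  delete fw;
  return List::create(_["counts"] = counts, _["lattice"] = latOut,
                      _["z"] = zOut, _["w"] = wOut,
                      _["snapshots"] = snapshots, _["snapshot_times"] = snapTimes);
}
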