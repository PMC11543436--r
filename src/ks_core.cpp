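// Metropolis Monte-Carlo core for the kinetic-segregation membrane simulator
// and small numeric kernels shared by the phosphorylation model.
//
// Units: lengths nm, energies kT, times s. The height field z lives on an
// n x n grid of cell centers (spacing a); a molecule reads the height of the
// cell it occupies. Heights outside the patch are clamped to boundary_h
// (single-protrusion patch); molecules use periodic boundaries.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Sim {
  int n;             // grid nodes per side
  double a;          // grid spacing nm
  double L;          // patch size nm (n * a)
  double boundary_h; // clamped height outside the patch
  NumericMatrix z;

  // molecules: [0, nt) TCR, [nt, nt+nc) CD45, [nt+nc, nt+nc+np) pMHC
  int nt, nc, np;
  std::vector<double> x, y;
  std::vector<int> tcr_partner;  // pMHC index (global) or -1
  std::vector<int> pmhc_owner;   // TCR index or -1, by local pMHC index

  // energy parameters
  double R, hb, hc, U, Sent, urep, uadh, wadh, kb;
  double tether_k;       // weak per-node restoring toward boundary_h
  double corral;         // max TCR distance from the patch center (<=0: none)
  double capture, bind_tol;

  // move parameters
  double step_sd, pmhc_step_sd, hstep;

  bool clamp_active;           // distance constraint currently applied
  std::vector<char> clamp_mask; // nodes held at clamp height while active
  double clamp_h;

  std::vector<std::vector<int> > cells;

  int cell_of(double xx, double yy) const {
    int i = (int)std::floor(xx / a), j = (int)std::floor(yy / a);
    if (i < 0) i = 0; if (i >= n) i = n - 1;
    if (j < 0) j = 0; if (j >= n) j = n - 1;
    return i * n + j;
  }

  double node(int i, int j) const {
    if (i < 0 || i >= n || j < 0 || j >= n) return boundary_h;
    return z(i, j);
  }

  // membrane height seen by a molecule at (xx, yy): its cell's node
  double interp(double xx, double yy) const {
    int i = (int)std::floor(xx / a), j = (int)std::floor(yy / a);
    if (i < 0) i = 0; if (i >= n) i = n - 1;
    if (j < 0) j = 0; if (j >= n) j = n - 1;
    return z(i, j);
  }

  double spring_E(double zz) const { double d = zz - hb; return kb * d * d; }

  double cd45_E(double zz) const {
    double e = 0.0;
    if (zz < hc) { double d = hc - zz; e += urep * d * d; }
    double g = (zz - hc) / wadh;
    e -= uadh * std::exp(-g * g);
    return e;
  }

  // membrane-coupled energy of molecule m at height zz (0 if not coupled)
  double mol_E(int m, double zz) const {
    if (m < nt) return (tcr_partner[m] >= 0) ? spring_E(zz) : 0.0;
    if (m < nt + nc) return cd45_E(zz);
    return 0.0; // pMHC sits on the APC
  }

  double lap(int i, int j) const {
    return node(i + 1, j) + node(i - 1, j) + node(i, j + 1) + node(i, j - 1) -
           4.0 * node(i, j);
  }

  double bend_coef() const { return R / (a * a); }

  void wrap(double &xx, double &yy) const {
    xx -= L * std::floor(xx / L);
    yy -= L * std::floor(yy / L);
    if (xx >= L) xx = 0; // guard against rounding at the edge
    if (yy >= L) yy = 0;
  }

  void rebuild_cells() {
    cells.assign(n * n, std::vector<int>());
    for (int m = 0; m < nt + nc + np; ++m) cells[cell_of(x[m], y[m])].push_back(m);
  }

  void move_cell(int m, int from, int to) {
    if (from == to) return;
    std::vector<int> &v = cells[from];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == m) { v[k] = v.back(); v.pop_back(); break; }
    cells[to].push_back(m);
  }

  double total_energy() const {
    double e = 0.0, bc = bend_coef();
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) { double l = lap(i, j); e += bc * l * l; }
    for (int m = 0; m < nt + nc; ++m) e += mol_E(m, interp(x[m], y[m]));
    for (int m = 0; m < nt; ++m) if (tcr_partner[m] >= 0) e -= U;
    return e;
  }
};

inline bool metro(double dE) {
  if (dE <= 0) return true;
  return unif_rand() < std::exp(-dE);
}

// one pass of single-node height moves; returns acceptance fraction
double height_sweep(Sim &S) {
  int acc = 0, tot = 0;
  double bc = S.bend_coef();
  for (int i = 0; i < S.n; ++i) {
    for (int j = 0; j < S.n; ++j) {
      if (S.clamp_active && S.clamp_mask[i * S.n + j]) continue;
      double d = (2.0 * unif_rand() - 1.0) * S.hstep;
      double z0 = S.z(i, j);
      if (z0 + d < 0) { ++tot; continue; } // membrane cannot cross the APC
      // bending: Laplacian at (i,j) changes by -4d, at in-range neighbors by +d
      double dE = 0.0, l0 = S.lap(i, j);
      dE += bc * ((l0 - 4 * d) * (l0 - 4 * d) - l0 * l0);
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= S.n || jj < 0 || jj >= S.n) continue;
        double l = S.lap(ii, jj);
        dE += bc * ((l + d) * (l + d) - l * l);
      }
      // molecules in this cell read its node height
      {
        const std::vector<int> &v = S.cells[i * S.n + j];
        for (size_t k = 0; k < v.size(); ++k) {
          int m = v[k];
          if (m >= S.nt + S.nc) continue;               // pMHC
          if (m < S.nt && S.tcr_partner[m] < 0) continue; // free TCR
          dE += S.mol_E(m, z0 + d) - S.mol_E(m, z0);
        }
      }
      if (S.tether_k > 0) {
        double e0 = z0 - S.boundary_h;
        dE += S.tether_k * ((e0 + d) * (e0 + d) - e0 * e0);
      }
      ++tot;
      if (metro(dE)) { S.z(i, j) = z0 + d; ++acc; }
    }
  }
  return tot ? (double)acc / tot : NA_REAL;
}

// collective square-block height shifts: accelerate long-wavelength
// relaxation, which single-node moves sample poorly on stiff membranes
void block_sweep(Sim &S) {
  const int sizes[4] = {2, 4, 8, 16};
  double bc = S.bend_coef();
  for (int si = 0; si < 4; ++si) {
    int bs = sizes[si];
    if (bs > S.n) continue;
    int reps = (S.n / bs) * (S.n / bs);
    for (int rep = 0; rep < reps; ++rep) {
      int i0 = (int)(unif_rand() * (S.n - bs + 1));
      int j0 = (int)(unif_rand() * (S.n - bs + 1));
      if (S.clamp_active) { // skip blocks touching clamped nodes
        bool touches = false;
        for (int i = i0; i < i0 + bs && !touches; ++i)
          for (int j = j0; j < j0 + bs; ++j)
            if (S.clamp_mask[i * S.n + j]) { touches = true; break; }
        if (touches) continue;
      }
      double d = (2.0 * unif_rand() - 1.0) * S.hstep;
      if (d < 0) { // membrane cannot cross the APC
        double zmin = R_PosInf;
        for (int i = i0; i < i0 + bs; ++i)
          for (int j = j0; j < j0 + bs; ++j)
            if (S.z(i, j) < zmin) zmin = S.z(i, j);
        if (zmin + d < 0) continue;
      }
      // bending: Laplacians change only near the block boundary
      double dE = 0.0;
      for (int i = i0 - 1; i <= i0 + bs; ++i) {
        for (int j = j0 - 1; j <= j0 + bs; ++j) {
          if (i < 0 || i >= S.n || j < 0 || j >= S.n) continue;
          bool inside = (i >= i0 && i < i0 + bs && j >= j0 && j < j0 + bs);
          int cnt = 0; // neighbors on the other side of the block boundary
          const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
          for (int k = 0; k < 4; ++k) {
            int ii = i + di[k], jj = j + dj[k];
            bool nin = (ii >= i0 && ii < i0 + bs && jj >= j0 && jj < j0 + bs);
            if (inside) {
              // clamped out-of-grid neighbors do not shift
              if (!nin) ++cnt;
            } else {
              if (nin) ++cnt;
            }
          }
          if (cnt == 0) continue;
          double l = S.lap(i, j);
          double dl = inside ? -cnt * d : cnt * d;
          dE += bc * ((l + dl) * (l + dl) - l * l);
        }
      }
      // molecules inside the block shift with their cell
      for (int ci = i0; ci < i0 + bs; ++ci) {
        for (int cj = j0; cj < j0 + bs; ++cj) {
          const std::vector<int> &v = S.cells[ci * S.n + cj];
          for (size_t k = 0; k < v.size(); ++k) {
            int m = v[k];
            if (m >= S.nt + S.nc) continue;
            if (m < S.nt && S.tcr_partner[m] < 0) continue;
            double zm = S.z(ci, cj);
            dE += S.mol_E(m, zm + d) - S.mol_E(m, zm);
          }
        }
      }
      if (S.tether_k > 0) {
        double acc_z = 0.0;
        for (int i = i0; i < i0 + bs; ++i)
          for (int j = j0; j < j0 + bs; ++j) acc_z += S.z(i, j) - S.boundary_h;
        dE += S.tether_k * (2 * d * acc_z + bs * bs * d * d);
      }
      if (metro(dE)) {
        for (int i = i0; i < i0 + bs; ++i)
          for (int j = j0; j < j0 + bs; ++j) S.z(i, j) += d;
      }
    }
  }
}

double molecule_sweep(Sim &S) {
  int acc = 0, tot = 0;
  int N = S.nt + S.nc + S.np;
  bool pmhc_mobile = S.pmhc_step_sd > 0;
  for (int m = 0; m < N; ++m) {
    if (m >= S.nt + S.nc) {
      if (S.pmhc_owner[m - S.nt - S.nc] >= 0) continue; // dragged by its TCR
      if (!pmhc_mobile) continue;
    }
    double sd = (m >= S.nt + S.nc) ? S.pmhc_step_sd : S.step_sd;
    double dx = norm_rand() * sd, dy = norm_rand() * sd;
    double nx = S.x[m] + dx, ny = S.y[m] + dy;
    S.wrap(nx, ny);
    if (m < S.nt && S.corral > 0) { // pre-formed cluster held in a corral
      double cx = nx - S.L / 2, cy = ny - S.L / 2;
      if (cx * cx + cy * cy > S.corral * S.corral) { ++tot; continue; }
    }
    bool bound_tcr = (m < S.nt && S.tcr_partner[m] >= 0);
    if (bound_tcr && !pmhc_mobile) {
      // tethered to an immobile pMHC: stay within the capture radius
      int p = S.tcr_partner[m];
      double ddx = nx - S.x[p], ddy = ny - S.y[p];
      if (ddx * ddx + ddy * ddy > S.capture * S.capture) { ++tot; continue; }
    }
    double dE = 0.0;
    if (m < S.nt + S.nc)
      dE = S.mol_E(m, S.interp(nx, ny)) - S.mol_E(m, S.interp(S.x[m], S.y[m]));
    ++tot;
    if (metro(dE)) {
      int from = S.cell_of(S.x[m], S.y[m]), to = S.cell_of(nx, ny);
      S.x[m] = nx; S.y[m] = ny; S.move_cell(m, from, to);
      if (bound_tcr && pmhc_mobile) { // drag the bound pMHC along
        int p = S.tcr_partner[m];
        double px = S.x[p] + dx, py = S.y[p] + dy;
        S.wrap(px, py);
        int pfrom = S.cell_of(S.x[p], S.y[p]), pto = S.cell_of(px, py);
        S.x[p] = px; S.y[p] = py; S.move_cell(p, pfrom, pto);
      }
      ++acc;
    }
  }
  return tot ? (double)acc / tot : NA_REAL;
}

// squared lateral distance with periodic wrapping
double pdist2(const Sim &S, int m1, int m2) {
  double dx = std::fabs(S.x[m1] - S.x[m2]), dy = std::fabs(S.y[m1] - S.y[m2]);
  if (dx > S.L / 2) dx = S.L - dx;
  if (dy > S.L / 2) dy = S.L - dy;
  return dx * dx + dy * dy;
}

void bond_sweep(Sim &S) {
  for (int t = 0; t < S.nt; ++t) {
    double zt = S.interp(S.x[t], S.y[t]);
    if (S.tcr_partner[t] >= 0) {
      // unbinding: lose the net binding free energy (association energy less
      // the binding entropy), recover the spring strain
      double dE = (S.U - S.Sent) - S.spring_E(zt);
      if (metro(dE)) {
        S.pmhc_owner[S.tcr_partner[t] - S.nt - S.nc] = -1;
        S.tcr_partner[t] = -1;
      }
    } else {
      if (std::fabs(zt - S.hb) > S.bind_tol) continue; // membrane out of reach
      // nearest free pMHC within the capture radius
      int i = (int)std::floor(S.x[t] / S.a), j = (int)std::floor(S.y[t] / S.a);
      int best = -1; double bestd = S.capture * S.capture;
      for (int ci = i - 1; ci <= i + 1; ++ci) {
        for (int cj = j - 1; cj <= j + 1; ++cj) {
          int wi = (ci % S.n + S.n) % S.n, wj = (cj % S.n + S.n) % S.n;
          const std::vector<int> &v = S.cells[wi * S.n + wj];
          for (size_t k = 0; k < v.size(); ++k) {
            int m = v[k];
            if (m < S.nt + S.nc) continue;
            if (S.pmhc_owner[m - S.nt - S.nc] >= 0) continue;
            double d2 = pdist2(S, t, m);
            if (d2 <= bestd) { bestd = d2; best = m; }
          }
        }
      }
      if (best < 0) continue;
      double dE = -(S.U - S.Sent) + S.spring_E(zt);
      if (metro(dE)) {
        S.tcr_partner[t] = best;
        S.pmhc_owner[best - S.nt - S.nc] = t;
      }
    }
  }
}

List snapshot(const Sim &S, double t) {
  int N = S.nt + S.nc + S.np;
  IntegerVector species(N), bound(N);
  NumericVector xs(N), ys(N);
  for (int m = 0; m < N; ++m) {
    species[m] = (m < S.nt) ? 1 : (m < S.nt + S.nc ? 2 : 3);
    xs[m] = S.x[m]; ys[m] = S.y[m];
    if (m < S.nt) bound[m] = (S.tcr_partner[m] >= 0) ? S.tcr_partner[m] + 1 : NA_INTEGER;
    else if (m >= S.nt + S.nc)
      bound[m] = (S.pmhc_owner[m - S.nt - S.nc] >= 0) ? S.pmhc_owner[m - S.nt - S.nc] + 1
                                                      : NA_INTEGER;
    else bound[m] = NA_INTEGER;
  }
  return List::create(_["t"] = t, _["z"] = clone(S.z), _["species"] = species,
                      _["x"] = xs, _["y"] = ys, _["partner"] = bound);
}

} // namespace

// [[Rcpp::export(name = ".ks_run_cpp")]]
List ks_run_cpp(int n, double a, double boundary_h, NumericMatrix z_init,
                NumericVector tcr_x, NumericVector tcr_y,
                NumericVector cd45_x, NumericVector cd45_y,
                NumericVector pmhc_x, NumericVector pmhc_y,
                double R, double hb, double hc, double U, double Sent,
                double urep, double uadh, double wadh, double kb,
                double tether_k, double corral,
                double capture, double bind_tol,
                double step_sd, double pmhc_step_sd, double hstep,
                double sweep_dt, double t_end, NumericVector sample_times,
                double clamp_until, double clamp_h, double clamp_radius,
                int log_every) {
  RNGScope scope;
  Sim S;
  S.n = n; S.a = a; S.L = n * a; S.boundary_h = boundary_h;
  S.z = clone(z_init);
  S.clamp_active = clamp_until > 0;
  S.clamp_h = clamp_h;
  S.clamp_mask.assign(n * n, 0);
  if (S.clamp_active) {
    // hold a central disk at the clamp height; the rest starts at init_h
    double c = n * a / 2.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double dx = (i + 0.5) * a - c, dy = (j + 0.5) * a - c;
        if (dx * dx + dy * dy <= clamp_radius * clamp_radius) {
          S.clamp_mask[i * S.n + j] = 1;
          S.z(i, j) = clamp_h;
        }
      }
  }
  S.nt = tcr_x.size(); S.nc = cd45_x.size(); S.np = pmhc_x.size();
  int N = S.nt + S.nc + S.np;
  S.x.resize(N); S.y.resize(N);
  for (int i = 0; i < S.nt; ++i) { S.x[i] = tcr_x[i]; S.y[i] = tcr_y[i]; }
  for (int i = 0; i < S.nc; ++i) { S.x[S.nt + i] = cd45_x[i]; S.y[S.nt + i] = cd45_y[i]; }
  for (int i = 0; i < S.np; ++i) { S.x[S.nt + S.nc + i] = pmhc_x[i]; S.y[S.nt + S.nc + i] = pmhc_y[i]; }
  S.tcr_partner.assign(S.nt, -1);
  S.pmhc_owner.assign(S.np, -1);
  S.R = R; S.hb = hb; S.hc = hc; S.U = U; S.Sent = Sent;
  S.urep = urep; S.uadh = uadh;
  S.wadh = wadh; S.kb = kb; S.tether_k = tether_k; S.corral = corral;
  S.capture = capture; S.bind_tol = bind_tol;
  S.step_sd = step_sd; S.pmhc_step_sd = pmhc_step_sd; S.hstep = hstep;
  S.rebuild_cells();

  int n_sweeps = (int)std::ceil(t_end / sweep_dt - 1e-9);
  std::vector<double> st(sample_times.begin(), sample_times.end());
  std::sort(st.begin(), st.end());
  List states;
  size_t next_sample = 0;
  // samples requested at t = 0
  while (next_sample < st.size() && st[next_sample] <= 1e-12) {
    states.push_back(snapshot(S, 0.0));
    ++next_sample;
  }

  std::vector<double> log_t, log_E, log_accH, log_accM, log_nb;

  for (int sw = 1; sw <= n_sweeps; ++sw) {
    double t = sw * sweep_dt;
    if (S.clamp_active && t > clamp_until + 1e-12) S.clamp_active = false;
    double ah = height_sweep(S);
    block_sweep(S);
    double am = molecule_sweep(S);
    bond_sweep(S);
    if (log_every > 0 && (sw % log_every == 0 || sw == n_sweeps)) {
      double E = S.total_energy();
      if (!std::isfinite(E))
        stop("simulation diverged: non-finite total energy at t=%f", t);
      int nb = 0;
      for (int m = 0; m < S.nt; ++m) if (S.tcr_partner[m] >= 0) ++nb;
      log_t.push_back(t); log_E.push_back(E);
      log_accH.push_back(ah); log_accM.push_back(am); log_nb.push_back(nb);
    }
    while (next_sample < st.size() && st[next_sample] <= t + 1e-9) {
      states.push_back(snapshot(S, st[next_sample]));
      ++next_sample;
    }
  }

  return List::create(
      _["states"] = states,
      _["log"] = DataFrame::create(_["t"] = log_t, _["energy"] = log_E,
                                   _["acc_height"] = log_accH,
                                   _["acc_molecule"] = log_accM,
                                   _["n_bound"] = log_nb));
}

// Summed exponential Lck* kernel: out[i, k] = sum_j exp(-d(query_i, cd45_j)/dl_k)
// [[Rcpp::export(name = ".density_sum_cpp")]]
NumericMatrix density_sum_cpp(NumericVector qx, NumericVector qy,
                              NumericVector cx, NumericVector cy,
                              NumericVector dl) {
  int nq = qx.size(), nc = cx.size(), nd = dl.size();
  NumericMatrix out(nq, nd);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nc; ++j) {
      double dx = qx[i] - cx[j], dy = qy[i] - cy[j];
      double d = std::sqrt(dx * dx + dy * dy);
      for (int k = 0; k < nd; ++k) out(i, k) += std::exp(-d / dl[k]);
    }
  }
  return out;
}

// 2D random walks from the origin with per-step deactivation probability.
// Frozen at deactivation; returns end distance and status after n_steps.
// [[Rcpp::export(name = ".lck_walk_cpp")]]
List lck_walk_cpp(int n_walkers, int n_steps, double step_sd, double p_step) {
  RNGScope scope;
  NumericVector dist(n_walkers);
  LogicalVector dead(n_walkers);
  IntegerVector steps(n_walkers);
  for (int w = 0; w < n_walkers; ++w) {
    double xx = 0, yy = 0;
    int s = 0;
    bool off = false;
    while (s < n_steps) {
      xx += norm_rand() * step_sd;
      yy += norm_rand() * step_sd;
      ++s;
      if (p_step > 0 && unif_rand() < p_step) { off = true; break; }
    }
    dist[w] = std::sqrt(xx * xx + yy * yy);
    dead[w] = off;
    steps[w] = s;
  }
  return List::create(_["end_distance"] = dist, _["deactivated"] = dead,
                      _["steps"] = steps);
}
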