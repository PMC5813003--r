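#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Linear interpolation of a tabulated gradient. The potential F is supplied on
// a uniform grid (values in kBT); the force used by the integrator is the
// segment slope, i.e. piecewise-constant -dF/dz. Outside the grid the force
// is zero (bulk).
static inline double grad_tab(const std::vector<double> &F, double z0,
                              double dz, int n, double z) {
  double u = (z - z0) / dz;
  int i = (int)std::floor(u);
  if (i < 0 || i >= n - 1) return 0.0;
  return (F[i + 1] - F[i]) / dz;
}

// Overdamped Langevin dynamics in 1D under a tabulated potential.
//
// z_{t+dt} = z_t - D * F'(z_t) * dt + sqrt(2 D dt) * eta    (F in kBT)
//
// Optional single-file constraint inside |z| < sf_region: a soft
// short-range repulsion between axial neighbours plus an exact no-passing
// rule (positions of the particles involved are re-assigned rank-wise
// after each step, the overdamped equivalent of an elastic collision for
// equal-mobility particles). Outside the region (the bulk reservoirs,
// which stand in for passable 3D bulk) particles may pass each other.
//
// Boundaries at +/- wall: "reflect" mirrors the particle back, "reinject"
// draws a fresh position uniformly from a bulk slab on a random side.
// [[Rcpp::export]]
NumericMatrix cpp_langevin(NumericVector grid_z, NumericVector grid_F,
                           double D, double dt, int n_steps, int out_every,
                           NumericVector z_init, bool single_file,
                           double rep_eps, double rep_rc, double wall,
                           std::string boundary, double bulk_lo,
                           double bulk_hi, double sf_region) {
  int np = z_init.size();
  int ng = grid_z.size();
  double z0 = grid_z[0];
  double dz = (grid_z[ng - 1] - grid_z[0]) / (ng - 1);
  std::vector<double> F(grid_F.begin(), grid_F.end());

  // stability: drift per step must stay well below one grid cell
  double maxslope = 0.0;
  for (int i = 0; i + 1 < ng; ++i)
    maxslope = std::max(maxslope, std::fabs((F[i + 1] - F[i]) / dz));
  if (maxslope * D * dt > 0.5)
    stop("time step too large for potential gradient (|F'| D dt > 0.5 Angstrom)");

  int n_out = n_steps / out_every;
  NumericMatrix out(n_out, np);
  std::vector<double> z(z_init.begin(), z_init.end());
  std::vector<double> zprev(np), f(np), vals(np);
  std::vector<int> idx(np), sub(np);

  double noise = std::sqrt(2.0 * D * dt);
  RNGScope scope;
  int row = 0;
  for (int s = 1; s <= n_steps; ++s) {
    zprev = z;
    for (int i = 0; i < np; ++i) idx[i] = i;
    if (single_file)
      std::sort(idx.begin(), idx.end(),
                [&](int a, int b) { return zprev[a] < zprev[b]; });

    for (int i = 0; i < np; ++i)
      f[i] = -grad_tab(F, z0, dz, ng, z[i]);
    if (single_file && rep_eps > 0.0) {
      // repulsion between axial neighbours, active inside the file region
      for (int r = 0; r + 1 < np; ++r) {
        int a = idx[r], b = idx[r + 1];
        if (std::fabs(zprev[a]) > sf_region + rep_rc &&
            std::fabs(zprev[b]) > sf_region + rep_rc)
          continue;
        double d = z[b] - z[a];
        if (d < rep_rc) {
          double fr = 2.0 * rep_eps / rep_rc * (1.0 - d / rep_rc);
          f[a] -= fr;
          f[b] += fr;
        }
      }
    }
    for (int i = 0; i < np; ++i) {
      double zn = z[i] + D * f[i] * dt + noise * norm_rand();
      if (boundary == "reinject" && std::fabs(zn) > wall) {
        double side = (unif_rand() < 0.5) ? -1.0 : 1.0;
        zn = side * (bulk_lo + unif_rand() * (bulk_hi - bulk_lo));
      } else {
        // reflect (also the fallback for reinject overshoot)
        while (std::fabs(zn) > wall)
          zn = (zn > wall) ? 2.0 * wall - zn : -2.0 * wall - zn;
      }
      z[i] = zn;
    }
    if (single_file) {
      // exact no-passing among particles touching the file region, in the
      // order they held before the step
      int ns = 0;
      for (int r = 0; r < np; ++r) {
        int i = idx[r];
        if (std::fabs(zprev[i]) < sf_region || std::fabs(z[i]) < sf_region)
          sub[ns++] = i;
      }
      if (ns > 1) {
        for (int r = 0; r < ns; ++r) vals[r] = z[sub[r]];
        std::sort(vals.begin(), vals.begin() + ns);
        for (int r = 0; r < ns; ++r) z[sub[r]] = vals[r];
      }
    }
    if (s % out_every == 0) {
      for (int i = 0; i < np; ++i) out(row, i) = z[i];
      ++row;
    }
  }
  return out;
}

// Adaptive-weight-histogram sampling of a 1D free-energy profile.
//
// A single walker follows overdamped Langevin dynamics under the model
// potential plus a harmonic coupling (1/2) k (z - z_lambda)^2 to the current
// coupling point.  lambda is Gibbs-resampled each step from its conditional
// P(i | z) prop-to exp(g_i - V_i(z)/kBT) with bias g = Fhat (kBT).  The
// free-energy estimate is updated with the zero-drift weight-histogram rule
//   Fhat_i <- Fhat_i + (1/N) (1 - M w_i),
// where w_i are the conditional weights, M the number of points and N the
// reference histogram size.  N doubles at every full covering of the grid in
// the initial stage and grows by one per sample in the final stage.
// The returned profile is the bias-reweighted z histogram:
//   F(z_bin) = -kBT ln sum_t [ 1 / sum_i exp(g_i(t) - V_i(z_t)/kBT) ].
// [[Rcpp::export]]
List cpp_awh_run(NumericVector grid_z, NumericVector model_gz,
                 NumericVector model_gF, double k_kbt, double D, double dt,
                 double n0, int n_steps, double z_start) {
  int M = grid_z.size();
  double g0 = grid_z[0];
  double dg = (grid_z[M - 1] - grid_z[0]) / (M - 1);
  double lo = grid_z[0], hi = grid_z[M - 1];

  int ngm = model_gz.size();
  double mz0 = model_gz[0];
  double mdz = (model_gz[ngm - 1] - model_gz[0]) / (ngm - 1);
  std::vector<double> mF(model_gF.begin(), model_gF.end());

  std::vector<double> fhat(M, 0.0), W(M, 0.0), hist(M, 0.0), w(M, 0.0);
  std::vector<double> occ_first(M, 0.0), occ_last(M, 0.0);
  std::vector<bool> visited(M, false);
  int third = std::max(1, n_steps / 3);

  double N = n0;
  bool initial_stage = true;
  long coverings = 0, samples = 0;
  int n_visited = 0;

  // traversal bookkeeping on the walker position
  double span = hi - lo;
  double lo_thr = lo + 0.025 * span, hi_thr = hi - 0.025 * span;
  int side = 0; // 0 unset, -1 low, +1 high
  long traversals = 0;

  double z = z_start;
  int lam = (int)std::round((z - g0) / dg);
  lam = std::max(0, std::min(M - 1, lam));
  double wcut = std::sqrt(2.0 * 40.0 / k_kbt); // V_i beyond this is > 40 kBT
  double noise = std::sqrt(2.0 * D * dt);

  RNGScope scope;
  for (int s = 0; s < n_steps; ++s) {
    // walker step under model force + harmonic coupling to current lambda
    double fm = -grad_tab(mF, mz0, mdz, ngm, z);
    double fc = -k_kbt * (z - grid_z[lam]);
    double zn = z + D * (fm + fc) * dt + noise * norm_rand();
    while (zn < lo || zn > hi)
      zn = (zn > hi) ? 2.0 * hi - zn : 2.0 * lo - zn;
    z = zn;

    // Gibbs resample lambda within the relevant window
    int jlo = std::max(0, (int)std::ceil((z - wcut - g0) / dg));
    int jhi = std::min(M - 1, (int)std::floor((z + wcut - g0) / dg));
    double wmaxexp = -1e300;
    for (int j = jlo; j <= jhi; ++j) {
      double d = z - grid_z[j];
      double e = fhat[j] - 0.5 * k_kbt * d * d;
      w[j] = e;
      if (e > wmaxexp) wmaxexp = e;
    }
    double S = 0.0;
    for (int j = jlo; j <= jhi; ++j) {
      w[j] = std::exp(w[j] - wmaxexp);
      S += w[j];
    }
    double u = unif_rand() * S, acc = 0.0;
    lam = jhi;
    for (int j = jlo; j <= jhi; ++j) {
      acc += w[j];
      if (u <= acc) { lam = j; break; }
    }

    // reweighted z histogram: weight 1/sum_i exp(g_i - V_i(z));
    // exp(wmaxexp) restores the absolute normalisation of the bias
    int zb = (int)std::round((z - g0) / dg);
    zb = std::max(0, std::min(M - 1, zb));
    hist[zb] += 1.0 / (S * std::exp(wmaxexp));

    // weight-histogram update of the free-energy estimate (zero drift)
    ++samples;
    double invN = 1.0 / N;
    for (int j = jlo; j <= jhi; ++j) {
      double om = w[j] / S;
      W[j] += om;
      fhat[j] += invN * (1.0 - M * om);
    }
    // points outside the window received zero weight-mass
    for (int j = 0; j < jlo; ++j) fhat[j] += invN;
    for (int j = jhi + 1; j < M; ++j) fhat[j] += invN;

    if (s < third) occ_first[lam] += 1.0;
    else if (s >= n_steps - third) occ_last[lam] += 1.0;
    if (!visited[lam]) { visited[lam] = true; ++n_visited; }
    if (initial_stage) {
      if (n_visited == M) { // full covering
        N *= 2.0;
        ++coverings;
        std::fill(visited.begin(), visited.end(), false);
        n_visited = 0;
        // the bias changed substantially during this covering: restart the
        // reweighted histogram so stale weights do not bias the estimate
        std::fill(hist.begin(), hist.end(), 0.0);
        if (N >= (double)samples) initial_stage = false;
      }
    } else {
      N += 1.0;
    }

    if (z < lo_thr) {
      if (side == 1) ++traversals;
      side = -1;
    } else if (z > hi_thr) {
      if (side == -1) ++traversals;
      side = 1;
    }
  }

  // reference estimates to min = 0
  double fmin = *std::min_element(fhat.begin(), fhat.end());
  NumericVector fh(M), pm(M), Wv(M), hv(M);
  double hmax = *std::max_element(hist.begin(), hist.end());
  for (int j = 0; j < M; ++j) {
    fh[j] = fhat[j] - fmin;
    pm[j] = (hist[j] > 0.0) ? -std::log(hist[j] / hmax) : NA_REAL;
    Wv[j] = W[j];
    hv[j] = hist[j];
  }
  return List::create(_["fhat"] = fh, _["pmf"] = pm, _["W"] = Wv,
                      _["hist"] = hv,
                      _["occ_first"] = NumericVector(occ_first.begin(),
                                                     occ_first.end()),
                      _["occ_last"] = NumericVector(occ_last.begin(),
                                                    occ_last.end()),
                      _["traversals"] = (double)traversals,
                      _["coverings"] = (double)coverings,
                      _["samples"] = (double)samples,
                      _["final_stage"] = !initial_stage,
                      _["hist_size"] = N, _["z_end"] = z);
}

// Boundary-crossing statistics on a finely sampled 1D path.
//
// Counts directional crossings at z_l, z_0 and z_u, resolves the fate of
// every z_0 crossing (reach the nearer outer boundary before returning to
// z_0), and assigns an exit side to every pore visit that touched z_0.
// Also counts full one-way passages between the outer regions, and keeps
// a capped event log (frame, boundary code, direction, fate code).
// [[Rcpp::export]]
List cpp_detect_crossings(NumericVector z, double zl, double z0, double zu,
                          int log_cap) {
  int n = z.size();
  std::vector<int> ev_frame, ev_bnd, ev_dir, ev_fate;
  int pend_log = -1; // index into the log of the unresolved z0 crossing
  auto log_ev = [&](int frame, int bnd, int dir, int fate) {
    if ((int)ev_frame.size() >= log_cap) return -1;
    ev_frame.push_back(frame);
    ev_bnd.push_back(bnd);
    ev_dir.push_back(dir);
    ev_fate.push_back(fate);
    return (int)ev_frame.size() - 1;
  };
  long kl_up = 0, kl_down = 0, ku_up = 0, ku_down = 0;
  long k0_up = 0, k0_down = 0;
  long n0d = 0, n0d_l = 0, n0u = 0, n0u_u = 0; // z0-crossing fates
  long exit_u = 0, exit_l = 0;                 // pore-visit exits via z0
  long full_up = 0, full_down = 0;
  int pend = 0;       // 0 none, -1 tracking z0 down-crossing, +1 up-crossing
  bool touched0 = false;
  int outer = 0;      // last outer region: -1 below zl, +1 above zu, 0 unset

  for (int i = 1; i < n; ++i) {
    double a = z[i - 1], b = z[i];
    if (a < zl && b >= zl) { ++kl_up; log_ev(i, -1, 1, 0); }
    if (a > zl && b <= zl) { ++kl_down; log_ev(i, -1, -1, 0); }
    if (a < zu && b >= zu) { ++ku_up; log_ev(i, 1, 1, 0); }
    if (a > zu && b <= zu) { ++ku_down; log_ev(i, 1, -1, 0); }
    bool up0 = (a < z0 && b >= z0), down0 = (a > z0 && b <= z0);
    if (up0) ++k0_up;
    if (down0) ++k0_down;

    // fate of an ongoing z0 crossing
    if (pend == -1) {
      if (b <= zl) { ++n0d_l; pend = 0;
        if (pend_log >= 0) ev_fate[pend_log] = 1; pend_log = -1; }
      else if (b > z0) { pend = 0;
        if (pend_log >= 0) ev_fate[pend_log] = 2; pend_log = -1; }
    } else if (pend == 1) {
      if (b >= zu) { ++n0u_u; pend = 0;
        if (pend_log >= 0) ev_fate[pend_log] = 1; pend_log = -1; }
      else if (b < z0) { pend = 0;
        if (pend_log >= 0) ev_fate[pend_log] = 2; pend_log = -1; }
    }
    if (pend == 0) {
      if (down0) {
        ++n0d; pend = -1;
        pend_log = log_ev(i, 0, -1, 0);
        if (b <= zl) { ++n0d_l; pend = 0;
          if (pend_log >= 0) ev_fate[pend_log] = 1; pend_log = -1; }
      } else if (up0) {
        ++n0u; pend = 1;
        pend_log = log_ev(i, 0, 1, 0);
        if (b >= zu) { ++n0u_u; pend = 0;
          if (pend_log >= 0) ev_fate[pend_log] = 1; pend_log = -1; }
      }
    }

    if (up0 || down0) touched0 = true;
    if (b <= zl) {
      if (touched0) ++exit_l;
      touched0 = false;
      if (outer == 1) ++full_down;
      outer = -1;
    } else if (b >= zu) {
      if (touched0) ++exit_u;
      touched0 = false;
      if (outer == -1) ++full_up;
      outer = 1;
    }
  }
  return List::create(
      _["kl_up"] = (double)kl_up, _["kl_down"] = (double)kl_down,
      _["ku_up"] = (double)ku_up, _["ku_down"] = (double)ku_down,
      _["k0_up"] = (double)k0_up, _["k0_down"] = (double)k0_down,
      _["n0_down"] = (double)n0d, _["n0_down_reach_l"] = (double)n0d_l,
      _["n0_up"] = (double)n0u, _["n0_up_reach_u"] = (double)n0u_u,
      _["exit_u"] = (double)exit_u, _["exit_l"] = (double)exit_l,
      _["full_up"] = (double)full_up, _["full_down"] = (double)full_down,
      _["ev_frame"] = IntegerVector(ev_frame.begin(), ev_frame.end()),
      _["ev_bnd"] = IntegerVector(ev_bnd.begin(), ev_bnd.end()),
      _["ev_dir"] = IntegerVector(ev_dir.begin(), ev_dir.end()),
      _["ev_fate"] = IntegerVector(ev_fate.begin(), ev_fate.end()));
}

// Discrete-time Markov chain on a small state space (row-stochastic P),
// returning the 1-based state path. Used for toy-model trajectories.
// [[Rcpp::export]]
IntegerVector cpp_markov_chain(NumericMatrix P, int init, int n_steps) {
  int m = P.nrow();
  IntegerVector path(n_steps);
  int s = init - 1;
  RNGScope scope;
  for (int t = 0; t < n_steps; ++t) {
    double u = unif_rand(), acc = 0.0;
    int nxt = m - 1;
    for (int j = 0; j < m; ++j) {
      acc += P(s, j);
      if (u <= acc) { nxt = j; break; }
    }
    s = nxt;
    path[t] = s + 1;
  }
  return path;
}
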