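#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Thomas algorithm; overwrites b and d. a is sub-diagonal (a[0] unused),
// c super-diagonal (c[n-1] unused).
static void thomas(int n, const double* a, double* b, const double* c, double* d) {
  for (int i = 1; i < n; ++i) {
    if (b[i - 1] == 0.0) stop("singular tridiagonal system");
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  if (b[n - 1] == 0.0) stop("singular tridiagonal system");
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// [[Rcpp::export]]
NumericVector thomas_solve(NumericVector lower, NumericVector diag,
                           NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  if (lower.size() != n || upper.size() != n || rhs.size() != n)
    stop("all bands must have length n");
  std::vector<double> a(lower.begin(), lower.end());
  std::vector<double> b(diag.begin(), diag.end());
  std::vector<double> c(upper.begin(), upper.end());
  std::vector<double> d(rhs.begin(), rhs.end());
  thomas(n, a.data(), b.data(), c.data(), d.data());
  return NumericVector(d.begin(), d.end());
}

// Banded Gaussian elimination (bandwidth 2 each side, no pivoting) for the
// interleaved sulfate/methane steady-state Newton system.  diags is a 5 x n
// matrix holding the bands (-2, -1, 0, +1, +2 offsets) row-wise.
// [[Rcpp::export]]
NumericVector band2_solve(NumericMatrix diags, NumericVector rhs) {
  int n = rhs.size();
  if (diags.nrow() != 5 || diags.ncol() != n) stop("diags must be 5 x n");
  std::vector<double> m2(n), m1(n), d0(n), p1(n), p2(n), b(rhs.begin(), rhs.end());
  for (int i = 0; i < n; ++i) {
    m2[i] = diags(0, i); m1[i] = diags(1, i); d0[i] = diags(2, i);
    p1[i] = diags(3, i); p2[i] = diags(4, i);
  }
  // forward elimination
  for (int i = 0; i < n - 1; ++i) {
    if (d0[i] == 0.0) stop("singular banded system");
    double w1 = m1[i + 1] / d0[i];
    m1[i + 1] = 0.0;
    d0[i + 1] -= w1 * p1[i];
    if (i + 2 < n) p1[i + 1] -= w1 * p2[i];
    b[i + 1] -= w1 * b[i];
    if (i + 2 < n) {
      double w2 = m2[i + 2] / d0[i];
      m2[i + 2] = 0.0;
      m1[i + 2] -= w2 * p1[i];
      d0[i + 2] -= w2 * p2[i];
      b[i + 2] -= w2 * b[i];
    }
  }
  // back substitution
  NumericVector x(n);
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    if (i + 1 < n) s -= p1[i] * x[i + 1];
    if (i + 2 < n) s -= p2[i] * x[i + 2];
    if (d0[i] == 0.0) stop("singular banded system");
    x[i] = s / d0[i];
  }
  return x;
}

// One Crank-Nicolson step of the conservative diffusion operator
//   phi dC/dt = d/dz( phi D dC/dz )
// on a (possibly non-uniform) finite-volume grid. Boundary types:
//   upper: 0 = fixed value at the z=0 interface, 1 = no flux
//   lower: 0 = fixed value at the z=L interface, 1 = no flux,
//          2 = fixed gradient dC/dz (geothermal-style)
// bc values are supplied at t (v0) and t+dt (v1) so time-varying forcing is
// second order in time.
// [[Rcpp::export]]
NumericVector cn_step_general(NumericVector conc, NumericVector phi,
                              NumericVector Ds, NumericVector dxv, double dt,
                              int ubc_type, double ubc_v0, double ubc_v1,
                              int lbc_type, double lbc_v0, double lbc_v1) {
  int n = conc.size();
  if (phi.size() != n || Ds.size() != n || dxv.size() != n)
    stop("phi, Ds and dx must match the grid");
  if (dt <= 0) stop("dt must be positive");
  std::vector<double> a(n, 0.0), b(n, 0.0), c(n, 0.0), d(n, 0.0);
  std::vector<double> tup(n, 0.0), tdn(n, 0.0); // face transmissibilities / (phi_i dx_i)
  // interior faces: harmonic mean of phi*D over the half-cell distances
  for (int i = 1; i < n; ++i) {
    double k1 = phi[i - 1] * Ds[i - 1], k2 = phi[i] * Ds[i];
    double h = 0.5 * (dxv[i - 1] + dxv[i]);
    double kf = (k1 <= 0.0 || k2 <= 0.0) ? 0.0 : (dxv[i - 1] + dxv[i]) * k1 * k2 /
                (dxv[i - 1] * k2 + dxv[i] * k1) ;
    double t = kf / h;
    tup[i] = t / (phi[i] * dxv[i]);
    tdn[i - 1] = t / (phi[i - 1] * dxv[i - 1]);
  }
  double t_top = 0.0, t_bot = 0.0;
  if (ubc_type == 0) t_top = Ds[0] / (0.5 * dxv[0] * dxv[0]);       // phi cancels
  if (lbc_type == 0) t_bot = Ds[n - 1] / (0.5 * dxv[n - 1] * dxv[n - 1]);
  for (int i = 0; i < n; ++i) {
    double al = 0.5 * dt;
    double diag_op = tup[i] + tdn[i];
    if (i == 0) diag_op += t_top;
    if (i == n - 1) diag_op += t_bot;
    b[i] = 1.0 + al * diag_op;
    if (i > 0) a[i] = -al * tup[i];
    if (i < n - 1) c[i] = -al * tdn[i];
    // explicit half
    double lap = 0.0;
    if (i > 0) lap += tup[i] * (conc[i - 1] - conc[i]);
    if (i < n - 1) lap += tdn[i] * (conc[i + 1] - conc[i]);
    if (i == 0) lap += t_top * (ubc_v0 - conc[i]);
    if (i == n - 1) lap += t_bot * (lbc_v0 - conc[i]);
    d[i] = conc[i] + al * lap;
    if (i == 0) d[i] += al * t_top * ubc_v1;
    if (i == n - 1) d[i] += al * t_bot * lbc_v1;
  }
  if (lbc_type == 2) {
    // prescribed gradient g: diffusive flux through the bottom face is
    // -phi D g (downward positive z); it enters the last cell as a constant
    // source, identical in both half-steps.
    double g = 0.5 * (lbc_v0 + lbc_v1);
    d[n - 1] += dt * Ds[n - 1] * g / dxv[n - 1];
  }
  thomas(n, a.data(), b.data(), c.data(), d.data());
  return NumericVector(d.begin(), d.end());
}

// First-order upwind advection, uniform sign of velocity, one step.
// v > 0 transports downward (into the sediment); inflow is the concentration
// carried across the inflow boundary.
// [[Rcpp::export]]
NumericVector upwind_step(NumericVector conc, double v, NumericVector dxv,
                          double dt, double inflow) {
  int n = conc.size();
  NumericVector out(n);
  if (v == 0.0) { return clone(conc); }
  for (int i = 0; i < n; ++i) {
    double cfl = std::fabs(v) * dt / dxv[i];
    if (cfl > 1.0) stop("CFL violation: |v|*dt exceeds dx; sub-step the advection");
  }
  if (v > 0) {
    for (int i = 0; i < n; ++i) {
      double up = (i == 0) ? inflow : conc[i - 1];
      out[i] = conc[i] - v * dt / dxv[i] * (conc[i] - up);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double up = (i == n - 1) ? inflow : conc[i + 1];
      out[i] = conc[i] - std::fabs(v) * dt / dxv[i] * (conc[i] - up);
    }
  }
  return out;
}

// Coupled sulfate-methane column driver used by the pulse-dating model.
// Uniform grid, constant porous diffusivities; sulfate: fixed seawater value
// at the top interface, no-flux bottom; methane: fixed 0 at the top, fixed
// reservoir value at the bottom interface. Dual-Monod AOM applied explicitly
// (operator split) after the two diffusion solves; consumption is clipped so
// the 1:1 stoichiometry is exact even at sharp fronts.
// Optionally evaluates a depth-weighted misfit against an observed sulfate
// profile every `misfit_every` steps, with an early-stop rule once the misfit
// has passed a clear minimum.
// [[Rcpp::export]]
List cn_run_reduced(NumericVector so4_init, NumericVector ch4_init,
                    double dx, double dt, double D_so4, double D_ch4,
                    double so4_top, double ch4_top, double ch4_bottom,
                    double kmax, double Ks, double Km,
                    int n_steps,
                    IntegerVector obs_i0, NumericVector obs_w,
                    NumericVector obs_val, NumericVector obs_wt,
                    int misfit_every, double stop_factor, double stop_overshoot,
                    int stop_window, IntegerVector snap_steps) {
  int n = so4_init.size();
  std::vector<double> s(so4_init.begin(), so4_init.end());
  std::vector<double> m(ch4_init.begin(), ch4_init.end());
  std::vector<double> d(n);
  double rs = D_so4 * dt / (2.0 * dx * dx);
  double rm = D_ch4 * dt / (2.0 * dx * dx);
  // pre-factored Thomas coefficients (matrices are constant over the run)
  // sulfate: diag 1+3rs (top Dirichlet), 1+2rs interior, 1+rs (no-flux bottom)
  // methane: diag 1+3rm top, 1+2rm interior, 1+3rm bottom (Dirichlet)
  std::vector<double> cpS(n), invS(n), cpM(n), invM(n);
  {
    double bS, bM;
    for (int i = 0; i < n; ++i) {
      bS = 1.0 + ((i == 0) ? 3.0 : (i == n - 1) ? 1.0 : 2.0) * rs;
      bM = 1.0 + ((i == 0 || i == n - 1) ? 3.0 : 2.0) * rm;
      if (i > 0) { bS += rs * cpS[i - 1]; bM += rm * cpM[i - 1]; }
      invS[i] = 1.0 / bS; invM[i] = 1.0 / bM;
      cpS[i] = -rs * invS[i]; cpM[i] = -rm * invM[i];
    }
  }
  int n_obs = obs_i0.size();
  std::vector<double> mis_t, mis_v;
  double best = R_PosInf; int best_step = -1;
  long clip_count = 0; double cum_aom = 0.0;
  int n_snap = snap_steps.size(), isnap = 0;
  NumericMatrix snap_so4(n_snap, n), snap_ch4(n_snap, n);
  int steps_done = 0;

  auto misfit_now = [&](void) {
    double num = 0.0, den = 0.0;
    for (int k = 0; k < n_obs; ++k) {
      int i0 = obs_i0[k];
      double sim = (1.0 - obs_w[k]) * s[i0] +
                   obs_w[k] * s[std::min(i0 + 1, n - 1)];
      double e = sim - obs_val[k];
      num += obs_wt[k] * e * e; den += obs_wt[k];
    }
    return std::sqrt(num / den);
  };
  if (misfit_every > 0) { mis_t.push_back(0.0); mis_v.push_back(misfit_now());
    if (mis_v.back() < best) { best = mis_v.back(); best_step = 0; } }

  for (int step = 1; step <= n_steps; ++step) {
    // sulfate: fixed top value, no-flux bottom; explicit CN half then
    // pre-factored forward/back sweeps
    for (int i = 0; i < n; ++i) {
      double lap;
      if (i == 0)
        lap = 2.0 * rs * (so4_top - s[0]) + ((n > 1) ? rs * (s[1] - s[0]) : 0.0);
      else if (i == n - 1)
        lap = rs * (s[n - 2] - s[n - 1]);
      else
        lap = rs * (s[i - 1] - 2.0 * s[i] + s[i + 1]);
      d[i] = s[i] + lap;
    }
    d[0] += 2.0 * rs * so4_top;
    d[0] *= invS[0];
    for (int i = 1; i < n; ++i) d[i] = (d[i] + rs * d[i - 1]) * invS[i];
    s[n - 1] = d[n - 1];
    for (int i = n - 2; i >= 0; --i) s[i] = d[i] - cpS[i] * s[i + 1];
    // methane: fixed 0 top, fixed reservoir value at bottom interface
    for (int i = 0; i < n; ++i) {
      double lap;
      if (i == 0)
        lap = 2.0 * rm * (ch4_top - m[0]) + ((n > 1) ? rm * (m[1] - m[0]) : 0.0);
      else if (i == n - 1)
        lap = rm * (m[n - 2] - m[n - 1]) + 2.0 * rm * (ch4_bottom - m[n - 1]);
      else
        lap = rm * (m[i - 1] - 2.0 * m[i] + m[i + 1]);
      d[i] = m[i] + lap;
    }
    d[0] += 2.0 * rm * ch4_top;
    d[n - 1] += 2.0 * rm * ch4_bottom;
    d[0] *= invM[0];
    for (int i = 1; i < n; ++i) d[i] = (d[i] + rm * d[i - 1]) * invM[i];
    m[n - 1] = d[n - 1];
    for (int i = n - 2; i >= 0; --i) m[i] = d[i] - cpM[i] * m[i + 1];
    // explicit AOM, 1:1, clipped
    for (int i = 0; i < n; ++i) {
      double r = dt * kmax * s[i] / (Ks + s[i]) * m[i] / (Km + m[i]);
      double reff = r;
      if (reff > s[i]) reff = s[i];
      if (reff > m[i]) reff = m[i];
      if (reff < r) ++clip_count;
      s[i] -= reff; m[i] -= reff; cum_aom += reff;
      if (s[i] < 0) s[i] = 0;
      if (m[i] < 0) m[i] = 0;
    }
    steps_done = step;
    if (misfit_every > 0 && step % misfit_every == 0) {
      double mv = misfit_now();
      mis_t.push_back(step * dt); mis_v.push_back(mv);
      if (mv < best) { best = mv; best_step = step; }
      else if (stop_factor > 0 && best_step > 0 &&
               mv > stop_factor * best &&
               step > stop_overshoot * best_step) break;
      if (stop_window > 0 && step > 2 * best_step + stop_window) break;
    }
    if (isnap < n_snap && snap_steps[isnap] == step) {
      for (int i = 0; i < n; ++i) { snap_so4(isnap, i) = s[i]; snap_ch4(isnap, i) = m[i]; }
      ++isnap;
    }
  }
  return List::create(
    _["so4"] = NumericVector(s.begin(), s.end()),
    _["ch4"] = NumericVector(m.begin(), m.end()),
    _["misfit_time"] = NumericVector(mis_t.begin(), mis_t.end()),
    _["misfit"] = NumericVector(mis_v.begin(), mis_v.end()),
    _["best_time"] = best_step < 0 ? NA_REAL : best_step * dt,
    _["best_misfit"] = best,
    _["steps_done"] = steps_done,
    _["clip_count"] = (double) clip_count,
    _["cum_aom"] = cum_aom,
    _["snap_so4"] = snap_so4, _["snap_ch4"] = snap_ch4,
    _["n_snaps_filled"] = isnap);
}

// Heat conduction driver: uniform grid, fixed top value forcing(t), fixed
// gradient (geothermal) at the bottom. Returns snapshots every `snap_every`
// steps (step 0 included).
// [[Rcpp::export]]
List cn_run_heat(NumericVector T_init, double dx, double dt, double kappa,
                 NumericVector top_vals, double grad_bottom, int snap_every) {
  int n = T_init.size();
  int n_steps = top_vals.size() - 1;
  if (n_steps < 1) stop("top_vals must have length n_steps + 1");
  std::vector<double> T(T_init.begin(), T_init.end());
  std::vector<double> a(n), b(n), c(n), d(n);
  double r = kappa * dt / (2.0 * dx * dx);
  int n_snap = n_steps / snap_every + 1;
  NumericMatrix snaps(n_snap, n);
  NumericVector snap_t(n_snap);
  int isnap = 0;
  for (int i = 0; i < n; ++i) snaps(0, i) = T[i];
  snap_t[0] = 0.0; isnap = 1;
  for (int step = 1; step <= n_steps; ++step) {
    double f0 = top_vals[step - 1], f1 = top_vals[step];
    for (int i = 0; i < n; ++i) {
      double lap = 0.0;
      a[i] = (i > 0) ? -r : 0.0;
      c[i] = (i < n - 1) ? -r : 0.0;
      double diag_op = 0.0;
      if (i > 0) { diag_op += r; lap += r * (T[i - 1] - T[i]); }
      if (i < n - 1) { diag_op += r; lap += r * (T[i + 1] - T[i]); }
      if (i == 0) { diag_op += 2.0 * r; lap += 2.0 * r * (f0 - T[i]); }
      b[i] = 1.0 + diag_op;
      d[i] = T[i] + lap;
      if (i == 0) d[i] += 2.0 * r * f1;
      if (i == n - 1) d[i] += dt * kappa * grad_bottom / dx;
    }
    thomas(n, a.data(), b.data(), c.data(), d.data());
    for (int i = 0; i < n; ++i) T[i] = d[i];
    if (step % snap_every == 0 && isnap < n_snap) {
      for (int i = 0; i < n; ++i) snaps(isnap, i) = T[i];
      snap_t[isnap] = step * dt; ++isnap;
    }
  }
  return List::create(_["T"] = snaps, _["time"] = snap_t,
                      _["T_final"] = NumericVector(T.begin(), T.end()));
}
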