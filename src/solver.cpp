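// Core numerics: axisymmetric finite-volume transport of fluid-phase ligand
// in one hollow fiber, coupled to the cell-surface binding network at the
// wall.  Concentrations are mol/m^3, lengths m, times s; surface species are
// sites (or molecules) per cell.  All rate constants arrive here already
// converted to per-second / per-(mol m^-3) units.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NAV = 6.02214076e23;

// kinetic parameter order (solver units):
// 0 kaFR  1 kdFR  2 kaFH  3 kdFH  4 kc  5 kuc  6 kdFHR  7 kint  8 kintD
// 9 kdim  10 kundim  (homodimerization; defaults inherit kc/kuc)
// surface state order:
// 0 R  1 H  2 C  3 G  4 C2  5 G2  6 T  7 T2  8 I  9 IR  10 IH
// y[11] (when present) is the wall-adjacent fluid concentration F (mol/m^3).

// Mass-action rates.  `uptake` is the net rate (molecules/cell/s) at which
// ligand leaves the fluid phase: association to R and H minus dissociation
// from C, G and the ternary complex T.  Dimerization, coupling and
// internalization move ligand between surface pools only.
static inline void surface_rates(const double* y, double F, const double* p,
                                 bool internalize, double* dy, double& uptake) {
  const double aFR = p[0] * F * y[0];
  const double dFR = p[1] * y[2];
  const double aFH = p[2] * F * y[1];
  const double dFH = p[3] * y[3];
  const double cCH = p[4] * y[2] * y[1];   // C + H -> T
  const double cGR = p[4] * y[3] * y[0];   // G + R -> T
  const double u1  = p[5] * y[6];          // T -> C + H
  const double u2  = p[5] * y[6];          // T -> G + R
  const double fC2 = p[9] * y[2] * y[2];
  const double bC2 = p[10] * y[4];
  const double fG2 = p[9] * y[3] * y[3];
  const double bG2 = p[10] * y[5];
  const double fT2 = p[9] * y[6] * y[6];
  const double bT2 = p[10] * y[7];
  const double tern = p[6] * y[6];         // T -> R + H, ligand to fluid
  const double ki  = internalize ? p[7] : 0.0;
  const double kiD = internalize ? p[8] : 0.0;
  const double iC = ki * y[2], iG = ki * y[3], iT = ki * y[6];
  const double iC2 = kiD * y[4], iG2 = kiD * y[5], iT2 = kiD * y[7];

  dy[0]  = -aFR + dFR - cGR + u2 + tern;
  dy[1]  = -aFH + dFH - cCH + u1 + tern;
  dy[2]  =  aFR - dFR - cCH + u1 - 2.0 * fC2 + 2.0 * bC2 - iC;
  dy[3]  =  aFH - dFH - cGR + u2 - 2.0 * fG2 + 2.0 * bG2 - iG;
  dy[4]  =  fC2 - bC2 - iC2;
  dy[5]  =  fG2 - bG2 - iG2;
  dy[6]  =  cCH + cGR - u1 - u2 - tern - 2.0 * fT2 + 2.0 * bT2 - iT;
  dy[7]  =  fT2 - bT2 - iT2;
  dy[8]  =  iC + iG + iT + 2.0 * (iC2 + iG2 + iT2);
  dy[9]  =  iC + iT + 2.0 * (iC2 + iT2);
  dy[10] =  iG + iT + 2.0 * (iG2 + iT2);
  uptake =  aFR + aFH - dFR - dFH - tern;
}

// Full 12-state derivative including the local fluid depletion coupling.
// conv converts molecules/cell/s to (mol/m^3)/s for the wall fluid cell:
// conv = cells_in_cell / (V_cell_fluid * N_A).  conv = 0 freezes F.
static inline void coupled_rates(const double* y, const double* p,
                                 bool internalize, double conv, double* dy) {
  double uptake;
  double F = y[11] > 0.0 ? y[11] : 0.0;
  surface_rates(y, F, p, internalize, dy, uptake);
  dy[11] = -uptake * conv;
}

// Cash-Karp embedded Runge-Kutta 4(5) with standard step-size control.
// Integrates the 12-state coupled system over exactly `dt`.
static int rk45_advance(double* y, const double* p, bool internalize,
                        double conv, double dt, double rtol, double atol) {
  static const double
    b21 = 1.0 / 5.0,
    b31 = 3.0 / 40.0, b32 = 9.0 / 40.0,
    b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0,
    b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0, b54 = 35.0 / 27.0,
    b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
    b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0,
    c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
    c6 = 512.0 / 1771.0,
    dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
    dc6 = c6 - 1.0 / 4.0;
  const int n = 12;
  double k1[n], k2[n], k3[n], k4[n], k5[n], k6[n], yt[n], y5[n], err[n];
  double t = 0.0, h = dt;
  int nstep = 0;
  const double hmin = dt * 1e-12;

  while (t < dt) {
    if (t + h > dt) h = dt - t;
    coupled_rates(y, p, internalize, conv, k1);
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * b21 * k1[i];
    coupled_rates(yt, p, internalize, conv, k2);
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    coupled_rates(yt, p, internalize, conv, k3);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    coupled_rates(yt, p, internalize, conv, k4);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
    coupled_rates(yt, p, internalize, conv, k5);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                          b64 * k4[i] + b65 * k5[i]);
    coupled_rates(yt, p, internalize, conv, k6);

    double emax = 0.0;
    for (int i = 0; i < n; ++i) {
      y5[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      err[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] +
                    dc5 * k5[i] + dc6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = std::fabs(err[i]) / sc;
      if (e > emax) emax = e;
    }
    if (emax <= 1.0 || h <= hmin) {
      t += h;
      for (int i = 0; i < n; ++i) {
        y[i] = y5[i];
        // atol-level negatives are integration noise, not physics
        if (y[i] < 0.0 && y[i] > -1e-6) y[i] = 0.0;
      }
      ++nstep;
      double fac = emax > 0.0 ? 0.9 * std::pow(emax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(emax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < hmin) h = hmin;
    }
    if (nstep > 1000000) stop("surface ODE integrator exceeded step limit");
  }
  return nstep;
}

// [[Rcpp::export]]
List cpp_surface_rates(NumericVector y, double F, NumericVector par,
                       bool internalize) {
  if (y.size() != 11) stop("surface state must have 11 components");
  double dy[11], uptake;
  surface_rates(REAL(y), F, REAL(par), internalize, dy, uptake);
  NumericVector out(11);
  for (int i = 0; i < 11; ++i) out[i] = dy[i];
  return List::create(_["deriv"] = out, _["uptake"] = uptake);
}

// [[Rcpp::export]]
List cpp_advance_surface(NumericVector y, double F, double dt,
                         NumericVector par, bool internalize, double conv,
                         double rtol, double atol) {
  if (y.size() != 11) stop("surface state must have 11 components");
  double yy[12];
  for (int i = 0; i < 11; ++i) yy[i] = y[i];
  yy[11] = F;
  int ns = rk45_advance(yy, REAL(par), internalize, conv, dt, rtol, atol);
  NumericVector out(11);
  for (int i = 0; i < 11; ++i) out[i] = yy[i];
  return List::create(_["state"] = out, _["F"] = yy[11], _["n_substeps"] = ns);
}

// Full simulation of one fiber, scaled to the cartridge by n_fibers.
// [[Rcpp::export]]
List cpp_simulate(int n_r, int n_z, double radius, double length,
                  double n_fibers, double cells_per_fiber,
                  double u_mean, int pulsatile, double omega,
                  double D, int reservoir_mode, // 0 well-mixed, 1 plug
                  double C0, double V_res, double q_total, double pulse_rate,
                  NumericVector par, NumericVector R0_z, NumericVector H0_z,
                  IntegerVector internalize_z,
                  double dt, double total_time, double out_dt,
                  NumericVector snapshot_times, double rtol, double atol,
                  double neg_tol) {
  const double dr = radius / n_r, dz = length / n_z;
  std::vector<double> r(n_r), u0(n_r), Az(n_r), Vol(n_r), Ar(n_r);
  for (int i = 0; i < n_r; ++i) {
    r[i] = (i + 0.5) * dr;
    u0[i] = 2.0 * u_mean * (1.0 - (r[i] / radius) * (r[i] / radius));
    Az[i] = 2.0 * M_PI * r[i] * dr;       // axial face area
    Vol[i] = Az[i] * dz;                  // cell volume
    Ar[i] = 2.0 * M_PI * (i + 1.0) * dr * dz; // outer radial face area
  }
  const double n_cell_slice = cells_per_fiber / n_z;
  const double conv = n_cell_slice / (Vol[n_r - 1] * NAV);

  std::vector<double> F(n_r * n_z, 0.0), Fn(n_r * n_z, 0.0);
  std::vector<double> surf(11 * n_z, 0.0);
  for (int j = 0; j < n_z; ++j) {
    surf[11 * j + 0] = R0_z[j];
    surf[11 * j + 1] = H0_z[j];
  }

  const int n_steps = (int)std::ceil(total_time / dt - 1e-9);
  const int rec_every = std::max(1, (int)std::lround(out_dt / dt));
  const int n_rec = n_steps / rec_every + 2;

  NumericVector rec_t(n_rec), rec_Cin(n_rec), rec_cum_exit(n_rec),
      rec_res(n_rec), rec_fluid(n_rec), rec_bound(n_rec), rec_int(n_rec),
      rec_rate(n_rec);
  NumericMatrix bound_z(n_rec, n_z), intern_z(n_rec, n_z);
  const int probes[3] = {0, n_z / 2, n_z - 1};
  NumericMatrix probe_series(n_rec, 33);

  double reservoir_mass = C0 * V_res;  // mol (post nonspecific loss)
  double cum_exit = 0.0;               // mol, cartridge
  double C_pulse = C0;                 // inlet conc held over current pulse
  const double Tp = pulse_rate > 0 ? 1.0 / pulse_rate : total_time;
  double vol_delivered = 0.0;

  List snapshots;
  NumericVector snap_done(snapshot_times.size());
  int irec = 0;
  long tot_substeps = 0;

  // mesh-level flux weights: discrete sum of u0*Az gives per-fiber flow
  double q_mesh = 0.0;
  for (int i = 0; i < n_r; ++i) q_mesh += u0[i] * Az[i];

  auto record = [&](double t, double inst_rate, double Cin) {
    if (irec >= n_rec) return;
    double fluid = 0.0;
    for (int j = 0; j < n_z; ++j)
      for (int i = 0; i < n_r; ++i) fluid += F[i + j * n_r] * Vol[i];
    fluid *= n_fibers;
    double bnd = 0.0, internal = 0.0;
    for (int j = 0; j < n_z; ++j) {
      const double* y = &surf[11 * j];
      double b = y[2] + y[3] + 2.0 * (y[4] + y[5] + y[7]) + y[6];
      bound_z(irec, j) = b;
      intern_z(irec, j) = y[8];
      bnd += b * n_cell_slice;
      internal += y[8] * n_cell_slice;
    }
    bnd *= n_fibers / NAV;
    internal *= n_fibers / NAV;
    rec_t[irec] = t;
    rec_Cin[irec] = Cin;
    rec_cum_exit[irec] = cum_exit;
    rec_rate[irec] = inst_rate;
    rec_res[irec] = reservoir_mass;
    rec_fluid[irec] = fluid;
    rec_bound[irec] = bnd;
    rec_int[irec] = internal;
    for (int k = 0; k < 3; ++k)
      for (int s = 0; s < 11; ++s)
        probe_series(irec, 11 * k + s) = surf[11 * probes[k] + s];
    ++irec;
  };

  record(0.0, 0.0, reservoir_mode == 1 ? C0 : C_pulse);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt, t_mid = t + 0.5 * dt;
    const double w = pulsatile ? (1.0 + std::sin(omega * t_mid)) : 1.0;

    // inlet concentration for this step
    // the reservoir is diluted per pump stroke regardless of the velocity
    // waveform, so steady-vs-pulsatile comparisons isolate the waveform
    double Cin;
    if (reservoir_mode == 1) {           // plug displacement
      Cin = (vol_delivered < V_res) ? C0 : 0.0;
    } else {                             // well-mixed, diluted per pulse
      Cin = C_pulse;
    }
    // never deliver more than the reservoir holds (guards plug-mode tail)
    const double influx_nominal = q_mesh * w * Cin * dt * n_fibers;
    if (influx_nominal > reservoir_mass && influx_nominal > 0.0)
      Cin *= reservoir_mass / influx_nominal;

    // ---- explicit finite-volume transport update ----
    double outflux = 0.0, influx = 0.0;
    for (int j = 0; j < n_z; ++j) {
      for (int i = 0; i < n_r; ++i) {
        const int id = i + j * n_r;
        const double ui = u0[i] * w;
        const double up_in = (j == 0) ? Cin : F[i + (j - 1) * n_r];
        double dM = ui * (up_in - F[id]) * Az[i];   // upwind advection
        // axial diffusion, interior faces only (zero-gradient at both ends)
        if (j < n_z - 1)
          dM += D * (F[i + (j + 1) * n_r] - F[id]) / dz * Az[i];
        if (j > 0)
          dM += D * (F[i + (j - 1) * n_r] - F[id]) / dz * Az[i];
        // radial diffusion
        if (i < n_r - 1)
          dM += D * (F[id + 1] - F[id]) / dr * Ar[i];
        if (i > 0)
          dM += D * (F[id - 1] - F[id]) / dr * Ar[i - 1];
        Fn[id] = F[id] + dM * dt / Vol[i];
        if (j == 0) influx += ui * Cin * Az[i] * dt;
        if (j == n_z - 1) outflux += ui * F[id] * Az[i] * dt;
      }
    }
    std::swap(F, Fn);

    reservoir_mass -= influx * n_fibers;
    if (reservoir_mass < 0.0) reservoir_mass = 0.0;
    cum_exit += outflux * n_fibers;
    vol_delivered += q_mesh * w * dt * n_fibers;

    // ---- surface kinetics on each wall cell (local fluid depletion) ----
    for (int j = 0; j < n_z; ++j) {
      double* y = &surf[11 * j];
      double yy[12];
      for (int s = 0; s < 11; ++s) yy[s] = y[s];
      yy[11] = F[(n_r - 1) + j * n_r];
      if (yy[11] > 0.0 || yy[2] + yy[3] + yy[6] > 0.0) {
        tot_substeps += rk45_advance(yy, REAL(par), internalize_z[j] != 0,
                                     conv, dt, rtol, atol);
        for (int s = 0; s < 11; ++s) y[s] = yy[s];
        F[(n_r - 1) + j * n_r] = yy[11];
      }
    }

    // negativity guard (scaled by the initial inlet concentration)
    for (int id = 0; id < n_r * n_z; ++id) {
      if (F[id] < 0.0) {
        if (F[id] < -neg_tol * C0)
          stop("negative concentration beyond tolerance at step %d", step);
        F[id] = 0.0;
      }
    }

    const double t_next = t + dt;
    // pulse-boundary dilution (well-mixed reservoir)
    if (reservoir_mode == 0 &&
        std::floor(t_next / Tp + 1e-9) > std::floor(t / Tp + 1e-9))
      C_pulse = reservoir_mass / V_res;

    for (int k = 0; k < snapshot_times.size(); ++k) {
      if (!snap_done[k] && t_next >= snapshot_times[k] - 1e-9) {
        NumericMatrix snap(n_r, n_z);
        for (int j = 0; j < n_z; ++j)
          for (int i = 0; i < n_r; ++i) snap(i, j) = F[i + j * n_r];
        snapshots.push_back(List::create(_["time"] = t_next, _["F"] = snap));
        snap_done[k] = 1;
      }
    }
    if ((step + 1) % rec_every == 0 || step == n_steps - 1)
      record(t_next, outflux * n_fibers / dt, Cin);
  }

  NumericMatrix field(n_r, n_z);
  for (int j = 0; j < n_z; ++j)
    for (int i = 0; i < n_r; ++i) field(i, j) = F[i + j * n_r];
  NumericMatrix surf_final(11, n_z);
  for (int j = 0; j < n_z; ++j)
    for (int s = 0; s < 11; ++s) surf_final(s, j) = surf[11 * j + s];

  Range keep(0, irec - 1);
  return List::create(
      _["time"] = rec_t[keep], _["inlet_conc"] = rec_Cin[keep],
      _["cum_exit"] = rec_cum_exit[keep], _["exit_rate"] = rec_rate[keep],
      _["reservoir"] = rec_res[keep], _["fluid"] = rec_fluid[keep],
      _["bound"] = rec_bound[keep], _["internalized"] = rec_int[keep],
      _["bound_z"] = bound_z(keep, _), _["intern_z"] = intern_z(keep, _),
      _["probe_series"] = probe_series(keep, _),
      _["field"] = field, _["surface_final"] = surf_final,
      _["snapshots"] = snapshots, _["n_substeps"] = (double)tot_substeps,
      _["dr"] = dr, _["dz"] = dz, _["dt"] = dt, _["q_mesh"] = q_mesh);
}
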