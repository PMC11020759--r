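#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-variable excitable model (fast inward / slow outward currents with a
// single recovery gate) coupled to a driven calcium relaxation equation.
//
//   dv/dt = h * v^2 (1 - v) / tau_in - v / tau_out + D lap(v) + I_stim
//   dh/dt = (1 - h) / tau_open          if v <  v_gate
//         = -h / tau_close(x, y)        if v >= v_gate
//   dca/dt = ca_gain * S(w) * s(v) - ca / tau_ca,
//            s(v) = v^4 / (v^4 + 0.35^4),  S(w) = 1/(1 + exp(-(w-0.5)/0.02))
//   dw/dt  = (1 - w) / tau_open        if v <  v_gate   (release recovery)
//          = -w / tau_rel              if v >= v_gate   (release inactivation)
//
// w is a calcium-release gate: release stays on for about tau_rel*ln(2) ms
// after the upstroke and then shuts off sharply (sigmoid S), so the
// transient peaks mid-plateau and afterwards decays as a clean
// monoexponential with tau_ca, independent of the action potential
// duration.
//
// Forward Euler, 5-point Laplacian, no-flux outer boundaries; scar cells are
// unexcitable internal no-flux holes (state frozen at rest). tau_close is a
// per-cell map so infarct border zones and drug effects can modulate APD.
//
// The solver records, besides the down-sampled frames, every sub-frame-
// interpolated crossing of v through act_level (both directions), which the
// R side turns into ground-truth activation times and APDs.

// [[Rcpp::export]]
List ms_solve_cpp(NumericMatrix v0, NumericMatrix h0, NumericMatrix ca0,
                  IntegerMatrix scar, NumericMatrix tau_close_map,
                  double tau_in, double tau_out, double tau_open,
                  double v_gate, double diffusion, double dx, double dt,
                  double t0, int n_steps, NumericMatrix stim,
                  double ca_gain, double tau_ca, double tau_rel,
                  int record_every, double record_from,
                  double act_level = 0.2) {
  const int H = v0.nrow(), W = v0.ncol(), N = H * W;
  std::vector<double> v(N), h(N), ca(N), vn(N), w(N, 1.0);
  std::vector<int> sc(N);
  std::vector<double> tcl(N);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int k = i + j * H;
      v[k] = v0(i, j); h[k] = h0(i, j); ca[k] = ca0(i, j);
      sc[k] = scar(i, j); tcl[k] = tau_close_map(i, j);
      if (sc[k]) { v[k] = 0.0; h[k] = 1.0; ca[k] = 0.0; }
    }

  const int n_stim = stim.nrow();
  const double r_dx2 = diffusion / (dx * dx);

  // count frames to record
  int n_frames = 0;
  if (record_every > 0) {
    for (int s = 0; s < n_steps; ++s) {
      double t = t0 + s * dt;
      if (s % record_every == 0 && t >= record_from - 1e-9) ++n_frames;
    }
  }
  NumericVector vfr(record_every > 0 ? (R_xlen_t)n_frames * N : 0);
  NumericVector cafr(record_every > 0 ? (R_xlen_t)n_frames * N : 0);
  NumericVector ftimes(n_frames);
  int fr = 0;

  std::vector<double> ev_t, ev_i, ev_j, ev_dir;  // crossing events
  std::vector<double> prev_v(v);

  for (int s = 0; s < n_steps; ++s) {
    double t = t0 + s * dt;
    if (record_every > 0 && s % record_every == 0 && t >= record_from - 1e-9) {
      double *pv = REAL(vfr) + (R_xlen_t)fr * N;
      double *pc = REAL(cafr) + (R_xlen_t)fr * N;
      for (int k = 0; k < N; ++k) { pv[k] = v[k]; pc[k] = ca[k]; }
      ftimes[fr] = t;
      ++fr;
    }

    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        int k = i + j * H;
        if (sc[k]) { vn[k] = 0.0; continue; }
        double vc = v[k];
        // no-flux: missing/scar neighbours mirror the centre value
        double vup = (i > 0     && !sc[k - 1]) ? v[k - 1] : vc;
        double vdn = (i < H - 1 && !sc[k + 1]) ? v[k + 1] : vc;
        double vlf = (j > 0     && !sc[k - H]) ? v[k - H] : vc;
        double vrt = (j < W - 1 && !sc[k + H]) ? v[k + H] : vc;
        double lap = (vup + vdn + vlf + vrt - 4.0 * vc) * r_dx2;
        double dv = h[k] * vc * vc * (1.0 - vc) / tau_in - vc / tau_out + lap;
        vn[k] = vc + dt * dv;
        // gates
        if (vc < v_gate) {
          h[k] += dt * (1.0 - h[k]) / tau_open;
          w[k] += dt * (1.0 - w[k]) / tau_open;
        } else {
          h[k] -= dt * h[k] / tcl[k];
          w[k] -= dt * w[k] / tau_rel;
        }
        // calcium release gated on depolarisation and the release gate
        double v4 = vc * vc * vc * vc;
        double gate = 1.0 / (1.0 + std::exp(-(w[k] - 0.5) / 0.02));
        double src = gate * v4 / (v4 + 0.015006250000000001); // 0.35^4
        ca[k] += dt * (ca_gain * src - ca[k] / tau_ca);
      }
    }

    // stimuli (additive current inside a disc)
    for (int q = 0; q < n_stim; ++q) {
      if (t >= stim(q, 0) && t < stim(q, 1)) {
        int ci = (int)stim(q, 2) - 1, cj = (int)stim(q, 3) - 1;
        double rad = stim(q, 4), amp = stim(q, 5);
        int r = (int)std::ceil(rad);
        for (int dj = -r; dj <= r; ++dj)
          for (int di = -r; di <= r; ++di) {
            int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (di * di + dj * dj > rad * rad) continue;
            int k = ii + jj * H;
            if (!sc[k]) vn[k] += dt * amp;
          }
      }
    }

    // crossing bookkeeping + stability check
    for (int k = 0; k < N; ++k) {
      double a = prev_v[k], b = vn[k];
      if (a < act_level && b >= act_level) {
        double tc = t + dt * (act_level - a) / (b - a);
        ev_t.push_back(tc); ev_i.push_back(k % H + 1);
        ev_j.push_back(k / H + 1); ev_dir.push_back(1.0);
      } else if (a >= act_level && b < act_level) {
        double tc = t + dt * (a - act_level) / (a - b);
        ev_t.push_back(tc); ev_i.push_back(k % H + 1);
        ev_j.push_back(k / H + 1); ev_dir.push_back(-1.0);
      }
      prev_v[k] = b;
    }
    std::swap(v, vn);

    if (s % 200 == 0) {
      for (int k = 0; k < N; k += 17)
        if (!std::isfinite(v[k]))
          stop("unstable integration: non-finite state at t = %.3f ms (step %d)",
               t, s);
    }
  }

  NumericMatrix vfin(H, W), hfin(H, W), cafin(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int k = i + j * H;
      vfin(i, j) = v[k]; hfin(i, j) = h[k]; cafin(i, j) = ca[k];
      if (!std::isfinite(v[k]))
        stop("unstable integration: non-finite state at end (t = %.3f ms)",
             t0 + n_steps * dt);
    }

  int ne = ev_t.size();
  NumericMatrix events(ne, 4);
  for (int e = 0; e < ne; ++e) {
    events(e, 0) = ev_t[e]; events(e, 1) = ev_i[e];
    events(e, 2) = ev_j[e]; events(e, 3) = ev_dir[e];
  }
  colnames(events) = CharacterVector::create("time_ms", "row", "col", "dir");

  if (record_every > 0) {
    vfr.attr("dim") = IntegerVector::create(H, W, n_frames);
    cafr.attr("dim") = IntegerVector::create(H, W, n_frames);
  }

  return List::create(_["v_frames"] = vfr, _["ca_frames"] = cafr,
                      _["frame_times"] = ftimes, _["events"] = events,
                      _["v_final"] = vfin, _["h_final"] = hfin,
                      _["ca_final"] = cafin, _["t_end"] = t0 + n_steps * dt);
}
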