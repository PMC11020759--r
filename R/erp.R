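# low-level solver call with explicit initial state (snapshot resume)
run_solver_state <- function(geometry, params, v0, h0, ca0, t0, duration_ms,
                             stim, dt = 0.1, record_every = 0L,
                             record_from = 0, tau_close_map = NULL) {
  H <- geometry$height; W <- geometry$width
  if (is.null(tau_close_map)) tau_close_map <- matrix(params$tau_close, H, W)
  stim_mat <- if (is.null(stim) || !nrow(stim)) matrix(0, 0, 6) else
    as.matrix(stim[, c("t_on", "t_off", "row", "col", "radius", "amplitude")])
  ms_solve_cpp(v0, h0, ca0, matrix(as.integer(geometry$scar_mask), H, W),
               tau_close_map, params$tau_in, params$tau_out, params$tau_open,
               params$v_gate, params$diffusion_coeff, geometry$pixel_pitch,
               dt, t0, ceiling(duration_ms / dt), stim_mat,
               params$ca_amplitude_gain, params$tau_ca_decay,
               params$tau_ca_release, record_every, record_from)
}

stim_row <- function(t, site, amplitude = 2, duration = 2, radius = 2.5)
  data.frame(t_on = t, t_off = t + duration, row = site[1], col = site[2],
             radius = radius, amplitude = amplitude)

#' Ground-truth effective refractory period by S1-S2 scanning
#'
#' Delivers an S1 drive train, snapshots the tissue state, then resumes from
#' the snapshot with a single premature S2 at progressively shorter coupling
#' intervals. The ERP is the longest S1-S2 interval that fails to elicit a
#' propagated response, where capture means an activation detected at least
#' `capture_distance_px` pixels from the stimulus site.
#'
#' @param geometry a [tissue_geometry()].
#' @param params a [cell_model_params()].
#' @param s1s1 S1-S1 interval, ms.
#' @param s2_scan `list(start =, step =, min =)`: scan starts at `start` ms
#'   above the expected ERP and decrements by `step` ms down to `min`
#'   (default 0).
#' @param s1_count drive-train beats.
#' @param stim_site `c(row, col)`.
#' @param capture_distance_px propagation criterion, pixels.
#' @param dt integration step, ms.
#' @param border_apd_factor border-zone `tau_close` multiplier (see
#'   [simulate_tissue()]).
#' @return list with `erp_ms`, `scanned` (data.frame `s1s2`, `captured`).
#' @export
measure_true_erp <- function(geometry, params, s1s1 = 300,
                             s2_scan = list(start = 200, step = 2),
                             s1_count = 6L, stim_site = c(3L, 3L),
                             capture_distance_px = 10, dt = 0.1,
                             border_apd_factor = 1) {
  stopifnot(inherits(geometry, "tissue_geometry"),
            inherits(params, "cell_model_params"))
  if (s2_scan$step <= 0) stop("s2 scan step must be positive")
  H <- geometry$height; W <- geometry$width
  if (geometry$scar_mask[stim_site[1], stim_site[2]])
    stop("stimulus site lies inside the scar")
  tcl <- matrix(params$tau_close, H, W)
  if (border_apd_factor != 1)
    tcl[geometry$border_zone_mask] <- params$tau_close * border_apd_factor

  s1_times <- (seq_len(s1_count) - 1L) * s1s1
  train <- run_solver_state(geometry, params, matrix(0, H, W),
                            matrix(1, H, W), matrix(0, H, W), 0,
                            max(s1_times) + 2, do.call(rbind, lapply(
                              s1_times, stim_row, site = stim_site)),
                            dt = dt, tau_close_map = tcl)
  t_s1 <- max(s1_times)

  test_capture <- function(s1s2) {
    ts2 <- t_s1 + s1s2
    o <- run_solver_state(geometry, params, train$v_final, train$h_final,
                          train$ca_final, train$t_end,
                          s1s2 + 250, stim_row(ts2, stim_site), dt = dt,
                          tau_close_map = tcl)
    ev <- o$events
    ups <- ev[ev[, "dir"] > 0, , drop = FALSE]
    d2 <- (ups[, "row"] - stim_site[1])^2 + (ups[, "col"] - stim_site[2])^2
    any(ups[, "time_ms"] > ts2 & d2 >= capture_distance_px^2)
  }

  scan <- seq(s2_scan$start, s2_scan$min %||% 0, by = -s2_scan$step)
  tested <- data.frame(s1s2 = numeric(), captured = logical())
  erp <- NA_real_
  for (s1s2 in scan) {
    cap <- test_capture(s1s2)
    tested <- rbind(tested, data.frame(s1s2 = s1s2, captured = cap))
    if (s1s2 == s2_scan$start && !cap)
      stop("S2 scan start failed to capture; start the scan above the ERP")
    if (!cap) { erp <- s1s2; break }
  }
  if (is.na(erp))
    stop("ERP below scan range: capture persisted at the smallest interval")
  list(erp_ms = erp, scanned = tested)
}
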