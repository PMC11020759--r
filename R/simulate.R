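#' Build the stimulus schedule implied by a pacing protocol
#'
#' @param protocol a [pacing_protocol()].
#' @return data.frame with columns `t_on`, `t_off`, `row`, `col`, `radius`,
#'   `amplitude`, `label` (`"s1"`, `"s2"`, ... or `"burst"`), one row per
#'   stimulus, times in ms from protocol start.
#' @export
stimulus_schedule <- function(protocol) {
  p <- protocol
  if (p$kind == "none")
    return(data.frame(t_on = numeric(), t_off = numeric(), row = integer(),
                      col = integer(), radius = numeric(),
                      amplitude = numeric(), label = character()))
  pre <- p$steady_beats_before_acquisition
  if (p$kind == "burst") {
    times <- (seq_len(pre + p$s1_count) - 1L) * p$s1s1
    labels <- rep("burst", length(times))
  } else {
    times <- (seq_len(pre + p$s1_count) - 1L) * p$s1s1
    labels <- rep("s1", length(times))
    t_last <- max(times)
    for (k in seq_along(p$extra_intervals)) {
      t_last <- t_last + p$extra_intervals[k]
      times <- c(times, t_last)
      labels <- c(labels, paste0("s", k + 1L))
    }
  }
  data.frame(t_on = times, t_off = times + p$stim_duration,
             row = p$stim_site[1], col = p$stim_site[2],
             radius = 2.5, amplitude = p$stim_amplitude, label = labels,
             stringsAsFactors = FALSE)
}

#' Simulate a paced cardiac tissue recording
#'
#' Integrates the two-variable excitable model with the driven calcium
#' subsystem on the given geometry, delivers the protocol's stimuli, and
#' returns camera-like dual-channel movies (2 ms frames by default), a
#' pseudo-ECG, a stimulus log with capture flags, and a fully populated
#' ground-truth record. The voltage channel is emitted with inverted
#' fluorescence polarity (voltage-dye convention); the calcium channel is
#' upright. Scar pixels carry baseline plus noise only.
#'
#' The recording window opens after `steady_beats_before_acquisition` paced
#' beats, mirroring the practice of acquiring after a conditioning train.
#'
#' @param geometry a [tissue_geometry()].
#' @param params a [cell_model_params()] (apply [apply_drug()] first for the
#'   drug condition).
#' @param protocol a [pacing_protocol()].
#' @param noise_snr signal-to-noise ratio in dB, defined as peak-to-peak
#'   signal over noise standard deviation; `Inf` for noise-free.
#' @param seed integer seed fixing all randomness.
#' @param dt_internal integration step, ms (0.05-0.1 recommended; stability
#'   requires `diffusion_coeff * dt / pixel_pitch^2 <= 0.25`).
#' @param frame_interval output frame interval, ms.
#' @param tail_ms recording continued after the last stimulus, ms.
#' @param duration_ms total duration for `kind = "none"` protocols, ms.
#' @param extra_stimuli optional extra stimulus data.frame (same columns as
#'   [stimulus_schedule()]), e.g. ectopic beats from [inject_ectopy()].
#' @param border_apd_factor multiplier on `tau_close` inside the border zone
#'   (peri-infarct APD prolongation); 1 disables the gradient.
#' @param bleach_tau_ms optional photobleaching time constant (ms); `NULL`
#'   disables the slow exponential fluorescence drift.
#' @param capture_distance_px a stimulus counts as captured when an
#'   activation is detected at least this many pixels from the stimulus site.
#' @param electrodes pseudo-ECG electrode positions; see
#'   [compute_pseudo_ecg()].
#' @return an object of class `sim_output`: list with `vm`, `cai`
#'   ([optical_movie()]), `pseudo_ecg`, `stimulus_log`, `truth`, and the
#'   generating `geometry`, `params`, `protocol`, `seed`.
#' @export
simulate_tissue <- function(geometry, params, protocol, noise_snr = Inf,
                            seed = 1L, dt_internal = 0.1, frame_interval = 2,
                            tail_ms = 400, duration_ms = 400,
                            extra_stimuli = NULL, border_apd_factor = 1,
                            bleach_tau_ms = NULL, capture_distance_px = 10,
                            electrodes = NULL) {
  stopifnot(inherits(geometry, "tissue_geometry"),
            inherits(params, "cell_model_params"),
            inherits(protocol, "pacing_protocol"))
  H <- geometry$height; W <- geometry$width
  if (protocol$kind != "none" &&
      geometry$scar_mask[protocol$stim_site[1], protocol$stim_site[2]])
    stop("stimulus site lies inside the scar")

  sched <- stimulus_schedule(protocol)
  if (!is.null(extra_stimuli) && nrow(extra_stimuli)) {
    if (any(geometry$scar_mask[cbind(extra_stimuli$row, extra_stimuli$col)]))
      stop("ectopic origin lies inside the scar")
    sched <- rbind(sched, extra_stimuli[, names(sched)])
    sched <- sched[order(sched$t_on), , drop = FALSE]
  }

  if (nrow(sched)) {
    paced_times <- sort(sched$t_on[sched$label %in% c("s1", "burst")])
    n_pre <- protocol$steady_beats_before_acquisition
    record_from <- if (n_pre == 0L || !length(paced_times)) 0
      else if (n_pre < length(paced_times)) paced_times[n_pre + 1L]
      else max(sched$t_on)
    t_end <- max(sched$t_off) + tail_ms
  } else {
    record_from <- 0
    t_end <- duration_ms
  }

  tcl_map <- matrix(params$tau_close, H, W)
  if (border_apd_factor != 1)
    tcl_map[geometry$border_zone_mask] <-
      params$tau_close * border_apd_factor

  record_every <- max(1L, round(frame_interval / dt_internal))
  n_steps <- ceiling(t_end / dt_internal)

  stim_mat <- if (nrow(sched))
    as.matrix(sched[, c("t_on", "t_off", "row", "col", "radius", "amplitude")])
  else matrix(0, 0, 6)

  sol <- ms_solve_cpp(matrix(0, H, W), matrix(1, H, W), matrix(0, H, W),
                      matrix(as.integer(geometry$scar_mask), H, W), tcl_map,
                      params$tau_in, params$tau_out, params$tau_open,
                      params$v_gate, params$diffusion_coeff,
                      geometry$pixel_pitch, dt_internal, 0, n_steps,
                      stim_mat, params$ca_amplitude_gain,
                      params$tau_ca_decay, params$tau_ca_release,
                      record_every, record_from)

  ev <- sol$events
  capture <- logical(nrow(sched))
  if (nrow(sched)) {
    ups <- ev[ev[, "dir"] > 0, , drop = FALSE]
    for (q in seq_len(nrow(sched))) {
      t0 <- sched$t_on[q]
      t1 <- if (q < nrow(sched)) sched$t_on[q + 1L] else t0 + tail_ms
      d2 <- (ups[, "row"] - sched$row[q])^2 + (ups[, "col"] - sched$col[q])^2
      capture[q] <- any(ups[, "time_ms"] > t0 & ups[, "time_ms"] <= t1 + 50 &
                          d2 >= capture_distance_px^2)
    }
  }

  # truth APD per site/beat from sub-step level crossings on the raw state
  truth_apd <- events_to_apd(ev)

  ft <- sol$frame_times
  nT <- length(ft)
  if (nT < 2) stop("recording window too short: fewer than 2 frames")

  # pseudo-ECG on the noise-free voltage frames
  vm_raw <- optical_movie(sol$v_frames, frame_interval, geometry$pixel_pitch,
                          channel = "vm", polarity = "upright",
                          metadata = list(t0_ms = ft[1]))
  ecg <- compute_pseudo_ecg(vm_raw, electrodes = electrodes)

  # fluorescence model (seeded noise)
  out <- with_seed(seed, {
    sig_gain <- ifelse(geometry$scar_mask, 0, 1)
    drift <- if (is.null(bleach_tau_ms)) rep(1, nT) else
      exp(-(ft - ft[1]) / bleach_tau_ms)
    fl <- function(frames, baseline, gain, invert) {
      m <- matrix(frames, ncol = nT)
      rmax <- m[, 1]; rmin <- m[, 1]
      for (t in seq_len(nT)[-1]) {
        rmax <- pmax(rmax, m[, t]); rmin <- pmin(rmin, m[, t])
      }
      p2p <- stats::median((rmax - rmin)[!as.vector(geometry$scar_mask)]) *
        gain
      sigma <- if (is.finite(noise_snr)) p2p / 10^(noise_snr / 20) else 0
      g <- as.vector(sig_gain) * gain * (if (invert) -1 else 1)
      m <- baseline + m * g * rep(drift, each = nrow(m))
      if (sigma > 0) m <- m + rnorm(length(m), 0, sigma)
      array(m, dim = dim(frames))
    }
    list(vm = fl(sol$v_frames, baseline = 1, gain = 0.8, invert = TRUE),
         cai = fl(sol$ca_frames, baseline = 0.1, gain = 0.8, invert = FALSE))
  })

  meta <- list(t0_ms = ft[1], seed = seed, noise_snr = noise_snr,
               stim_times_ms = sched$t_on - ft[1],
               stim_labels = sched$label)
  vm <- optical_movie(out$vm, frame_interval, geometry$pixel_pitch,
                      channel = "vm", polarity = "inverted", metadata = meta)
  cai <- optical_movie(out$cai, frame_interval, geometry$pixel_pitch,
                       channel = "cai", polarity = "upright", metadata = meta)

  stim_log <- cbind(sched, captured = capture)
  ect <- sched$t_on[sched$label == "ectopic"]

  structure(list(
    vm = vm, cai = cai,
    pseudo_ecg = data.frame(time_ms = ft, ecg),
    stimulus_log = stim_log,
    truth = list(apd80 = truth_apd, events = ev, tau_ca = params$tau_ca_decay,
                 ectopic_times = ect, record_from_ms = ft[1],
                 frame_times_ms = ft,
                 v_frames = sol$v_frames, ca_frames = sol$ca_frames),
    geometry = geometry, params = params, protocol = protocol, seed = seed),
    class = "sim_output")
}

# per-site per-beat APD truth from the solver's level-crossing events
events_to_apd <- function(ev) {
  if (!nrow(ev)) return(data.frame(row = integer(), col = integer(),
                                   beat = integer(), t_act = numeric(),
                                   apd = numeric()))
  df <- as.data.frame(ev)
  key <- paste(df$row, df$col)
  res <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_ms), ]
    ups <- d$time_ms[d$dir > 0]
    dns <- d$time_ms[d$dir < 0]
    if (!length(ups)) return(NULL)
    apd <- vapply(ups, function(u) {
      nx <- dns[dns > u]
      if (length(nx)) min(nx) - u else NA_real_
    }, numeric(1))
    data.frame(row = d$row[1], col = d$col[1], beat = seq_along(ups),
               t_act = ups, apd = apd)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d x %d tissue, %d frames, %d stimuli (%d captured), seed %d\n",
              x$geometry$height, x$geometry$width, n_frames(x$vm),
              nrow(x$stimulus_log), sum(x$stimulus_log$captured), x$seed))
  invisible(x)
}
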