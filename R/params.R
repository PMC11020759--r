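#' Tissue geometry for the synthetic generator
#'
#' Defines the simulated preparation: grid size, pixel pitch, an optional
#' infarct scar (unexcitable, signal-free) and its border zone. Defaults match
#' a 100 x 100 pixel field of view at 0.25 mm/pixel (2.5 x 2.5 cm).
#'
#' @param height,width grid size in cells (>= 16).
#' @param pixel_pitch cell/pixel size in mm.
#' @param scar_mask logical matrix (`height` x `width`); `TRUE` marks infarct.
#'   `NULL` means no scar.
#' @param border_zone_px width of the peri-infarct border zone, in pixels,
#'   grown outward from the scar by chebyshev distance.
#' @return an object of class `tissue_geometry`.
#' @export
tissue_geometry <- function(height = 100L, width = 100L, pixel_pitch = 0.25,
                            scar_mask = NULL, border_zone_px = 3L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 16L || width < 16L)
    stop("grid dimensions must be at least 16 x 16")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  if (is.null(scar_mask)) scar_mask <- matrix(FALSE, height, width)
  if (!is.logical(scar_mask) || !identical(dim(scar_mask), c(height, width)))
    stop("scar_mask must be a logical height x width matrix")
  bz <- grow_mask(scar_mask, border_zone_px) & !scar_mask
  structure(list(height = height, width = width, pixel_pitch = pixel_pitch,
                 scar_mask = scar_mask, border_zone_mask = bz),
            class = "tissue_geometry")
}

# chebyshev dilation of a logical mask by r pixels
grow_mask <- function(mask, r) {
  if (r <= 0L || !any(mask)) return(mask)
  out <- mask
  H <- nrow(mask); W <- ncol(mask)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0L && dj == 0L) next
    src_i <- max(1L, 1L - di):min(H, H - di)
    src_j <- max(1L, 1L - dj):min(W, W - dj)
    out[src_i + di, src_j + dj] <- out[src_i + di, src_j + dj] |
      mask[src_i, src_j]
  }
  out
}

#' Disc-shaped scar mask
#'
#' Convenience builder for the default single connected infarct region.
#'
#' @param height,width grid size.
#' @param center `c(row, col)`; defaults to the upper-left quadrant.
#' @param radius_px scar radius in pixels.
#' @return logical matrix.
#' @export
disc_scar <- function(height, width, center = NULL, radius_px = NULL) {
  if (is.null(center)) center <- c(round(height * 0.3), round(width * 0.3))
  if (is.null(radius_px)) radius_px <- round(min(height, width) * 0.14)
  ii <- matrix(seq_len(height), height, width)
  jj <- matrix(seq_len(width), height, width, byrow = TRUE)
  (ii - center[1])^2 + (jj - center[2])^2 <= radius_px^2
}

#' Cell model parameters
#'
#' Parameters of the two-variable excitable membrane model (fast inward /
#' slow outward current with a single recovery gate) and the driven calcium
#' relaxation subsystem, plus the parametric drug effect. Defaults are
#' calibrated so that a paced 2D sheet yields APD80 near 123 ms at a pacing
#' cycle length of 300 ms, an effective refractory period near 135 ms, a
#' conduction velocity near 0.33 mm/ms, and a calcium decay constant equal to
#' `tau_ca_decay`.
#'
#' @param tau_in,tau_out,tau_open,tau_close membrane time constants (ms).
#' @param v_gate dimensionless gate threshold.
#' @param diffusion_coeff voltage diffusion coefficient (mm^2/ms).
#' @param ca_amplitude_gain source gain of the calcium subsystem (1/ms).
#' @param tau_ca_decay calcium decay time constant (ms).
#' @param tau_ca_release inactivation constant of the calcium release gate
#'   (ms); release shuts off about `tau_ca_release * log(2)` ms after the
#'   upstroke, setting when the transient peaks. Not affected by the drug.
#' @param drug_apd_factor multiplier applied to `tau_close` when the drug
#'   condition is simulated; > 1 prolongs APD and ERP.
#' @param drug_ca_factor multiplier applied to `tau_ca_decay` under drug;
#'   < 1 accelerates calcium decay.
#' @return an object of class `cell_model_params`.
#' @export
cell_model_params <- function(tau_in = 0.3, tau_out = 6, tau_open = 30,
                              tau_close = 60, v_gate = 0.13,
                              diffusion_coeff = 0.1,
                              ca_amplitude_gain = 0.02, tau_ca_decay = 50.3,
                              tau_ca_release = 80,
                              drug_apd_factor = 1, drug_ca_factor = 1) {
  tc <- c(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
          tau_close = tau_close, tau_ca_decay = tau_ca_decay,
          tau_ca_release = tau_ca_release)
  if (any(tc <= 0)) stop("all time constants must be positive")
  if (drug_apd_factor <= 0 || drug_ca_factor <= 0)
    stop("drug factors must be positive")
  if (diffusion_coeff <= 0) stop("diffusion_coeff must be positive")
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, v_gate = v_gate,
                 diffusion_coeff = diffusion_coeff,
                 ca_amplitude_gain = ca_amplitude_gain,
                 tau_ca_decay = tau_ca_decay,
                 tau_ca_release = tau_ca_release,
                 drug_apd_factor = drug_apd_factor,
                 drug_ca_factor = drug_ca_factor),
            class = "cell_model_params")
}

#' Apply the drug condition to a parameter set
#'
#' Multiplies `tau_close` by `drug_apd_factor` and `tau_ca_decay` by
#' `drug_ca_factor`, returning a new parameter set with factors reset to 1.
#' The drug is represented purely parametrically (no kinetics or washout).
#'
#' @param params a [cell_model_params()] object.
#' @return a `cell_model_params` object.
#' @export
apply_drug <- function(params) {
  stopifnot(inherits(params, "cell_model_params"))
  p <- params
  p$tau_close <- p$tau_close * p$drug_apd_factor
  p$tau_ca_decay <- p$tau_ca_decay * p$drug_ca_factor
  p$drug_apd_factor <- 1
  p$drug_ca_factor <- 1
  p
}

#' Pacing protocol description
#'
#' @param kind `"extrastimulus"` (S1 drive train plus premature S2..Sn),
#'   `"burst"` (constant-cycle train), or `"none"`.
#' @param s1_count number of S1 beats.
#' @param s1s1 S1-S1 interval, ms.
#' @param extra_intervals premature coupling intervals S2..Sn (ms),
#'   strictly positive and non-increasing.
#' @param burst_start,burst_step,burst_min decremental burst scan (ms):
#'   starting cycle length, decrement and floor.
#' @param stim_site `c(row, col)` of the stimulus electrode.
#' @param stim_amplitude stimulus current (model units).
#' @param stim_duration stimulus duration, ms.
#' @param steady_beats_before_acquisition paced beats delivered before the
#'   recording window opens (cardiac-memory conditioning).
#' @return an object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(kind = c("burst", "extrastimulus", "none"),
                            s1_count = 6L, s1s1 = 300,
                            extra_intervals = numeric(),
                            burst_start = 300, burst_step = 10,
                            burst_min = 80,
                            stim_site = c(3L, 3L),
                            stim_amplitude = 2, stim_duration = 2,
                            steady_beats_before_acquisition = 30L) {
  kind <- match.arg(kind)
  if (s1s1 <= 0) stop("s1s1 must be positive")
  if (length(extra_intervals)) {
    if (any(extra_intervals <= 0)) stop("extra_intervals must be positive")
    if (any(diff(extra_intervals) > 0))
      stop("extra_intervals must be non-increasing")
  }
  if (burst_step <= 0) stop("burst_step must be positive")
  if (steady_beats_before_acquisition < 0)
    stop("steady_beats_before_acquisition must be >= 0")
  structure(list(kind = kind, s1_count = as.integer(s1_count), s1s1 = s1s1,
                 extra_intervals = extra_intervals, burst_start = burst_start,
                 burst_step = burst_step, burst_min = burst_min,
                 stim_site = as.integer(stim_site),
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration,
                 steady_beats_before_acquisition =
                   as.integer(steady_beats_before_acquisition)),
            class = "pacing_protocol")
}

#' APD / CV restitution map
#'
#' Phenomenological restitution formalism used by the fast cable surrogate:
#' `APD_{n+1} = apd_max - amplitude_a * exp(-DI_n / tau_restitution)`, with an
#' optional conduction-velocity restitution
#' `CV(DI) = cv0 * (1 - cv_b * exp(-DI / cv_tau))`. The map's slope at
#' diastolic interval DI is `(amplitude_a / tau_restitution) *
#' exp(-DI / tau_restitution)`; alternans onset is the slope-1 condition,
#' giving the analytic bifurcation cycle length
#' `apd_max - tau_restitution + tau_restitution * log(amplitude_a /
#' tau_restitution)`.
#'
#' Defaults reproduce the study conditions this generator emulates: APD near
#' 127 ms at long cycle lengths and a period-doubling onset near 132 ms, so
#' that decremental burst scanning with the >10 ms alternans rule detects a
#' threshold near 127 ms.
#'
#' @param apd_max asymptotic APD, ms.
#' @param amplitude_a restitution amplitude, ms (`0 < amplitude_a < apd_max`).
#' @param tau_restitution restitution time constant, ms.
#' @param cv_restitution `NULL`, or `list(cv0 =, cv_b =, cv_tau =)` with cv0
#'   in mm/ms.
#' @return an object of class `restitution_map`.
#' @export
restitution_map <- function(apd_max = 127, amplitude_a = 50,
                            tau_restitution = 12, cv_restitution = NULL) {
  if (!(apd_max > amplitude_a && amplitude_a > 0))
    stop("need apd_max > amplitude_a > 0")
  if (tau_restitution <= 0) stop("tau_restitution must be positive")
  if (!is.null(cv_restitution))
    stopifnot(all(c("cv0", "cv_b", "cv_tau") %in% names(cv_restitution)))
  structure(list(apd_max = apd_max, amplitude_a = amplitude_a,
                 tau_restitution = tau_restitution,
                 cv_restitution = cv_restitution),
            class = "restitution_map")
}

#' Next-beat APD predicted by a restitution map
#' @param map a [restitution_map()].
#' @param di diastolic interval(s), ms.
#' @return APD in ms (same length as `di`).
#' @export
restitution_apd <- function(map, di)
  map$apd_max - map$amplitude_a * exp(-di / map$tau_restitution)

#' Restitution slope at a diastolic interval
#' @inheritParams restitution_apd
#' @export
restitution_slope <- function(map, di)
  (map$amplitude_a / map$tau_restitution) * exp(-di / map$tau_restitution)

#' Analytic period-doubling cycle length of a restitution map
#'
#' Cycle length at which the map slope equals 1 at the fixed point; below
#' this PCL the 1:1 rhythm is unstable and APD alternans grow.
#'
#' @param map a [restitution_map()].
#' @return PCL in ms, or `NA` if the map has no slope-1 point at positive DI.
#' @export
restitution_bifurcation_pcl <- function(map) {
  if (map$amplitude_a <= map$tau_restitution) return(NA_real_)
  di_star <- map$tau_restitution * log(map$amplitude_a / map$tau_restitution)
  map$apd_max - map$tau_restitution + di_star
}
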