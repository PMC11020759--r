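#' Draw spontaneous focal ectopic beats
#'
#' Ectopic (premature ventricular) beat times are drawn from a homogeneous
#' Poisson process at `rate` events/min over `duration_min`, then thinned by
#' refractoriness: a candidate falling within `refractory_ms` of a paced beat
#' or of the previous delivered ectopic is suppressed. The origin must lie in
#' the peri-infarct border zone.
#'
#' @param geometry a [tissue_geometry()].
#' @param rate ectopy rate, events/min (>= 0).
#' @param origin `c(row, col)` inside `geometry$border_zone_mask`.
#' @param duration_min observation window, minutes.
#' @param paced_times paced stimulus times (ms) used for refractory
#'   suppression.
#' @param refractory_ms refractory window, ms.
#' @param seed RNG seed.
#' @param stim_amplitude,stim_duration stimulus shape of the focal source.
#' @return list with `times_ms` (delivered ectopic times), `stimuli` (a
#'   stimulus data.frame usable as `extra_stimuli` in [simulate_tissue()],
#'   label `"ectopic"`), and `candidates_ms` (pre-thinning draw).
#' @export
inject_ectopy <- function(geometry, rate, origin, duration_min = 20,
                          paced_times = numeric(), refractory_ms = 180,
                          seed = 1L, stim_amplitude = 2, stim_duration = 2) {
  stopifnot(inherits(geometry, "tissue_geometry"))
  if (rate < 0) stop("rate must be >= 0")
  if (geometry$scar_mask[origin[1], origin[2]])
    stop("ectopic origin lies inside the scar")
  if (!geometry$border_zone_mask[origin[1], origin[2]])
    stop("ectopic origin must lie inside the border zone")
  cand <- if (rate == 0) numeric() else with_seed(seed, {
    n <- rpois(1, rate * duration_min)
    sort(runif(n, 0, duration_min * 60000))
  })
  delivered <- numeric()
  last <- -Inf
  for (tc in cand) {
    near_paced <- length(paced_times) &&
      any(tc - paced_times >= 0 & tc - paced_times < refractory_ms)
    near_paced <- near_paced ||
      (length(paced_times) && any(abs(paced_times - tc) < stim_duration))
    if (!near_paced && tc - last >= refractory_ms) {
      delivered <- c(delivered, tc)
      last <- tc
    }
  }
  n <- length(delivered)
  stimuli <- data.frame(t_on = delivered, t_off = delivered + stim_duration,
                        row = rep(origin[1], n), col = rep(origin[2], n),
                        radius = rep(2.5, n),
                        amplitude = rep(stim_amplitude, n),
                        label = rep("ectopic", n), stringsAsFactors = FALSE)
  list(times_ms = delivered, stimuli = stimuli, candidates_ms = cand)
}

#' Synthesise a pseudo-ECG trace from beat times
#'
#' Places a biphasic wavelet at each beat time on a flat baseline with
#' optional Gaussian noise; used for long rhythm recordings where a full
#' tissue simulation would be wasteful (e.g. 20-minute ectopy burden
#' monitoring) and in rhythm-module tests.
#'
#' @param beat_times beat times, ms.
#' @param duration_ms trace length, ms.
#' @param dt sampling interval, ms.
#' @param amplitude wavelet amplitude.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed for the noise.
#' @return data.frame `time_ms`, `ecg`.
#' @export
synthesize_ecg <- function(beat_times, duration_ms, dt = 2, amplitude = 1,
                           noise_sd = 0, seed = 1L) {
  tt <- seq(0, duration_ms, by = dt)
  x <- numeric(length(tt))
  # biphasic wavelet: derivative-of-gaussian, ~40 ms support
  wt <- seq(-20, 20, by = dt)
  w <- -wt * exp(-wt^2 / (2 * 6^2))
  w <- amplitude * w / max(abs(w))
  for (b in beat_times) {
    i0 <- round((b - 20) / dt) + 1L
    ii <- seq_along(wt) + i0 - 1L
    ok <- ii >= 1L & ii <= length(x)
    x[ii[ok]] <- x[ii[ok]] + w[ok]
  }
  if (noise_sd > 0) x <- with_seed(seed, x + rnorm(length(x), 0, noise_sd))
  data.frame(time_ms = tt, ecg = x)
}
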