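#' Iterate a restitution-map cable
#'
#' Fast surrogate for paced tissue built from the APD restitution map
#' `APD_{n+1} = apd_max - amplitude_a * exp(-DI_n / tau_restitution)` with
#' `DI_n = interval - APD_n`. With `n_sites > 1` the stimulus is delivered at
#' site 1 and the wavefront propagates with conduction-velocity restitution,
#' which is the classical route to spatially discordant alternans. A beat
#' whose local diastolic interval would be negative is a loss of capture
#' (2:1 block) at that site; conduction does not continue past a blocked
#' site.
#'
#' @param map a [restitution_map()].
#' @param pcl pacing cycle length, ms (ignored when `stim_times` given).
#' @param n_beats number of stimuli (>= 2) when pacing at `pcl`.
#' @param n_sites number of cable sites.
#' @param stim_times explicit stimulus times (ms), e.g. an extrastimulus
#'   protocol; overrides `pcl`/`n_beats`.
#' @param dx_mm inter-site spacing, mm.
#' @param apd_gradient fractional increase of `apd_max` from site 1 to site
#'   `n_sites` (spatial heterogeneity, e.g. a peri-infarct gradient).
#' @param apd_profile optional per-site multipliers on `apd_max` (length
#'   `n_sites`), e.g. a border-zone step; overrides `apd_gradient`.
#' @param initial_apd APD state before the first stimulus; defaults to the
#'   fully-rested APD at DI = 400 ms.
#' @return data.frame with columns `site`, `beat`, `t_stim`, `t_act`, `di`,
#'   `apd`, `captured`. Blocked (non-captured) site-beats carry `NA`
#'   activation and APD. The generating map is attached as attribute `"map"`.
#' @export
run_restitution_cable <- function(map, pcl = NULL, n_beats = 10L,
                                  n_sites = 1L, stim_times = NULL,
                                  dx_mm = 0.25, apd_gradient = 0,
                                  apd_profile = NULL, initial_apd = NULL) {
  stopifnot(inherits(map, "restitution_map"))
  if (is.null(stim_times)) {
    if (is.null(pcl) || pcl <= 0) stop("pcl must be positive")
    if (n_beats < 2L) stop("n_beats must be >= 2")
    stim_times <- (seq_len(n_beats) - 1L) * pcl
  } else {
    if (any(diff(stim_times) <= 0)) stop("stim_times must be increasing")
    n_beats <- length(stim_times)
  }
  n_sites <- as.integer(n_sites)
  apd_max_site <- if (!is.null(apd_profile)) {
    stopifnot(length(apd_profile) == n_sites)
    map$apd_max * apd_profile
  } else map$apd_max * (1 + apd_gradient * (seq_len(n_sites) - 1L) /
                          max(1L, n_sites - 1L))
  cvr <- map$cv_restitution
  cv_of <- function(di) {
    if (is.null(cvr)) return(rep(Inf, length(di)))
    pmax(cvr$cv0 * (1 - cvr$cv_b * exp(-di / cvr$cv_tau)), 1e-3)
  }
  if (is.null(initial_apd)) initial_apd <- map$apd_max -
      map$amplitude_a * exp(-400 / map$tau_restitution)

  # state per site: time of last activation and that beat's APD. The
  # previous train is represented by one virtual beat ending initial_apd ms
  # after an activation one cycle before the first stimulus, so decremental
  # scans continue smoothly from the preceding cycle length.
  cl0 <- if (n_beats >= 2L) stim_times[2] - stim_times[1] else 400
  last_act <- rep(stim_times[1] - cl0, n_sites)
  last_apd <- rep(initial_apd, n_sites)

  out <- vector("list", n_beats)
  for (b in seq_len(n_beats)) {
    t_arr <- stim_times[b]
    t_act <- rep(NA_real_, n_sites)
    di <- rep(NA_real_, n_sites)
    apd <- rep(NA_real_, n_sites)
    cap <- rep(FALSE, n_sites)
    for (s in seq_len(n_sites)) {
      this_di <- t_arr - (last_act[s] + last_apd[s])
      if (this_di < 0) break  # local refractoriness: conduction stops here
      di[s] <- this_di
      apd[s] <- apd_max_site[s] - map$amplitude_a *
        exp(-this_di / map$tau_restitution)
      t_act[s] <- t_arr
      cap[s] <- TRUE
      last_act[s] <- t_arr
      last_apd[s] <- apd[s]
      if (s < n_sites) t_arr <- t_arr + dx_mm / cv_of(this_di)
    }
    out[[b]] <- data.frame(site = seq_len(n_sites), beat = b,
                           t_stim = stim_times[b], t_act = t_act, di = di,
                           apd = apd, captured = cap)
  }
  res <- do.call(rbind, out)
  attr(res, "map") <- map
  attr(res, "dx_mm") <- dx_mm
  res
}

#' Signed beat-to-beat APD differences on a cable result
#'
#' Mean over consecutive beat pairs of (first - second), per site, using only
#' captured beats; the generator-side truth against which the analysis-side
#' alternans map is checked.
#'
#' @param cable result of [run_restitution_cable()].
#' @param discard leading beats dropped before pairing.
#' @return data.frame `site`, `delta_apd`, `n_pairs`.
#' @export
cable_alternans_truth <- function(cable, discard = 4L) {
  res <- lapply(split(cable, cable$site), function(d) {
    d <- d[order(d$beat), ]
    a <- d$apd[d$captured]
    n11 <- match(FALSE, d$captured, nomatch = nrow(d) + 1L) - 1L
    a <- d$apd[seq_len(n11)]
    dd <- min(discard, max(0L, length(a) - 4L))
    a <- a[-seq_len(dd)][seq_len(2L * ((length(a) - dd) %/% 2L))]
    if (length(a) < 2L)
      return(data.frame(site = d$site[1], delta_apd = NA_real_, n_pairs = 0L))
    pr <- matrix(a, nrow = 2L)
    data.frame(site = d$site[1], delta_apd = mean(pr[1, ] - pr[2, ]),
               n_pairs = ncol(pr))
  })
  out <- do.call(rbind, res)
  out[order(out$site), ]
}

#' Render a cable result as a dual-channel optical movie
#'
#' Synthesises stylised action-potential waveforms (2 ms upstroke, plateau,
#' logistic repolarisation shaped so the 80%-repolarisation duration equals
#' the cable's APD) at each site, replicated over `n_rows` pixel rows, so the
#' image-analysis pipeline can be run against cable ground truth.
#'
#' @param cable result of [run_restitution_cable()].
#' @param n_rows number of pixel rows the cable is replicated over.
#' @param frame_interval frame interval, ms.
#' @param tail_ms padding after the last beat, ms.
#' @param noise_sd additive Gaussian noise SD (normalised units).
#' @param seed RNG seed for the noise.
#' @return list with elements `vm` (an upright [optical_movie()]) and
#'   `stim_times` (ms, relative to movie start).
#' @export
cable_to_movie <- function(cable, n_rows = 12L, frame_interval = 2,
                           tail_ms = 250, noise_sd = 0, seed = 1L) {
  n_sites <- max(cable$site)
  t_end <- max(cable$t_act, na.rm = TRUE) + tail_ms
  tt <- seq(0, t_end, by = frame_interval)
  nT <- length(tt)
  w <- 6  # logistic repolarisation width, ms
  tr <- matrix(0, n_sites, nT)
  for (s in seq_len(n_sites)) {
    d <- cable[cable$site == s & cable$captured, , drop = FALSE]
    for (b in seq_len(nrow(d))) {
      t0 <- d$t_act[b]; apd <- d$apd[b]
      # crossing of 0.2 at t0 + apd: logistic centre c solves 1/(1+e^((apd-c)/w)) = 0.2
      cc <- apd - w * log(4)
      up <- pmin(pmax((tt - t0) / 2, 0), 1)            # 2 ms linear upstroke
      rep_ <- 1 / (1 + exp(((tt - t0) - cc) / w))
      tr[s, ] <- pmax(tr[s, ], up * rep_)
    }
  }
  arr <- array(NA_real_, dim = c(n_rows, n_sites, nT))
  for (r in seq_len(n_rows)) arr[r, , ] <- tr
  if (noise_sd > 0)
    arr <- with_seed(seed, arr + array(rnorm(length(arr), 0, noise_sd),
                                       dim = dim(arr)))
  mv <- optical_movie(arr, frame_interval, attr(cable, "dx_mm") %||% 0.25,
                      channel = "vm", polarity = "upright",
                      metadata = list(source = "restitution_cable"))
  list(vm = mv, stim_times = sort(unique(cable$t_stim)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
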