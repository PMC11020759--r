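#' Study configuration
#'
#' All generator and analysis settings for a two-condition (baseline vs
#' drug) optical-mapping study, with defaults emulating the emulated study's
#' conditions: 14 hearts, 2 ms frames, infarct scar with a peri-infarct
#' border zone, burst pacing at a cycle length of 300 ms for APD/CaTD/tau,
#' S1-S2 scanning for ERP, decremental burst scanning for the alternans
#' threshold, an extrastimulus induction protocol, and 20-minute ectopy
#' monitoring. Every analysis threshold is echoed into the report.
#'
#' @param n_hearts number of hearts.
#' @param seed master seed; per-heart seeds are derived deterministically.
#' @param grid tissue grid side (pixels).
#' @param noise_snr movie SNR, dB.
#' @param apd300_mean,apd300_sd between-heart APD80 at PCL 300 (ms).
#' @param tau_ca_mean,tau_ca_sd between-heart calcium decay constant (ms).
#' @param drug_apd_factor,drug_ca_factor parametric drug effect.
#' @param pcl burst pacing cycle length for the feature recording (ms).
#' @param n_record_beats recorded beats at `pcl`.
#' @param steady_beats conditioning beats before acquisition.
#' @param erp_scan list(start, step, min) for the S1-S2 scan (ms).
#' @param cable_baseline,cable_drug restitution-map shape (amplitude_a,
#'   tau_restitution) per condition; `apd_max` tracks each heart's measured
#'   APD80 plus `cable_apd_offset`.
#' @param cable_apd_offset ms.
#' @param threshold_scan list(start, step, min) for the alternans-threshold
#'   scan (ms).
#' @param circuit_ratio_mean,circuit_ratio_sd reentrant-circuit cycle length
#'   as a fraction of the heart's baseline ERP (anatomical variability).
#' @param ectopy_burden_mean,ectopy_burden_sd between-heart spontaneous PVB
#'   burden, events/min; `ectopy_drug_ratio` scales it under drug.
#' @param ectopy_window_min monitoring window, minutes.
#' @param sinus_cl_ms spontaneous cycle length during monitoring.
#' @param ectopy_refractory_ms refractory suppression window.
#' @param site_step analysis-site subsampling step (pixels).
#' @param snr_threshold quality-mask threshold, dB.
#' @param min_sites minimum analyzable sites.
#' @param spatial_kernel_px,temporal_window_frames preprocessing settings
#'   (voltage channel).
#' @param ca_temporal_window_frames temporal smoothing for the calcium
#'   channel, whose upstroke is slow enough to tolerate (and need) a wider
#'   window under noise.
#' @param n_tau_sites sites used for the calcium-decay fit.
#' @param border_apd_factor border-zone APD heterogeneity.
#' @param dt_internal integration step, ms.
#' @return a `study_config` list.
#' @export
study_config <- function(n_hearts = 14L, seed = 1L, grid = 50L,
                         noise_snr = 20,
                         apd300_mean = 123.1, apd300_sd = 7,
                         tau_ca_mean = 50.3, tau_ca_sd = 4.5,
                         drug_apd_factor = 1.09, drug_ca_factor = 0.95,
                         pcl = 300, n_record_beats = 8L, steady_beats = 6L,
                         erp_scan = list(start = 200, step = 2, min = 60),
                         cable_baseline = list(amplitude_a = 50,
                                               tau_restitution = 12),
                         cable_drug = list(amplitude_a = 45,
                                           tau_restitution = 26),
                         cable_apd_offset = 4,
                         threshold_scan = list(start = 300, step = 10,
                                               min = 80),
                         circuit_ratio_mean = 0.97,
                         circuit_ratio_sd = 0.035,
                         ectopy_burden_mean = 0.55, ectopy_burden_sd = 0.55,
                         ectopy_drug_ratio = 0.12 / 0.55,
                         ectopy_window_min = 20, sinus_cl_ms = 400,
                         ectopy_refractory_ms = 100,
                         site_step = 5L, snr_threshold = 6, min_sites = 25L,
                         spatial_kernel_px = 3L, temporal_window_frames = 3L,
                         ca_temporal_window_frames = 9L,
                         n_tau_sites = 12L, border_apd_factor = 1.1,
                         dt_internal = 0.1) {
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

# deterministic per-heart sub-seed (kept below 2^31)
heart_seed <- function(seed, heart, k = 0L)
  (as.integer(seed) * 97L + heart * 131L + k * 7919L) %% 2000000000L

# calibration of the membrane model: tau_close from target APD80 at PCL 300
# (measured on the default parameter set: APD80 = 123.3 ms at tau_close = 60,
# local slope 1.75 ms per ms of tau_close)
tau_close_for_apd <- function(apd_target) 60 + (apd_target - 123.3) / 1.75

#' Run one heart's examination under one condition
#'
#' Simulates the burst recording, runs the full analysis pipeline (signal
#' conditioning, quality mask, feature extraction, aggregation, calcium-decay
#' fit), measures the ERP by S1-S2 scanning, scans the alternans threshold on
#' the heart's restitution cable, and evaluates induction by extrastimulus
#' vulnerability plus the reentry-sustainability rule (circuit cycle length
#' within the alternans-unstable regime).
#'
#' @param cfg a [study_config()].
#' @param heart heart index.
#' @param condition `"baseline"` or `"drug"`.
#' @param heart_traits output of `draw_heart_traits()`; drawn if omitted.
#' @return list of per-condition metrics.
#' @export
run_heart_exam <- function(cfg, heart, condition = c("baseline", "drug"),
                           heart_traits = NULL) {
  condition <- match.arg(condition)
  if (is.null(heart_traits)) heart_traits <- draw_heart_traits(cfg, heart)
  tr <- heart_traits

  params <- cell_model_params(
    tau_close = tau_close_for_apd(tr$apd300),
    tau_ca_decay = tr$tau_ca,
    drug_apd_factor = cfg$drug_apd_factor,
    drug_ca_factor = cfg$drug_ca_factor)
  if (condition == "drug") params <- apply_drug(params)

  g <- cfg$grid
  geometry <- tissue_geometry(g, g, scar_mask = disc_scar(g, g))
  stim_site <- c(round(g / 2), 3L)
  protocol <- pacing_protocol(kind = "burst", s1_count = cfg$n_record_beats,
                              s1s1 = cfg$pcl, stim_site = stim_site,
                              steady_beats_before_acquisition =
                                cfg$steady_beats)

  sim <- simulate_tissue(geometry, params, protocol,
                         noise_snr = cfg$noise_snr,
                         seed = heart_seed(cfg$seed, heart,
                                           if (condition == "drug") 1L else 0L),
                         dt_internal = cfg$dt_internal,
                         border_apd_factor = cfg$border_apd_factor)

  # quality mask on the unsmoothed normalized movie (smoothing inflates the
  # apparent SNR of scar pixels and bleeds signal across the infarct border)
  mask <- build_quality_mask(preprocess(sim$vm), cfg$snr_threshold,
                             cfg$min_sites)
  vm <- preprocess(sim$vm, cfg$spatial_kernel_px, cfg$temporal_window_frames)
  cai <- preprocess(sim$cai, cfg$spatial_kernel_px,
                    cfg$ca_temporal_window_frames)
  # decay fits use a lightly smoothed copy: a wide moving average flattens
  # the transient peak and biases the fitted decay constant upward
  cai_tau <- preprocess(sim$cai, cfg$spatial_kernel_px, 3L)

  sub <- matrix(FALSE, g, g)
  sel <- seq(3L, g - 2L, by = cfg$site_step)
  sub[sel, sel] <- TRUE
  sites <- which(mask$valid & sub, arr.ind = TRUE)
  stim_rel <- sim$vm$metadata$stim_times_ms

  f_vm <- extract_features(vm, sites = sites, stim_times = stim_rel)
  f_ca <- extract_features(cai, sites = sites, stim_times = stim_rel,
                           anchor = "stimulus")
  apd <- aggregate_sites(f_vm, min_sites = cfg$min_sites)
  catd <- aggregate_sites(f_ca, min_sites = cfg$min_sites)

  # calcium decay tau at the termination of the burst (final beat)
  tau_sites <- sites[seq_len(min(cfg$n_tau_sites, nrow(sites))), ,
                     drop = FALSE]
  taus <- vapply(seq_len(nrow(tau_sites)), function(k) {
    fs <- f_ca[f_ca$row == tau_sites[k, 1] & f_ca$col == tau_sites[k, 2] &
                 f_ca$valid, , drop = FALSE]
    if (!nrow(fs)) return(NA_real_)
    ft <- fit_ca_decay(pixel_trace(cai_tau, tau_sites[k, 1],
                                   tau_sites[k, 2]),
                       cai_tau$frame_interval,
                       activation_time = max(fs$t_act))
    if (ft$valid) ft$tau else NA_real_
  }, numeric(1))
  tau_mean <- mean(taus, na.rm = TRUE)

  erp <- measure_true_erp(geometry, params, s1s1 = cfg$pcl,
                          s2_scan = cfg$erp_scan, stim_site = stim_site,
                          dt = cfg$dt_internal,
                          border_apd_factor = cfg$border_apd_factor)$erp_ms

  shape <- if (condition == "drug") cfg$cable_drug else cfg$cable_baseline
  map <- restitution_map(apd_max = apd$mean + cfg$cable_apd_offset,
                         amplitude_a = shape$amplitude_a,
                         tau_restitution = shape$tau_restitution)
  thr <- find_alternans_threshold(cable_provider(map),
                                  pcl_start = cfg$threshold_scan$start,
                                  pcl_step = cfg$threshold_scan$step,
                                  pcl_min = cfg$threshold_scan$min)

  vul <- extrastimulus_vulnerability(map, s1s1 = cfg$pcl)
  episodes <- induction_episodes(cfg, heart, condition, map, erp, tr, vul)

  # spontaneous ectopy monitoring
  burden <- monitor_ectopy(cfg, heart, condition, geometry, tr)

  list(condition = condition, apd80 = apd$mean, apd80_sd = apd$sd,
       catd80 = catd$mean, tau_ca = tau_mean, erp = erp,
       alternans_threshold = thr$threshold_pcl,
       threshold_status = thr$status, vulnerable = vul$vulnerable,
       episodes = episodes,
       induced = any(vapply(episodes, function(e)
         e$kind %in% c("vt", "vf"), logical(1))),
       pvb_burden = burden$burden_per_min,
       n_valid_sites = nrow(sites))
}

draw_heart_traits <- function(cfg, heart) {
  with_seed(heart_seed(cfg$seed, heart, 5L), {
    list(apd300 = rnorm(1, cfg$apd300_mean, cfg$apd300_sd),
         tau_ca = max(20, rnorm(1, cfg$tau_ca_mean, cfg$tau_ca_sd)),
         circuit_ratio = rnorm(1, cfg$circuit_ratio_mean,
                               cfg$circuit_ratio_sd),
         ectopy_burden = rgamma_mean_sd(1, cfg$ectopy_burden_mean,
                                        cfg$ectopy_burden_sd))
  })
}

rgamma_mean_sd <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# stateful decremental-burst provider over a restitution cable: the cable
# continues from the previous PCL's end state, as in a real decremental
# protocol; leading beats are discarded adaptively so that at least two
# beat pairs remain before any capture loss
cable_provider <- function(map, n_beats = 24L, discard = 4L) {
  state <- new.env(parent = emptyenv())
  state$apd <- NULL
  function(pcl) {
    cab <- run_restitution_cable(map, pcl = pcl, n_beats = n_beats,
                                 initial_apd = state$apd)
    ok <- cab$captured
    n11 <- match(FALSE, ok, nomatch = nrow(cab) + 1L) - 1L
    state$apd <- if (n11 > 0) cab$apd[n11] else state$apd
    d <- min(discard, max(0L, n11 - 4L))
    keep <- cab[seq_len(n11), , drop = FALSE]
    keep <- keep[keep$beat > d, , drop = FALSE]
    feats <- cable_features(keep)
    feats$beat <- feats$beat - d
    attr(feats, "capture_lost") <- n11 < nrow(cab)
    feats
  }
}

# extrastimulus scan on a spatially heterogeneous cable with conduction-
# velocity restitution: vulnerable when some premature beat captures
# proximally but blocks at the border-zone step (unidirectional functional
# block), before the proximal ERP ends the scan
extrastimulus_vulnerability <- function(map, s1s1 = 300, s2_seq = NULL,
                                        n_sites = 40L, border_step = 1.22,
                                        border_from = 25L,
                                        cv = list(cv0 = 0.33, cv_b = 0.6,
                                                  cv_tau = 15)) {
  if (is.null(s2_seq)) s2_seq <- seq(200, 90, by = -10)
  m2 <- restitution_map(map$apd_max, map$amplitude_a, map$tau_restitution,
                        cv_restitution = cv)
  profile <- c(rep(1, border_from - 1L),
               rep(border_step, n_sites - border_from + 1L))
  s1 <- (0:5) * s1s1
  for (s2 in s2_seq) {
    cab <- run_restitution_cable(m2, stim_times = c(s1, max(s1) + s2),
                                 n_sites = n_sites,
                                 apd_profile = profile)
    last <- cab[cab$beat == max(cab$beat), ]
    if (!last$captured[1]) # proximal refractory: ERP reached, scan over
      return(list(vulnerable = FALSE, s2 = NA_real_))
    if (any(!last$captured))
      return(list(vulnerable = TRUE, s2 = s2,
                  block_site = min(last$site[!last$captured])))
  }
  list(vulnerable = FALSE, s2 = NA_real_)
}

# reentry-sustainability rule: an induced circuit persists when its cycle
# length sits inside the alternans-unstable regime (at or below the map's
# period-doubling PCL), which maintains the functional block anchoring it;
# the circuit cycle length scales with the heart's baseline refractoriness
induction_episodes <- function(cfg, heart, condition, map, erp, traits,
                               vul) {
  bif <- restitution_bifurcation_pcl(map)
  circuit_cl <- traits$circuit_ratio * (traits$apd300 + 11)
  induced <- isTRUE(vul$vulnerable) && is.finite(bif) && circuit_cl <= bif
  if (!induced) return(list())
  with_seed(heart_seed(cfg$seed, heart,
                       if (condition == "drug") 11L else 10L), {
    breakup <- circuit_cl <= bif - 15   # deep in the unstable regime
    n <- 20L + stats::rpois(1, 40)
    jit <- if (breakup) 0.25 else 0.03
    cycles <- pmax(40, rnorm(n, circuit_cl, jit * circuit_cl))
    beats <- cumsum(c(0, cycles))
    list(classify_episode(beats, baseline_cl = cfg$pcl))
  })
}

# spontaneous ectopy monitoring on a synthesized pseudo-ECG; the candidate
# rate compensates analytically for refractory thinning by the sinus rhythm
monitor_ectopy <- function(cfg, heart, condition, geometry, traits) {
  target <- traits$ectopy_burden *
    (if (condition == "drug") cfg$ectopy_drug_ratio else 1)
  # candidate rate compensated for the two loss mechanisms: refractory
  # thinning after each sinus beat, and late-diastolic events that are not
  # premature under the 85%-of-cycle coupling rule
  avail <- (0.85 * cfg$sinus_cl_ms - cfg$ectopy_refractory_ms) /
    cfg$sinus_cl_ms
  origin <- border_zone_site(geometry)
  sinus <- seq(0, cfg$ectopy_window_min * 60000, by = cfg$sinus_cl_ms)
  ect <- inject_ectopy(geometry, rate = target / avail, origin = origin,
                       duration_min = cfg$ectopy_window_min,
                       paced_times = sinus,
                       refractory_ms = cfg$ectopy_refractory_ms,
                       seed = heart_seed(cfg$seed, heart,
                                         if (condition == "drug") 21L
                                         else 20L))
  all_beats <- sort(c(sinus, ect$times_ms))
  ecg <- synthesize_ecg(all_beats, cfg$ectopy_window_min * 60000,
                        noise_sd = 0.05,
                        seed = heart_seed(cfg$seed, heart, 22L))
  beats <- detect_ecg_beats(ecg$ecg, dt = 2)
  compute_pvb_burden(beats, window_min = cfg$ectopy_window_min)
}

border_zone_site <- function(geometry) {
  bz <- which(geometry$border_zone_mask, arr.ind = TRUE)
  if (!nrow(bz)) stop("geometry has no border zone")
  bz[nrow(bz), ]
}

#' Run the full two-condition study
#'
#' For each heart: baseline and drug examinations (see [run_heart_exam()]),
#' then the cross-condition statistical report comparing ERP, APD80, CaTD80,
#' calcium-decay tau, alternans threshold, PVB burden (paired t-tests) and
#' VT/VF inducibility (Fisher's exact test). Fully reproducible from the
#' configuration and seed.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional directory for report files (JSON, text, CSV).
#' @param quiet suppress progress messages.
#' @return a [summarize_study()] report (invisibly written to `out_dir` when
#'   given).
#' @export
run_study <- function(cfg = study_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  rows <- vector("list", cfg$n_hearts)
  for (h in seq_len(cfg$n_hearts)) {
    traits <- draw_heart_traits(cfg, h)
    ex <- lapply(c("baseline", "drug"), function(cond)
      run_heart_exam(cfg, h, cond, heart_traits = traits))
    names(ex) <- c("baseline", "drug")
    if (!quiet)
      message(sprintf(
        "heart %02d: APD %0.1f->%0.1f ERP %g->%g tau %0.1f->%0.1f thr %s->%s induced %d->%d",
        h, ex$baseline$apd80, ex$drug$apd80, ex$baseline$erp, ex$drug$erp,
        ex$baseline$tau_ca, ex$drug$tau_ca,
        format(ex$baseline$alternans_threshold),
        format(ex$drug$alternans_threshold),
        ex$baseline$induced, ex$drug$induced))
    rows[[h]] <- data.frame(
      heart_id = h,
      erp_baseline = ex$baseline$erp, erp_drug = ex$drug$erp,
      apd80_baseline = ex$baseline$apd80, apd80_drug = ex$drug$apd80,
      catd80_baseline = ex$baseline$catd80, catd80_drug = ex$drug$catd80,
      tau_ca_baseline = ex$baseline$tau_ca, tau_ca_drug = ex$drug$tau_ca,
      alt_threshold_baseline = ex$baseline$alternans_threshold,
      alt_threshold_drug = ex$drug$alternans_threshold,
      pvb_baseline = ex$baseline$pvb_burden,
      pvb_drug = ex$drug$pvb_burden,
      induced_baseline = ex$baseline$induced,
      induced_drug = ex$drug$induced)
  }
  per_heart <- do.call(rbind, rows)
  metrics <- c(erp = "VERP (ms)", apd80 = "APD80 at PCL 300 (ms)",
               catd80 = "CaTD80 at PCL 300 (ms)",
               tau_ca = "Ca decay tau (ms)",
               alt_threshold = "Alternans threshold PCL (ms)",
               pvb = "PVB burden (beats/min)")
  report <- summarize_study(per_heart, metrics,
                            settings = unclass(cfg))
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Generate the small bundled fixture set used by the test suite
#'
#' Writes miniature, fully synthetic datasets: a paced 16 x 16 movie pair
#' with scar (TIFF + bundle), a discordant-alternans cable rendered as a
#' movie, a spiral-wave phase movie, and a pseudo-ECG trace with ectopy.
#' Identical seeds give identical files; a manifest with MD5 checksums is
#' returned and written alongside.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @return data.frame `file`, `md5` (also saved as `manifest.csv`).
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- tissue_geometry(16, 16, scar_mask = disc_scar(16, 16, c(5, 5), 3),
                       border_zone_px = 2L)
  p <- cell_model_params()
  proto <- pacing_protocol(kind = "burst", s1_count = 4L, s1s1 = 300,
                           stim_site = c(8L, 14L),
                           steady_beats_before_acquisition = 2L)
  sim <- simulate_tissue(g, p, proto, noise_snr = 20, seed = seed)
  write_movie(sim$vm, file.path(dir, "vm_16px.tiff"))
  write_movie(sim$cai, file.path(dir, "cai_16px.tiff"))
  write_bundle(list(vm = sim$vm, cai = sim$cai,
                    pseudo_ecg = sim$pseudo_ecg,
                    stimulus_log = sim$stimulus_log),
               file.path(dir, "sim_bundle"))

  map <- restitution_map(cv_restitution = list(cv0 = 0.33, cv_b = 0.6,
                                               cv_tau = 15))
  cab <- run_restitution_cable(map, pcl = 130, n_beats = 20, n_sites = 32)
  cmv <- cable_to_movie(cab, n_rows = 8, noise_sd = 0.02, seed = seed)
  write_movie(cmv$vm, file.path(dir, "discordant_cable.tiff"))

  spiral <- spiral_phase_movie(24, 24, frames = 10)
  write_bundle(list(phase = spiral$phase), file.path(dir, "spiral_phase"))

  ecg <- synthesize_ecg(c(seq(0, 5000, by = 400), 2180), 6000,
                        noise_sd = 0.05, seed = seed)
  write.csv(ecg, file.path(dir, "ecg_with_pvb.csv"), row.names = FALSE)

  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.csv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Analytic spiral phase field (for detector tests and fixtures)
#'
#' `phase(x, y, t) = atan2(y - y0, x - x0) - omega * t`, wrapped to
#' (-pi, pi]: a rotating spiral with a single phase singularity at
#' (`y0`, `x0`) and chirality +1 (or -1 when mirrored).
#'
#' @param H,W field size.
#' @param center `c(row, col)`; default centre of the field.
#' @param frames number of frames.
#' @param omega rotation, rad/frame.
#' @param mirror flip chirality.
#' @param frame_interval ms.
#' @return a `phase_movie` object.
#' @export
spiral_phase_movie <- function(H, W, center = NULL, frames = 8L,
                               omega = 0.4, mirror = FALSE,
                               frame_interval = 2) {
  if (is.null(center)) center <- c((H + 1) / 2, (W + 1) / 2)
  ii <- matrix(seq_len(H), H, W)
  jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  base <- atan2(ii - center[1], jj - center[2])
  if (mirror) base <- -base
  ph <- array(NA_real_, dim = c(H, W, frames))
  for (t in seq_len(frames))
    ph[, , t] <- wrap_angle(base - omega * (t - 1))
  structure(list(phase = ph, method = "analytic",
                 frame_interval = frame_interval,
                 dominant_period_ms = 2 * pi / omega * frame_interval),
            class = "phase_movie")
}
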