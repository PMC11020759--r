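#' Beat detection on a pseudo-ECG
#'
#' Detrends with a running median, rectifies, smooths, and picks peaks above
#' an adaptive threshold with a refractory guard. Beats within
#' `paced_latency_ms` after a stimulus are labelled paced.
#'
#' @param ecg numeric trace (or data.frame with column `ecg`).
#' @param dt sampling interval, ms.
#' @param stim_times stimulus times, ms (same clock).
#' @param refractory_ms minimum beat separation.
#' @param paced_latency_ms stimulus-to-beat window for the paced label.
#' @param threshold_k detection threshold in robust SDs of the conditioned
#'   signal.
#' @param baseline_win_ms running-median detrend window.
#' @return data.frame `time_ms`, `paced`.
#' @export
detect_ecg_beats <- function(ecg, dt = 2, stim_times = NULL,
                             refractory_ms = 60, paced_latency_ms = 40,
                             threshold_k = 8, baseline_win_ms = 400) {
  if (is.data.frame(ecg)) ecg <- ecg$ecg
  n <- length(ecg)
  empty <- data.frame(time_ms = numeric(), paced = logical())
  if (n < 5) return(empty)
  k <- max(3L, round(baseline_win_ms / dt))
  if (k %% 2L == 0L) k <- k + 1L
  base <- stats::runmed(ecg, k)
  x <- abs(ecg - base)
  # the envelope window spans a whole deflection so biphasic complexes
  # merge into one peak centred on the beat
  x <- moving_average(x, max(5L, round(20 / dt) * 2L + 1L))
  # threshold above the running envelope's own level: the rectified
  # envelope has a positive floor, so the cutoff is median + k robust SDs
  s <- mad(x)
  thr <- median(x) + threshold_k * s
  if (!is.finite(thr) || s <= 0) return(empty)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  if (!length(cand)) return(empty)
  gap <- max(1L, round(refractory_ms / dt))
  keep <- integer()
  for (i in order(-x[cand])) {
    ci <- cand[i]
    if (!length(keep) || all(abs(keep - ci) >= gap)) keep <- c(keep, ci)
  }
  keep <- sort(keep)
  times <- (keep - 1) * dt
  paced <- rep(FALSE, length(times))
  if (!is.null(stim_times) && length(stim_times)) {
    for (i in seq_along(times)) {
      dd <- times[i] - stim_times
      paced[i] <- any(dd >= -dt & dd <= paced_latency_ms)
    }
  }
  data.frame(time_ms = times, paced = paced)
}

#' Premature-ventricular-beat burden
#'
#' A non-paced beat is a PVB when its coupling interval is shorter than
#' `prematurity_frac` of the running median cycle length. Burden is PVB
#' count divided by the observation window.
#'
#' @param beats data.frame from [detect_ecg_beats()] (`time_ms`, `paced`).
#' @param window_min observation window, minutes.
#' @param prematurity_frac default 0.85.
#' @param median_beats running-median span (beats).
#' @return list `burden_per_min`, `n_pvb`, `pvb_times`.
#' @export
compute_pvb_burden <- function(beats, window_min, prematurity_frac = 0.85,
                               median_beats = 7L) {
  if (window_min <= 0) stop("window_min must be positive")
  tt <- beats$time_ms
  if (length(tt) < 2)
    return(list(burden_per_min = 0, n_pvb = 0L, pvb_times = numeric()))
  cyc <- diff(tt)
  is_pvb <- logical(length(tt))
  for (i in seq_along(cyc)) {
    lo <- max(1L, i - median_beats + 1L)
    ref <- median(cyc[lo:i])
    # the beat after an ectopic is not itself premature: its short coupling
    # interval is an artifact of the ectopic's timing
    is_pvb[i + 1L] <- !beats$paced[i + 1L] && !is_pvb[i] &&
      cyc[i] < prematurity_frac * ref
  }
  list(burden_per_min = sum(is_pvb) / window_min, n_pvb = sum(is_pvb),
       pvb_times = tt[is_pvb])
}

#' Classify a post-pacing rhythm episode
#'
#' Ventricular tachycardia: three or more consecutive rapid organized
#' non-paced beats; fibrillation: rapid but disorganized. "Rapid" means the
#' coupling interval is below `rapid_frac` of the baseline cycle length;
#' "organized" means the sliding `cv_window`-beat coefficient of variation
#' of cycle lengths stays at or below `cv_threshold` (median across
#' windows). Episodes lasting 30 s or more are flagged sustained.
#'
#' @param beat_times non-paced beat times after the last stimulus, ms.
#' @param baseline_cl pre-protocol baseline cycle length, ms.
#' @param rapid_frac default 0.8.
#' @param cv_threshold default 0.15.
#' @param cv_window sliding window, beats.
#' @param sustained_ms sustained-episode duration, ms.
#' @return an object of class `episode_label`: list `kind` (`"none"`,
#'   `"vt"`, `"vf"`), `start`, `end`, `beat_times`, `organized`,
#'   `sustained`, `n_beats`, `mean_cycle_ms`.
#' @export
classify_episode <- function(beat_times, baseline_cl, rapid_frac = 0.8,
                             cv_threshold = 0.15, cv_window = 5L,
                             sustained_ms = 30000) {
  beat_times <- sort(beat_times)
  none <- structure(list(kind = "none", start = NA_real_, end = NA_real_,
                         beat_times = beat_times, organized = NA,
                         sustained = FALSE, n_beats = 0L,
                         mean_cycle_ms = NA_real_),
                    class = "episode_label")
  if (length(beat_times) < 3) return(none)
  cyc <- diff(beat_times)
  rapid <- cyc < rapid_frac * baseline_cl
  # longest run of consecutive rapid cycles; three or more rapid beats
  # means three or more rapid coupling intervals
  r <- rle(rapid)
  if (!any(r$values & r$lengths >= 3)) return(none)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 3)
  bi <- which.max(r$lengths[runs])
  i0 <- starts[runs[bi]]; i1 <- ends[runs[bi]]
  ep_beats <- beat_times[i0:(i1 + 1L)]
  ep_cyc <- cyc[i0:i1]
  if (length(ep_cyc) >= cv_window) {
    cvs <- vapply(seq_len(length(ep_cyc) - cv_window + 1L), function(s) {
      w <- ep_cyc[s:(s + cv_window - 1L)]
      sd(w) / mean(w)
    }, numeric(1))
    organized <- median(cvs) <= cv_threshold
  } else organized <- (sd(ep_cyc) / mean(ep_cyc)) <= cv_threshold
  dur <- ep_beats[length(ep_beats)] - ep_beats[1]
  structure(list(kind = if (organized) "vt" else "vf",
                 start = ep_beats[1], end = ep_beats[length(ep_beats)],
                 beat_times = ep_beats, organized = organized,
                 sustained = dur >= sustained_ms,
                 n_beats = length(ep_beats),
                 mean_cycle_ms = mean(ep_cyc)),
            class = "episode_label")
}

#' @export
print.episode_label <- function(x, ...) {
  if (x$kind == "none") cat("<episode_label> no episode\n")
  else cat(sprintf("<episode_label> %s: %d beats, mean cycle %.0f ms%s\n",
                   toupper(x$kind), x$n_beats, x$mean_cycle_ms,
                   if (x$sustained) ", sustained" else ""))
  invisible(x)
}

#' Per-heart, per-condition inducibility table
#'
#' A heart/condition is induced when any of its induction-protocol episodes
#' is VT or VF. Hearts missing a condition are excluded with a message.
#'
#' @param recordings data.frame with columns `heart_id`, `condition`, and a
#'   list-column `episodes` (lists of [classify_episode()] results), or a
#'   list of such rows.
#' @param conditions the conditions every heart must have.
#' @return data.frame `heart_id`, `condition`, `induced`, `n_episodes`.
#' @export
assess_inducibility <- function(recordings,
                                conditions = c("baseline", "drug")) {
  if (!is.data.frame(recordings)) recordings <- do.call(rbind, lapply(
    recordings, function(r) data.frame(heart_id = r$heart_id,
                                       condition = r$condition,
                                       episodes = I(list(r$episodes)))))
  rows <- lapply(seq_len(nrow(recordings)), function(i) {
    eps <- recordings$episodes[[i]]
    kinds <- vapply(eps, function(e) e$kind, "")
    data.frame(heart_id = recordings$heart_id[i],
               condition = recordings$condition[i],
               induced = any(kinds %in% c("vt", "vf")),
               n_episodes = sum(kinds %in% c("vt", "vf")))
  })
  out <- do.call(rbind, rows)
  complete <- vapply(split(out$condition, out$heart_id),
                     function(x) all(conditions %in% x), logical(1))
  bad <- names(complete)[!complete]
  if (length(bad)) {
    message("excluding hearts with missing conditions: ",
            paste(bad, collapse = ", "))
    out <- out[!(out$heart_id %in% bad), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
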