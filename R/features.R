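#' Detect activation times on a normalized trace
#'
#' Activation is the time of maximal upstroke velocity (max dF/dt) within
#' each beat, refined to sub-frame precision by parabolic interpolation of
#' the derivative peak. Candidate upstrokes are local derivative maxima above
#' `dvdt_frac` of the global maximum, separated by at least
#' `min_interval_ms`. A flat trace yields an empty result, not an error.
#'
#' An alternative 50%-amplitude-crossing detector is available via
#' `method = "midpoint"`.
#'
#' @param trace numeric vector, normalized and depolarisation-positive.
#' @param frame_interval ms per sample.
#' @param stim_times optional stimulus times (ms, same clock as the trace);
#'   each activation is assigned to the nearest preceding stimulus (index
#'   into `stim_times`) or `NA` if none precedes it within
#'   `max_latency_ms`.
#' @param min_interval_ms minimum beat separation.
#' @param dvdt_frac candidate threshold as a fraction of max dF/dt.
#' @param min_range minimum trace dynamic range to attempt detection.
#' @param method `"max_dvdt"` (default) or `"midpoint"`.
#' @param max_latency_ms stimulus-assignment window; generous by default
#'   because distal sites activate after a propagation delay.
#' @return data.frame `time_ms`, `stim_index` (NA = non-paced).
#' @export
detect_activations <- function(trace, frame_interval = 2, stim_times = NULL,
                               min_interval_ms = 60, dvdt_frac = 0.35,
                               min_range = 0.2,
                               method = c("max_dvdt", "midpoint"),
                               max_latency_ms = 150) {
  method <- match.arg(method)
  n <- length(trace)
  empty <- data.frame(time_ms = numeric(), stim_index = integer())
  if (n < 3 || diff(range(trace)) < min_range) return(empty)
  # centred differences: a one-sided derivative biases activation times by
  # half a frame
  dv <- c(0, (trace[3:n] - trace[1:(n - 2)]) / (2 * frame_interval), 0)
  thr <- max(dv) * dvdt_frac
  if (max(dv) <= 0) return(empty)
  min_gap <- max(1L, round(min_interval_ms / frame_interval))
  # local maxima of the derivative above threshold
  cand <- which(dv > thr)
  cand <- cand[cand > 1 & cand < n - 1]
  cand <- cand[dv[cand] >= dv[pmax(cand - 1, 1)] &
                 dv[cand] >= dv[pmin(cand + 1, n)]]
  if (!length(cand)) return(empty)
  # enforce minimum separation keeping the larger derivative
  keep <- integer()
  for (i in order(-dv[cand])) {
    ci <- cand[i]
    if (!length(keep) || all(abs(keep - ci) >= min_gap)) keep <- c(keep, ci)
  }
  keep <- sort(keep)
  times <- vapply(keep, function(i) {
    if (method == "midpoint") {
      # 50% crossing between local baseline and following peak
      i0 <- max(1L, i - min_gap %/% 2L)
      i1 <- min(n, i + min_gap %/% 2L)
      base <- min(trace[i0:i]); peak <- max(trace[i:i1])
      lev <- (base + peak) / 2
      seg <- i0:(i1 - 1L)
      hit <- seg[trace[seg] < lev & trace[seg + 1L] >= lev]
      if (!length(hit)) return((i - 1) * frame_interval)
      j <- hit[which.min(abs(hit - i))]
      ((j - 1) + (lev - trace[j]) / (trace[j + 1L] - trace[j])) *
        frame_interval
    } else {
      # parabolic sub-sample refinement of the derivative peak
      y0 <- dv[i - 1L]; y1 <- dv[i]; y2 <- dv[i + 1L]
      den <- y0 - 2 * y1 + y2
      off <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
      off <- max(min(off, 0.5), -0.5)
      ((i - 1) + off) * frame_interval
    }
  }, numeric(1))
  stim_index <- rep(NA_integer_, length(times))
  if (!is.null(stim_times) && length(stim_times)) {
    for (k in seq_along(times)) {
      prec <- which(stim_times <= times[k] + frame_interval / 2)
      if (length(prec)) {
        j <- max(prec)
        if (times[k] - stim_times[j] <= max_latency_ms) stim_index[k] <- j
      }
    }
  }
  data.frame(time_ms = times, stim_index = stim_index)
}

#' Duration at a repolarization level for one beat
#'
#' Duration from the activation time to the first downward crossing of
#' `peak - level * (peak - baseline)`, with linear interpolation between
#' frames. The baseline is the median of the 20 ms window preceding the
#' upstroke (robust to drift); the peak is the maximum between activation
#' and the next activation (or trace end). If repolarization to the level is
#' not reached before the next beat the result is flagged invalid, not an
#' error.
#'
#' @param trace normalized, depolarisation-positive trace.
#' @param frame_interval ms per sample.
#' @param activation_time activation time, ms (trace clock, first sample at
#'   0 ms).
#' @param level repolarization level in (0, 1]; 0.8 gives APD80/CaTD80.
#' @param next_activation_time end of the beat window, ms (optional).
#' @param baseline override the estimated diastolic baseline (used by the
#'   stimulus-anchored extractor, whose activation marker sits mid-upstroke).
#' @return list `duration_ms`, `amplitude`, `baseline`, `peak`, `valid`.
#' @export
compute_duration <- function(trace, frame_interval = 2, activation_time,
                             level = 0.8, next_activation_time = NULL,
                             baseline = NULL) {
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  n <- length(trace)
  tt <- (seq_len(n) - 1) * frame_interval
  i_act <- findInterval(activation_time, tt)
  i_end <- if (is.null(next_activation_time)) n else
    max(i_act + 1L, findInterval(next_activation_time, tt))
  if (is.null(baseline)) {
    i_base0 <- findInterval(max(0, activation_time - 20), tt)
    i_base1 <- max(i_base0, i_act - 1L)
    baseline <- median(trace[i_base0:i_base1])
  }
  win <- i_act:min(i_end, n)
  peak_i <- win[which.max(trace[win])]
  peak <- trace[peak_i]
  amp <- peak - baseline
  lev_val <- peak - level * (peak - baseline)
  tc <- cross_down_time(tt, trace, lev_val, from = peak_i)
  valid <- !is.na(tc) && tc <= tt[min(i_end, n)] + frame_interval &&
    amp > .Machine$double.eps^0.5
  dur <- if (valid) tc - activation_time else NA_real_
  if (!is.na(dur) && dur <= 0) { dur <- NA_real_; valid <- FALSE }
  list(duration_ms = dur, amplitude = amp, baseline = baseline, peak = peak,
       valid = valid)
}

#' Per-site, per-beat feature table from a movie
#'
#' Runs activation detection and per-beat duration measurement at every
#' requested site, producing the beat feature table consumed by the
#' alternans, mapping and aggregation stages. Diastolic intervals are
#' `DI_n = t_act_{n+1} - (t_act_n + duration_n)`.
#'
#' @param movie a preprocessed [optical_movie()].
#' @param mask optional [build_quality_mask()] result restricting sites.
#' @param sites optional 2-column matrix (row, col); default: all valid
#'   pixels (or every pixel if no mask).
#' @param stim_times optional stimulus times (ms, movie clock).
#' @param level repolarization level (0.8 = APD80/CaTD80).
#' @param anchor `"auto"`: free-running activation detection (max dF/dt).
#'   `"stimulus"`: one beat per stimulus, activation at the 50%-amplitude
#'   upstroke crossing inside each stimulus window — robust for slow
#'   upstrokes (calcium channel) under noise; requires `stim_times`.
#' @param ... passed to [detect_activations()].
#' @return data.frame with columns `row`, `col`, `beat`, `t_act`,
#'   `duration`, `amplitude`, `di`, `stim_index`, `valid`.
#' @export
extract_features <- function(movie, mask = NULL, sites = NULL,
                             stim_times = NULL, level = 0.8,
                             anchor = c("auto", "stimulus"), ...) {
  stopifnot(inherits(movie, "optical_movie"))
  anchor <- match.arg(anchor)
  if (anchor == "stimulus" && (is.null(stim_times) || !length(stim_times)))
    stop("anchor = \"stimulus\" requires stim_times")
  d <- dim(movie$data)
  if (is.null(sites)) {
    ok <- if (is.null(mask)) matrix(TRUE, d[1], d[2]) else mask$valid
    sites <- which(ok, arr.ind = TRUE)
  } else if (!is.null(mask)) {
    keep <- mask$valid[sites]
    sites <- sites[keep, , drop = FALSE]
  }
  sites <- matrix(as.integer(sites), ncol = 2)
  fi <- movie$frame_interval
  res <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    tr <- as.numeric(movie$data[sites[s, 1], sites[s, 2], ])
    acts <- if (anchor == "stimulus")
      stim_anchored_activations(tr, fi, stim_times)
    else detect_activations(tr, fi, stim_times = stim_times, ...)
    if (!nrow(acts)) next
    nb <- nrow(acts)
    dur <- amp <- rep(NA_real_, nb); ok <- logical(nb)
    for (b in seq_len(nb)) {
      nxt <- if (b < nb) acts$time_ms[b + 1] else NULL
      m <- compute_duration(tr, fi, acts$time_ms[b], level = level,
                            next_activation_time = nxt,
                            baseline = acts$baseline[b])
      dur[b] <- m$duration_ms; amp[b] <- m$amplitude; ok[b] <- m$valid
    }
    di <- c(acts$time_ms[-1] - (acts$time_ms[-nb] + dur[-nb]), NA_real_)
    res[[s]] <- data.frame(row = sites[s, 1], col = sites[s, 2],
                           beat = seq_len(nb), t_act = acts$time_ms,
                           duration = dur, amplitude = amp, di = di,
                           stim_index = acts$stim_index, valid = ok)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(row = integer(), col = integer(), beat = integer(),
                      t_act = numeric(), duration = numeric(),
                      amplitude = numeric(), di = numeric(),
                      stim_index = integer(), valid = logical())
  rownames(out) <- NULL
  out
}

# one activation per stimulus window: 50%-amplitude upstroke crossing
stim_anchored_activations <- function(trace, frame_interval, stim_times,
                                      min_range = 0.2) {
  n <- length(trace)
  tt <- (seq_len(n) - 1) * frame_interval
  t_end <- tt[n]
  out <- list()
  for (b in seq_along(stim_times)) {
    w0 <- stim_times[b]
    w1 <- if (b < length(stim_times)) stim_times[b + 1] else t_end
    sel <- which(tt >= w0 & tt < w1)
    if (length(sel) < 4) next
    y <- trace[sel]
    base <- quantile(y, 0.1, names = FALSE)
    peak <- max(y)
    if (peak - base < min_range) next
    lev <- base + 0.5 * (peak - base)
    idx <- sel[seq_len(length(sel) - 1L)]
    hit <- idx[trace[idx] < lev & trace[idx + 1L] >= lev]
    if (!length(hit)) next
    i <- hit[1L]
    tc <- tt[i] + frame_interval * (lev - trace[i]) /
      (trace[i + 1L] - trace[i])
    out[[length(out) + 1L]] <- data.frame(time_ms = tc, stim_index = b,
                                          baseline = base)
  }
  if (!length(out)) return(data.frame(time_ms = numeric(),
                                      stim_index = integer(),
                                      baseline = numeric()))
  do.call(rbind, out)
}

#' Monoexponential calcium-decay fit
#'
#' Least-squares fit of `A * exp(-(t - t0) / tau) + C` to the decay of one
#' calcium transient, starting at the 20%-repolarization crossing of that
#' beat and ending at the close of the beat's diastole (the next activation
#' or the trace end): with a free offset, stopping the window at deep
#' repolarization leaves `tau` and `C` ill-determined under noise. The
#' fitted beat should be the last of its train so the decay is untruncated.
#' `tau` is invariant under affine rescaling of the trace.
#'
#' @param trace normalized, upright calcium trace.
#' @param frame_interval ms per sample.
#' @param activation_time activation time of the fitted beat (ms); default:
#'   the last detected activation.
#' @param start_level fraction of repolarization at the fit start (0.2 =
#'   20% repolarization).
#' @param tau_bounds admissible range for tau, ms; outside it the fit is
#'   flagged invalid with a diagnostic.
#' @param next_activation_time optional end of the beat's diastole (ms) when
#'   the fitted beat is not the last of the recording.
#' @return an object of class `tau_fit`: list with `tau`, `amplitude`,
#'   `offset`, `fit_window`, `rss`, `valid`, `diagnostic`.
#' @export
fit_ca_decay <- function(trace, frame_interval = 2, activation_time = NULL,
                         start_level = 0.2, tau_bounds = c(1, 1000),
                         next_activation_time = NULL) {
  n <- length(trace)
  tt <- (seq_len(n) - 1) * frame_interval
  # fit-window landmarks are located on a lightly smoothed copy (noise on
  # the raw trace shifts threshold crossings systematically early); the
  # least-squares fit itself uses the raw samples
  sm <- moving_average(trace, 5L)
  if (is.null(activation_time)) {
    acts <- detect_activations(sm, frame_interval)
    if (!nrow(acts)) return(invalid_tau_fit("no beat detected"))
    activation_time <- max(acts$time_ms)
  }
  m <- compute_duration(sm, frame_interval, activation_time,
                        level = start_level,
                        baseline = quantile(sm, 0.1, names = FALSE))
  if (!m$valid) return(invalid_tau_fit("no start-level crossing found"))
  t0 <- activation_time + m$duration_ms
  # the fit window runs to the end of the beat's diastole (the next
  # activation when the caller supplies it, otherwise the trace end, the
  # fitted beat being the last of its train): truncating at deep
  # repolarization leaves the offset and tau ill-determined under noise
  t_end <- if (is.null(next_activation_time)) tt[n] else
    next_activation_time - 5 * frame_interval
  sel <- which(tt >= t0 & tt <= t_end)
  if (length(sel) < 5) return(invalid_tau_fit("fit window too short"))
  x <- tt[sel] - t0
  y <- trace[sel]
  # starting values: offset from the window tail, rate from a log-linear fit
  c0 <- median(tail(y, max(5L, length(y) %/% 10L)))
  a0 <- y[1] - c0
  lf <- lm(log(pmax(y - c0 + 0.02 * abs(a0), 1e-9)) ~ x)
  tau0 <- -1 / coef(lf)[2]
  span <- diff(range(x))
  if (!is.finite(tau0) || tau0 <= 2 || tau0 > 2 * span) tau0 <- span / 4
  fit <- tryCatch(suppressWarnings(
    nls(y ~ A * exp(-x / tau) + C,
        start = list(A = a0, tau = tau0, C = c0),
        control = nls.control(maxiter = 100, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(invalid_tau_fit("nonlinear fit did not converge"))
  cf <- coef(fit)
  tau <- cf[["tau"]]
  rss <- sum(residuals(fit)^2)
  out <- structure(list(tau = tau, amplitude = cf[["A"]], offset = cf[["C"]],
                        fit_window = c(start_ms = t0, end_ms = t_end),
                        rss = rss, valid = TRUE, diagnostic = NA_character_),
                   class = "tau_fit")
  if (!is.finite(tau) || tau < tau_bounds[1] || tau > tau_bounds[2]) {
    out$valid <- FALSE
    out$diagnostic <- sprintf("tau = %.3g ms outside (%g, %g)", tau,
                              tau_bounds[1], tau_bounds[2])
  }
  out
}

invalid_tau_fit <- function(msg)
  structure(list(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
                 fit_window = c(start_ms = NA_real_, end_ms = NA_real_),
                 rss = NA_real_, valid = FALSE, diagnostic = msg),
            class = "tau_fit")

#' @export
print.tau_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<tau_fit> tau = %.2f ms (window %.1f-%.1f ms, rss %.3g)\n",
                x$tau, x$fit_window[1], x$fit_window[2], x$rss))
  else cat("<tau_fit> invalid:", x$diagnostic, "\n")
  invisible(x)
}

#' Aggregate per-site features over the analyzable sites
#'
#' Per-recording mean and SD over valid sites of the per-site mean steady-
#' state value, enforcing the minimum-analyzable-sites rule (default 25).
#'
#' @param features a feature table from [extract_features()].
#' @param metric column to aggregate (`"duration"` or `"amplitude"`).
#' @param min_sites minimum number of contributing sites.
#' @param min_beat_index only beats with `beat >= min_beat_index` are used
#'   (steady-state rule; recordings made after a conditioning train may use
#'   1).
#' @return list `mean`, `sd`, `n_sites`, `per_site` (data.frame).
#' @export
aggregate_sites <- function(features, metric = "duration", min_sites = 25L,
                            min_beat_index = 1L) {
  f <- features[features$valid & features$beat >= min_beat_index &
                  !is.na(features[[metric]]), , drop = FALSE]
  if (!nrow(f)) insufficient_sites_error(0L, min_sites)
  key <- paste(f$row, f$col)
  per_site <- do.call(rbind, lapply(split(f, key), function(d)
    data.frame(row = d$row[1], col = d$col[1], value = mean(d[[metric]]),
               n_beats = nrow(d))))
  if (nrow(per_site) < min_sites)
    insufficient_sites_error(nrow(per_site), min_sites)
  list(mean = mean(per_site$value), sd = sd(per_site$value),
       n_sites = nrow(per_site), per_site = per_site)
}

#' ERP from a recorded S1-S2 scan
#'
#' Analysis-side counterpart of [measure_true_erp()]: given recordings (or
#' pre-extracted activation tables) of S2 test beats at decreasing coupling
#' intervals, the ERP is the longest interval with no propagated activation
#' beyond `capture_distance_px` of the stimulus site. Activations confined
#' to the stimulus neighbourhood count as non-capture.
#'
#' @param scans list of entries `list(s1s2 =, features =, s2_time =)` where
#'   `features` is an [extract_features()] table of the post-S2 window and
#'   `s2_time` the S2 time on that table's clock (ms).
#' @param stim_site `c(row, col)`.
#' @param capture_distance_px propagation criterion, pixels.
#' @return list `erp_ms`, `scanned` (data.frame `s1s2`, `captured`).
#' @export
measure_erp_from_protocol <- function(scans, stim_site,
                                      capture_distance_px = 10) {
  s1s2 <- vapply(scans, function(s) s$s1s2, numeric(1))
  o <- order(-s1s2)
  tested <- data.frame(s1s2 = numeric(), captured = logical())
  erp <- NA_real_
  for (k in o) {
    sc <- scans[[k]]
    f <- sc$features
    d2 <- (f$row - stim_site[1])^2 + (f$col - stim_site[2])^2
    cap <- any(f$t_act > sc$s2_time & d2 >= capture_distance_px^2)
    tested <- rbind(tested, data.frame(s1s2 = sc$s1s2, captured = cap))
    if (!cap) { erp <- sc$s1s2; break }
  }
  if (is.na(erp))
    stop("ERP below scan range: capture persisted at the smallest interval")
  list(erp_ms = erp, scanned = tested)
}
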