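#' Phase movie from an optical movie
#'
#' Per-pixel instantaneous phase in (-pi, pi]. Default method: analytic-
#' signal (Hilbert-transform) phase of the mean-subtracted trace, computed
#' via FFT; a periodically paced pixel sweeps 2*pi per cycle. Alternative:
#' delay embedding, `atan2(x(t - delay) - mean, x(t) - mean)`. Pixels with
#' no dynamic range are invalidated (NA phase).
#'
#' @param movie a preprocessed [optical_movie()].
#' @param method `"hilbert"` or `"delay_embedding"`.
#' @param delay_ms embedding delay (delay method only).
#' @param min_range pixels whose dynamic range is below this are invalid.
#' @param min_cycles fail unless the recording spans at least this many
#'   dominant-period cycles (default 2).
#' @return an object of class `phase_movie`: list with `phase` (H x W x T
#'   array), `method`, `frame_interval`.
#' @export
compute_phase <- function(movie, method = c("hilbert", "delay_embedding"),
                          delay_ms = 20, min_range = 0.15, min_cycles = 2) {
  stopifnot(inherits(movie, "optical_movie"))
  method <- match.arg(method)
  d <- dim(movie$data)
  H <- d[1]; W <- d[2]; nT <- d[3]
  m <- matrix(movie$data, H * W, nT)
  rng <- apply(m, 1, function(x) diff(range(x)))
  valid <- rng >= min_range
  if (!any(valid)) stop("no valid pixels for phase computation")

  # dominant period from the mean valid trace
  mt <- colMeans(m[valid, , drop = FALSE])
  mt <- mt - mean(mt)
  sp <- Mod(fft(mt))^2
  half <- 2:(floor(nT / 2))
  kdom <- half[which.max(sp[half])] - 1
  period_ms <- nT * movie$frame_interval / kdom
  if (nT * movie$frame_interval < min_cycles * period_ms)
    stop("window shorter than ", min_cycles, " cycles of the dominant period")

  ph <- matrix(NA_real_, H * W, nT)
  if (method == "hilbert") {
    hsel <- rep(0, nT)
    hsel[1] <- 1
    if (nT %% 2 == 0) {
      hsel[nT / 2 + 1] <- 1
      hsel[2:(nT / 2)] <- 2
    } else hsel[2:((nT + 1) / 2)] <- 2
    for (k in which(valid)) {
      x <- m[k, ] - mean(m[k, ])
      z <- fft(fft(x) * hsel, inverse = TRUE) / nT
      ph[k, ] <- Arg(z)
    }
  } else {
    lag <- max(1L, round(delay_ms / movie$frame_interval))
    for (k in which(valid)) {
      x <- m[k, ] - mean(m[k, ])
      xd <- c(rep(x[1], lag), x[seq_len(nT - lag)])
      ph[k, ] <- atan2(xd, x)
    }
  }
  structure(list(phase = array(ph, dim = d), method = method,
                 frame_interval = movie$frame_interval,
                 dominant_period_ms = period_ms),
            class = "phase_movie")
}

#' Topological charge field of one phase frame
#'
#' Winding number of the phase around each 2 x 2 plaquette: the closed-loop
#' sum of wrapped phase differences, which is -2*pi, 0 or +2*pi. Plaquettes
#' touching an invalid (NA) pixel are skipped.
#'
#' @param phase_frame H x W phase matrix.
#' @return (H-1) x (W-1) matrix of winding numbers in turns (-1, 0, +1).
#' @export
phase_charge <- function(phase_frame) {
  p <- phase_frame
  H <- nrow(p); W <- ncol(p)
  p11 <- p[-H, -W]; p12 <- p[-H, -1]; p22 <- p[-1, -1]; p21 <- p[-1, -W]
  s <- wrap_angle(p12 - p11) + wrap_angle(p22 - p12) +
    wrap_angle(p21 - p22) + wrap_angle(p11 - p21)
  round(s / (2 * pi))
}

#' Detect and track phase singularities
#'
#' Per frame, phase singularities are plaquettes with winding number +/-1
#' (topological charge +/-2*pi); they are linked across frames by nearest-
#' neighbour association within `link_radius_px` and matching chirality.
#' Tracks shorter than `min_lifespan_frames` are discarded.
#'
#' @param phase a [compute_phase()] result.
#' @param link_radius_px maximum per-frame movement.
#' @param min_lifespan_frames minimum track length in frames.
#' @return list of tracks; each a data.frame `frame`, `time_ms`, `row`,
#'   `col`, `chirality`, with attribute-free plain positions at plaquette
#'   centres (row/col + 0.5).
#' @export
detect_singularities <- function(phase, link_radius_px = 3,
                                 min_lifespan_frames = 2L) {
  stopifnot(inherits(phase, "phase_movie"))
  d <- dim(phase$phase)
  nT <- d[3]
  per_frame <- vector("list", nT)
  for (t in seq_len(nT)) {
    q <- phase_charge(phase$phase[, , t])
    hit <- which(!is.na(q) & q != 0, arr.ind = TRUE)
    per_frame[t] <- list(if (nrow(hit)) data.frame(
      frame = t, time_ms = (t - 1) * phase$frame_interval,
      row = hit[, 1] + 0.5, col = hit[, 2] + 0.5,
      chirality = q[hit]) else NULL)
  }
  # greedy nearest-neighbour linking
  tracks <- list()
  active <- list()   # each: list(df =, last_row =, last_col =, chir =)
  for (t in seq_len(nT)) {
    pts <- per_frame[[t]]
    used <- if (is.null(pts)) logical(0) else rep(FALSE, nrow(pts))
    keep <- list()
    for (tr in active) {
      best <- NA_integer_; best_d <- Inf
      if (!is.null(pts)) for (k in seq_len(nrow(pts))) {
        if (used[k] || pts$chirality[k] != tr$chir) next
        dd <- sqrt((pts$row[k] - tr$last_row)^2 + (pts$col[k] - tr$last_col)^2)
        if (dd <= link_radius_px && dd < best_d) { best <- k; best_d <- dd }
      }
      if (!is.na(best)) {
        used[best] <- TRUE
        tr$df <- rbind(tr$df, pts[best, ])
        tr$last_row <- pts$row[best]; tr$last_col <- pts$col[best]
        keep[[length(keep) + 1L]] <- tr
      } else tracks[[length(tracks) + 1L]] <- tr$df
    }
    if (!is.null(pts)) for (k in which(!used))
      keep[[length(keep) + 1L]] <- list(df = pts[k, ], last_row = pts$row[k],
                                        last_col = pts$col[k],
                                        chir = pts$chirality[k])
    active <- keep
  }
  for (tr in active) tracks[[length(tracks) + 1L]] <- tr$df
  tracks <- Filter(function(df) nrow(df) >= min_lifespan_frames, tracks)
  lapply(tracks, function(df) { rownames(df) <- NULL; df })
}

#' Lifespan and rotation count of a singularity track
#'
#' @param track one element of [detect_singularities()] output.
#' @param period_ms rotation period (e.g. the phase movie's dominant
#'   period); when given, `rotations = lifespan / period`.
#' @return list `lifespan_ms`, `rotations`, `chirality`.
#' @export
track_summary <- function(track, period_ms = NULL) {
  lifespan <- diff(range(track$time_ms))
  list(lifespan_ms = lifespan,
       rotations = if (is.null(period_ms)) NA_real_ else lifespan / period_ms,
       chirality = track$chirality[1])
}
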