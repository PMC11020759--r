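#' Condition a raw fluorescence movie into normalized traces
#'
#' Applies, in order: polarity correction (inverted channels are flipped so
#' depolarisation is positive), optional per-pixel detrending, spatial boxcar
#' smoothing, zero-phase temporal smoothing (centred moving average, so
#' activation times are not biased), and per-pixel robust normalization to
#' the unit interval using the 2nd/98th percentiles. Pixels with no dynamic range are
#' marked invalid in `metadata$invalid_pixels` rather than divided by zero.
#'
#' @param movie an [optical_movie()].
#' @param spatial_kernel_px odd boxcar width in pixels (1 = off).
#' @param temporal_window_frames odd moving-average width in frames (1 = off).
#' @param detrend `"none"`, `"linear"` (per-pixel least-squares line), or
#'   `"exponential"` (per-pixel monoexponential photobleaching fit, falling
#'   back to linear when the fit fails).
#' @param percentiles robust range for normalization.
#' @return a normalized [optical_movie()], polarity `"upright"`; the applied
#'   settings are recorded in `metadata$preprocess`.
#' @export
preprocess <- function(movie, spatial_kernel_px = 1L,
                       temporal_window_frames = 1L,
                       detrend = c("none", "linear", "exponential"),
                       percentiles = c(0.02, 0.98)) {
  stopifnot(inherits(movie, "optical_movie"))
  detrend <- match.arg(detrend)
  if (spatial_kernel_px %% 2L != 1L || temporal_window_frames %% 2L != 1L)
    stop("spatial kernel and temporal window must be odd and >= 1")
  d <- dim(movie$data)
  H <- d[1]; W <- d[2]; nT <- d[3]
  m <- matrix(movie$data, H * W, nT)
  if (movie$polarity == "inverted") m <- -m

  if (detrend != "none") {
    tt <- seq_len(nT)
    if (detrend == "linear") {
      # per-pixel least-squares line, removed keeping the mean
      tc <- tt - mean(tt)
      slope <- (m %*% tc) / sum(tc^2)
      m <- m - slope %*% t(tc)
    } else {
      base <- rowMeans(m)
      for (k in seq_len(nrow(m))) {
        y <- m[k, ]
        fit <- tryCatch(nls(y ~ a * exp(-tt / tb) + c0,
                            start = list(a = y[1] - min(y),
                                         tb = nT, c0 = min(y)),
                            control = list(warnOnly = TRUE)),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          cf <- coef(fit)
          m[k, ] <- y - cf[["a"]] * exp(-tt / cf[["tb"]])
        } else {
          tc <- tt - mean(tt)
          m[k, ] <- y - sum(y * tc) / sum(tc^2) * tc
        }
      }
      m <- m - rowMeans(m) + base
    }
  }

  if (spatial_kernel_px > 1L) {
    half <- (spatial_kernel_px - 1L) %/% 2L
    arr <- array(m, dim = c(H, W, nT))
    acc <- array(0, dim = c(H, W, nT)); cnt <- matrix(0, H, W)
    for (di in -half:half) for (dj in -half:half) {
      si <- max(1, 1 - di):min(H, H - di)
      sj <- max(1, 1 - dj):min(W, W - dj)
      acc[si + di, sj + dj, ] <- acc[si + di, sj + dj, , drop = FALSE] +
        arr[si, sj, , drop = FALSE]
      cnt[si + di, sj + dj] <- cnt[si + di, sj + dj] + 1
    }
    m <- matrix(acc / as.vector(cnt), H * W, nT)
  }

  if (temporal_window_frames > 1L)
    m <- t(apply(m, 1, moving_average, window = temporal_window_frames))

  lo <- apply(m, 1, quantile, probs = percentiles[1], names = FALSE)
  hi <- apply(m, 1, quantile, probs = percentiles[2], names = FALSE)
  rng <- hi - lo
  invalid <- rng <= .Machine$double.eps^0.5
  rng[invalid] <- 1
  m <- pmin(pmax((m - lo) / rng, 0), 1)
  m[invalid, ] <- 0

  meta <- movie$metadata
  meta$invalid_pixels <- matrix(invalid, H, W)
  meta$preprocess <- list(spatial_kernel_px = spatial_kernel_px,
                          temporal_window_frames = temporal_window_frames,
                          detrend = detrend, percentiles = percentiles)
  optical_movie(array(m, dim = d), movie$frame_interval, movie$pixel_pitch,
                channel = movie$channel, polarity = "upright",
                metadata = meta)
}

#' Per-pixel signal quality mask
#'
#' SNR estimator: ratio of the variance of the temporally smoothed trace
#' (beat-band signal) to the high-frequency residual variance estimated from
#' first differences (`var(diff(x)) / 2`), in dB. Pixels below
#' `snr_threshold` (and pixels flagged invalid during preprocessing) are
#' excluded; this reproduces the practice of excluding the infarct zone,
#' whose pixels carry only noise. Fails explicitly when fewer than
#' `min_valid_sites` pixels survive.
#'
#' @param movie a preprocessed [optical_movie()].
#' @param snr_threshold dB; default 6.
#' @param min_valid_sites minimum analyzable sites (default 25).
#' @param smooth_frames width of the beat-band smoother, frames.
#' @return an object of class `quality_mask`: list with `valid` (logical
#'   matrix), `snr_map` (dB), `snr_threshold`, `n_valid`.
#' @export
build_quality_mask <- function(movie, snr_threshold = 6,
                               min_valid_sites = 25L, smooth_frames = 9L) {
  stopifnot(inherits(movie, "optical_movie"))
  d <- dim(movie$data)
  H <- d[1]; W <- d[2]; nT <- d[3]
  m <- matrix(movie$data, H * W, nT)
  sig_var <- numeric(nrow(m)); noise_var <- numeric(nrow(m))
  for (k in seq_len(nrow(m))) {
    x <- m[k, ]
    s <- moving_average(x, smooth_frames)
    sig_var[k] <- var(s)
    noise_var[k] <- var(diff(x)) / 2
  }
  snr <- 10 * log10(pmax(sig_var, 1e-300) / pmax(noise_var, 1e-300))
  snr[sig_var == 0] <- -Inf
  snr_map <- matrix(snr, H, W)
  valid <- snr_map >= snr_threshold
  inv <- movie$metadata$invalid_pixels
  if (!is.null(inv)) valid <- valid & !inv
  n_valid <- sum(valid)
  if (n_valid < min_valid_sites)
    insufficient_sites_error(n_valid, min_valid_sites)
  structure(list(valid = valid, snr_map = snr_map,
                 snr_threshold = snr_threshold, n_valid = n_valid),
            class = "quality_mask")
}

#' @export
print.quality_mask <- function(x, ...) {
  cat(sprintf("<quality_mask> %d/%d valid pixels (SNR threshold %g dB)\n",
              x$n_valid, length(x$valid), x$snr_threshold))
  invisible(x)
}
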