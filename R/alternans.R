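#' Beat-to-beat alternans map
#'
#' Per-site signed alternans magnitude: the mean over consecutive beat pairs
#' of (first - second). For APD the significance rule is a difference of
#' more than 10 ms between consecutive beats; for calcium amplitude, more
#' than 5% relative to the mean of the two amplitudes in a pair. Sites with
#' fewer than `min_beats` usable beats are invalid; an odd trailing beat is
#' ignored.
#'
#' @param features feature table from [extract_features()] (or a cable
#'   result via [cable_features()]).
#' @param channel `"apd"` (uses `duration`) or `"ca_amplitude"` (uses
#'   `amplitude`, percent units).
#' @param min_beats minimum usable beats per site (>= 4).
#' @param apd_threshold_ms significance threshold for APD alternans.
#' @param ca_threshold_pct significance threshold for Ca-amplitude
#'   alternans.
#' @param min_beat_index first steady-state beat.
#' @return an object of class `alternans_map`: list with matrices `delta`
#'   (signed; ms or %), `significant`, `parity_sign` (NA where not
#'   significant), `n_pairs`, plus `channel`, `threshold`, and `dims`.
#' @export
compute_alternans_map <- function(features,
                                  channel = c("apd", "ca_amplitude"),
                                  min_beats = 4L, apd_threshold_ms = 10,
                                  ca_threshold_pct = 5, min_beat_index = 1L) {
  channel <- match.arg(channel)
  metric <- if (channel == "apd") "duration" else "amplitude"
  f <- features
  # align beat parity across sites on the stimulus index when available:
  # a missed first beat at one site must not flip its apparent phase
  if ("stim_index" %in% names(f) && any(!is.na(f$stim_index))) {
    f <- f[!is.na(f$stim_index), , drop = FALSE]
    f$beat <- f$stim_index
  }
  f <- f[f$valid & f$beat >= min_beat_index & !is.na(f[[metric]]), ,
         drop = FALSE]
  H <- max(c(features$row, 1L)); W <- max(c(features$col, 1L))
  delta <- matrix(NA_real_, H, W)
  npair <- matrix(0L, H, W)
  for (d in split(f, paste(f$row, f$col))) {
    d <- d[order(d$beat), ]
    # consecutive-beat runs only: a dropped beat breaks pairing
    runs <- split(d, cumsum(c(1, diff(d$beat) != 1)))
    vals <- unlist(lapply(runs, function(r) {
      v <- r[[metric]]
      if (length(v) < 2L) return(NULL)
      v[seq_len(2L * (length(v) %/% 2L))]
    }))
    if (is.null(vals) || length(vals) < min_beats) next
    pr <- matrix(vals, nrow = 2L)
    dd <- pr[1, ] - pr[2, ]
    if (channel == "ca_amplitude") dd <- 100 * dd / colMeans(pr)
    delta[d$row[1], d$col[1]] <- mean(dd)
    npair[d$row[1], d$col[1]] <- ncol(pr)
  }
  thr <- if (channel == "apd") apd_threshold_ms else ca_threshold_pct
  significant <- !is.na(delta) & abs(delta) > thr
  parity <- matrix(NA_real_, H, W)
  parity[significant] <- sign(delta[significant])
  structure(list(delta = delta, significant = significant,
                 parity_sign = parity, n_pairs = npair, channel = channel,
                 threshold = thr, dims = c(H, W)),
            class = "alternans_map")
}

#' @export
print.alternans_map <- function(x, ...) {
  cat(sprintf("<alternans_map> %s: %d/%d sites significant (|delta| > %g %s)\n",
              x$channel, sum(x$significant), sum(!is.na(x$delta)),
              x$threshold, if (x$channel == "apd") "ms" else "%"))
  invisible(x)
}

#' Convert a cable result into a feature table
#'
#' Maps the cable's per-site APD series onto a one-row feature table so the
#' alternans machinery can consume generator output directly.
#'
#' @param cable result of [run_restitution_cable()].
#' @return feature table (row = 1, col = site).
#' @export
cable_features <- function(cable) {
  if (!nrow(cable))
    return(data.frame(row = integer(), col = integer(), beat = integer(),
                      t_act = numeric(), duration = numeric(),
                      amplitude = numeric(), di = numeric(),
                      stim_index = integer(), valid = logical()))
  data.frame(row = 1L, col = cable$site, beat = cable$beat,
             t_act = cable$t_act, duration = cable$apd,
             amplitude = cable$apd, di = cable$di,
             stim_index = cable$beat, valid = cable$captured)
}

#' Classify the spatial pattern of an alternans map
#'
#' Discordant alternans requires significant sites of both parity signs,
#' each forming a connected region of at least `min_region_px` pixels; the
#' nodal line is then the zero-level contour of the smoothed signed map.
#' Maps with significant sites of a single sign are concordant.
#'
#' @param map an [compute_alternans_map()] result.
#' @param min_region_px minimum connected area per sign (suppresses noise
#'   speckle).
#' @return list `pattern` (`"none"`, `"concordant"`, `"discordant"`),
#'   `nodal_lines` (list of data.frames `x` (col), `y` (row)),
#'   `region_px` (named sizes).
#' @export
classify_spatial_pattern <- function(map, min_region_px = 10L) {
  stopifnot(inherits(map, "alternans_map"))
  sm <- if (map$dims[1] > 2 && map$dims[2] > 2) smooth_matrix(map$delta)
        else map$delta
  pos <- map$significant & !is.na(sm) & sm > 0
  neg <- map$significant & !is.na(sm) & sm < 0
  area <- function(m) if (!any(m)) 0L else max(tabulate(label_components(m)))
  a_pos <- area(pos); a_neg <- area(neg)
  if (!any(map$significant))
    return(list(pattern = "none", nodal_lines = list(),
                region_px = c(pos = a_pos, neg = a_neg)))
  discordant <- a_pos >= min_region_px && a_neg >= min_region_px
  nodal <- list()
  if (discordant) nodal <- nodal_lines(sm)
  list(pattern = if (discordant) "discordant" else "concordant",
       nodal_lines = nodal, region_px = c(pos = a_pos, neg = a_neg))
}

# zero-level contours of a signed map (NA treated as locally absent)
nodal_lines <- function(delta) {
  H <- nrow(delta); W <- ncol(delta)
  if (H == 1L || W == 1L) {
    v <- as.vector(delta)
    i <- which(!is.na(v))
    v <- v[i]
    if (length(v) < 2) return(list())
    sgn <- sign(v)
    cross <- which(sgn[-length(sgn)] * sgn[-1] < 0)
    out <- lapply(cross, function(k) {
      p <- i[k] + v[k] / (v[k] - v[k + 1])
      if (H == 1L) data.frame(x = p, y = 1) else data.frame(x = 1, y = p)
    })
    return(out)
  }
  z <- delta
  z[is.na(z)] <- 0
  cl <- contourLines(x = seq_len(H), y = seq_len(W), z = z, levels = 0)
  lapply(cl, function(c_) data.frame(x = c_$y, y = c_$x))  # x = col, y = row
}

#' Decremental burst-pacing alternans threshold
#'
#' Scans pacing cycle lengths downward from `pcl_start`; at each PCL the
#' provider supplies a steady-state feature table, the alternans map is
#' computed, and the site with maximum |delta| is evaluated against the
#' significance rule. The threshold is the first (longest) PCL with any
#' significant site. Scanning stops when 1:1 capture is lost.
#'
#' @param movie_provider function(pcl) returning a feature table (e.g. from
#'   a simulated movie or a cable). Loss of 1:1 capture is signalled by the
#'   table's `valid`/`captured` flags (any non-captured paced beat).
#' @param pcl_start,pcl_step,pcl_min scan grid, ms.
#' @param channel passed to [compute_alternans_map()].
#' @param min_beats beats required per site in the scan; the default (2,
#'   one beat pair) lets the last 1:1 pair before capture loss be
#'   evaluated, where alternans are typically largest.
#' @param ... further arguments to [compute_alternans_map()].
#' @return an object of class `alternans_threshold`: list with
#'   `threshold_pcl` (NA if none found), `status`
#'   (`"found"`, `"capture_lost"`, `"no_threshold_in_range"`), `scanned`
#'   (data.frame `pcl`, `max_abs_delta`, `any_significant`,
#'   `capture_lost`).
#' @export
find_alternans_threshold <- function(movie_provider, pcl_start = 300,
                                     pcl_step = 10, pcl_min = 80,
                                     channel = "apd", min_beats = 2L, ...) {
  scanned <- data.frame(pcl = numeric(), max_abs_delta = numeric(),
                        any_significant = logical(), capture_lost = logical())
  for (pcl in seq(pcl_start, pcl_min, by = -pcl_step)) {
    feats <- movie_provider(pcl)
    lost <- attr(feats, "capture_lost") %||% any(!feats$valid)
    amap <- compute_alternans_map(feats, channel = channel,
                                  min_beats = min_beats, ...)
    mx <- suppressWarnings(max(abs(amap$delta), na.rm = TRUE))
    if (!is.finite(mx)) mx <- NA_real_
    sig <- any(amap$significant)
    scanned <- rbind(scanned, data.frame(pcl = pcl, max_abs_delta = mx,
                                         any_significant = sig,
                                         capture_lost = lost))
    if (sig)
      return(structure(list(threshold_pcl = pcl, status = "found",
                            scanned = scanned),
                       class = "alternans_threshold"))
    if (lost)
      return(structure(list(threshold_pcl = NA_real_,
                            status = "capture_lost", scanned = scanned),
                       class = "alternans_threshold"))
  }
  structure(list(threshold_pcl = NA_real_, status = "no_threshold_in_range",
                 scanned = scanned), class = "alternans_threshold")
}

#' @export
print.alternans_threshold <- function(x, ...) {
  if (x$status == "found")
    cat(sprintf("<alternans_threshold> %g ms (%d PCLs scanned)\n",
                x$threshold_pcl, nrow(x$scanned)))
  else cat("<alternans_threshold>", x$status, "\n")
  invisible(x)
}
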