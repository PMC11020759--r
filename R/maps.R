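#' Isochrone (activation-time) map for one beat
#'
#' Activation times relative to the beat's earliest activation. Sites with
#' no activation for the beat (scar, invalid pixels, conduction failure) are
#' flagged unactivated.
#'
#' @param features feature table from [extract_features()].
#' @param beat_index which beat (per-site beat counter) to map; or use
#'   `stim_index` when the table was built with stimulus times.
#' @param by `"beat"` or `"stim"`.
#' @param dims `c(H, W)`; inferred from the table when omitted.
#' @return an object of class `isochrone_map`: list with `activation_time`
#'   (matrix, ms, NA where unactivated), `unactivated` (logical),
#'   `reference_time` (earliest absolute activation, ms).
#' @export
build_isochrone <- function(features, beat_index, by = c("beat", "stim"),
                            dims = NULL) {
  by <- match.arg(by)
  col_ <- if (by == "beat") "beat" else "stim_index"
  f <- features[!is.na(features[[col_]]) & features[[col_]] == beat_index, ,
                drop = FALSE]
  if (is.null(dims)) dims <- c(max(features$row), max(features$col))
  at <- matrix(NA_real_, dims[1], dims[2])
  if (nrow(f)) at[cbind(f$row, f$col)] <- f$t_act
  ref <- suppressWarnings(min(at, na.rm = TRUE))
  if (!is.finite(ref)) ref <- NA_real_
  structure(list(activation_time = at - ref, unactivated = is.na(at),
                 reference_time = ref, dims = dims),
            class = "isochrone_map")
}

#' Local conduction-velocity field from an isochrone map
#'
#' Fits a local plane to activation time T(x, y) in a square neighbourhood
#' around each activated site; the velocity vector is `grad(T) / |grad(T)|^2`
#' (mm/ms). Sites whose plane fit leaves a large residual, or with too few
#' activated neighbours, are excluded.
#'
#' @param iso an [build_isochrone()] result.
#' @param pixel_pitch mm per pixel.
#' @param neighborhood_px odd window size for the plane fit.
#' @param min_points minimum activated neighbours.
#' @param max_residual_ms residual RMS threshold.
#' @return list with `vx`, `vy` (matrices, mm/ms), `speed` (matrix),
#'   `median_speed`.
#' @export
estimate_cv <- function(iso, pixel_pitch = 0.25, neighborhood_px = 5L,
                        min_points = 6L, max_residual_ms = 3) {
  stopifnot(inherits(iso, "isochrone_map"))
  at <- iso$activation_time
  H <- nrow(at); W <- ncol(at)
  half <- (neighborhood_px - 1L) %/% 2L
  vx <- vy <- speed <- matrix(NA_real_, H, W)
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (is.na(at[i, j])) next
    ii <- max(1, i - half):min(H, i + half)
    jj <- max(1, j - half):min(W, j + half)
    sub <- at[ii, jj, drop = FALSE]
    ok <- !is.na(sub)
    if (sum(ok) < min_points) next
    y <- rep(ii, times = length(jj))[ok] * pixel_pitch
    x <- rep(jj, each = length(ii))[ok] * pixel_pitch
    tv <- sub[ok]
    X <- cbind(1, x, y)
    fit <- tryCatch(qr.solve(X, tv), error = function(e) NULL)
    if (is.null(fit)) next
    res <- tv - X %*% fit
    if (sqrt(mean(res^2)) > max_residual_ms) next
    g2 <- fit[2]^2 + fit[3]^2
    if (g2 < 1e-12) next
    vx[i, j] <- fit[2] / g2
    vy[i, j] <- fit[3] / g2
    speed[i, j] <- 1 / sqrt(g2)
  }
  list(vx = vx, vy = vy, speed = speed,
       median_speed = median(speed, na.rm = TRUE))
}

#' Conduction-block lines on an isochrone map
#'
#' Block edges are (i) shared edges between adjacent activated sites whose
#' activation-time difference exceeds `grad_threshold` (ms/pixel), and (ii)
#' boundaries between activated sites and unactivated-but-valid regions.
#' Edges adjacent to the scar/invalid mask are labelled `"fixed"`; the rest
#' are `"functional"`, and when an alternans map with nodal lines is
#' supplied each functional edge is annotated with its distance to the
#' nearest nodal line.
#'
#' @param iso an [build_isochrone()] result.
#' @param grad_threshold ms per pixel (default 4, i.e. apparent conduction
#'   slower than 0.0625 mm/ms at 0.25 mm pitch).
#' @param valid_mask logical matrix of analyzable pixels; unactivated valid
#'   pixels count as functional block regions.
#' @param scar_mask optional logical matrix; adjacency to it makes an edge
#'   `"fixed"`.
#' @param nodal list of nodal-line data.frames (from
#'   [classify_spatial_pattern()]).
#' @return data.frame `row1`, `col1`, `row2`, `col2`, `type`,
#'   `nodal_dist_px` (NA when no nodal lines given).
#' @export
detect_conduction_block <- function(iso, grad_threshold = 4,
                                    valid_mask = NULL, scar_mask = NULL,
                                    nodal = NULL) {
  stopifnot(inherits(iso, "isochrone_map"))
  at <- iso$activation_time
  H <- nrow(at); W <- ncol(at)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, H, W)
  edges <- list()
  add_edge <- function(i1, j1, i2, j2) {
    edges[[length(edges) + 1L]] <<- c(i1, j1, i2, j2)
  }
  for (j in seq_len(W)) for (i in seq_len(H)) {
    for (nb in list(c(i + 1L, j), c(i, j + 1L))) {
      i2 <- nb[1]; j2 <- nb[2]
      if (i2 > H || j2 > W) next
      a1 <- at[i, j]; a2 <- at[i2, j2]
      v1 <- valid_mask[i, j]; v2 <- valid_mask[i2, j2]
      if (!is.na(a1) && !is.na(a2)) {
        if (abs(a1 - a2) > grad_threshold) add_edge(i, j, i2, j2)
      } else if (v1 && v2 && (is.na(a1) != is.na(a2))) {
        add_edge(i, j, i2, j2)  # boundary of an unactivated valid region
      } else if (xor(v1, v2) &&
                 !is.na(if (v1) a1 else a2)) {
        add_edge(i, j, i2, j2)  # obstacle boundary: activated tissue
                                # against the excluded (scar) region
      }
    }
  }
  if (!length(edges))
    return(data.frame(row1 = integer(), col1 = integer(), row2 = integer(),
                      col2 = integer(), type = character(),
                      nodal_dist_px = numeric()))
  e <- as.data.frame(do.call(rbind, edges))
  names(e) <- c("row1", "col1", "row2", "col2")
  near_scar <- function(i, j) {
    if (is.null(scar_mask)) return(FALSE)
    ii <- max(1, i - 1):min(H, i + 1)
    jj <- max(1, j - 1):min(W, j + 1)
    any(scar_mask[ii, jj])
  }
  e$type <- ifelse(mapply(near_scar, e$row1, e$col1) |
                     mapply(near_scar, e$row2, e$col2),
                   "fixed", "functional")
  e$nodal_dist_px <- NA_real_
  if (!is.null(nodal) && length(nodal)) {
    np <- do.call(rbind, nodal)
    mid_r <- (e$row1 + e$row2) / 2
    mid_c <- (e$col1 + e$col2) / 2
    e$nodal_dist_px <- vapply(seq_len(nrow(e)), function(k)
      sqrt(min((np$y - mid_r[k])^2 + (np$x - mid_c[k])^2)), numeric(1))
  }
  e
}
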