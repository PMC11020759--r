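#' Pseudo-ECG from a voltage movie
#'
#' Far-field electrogram computed from the discrete voltage gradient dotted
#' with the gradient of inverse distance to each electrode,
#' `phi_e(t) = sum_pixels grad(V) . grad(1/r)`, then differenced between
#' electrode pairs to form bipolar leads. The operator is linear in V.
#'
#' @param vm_movie an [optical_movie()] of the voltage channel. Upright
#'   polarity is assumed (use the raw simulator state or a preprocessed,
#'   polarity-corrected movie).
#' @param electrodes numeric matrix with one row per electrode and columns
#'   `x`, `y`, `z` in mm (tissue plane is z = 0, x along columns, y along
#'   rows). Default: three electrodes around the tissue at 5 mm elevation.
#' @return data.frame with columns `lead12`, `lead23`, `lead13` (bipolar
#'   leads, one sample per frame, arbitrary mV-like units).
#' @export
compute_pseudo_ecg <- function(vm_movie, electrodes = NULL) {
  stopifnot(inherits(vm_movie, "optical_movie"))
  d <- dim(vm_movie$data)
  H <- d[1]; W <- d[2]; nT <- d[3]
  px <- vm_movie$pixel_pitch
  if (is.null(electrodes)) {
    ex <- W * px; ey <- H * px
    electrodes <- rbind(c(-0.2 * ex, ey / 2, 5),
                        c(1.2 * ex, ey / 2, 5),
                        c(ex / 2, 1.2 * ey, 5))
  }
  electrodes <- as.matrix(electrodes)
  if (ncol(electrodes) != 3 || nrow(electrodes) < 2)
    stop("electrodes must be a matrix of >= 2 rows of (x, y, z) mm")

  # pixel centre coordinates (mm)
  xs <- (seq_len(W) - 0.5) * px
  ys <- (seq_len(H) - 0.5) * px
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)

  # per-electrode gradient of 1/r over the tissue plane
  lead_fields <- lapply(seq_len(nrow(electrodes)), function(e) {
    dxv <- X - electrodes[e, 1]
    dyv <- Y - electrodes[e, 2]
    dzv <- -electrodes[e, 3]
    r <- sqrt(dxv^2 + dyv^2 + dzv^2)
    if (any(r < px / 2))
      stop("electrode coincides with a pixel centre (singular 1/r)")
    list(gx = -dxv / r^3, gy = -dyv / r^3)
  })

  # spatial gradients of V per frame, central differences (ms: none; mm)
  m <- matrix(vm_movie$data, H * W, nT)
  phi <- matrix(0, nT, nrow(electrodes))
  # build sparse-like row/col shift index maps once
  idx <- matrix(seq_len(H * W), H, W)
  up <- rbind(idx[1, ], idx[-H, ]); dn <- rbind(idx[-1, ], idx[H, ])
  lf <- cbind(idx[, 1], idx[, -W]); rt <- cbind(idx[, -1], idx[, W])
  denom_y <- matrix(2, H, W); denom_y[c(1, H), ] <- 1
  denom_x <- matrix(2, H, W); denom_x[, c(1, W)] <- 1
  dy <- (m[as.vector(dn), , drop = FALSE] - m[as.vector(up), , drop = FALSE]) /
    (as.vector(denom_y) * px)
  dx <- (m[as.vector(rt), , drop = FALSE] - m[as.vector(lf), , drop = FALSE]) /
    (as.vector(denom_x) * px)
  for (e in seq_along(lead_fields)) {
    gx <- as.vector(lead_fields[[e]]$gx)
    gy <- as.vector(lead_fields[[e]]$gy)
    phi[, e] <- as.vector(crossprod(dx, gx) + crossprod(dy, gy))
  }
  out <- data.frame(lead12 = phi[, 1] - phi[, 2])
  if (nrow(electrodes) >= 3) {
    out$lead23 <- phi[, 2] - phi[, 3]
    out$lead13 <- phi[, 1] - phi[, 3]
  }
  out
}
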