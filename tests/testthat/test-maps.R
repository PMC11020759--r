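plane_features <- function(H = 20, W = 20, cv = 0.4, pitch = 0.25) {
  # T(x, y) = x / cv with x in mm: planar wave moving along columns
  g <- expand.grid(row = seq_len(H), col = seq_len(W))
  data.frame(row = g$row, col = g$col, beat = 1L,
             t_act = g$col * pitch / cv, duration = 120, amplitude = 1,
             di = NA_real_, stim_index = 1L, valid = TRUE)
}

test_that("isochrone maps reference the earliest activation and flag gaps", {
  f <- plane_features()
  iso <- build_isochrone(f, 1L)
  expect_equal(min(iso$activation_time, na.rm = TRUE), 0)
  expect_false(any(iso$unactivated))
  # single-site activation
  f1 <- f[f$row == 5 & f$col == 5, ]
  iso1 <- build_isochrone(f1, 1L, dims = c(20, 20))
  expect_equal(iso1$activation_time[5, 5], 0)
  expect_equal(sum(!iso1$unactivated), 1L)
})

test_that("scar sites stay unactivated on simulated isochrones", {
  sim <- small_sim_clean()
  vm <- preprocess(sim$vm)
  stim_rel <- sim$vm$metadata$stim_times_ms
  f <- extract_features(vm, stim_times = stim_rel)
  iso <- build_isochrone(f, 5L, by = "stim", dims = c(20, 20))
  expect_identical(iso$unactivated, sim$geometry$scar_mask)
})

test_that("planar-wave speed is recovered within 1% from analytic isochrones", {
  iso <- build_isochrone(plane_features(cv = 0.4), 1L)
  cv <- estimate_cv(iso, pixel_pitch = 0.25)
  expect_equal(cv$median_speed, 0.4, tolerance = 0.01)
  # velocity direction along +x (columns)
  expect_equal(median(cv$vy, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_gt(median(cv$vx, na.rm = TRUE), 0)
})

test_that("point-source waves give radial velocity vectors", {
  H <- 25; W <- 25; pitch <- 0.25; cv0 <- 0.3
  g <- expand.grid(row = seq_len(H), col = seq_len(W))
  r <- sqrt((g$row - 13)^2 + (g$col - 13)^2) * pitch
  f <- data.frame(row = g$row, col = g$col, beat = 1L, t_act = r / cv0,
                  duration = 120, amplitude = 1, di = NA_real_,
                  stim_index = 1L, valid = TRUE)
  cv <- estimate_cv(build_isochrone(f, 1L), pixel_pitch = pitch)
  ang_err <- c()
  for (i in seq_len(H)) for (j in seq_len(W)) {
    rr <- sqrt((i - 13)^2 + (j - 13)^2)
    if (rr <= 5 || is.na(cv$vx[i, j])) next
    v <- c(cv$vx[i, j], cv$vy[i, j])
    u <- c(j - 13, i - 13) / rr
    cosang <- sum(v * u) / sqrt(sum(v^2))
    ang_err <- c(ang_err, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
  }
  expect_lt(quantile(ang_err, 0.95), 5)
})

test_that("the velocity field is equivariant under 90-degree rotation", {
  f <- plane_features(H = 15, W = 15)
  iso <- build_isochrone(f, 1L)
  cv <- estimate_cv(iso, pixel_pitch = 0.25)
  rot <- iso
  rot$activation_time <- t(iso$activation_time)[15:1, ]
  rot$unactivated <- t(iso$unactivated)[15:1, ]
  cvr <- estimate_cv(rot, pixel_pitch = 0.25)
  expect_equal(cvr$median_speed, cv$median_speed, tolerance = 1e-9)
  expect_equal(median(abs(cvr$vy), na.rm = TRUE),
               median(abs(cv$vx), na.rm = TRUE), tolerance = 1e-9)
})

test_that("planar waves have no block; blocked regions produce block lines", {
  iso <- build_isochrone(plane_features(), 1L)
  expect_equal(nrow(detect_conduction_block(iso)), 0L)
  # functional block: right half valid but unactivated
  f <- plane_features()
  f <- f[f$col <= 10, ]
  isob <- build_isochrone(f, 1L, dims = c(20, 20))
  blk <- detect_conduction_block(isob, valid_mask = matrix(TRUE, 20, 20))
  expect_true(all(blk$type == "functional"))
  expect_true(all(blk$col1 == 10 & blk$col2 == 11))
})

test_that("waves around a scar produce fixed block on the scar boundary", {
  sim <- small_sim_clean()
  vm <- preprocess(sim$vm)
  stim_rel <- sim$vm$metadata$stim_times_ms
  f <- extract_features(vm, stim_times = stim_rel)
  iso <- build_isochrone(f, 5L, by = "stim", dims = c(20, 20))
  scar <- sim$geometry$scar_mask
  blk <- detect_conduction_block(iso, valid_mask = !scar, scar_mask = scar)
  expect_gt(nrow(blk), 0)
  expect_true(all(blk$type == "fixed"))
  # every block edge touches the scar neighbourhood
  near <- cardiomap:::grow_mask(scar, 2L)
  expect_true(all(near[cbind(blk$row1, blk$col1)] |
                    near[cbind(blk$row2, blk$col2)]))
})
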