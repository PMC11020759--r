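test_that("a pure sinusoid sweeps 2*pi per cycle", {
  n <- 400
  tt <- (seq_len(n) - 1) * 2
  arr <- array(rep(0.5 + 0.4 * sin(2 * pi * tt / 200), each = 16),
               dim = c(4, 4, n))
  mv <- optical_movie(arr, 2, 0.25, "vm", "upright")
  ph <- compute_phase(mv)
  x <- ph$phase[2, 2, ]
  un <- x + 2 * pi * cumsum(c(0, diff(x) < -pi))
  core <- 30:(n - 30)
  slope <- coef(lm(un[core] ~ tt[core]))[2]
  expect_equal(unname(slope), 2 * pi / 200, tolerance = 0.01)
  resid <- un[core] - (un[core][1] + slope * (tt[core] - tt[core][1]))
  expect_lt(max(abs(resid - mean(resid))), 0.1)
  expect_equal(ph$dominant_period_ms, 200, tolerance = 0.01)
})

test_that("constant pixels are invalidated and short windows rejected", {
  n <- 300
  tt <- (seq_len(n) - 1) * 2
  arr <- array(rep(0.5 + 0.4 * sin(2 * pi * tt / 200), each = 16),
               dim = c(4, 4, n))
  arr[1, 1, ] <- 0.7
  mv <- optical_movie(arr, 2, 0.25, "vm", "upright")
  ph <- compute_phase(mv)
  expect_true(all(is.na(ph$phase[1, 1, ])))
  expect_false(anyNA(ph$phase[2, 2, ]))
  short <- optical_movie(arr[, , 1:60, drop = FALSE], 2, 0.25, "vm",
                         "upright")
  expect_error(compute_phase(short), "shorter than")
})

test_that("delay embedding also yields one sweep per cycle", {
  n <- 400
  tt <- (seq_len(n) - 1) * 2
  arr <- array(rep(0.5 + 0.4 * sin(2 * pi * tt / 200), each = 4),
               dim = c(2, 2, n))
  mv <- optical_movie(arr, 2, 0.25, "vm", "upright")
  ph <- compute_phase(mv, method = "delay_embedding", delay_ms = 50)
  x <- ph$phase[1, 1, ]
  wraps <- sum(diff(x) < -pi)
  expect_equal(wraps, floor(n * 2 / 200), tolerance = 1)
})

test_that("spiral fields contain exactly one singularity of known chirality", {
  sp <- spiral_phase_movie(24, 24, frames = 8)
  tracks <- detect_singularities(sp)
  expect_length(tracks, 1L)
  tr <- tracks[[1]]
  expect_equal(nrow(tr), 8L)
  expect_true(all(abs(tr$row - 12.5) <= 1))
  expect_true(all(abs(tr$col - 12.5) <= 1))
  expect_true(all(tr$chirality == tr$chirality[1]))
  mir <- spiral_phase_movie(24, 24, frames = 8, mirror = TRUE)
  tm <- detect_singularities(mir)[[1]]
  expect_equal(tm$chirality[1], -tr$chirality[1])
  # planar phase field: no singularities
  pl <- spiral_phase_movie(24, 24, frames = 4)
  for (t in 1:4)
    pl$phase[, , t] <- wrap_angle(matrix(seq(0, 4 * pi, length.out = 24),
                                         24, 24, byrow = TRUE))
  expect_length(detect_singularities(pl), 0L)
})

test_that("total charge equals the boundary winding on synthetic fields", {
  boundary_winding <- function(p) {
    H <- nrow(p); W <- ncol(p)
    loop <- c(p[1, 1:W], p[2:H, W], p[H, (W - 1):1], p[(H - 1):2, 1])
    sum(cardiomap::wrap_angle(diff(c(loop, loop[1])))) / (2 * pi)
  }
  sp <- spiral_phase_movie(20, 20, frames = 3)
  for (t in 1:3) {
    q <- phase_charge(sp$phase[, , t])
    expect_equal(sum(q), round(boundary_winding(sp$phase[, , t])))
  }
  # figure-eight: two opposite spirals -> zero net charge, two tracks
  ii <- matrix(1:20, 20, 30)
  jj <- matrix(1:30, 20, 30, byrow = TRUE)
  f8 <- atan2(ii - 10, jj - 8) - atan2(ii - 10, jj - 22)
  arr <- array(NA_real_, dim = c(20, 30, 4))
  for (t in 1:4) arr[, , t] <- wrap_angle(f8 - 0.3 * t)
  pm <- structure(list(phase = arr, method = "analytic", frame_interval = 2,
                       dominant_period_ms = 2 * pi / 0.3 * 2),
                  class = "phase_movie")
  q <- phase_charge(arr[, , 1])
  expect_equal(sum(q), round(boundary_winding(arr[, , 1])))
  tracks <- detect_singularities(pm)
  expect_length(tracks, 2L)
  chir <- sort(vapply(tracks, function(d) d$chirality[1], numeric(1)))
  expect_equal(chir, c(-1, 1))
})

test_that("singularity counting survives rotation and phase offset", {
  sp <- spiral_phase_movie(21, 21, frames = 5)
  base <- detect_singularities(sp)
  off <- sp
  off$phase <- wrap_angle(sp$phase + 1.7)
  expect_length(detect_singularities(off), length(base))
  rot <- sp
  rot$phase <- array(apply(sp$phase, 3, function(m) t(m)[21:1, ]),
                     dim = dim(sp$phase))
  expect_length(detect_singularities(rot), length(base))
})

test_that("rotation count times period matches the episode duration", {
  omega <- 0.4
  sp <- spiral_phase_movie(20, 20, frames = 40, omega = omega)
  tr <- detect_singularities(sp)[[1]]
  s <- track_summary(tr, period_ms = 2 * pi / omega * sp$frame_interval)
  expect_equal(s$lifespan_ms, 39 * 2)
  expect_equal(s$rotations * (2 * pi / omega * 2), s$lifespan_ms,
               tolerance = 1e-9)
})

test_that("simulated paced movies have phase defined and no spurious pivots", {
  sim <- small_sim_clean()
  vm <- preprocess(sim$vm)
  ph <- compute_phase(vm)
  scar <- sim$geometry$scar_mask
  expect_false(anyNA(ph$phase[10, 15, ]))
  expect_true(all(is.na(ph$phase[6, 6, ])))  # scar pixel invalid
  tracks <- detect_singularities(ph, min_lifespan_frames = 10L)
  # planar paced activity far from scar carries no long-lived pivots
  long_far <- Filter(function(d)
    any(!scar[cbind(pmin(pmax(round(d$row), 1), 20),
                    pmin(pmax(round(d$col), 1), 20))]) &&
      nrow(d) > 50, tracks)
  expect_length(long_far, 0L)
})
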