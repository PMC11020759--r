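test_that("constructors enforce their invariants", {
  expect_error(tissue_geometry(10, 10), "16 x 16")
  g <- small_geometry()
  expect_false(any(g$scar_mask & g$border_zone_mask))
  expect_true(any(g$border_zone_mask))
  expect_error(cell_model_params(tau_close = -1), "positive")
  expect_error(cell_model_params(drug_apd_factor = 0), "positive")
  expect_error(pacing_protocol(extra_intervals = c(150, 200)),
               "non-increasing")
  expect_error(restitution_map(apd_max = 30, amplitude_a = 50),
               "apd_max > amplitude_a")
})

test_that("no stimulus and no noise gives a constant resting movie", {
  sim <- simulate_tissue(small_geometry(scar = FALSE), cell_model_params(),
                         pacing_protocol(kind = "none"), noise_snr = Inf,
                         seed = 1L, duration_ms = 100)
  expect_equal(var(as.vector(sim$vm$data)), 0)
  expect_equal(var(as.vector(sim$cai$data)), 0)
  expect_equal(nrow(sim$stimulus_log), 0L)
})

test_that("identical seed and inputs give identical output", {
  g <- small_geometry()
  p <- cell_model_params()
  proto <- small_burst_protocol(n_beats = 3L)
  a <- simulate_tissue(g, p, proto, noise_snr = 20, seed = 7L)
  b <- simulate_tissue(g, p, proto, noise_snr = 20, seed = 7L)
  expect_identical(a$vm$data, b$vm$data)
  expect_identical(a$cai$data, b$cai$data)
  expect_identical(a$stimulus_log, b$stimulus_log)
  expect_identical(a$truth$apd80, b$truth$apd80)
  d <- simulate_tissue(g, p, proto, noise_snr = 20, seed = 8L)
  expect_false(identical(a$vm$data, d$vm$data))
})

test_that("planar wavefront speed agrees with a frame-tracking oracle", {
  g <- tissue_geometry(16, 50, scar_mask = NULL)
  proto <- pacing_protocol(kind = "burst", s1_count = 3L, s1s1 = 300,
                           stim_site = c(8L, 3L),
                           steady_beats_before_acquisition = 0L)
  sim <- simulate_tissue(g, cell_model_params(), proto, noise_snr = Inf,
                         seed = 1L)
  # oracle: track the front (first column with v >= 0.5) frame by frame in
  # the raw state during the last beat
  v <- sim$truth$v_frames
  ft <- sim$truth$frame_times_ms
  t_last <- max(sim$stimulus_log$t_on)
  sel <- which(ft > t_last + 10 & ft < t_last + 80)
  front <- vapply(sel, function(k) {
    cols <- which(apply(v[, , k] >= 0.5, 2, any))
    if (length(cols)) max(cols) else NA_real_
  }, numeric(1))
  ok <- !is.na(front) & front < 48
  fit <- lm(front[ok] * g$pixel_pitch ~ ft[sel][ok])
  cv_oracle <- unname(coef(fit)[2])
  # independent route: per-site sub-step activation times from the solver's
  # level crossings along the centre row
  tr <- sim$truth$apd80
  tr <- tr[tr$row == 8 & tr$beat == 3 & tr$col > 5 & tr$col < 45, ]
  cv_events <- g$pixel_pitch / unname(coef(lm(tr$t_act ~ tr$col))[2])
  expect_lt(abs(cv_oracle - cv_events) / cv_events, 0.05)
  expect_gt(cv_events, 0.2)
  expect_lt(cv_events, 0.45)
})

test_that("scar pixels carry baseline plus noise only", {
  sim <- small_sim_clean()
  scar <- sim$geometry$scar_mask
  m <- matrix(sim$vm$data, nrow = prod(dim(scar)))
  expect_equal(max(apply(m[scar, ], 1, var)), 0)
  # noisy case: scar traces uncorrelated with the paced signal
  simn <- small_sim()
  mn <- matrix(simn$vm$data, nrow = prod(dim(scar)))
  ref <- colMeans(mn[!scar, ])
  cors <- abs(apply(mn[scar, ], 1, cor, y = ref))
  expect_lt(median(cors), 0.2)
})

test_that("captured stimuli equal wavefronts crossing a distal line", {
  sim <- small_sim_clean()
  n_cap <- sum(sim$stimulus_log$captured)
  ev <- sim$truth$events
  distal <- ev[ev[, "row"] == 10 & ev[, "col"] == 4 & ev[, "dir"] > 0, ,
               drop = FALSE]
  expect_equal(nrow(distal), n_cap)
})

test_that("bad inputs are rejected with clear errors", {
  g <- small_geometry()
  proto <- pacing_protocol(kind = "burst", stim_site = c(6L, 6L))
  expect_error(simulate_tissue(g, cell_model_params(), proto),
               "inside the scar")
  expect_error(
    simulate_tissue(small_geometry(scar = FALSE), cell_model_params(),
                    small_burst_protocol(n_beats = 2L), seed = 1L,
                    dt_internal = 1),
    "unstable integration")
})

test_that("photobleaching drift is applied when requested", {
  g <- small_geometry(scar = FALSE)
  sim <- simulate_tissue(g, cell_model_params(), small_burst_protocol(4L),
                         noise_snr = Inf, seed = 1L, bleach_tau_ms = 2000)
  tr <- pixel_trace(sim$cai, 10, 10)
  peaks <- tapply(tr, cut(frame_times(sim$cai), 4), max)
  expect_true(all(diff(peaks) < 0))
})
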