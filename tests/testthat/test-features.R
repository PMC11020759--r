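test_that("APD80 of a triangular beat is the analytic 80% point", {
  tr <- triangular_trace()  # rise at 100 ms, linear fall over 200 ms
  acts <- detect_activations(tr, 2)
  expect_equal(nrow(acts), 1L)
  m <- compute_duration(tr, 2, acts$time_ms[1], level = 0.8)
  expect_true(m$valid)
  # activation sits on the upstroke near 100 ms; the 80% crossing is at 260
  expect_equal(m$duration_ms + (acts$time_ms[1] - 100), 160, tolerance = 1)
  # duration is monotone in the repolarization level
  lvls <- c(0.2, 0.5, 0.8, 0.99)
  durs <- vapply(lvls, function(l)
    compute_duration(tr, 2, acts$time_ms[1], level = l)$duration_ms,
    numeric(1))
  expect_true(all(diff(durs) > 0))
  expect_equal(durs[4] + (acts$time_ms[1] - 100), 198, tolerance = 2)
  expect_lt(durs[1], 45)
})

test_that("activation detection is accurate and guarded", {
  # analytic beat with known steepest ascent: logistic upstroke centred
  # 50 ms; repolarisation starts only after the upstroke is complete
  tt <- seq(0, 400, by = 2)
  tr <- 1 / (1 + exp(-(tt - 50) / 4)) * exp(-pmax(tt - 80, 0) / 150)
  a <- detect_activations(tr, 2)
  expect_equal(nrow(a), 1L)
  expect_lt(abs(a$time_ms - 50), 1)
  # periodic train: 10 beats at 300 ms
  tr10 <- rep(0, 1620)
  for (b in 0:9) {
    seg <- triangular_trace(t_rise = 10, fall_ms = 150, total_ms = 298)
    tr10[(b * 150 + 1):(b * 150 + length(seg))] <- seg
  }
  a10 <- detect_activations(tr10, 2)
  expect_equal(nrow(a10), 10L)
  expect_true(all(abs(diff(a10$time_ms) - 300) <= 1))
  # flat trace: empty, not an error
  expect_equal(nrow(detect_activations(rep(0.5, 100), 2)), 0L)
})

test_that("pipeline activation times match simulator truth", {
  sim <- small_sim()
  vm <- preprocess(sim$vm, 3L, 3L)
  mask <- build_quality_mask(preprocess(sim$vm))
  stim_rel <- sim$vm$metadata$stim_times_ms
  f <- extract_features(vm, mask = mask, stim_times = stim_rel)
  tru <- sim$truth$apd80
  tru$t_rel <- tru$t_act - sim$truth$record_from_ms
  tru <- tru[tru$t_rel > 0, ]
  merged <- merge(f[f$valid & !is.na(f$stim_index), ],
                  tru, by = c("row", "col"))
  merged <- merged[abs(merged$t_act.x - merged$t_rel) < 100, ]
  err <- abs(merged$t_act.x - merged$t_rel)
  expect_gt(nrow(merged), 500)
  expect_gte(mean(err <= 2), 0.95)
})

test_that("APD80 recovers simulator truth within 2 ms at SNR 20 dB", {
  sim <- small_sim()
  vm <- preprocess(sim$vm, 3L, 3L)
  mask <- build_quality_mask(preprocess(sim$vm))
  stim_rel <- sim$vm$metadata$stim_times_ms
  f <- extract_features(vm, mask = mask, stim_times = stim_rel)
  apd <- aggregate_sites(f)
  tru <- sim$truth$apd80
  tru <- tru[!sim$geometry$scar_mask[cbind(tru$row, tru$col)] &
               tru$t_act > sim$truth$record_from_ms & !is.na(tru$apd), ]
  expect_equal(apd$mean, mean(tru$apd), tolerance = 2 / mean(tru$apd))
})

test_that("calcium decay fit is exact, affine-invariant and noise-stable", {
  tt <- seq(0, 400, by = 2)
  y <- ifelse(tt < 20, tt / 20, exp(-(tt - 20) / 50))
  f0 <- fit_ca_decay(y, 2, activation_time = 10)
  expect_true(f0$valid)
  expect_equal(f0$tau, 50, tolerance = 0.1 / 50)
  f_aff <- fit_ca_decay(3 * y + 0.2, 2, activation_time = 10)
  expect_equal(f_aff$tau, f0$tau, tolerance = 1e-6)
  # reduced Monte-Carlo (the acceptance suite runs the full 200 seeds)
  taus <- vapply(1:40, function(s) {
    set.seed(s)
    ft <- fit_ca_decay(y + rnorm(length(y), 0, 0.1), 2,
                       activation_time = 10)
    ft$tau
  }, numeric(1))
  expect_equal(mean(taus), 50, tolerance = 0.04)
  # degenerate input
  expect_false(fit_ca_decay(rep(0.1, 50), 2)$valid)
})

test_that("site aggregation follows the minimum-sites rule", {
  mk <- function(n_sites, value = 120) {
    expand.grid(row = seq_len(n_sites), col = 1L) |>
      transform(beat = 1L, t_act = 10, duration = value, amplitude = 1,
                di = NA_real_, stim_index = 1L, valid = TRUE)
  }
  f <- mk(30)
  agg <- aggregate_sites(f)
  expect_equal(agg$mean, 120)
  expect_equal(agg$sd, 0)
  expect_equal(agg$n_sites, 30L)
  expect_no_sites_error(aggregate_sites(mk(24)))
  # sampling check: site values from N(120, 5^2)
  set.seed(9)
  f2 <- mk(100)
  f2$duration <- rnorm(100, 120, 5)
  agg2 <- aggregate_sites(f2)
  expect_lt(abs(agg2$mean - 120), 1.5)  # 3 standard errors
})

test_that("recorded S1-S2 scans yield the ERP with capture-distance rule", {
  feats <- function(propagated) {
    cols <- if (propagated) 3:18 else 3:5
    data.frame(row = 10L, col = cols, beat = 1L,
               t_act = 1000 + (cols - 3) * 2, duration = 120, amplitude = 1,
               di = NA, stim_index = 1L, valid = TRUE)
  }
  scans <- list(list(s1s2 = 160, features = feats(TRUE), s2_time = 990),
                list(s1s2 = 150, features = feats(TRUE), s2_time = 990),
                list(s1s2 = 140, features = feats(FALSE), s2_time = 990))
  out <- measure_erp_from_protocol(scans, stim_site = c(10L, 3L),
                                   capture_distance_px = 10)
  expect_equal(out$erp_ms, 140)
  expect_error(
    measure_erp_from_protocol(scans[1:2], stim_site = c(10L, 3L)),
    "below scan range")
})

test_that("true ERP scanning respects grid resolution and drug ordering", {
  g <- tissue_geometry(16, 30)
  p <- cell_model_params()
  erp2 <- measure_true_erp(g, p, s2_scan = list(start = 170, step = 2),
                           stim_site = c(8L, 3L))
  erp1 <- measure_true_erp(g, p, s2_scan = list(start = 170, step = 1),
                           stim_site = c(8L, 3L))
  expect_lte(abs(erp2$erp_ms - erp1$erp_ms), 2)
  pd <- cell_model_params(drug_apd_factor = 1.10)
  erp_drug <- measure_true_erp(g, apply_drug(pd),
                               s2_scan = list(start = 190, step = 2),
                               stim_site = c(8L, 3L))
  expect_gt(erp_drug$erp_ms, erp2$erp_ms)
  expect_error(
    measure_true_erp(g, p, s2_scan = list(start = 100, step = 2),
                     stim_site = c(8L, 3L)),
    "failed to capture")
})
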