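test_that("paced beats are detected and labelled", {
  beats_true <- seq(100, 2800, by = 300)
  ecg <- synthesize_ecg(beats_true, 3200, noise_sd = 0.03, seed = 1)
  det <- detect_ecg_beats(ecg$ecg, dt = 2, stim_times = beats_true - 4)
  expect_equal(nrow(det), 10L)
  expect_true(all(det$paced))
  expect_true(all(abs(det$time_ms - beats_true) <= 4))
})

test_that("an ectopic between paced beats is found near its true time", {
  beats_true <- seq(100, 2800, by = 300)
  ect <- 1450
  ecg <- synthesize_ecg(c(beats_true, ect), 3200, noise_sd = 0.03, seed = 2)
  det <- detect_ecg_beats(ecg$ecg, dt = 2, stim_times = beats_true - 4)
  np <- det[!det$paced, ]
  expect_equal(nrow(np), 1L)
  expect_lte(abs(np$time_ms - ect), 4)
})

test_that("false positives on pure noise stay under 1 beat/min", {
  fp <- vapply(1:10, function(s) {
    ecg <- synthesize_ecg(numeric(), 120000, noise_sd = 0.1, seed = s)
    nrow(detect_ecg_beats(ecg$ecg, dt = 2))
  }, numeric(1))
  expect_lt(mean(fp) / 2, 1)  # per minute over 2-minute traces
})

test_that("flat signal yields no beats", {
  expect_equal(nrow(detect_ecg_beats(rep(0, 5000), dt = 2)), 0L)
})

test_that("PVB burden counts premature non-paced beats per minute", {
  sinus <- seq(0, 120000, by = 400)
  pvb <- c(30180, 75380)
  beats <- data.frame(time_ms = sort(c(sinus, pvb)), paced = FALSE)
  out <- compute_pvb_burden(beats, window_min = 2)
  expect_equal(out$n_pvb, 2L)
  expect_equal(out$burden_per_min, 1)
  expect_true(all(abs(out$pvb_times - pvb) < 1))
  # no non-paced beats -> zero
  paced <- data.frame(time_ms = sinus, paced = TRUE)
  expect_equal(compute_pvb_burden(paced, 2)$burden_per_min, 0)
  # doubling the window with the same events halves the burden
  expect_equal(compute_pvb_burden(beats, 4)$burden_per_min, 0.5)
})

test_that("ectopy injection obeys rate, refractoriness and suppression", {
  g <- small_geometry()
  origin <- which(g$border_zone_mask, arr.ind = TRUE)[1, ]
  expect_length(inject_ectopy(g, 0, origin, seed = 1)$times_ms, 0L)
  scar_site <- which(g$scar_mask, arr.ind = TRUE)[1, ]
  expect_error(inject_ectopy(g, 1, scar_site), "scar")
  # dense pacing suppresses every candidate
  paced <- seq(0, 60000, by = 150)
  sup <- inject_ectopy(g, 30, origin, duration_min = 1,
                       paced_times = paced, refractory_ms = 200, seed = 3)
  expect_length(sup$times_ms, 0L)
  expect_gt(length(sup$candidates_ms), 0L)
  # free-running: recovered rate near nominal (acceptance runs 200 seeds)
  rates <- vapply(1:60, function(s)
    length(inject_ectopy(g, 0.55, origin, duration_min = 20,
                         seed = s)$times_ms) / 20, numeric(1))
  expect_lt(abs(mean(rates) - 0.55) / 0.55, 0.1)
})

test_that("episode classification follows the 3-beat, organized, 30 s rules", {
  base_cl <- 300
  # two rapid beats then sinus: not an episode
  e2 <- classify_episode(c(0, 130, 260, 560, 860), base_cl)
  expect_identical(e2$kind, "none")
  # 12 beats at constant 130 ms: organized VT
  vt <- classify_episode(cumsum(c(0, rep(130, 11))), base_cl)
  expect_identical(vt$kind, "vt")
  expect_true(vt$organized)
  expect_false(vt$sustained)
  # rapid but disorganized cycles: VF
  set.seed(4)
  vf <- classify_episode(cumsum(c(0, runif(11, 60, 140))), base_cl)
  expect_identical(vf$kind, "vf")
  # sustained flag at >= 30 s
  sus <- classify_episode(cumsum(c(0, rep(130, 260))), base_cl)
  expect_true(sus$sustained)
  # invariance to a uniform time shift
  vt2 <- classify_episode(1e5 + cumsum(c(0, rep(130, 11))), base_cl)
  expect_identical(vt2$kind, vt$kind)
  expect_equal(vt2$n_beats, vt$n_beats)
})

test_that("raising cycle variability switches VT to VF, never to none", {
  base_cl <- 300
  set.seed(8)
  for (jit in c(0.01, 0.05, 0.1, 0.2, 0.35)) {
    cyc <- pmax(50, rnorm(15, 130, jit * 130))
    e <- classify_episode(cumsum(c(0, cyc)), base_cl)
    expect_true(e$kind %in% c("vt", "vf"))
  }
})

test_that("inducibility bookkeeping reproduces programmed outcomes", {
  mk <- function(h, cond, induced) list(
    heart_id = h, condition = cond,
    episodes = if (induced)
      list(classify_episode(cumsum(c(0, rep(130, 11))), 300)) else list())
  recs <- c(lapply(1:14, function(h) mk(h, "baseline", h <= 10)),
            lapply(1:14, function(h) mk(h, "drug", h <= 2)))
  tab <- assess_inducibility(recs)
  bl <- tab[tab$condition == "baseline", ]
  dr <- tab[tab$condition == "drug", ]
  expect_equal(100 * mean(bl$induced), 71.4, tolerance = 0.01)
  expect_equal(100 * mean(dr$induced), 14.3, tolerance = 0.01)
  # a heart missing one condition is excluded
  recs2 <- recs[-15]  # drop heart 1's drug exam
  expect_message(tab2 <- assess_inducibility(recs2), "excluding")
  expect_false(1 %in% tab2$heart_id)
})
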