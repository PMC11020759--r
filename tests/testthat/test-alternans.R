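feature_row <- function(col, beat, duration, amplitude = duration) {
  data.frame(row = 1L, col = col, beat = beat, t_act = beat * 300,
             duration = duration, amplitude = amplitude, di = NA_real_,
             stim_index = beat, valid = TRUE)
}
seq_features <- function(values, col = 1L, amplitudes = values)
  do.call(rbind, Map(feature_row, col, seq_along(values), values,
                     amplitudes))

test_that("the 10 ms APD rule and 5% calcium rule classify exactly", {
  # constant sequence: delta 0, not significant
  m0 <- compute_alternans_map(seq_features(c(120, 120, 120, 120)))
  expect_equal(m0$delta[1, 1], 0)
  expect_false(m0$significant[1, 1])
  # 130/115 alternation: delta 15 ms, significant
  m1 <- compute_alternans_map(seq_features(c(130, 115, 130, 115)))
  expect_equal(m1$delta[1, 1], 15)
  expect_true(m1$significant[1, 1])
  # exactly 10 ms is NOT more than 10 ms
  m10 <- compute_alternans_map(seq_features(c(125, 115, 125, 115)))
  expect_false(m10$significant[1, 1])
  # calcium amplitude: 1.00/0.96 is ~4.1%, below the 5% rule
  c1 <- compute_alternans_map(seq_features(rep(120, 4),
                                           amplitudes = c(1, 0.96, 1, 0.96)),
                              channel = "ca_amplitude")
  expect_false(c1$significant[1, 1])
  expect_equal(c1$delta[1, 1], 100 * 0.04 / 0.98, tolerance = 1e-9)
  # 1.00/0.94 is ~6.2%, significant
  c2 <- compute_alternans_map(seq_features(rep(120, 4),
                                           amplitudes = c(1, 0.94, 1, 0.94)),
                              channel = "ca_amplitude")
  expect_true(c2$significant[1, 1])
  expect_equal(c2$delta[1, 1], 100 * 0.06 / 0.97, tolerance = 1e-9)
})

test_that("fewer than four beats invalidates a site", {
  m <- compute_alternans_map(seq_features(c(130, 115, 130)))
  expect_true(is.na(m$delta[1, 1]))
})

test_that("swapping beat parity flips signs but not significance", {
  f <- rbind(seq_features(c(130, 114, 130, 114, 130, 114), col = 1L),
             seq_features(c(112, 130, 112, 130, 112, 130), col = 2L))
  m <- compute_alternans_map(f)
  f2 <- f[f$beat > 1, ]
  f2$beat <- f2$beat - 1L
  m2 <- compute_alternans_map(f2)
  expect_equal(m2$parity_sign[1, 1:2], -m$parity_sign[1, 1:2])
  expect_equal(m2$significant, m$significant)
})

test_that("spatial patterns classify with nodal lines on the zero contour", {
  mk_map <- function(left, right) {
    f <- do.call(rbind, lapply(1:12, function(r)
      do.call(rbind, lapply(1:12, function(cc) {
        v <- if (cc <= 6) left else right
        d <- seq_features(120 + c(v, -v, v, -v) / 2, col = cc)
        d$row <- r
        d
      }))))
    compute_alternans_map(f)
  }
  conc <- classify_spatial_pattern(mk_map(15, 15))
  expect_identical(conc$pattern, "concordant")
  expect_length(conc$nodal_lines, 0)
  disc <- classify_spatial_pattern(mk_map(15, -15))
  expect_identical(disc$pattern, "discordant")
  expect_gte(length(disc$nodal_lines), 1)
  xs <- unlist(lapply(disc$nodal_lines, function(d) d$x))
  expect_true(all(abs(xs - 6.5) <= 1))
  # global sign flip leaves the nodal line in place
  disc2 <- classify_spatial_pattern(mk_map(-15, 15))
  xs2 <- unlist(lapply(disc2$nodal_lines, function(d) d$x))
  expect_equal(sort(xs), sort(xs2), tolerance = 1e-9)
  none <- classify_spatial_pattern(mk_map(4, -4))
  expect_identical(none$pattern, "none")
})

test_that("discordant cable nodal line is recovered within 2 px of truth", {
  cab <- run_restitution_cable(discordant_map(), pcl = 130, n_beats = 20,
                               n_sites = 40)
  tru <- cable_alternans_truth(cab, discard = 8)
  s <- sign(tru$delta_apd)
  cross <- which(s[-length(s)] * s[-1] < 0)
  truth_nodes <- cross + abs(tru$delta_apd[cross]) /
    (abs(tru$delta_apd[cross]) + abs(tru$delta_apd[cross + 1]))
  cmv <- cable_to_movie(cab, n_rows = 8, noise_sd = 0.02, seed = 2)
  f <- extract_features(cmv$vm, stim_times = cmv$stim_times)
  am <- compute_alternans_map(f, min_beat_index = 9L)
  cp <- classify_spatial_pattern(am)
  expect_identical(cp$pattern, "discordant")
  det <- vapply(cp$nodal_lines, function(d) mean(d$x), numeric(1))
  # every detected line lies within 2 px of a truth node
  for (x in det) expect_lte(min(abs(truth_nodes - x)), 2)
  # the main truth nodes are each matched by a detected line
  for (tn in truth_nodes)
    expect_lte(min(abs(det - tn)), 2)
})

test_that("threshold scanning finds the bifurcation and handles edge cases", {
  map <- restitution_map()  # analytic bifurcation 132.1 ms
  thr <- find_alternans_threshold(cardiomap:::cable_provider(map))
  expect_identical(thr$status, "found")
  expect_lte(abs(thr$threshold_pcl - restitution_bifurcation_pcl(map)), 10)
  # flattened (drug-like) restitution: threshold strictly lower
  mapd <- restitution_map(apd_max = 136, amplitude_a = 45,
                          tau_restitution = 26)
  thrd <- find_alternans_threshold(cardiomap:::cable_provider(mapd))
  expect_lt(thrd$threshold_pcl, thr$threshold_pcl)
  # a stable map in range: no threshold
  maps <- restitution_map(apd_max = 60, amplitude_a = 20,
                          tau_restitution = 40)
  thrs <- find_alternans_threshold(cardiomap:::cable_provider(maps))
  expect_true(is.na(thrs$threshold_pcl))
  expect_identical(thrs$status, "no_threshold_in_range")
})
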