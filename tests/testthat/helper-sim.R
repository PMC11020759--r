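# shared miniature fixtures, generated once per test run

small_geometry <- function(scar = TRUE)
  tissue_geometry(20, 20,
                  scar_mask = if (scar) disc_scar(20, 20, c(6, 6), 3)
                  else NULL,
                  border_zone_px = 2L)

small_burst_protocol <- function(n_beats = 6L, pcl = 300)
  pacing_protocol(kind = "burst", s1_count = n_beats, s1s1 = pcl,
                  stim_site = c(10L, 17L),
                  steady_beats_before_acquisition = 2L)

# cached noisy reference simulation (scar, 6 recorded beats at PCL 300)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_tissue(small_geometry(), cell_model_params(),
                                small_burst_protocol(), noise_snr = 20,
                                seed = 42L)
    cache
  }
})

# cached noise-free twin
small_sim_clean <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_tissue(small_geometry(), cell_model_params(),
                                small_burst_protocol(), noise_snr = Inf,
                                seed = 42L)
    cache
  }
})

# discordant-alternans cable at PCL 130 (CV restitution on), 21-beat train
discordant_map <- function()
  restitution_map(apd_max = 127, amplitude_a = 50, tau_restitution = 12,
                  cv_restitution = list(cv0 = 0.33, cv_b = 0.6,
                                        cv_tau = 15))

# triangular test beat: instant rise to 1 at t_rise, linear fall to 0 over
# fall_ms; frame interval 2 ms
triangular_trace <- function(t_rise = 100, fall_ms = 200, total_ms = 600,
                             dt = 2) {
  tt <- seq(0, total_ms, by = dt)
  ifelse(tt < t_rise, 0,
         pmax(0, 1 - (tt - t_rise) / fall_ms))
}

expect_no_sites_error <- function(expr)
  expect_error(expr, class = "cardiomap_insufficient_sites")

# independent oracle: full hypergeometric enumeration from binomial
# coefficients, no shared code with fisher_exact
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0 || r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  p <- choose(c1, xs) * choose(n - c1, r1 - xs) / choose(n, r1)
  pobs <- choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  min(sum(p[p <= pobs * (1 + 1e-7)]), 1)
}
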