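test_that("paired t-test matches closed-form and numeric-integration oracle", {
  # identical samples: t = 0, p = 1 (degenerate, warned)
  expect_warning(r0 <- paired_t_test(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # diffs 1, 2, 3: t = 2 / (1 / sqrt(3)) = 3.464, df = 2
  r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  # oracle: numeric integration of the t density with 2 df
  dens <- function(x, df) gamma((df + 1) / 2) / (sqrt(df * pi) *
    gamma(df / 2)) * (1 + x^2 / df)^(-(df + 1) / 2)
  p_oracle <- 2 * integrate(dens, lower = r$t, upper = Inf, df = 2)$value
  expect_equal(r$p, p_oracle, tolerance = 1e-8)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  # cross-check against the reference implementation
  set.seed(11)
  a <- rnorm(20, 10, 2); b <- rnorm(20, 9, 2)
  mine <- paired_t_test(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("power at a programmed shift is adequate", {
  set.seed(21)
  hits <- vapply(1:500, function(i) {
    a <- rnorm(14, 123, 8)
    b <- a + rnorm(14, 9.5, 3)   # programmed paired shift
    paired_t_test(b, a)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("paired t p-values are uniform under the null", {
  set.seed(31)
  ps <- vapply(1:2000, function(i) {
    a <- rnorm(12); b <- rnorm(12)
    paired_t_test(a, b)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("fisher_exact equals enumeration exactly for all tables N <= 40", {
  worst <- 0
  for (n in 0:40) for (a in 0:n) for (b in 0:(n - a)) {
    remaining <- n - a - b
    for (cc in 0:remaining) {
      d <- remaining - cc
      worst <- max(worst, abs(fisher_exact(a, b, cc, d) -
                                fisher_oracle(a, b, cc, d)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("the study's inducibility table gives the printed-count p-value", {
  p <- fisher_exact(rbind(c(10, 4), c(2, 12)))
  expect_equal(p, fisher_oracle(10, 4, 2, 12), tolerance = 1e-12)
  expect_equal(p, fisher.test(rbind(c(10, 4), c(2, 12)))$p.value,
               tolerance = 1e-12)
  expect_equal(p, 0.00633, tolerance = 1e-3)
  # symmetries
  expect_equal(fisher_exact(4, 10, 12, 2), p, tolerance = 1e-14)
  expect_equal(fisher_exact(2, 12, 10, 4), p, tolerance = 1e-14)
  # balanced table and degenerate margins
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
  expect_equal(fisher_exact(0, 0, 3, 4), 1)
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
})

test_that("study reports summarize, print and serialize deterministically", {
  per_heart <- data.frame(
    heart_id = 1:6,
    apd80_baseline = c(120, 118, 125, 122, 119, 124),
    apd80_drug = c(130, 127, 133, 131, 128, 134),
    induced_baseline = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    induced_drug = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  rep1 <- summarize_study(per_heart, c(apd80 = "APD80 (ms)"),
                          settings = list(alpha = 0.05))
  expect_identical(rep1$metrics$apd80$direction, "increase")
  expect_lt(rep1$metrics$apd80$p, 0.05)
  expect_identical(rep1$inducibility$direction, "decrease")
  expect_equal(rep1$settings$alpha, 0.05)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep1, d1)
  write_report(summarize_study(per_heart, c(apd80 = "APD80 (ms)"),
                               settings = list(alpha = 0.05)), d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  back <- jsonlite::read_json(file.path(d1, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$metrics$apd80$p, rep1$metrics$apd80$p,
               tolerance = 1e-12)
  # empty metric set: empty but valid report
  rep0 <- summarize_study(per_heart[, 1, drop = FALSE], character(0))
  expect_length(rep0$metrics, 0L)
})
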