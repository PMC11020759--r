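#' Paired Student's t-test
#'
#' Two-sided paired t-test computed from first principles:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = value_a - value_b` and
#' `df = n - 1`; the p-value comes from the t distribution. When every
#' difference is identical the sampling SD is zero and the p-value
#' degenerates to 0 (nonzero shift) or 1 (no shift), with a warning.
#'
#' @param value_a,value_b paired measurements (same hearts, two conditions);
#'   pairs with a missing member are dropped.
#' @return list `t`, `df`, `p`, `mean_diff`, `sd_diff`, `n`.
#' @export
paired_t_test <- function(value_a, value_b) {
  if (length(value_a) != length(value_b))
    stop("paired samples must have equal length")
  ok <- !is.na(value_a) & !is.na(value_b)
  d <- value_a[ok] - value_b[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    warning("zero variance of paired differences; p is degenerate")
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1,
                p = if (m == 0) 1 else 0, mean_diff = m, sd_diff = 0, n = n))
  }
  tstat <- m / (s / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), df = n - 1),
       mean_diff = m, sd_diff = s, n = n)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration with the
#' point-probability rule: with margins fixed, p is the sum of the
#' probabilities of all tables whose point probability does not exceed that
#' of the observed table (within a 1e-7 relative guard against floating-
#' point ties). Probabilities are computed from log binomial coefficients.
#' Degenerate margins (an empty row or column) give p = 1.
#'
#' @param table 2 x 2 integer matrix `rbind(c(a, b), c(c, d))` (condition x
#'   outcome), or four counts `a, b, c, d`.
#' @param b,c,d optional counts when `table` is given as `a`.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    a <- table[1, 1]; bb <- table[1, 2]; cc <- table[2, 1]; dd <- table[2, 2]
  } else {
    a <- table; bb <- b; cc <- c; dd <- d
  }
  cnt <- c(a, bb, cc, dd)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  r1 <- a + bb; r2 <- cc + dd; c1 <- a + cc; c2 <- bb + dd
  n <- r1 + r2
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  # P(X = x) for x successes in row 1, margins fixed
  logp <- function(x)
    lchoose(c1, x) + lchoose(c2, r1 - x) - lchoose(n, r1)
  xs <- max(0, r1 - c2):min(r1, c1)
  lp <- logp(xs)
  lobs <- logp(a)
  sum(exp(lp[lp <= lobs + 1e-7])) |> min(1)
}

#' Summarize a two-condition study into a report
#'
#' Builds the cross-condition report: per-metric mean +/- SD and paired
#' t-test for continuous metrics, counts and Fisher's exact test for
#' inducibility, plus the direction of each effect. All analysis settings
#' passed in `settings` are echoed for provenance. Deterministic given its
#' inputs.
#'
#' @param per_heart data.frame with one row per heart and columns
#'   `heart_id`, then `<metric>_baseline` / `<metric>_drug` pairs for each
#'   continuous metric, and logical `induced_baseline` / `induced_drug`.
#' @param metrics named character vector: names are metric column stems,
#'   values are human-readable labels with units.
#' @param settings list of analysis settings to echo.
#' @return an object of class `study_report`: list with `metrics` (named
#'   list of per-metric summaries), `inducibility`, `n_hearts`, `settings`.
#' @export
summarize_study <- function(per_heart, metrics, settings = list()) {
  out <- list()
  for (stem in names(metrics)) {
    va <- per_heart[[paste0(stem, "_baseline")]]
    vb <- per_heart[[paste0(stem, "_drug")]]
    if (is.null(va) || is.null(vb)) next
    tt <- tryCatch(paired_t_test(vb, va),  # drug - baseline
                   error = function(e) list(
                     t = NA_real_, df = NA_integer_, p = NA_real_,
                     mean_diff = mean(vb, na.rm = TRUE) -
                       mean(va, na.rm = TRUE),
                     sd_diff = NA_real_, n = sum(!is.na(va) & !is.na(vb))))
    out[[stem]] <- list(
      label = unname(metrics[[stem]]),
      baseline_mean = mean(va, na.rm = TRUE),
      baseline_sd = sd(va, na.rm = TRUE),
      drug_mean = mean(vb, na.rm = TRUE), drug_sd = sd(vb, na.rm = TRUE),
      mean_change = tt$mean_diff,
      direction = if (tt$mean_diff > 0) "increase" else
        if (tt$mean_diff < 0) "decrease" else "none",
      t = tt$t, df = tt$df, p = tt$p, n = tt$n)
  }
  ind <- NULL
  if (!is.null(per_heart$induced_baseline)) {
    ia <- sum(per_heart$induced_baseline); na <- nrow(per_heart)
    ib <- sum(per_heart$induced_drug); nb <- nrow(per_heart)
    tab <- rbind(c(ia, na - ia), c(ib, nb - ib))
    ind <- list(baseline_induced = ia, baseline_n = na,
                baseline_pct = 100 * ia / na,
                drug_induced = ib, drug_n = nb, drug_pct = 100 * ib / nb,
                direction = if (ib < ia) "decrease" else
                  if (ib > ia) "increase" else "none",
                fisher_p = fisher_exact(tab))
  }
  structure(list(metrics = out, inducibility = ind,
                 n_hearts = nrow(per_heart), settings = settings,
                 per_heart = per_heart),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d hearts\n", x$n_hearts))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-28s %7.2f +/- %5.2f -> %7.2f +/- %5.2f  (%s, p = %.3g)\n",
                m$label, m$baseline_mean, m$baseline_sd, m$drug_mean,
                m$drug_sd, m$direction, m$p))
  }
  if (!is.null(x$inducibility)) {
    i <- x$inducibility
    cat(sprintf("  %-28s %d/%d (%.0f%%) -> %d/%d (%.0f%%)  (%s, Fisher p = %.3g)\n",
                "VT/VF inducibility", i$baseline_induced, i$baseline_n,
                i$baseline_pct, i$drug_induced, i$drug_n, i$drug_pct,
                i$direction, i$fisher_p))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `report.json` (machine-readable, schema-stable) and `report.txt`
#' (the printed rendering). No timestamps are written, so identical inputs
#' give byte-identical files.
#'
#' @param report a [summarize_study()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(metrics = report$metrics,
                  inducibility = report$inducibility,
                  n_hearts = report$n_hearts, settings = report$settings)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  if (!is.null(report$per_heart))
    write.csv(report$per_heart, file.path(dir, "per_heart.csv"),
              row.names = FALSE)
  invisible(dir)
}
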