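# run code with a locally-set RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# condition constructor for the analyzable-sites rule shared by several stages
insufficient_sites_error <- function(n_valid, min_sites) {
  stop(structure(class = c("cardiomap_insufficient_sites", "error",
                           "condition"),
                 list(message = sprintf(
                   "insufficient analyzable sites: %d valid, %d required",
                   n_valid, min_sites), call = sys.call(-1))))
}

# linear interpolation of the time at which y crosses `level`, scanning
# downward between consecutive samples; returns NA if never crossed
cross_down_time <- function(t, y, level, from = 1L) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- from:(n - 1L)
  hit <- idx[y[idx] >= level & y[idx + 1L] < level]
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  t[i] + (t[i + 1L] - t[i]) * (y[i] - level) / (y[i] - y[i + 1L])
}

#' Wrap angles to (-pi, pi]
#' @param x angles in radians.
#' @export
wrap_angle <- function(x) Arg(exp(1i * x))

# centered moving average with reflected edges (zero phase, no frame shift)
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  xp <- c(rev(x[seq_len(half) + 1L]), x, rev(x[(n - half):(n - 1L)]))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[
    (half + 1L):(half + n)]
}

# 3x3 NA-aware mean smoothing of a matrix
smooth_matrix <- function(m) {
  H <- nrow(m); W <- ncol(m)
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (di in -1:1) for (dj in -1:1) {
    si <- max(1, 1 - di):min(H, H - di)
    sj <- max(1, 1 - dj):min(W, W - dj)
    v <- m[si, sj, drop = FALSE]
    ok <- !is.na(v)
    a <- acc[si + di, sj + dj, drop = FALSE]
    a[ok] <- a[ok] + v[ok]
    acc[si + di, sj + dj] <- a
    cc <- cnt[si + di, sj + dj, drop = FALSE]
    cc[ok] <- cc[ok] + 1
    cnt[si + di, sj + dj] <- cc
  }
  out <- acc / cnt
  out[cnt == 0] <- NA
  out
}

# connected components (4-neighbour) of a logical matrix; returns integer
# labels, 0 = background
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx <- which(mask)
  for (k in idx) {
    if (lab[k] > 0L) next
    cur <- cur + 1L
    queue <- k
    lab[k] <- cur
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      i <- (p - 1L) %% H + 1L; j <- (p - 1L) %/% H + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1L || nb[1] > H || nb[2] < 1L || nb[2] > W) next
        q <- nb[1] + (nb[2] - 1L) * H
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}
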