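#' Write an optical movie to disk
#'
#' Two formats are supported. `"tiff_stack"`: a multi-page TIFF (one 32-bit
#' float page per frame) plus a JSON sidecar `<path>.json` holding the
#' mandatory metadata. `"bundle"`: a flat self-describing container directory
#' with a `manifest.json` and raw little-endian float64 datasets, which
#' round-trips losslessly and can also hold a full simulation output (see
#' [write_bundle()]).
#'
#' @param movie an [optical_movie()].
#' @param path file path (TIFF) or directory (bundle).
#' @param format `"tiff_stack"` or `"bundle"`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, format = c("tiff_stack", "bundle")) {
  stopifnot(inherits(movie, "optical_movie"))
  format <- match.arg(format)
  if (format == "tiff_stack") {
    d <- dim(movie$data)
    # TIFF pages hold the data rescaled to [0, 1] at 32-bit depth; the
    # affine scale is stored in the sidecar so reads restore original units
    lo <- min(movie$data); hi <- max(movie$data)
    sc <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[3]), function(t) (movie$data[, , t] - lo) / sc)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    meta <- list(frame_interval_ms = movie$frame_interval,
                 pixel_pitch_mm = movie$pixel_pitch,
                 channel = movie$channel, polarity = movie$polarity,
                 data_min = lo, data_scale = sc,
                 metadata = movie$metadata)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    write_bundle(setNames(list(movie), movie$channel), path)
  }
  invisible(path)
}

#' Read an optical movie
#'
#' Missing mandatory metadata (frame interval, pixel pitch, channel,
#' polarity) is an explicit error naming the field, never a silent default.
#'
#' @param path file path (TIFF stack with `<path>.json` sidecar) or bundle
#'   directory.
#' @param format `"tiff_stack"` or `"bundle"`.
#' @param channel for bundles holding several channels: which one to read.
#' @return an [optical_movie()].
#' @export
read_movie <- function(path, format = c("tiff_stack", "bundle"),
                       channel = NULL) {
  format <- match.arg(format)
  if (format == "tiff_stack") {
    if (!file.exists(path)) stop("file not found: ", path)
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("metadata sidecar not found: ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (f in c("frame_interval_ms", "pixel_pitch_mm", "channel", "polarity"))
      if (is.null(meta[[f]]))
        stop("metadata field missing from sidecar: ", f)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    lo <- meta$data_min %||% 0
    sc <- meta$data_scale %||% 1
    data <- array(NA_real_, dim = c(d[1], d[2], length(pages)))
    for (t in seq_along(pages)) data[, , t] <- pages[[t]] * sc + lo
    optical_movie(data, meta$frame_interval_ms, meta$pixel_pitch_mm,
                  channel = meta$channel, polarity = meta$polarity,
                  metadata = as.list(meta$metadata))
  } else {
    b <- read_bundle(path)
    movies <- Filter(function(x) inherits(x, "optical_movie"), b)
    if (!length(movies)) stop("bundle contains no movie dataset: ", path)
    if (is.null(channel)) movies[[1]] else {
      hit <- which(vapply(movies, function(m) m$channel, "") == channel)
      if (!length(hit)) stop("bundle has no channel '", channel, "'")
      movies[[hit[1]]]
    }
  }
}

#' Write a simulation bundle
#'
#' Flat container: a directory holding `manifest.json` plus one raw
#' little-endian float64 `.bin` file per array dataset. Movies keep their
#' mandatory attributes in the manifest; data frames are stored as CSV.
#'
#' @param datasets named list of [optical_movie()], numeric arrays/vectors,
#'   or data.frames (e.g. `list(vm =, cai =, pseudo_ecg =, stimulus_log =)`).
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(datasets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "cardiomap-bundle", version = 1L,
                   datasets = list())
  for (nm in names(datasets)) {
    x <- datasets[[nm]]
    if (inherits(x, "optical_movie")) {
      fn <- paste0(nm, ".bin")
      con <- file(file.path(dir, fn), "wb")
      writeBin(as.vector(x$data), con, size = 8, endian = "little")
      close(con)
      manifest$datasets[[nm]] <- list(
        kind = "movie", file = fn, dim = dim(x$data),
        frame_interval_ms = x$frame_interval, pixel_pitch_mm = x$pixel_pitch,
        channel = x$channel, polarity = x$polarity, metadata = x$metadata)
    } else if (is.data.frame(x)) {
      fn <- paste0(nm, ".csv")
      write.csv(x, file.path(dir, fn), row.names = FALSE)
      manifest$datasets[[nm]] <- list(kind = "table", file = fn)
    } else if (is.numeric(x)) {
      fn <- paste0(nm, ".bin")
      con <- file(file.path(dir, fn), "wb")
      writeBin(as.vector(x), con, size = 8, endian = "little")
      close(con)
      manifest$datasets[[nm]] <- list(kind = "array", file = fn,
                                      dim = dim(x) %||% length(x))
    } else stop("unsupported dataset type for '", nm, "'")
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulation bundle written by [write_bundle()]
#' @param dir bundle directory.
#' @return named list of datasets.
#' @export
read_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a bundle (no manifest.json): ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  out <- list()
  for (nm in names(manifest$datasets)) {
    ds <- manifest$datasets[[nm]]
    fp <- file.path(dir, ds$file)
    if (!file.exists(fp)) stop("bundle dataset file missing: ", fp)
    if (ds$kind == "table") {
      out[[nm]] <- utils::read.csv(fp)
    } else {
      n <- prod(unlist(ds$dim))
      con <- file(fp, "rb")
      v <- readBin(con, "double", n = n, size = 8, endian = "little")
      close(con)
      if (length(v) != n)
        stop("bundle dataset '", nm, "': stored length ", length(v),
             " does not match declared dim")
      if (ds$kind == "movie") {
        for (f in c("frame_interval_ms", "pixel_pitch_mm", "channel",
                    "polarity"))
          if (is.null(ds[[f]])) stop("metadata field missing: ", f)
        out[[nm]] <- optical_movie(array(v, dim = unlist(ds$dim)),
                                   ds$frame_interval_ms, ds$pixel_pitch_mm,
                                   channel = ds$channel,
                                   polarity = ds$polarity,
                                   metadata = as.list(ds$metadata))
      } else {
        dim_ <- unlist(ds$dim)
        out[[nm]] <- if (length(dim_) > 1) array(v, dim = dim_) else v
      }
    }
  }
  out
}
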