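#' Optical-mapping movie container
#'
#' One channel's fluorescence stack with its mandatory acquisition metadata.
#' Silent unit errors are the dominant failure mode in optical mapping, so
#' `frame_interval`, `pixel_pitch`, `channel` and `polarity` are required and
#' validated; readers refuse files that lack them.
#'
#' @param data numeric array `height x width x frames` (at least 2 frames).
#' @param frame_interval frame interval, ms.
#' @param pixel_pitch pixel size, mm.
#' @param channel `"vm"` (membrane potential) or `"cai"` (intracellular Ca).
#' @param polarity `"upright"` (depolarisation increases fluorescence) or
#'   `"inverted"` (voltage-sensitive dye convention).
#' @param metadata free-form provenance list.
#' @return an object of class `optical_movie`.
#' @export
optical_movie <- function(data, frame_interval = 2, pixel_pitch = 0.25,
                          channel = c("vm", "cai"),
                          polarity = c("upright", "inverted"),
                          metadata = list()) {
  channel <- match.arg(channel)
  polarity <- match.arg(polarity)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a height x width x frames array")
  if (dim(data)[3] < 2L) stop("movie must have at least 2 frames (T >= 2)")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be positive")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  structure(list(data = data, frame_interval = frame_interval,
                 pixel_pitch = pixel_pitch, channel = channel,
                 polarity = polarity, metadata = metadata),
            class = "optical_movie")
}

#' @export
print.optical_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<optical_movie> %s channel, %d x %d px, %d frames @ %g ms (%g mm/px), polarity %s\n",
              x$channel, d[1], d[2], d[3], x$frame_interval, x$pixel_pitch,
              x$polarity))
  invisible(x)
}

#' @export
dim.optical_movie <- function(x) dim(x$data)

#' Number of frames in a movie
#' @param movie an [optical_movie()].
#' @export
n_frames <- function(movie) dim(movie$data)[3]

#' Frame time axis of a movie (ms, starting at 0)
#' @param movie an [optical_movie()].
#' @export
frame_times <- function(movie)
  (seq_len(n_frames(movie)) - 1) * movie$frame_interval

#' Extract one pixel's time course
#' @param movie an [optical_movie()].
#' @param row,col pixel coordinates.
#' @return numeric vector of length `n_frames(movie)`.
#' @export
pixel_trace <- function(movie, row, col) as.numeric(movie$data[row, col, ])
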