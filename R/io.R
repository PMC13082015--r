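#' @title Plain-format readers and writers
#' @description CSV for traces, spike trains and schedules; multipage TIFF
#'   for movies (via the optional tiff package); YAML for scene specs.
#' @name io
NULL

#' Write / read a trace as CSV
#'
#' Columns `time_s`, `value`; the sampling rate and units are stored as
#' commented header lines.
#' @param trace a `vs_trace`.
#' @param path output file.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "vs_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g units=%s", trace$rate, trace$units),
             con)
  utils::write.csv(data.frame(time_s = trace_time(trace),
                              value = trace$values),
                   con, row.names = FALSE)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  rate <- as.numeric(sub(".*rate_hz=([0-9.eE+-]+).*", "\\1", hdr))
  units <- sub(".*units=(\\S+).*", "\\1", hdr)
  d <- utils::read.csv(path, comment.char = "#")
  vs_trace(d$value, rate, units, t0 = d$time_s[1] - 0.5 / rate)
}

#' Write a spike train as CSV
#'
#' Columns `time_s`, `index`, `amplitude`; the detector name and
#' configuration are echoed in commented header lines.
#' @param train a `vs_spikes`.
#' @param path output file.
#' @export
write_spikes_csv <- function(train, path) {
  stopifnot(inherits(train, "vs_spikes"))
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- paste(names(train$config),
               vapply(train$config, function(v) paste(v, collapse = ";"),
                      character(1)),
               sep = "=", collapse = " ")
  writeLines(c(sprintf("# detector=%s threshold=%.10g", train$detector,
                       train$threshold),
               paste0("# config: ", cfg)), con)
  utils::write.csv(data.frame(time_s = train$times_s, index = train$index,
                              amplitude = train$amplitude),
                   con, row.names = FALSE)
}

#' Write / read a movie as multipage TIFF
#'
#' Requires the tiff package. Intensities are scaled to [0, 1] on write
#' (the scale factor is returned) and restored on read when given.
#' @param movie a `vs_movie`.
#' @param path file path.
#' @return the intensity scale factor used.
#' @export
write_movie_tiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF output", call. = FALSE)
  stopifnot(inherits(movie, "vs_movie"))
  sc <- max(movie$data, 1e-12)
  pages <- lapply(seq_len(dim(movie$data)[1]),
                  function(f) movie$data[f, , ] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(sc)
}

#' @rdname write_movie_tiff
#' @param rate frame rate of the stored movie (Hz).
#' @param scale intensity scale factor returned by [write_movie_tiff()].
#' @export
read_movie_tiff <- function(path, rate, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF input", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                          ncol(pages[[1]])))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * scale
  vs_movie(arr, rate)
}
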