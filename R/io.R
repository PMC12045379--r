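#' Write a movie stack as a multi-page 16-bit TIFF
#'
#' Counts are clipped to `[0, 65535]` and stored as 16-bit unsigned
#' integers, one page per frame. Exposure is not stored in the TIFF; keep
#' it in the run configuration.
#'
#' @param movie A [movie_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  pages <- lapply(seq_len(d[1]), function(t) {
    m <- movie$data[t, , ]
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    round(m) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a movie stack
#'
#' @param path TIFF file path.
#' @param exposure Exposure time per frame in seconds.
#' @param channel Channel label.
#' @return A [movie_stack()] with counts on the original 16-bit scale.
#' @export
read_movie_tiff <- function(path, exposure, channel = "ch1") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]] * 65535
  movie_stack(arr, exposure = exposure, channel = channel)
}

#' Write and read trace tables
#'
#' Traces are stored as plain CSV with documented columns (`frame`,
#' `time_s`, `intensity`, optionally `true_state`, `state`, `trace_id`).
#'
#' @param traces A data frame of one or many traces.
#' @param path CSV path.
#' @return `path` / a tibble.
#' @export
write_trace_csv <- function(traces, path) {
  write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' Serialize configuration objects to YAML
#'
#' [sim_config()], [filter_thresholds()], [burst_params()] and plain
#' lists round-trip through YAML key-value files whose keys mirror the
#' constructor arguments.
#'
#' @param config A configuration object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$.class <- class(config)[1]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @param ... Unused.
#' @export
read_config_yaml <- function(path, ...) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  if (!is.null(cls) &&
      cls %in% c("sim_config", "filter_thresholds", "burst_params"))
    do.call(cls, x)
  else x
}
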