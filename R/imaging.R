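#' Per-pixel intensity fluctuation map
#'
#' Candidate binding sites blink as probes arrive and leave, so the mean
#' absolute frame-to-frame intensity change concentrates at true sites while
#' static background averages to the noise floor. `map[p] = mean_t
#' |I(t+1, p) - I(t, p)|`.
#'
#' @param movie A [movie_stack()] (>= 2 frames).
#' @return A numeric matrix (`rows x cols`) of class `fluctuation_map`.
#' @export
compute_fluctuation_map <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  if (d[1] < 2L)
    stop_bad_config("fluctuation map needs at least 2 frames, got %d", d[1])
  dif <- abs(movie$data[-1, , , drop = FALSE] -
               movie$data[-d[1], , , drop = FALSE])
  m <- apply(dif, c(2, 3), mean)
  structure(m, class = c("fluctuation_map", class(m)))
}

#' Detect candidate binding-site ROIs on a fluctuation map
#'
#' Finds local maxima (strictly greater than all 8 neighbors) above a
#' threshold, suppresses non-maxima within `min_separation` pixels
#' (brightest first), and keeps only peaks whose 5x5 neighborhood (3x3
#' signal window plus background ring) lies fully inside the image.
#' Ordering is deterministic: descending peak value, ties broken by
#' row-major position.
#'
#' @param map A matrix, typically from [compute_fluctuation_map()].
#' @param min_separation Minimum center-to-center distance in pixels.
#' @param threshold Either a number (absolute threshold on the map) or
#'   `NULL` for the default policy: map mean + 4 robust sds
#'   (median absolute deviation scaled to the normal).
#' @param channel Channel label carried into the ROI table.
#' @return A tibble with columns `roi_id`, `row`, `col` (0-based center
#'   pixel), `peak`, `channel`. May have zero rows.
#' @export
detect_rois <- function(map, min_separation = 3, threshold = NULL,
                        channel = "ch1") {
  stopifnot(is.matrix(map))
  check_number(min_separation, "min_separation", lower = 0)
  if (is.null(threshold))
    threshold <- mean(map) + 4 * stats::mad(map)
  nr <- nrow(map); nc <- ncol(map)
  empty <- tibble::tibble(roi_id = integer(), row = integer(),
                          col = integer(), peak = numeric(),
                          channel = character())
  if (nr < 5L || nc < 5L) return(empty)
  # interior such that the 5x5 neighborhood fits (0-based coords 2..n-3)
  core <- map[3:(nr - 2), 3:(nc - 2), drop = FALSE]
  is_max <- core > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- map[(3 + dr):(nr - 2 + dr), (3 + dc):(nc - 2 + dc), drop = FALSE]
    is_max <- is_max & (core > nb | (core == nb & (dr > 0 | (dr == 0 & dc > 0))))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- tibble::tibble(
    row = idx[, 1] + 1L,   # back to 0-based full-image coordinates
    col = idx[, 2] + 1L,
    peak = core[idx]
  )
  cand <- cand[order(-cand$peak, cand$row, cand$col), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand$row[j] - cand$row[i])^2 + (cand$col[j] - cand$col[i])^2
      keep[j][d2 < min_separation^2] <- FALSE
    }
  }
  out <- cand[keep, ]
  tibble::tibble(roi_id = seq_len(nrow(out)), row = as.integer(out$row),
                 col = as.integer(out$col), peak = out$peak,
                 channel = channel)
}

#' Extract a background-subtracted intensity trace from an ROI
#'
#' Per frame, sums the 3x3 pixel window centered on the ROI and subtracts
#' 9 times the local background, estimated as the median of the 16-pixel
#' ring of the surrounding 5x5 neighborhood. The ring median resists
#' bleed-through from neighboring spots.
#'
#' @param movie A [movie_stack()].
#' @param roi A one-row data frame with 0-based `row`, `col` (e.g. one row
#'   of [detect_rois()] output), or a length-2 numeric `c(row, col)`.
#' @return A tibble with columns `frame`, `time_s`, `intensity`.
#' @export
extract_trace <- function(movie, roi) {
  stopifnot(inherits(movie, "movie_stack"))
  if (is.data.frame(roi)) {
    stopifnot(nrow(roi) == 1L)
    r0 <- roi$row[1]; c0 <- roi$col[1]
  } else {
    r0 <- roi[1]; c0 <- roi[2]
  }
  d <- dim(movie$data)
  if (r0 < 2 || c0 < 2 || r0 > d[2] - 3 || c0 > d[3] - 3)
    stop_bad_config("ROI at (%d, %d) is too close to the border for a 5x5 neighborhood",
                    r0, c0)
  ri <- r0 + 1L; ci <- c0 + 1L  # 1-based
  block5 <- movie$data[, (ri - 2):(ri + 2), (ci - 2):(ci + 2), drop = FALSE]
  block3 <- movie$data[, (ri - 1):(ri + 1), (ci - 1):(ci + 1), drop = FALSE]
  sig <- apply(block3, 1, sum)
  flat5 <- matrix(block5, nrow = d[1])
  ring_cols <- setdiff(seq_len(25), c(7, 8, 9, 12, 13, 14, 17, 18, 19))
  bg <- apply(flat5[, ring_cols, drop = FALSE], 1, median)
  tibble::tibble(frame = seq_len(d[1]),
                 time_s = (seq_len(d[1]) - 1) * movie$exposure,
                 intensity = sig - 9 * bg)
}

#' Match ROIs across two registered channels
#'
#' One-to-one greedy nearest-neighbor matching: candidate pairs within
#' `radius` are accepted closest first, each ROI used at most once. Ties in
#' distance are broken by the (a, b) index pair for determinism.
#'
#' @param a,b ROI tibbles from [detect_rois()] (need `roi_id`, `row`,
#'   `col`).
#' @param radius Maximum matching distance in pixels (>= 0).
#' @return A list with `pairs` (tibble: `roi_a`, `roi_b`, `distance`),
#'   `unmatched_a`, `unmatched_b` (integer roi_id vectors).
#' @export
colocalize_rois <- function(a, b, radius = 2) {
  check_number(radius, "radius", lower = 0)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(list(pairs = tibble::tibble(roi_a = integer(), roi_b = integer(),
                                       distance = numeric()),
                unmatched_a = a$roi_id, unmatched_b = b$roi_id))
  dm <- outer(a$row, b$row, "-")^2 + outer(a$col, b$col, "-")^2
  cand <- which(dm <= radius^2, arr.ind = TRUE)
  ord <- order(dm[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pairs[[length(pairs) + 1L]] <-
      c(a$roi_id[i], b$roi_id[j], sqrt(dm[i, j]))
  }
  pairs <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    tibble::tibble(roi_a = as.integer(m[, 1]), roi_b = as.integer(m[, 2]),
                   distance = m[, 3])
  } else {
    tibble::tibble(roi_a = integer(), roi_b = integer(),
                   distance = numeric())
  }
  list(pairs = pairs,
       unmatched_a = a$roi_id[!used_a],
       unmatched_b = b$roi_id[!used_b])
}
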