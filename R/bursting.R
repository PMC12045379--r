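#' Burst-detection parameters
#'
#' @param max_isi_in_burst Maximal inter-spike interval (s) allowed inside
#'   a burst; default 40.
#' @param alpha Rank-Surprise acceptance cutoff (natural-log scale;
#'   `alpha = 3` corresponds to p < exp(-3) ~ 0.05); default 3.
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(max_isi_in_burst = 40, alpha = 3) {
  check_number(max_isi_in_burst, "max_isi_in_burst", lower = 1e-12,
               allow_inf = TRUE)
  check_number(alpha, "alpha", lower = 1e-12)
  structure(list(max_isi_in_burst = max_isi_in_burst, alpha = alpha),
            class = "burst_params")
}

#' Inter-spike intervals of a binding-event train
#'
#' `ISI_k` is the gap between consecutive binding events: start of event
#' k+1 minus end of event k. This matches the unbound dwell times of the
#' underlying trace. Fewer than two events yield zero ISIs.
#'
#' @param events Tibble of binding-event intervals with `start_s`, `end_s`,
#'   optionally `molecule` (grouped per molecule) and `state` (rows with
#'   `state != 1` are dropped, so a run table from [extract_dwells()]-style
#'   events can be passed directly).
#' @return A tibble with `molecule`, `isi_index`, `isi_s`.
#' @export
compute_isis <- function(events) {
  stopifnot(all(c("start_s", "end_s") %in% names(events)))
  if ("state" %in% names(events))
    events <- events[events$state == 1L, , drop = FALSE]
  if (!"molecule" %in% names(events)) events$molecule <- 1L
  events |>
    dplyr::group_by(.data$molecule) |>
    dplyr::arrange(.data$start_s, .by_group = TRUE) |>
    dplyr::reframe(isi_s = if (dplyr::n() >= 2)
      .data$start_s[-1] - .data$end_s[-dplyr::n()] else numeric(0)) |>
    dplyr::group_by(.data$molecule) |>
    dplyr::mutate(isi_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::relocate("molecule", "isi_index", "isi_s")
}

# Exact null CDF of the sum of q i.i.d. discrete-uniform{1..N} ranks,
# by iterated convolution. Returns the full CDF over support q..qN.
rank_sum_null_cdf <- function(q, N) {
  p <- rep(1 / N, N)
  cur <- p
  if (q > 1) for (i in 2:q) cur <- stats::convolve(cur, rev(p), type = "open")
  cur[cur < 0] <- 0
  cumsum(cur) / sum(cur)
}

# log P(sum of q ranks <= S); exact for q <= q_exact, Gaussian with
# continuity correction beyond. Average (tied) ranks give half-integer S;
# the integer-valued null makes floor(S) exact.
rank_surprise_logp <- function(S, q, N, q_exact = 10, cache = NULL) {
  if (q <= q_exact) {
    cdf <- if (!is.null(cache) && !is.null(cache[[as.character(q)]]))
      cache[[as.character(q)]] else rank_sum_null_cdf(q, N)
    idx <- floor(S) - q + 1
    if (idx < 1) return(-Inf)
    idx <- min(idx, length(cdf))
    log(max(cdf[idx], 1e-300))
  } else {
    mu <- q * (N + 1) / 2
    sg <- sqrt(q * (N^2 - 1) / 12)
    pnorm(floor(S) + 0.5, mu, sg, log.p = TRUE)
  }
}

#' Global Rank-Surprise burst detection
#'
#' All ISIs across all molecules are pooled and ranked once (average ranks
#' for ties), so a burst is a global property of the dataset rather than
#' of a single molecule. Within each molecule, maximal runs of consecutive
#' ISIs each no longer than `max_isi_in_burst` form candidate regions; in
#' each region every contiguous sub-window is scored with the
#' Rank-Surprise statistic `RS = -log P(sum of q i.i.d. uniform ranks <=
#' observed rank sum)` and bursts are accepted greedily, largest RS first,
#' recursing on the flanking remainders, while `RS > alpha`. The null
#' probability is exact (iterated convolution) for runs of up to 10 ISIs
#' and a continuity-corrected Gaussian beyond. A burst spans from the
#' event preceding its first ISI to the event following its last ISI.
#'
#' @param isis Tibble from [compute_isis()] (`molecule`, `isi_index`,
#'   `isi_s`).
#' @param params A [burst_params()].
#' @return A list of class `burst_annotation`: `bursts` (tibble:
#'   `molecule`, `burst_id`, `first_event`, `last_event`, `first_isi`,
#'   `last_isi`, `n_isis`, `rank_sum`, `rs`), `isis` (input plus `rank`,
#'   `in_burst`, `burst_id`), `params`, `n_total_isis`.
#' @export
global_rank_surprise <- function(isis, params = burst_params()) {
  stopifnot(inherits(params, "burst_params"))
  stopifnot(all(c("molecule", "isi_index", "isi_s") %in% names(isis)))
  if (any(!is.finite(isis$isi_s)))
    stop_bad_config("ISIs must be finite")
  N <- nrow(isis)
  out_isis <- dplyr::mutate(isis,
                            rank = rank(.data$isi_s, ties.method = "average"),
                            in_burst = FALSE, burst_id = NA_integer_)
  bursts <- list()
  if (N > 0) {
    cache <- new.env(parent = emptyenv())
    get_cdf <- function(q) {
      key <- as.character(q)
      if (is.null(cache[[key]])) cache[[key]] <- rank_sum_null_cdf(q, N)
      cache[[key]]
    }
    for (mol in unique(out_isis$molecule)) {
      sel <- which(out_isis$molecule == mol)
      r <- out_isis$rank[sel]
      v <- out_isis$isi_s[sel]
      ok <- v <= params$max_isi_in_burst
      runs <- rle(ok)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values)) {
        found <- scan_region(starts[k], ends[k], r, N, params$alpha, get_cdf)
        for (b in found) {
          bid <- length(bursts) + 1L
          bursts[[bid]] <- tibble::tibble(
            molecule = mol, burst_id = bid,
            first_event = b$p, last_event = b$q + 1L,
            first_isi = b$p, last_isi = b$q,
            n_isis = b$q - b$p + 1L, rank_sum = b$S, rs = b$rs)
          out_isis$in_burst[sel[b$p:b$q]] <- TRUE
          out_isis$burst_id[sel[b$p:b$q]] <- bid
        }
      }
    }
  }
  bursts <- if (length(bursts)) dplyr::bind_rows(bursts) else
    tibble::tibble(molecule = integer(), burst_id = integer(),
                   first_event = integer(), last_event = integer(),
                   first_isi = integer(), last_isi = integer(),
                   n_isis = integer(), rank_sum = numeric(), rs = numeric())
  structure(list(bursts = bursts, isis = out_isis, params = params,
                 n_total_isis = N),
            class = "burst_annotation")
}

# Exhaustive-surprise scan of one candidate region [i..j] (ISI indices in
# the molecule's local coordinates, ranks r): find the sub-window with the
# largest RS; if above alpha accept it and recurse on both flanks.
scan_region <- function(i, j, r, N, alpha, get_cdf) {
  if (j < i) return(list())
  cs <- c(0, cumsum(r))
  best_rs <- -Inf; best <- NULL
  for (p in i:j) for (q in p:j) {
    len <- q - p + 1L
    S <- cs[q + 1L] - cs[p]
    lp <- if (len <= 10) {
      cdf <- get_cdf(len)
      idx <- floor(S) - len + 1
      if (idx < 1) -Inf else log(max(cdf[min(idx, length(cdf))], 1e-300))
    } else {
      mu <- len * (N + 1) / 2
      sg <- sqrt(len * (N^2 - 1) / 12)
      pnorm(floor(S) + 0.5, mu, sg, log.p = TRUE)
    }
    rs <- -lp
    if (rs > best_rs + 1e-12 ||
        (abs(rs - best_rs) <= 1e-12 && !is.null(best) &&
           len > (best$q - best$p + 1L))) {
      best_rs <- rs
      best <- list(p = p, q = q, S = S, rs = rs)
    }
  }
  if (is.null(best) || !(best_rs > alpha)) return(list())
  c(scan_region(i, best$p - 1L, r, N, alpha, get_cdf),
    list(best),
    scan_region(best$q + 1L, j, r, N, alpha, get_cdf))
}

#' @export
print.burst_annotation <- function(x, ...) {
  cat(sprintf("<burst_annotation> %d bursts over %d molecules, %d ISIs (%.1f%% in bursts)\n",
              nrow(x$bursts), length(unique(x$isis$molecule)),
              x$n_total_isis,
              if (x$n_total_isis) 100 * mean(x$isis$in_burst) else 0))
  invisible(x)
}

#' Burst versus non-burst ISI statistics
#'
#' Splits ISIs by burst label, reports their distributions and
#' single-exponential CDF fits (whose lifetimes are the characteristic
#' burst and non-burst timescales), and emits per-molecule burst and
#' non-burst duration tables (a period's duration is the sum of its
#' ISIs). A warning is emitted when the burst ISI timescale is not at
#' least 10 times faster than the non-burst timescale, since burst
#' detection is only meaningful when probe binding is much faster than the
#' slow modulation it probes.
#'
#' @param annotation A `burst_annotation` from [global_rank_surprise()].
#' @param grid Optional frame spacing (s) passed to the fits.
#' @return A list: `isi_summary` (tibble per class: `n`, `median_isi`,
#'   `mean_isi`), `fits` (list with `burst`, `non_burst`; `NULL` when a
#'   class has fewer than 5 ISIs), `durations` (tibble: `molecule`,
#'   `class`, `period_id`, `duration_s`, `n_isis`).
#' @export
burst_statistics <- function(annotation, grid = NULL) {
  stopifnot(inherits(annotation, "burst_annotation"))
  isis <- annotation$isis
  cls <- ifelse(isis$in_burst, "burst", "non_burst")
  isi_summary <- tibble::tibble(class = cls, isi_s = isis$isi_s) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), median_isi = median(.data$isi_s),
                     mean_isi = mean(.data$isi_s), .groups = "drop")
  fit_class <- function(v) {
    if (length(v) < 5) return(NULL)
    fit_exponential_cdf(v, order = 1, grid = grid)
  }
  fits <- list(burst = fit_class(isis$isi_s[isis$in_burst]),
               non_burst = fit_class(isis$isi_s[!isis$in_burst]))
  if (!is.null(fits$burst) && !is.null(fits$non_burst) &&
      fits$burst$tau * 10 > fits$non_burst$tau)
    warning(paste("probe binding is less than 10x faster than the",
                  "non-burst timescale; burst timescales may be unreliable"),
            call. = FALSE)
  durations <- isis |>
    dplyr::group_by(.data$molecule) |>
    dplyr::group_modify(~ {
      r <- rle(.x$in_burst)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      tibble::tibble(
        class = ifelse(r$values, "burst", "non_burst"),
        period_id = seq_along(r$values),
        duration_s = vapply(seq_along(r$values), function(k)
          sum(.x$isi_s[starts[k]:ends[k]]), 0),
        n_isis = r$lengths)
    }) |>
    dplyr::ungroup()
  list(isi_summary = isi_summary, fits = fits, durations = durations)
}
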