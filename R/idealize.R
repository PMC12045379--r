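#' Two-state HMM idealization of an intensity trace
#'
#' Fits a two-state Gaussian-emission hidden Markov model by maximum
#' likelihood (EM) and returns the Viterbi state path. Initialization is
#' deterministic: state levels at the 10th and 90th intensity percentiles,
#' stay probability 0.9, equal initial state weights; EM runs for at most
#' `max_iter` iterations or until the log-likelihood improves by less than
#' `tol`. Viterbi (rather than posterior-marginal) decoding avoids
#' single-frame flicker in the dwell sequence.
#'
#' If the two fitted levels are separated by less than one pooled fitted
#' sd, or if a single-Gaussian model is preferred by BIC (as for a
#' pure-noise trace with no real binding), the trace is returned as a
#' single-state (unbound) idealization with zero transitions.
#'
#' @param trace A data frame with an `intensity` column (and optionally
#'   `frame`, `time_s`), or a numeric vector.
#' @param exposure Exposure time per frame in seconds.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An object of class `ideal_trace`: list with `data` (tibble
#'   `frame`, `time_s`, `intensity`, `state`; state 1 = bound), `mu`
#'   (levels, unbound then bound), `sigma` (per-state noise sd), `trans`,
#'   `loglik`, `n_transitions`, `single_state`, `exposure`.
#' @export
idealize_two_state <- function(trace, exposure = 0.1, max_iter = 100,
                               tol = 1e-6) {
  x <- if (is.data.frame(trace)) trace$intensity else as.numeric(trace)
  if (length(x) < 10L)
    stop_bad_config("idealization needs at least 10 frames, got %d", length(x))
  if (any(!is.finite(x)))
    stop_bad_config("trace contains non-finite intensities")
  check_number(exposure, "exposure", lower = 1e-12)

  rng <- diff(range(x))
  floor_sigma <- max(rng * 1e-4, 1e-9)
  mu <- unname(quantile(x, c(0.1, 0.9)))
  if (diff(mu) < .Machine$double.eps * max(1, abs(mu[1]))) {
    return(new_ideal_trace(trace, x, rep(0L, length(x)),
                           mu = c(mu[1], mu[1]),
                           sigma = c(max(sd(x), floor_sigma),
                                     max(sd(x), floor_sigma)),
                           trans = diag(2), loglik = NA_real_,
                           exposure = exposure, single_state = TRUE))
  }
  sigma <- rep(max(sd(x) / 2, floor_sigma), 2)
  trans <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  init <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    es <- hmm2_estep(x, mu, sigma, trans, init)
    g <- es$gamma
    w <- colSums(g)
    mu_new <- colSums(g * x) / w
    sigma_new <- sqrt(colSums(g * (outer(x, mu_new, "-")^2)) / w)
    sigma_new <- pmax(sigma_new, floor_sigma)
    xi <- es$xi
    trans_new <- xi / pmax(rowSums(xi), 1e-300)
    bad <- rowSums(xi) <= 1e-300
    if (any(bad)) trans_new[bad, ] <- c(0.5, 0.5)
    init_new <- pmax(g[1, ], 1e-12); init_new <- init_new / sum(init_new)
    mu <- mu_new; sigma <- sigma_new; trans <- trans_new; init <- init_new
    if (is.finite(es$loglik) && abs(es$loglik - ll_old) < tol) break
    ll_old <- es$loglik
  }
  # order: state 1 (index 1) = unbound/lower level, state 2 = bound/higher
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sigma <- rev(sigma); init <- rev(init)
    trans <- trans[2:1, 2:1]
  }
  # Reject the two-state model when the levels are indistinguishable
  # (separation under one pooled sd) or when a single Gaussian explains
  # the trace as well by BIC -- a pure-noise trace is Gaussian and must
  # not be shredded into spurious one-frame events.
  n <- length(x)
  ll1 <- sum(stats::dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)),
                          log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * ll_old + 7 * log(n)
  pooled_sd <- sqrt(mean(sigma^2))
  if ((mu[2] - mu[1]) < pooled_sd || bic1 <= bic2) {
    return(new_ideal_trace(trace, x, rep(0L, length(x)), mu = mu,
                           sigma = sigma, trans = trans,
                           loglik = ll_old, exposure = exposure,
                           single_state = TRUE))
  }
  path <- hmm2_viterbi(x, mu, sigma, trans, init)
  new_ideal_trace(trace, x, as.integer(path), mu = mu, sigma = sigma,
                  trans = trans, loglik = ll_old, exposure = exposure,
                  single_state = FALSE)
}

new_ideal_trace <- function(trace, x, state, mu, sigma, trans, loglik,
                            exposure, single_state) {
  n <- length(x)
  frame <- if (is.data.frame(trace) && "frame" %in% names(trace))
    trace$frame else seq_len(n)
  time_s <- if (is.data.frame(trace) && "time_s" %in% names(trace))
    trace$time_s else (seq_len(n) - 1) * exposure
  structure(list(
    data = tibble::tibble(frame = frame, time_s = time_s, intensity = x,
                          state = state),
    mu = unname(mu), sigma = unname(sigma), trans = trans,
    loglik = loglik, exposure = exposure,
    n_transitions = sum(diff(state) != 0L),
    single_state = single_state
  ), class = "ideal_trace")
}

#' @export
print.ideal_trace <- function(x, ...) {
  cat(sprintf(paste0("<ideal_trace> %d frames @ %.3g s; levels %.4g / %.4g,",
                     " sd %.3g / %.3g; %d transitions%s\n"),
              nrow(x$data), x$exposure, x$mu[1], x$mu[2], x$sigma[1],
              x$sigma[2], x$n_transitions,
              if (x$single_state) " (single state)" else ""))
  invisible(x)
}

#' Extract bound/unbound dwell times from an idealized trace
#'
#' Runs of constant state are converted to dwell durations in seconds
#' (run length times exposure). The first and last runs touch the trace
#' boundary, are necessarily truncated, and are flagged so downstream fits
#' can exclude them.
#'
#' @param ideal An `ideal_trace`, or a data frame with a `state` column.
#' @param exposure Exposure in seconds (only needed for the data-frame
#'   form).
#' @return A tibble with columns `state` (1 = bound), `start_frame`,
#'   `n_frames`, `duration_s`, `truncated`.
#' @export
extract_dwells <- function(ideal, exposure = NULL) {
  if (inherits(ideal, "ideal_trace")) {
    state <- ideal$data$state
    exposure <- ideal$exposure
  } else {
    state <- ideal$state
    if (is.null(exposure))
      stop_bad_config("`exposure` is required when `ideal` is a data frame")
  }
  r <- rle(as.integer(state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$lengths)
  tibble::tibble(
    state = r$values,
    start_frame = starts,
    n_frames = r$lengths,
    duration_s = r$lengths * exposure,
    truncated = seq_len(k) %in% c(1L, k)
  )
}

#' Per-trace kinetic fingerprint statistics
#'
#' Summarizes an idealized trace with the quantities used for kinetic
#' filtering: `n_events` (the number of binding plus dissociation
#' transitions), median bound and unbound dwell times and the maximum
#' unbound dwell over complete (non-truncated) dwells, and the
#' level-separation-to-noise summary. The field convention follows the
#' noise-to-signal definition (`noise_to_signal` = pooled intensity sd
#' divided by the mean level difference) with its reciprocal stored as
#' `snr`; filters reference `snr`.
#'
#' @param ideal An `ideal_trace`.
#' @param dwells Optional dwell table from [extract_dwells()]; computed if
#'   missing.
#' @return A one-row tibble: `n_events`, `tau_on_median`, `tau_off_median`,
#'   `tau_off_max` (seconds; `NA` when no complete dwell of that kind),
#'   `snr`, `noise_to_signal`, `level_unbound`, `level_bound`.
#' @export
compute_fingerprint_stats <- function(ideal, dwells = NULL) {
  stopifnot(inherits(ideal, "ideal_trace"))
  if (is.null(dwells)) dwells <- extract_dwells(ideal)
  comp <- dwells[!dwells$truncated, , drop = FALSE]
  on_d <- comp$duration_s[comp$state == 1L]
  off_d <- comp$duration_s[comp$state == 0L]
  sep <- ideal$mu[2] - ideal$mu[1]
  pooled_sd <- sqrt(mean(ideal$sigma^2))
  n2s <- if (sep > 0) pooled_sd / sep else Inf
  tibble::tibble(
    n_events = ideal$n_transitions,
    tau_on_median = if (length(on_d)) median(on_d) else NA_real_,
    tau_off_median = if (length(off_d)) median(off_d) else NA_real_,
    tau_off_max = if (length(off_d)) max(off_d) else NA_real_,
    snr = 1 / n2s,
    noise_to_signal = n2s,
    level_unbound = ideal$mu[1],
    level_bound = ideal$mu[2]
  )
}

#' Idealize and summarize a population of traces
#'
#' Convenience wrapper mapping [idealize_two_state()], [extract_dwells()]
#' and [compute_fingerprint_stats()] over the rows of a population tibble
#' (e.g. from [simulate_population()]).
#'
#' @param population A tibble with a `trace` list-column of trace data
#'   frames (and optionally `trace_id`).
#' @param exposure Exposure in seconds.
#' @return A list with `stats` (tibble of per-trace fingerprints, one row
#'   per trace, keyed by `trace_id`), `dwells` (long tibble of all dwells
#'   with `trace_id`), `ideals` (list of `ideal_trace`).
#' @export
fingerprint_population <- function(population, exposure = 0.1) {
  ids <- population$trace_id %||% seq_len(nrow(population))
  ideals <- lapply(population$trace, idealize_two_state, exposure = exposure)
  dwell_tabs <- lapply(ideals, extract_dwells)
  stats <- purrr::map2_dfr(ideals, dwell_tabs, compute_fingerprint_stats)
  stats <- dplyr::bind_cols(tibble::tibble(trace_id = ids), stats)
  dwells <- dplyr::bind_rows(
    purrr::map2(dwell_tabs, ids, ~ dplyr::mutate(.x, trace_id = .y))
  )
  list(stats = stats, dwells = dwells, ideals = ideals)
}
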