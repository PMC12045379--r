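#' Tidy an exponential dwell-time fit
#'
#' One row per model component with the fitted lifetime and amplitude.
#'
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `tau`, `amplitude`,
#'   `offset`.
#' @export
tidy.exp_fit <- function(x, ...) {
  if (x$order == 1) {
    tibble::tibble(component = 1L, tau = x$tau1, amplitude = x$m,
                   offset = x$c)
  } else {
    tibble::tibble(component = 1:2, tau = c(x$tau1, x$tau2),
                   amplitude = c(x$m, x$n), offset = x$c)
  }
}

#' @rdname tidy.exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(order = x$order, tau = x$tau, sse = x$sse,
                 r_squared = x$r_squared, n_dwells = x$n_dwells,
                 weighting = x$weighting, converged = x$converged)
}

#' Tidy an idealized trace
#'
#' @param x An `ideal_trace`.
#' @param ... Unused.
#' @return The per-frame tibble (`frame`, `time_s`, `intensity`, `state`).
#' @export
tidy.ideal_trace <- function(x, ...) x$data

#' @rdname tidy.ideal_trace
#' @export
glance.ideal_trace <- function(x, ...) {
  tibble::tibble(level_unbound = x$mu[1], level_bound = x$mu[2],
                 sigma_unbound = x$sigma[1], sigma_bound = x$sigma[2],
                 loglik = x$loglik, n_transitions = x$n_transitions,
                 single_state = x$single_state, exposure = x$exposure)
}

#' Tidy a kinetic population assignment
#'
#' @param x A `population_assignment`.
#' @param ... Unused.
#' @return The per-trace label tibble.
#' @export
tidy.population_assignment <- function(x, ...) x$assignments

#' @rdname tidy.population_assignment
#' @export
glance.population_assignment <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::select(x$fractions, "label", "fraction"),
    names_from = "label", values_from = "fraction",
    names_prefix = "fraction_")
  dplyr::bind_cols(tibble::tibble(n_components = x$n_components), wide)
}

#' Tidy a per-trace precision summary
#'
#' @param x A `precision_summary`.
#' @param ... Unused.
#' @return The per-trace lifetime tibble.
#' @export
tidy.precision_summary <- function(x, ...) x$per_trace

#' @rdname tidy.precision_summary
#' @export
glance.precision_summary <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "kind",
                     values_from = c("n_traces", "mean_tau", "sd_tau",
                                     "cv_pct"))
}

#' Tidy a burst annotation
#'
#' @param x A `burst_annotation`.
#' @param ... Unused.
#' @return The burst table.
#' @export
tidy.burst_annotation <- function(x, ...) x$bursts

#' @rdname tidy.burst_annotation
#' @export
glance.burst_annotation <- function(x, ...) {
  tibble::tibble(n_bursts = nrow(x$bursts),
                 n_molecules = length(unique(x$isis$molecule)),
                 n_isis = x$n_total_isis,
                 frac_isis_in_burst = if (x$n_total_isis)
                   mean(x$isis$in_burst) else NA_real_,
                 max_isi_in_burst = x$params$max_isi_in_burst,
                 alpha = x$params$alpha)
}
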