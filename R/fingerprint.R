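#' Kinetic filter thresholds
#'
#' Acceptance cutoffs applied to per-trace fingerprint statistics. A trace
#' is accepted only if every bound is satisfied; `-Inf`/`Inf`/0 bounds are
#' permissive. `amplitude` refers to the fitted level separation
#' `level_bound - level_unbound` in counts.
#'
#' @param min_n_events Minimum number of binding + dissociation events.
#' @param min_tau_on_median,max_tau_on_median Bounds on the median bound
#'   dwell (s).
#' @param min_tau_off_median,max_tau_off_median Bounds on the median
#'   unbound dwell (s).
#' @param max_tau_off_max Maximum allowed longest unbound dwell (s).
#' @param min_snr Minimum level-separation-to-noise ratio.
#' @param min_amplitude,max_amplitude Bounds on the fitted level
#'   separation (counts).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_n_events = 0,
                              min_tau_on_median = 0,
                              max_tau_on_median = Inf,
                              min_tau_off_median = 0,
                              max_tau_off_median = Inf,
                              max_tau_off_max = Inf,
                              min_snr = 0,
                              min_amplitude = -Inf,
                              max_amplitude = Inf) {
  thr <- list(min_n_events = min_n_events,
              min_tau_on_median = min_tau_on_median,
              max_tau_on_median = max_tau_on_median,
              min_tau_off_median = min_tau_off_median,
              max_tau_off_median = max_tau_off_median,
              max_tau_off_max = max_tau_off_max,
              min_snr = min_snr,
              min_amplitude = min_amplitude,
              max_amplitude = max_amplitude)
  for (nm in names(thr)) check_number(thr[[nm]], nm, allow_inf = TRUE)
  if (thr$min_tau_on_median > thr$max_tau_on_median ||
      thr$min_tau_off_median > thr$max_tau_off_median ||
      thr$min_amplitude > thr$max_amplitude)
    stop_bad_config("threshold min bounds must not exceed max bounds")
  structure(thr, class = "filter_thresholds")
}

# A missing statistic passes a bound only when that bound is fully
# permissive; tightening any bound therefore never gains a trace.
pass_min <- function(stat, bound) {
  ifelse(is.na(stat), bound <= 0, stat >= bound)
}
pass_max <- function(stat, bound) {
  ifelse(is.na(stat), !is.finite(bound) & bound > 0, stat <= bound)
}

#' Apply kinetic filter thresholds to fingerprint statistics
#'
#' @param stats Tibble of per-trace fingerprints (see
#'   [compute_fingerprint_stats()]).
#' @param thresholds A [filter_thresholds()].
#' @return `stats` with an added logical `accepted` column; the number of
#'   accepted traces is in attribute `n_accepted`.
#' @export
filter_traces <- function(stats, thresholds) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  amp <- stats$level_bound - stats$level_unbound
  acc <- pass_min(stats$n_events, thresholds$min_n_events) &
    pass_min(stats$tau_on_median, thresholds$min_tau_on_median) &
    pass_max(stats$tau_on_median, thresholds$max_tau_on_median) &
    pass_min(stats$tau_off_median, thresholds$min_tau_off_median) &
    pass_max(stats$tau_off_median, thresholds$max_tau_off_median) &
    pass_max(stats$tau_off_max, thresholds$max_tau_off_max) &
    pass_min(stats$snr, thresholds$min_snr) &
    pass_min(amp, thresholds$min_amplitude) &
    pass_max(amp, thresholds$max_amplitude)
  out <- dplyr::mutate(stats, accepted = acc)
  attr(out, "n_accepted") <- sum(acc)
  out
}

#' Optimize kinetic filter thresholds on labeled data
#'
#' Grid search maximizing the number of accepted positives subject to the
#' number of accepted negatives not exceeding `fp_budget` per
#' field-of-view-equivalent. Candidate cutoffs are drawn from quantiles of
#' the pooled statistics for the four most discriminative parameters
#' (`min_n_events`, `max_tau_on_median`, `max_tau_off_max`, `min_snr`);
#' the remaining bounds stay permissive. Ties are broken deterministically
#' in favor of stricter thresholds.
#'
#' @param positive_stats,negative_stats Fingerprint tibbles for labeled
#'   specific traces and negative-control traces.
#' @param fp_budget Allowed accepted negatives per FOV-equivalent
#'   (default 2, matching typical negative-control levels).
#' @param fov_equivalents How many FOV-equivalents the negative set
#'   represents (default 1).
#' @param n_candidates Candidate cutoffs per parameter.
#' @return A [filter_thresholds()] with attribute `performance` (tibble:
#'   `n_true_positive`, `n_false_positive`, `sensitivity`).
#' @export
optimize_thresholds <- function(positive_stats, negative_stats,
                                fp_budget = 2, fov_equivalents = 1,
                                n_candidates = 8) {
  if (nrow(positive_stats) == 0L)
    stop_bad_config("positive set is empty")
  if (nrow(negative_stats) == 0L)
    stop_bad_config("negative set is empty")
  check_number(fp_budget, "fp_budget", lower = 0)
  pool <- dplyr::bind_rows(positive_stats, negative_stats)
  qs <- seq(0, 1, length.out = n_candidates)
  cand_ne <- sort(unique(c(0, round(quantile(pool$n_events, qs,
                                             na.rm = TRUE)))))
  cand_on <- sort(unique(c(Inf, quantile(pool$tau_on_median, qs,
                                         na.rm = TRUE))))
  cand_om <- sort(unique(c(Inf, quantile(pool$tau_off_max, qs,
                                         na.rm = TRUE))))
  cand_sn <- sort(unique(c(0, quantile(pool$snr, qs, na.rm = TRUE))))

  eval_set <- function(stats) {
    list(ne = stats$n_events, on = stats$tau_on_median,
         om = stats$tau_off_max, sn = stats$snr)
  }
  p <- eval_set(positive_stats); n <- eval_set(negative_stats)
  best <- NULL
  for (ne in cand_ne) for (on in cand_on) for (om in cand_om)
    for (sn in cand_sn) {
      acc_p <- pass_min(p$ne, ne) & pass_max(p$on, on) &
        pass_max(p$om, om) & pass_min(p$sn, sn)
      acc_n <- pass_min(n$ne, ne) & pass_max(n$on, on) &
        pass_max(n$om, om) & pass_min(n$sn, sn)
      tp <- sum(acc_p); fp <- sum(acc_n)
      if (fp / fov_equivalents > fp_budget) next
      strict <- c(ne, -on, -om, sn)  # larger = stricter
      if (is.null(best) || tp > best$tp ||
          (tp == best$tp && fp < best$fp) ||
          (tp == best$tp && fp == best$fp &&
             lex_greater(strict, best$strict))) {
        best <- list(tp = tp, fp = fp, thr = c(ne = ne, on = on, om = om,
                                               sn = sn), strict = strict)
      }
    }
  if (is.null(best)) {
    # even rejecting everything exceeds the budget only if budget < 0;
    # fall back to the strictest corner, which accepts nothing
    best <- list(tp = 0, fp = 0,
                 thr = c(ne = Inf, on = 0, om = 0, sn = Inf))
  }
  out <- filter_thresholds(min_n_events = best$thr[["ne"]],
                           max_tau_on_median = best$thr[["on"]],
                           max_tau_off_max = best$thr[["om"]],
                           min_snr = best$thr[["sn"]])
  attr(out, "performance") <- tibble::tibble(
    n_true_positive = best$tp, n_false_positive = best$fp,
    sensitivity = best$tp / nrow(positive_stats))
  out
}

lex_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' Classify accepted traces into kinetic subpopulations
#'
#' Gaussian mixture model on `(log tau_on_median, log tau_off_median)`
#' with the number of components (1 or 2) chosen by BIC; initialization is
#' the deterministic hierarchical scheme of the mixture fitter, so results
#' do not depend on trace order or random state. With two components the
#' cluster with the smaller mean log bound dwell is labeled `"transient"`
#' and the other `"long_lived"`; with one component the population is
#' labeled by whether its mean bound dwell is below 1 s. Traces lacking
#' complete dwells are labeled `"rejected"`.
#'
#' @param stats Fingerprint tibble of accepted traces (needs `trace_id`,
#'   `tau_on_median`, `tau_off_median`).
#' @param min_traces Minimum usable traces (default 20).
#' @return A list of class `population_assignment`: `assignments` (tibble:
#'   `trace_id`, `label`, `prob`), `fractions` (tibble: `label`,
#'   `fraction`, `se`, `n`), `n_components`, `means` (per-component mean
#'   log dwells).
#' @export
classify_kinetic_populations <- function(stats, min_traces = 20) {
  usable <- stats[is.finite(stats$tau_on_median) &
                    is.finite(stats$tau_off_median) &
                    stats$tau_on_median > 0 & stats$tau_off_median > 0, ]
  if (nrow(usable) < min_traces)
    stop_bad_config("need at least %d traces with complete dwells, got %d",
                    min_traces, nrow(usable))
  X <- cbind(log_tau_on = log(usable$tau_on_median),
             log_tau_off = log(usable$tau_off_median))
  mc <- mclust::Mclust(X, G = 1:2, verbose = FALSE)
  g <- mc$G
  if (g == 2) {
    mu_on <- mc$parameters$mean["log_tau_on", ]
    lab_map <- if (mu_on[1] <= mu_on[2]) c("transient", "long_lived")
               else c("long_lived", "transient")
    labels <- lab_map[mc$classification]
    prob <- apply(mc$z, 1, max)
  } else {
    lab <- if (mean(X[, "log_tau_on"]) < log(1)) "transient" else "long_lived"
    labels <- rep(lab, nrow(X))
    prob <- rep(1, nrow(X))
  }
  assignments <- tibble::tibble(trace_id = usable$trace_id, label = labels,
                                prob = prob)
  rejected <- setdiff(stats$trace_id, usable$trace_id)
  if (length(rejected))
    assignments <- dplyr::bind_rows(
      assignments,
      tibble::tibble(trace_id = rejected, label = "rejected", prob = NA_real_))
  frac <- assignments |>
    dplyr::filter(.data$label != "rejected") |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n),
                  se = sqrt(.data$fraction * (1 - .data$fraction) /
                              sum(.data$n)))
  structure(list(assignments = assignments, fractions = frac,
                 n_components = g,
                 means = if (g >= 1) t(mc$parameters$mean) else NULL,
                 model = mc$modelName),
            class = "population_assignment")
}

#' @export
print.population_assignment <- function(x, ...) {
  cat(sprintf("<population_assignment> %d component(s)\n", x$n_components))
  print(x$fractions)
  invisible(x)
}

#' Joint two-channel accessibility of colocalized molecules
#'
#' Combines colocalization pairs with per-channel acceptance (and optional
#' kinetic labels) into molecule-level contingency fractions: channel-A
#' only, channel-B only, both, neither. Each matched pair counts as one
#' molecule; unmatched ROIs count as single-channel molecules. Also
#' reports, for each label in channel B, the fraction of those molecules
#' with any channel-A acceptance.
#'
#' @param coloc Result of [colocalize_rois()].
#' @param flags_a,flags_b Tibbles with `roi_id`, logical `accepted`, and
#'   optionally `label` (channel B).
#' @return A list: `fractions` (tibble `category`, `n`, `fraction`),
#'   `conditionals` (tibble `label_b`, `n`, `fraction_with_a`), `n_molecules`.
#' @export
joint_accessibility <- function(coloc, flags_a, flags_b) {
  acc_a <- setNames(flags_a$accepted, flags_a$roi_id)
  acc_b <- setNames(flags_b$accepted, flags_b$roi_id)
  lab_b <- if ("label" %in% names(flags_b))
    setNames(flags_b$label, flags_b$roi_id) else NULL
  mol <- dplyr::bind_rows(
    tibble::tibble(roi_a = coloc$pairs$roi_a, roi_b = coloc$pairs$roi_b),
    tibble::tibble(roi_a = coloc$unmatched_a, roi_b = NA_integer_),
    tibble::tibble(roi_a = NA_integer_, roi_b = coloc$unmatched_b))
  a_ok <- !is.na(mol$roi_a) & acc_a[as.character(mol$roi_a)] %in% TRUE
  b_ok <- !is.na(mol$roi_b) & acc_b[as.character(mol$roi_b)] %in% TRUE
  category <- dplyr::case_when(
    a_ok & b_ok ~ "both",
    a_ok ~ "a_only",
    b_ok ~ "b_only",
    TRUE ~ "neither")
  fractions <- tibble::tibble(category =
                                c("a_only", "b_only", "both", "neither")) |>
    dplyr::left_join(tibble::tibble(category = category) |>
                       dplyr::count(.data$category),
                     by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = .data$n / nrow(mol))
  conditionals <- NULL
  if (!is.null(lab_b)) {
    keep <- b_ok
    lb <- lab_b[as.character(mol$roi_b[keep])]
    conditionals <- tibble::tibble(label_b = lb, with_a = a_ok[keep]) |>
      dplyr::group_by(.data$label_b) |>
      dplyr::summarise(n = dplyr::n(),
                       fraction_with_a = mean(.data$with_a),
                       .groups = "drop")
  }
  list(fractions = fractions, conditionals = conditionals,
       n_molecules = nrow(mol))
}
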