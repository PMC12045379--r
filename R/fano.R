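#' Chi-square (gamma-quantile) confidence band for a Poisson Fano factor
#'
#' The 2.5% and 97.5% quantiles of `Gamma(shape = (n-1)/2, scale =
#' 2/(n-1))`, equivalently `chisq(n-1)/(n-1)`: the null distribution of a
#' variance/mean ratio estimated from `n` Poisson count samples.
#'
#' @param n Sample size (>= 2).
#' @return Named numeric `c(lo, hi)` with `lo < 1 < hi`.
#' @export
fano_confidence_bounds <- function(n) {
  check_number(n, "n", lower = 2)
  b <- qgamma(c(0.025, 0.975), shape = (n - 1) / 2, scale = 2 / (n - 1))
  c(lo = b[1], hi = b[2])
}

#' Windowed Fano factor of binding-event trains
#'
#' For each molecule, `samples_per_molecule` windows of length `T` are
#' placed uniformly at random within the observation span and the number
#' of binding-event onsets in each window is counted. The Fano factor
#' `F = var/mean` is computed over all pooled counts, and per molecule.
#' The confidence band is the chi-square null range for a single
#' molecule's Fano estimate, i.e. [fano_confidence_bounds()] at
#' `n = samples_per_molecule`; the pooled F of a Poisson process
#' concentrates well inside it.
#'
#' @param trains Tibble of event onsets with columns `molecule`,
#'   `onset_s`; molecules with no events still contribute zero counts if
#'   present as zero-row groups of `molecule` levels found in `molecules`.
#' @param duration Observation span per molecule, seconds.
#' @param T_s Window length(s) in seconds; may be a vector.
#' @param samples_per_molecule Windows drawn per molecule (default 100).
#' @param seed Integer seed for window placement.
#' @param molecules Optional vector of molecule ids (to include molecules
#'   with zero events); defaults to `unique(trains$molecule)`.
#' @return A tibble of class `fano_result` with one row per `T_s`:
#'   `T_s`, `fano`, `mean_count`, `n_samples`, `n_molecules`, `ci_lo`,
#'   `ci_hi`, `n_ci`; attribute `per_molecule` holds the per-molecule
#'   tibble (`molecule`, `T_s`, `fano`).
#' @export
fano_factor <- function(trains, duration, T_s = c(5, 10, 20, 40),
                        samples_per_molecule = 100, seed = 1L,
                        molecules = NULL) {
  check_number(duration, "duration", lower = 1e-12)
  check_number(samples_per_molecule, "samples_per_molecule", lower = 1)
  if (any(T_s > duration))
    stop_bad_config("window T (%.3g s) exceeds the observation span (%.3g s)",
                    max(T_s), duration)
  if (is.null(molecules)) molecules <- unique(trains$molecule)
  ev <- split(trains$onset_s, factor(trains$molecule, levels = molecules))
  with_seed_local(seed, {
    rows <- list(); per_mol <- list()
    for (Tw in T_s) {
      counts <- lapply(molecules, function(m) {
        st <- runif(samples_per_molecule, 0, duration - Tw)
        e <- ev[[as.character(m)]]
        vapply(st, function(s) sum(e >= s & e < s + Tw), 0)
      })
      all_counts <- unlist(counts)
      f <- var(all_counts) / mean(all_counts)
      ci <- fano_confidence_bounds(samples_per_molecule)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        T_s = Tw, fano = f, mean_count = mean(all_counts),
        n_samples = length(all_counts), n_molecules = length(molecules),
        ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
        n_ci = samples_per_molecule)
      per_mol[[length(per_mol) + 1L]] <- tibble::tibble(
        molecule = molecules, T_s = Tw,
        fano = vapply(counts, function(x) var(x) / mean(x), 0))
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "per_molecule") <- dplyr::bind_rows(per_mol)
    class(out) <- c("fano_result", class(out))
    out
  })
}

#' Poisson reference Fano computation
#'
#' Simulates the matched null: for each of `n_trains` molecules, counts
#' are drawn directly from a Poisson random number generator with mean
#' `rate * T` (independent samples, matching how a memoryless binding
#' process populates disjoint windows) with the same number of samplings
#' per molecule, and the Fano factor is computed identically to
#' [fano_factor()].
#'
#' @param rate Event rate in events/s.
#' @param n_trains Number of molecules to simulate.
#' @param T_s Window length(s), seconds.
#' @param samples_per_molecule Samplings per molecule (default 100).
#' @param seed Integer seed.
#' @return A `fano_result` tibble as in [fano_factor()].
#' @export
poisson_fano_reference <- function(rate, n_trains, T_s = c(5, 10, 20, 40),
                                   samples_per_molecule = 100, seed = 1L) {
  check_number(rate, "rate", lower = 0)
  check_number(n_trains, "n_trains", lower = 1)
  with_seed_local(seed, {
    rows <- list(); per_mol <- list()
    for (Tw in T_s) {
      counts <- matrix(rpois(n_trains * samples_per_molecule, rate * Tw),
                       nrow = samples_per_molecule)
      all_counts <- as.vector(counts)
      f <- var(all_counts) / mean(all_counts)
      ci <- fano_confidence_bounds(samples_per_molecule)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        T_s = Tw, fano = f, mean_count = mean(all_counts),
        n_samples = length(all_counts), n_molecules = n_trains,
        ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
        n_ci = samples_per_molecule)
      per_mol[[length(per_mol) + 1L]] <- tibble::tibble(
        molecule = seq_len(n_trains), T_s = Tw,
        fano = apply(counts, 2, function(x) var(x) / mean(x)))
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "per_molecule") <- dplyr::bind_rows(per_mol)
    class(out) <- c("fano_result", class(out))
    out
  })
}
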