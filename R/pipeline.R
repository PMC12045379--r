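#' Assemble a pipeline configuration
#'
#' A plain list validated and filled with defaults; can be serialized with
#' [write_config_yaml()] and read back. Stages communicate only via files
#' in `out_dir`, so any suffix of the pipeline can be re-run on existing
#' artifacts.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param stages Character vector of stages to run, in pipeline order,
#'   from: `simulate`, `detect`, `extract`, `idealize`, `fingerprint`,
#'   `fit`, `burst`, `fano`, `report`.
#' @param simulation List: `mode` (`"traces"` or `"movie"`), `n_traces`,
#'   and [sim_config()] fields (`tau_bound`, `tau_unbound`, `n_frames`,
#'   `exposure`, `bound_level`, `noise_sigma`), plus
#'   `background_trace_rate` and movie geometry (`rows`, `cols`,
#'   `psf_sigma`, `background`, `read_noise`) for movie mode.
#' @param detection List: `min_separation`, `threshold` (NULL = default
#'   policy).
#' @param thresholds A [filter_thresholds()] (default permissive with
#'   `min_n_events = 4` and `min_snr = 2`).
#' @param concentration_M Probe concentration in molar (default 5e-8,
#'   i.e. 50 nM).
#' @param burst A [burst_params()].
#' @param fano List: `T_s`, `samples_per_molecule`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("simulate", "idealize", "fingerprint",
                                       "fit", "burst", "fano", "report"),
                            simulation = list(),
                            detection = list(),
                            thresholds = filter_thresholds(min_n_events = 4,
                                                           min_snr = 2),
                            concentration_M = 5e-8,
                            burst = burst_params(),
                            fano = list()) {
  sim_defaults <- list(mode = "traces", n_traces = 50, tau_bound = 1.4,
                       tau_unbound = 3.5, n_frames = 2000, exposure = 0.1,
                       bound_level = 4000, noise_sigma = 400,
                       background_trace_rate = 0, rows = 64, cols = 64,
                       psf_sigma = 1, background = 200, read_noise = 60)
  simulation <- utils::modifyList(sim_defaults, simulation)
  detection <- utils::modifyList(list(min_separation = 3, threshold = NULL),
                                 detection)
  fano <- utils::modifyList(list(T_s = c(5, 10, 20, 40),
                                 samples_per_molecule = 100), fano)
  known <- c("simulate", "detect", "extract", "idealize", "fingerprint",
             "fit", "burst", "fano", "report")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop_bad_config("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, simulation = simulation,
                 detection = detection, thresholds = thresholds,
                 concentration_M = concentration_M, burst = burst,
                 fano = fano),
            class = "pipeline_config")
}

pipe_path <- function(config, name) file.path(config$out_dir, name)

pipe_log <- function(config, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  cat(line, "\n", file = pipe_path(config, "run_log.txt"), append = TRUE)
  message(line)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order (simulate, detect, extract,
#' idealize, fingerprint, fit, burst, fano, report), writing each stage's
#' artifacts as CSV/TIFF under `out_dir` and reading its inputs back from
#' the previous stage's files, so partial reruns work on existing
#' artifacts. The final report (`summary.yaml`) collects accepted counts,
#' rate constants, per-trace lifetime CVs, burst and Fano summaries, the
#' seed, package version and a hash of the configuration; given the same
#' configuration and seed the outputs are identical.
#'
#' @param config A [pipeline_config()] or the path of a YAML file written
#'   by [write_config_yaml()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- as_pipeline_config(read_config_yaml(config))
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    pipe_log(config, "stage %s: start", name)
    tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  sim <- config$simulation
  exposure <- sim$exposure

  run_stage("simulate", function() {
    spec <- population_spec(
      components = list(main = list(
        config = sim_config(tau_bound = sim$tau_bound,
                            tau_unbound = sim$tau_unbound,
                            n_frames = sim$n_frames,
                            exposure = sim$exposure,
                            bound_level = sim$bound_level,
                            noise_sigma = sim$noise_sigma),
        fraction = 1)),
      n_traces = sim$n_traces,
      background_trace_rate = sim$background_trace_rate)
    if (identical(sim$mode, "movie")) {
      mv <- simulate_movie(spec, rows = sim$rows, cols = sim$cols,
                           psf_sigma = sim$psf_sigma,
                           background = sim$background,
                           read_noise = sim$read_noise,
                           seed = config$seed)
      write_movie_tiff(mv$movie, pipe_path(config, "movie.tif"))
      write.csv(dplyr::select(mv$spots, "spot_id", "row", "col",
                              "component", "captured_flux_3x3"),
                pipe_path(config, "spots_truth.csv"), row.names = FALSE)
    } else {
      pop <- simulate_population(spec, seed = config$seed)
      long <- tidyr::unnest(
        dplyr::select(pop, "trace_id", "component", "trace"),
        "trace")
      write_trace_csv(long, pipe_path(config, "traces.csv"))
    }
  })

  run_stage("detect", function() {
    movie <- read_movie_tiff(pipe_path(config, "movie.tif"), exposure)
    fmap <- compute_fluctuation_map(movie)
    rois <- detect_rois(fmap, min_separation = config$detection$min_separation,
                        threshold = config$detection$threshold)
    write.csv(rois, pipe_path(config, "rois.csv"), row.names = FALSE)
  })

  run_stage("extract", function() {
    movie <- read_movie_tiff(pipe_path(config, "movie.tif"), exposure)
    rois <- read.csv(pipe_path(config, "rois.csv"))
    traces <- purrr::map_dfr(seq_len(nrow(rois)), function(i) {
      tr <- extract_trace(movie, rois[i, ])
      tr$trace_id <- rois$roi_id[i]
      tr
    })
    write_trace_csv(traces, pipe_path(config, "traces.csv"))
  })

  run_stage("idealize", function() {
    long <- read_trace_csv(pipe_path(config, "traces.csv"))
    pop <- tidyr::nest(long, trace = !dplyr::any_of(c("trace_id",
                                                      "component")))
    fp <- fingerprint_population(pop, exposure = exposure)
    write.csv(fp$stats, pipe_path(config, "fingerprints.csv"),
              row.names = FALSE)
    write.csv(fp$dwells, pipe_path(config, "dwells.csv"), row.names = FALSE)
    states <- dplyr::bind_rows(purrr::map2(
      fp$ideals, pop$trace_id %||% seq_along(fp$ideals),
      ~ dplyr::mutate(.x$data, trace_id = .y)))
    write_trace_csv(states, pipe_path(config, "idealized.csv"))
  })

  run_stage("fingerprint", function() {
    stats <- tibble::as_tibble(read.csv(pipe_path(config, "fingerprints.csv")))
    flt <- filter_traces(stats, config$thresholds)
    write.csv(flt, pipe_path(config, "accepted.csv"), row.names = FALSE)
    pipe_log(config, "fingerprint: %d of %d traces accepted",
             attr(flt, "n_accepted"), nrow(flt))
  })

  run_stage("fit", function() {
    dwells <- tibble::as_tibble(read.csv(pipe_path(config, "dwells.csv")))
    acc <- accepted_ids(config)
    dwells <- dwells[dwells$trace_id %in% acc, ]
    comp <- dwells[!dwells$truncated, ]
    fit_b <- select_cdf_model(comp$duration_s[comp$state == 1],
                              grid = exposure,
                              min_dwell = 2 * exposure)
    fit_u <- select_cdf_model(comp$duration_s[comp$state == 0],
                              grid = exposure,
                              min_dwell = 2 * exposure)
    rates <- compute_rate_constants(fit_b, fit_u, config$concentration_M)
    write.csv(dplyr::bind_rows(
      dplyr::mutate(glance(fit_b), kind = "bound"),
      dplyr::mutate(glance(fit_u), kind = "unbound")),
      pipe_path(config, "pooled_fits.csv"), row.names = FALSE)
    write.csv(rates, pipe_path(config, "rate_constants.csv"),
              row.names = FALSE)
    prec <- per_trace_lifetimes(dwells, exposure = exposure)
    write.csv(prec$per_trace, pipe_path(config, "per_trace_lifetimes.csv"),
              row.names = FALSE)
    write.csv(prec$summary, pipe_path(config, "lifetime_cv.csv"),
              row.names = FALSE)
  })

  run_stage("burst", function() {
    ev <- accepted_binding_events(config)
    isis <- compute_isis(ev)
    ann <- global_rank_surprise(isis, config$burst)
    write.csv(ann$bursts, pipe_path(config, "bursts.csv"), row.names = FALSE)
    write.csv(ann$isis, pipe_path(config, "isis.csv"), row.names = FALSE)
  })

  run_stage("fano", function() {
    ev <- accepted_binding_events(config)
    trains <- tibble::tibble(molecule = ev$molecule, onset_s = ev$start_s)
    duration <- sim$n_frames * exposure
    fr <- fano_factor(trains, duration = duration,
                      T_s = config$fano$T_s,
                      samples_per_molecule = config$fano$samples_per_molecule,
                      seed = config$seed + 7L,
                      molecules = sort(unique(ev$molecule)))
    write.csv(as.data.frame(fr), pipe_path(config, "fano.csv"),
              row.names = FALSE)
  })

  summary <- NULL
  run_stage("report", function() {
    summary <<- build_report(config)
    yaml::write_yaml(summary, pipe_path(config, "summary.yaml"))
  })
  pipe_log(config, "pipeline done")
  invisible(summary)
}

as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  x$thresholds <- if (!is.null(x$thresholds))
    do.call(filter_thresholds, x$thresholds) else filter_thresholds()
  x$burst <- if (!is.null(x$burst)) do.call(burst_params, x$burst)
             else burst_params()
  do.call(pipeline_config,
          x[intersect(names(x), names(formals(pipeline_config)))])
}

accepted_ids <- function(config) {
  p <- pipe_path(config, "accepted.csv")
  if (file.exists(p)) {
    acc <- read.csv(p)
    acc$trace_id[acc$accepted]
  } else {
    unique(read.csv(pipe_path(config, "fingerprints.csv"))$trace_id)
  }
}

accepted_binding_events <- function(config) {
  ideal <- read_trace_csv(pipe_path(config, "idealized.csv"))
  acc <- accepted_ids(config)
  ideal <- ideal[ideal$trace_id %in% acc, ]
  exposure <- config$simulation$exposure
  ideal |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::group_modify(~ {
      dw <- extract_dwells(.x, exposure = exposure)
      ends <- cumsum(dw$n_frames)
      dw$start_s <- (dw$start_frame - 1) * exposure
      dw$end_s <- ends * exposure
      dw[dw$state == 1L, c("start_s", "end_s")]
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(molecule = "trace_id")
}

build_report <- function(config) {
  grab <- function(name) {
    p <- pipe_path(config, name)
    if (file.exists(p)) read.csv(p) else NULL
  }
  acc <- grab("accepted.csv")
  rates <- grab("rate_constants.csv")
  cv <- grab("lifetime_cv.csv")
  fano <- grab("fano.csv")
  bursts <- grab("bursts.csv")
  list(
    package_version = as.character(utils::packageVersion("smkinetics")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_traces = if (!is.null(acc)) nrow(acc) else NA,
    n_accepted = if (!is.null(acc)) sum(acc$accepted) else NA,
    rate_constants = if (!is.null(rates)) as.list(rates[1, ]) else NULL,
    lifetime_cv = if (!is.null(cv))
      lapply(split(cv, cv$kind), function(r) as.list(r[1, ])) else NULL,
    n_bursts = if (!is.null(bursts)) nrow(bursts) else NA,
    fano = if (!is.null(fano))
      lapply(seq_len(nrow(fano)), function(i) as.list(fano[i, ])) else NULL
  )
}
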