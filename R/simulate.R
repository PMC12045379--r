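#' Configuration for a two-state binding trace simulation
#'
#' Describes a memoryless two-state (bound/unbound) Markov switching process
#' observed at a fixed camera exposure. State lifetimes are converted to
#' per-frame stay probabilities `exp(-exposure / tau)`, so dwell times are
#' geometric in frames with mean `tau / exposure`; the bound state adds
#' `bound_level` counts on top of a zero baseline and i.i.d. Gaussian read
#' noise of sd `noise_sigma` is added to every frame.
#'
#' @param tau_bound Mean bound-state lifetime in seconds (> 0, may be `Inf`).
#' @param tau_unbound Mean unbound-state lifetime in seconds (> 0, may be
#'   `Inf`).
#' @param n_frames Number of frames (>= 2).
#' @param exposure Exposure time per frame in seconds (> 0).
#' @param bound_level Mean intensity of the bound state, in camera counts.
#' @param noise_sigma Per-frame Gaussian noise sd, in counts (>= 0).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param initial_state `"random"` draws the first frame from the stationary
#'   distribution; `"bound"`/`"unbound"` pin it.
#' @param photobleach_rate Optional photobleaching rate in 1/s; after an
#'   exponentially distributed bleaching time the trace emits no further
#'   binding. Default 0 (off), since typical measured bleaching rates
#'   (~0.001/s) are negligible on a 200 s trace.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tau_bound = 1.4, tau_unbound = 3.5, n_frames = 2000,
                       exposure = 0.1, bound_level = 4000, noise_sigma = 400,
                       seed = NULL, initial_state = c("random", "bound", "unbound"),
                       photobleach_rate = 0) {
  initial_state <- match.arg(initial_state)
  check_number(tau_bound, "tau_bound", lower = 1e-12, allow_inf = TRUE)
  check_number(tau_unbound, "tau_unbound", lower = 1e-12, allow_inf = TRUE)
  check_number(n_frames, "n_frames", lower = 2)
  check_number(exposure, "exposure", lower = 1e-12)
  check_number(bound_level, "bound_level")
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(photobleach_rate, "photobleach_rate", lower = 0)
  structure(list(tau_bound = tau_bound, tau_unbound = tau_unbound,
                 n_frames = as.integer(n_frames), exposure = exposure,
                 bound_level = bound_level, noise_sigma = noise_sigma,
                 seed = seed, initial_state = initial_state,
                 photobleach_rate = photobleach_rate),
            class = "sim_config")
}

#' Configuration for a conformationally modulated (bursting) trace
#'
#' Adds a slow hidden accessible/blocked layer on top of a [sim_config()]:
#' the molecule interconverts between an accessible conformation (binding at
#' the base association rate) and a blocked conformation in which the
#' association probability is multiplied by `blocked_binding_factor`
#' (0 = no binding at all). Dissociation is unaffected. This produces
#' bursting binding patterns: runs of rapid repeated binding separated by
#' quiet periods.
#'
#' @param base A [sim_config()].
#' @param accessible_lifetime Mean lifetime of the accessible conformation, s.
#' @param blocked_lifetime Mean lifetime of the blocked conformation, s.
#' @param blocked_binding_factor Multiplier on the per-frame binding
#'   probability while blocked, in `[0, 1]`.
#' @return An object of class `modulated_sim_config`.
#' @export
modulated_sim_config <- function(base = sim_config(),
                                 accessible_lifetime = 10,
                                 blocked_lifetime = 30,
                                 blocked_binding_factor = 0) {
  stopifnot(inherits(base, "sim_config"))
  check_number(accessible_lifetime, "accessible_lifetime", lower = 1e-12,
               allow_inf = TRUE)
  check_number(blocked_lifetime, "blocked_lifetime", lower = 1e-12,
               allow_inf = TRUE)
  check_number(blocked_binding_factor, "blocked_binding_factor",
               lower = 0, upper = 1)
  structure(list(base = base, accessible_lifetime = accessible_lifetime,
                 blocked_lifetime = blocked_lifetime,
                 blocked_binding_factor = blocked_binding_factor),
            class = "modulated_sim_config")
}

#' Specification of a heterogeneous trace population
#'
#' @param components Named list of mixture components; each element is a
#'   list with fields `config` (a [sim_config()] or
#'   [modulated_sim_config()]) and `fraction`. Fractions must sum to 1.
#' @param n_traces Number of traces to draw (>= 1).
#' @param background_trace_rate Fraction of traces replaced by nonspecific
#'   "sticking" background traces: rare, long, heavy-tailed intensity
#'   excursions that lack the rapid repeated binding of specific sites.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(components, n_traces,
                            background_trace_rate = 0) {
  if (length(components) == 0L)
    stop_bad_config("`components` must contain at least one component")
  fr <- vapply(components, function(co) co$fraction, 0)
  if (abs(sum(fr) - 1) > 1e-8)
    stop_bad_config("component fractions must sum to 1 (got %s)",
                    format(sum(fr)))
  ok <- vapply(components, function(co)
    inherits(co$config, "sim_config") ||
      inherits(co$config, "modulated_sim_config"), TRUE)
  if (!all(ok))
    stop_bad_config("every component needs a sim_config or modulated_sim_config")
  check_number(n_traces, "n_traces", lower = 1)
  check_number(background_trace_rate, "background_trace_rate",
               lower = 0, upper = 1)
  if (is.null(names(components)))
    names(components) <- paste0("component_", seq_along(components))
  structure(list(components = components, n_traces = as.integer(n_traces),
                 background_trace_rate = background_trace_rate),
            class = "population_spec")
}

# Alternating geometric run lengths: the exact dwell law of the per-frame
# scheme P(stay) = exp(-1/tau_frames). Returns per-frame state vector.
sample_state_path <- function(n_frames, p_stay, first_state) {
  lens <- integer(0)
  vals <- integer(0)
  cur <- first_state
  total <- 0L
  while (total < n_frames) {
    p <- p_stay[cur + 1L]
    len <- if (p >= 1) n_frames - total else rgeom(1L, 1 - p) + 1L
    len <- min(len, n_frames - total)
    lens[length(lens) + 1L] <- len
    vals[length(vals) + 1L] <- cur
    total <- total + len
    cur <- 1L - cur
  }
  rep.int(vals, lens)
}

stay_prob <- function(tau_s, exposure) {
  if (is.infinite(tau_s)) 1 else exp(-exposure / tau_s)
}

finish_trace <- function(states, config, conformation = NULL) {
  n <- config$n_frames
  noiseless <- states * config$bound_level
  intensity <- noiseless + rnorm(n, 0, config$noise_sigma)
  trace <- tibble::tibble(
    frame = seq_len(n),
    time_s = (seq_len(n) - 1) * config$exposure,
    intensity = intensity,
    true_state = states
  )
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  events <- tibble::tibble(
    state = r$values,
    start_frame = starts,
    n_frames = r$lengths,
    start_s = (starts - 1L) * config$exposure,
    end_s = ends * config$exposure
  )
  out <- list(trace = trace, events = events, config = config)
  if (!is.null(conformation)) out$conformation <- conformation
  structure(out, class = "sm_trace_sim")
}

#' Simulate a two-state single-molecule binding trace
#'
#' Kinetic Monte Carlo simulation of a memoryless bound/unbound switching
#' process sampled at the camera frame rate. The per-frame stay probability
#' in state i is `exp(-1 / tau_i_frames)` with `tau_i_frames =
#' tau_i / exposure`, so dwell times are geometric in frames. States (0 or
#' 1) are scaled by `bound_level` and Gaussian noise of sd `noise_sigma` is
#' added afterwards; random draws are consumed in a fixed order (initial
#' state, state path, then noise) so a seed pins the full output.
#'
#' @param config A [sim_config()].
#' @return A `sm_trace_sim`: list with `trace` (tibble: `frame`, `time_s`,
#'   `intensity`, `true_state`), `events` (tibble of state runs with start
#'   and end times in seconds) and the echoed `config`.
#' @examples
#' sim <- simulate_two_state_trace(sim_config(n_frames = 500, seed = 1))
#' head(sim$trace)
#' @export
simulate_two_state_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() {
    p_stay <- c(stay_prob(config$tau_unbound, config$exposure),
                stay_prob(config$tau_bound, config$exposure))
    first <- switch(config$initial_state,
      bound = 1L,
      unbound = 0L,
      random = {
        pb <- if (is.infinite(config$tau_unbound)) 0 else
          if (is.infinite(config$tau_bound)) 1 else
            config$tau_bound / (config$tau_bound + config$tau_unbound)
        as.integer(runif(1) < pb)
      })
    states <- sample_state_path(config$n_frames, p_stay, first)
    if (config$photobleach_rate > 0) {
      bleach_frame <- ceiling(rexp(1, config$photobleach_rate) / config$exposure)
      if (bleach_frame < config$n_frames)
        states[(bleach_frame + 1L):config$n_frames] <- 0L
    }
    finish_trace(states, config)
  }
  if (!is.null(config$seed)) with_seed_local(config$seed, run()) else run()
}

#' Simulate a conformationally modulated (bursting) trace
#'
#' A hidden accessible/blocked conformational layer evolves with geometric
#' dwells at the stated lifetimes; probe binding proceeds at the base
#' association probability during accessible periods and at
#' `blocked_binding_factor` times that probability during blocked periods.
#' Dissociation is unaffected. Draw order: conformational path, initial
#' binding state, per-frame binding transitions, then noise.
#'
#' @param config A [modulated_sim_config()].
#' @return A `sm_trace_sim` as in [simulate_two_state_trace()], with an
#'   extra `conformation` tibble (`frame`, `accessible`).
#' @export
simulate_bursting_trace <- function(config) {
  stopifnot(inherits(config, "modulated_sim_config"))
  base <- config$base
  run <- function() {
    n <- base$n_frames
    p_stay_conf <- c(stay_prob(config$blocked_lifetime, base$exposure),
                     stay_prob(config$accessible_lifetime, base$exposure))
    pa <- config$accessible_lifetime /
      (config$accessible_lifetime + config$blocked_lifetime)
    conf_first <- as.integer(runif(1) < pa)  # 1 = accessible
    conf <- sample_state_path(n, p_stay_conf, conf_first)

    p_bind_base <- 1 - stay_prob(base$tau_unbound, base$exposure)
    p_unbind <- 1 - stay_prob(base$tau_bound, base$exposure)
    p_bind <- ifelse(conf == 1L, p_bind_base,
                     p_bind_base * config$blocked_binding_factor)
    first <- switch(base$initial_state,
      bound = 1L, unbound = 0L,
      random = as.integer(runif(1) < base$tau_bound /
                            (base$tau_bound + base$tau_unbound)))
    u <- runif(n)
    states <- integer(n)
    cur <- first
    states[1L] <- cur
    for (t in 2:n) {
      cur <- if (cur == 1L) {
        if (u[t] < p_unbind) 0L else 1L
      } else {
        if (u[t] < p_bind[t]) 1L else 0L
      }
      states[t] <- cur
    }
    finish_trace(states, base,
                 conformation = tibble::tibble(frame = seq_len(n),
                                               accessible = conf))
  }
  if (!is.null(base$seed)) with_seed_local(base$seed, run()) else run()
}

# Nonspecific sticking trace: sparse Poisson arrivals of long, heavy-tailed
# (Pareto) dwells. Defeats event-count filters the way negative controls do.
simulate_background_trace <- function(config, event_rate = 0.005,
                                      min_dwell_s = 5, pareto_alpha = 1.2) {
  n <- config$n_frames
  duration <- n * config$exposure
  n_ev <- rpois(1L, event_rate * duration)
  states <- integer(n)
  if (n_ev > 0) {
    starts <- sort(runif(n_ev, 0, duration))
    dur <- min_dwell_s * (1 - runif(n_ev))^(-1 / pareto_alpha)
    for (k in seq_len(n_ev)) {
      f0 <- max(1L, ceiling(starts[k] / config$exposure))
      f1 <- min(n, f0 + max(1L, round(dur[k] / config$exposure)) - 1L)
      states[f0:f1] <- 1L
    }
  }
  finish_trace(states, config)
}

#' Simulate a labeled population of traces
#'
#' Draws `n_traces` i.i.d. from the mixture components of a
#' [population_spec()]; with probability `background_trace_rate` a trace is
#' instead a nonspecific sticking background trace. Component labels and
#' per-trace ground truth are retained.
#'
#' @param spec A [population_spec()].
#' @param seed Integer master seed.
#' @return A tibble with one row per trace: `trace_id`, `component`
#'   (component name or `"background"`), and list-columns `trace`, `events`,
#'   `sim` (the full `sm_trace_sim`).
#' @export
simulate_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed_local(seed, {
    n <- spec$n_traces
    is_bg <- runif(n) < spec$background_trace_rate
    fr <- vapply(spec$components, function(co) co$fraction, 0)
    comp_idx <- sample.int(length(fr), n, replace = TRUE, prob = fr)
    labels <- ifelse(is_bg, "background", names(spec$components)[comp_idx])
    sims <- vector("list", n)
    for (i in seq_len(n)) {
      if (is_bg[i]) {
        cfg <- spec$components[[comp_idx[i]]]$config
        base <- if (inherits(cfg, "modulated_sim_config")) cfg$base else cfg
        base$seed <- NULL
        sims[[i]] <- simulate_background_trace(base)
      } else {
        cfg <- spec$components[[comp_idx[i]]]$config
        if (inherits(cfg, "modulated_sim_config")) {
          cfg$base$seed <- NULL
          sims[[i]] <- simulate_bursting_trace(cfg)
        } else {
          cfg$seed <- NULL
          sims[[i]] <- simulate_two_state_trace(cfg)
        }
      }
    }
    tibble::tibble(
      trace_id = seq_len(n),
      component = labels,
      trace = lapply(sims, `[[`, "trace"),
      events = lapply(sims, `[[`, "events"),
      sim = sims
    )
  })
}

#' Simulate a homogeneous Poisson spike train
#'
#' Event times are uniform on `[0, duration]` given a Poisson-distributed
#' event count with mean `rate * duration`.
#'
#' @param rate Event rate in events/s (>= 0).
#' @param duration Observation span in seconds (> 0).
#' @param seed Optional integer seed.
#' @return A tibble with column `onset_s` (sorted) and attribute
#'   `duration`.
#' @export
simulate_poisson_spike_train <- function(rate, duration, seed = NULL) {
  check_number(rate, "rate", lower = 0)
  check_number(duration, "duration", lower = 1e-12)
  run <- function() {
    n <- rpois(1L, rate * duration)
    tibble::tibble(onset_s = sort(runif(n, 0, duration)))
  }
  out <- if (!is.null(seed)) with_seed_local(seed, run()) else run()
  attr(out, "duration") <- duration
  out
}

#' Simulate a fluorescence movie with ground-truth spots
#'
#' Renders each simulated trace as a diffraction-limited spot: a 2D Gaussian
#' point-spread function (flux-normalized over a patch of radius
#' `4 * psf_sigma`) whose total flux per frame is the trace's noiseless
#' intensity. A constant background and per-pixel Gaussian read noise are
#' added, and counts are clipped at zero.
#'
#' @param spec A [population_spec()]; one spot per trace.
#' @param rows,cols Image dimensions in pixels.
#' @param psf_sigma Gaussian PSF sd in pixels.
#' @param background Constant background level in counts.
#' @param read_noise Per-pixel Gaussian noise sd in counts.
#' @param seed Integer master seed.
#' @param centers Optional matrix/data frame of spot centers (`row`, `col`,
#'   0-based); by default spots are placed on a jittered grid with centers
#'   separated by at least `4 * psf_sigma` and at least 6 px from borders.
#' @param allow_crowding If `FALSE` (default), an overcrowded default layout
#'   is an error.
#' @return A list with `movie` (a `movie_stack`: `data` array of dim
#'   `frames x rows x cols`, `exposure`, `channel`) and `spots` (tibble:
#'   `spot_id`, `row`, `col`, `component`, `captured_flux_3x3` -- the
#'   fraction of `bound_level` flux falling in the central 3x3 window --
#'   plus list-columns `trace`, `events`).
#' @export
simulate_movie <- function(spec, rows = 64, cols = 64, psf_sigma = 1.0,
                           background = 200, read_noise = 60, seed = 1L,
                           centers = NULL, allow_crowding = FALSE) {
  stopifnot(inherits(spec, "population_spec"))
  check_number(rows, "rows", lower = 8)
  check_number(cols, "cols", lower = 8)
  check_number(psf_sigma, "psf_sigma", lower = 0.2)
  n_spots <- spec$n_traces
  sep <- 4 * psf_sigma
  margin <- 6
  if (is.null(centers)) {
    pitch <- ceiling(sep) + 2
    rpos <- seq(margin, rows - 1 - margin, by = pitch)
    cpos <- seq(margin, cols - 1 - margin, by = pitch)
    capacity <- length(rpos) * length(cpos)
    if (capacity < n_spots && !allow_crowding)
      stop_bad_config(paste0("cannot place %d spots with separation %.1f px",
                             " in a %dx%d image (capacity %d)"),
                      n_spots, sep, rows, cols, capacity)
    grid <- expand.grid(row = rpos, col = cpos)
    centers <- grid[seq_len(min(n_spots, capacity)), , drop = FALSE]
  } else {
    centers <- as.data.frame(centers)
  }
  pop <- simulate_population(spec, seed = seed)
  pop <- pop[seq_len(nrow(centers)), , drop = FALSE]
  exposure <- first_exposure(spec)
  n_frames <- first_n_frames(spec)

  with_seed_local(seed + 104729L, {
    movie <- array(0, dim = c(n_frames, rows, cols))
    rad <- ceiling(4 * psf_sigma)
    off <- seq(-rad, rad)
    flux3 <- numeric(nrow(centers))
    flux3_net <- numeric(nrow(centers))
    for (i in seq_len(nrow(centers))) {
      r0 <- centers$row[i]; c0 <- centers$col[i]
      kr <- exp(-off^2 / (2 * psf_sigma^2))
      kern <- outer(kr, kr)
      kern <- kern / sum(kern)
      rr <- r0 + off + 1L  # to 1-based array index
      cc <- c0 + off + 1L
      keep_r <- rr >= 1 & rr <= rows
      keep_c <- cc >= 1 & cc <= cols
      amp <- pop$trace[[i]]$true_state * pop$sim[[i]]$config$bound_level
      patch <- outer(amp, as.vector(kern[keep_r, keep_c, drop = FALSE]))
      dim(patch) <- c(n_frames, sum(keep_r), sum(keep_c))
      movie[, rr[keep_r], cc[keep_c]] <-
        movie[, rr[keep_r], cc[keep_c]] + patch
      ctr <- which(off == 0)
      flux3[i] <- sum(kern[(ctr - 1):(ctr + 1), (ctr - 1):(ctr + 1)])
      ring <- kern[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2)]
      ring_vals <- as.vector(ring)[-c(7:9, 12:14, 17:19)]
      flux3_net[i] <- flux3[i] - 9 * median(ring_vals)
    }
    movie <- movie + background +
      rnorm(length(movie), 0, read_noise)
    movie[movie < 0] <- 0
    spots <- tibble::tibble(
      spot_id = seq_len(nrow(centers)),
      row = as.numeric(centers$row),
      col = as.numeric(centers$col),
      component = pop$component,
      captured_flux_3x3 = flux3,
      captured_flux_net = flux3_net,
      trace = pop$trace,
      events = pop$events
    )
    list(movie = movie_stack(movie, exposure = exposure), spots = spots)
  })
}

first_component_base <- function(spec) {
  cfg <- spec$components[[1]]$config
  if (inherits(cfg, "modulated_sim_config")) cfg$base else cfg
}
first_exposure <- function(spec) first_component_base(spec)$exposure
first_n_frames <- function(spec) first_component_base(spec)$n_frames

#' Construct a movie stack container
#'
#' @param data Numeric array of dim `frames x rows x cols`.
#' @param exposure Exposure time per frame, seconds.
#' @param channel Channel label.
#' @param pixel_size Pixel size (arbitrary units; metadata only).
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, exposure, channel = "ch1", pixel_size = 1) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  check_number(exposure, "exposure", lower = 1e-12)
  structure(list(data = data, exposure = exposure, channel = channel,
                 pixel_size = pixel_size),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames x %d x %d px, exposure %.3g s (%s), duration %.3g s\n",
              d[1], d[2], d[3], x$exposure, x$channel, d[1] * x$exposure))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> tau_bound %.3g s, tau_unbound %.3g s, ",
                     "%d frames @ %.3g s, level %.5g, sigma %.4g\n"),
              x$tau_bound, x$tau_unbound, x$n_frames, x$exposure,
              x$bound_level, x$noise_sigma))
  invisible(x)
}
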