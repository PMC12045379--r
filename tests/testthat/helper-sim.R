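# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

std_config <- function(...) {
  args <- utils::modifyList(
    list(tau_bound = 1.4, tau_unbound = 3.5, n_frames = 2000,
         exposure = 0.1, bound_level = 4000, noise_sigma = 400),
    list(...))
  do.call(sim_config, args)
}

homog_spec <- function(n_traces, n_frames = 2000, ...) {
  population_spec(
    components = list(main = list(config = std_config(n_frames = n_frames,
                                                      ...),
                                  fraction = 1)),
    n_traces = n_traces)
}

# 60 specific + 60 sticking-background traces, idealized and fingerprinted
labeled_fingerprints <- function() {
  fixture("labeled_fp", function() {
    pos <- fingerprint_population(
      simulate_population(homog_spec(60), seed = 301), exposure = 0.1)
    neg_spec <- population_spec(
      components = list(main = list(config = std_config(), fraction = 1)),
      n_traces = 60, background_trace_rate = 1)
    neg <- fingerprint_population(
      simulate_population(neg_spec, seed = 302), exposure = 0.1)
    list(pos = pos, neg = neg)
  })
}

# Midpoint-threshold idealization oracle for noiseless two-level traces
threshold_oracle <- function(intensity, level) as.integer(intensity > level / 2)

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}
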