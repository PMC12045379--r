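# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)))
    stop_bad_config("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stop_bad_config("`%s` must be in [%s, %s], got %s", name,
                    format(lower), format(upper), format(x))
  invisible(x)
}

# Deterministic child seeds derived from a master seed; kept well below
# 2^31 so they are valid R integer seeds on every platform.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) %% 1000003L) * 1000L + seq_len(n) %% 1000L +
    seq_len(n) * 7919L %% 2000000000L
}

with_seed_local <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
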