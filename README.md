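# smkinetics

Single-molecule kinetic fingerprinting analysis in R.

In single-molecule fluorescence kinetic fingerprinting, a dye-labeled
oligonucleotide probe binds a surface-captured target (for example a
microRNA-loaded Argonaute complex pulled down from cell extract)
transiently and repeatedly. Each captured molecule produces an
intensity-versus-time trace whose on/off pattern — the *kinetic
fingerprint* — separates specific repeated binding from nonspecific
sticking, and whose dwell times carry the binding kinetics. `smkinetics`
implements the full analysis chain for such experiments, together with a
ground-truth-labeled simulator so every stage is testable without
microscope data:

* **Simulation** — kinetic Monte Carlo two-state traces (geometric dwell
  times from per-frame stay probabilities `exp(-exposure/tau)`),
  conformationally modulated (bursting) traces, heterogeneous populations
  with nonspecific background traces, Poisson spike trains, and TIFF
  movies with Gaussian-PSF spots.
* **Imaging** — per-pixel fluctuation maps (mean absolute frame-to-frame
  change), local-maximum ROI detection, background-subtracted 3×3 trace
  extraction, and two-channel colocalization.
* **Idealization** — two-state Gaussian-emission HMM (maximum-likelihood
  EM, Viterbi decoding), dwell-time extraction with truncation flags, and
  per-trace fingerprint statistics (N_b+d, median dwell times, maximum
  unbound dwell, signal-to-noise).
* **Fingerprinting** — kinetic filter thresholds, an optimizer trading
  accepted positives against a false-positive budget, Gaussian-mixture
  classification of kinetic subpopulations on log dwell medians, and
  joint two-channel accessibility tables.
* **Kinetics** — single/double exponential dwell-time CDF fits (with an
  SSE < 0.05, R² > 0.99 model-selection rule), rate constants
  `k_dis = 1/τ_bound`, `k_a = 1/(τ_unbound·c)`, `K_D = k_dis/k_a`, and
  per-trace lifetime precision (CV) summaries.
* **Bursting** — global Rank-Surprise burst detection on inter-spike
  intervals, with exact discrete rank-sum null probabilities for short
  runs.
* **Fano statistics** — windowed Fano factors of binding-event trains
  with the χ²/(n−1) 95% null band and a matched Poisson reference.

Results are tibbles, functions compose with the pipe, fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate 50 molecules under typical assay conditions (bound lifetime
1.4 s, unbound 3.5 s at 50 nM probe, 2000 frames at 0.1 s, ~10:1
signal-to-noise), idealize, and summarize:

```r
library(smkinetics)

spec <- population_spec(
  components = list(miRISC = list(
    config = sim_config(tau_bound = 1.4, tau_unbound = 3.5,
                        n_frames = 2000, exposure = 0.1,
                        bound_level = 4000, noise_sigma = 400),
    fraction = 1)),
  n_traces = 50)
pop <- simulate_population(spec, seed = 42)
fp  <- fingerprint_population(pop, exposure = 0.1)
fp$stats
#> # A tibble: 50 × 9
#>   trace_id n_events tau_on_median tau_off_median tau_off_max   snr ...
#> 1        1       83          0.9             2.5        14   10.1
#> 2        2       82          0.75           2.3        16.5 10.1
```

Each trace shows ~80 binding-plus-dissociation events over 200 s — the
repeated probing that gives the method its per-molecule precision.
Pooled dwell-time fits recover the simulated kinetics:

```r
fit_b <- select_cdf_model(dplyr::filter(fp$dwells, state == 1, !truncated),
                          grid = 0.1, min_dwell = 0.2)
fit_b
#> <exp_fit> order 1: tau 1.399 s (m 1, c 0); SSE 0.00164, R2 0.99961, n 1938

fit_u <- select_cdf_model(dplyr::filter(fp$dwells, state == 0, !truncated),
                          grid = 0.1, min_dwell = 0.2)
compute_rate_constants(fit_b, fit_u, conc = 50e-9)
#> # A tibble: 1 × 6
#>   tau_bound tau_unbound k_dis      k_a         K_D       conc
#> 1      1.40        3.23 0.715 6198246. 0.000000115 0.00000005
```

The bound lifetime is recovered to 0.1% (`tau = 1.399 s` versus the
simulated 1.4 s); the pooled unbound lifetime (3.23 s) sits slightly
below the simulated 3.5 s because long unbound dwells are preferentially
censored at trace boundaries in a finite 200 s observation. The derived
rate constants (`k_dis = 0.72 /s`, `k_a = 6.2e6 /M/s`,
`K_D = 115 nM`) satisfy `K_D × k_a = k_dis` exactly. Per-trace
single-exponential fits quantify the per-molecule precision:

```r
per_trace_lifetimes(fp$dwells, exposure = 0.1)
#> # A tibble: 2 × 5
#>   kind    n_traces mean_tau sd_tau cv_pct
#> 1 bound         50     1.40  0.239   17.0
#> 2 unbound       50     3.30  0.641   19.4
```

i.e. a single 200 s trace pins each lifetime to ~17% — close to the
1/sqrt(n_dwells) statistical floor — versus ~100% for a single binding
event. An end-to-end run (`run_pipeline(pipeline_config(...))`) writes
all intermediate CSV/TIFF artifacts plus a machine-readable summary, and
`inst/cli/smkinetics.R` exposes the same stages as a command-line tool.

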