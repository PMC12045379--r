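---
title: "Models and methods behind smkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smkinetics)
```

# The measurement and its model

A kinetic fingerprinting experiment watches one immobilized target
molecule at a time while a fluorescent probe in solution binds and
dissociates repeatedly. The camera integrates fluorescence over frames
of fixed exposure (typically 0.1 s), so the raw datum per molecule is an
intensity trace $I_t$, $t = 1 \dots n$. The package's working model is a
two-state hidden Markov chain: an unbound state emitting
$\mathcal{N}(0, \sigma^2)$ and a bound state emitting
$\mathcal{N}(\mu, \sigma^2)$ with level $\mu \approx 4000$ counts and
$\sigma \approx 0.1\mu$ (signal-to-noise $\approx$ 10). State lifetimes
$\tau_b$ and $\tau_{ub}$ (seconds) translate to per-frame stay
probabilities

$$P_{i \to i} = e^{-1/\tau_i^{(f)}}, \qquad
  \tau_i^{(f)} = \tau_i / \mathrm{exposure},$$

so dwell times are *geometric in frames*; at the camera grid
$x = k \cdot \mathrm{exposure}$ the survival function equals the
continuous exponential, $S(x) = e^{-x/\tau}$, exactly. Memorylessness is
assumed throughout: it underlies the dwell-time fits, the left-truncation
corrections, and the Poisson reference for the Fano factor.

# Synthetic data

`simulate_two_state_trace()` implements exactly this discrete-frame
model rather than simulating continuous-time exponentials and binning:
the discrete model is the one whose statistics the analysis assumes, and
run-length (geometric) sampling of whole dwells produces the identical
law as a frame-by-frame coin flip while being much faster. Random draws
are consumed in a fixed, documented order — initial state, state path,
then noise — so a seed pins the output bit-for-bit, and statistically
equivalent reimplementations can match the contract without matching the
RNG.

Three elaborations cover the phenomena the analysis has to face:

* **Conformational modulation** (`simulate_bursting_trace()`): a hidden
  accessible/blocked layer with its own lifetimes (defaults 10 s / 30 s)
  multiplies the association probability by `blocked_binding_factor`
  (default 0) while blocked. This is a generative stand-in for slow
  switching of binding-site accessibility; it produces bursting event
  trains with Fano factors well above 1. Setting the factor to 1
  provably collapses to the homogeneous model (tested by a
  Kolmogorov–Smirnov comparison of event counts).
* **Nonspecific background** (`background_trace_rate` in
  `simulate_population()`): sticking traces are sparse Poisson arrivals
  (0.005 events/s) of long Pareto-tailed dwells (minimum 5 s, tail index
  1.2). The heavy tail matters: such traces show one or two long, bright
  excursions — enough to fool an intensity threshold, few enough events
  to be rejected by kinetic filters, which is precisely the behavior of
  negative controls.
* **Movies** (`simulate_movie()`): each trace is rendered as a 2D
  Gaussian point-spread function (default sd 1 px) whose *total* flux per
  frame is the trace's noiseless intensity, on a constant background with
  per-pixel read noise, 16-bit TIFF-writable. Spot centers default to a
  jittered grid separated by at least $4\sigma_{\mathrm{PSF}}$. The
  ground truth records, per spot, the fraction of flux captured by the
  central 3×3 window and the same fraction net of the ring-median
  background estimate, which is the exact oracle for the extracted trace
  amplitude. Optical realism beyond this (EMCCD gain statistics,
  evanescent-field profiles, drift) is deliberately out of scope.

Photobleaching is off by default — measured bleaching rates in this kind
of assay (~0.001/s) are negligible over 200 s — but an exponential
bleaching channel is available.

# Spot detection and trace extraction

Binding sites blink; static features do not. The fluctuation map
(mean absolute frame-to-frame change per pixel) therefore concentrates
at true sites, and ROIs are the 3×3 windows centered on its local
maxima. Implementation decisions the upstream description leaves open:

* Detection threshold: map mean + 4 robust (MAD-based) standard
  deviations, exposed as a parameter. At 2000 frames this gives
  recall and precision of 1.0 on simulated fields at SNR 10; at a few
  hundred frames molecules with few events hover near the noise floor.
* Background estimator: per-frame *median* of the 16-pixel ring of the
  surrounding 5×5 neighborhood, times 9, subtracted from the window sum.
  The median resists bleed-through from neighboring spots. Error
  propagation: the extracted trace noise is
  $\sqrt{9\sigma^2 + 81 \cdot \frac{\pi}{32}\sigma^2} \approx 4.1\sigma$
  per frame, slightly above the $3\sigma$ of the bare window sum — the
  ring median is not free.
* Coordinates are 0-based `(row, col)`; ROIs must sit at least 2 px from
  the border so the 5×5 neighborhood fits.
* Colocalization is greedy one-to-one nearest-neighbor matching within a
  radius; channels are assumed registered (an affine-registration hook
  is out of scope for synthetic data).

# Idealization

Traces are idealized with a two-state Gaussian-emission HMM fitted by
maximum-likelihood EM: deterministic initialization (levels at the
10th/90th intensity percentiles, stay probability 0.9), at most 100
iterations, log-likelihood tolerance $10^{-6}$, and Viterbi decoding.
Viterbi rather than posterior-marginal decoding avoids single-frame
flicker at level crossings. A variational-Bayes treatment would add a
prior over models but the contract here is the idealized path, for which
ML-EM is sufficient and simpler to pin down deterministically.

Two guards return a single-state idealization (all unbound, zero
transitions): fitted levels closer than one pooled standard deviation,
and a BIC comparison against a single-Gaussian model. The BIC guard is
essential for pure-noise traces: an unconstrained two-state fit of
Gaussian noise happily splits the distribution into two nearby levels
and produces hundreds of spurious one-frame events; the single-Gaussian
model explains such traces with two parameters instead of seven and wins
by BIC, while any genuine two-level trace at workable SNR prefers the
HMM by a wide margin.

Dwells are runs of constant Viterbi state, converted to seconds; the
first and last runs are flagged truncated and excluded from all fits.
No minimum event length is imposed at this stage — event filtering
belongs to the threshold stage downstream.

# Dwell-time fitting

The empirical CDF is represented at *unique* dwell values (top of each
step), which for frame-quantized data evaluates the model survival
exactly at the sampling grid and makes goodness-of-fit scale-free.

Two fitting routes are offered:

* `weighting = "likelihood"` (default): maximum likelihood on the CDF
  cell increments. With the frame `grid` supplied this is the exact
  geometric MLE (closed form for order 1), unbiased on discretized
  dwells and attaining the $\tau/\sqrt{n}$ efficiency floor. Left
  truncation (the `min_dwell` guard, default 2 frames in the per-trace
  path, protecting against events near the instrument resolution) is
  handled exactly via memorylessness. Order-2 fits use a deterministic
  multi-start EM for two-component geometric/exponential mixtures.
* `weighting = "ls"`: the conventional unweighted least-squares fit of
  the cumulative frequency against $1 - m e^{-x/\tau} + c$ (or the
  two-component analogue), amplitudes free, offset $c$ constrained to
  $[-0.05, 0.05]$.

The likelihood route is the default for a measured reason: at the
per-trace sample sizes this assay produces (~40 complete dwells per
200 s trace), the plain least-squares estimator of $\tau$ carries about
$\sqrt{2}$ more standard error (CV ≈ 22% versus ≈ 16%). The per-molecule
precision this package reports — and the precision the method is valued
for — is only reachable with an efficient estimator; the LS route is
retained for cross-checks and for data without a natural grid.

Model selection (`select_cdf_model()`) fits order 1 first and keeps it
iff SSE < 0.05 and $R^2 > 0.99$ on the normalized ECDF *and* the largest
CDF residual stays inside the 5% Kolmogorov–Smirnov band
($1.358/\sqrt{n}$). The sup-norm band replaces a sign-based runs test
deliberately: ECDF residuals are strongly autocorrelated, so a runs test
rejects correct models at any sample size, while the KS band is valid
and, with fitted parameters, conservative. Whether the SSE rule applies
to raw counts or normalized frequency is ambiguous in the field; we
normalize, which makes 0.05 meaningful across sample sizes (on all $n$
points the SSE of a perfect model concentrates near 1/6 regardless of
fit quality).

Rate constants follow from the fitted (weighted-mean) lifetimes:
$k_{dis} = 1/\tau_b$, $k_a = 1/(\tau_{ub} \cdot c)$ at probe
concentration $c$ (default 50 nM in the pipeline), $K_D = k_{dis}/k_a$,
an identity that holds to machine precision by construction. One known
small-sample effect is worth naming: in a finite trace of length $T$,
long dwells are preferentially truncated at the boundaries, biasing
complete-dwell lifetimes low by roughly $\tau/T$ relative terms
(~2% for $\tau_{ub} = 3.5$ s at $T = 200$ s). This is a property of the
experiment, not the estimator, and affects pooled and per-trace fits
alike.

# Kinetic filtering and classification

`filter_traces()` accepts a trace iff every threshold is satisfied;
missing statistics (a trace without complete dwells) pass only fully
permissive bounds, which keeps acceptance monotone: tightening any
single threshold can only shrink the accepted set.
`optimize_thresholds()` grid-searches candidate cutoffs (quantiles of
the pooled statistics) over the four most discriminative parameters
(minimum event count, maximum median bound dwell, maximum longest
unbound dwell, minimum signal-to-noise), maximizing accepted positives
subject to a false-positive budget (default 2 per field of view,
matching typical negative-control levels), with ties broken toward
stricter thresholds. No per-probe threshold presets are shipped — the
optimizer is the supported path.

The signal-to-noise convention deserves a note: the upstream definition
reads as noise-to-signal (intensity sd divided by level separation).
Both quantities are stored (`noise_to_signal` and its reciprocal `snr`);
filters reference `snr`, so larger is better.

Subpopulation structure is classified on
$(\log \tau_{on,\mathrm{med}}, \log \tau_{off,\mathrm{med}})$ — kinetic
clusters separate in log space — with a Gaussian mixture whose component
count (1 or 2) is chosen by BIC, using the mixture fitter's
deterministic hierarchical initialization. With two components the
cluster with the smaller mean log bound dwell is `"transient"`; with one
component the population is labeled by whether its mean bound dwell is
under 1 s (an absolute convention, documented rather than inferred).

# Burst detection

Binding-event trains are treated like neuronal spike trains. ISIs (gaps
between consecutive binding events, identical to complete unbound
dwells) from *all* molecules are pooled and ranked once — the global
variant, so a burst is defined against the whole dataset and molecules
with few events are not penalized. Within a molecule, maximal runs of
ISIs each ≤ 40 s (the default `max_isi_in_burst`) are candidate regions;
every contiguous sub-window is scored with
$RS = -\log P(\text{sum of } q \text{ i.i.d. uniform ranks} \le S)$,
and bursts are accepted greedily (largest RS first, recursing on the
flanks) while $RS > \alpha$ (default 3, natural log — the convention in
which a surprise of 10 means $p = 4.5\times10^{-5}$). The null CDF is
computed by exact iterated convolution for runs of up to 10 ISIs
(matched against brute-force enumeration to $10^{-9}$ in the tests) and
by a continuity-corrected Gaussian beyond. Ties receive average ranks,
which prevents spurious surprise from frame-discretized dwell times.

A property of the published parameterization worth knowing: on a purely
homogeneous (Poisson) dataset the exhaustive scan at $\alpha = 3$ labels
roughly 15% of ISIs as burst — $\alpha = 3$ is a per-window $p < 0.05$
applied to many windows. The protection the method actually relies on is
the *global* ranking: memoryless molecules pooled with genuinely bursty
ones collect almost no burst labels (measured ≈ 2% in the tests),
because their ISIs rank high in the shared ranking. Downstream,
`burst_statistics()` fits single exponentials to burst and non-burst ISI
classes and warns when the burst timescale is not at least 10× faster
than the non-burst timescale, the regime in which interpreting the
non-burst class as a slow conformational process is sound.

# Fano factors

A "spike" is a binding-event onset. For each molecule,
`samples_per_molecule` (default 100) windows of length $T$ are placed
uniformly at random within the observation span; $F = \mathrm{var}/\mathrm{mean}$
of the pooled counts is reported per $T$ (defaults 5, 10, 20, 40 s),
alongside per-molecule Fano values. The 95% band is the
$\chi^2_{n-1}/(n-1)$ (equivalently Gamma$((n-1)/2,\ 2/(n-1))$) null
range with $n$ = the *per-molecule* sampling count, i.e. the null for a
single molecule's Fano estimate. This convention was chosen after
measurement: taking $n$ as the total pooled sample count makes the band
so narrow that the four-window joint coverage of a genuinely Poisson
process drops to $0.95^4 \approx 81\%$, and overlapping windows from a
shared train (whose counts are correlated) collapse it entirely; against
the per-molecule band, the aggregate $F$ of a Poisson process sits
comfortably inside while per-molecule values hit the band at the nominal
~95% rate — both properties are asserted in the tests. The Poisson
reference (`poisson_fano_reference()`) draws counts directly from a
Poisson generator at the matched rate and sampling depth, mirroring how
a memoryless process populates disjoint windows.

# Pipeline, determinism, and problem sizes

`run_pipeline()` executes simulate → (detect → extract) → idealize →
fingerprint → fit → burst → fano → report, with stages communicating
only via CSV/TIFF files in the output directory, so any suffix of the
pipeline can be re-run on existing artifacts. The report embeds the
seed, package version, and a hash of the configuration; identical
configuration and seed give byte-identical tables. All randomness flows
from explicit seeds (kept below $2^{31}$), including per-stage derived
seeds.

The test suite runs every module at desk scale: $10^5$-dwell simulations
for distributional laws, 400-trace precision simulations (about six
seconds with the compiled HMM core), 2000-frame detection movies, and
200-replicate Fano calibrations. The acceptance script averages the
per-trace CV over three independent 400-trace repetitions to report a
stable estimate of the same experiment.

# What passing tests do and do not show

The simulator generates the statistical structure the analysis assumes —
Markovian two-state switching, Gaussian noise, geometric dwells, slow
two-state modulation, heavy-tailed sticking. Real traces add effects the
generator deliberately omits: camera gain noise and pixel nonuniformity,
stage drift, fluorophore blinking and photophysics beyond simple
bleaching, diffusion-limited rebinding, and continuous (rather than
two-state) heterogeneity in binding kinetics. Green tests therefore
certify the *analysis chain* — that each stage recovers what the model
says it should, at the stated precision — not that the model captures
any particular instrument. Quantities that depend on real cell-extract
data (experimental rate-constant tables, accepted-molecule counts per
field of view, experimental population fractions) are exposed as
computations and validated by properties (identities, generator labels,
permutation controls), not by their published values.
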