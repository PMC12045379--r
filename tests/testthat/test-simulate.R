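test_that("per-frame stay probability matches exp(-1/tau_frames)", {
  # tau_bound = 14 frames; empirical bound->bound frequency over >= 1e6
  # frames must match exp(-1/14) = 0.93117 closely
  cfg <- sim_config(tau_bound = 1.4, tau_unbound = 0.3, n_frames = 1.2e6,
                    exposure = 0.1, noise_sigma = 0, seed = 101)
  s <- simulate_two_state_trace(cfg)$trace$true_state
  from_b <- which(s[-length(s)] == 1L)
  freq <- mean(s[from_b + 1L] == 1L)
  expect_equal(freq, exp(-1 / 14), tolerance = 0.001 / exp(-1 / 14))
  # unbound side too (tau = 3 frames)
  from_u <- which(s[-length(s)] == 0L)
  expect_equal(mean(s[from_u + 1L] == 0L), exp(-1 / 3), tolerance = 0.005)
})

test_that("empirical dwell distribution is geometric with the right mean", {
  cfg <- sim_config(tau_bound = 0.3, tau_unbound = 0.3, n_frames = 8.5e5,
                    exposure = 0.1, noise_sigma = 0, seed = 102)
  ev <- simulate_two_state_trace(cfg)$events
  k <- ev$n_frames[ev$state == 1L]
  k <- k[-c(1, length(k))]
  expect_gt(length(k), 9e4)
  # chi-square goodness of fit against geometric(p) with the true p,
  # tail lumped so expected counts stay large
  p <- 1 - exp(-1 / 3)
  kmax <- 15
  obs <- tabulate(pmin(k, kmax), nbins = kmax)
  expected <- (1 - p)^(seq_len(kmax) - 1) * p
  expected[kmax] <- (1 - p)^(kmax - 1)
  chi2 <- sum((obs - length(k) * expected)^2 / (length(k) * expected))
  expect_lt(chi2, qchisq(0.99, df = kmax - 1))
  expect_equal(mean(k), 1 / p, tolerance = 0.02)
})

test_that("noise calibration and seed determinism hold", {
  cfg <- sim_config(tau_unbound = Inf, initial_state = "unbound",
                    n_frames = 1e5, noise_sigma = 400, seed = 103)
  s <- simulate_two_state_trace(cfg)
  expect_true(all(s$trace$true_state == 0L))
  expect_equal(sd(s$trace$intensity), 400, tolerance = 0.02)
  expect_equal(mean(s$trace$intensity), 0, tolerance = 5)
  s2 <- simulate_two_state_trace(cfg)
  expect_identical(s$trace, s2$trace)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(tau_bound = 0), "tau_bound")
  expect_error(sim_config(tau_bound = NaN), "tau_bound")
  expect_error(sim_config(n_frames = 1), "n_frames")
  expect_error(sim_config(noise_sigma = -1), "noise_sigma")
  expect_error(modulated_sim_config(sim_config(), blocked_binding_factor = 2),
               "blocked_binding_factor")
  expect_error(population_spec(list(), 5), "component")
  expect_error(population_spec(
    list(a = list(config = sim_config(), fraction = 0.5)), 5), "sum to 1")
})

test_that("degenerate modulation reduces to the homogeneous model", {
  base <- sim_config(tau_bound = 1.4, tau_unbound = 3.5, n_frames = 2000,
                     noise_sigma = 0)
  mc <- modulated_sim_config(base, accessible_lifetime = 10,
                             blocked_lifetime = 30,
                             blocked_binding_factor = 1)
  set.seed(104)
  n_mod <- replicate(120, sum(diff(
    simulate_bursting_trace(mc)$trace$true_state) == 1L))
  n_hom <- replicate(120, sum(diff(
    simulate_two_state_trace(base)$trace$true_state) == 1L))
  expect_gt(suppressWarnings(ks.test(n_mod, n_hom)$p.value), 0.01)
})

test_that("fully blocked periods carry no events and match occupancy", {
  base <- sim_config(tau_bound = 0.5, tau_unbound = 1, n_frames = 4e4,
                     noise_sigma = 0)
  mc <- modulated_sim_config(base, accessible_lifetime = 10,
                             blocked_lifetime = 30,
                             blocked_binding_factor = 0)
  set.seed(105)
  s <- simulate_bursting_trace(mc)
  blocked_frac <- mean(s$conformation$accessible == 0L)
  expect_equal(blocked_frac, 0.75, tolerance = 0.1)
  # no binding transition may start while blocked
  starts <- which(diff(s$trace$true_state) == 1L) + 1L
  expect_true(all(s$conformation$accessible[starts] == 1L))
})

test_that("population draws respect fractions and keep labels", {
  spec <- population_spec(
    components = list(
      a = list(config = sim_config(n_frames = 50), fraction = 0.5),
      b = list(config = sim_config(tau_bound = 20, n_frames = 50),
               fraction = 0.5)),
    n_traces = 1000)
  pop <- simulate_population(spec, seed = 106)
  n_a <- sum(pop$component == "a")
  # binomial 99% interval around 500
  expect_true(abs(n_a - 500) < qnorm(0.995) * sqrt(1000 * 0.25) + 1)
  single <- simulate_population(
    population_spec(components = list(
      only = list(config = sim_config(n_frames = 50), fraction = 1)),
      n_traces = 20), seed = 107)
  expect_true(all(single$component == "only"))
})

test_that("poisson spike trains have the right moments and determinism", {
  expect_equal(nrow(simulate_poisson_spike_train(0, 100, seed = 1)), 0L)
  set.seed(108)
  counts <- replicate(3000, nrow(simulate_poisson_spike_train(0.2, 200)))
  expect_equal(mean(counts), 40, tolerance = 0.03)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.08)
  t1 <- simulate_poisson_spike_train(0.5, 100, seed = 42)
  t2 <- simulate_poisson_spike_train(0.5, 100, seed = 42)
  expect_identical(t1, t2)
  expect_error(simulate_poisson_spike_train(-1, 10), "rate")
})

test_that("movie simulation produces correct metadata and layout limits", {
  spec <- homog_spec(4, n_frames = 40)
  mv <- simulate_movie(spec, rows = 32, cols = 32, seed = 109)
  d <- dim(mv$movie$data)
  expect_equal(d, c(40, 32, 32))
  expect_equal(d[1] * mv$movie$exposure, 4)
  expect_true(all(mv$movie$data >= 0))
  expect_equal(nrow(mv$spots), 4)
  # overcrowding: far too many spots for the image
  expect_error(simulate_movie(homog_spec(500, n_frames = 10),
                              rows = 16, cols = 16, seed = 1),
               "cannot place")
})

test_that("photobleaching truncates binding activity", {
  cfg <- sim_config(tau_bound = 1, tau_unbound = 1, n_frames = 5000,
                    noise_sigma = 0, photobleach_rate = 0.05, seed = 110)
  s <- simulate_two_state_trace(cfg)
  last_bound <- max(which(s$trace$true_state == 1L))
  expect_lt(last_bound, 5000)
})
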