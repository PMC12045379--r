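test_that("ISIs are gaps between consecutive binding events", {
  ev <- tibble::tibble(start_s = c(1, 5), end_s = c(2, 6))
  expect_equal(compute_isis(ev)$isi_s, 3)
  expect_equal(nrow(compute_isis(ev[1, ])), 0L)
  # ISI multiset of a simulated trace equals its complete unbound dwells
  sim <- simulate_two_state_trace(sim_config(n_frames = 3000, seed = 701))
  isis <- compute_isis(sim$events)
  k <- nrow(sim$events)
  interior_unbound <- sim$events$n_frames[sim$events$state == 0L &
                                            !seq_len(k) %in% c(1L, k)] * 0.1
  expect_equal(sort(isis$isi_s), sort(interior_unbound))
})

test_that("exact rank-sum null matches brute-force enumeration to 1e-9", {
  for (N in c(7, 12, 40)) {
    for (q in 1:3) {
      cdf <- smkinetics:::rank_sum_null_cdf(q, N)
      grids <- do.call(expand.grid, rep(list(seq_len(N)), q))
      sums <- rowSums(grids)
      brute <- vapply(seq(q, q * N), function(s) mean(sums <= s), 0)
      expect_lt(max(abs(cdf - brute)), 1e-9)
    }
  }
})

test_that("a run of short ISIs among long ones is detected as one burst", {
  isis <- tibble::tibble(molecule = 1L, isi_index = 1:40,
                         isi_s = c(rep(30, 10), rep(0.2, 20), rep(30, 10)))
  ann <- global_rank_surprise(isis, burst_params(max_isi_in_burst = 40,
                                                 alpha = 3))
  expect_equal(nrow(ann$bursts), 1L)
  expect_equal(ann$bursts$first_isi, 11L)
  expect_equal(ann$bursts$last_isi, 30L)
  expect_equal(ann$bursts$n_isis, 20L)
  # burst boundary convention: events bracketing the ISI run
  expect_equal(ann$bursts$first_event, 11L)
  expect_equal(ann$bursts$last_event, 31L)
  expect_equal(sum(ann$isis$in_burst), 20L)
})

test_that("burst RS values agree with enumeration on a small instance", {
  # three clearly short ISIs among 27 long ones: burst of q = 3
  isis <- tibble::tibble(molecule = 1L, isi_index = 1:30,
                         isi_s = c(rep(20, 14), c(0.2, 0.3, 0.25),
                                   rep(20, 13)))
  ann <- global_rank_surprise(isis, burst_params(max_isi_in_burst = 40,
                                                 alpha = 3))
  expect_equal(nrow(ann$bursts), 1L)
  expect_equal(ann$bursts$n_isis, 3L)
  N <- 30
  r <- rank(isis$isi_s, ties.method = "average")
  S <- sum(r[15:17])
  expect_equal(ann$bursts$rank_sum, S)
  grids <- do.call(expand.grid, rep(list(seq_len(N)), 3))
  p_brute <- mean(rowSums(grids) <= floor(S))
  expect_equal(ann$bursts$rs, -log(p_brute), tolerance = 1e-9)
})

test_that("uniform ISIs carry no surprise and Poisson trains few bursts", {
  flat <- tibble::tibble(molecule = rep(1:3, each = 10),
                         isi_index = rep(1:10, 3), isi_s = 2)
  ann <- global_rank_surprise(flat, burst_params(max_isi_in_burst = 40,
                                                 alpha = 3))
  expect_equal(nrow(ann$bursts), 0L)

  # on a purely homogeneous dataset the exhaustive scan flags a bounded
  # fraction of ISIs, and a stricter cutoff flags monotonically fewer
  set.seed(702)
  pois <- dplyr::bind_rows(lapply(1:80, function(m)
    tibble::tibble(molecule = m, isi_index = 1:25,
                   isi_s = rexp(25, 1 / 3))))
  annp <- global_rank_surprise(pois, burst_params(max_isi_in_burst = 40,
                                                  alpha = 3))
  expect_lte(mean(annp$isis$in_burst), 0.25)
  ann6 <- global_rank_surprise(pois, burst_params(max_isi_in_burst = 40,
                                                  alpha = 6))
  expect_lt(mean(ann6$isis$in_burst), mean(annp$isis$in_burst))
  expect_lte(mean(ann6$isis$in_burst), 0.05)
})

test_that("global ranking protects homogeneous molecules in mixed datasets", {
  # the false-positive control that matches the global method: memoryless
  # molecules pooled with bursty ones collect almost no burst labels,
  # because their ISIs rank high in the shared ranking
  set.seed(705)
  mc <- modulated_sim_config(
    sim_config(tau_bound = 0.5, tau_unbound = 2, n_frames = 2000,
               noise_sigma = 0),
    accessible_lifetime = 10, blocked_lifetime = 30,
    blocked_binding_factor = 0)
  bursty <- dplyr::bind_rows(lapply(1:40, function(m)
    dplyr::mutate(compute_isis(simulate_bursting_trace(mc)$events),
                  molecule = m)))
  pois <- dplyr::bind_rows(lapply(41:80, function(m)
    tibble::tibble(molecule = m, isi_index = 1:10,
                   isi_s = rexp(10, 1 / 20))))
  ann <- global_rank_surprise(dplyr::bind_rows(bursty, pois),
                              burst_params(40, 3))
  lab <- ann$isis
  expect_lte(mean(lab$in_burst[lab$molecule > 40]), 0.05)
  expect_gte(mean(lab$in_burst[lab$molecule <= 40]), 0.2)
  # burst-labeled ISIs are systematically shorter
  expect_lt(median(lab$isi_s[lab$in_burst]),
            median(lab$isi_s[!lab$in_burst]))
})

test_that("burst labels are invariant to a common time rescaling", {
  set.seed(703)
  isis <- dplyr::bind_rows(lapply(1:10, function(m)
    tibble::tibble(molecule = m, isi_index = 1:30,
                   isi_s = rexp(30, 1 / ifelse(m %% 2, 0.5, 10)))))
  a1 <- global_rank_surprise(isis, burst_params(40, 3))
  scaled <- dplyr::mutate(isis, isi_s = isi_s * 7)
  a2 <- global_rank_surprise(scaled, burst_params(40 * 7, 3))
  expect_equal(a1$isis$in_burst, a2$isis$in_burst)
  expect_equal(a1$bursts$rs, a2$bursts$rs)
  expect_equal(a1$isis$rank, a2$isis$rank)
})

test_that("burst statistics separate modulated timescales", {
  set.seed(704)
  mc <- modulated_sim_config(
    sim_config(tau_bound = 0.5, tau_unbound = 2, n_frames = 4000,
               noise_sigma = 0),
    accessible_lifetime = 10, blocked_lifetime = 30,
    blocked_binding_factor = 0)
  ev <- dplyr::bind_rows(lapply(1:25, function(m) {
    e <- simulate_bursting_trace(mc)$events
    e <- e[e$state == 1L, ]
    e$molecule <- m
    e
  }))
  ann <- global_rank_surprise(compute_isis(ev), burst_params(40, 3))
  bs <- suppressWarnings(burst_statistics(ann, grid = 0.1))
  med <- setNames(bs$isi_summary$median_isi, bs$isi_summary$class)
  expect_lt(med[["burst"]], med[["non_burst"]])
  expect_true(all(c("burst", "non_burst") %in% bs$durations$class))
  # no-burst edge case: burst class reported as missing
  flat <- global_rank_surprise(
    tibble::tibble(molecule = 1, isi_index = 1:10, isi_s = 2),
    burst_params(40, 3))
  bs0 <- burst_statistics(flat)
  expect_null(bs0$fits$burst)
  expect_equal(sum(bs0$isi_summary$n), 10)
})
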