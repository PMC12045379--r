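fake_stats <- function(n_events, tau_on, tau_off, tau_off_max, snr,
                       amp = 4000) {
  tibble::tibble(trace_id = seq_along(n_events), n_events = n_events,
                 tau_on_median = tau_on, tau_off_median = tau_off,
                 tau_off_max = tau_off_max, snr = snr,
                 noise_to_signal = 1 / snr, level_unbound = 0,
                 level_bound = amp)
}

test_that("filtering applies every bound and matches hand computation", {
  st <- fake_stats(n_events = c(40, 3, 60),
                   tau_on = c(1, 1, 8),
                   tau_off = c(3, 3, 3),
                   tau_off_max = c(20, 20, 20),
                   snr = c(10, 10, 10))
  thr <- filter_thresholds(min_n_events = 10, max_tau_on_median = 5)
  fl <- filter_traces(st, thr)
  expect_equal(fl$accepted, c(TRUE, FALSE, FALSE))
  expect_equal(attr(fl, "n_accepted"), 1L)
  # unsatisfiable thresholds accept nothing
  none <- filter_traces(st, filter_thresholds(min_n_events = Inf))
  expect_equal(attr(none, "n_accepted"), 0L)
  # missing statistics fail finite bounds but pass permissive ones
  st$tau_on_median[1] <- NA
  expect_false(filter_traces(st, thr)$accepted[1])
  expect_true(filter_traces(st, filter_thresholds())$accepted[1])
  expect_error(filter_thresholds(min_tau_on_median = 2,
                                 max_tau_on_median = 1), "bounds")
})

test_that("tightening any single threshold never gains traces", {
  set.seed(601)
  st <- fake_stats(n_events = rpois(200, 30),
                   tau_on = rexp(200, 1), tau_off = rexp(200, 1 / 3),
                   tau_off_max = rexp(200, 1 / 20), snr = runif(200, 2, 12))
  base <- filter_thresholds(min_n_events = 10, max_tau_on_median = 3,
                            max_tau_off_median = 10, max_tau_off_max = 60,
                            min_snr = 4)
  n0 <- attr(filter_traces(st, base), "n_accepted")
  tighter <- list(
    filter_thresholds(min_n_events = 20, max_tau_on_median = 3,
                      max_tau_off_median = 10, max_tau_off_max = 60,
                      min_snr = 4),
    filter_thresholds(min_n_events = 10, max_tau_on_median = 1,
                      max_tau_off_median = 10, max_tau_off_max = 60,
                      min_snr = 4),
    filter_thresholds(min_n_events = 10, max_tau_on_median = 3,
                      max_tau_off_median = 4, max_tau_off_max = 60,
                      min_snr = 4),
    filter_thresholds(min_n_events = 10, max_tau_on_median = 3,
                      max_tau_off_median = 10, max_tau_off_max = 30,
                      min_snr = 4),
    filter_thresholds(min_n_events = 10, max_tau_on_median = 3,
                      max_tau_off_median = 10, max_tau_off_max = 60,
                      min_snr = 8))
  for (thr in tighter)
    expect_lte(attr(filter_traces(st, thr), "n_accepted"), n0)
})

test_that("threshold optimization separates separable sets perfectly", {
  pos <- fake_stats(n_events = 60 + 1:20, tau_on = 1, tau_off = 3,
                    tau_off_max = 15, snr = 10)
  neg <- fake_stats(n_events = rep(2, 20), tau_on = 30, tau_off = 50,
                    tau_off_max = 150, snr = 3)
  thr <- optimize_thresholds(pos, neg, fp_budget = 0)
  perf <- attr(thr, "performance")
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$n_false_positive, 0L)
  expect_error(optimize_thresholds(pos[0, ], neg), "positive")
})

test_that("zero budget with overlapping sets yields strict feasible thresholds", {
  set.seed(602)
  pos <- fake_stats(n_events = rpois(50, 40), tau_on = 1, tau_off = 3,
                    tau_off_max = 15, snr = 10)
  neg <- fake_stats(n_events = rpois(50, 40), tau_on = 1, tau_off = 3,
                    tau_off_max = 15, snr = 10)   # identical distributions
  thr <- optimize_thresholds(pos, neg, fp_budget = 0)
  expect_equal(attr(thr, "performance")$n_false_positive, 0L)
})

test_that("optimized filters keep positives and reject sticking negatives", {
  fx <- labeled_fingerprints()
  thr <- optimize_thresholds(fx$pos$stats, fx$neg$stats, fp_budget = 2)
  perf <- attr(thr, "performance")
  expect_gte(perf$sensitivity, 0.90)
  expect_lte(perf$n_false_positive, 2L)
  # negative-only field of view: at most 2 accepted
  fl <- filter_traces(fx$neg$stats, thr)
  expect_lte(attr(fl, "n_accepted"), 2L)
})

test_that("kinetic subpopulations are recovered from dwell statistics", {
  # per-trace median dwells sampled at the study's per-trace depth,
  # without the (already tested) HMM step
  make_stats <- function(n, tau_on_s, seed) {
    set.seed(seed)
    tibble::tibble(
      trace_id = seq_len(n),
      tau_on_median = vapply(seq_len(n), function(i)
        median((rgeom(40, 1 - exp(-1 / (tau_on_s / 0.1))) + 1) * 0.1), 0),
      tau_off_median = vapply(seq_len(n), function(i)
        median((rgeom(40, 1 - exp(-1 / 35)) + 1) * 0.1), 0))
  }
  mix <- dplyr::bind_rows(make_stats(100, 0.2, 603),
                          dplyr::mutate(make_stats(100, 20, 604),
                                        trace_id = trace_id + 100))
  cl <- classify_kinetic_populations(mix)
  expect_equal(cl$n_components, 2L)
  fr <- cl$fractions
  expect_equal(fr$fraction[fr$label == "transient"], 0.5, tolerance = 0.1)
  # labels line up with the generating population
  lab <- tidy(cl)
  expect_gte(mean(lab$label[lab$trace_id <= 100] == "transient"), 0.95)
  expect_gte(mean(lab$label[lab$trace_id > 100] == "long_lived"), 0.95)

  # 25/75 mixture: ordering and fractions within 5 points
  mix2 <- dplyr::bind_rows(make_stats(50, 0.2, 605),
                           dplyr::mutate(make_stats(150, 20, 606),
                                         trace_id = trace_id + 50))
  cl2 <- classify_kinetic_populations(mix2)
  fr2 <- cl2$fractions
  expect_equal(fr2$fraction[fr2$label == "transient"], 0.25,
               tolerance = 0.2)
  # single population: one component
  single <- classify_kinetic_populations(make_stats(80, 1.4, 607))
  expect_equal(single$n_components, 1L)
  expect_error(classify_kinetic_populations(make_stats(5, 1.4, 608)),
               "at least")
})

test_that("classification is invariant to trace order and time rescaling", {
  set.seed(609)
  st <- tibble::tibble(
    trace_id = 1:60,
    tau_on_median = c(rexp(30, 1 / 0.2), rexp(30, 1 / 20)) + 0.05,
    tau_off_median = rexp(60, 1 / 3) + 0.05)
  cl <- classify_kinetic_populations(st)
  perm <- sample(60)
  cl_perm <- classify_kinetic_populations(st[perm, ])
  m <- match(tidy(cl)$trace_id, tidy(cl_perm)$trace_id)
  expect_equal(tidy(cl)$label, tidy(cl_perm)$label[m])
  cl_scaled <- classify_kinetic_populations(
    dplyr::mutate(st, tau_on_median = tau_on_median * 60,
                  tau_off_median = tau_off_median * 60))
  expect_equal(tidy(cl)$label, tidy(cl_scaled)$label)
})

test_that("joint accessibility fractions and permutation control behave", {
  a <- tibble::tibble(roi_id = 1:40, row = rep(1:8, 5) * 10,
                      col = rep(1:5, each = 8) * 10)
  b <- dplyr::mutate(a, roi_id = roi_id)
  coloc <- colocalize_rois(a, b, radius = 1)
  fa <- tibble::tibble(roi_id = 1:40, accepted = rep(c(TRUE, FALSE), 20))
  fb <- tibble::tibble(roi_id = 1:40, accepted = rep(c(TRUE, FALSE), 20),
                       label = rep(c("transient", "long_lived"), each = 20))
  ja <- joint_accessibility(coloc, fa, fb)
  expect_equal(sum(ja$fractions$fraction), 1)
  expect_equal(ja$fractions$fraction[ja$fractions$category == "both"], 0.5)
  # disjoint ROI sets: no molecule can be 'both'
  b_far <- dplyr::mutate(b, row = row + 500)
  ja2 <- joint_accessibility(colocalize_rois(a, b_far, radius = 1), fa, fb)
  expect_equal(ja2$fractions$fraction[ja2$fractions$category == "both"], 0)

  # permutation control: random channel-B positions colocalize at most at
  # the analytic chance level (density times matching area)
  set.seed(610)
  both_frac <- replicate(40, {
    b_rand <- tibble::tibble(roi_id = 1:40, row = runif(40, 0, 100),
                             col = runif(40, 0, 100))
    cl <- colocalize_rois(a, b_rand, radius = 1)
    ja <- joint_accessibility(cl, fa, dplyr::mutate(b_rand, accepted = TRUE))
    sum(ja$fractions$n[ja$fractions$category == "both"])
  })
  chance_pairs <- 40 * (40 * pi * 1^2 / 100^2) * 0.5  # accepted half of A
  expect_lt(mean(both_frac), chance_pairs + 3 * sd(both_frac) /
              sqrt(length(both_frac)) + 0.5)
})
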