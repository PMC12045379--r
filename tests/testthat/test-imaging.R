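make_movie <- function(arr, exposure = 0.1) movie_stack(arr, exposure)

test_that("fluctuation map averages absolute frame differences", {
  m <- array(5, dim = c(10, 8, 8))
  expect_true(all(compute_fluctuation_map(make_movie(m)) == 0))
  m[, 4, 5] <- rep(c(0, 4000), 5)
  fm <- compute_fluctuation_map(make_movie(m))
  expect_equal(fm[4, 5], 4000)
  expect_equal(sum(fm != 0), 1)
  expect_error(compute_fluctuation_map(make_movie(array(1, c(1, 8, 8)))),
               "2 frames")
})

test_that("ROI detection finds maxima, suppresses neighbors, orders deterministically", {
  expect_equal(nrow(detect_rois(matrix(0, 16, 16), threshold = 0.5)), 0L)
  m <- matrix(0, 16, 16)
  m[8, 8] <- 10          # 0-based (7, 7)
  m[8, 9] <- 8           # 1 px away, dimmer
  m[12, 4] <- 9
  rois <- detect_rois(m, min_separation = 2, threshold = 1)
  expect_equal(rois$row, c(7L, 11L))
  expect_equal(rois$col, c(7L, 3L))
  expect_equal(rois$peak, c(10, 9))
})

test_that("ROI detection is translation-equivariant", {
  spec <- homog_spec(3, n_frames = 200)
  mv <- simulate_movie(spec, rows = 32, cols = 32, seed = 201)
  fm <- compute_fluctuation_map(mv$movie)
  r0 <- detect_rois(fm, threshold = mean(fm) + 4 * mad(fm))
  shifted <- fm[c(2:nrow(fm), 1), ]   # shift up by one row
  r1 <- detect_rois(shifted, threshold = mean(fm) + 4 * mad(fm))
  keep <- r0$row >= 3   # rows that stay interior after the shift
  expect_setequal(paste(r0$row[keep] - 1, r0$col[keep]),
                  paste(r1$row, r1$col))
})

test_that("spot recovery on a simulated SNR-10 movie is nearly perfect", {
  spec <- homog_spec(10, n_frames = 2000)
  mv <- simulate_movie(spec, rows = 48, cols = 48, psf_sigma = 1,
                       background = 200, read_noise = 60, seed = 202)
  fm <- compute_fluctuation_map(mv$movie)
  rois <- detect_rois(fm, min_separation = 3)
  d_truth <- sapply(seq_len(nrow(mv$spots)), function(i)
    min(sqrt((rois$row - mv$spots$row[i])^2 +
               (rois$col - mv$spots$col[i])^2)))
  d_roi <- sapply(seq_len(nrow(rois)), function(j)
    min(sqrt((rois$row[j] - mv$spots$row)^2 +
               (rois$col[j] - mv$spots$col)^2)))
  expect_gte(mean(d_truth <= 1), 0.95)   # recall
  expect_gte(mean(d_roi <= 1), 0.95)     # precision
  # top fluctuation maxima coincide with true centers
  expect_true(all(d_roi[seq_len(5)] <= 1))

  # extracted amplitude matches the rendered-flux oracle within 5%
  i <- which(mv$spots$row == rois$row[1] & mv$spots$col == rois$col[1])
  tr <- extract_trace(mv$movie, rois[1, ])
  id <- idealize_two_state(tr, exposure = 0.1)
  expect_equal(id$mu[2] - id$mu[1],
               4000 * mv$spots$captured_flux_net[i], tolerance = 0.05)
})

test_that("trace extraction subtracts the ring-median background", {
  m <- array(7, dim = c(5, 12, 12))    # ring value b = 7
  m[, 5:7, 5:7] <- 20                  # window value c = 20
  tr <- extract_trace(make_movie(m), c(5, 5))
  expect_true(all(tr$intensity == 9 * (20 - 7)))
  # linearity in the movie
  tr2 <- extract_trace(make_movie(m * 3), c(5, 5))
  expect_equal(tr2$intensity, 3 * tr$intensity)
  # border ROIs are rejected
  expect_error(extract_trace(make_movie(m), c(1, 5)), "border")
})

test_that("all-background ROI traces have near-zero mean and expected noise", {
  set.seed(203)
  m <- array(rnorm(200 * 20 * 20, mean = 100, sd = 60), c(200, 20, 20))
  tr <- extract_trace(make_movie(m), c(10, 10))
  expect_lt(abs(mean(tr$intensity)), 3 * 60 / sqrt(200) * 3)
  # error propagation: var = 9 sigma^2 (window sum) plus 81 times the
  # variance of a median of 16 normals (~ pi/(2*16) sigma^2)
  expected_sd <- sqrt(9 * 60^2 + 81 * pi / 32 * 60^2)
  expect_equal(sd(tr$intensity), expected_sd, tolerance = 0.1)
})

test_that("colocalization matches greedily one-to-one within the radius", {
  a <- tibble::tibble(roi_id = 1:4, row = c(5, 10, 15, 20),
                      col = c(5, 10, 15, 20))
  same <- colocalize_rois(a, a, radius = 0)
  expect_equal(nrow(same$pairs), 4)
  expect_equal(same$pairs$roi_a, same$pairs$roi_b)
  none <- colocalize_rois(a, a[0, ], radius = 5)
  expect_equal(nrow(none$pairs), 0)
  expect_equal(none$unmatched_a, 1:4)
  expect_error(colocalize_rois(a, a, radius = -1), "radius")
})

test_that("jittered channel copies are matched and agree with brute force", {
  set.seed(204)
  n <- 60
  a <- tibble::tibble(roi_id = seq_len(n),
                      row = runif(n, 10, 90), col = runif(n, 10, 90))
  b <- dplyr::mutate(a, row = row + rnorm(n, 0, 0.5),
                     col = col + rnorm(n, 0, 0.5))
  res <- colocalize_rois(a, b, radius = 2)
  expect_gte(nrow(res$pairs), ceiling(0.99 * n) - 1)
  expect_true(all(res$pairs$distance <= 2))

  # brute-force assignment oracle on small jittered instances: enumerate
  # all one-to-one assignments and compare matched cardinality
  perms <- all_permutations(4)
  for (rep in 1:20) {
    aa <- tibble::tibble(roi_id = 1:4, row = runif(4, 0, 20),
                         col = runif(4, 0, 20))
    bb <- dplyr::mutate(aa, row = row + rnorm(4, 0, 0.4),
                        col = col + rnorm(4, 0, 0.4))
    got <- nrow(colocalize_rois(aa, bb, radius = 2.5)$pairs)
    dm <- outer(aa$row, bb$row, "-")^2 + outer(aa$col, bb$col, "-")^2
    ok <- dm <= 2.5^2
    best <- max(apply(perms, 1, function(p) sum(ok[cbind(1:4, p)])))
    expect_equal(got, best)
  }
})
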