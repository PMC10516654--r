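test_that("expected width matches the hand-computed value on rectangular bumps", {
  # background 2 over 1000 bp; rectangles of height 30 spanning 20 and 30 bp:
  # mean = 3.4, threshold = 10.2, half-height widths {20, 30}, median 25
  tr <- rect_track(1000, background = 2,
                   bumps = list(c(101, 20, 30), c(401, 30, 30)))
  expect_equal(mean(tr$coverage), 3.4)
  expect_equal(estimate_expected_width(tr), 25)
})

test_that("expected width estimation errors on constant coverage", {
  tr <- track_from_values(rep(5, 500))
  expect_error(estimate_expected_width(tr), class = "mrpr_no_candidate_error")
})

test_that("expected width agrees with a brute-force scan on a triangular bump", {
  v <- rep(1, 800)
  apex <- 400
  for (i in 0:60) {
    v[apex - i] <- max(v[apex - i], 61 - i)
    v[apex + i] <- max(v[apex + i], 61 - i)
  }
  tr <- track_from_values(v)

  # independent linear-scan oracle
  half <- v[apex] / 2
  l <- apex
  while (v[l] >= half) l <- l - 1
  r <- apex
  while (v[r] >= half) r <- r + 1
  oracle <- r - l - 1

  expect_equal(estimate_expected_width(tr), oracle)
})

test_that("the kernel has the documented geometry and exact zero sum", {
  k <- build_kernel(10)
  expect_equal(k$sigma, 5)
  expect_equal(length(k$weights), 41)
  expect_lt(abs(sum(k$weights)), 1e-12)
  # symmetric, center-positive
  expect_equal(k$weights, rev(k$weights))
  expect_equal(which.max(k$weights), 21)
  # the underlying Ricker shape changes sign at |x| = sigma
  raw <- function(x) (1 - x^2 / k$sigma^2) * exp(-x^2 / (2 * k$sigma^2))
  expect_gt(raw(k$sigma - 1), 0)
  expect_lt(raw(k$sigma + 1), 0)
  expect_error(build_kernel(1), ">= 2")
})

test_that("convolution nulls constant tracks, is linear, and peaks on impulses", {
  k <- build_kernel(10)
  const <- track_from_values(rep(7, 300))
  expect_true(all(abs(convolve_track(const, k)) < 1e-9))

  imp <- rep(0, 300)
  imp[150] <- 1
  resp <- convolve_track(track_from_values(imp), k)
  expect_equal(which.max(resp), 150)
  expect_equal(resp[150], max(k$weights))

  a <- rpois(300, 5)
  b <- rpois(300, 3)
  ra <- convolve_track(track_from_values(a), k)
  rb <- convolve_track(track_from_values(b), k)
  rab <- convolve_track(track_from_values(a + b), k)
  expect_equal(rab, ra + rb, tolerance = 1e-12)

  expect_error(convolve_track(track_from_values(rep(1, 10)), k), "support")
})

test_that("call_peaks finds planted bumps at their centers and nothing on flat tracks", {
  k <- build_kernel(180)
  flat <- track_from_values(rep(50, 5000))
  expect_equal(nrow(call_peaks(flat, k)), 0)

  # one noise-free Gaussian bump, enrichment 20x on 50x background
  g <- plant_sites(gen_genome(5000, seed = 1), "ACGTACGTACGTACG", 2500,
                   enrichment = 20)
  tr <- simulate_coverage(g, coverage_config(mean_depth = 50, peak_shape_sd = 75,
                                             noise = "none", n_replicates = 1))
  peaks <- call_peaks(tr, k)
  expect_equal(nrow(peaks), 1)
  center <- g$planted_sites$center
  expect_lte(abs(peaks$summit - center), 2)
  # brute-force argmax oracle on the noise-free track
  expect_equal(tr$pos[which.max(tr$coverage)], center)
  expect_true(peaks$start <= peaks$summit && peaks$summit < peaks$end)
  expect_gt(peaks$conv_score, 0)

  # determinism
  expect_identical(peaks, call_peaks(tr, k))
})

test_that("every planted site yields one peak near its center on noise-free tracks", {
  g <- gen_genome(60000, seed = 3)
  pos <- spread_positions(60000, 5, seed = 4)
  g <- plant_sites(g, "ACGTACGTACGTACG", pos, enrichment = 20)
  tr <- simulate_coverage(g, coverage_config(mean_depth = 50, peak_shape_sd = 75,
                                             noise = "none", n_replicates = 1))
  k <- build_kernel(estimate_expected_width(tr))
  peaks <- call_peaks(tr, k)
  expect_equal(nrow(peaks), 5)
  expect_true(all(abs(peaks$summit - g$planted_sites$center) <= 2))
  # no peak farther than 4 sigma from any planted site
  dmin <- vapply(peaks$summit,
                 function(s) min(abs(s - g$planted_sites$center)), double(1))
  expect_true(all(dmin <= 4 * k$sigma))
})

test_that("normalized intensity follows the hand-computed ratio and is scale invariant", {
  peaks <- tibble::tibble(contig = "chr", start = 10L, end = 60L, summit = 30L,
                          conv_score = 5, raw_intensity = 1000, replicate = 1L)
  class(peaks) <- c("mrpr_peaks", class(peaks))
  v <- rep(1, 1000)
  v[1] <- 100001   # total coverage 101000
  tr <- track_from_values(v)
  norm <- normalize_peaks(peaks, tr)
  expect_equal(norm$normalized_intensity, 1000 / 100000 * 1e6)

  # literal reading inverts the ratio
  lit <- normalize_peaks(peaks, tr, normalization = "literal")
  expect_equal(lit$normalized_intensity, 100000 / 1000)

  # doubling the track (peaks and background) leaves the ratio unchanged
  peaks2 <- dplyr::mutate(peaks, raw_intensity = raw_intensity * 2)
  tr2 <- track_from_values(v * 2)
  norm2 <- normalize_peaks(peaks2, tr2)
  expect_equal(norm2$normalized_intensity, norm$normalized_intensity,
               tolerance = 1e-9)

  # degenerate background: peaks swallow all coverage
  all_peak <- dplyr::mutate(peaks, raw_intensity = 101000)
  expect_error(normalize_peaks(all_peak, tr),
               class = "mrpr_degenerate_background_error")
})

test_that("replicate merging counts support and averages intensities", {
  mk <- function(summit, rep, ni = 10) {
    out <- tibble::tibble(contig = "chr", start = summit - 50L,
                          end = summit + 50L, summit = as.integer(summit),
                          conv_score = 1, raw_intensity = 100,
                          replicate = as.integer(rep),
                          normalized_intensity = ni)
    class(out) <- c("mrpr_peaks", class(out))
    out
  }
  peaks <- dplyr::bind_rows(mk(1000, 1, 10), mk(1003, 2, 30), mk(5000, 1, 8))
  merged <- merge_replicate_peaks(peaks, overlap_tol = 90)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$n_replicates, c(2L, 1L))
  expect_equal(merged$normalized_intensity[1], 20)
  expect_equal(merged$summit[1], 1002L)

  # identical replicates all carry full support
  two <- dplyr::bind_rows(mk(1000, 1), mk(1000, 2))
  expect_equal(merge_replicate_peaks(two, 90)$n_replicates, 2L)
})
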