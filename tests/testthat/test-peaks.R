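test_that("annulus map partitions good pixels by floor(radius)", {
  g <- detector_geometry(101, 101, 0.1, 100, 50, 50, 1.0)
  am <- build_annulus_map(g)
  expect_s3_class(am, "annulus_map")
  expect_identical(am$index[51, 51], 0L)  # beam-centre pixel
  # floor binning: pixel at radius sqrt(70^2+72^2)... use an exact case
  expect_identical(am$index[51 + 30, 51 + 40], 50L)  # 3-4-5 triangle, r = 50
  # partition: every good pixel in exactly one annulus
  expect_equal(sum(tabulate(am$index + 1L, nbins = am$n_annuli)), 101 * 101)
  # bad pixels are excluded
  msk <- matrix(FALSE, 101, 101); msk[1:10, 1] <- TRUE
  am2 <- build_annulus_map(g, msk)
  expect_true(all(am2$index[1:10, 1] == -1L))
})

test_that("floor binning assigns fractional radii to the right annulus", {
  g <- detector_geometry(301, 301, 0.1, 100, 150, 150, 1.0)
  am <- build_annulus_map(g)
  # pixel at radius sqrt(100^2 + 12^2) = 100.719 -> annulus 100
  expect_identical(am$index[151 + 100, 151 + 12], 100L)
})

test_that("radial statistics: constants, robustness, and fast-mode equality", {
  g <- detector_geometry(64, 64, 0.1, 100, 32, 32, 1.0)
  am <- build_annulus_map(g)
  img <- matrix(7.5, 64, 64)
  st <- radial_stats(img, am)
  expect_true(all(st$mean[st$usable] == 7.5))
  expect_true(all(st$sigma[st$usable] == 0))
  # every annulus here has at most 100 + a few pixels; where the
  # population is <= the sample size, fast mode equals full mode exactly
  stf <- radial_stats(img, am, peak_search_options(fast_mode = TRUE))
  small <- st$n_used <= 100 & st$usable
  expect_equal(stf$mean[small], st$mean[small])
  expect_equal(stf$n_used[small], st$n_used[small])
  # Gaussian background: estimated mean within 4 sigma / sqrt(n) of truth
  set.seed(11)
  gb <- matrix(rnorm(64 * 64, 0, 3), 64, 64)
  stg <- radial_stats(gb, am)
  ok <- stg$usable & stg$n_used >= 20
  expect_true(all(abs(stg$mean[ok]) <= 4 * 3 / sqrt(stg$n_used[ok])))
  # outlier rejection: a planted hot streak does not poison the mean
  hot <- gb; hot[40, 40] <- 1e6
  sth <- radial_stats(hot, am)
  expect_lt(max(abs(sth$mean[ok])), 4)
})

test_that("planted Gaussian spots are recovered with sub-pixel centroids", {
  g <- std_geometry()
  am <- build_annulus_map(g)
  pat <- test_pattern(301)
  # plant isolated spots: keep peaks at least 8 px from one another
  pk <- pat$peaks
  sep <- rep(TRUE, nrow(pk))
  dd0 <- outer(pk$fast, pk$fast, "-")^2 + outer(pk$slow, pk$slow, "-")^2
  diag(dd0) <- Inf
  sep <- apply(dd0, 1, min) > 64
  truth <- pk[sep, ][seq_len(min(20, sum(sep))), ]
  pat$peaks <- truth
  fr <- render_frame(pat, g, spot_counts = 20000, background_mean = 10)
  pk <- find_peaks(fr, g, annulus_map = am)
  dd <- outer(truth$fast, pk$fast, "-")^2 + outer(truth$slow, pk$slow, "-")^2
  expect_true(all(apply(dd, 1, min) < 1))  # every spot found within 1 px
  expect_true(all(pk$snr >= 6))
  expect_true(all(diff(pk$intensity) <= 0))  # sorted by descending intensity
})

test_that("flat frames yield no peaks and masked spots are suppressed", {
  g <- detector_geometry(128, 128, 0.2, 100, 64, 64, 1.0)
  am <- build_annulus_map(g)
  set.seed(5)
  flat <- matrix(rpois(128 * 128, 10), 128, 128)
  expect_equal(nrow(find_peaks(flat, g, annulus_map = am)), 0)
  # one bright spot, then masked: must disappear
  spot <- flat
  spot[60:62, 70:72] <- 500
  expect_gt(nrow(find_peaks(spot, g, annulus_map = am)), 0)
  msk <- matrix(FALSE, 128, 128)
  msk[58:64, 68:74] <- TRUE
  amm <- build_annulus_map(g, msk)
  pk <- find_peaks(spot, g, mask = msk, annulus_map = amm)
  expect_equal(nrow(pk), 0)
})

test_that("peak search is deterministic and annulus-map reuse is exact", {
  g <- std_geometry()
  pat <- test_pattern(302)
  fr <- render_frame(pat, g, spot_counts = 20000, background_mean = 10)
  for (fm in c(FALSE, TRUE)) {
    opt <- peak_search_options(fast_mode = fm, rng_seed = 9)
    a <- find_peaks(fr, g, options = opt)
    b <- find_peaks(fr, g, options = opt)
    expect_identical(a, b)
    # rebuilding the map per frame changes nothing
    am <- build_annulus_map(g)
    c1 <- find_peaks(fr, g, options = opt, annulus_map = am)
    expect_identical(a, c1)
  }
})

test_that("fast-mode subsampled statistics find the same peaks", {
  g <- std_geometry()
  am <- build_annulus_map(g)
  for (s in 1:3) {
    pat <- test_pattern(400 + s)
    fr <- render_frame(pat, g, spot_counts = 20000, background_mean = 10)
    full <- find_peaks(fr, g, options = peak_search_options(), annulus_map = am)
    fast <- find_peaks(fr, g,
                       options = peak_search_options(fast_mode = TRUE,
                                                     rng_seed = s),
                       annulus_map = am)
    expect_gte(peak_match_fraction(full, fast), 0.95)
    expect_gte(peak_match_fraction(fast, full), 0.95)
  }
})

test_that("peak lists round-trip through TSV at full precision", {
  pk <- data.frame(fast = c(1.23456789012345, 400.5), slow = c(9.87, 2.25),
                   intensity = c(1234.5678, 9.1), snr = c(10.5, 7.2),
                   n_pixels = c(5L, 9L))
  path <- tempfile(fileext = ".tsv")
  write_peaks_tsv(pk, path)
  rd <- read_peaks_tsv(path)
  expect_equal(rd$fast, pk$fast)
  expect_equal(rd$intensity, pk$intensity)
  expect_equal(rd$n_pixels, pk$n_pixels)
})
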