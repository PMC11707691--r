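test_that("pixel/lab mapping follows the frame convention and inverts", {
  g <- detector_geometry(512, 512, 0.075, 150, 200.5, 300.25, 0.9)
  # beam centre maps to (0, 0, clen)
  expect_equal(as.numeric(pixel_to_lab(g, 200.5, 300.25)), c(0, 0, 150))
  # one pixel step along fast is one pixel size along +x
  expect_equal(pixel_to_lab(g, 201.5, 300.25)[1, "x"], 0.075,
               ignore_attr = TRUE)
  # round trip for arbitrary fractional pixels
  set.seed(1)
  f <- runif(50, 0, 511); s <- runif(50, 0, 511)
  back <- lab_to_pixel(g, pixel_to_lab(g, f, s))
  expect_lt(max(abs(back[, "fast"] - f)), 1e-9)
  expect_lt(max(abs(back[, "slow"] - s)), 1e-9)
  expect_error(pixel_to_lab(g, NaN, 1), "finite")
})

test_that("Ewald mapping is exact: closed-form |q| and sphere membership", {
  g <- std_geometry()
  # beam-centre peak scatters straight through: q = 0
  q0 <- map_peaks_to_reciprocal(data.frame(fast = 256, slow = 256), g)
  expect_equal(c(q0$qx, q0$qy, q0$qz), c(0, 0, 0))
  # 2theta = 45 degrees: |q| = 2 sin(22.5 deg) / lambda
  g45 <- detector_geometry(2048, 2048, 0.2, 100, 0, 0, 1.0)
  p45 <- data.frame(fast = 100 / 0.2, slow = 0)  # lab (clen, 0, clen)
  q45 <- map_peaks_to_reciprocal(p45, g45)
  expect_equal(sqrt(q45$qx^2 + q45$qy^2 + q45$qz^2), 2 * sin(pi / 8),
               tolerance = 1e-12)
  # membership property over random geometries and pixels
  set.seed(42)
  for (i in 1:20) {
    gr <- detector_geometry(sample(100:600, 1), sample(100:600, 1),
                            runif(1, 0.05, 0.3), runif(1, 50, 300),
                            runif(1, 50, 200), runif(1, 50, 200),
                            runif(1, 0.5, 2))
    pk <- data.frame(fast = runif(25, 0, gr$n_fast - 1),
                     slow = runif(25, 0, gr$n_slow - 1))
    q <- map_peaks_to_reciprocal(pk, gr)
    resid <- abs(sqrt(q$qx^2 + q$qy^2 + (q$qz + 1 / gr$wavelength)^2) -
                   1 / gr$wavelength)
    expect_lt(max(resid), 1e-9 / gr$wavelength)
  }
})

test_that("lab mask rectangles convert to the exact pixel set", {
  g <- detector_geometry(64, 64, 0.1, 100, 32, 32, 1.0)
  # rectangle chosen to cover exactly pixel centres 10..20 x 30..40
  # centre of fast pixel f sits at (f - 32) * 0.1 mm
  rect <- c((10 - 32) * 0.1 - 0.04, (20 - 32) * 0.1 + 0.04,
            (30 - 32) * 0.1 - 0.04, (40 - 32) * 0.1 + 0.04)
  pr <- lab_mask_to_pixel_ranges(g, rect)
  expect_identical(pr, c(10L, 20L, 30L, 40L))
  # zero-area rectangle between pixel centres -> empty
  expect_null(lab_mask_to_pixel_ranges(g, c(0.05, 0.05, 0.05, 0.05)))
  # entirely off-detector -> empty, not an error
  expect_null(lab_mask_to_pixel_ranges(g, c(50, 60, 50, 60)))
  # equivalence with the brute-force per-pixel test for random rectangles
  set.seed(7)
  f <- matrix(0:(64 - 1), 64, 64)
  s <- t(f)
  x <- (f - 32) * 0.1; y <- (s - 32) * 0.1
  for (i in 1:30) {
    r <- sort(runif(2, -4, 4)); rr <- sort(runif(2, -4, 4))
    rect <- c(r[1], r[2], rr[1], rr[2])
    brute <- x >= rect[1] & x <= rect[2] & y >= rect[3] & y <= rect[4]
    pr <- lab_mask_to_pixel_ranges(g, rect)
    conv <- matrix(FALSE, 64, 64)
    if (!is.null(pr)) conv[(pr[1]:pr[2]) + 1, (pr[3]:pr[4]) + 1] <- TRUE
    expect_identical(conv, brute)
  }
})

test_that("bad-pixel mask is the union of sentinel and region sources", {
  g <- detector_geometry(32, 32, 0.1, 100, 16, 16, 1.0)
  img <- matrix(0L, 32, 32)
  expect_equal(sum(build_bad_pixel_mask(img, mask_spec(), g)), 0)
  img[5, 9] <- 65535L
  m <- build_bad_pixel_mask(img, mask_spec(), g)
  expect_equal(which(m), 5 + (9 - 1) * 32)
  # overlapping pixel regions: masked count is |A union B|
  sp <- mask_spec(pixel_rects = list(c(0, 10, 0, 10), c(5, 15, 5, 15)))
  m2 <- build_bad_pixel_mask(matrix(0L, 32, 32), sp, g)
  brute <- matrix(FALSE, 32, 32)
  brute[1:11, 1:11] <- TRUE
  brute[6:16, 6:16] <- TRUE
  expect_identical(m2, brute)
  expect_error(build_bad_pixel_mask(matrix(0L, 8, 8), sp, g), "shape")
})

test_that("binning sums blocks, propagates masks and conserves counts", {
  set.seed(3)
  img <- matrix(rpois(30 * 20, 50), 30, 20)
  expect_identical(bin_image(img, 1)$image, img)
  for (f in 2:4) {
    b <- bin_image(img, f)
    expect_identical(dim(b$image), as.integer(ceiling(dim(img) / f)))
    expect_equal(sum(b$image), sum(img))  # conservation, unmasked
  }
  # block content: output pixel (1,1) at factor 2 is the 2x2 corner sum
  b2 <- bin_image(img, 2)
  expect_equal(b2$image[1, 1], sum(img[1:2, 1:2]))
  # any masked member masks the output pixel, and its value drops out
  msk <- matrix(FALSE, 30, 20); msk[1, 1] <- TRUE
  bm <- bin_image(img, 2, msk)
  expect_true(bm$mask[1, 1])
  expect_false(any(bm$mask[-1, ]))
  expect_equal(bm$image[1, 1], sum(img[1:2, 1:2]) - img[1, 1])
  expect_error(bin_image(img, 0), "positive")
})

test_that("geometry files round-trip including mask regions", {
  g <- std_geometry()
  sp <- mask_spec(pixel_rects = list(c(0, 4, 0, 4)),
                  lab_rects = list(c(-1, 1, -1, 1)), sentinel_value = 65535L)
  path <- tempfile(fileext = ".geom")
  write_geometry_file(g, path, sp)
  rd <- read_geometry_file(path)
  expect_equal(rd$geometry$wavelength, g$wavelength)
  expect_equal(rd$geometry$n_fast, g$n_fast)
  expect_equal(rd$mask$pixel_rects, sp$pixel_rects)
  expect_equal(rd$mask$lab_rects, sp$lab_rects)
  expect_equal(rd$mask$sentinel_value, 65535L)
})
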