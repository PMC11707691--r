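test_that("triplet generation is exhaustive when small, sampled when large", {
  pts <- cbind(qx = rnorm(5), qy = rnorm(5), qz = rnorm(5))
  t3 <- generate_triplets(pts[1:3, ], asdf_options())
  expect_equal(nrow(t3$indices), 1)
  t5 <- generate_triplets(pts, asdf_options())
  expect_equal(nrow(t5$indices), choose(5, 3))
  expect_equal(max(abs(rowSums(t5$n_hat^2) - 1)), 0, tolerance = 1e-12)
  # 2000 points: exactly the triplet budget, all index-sets distinct
  set.seed(2)
  big <- cbind(rnorm(2000), rnorm(2000), rnorm(2000), runif(2000))
  tb <- generate_triplets(big, asdf_options(rng_seed = 4))
  expect_equal(nrow(tb$indices), 20000)
  keys <- tb$indices %*% c(2000^2, 2000, 1)
  expect_false(any(duplicated(keys)))
  # deterministic given the seed
  tb2 <- generate_triplets(big, asdf_options(rng_seed = 4))
  expect_identical(tb$indices, tb2$indices)
  # collinear triplets are dropped
  col <- rbind(c(0, 0, 1), c(0, 0, 2), c(0, 0, 3), c(1, 0, 0))
  tc <- generate_triplets(col, asdf_options())
  expect_equal(nrow(tc$indices), choose(4, 3) - 1)
  expect_error(generate_triplets(pts[1:2, ], asdf_options()), "at least 3")
})

test_that("projection distances behave like signed dot products", {
  expect_equal(project_distances(rbind(c(0.3, 0.1, 0.05)), c(0, 0, 1)), 0.05)
  set.seed(8)
  pts <- matrix(rnorm(60), 20)
  nh <- c(1, 2, 2) / 3
  d <- project_distances(pts, nh)
  expect_equal(project_distances(pts, -nh), -d)
  # joint rotation leaves distances unchanged
  R <- random_orientation(99)
  expect_equal(project_distances(pts %*% t(R), as.numeric(R %*% nh)), d,
               tolerance = 1e-12)
})

test_that("the periodicity histogram maps endpoints and conserves counts", {
  h <- periodicity_histogram(c(-0.2, 0.5), 1024)
  expect_equal(h$histogram[1], 1)
  expect_equal(h$histogram[1024], 1)
  expect_equal(sum(h$histogram), 2)
  set.seed(12)
  d <- rnorm(500)
  expect_equal(sum(periodicity_histogram(d)$histogram), 500)
  # pigeonhole: a uniform grid of 1025 distances occupies every bin
  hu <- periodicity_histogram(seq(0, 1024), 1024)
  expect_true(all(hu$histogram >= 1))
  expect_error(periodicity_histogram(rep(1, 5)), "identical")
})

test_that("the transform picks the planted period and scales correctly", {
  d <- seq(0, 10) * 0.0125   # planted repeat 0.0125 1/A -> L = 80 A
  h <- periodicity_histogram(d, 1024)
  L <- fft_candidate_length(h$histogram, h$range,
                            asdf_options(direct_length_min = 2,
                                         direct_length_max = 250))
  # brute-force oracle: the repeat maximising the number of fitting points
  score <- function(Lt) refine_repeat(d, Lt, asdf_options())$n_fit
  grid <- seq(40, 120, 0.5)
  Lbest <- grid[which.max(vapply(grid, score, numeric(1)))]
  expect_lt(abs(L - 80), 1 / h$range + 1e-9)  # within one transform bin
  expect_equal(refine_repeat(d, L, asdf_options())$length,
               refine_repeat(d, Lbest, asdf_options())$length,
               tolerance = 1e-9)
  # doubling all distances halves the implied length
  h2 <- periodicity_histogram(2 * d, 1024)
  L2 <- fft_candidate_length(h2$histogram, h2$range,
                             asdf_options(direct_length_min = 2,
                                          direct_length_max = 250))
  expect_equal(L2, L / 2, tolerance = 1e-9)
  # a band containing no transform index -> NULL
  expect_null(fft_candidate_length(h$histogram, h$range,
                                   asdf_options(direct_length_min = 100.1,
                                                direct_length_max = 103)))
})

test_that("repeat refinement reproduces the closed form and the 7-fit rule", {
  p <- 0.0125
  d <- (-5:5) * p
  rf <- refine_repeat(d, 1 / p, asdf_options())
  expect_equal(rf$repeat_p, p)        # exact multiples: exact recovery
  expect_equal(rf$n_fit, 10)          # all non-zero m fit
  expect_true(rf$accepted)
  # exactly 6 fitting points reject, 7 accept ("more than six")
  d6 <- c(1:3, -(1:3)) * p
  expect_false(refine_repeat(d6, 1 / p, asdf_options())$accepted)
  d7 <- c(1:4, -(1:3)) * p
  expect_true(refine_repeat(d7, 1 / p, asdf_options())$accepted)
  # noisy multiples: equals the closed form evaluated independently once
  # the assignment is stable
  set.seed(77)
  m <- c(-6:-1, 1:6)
  dn <- m * p + rnorm(12, 0, 0.0004)
  rfn <- refine_repeat(dn, 1 / p, asdf_options())
  mm <- round(dn / rfn$repeat_p)
  fit <- mm != 0 & abs(dn - mm * rfn$repeat_p) <= 0.15 * rfn$repeat_p
  expect_equal(rfn$repeat_p, sum(mm[fit] * dn[fit]) / sum(mm[fit]^2),
               tolerance = 1e-12)
  # all distances in the origin slab carry no information
  expect_null(refine_repeat(c(0, 1e-6, -1e-6), 100, asdf_options()))
})

test_that("candidate merging collapses sign and near-duplicates", {
  cand <- data.frame(tx = c(10, -10, 0, 10.05), ty = c(0, 0, 12, 0),
                     tz = c(0, 0, 0, 0),
                     L = c(10, 10, 12, 10.05), n_fit = c(9, 11, 8, 7))
  m <- merge_candidates(cand)
  expect_equal(nrow(m), 2)        # +-x family merges; y kept
  expect_equal(m$L, c(10, 12))    # sorted ascending, best-fit kept
  expect_equal(m$n_fit[1], 11)
  expect_equal(m$sources[1], 3)
  # brute-force clustering oracle on random candidates
  set.seed(13)
  n <- 40
  dirs <- matrix(rnorm(3 * n), n)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  Ls <- runif(n, 5, 100)
  cand2 <- data.frame(tx = dirs[, 1] * Ls, ty = dirs[, 2] * Ls,
                      tz = dirs[, 3] * Ls, L = Ls,
                      n_fit = sample(7:30, n, replace = TRUE))
  m2 <- merge_candidates(cand2)
  # oracle: greedy clustering in the same preference order
  ord <- order(-cand2$n_fit)
  centres <- list()
  for (i in ord) {
    u <- dirs[i, ]; L <- Ls[i]
    dup <- any(vapply(centres, function(ct)
      abs(sum(u * ct$u)) >= cos(3 * pi / 180) &&
        abs(L - ct$L) <= 0.01 * max(L, ct$L), logical(1)))
    if (!dup) centres[[length(centres) + 1]] <- list(u = u, L = L)
  }
  expect_equal(nrow(m2), length(centres))
})

test_that("basis assembly honours independence and the volume constraint", {
  cand <- data.frame(
    tx = c(79.2, 0, 0, 79.2), ty = c(0, 79.2, 0, 79.2),
    tz = c(0, 0, 38, 0),
    L = c(79.2, 79.2, 38, 79.2 * sqrt(2)), n_fit = c(20, 20, 20, 15))
  cand$sources <- 1L
  lys <- lys_cell()
  res <- find_basis(cand, lys, asdf_options())
  expect_true(res$success)
  expect_equal(res$cell$volume, 79.2 * 79.2 * 38, tolerance = 1e-3)
  expect_gt(det(res$cell$basis), 0)  # right-handed
  # coplanar candidates cannot form a basis
  cop <- data.frame(tx = c(10, 20, 30), ty = c(1, 2, 3), tz = c(0, 0, 0),
                    L = sqrt(c(101, 404, 909)), n_fit = c(9, 9, 9),
                    sources = 1L)
  resc <- find_basis(cop, NULL, asdf_options())
  expect_false(resc$success)
  expect_match(resc$failure_reason, "no independent basis")
  # a reference with triple the volume rejects the assembly
  big <- cell_from_parameters(3 * 79.2, 79.2, 38, 90, 90, 90)
  resv <- find_basis(cand, big, asdf_options())
  expect_false(resv$success)
})

test_that("compiled scan agrees with the R reference path", {
  set.seed(55)
  for (trial in 1:5) {
    pat <- test_pattern(600 + trial)
    rp <- map_peaks_to_reciprocal(pat$peaks, std_geometry())
    pts <- cbind(rp$qx, rp$qy, rp$qz)
    idx <- t(utils::combn(min(nrow(pts), 12), 3))
    cpp <- serialindex:::asdf_scan(pts, idx, 2, 95.04, 1024L, 0.15, 7L)
    ref <- scan_triplets_r(pts, idx, 2, 95.04)
    expect_equal(nrow(cpp), nrow(ref))
    if (nrow(cpp) > 0) expect_equal(unname(cpp), unname(ref),
                                    tolerance = 1e-6)
  }
})

test_that("full-chain indexing recovers the simulated cell deterministically", {
  g <- std_geometry()
  lys <- lys_cell()
  pat <- test_pattern(42)
  res <- asdf_index(pat$peaks, g, lys, asdf_options(rng_seed = 3))
  expect_true(res$success)
  chk <- check_cell(res$cell, pat$true_cell, 0.01, 0.5)
  expect_true(chk$matched)
  # determinism: bit-identical result for identical input and seed
  res2 <- asdf_index(pat$peaks, g, lys, asdf_options(rng_seed = 3))
  expect_identical(res$cell$basis, res2$cell$basis)
  # degenerate inputs fail as results, not errors
  empty <- data.frame(fast = numeric(0), slow = numeric(0),
                      intensity = numeric(0))
  expect_false(asdf_index(empty, g, lys)$success)
  few <- pat$peaks[1:5, ]
  expect_false(asdf_index(few, g, lys)$success)
})

test_that("indexing is rotation-equivariant in the reduced cell", {
  g <- std_geometry()
  lys <- lys_cell()
  pat <- test_pattern(43)
  rp <- map_peaks_to_reciprocal(pat$peaks, g)
  res1 <- asdf_index(rp, NULL, lys, asdf_options(rng_seed = 5))
  R <- random_orientation(1234)
  q2 <- as.matrix(cbind(rp$qx, rp$qy, rp$qz)) %*% t(R)
  rp2 <- data.frame(qx = q2[, 1], qy = q2[, 2], qz = q2[, 3],
                    intensity = rp$intensity)
  class(rp2) <- c("reciprocal_peaks", "data.frame")
  res2 <- asdf_index(rp2, NULL, lys, asdf_options(rng_seed = 5))
  expect_true(res1$success && res2$success)
  expect_equal(niggli_reduce(res2$cell)$parameters,
               niggli_reduce(res1$cell)$parameters, tolerance = 1e-4)
  # and the recovered basis rotates with the points
  expect_true(check_cell(res2$cell, transform_cell(res1$cell, diag(3)))$matched)
})
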