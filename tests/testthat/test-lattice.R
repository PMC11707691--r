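test_that("cells built from parameters have the closed-form volume and invert", {
  lys <- lys_cell()
  expect_equal(lys$volume, 79.2 * 79.2 * 38)  # V = abc for right angles
  cub <- cell_from_parameters(1, 1, 1, 90, 90, 90)
  expect_equal(cub$basis, diag(3))
  expect_equal(cub$volume, 1)
  # parameters -> vectors -> parameters round trip
  p0 <- c(27.1, 31.9, 44.3, 88.2, 100.4, 93.7)
  cell <- cell_from_parameters(p0[1], p0[2], p0[3], p0[4], p0[5], p0[6])
  expect_equal(unname(cell$parameters), p0, tolerance = 1e-9)
  # cached reciprocal is the inverse transpose: M* . basis^T = I
  expect_equal(t(cell$recip) %*% cell$basis, diag(3), tolerance = 1e-10)
  expect_error(cell_from_parameters(1, 1, 1, 1, 1, 179), "infeasible")
})

test_that("scattering vectors match an independent trigonometric oracle", {
  lys <- lys_cell()
  expect_equal(as.numeric(scattering_vector(lys, 0, 0, 0)), c(0, 0, 0))
  cub <- cell_from_parameters(10, 10, 10, 90, 90, 90)
  expect_equal(sqrt(sum(scattering_vector(cub, 1, 0, 0)^2)), 0.1)
  set.seed(21)
  for (i in 1:100) {
    p <- c(runif(3, 10, 120), runif(3, 70, 110))
    cell <- cell_from_parameters(p[1], p[2], p[3], p[4], p[5], p[6])
    Rt <- recip_trig(p[1], p[2], p[3], p[4], p[5], p[6])
    hkl <- matrix(sample(-15:15, 30, replace = TRUE), 3)
    q1 <- scattering_vector(cell, hkl[1, ], hkl[2, ], hkl[3, ])
    q2 <- t(Rt %*% hkl)
    expect_lt(max(abs(q1 - q2)), 1e-10)
  }
})

test_that("Niggli reduction is idempotent and lattice-invariant", {
  lys <- lys_cell()
  r1 <- niggli_reduce(lys)
  expect_equal(niggli_reduce(r1)$parameters, r1$parameters, tolerance = 1e-9)
  # re-expressing the basis leaves the reduced cell unchanged
  sheared <- transform_cell(lys, matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3, 3))
  expect_equal(sort(niggli_reduce(sheared)$parameters[1:3]),
               sort(r1$parameters[1:3]), tolerance = 1e-8)
  # property: 100 random unimodular transforms of random cells
  set.seed(31)
  for (i in 1:20) {
    p <- c(runif(3, 20, 90), runif(3, 75, 105))
    cell <- cell_from_parameters(p[1], p[2], p[3], p[4], p[5], p[6])
    ref <- niggli_reduce(cell)$parameters
    for (j in 1:5) {
      tr <- transform_cell(cell, random_unimodular())
      expect_equal(niggli_reduce(tr)$parameters, ref, tolerance = 1e-6)
    }
  }
})

test_that("the primitive setting of a C-centred cell reduces to half volume", {
  # C-centred orthorhombic 20 x 30 x 40; primitive basis via the standard
  # centring vectors (a/2 + b/2, a/2 - b/2, c)
  Cc <- cell_from_parameters(20, 30, 40, 90, 90, 90)
  Bp <- cbind(c(10, -15, 0), c(10, 15, 0), c(0, 0, 40))
  prim <- unit_cell(Bp)
  expect_equal(prim$volume, Cc$volume / 2)
  red <- niggli_reduce(prim)
  expect_equal(red$volume, Cc$volume / 2)
  # the reduced primitive cell of this lattice has axes 18.03, 18.03, 40
  expect_equal(unname(sort(red$parameters[1:3])),
               c(sqrt(10^2 + 15^2), sqrt(10^2 + 15^2), 40), tolerance = 1e-9)
})

test_that("cell checking matches across representations and tolerances", {
  lys <- lys_cell()
  expect_true(check_cell(lys, lys)$matched)
  doubled <- cell_from_parameters(158.4, 79.2, 38, 90, 90, 90)
  expect_false(check_cell(doubled, lys)$matched)
  set.seed(41)
  for (i in 1:25) {
    tr <- transform_cell(lys, random_unimodular())
    m <- check_cell(tr, lys)
    expect_true(m$matched)
    # symmetric in its arguments
    m2 <- check_cell(lys, tr)
    expect_equal(m$matched, m2$matched)
    expect_equal(m$length_reldev, m2$length_reldev, tolerance = 1e-9)
  }
  # G6 vector of the reduced tetragonal cell: (c^2, a^2, a^2, 0, 0, 0)
  g6 <- check_cell(lys, lys)$g6_reference
  expect_equal(g6, c(38^2, 79.2^2, 79.2^2, 0, 0, 0), tolerance = 1e-6)
})

test_that("unique-reflection counting matches hand enumeration and is monotone", {
  cub <- cell_from_parameters(10, 10, 10, 90, 90, 90)
  # h^2+k^2+l^2 <= 4, origin excluded, Friedel-merged: 16 classes
  expect_identical(count_unique_reflections(cub, "-1", 100, 5), 16L)
  # empty window
  expect_identical(count_unique_reflections(cub, "-1", 7, 7), 0L)
  lys <- lys_cell()
  # monotone as d_min decreases; higher symmetry merges more
  c1 <- count_unique_reflections(lys, "4/mmm", Inf, 3.0)
  c2 <- count_unique_reflections(lys, "4/mmm", Inf, 2.5)
  expect_gt(c2, c1)
  expect_gte(count_unique_reflections(lys, "-1", Inf, 3.0), c1)
  expect_error(count_unique_reflections(lys, "6/mmm", Inf, 3.0), "unsupported")
})

test_that("cell files round-trip and CRYST1 records parse", {
  lys <- lys_cell()
  path <- tempfile(fileext = ".cell")
  write_cell_file(lys, path)
  rd <- read_cell_file(path)
  expect_equal(rd$parameters, lys$parameters, tolerance = 1e-6)
  cr <- tempfile()
  writeLines("CRYST1   79.200   79.200   38.000  90.00  90.00  90.00 P 43 21 2", cr)
  rd2 <- read_cell_file(cr)
  expect_equal(unname(rd2$parameters[1:3]), c(79.2, 79.2, 38))
})
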