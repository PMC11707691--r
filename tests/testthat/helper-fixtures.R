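# Shared fixtures: a desk-scale single-panel detector and the tetragonal
# lysozyme-like reference cell used throughout.

std_geometry <- function(n = 512L) {
  detector_geometry(n_fast = n, n_slow = n, pixel_size = 0.2,
                    camera_length = 100, beam_centre_fast = n / 2,
                    beam_centre_slow = n / 2, wavelength = 1.0)
}

lys_params <- c(79.2, 79.2, 38, 90, 90, 90)

lys_cell <- function() cell_from_parameters(79.2, 79.2, 38, 90, 90, 90)

# Noise-free simulated pattern with a seeded random orientation; the
# tolerance is the package's study condition giving 25-60 peaks on the
# standard geometry for most orientations.
test_pattern <- function(seed, geometry = std_geometry(), ...) {
  simulate_peaks(lys_params, random_orientation(seed), geometry,
                 sim_tolerance = list(abs = 1e-4, rel = 1e-4),
                 seed = seed, ...)
}

# First `n` seeded patterns (offset by `base`) with between 25 and 60 peaks.
test_pattern_set <- function(n, base = 100000L, geometry = std_geometry()) {
  out <- list()
  s <- 0L
  while (length(out) < n) {
    s <- s + 1L
    pat <- test_pattern(base + s, geometry)
    if (nrow(pat$peaks) >= 25 && nrow(pat$peaks) <= 60)
      out[[length(out) + 1]] <- pat
  }
  out
}

# Random unimodular integer matrix with entries in [-2, 2] (rejection
# sampling on the determinant).
random_unimodular <- function() {
  repeat {
    m <- matrix(sample(-2:2, 9, replace = TRUE), 3, 3)
    d <- round(det(m))
    if (abs(d) == 1) return(m)
  }
}

# Independent trigonometric construction of the reciprocal basis, used as
# the oracle for the cached-matrix scattering-vector path.
recip_trig <- function(a, b, c, al, be, ga) {
  ca <- cos(al * pi / 180); cb <- cos(be * pi / 180); cg <- cos(ga * pi / 180)
  avec <- c(a, 0, 0)
  bvec <- c(b * cg, b * sin(ga * pi / 180), 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sin(ga * pi / 180)
  cvec <- c(cx, cy, sqrt(c^2 - cx^2 - cy^2))
  V <- sum(avec * cross_prod(bvec, cvec))
  cbind(cross_prod(bvec, cvec) / V, cross_prod(cvec, avec) / V,
        cross_prod(avec, bvec) / V)
}

cross_prod <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Fraction of peaks in `a` matched within `tol` pixels by a peak in `b`.
peak_match_fraction <- function(a, b, tol = 2) {
  if (nrow(a) == 0) return(1)
  if (nrow(b) == 0) return(0)
  dd <- outer(a$fast, b$fast, "-")^2 + outer(a$slow, b$slow, "-")^2
  mean(apply(dd, 1, min) <= tol^2)
}
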