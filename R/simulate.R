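#' Uniform random rotation
#'
#' Draws a rotation uniformly over orientation space via a normalised
#' random quaternion (four independent standard normals).
#'
#' @param seed Integer seed.
#' @return 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
random_orientation <- function(seed) {
  q <- local_seed(seed, stats::rnorm(4))
  q <- q / vec_norm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Simulate the peak list of one still diffraction pattern
#'
#' Builds the oriented cell, enumerates the reciprocal-lattice points
#' within the excitation-error tolerance of the Ewald sphere, projects them
#' onto the detector (the exact inverse of reflection prediction, sharing
#' the same geometry code), and then degrades the list: Gaussian positional
#' jitter, random dropping of a subset, and uniformly placed spurious
#' peaks. Intensities are exponentially distributed. Everything is seeded.
#'
#' @param cell_params Numeric `c(a, b, c, alpha, beta, gamma)` or a
#'   [unit_cell()] (unoriented, canonical setting).
#' @param orientation 3x3 rotation matrix (e.g. [random_orientation()]).
#' @param geometry A [detector_geometry()].
#' @param sim_tolerance List with `abs` and `rel` excitation-error
#'   tolerances (defaults mirror [integration_options()]).
#' @param d_min Resolution limit for the enumeration (Angstrom).
#' @param n_false Number of spurious peaks to append (default 0).
#' @param pos_jitter Gaussian positional jitter, standard deviation in
#'   pixels (default 0).
#' @param drop_fraction Fraction of true peaks dropped at random
#'   (default 0).
#' @param seed Integer seed.
#' @param mean_intensity Mean of the exponential intensity distribution.
#' @return An object of class `simulated_pattern`: list with `true_cell`
#'   (oriented [unit_cell()]), `peaks` (data frame `fast`, `slow`,
#'   `intensity`), `hkls` (integer matrix, one row per peak; `NA` rows for
#'   spurious peaks), `geometry`, `seed`.
#' @export
simulate_peaks <- function(cell_params, orientation, geometry,
                           sim_tolerance = list(abs = 0.001, rel = 0.002),
                           d_min = 2.0, n_false = 0L, pos_jitter = 0,
                           drop_fraction = 0, seed = 1L,
                           mean_intensity = 1000) {
  cell0 <- if (inherits(cell_params, "unit_cell")) cell_params else
    cell_from_parameters(cell_params[1], cell_params[2], cell_params[3],
                         cell_params[4], cell_params[5], cell_params[6])
  oriented <- unit_cell(orientation %*% cell0$basis)
  refl <- ewald_reflections(oriented, geometry, sim_tolerance$abs,
                            sim_tolerance$rel, d_min)
  refl <- refl[refl$flag == "ok", , drop = FALSE]
  local_seed(seed, {
    n <- nrow(refl)
    keep <- if (drop_fraction > 0) stats::runif(n) >= drop_fraction else
      rep(TRUE, n)
    refl <- refl[keep, , drop = FALSE]
    n <- nrow(refl)
    fast <- refl$fast + if (pos_jitter > 0) stats::rnorm(n, 0, pos_jitter) else 0
    slow <- refl$slow + if (pos_jitter > 0) stats::rnorm(n, 0, pos_jitter) else 0
    inten <- stats::rexp(n, 1 / mean_intensity)
    hkls <- as.matrix(refl[, c("h", "k", "l")])
    if (n_false > 0) {
      fast <- c(fast, stats::runif(n_false, 0, geometry$n_fast - 1))
      slow <- c(slow, stats::runif(n_false, 0, geometry$n_slow - 1))
      inten <- c(inten, stats::rexp(n_false, 1 / mean_intensity))
      hkls <- rbind(hkls, matrix(NA_integer_, n_false, 3))
    }
    inb <- fast >= 0 & fast <= geometry$n_fast - 1 &
      slow >= 0 & slow <= geometry$n_slow - 1
    peaks <- data.frame(fast = fast[inb], slow = slow[inb],
                        intensity = inten[inb])
    structure(list(true_cell = oriented, peaks = peaks,
                   hkls = hkls[inb, , drop = FALSE],
                   geometry = geometry, seed = seed),
              class = "simulated_pattern")
  })
}

#' Render a simulated pattern as a detector frame
#'
#' Poisson background plus 2D Gaussian spots at the simulated peak
#' positions; masked pixels are set to the sentinel value. Returns integer
#' counts.
#'
#' @param pattern A [simulate_peaks()] result.
#' @param geometry A [detector_geometry()] (defaults to the pattern's).
#' @param spot_sigma Gaussian spot width (px, default 1.2).
#' @param spot_counts Expected integrated counts per spot; scalar or one
#'   per peak (default 5000).
#' @param background_mean Poisson background mean per pixel (default 10).
#' @param mask_spec Optional [mask_spec()]; its regions are stamped with
#'   the sentinel value.
#' @param seed Seed for the Poisson noise (defaults to the pattern seed).
#' @return Integer matrix `[fast, slow]`.
#' @export
render_frame <- function(pattern, geometry = pattern$geometry,
                         spot_sigma = 1.2, spot_counts = 5000,
                         background_mean = 10, mask_spec = NULL,
                         seed = pattern$seed) {
  nf <- geometry$n_fast; ns <- geometry$n_slow
  lambda <- matrix(background_mean, nf, ns)
  pk <- pattern$peaks
  counts <- rep_len(spot_counts, nrow(pk))
  w <- ceiling(4 * spot_sigma)
  for (i in seq_len(nrow(pk))) {
    f0 <- pk$fast[i]; s0 <- pk$slow[i]
    fr <- max(0, floor(f0) - w):min(nf - 1, ceiling(f0) + w)
    sr <- max(0, floor(s0) - w):min(ns - 1, ceiling(s0) + w)
    if (length(fr) == 0 || length(sr) == 0) next
    gf <- exp(-((fr - f0)^2) / (2 * spot_sigma^2))
    gs <- exp(-((sr - s0)^2) / (2 * spot_sigma^2))
    spot <- counts[i] * outer(gf, gs) / (2 * pi * spot_sigma^2)
    lambda[fr + 1, sr + 1] <- lambda[fr + 1, sr + 1] + spot
  }
  frame <- local_seed(seed, {
    m <- matrix(stats::rpois(nf * ns, lambda), nf, ns)
    m
  })
  if (!is.null(mask_spec)) {
    region <- static_region_mask(mask_spec, geometry)
    frame[region] <- mask_spec$sentinel_value
  }
  storage.mode(frame) <- "integer"
  frame
}

#' Simulate a multi-frame acquisition run
#'
#' A seeded sequence of hit (lattice-bearing) and blank (background-only)
#' frames in random order, with a ground-truth manifest. Each hit frame
#' gets its own orientation and derived seed, so runs are reproducible
#' frame-by-frame regardless of processing order.
#'
#' @param n_frames Number of frames.
#' @param hit_fraction Probability that a frame is a hit (in \[0, 1\]).
#' @param cell_params Cell parameters for hit frames (as in
#'   [simulate_peaks()]).
#' @param geometry A [detector_geometry()].
#' @param seed Integer run seed.
#' @param render If `TRUE` (default), frames are rendered images; if
#'   `FALSE`, only peak lists are produced (the `frames` element is then a
#'   list of `NULL`s and peak lists live in the manifest attribute).
#' @param ... Further arguments passed to [simulate_peaks()] /
#'   [render_frame()] (`sim_tolerance`, `spot_counts`,
#'   `background_mean`, ...).
#' @return List of class `simulated_run`: `frames` (list of frame
#'   matrices, blanks included), `manifest` (data frame `frame_id`
#'   (0-based), `hit`, `seed`), `patterns` (list of
#'   [simulate_peaks()] results, `NULL` for blanks), `geometry`.
#' @export
make_run <- function(n_frames, hit_fraction, cell_params, geometry,
                     seed = 1L, render = TRUE,
                     sim_tolerance = list(abs = 0.001, rel = 0.002),
                     d_min = 2.0, spot_sigma = 1.2, spot_counts = 5000,
                     background_mean = 10, mask_spec = NULL, ...) {
  stopifnot(hit_fraction >= 0, hit_fraction <= 1, n_frames >= 0)
  is_hit <- local_seed(seed, stats::runif(n_frames) < hit_fraction)
  frames <- vector("list", n_frames)
  patterns <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    fseed <- derive_seed(seed, i)
    if (is_hit[i]) {
      ori <- random_orientation(derive_seed(fseed, 1))
      patterns[[i]] <- simulate_peaks(cell_params, ori, geometry,
                                      sim_tolerance = sim_tolerance,
                                      d_min = d_min, seed = fseed, ...)
      if (render)
        frames[[i]] <- render_frame(patterns[[i]], geometry,
                                    spot_sigma = spot_sigma,
                                    spot_counts = spot_counts,
                                    background_mean = background_mean,
                                    mask_spec = mask_spec, seed = fseed)
    } else if (render) {
      blank <- structure(list(true_cell = NULL,
                              peaks = data.frame(fast = numeric(0),
                                                 slow = numeric(0),
                                                 intensity = numeric(0)),
                              geometry = geometry, seed = fseed),
                         class = "simulated_pattern")
      frames[[i]] <- render_frame(blank, geometry, spot_sigma = spot_sigma,
                                  spot_counts = spot_counts,
                                  background_mean = background_mean,
                                  mask_spec = mask_spec, seed = fseed)
    }
  }
  manifest <- data.frame(frame_id = seq_len(n_frames) - 1L, hit = is_hit,
                         seed = vapply(seq_len(n_frames),
                                       function(i) derive_seed(seed, i),
                                       integer(1)))
  structure(list(frames = frames, manifest = manifest, patterns = patterns,
                 geometry = geometry),
            class = "simulated_run")
}

#' Write a run manifest as TSV
#'
#' @param run A [make_run()] result.
#' @param path File path.
#' @export
write_manifest_tsv <- function(run, path) {
  utils::write.table(run$manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
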