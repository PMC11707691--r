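#' Options for the FFT autoindexing algorithm
#'
#' The algorithm searches one-dimensional periodicities of the
#' reciprocal-space peak positions along plane normals defined by triplets
#' of peaks. These options bound the search and fix the acceptance rules.
#'
#' @param fast If `TRUE`, use the reduced fast-mode limits (10 000 triplets,
#'   120 reciprocal points) instead of the full limits (20 000 / 2000).
#' @param max_triplets Triplet budget; when the number of possible triplets
#'   exceeds it, this many distinct triplets are drawn at random (seeded).
#' @param max_points Number of strongest reciprocal points considered.
#' @param n_bins Length of the real-valued projection histogram (1024; must
#'   be a power of two).
#' @param fit_tolerance A projected distance counts as fitting when it lies
#'   within this fraction of the repeat from an integer multiple
#'   (default 0.15).
#' @param min_fit_points Minimum number of fitting points for an accepted
#'   candidate vector; the acceptance rule is "more than six", i.e. 7.
#' @param volume_tolerance Relative tolerance on the cell volume against
#'   the reference cell (default 0.10).
#' @param direct_length_min,direct_length_max Direct-space search band in
#'   Angstrom for candidate lattice-vector lengths. Defaults: 2 Angstrom
#'   and 1.2 x the longest reference axis (250 Angstrom without a
#'   reference). The band also suppresses the low-frequency transform
#'   elements (DC is always excluded).
#' @param rng_seed Seed for triplet sampling.
#' @param combination_budget How many three-combinations of candidate
#'   vectors to try when assembling a basis (default 100).
#' @param min_fit_fraction Candidates entering basis assembly must have at
#'   least this fraction of the best candidate fit count (default 0.75).
#'   Along a true lattice-vector direction essentially every reflection
#'   fits, so genuine candidates cluster near the maximum while chance
#'   periodicities fit far fewer points.
#' @param max_candidates Cap on the number of candidates kept (strongest
#'   fit counts first) before merging (default 500).
#' @param hkl_tolerance,min_indexed_fraction Solution validation: an
#'   assembled basis is accepted only if at least `min_indexed_fraction`
#'   of the reciprocal points have all three fractional Miller indices
#'   within `hkl_tolerance` of integers (defaults 0.2 and 0.8). A correct
#'   cell indexes nearly all peaks; a chance basis indexes almost none.
#' @return An object of class `asdf_options`.
#' @export
asdf_options <- function(fast = FALSE,
                         max_triplets = if (fast) 10000L else 20000L,
                         max_points = if (fast) 120L else 2000L,
                         n_bins = 1024L,
                         fit_tolerance = 0.15,
                         min_fit_points = 7L,
                         volume_tolerance = 0.10,
                         direct_length_min = 2,
                         direct_length_max = NULL,
                         rng_seed = 1L,
                         combination_budget = 100L,
                         min_fit_fraction = 0.75,
                         max_candidates = 500L,
                         hkl_tolerance = 0.2,
                         min_indexed_fraction = 0.8) {
  stopifnot(max_points >= 3, fit_tolerance > 0, fit_tolerance < 0.5,
            n_bins >= 2, bitwAnd(as.integer(n_bins), as.integer(n_bins) - 1L) == 0L)
  structure(list(
    fast = isTRUE(fast),
    max_triplets = as.integer(max_triplets),
    max_points = as.integer(max_points),
    n_bins = as.integer(n_bins),
    fit_tolerance = fit_tolerance,
    min_fit_points = as.integer(min_fit_points),
    volume_tolerance = volume_tolerance,
    direct_length_min = direct_length_min,
    direct_length_max = direct_length_max,
    rng_seed = as.integer(rng_seed),
    combination_budget = as.integer(combination_budget),
    min_fit_fraction = min_fit_fraction,
    max_candidates = as.integer(max_candidates),
    hkl_tolerance = hkl_tolerance,
    min_indexed_fraction = min_indexed_fraction
  ), class = "asdf_options")
}

# Resolve the direct-length search band given an optional reference cell.
asdf_length_band <- function(options, reference = NULL) {
  lmax <- options$direct_length_max
  if (is.null(lmax)) {
    lmax <- if (is.null(reference)) 250 else
      1.2 * max(reference$parameters[c("a", "b", "c")])
  }
  c(options$direct_length_min, lmax)
}

#' Generate peak triplets for the periodicity search
#'
#' Points are ordered by descending intensity and truncated to
#' `max_points` ("strongest first" defines the considered set). If the
#' number of possible triplets does not exceed `max_triplets`, all are
#' generated; otherwise `max_triplets` distinct triplets are drawn at
#' random with the stored seed. Collinear triplets are dropped.
#'
#' @param points A `reciprocal_peaks` data frame (see
#'   [map_peaks_to_reciprocal()]) or a matrix with columns qx, qy, qz.
#' @param options An [asdf_options()].
#' @return List of class `asdf_triplets`: `indices` (m x 3 integer matrix
#'   of 1-based rows into the truncated point set), `points` (the truncated
#'   n x 3 coordinate matrix), `n_hat` (m x 3 unit plane normals).
#' @export
generate_triplets <- function(points, options = asdf_options()) {
  pts <- as_q_matrix(points)
  inten <- attr(pts, "intensity")
  if (nrow(pts) < 3) stop("at least 3 reciprocal points are required")
  ord <- order(-inten)
  pts <- pts[ord, , drop = FALSE]
  if (nrow(pts) > options$max_points)
    pts <- pts[seq_len(options$max_points), , drop = FALSE]
  n <- nrow(pts)
  n_all <- choose(n, 3)
  if (n_all <= options$max_triplets) {
    idx <- t(utils::combn(n, 3))
  } else {
    idx <- local_seed(options$rng_seed, {
      acc <- matrix(0L, 0, 3)
      keys <- numeric(0)
      while (nrow(acc) < options$max_triplets) {
        need <- options$max_triplets - nrow(acc)
        draw <- matrix(sample.int(n, 3L * ceiling(need * 1.5),
                                  replace = TRUE), ncol = 3)
        lo <- pmin(draw[, 1], draw[, 2], draw[, 3])
        hi <- pmax(draw[, 1], draw[, 2], draw[, 3])
        mid <- draw[, 1] + draw[, 2] + draw[, 3] - lo - hi
        ok <- lo < mid & mid < hi
        key <- (as.numeric(lo[ok]) * n + mid[ok]) * n + hi[ok]
        draw <- cbind(lo[ok], mid[ok], hi[ok])
        new <- !duplicated(key) & !(key %in% keys)
        acc <- rbind(acc, draw[new, , drop = FALSE])
        keys <- c(keys, key[new])
      }
      acc[seq_len(options$max_triplets), , drop = FALSE]
    })
  }
  u <- pts[idx[, 2], , drop = FALSE] - pts[idx[, 1], , drop = FALSE]
  v <- pts[idx[, 3], , drop = FALSE] - pts[idx[, 1], , drop = FALSE]
  nh <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nn <- sqrt(rowSums(nh^2))
  ok <- nn >= 1e-12
  idx <- idx[ok, , drop = FALSE]
  nh <- nh[ok, , drop = FALSE] / nn[ok]
  structure(list(indices = idx, points = pts, n_hat = nh),
            class = "asdf_triplets")
}

as_q_matrix <- function(points) {
  if (is.matrix(points)) {
    m <- points[, 1:3, drop = FALSE]
    inten <- if (ncol(points) >= 4) points[, 4] else rep(1, nrow(points))
  } else {
    d <- as.data.frame(points)
    m <- cbind(d$qx, d$qy, d$qz)
    inten <- if (!is.null(d$intensity)) d$intensity else rep(1, nrow(m))
  }
  attr(m, "intensity") <- inten
  m
}

#' Project reciprocal points onto a direction
#'
#' Signed distances d_i = q_i . n_hat of every point from the origin along
#' the line through the origin with direction `n_hat`.
#'
#' @param points Reciprocal points (as in [generate_triplets()]).
#' @param n_hat Unit 3-vector.
#' @return Numeric vector of signed distances (inverse Angstrom).
#' @export
project_distances <- function(points, n_hat) {
  pts <- as_q_matrix(points)
  stopifnot(abs(vec_norm(n_hat) - 1) < 1e-6)
  as.numeric(pts %*% n_hat)
}

#' Histogram of projected distances
#'
#' A real-valued array of `n_bins` elements; the first bin corresponds to
#' the most negative distance, the last to the most positive, linear in
#' between. Each distance adds 1 to its bin; the maximum distance falls in
#' the last bin (bins are half-open, the last bin closed).
#'
#' @param distances Numeric vector (at least two distinct values).
#' @param n_bins Number of bins (default 1024).
#' @return List `histogram` (length `n_bins`), `range` (dmax - dmin) and
#'   `d_min`.
#' @export
periodicity_histogram <- function(distances, n_bins = 1024L) {
  dmin <- min(distances); dmax <- max(distances)
  R <- dmax - dmin
  if (R <= 0) stop("all distances identical: no periodicity to histogram")
  b <- floor((distances - dmin) / R * n_bins)
  b[b >= n_bins] <- n_bins - 1
  b[b < 0] <- 0
  h <- tabulate(b + 1L, nbins = n_bins)
  list(histogram = as.numeric(h), range = R, d_min = dmin)
}

#' Strongest periodicity in a projection histogram
#'
#' Fourier-transforms the histogram; transform index k corresponds to a
#' direct-space length L_k = k / R. Among indices whose implied length lies
#' inside the search band (DC excluded, k below the Nyquist index), the
#' index with the largest transform magnitude wins.
#'
#' @param histogram Histogram vector from [periodicity_histogram()].
#' @param range The distance range R (inverse Angstrom).
#' @param options An [asdf_options()]; `direct_length_min` /
#'   `direct_length_max` bound the band (a `NULL` maximum falls back to
#'   250 Angstrom here, where no reference cell is in scope).
#' @return The candidate direct-space length L (Angstrom), or `NULL` when
#'   the band contains no transform index.
#' @export
fft_candidate_length <- function(histogram, range, options = asdf_options()) {
  band <- asdf_length_band(options, NULL)
  n_bins <- length(histogram)
  kmin <- max(1, ceiling(band[1] * range - 1e-9))
  kmax <- min(n_bins / 2 - 1, floor(band[2] * range + 1e-9))
  if (kmin > kmax) return(NULL)
  Fm <- Mod(stats::fft(histogram))
  ks <- kmin:kmax
  k <- ks[which.max(Fm[ks + 1])]
  k / range
}

#' Least-squares refinement of a candidate repeat length
#'
#' With p the trial reciprocal repeat (initially 1/L0), each distance is
#' assigned m_i = round(d_i / p); points with
#' |d_i - m_i p| <= fit_tolerance * p and m_i != 0 are fitting (the m = 0
#' origin slab carries no period information). The repeat is re-estimated
#' by the closed-form least-squares solution p = sum(m_i d_i) / sum(m_i^2)
#' over the fitting points, the multiples re-assigned at the new repeat,
#' and the fit iterated until stable (at most 10 rounds). The fitting
#' points are then counted at the refined repeat and the candidate is
#' accepted iff at least `min_fit_points` (7, "more than six") fit.
#'
#' @param distances Projected distances (inverse Angstrom).
#' @param L0 Candidate direct length (Angstrom), positive.
#' @param options An [asdf_options()].
#' @return List `length` (refined L), `repeat_p` (refined reciprocal
#'   repeat), `n_fit`, `accepted`; or `NULL` when no point carries period
#'   information (sum m^2 = 0).
#' @export
refine_repeat <- function(distances, L0, options = asdf_options()) {
  stopifnot(L0 > 0)
  p <- 1 / L0
  tol <- options$fit_tolerance
  for (it in 1:10) {
    m <- round(distances / p)
    fit <- m != 0 & abs(distances - m * p) <= tol * p
    sm2 <- sum(m[fit]^2)
    if (sm2 == 0) return(NULL)
    pnew <- sum(m[fit] * distances[fit]) / sm2
    if (pnew <= 0) return(NULL)
    converged <- abs(pnew - p) <= 1e-12 * p
    p <- pnew
    if (converged) break
  }
  m <- round(distances / p)
  fit <- m != 0 & abs(distances - m * p) <= tol * p
  n_fit <- sum(fit)
  list(length = 1 / p, repeat_p = p, n_fit = n_fit,
       accepted = n_fit >= options$min_fit_points)
}

#' Merge duplicate candidate lattice vectors
#'
#' Candidates from different triplets that describe the same lattice vector
#' (equal up to sign, lengths within 1 percent, directions within 3
#' degrees) are merged, keeping the higher fit count and summing the
#' source counts. The output is sorted by ascending length.
#'
#' @param candidates Data frame with columns `tx`, `ty`, `tz`, `L`,
#'   `n_fit` and optionally `sources` (defaults to 1 per row).
#' @return Merged data frame, sorted by ascending `L`, with a `sources`
#'   column.
#' @export
merge_candidates <- function(candidates) {
  cand <- as.data.frame(candidates)
  if (nrow(cand) == 0) {
    cand$sources <- integer(0)
    return(cand)
  }
  if (is.null(cand$sources)) cand$sources <- 1L
  cand <- cand[order(-cand$n_fit), , drop = FALSE]
  tm <- as.matrix(cand[, c("tx", "ty", "tz")])
  L <- cand$L
  un <- tm / L
  cos_tol <- cos(3 * pi / 180)
  taken <- rep(FALSE, nrow(cand))
  out <- list()
  for (i in seq_len(nrow(cand))) {
    if (taken[i]) next
    same <- !taken &
      abs(L - L[i]) <= 0.01 * pmax(L, L[i]) &
      abs(as.numeric(un %*% un[i, ])) >= cos_tol
    taken[same] <- TRUE
    row <- cand[i, , drop = FALSE]
    row$sources <- sum(cand$sources[same])
    out[[length(out) + 1]] <- row
  }
  res <- do.call(rbind, out)
  res <- res[order(res$L), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble a unit-cell basis from candidate lattice vectors
#'
#' Tries three-combinations of the (merged, length-sorted) candidates in
#' order of increasing total length. A combination is a basis when the
#' magnitude of the scalar triple product of its unit vectors exceeds 0.05
#' (not coplanar) and, when a reference cell is supplied, the cell volume
#' matches the reference volume within `volume_tolerance` (relative). The
#' basis is re-ordered right-handed (the third vector is negated if
#' needed). At most `combination_budget` combinations are examined.
#'
#' @param candidates Merged candidate data frame (see
#'   [merge_candidates()]).
#' @param reference Optional reference [unit_cell()] for the volume
#'   constraint.
#' @param options An [asdf_options()].
#' @param points Optional reciprocal-point matrix (n x 3); when supplied,
#'   an assembled basis is additionally validated by the fraction of
#'   points it indexes to near-integer Miller triples (see
#'   [asdf_options()]).
#' @return An `indexing_result`: list with `success`, `cell` (oriented
#'   [unit_cell()] on success), `n_candidates`, `failure_reason`.
#' @export
find_basis <- function(candidates, reference = NULL,
                       options = asdf_options(), points = NULL) {
  cand <- as.data.frame(candidates)
  result <- function(success, cell = NULL, reason = NA_character_) {
    structure(list(success = success, cell = cell,
                   n_candidates = nrow(cand), failure_reason = reason),
              class = "indexing_result")
  }
  if (nrow(cand) < 3) return(result(FALSE, reason = "fewer than 3 candidate vectors"))
  cand <- cand[order(cand$L), , drop = FALSE]
  # per-direction dedupe: among near-parallel candidates (within 3 degrees,
  # sign-insensitive) keep the best-supported one - most fitting points,
  # then most contributing triplets, then the shortest - so a slightly
  # mis-refined repeat cannot shadow the well-supported one
  un <- as.matrix(cand[, c("tx", "ty", "tz")]) / cand$L
  cos_tol <- cos(3 * pi / 180)
  keep <- rep(TRUE, nrow(cand))
  src <- if (is.null(cand$sources)) rep(1L, nrow(cand)) else cand$sources
  pref <- order(-cand$n_fit, -src, cand$L)
  seen <- matrix(0, 0, 3)
  for (i in pref) {
    if (nrow(seen) > 0 && any(abs(seen %*% un[i, ]) >= cos_tol))
      keep[i] <- FALSE
    else seen <- rbind(seen, un[i, ])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) < 3) return(result(FALSE, reason = "no independent basis"))
  # combinations are tried in increasing total length, so only the shortest
  # budget+2 candidates can ever take part within the budget
  n_keep <- min(nrow(cand), options$combination_budget + 2L)
  cand_top <- cand[seq_len(n_keep), , drop = FALSE]
  tm <- as.matrix(cand_top[, c("tx", "ty", "tz")])
  L <- cand_top$L
  combs <- utils::combn(n_keep, 3)
  tot <- L[combs[1, ]] + L[combs[2, ]] + L[combs[3, ]]
  ord <- order(tot)
  combs <- combs[, ord, drop = FALSE]
  n_try <- min(ncol(combs), options$combination_budget)
  saw_independent <- FALSE
  best_B <- NULL
  best_score <- -Inf
  for (ci in seq_len(n_try)) {
    sel <- combs[, ci]
    B <- t(tm[sel, , drop = FALSE])         # columns are the three vectors
    U <- sweep(B, 2, L[sel], "/")
    trip <- det(U)
    if (abs(trip) <= 0.05) next
    saw_independent <- TRUE
    if (det(B) < 0) B[, 3] <- -B[, 3]
    vol <- det(B)
    if (!is.null(reference)) {
      if (abs(vol - reference$volume) / reference$volume >
          options$volume_tolerance) next
    }
    if (is.null(points)) return(result(TRUE, cell = unit_cell(B)))
    # h = q . a etc.: fractional Miller indices of every point
    hkl <- points %*% B
    frac <- abs(hkl - round(hkl))
    ok <- rowSums(frac <= options$hkl_tolerance) == 3
    if (mean(ok) < options$min_indexed_fraction) next
    # among acceptable combinations keep the one indexing the most peaks
    # at a sharpened tolerance; combinations are visited shortest first,
    # so ties go to the shortest basis
    score <- mean(rowSums(frac <= options$hkl_tolerance / 2) == 3)
    if (score > best_score + 1e-9) {
      best_score <- score
      best_B <- B
    }
  }
  if (!is.null(best_B)) return(result(TRUE, cell = unit_cell(best_B)))
  if (!saw_independent) return(result(FALSE, reason = "no independent basis"))
  result(FALSE, reason = "no acceptable combination (volume/indexing constraints)")
}

#' @export
print.indexing_result <- function(x, ...) {
  if (x$success) {
    cat("<indexing_result> success\n")
    print(x$cell)
  } else {
    cat(sprintf("<indexing_result> failure: %s (candidates: %d)\n",
                x$failure_reason, x$n_candidates))
  }
  invisible(x)
}

#' FFT-based autoindexing of a still diffraction pattern
#'
#' Runs the full autoindexing chain: map detector peaks to reciprocal space
#' via the Ewald construction, generate peak triplets, search each triplet
#' plane normal for a one-dimensional periodicity (histogram + FFT), refine
#' accepted repeats by least squares, merge duplicate candidate lattice
#' vectors, and assemble the three shortest independent candidates into a
#' unit cell under the reference-volume constraint. Deterministic given
#' `rng_seed`.
#'
#' The per-triplet scan runs in compiled code; the exported R functions
#' ([project_distances()], [periodicity_histogram()],
#' [fft_candidate_length()], [refine_repeat()]) implement the identical
#' rules and serve as the reference path.
#'
#' @param peaks Peak data frame (columns `fast`, `slow`, optionally
#'   `intensity`) or a `reciprocal_peaks` data frame.
#' @param geometry A [detector_geometry()] (ignored when `peaks` is
#'   already in reciprocal space).
#' @param reference Optional reference [unit_cell()].
#' @param options An [asdf_options()].
#' @return An `indexing_result` (see [find_basis()]). Fewer than 7 peaks
#'   is an immediate failure result, not an error.
#' @export
asdf_index <- function(peaks, geometry = NULL, reference = NULL,
                       options = asdf_options()) {
  rp <- if (inherits(peaks, "reciprocal_peaks")) peaks else {
    stopifnot(inherits(geometry, "detector_geometry"))
    map_peaks_to_reciprocal(peaks, geometry)
  }
  if (nrow(rp) < 7) {
    return(structure(list(success = FALSE, cell = NULL, n_candidates = 0L,
                          failure_reason = "fewer than 7 peaks"),
                     class = "indexing_result"))
  }
  trip <- generate_triplets(rp, options)
  band <- asdf_length_band(options, reference)
  cand <- asdf_scan(trip$points, trip$indices, band[1], band[2],
                    options$n_bins, options$fit_tolerance,
                    options$min_fit_points)
  cand <- as.data.frame(cand)
  if (nrow(cand) == 0) {
    return(structure(list(success = FALSE, cell = NULL, n_candidates = 0L,
                          failure_reason = "no candidate lattice vectors"),
                     class = "indexing_result"))
  }
  # keep only candidates whose fit count is competitive with the best, and
  # cap the list so merging stays cheap on pathological inputs
  cand <- cand[cand$n_fit >= options$min_fit_fraction * max(cand$n_fit), ,
               drop = FALSE]
  if (nrow(cand) > options$max_candidates)
    cand <- cand[order(-cand$n_fit, cand$L)[seq_len(options$max_candidates)], ,
                 drop = FALSE]
  merged <- merge_candidates(cand)
  find_basis(merged, reference, options, points = trip$points)
}
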