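#' Options for the annular-statistics peak search
#'
#' @param min_snr Minimum signal-to-noise ratio for a returned peak
#'   (default 6).
#' @param adc_threshold Minimum pixel value (counts) for a candidate pixel
#'   (default 10).
#' @param min_pix,max_pix Connected-region size limits (defaults 2, 200).
#' @param fast_mode If `TRUE`, estimate the annulus statistics from a fixed
#'   random subsample of at most `fast_sample_size` pixels per annulus
#'   instead of the full annulus population. Sample positions are drawn
#'   once per annulus map (seeded), not per frame.
#' @param fast_sample_size Subsample size per annulus in fast mode
#'   (default 100).
#' @param rng_seed Seed for the fast-mode sample positions.
#' @return An object of class `peak_search_options`.
#' @export
peak_search_options <- function(min_snr = 6.0, adc_threshold = 10,
                                min_pix = 2L, max_pix = 200L,
                                fast_mode = FALSE, fast_sample_size = 100L,
                                rng_seed = 1L) {
  stopifnot(min_pix <= max_pix, fast_sample_size >= 2)
  structure(list(min_snr = min_snr, adc_threshold = adc_threshold,
                 min_pix = as.integer(min_pix), max_pix = as.integer(max_pix),
                 fast_mode = isTRUE(fast_mode),
                 fast_sample_size = as.integer(fast_sample_size),
                 rng_seed = as.integer(rng_seed)),
            class = "peak_search_options")
}

#' Precompute the annulus assignment of every pixel
#'
#' Assigns each pixel to a thin annulus around the beam centre:
#' `floor(radial distance in px / annulus_width)`. Bad pixels get -1. The
#' map depends only on the geometry and mask, not on frame content, so it
#' is computed once and reused for all frames of a run.
#'
#' @param geometry A [detector_geometry()].
#' @param mask Optional logical bad-pixel matrix (`TRUE` = bad).
#' @param annulus_width Radial width in pixels (default 1, i.e. thin
#'   annuli matching the radial scale of background variation).
#' @return An object of class `annulus_map` with elements `index`
#'   (integer matrix, -1 for bad), `n_annuli`, `annulus_width`.
#' @export
build_annulus_map <- function(geometry, mask = NULL, annulus_width = 1) {
  stopifnot(inherits(geometry, "detector_geometry"), annulus_width > 0)
  f <- matrix(seq_len(geometry$n_fast) - 1, geometry$n_fast, geometry$n_slow)
  s <- matrix(seq_len(geometry$n_slow) - 1, geometry$n_fast, geometry$n_slow,
              byrow = TRUE)
  r <- sqrt((f - geometry$beam_centre_fast)^2 +
              (s - geometry$beam_centre_slow)^2)
  idx <- as.integer(floor(r / annulus_width))
  dim(idx) <- dim(r)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(idx)))
    idx[mask] <- -1L
  }
  structure(list(index = idx, n_annuli = max(idx) + 1L,
                 annulus_width = annulus_width),
            class = "annulus_map")
}

# Fixed subsample positions per annulus for fast-mode statistics:
# deterministic in (map, sample_size, seed), hence identical for every
# frame processed with the same map and options.
annulus_sample_indices <- function(map, sample_size, seed) {
  good <- which(map$index >= 0L)
  groups <- split(good, map$index[good])
  local_seed(seed, {
    lapply(groups, function(g) {
      if (length(g) <= sample_size) g else sample(g, sample_size)
    })
  })
}

#' Robust annular background statistics for one frame
#'
#' Computes the per-annulus mean and standard deviation of pixel
#' intensities. Bragg peaks bias naive statistics, so three iterations of
#' outlier rejection discard pixels above mean + 3 sd before the final
#' estimates. In fast mode only a fixed seeded subsample of at most
#' `fast_sample_size` pixels per annulus is used; for annuli no larger
#' than the subsample this is exactly the full computation.
#'
#' @param image Numeric matrix `[fast, slow]`.
#' @param annulus_map An [build_annulus_map()] result.
#' @param options A [peak_search_options()].
#' @param mask Optional per-frame logical bad-pixel matrix (`TRUE` = bad);
#'   pixels masked only in this frame (e.g. sentinel values) are excluded
#'   on top of the map's static exclusions. In fast mode the sample
#'   positions stay fixed per map; frame-masked samples are merely
#'   skipped.
#' @return An object of class `radial_stats`: list of per-annulus vectors
#'   `mean`, `sigma`, `n_used`, `usable` (annuli with fewer than 2 usable
#'   pixels are flagged unusable).
#' @export
radial_stats <- function(image, annulus_map, options = peak_search_options(),
                         mask = NULL) {
  stopifnot(inherits(annulus_map, "annulus_map"),
            identical(dim(image), dim(annulus_map$index)))
  n_ann <- annulus_map$n_annuli
  if (options$fast_mode) {
    idx <- annulus_sample_indices(annulus_map, options$fast_sample_size,
                                  options$rng_seed)
    pix <- unlist(idx, use.names = FALSE)
  } else {
    pix <- which(annulus_map$index >= 0L)
  }
  if (!is.null(mask)) pix <- pix[!mask[pix]]
  a <- annulus_map$index[pix]
  v <- image[pix]
  keep <- rep(TRUE, length(v))
  for (i in 1:3) {
    st <- group_stats(v[keep], a[keep], n_ann)
    thr <- st$mean + 3 * st$sigma
    bad <- keep & v > thr[a + 1L]
    bad[is.na(bad)] <- FALSE
    if (!any(bad)) break
    keep <- keep & !bad
  }
  st <- group_stats(v[keep], a[keep], n_ann)
  structure(list(mean = st$mean, sigma = st$sigma, n_used = st$n,
                 usable = st$n >= 2L),
            class = "radial_stats")
}

# per-group mean / sd / count over integer groups 0..(n_groups-1)
group_stats <- function(v, g, n_groups) {
  n <- tabulate(g + 1L, nbins = n_groups)
  s1 <- rep(0, n_groups); s2 <- rep(0, n_groups)
  if (length(v)) {
    rs <- rowsum(cbind(v, v^2), g, reorder = TRUE)
    gi <- as.integer(rownames(rs)) + 1L
    s1[gi] <- rs[, 1]; s2[gi] <- rs[, 2]
  }
  m <- ifelse(n > 0, s1 / n, NA_real_)
  var <- ifelse(n > 1, pmax(0, (s2 - n * m^2) / (n - 1)), NA_real_)
  list(mean = m, sigma = sqrt(var), n = n)
}

#' Annular-statistics Bragg-peak search
#'
#' Candidate pixels are good pixels whose value exceeds
#' `max(adc_threshold, mean_r + min_snr * sigma_r)` for their annulus.
#' Candidates are grouped by 8-connectivity; regions with
#' `min_pix <= size <= max_pix` are kept. The centroid is the
#' intensity-weighted (background-subtracted) centre of mass, the peak
#' intensity is the background-subtracted sum, and the reported
#' signal-to-noise ratio is `intensity / (sigma_r * sqrt(n_pixels))` with
#' `sigma_r` taken at the centroid's annulus. Pixels in annuli with
#' unusable statistics are never candidates, and a peak whose centroid
#' falls on a bad pixel is dropped.
#'
#' @param image Numeric matrix `[fast, slow]`.
#' @param annulus_map An [build_annulus_map()] result (built with the same
#'   mask).
#' @param stats A [radial_stats()] result for this frame.
#' @param mask Logical bad-pixel matrix (`TRUE` = bad), or `NULL`.
#' @param options A [peak_search_options()].
#' @return Data frame with columns `fast`, `slow` (fractional 0-based
#'   centroid), `intensity`, `snr`, `n_pixels`, sorted by descending
#'   intensity.
#' @export
peakfinder8_search <- function(image, annulus_map, stats, mask = NULL,
                               options = peak_search_options()) {
  stopifnot(inherits(stats, "radial_stats"),
            identical(dim(image), dim(annulus_map$index)))
  idx <- annulus_map$index
  good <- idx >= 0L
  if (!is.null(mask)) good <- good & !mask
  ann1 <- idx + 1L
  usable <- stats$usable
  thr <- pmax(options$adc_threshold,
              stats$mean[pmax(ann1, 1L)] +
                options$min_snr * stats$sigma[pmax(ann1, 1L)])
  dim(thr) <- dim(image)
  cand <- good & usable[pmax(ann1, 1L)] & !is.na(thr) & image > thr
  cand[is.na(cand)] <- FALSE
  labels <- label_connected8(cand)
  n_reg <- max(labels)
  empty <- data.frame(fast = numeric(0), slow = numeric(0),
                      intensity = numeric(0), snr = numeric(0),
                      n_pixels = integer(0))
  if (n_reg == 0) return(empty)
  pix <- which(labels > 0L)
  lab <- labels[pix]
  sizes <- tabulate(lab, nbins = n_reg)
  keep_reg <- sizes >= options$min_pix & sizes <= options$max_pix
  if (!any(keep_reg)) return(empty)
  sel <- keep_reg[lab]
  pix <- pix[sel]; lab <- lab[sel]
  nf <- nrow(image)
  fpix <- (pix - 1L) %% nf          # 0-based fast coordinate
  spix <- (pix - 1L) %/% nf         # 0-based slow coordinate
  w <- image[pix] - stats$mean[idx[pix] + 1L]   # background-subtracted
  rs <- rowsum(cbind(w, w * fpix, w * spix), lab, reorder = TRUE)
  reg_ids <- as.integer(rownames(rs))
  intensity <- rs[, 1]
  fast <- rs[, 2] / intensity
  slow <- rs[, 3] / intensity
  n_pixels <- sizes[reg_ids]
  # sigma at the centroid's annulus
  cf <- pmin(pmax(round(fast), 0), nf - 1)
  cs <- pmin(pmax(round(slow), 0), ncol(image) - 1)
  cpix <- cf + 1L + cs * nf
  cann <- idx[cpix]
  sig <- ifelse(cann >= 0L & usable[pmax(cann + 1L, 1L)],
                stats$sigma[pmax(cann + 1L, 1L)], NA_real_)
  snr <- intensity / (sig * sqrt(n_pixels))
  cent_bad <- if (is.null(mask)) rep(FALSE, length(cpix)) else mask[cpix]
  ok <- !cent_bad & !is.na(snr) & snr >= options$min_snr
  out <- data.frame(fast = fast[ok], slow = slow[ok],
                    intensity = intensity[ok], snr = snr[ok],
                    n_pixels = n_pixels[ok])
  out <- out[order(-out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full annular peak search on one frame
#'
#' Convenience wrapper: builds (or reuses) the annulus map, computes the
#' robust radial statistics and runs the search.
#'
#' @inheritParams peakfinder8_search
#' @param geometry A [detector_geometry()].
#' @param annulus_map Optional precomputed [build_annulus_map()]; built on
#'   the fly when `NULL`.
#' @return As [peakfinder8_search()].
#' @export
find_peaks <- function(image, geometry, mask = NULL,
                       options = peak_search_options(), annulus_map = NULL) {
  if (is.null(annulus_map)) annulus_map <- build_annulus_map(geometry, mask)
  st <- radial_stats(image, annulus_map, options, mask)
  peakfinder8_search(image, annulus_map, st, mask, options)
}
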