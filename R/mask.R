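#' Bad-pixel mask specification
#'
#' A mask combines three sources of bad pixels: rectangular pixel-index
#' regions (defective areas tied to the data axes), rectangular
#' laboratory-frame regions (e.g. the beam-stop shadow, which moves with the
#' detector), and a sentinel pixel value written by the detector for
#' unusable pixels.
#'
#' @param pixel_rects List of numeric vectors
#'   `c(fast_min, fast_max, slow_min, slow_max)` (0-based pixel indices,
#'   inclusive).
#' @param lab_rects List of numeric vectors `c(x_min, x_max, y_min, y_max)`
#'   (mm, laboratory frame).
#' @param sentinel_value Integer pixel value treated as bad (default 65535,
#'   the 16-bit saturation value used by the detector).
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(pixel_rects = list(), lab_rects = list(),
                      sentinel_value = 65535L) {
  for (r in c(pixel_rects, lab_rects)) {
    stopifnot(length(r) == 4, is.numeric(r))
    if (r[1] > r[2] || r[3] > r[4]) stop("mask rectangle ranges must be well-ordered (min <= max)")
  }
  structure(list(pixel_rects = pixel_rects, lab_rects = lab_rects,
                 sentinel_value = sentinel_value),
            class = "mask_spec")
}

#' Convert a laboratory-frame mask rectangle to a pixel-index range
#'
#' Returns the minimal pixel rectangle containing every pixel whose centre
#' lies inside the (axis-aligned) laboratory rectangle. This conversion is
#' done once per geometry, not per frame, so that per-frame masking is a
#' cheap pixel-range fill rather than a per-pixel coordinate test.
#'
#' @param geometry A [detector_geometry()].
#' @param lab_rect Numeric `c(x_min, x_max, y_min, y_max)` (mm).
#' @return Integer vector `c(fast_min, fast_max, slow_min, slow_max)`
#'   (0-based, inclusive), or `NULL` if no pixel centre falls inside the
#'   rectangle (an off-detector rectangle is not an error).
#' @export
lab_mask_to_pixel_ranges <- function(geometry, lab_rect) {
  stopifnot(inherits(geometry, "detector_geometry"), length(lab_rect) == 4)
  ps <- geometry$pixel_size
  # pixel centre fast index f has x = (f - bc_fast) * ps; invert the bounds
  f_lo <- ceiling(lab_rect[1] / ps + geometry$beam_centre_fast)
  f_hi <- floor(lab_rect[2] / ps + geometry$beam_centre_fast)
  s_lo <- ceiling(lab_rect[3] / ps + geometry$beam_centre_slow)
  s_hi <- floor(lab_rect[4] / ps + geometry$beam_centre_slow)
  f_lo <- max(f_lo, 0); s_lo <- max(s_lo, 0)
  f_hi <- min(f_hi, geometry$n_fast - 1); s_hi <- min(s_hi, geometry$n_slow - 1)
  if (f_lo > f_hi || s_lo > s_hi) return(NULL)
  as.integer(c(f_lo, f_hi, s_lo, s_hi))
}

#' Build the bad-pixel mask for one frame
#'
#' A pixel is bad iff its value equals the sentinel, or it lies inside any
#' pixel-index rectangle, or inside any laboratory rectangle (after
#' conversion to pixel ranges via [lab_mask_to_pixel_ranges()]). The
#' region-derived part depends only on the geometry and can be reused
#' across frames; only the sentinel test is per-frame.
#'
#' @param image Numeric/integer matrix `[fast, slow]` matching the geometry.
#' @param spec A [mask_spec()].
#' @param geometry A [detector_geometry()].
#' @return Logical matrix, `TRUE` = bad pixel.
#' @export
build_bad_pixel_mask <- function(image, spec, geometry) {
  stopifnot(inherits(spec, "mask_spec"), inherits(geometry, "detector_geometry"))
  if (nrow(image) != geometry$n_fast || ncol(image) != geometry$n_slow)
    stop("image shape does not match the detector geometry")
  mask <- static_region_mask(spec, geometry)
  mask | (image == spec$sentinel_value)
}

# Frame-independent part of the mask (pixel rectangles + converted lab
# rectangles). Computed once per run and reused.
static_region_mask <- function(spec, geometry) {
  mask <- matrix(FALSE, geometry$n_fast, geometry$n_slow)
  rects <- spec$pixel_rects
  for (lr in spec$lab_rects) {
    pr <- lab_mask_to_pixel_ranges(geometry, lr)
    if (!is.null(pr)) rects <- c(rects, list(pr))
  }
  for (r in rects) {
    f <- max(0, ceiling(r[1])):min(geometry$n_fast - 1, floor(r[2]))
    s <- max(0, ceiling(r[3])):min(geometry$n_slow - 1, floor(r[4]))
    if (r[1] > geometry$n_fast - 1 || r[2] < 0 ||
        r[3] > geometry$n_slow - 1 || r[4] < 0) next
    mask[f + 1, s + 1] <- TRUE
  }
  mask
}
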