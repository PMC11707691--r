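#' Detector geometry for a single-panel still-diffraction detector
#'
#' Describes a flat single-panel detector normal to the beam, together with
#' the beam parameters needed for the Ewald construction. The fixed frame
#' convention is: beam along +z, detector plane at z = `camera_length`, the
#' fast-scan axis along +x and the slow-scan axis along +y. Pixel
#' coordinates are 0-based and a pixel's laboratory position is its centre.
#'
#' Internal units are Angstrom for the wavelength, inverse Angstrom for
#' reciprocal-space vectors and millimetre for laboratory coordinates.
#'
#' @param n_fast,n_slow Pixel counts along the fast and slow scan axes.
#' @param pixel_size Pixel edge length (mm).
#' @param camera_length Sample-to-detector distance along the beam (mm).
#' @param beam_centre_fast,beam_centre_slow Beam centre in (possibly
#'   fractional) pixel coordinates.
#' @param wavelength Radiation wavelength (Angstrom).
#' @return An object of class `detector_geometry`. The object carries a
#'   `panels` list of length one so that a segmented-detector extension
#'   remains possible without changing the interface.
#' @examples
#' g <- detector_geometry(512, 512, 0.2, 100, 256, 256, 1.0)
#' pixel_to_lab(g, 256, 256)  # the beam centre maps to (0, 0, camera_length)
#' @export
detector_geometry <- function(n_fast, n_slow, pixel_size, camera_length,
                              beam_centre_fast, beam_centre_slow,
                              wavelength) {
  stopifnot(
    is.numeric(n_fast), n_fast >= 1,
    is.numeric(n_slow), n_slow >= 1,
    is.numeric(pixel_size), pixel_size > 0,
    is.numeric(camera_length), camera_length > 0,
    is.numeric(wavelength), wavelength > 0,
    is.finite(beam_centre_fast), is.finite(beam_centre_slow)
  )
  g <- list(
    n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
    pixel_size = pixel_size, camera_length = camera_length,
    beam_centre_fast = beam_centre_fast, beam_centre_slow = beam_centre_slow,
    wavelength = wavelength
  )
  g$panels <- list(g[c("n_fast", "n_slow", "pixel_size", "camera_length",
                       "beam_centre_fast", "beam_centre_slow")])
  class(g) <- "detector_geometry"
  g
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> %d x %d px, %.4g mm/px, clen %.4g mm, centre (%.2f, %.2f), lambda %.4g A\n",
    x$n_fast, x$n_slow, x$pixel_size, x$camera_length,
    x$beam_centre_fast, x$beam_centre_slow, x$wavelength))
  invisible(x)
}

#' Map pixel coordinates to the laboratory frame
#'
#' @param geometry A [detector_geometry()].
#' @param fast,slow Pixel coordinates (0-based, fractional allowed). Vectors
#'   are mapped element-wise.
#' @return A matrix with one row per input coordinate and columns
#'   `x`, `y`, `z` (mm).
#' @export
pixel_to_lab <- function(geometry, fast, slow) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (any(!is.finite(fast)) || any(!is.finite(slow)))
    stop("pixel coordinates must be finite")
  cbind(
    x = (fast - geometry$beam_centre_fast) * geometry$pixel_size,
    y = (slow - geometry$beam_centre_slow) * geometry$pixel_size,
    z = rep_len(geometry$camera_length, length(fast))
  )
}

#' Map laboratory coordinates on the detector plane back to pixels
#'
#' Inverse of [pixel_to_lab()] for points on the detector plane; the z
#' component is ignored.
#'
#' @inheritParams pixel_to_lab
#' @param lab Matrix (or length-3 vector) of laboratory coordinates (mm).
#' @return Matrix with columns `fast`, `slow` (pixels).
#' @export
lab_to_pixel <- function(geometry, lab) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = 3)
  cbind(
    fast = lab[, 1] / geometry$pixel_size + geometry$beam_centre_fast,
    slow = lab[, 2] / geometry$pixel_size + geometry$beam_centre_slow
  )
}

#' Map detector peaks to reciprocal space via the Ewald construction
#'
#' Each peak at laboratory position p defines a scattered-beam direction
#' s = p/|p|; its reciprocal-space coordinate is q = (s - z)/lambda with z
#' the unit beam vector. The mapping is monochromatic (zero wavelength
#' spread), so every q lies exactly on the Ewald sphere:
#' |q + z/lambda| = 1/lambda.
#'
#' @param peaks A peak data frame with columns `fast` and `slow` (pixel
#'   centroids) and optionally `intensity`.
#' @param geometry A [detector_geometry()].
#' @return A data frame of class `reciprocal_peaks` with columns `qx`, `qy`,
#'   `qz` (inverse Angstrom), `intensity`, and the source `fast`, `slow`
#'   columns; row order follows the input.
#' @export
map_peaks_to_reciprocal <- function(peaks, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0) {
    out <- data.frame(qx = numeric(0), qy = numeric(0), qz = numeric(0),
                      intensity = numeric(0), fast = numeric(0),
                      slow = numeric(0))
    class(out) <- c("reciprocal_peaks", "data.frame")
    return(out)
  }
  p <- pixel_to_lab(geometry, peaks$fast, peaks$slow)
  nrm <- sqrt(rowSums(p^2))
  if (any(nrm == 0)) stop("peak at the sample position has no direction")
  s <- p / nrm
  lambda <- geometry$wavelength
  out <- data.frame(
    qx = s[, 1] / lambda,
    qy = s[, 2] / lambda,
    qz = (s[, 3] - 1) / lambda,
    intensity = if ("intensity" %in% names(peaks)) peaks$intensity else
      rep_len(1, nrow(peaks)),
    fast = peaks$fast, slow = peaks$slow
  )
  class(out) <- c("reciprocal_peaks", "data.frame")
  out
}

#' Bin an image (and its mask) in square blocks
#'
#' Combines pixel readout values in squares with side length `factor`
#' (1 to 4 are the intended factors, larger values work). Output dimensions
#' are `ceiling(dim/factor)`; each output pixel is the sum of its unmasked
#' member pixels, and an output pixel is masked iff any member pixel is
#' masked. Blocks truncated at the detector edge simply have fewer members.
#'
#' @param image Numeric matrix, indexed `[fast, slow]`.
#' @param factor Positive integer binning factor; 1 is the identity.
#' @param mask Optional logical matrix, `TRUE` = bad pixel.
#' @return `list(image = <binned matrix>, mask = <binned logical matrix>)`.
#' @export
bin_image <- function(image, factor, mask = NULL) {
  stopifnot(is.matrix(image))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(image), ncol(image))
  stopifnot(identical(dim(mask), dim(image)))
  if (factor == 1L) return(list(image = image, mask = mask))
  gi <- (seq_len(nrow(image)) - 1L) %/% factor
  gj <- (seq_len(ncol(image)) - 1L) %/% factor
  vals <- image
  vals[mask] <- 0
  # sum rows within row-groups, then columns within column-groups
  sr <- rowsum(vals, gi, reorder = TRUE)
  binned <- t(rowsum(t(sr), gj, reorder = TRUE))
  mr <- rowsum(mask + 0, gi, reorder = TRUE)
  mb <- t(rowsum(t(mr), gj, reorder = TRUE)) > 0
  dimnames(binned) <- NULL
  dimnames(mb) <- NULL
  list(image = binned, mask = mb)
}
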