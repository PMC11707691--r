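#' Options for reflection prediction and integration
#'
#' For still images a reflection is recorded when its reciprocal-lattice
#' point lies close enough to the Ewald sphere. The excitation-error band
#' used here is linear in |q|: a reflection is predicted when
#' `|e| <= e_max_abs + e_max_rel * |q|`, the minimal still-diffraction
#' convention in the absence of a physical partiality model.
#'
#' @param e_max_abs Absolute excitation-error tolerance (inverse Angstrom,
#'   default 0.001).
#' @param e_max_rel Excitation-error tolerance as a fraction of |q|
#'   (default 0.002).
#' @param d_min,d_max Resolution window (Angstrom).
#' @param peak_radius Integration disc radius (px, default 4).
#' @param bg_inner,bg_outer Background annulus radii (px, defaults 5, 7);
#'   must satisfy `bg_outer > bg_inner > peak_radius`.
#' @return An object of class `integration_options`.
#' @export
integration_options <- function(e_max_abs = 0.001, e_max_rel = 0.002,
                                d_min = 1.5, d_max = Inf,
                                peak_radius = 4, bg_inner = 5, bg_outer = 7) {
  stopifnot(bg_outer > bg_inner, bg_inner > peak_radius, d_max > d_min,
            d_min > 0, e_max_abs >= 0, e_max_rel >= 0)
  structure(list(e_max_abs = e_max_abs, e_max_rel = e_max_rel,
                 d_min = d_min, d_max = d_max, peak_radius = peak_radius,
                 bg_inner = bg_inner, bg_outer = bg_outer),
            class = "integration_options")
}

# Enumerate reciprocal-lattice points of an oriented cell near the Ewald
# sphere and project them onto the detector. Shared by prediction and by
# the pattern simulator so the two stay exact duals.
ewald_reflections <- function(cell, geometry, e_max_abs, e_max_rel,
                              d_min, d_max = Inf) {
  stopifnot(inherits(cell, "unit_cell"), inherits(geometry, "detector_geometry"))
  p <- cell$parameters
  hmax <- floor(p["a"] / d_min) + 1
  kmax <- floor(p["b"] / d_min) + 1
  lmax <- floor(p["c"] / d_min) + 1
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  q <- scattering_vector(cell, g$h, g$k, g$l)
  aq <- sqrt(rowSums(q^2))
  keep <- aq > 0 & 1 / aq >= d_min & 1 / aq <= d_max
  g <- g[keep, , drop = FALSE]; q <- q[keep, , drop = FALSE]; aq <- aq[keep]
  lambda <- geometry$wavelength
  # excitation error: distance from the Ewald sphere centred at -z/lambda
  kout <- cbind(q[, 1], q[, 2], q[, 3] + 1 / lambda)
  akout <- sqrt(rowSums(kout^2))
  e <- akout - 1 / lambda
  keep <- abs(e) <= e_max_abs + e_max_rel * aq
  g <- g[keep, , drop = FALSE]; q <- q[keep, , drop = FALSE]
  kout <- kout[keep, , drop = FALSE]; e <- e[keep]
  # project the scattered direction onto the detector plane z = clen
  sz <- kout[, 3]
  ok_dir <- sz > 1e-12
  tt <- ifelse(ok_dir, geometry$camera_length / sz, NA_real_)
  x <- kout[, 1] * tt; y <- kout[, 2] * tt
  fast <- x / geometry$pixel_size + geometry$beam_centre_fast
  slow <- y / geometry$pixel_size + geometry$beam_centre_slow
  on_det <- ok_dir & fast >= 0 & fast <= geometry$n_fast - 1 &
    slow >= 0 & slow <= geometry$n_slow - 1
  data.frame(h = g$h, k = g$k, l = g$l,
             qx = q[, 1], qy = q[, 2], qz = q[, 3], e = e,
             fast = fast, slow = slow,
             flag = ifelse(on_det, "ok", "off-detector"),
             stringsAsFactors = FALSE)
}

#' Predict reflection positions from an oriented cell
#'
#' Enumerates Miller indices in the resolution window, keeps those whose
#' excitation error is inside the tolerance band, and projects the
#' scattered-beam direction onto the detector plane. Reflections whose
#' projection falls outside the detector are flagged `off-detector`.
#'
#' @param cell An oriented [unit_cell()] (e.g. from [asdf_index()]).
#' @param geometry A [detector_geometry()].
#' @param options An [integration_options()].
#' @return Data frame with columns `h`, `k`, `l`, `qx`, `qy`, `qz`, `e`
#'   (excitation error), `fast`, `slow`, `flag`, plus `intensity` and
#'   `sigma` columns initialised to `NA` for [integrate_reflections()].
#' @export
predict_reflections <- function(cell, geometry,
                                options = integration_options()) {
  refl <- ewald_reflections(cell, geometry, options$e_max_abs,
                            options$e_max_rel, options$d_min, options$d_max)
  refl$intensity <- NA_real_
  refl$sigma <- NA_real_
  refl
}

#' Integrate predicted reflections on an image
#'
#' For each predicted on-detector reflection, sums the
#' background-subtracted counts over a disc of `peak_radius` pixels around
#' the predicted position. The local background is the median of the
#' annulus between `bg_inner` and `bg_outer`; sigma is
#' `sqrt(sum(counts) + n_px * var(background))`. Reflections whose disc
#' touches a bad pixel are flagged `masked`; discs extending beyond the
#' detector are flagged `off-detector`.
#'
#' @param image Numeric matrix `[fast, slow]`.
#' @param reflections Output of [predict_reflections()].
#' @param mask Logical bad-pixel matrix or `NULL`.
#' @param options An [integration_options()].
#' @return The reflection data frame with `intensity`, `sigma` and `flag`
#'   filled in.
#' @export
integrate_reflections <- function(image, reflections, mask = NULL,
                                  options = integration_options()) {
  nf <- nrow(image); ns <- ncol(image)
  r_out <- ceiling(options$bg_outer)
  # relative offsets within the bounding box, computed once
  off <- expand.grid(df = -r_out:r_out, ds = -r_out:r_out)
  rr <- sqrt(off$df^2 + off$ds^2)
  disc <- rr <= options$peak_radius
  annulus <- rr >= options$bg_inner & rr <= options$bg_outer
  refl <- reflections
  for (i in seq_len(nrow(refl))) {
    if (refl$flag[i] != "ok") next
    cf <- round(refl$fast[i]); cs <- round(refl$slow[i])
    f <- cf + off$df; s <- cs + off$ds
    inside <- f >= 0 & f < nf & s >= 0 & s < ns
    if (!all(inside[disc])) { refl$flag[i] <- "off-detector"; next }
    pix <- (f + 1L) + s * nf
    if (!is.null(mask) && any(mask[pix[disc & inside]])) {
      refl$flag[i] <- "masked"; next
    }
    bgpix <- pix[annulus & inside]
    if (!is.null(mask)) bgpix <- bgpix[!mask[bgpix]]
    if (length(bgpix) < 3) { refl$flag[i] <- "masked"; next }
    bg <- stats::median(image[bgpix])
    bgvar <- stats::var(image[bgpix])
    vals <- image[pix[disc]]
    refl$intensity[i] <- sum(vals - bg)
    refl$sigma[i] <- sqrt(max(0, sum(vals)) + sum(disc) * bgvar)
  }
  refl
}

#' Classify a frame as a hit
#'
#' A frame is a hit (a plausibly useful diffraction pattern) when the peak
#' search found at least `min_peaks` peaks.
#'
#' @param peaks Peak data frame.
#' @param min_peaks Threshold (default 15).
#' @return Logical.
#' @export
classify_hit <- function(peaks, min_peaks = 15L) {
  nrow(as.data.frame(peaks)) >= min_peaks
}
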