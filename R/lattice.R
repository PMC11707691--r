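#' Unit cell with cached reciprocal matrix
#'
#' A unit cell is stored as its direct-space basis matrix (columns a, b, c,
#' in Angstrom). The reciprocal Cartesian matrix (columns a*, b*, c*) and
#' the volume are computed once at construction and cached, so that
#' per-reflection scattering-vector computation is a single matrix product
#' with no trigonometric calls and no repeated inversion.
#'
#' @param basis 3x3 numeric matrix with the direct-space basis vectors as
#'   columns (Angstrom). Must be right-handed (positive determinant).
#' @return An object of class `unit_cell` with elements `basis`, `recip`
#'   (columns a*, b*, c*, inverse Angstrom), `volume` (cubic Angstrom) and
#'   `parameters` (named vector a, b, c, alpha, beta, gamma; Angstrom and
#'   degrees).
#' @seealso [cell_from_parameters()], [scattering_vector()], [niggli_reduce()]
#' @export
unit_cell <- function(basis) {
  stopifnot(is.matrix(basis), all(dim(basis) == c(3, 3)), all(is.finite(basis)))
  vol <- det(basis)
  if (abs(vol) < 1e-9) stop("degenerate (coplanar) basis")
  if (vol < 0) stop("basis must be right-handed (positive determinant)")
  structure(list(
    basis = basis,
    recip = t(solve(basis)),
    volume = vol,
    parameters = basis_parameters(basis)
  ), class = "unit_cell")
}

basis_parameters <- function(basis) {
  a <- basis[, 1]; b <- basis[, 2]; cc <- basis[, 3]
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(cc^2))
  ang <- function(u, v, lu, lv) {
    x <- sum(u * v) / (lu * lv)
    acos(max(-1, min(1, x))) * 180 / pi
  }
  c(a = la, b = lb, c = lc,
    alpha = ang(b, cc, lb, lc), beta = ang(a, cc, la, lc),
    gamma = ang(a, b, la, lb))
}

#' @export
print.unit_cell <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "<unit_cell> a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg  V=%.1f A^3\n",
    p["a"], p["b"], p["c"], p["alpha"], p["beta"], p["gamma"], x$volume))
  invisible(x)
}

#' Construct a unit cell from scalar parameters
#'
#' Builds the canonical orientation: a along +x, b in the xy-plane, c
#' completing a right-handed set.
#'
#' @param a,b,c Axis lengths (Angstrom), positive.
#' @param alpha,beta,gamma Cell angles (degrees), in (0, 180) and jointly
#'   feasible.
#' @return A [unit_cell()].
#' @examples
#' lys <- cell_from_parameters(79.2, 79.2, 38, 90, 90, 90)
#' lys$volume  # 238 371.8 cubic Angstrom
#' @export
cell_from_parameters <- function(a, b, c, alpha, beta, gamma) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  cz2 <- 1 - cb^2 - ((ca - cb * cg) / sg)^2
  if (cz2 <= 0) stop("infeasible cell parameters")
  basis <- cbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(cz2))
  )
  unit_cell(basis)
}

#' Scattering vector for a reflection
#'
#' q = h a* + k b* + l c*, computed as a product with the cached reciprocal
#' matrix. Vectorised over reflections.
#'
#' @param cell A [unit_cell()].
#' @param h,k,l Integer Miller indices (equal-length vectors).
#' @return Matrix with one row per reflection, columns `qx`, `qy`, `qz`
#'   (inverse Angstrom).
#' @export
scattering_vector <- function(cell, h, k, l) {
  stopifnot(inherits(cell, "unit_cell"))
  q <- cell$recip %*% rbind(h, k, l)
  out <- t(q)
  colnames(out) <- c("qx", "qy", "qz")
  out
}

#' Apply a unimodular (integer, det +-1) transform to a cell basis
#'
#' The transformed cell describes the same lattice. Used for reduction and
#' in lattice-invariance tests.
#'
#' @param cell A [unit_cell()].
#' @param m 3x3 integer matrix with determinant +1 or -1; the new basis is
#'   `basis %*% m` (a column mix of the old basis vectors). When the
#'   determinant is negative the third new vector is negated to keep the
#'   basis right-handed (same lattice).
#' @return A [unit_cell()].
#' @export
transform_cell <- function(cell, m) {
  stopifnot(inherits(cell, "unit_cell"), all(dim(m) == c(3, 3)))
  d <- round(det(m))
  if (abs(d) != 1) stop("transform must be unimodular (|det| = 1)")
  b <- cell$basis %*% m
  if (d < 0) b[, 3] <- -b[, 3]
  unit_cell(b)
}

#' G6 vector of a cell
#'
#' The six-component representation (a^2, b^2, c^2, 2bc cos(alpha),
#' 2ca cos(beta), 2ab cos(gamma)) used for reduced-cell comparison.
#'
#' @param cell A [unit_cell()].
#' @return Numeric length-6 vector.
#' @export
g6_vector <- function(cell) {
  b <- cell$basis
  a <- b[, 1]; bb <- b[, 2]; cc <- b[, 3]
  c(sum(a^2), sum(bb^2), sum(cc^2),
    2 * sum(bb * cc), 2 * sum(a * cc), 2 * sum(a * bb))
}
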