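laue_ops <- function(laue_group) {
  switch(laue_group,
    "-1" = list(function(h, k, l) cbind(h, k, l)),
    "4/mmm" = list(
      function(h, k, l) cbind(h, k, l),
      function(h, k, l) cbind(-h, -k, l),
      function(h, k, l) cbind(-k, h, l),
      function(h, k, l) cbind(k, -h, l),
      function(h, k, l) cbind(-h, k, -l),
      function(h, k, l) cbind(h, -k, -l),
      function(h, k, l) cbind(k, h, -l),
      function(h, k, l) cbind(-k, -h, -l)
    ),
    stop("unsupported Laue group: ", laue_group)
  )
}

#' Count symmetry-unique reflections in a resolution range
#'
#' Enumerates all Miller indices with `d_min <= d(hkl) <= d_max`, where
#' d = 1/|h a* + k b* + l c*|, merges them into Laue-group equivalence
#' classes (Friedel mates always merged), and counts the distinct classes.
#' (0,0,0) is excluded; systematically absent reflections are included,
#' since merging by Laue symmetry alone cannot know the space group.
#'
#' Resolution bounds are inclusive at both ends, with a small relative
#' tolerance (`1e-9`) so that reflections whose d equals a bound exactly in
#' real arithmetic are not lost to floating-point rounding. `d_max = Inf`
#' counts the full low-resolution range.
#'
#' The class representative is the lexicographically greatest equivalent
#' (h, k, l) tuple including Friedel mates, which gives deterministic class
#' labels.
#'
#' @param cell A [unit_cell()].
#' @param laue_group `"-1"` (triclinic, Friedel only) or `"4/mmm"`
#'   (tetragonal holohedry).
#' @param d_max,d_min Resolution limits (Angstrom), `d_max > d_min > 0`;
#'   `d_max` may be `Inf`.
#' @return Integer count of distinct reflection classes.
#' @examples
#' lys <- cell_from_parameters(79.2, 79.2, 38, 90, 90, 90)
#' count_unique_reflections(lys, "4/mmm", Inf, 1.80)  # 11716
#' @export
count_unique_reflections <- function(cell, laue_group, d_max, d_min) {
  stopifnot(inherits(cell, "unit_cell"), d_max >= d_min, d_min > 0)
  ops <- laue_ops(laue_group)
  p <- cell$parameters
  tol <- 1e-9
  hmax <- floor(p["a"] / d_min * (1 + tol)) + 1
  kmax <- floor(p["b"] / d_min * (1 + tol)) + 1
  lmax <- floor(p["c"] / d_min * (1 + tol)) + 1
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  q <- scattering_vector(cell, g$h, g$k, g$l)
  q2 <- rowSums(q^2)
  d <- 1 / sqrt(q2)
  keep <- q2 > 0 & d >= d_min * (1 - tol) &
    (is.infinite(d_max) | d <= d_max * (1 + tol))
  h <- g$h[keep]; k <- g$k[keep]; l <- g$l[keep]
  if (length(h) == 0) return(0L)
  # lexicographic max over equivalents via an exact integer key
  B <- 2048
  stopifnot(max(abs(c(h, k, l))) < B)
  key <- rep(-Inf, length(h))
  for (op in ops) {
    for (sgn in c(1, -1)) {  # Friedel
      e <- sgn * op(h, k, l)
      ki <- ((e[, 1] + B) * 4096 + (e[, 2] + B)) * 4096 + (e[, 3] + B)
      key <- pmax(key, ki)
    }
  }
  length(unique(key))
}

#' Read a unit cell from a plain-text file
#'
#' Accepts either a line `a b c alpha beta gamma` (whitespace- or
#' comma-separated, Angstrom and degrees, optionally followed by a
#' lattice-type/centring letter which is ignored for the primitive
#' construction), or a PDB `CRYST1` record. Lines starting with `#` are
#' skipped.
#'
#' @param path File path.
#' @return A [unit_cell()] in the canonical orientation.
#' @export
read_cell_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no cell found in ", path)
  ln <- lines[[1]]
  if (startsWith(ln, "CRYST1")) {
    v <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                      substr(ln, 25, 33), substr(ln, 34, 40),
                      substr(ln, 41, 47), substr(ln, 48, 54)))
  } else {
    tok <- strsplit(gsub(",", " ", ln), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    v <- v[!is.na(v)]
  }
  if (length(v) < 6) stop("cell line must contain a b c alpha beta gamma")
  cell_from_parameters(v[1], v[2], v[3], v[4], v[5], v[6])
}

#' Write a unit cell to a plain-text file
#'
#' @param cell A [unit_cell()].
#' @param path File path.
#' @export
write_cell_file <- function(cell, path) {
  p <- cell$parameters
  writeLines(sprintf("%.6f %.6f %.6f %.6f %.6f %.6f",
                     p["a"], p["b"], p["c"], p["alpha"], p["beta"],
                     p["gamma"]), path)
  invisible(path)
}
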