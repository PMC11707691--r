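#' Read a detector geometry (and mask) description file
#'
#' Plain-text `key = value` dialect. Recognised keys: `wavelength_A`,
#' `clen_mm`, `pixel_size_mm`, `beam_centre_fast_px`, `beam_centre_slow_px`,
#' `n_fast`, `n_slow`, `mask_value`, and the repeatable `mask_rect_px` /
#' `mask_rect_lab_mm` (each a comma- or space-separated quadruple
#' min,max,min,max in pixel indices or lab mm). Lines starting with `#`
#' or `;` are comments.
#'
#' @param path File path.
#' @return `list(geometry = <detector_geometry>, mask = <mask_spec>)`.
#' @export
read_geometry_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^[#;]", lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_,
                 character(1))
  if (anyNA(keys)) stop("malformed geometry line: ", lines[which(is.na(keys))[1]])
  num <- function(key, default = NULL) {
    i <- which(keys == key)
    if (length(i) == 0) {
      if (is.null(default)) stop("missing geometry key: ", key)
      return(default)
    }
    as.numeric(vals[i[length(i)]])
  }
  quad <- function(v) {
    x <- suppressWarnings(as.numeric(strsplit(gsub(",", " ", v), "\\s+")[[1]]))
    x <- x[!is.na(x)]
    if (length(x) != 4) stop("mask rectangle must have 4 numbers: ", v)
    x
  }
  geometry <- detector_geometry(
    n_fast = num("n_fast"), n_slow = num("n_slow"),
    pixel_size = num("pixel_size_mm"), camera_length = num("clen_mm"),
    beam_centre_fast = num("beam_centre_fast_px"),
    beam_centre_slow = num("beam_centre_slow_px"),
    wavelength = num("wavelength_A")
  )
  mask <- mask_spec(
    pixel_rects = lapply(vals[keys == "mask_rect_px"], quad),
    lab_rects = lapply(vals[keys == "mask_rect_lab_mm"], quad),
    sentinel_value = as.integer(num("mask_value", 65535))
  )
  list(geometry = geometry, mask = mask)
}

#' Write a detector geometry (and mask) description file
#'
#' @param geometry A [detector_geometry()].
#' @param path File path.
#' @param mask Optional [mask_spec()].
#' @export
write_geometry_file <- function(geometry, path, mask = NULL) {
  ln <- c(
    sprintf("wavelength_A = %.9g", geometry$wavelength),
    sprintf("clen_mm = %.9g", geometry$camera_length),
    sprintf("pixel_size_mm = %.9g", geometry$pixel_size),
    sprintf("beam_centre_fast_px = %.9g", geometry$beam_centre_fast),
    sprintf("beam_centre_slow_px = %.9g", geometry$beam_centre_slow),
    sprintf("n_fast = %d", geometry$n_fast),
    sprintf("n_slow = %d", geometry$n_slow)
  )
  if (!is.null(mask)) {
    ln <- c(ln, sprintf("mask_value = %d", mask$sentinel_value),
            vapply(mask$pixel_rects, function(r)
              sprintf("mask_rect_px = %s", paste(r, collapse = ",")),
              character(1)),
            vapply(mask$lab_rects, function(r)
              sprintf("mask_rect_lab_mm = %s", paste(r, collapse = ",")),
              character(1)))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Write a peak list as TSV
#'
#' Columns: fast, slow, intensity, snr, n_pixels. Full numeric precision is
#' preserved on round trip.
#'
#' @param peaks Peak data frame (see [peakfinder8_search()]).
#' @param path File path.
#' @export
write_peaks_tsv <- function(peaks, path) {
  utils::write.table(
    format(as.data.frame(peaks), digits = 17, trim = TRUE, scientific = NA),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak list written by [write_peaks_tsv()]
#'
#' @param path File path.
#' @return Peak data frame.
#' @export
read_peaks_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
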