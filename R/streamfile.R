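fmt_num <- function(x) sprintf("%.17g", x)

#' Write one processed frame as a text stream chunk
#'
#' Chunked text output in the spirit of serial-crystallography stream
#' files: each chunk is delimited by begin/end markers and contains the
#' peak table, the oriented cell basis when the frame was indexed, and the
#' integrated reflection table. All numeric fields are written with 17
#' significant digits so that parsing recovers them exactly.
#'
#' @param sink A connection, a file path (appended to), or `NULL` to just
#'   return the lines.
#' @param frame_id Integer frame id.
#' @param peaks Peak data frame (`fast`, `slow`, `intensity`, `snr`,
#'   `n_pixels`); `NULL` or empty for blank frames.
#' @param indexing An `indexing_result` or `NULL` (non-hit).
#' @param reflections Integrated reflection data frame or `NULL`.
#' @return The lines written, invisibly.
#' @export
write_stream_chunk <- function(sink, frame_id, peaks = NULL,
                               indexing = NULL, reflections = NULL) {
  ln <- c("----- Begin chunk -----",
          sprintf("Frame id: %d", as.integer(frame_id)))
  pk <- if (is.null(peaks)) data.frame() else as.data.frame(peaks)
  ln <- c(ln, sprintf("num_peaks = %d", nrow(pk)),
          "Peaks from peak search",
          "  fast  slow  intensity  snr  n_pixels")
  if (nrow(pk) > 0)
    ln <- c(ln, sprintf("  %s %s %s %s %d", fmt_num(pk$fast),
                        fmt_num(pk$slow), fmt_num(pk$intensity),
                        fmt_num(pk$snr), as.integer(pk$n_pixels)))
  ln <- c(ln, "End of peak list")
  if (!is.null(indexing) && isTRUE(indexing$success)) {
    b <- indexing$cell$basis
    ln <- c(ln, "--- Begin crystal",
            sprintf("a_vec = %s %s %s", fmt_num(b[1, 1]), fmt_num(b[2, 1]),
                    fmt_num(b[3, 1])),
            sprintf("b_vec = %s %s %s", fmt_num(b[1, 2]), fmt_num(b[2, 2]),
                    fmt_num(b[3, 2])),
            sprintf("c_vec = %s %s %s", fmt_num(b[1, 3]), fmt_num(b[2, 3]),
                    fmt_num(b[3, 3])))
    rf <- if (is.null(reflections)) data.frame() else
      as.data.frame(reflections)
    ln <- c(ln, sprintf("num_reflections = %d", nrow(rf)),
            "Reflections measured after indexing",
            "  h  k  l  intensity  sigma  fast  slow  flag")
    if (nrow(rf) > 0)
      ln <- c(ln, sprintf("  %d %d %d %s %s %s %s %s",
                          rf$h, rf$k, rf$l,
                          fmt_num(ifelse(is.na(rf$intensity), NaN,
                                         rf$intensity)),
                          fmt_num(ifelse(is.na(rf$sigma), NaN, rf$sigma)),
                          fmt_num(rf$fast), fmt_num(rf$slow), rf$flag))
    ln <- c(ln, "End of reflections", "--- End crystal")
  }
  ln <- c(ln, "----- End chunk -----")
  if (is.character(sink)) {
    con <- file(sink, open = "a")
    on.exit(close(con))
    writeLines(ln, con)
  } else if (!is.null(sink)) writeLines(ln, sink)
  invisible(ln)
}

#' Parse a stream file back into chunks
#'
#' Inverse of [write_stream_chunk()]: numeric fields round-trip at full
#' precision.
#'
#' @param path File path (or character vector of lines).
#' @return List of chunks; each is a list with `frame_id`, `peaks` (data
#'   frame), `cell` ([unit_cell()] or `NULL`) and `reflections` (data
#'   frame or `NULL`).
#' @export
parse_stream <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else path
  starts <- which(lines == "----- Begin chunk -----")
  ends <- which(lines == "----- End chunk -----")
  stopifnot(length(starts) == length(ends))
  lapply(seq_along(starts), function(ci) {
    ch <- lines[starts[ci]:ends[ci]]
    frame_id <- as.integer(sub("Frame id: ", "",
                               grep("^Frame id:", ch, value = TRUE)[1]))
    npk <- as.integer(sub("num_peaks = ", "",
                          grep("^num_peaks =", ch, value = TRUE)[1]))
    pk_start <- which(ch == "  fast  slow  intensity  snr  n_pixels")[1] + 1
    peaks <- if (npk > 0) {
      rows <- ch[pk_start:(pk_start + npk - 1)]
      m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
      data.frame(fast = m[, 1], slow = m[, 2], intensity = m[, 3],
                 snr = m[, 4], n_pixels = as.integer(m[, 5]))
    } else data.frame(fast = numeric(0), slow = numeric(0),
                      intensity = numeric(0), snr = numeric(0),
                      n_pixels = integer(0))
    cell <- NULL; reflections <- NULL
    if (any(ch == "--- Begin crystal")) {
      vec <- function(key) {
        v <- grep(paste0("^", key, " = "), ch, value = TRUE)[1]
        as.numeric(strsplit(sub(paste0(key, " = "), "", v), " ")[[1]])
      }
      cell <- unit_cell(cbind(vec("a_vec"), vec("b_vec"), vec("c_vec")))
      nrf <- as.integer(sub("num_reflections = ", "",
                            grep("^num_reflections =", ch, value = TRUE)[1]))
      if (!is.na(nrf)) {
        rf_start <- which(ch == "  h  k  l  intensity  sigma  fast  slow  flag")[1] + 1
        reflections <- if (nrf > 0) {
          rows <- strsplit(trimws(ch[rf_start:(rf_start + nrf - 1)]), "\\s+")
          m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[1:7])))
          data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                     l = as.integer(m[, 3]),
                     intensity = ifelse(is.nan(m[, 4]), NA, m[, 4]),
                     sigma = ifelse(is.nan(m[, 5]), NA, m[, 5]),
                     fast = m[, 6], slow = m[, 7],
                     flag = vapply(rows, `[`, character(1), 8),
                     stringsAsFactors = FALSE)
        } else data.frame()
      }
    }
    list(frame_id = frame_id, peaks = peaks, cell = cell,
         reflections = reflections)
  })
}
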