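#' Write frames to batch files with a master index
#'
#' Frames are grouped in batches (1000 per file by default, giving a
#' manageable number of reasonably sized files for long runs) and a master
#' index file exposes the whole run as one logical stack: frame k (0-based)
#' lives in batch file `floor(k / batch_size)` at slot `k mod batch_size`.
#' Round-tripping through [read_batched_frames()] is bit-identical.
#'
#' @param frames List of frame matrices with uniform shape.
#' @param out_dir Output directory (created if needed).
#' @param batch_size Frames per batch file (default 1000).
#' @param prefix File-name prefix (default `"batch"`).
#' @return Path of the master index (JSON) file, invisibly.
#' @export
write_batched_frames <- function(frames, out_dir, batch_size = 1000L,
                                 prefix = "batch") {
  stopifnot(batch_size >= 1)
  n <- length(frames)
  if (n > 0) {
    shp <- dim(frames[[1]])
    for (f in frames)
      if (!identical(dim(f), shp)) stop("frame shape changed mid-run")
  } else shp <- integer(0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_batches <- ceiling(n / batch_size)
  files <- character(0)
  for (b in seq_len(n_batches)) {
    lo <- (b - 1L) * batch_size + 1L
    hi <- min(n, b * batch_size)
    fn <- sprintf("%s-%04d.rds", prefix, b - 1L)
    saveRDS(frames[lo:hi], file.path(out_dir, fn))
    files <- c(files, fn)
  }
  master <- file.path(out_dir, paste0(prefix, "-master.json"))
  jsonlite::write_json(
    list(n_frames = n, batch_size = as.integer(batch_size),
         shape = as.integer(shp), files = files),
    master, auto_unbox = TRUE)
  invisible(master)
}

#' Read all frames behind a master index
#'
#' @param master Path to the master index written by
#'   [write_batched_frames()].
#' @return List of frame matrices in run order.
#' @export
read_batched_frames <- function(master) {
  idx <- jsonlite::read_json(master, simplifyVector = TRUE)
  dirn <- dirname(master)
  out <- list()
  for (fn in idx$files) out <- c(out, readRDS(file.path(dirn, fn)))
  out
}

#' Random access to one frame behind a master index
#'
#' @param master Path to the master index.
#' @param k 0-based frame index.
#' @return The frame matrix.
#' @export
read_batched_frame <- function(master, k) {
  idx <- jsonlite::read_json(master, simplifyVector = TRUE)
  if (k < 0 || k >= idx$n_frames) stop("frame index out of range")
  b <- k %/% idx$batch_size
  slot <- k %% idx$batch_size
  batch <- readRDS(file.path(dirname(master), idx$files[b + 1]))
  batch[[slot + 1]]
}
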