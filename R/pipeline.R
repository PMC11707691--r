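#' Options for the end-to-end processing pipeline
#'
#' @param peak_options A [peak_search_options()].
#' @param asdf An [asdf_options()].
#' @param integration An [integration_options()].
#' @param min_peaks Hit threshold for [classify_hit()] (default 15).
#' @param retry Number of indexing retries (0-5). Each retry deletes the
#'   two weakest remaining peaks and indexes again. Default 0: the
#'   real-time configuration does not retry failed indexing attempts.
#' @param seed Global seed; each frame derives its own RNG seed from
#'   (seed, frame id), so results are independent of processing order and
#'   worker count.
#' @param profile If `TRUE`, collect per-frame profile records.
#' @return A list of class `pipeline_options`.
#' @export
pipeline_options <- function(peak_options = peak_search_options(),
                             asdf = asdf_options(),
                             integration = integration_options(),
                             min_peaks = 15L, retry = 0L, seed = 1L,
                             profile = FALSE) {
  stopifnot(retry >= 0, retry <= 5)
  structure(list(peak_options = peak_options, asdf = asdf,
                 integration = integration, min_peaks = as.integer(min_peaks),
                 retry = as.integer(retry), seed = as.integer(seed),
                 profile = isTRUE(profile)),
            class = "pipeline_options")
}

# Normalise the frame source to list(list(frame_id, image), ...)
pipeline_frames <- function(source) {
  if (inherits(source, "simulated_run")) {
    return(lapply(seq_along(source$frames), function(i)
      list(frame_id = source$manifest$frame_id[i],
           image = source$frames[[i]])))
  }
  if (inherits(source, "run_stream")) {
    register_consumer_group(source, ".pipeline")
    out <- list()
    repeat {
      m <- next_message(source, ".pipeline", timeout = 0)
      if (is_stream_timeout(m)) break
      out[[length(out) + 1]] <- list(frame_id = m$frame_id,
                                     image = m$payload)
    }
    return(out)
  }
  if (is.list(source)) {
    return(lapply(seq_along(source), function(i)
      list(frame_id = i - 1L, image = source[[i]])))
  }
  stop("unsupported frame source")
}

# Process one frame; returns list(chunk_lines, hit, indexed, record)
process_frame <- function(frame_id, image, geometry, mask_static, spec,
                          annulus_map, reference, opts, prof) {
  rec_body <- function() {
    pk_opts <- opts$peak_options
    mask <- time_block(prof, "flag-values",
                       mask_static | (image == spec$sentinel_value))
    peaks <- time_block(prof, "peak-search", {
      st <- time_block(prof, "pf8-rstats",
                       radial_stats(image, annulus_map, pk_opts, mask))
      time_block(prof, "pf8-search",
                 peakfinder8_search(image, annulus_map, st, mask, pk_opts))
    })
    hit <- classify_hit(peaks, opts$min_peaks)
    idx <- NULL; refl <- NULL; indexed <- FALSE
    if (hit) {
      aopt <- opts$asdf
      aopt$rng_seed <- derive_seed(opts$seed, frame_id)
      idx <- time_block(prof, "asdf-search", {
        res <- asdf_index(peaks, geometry, reference, aopt)
        tries <- 0L
        pk <- peaks
        while (!res$success && tries < opts$retry && nrow(pk) > 9) {
          # drop the two weakest remaining peaks and retry
          pk <- pk[order(-pk$intensity), , drop = FALSE]
          pk <- pk[seq_len(nrow(pk) - 2L), , drop = FALSE]
          tries <- tries + 1L
          res <- asdf_index(pk, geometry, reference, aopt)
        }
        res
      })
      if (idx$success && !is.null(reference)) {
        chk <- time_block(prof, "prerefine-cell-check",
                          check_cell(idx$cell, reference))
        if (!chk$matched) {
          idx <- structure(list(success = FALSE, cell = NULL,
                                n_candidates = idx$n_candidates,
                                failure_reason = "cell check failed"),
                           class = "indexing_result")
        }
      }
      if (idx$success) {
        indexed <- TRUE
        refl <- time_block(prof, "integration", {
          pr <- predict_reflections(idx$cell, geometry, opts$integration)
          integrate_reflections(image, pr, mask, opts$integration)
        })
      }
    }
    chunk <- write_stream_chunk(NULL, frame_id, peaks, idx, refl)
    list(chunk = chunk, hit = hit, indexed = indexed,
         n_peaks = nrow(peaks))
  }
  if (is.null(prof)) prof <- profiler()  # discarded when profiling is off
  prof_record(prof, rec_body())
}

#' Run the full still-image processing pipeline
#'
#' Per frame: build the bad-pixel mask (static regions plus sentinel
#' values), run the annular peak search, classify the frame as hit or
#' blank (blanks are finished right after the peak search), autoindex
#' hits, check the cell against the reference, predict and integrate
#' reflections, and emit a stream chunk. One profile record is collected
#' per frame when profiling is on. Frames are distributed over
#' `n_workers` logical workers in consumer-group fashion (round robin) and
#' the output is merged by frame id, so all scientific output is
#' independent of the worker count.
#'
#' @param source Frame source: a [make_run()] result, a list of frame
#'   matrices, or a [run_stream()].
#' @param geometry A [detector_geometry()].
#' @param reference Optional reference [unit_cell()] for indexing and the
#'   cell check.
#' @param mask Optional [mask_spec()].
#' @param options A [pipeline_options()].
#' @param n_workers Number of logical workers (default 1).
#' @param output Optional path for the stream text output.
#' @return List of class `pipeline_result`: `summary` (data frame with
#'   `n_frames`, `n_hits`, `n_indexed`), `frame_info` (per-frame data
#'   frame), `stream` (character lines), `profile` (list of records or
#'   `NULL`).
#' @export
run_pipeline <- function(source, geometry, reference = NULL, mask = NULL,
                         options = pipeline_options(), n_workers = 1L,
                         output = NULL) {
  stopifnot(inherits(geometry, "detector_geometry"), n_workers >= 1)
  if (is.null(mask)) mask <- mask_spec()
  frames <- pipeline_frames(source)
  n <- length(frames)
  # per-run precomputation, shared by all workers of the run: static mask
  # regions and the annulus assignments (frame-content independent)
  mask_static <- static_region_mask(mask, geometry)
  annulus_map <- build_annulus_map(geometry, mask_static)
  prof <- if (options$profile) profiler() else NULL
  worker_of <- (seq_len(n) - 1L) %% n_workers  # consumer-group partition
  results <- vector("list", n)
  for (w in seq_len(n_workers) - 1L) {
    for (i in which(worker_of == w)) {
      fr <- frames[[i]]
      results[[i]] <- process_frame(fr$frame_id, fr$image, geometry,
                                    mask_static, mask, annulus_map,
                                    reference, options, prof)
    }
  }
  ids <- vapply(frames, function(f) as.integer(f$frame_id), integer(1))
  ord <- order(ids)
  stream <- unlist(lapply(results[ord], `[[`, "chunk"))
  if (!is.null(output)) writeLines(stream, output)
  frame_info <- data.frame(
    frame_id = ids[ord],
    n_peaks = vapply(results[ord], `[[`, integer(1), "n_peaks"),
    hit = vapply(results[ord], `[[`, logical(1), "hit"),
    indexed = vapply(results[ord], `[[`, logical(1), "indexed"))
  structure(list(
    summary = data.frame(n_frames = n,
                         n_hits = sum(frame_info$hit),
                         n_indexed = sum(frame_info$indexed)),
    frame_info = frame_info,
    stream = stream,
    profile = if (is.null(prof)) NULL else profile_records(prof)
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_result> %d frames, %d hits, %d indexed\n",
              s$n_frames, s$n_hits, s$n_indexed))
  invisible(x)
}
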