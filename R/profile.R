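#' Hierarchical wall-clock profiler
#'
#' Collects one timing record per processing-loop iteration. Each record is
#' a tree: instrumented segments nested inside other segments become
#' children, and the whole iteration forms the root node (named `"root"`).
#' Wall-clock time is used (not CPU time allocated by the scheduler), so
#' waiting on data sources is included. A record is produced for every
#' iteration regardless of whether the full processing arc completed.
#'
#' @return A profiler object (environment) to pass to [prof_record()] /
#'   [time_block()].
#' @examples
#' p <- profiler()
#' prof_record(p, {
#'   time_block(p, "peak-search", {
#'     time_block(p, "pf8-rstats", Sys.sleep(0.01))
#'   })
#' })
#' profile_records(p)
#' @export
profiler <- function() {
  p <- new.env(parent = emptyenv())
  p$records <- list()
  p$stack <- list()
  class(p) <- "profiler"
  p
}

prof_now <- function() proc.time()[["elapsed"]]

#' Open a profiling segment (low level)
#'
#' Prefer [time_block()]; enter/leave must balance, and mismatched names
#' are an error.
#' @param p A [profiler()].
#' @param name Segment name.
#' @export
prof_enter <- function(p, name) {
  if (length(p$stack) == 0) stop("no open record; use prof_record()")
  p$stack[[length(p$stack) + 1]] <- list(name = name, t0 = prof_now(),
                                         children = list())
  invisible(p)
}

#' Close the current profiling segment (low level)
#' @param p A [profiler()].
#' @param name Segment name; must match the innermost open segment.
#' @export
prof_leave <- function(p, name) {
  k <- length(p$stack)
  if (k < 2) stop("unbalanced profiling leave: no segment open")
  top <- p$stack[[k]]
  if (top$name != name)
    stop(sprintf("unbalanced profiling leave: expected '%s', got '%s'",
                 top$name, name))
  node <- list(name = top$name, duration = prof_now() - top$t0,
               children = top$children)
  p$stack[[k]] <- NULL
  parent <- p$stack[[k - 1]]
  parent$children[[length(parent$children) + 1]] <- node
  p$stack[[k - 1]] <- parent
  invisible(p)
}

#' Time a code block as a named segment
#'
#' Nesting builds the tree; time in a parent not covered by its children
#' remains attributed to the parent's own name (its catch-all).
#'
#' @param p A [profiler()].
#' @param name Segment name.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
time_block <- function(p, name, expr) {
  prof_enter(p, name)
  on.exit(prof_leave(p, name))
  expr
}

#' Run one processing-loop iteration under the profiler
#'
#' Opens a fresh record whose root node is named `"root"`, evaluates
#' `expr`, closes the record and appends it to the profiler's record list
#' (in completion order) even if `expr` exits early via an error or
#' condition.
#'
#' @param p A [profiler()].
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
prof_record <- function(p, expr) {
  if (length(p$stack) != 0) stop("a record is already open")
  p$stack <- list(list(name = "root", t0 = prof_now(), children = list()))
  on.exit({
    top <- p$stack[[1]]
    rec <- list(name = "root", duration = prof_now() - top$t0,
                children = top$children)
    p$stack <- list()
    p$records[[length(p$records) + 1]] <- rec
  })
  expr
}

#' Retrieve collected profile records
#' @param p A [profiler()].
#' @return List of record trees (lists with `name`, `duration`,
#'   `children`), in completion order.
#' @export
profile_records <- function(p) p$records

# Flatten one record into per-category self-times: each node contributes
# (duration - sum of child durations) to its own name, so the category
# times of one record sum exactly to the root duration.
record_self_times <- function(rec) {
  acc <- new.env(parent = emptyenv())
  add <- function(name, dt) {
    cur <- if (is.null(acc[[name]])) 0 else acc[[name]]
    acc[[name]] <- cur + dt
  }
  walk <- function(node) {
    child_sum <- 0
    for (ch in node$children) {
      child_sum <- child_sum + ch$duration
      walk(ch)
    }
    add(node$name, node$duration - child_sum)
  }
  walk(rec)
  unlist(as.list(acc))
}

#' Aggregate profile records for stacked-area reporting
#'
#' Records are taken in completion order and averaged in consecutive
#' batches of `batch_size` (the final partial batch is kept). Category
#' identity is the segment name, flattened across tree positions; each
#' category's value is its self-time (duration minus instrumented
#' children), so no time is counted twice or dropped. Categories are
#' ranked by their total time over the whole input; the `top_n` largest
#' are kept and the remainder summed into `"other"`. Per batch, the
#' category means (including `"other"`) sum to the mean root duration.
#'
#' @param records List of record trees (see [profile_records()]).
#' @param batch_size Records per batch (>= 1).
#' @param top_n Number of named categories to keep (default 10).
#' @return Data frame with columns `batch` (1-based), `category`,
#'   `mean_seconds`, in batch order with categories in global rank order
#'   (then `"other"`).
#' @export
aggregate_profiles <- function(records, batch_size, top_n = 10L) {
  stopifnot(batch_size >= 1)
  if (length(records) == 0)
    return(data.frame(batch = integer(0), category = character(0),
                      mean_seconds = numeric(0)))
  selfs <- lapply(records, record_self_times)
  cats <- unique(unlist(lapply(selfs, names)))
  mat <- matrix(0, length(records), length(cats),
                dimnames = list(NULL, cats))
  for (i in seq_along(selfs)) mat[i, names(selfs[[i]])] <- selfs[[i]]
  totals <- colSums(mat)
  ranked <- names(sort(totals, decreasing = TRUE))
  top <- ranked[seq_len(min(top_n, length(ranked)))]
  rest <- setdiff(ranked, top)
  batch_id <- (seq_along(records) - 1L) %/% as.integer(batch_size) + 1L
  out <- list()
  for (b in unique(batch_id)) {
    rows <- batch_id == b
    means <- colMeans(mat[rows, , drop = FALSE])
    df <- data.frame(batch = b, category = top,
                     mean_seconds = as.numeric(means[top]))
    if (length(rest) > 0)
      df <- rbind(df, data.frame(batch = b, category = "other",
                                 mean_seconds = sum(means[rest])))
    out[[length(out) + 1]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an aggregated profile table as TSV
#'
#' @param table Output of [aggregate_profiles()].
#' @param path File path.
#' @export
write_profile_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
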