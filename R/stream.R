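#' In-memory acquisition run stream with consumer groups
#'
#' A single-process analogue of a streaming data service: one stream holds
#' the ordered messages of one acquisition run; each registered consumer
#' group has its own delivery cursor, so within one group every message is
#' delivered to exactly one consumer, while distinct groups each observe
#' the complete stream in order. A bounded cache size models the volatile
#' memory window of the real service: when the cache overflows, the oldest
#' unconsumed-by-all messages are evicted (pushing then fails for a group
#' that has fallen too far behind).
#'
#' @param name Stream (run) name.
#' @param cache_size Maximum number of messages held (default `Inf`).
#' @return A `run_stream` object (environment).
#' @export
run_stream <- function(name, cache_size = Inf) {
  s <- new.env(parent = emptyenv())
  s$name <- name
  s$cache_size <- cache_size
  s$messages <- list()       # each: list(frame_id, payload, meta)
  s$first_id <- 1L           # index (1-based position) of messages[[1]] in the run
  s$groups <- new.env(parent = emptyenv())  # group name -> next position
  class(s) <- "run_stream"
  s
}

#' Push a message into a run stream
#'
#' @param stream A [run_stream()].
#' @param frame_id Integer frame id (0-based; the ordering key).
#' @param payload The frame data (any R object, typically a matrix).
#' @param meta Optional metadata list.
#' @export
stream_push <- function(stream, frame_id, payload, meta = list()) {
  stopifnot(inherits(stream, "run_stream"))
  stream$messages[[length(stream$messages) + 1]] <-
    list(frame_id = frame_id, payload = payload, meta = meta)
  while (length(stream$messages) > stream$cache_size) {
    stream$messages[[1]] <- NULL
    stream$first_id <- stream$first_id + 1L
  }
  invisible(stream)
}

#' Register a consumer group on a stream
#'
#' @param stream A [run_stream()].
#' @param group Group name.
#' @export
register_consumer_group <- function(stream, group) {
  stopifnot(inherits(stream, "run_stream"))
  if (is.null(stream$groups[[group]])) stream$groups[[group]] <- 1L
  invisible(stream)
}

#' Fetch the next message for a consumer group
#'
#' Delivery is at-most-once within a group: the group's cursor advances on
#' every delivery, so two consumers of one group calling alternately
#' partition the stream between them. When no message is available the
#' call returns a distinguishable timeout signal (not an error) after
#' `timeout` seconds.
#'
#' @param stream A [run_stream()].
#' @param group Registered group name.
#' @param timeout Seconds to wait when the stream is empty (default 3, the
#'   conventional online-processing setting).
#' @return The message (`list(frame_id, payload, meta)`), or an object of
#'   class `stream_timeout`.
#' @export
next_message <- function(stream, group, timeout = 3) {
  if (!inherits(stream, "run_stream")) stop("unknown stream")
  pos <- stream$groups[[group]]
  if (is.null(pos)) stop("unregistered consumer group: ", group)
  deadline <- prof_now() + timeout
  repeat {
    avail <- stream$first_id + length(stream$messages) - 1L
    if (pos <= avail) {
      if (pos < stream$first_id)
        stop("consumer group fell behind the stream cache")
      msg <- stream$messages[[pos - stream$first_id + 1L]]
      stream$groups[[group]] <- pos + 1L
      return(msg)
    }
    if (prof_now() >= deadline)
      return(structure(list(group = group, timeout = timeout),
                       class = "stream_timeout"))
    Sys.sleep(min(0.01, max(0, deadline - prof_now())))
  }
}

#' Test for the timeout signal returned by [next_message()]
#' @param x Object to test.
#' @export
is_stream_timeout <- function(x) inherits(x, "stream_timeout")
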