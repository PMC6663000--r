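#' Event tables
#'
#' An `event_table` is the universal currency of the pipeline: a numeric
#' matrix of cytometric events (rows) by named channels (columns), plus a
#' metadata list describing the sample it came from.
#'
#' @param events numeric matrix, `n_events x n_channels`. Values are raw
#'   detector arbitrary units unless a transform has been applied.
#' @param channel_names character vector of unique channel names, e.g.
#'   `c("FSC-A","FSC-H","FSC-W","SSC-A","SSC-H","SSC-W","FL1-A")`. Defaults
#'   to the column names of `events`.
#' @param metadata named list; recognised entries are `sample_id`, `strain`,
#'   `time_h` (hours) and `replicate`. Missing entries are left `NULL`.
#'
#' @return an object of class `event_table` with elements `events`
#'   (matrix with column names) and `metadata` (list).
#' @export
#' @examples
#' tb <- event_table(matrix(rnorm(20), 10, 2), c("SSC-A", "FL1-A"),
#'                   metadata = list(sample_id = "s1"))
#' n_events(tb)
#' channels(tb)
event_table <- function(events, channel_names = colnames(events),
                        metadata = list()) {
  if (!is.matrix(events)) events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (is.null(channel_names)) {
    stop("channel names are required (either `channel_names` or column names)")
  }
  channel_names <- as.character(channel_names)
  if (ncol(events) != length(channel_names)) {
    stop("length of `channel_names` must equal ncol(events)")
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique")
  }
  if (nrow(events) > 0 && anyNA(events)) {
    stop("event matrix must not contain missing values")
  }
  colnames(events) <- channel_names
  if (!is.list(metadata)) stop("`metadata` must be a list")
  structure(list(events = events, metadata = metadata), class = "event_table")
}

#' @rdname event_table
#' @param x an `event_table`.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "event_table"))
  nrow(x$events)
}

#' @rdname event_table
#' @export
channels <- function(x) {
  stopifnot(inherits(x, "event_table"))
  colnames(x$events)
}

#' Extract channel values by name
#'
#' Lookup is by name, never by column position, so channel order in the
#' file does not matter downstream.
#'
#' @param x an `event_table`.
#' @param which character vector of channel names.
#' @return numeric matrix (or vector when a single channel is requested
#'   and `drop = TRUE`).
#' @param drop drop to a vector for a single channel (default `TRUE`).
#' @export
channel_values <- function(x, which, drop = TRUE) {
  stopifnot(inherits(x, "event_table"))
  missing_ch <- setdiff(which, channels(x))
  if (length(missing_ch)) {
    stop("unknown channel(s): ", paste(missing_ch, collapse = ", "))
  }
  x$events[, which, drop = drop && length(which) == 1L]
}

#' Subset events by row index or logical mask
#'
#' @param x an `event_table`.
#' @param i integer indices or logical vector of length `n_events(x)`.
#' @return an `event_table` with the selected events and unchanged metadata.
#' @export
subset_events <- function(x, i) {
  stopifnot(inherits(x, "event_table"))
  if (is.logical(i) && length(i) != n_events(x)) {
    stop("logical mask must have length n_events")
  }
  event_table(x$events[i, , drop = FALSE], channels(x), x$metadata)
}

#' @export
print.event_table <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<event_table> %d events x %d channels\n",
              n_events(x), length(channels(x))))
  cat("  channels: ", paste(channels(x), collapse = ", "), "\n", sep = "")
  if (length(md)) {
    shown <- md[intersect(c("sample_id", "strain", "time_h", "replicate"),
                          names(md))]
    if (length(shown)) {
      cat("  metadata: ",
          paste(sprintf("%s=%s", names(shown), unlist(shown)), collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$events)
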