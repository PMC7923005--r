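#' Per-event cytometry table
#'
#' The universal currency of the pipeline: one row per recorded event, one
#' column per detector channel plus a `time` column (seconds since acquisition
#' start), with acquisition metadata attached as an attribute.
#'
#' @param channels Data frame or matrix of non-negative channel intensities
#'   with unique column names.
#' @param time Numeric vector of per-event timestamps in seconds, same length
#'   as the channel columns.
#' @param meta List of acquisition metadata. Recognised fields: `flow_rate`
#'   (uL/min, > 0), `duration` (s, > 0), `dilution_factor` (>= 1, default 1),
#'   `sample_meta` (free-form list: panel, arm, treatment, replicate, ...),
#'   `counts` (per-population generated/triggered counts, kept as a simulation
#'   ground-truth oracle), plus free-form instrument settings.
#' @param population Optional character vector labelling the source population
#'   of each event (simulation ground truth).
#' @param sort_by_time Sort events by timestamp (default `TRUE`).
#' @return An object of class `event_table` (a data frame of channels +
#'   `time`, with `meta` and optional `population` attributes).
#' @export
event_table <- function(channels, time, meta = list(), population = NULL,
                        sort_by_time = TRUE) {
  channels <- as.data.frame(channels, optional = TRUE)
  if (anyDuplicated(names(channels))) {
    stop("channel names must be unique", call. = FALSE)
  }
  if ("time" %in% names(channels)) {
    stop("'time' is reserved; pass timestamps via the time argument",
         call. = FALSE)
  }
  n <- nrow(channels)
  if (length(time) != n) {
    stop("time must have one entry per event", call. = FALSE)
  }
  if (!is.null(population) && length(population) != n) {
    stop("population labels must have one entry per event", call. = FALSE)
  }
  if (!is.null(meta$flow_rate) && meta$flow_rate <= 0) {
    stop("meta$flow_rate must be > 0", call. = FALSE)
  }
  if (!is.null(meta$duration) && meta$duration <= 0) {
    stop("meta$duration must be > 0", call. = FALSE)
  }
  if (is.null(meta$dilution_factor)) meta$dilution_factor <- 1
  if (meta$dilution_factor < 1) {
    stop("meta$dilution_factor must be >= 1", call. = FALSE)
  }
  df <- cbind(channels, time = as.numeric(time))
  if (sort_by_time && n > 1L) {
    ord <- order(df$time)
    df <- df[ord, , drop = FALSE]
    if (!is.null(population)) population <- population[ord]
    rownames(df) <- NULL
  }
  structure(df,
            meta = meta,
            population = population,
            class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<event_table> %d events x %d channels (%s)\n",
              nrow(x), length(channel_names(x)),
              paste(channel_names(x), collapse = ", ")))
  if (!is.null(m$duration)) {
    cat(sprintf("  acquisition: %g s at %g uL/min\n",
                m$duration, m$flow_rate))
  }
  pop <- attr(x, "population")
  if (!is.null(pop)) {
    tb <- table(pop)
    cat("  populations:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Channel names of an event table
#' @param events An [event_table()].
#' @return Character vector (excludes `time`).
#' @export
channel_names <- function(events) {
  setdiff(names(events), "time")
}

#' Acquisition metadata of an event table
#' @param events An [event_table()].
#' @return The metadata list.
#' @export
acq_meta <- function(events) {
  attr(events, "meta")
}

#' Per-event population labels (simulation ground truth)
#' @param events An [event_table()].
#' @return Character vector or `NULL` for real (non-synthetic) data.
#' @export
event_populations <- function(events) {
  attr(events, "population")
}

# Subset an event table by a logical/integer row index, preserving metadata
# and population labels.
subset_events <- function(events, idx) {
  df <- as.data.frame(events)[idx, , drop = FALSE]
  rownames(df) <- NULL
  pop <- attr(events, "population")
  structure(df,
            meta = attr(events, "meta"),
            population = if (!is.null(pop)) pop[idx],
            class = c("event_table", "data.frame"))
}

# Row-bind event tables; metadata taken from the first, population labels
# concatenated (missing labels become NA).
bind_events <- function(tables, sort_by_time = TRUE) {
  tables <- tables[vapply(tables, nrow, 1L) >= 0]
  df <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(df) <- NULL
  pops <- lapply(tables, function(t) {
    p <- attr(t, "population")
    if (is.null(p)) rep(NA_character_, nrow(t)) else p
  })
  pop <- unlist(pops, use.names = FALSE)
  if (all(is.na(pop))) pop <- NULL
  meta <- attr(tables[[1L]], "meta")
  event_table(df[setdiff(names(df), "time")], df$time, meta = meta,
              population = pop, sort_by_time = sort_by_time)
}
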