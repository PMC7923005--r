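#' Apply fluorescence spillover compensation
#'
#' Replaces the fluorescence columns by `observed %*% solve(S)` (row-vector
#' convention: S\[i, j\] is the fraction of fluorophore i's signal detected in
#' channel j). Scatter channels and timestamps are untouched. Negative
#' compensated values are retained, not clipped: the percentile positivity
#' gates must see the full compensated distribution, and clipping would bias
#' the 99th-percentile thresholds upward.
#'
#' @param events An [event_table()].
#' @param spill A [spillover_matrix()] whose channels are all present in
#'   `events`.
#' @return The compensated [event_table()].
#' @examples
#' s <- spillover_matrix(matrix(c(1, 0, 0.5, 1), 2,
#'   dimnames = list(c("FITC", "PE"), c("FITC", "PE"))))
#' ev <- event_table(data.frame(FITC = 100, PE = 100), time = 0)
#' compensate(ev, s) # recovers FITC 100, PE 50
#' @export
compensate <- function(events, spill) {
  stopifnot(inherits(events, "event_table"))
  if (!inherits(spill, "spillover_matrix")) spill <- spillover_matrix(spill)
  ch <- rownames(spill)
  missing <- setdiff(ch, channel_names(events))
  if (length(missing)) {
    stop("spillover channels missing from events: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  inv <- tryCatch(solve(unclass(spill)),
                  error = function(e) stop("spillover matrix is singular",
                                           call. = FALSE))
  out <- events
  mat <- as.matrix(as.data.frame(events)[ch])
  comp <- mat %*% inv
  for (j in seq_along(ch)) out[[ch[j]]] <- comp[, j]
  attr(out, "compensated") <- TRUE
  out
}
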