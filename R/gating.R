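# Three-stage gating: time-stability QC, bead-calibrated EV-size gate,
# control-derived fluorescence positivity gates. All percentiles use linear
# interpolation between order statistics (quantile type 7), pinned by a
# brute-force oracle in the tests.

ev_quantile <- function(x, p) {
  unname(stats::quantile(x, p, type = 7, names = FALSE))
}

#' Fit the time-stability QC gate
#'
#' Bins event timestamps into `bin_width`-second bins over the acquisition and
#' excludes bins whose event count deviates from the median bin count by more
#' than `k` times the MAD (scaled to a sigma equivalent, floored at one
#' count). This is a reproducible stand-in for the manual removal of time
#' points with erratic event rates; it is deterministic given the events.
#'
#' @param events An [event_table()] whose metadata includes `duration`.
#' @param bin_width Bin width in seconds (duration must be >= 10 bins).
#' @param k Robust threshold multiplier (default 5).
#' @return A `time_gate`: list with `bin_width`, `breaks`, `excluded_bins`
#'   (matrix of \[start, end) times), `retained_time`, and the per-bin counts.
#' @export
fit_time_gate <- function(events, bin_width = 1, k = 5) {
  stopifnot(inherits(events, "event_table"))
  duration <- acq_meta(events)$duration
  if (is.null(duration)) stop("events lack acquisition duration", call. = FALSE)
  if (duration < 10 * bin_width) {
    stop("duration must cover at least 10 bins", call. = FALSE)
  }
  breaks <- seq(0, duration, by = bin_width)
  if (breaks[length(breaks)] < duration) breaks <- c(breaks, duration)
  counts <- as.integer(table(cut(events$time, breaks = breaks,
                                 include.lowest = TRUE, right = FALSE)))
  med <- stats::median(counts)
  mad_sigma <- max(stats::mad(counts), 1)
  bad <- abs(counts - med) > k * mad_sigma
  if (all(bad)) stop("no stable acquisition window", call. = FALSE)
  excluded <- cbind(start = breaks[-length(breaks)][bad],
                    end = breaks[-1][bad])
  retained <- duration - sum(excluded[, "end"] - excluded[, "start"])
  structure(list(bin_width = bin_width, k = k, breaks = breaks,
                 counts = counts, excluded_bins = excluded,
                 retained_time = retained),
            class = "time_gate")
}

#' @export
print.time_gate <- function(x, ...) {
  cat(sprintf("<time_gate> %d/%d bins excluded, retained %g s\n",
              nrow(x$excluded_bins), length(x$counts), x$retained_time))
  invisible(x)
}

# Logical mask of events passing a time gate.
time_gate_mask <- function(events, gate) {
  keep <- rep(TRUE, nrow(events))
  for (i in seq_len(nrow(gate$excluded_bins))) {
    keep <- keep & !(events$time >= gate$excluded_bins[i, "start"] &
                       events$time < gate$excluded_bins[i, "end"])
  }
  keep
}

#' Fit the bead-calibrated EV-size gate
#'
#' Selects the calibration-bead cluster and sets the gate thresholds at the
#' first percentile of the bead SALS and LALS distributions; an event is
#' inside the EV-size gate when SALS < sals_max AND LALS < lals_max (strict
#' inequalities, so sub-bead events are retained).
#'
#' The bead cluster is selected deterministically: events with SALS above
#' `sals_floor` (by default the 99.5th percentile of a noise-calibration
#' sample's SALS), then trimmed to within a factor 5 of the selection's median
#' SALS to shed stray noise events.
#'
#' @param bead_events [event_table()] from a bead reference acquisition.
#' @param sals_floor Scatter floor above which the bead cluster lies; computed
#'   from `noise_events` when `NULL`.
#' @param noise_events Optional noise-calibration acquisition used to derive
#'   `sals_floor`.
#' @return A `size_gate`: list with `sals_max`, `lals_max`, `n_beads`,
#'   `sals_floor`.
#' @export
fit_size_gate <- function(bead_events, sals_floor = NULL,
                          noise_events = NULL) {
  stopifnot(inherits(bead_events, "event_table"))
  if (is.null(sals_floor)) {
    if (is.null(noise_events)) {
      stop("size-gate calibration needs a bead reference: supply sals_floor ",
           "or a noise-calibration sample", call. = FALSE)
    }
    sals_floor <- ev_quantile(noise_events$SALS, 0.995)
  }
  sel <- bead_events$SALS > sals_floor
  if (sum(sel) > 0) {
    m <- stats::median(bead_events$SALS[sel])
    trimmed <- sel & bead_events$SALS > m / 5 & bead_events$SALS < m * 5
    # keep the trim only when it leaves a usable cluster; a broad but small
    # selection falls back to everything above the floor
    if (sum(trimmed) >= 100) sel <- trimmed
  }
  if (sum(sel) < 100) {
    stop("size-gate calibration failed: fewer than 100 bead events above ",
         "the scatter floor", call. = FALSE)
  }
  structure(list(sals_max = ev_quantile(bead_events$SALS[sel], 0.01),
                 lals_max = ev_quantile(bead_events$LALS[sel], 0.01),
                 n_beads = sum(sel), sals_floor = sals_floor),
            class = "size_gate")
}

#' @export
print.size_gate <- function(x, ...) {
  cat(sprintf("<size_gate> SALS < %.4g, LALS < %.4g (from %d bead events)\n",
              x$sals_max, x$lals_max, x$n_beads))
  invisible(x)
}

size_gate_mask <- function(events, gate) {
  events$SALS < gate$sals_max & events$LALS < gate$lals_max
}

#' Fit a fluorescence positivity gate from a control sample
#'
#' Threshold = 99th percentile (linear interpolation) of the control's
#' compensated channel values among events inside the EV-size gate; an event
#' is positive when its value is strictly above the threshold. By
#' construction about 1% of the control's own size-gated events are positive.
#'
#' @param control_events Compensated [event_table()] of the control (triton
#'   lysis control for the lactadherin-FITC gate, isotype control for the
#'   other channels).
#' @param channel Fluorescence channel name.
#' @param size_gate A [fit_size_gate()] result applied before the percentile
#'   is taken.
#' @param time_gate Optional [fit_time_gate()] result applied first.
#' @param percentile Positivity percentile (default 0.99).
#' @param control_kind `"triton"` or `"isotype"` (provenance only).
#' @return A `fluor_gate`: list with `channel`, `threshold`, `control_kind`,
#'   `n_control`.
#' @export
fit_fluor_gate <- function(control_events, channel, size_gate,
                           time_gate = NULL, percentile = 0.99,
                           control_kind = c("isotype", "triton")) {
  stopifnot(inherits(control_events, "event_table"))
  control_kind <- match.arg(control_kind)
  if (!channel %in% channel_names(control_events)) {
    stop("control lacks channel ", channel, call. = FALSE)
  }
  keep <- if (is.null(time_gate)) rep(TRUE, nrow(control_events)) else
    time_gate_mask(control_events, time_gate)
  keep <- keep & size_gate_mask(control_events, size_gate)
  vals <- control_events[[channel]][keep]
  if (length(vals) < 100) {
    stop("fewer than 100 control events inside the size gate; the ",
         percentile * 100, "th percentile is unstable", call. = FALSE)
  }
  structure(list(channel = channel,
                 threshold = ev_quantile(vals, percentile),
                 percentile = percentile, control_kind = control_kind,
                 n_control = length(vals)),
            class = "fluor_gate")
}

#' @export
print.fluor_gate <- function(x, ...) {
  cat(sprintf("<fluor_gate> %s > %.4g (%sth pct of %s control, n=%d)\n",
              x$channel, x$threshold, format(x$percentile * 100),
              x$control_kind, x$n_control))
  invisible(x)
}

#' Assemble a gate set
#'
#' @param time_gate A `time_gate` (or `NULL` to skip time QC).
#' @param size_gate A `size_gate`.
#' @param fluor_gates Named list of `fluor_gate`s keyed by channel.
#' @param provenance Optional free-form provenance list (source samples,
#'   session id).
#' @return A `gate_set`.
#' @export
gate_set <- function(time_gate, size_gate, fluor_gates, provenance = list()) {
  stopifnot(inherits(size_gate, "size_gate"))
  if (!length(fluor_gates) || is.null(names(fluor_gates))) {
    stop("fluor_gates must be a named list of fluorescence gates",
         call. = FALSE)
  }
  structure(list(time_gate = time_gate, size_gate = size_gate,
                 fluor_gates = fluor_gates, provenance = provenance),
            class = "gate_set")
}

#' @export
print.gate_set <- function(x, ...) {
  cat("<gate_set>\n")
  if (!is.null(x$time_gate)) print(x$time_gate)
  print(x$size_gate)
  for (g in x$fluor_gates) print(g)
  invisible(x)
}

#' Apply a gate set to a sample
#'
#' Fixed pipeline order: time gate, then EV-size gate, then per-channel
#' fluorescence positivity. The sample's own time gate is fitted here (time
#' QC is per acquisition) unless `refit_time_gate = FALSE`, in which case the
#' gate set's time gate is reused.
#'
#' @param events Compensated [event_table()].
#' @param gates A [gate_set()].
#' @param channels Channels to report; defaults to all gated channels. A
#'   requested channel without a fluorescence gate is an error.
#' @param refit_time_gate Fit the time gate on `events` (default `TRUE`).
#' @return List with `channel_counts` (named integer vector of events passing
#'   all three gates), `size_gated_count`, `retained_time`, and the time gate
#'   used.
#' @export
apply_gates <- function(events, gates, channels = NULL,
                        refit_time_gate = TRUE) {
  stopifnot(inherits(events, "event_table"), inherits(gates, "gate_set"))
  if (is.null(channels)) channels <- names(gates$fluor_gates)
  missing <- setdiff(channels, names(gates$fluor_gates))
  if (length(missing)) {
    stop("no fluorescence gate for channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tg <- if (refit_time_gate) {
    fit_time_gate(events,
                  bin_width = if (is.null(gates$time_gate)) 1 else
                    gates$time_gate$bin_width,
                  k = if (is.null(gates$time_gate)) 5 else gates$time_gate$k)
  } else {
    gates$time_gate
  }
  keep <- if (is.null(tg)) rep(TRUE, nrow(events)) else
    time_gate_mask(events, tg)
  keep <- keep & size_gate_mask(events, gates$size_gate)
  counts <- vapply(channels, function(ch) {
    sum(keep & events[[ch]] > gates$fluor_gates[[ch]]$threshold)
  }, integer(1))
  retained <- if (is.null(tg)) acq_meta(events)$duration else tg$retained_time
  list(channel_counts = counts, size_gated_count = sum(keep),
       retained_time = retained, time_gate = tg)
}

#' Serialize a gate set to JSON
#' @param gates A [gate_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gates_json <- function(gates, path) {
  x <- list(
    time_gate = if (!is.null(gates$time_gate)) {
      list(bin_width = gates$time_gate$bin_width, k = gates$time_gate$k,
           excluded_bins = gates$time_gate$excluded_bins,
           retained_time = gates$time_gate$retained_time)
    },
    size_gate = gates$size_gate[c("sals_max", "lals_max", "n_beads",
                                  "sals_floor")],
    fluor_gates = lapply(gates$fluor_gates, function(g) {
      g[c("channel", "threshold", "percentile", "control_kind", "n_control")]
    }),
    provenance = gates$provenance
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
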