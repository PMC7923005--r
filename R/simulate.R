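# Synthetic acquisition generator.
#
# Event mechanics: per population the number of candidate particles in the
# acquired volume is Poisson(concentration x flow_rate x duration / 60);
# intensities are log-normal with a shared latent size factor; fluorescence is
# mixed through the spillover matrix; only events whose trigger-channel
# intensity exceeds the threshold are recorded; timestamps are a homogeneous
# Poisson process approximated by uniform draws on [0, duration].

# Deterministic per-sample substream: a small integer hash of (seed, index)
# so any subset of an experiment can be regenerated in isolation.
derive_seed <- function(seed, index) {
  (as.double(seed) %% 2147483647 + 104729 * as.double(index)) %% 2147483646 + 1
}

# Draw n events from one population over the given channels. Channels the
# spec does not mention get a dim floor (log-normal meanlog log(1), sdlog 0.5)
# so every event table is complete over the instrument layout.
draw_population <- function(pop, n, channels) {
  scatter_ch <- intersect(channels, ev_channels("scatter"))
  rho <- pop$scatter_fluor_corr
  load <- sqrt(abs(rho))
  z <- stats::rnorm(n)
  out <- matrix(0, nrow = n, ncol = length(channels),
                dimnames = list(NULL, channels))
  for (ch in channels) {
    p <- pop$scatter[[ch]]
    if (is.null(p)) p <- pop$fluor[[ch]]
    if (is.null(p)) p <- c(0, 0.5)
    l <- if (ch %in% scatter_ch) load else sign(rho) * load
    eps <- stats::rnorm(n)
    out[, ch] <- exp(p[1L] + p[2L] * (l * z + sqrt(1 - load^2) * eps))
  }
  out
}

apply_spillover <- function(mat, spill) {
  ch <- rownames(spill)
  missing <- setdiff(ch, colnames(mat))
  if (length(missing)) {
    stop("spillover channels not present in events: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mat[, ch] <- mat[, ch, drop = FALSE] %*% unclass(spill)
  mat
}

#' Simulate one synthetic acquisition
#'
#' Draws, for each population, Poisson(concentration x flow_rate x duration /
#' 60) candidate events with log-normal channel intensities, mixes
#' fluorescence through the configured spillover matrix, keeps events whose
#' trigger-channel intensity exceeds the trigger threshold, and assigns
#' uniform timestamps on \[0, duration\]. Events are returned in time order.
#'
#' Ground truth for test oracles is stored in the result: per-population
#' generated and triggered counts in `acq_meta(x)$counts`, per-event
#' population labels, and the pre-spillover fluorescence in
#' `attr(x, "fluor_true")`.
#'
#' @param populations List of [population_spec()] (at least one).
#' @param config An [acquisition_config()] with a non-`NULL` seed.
#' @param channels Channel layout of the output table.
#' @return An [event_table()].
#' @examples
#' cfg <- acquisition_config(trigger_threshold = 0, seed = 1)
#' pop <- population_spec("agg", 1000,
#'   scatter = list(SALS = c(log(600), 1), MALS = c(log(400), 1),
#'                  LALS = c(log(180), 1)),
#'   fluor = list(FITC = c(log(3000), 1)), scatter_fluor_corr = 0.6)
#' ev <- simulate_sample(list(pop), cfg)
#' @export
simulate_sample <- function(populations, config,
                            channels = ev_channels()) {
  if (inherits(populations, "population_spec")) {
    populations <- list(populations)
  }
  if (!length(populations)) {
    stop("at least one population is required", call. = FALSE)
  }
  stopifnot(inherits(config, "acquisition_config"))
  if (is.null(config$seed)) {
    stop("config$seed must be set for simulation", call. = FALSE)
  }
  set.seed(as.integer(config$seed))
  simulate_sample_impl(populations, config, channels)
}

# Core generator; assumes the RNG state is already positioned.
simulate_sample_impl <- function(populations, config,
                                 channels = ev_channels()) {
  volume <- config$flow_rate * config$duration / 60
  fluor_ch <- rownames(config$spillover)
  tabs <- list()
  counts <- data.frame(population = character(), n_generated = integer(),
                       n_removed = integer(), n_triggered = integer(),
                       stringsAsFactors = FALSE)
  for (pop in populations) {
    n_gen <- stats::rpois(1L, pop$concentration * volume)
    mat <- draw_population(pop, n_gen, channels)
    n_rem <- 0L
    removal <- attr(pop, "removal")
    if (!is.null(removal) && removal$fraction > 0 && n_gen > 0L) {
      keep <- removal_survivors(mat[, "SALS"], removal$fraction,
                                removal$size_selectivity)
      n_rem <- n_gen - length(keep)
      mat <- mat[keep, , drop = FALSE]
    }
    true_fluor <- mat[, fluor_ch, drop = FALSE]
    mat <- apply_spillover(mat, config$spillover)
    trig <- mat[, config$trigger_channel] > config$trigger_threshold
    mat <- mat[trig, , drop = FALSE]
    true_fluor <- true_fluor[trig, , drop = FALSE]
    counts <- rbind(counts, data.frame(
      population = pop$name, n_generated = n_gen, n_removed = n_rem,
      n_triggered = nrow(mat), stringsAsFactors = FALSE))
    tabs[[length(tabs) + 1L]] <- list(mat = mat, true = true_fluor,
                                      name = pop$name)
  }
  mat <- do.call(rbind, lapply(tabs, `[[`, "mat"))
  true_fluor <- do.call(rbind, lapply(tabs, `[[`, "true"))
  pop_lab <- unlist(lapply(tabs, function(t) rep(t$name, nrow(t$mat))),
                    use.names = FALSE)
  n <- nrow(mat)
  time <- stats::runif(n, 0, config$duration)
  ord <- order(time)
  meta <- list(flow_rate = config$flow_rate, duration = config$duration,
               trigger_channel = config$trigger_channel,
               trigger_threshold = config$trigger_threshold,
               counts = counts)
  ev <- event_table(as.data.frame(mat[ord, , drop = FALSE]), time[ord],
                    meta = meta, population = pop_lab[ord],
                    sort_by_time = FALSE)
  attr(ev, "fluor_true") <- true_fluor[ord, , drop = FALSE]
  ev
}

# Indices of aggregate events surviving a removal of `fraction` with the
# given size selectivity: a share `selectivity` of the removals is taken from
# the top of the scatter (SALS) ranking, the rest uniformly at random.
removal_survivors <- function(sals, fraction, selectivity) {
  n <- length(sals)
  n_remove <- round(fraction * n)
  if (n_remove <= 0L) return(seq_len(n))
  if (n_remove >= n) return(integer())
  n_top <- round(selectivity * n_remove)
  ord <- order(sals, decreasing = TRUE)
  removed <- ord[seq_len(n_top)]
  rest <- setdiff(seq_len(n), removed)
  if (n_remove > n_top) {
    removed <- c(removed, sample(rest, n_remove - n_top))
  }
  setdiff(seq_len(n), removed)
}

#' Simulate an unstained-buffer background acquisition
#'
#' Generates the instrument/buffer noise a pure-buffer (unstained PBS)
#' acquisition would record. With the shipped defaults the noise population
#' sits mostly below the trigger threshold, and the triggered event rate is
#' well under 100 events per second — the calibration contract for setting a
#' trigger "above background".
#'
#' @param config An [acquisition_config()] with a seed.
#' @param noise_spec A [population_spec()] describing the buffer noise.
#' @return An [event_table()].
#' @export
simulate_background <- function(config,
                                noise_spec = default_noise_population()) {
  simulate_sample(list(noise_spec), config)
}

#' Default calibration-bead reference populations
#'
#' A tight, very high-scatter bead population (the 1300 nm silica-bead
#' surrogate used to anchor the EV-size gate) over an EV-scale noise floor.
#' Median bead SALS and LALS are two orders of magnitude above the noise
#' floor, so the bead cluster is unambiguous.
#'
#' @param bead_concentration,noise_concentration Particles per uL.
#' @return List of two [population_spec()]s named `bead` and `noise_floor`.
#' @export
default_bead_populations <- function(bead_concentration = 1000,
                                     noise_concentration = 2000) {
  list(
    bead = population_spec(
      "bead", bead_concentration,
      scatter = list(SALS = c(log(30000), 0.08),
                     MALS = c(log(20000), 0.08),
                     LALS = c(log(8000), 0.08)),
      fluor = lapply(stats::setNames(nm = ev_channels("fluor")),
                     function(ch) c(log(50), 0.3)),
      scatter_fluor_corr = 0
    ),
    noise_floor = population_spec(
      "noise_floor", noise_concentration,
      scatter = list(SALS = c(log(150), 0.7),
                     MALS = c(log(300), 0.8),
                     LALS = c(log(50), 0.7)),
      fluor = lapply(stats::setNames(nm = ev_channels("fluor")),
                     function(ch) c(log(5), 0.8)),
      scatter_fluor_corr = 0
    )
  )
}

#' Simulate a calibration-bead reference acquisition
#'
#' @param config An [acquisition_config()] with a seed.
#' @param populations Bead + noise-floor populations, see
#'   [default_bead_populations()].
#' @return An [event_table()] whose `population` labels mark bead events.
#' @export
simulate_bead_reference <- function(config,
                                    populations = default_bead_populations()) {
  simulate_sample(populations, config)
}

#' Inject erratic-rate segments into an acquisition
#'
#' Multiplies the event rate inside given time segments by adding events drawn
#' from a wide nuisance population, emulating the unstable-flow episodes the
#' time-stability QC gate must detect and remove. Segment bounds are recorded
#' in `attr(x, "erratic_segments")` as the test oracle.
#'
#' @param events An [event_table()].
#' @param segments List of numeric vectors `c(start, end, multiplier)` in
#'   seconds; segments must lie within the acquisition, not overlap, and have
#'   multiplier >= 1 (1 = no change).
#' @param nuisance Optional [population_spec()] for the extra events; the
#'   default is a broad mid-scatter population.
#' @return An [event_table()] with the extra events merged in time order.
#' @export
inject_erratic_segments <- function(events, segments, nuisance = NULL) {
  stopifnot(inherits(events, "event_table"))
  if (!length(segments)) return(events)
  seg <- do.call(rbind, lapply(segments, function(s) {
    if (length(s) != 3L || !is.numeric(s)) {
      stop("each segment must be c(start, end, multiplier)", call. = FALSE)
    }
    s
  }))
  colnames(seg) <- c("start", "end", "multiplier")
  dur <- acq_meta(events)$duration
  if (any(seg[, "start"] < 0) || any(seg[, "end"] > dur) ||
      any(seg[, "start"] >= seg[, "end"])) {
    stop("segments must satisfy 0 <= start < end <= duration", call. = FALSE)
  }
  if (any(seg[, "multiplier"] < 1)) {
    stop("rate multiplier must be >= 1", call. = FALSE)
  }
  o <- order(seg[, "start"])
  seg <- seg[o, , drop = FALSE]
  if (nrow(seg) > 1L &&
      any(seg[-1L, "start"] < seg[-nrow(seg), "end"])) {
    stop("segments must not overlap", call. = FALSE)
  }
  if (is.null(nuisance)) {
    nuisance <- population_spec(
      "erratic", 0,
      scatter = list(SALS = c(log(300), 1.5), MALS = c(log(300), 1.5),
                     LALS = c(log(120), 1.5)),
      fluor = lapply(stats::setNames(nm = ev_channels("fluor")),
                     function(ch) c(log(30), 1.5)),
      scatter_fluor_corr = 0
    )
  }
  base_rate <- nrow(events) / dur
  channels <- channel_names(events)
  extra <- list()
  for (i in seq_len(nrow(seg))) {
    lambda <- (seg[i, "multiplier"] - 1) * base_rate *
      (seg[i, "end"] - seg[i, "start"])
    if (lambda <= 0) next
    n <- stats::rpois(1L, lambda)
    if (n == 0L) next
    mat <- draw_population(nuisance, n, channels)
    t <- stats::runif(n, seg[i, "start"], seg[i, "end"])
    extra[[length(extra) + 1L]] <- event_table(
      as.data.frame(mat), t, meta = acq_meta(events),
      population = rep("erratic", n))
  }
  out <- if (length(extra)) {
    bind_events(c(list(events), extra))
  } else {
    events
  }
  attr(out, "erratic_segments") <- seg
  out
}
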