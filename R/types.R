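#' @keywords internal
"_PACKAGE"

# Canonical channel layout of the instrument this package emulates:
# three scatter detectors off the violet laser and five fluorescence
# detectors. All event tables use this ordering unless configured otherwise.
EV_SCATTER_CHANNELS <- c("SALS", "MALS", "LALS")
EV_FLUOR_CHANNELS <- c("FITC", "PE", "APC", "AF700", "BV510")

#' Standard channel names
#'
#' Returns the default channel layout used throughout the package: small-,
#' medium- and large-angle light scatter (SALS, MALS, LALS) plus the five
#' fluorescence channels (FITC, PE, APC, AF700, BV510).
#'
#' @param which `"all"`, `"scatter"` or `"fluor"`.
#' @return Character vector of channel names.
#' @export
ev_channels <- function(which = c("all", "scatter", "fluor")) {
  which <- match.arg(which)
  switch(which,
    all = c(EV_SCATTER_CHANNELS, EV_FLUOR_CHANNELS),
    scatter = EV_SCATTER_CHANNELS,
    fluor = EV_FLUOR_CHANNELS
  )
}

#' Define a synthetic particle population
#'
#' A population is a homogeneous class of particles (buffer noise, label
#' aggregates of one fluorophore, EVs, calibration beads) whose per-event
#' scatter and fluorescence intensities are log-normal. A single latent
#' "size" factor couples scatter and fluorescence in log space, so larger
#' particles both scatter more light and carry more label — the structure
#' filtration exploits when it removes the largest, brightest aggregates.
#'
#' @param name Population label (stored per event for test oracles).
#' @param concentration Particles per microlitre of measured (post-dilution)
#'   sample. Must be >= 0.
#' @param scatter Named list over scatter channels; each element
#'   `c(meanlog, sdlog)` of the log-normal intensity.
#' @param fluor Named list over fluorescence channels, same format.
#' @param scatter_fluor_corr Correlation, in log space, between scatter and
#'   fluorescence channels, in \[-1, 1\]. Implemented as a one-factor model:
#'   every channel loads sqrt(|corr|) on a shared latent normal (fluorescence
#'   loadings carry the sign), which keeps the implied correlation matrix
#'   positive semi-definite and leaves every marginal exactly log-normal.
#' @param aggregate Logical; is this population a label aggregate (and hence
#'   subject to pre-treatment removal)?
#' @return An object of class `population_spec`.
#' @examples
#' population_spec("agg_FITC", 1000,
#'   scatter = list(SALS = c(log(600), 1), MALS = c(log(400), 1),
#'                  LALS = c(log(180), 1)),
#'   fluor = list(FITC = c(log(3000), 1)),
#'   scatter_fluor_corr = 0.6, aggregate = TRUE)
#' @export
population_spec <- function(name, concentration, scatter, fluor = list(),
                            scatter_fluor_corr = 0, aggregate = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0) {
    stop("concentration must be a single number >= 0", call. = FALSE)
  }
  check_params <- function(p, kind) {
    if (length(p) == 0L) return(invisible())
    if (is.null(names(p)) || any(names(p) == "")) {
      stop(kind, " parameters must be a named list", call. = FALSE)
    }
    for (ch in names(p)) {
      v <- p[[ch]]
      if (length(v) != 2L || !is.numeric(v) || any(!is.finite(v))) {
        stop(kind, " parameters for ", ch,
             " must be c(meanlog, sdlog)", call. = FALSE)
      }
      if (v[2L] <= 0) {
        stop("sdlog for ", ch, " must be > 0", call. = FALSE)
      }
    }
  }
  check_params(scatter, "scatter")
  check_params(fluor, "fluor")
  if (!is.numeric(scatter_fluor_corr) || abs(scatter_fluor_corr) > 1) {
    stop("scatter_fluor_corr must lie in [-1, 1]", call. = FALSE)
  }
  structure(
    list(name = name, concentration = concentration,
         scatter = scatter, fluor = fluor,
         scatter_fluor_corr = scatter_fluor_corr,
         aggregate = isTRUE(aggregate)),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s: %.4g particles/uL%s, corr %.2f\n",
              x$name, x$concentration,
              if (x$aggregate) " [aggregate]" else "",
              x$scatter_fluor_corr))
  invisible(x)
}

#' Spillover matrix
#'
#' Square matrix over fluorescence channels; entry (i, j) is the fraction of
#' fluorophore i's signal detected in channel j (row convention: observed =
#' true %*% S). The diagonal must be 1, off-diagonals in \[0, 1), and the
#' matrix invertible.
#'
#' @param mat Numeric square matrix with identical row and column names.
#' @return A `spillover_matrix`.
#' @seealso [compensate()], [identity_spillover()], [default_spillover()]
#' @export
spillover_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("spillover matrix must be square", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)) ||
      !identical(rownames(mat), colnames(mat))) {
    stop("spillover matrix needs identical row and column channel names",
         call. = FALSE)
  }
  if (any(abs(diag(mat) - 1) > 1e-12)) {
    stop("spillover matrix diagonal must be 1", call. = FALSE)
  }
  off <- mat[row(mat) != col(mat)]
  if (any(off < 0 | off >= 1)) {
    stop("spillover off-diagonals must lie in [0, 1)", call. = FALSE)
  }
  if (abs(det(mat)) < 1e-12) stop("spillover matrix is singular", call. = FALSE)
  structure(mat, class = c("spillover_matrix", "matrix"))
}

#' Identity spillover over the given channels
#' @param channels Fluorescence channel names.
#' @return A `spillover_matrix` equal to the identity.
#' @export
identity_spillover <- function(channels = ev_channels("fluor")) {
  m <- diag(length(channels))
  dimnames(m) <- list(channels, channels)
  spillover_matrix(m)
}

#' Default spillover matrix
#'
#' Modest spillover (<= 0.15) between spectrally adjacent fluorophores,
#' zero elsewhere. The study instrument's matrix is not public; these values
#' are a calibration choice with a realistic magnitude.
#'
#' @return A `spillover_matrix` over the default fluorescence channels.
#' @export
default_spillover <- function() {
  ch <- ev_channels("fluor")
  m <- diag(length(ch))
  dimnames(m) <- list(ch, ch)
  m["FITC", "PE"] <- 0.12
  m["PE", "FITC"] <- 0.04
  m["APC", "AF700"] <- 0.15
  m["AF700", "APC"] <- 0.08
  m["BV510", "FITC"] <- 0.05
  spillover_matrix(m)
}

#' Acquisition configuration
#'
#' Instrument-side settings for one synthetic acquisition: volumetric flow
#' rate, acquisition duration, trigger channel and threshold, spillover
#' applied at "detection", and the random seed.
#'
#' Defaults mirror the acquisition protocol the package emulates: 120 s at
#' 0.75 uL/min with a medium-angle light scatter (MALS) trigger set above the
#' buffer background.
#'
#' @param flow_rate Sample flow rate in uL/min (> 0).
#' @param duration Acquisition duration in seconds (> 0).
#' @param trigger_channel Channel the trigger threshold applies to.
#' @param trigger_threshold Intensity below which events are not recorded
#'   (>= 0; `Inf` records nothing).
#' @param spillover A [spillover_matrix()] mixed into the fluorescence
#'   channels at simulation time.
#' @param seed Integer seed; required by the simulators.
#' @return An `acquisition_config`.
#' @export
acquisition_config <- function(flow_rate = 0.75, duration = 120,
                               trigger_channel = "MALS",
                               trigger_threshold = default_trigger_threshold(),
                               spillover = identity_spillover(),
                               seed = NULL) {
  if (!is.numeric(flow_rate) || length(flow_rate) != 1L || flow_rate <= 0) {
    stop("flow_rate must be a single positive number (uL/min)", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("duration must be a single positive number (s)", call. = FALSE)
  }
  if (!is.numeric(trigger_threshold) || length(trigger_threshold) != 1L ||
      is.na(trigger_threshold) || trigger_threshold < 0) {
    stop("trigger_threshold must be a single number >= 0", call. = FALSE)
  }
  if (!inherits(spillover, "spillover_matrix")) {
    spillover <- spillover_matrix(spillover)
  }
  structure(
    list(flow_rate = flow_rate, duration = duration,
         trigger_channel = trigger_channel,
         trigger_threshold = trigger_threshold,
         spillover = spillover, seed = seed),
    class = "acquisition_config"
  )
}

#' Default trigger threshold
#'
#' The MALS intensity above which the synthetic instrument records an event.
#' Calibrated jointly with [default_noise_population()] so that an unstained
#' buffer acquisition triggers at well under 100 events per second while
#' EV-scale and aggregate populations are recorded essentially completely.
#'
#' @return A single intensity value.
#' @export
default_trigger_threshold <- function() 80

#' Default unstained-buffer noise population
#'
#' Instrument/buffer background: ~40,000 sub-trigger particles per uL whose
#' MALS distribution leaves only a small upper tail above the default trigger
#' threshold (about 6%, i.e. ~30 triggered events/s at 0.75 uL/min). The
#' fluorescence channels are dim with a heavy tail (sdlog 1.6), so an
#' unlabelled-buffer acquisition still yields a small positive-event
#' concentration above the control-derived gates — as real unstained buffer
#' does — giving the fold-change denominator a non-zero mean.
#'
#' @param concentration Particles per uL before trigger thinning.
#' @return A [population_spec()].
#' @export
default_noise_population <- function(concentration = 40000) {
  population_spec(
    "background", concentration,
    scatter = list(SALS = c(log(150), 0.7),
                   MALS = c(log(20), 0.9),
                   LALS = c(log(50), 0.7)),
    fluor = lapply(stats::setNames(nm = ev_channels("fluor")),
                   function(ch) c(log(5), 1.6)),
    scatter_fluor_corr = 0
  )
}

#' Label pre-treatment model
#'
#' Describes how a pre-treatment (centrifugation or filtration of the label
#' before staining) removes aggregate particles. `removal_fraction` is the
#' mean fraction of aggregate particles removed; a replicate-specific value is
#' drawn from a Normal with SD `removal_sd` and clipped to \[0, 1\], with the
#' Normal's location solved (see [clipped_normal_location()]) so that the
#' clipped draw's mean equals `removal_fraction` — the calibration target is
#' the realized mean removal, not the pre-clip location.
#' `size_selectivity` in \[0, 1\] is the degree to which removal targets the
#' largest (highest log-scatter) aggregates first: 0 removes uniformly, 1
#' removes strictly from the top of the scatter distribution, matching the
#' observation that filtration removes the aggregates that scatter more light
#' and fluoresce more.
#'
#' @param treatment Label: one of `"U"`, `"C5"`, `"C10"`, `"C30"`, `"F"`,
#'   `"WF"` (untreated; 17,000 g centrifugation 5/10/30 min; filtration;
#'   washed-filter filtration) or any user-defined label.
#' @param removal_fraction Mean removal fraction in \[0, 1\]; `"U"` must be 0.
#' @param removal_sd Between-replicate SD of the removal fraction (>= 0).
#' @param size_selectivity See above.
#' @return A `treatment_model`.
#' @export
treatment_model <- function(treatment, removal_fraction, removal_sd = 0,
                            size_selectivity = 0) {
  stopifnot(is.character(treatment), length(treatment) == 1L)
  if (!is.numeric(removal_fraction) || removal_fraction < 0 ||
      removal_fraction > 1) {
    stop("removal_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (identical(treatment, "U") && removal_fraction != 0) {
    stop("treatment U (untreated) must have removal_fraction = 0",
         call. = FALSE)
  }
  if (!is.numeric(removal_sd) || removal_sd < 0) {
    stop("removal_sd must be >= 0", call. = FALSE)
  }
  if (!is.numeric(size_selectivity) || size_selectivity < 0 ||
      size_selectivity > 1) {
    stop("size_selectivity must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(treatment = treatment, removal_fraction = removal_fraction,
         removal_sd = removal_sd, size_selectivity = size_selectivity,
         latent_mean = clipped_normal_location(removal_fraction, removal_sd)),
    class = "treatment_model"
  )
}

#' Location of a Normal whose \[0, 1\]-clipped mean hits a target
#'
#' The replicate-specific removal fraction is `clip(Normal(mu, sd), 0, 1)`.
#' Clipping shifts the mean (a Normal centred at 0.02 with SD 0.45 clips to a
#' mean near 0.19), so the location `mu` is solved such that
#' `E[clip(Normal(mu, sd), 0, 1)] = target`, keeping the published
#' per-treatment mean removals as the model's realized means.
#'
#' @param target Desired mean of the clipped draw, in \[0, 1\].
#' @param sd SD of the underlying Normal (>= 0).
#' @return The location `mu`.
#' @export
clipped_normal_location <- function(target, sd) {
  if (sd == 0) return(target)
  clipped_mean <- function(mu) {
    stats::pnorm((mu - 1) / sd) +
      mu * (stats::pnorm((1 - mu) / sd) - stats::pnorm(-mu / sd)) +
      sd * (stats::dnorm(mu / sd) - stats::dnorm((1 - mu) / sd))
  }
  stats::uniroot(function(mu) clipped_mean(mu) - target,
                 lower = -10, upper = 10, tol = 1e-10)$root
}

#' Default treatment models
#'
#' Mean removal fractions and between-replicate SDs calibrated to the
#' published per-treatment mean percent reductions (F 47 +/- 24, WF 57 +/- 18,
#' C5 2 +/- 45, C10 13 +/- 37, C30 19 +/- 42, all as fractions). Filtration
#' arms are strongly size-selective; centrifugation arms weakly so.
#'
#' @return Named list of [treatment_model()] objects keyed by treatment.
#' @export
default_treatment_models <- function() {
  list(
    U   = treatment_model("U",   0.00, 0.00, 0.0),
    C5  = treatment_model("C5",  0.02, 0.45, 0.3),
    C10 = treatment_model("C10", 0.13, 0.37, 0.3),
    C30 = treatment_model("C30", 0.19, 0.42, 0.3),
    F   = treatment_model("F",   0.47, 0.24, 0.9),
    WF  = treatment_model("WF",  0.57, 0.18, 0.9)
  )
}
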