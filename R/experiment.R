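# Full-experiment generator: the two-panel, two-arm, six-treatment,
# five-replicate grid with per-panel gating controls, calibration-bead
# reference, unstained background, and unlabelled-buffer samples.

#' Default experiment design grid
#'
#' Panels P1 (3 labels: FITC, PE, APC) and P2 (4 labels: FITC, PE, APC,
#' AF700), arms specific/isotype, treatments U/C5/C10/C30/F/WF, 5 replicates:
#' 120 stained-buffer samples, 70 label series per treatment.
#'
#' @param panels,arms,treatments,replicates Grid factors.
#' @return Data frame with columns `panel`, `arm`, `treatment`, `replicate`.
#' @export
default_design <- function(panels = c("P1", "P2"),
                           arms = c("specific", "isotype"),
                           treatments = c("U", "C5", "C10", "C30", "F", "WF"),
                           replicates = 5) {
  g <- expand.grid(panel = panels, arm = arms, treatment = treatments,
                   replicate = seq_len(replicates),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g[order(g$panel, g$arm, g$treatment, g$replicate), , drop = FALSE]
}

#' Channels measured by a panel
#' @param panel `"P1"` or `"P2"`.
#' @return Character vector of fluorescence channels.
#' @export
panel_channels <- function(panel) {
  switch(panel,
    P1 = c("FITC", "PE", "APC"),
    P2 = c("FITC", "PE", "APC", "AF700"),
    stop("unknown panel: ", panel, call. = FALSE)
  )
}

# Untreated aggregate concentrations (particles/uL of measured sample) per
# panel x arm x fluorophore. These are a desk-scale calibration: published
# untreated mean concentrations scaled down 20-fold so a full experiment
# simulates in seconds, preserving the relative structure between labels.
default_aggregate_concentrations <- function() {
  list(
    P1 = list(
      specific = c(FITC = 3310, PE = 505, APC = 92),
      isotype  = c(FITC = 3490, PE = 505, APC = 87)
    ),
    P2 = list(
      specific = c(FITC = 1910, PE = 1875, APC = 1230, AF700 = 1295),
      isotype  = c(FITC = 5315, PE = 3355, APC = 3180, AF700 = 2445)
    )
  )
}

#' Aggregate populations for one stained-buffer sample
#'
#' One aggregate population per label of the panel, bright in its own
#' fluorescence channel, with positively correlated scatter and fluorescence
#' (larger aggregates scatter and fluoresce more), plus a residual buffer
#' population.
#'
#' @param panel,arm Design coordinates.
#' @param concentrations See [default_aggregate_concentrations()].
#' @param buffer_concentration Residual buffer particles per uL.
#' @return List of [population_spec()]s.
#' @export
default_label_populations <- function(panel, arm,
                                      concentrations =
                                        default_aggregate_concentrations(),
                                      buffer_concentration = 2000) {
  conc <- concentrations[[panel]][[arm]]
  pops <- lapply(names(conc), function(ch) {
    population_spec(
      paste0("agg_", ch), conc[[ch]],
      scatter = list(SALS = c(log(600), 1.0), MALS = c(log(400), 1.0),
                     LALS = c(log(180), 1.0)),
      fluor = stats::setNames(list(c(log(3000), 1.0)), ch),
      scatter_fluor_corr = 0.6, aggregate = TRUE
    )
  })
  names(pops) <- names(conc)
  c(pops, list(buffer = residual_buffer_population(buffer_concentration)))
}

# Residual buffer particles present in every measured sample; same shape as
# the unstained background but at the dilution of a stained sample.
residual_buffer_population <- function(concentration = 2000) {
  p <- default_noise_population(concentration)
  p$name <- "buffer"
  p
}

# EV-like / lysis-debris populations for the plasma gating controls. The
# triton control carries detergent debris with a moderately elevated FITC
# tail (it defines the lactadherin-FITC positivity threshold); the isotype
# control carries intact EVs dim in all label channels (it defines the
# PE/APC/AF700/BV510 thresholds).
control_populations <- function(kind = c("triton", "isotype"),
                                concentration = 4000) {
  kind <- match.arg(kind)
  fluor <- lapply(stats::setNames(nm = ev_channels("fluor")),
                  function(ch) c(log(8), 0.9))
  if (kind == "triton") fluor$FITC <- c(log(20), 1.0)
  list(
    population_spec(
      if (kind == "triton") "debris" else "EV", concentration,
      scatter = list(SALS = c(log(300), 0.8), MALS = c(log(300), 0.8),
                     LALS = c(log(100), 0.8)),
      fluor = fluor, scatter_fluor_corr = 0.3
    ),
    buffer = residual_buffer_population()
  )
}

#' Simulate a full label pre-treatment experiment
#'
#' Generates, under one global seed with per-sample substreams, every sample
#' of the design grid plus the session controls: a calibration-bead
#' reference, an unstained-buffer background, unlabelled-buffer samples, and
#' per-panel triton and isotype plasma gating controls.
#'
#' For each aggregate population of each sample the pre-treatment draws a
#' replicate-specific removal fraction Normal(mean, sd) clipped to \[0, 1\]
#' and removes that share of simulated particles, targeting the
#' highest-scatter particles first according to the model's size selectivity.
#' Between-replicate label-preparation variability is a mean-preserving
#' log-normal jitter on each aggregate concentration. Ground truth (realized
#' concentrations and removal fractions) is returned for recovery tests.
#'
#' @param design Data frame from [default_design()].
#' @param treatment_models Named list from [default_treatment_models()]; every
#'   treatment in the design must be present.
#' @param config An [acquisition_config()] with a seed.
#' @param concentrations Untreated aggregate concentrations, see
#'   [default_aggregate_concentrations()].
#' @param replicate_cv Log-normal coefficient of variation of the
#'   between-replicate concentration jitter (default 0.3).
#' @param n_buffer_samples Number of unlabelled-buffer samples (default 5).
#' @return An object of class `ev_experiment`: list with `samples` (each a
#'   list of `meta` and `events`), `controls`, `truth` (data frame), `design`
#'   and `config`.
#' @export
simulate_experiment <- function(design = default_design(),
                                treatment_models = default_treatment_models(),
                                config = acquisition_config(seed = 1),
                                concentrations =
                                  default_aggregate_concentrations(),
                                replicate_cv = 0.3,
                                n_buffer_samples = 5) {
  stopifnot(inherits(config, "acquisition_config"))
  if (is.null(config$seed)) {
    stop("config$seed must be set for simulation", call. = FALSE)
  }
  unknown <- setdiff(unique(design$treatment), names(treatment_models))
  if (length(unknown)) {
    stop("unknown treatment label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seed <- as.integer(config$seed)
  samples <- vector("list", nrow(design))
  truth <- list()
  sdlog <- sqrt(log(1 + replicate_cv^2))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    set.seed(derive_seed(seed, i))
    tm <- treatment_models[[row$treatment]]
    pops <- default_label_populations(row$panel, row$arm, concentrations)
    for (ch in names(pops)) {
      pop <- pops[[ch]]
      if (!pop$aggregate) next
      base_conc <- pop$concentration
      jitter <- stats::rlnorm(1L, -sdlog^2 / 2, sdlog)
      pop$concentration <- base_conc * jitter
      removal <- min(max(stats::rnorm(
        1L, tm$latent_mean, tm$removal_sd), 0), 1)
      attr(pop, "removal") <- list(fraction = removal,
                                   size_selectivity = tm$size_selectivity)
      pops[[ch]] <- pop
      truth[[length(truth) + 1L]] <- data.frame(
        sample = i, panel = row$panel, arm = row$arm,
        treatment = row$treatment, replicate = row$replicate,
        channel = ch, base_concentration = base_conc,
        concentration_pre = pop$concentration,
        removal_fraction = removal,
        concentration_post = pop$concentration * (1 - removal),
        stringsAsFactors = FALSE)
    }
    ev <- simulate_sample_impl(pops, config)
    meta <- attr(ev, "meta")
    meta$sample_meta <- list(panel = row$panel, arm = row$arm,
                             treatment = row$treatment,
                             replicate = row$replicate, matrix = "PBS",
                             dilution_factor = 17)
    attr(ev, "meta") <- meta
    samples[[i]] <- list(meta = meta$sample_meta, events = ev)
  }
  truth <- do.call(rbind, truth)
  n0 <- nrow(design)

  with_seed <- function(offset, expr) {
    set.seed(derive_seed(seed, n0 + offset))
    expr
  }
  cfg0 <- config
  cfg0$seed <- NULL
  controls <- list(
    bead = with_seed(1L, simulate_sample_impl(default_bead_populations(),
                                              cfg0)),
    background = with_seed(2L, simulate_sample_impl(
      list(default_noise_population()), cfg0)),
    pbs = lapply(seq_len(n_buffer_samples), function(r) {
      with_seed(2L + r,
                simulate_sample_impl(list(default_noise_population()), cfg0))
    }),
    triton = lapply(stats::setNames(nm = c("P1", "P2")), function(p) {
      with_seed(10L + match(p, c("P1", "P2")),
                simulate_sample_impl(control_populations("triton"), cfg0))
    }),
    isotype = lapply(stats::setNames(nm = c("P1", "P2")), function(p) {
      with_seed(20L + match(p, c("P1", "P2")),
                simulate_sample_impl(control_populations("isotype"), cfg0))
    })
  )
  structure(list(samples = samples, controls = controls, truth = truth,
                 design = design, config = config),
            class = "ev_experiment")
}

#' @export
print.ev_experiment <- function(x, ...) {
  cat(sprintf("<ev_experiment> %d samples (%s), seed %s\n",
              length(x$samples),
              paste(dim(table(x$design$panel, x$design$treatment)),
                    collapse = " x "),
              format(x$config$seed)))
  invisible(x)
}
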