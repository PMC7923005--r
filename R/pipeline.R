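# End-to-end orchestration: simulate -> compensate -> gate -> quantify ->
# compare, with provenance (config + gate JSON + log) written to the output
# directory.

#' Default run configuration
#'
#' @param seed Global seed for the run.
#' @param out_dir Output directory (`NULL`: return results only).
#' @param format Event-file format when `write_event_files` is `TRUE`.
#' @param replicates Replicates per design cell.
#' @param bin_width,k Time-gate parameters (seconds; robust multiplier).
#' @param fluor_percentile Positivity percentile for the fluorescence gates.
#' @param replicate_cv Between-replicate concentration jitter CV.
#' @param write_event_files Write per-sample event files (off by default; the
#'   manifest and summary tables are always written when `out_dir` is set).
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1, out_dir = NULL,
                               format = c("csv", "fcs"), replicates = 5,
                               bin_width = 1, k = 5, fluor_percentile = 0.99,
                               replicate_cv = 0.3,
                               write_event_files = FALSE) {
  structure(list(seed = seed, out_dir = out_dir, format = match.arg(format),
                 replicates = replicates, bin_width = bin_width, k = k,
                 fluor_percentile = fluor_percentile,
                 replicate_cv = replicate_cv,
                 write_event_files = write_event_files),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with any subset of [default_run_config()]'s fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(vals)) cfg[[nm]] <- vals[[nm]]
  cfg
}

#' Fit the session gate set for one panel
#'
#' Size gate from the bead reference (scatter floor from the unstained
#' background), lactadherin-FITC gate from the panel's triton lysis control,
#' and all other panel channels from the panel's isotype control. Controls
#' are compensated before the percentiles are taken.
#'
#' @param experiment An `ev_experiment` (or a list with the same `controls`).
#' @param panel `"P1"` or `"P2"`.
#' @param fluor_percentile Positivity percentile.
#' @return A [gate_set()].
#' @export
fit_session_gates <- function(experiment, panel, fluor_percentile = 0.99) {
  ctr <- experiment$controls
  if (is.null(ctr$bead)) {
    stop("gate fitting failed: experiment has no bead reference sample",
         call. = FALSE)
  }
  spill <- experiment$config$spillover
  size_gate <- fit_size_gate(ctr$bead, noise_events = ctr$background)
  triton <- compensate(ctr$triton[[panel]], spill)
  isotype <- compensate(ctr$isotype[[panel]], spill)
  channels <- panel_channels(panel)
  fg <- list()
  for (ch in channels) {
    src <- if (ch == "FITC") triton else isotype
    kind <- if (ch == "FITC") "triton" else "isotype"
    fg[[ch]] <- fit_fluor_gate(src, ch, size_gate,
                               percentile = fluor_percentile,
                               control_kind = kind)
  }
  gate_set(time_gate = NULL, size_gate = size_gate, fluor_gates = fg,
           provenance = list(panel = panel,
                             size_source = "bead reference",
                             fitc_source = paste0(panel, " triton control"),
                             other_source = paste0(panel, " isotype control")))
}

#' Analyze a simulated experiment
#'
#' Runs the full analysis on an `ev_experiment`: per-panel session gates,
#' compensation, per-sample time QC, gating, concentration estimation,
#' normalization to untreated means, fold changes against unlabelled buffer,
#' per-treatment reductions, and pairwise Wilcoxon comparisons at the three
#' aggregation levels.
#'
#' @param experiment From [simulate_experiment()].
#' @param bin_width,k Time-gate parameters.
#' @param fluor_percentile Positivity percentile for fluorescence gates.
#' @return List with `gates` (per panel), `records`, `pbs_records`,
#'   `normalized`, `fold_changes`, `reductions`, `comparisons` (list of data
#'   frames by level).
#' @export
analyze_experiment <- function(experiment, bin_width = 1, k = 5,
                               fluor_percentile = 0.99) {
  stopifnot(inherits(experiment, "ev_experiment"))
  spill <- experiment$config$spillover
  panels <- unique(experiment$design$panel)
  gates <- lapply(stats::setNames(nm = panels), function(p) {
    g <- fit_session_gates(experiment, p, fluor_percentile)
    g$time_gate <- fit_time_gate(experiment$controls$background,
                                 bin_width = bin_width, k = k)
    g$time_gate$bin_width <- bin_width
    g$time_gate$k <- k
    g
  })

  records <- do.call(rbind, lapply(experiment$samples, function(s) {
    ev <- compensate(s$events, spill)
    quantify_sample(ev, gates[[s$meta$panel]],
                    channels = panel_channels(s$meta$panel),
                    sample_meta = s$meta)
  }))

  pbs_records <- do.call(rbind, lapply(panels, function(p) {
    do.call(rbind, lapply(seq_along(experiment$controls$pbs), function(r) {
      ev <- compensate(experiment$controls$pbs[[r]], spill)
      q <- quantify_sample(ev, gates[[p]], channels = panel_channels(p))
      cbind(panel = p, replicate = r, q, stringsAsFactors = FALSE)
    }))
  }))

  normalized <- normalize_to_untreated(records)
  fold_changes <- fold_change_table(records, pbs_records)
  reductions <- reduction_table(normalized)
  comparisons <- lapply(
    stats::setNames(nm = c("all", "panel", "label")),
    function(lv) compare_treatments(normalized, lv))

  list(gates = gates, records = records, pbs_records = pbs_records,
       normalized = normalized, fold_changes = fold_changes,
       reductions = reductions, comparisons = comparisons)
}

#' Fold-change table against unlabelled buffer
#'
#' One row per panel x arm x fluorophore for the untreated samples, plus
#' pooled "total" rows per fluorophore: fold change of the mean untreated
#' concentration over the mean unlabelled-buffer concentration in the same
#' channel, with the per-replicate mean +/- SD.
#'
#' @param records Concentration records of the stained samples.
#' @param pbs_records Concentration records of the unlabelled-buffer samples
#'   (columns `panel`, `channel`, `concentration`).
#' @return Data frame with columns `panel`, `arm`, `channel`, `n`,
#'   `mean_concentration`, `fc`, `fc_sd`, `buffer_mean`.
#' @export
fold_change_table <- function(records, pbs_records) {
  u <- records[records$treatment == "U", ]
  rows <- list()
  add_row <- function(panel, arm, ch, lab, buf) {
    f <- fold_change(lab, buf)
    rows[[length(rows) + 1L]] <<- data.frame(
      panel = panel, arm = arm, channel = ch, n = length(lab),
      mean_concentration = mean(lab), fc = f$fc, fc_sd = f$fc_sd,
      buffer_mean = mean(buf), stringsAsFactors = FALSE)
  }
  for (p in unique(u$panel)) {
    for (a in unique(u$arm[u$panel == p])) {
      for (ch in unique(u$channel[u$panel == p & u$arm == a])) {
        lab <- u$concentration[u$panel == p & u$arm == a & u$channel == ch]
        buf <- pbs_records$concentration[pbs_records$panel == p &
                                           pbs_records$channel == ch]
        add_row(p, a, ch, lab, buf)
      }
    }
  }
  for (ch in unique(u$channel)) {
    lab <- u$concentration[u$channel == ch]
    buf <- pbs_records$concentration[pbs_records$channel == ch]
    add_row("total", "all", ch, lab, buf)
  }
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' Simulates an experiment under the config's seed, analyzes it, and (when
#' `out_dir` is set) writes the provenance config, per-panel gate JSON, the
#' manifest, concentration/normalized/fold-change/reduction CSVs, the
#' per-level p-value tables and a log. Outputs are deterministic given the
#' seed.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return The [analyze_experiment()] result, plus `experiment`, invisibly
#'   when writing.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("simulate: seed %d, %d replicates", config$seed, config$replicates)
  experiment <- simulate_experiment(
    design = default_design(replicates = config$replicates),
    config = acquisition_config(spillover = default_spillover(),
                                seed = config$seed),
    replicate_cv = config$replicate_cv)
  say("analyze: bin_width %g s, k %g, fluorescence percentile %g",
      config$bin_width, config$k, config$fluor_percentile)
  res <- analyze_experiment(experiment, bin_width = config$bin_width,
                            k = config$k,
                            fluor_percentile = config$fluor_percentile)
  for (p in names(res$gates)) {
    g <- res$gates[[p]]
    say("gates[%s]: SALS < %.6g, LALS < %.6g; %s", p,
        g$size_gate$sals_max, g$size_gate$lals_max,
        paste(vapply(g$fluor_gates, function(f)
          sprintf("%s > %.6g", f$channel, f$threshold), ""), collapse = ", "))
  }
  res$experiment <- experiment

  out <- config$out_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cfg <- unclass(config)
    cfg$out_dir <- NULL
    yaml::write_yaml(cfg, file.path(out, "config.yaml"))
    for (p in names(res$gates)) {
      write_gates_json(res$gates[[p]],
                       file.path(out, sprintf("gates_%s.json", p)))
    }
    num <- function(df) {
      df[] <- lapply(df, function(col)
        if (is.numeric(col)) signif(col, 10) else col)
      df
    }
    utils::write.csv(num(res$records),
                     file.path(out, "concentrations.csv"), row.names = FALSE)
    utils::write.csv(num(res$normalized),
                     file.path(out, "normalized.csv"), row.names = FALSE)
    utils::write.csv(num(res$fold_changes),
                     file.path(out, "fold_change.csv"), row.names = FALSE)
    utils::write.csv(num(res$reductions),
                     file.path(out, "reductions.csv"), row.names = FALSE)
    for (lv in names(res$comparisons)) {
      utils::write.csv(num(res$comparisons[[lv]]),
                       file.path(out, sprintf("comparisons_%s.csv", lv)),
                       row.names = FALSE)
    }
    manifest <- cbind(experiment$design,
                      file = sprintf("sample_%03d.%s",
                                     seq_len(nrow(experiment$design)),
                                     config$format))
    utils::write.csv(manifest, file.path(out, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(num(experiment$truth), file.path(out, "truth.csv"),
                     row.names = FALSE)
    if (isTRUE(config$write_event_files)) {
      evdir <- file.path(out, "events")
      dir.create(evdir, showWarnings = FALSE)
      for (i in seq_along(experiment$samples)) {
        write_events(experiment$samples[[i]]$events,
                     file.path(evdir, manifest$file[i]))
      }
    }
    writeLines(log_lines, file.path(out, "log.txt"))
    say("wrote outputs to %s", out)
    return(invisible(res))
  }
  res
}

#' Plot normalized concentration distributions per treatment
#'
#' Box plots of the normalized concentrations by treatment, optionally
#' faceted by panel x arm — the summary figure style for comparing label
#' pre-treatments.
#'
#' @param normalized Output of [normalize_to_untreated()].
#' @param facet Facet by panel x arm (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_normalized <- function(normalized, facet = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_normalized requires ggplot2", call. = FALSE)
  }
  p <- ggplot2::ggplot(normalized,
                       ggplot2::aes(x = .data$treatment,
                                    y = .data$normalized)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pre-treatment",
                  y = "concentration / mean untreated")
  if (facet) {
    p <- p + ggplot2::facet_grid(panel ~ arm)
  }
  p
}
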