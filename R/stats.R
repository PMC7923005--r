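# Statistical layer: normalization to untreated means, fold change against
# unlabelled buffer, percent reduction with CV, and unadjusted pairwise
# two-sided Wilcoxon rank-sum tests at three aggregation levels.

group_key <- function(records) {
  cols <- intersect(c("panel", "arm", "label", "channel"), names(records))
  interaction(records[cols], drop = TRUE, lex.order = TRUE)
}

#' Normalize concentrations to the untreated group mean
#'
#' Each concentration is divided by the mean untreated (`U`) concentration of
#' its own label group (panel x arm x label/channel), so the mean of the
#' normalized untreated values within a group is exactly 1.
#'
#' @param records Data frame with columns `treatment`, `concentration` and the
#'   grouping columns (`panel`, `arm`, `channel`, optionally `label`).
#' @return `records` with columns `u_mean` and `normalized` added.
#' @export
normalize_to_untreated <- function(records) {
  stopifnot(all(c("treatment", "concentration") %in% names(records)))
  key <- group_key(records)
  u_means <- tapply(records$concentration[records$treatment == "U"],
                    droplevels(key[records$treatment == "U"]), mean)
  missing <- setdiff(levels(key), names(u_means))
  if (length(missing)) {
    stop("no untreated (U) replicates for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- names(u_means)[!is.finite(u_means) | u_means <= 0]
  if (length(bad)) {
    stop("untreated mean is zero for group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  records$u_mean <- as.numeric(u_means[as.character(key)])
  records$normalized <- records$concentration / records$u_mean
  records
}

#' Fold change of labelled buffer over unlabelled buffer
#'
#' `fc` is the ratio of the labelled group's mean concentration to the
#' unlabelled-buffer mean. The `fc_mean +/- fc_sd` pair is computed on
#' per-replicate ratios against the overall buffer mean (a SD on a ratio of
#' two means is only definable per replicate); with that denominator
#' `fc_mean` equals `fc`.
#'
#' @param labelled Numeric vector of labelled-buffer concentrations.
#' @param buffer Numeric vector of unlabelled-buffer concentrations.
#' @return List with `fc`, `fc_mean`, `fc_sd`, `n_labelled`, `n_buffer`.
#' @examples
#' fold_change(c(70130), c(3798))$fc # 18.46...
#' @export
fold_change <- function(labelled, buffer) {
  labelled <- labelled[is.finite(labelled)]
  buffer <- buffer[is.finite(buffer)]
  if (!length(labelled) || !length(buffer)) {
    stop("fold change needs at least one labelled and one buffer value",
         call. = FALSE)
  }
  mb <- mean(buffer)
  if (mb == 0) stop("unlabelled buffer mean is zero; fold change undefined",
                    call. = FALSE)
  per_rep <- labelled / mb
  list(fc = mean(labelled) / mb, fc_mean = mean(per_rep),
       fc_sd = stats::sd(per_rep),
       n_labelled = length(labelled), n_buffer = length(buffer))
}

#' Percent reduction relative to the untreated mean
#'
#' Per-replicate reduction is `(1 - concentration / u_mean) x 100`; positive
#' means fewer aggregates than untreated, negative values (increases) are
#' kept. The summary reports the mean, SD and `cv = 100 x SD / mean` of the
#' per-replicate reductions.
#'
#' @param treated Numeric vector of treated concentrations.
#' @param u_mean Mean untreated concentration of the same group (> 0), or a
#'   vector matching `treated` when replicates belong to different groups.
#' @return List with `reductions` (per replicate, %), `mean`, `sd`, `cv`, `n`.
#' @examples
#' reduction_percent(c(50, 60), u_mean = 100)
#' @export
reduction_percent <- function(treated, u_mean) {
  if (any(!is.finite(u_mean)) || any(u_mean <= 0)) {
    stop("untreated mean must be positive", call. = FALSE)
  }
  red <- (1 - treated / u_mean) * 100
  m <- mean(red)
  s <- stats::sd(red)
  list(reductions = red, mean = m, sd = s,
       cv = if (!is.na(s)) 100 * s / m else NA_real_, n = length(red))
}

#' Per-treatment reduction table
#'
#' Summarizes normalized concentrations as percent reductions per treatment,
#' split by fluorophore across panels and pooled over all labels, mirroring
#' the layout of a per-treatment reduction table (mean +/- SD and CV%).
#'
#' @param normalized Output of [normalize_to_untreated()].
#' @param treatments Treatments to summarize (default: all non-`U`).
#' @return Data frame with columns `treatment`, `group` (fluorophore or
#'   `"total"`), `n`, `mean_concentration`, `reduction_mean`, `reduction_sd`,
#'   `reduction_cv`.
#' @export
reduction_table <- function(normalized,
                            treatments = setdiff(unique(normalized$treatment),
                                                 "U")) {
  rows <- list()
  for (tr in treatments) {
    sub <- normalized[normalized$treatment == tr, ]
    groups <- c(stats::setNames(nm = unique(sub$channel)), total = "total")
    for (g in names(groups)) {
      s <- if (g == "total") sub else sub[sub$channel == g, ]
      r <- reduction_percent(s$normalized, u_mean = 1)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, group = g, n = r$n,
        mean_concentration = mean(s$concentration),
        reduction_mean = r$mean, reduction_sd = r$sd, reduction_cv = r$cv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unadjusted pairwise Wilcoxon rank-sum tests
#'
#' Two-sided rank-sum test for every pair of treatment groups, with no
#' multiple-comparison adjustment. The exact null distribution is used when
#' both groups have fewer than 50 values and there are no ties; otherwise the
#' normal approximation with tie and continuity correction (the default
#' behaviour of [stats::wilcox.test()], which performs the tests).
#'
#' @param values Numeric vector of (normalized) concentrations.
#' @param groups Treatment label per value.
#' @return Data frame with one row per unordered pair: `group_a`, `group_b`,
#'   `W`, `p`, `n_a`, `n_b`. Groups with fewer than 2 values are skipped with
#'   a warning.
#' @examples
#' wilcoxon_pairwise(c(1, 2, 3, 4), c("a", "a", "b", "b"))
#' @export
wilcoxon_pairwise <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("skipping group(s) with fewer than 2 values: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(names(sizes), small)
  if (length(keep) < 2) stop("need at least two groups with n >= 2",
                             call. = FALSE)
  pairs <- utils::combn(sort(keep), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    x <- values[groups == a]; y <- values[groups == b]
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    data.frame(group_a = a, group_b = b, W = unname(wt$statistic),
               p = wt$p.value, n_a = length(x), n_b = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split normalized data into the three analysis strata
#'
#' `"all"` pools every panel, arm and label (on the default design n = 70 per
#' treatment); `"panel"` keeps panel x arm strata (n = 15 for P1, 20 for P2,
#' per arm); `"label"` keeps panel x arm x label strata (n = 5).
#'
#' @param normalized Output of [normalize_to_untreated()].
#' @param level `"all"`, `"panel"` or `"label"`.
#' @return Named list of data frames, one per stratum.
#' @export
aggregate_levels <- function(normalized, level = c("all", "panel", "label")) {
  level <- match.arg(level)
  if (level == "all") return(list(all = normalized))
  cols <- switch(level, panel = c("panel", "arm"),
                 label = c("panel", "arm", "channel"))
  key <- interaction(normalized[cols], drop = TRUE, lex.order = TRUE,
                     sep = ".")
  split(normalized, key)
}

#' Pairwise treatment comparisons at an aggregation level
#'
#' @param normalized Output of [normalize_to_untreated()].
#' @param level Aggregation level, see [aggregate_levels()].
#' @return Data frame of [wilcoxon_pairwise()] results with a `stratum`
#'   column and the per-group n.
#' @export
compare_treatments <- function(normalized,
                               level = c("all", "panel", "label")) {
  level <- match.arg(level)
  strata <- aggregate_levels(normalized, level)
  rows <- lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    res <- wilcoxon_pairwise(s$normalized, s$treatment)
    cbind(stratum = nm, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
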