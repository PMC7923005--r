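# Independent brute-force oracles used to pin down the implementation's
# numerical conventions. None of these call the package's own code paths.

# Percentile by explicit linear interpolation between order statistics.
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n1 + n2, n1) assignments of the pooled ranks (tie-free data only).
brute_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  stopifnot(!anyDuplicated(c(x, y)))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  pooled_ranks <- seq_len(n1 + n2)
  ws <- apply(sets, 2, function(idx) {
    sum(pooled_ranks[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Triple-filter gate counts by explicit per-event loops over plain vectors.
brute_gate_counts <- function(df, excluded_bins, sals_max, lals_max,
                              thresholds) {
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    t <- df$time[i]
    for (j in seq_len(nrow(excluded_bins))) {
      if (t >= excluded_bins[j, 1] && t < excluded_bins[j, 2]) {
        keep[i] <- FALSE
      }
    }
    if (!(df$SALS[i] < sals_max && df$LALS[i] < lals_max)) keep[i] <- FALSE
  }
  out <- integer(length(thresholds))
  names(out) <- names(thresholds)
  for (ch in names(thresholds)) {
    out[ch] <- sum(keep & df[[ch]] > thresholds[[ch]])
  }
  list(channel_counts = out, size_gated_count = sum(keep))
}

# Group-wise normalization by explicit loops.
brute_normalize <- function(records) {
  out <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    sel <- records$panel == records$panel[i] &
      records$arm == records$arm[i] &
      records$channel == records$channel[i] &
      records$treatment == "U"
    out[i] <- records$concentration[i] / mean(records$concentration[sel])
  }
  out
}

# Small helper: an event table with given channel values and times.
make_events <- function(n = 100, duration = 120, flow_rate = 0.75,
                        seed = NULL, channels = ev_channels()) {
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(matrix(stats::runif(n * length(channels), 0, 1000),
                             nrow = n, ncol = length(channels),
                             dimnames = list(NULL, channels)))
  event_table(df, stats::runif(n, 0, duration),
              meta = list(flow_rate = flow_rate, duration = duration))
}

# Concentration records over the full design grid with log-normal noise.
fake_records <- function(seed = 1, treatments = c("U", "F"),
                         replicates = 3) {
  set.seed(seed)
  design <- default_design(treatments = treatments,
                           replicates = replicates)
  rows <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    chs <- panel_channels(design$panel[i])
    data.frame(design[i, , drop = FALSE], channel = chs, row.names = NULL)
  }))
  rows$concentration <- stats::rlnorm(nrow(rows), log(1000), 0.4)
  rows
}
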