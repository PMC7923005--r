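poisson_stream <- function(rate = 50, duration = 120, seed = 1) {
  set.seed(seed)
  n <- rpois(1, rate * duration)
  make_events(n = n, duration = duration)
}

test_that("time gate rarely excludes bins of a homogeneous stream", {
  frac_retained <- vapply(1:50, function(s) {
    ev <- poisson_stream(seed = s)
    tg <- fit_time_gate(ev, bin_width = 1, k = 5)
    1 - nrow(tg$excluded_bins) / length(tg$counts)
  }, 1)
  expect_true(all(frac_retained >= 0.95))
})

test_that("an injected burst is excluded bin-exactly", {
  bg <- simulate_background(acquisition_config(seed = 60))
  set.seed(61)
  burst <- inject_erratic_segments(bg, list(c(50, 60, 10)))
  tg <- fit_time_gate(burst, bin_width = 1, k = 5)
  expect_equal(tg$excluded_bins[, "start"], 50:59, ignore_attr = TRUE)
  expect_equal(tg$retained_time, 110)
  # perfectly constant bin counts: nothing excluded
  const <- event_table(data.frame(SALS = rep(1, 120)),
                       time = seq(0.5, 119.5, by = 1),
                       meta = list(flow_rate = 0.75, duration = 120))
  tg0 <- fit_time_gate(const)
  expect_equal(nrow(tg0$excluded_bins), 0L)
  expect_equal(tg0$retained_time, 120)
})

test_that("a uniformly unstable acquisition is rejected", {
  # 7 events in every other 1 s bin, none in between
  ev <- event_table(
    data.frame(SALS = rep(1, 7 * 60)),
    time = rep(seq(0.5, 119.5, 2), each = 7),
    meta = list(flow_rate = 0.75, duration = 120))
  expect_error(fit_time_gate(ev, bin_width = 1, k = 0.1),
               "no stable acquisition window")
  expect_error(fit_time_gate(ev, bin_width = 30), "at least 10 bins")
})

test_that("size gate sits at the bead first percentile with strict bounds", {
  # degenerate beads: all at (1e4, 1e3); the threshold equals that point and
  # an event exactly on it is OUTSIDE the gate
  beads <- event_table(
    data.frame(SALS = rep(1e4, 200), LALS = rep(1e3, 200)),
    time = seq_len(200) / 10,
    meta = list(flow_rate = 0.75, duration = 120))
  sg <- fit_size_gate(beads, sals_floor = 100)
  expect_equal(sg$sals_max, 1e4)
  expect_equal(sg$lals_max, 1e3)
  on_edge <- event_table(data.frame(SALS = 1e4, LALS = 1e3), time = 0)
  expect_false(evgate:::size_gate_mask(on_edge, sg))
  expect_error(fit_size_gate(beads[0, ], sals_floor = 100), "100 bead")
})

test_that("the percentile convention matches a brute-force oracle", {
  beads <- event_table(
    data.frame(SALS = sample(1:100), LALS = rep(500, 100)),
    time = seq_len(100), meta = list(duration = 120, flow_rate = 0.75))
  sg <- fit_size_gate(beads, sals_floor = 0)
  expect_equal(sg$sals_max, brute_quantile(1:100, 0.01))  # 1.99
  expect_equal(sg$sals_max, 1.99)
  set.seed(10)
  x <- rlnorm(501, log(1000), 0.3)
  beads2 <- event_table(
    data.frame(SALS = x, LALS = x / 3), time = seq_along(x),
    meta = list(duration = 600, flow_rate = 0.75))
  sg2 <- fit_size_gate(beads2, sals_floor = 0)
  expect_equal(sg2$sals_max, brute_quantile(x, 0.01))
})

test_that("bead-calibrated gate retains EV-scale events", {
  cfg <- acquisition_config(seed = 70)
  bead <- simulate_bead_reference(cfg)
  bg <- simulate_background(acquisition_config(seed = 71))
  sg <- fit_size_gate(bead, noise_events = bg)
  noise <- evgate:::subset_events(bead,
                                  event_populations(bead) == "noise_floor")
  inside <- evgate:::size_gate_mask(noise, sg)
  expect_gte(mean(inside), 0.99)
})

test_that("fluorescence gates mark ~1% of their own control positive", {
  sg <- structure(list(sals_max = Inf, lals_max = Inf), class = "size_gate")
  # constant control: threshold c, nothing strictly above it
  const <- event_table(data.frame(FITC = rep(7, 500), SALS = 1, LALS = 1),
                       time = seq_len(500) / 10,
                       meta = list(duration = 120, flow_rate = 0.75))
  fg <- fit_fluor_gate(const, "FITC", sg)
  expect_equal(fg$threshold, 7)
  expect_equal(sum(const$FITC > fg$threshold), 0L)
  # n = 1e4 control: own positive fraction in [0.009, 0.011]
  set.seed(80)
  ctrl <- event_table(
    data.frame(FITC = rlnorm(1e4, log(20), 1), SALS = 1, LALS = 1),
    time = runif(1e4, 0, 120),
    meta = list(duration = 120, flow_rate = 0.75))
  fg2 <- fit_fluor_gate(ctrl, "FITC", sg)
  frac <- mean(ctrl$FITC > fg2$threshold)
  expect_gte(frac, 0.009)
  expect_lte(frac, 0.011)
  expect_equal(fg2$threshold, brute_quantile(ctrl$FITC, 0.99))
  # determinism: identical control, identical threshold
  expect_identical(fit_fluor_gate(ctrl, "FITC", sg)$threshold, fg2$threshold)
  expect_error(fit_fluor_gate(ctrl[1:50, ], "FITC", sg), "100 control")
})

wide_open_gates <- function(channels) {
  fg <- lapply(channels, function(ch) {
    structure(list(channel = ch, threshold = 0, percentile = 0.99,
                   control_kind = "isotype", n_control = 1000),
              class = "fluor_gate")
  })
  names(fg) <- channels
  gate_set(time_gate = NULL,
           size_gate = structure(list(sals_max = Inf, lals_max = Inf),
                                 class = "size_gate"),
           fluor_gates = fg)
}

test_that("apply_gates honors the time -> size -> fluorescence order", {
  ev <- make_events(n = 400, seed = 90)
  gates <- wide_open_gates(c("FITC", "PE"))
  res <- apply_gates(ev, gates, refit_time_gate = FALSE)
  expect_equal(unname(res$channel_counts), c(400L, 400L))
  expect_equal(res$size_gated_count, 400L)
  expect_equal(res$retained_time, 120)
  # everything outside the size gate: all counts zero
  closed <- gates
  closed$size_gate <- structure(list(sals_max = -1, lals_max = -1),
                                class = "size_gate")
  res0 <- apply_gates(ev, closed, refit_time_gate = FALSE)
  expect_equal(unname(res0$channel_counts), c(0L, 0L))
  expect_error(apply_gates(ev, gates, channels = "APC"), "APC")
})

test_that("gated counts equal a brute-force triple filter", {
  set.seed(91)
  for (rep in 1:5) {
    ev <- make_events(n = 500)
    gates <- wide_open_gates(c("FITC", "PE", "APC"))
    gates$size_gate <- structure(
      list(sals_max = runif(1, 200, 900), lals_max = runif(1, 200, 900)),
      class = "size_gate")
    for (ch in names(gates$fluor_gates)) {
      gates$fluor_gates[[ch]]$threshold <- runif(1, 100, 900)
    }
    gates$time_gate <- structure(
      list(bin_width = 1, k = 5, counts = integer(120),
           excluded_bins = cbind(start = c(10, 50), end = c(20, 55)),
           retained_time = 105),
      class = "time_gate")
    got <- apply_gates(ev, gates, refit_time_gate = FALSE)
    want <- brute_gate_counts(
      as.data.frame(ev), gates$time_gate$excluded_bins,
      gates$size_gate$sals_max, gates$size_gate$lals_max,
      vapply(gates$fluor_gates, `[[`, 1, "threshold"))
    expect_identical(got$channel_counts, want$channel_counts)
    expect_equal(got$size_gated_count, want$size_gated_count)
  }
})

test_that("gated counts are monotone in events and thresholds", {
  ev <- make_events(n = 300, seed = 92)
  more <- make_events(n = 400, seed = 93)
  gates <- wide_open_gates("FITC")
  gates$size_gate <- structure(list(sals_max = 600, lals_max = 600),
                               class = "size_gate")
  gates$fluor_gates$FITC$threshold <- 500
  both <- evgate:::bind_events(list(ev, more))
  c1 <- apply_gates(ev, gates, refit_time_gate = FALSE)$channel_counts
  c2 <- apply_gates(both, gates, refit_time_gate = FALSE)$channel_counts
  expect_gte(c2, c1)
  tighter <- gates
  tighter$fluor_gates$FITC$threshold <- 700
  tighter$size_gate$sals_max <- 400
  c3 <- apply_gates(ev, tighter, refit_time_gate = FALSE)$channel_counts
  expect_lte(c3, c1)
})

test_that("gate sets serialize to JSON with provenance", {
  gates <- wide_open_gates("FITC")
  gates$provenance <- list(panel = "P1")
  path <- tempfile(fileext = ".json")
  write_gates_json(gates, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$fluor_gates$FITC$threshold, 0)
  expect_equal(parsed$provenance$panel, "P1")
  unlink(path)
})
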