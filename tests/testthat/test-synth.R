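one_pop <- function(conc = 1000, corr = 0.6) {
  population_spec(
    "agg", conc,
    scatter = list(SALS = c(log(600), 1), MALS = c(log(400), 1),
                   LALS = c(log(180), 1)),
    fluor = list(FITC = c(log(3000), 1)),
    scatter_fluor_corr = corr, aggregate = TRUE)
}

test_that("event counts are Poisson(concentration x acquired volume)", {
  # 1000/uL x 0.75 uL/min x 120 s / 60 = Poisson(1500); with no trigger the
  # mean count over 200 seeds must lie within 3 sd of the mean of 1500.
  counts <- vapply(1:200, function(s) {
    cfg <- acquisition_config(trigger_threshold = 0, seed = s)
    nrow(simulate_sample(list(one_pop()), cfg))
  }, 1L)
  expect_lt(abs(mean(counts) - 1500), 3 * sqrt(1500 / 200))
  # chi-square goodness of fit against the exact Poisson pmf at small lambda
  lam <- 10 * 0.75 * 120 / 60  # 15
  small <- vapply(1:200, function(s) {
    cfg <- acquisition_config(trigger_threshold = 0, seed = 1000 + s)
    nrow(simulate_sample(list(one_pop(conc = 10)), cfg))
  }, 1L)
  breaks <- c(-Inf, 10:20, Inf)
  probs <- diff(ppois(c(breaks[1], 10:20, Inf), lam))
  obs <- table(cut(small, breaks))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("degenerate simulation inputs behave as contracted", {
  cfg <- acquisition_config(trigger_threshold = 0, seed = 1)
  expect_error(simulate_sample(list(), cfg), "at least one population")
  expect_error(simulate_sample(list(one_pop()),
                               acquisition_config(seed = NULL)), "seed")
  ev0 <- simulate_sample(list(one_pop(conc = 0)), cfg)
  expect_equal(nrow(ev0), 0L)
  evinf <- simulate_sample(
    list(one_pop()), acquisition_config(trigger_threshold = Inf, seed = 1))
  expect_equal(nrow(evinf), 0L)
})

test_that("channel marginals match the specified log-normals", {
  # identity spillover, trigger 0: each channel is exactly log-normal
  cfg <- acquisition_config(trigger_threshold = 0, seed = 99)
  pop <- one_pop(conc = 7000)  # ~1e4 events
  ev <- simulate_sample(list(pop), cfg)
  expect_gt(nrow(ev), 9000)
  expect_gt(ks.test(log(ev$SALS), "pnorm", log(600), 1)$p.value, 0.01)
  expect_gt(ks.test(log(ev$FITC), "pnorm", log(3000), 1)$p.value, 0.01)
  # the latent size factor couples scatter and fluorescence at the set level
  expect_equal(cor(log(ev$SALS), log(ev$FITC)), 0.6, tolerance = 0.05)
})

test_that("simulation is reproducible and records ground-truth counts", {
  cfg <- acquisition_config(seed = 5)
  a <- simulate_sample(list(one_pop()), cfg)
  b <- simulate_sample(list(one_pop()), cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(event_populations(a), event_populations(b))
  cts <- acq_meta(a)$counts
  expect_equal(cts$population, "agg")
  expect_equal(cts$n_triggered, nrow(a))
  expect_true(cts$n_generated >= cts$n_triggered)
})

test_that("unstained-buffer background stays under 100 events per second", {
  rates <- vapply(1:20, function(s) {
    bg <- simulate_background(acquisition_config(seed = s))
    nrow(bg) / acq_meta(bg)$duration
  }, 1)
  expect_true(all(rates < 100))
  # with no trigger the rate equals the untruncated Poisson arrival rate
  cfg0 <- acquisition_config(trigger_threshold = 0, seed = 3)
  bg0 <- simulate_background(cfg0)
  lam <- 40000 * 0.75 * 120 / 60
  expect_lt(abs(nrow(bg0) - lam), 4 * sqrt(lam))
})

test_that("bead reference is abundant and well separated from the noise floor", {
  bead <- simulate_bead_reference(acquisition_config(seed = 11))
  pops <- event_populations(bead)
  expect_gte(sum(pops == "bead"), 500)
  sep_sals <- median(bead$SALS[pops == "bead"]) /
    median(bead$SALS[pops == "noise_floor"])
  sep_lals <- median(bead$LALS[pops == "bead"]) /
    median(bead$LALS[pops == "noise_floor"])
  expect_gte(sep_sals, 10)
  expect_gte(sep_lals, 10)
  # without the bead population, size-gate calibration fails loudly
  noise_only <- simulate_sample(default_bead_populations()["noise_floor"],
                                acquisition_config(seed = 12))
  bg <- simulate_background(acquisition_config(seed = 13))
  expect_error(fit_size_gate(noise_only, noise_events = bg),
               "size-gate calibration failed")
})

test_that("erratic segments multiply the local event rate and are recorded", {
  bg <- simulate_background(acquisition_config(seed = 21))
  noop <- inject_erratic_segments(bg, list(c(50, 60, 1)))
  expect_equal(as.data.frame(noop), as.data.frame(bg), ignore_attr = TRUE)
  expect_equal(nrow(noop), nrow(bg))
  set.seed(22)
  burst <- inject_erratic_segments(bg, list(c(50, 60, 10)))
  expect_equal(unname(attr(burst, "erratic_segments")[1, 1:2]), c(50, 60))
  per_sec <- table(cut(burst$time, 0:120))
  inside <- per_sec[51:60]
  outside <- median(per_sec[-(51:60)])
  expect_true(all(inside > 3 * outside))
  expect_error(
    inject_erratic_segments(bg, list(c(10, 30, 2), c(20, 40, 2))),
    "overlap")
  expect_error(inject_erratic_segments(bg, list(c(110, 130, 2))),
               "duration")
  expect_error(inject_erratic_segments(bg, list(c(10, 20, 0.5))),
               "multiplier")
})

test_that("experiment grid, reproducibility and untreated ground truth", {
  design <- default_design()
  expect_equal(nrow(design), 2 * 2 * 6 * 5)
  cfg <- acquisition_config(seed = 31)
  ex <- simulate_experiment(design = default_design(replicates = 1),
                            config = cfg)
  ex2 <- simulate_experiment(design = default_design(replicates = 1),
                             config = cfg)
  expect_identical(as.data.frame(ex$samples[[3]]$events),
                   as.data.frame(ex2$samples[[3]]$events))
  expect_identical(ex$truth, ex2$truth)
  u <- ex$truth[ex$truth$treatment == "U", ]
  expect_equal(u$concentration_post, u$concentration_pre)
  expect_true(all(u$removal_fraction == 0))
  expect_error(
    simulate_experiment(design = data.frame(panel = "P1", arm = "specific",
                                            treatment = "X", replicate = 1),
                        config = cfg),
    "unknown treatment")
})

test_that("fully size-selective removal lowers the surviving scatter", {
  design <- data.frame(panel = "P2", arm = "specific",
                       treatment = c("U", "F"), replicate = 1)
  models <- list(U = treatment_model("U", 0),
                 F = treatment_model("F", 0.5, 0, 1))
  ex <- simulate_experiment(design, models,
                            config = acquisition_config(seed = 41),
                            replicate_cv = 0)
  agg_sals <- function(s) {
    ev <- s$events
    log(ev$SALS[grepl("^agg_", event_populations(ev))])
  }
  med_u <- median(agg_sals(ex$samples[[which(design$treatment == "U")]]))
  med_f <- median(agg_sals(ex$samples[[which(design$treatment == "F")]]))
  expect_lt(med_f, med_u)
  f_truth <- ex$truth[ex$truth$treatment == "F", ]
  expect_true(all(f_truth$removal_fraction == 0.5))
})
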