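test_that("simulation is bit-identical under a fixed seed", {
  cfg <- synth_config(n_events = 2000L, seed = 123)
  a <- simulate_culture(cfg)
  b <- simulate_culture(cfg)
  expect_identical(a$table$events, b$table$events)
  expect_identical(a$labels, b$labels)
  expect_identical(a$doublet, b$doublet)
  c_ <- simulate_culture(synth_config(n_events = 2000L, seed = 124))
  expect_false(identical(a$table$events, c_$table$events))
})

test_that("per-label counts follow the multinomial bound", {
  props <- c(vegetative = 0.2, endospore = 0.3, spore = 0.5)
  n <- 100000L
  sim <- simulate_culture(synth_config(default_populations(props),
                                       n_events = n, doublet_rate = 0,
                                       seed = 9))
  counts <- table(sim$labels)
  for (l in names(props)) {
    p <- props[[l]]
    expect_lt(abs(counts[[l]] - n * p), 3 * sqrt(n * p * (1 - p)))
  }
})

test_that("doublet_rate = 0 yields no doublet flags; doublets inflate widths", {
  clean <- simulate_culture(synth_config(n_events = 1000L,
                                         doublet_rate = 0, seed = 1))
  expect_false(any(clean$doublet))

  sim <- simulate_culture(synth_config(n_events = 20000L,
                                       doublet_rate = 0.05,
                                       width_inflation = 2, seed = 2))
  expect_gt(sum(sim$doublet), 0)
  w_doub <- channel_values(sim$table, "SSC-W")[sim$doublet]
  w_sing <- channel_values(sim$table, "SSC-W")[!sim$doublet]
  # 2x width inflation: doublet widths sit far above the singlet band
  expect_gt(median(w_doub) / median(w_sing), 1.8)
  a_doub <- channel_values(sim$table, "FL1-A")[sim$doublet]
  expect_gt(median(a_doub), median(channel_values(sim$table,
                                                  "FL1-A")[!sim$doublet]))
})

test_that("per-population log-scale channel means match the spec within 3 SE", {
  pops <- default_populations()
  sim <- simulate_culture(synth_config(pops, n_events = 10000L,
                                       doublet_rate = 0, seed = 5))
  for (p in pops) {
    idx <- sim$labels == p$label
    for (ch in c("FSC-A", "SSC-A", "FL1-A", "SSC-W")) {
      lx <- log(channel_values(sim$table, ch)[idx])
      se <- p$log_sds[[ch]] / sqrt(sum(idx))
      expect_lt(abs(mean(lx) - p$log_means[[ch]]), 3 * se)
    }
  }
})

test_that("asinh-transformed populations are near-normal (small excess kurtosis)", {
  sim <- simulate_culture(synth_config(n_events = 10000L, doublet_rate = 0,
                                       seed = 6))
  tb <- asinh_transform(sim$table, default_transform())
  for (l in population_labels()) {
    idx <- sim$labels == l
    for (ch in c("SSC-A", "FL1-A")) {
      x <- channel_values(tb, ch)[idx]
      z <- (x - mean(x)) / stats::sd(x)
      kurt <- mean(z^4) - 3
      expect_lt(abs(kurt), 0.5)
    }
  }
})

test_that("invalid configurations are rejected", {
  pops <- default_populations(c(vegetative = 0.5, endospore = 0.4,
                                spore = 0.2))  # sums to 1.1
  expect_error(synth_config(pops), "sum to 1")
  expect_error(synth_config(doublet_rate = 1), "doublet_rate")
  expect_error(synth_config(width_inflation = 1), "width_inflation")
  expect_error(population_spec("spore", 0.5, c(a = 1), c(b = 1)),
               "same channels")
  expect_error(population_spec("spore", 0.5, c(a = 1), c(a = -1)),
               "positive")
})

test_that("a length-1 schedule reproduces simulate_culture with the derived seed", {
  base <- synth_config(n_events = 500L, seed = 77, sample_id = "tc")
  schedule <- data.frame(time_h = 48, p_vegetative = 0.2,
                         p_endospore = 0.3, p_spore = 0.5)
  tc <- simulate_timecourse(base, schedule)
  expect_length(tc, 1)
  expect_equal(tc[[1]]$table$metadata$time_h, 48)
  expect_equal(n_events(tc[[1]]$table), 500)
  # same draw as a directly-configured culture with the derived seed
  direct <- simulate_culture(synth_config(n_events = 500L,
                                          seed = sporegate:::derive_seed(77, 1),
                                          sample_id = "tc_t01",
                                          time_h = 48))
  expect_identical(tc[[1]]$table$events, direct$table$events)
})

test_that("a spore ramp has strictly increasing truth counts and distinct replicates", {
  base <- synth_config(n_events = 2000L, doublet_rate = 0, seed = 88)
  ramp <- seq(0.1, 0.9, length.out = 5)
  schedule <- data.frame(time_h = 1:5, p_vegetative = (1 - ramp) / 2,
                         p_endospore = (1 - ramp) / 2, p_spore = ramp)
  tc <- simulate_timecourse(base, schedule)
  spore_counts <- vapply(tc, function(s) sum(s$labels == "spore"), 0L)
  expect_true(all(diff(spore_counts) > 0))

  reps <- lapply(1:3, function(r) {
    simulate_culture(synth_config(n_events = 5000L, seed = 88 + r))
  })
  expect_false(identical(reps[[1]]$table$events, reps[[2]]$table$events))
  for (s in reps) {
    expect_lt(abs(mean(s$labels == "spore") - 0.5), 0.03)
  }
  bad <- data.frame(time_h = 1, p_vegetative = 0.5, p_endospore = 0.5,
                    p_spore = 0.5)
  expect_error(simulate_timecourse(base, bad), "sum to")
})
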