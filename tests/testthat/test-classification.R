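# A hand-built classifier with unit covariances at known centers, for
# exact geometric checks of the assignment rules.
make_classifier <- function(centers, labels, weights = rep(1 / 3, 3),
                            dims = c("SSC-A", "FL1-A"),
                            rule = "euclidean") {
  structure(list(
    model = structure(list(g = 3L, d = 2L, weights = weights,
                           means = centers,
                           covariances = replicate(3, diag(2),
                                                   simplify = FALSE),
                           log_likelihood = NA_real_, trace = numeric(0),
                           n_iter = 0L, converged = TRUE, dims = dims,
                           n = 0L, init = "manual"),
                      class = "gmm"),
    label_map = labels, dims = dims, rule = rule),
    class = "reference_classifier")
}

sim_transformed <- function(n, seed, doublet_rate = 0,
                            proportions = c(vegetative = 0.2,
                                            endospore = 0.3, spore = 0.5)) {
  cfg <- if (doublet_rate > 0) {
    synth_config(default_populations(proportions), n_events = n,
                 doublet_rate = doublet_rate, seed = seed)
  } else {
    # doublet_rate = 0 is expressed via the rate argument
    synth_config(default_populations(proportions), n_events = n,
                 doublet_rate = 0, seed = seed)
  }
  sim <- simulate_culture(cfg)
  sim$table <- asinh_transform(sim$table, default_transform())
  sim
}

test_that("the reference fit recovers generator centers and maps labels correctly", {
  sim <- sim_transformed(5000, seed = 21)
  ref <- fit_reference(sim$table, seed = 2)
  truth <- default_truth_centers()
  # each biological label's fitted center is close to its generator truth
  for (i in seq_len(3)) {
    lab <- population_labels()[i]
    k <- which(ref$label_map == lab)
    expect_length(k, 1)
    expect_lt(max(abs(ref$model$means[k, ] - truth[i, ])), 0.2)
  }
})

test_that("small references and ambiguous label maps are rejected", {
  sim <- sim_transformed(100, seed = 3)
  expect_error(fit_reference(sim$table), "at least 300")
  big <- sim_transformed(1000, seed = 4)
  expect_error(fit_reference(big$table, dims = c("SSC-A", "FSC-A")),
               "fluorescence")
})

test_that("a reference fit is unchanged by permuting the input rows", {
  sim <- sim_transformed(3000, seed = 5)
  ref1 <- fit_reference(sim$table, seed = 9)
  shuffled <- subset_events(sim$table,
                            sample(seq_len(n_events(sim$table))))
  ref2 <- fit_reference(shuffled, seed = 9)
  expect_identical(ref1$label_map, ref2$label_map)
  expect_equal(ref1$model$means, ref2$model$means, tolerance = 1e-6)
  expect_equal(ref1$model$weights, ref2$model$weights, tolerance = 1e-6)
})

test_that("assignment geometry: exact centers, tie-breaks, both rules", {
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4))
  cl <- make_classifier(centers, c("spore", "endospore", "vegetative"))
  at_centers <- event_table(centers, c("SSC-A", "FL1-A"))
  expect_equal(as.character(assign_labels(cl, at_centers)),
               c("spore", "endospore", "vegetative"))
  # equidistant from clusters 1 and 2 -> lowest index wins
  tie <- event_table(matrix(c(2, 0), 1, 2), c("SSC-A", "FL1-A"))
  expect_equal(as.character(assign_labels(cl, tie)), "spore")
  # with equal weights and unit covariances the posterior rule agrees
  pts <- event_table(matrix(runif(40, -1, 5), 20, 2), c("SSC-A", "FL1-A"))
  expect_identical(assign_labels(cl, pts, rule = "euclidean"),
                   assign_labels(cl, pts, rule = "posterior"))
  missing_dims <- event_table(matrix(1, 1, 1), "FSC-A")
  expect_error(assign_labels(cl, missing_dims), "unknown channel")
})

test_that("label transfer agrees with generator truth on well-separated data", {
  sim <- sim_transformed(10000, seed = 6)
  ref <- fit_reference(sim$table, seed = 1)
  lab <- assign_labels(ref, sim$table)
  expect_gt(mean(as.character(lab) == as.character(sim$labels)), 0.95)
})

test_that("posterior-rule transfer on the reference reproduces the mixture's own hard assignment", {
  sim <- sim_transformed(2000, seed = 7)
  ref <- fit_reference(sim$table, seed = 1, rule = "posterior")
  lab <- assign_labels(ref, sim$table)
  x <- channel_values(sim$table, ref$dims, drop = FALSE)
  hard <- max.col(gmm_posterior(ref$model, x), ties.method = "first")
  expect_identical(as.character(lab), ref$label_map[hard])
})

test_that("population fractions are exact arithmetic with zero-filled labels", {
  pf <- population_fractions(c("spore", "spore", "vegetative", "endospore"),
                             "s")
  expect_equal(pf$fractions,
               c(vegetative = 0.25, endospore = 0.25, spore = 0.5))
  expect_equal(sum(pf$counts), pf$n_total)
  all_one <- population_fractions(rep("spore", 10))
  expect_equal(all_one$fractions[["spore"]], 1)
  expect_equal(all_one$counts[["vegetative"]], 0L)
  expect_error(population_fractions(character(0)), "nonempty")
  expect_error(population_fractions(c("spore", "junk")), "labels must be")
})

test_that("fractions are invariant to event order and whole-set duplication", {
  labs <- sample(population_labels(), 500, replace = TRUE,
                 prob = c(0.2, 0.3, 0.5))
  base <- population_fractions(labs)
  expect_equal(population_fractions(rev(labs))$fractions, base$fractions)
  expect_equal(population_fractions(c(labs, labs))$fractions,
               base$fractions)
})

test_that("a time course reuses one classifier and tracks a monotone spore ramp", {
  ref_sim <- sim_transformed(5000, seed = 30)
  ref <- fit_reference(ref_sim$table, seed = 1)

  # single sample: identical to population_fractions on its labels
  tab1 <- timecourse_report(ref_sim$table, ref)
  pf <- population_fractions(assign_labels(ref, ref_sim$table),
                             ref_sim$table$metadata$sample_id)
  expect_equal(tab1$frac_spore, pf$fractions[["spore"]])
  expect_equal(tab1$n_total, pf$n_total)

  base <- synth_config(n_events = 10000L, doublet_rate = 0, seed = 31)
  ramp <- seq(0.1, 0.9, length.out = 5)
  schedule <- data.frame(time_h = c(48, 56, 72, 80, 96),
                         p_vegetative = (1 - ramp) / 2,
                         p_endospore = (1 - ramp) / 2,
                         p_spore = ramp)
  sims <- simulate_timecourse(base, schedule)
  tables <- lapply(sims, function(s) {
    asinh_transform(s$table, default_transform())
  })
  tab <- timecourse_report(tables, ref)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$time_h, schedule$time_h)
  expect_true(all(diff(tab$frac_spore) >= 0))
  expect_equal(tab$frac_vegetative + tab$frac_endospore + tab$frac_spore,
               rep(1, 5), tolerance = 1e-9)
})

test_that("replicate fractions vary only by sampling noise", {
  ref <- fit_reference(sim_transformed(5000, seed = 40)$table, seed = 1)
  fr <- vapply(1:3, function(r) {
    s <- sim_transformed(20000, seed = 40 + r)
    timecourse_report(s$table, ref)$frac_spore
  }, 0)
  expect_lt(stats::sd(fr), 0.02)
})

test_that("classifiers roundtrip through JSON", {
  sim <- sim_transformed(2000, seed = 50)
  ref <- fit_reference(sim$table, seed = 1)
  back <- classifier_from_json(classifier_to_json(ref))
  expect_identical(back$label_map, ref$label_map)
  expect_equal(back$model$means, ref$model$means, ignore_attr = TRUE)
  expect_identical(as.character(assign_labels(back, sim$table)),
                   as.character(assign_labels(ref, sim$table)))
})
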