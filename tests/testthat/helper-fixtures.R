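# Fixtures built in code: hand-constructed mixture models and small
# synthetic cultures used across the test files.

# Construct a univariate gmm object with known parameters, bypassing EM,
# so formula-level behaviour can be tested in isolation. Components are
# given sorted by mean, matching the fitted convention.
make_gmm1d <- function(means, sds, weights = rep(1 / length(means),
                                                 length(means)),
                       dims = "FL1-A") {
  ord <- order(means)
  structure(list(g = length(means), d = 1L,
                 weights = weights[ord],
                 means = matrix(means[ord], ncol = 1),
                 covariances = lapply(sds[ord]^2, function(v) {
                   matrix(v, 1, 1)
                 }),
                 log_likelihood = NA_real_, trace = numeric(0),
                 n_iter = 0L, converged = TRUE, dims = dims,
                 n = 0L, init = "manual"),
            class = "gmm")
}

# A two-population (cells + spores) culture with a configurable FL1
# separation in pooled SDs on the asinh scale.
two_pop_config <- function(n_events, sep_sds = 4, seed = 1,
                           doublet_rate = 0.05) {
  pops <- default_populations(c(vegetative = 0.5, endospore = 0,
                                spore = 0.5))
  # default FL1 log-sd is 0.25 for both populations
  pops[[3]]$log_means["FL1-A"] <- pops[[1]]$log_means["FL1-A"] -
    sep_sds * 0.25
  synth_config(populations = pops, n_events = n_events,
               doublet_rate = doublet_rate, seed = seed)
}

# Truth asinh-scale (cofactor 1) cluster centers of the default
# generator preset: asinh(exp(m + s z)) ~ m + log 2 for signals >> 1.
default_truth_centers <- function(dims = c("SSC-A", "FL1-A")) {
  pops <- default_populations()
  t(vapply(pops, function(p) p$log_means[dims] + log(2),
           numeric(length(dims))))
}

# Write a strains x times x replicates synthetic experiment to disk and
# return the sample sheet (data.frame).
write_synthetic_experiment <- function(dir, strains = c("A", "B"),
                                       times = c(48, 56, 72, 80, 96),
                                       replicates = 1:3,
                                       n_events = 2000, seed = 99) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  i <- 0L
  for (s in strains) for (t in times) for (r in replicates) {
    i <- i + 1L
    spore_frac <- 0.2 + 0.6 * (t - min(times)) / diff(range(times))
    props <- c(vegetative = (1 - spore_frac) * 0.4,
               endospore = (1 - spore_frac) * 0.6,
               spore = spore_frac)
    sid <- sprintf("%s_t%d_r%d", s, t, r)
    cfg <- synth_config(populations = default_populations(props),
                        n_events = n_events, seed = seed + i,
                        sample_id = sid, strain = s, time_h = t,
                        replicate = r)
    sim <- simulate_culture(cfg)
    path <- file.path(dir, paste0(sid, ".fcs"))
    write_fcs(sim$table, path)
    rows[[i]] <- data.frame(sample_id = sid, path = path, strain = s,
                            time_h = t, replicate = r,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
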