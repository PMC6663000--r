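#' Specification of one synthetic subpopulation
#'
#' Scatter and fluorescence pulse signals of a homogeneous cell
#' population are modelled as (correlated) log-normals: each channel
#' signal is `exp(m + s z)` with `z` standard normal, so that after the
#' asinh transform the population is near-normal with mean `~ m + log 2`
#' and standard deviation `~ s` (for signals well above the cofactor).
#'
#' @param label one of [population_labels()].
#' @param proportion expected fraction of events in `[0, 1]`.
#' @param log_means named numeric vector, natural-log mean of the raw
#'   signal per channel.
#' @param log_sds named numeric vector of positive log-scale standard
#'   deviations, same channels as `log_means`.
#' @return a `population_spec` object.
#' @export
population_spec <- function(label, proportion, log_means, log_sds) {
  label <- match.arg(label, population_labels())
  if (!is.numeric(proportion) || proportion < 0 || proportion > 1) {
    stopf("`proportion` must be in [0, 1]")
  }
  if (is.null(names(log_means)) || is.null(names(log_sds)) ||
        !setequal(names(log_means), names(log_sds))) {
    stopf("`log_means` and `log_sds` must be named with the same channels")
  }
  if (any(log_sds <= 0)) stopf("`log_sds` must all be positive")
  structure(list(label = label, proportion = as.double(proportion),
                 log_means = log_means, log_sds = log_sds[names(log_means)]),
            class = "population_spec")
}

#' Default synthetic subpopulations
#'
#' Encodes the qualitative ordering seen in sporulating nucleic-acid
#' stained cultures: the three populations differ strongly in
#' fluorescence (spores are dim because the coat/cortex blocks dye
#' uptake), somewhat in side scatter (the developing coat raises the
#' granularity of endospore-containing mother cells) and little in
#' forward scatter. Absolute values are generator constants, not claims
#' about any particular instrument. Height channels are given a larger
#' within-population spread than areas (pulse-peak detection is
#' noisier than integration), and widths are population-independent
#' transit times shared between the two detectors — which keeps the
#' height/width singlet-gating clouds elliptical and unimodal, the
#' regime the robust gate is designed for.
#'
#' On the asinh (cofactor 1) scale the defaults give pooled-SD
#' separations of about 5.7 between vegetative and endospore (carried
#' by SSC-A), 12.6 between vegetative and spore and 11.3 between
#' endospore and spore (carried by FL1-A) in the default
#' `(SSC-A, FL1-A)` feature space.
#'
#' @param proportions named numeric vector over [population_labels()],
#'   summing to 1 (default `c(0.2, 0.3, 0.5)`).
#' @return list of three [population_spec]s.
#' @export
default_populations <- function(proportions = c(vegetative = 0.2,
                                                endospore = 0.3,
                                                spore = 0.5)) {
  lv <- population_labels()
  if (is.null(names(proportions)) || !setequal(names(proportions), lv)) {
    stopf("`proportions` must be named over: %s", paste(lv, collapse = ", "))
  }
  mu <- list(
    vegetative = c("FSC-A" = 9.0, "FSC-H" = 8.6, "FSC-W" = 4.38,
                   "SSC-A" = 8.2, "SSC-H" = 9.00, "SSC-W" = 4.38,
                   "FL1-A" = 9.8),
    endospore  = c("FSC-A" = 9.3, "FSC-H" = 8.8, "FSC-W" = 4.38,
                   "SSC-A" = 9.6, "SSC-H" = 9.40, "SSC-W" = 4.38,
                   "FL1-A" = 9.6),
    spore      = c("FSC-A" = 8.9, "FSC-H" = 8.5, "FSC-W" = 4.38,
                   "SSC-A" = 9.2, "SSC-H" = 9.25, "SSC-W" = 4.38,
                   "FL1-A" = 6.8))
  sds <- c("FSC-A" = 0.30, "FSC-H" = 0.45, "FSC-W" = 0.06,
           "SSC-A" = 0.25, "SSC-H" = 0.50, "SSC-W" = 0.06,
           "FL1-A" = 0.25)
  lapply(lv, function(l) {
    population_spec(l, proportions[[l]], mu[[l]], sds)
  })
}

#' Default log-scale channel correlations
#'
#' Within a population: area and height of the same scatter signal are
#' positively correlated (same underlying pulse, correlation 0.6), and
#' the two width channels are nearly the same transit time measured on
#' two detectors (correlation 0.9). Everything else is independent.
#'
#' @param channels character vector of channel names.
#' @return a positive-definite correlation matrix.
#' @export
default_channel_correlations <- function(channels) {
  m <- diag(length(channels))
  dimnames(m) <- list(channels, channels)
  set_cor <- function(a, b, r) {
    if (all(c(a, b) %in% channels)) {
      m[a, b] <<- r; m[b, a] <<- r
    }
  }
  set_cor("FSC-A", "FSC-H", 0.6)
  set_cor("SSC-A", "SSC-H", 0.6)
  set_cor("FSC-W", "SSC-W", 0.9)
  m
}

#' Configuration for one synthetic culture
#'
#' @param populations list of [population_spec]s whose proportions sum
#'   to 1 (default [default_populations()]).
#' @param n_events number of events to draw (default 10000).
#' @param doublet_rate fraction of events that are agglomerates, in
#'   `[0, 1)` (default 0.05).
#' @param width_inflation factor (> 1) applied to the width channels of
#'   doublets (default 2).
#' @param seed integer seed; same config + seed gives bit-identical
#'   output.
#' @param channel_correlations log-scale correlation matrix; default
#'   [default_channel_correlations()] on the populations' channels.
#' @param sample_id,strain,time_h,replicate metadata carried into the
#'   generated table.
#' @return a `synth_config` object.
#' @export
synth_config <- function(populations = default_populations(),
                         n_events = 10000L, doublet_rate = 0.05,
                         width_inflation = 2, seed = 1L,
                         channel_correlations = NULL,
                         sample_id = "synthetic", strain = NA_character_,
                         time_h = NA_real_, replicate = NA) {
  if (!length(populations) ||
        !all(vapply(populations, inherits, TRUE, "population_spec"))) {
    stopf("`populations` must be a list of population_spec objects")
  }
  props <- vapply(populations, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-9) {
    stopf("population proportions must sum to 1 (got %.12g)", sum(props))
  }
  if (n_events < 0) stopf("`n_events` must be >= 0")
  if (doublet_rate < 0 || doublet_rate >= 1) {
    stopf("`doublet_rate` must be in [0, 1)")
  }
  if (width_inflation <= 1) stopf("`width_inflation` must be > 1")
  channels <- names(populations[[1]]$log_means)
  for (p in populations) {
    if (!setequal(names(p$log_means), channels)) {
      stopf("all populations must use the same channels")
    }
  }
  if (is.null(channel_correlations)) {
    channel_correlations <- default_channel_correlations(channels)
  }
  ev <- eigen(channel_correlations, symmetric = TRUE, only.values = TRUE)
  if (min(ev$values) < -1e-10) {
    stopf("`channel_correlations` must be positive semi-definite")
  }
  structure(list(populations = populations,
                 n_events = as.integer(n_events),
                 doublet_rate = doublet_rate,
                 width_inflation = width_inflation,
                 seed = as.integer(seed),
                 channels = channels,
                 channel_correlations = channel_correlations,
                 sample_id = sample_id, strain = strain,
                 time_h = time_h, replicate = replicate),
            class = "synth_config")
}

#' Simulate one synthetic culture
#'
#' Draws event counts per population multinomially from the configured
#' proportions, generates correlated log-normal channel signals per
#' population, and converts a `doublet_rate` fraction of events into
#' agglomerates by summing the area/height signals of two random
#' singlet draws and inflating the width channels by
#' `width_inflation`. Ground-truth labels and doublet flags are
#' returned alongside the raw (untransformed) event table.
#'
#' @param config a [synth_config].
#' @return list with `table` (raw [event_table]), `labels` (factor,
#'   one per event; doublets keep their primary parent's label) and
#'   `doublet` (logical vector of truth flags).
#' @export
simulate_culture <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  chs <- config$channels
  n <- config$n_events
  if (n == 0L) {
    return(list(table = event_table(matrix(numeric(0), 0, length(chs)), chs,
                                    synth_metadata(config)),
                labels = factor(character(0), population_labels()),
                doublet = logical(0)))
  }
  with_seed(config$seed, {
    props <- vapply(config$populations, `[[`, 0, "proportion")
    counts <- as.vector(stats::rmultinom(1, n, props))
    raw <- matrix(0, n, length(chs), dimnames = list(NULL, chs))
    labels <- character(n)
    chol_r <- chol(config$channel_correlations +
                     diag(1e-10, length(chs)))
    row0 <- 0L
    for (i in seq_along(config$populations)) {
      k <- counts[i]
      if (k == 0L) next
      p <- config$populations[[i]]
      z <- matrix(stats::rnorm(k * length(chs)), k) %*% chol_r
      logx <- sweep(sweep(z, 2, p$log_sds[chs], `*`), 2,
                    p$log_means[chs], `+`)
      raw[row0 + seq_len(k), ] <- exp(logx)
      labels[row0 + seq_len(k)] <- p$label
      row0 <- row0 + k
    }
    ord <- sample.int(n)
    raw <- raw[ord, , drop = FALSE]
    labels <- labels[ord]

    doublet <- rep(FALSE, n)
    n_doub <- stats::rbinom(1, n, config$doublet_rate)
    if (n_doub > 0) {
      singlet_pool <- raw  # parents are drawn from the unmodified singlets
      idx <- sample.int(n, n_doub)
      partner <- sample.int(n, n_doub, replace = TRUE)
      w_ch <- grepl("-W$", chs)
      ah_ch <- !w_ch
      raw[idx, ah_ch] <- singlet_pool[idx, ah_ch, drop = FALSE] +
        singlet_pool[partner, ah_ch, drop = FALSE]
      raw[idx, w_ch] <- config$width_inflation *
        (singlet_pool[idx, w_ch, drop = FALSE] +
           singlet_pool[partner, w_ch, drop = FALSE]) / 2
      doublet[idx] <- TRUE
    }
    list(table = event_table(raw, chs, synth_metadata(config)),
         labels = factor(labels, population_labels()),
         doublet = doublet)
  })
}

#' Simulate a sporulation time course
#'
#' One synthetic sample per schedule row, with the population
#' proportions of the base configuration replaced by the scheduled
#' ones and per-sample seeds derived deterministically from the base
#' seed and the row index.
#'
#' @param base a [synth_config] used as template.
#' @param schedule data.frame with columns `time_h`, `p_vegetative`,
#'   `p_endospore`, `p_spore`; each proportion triple must sum to 1.
#' @return list of [simulate_culture()] results, one per row, with
#'   `time_h` and a derived `sample_id` in the metadata.
#' @export
simulate_timecourse <- function(base, schedule) {
  stopifnot(inherits(base, "synth_config"))
  need <- c("time_h", "p_vegetative", "p_endospore", "p_spore")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule))) {
    stopf("`schedule` must be a data.frame with columns: %s",
          paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(schedule)), function(i) {
    row <- schedule[i, ]
    props <- c(vegetative = row$p_vegetative, endospore = row$p_endospore,
               spore = row$p_spore)
    if (abs(sum(props) - 1) > 1e-9) {
      stopf("schedule row %d proportions sum to %.12g, not 1", i, sum(props))
    }
    pops <- lapply(base$populations, function(p) {
      population_spec(p$label, props[[p$label]], p$log_means, p$log_sds)
    })
    cfg <- synth_config(populations = pops, n_events = base$n_events,
                        doublet_rate = base$doublet_rate,
                        width_inflation = base$width_inflation,
                        seed = derive_seed(base$seed, i),
                        channel_correlations = base$channel_correlations,
                        sample_id = sprintf("%s_t%02d", base$sample_id, i),
                        strain = base$strain, time_h = row$time_h,
                        replicate = base$replicate)
    simulate_culture(cfg)
  })
}

# -- internal ---------------------------------------------------------------

synth_metadata <- function(config) {
  list(sample_id = config$sample_id, strain = config$strain,
       time_h = config$time_h, replicate = config$replicate)
}
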