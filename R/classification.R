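#' Population labels used throughout the pipeline
#'
#' @return character vector `c("vegetative", "endospore", "spore")`.
#' @export
population_labels <- function() c("vegetative", "endospore", "spore")

#' Fit the three-population reference classifier
#'
#' Fits a `g = 3` Gaussian mixture on a reference sample known to
#' contain all three sporulation subpopulations, then names the
#' clusters using the staining mechanism: the dye stains nucleic acids,
#' and the finished spore's coat/cortex blocks dye uptake, so the
#' cluster with the *lowest* fluorescence mean is the free **spore**
#' population; of the two bright clusters, the developing coat inside
#' the mother cell raises granularity, so the one with the *higher*
#' side-scatter mean is the **endospore**-containing mother cell, and
#' the remaining cluster is the **vegetative** cell population.
#'
#' The classifier is fitted once per experiment set and reused for
#' every other sample (label transfer); see [assign_labels()] and
#' [timecourse_report()].
#'
#' @param table an [event_table], already asinh-transformed and
#'   singlet-gated, with at least `min_events` events.
#' @param dims channel names of the feature space (default
#'   `c("SSC-A", "FL1-A")`, the discriminating axes; forward scatter
#'   adds little and can be appended by the user).
#' @param seed integer seed for the mixture initialization.
#' @param rule default assignment rule for this classifier:
#'   `"euclidean"` (nearest component mean) or `"posterior"`
#'   (maximum-posterior component).
#' @param min_events minimum reference size (default 300).
#' @param fl_channel,ssc_channel channels used by the label-mapping
#'   rule; by default detected from `dims` by name (`"FL"` / `"SSC"`).
#' @return an object of class `reference_classifier`: `model` (the
#'   [gmm]), `label_map` (cluster index -> label), `dims`, `rule`.
#' @export
fit_reference <- function(table, dims = c("SSC-A", "FL1-A"), seed = 1L,
                          rule = c("euclidean", "posterior"),
                          min_events = 300L,
                          fl_channel = NULL, ssc_channel = NULL) {
  stopifnot(inherits(table, "event_table"))
  rule <- match.arg(rule)
  if (n_events(table) < min_events) {
    stopf("reference sample has %d events; at least %d are required",
          n_events(table), min_events)
  }
  x <- channel_values(table, dims, drop = FALSE)
  model <- fit_gmm(x, g = 3L, seed = seed, dims = dims)
  fl_channel <- fl_channel %||% dims[grepl("FL", dims)][1]
  ssc_channel <- ssc_channel %||% dims[grepl("SSC", dims)][1]
  if (is.na(fl_channel) || is.na(ssc_channel)) {
    stopf(paste0("cannot identify the fluorescence and side-scatter axes ",
                 "among dims (%s); pass fl_channel/ssc_channel explicitly"),
          paste(dims, collapse = ", "))
  }
  label_map <- map_cluster_labels(model, match(fl_channel, dims),
                                  match(ssc_channel, dims))
  small <- model$weights < 0.02
  if (any(small)) {
    warning(sprintf(
      "QC: fitted component weight(s) below 2%% (%s); the reference sample may not contain all three populations",
      paste(sprintf("%s=%.3f", label_map[small], model$weights[small]),
            collapse = ", ")), call. = FALSE)
  }
  structure(list(model = model, label_map = label_map, dims = dims,
                 rule = rule),
            class = "reference_classifier")
}

#' @export
print.reference_classifier <- function(x, ...) {
  cat(sprintf("<reference_classifier> dims = %s, rule = %s\n",
              paste(x$dims, collapse = " x "), x$rule))
  for (k in seq_len(3)) {
    cat(sprintf("  %-10s lambda=%.3f center=(%s)\n", x$label_map[k],
                x$model$weights[k],
                paste(signif(x$model$means[k, ], 5), collapse = ", ")))
  }
  invisible(x)
}

#' Transfer labels from a reference classifier to a sample
#'
#' Under the euclidean rule each event receives the label of the
#' nearest fitted component mean (l2-norm on the classifier's feature
#' channels); under the posterior rule, the label of the
#' maximum-posterior component. Ties go to the lowest cluster index.
#' The two rules agree when populations do not shift between samples.
#'
#' @param classifier a [fit_reference()] result.
#' @param table an [event_table] transformed on the same channels.
#' @param rule override the classifier's default rule.
#' @return factor of labels (levels [population_labels()]), one per
#'   event.
#' @export
assign_labels <- function(classifier, table, rule = NULL) {
  stopifnot(inherits(classifier, "reference_classifier"),
            inherits(table, "event_table"))
  rule <- rule %||% classifier$rule
  rule <- match.arg(rule, c("euclidean", "posterior"))
  x <- channel_values(table, classifier$dims, drop = FALSE)
  model <- classifier$model
  idx <- if (rule == "euclidean") {
    d2 <- sapply(seq_len(model$g), function(k) {
      rowSums(sweep(x, 2, model$means[k, ])^2)
    })
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
    max.col(-d2, ties.method = "first")
  } else {
    max.col(gmm_posterior(model, x), ties.method = "first")
  }
  factor(classifier$label_map[idx], levels = population_labels())
}

#' Tabulate population counts and fractions
#'
#' @param labels factor or character vector of per-event labels (from
#'   [assign_labels()]); must be nonempty, values restricted to
#'   [population_labels()].
#' @param sample_id sample identifier carried into the result.
#' @return an object of class `population_fractions`: `sample_id`,
#'   `counts` (named integer, zero for absent labels), `fractions`
#'   (`counts / n_total`), `n_total`.
#' @export
population_fractions <- function(labels, sample_id = NA_character_) {
  if (!length(labels)) stopf("`labels` must be nonempty")
  lv <- population_labels()
  if (!all(as.character(labels) %in% lv)) {
    stopf("labels must be among: %s", paste(lv, collapse = ", "))
  }
  labels <- factor(as.character(labels), levels = lv)
  counts <- table(labels)
  n <- length(labels)
  structure(list(sample_id = sample_id,
                 counts = stats::setNames(as.integer(counts), lv),
                 fractions = stats::setNames(as.numeric(counts) / n, lv),
                 n_total = n),
            class = "population_fractions")
}

#' @export
print.population_fractions <- function(x, ...) {
  cat(sprintf("<population_fractions> %s (n=%d)\n",
              x$sample_id, x$n_total))
  for (l in names(x$counts)) {
    cat(sprintf("  %-10s %8d  (%.1f%%)\n", l, x$counts[[l]],
                100 * x$fractions[[l]]))
  }
  invisible(x)
}

#' Population-fraction time course across an experiment set
#'
#' Applies the *same* reference classifier to every sample (label
#' transfer, never a per-sample refit) and returns one row of counts
#' and fractions per sample, keyed by the sample metadata.
#'
#' @param samples list of [event_table]s, all transformed on the
#'   classifier's channels; metadata fields `sample_id`, `strain`,
#'   `time_h`, `replicate` populate the output columns.
#' @param classifier a [fit_reference()] result.
#' @param rule optional rule override passed to [assign_labels()].
#' @return data.frame with columns `sample_id`, `strain`, `time_h`,
#'   `replicate`, `n_total`, `n_vegetative`, `n_endospore`, `n_spore`,
#'   `frac_vegetative`, `frac_endospore`, `frac_spore`.
#' @export
timecourse_report <- function(samples, classifier, rule = NULL) {
  stopifnot(inherits(classifier, "reference_classifier"))
  if (inherits(samples, "event_table")) samples <- list(samples)
  rows <- lapply(samples, function(tb) {
    stopifnot(inherits(tb, "event_table"))
    missing_ch <- setdiff(classifier$dims, channels(tb))
    if (length(missing_ch)) {
      stopf("sample '%s' lacks classifier channel(s): %s",
            tb$metadata$sample_id %||% "<unnamed>",
            paste(missing_ch, collapse = ", "))
    }
    pf <- population_fractions(assign_labels(classifier, tb, rule),
                               tb$metadata$sample_id %||% NA_character_)
    md <- tb$metadata
    data.frame(sample_id = pf$sample_id,
               strain = md$strain %||% NA_character_,
               time_h = md$time_h %||% NA_real_,
               replicate = md$replicate %||% NA,
               n_total = pf$n_total,
               n_vegetative = pf$counts[["vegetative"]],
               n_endospore = pf$counts[["endospore"]],
               n_spore = pf$counts[["spore"]],
               frac_vegetative = pf$fractions[["vegetative"]],
               frac_endospore = pf$fractions[["endospore"]],
               frac_spore = pf$fractions[["spore"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize / restore a reference classifier as JSON
#'
#' @param classifier a `reference_classifier`.
#' @param path optional file path.
#' @return the JSON string, or (for `classifier_from_json`) the
#'   restored classifier.
#' @export
classifier_to_json <- function(classifier, path = NULL) {
  stopifnot(inherits(classifier, "reference_classifier"))
  obj <- list(model = jsonlite::fromJSON(gmm_to_json(classifier$model)),
              label_map = classifier$label_map,
              dims = classifier$dims, rule = classifier$rule)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname classifier_to_json
#' @param json JSON string or file path from [classifier_to_json()].
#' @export
classifier_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  model <- gmm_from_json(jsonlite::toJSON(obj$model, digits = NA,
                                          auto_unbox = TRUE))
  structure(list(model = model, label_map = obj$label_map,
                 dims = obj$dims, rule = obj$rule),
            class = "reference_classifier")
}

# -- internal ---------------------------------------------------------------

map_cluster_labels <- function(model, fl_idx, ssc_idx) {
  fl <- model$means[, fl_idx]
  ssc <- model$means[, ssc_idx]
  scale_fl <- max(abs(fl), 1e-12)
  ord_fl <- order(fl)
  if (abs(fl[ord_fl[1]] - fl[ord_fl[2]]) < 1e-9 * scale_fl) {
    stopf(paste0("ambiguous label mapping: two clusters tie on the ",
                 "fluorescence mean (%.6g vs %.6g)"),
          fl[ord_fl[1]], fl[ord_fl[2]])
  }
  spore <- ord_fl[1]
  rest <- setdiff(seq_len(3), spore)
  scale_ssc <- max(abs(ssc), 1e-12)
  if (abs(ssc[rest[1]] - ssc[rest[2]]) < 1e-9 * scale_ssc) {
    stopf(paste0("ambiguous label mapping: the two high-fluorescence ",
                 "clusters tie on the side-scatter mean (%.6g)"),
          ssc[rest[1]])
  }
  endospore <- rest[which.max(ssc[rest])]
  vegetative <- setdiff(rest, endospore)
  lm <- character(3)
  lm[spore] <- "spore"
  lm[endospore] <- "endospore"
  lm[vegetative] <- "vegetative"
  lm
}
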