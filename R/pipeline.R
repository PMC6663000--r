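#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain (read -> subsample ->
#' asinh transform -> singlet gate -> model) into one serializable
#' object. All randomness in a run flows from the single `seed`:
#' per-sample seeds are derived deterministically from it and the
#' sample index, so a rerun with the same configuration is
#' reproducible bit for bit.
#'
#' @param transform list: `channels` to asinh-transform and `cofactor`.
#' @param singlet_gating list: `pairs` (list of channel pairs),
#'   `cutoff` (number or `"chi2_0.975"`), `scale_factor`,
#'   `pre_transform`, `fit_subsample` — see [exclude_agglomerates()].
#' @param mixture list: `tol`, `max_iter` for [fit_gmm()].
#' @param classification list: `dims`, `rule` for [fit_reference()].
#' @param n_max subsampling cap per analysis (default 100000).
#' @param seed top-level integer seed.
#' @return a `pipeline_config` object (a named list).
#' @export
pipeline_config <- function(transform = list(channels = c("FSC-A", "SSC-A",
                                                          "FL1-A"),
                                             cofactor = 1),
                            singlet_gating = list(
                              pairs = list(c("FSC-H", "FSC-W"),
                                           c("SSC-H", "SSC-W")),
                              cutoff = "chi2_0.975",
                              scale_factor = 1,
                              pre_transform = "asinh",
                              fit_subsample = 10000L),
                            mixture = list(tol = 1e-8, max_iter = 1000L),
                            classification = list(dims = c("SSC-A", "FL1-A"),
                                                  rule = "euclidean"),
                            n_max = 100000L,
                            seed = 1L) {
  structure(list(transform = transform, singlet_gating = singlet_gating,
                 mixture = mixture, classification = classification,
                 n_max = n_max, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys override the defaults.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- pipeline_config()
  for (key in intersect(names(raw), names(def))) {
    if (is.list(def[[key]]) && is.list(raw[[key]])) {
      for (sub in names(raw[[key]])) def[[key]][[sub]] <- raw[[key]][[sub]]
    } else {
      def[[key]] <- raw[[key]]
    }
  }
  if (!is.null(def$singlet_gating$pairs)) {
    def$singlet_gating$pairs <- lapply(def$singlet_gating$pairs, unlist)
  }
  def
}

#' Stain-quality control for one stained sample
#'
#' Runs the full chain on a single two-population sample (e.g. an
#' artificial cells + spores mixture): read, subsample to `n_max`,
#' asinh-transform, exclude agglomerates, fit a univariate
#' two-component mixture on the configured channel, and report the
#' separation statistics ([separation_metrics()]) together with the
#' density-crossover threshold ([find_threshold()]). Event counts are
#' logged at every stage.
#'
#' @param sample path to an FCS file, or an [event_table] of raw
#'   (untransformed) events.
#' @param config a [pipeline_config()].
#' @param channel the stained channel to score (default `"FL1-A"`).
#' @param dye optional dye label carried into the report.
#' @return list with `report` (a `separation_report`, threshold set),
#'   `model` (the fitted [gmm]), `counts` (named event counts per
#'   stage) and `table` (the processed [event_table]).
#' @export
run_stain_qc <- function(sample, config = pipeline_config(),
                         channel = "FL1-A", dye = NA_character_) {
  table <- pipeline_stage("read", {
    if (inherits(sample, "event_table")) sample else read_fcs(sample)
  })
  if (n_events(table) == 0L) {
    stopf("[read] sample '%s' contains no events",
          table$metadata$sample_id %||% "<unnamed>")
  }
  counts <- c(read = n_events(table))
  table <- pipeline_stage("subsample", {
    subsample_events(table, config$n_max, seed = derive_seed(config$seed, 1L))
  })
  counts["subsampled"] <- n_events(table)
  table <- pipeline_stage("transform", {
    asinh_transform(table, transform_spec(config$transform$channels,
                                          config$transform$cofactor))
  })
  mask <- pipeline_stage("singlet_gate", {
    sg <- config$singlet_gating
    exclude_agglomerates(table, pairs = sg$pairs, cutoff = sg$cutoff,
                         seed = derive_seed(config$seed, 2L),
                         scale_factor = sg$scale_factor %||% 1,
                         fit_subsample = sg$fit_subsample %||% 10000L,
                         pre_transform = sg$pre_transform %||% "asinh",
                         n_starts = sg$n_starts %||% 500L)
  })
  table <- subset_events(table, mask$keep)
  counts["singlets"] <- n_events(table)
  model <- pipeline_stage("mixture_fit", {
    fit_gmm(channel_values(table, channel), g = 2L,
            tol = config$mixture$tol, max_iter = config$mixture$max_iter,
            seed = derive_seed(config$seed, 3L), dims = channel)
  })
  report <- pipeline_stage("separation", {
    rep_ <- separation_metrics(model, channel = channel, dye = dye)
    rep_$threshold <- find_threshold(model, tol = config$mixture$tol)
    rep_
  })
  list(report = report, model = model, counts = counts, table = table)
}

#' Run a whole experiment set with label transfer
#'
#' Processes every sample of a sample sheet (read, subsample,
#' transform, singlet-gate), fits the three-population reference
#' classifier on the designated reference sample, transfers its labels
#' to all samples and tabulates the population-fraction time course.
#' When `out_dir` is given, writes `fractions.csv`,
#' `classifier.json`, `stage_log.csv` and `config_echo.yaml`
#' (configuration, package version and seed — enough to reproduce the
#' run).
#'
#' @param samplesheet path to a sample-sheet CSV (see
#'   [read_sample_sheet()]) or an equivalent data.frame.
#' @param reference `sample_id` of the reference sample (must contain
#'   all three populations).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `fractions` (data.frame, one row per sample),
#'   `classifier` (the [fit_reference()] result) and `log` (data.frame
#'   of per-stage event counts).
#' @export
run_experiment <- function(samplesheet, reference,
                           config = pipeline_config(), out_dir = NULL) {
  sheet <- if (is.data.frame(samplesheet)) samplesheet else {
    read_sample_sheet(samplesheet)
  }
  if (!reference %in% sheet$sample_id) {
    stopf("reference sample '%s' is not in the sample sheet", reference)
  }
  processed <- vector("list", nrow(sheet))
  log_rows <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
    tb <- pipeline_stage(paste0("read:", row$sample_id),
                         read_fcs(row$path))
    md <- tb$metadata
    md$sample_id <- row$sample_id
    for (f in c("strain", "time_h", "replicate")) {
      if (!is.na(row[[f]])) md[[f]] <- row[[f]]
    }
    tb$metadata <- md
    n_read <- n_events(tb)
    tb <- subsample_events(tb, config$n_max,
                           seed = derive_seed(config$seed, 10L * i + 1L))
    n_sub <- n_events(tb)
    tb <- asinh_transform(tb, transform_spec(config$transform$channels,
                                             config$transform$cofactor))
    sg <- config$singlet_gating
    mask <- pipeline_stage(paste0("singlet_gate:", row$sample_id), {
      exclude_agglomerates(tb, pairs = sg$pairs, cutoff = sg$cutoff,
                           seed = derive_seed(config$seed, 10L * i + 2L),
                           scale_factor = sg$scale_factor %||% 1,
                           fit_subsample = sg$fit_subsample %||% 10000L,
                           pre_transform = sg$pre_transform %||% "asinh",
                           n_starts = sg$n_starts %||% 500L)
    })
    tb <- subset_events(tb, mask$keep)
    processed[[i]] <- tb
    log_rows[[i]] <- data.frame(sample_id = row$sample_id, read = n_read,
                                subsampled = n_sub, singlets = n_events(tb),
                                stringsAsFactors = FALSE)
  }
  stage_log <- do.call(rbind, log_rows)

  ref_table <- processed[[match(reference, sheet$sample_id)]]
  classifier <- pipeline_stage("fit_reference", {
    fit_reference(ref_table, dims = config$classification$dims,
                  seed = derive_seed(config$seed, 5L),
                  rule = config$classification$rule)
  })
  fractions <- pipeline_stage("timecourse_report",
                              timecourse_report(processed, classifier))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fractions, file.path(out_dir, "fractions.csv"),
                     row.names = FALSE)
    classifier_to_json(classifier, file.path(out_dir, "classifier.json"))
    utils::write.csv(stage_log, file.path(out_dir, "stage_log.csv"),
                     row.names = FALSE)
    echo <- unclass(config)
    echo$package_version <- as.character(utils::packageVersion("sporegate"))
    echo$reference <- reference
    yaml::write_yaml(echo, file.path(out_dir, "config_echo.yaml"))
  }
  list(fractions = fractions, classifier = classifier, log = stage_log)
}

# -- internal ---------------------------------------------------------------

# Run one pipeline stage, attaching the stage name to any error.
pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (startsWith(msg, "[")) stop(e)  # already tagged by an inner stage
    stopf("[%s] %s", name, msg)
  })
}
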