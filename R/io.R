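## Text-format I/O and the run-all pipeline orchestration.

#' Read a multichannel recording
#'
#' CSV/TSV layout: one header row of channel labels, one row per sample.
#' The sampling rate comes from a JSON sidecar (`<path>.json` with fields
#' `rate`, optionally `labels`, `t0`) or the `rate` argument.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"` (`"edf"`/`"hdf5"` are not available in
#'   this build and raise an informative error).
#' @param rate sampling rate in Hz; overrides the sidecar.
#' @return an [mc_series()].
#' @export
read_recording <- function(path, format = c("csv", "tsv", "edf", "hdf5"),
                           rate = NULL) {
  format <- match.arg(format)
  if (format %in% c("edf", "hdf5"))
    stop(sprintf("format '%s' is not supported by this build; %s", format,
                 "export the recording to CSV/TSV with a JSON sidecar"),
         call. = FALSE)
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list()
  if (is.null(rate)) rate <- meta$rate
  if (is.null(rate))
    stop("sampling rate missing: supply `rate` or a sidecar JSON with a ",
         "`rate` field", call. = FALSE)
  sep <- if (format == "tsv") "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE)
  stop_if_not(nrow(df) > 0 && ncol(df) > 0, "empty or unparseable recording")
  stop_if_not(all(vapply(df, is.numeric, logical(1))),
              "non-numeric columns in recording")
  mc_series(t(as.matrix(df)), rate = rate, labels = colnames(df),
            t0 = if (is.null(meta$t0)) 0 else meta$t0)
}

#' Write a multichannel recording
#'
#' CSV (samples as rows, labelled columns) plus a JSON sidecar holding the
#' sampling rate, labels and time offset.
#'
#' @param series an [mc_series()].
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(series, path) {
  stop_if_not(inherits(series, "mc_series"), "`series` must be an mc_series")
  df <- as.data.frame(t(series$data))
  colnames(df) <- series$labels
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(rate = series$rate, labels = series$labels,
                            t0 = series$t0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a connectivity graph
#'
#' Edge list as JSON (and optionally TSV).
#'
#' @param graph a `conn_graph`.
#' @param path output JSON path.
#' @param tsv optional TSV path for the edge table.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, tsv = NULL) {
  stop_if_not(inherits(graph, "conn_graph"), "`graph` must be a conn_graph")
  jsonlite::write_json(list(edges = graph$edges), path, auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(tsv))
    write.table(graph$edges, tsv, sep = "\t", row.names = FALSE,
                quote = FALSE)
  invisible(path)
}

# Recognized configuration keys and their defaults.
default_config <- function() {
  list(
    seed = 1,
    bands = "mu",
    out_dir = NULL,
    n_per_group = 6,
    n_samples = 2500,
    rate = 250,
    order = 2,
    n_boot = 20,
    n_sensors = 24,
    sensor_noise_sd = 0.5,
    regularization = 0.05,
    trt = TRUE,
    dense_edges = 10,
    sparse_edges = 4,
    n_nodes = 5,
    n_trials = 80,
    svm_repeats = 2
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys before any stage runs.
#'
#' @param config named list (possibly partial), or a YAML file path.
#' @return the completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stop_if_not(is.list(config), "`config` must be a list or a YAML path")
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  modifyList(defaults, config)
}

#' Run the full pipeline
#'
#' Orchestrates synthetic-data generation, sensor projection,
#' preprocessing, DICS source estimation, tPDC connectivity with surrogate
#' and time-reversal testing, group statistics and SVM classification. Every
#' stochastic stage receives a sub-seed derived from the global seed, so a
#' config reproduces its run exactly.
#'
#' Per subject the chain is: ground-truth network from the group's profile,
#' source simulation, projection through a toy spherical lead field with
#' sensor noise, average re-referencing, band CSD + DICS filters at the
#' node grid, source series extraction, then the tPDC/bootstrap/TRT stage on
#' the estimated sources.
#'
#' @param config a [pipeline_config()] list (or partial list / YAML path).
#' @return a manifest list: `config`, `dataset`, `stats`, `classification`,
#'   `graphs`, and (when `out_dir` is set) `files` with MD5 hashes.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  seed <- cfg$seed
  bands <- lapply(cfg$bands, standard_band)
  groups <- c(rep("TDC", cfg$n_per_group), rep("ASD", cfg$n_per_group))
  dense <- group_network_profile("dense_longrange", n_nodes = cfg$n_nodes,
                                 n_edges = cfg$dense_edges)
  sparse <- group_network_profile("sparse_local", n_nodes = cfg$n_nodes,
                                  n_edges = cfg$sparse_edges)
  rows <- list(); graphs <- list()
  for (s in seq_along(groups)) {
    sseed <- derive_seed(seed, s)
    is_tdc <- groups[s] == "TDC"
    row <- data.frame(subject = s, group = groups[s])
    dp <- if (is_tdc) c(2.5, 2.0) else c(1.2, 1.0)
    beh_w <- simulate_behavior(cfg$n_trials, dp[1], dp[1] / 2, "walker",
                               seed = derive_seed(sseed, 90))
    beh_s <- simulate_behavior(cfg$n_trials, dp[2], dp[2] / 2, "scramble",
                               seed = derive_seed(sseed, 91))
    row$age <- with_seed(derive_seed(sseed, 92), runif(1, 9, 15))
    row$dprime_walker <- dprime(beh_w)
    row$dprime_scramble <- dprime(beh_s)
    row$hit_rate <- beh_w$hits / beh_w$n_signal_trials
    row$fa_rate <- beh_w$false_alarms / beh_w$n_noise_trials
    graphs[[s]] <- list()
    for (b in seq_along(bands)) {
      band <- bands[[b]]
      bseed <- derive_seed(sseed, b)
      prof <- if (is_tdc) dense else sparse
      net <- make_group_network(prof, band, rate = cfg$rate, seed = bseed)
      if (is_tdc) net$innovation_cov <- net$innovation_cov * 1.5
      src_true <- simulate_mvar(net, cfg$n_samples, rate = cfg$rate,
                                seed = derive_seed(bseed, 1))
      lf <- make_leadfield(net$coords, n_sensors = cfg$n_sensors)
      sens <- project_to_sensors(src_true, lf, cfg$sensor_noise_sd,
                                 seed = derive_seed(bseed, 2))
      sens <- average_rereference(sens)
      csd <- compute_csd(sens, band)
      filt <- dics_filter(lf, csd, cfg$regularization)
      src_est <- extract_source_series(filt, sens)
      conn <- analyze_subject_connectivity(src_est, net$coords, band,
                                           order = cfg$order,
                                           n_boot = cfg$n_boot,
                                           seed = derive_seed(bseed, 3),
                                           trt = cfg$trt)
      row[[paste0("power_", band$name)]] <-
        source_power_map(filt, csd)[1]
      row[[paste0("coherence_", band$name)]] <-
        mean_source_coherence(src_est, band)
      row[[paste0("connectivity_", band$name)]] <-
        conn$mean_directional_coherence
      graphs[[s]][[band$name]] <- conn$graph
    }
    rows[[s]] <- row
  }
  dataset <- do.call(rbind, rows)

  # group statistics on behaviour and connectivity
  tdc <- dataset[dataset$group == "TDC", ]
  asd <- dataset[dataset$group == "ASD", ]
  stats_out <- list(
    dprime_walker = mann_whitney(tdc$dprime_walker, asd$dprime_walker))
  for (band in bands) {
    cn <- paste0("connectivity_", band$name)
    hn <- paste0("coherence_", band$name)
    stats_out[[paste0("mdc_", band$name)]] <-
      kruskal_wallis(list(tdc[[cn]], asd[[cn]]))
    stats_out[[paste0("coherence_", band$name)]] <-
      kruskal_wallis(list(tdc[[hn]], asd[[hn]]))
    stats_out[[paste0("brain_behavior_", band$name)]] <-
      pearson_brain_behavior(dataset$hit_rate, dataset[[hn]])
  }

  sets <- build_feature_sets(dataset, bands = cfg$bands)
  classification <- lapply(sets, function(fs)
    repeat_cv(fs, n_repeats = cfg$svm_repeats,
              seed = derive_seed(seed, 7000)))

  manifest <- list(config = cfg, dataset = dataset, stats = stats_out,
                   classification = classification, graphs = graphs)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    ds_path <- file.path(cfg$out_dir, "cohort.tsv")
    write.table(dataset, ds_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
    acc <- lapply(classification, function(r) r$mean)
    res_path <- file.path(cfg$out_dir, "results.json")
    jsonlite::write_json(list(
      accuracy = acc,
      stats = lapply(stats_out, function(t)
        list(statistic = t$statistic, p = t$p_value))),
      res_path, auto_unbox = TRUE, digits = NA)
    files <- c(ds_path, res_path)
    manifest$files <- data.frame(path = files,
                                 md5 = unname(tools::md5sum(files)))
  }
  manifest
}
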