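#' Pipeline configuration
#'
#' Collects every tunable of the discovery workflow with its documented
#' default. The configuration round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param out_dir Artifact directory.
#' @param n_pos,n_neg Cohort class sizes (defaults 12 / 48).
#' @param n_replicates Replicate spots per sample and stream.
#' @param effect_size Log-fold shift of the planted discriminatory peak.
#' @param marker_cv Biological CV of the discriminatory peak.
#' @param grid_size Grid points per synthetic stream.
#' @param seed Master seed (explicit, never wall-clock derived).
#' @param baseline_half_window Baseline window half-width (grid points).
#' @param smooth_half_window Detection smoothing half-width.
#' @param noise_half_window Noise-threshold window half-width.
#' @param rel_tolerance Relative m/z tolerance for peak alignment.
#' @param min_support_frac Minimum fraction of samples supporting a cluster.
#' @param alpha Peak-significance threshold.
#' @param k_max Maximum peaks per model.
#' @param gamma_grid LS-SVM regularization grid.
#' @param selection_mode `"paper"` or `"nested"` hyperparameter selection.
#' @param n_qc,qc_mean,qc_sd Control-series length and in-control parameters.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "seldiflow_out",
                            n_pos = 12, n_neg = 48, n_replicates = 2,
                            effect_size = 3, marker_cv = 0.05,
                            grid_size = 2000,
                            seed = 1L,
                            baseline_half_window = 25,
                            smooth_half_window = 2,
                            noise_half_window = 100,
                            rel_tolerance = 0.008,
                            min_support_frac = 0.25,
                            alpha = 0.05, k_max = 10,
                            gamma_grid = lssvm_gamma_grid(),
                            selection_mode = "paper",
                            n_qc = 24, qc_mean = 100, qc_sd = 5) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

stage_dir <- function(config, ...) file.path(config$out_dir, ...)

read_peak_matrices <- function(config) {
  dir <- stage_dir(config, "peaks")
  files <- list.files(dir, pattern = "^peak_matrix_.*\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no peak matrices found in ", dir, call. = FALSE)
  out <- list()
  for (f in files) {
    df <- as.data.frame(data.table::fread(f))
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df[[1]]
    cols <- colnames(mat)
    parts <- strsplit(cols, "_")
    cl <- data.frame(
      cluster_id = seq_along(cols),
      consensus_mz = vapply(parts, function(p) as.numeric(p[3]), numeric(1)),
      diameter = NA_real_, n_samples = NA_integer_,
      chip = vapply(parts, `[`, character(1), 1),
      mass_range = vapply(parts, `[`, character(1), 2),
      column = cols, stringsAsFactors = FALSE)
    key <- sub("^peak_matrix_(.*)\\.csv$", "\\1", basename(f))
    out[[key]] <- structure(list(intensity = mat, clusters = cl),
                            class = "peak_matrix")
  }
  out
}

read_truth_labels <- function(config) {
  truth <- jsonlite::read_json(stage_dir(config, "raw", "truth.json"),
                               simplifyVector = TRUE)
  labels <- truth$labels
  stats::setNames(as.numeric(labels), names(labels))
}

write_peak_matrices <- function(matrices, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in names(matrices)) {
    mat <- matrices[[k]]$intensity
    df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
    data.table::fwrite(df, file.path(dir, paste0("peak_matrix_", k, ".csv")))
  }
}

#' Run one pipeline stage
#'
#' Stages, in order: `simulate` (synthetic cohort + QC series to CSV/JSON),
#' `preprocess` (baseline, TIC normalization, outlier flags, replicate
#' averaging), `peaks` (detection, noise filtering, alignment, peak matrix
#' per stream), `qc` (Shewhart limits and Westgard flags on the control
#' series), `stats` (Wilcoxon peak ranking), `loo` (leave-one-out weighted
#' LS-SVM validation), `report` (summary tables and ROC CSV). Each stage
#' reads the artifacts of its predecessors from `config$out_dir` and fails
#' with a clear error when they are missing. Re-running a stage with an
#' identical configuration reproduces its artifacts byte for byte.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return Invisibly, the stage's main in-memory result.
#' @export
run_stage <- function(stage = c("simulate", "preprocess", "peaks", "qc",
                                "stats", "loo", "report"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = {
      cohort <- generate_cohort(
        n_pos = config$n_pos, n_neg = config$n_neg,
        streams = default_streams(config$effect_size, config$marker_cv,
                                  config$grid_size),
        n_replicates = config$n_replicates, seed = config$seed)
      raw <- stage_dir(config, "raw")
      write_spectra(cohort$spectra, raw)
      jsonlite::write_json(
        list(labels = as.list(cohort$truth$labels),
             discriminatory_mz = cohort$truth$discriminatory_mz,
             planted = cohort$truth$planted),
        file.path(raw, "truth.json"), digits = NA, auto_unbox = TRUE)
      qc_dir <- stage_dir(config, "qc")
      dir.create(qc_dir, showWarnings = FALSE)
      qc_vals <- generate_qc_series(config$n_qc, config$qc_mean, config$qc_sd,
                                    seed = config$seed + 1L)
      data.table::fwrite(
        data.frame(run_id = seq_along(qc_vals), value = qc_vals),
        file.path(qc_dir, "qc_series.csv"))
      log_run(config, "simulate")
      invisible(cohort)
    },
    preprocess = {
      raw <- stage_dir(config, "raw")
      if (!file.exists(file.path(raw, "manifest.csv"))) {
        stop("simulate artifacts missing; run the simulate stage first",
             call. = FALSE)
      }
      spectra <- read_spectra(raw)
      pp <- preprocess_cohort(spectra, config$baseline_half_window)
      out <- stage_dir(config, "preprocessed")
      write_spectra(pp$spectra, out)
      data.table::fwrite(pp$manifest, file.path(out, "spot_manifest.csv"))
      log_run(config, "preprocess")
      invisible(pp)
    },
    peaks = {
      ppdir <- stage_dir(config, "preprocessed")
      if (!file.exists(file.path(ppdir, "manifest.csv"))) {
        stop("preprocess artifacts missing; run the preprocess stage first",
             call. = FALSE)
      }
      spectra <- read_spectra(ppdir)
      matrices <- detect_cohort_peaks(
        spectra, config$smooth_half_window, config$noise_half_window,
        config$rel_tolerance, config$min_support_frac)
      write_peak_matrices(matrices, stage_dir(config, "peaks"))
      log_run(config, "peaks")
      invisible(matrices)
    },
    qc = {
      f <- stage_dir(config, "qc", "qc_series.csv")
      if (!file.exists(f)) {
        stop("qc series missing; run the simulate stage first", call. = FALSE)
      }
      df <- as.data.frame(data.table::fread(f))
      qc <- qc_series(df$value)
      viol <- vapply(seq_along(qc$values), function(i) {
        paste(qc$violations$rule[qc$violations$index == i], collapse = ";")
      }, character(1))
      data.table::fwrite(
        data.frame(run_id = df$run_id, z = qc$z, rules_violated = viol),
        stage_dir(config, "qc", "qc_report.csv"))
      log_run(config, "qc")
      invisible(qc)
    },
    stats = {
      matrices <- read_peak_matrices(config)
      labels <- read_truth_labels(config)
      res <- rank_peaks(matrices, labels, config$alpha)
      dir.create(stage_dir(config, "stats"), showWarnings = FALSE)
      data.table::fwrite(res, stage_dir(config, "stats",
                                        "significant_peaks.csv"))
      log_run(config, "stats")
      invisible(res)
    },
    loo = {
      matrices <- read_peak_matrices(config)
      labels <- read_truth_labels(config)
      loo <- loo_pipeline(matrices, labels, k_max = config$k_max,
                          gamma_grid = config$gamma_grid,
                          selection_mode = config$selection_mode,
                          alpha = config$alpha, seed = config$seed)
      dir.create(stage_dir(config, "loo"), showWarnings = FALSE)
      data.table::fwrite(loo$records, stage_dir(config, "loo",
                                                "loo_records.csv"))
      occ <- summarize_occurrences(loo)
      data.table::fwrite(occ, stage_dir(config, "loo", "occurrence.csv"))
      jsonlite::write_json(
        list(auc = loo$auc, auc_se = loo$auc_se,
             sensitivity = loo$sensitivity, specificity = loo$specificity,
             ber = loo$ber, median_k = loo$median_k, mean_k = loo$mean_k,
             sd_k = loo$sd_k, selection_mode = loo$selection_mode,
             k_chosen = loo$k_chosen, gamma_chosen = loo$gamma_chosen),
        stage_dir(config, "loo", "loo_summary.json"),
        digits = NA, auto_unbox = TRUE)
      data.table::fwrite(loo$roc, stage_dir(config, "loo", "roc.csv"))
      log_run(config, "loo")
      invisible(loo)
    },
    report = {
      needed <- c(stage_dir(config, "loo", "loo_summary.json"),
                  stage_dir(config, "loo", "occurrence.csv"),
                  stage_dir(config, "stats", "significant_peaks.csv"),
                  stage_dir(config, "loo", "roc.csv"))
      missing <- needed[!file.exists(needed)]
      if (length(missing)) {
        stop("report inputs missing (run loo/stats stages first): ",
             paste(basename(missing), collapse = ", "), call. = FALSE)
      }
      rep_dir <- stage_dir(config, "report")
      dir.create(rep_dir, showWarnings = FALSE)
      sig <- as.data.frame(data.table::fread(
        stage_dir(config, "stats", "significant_peaks.csv")))
      matrices <- read_peak_matrices(config)
      streams <- names(matrices)
      counts <- data.frame(
        stream = streams,
        total_peaks = vapply(matrices, function(m) ncol(m$intensity),
                             integer(1)),
        significant_peaks = vapply(streams, function(k) {
          m <- matrices[[k]]$clusters
          sum(sig$column %in% m$column)
        }, integer(1)), row.names = NULL)
      data.table::fwrite(counts, file.path(rep_dir, "peak_counts.csv"))
      summ <- jsonlite::read_json(stage_dir(config, "loo",
                                            "loo_summary.json"),
                                  simplifyVector = TRUE)
      data.table::fwrite(
        data.frame(auc = summ$auc, auc_se = summ$auc_se,
                   sensitivity = summ$sensitivity,
                   specificity = summ$specificity,
                   median_k = summ$median_k, mean_k = summ$mean_k,
                   sd_k = summ$sd_k),
        file.path(rep_dir, "loo_performance.csv"))
      file.copy(stage_dir(config, "loo", "occurrence.csv"),
                file.path(rep_dir, "peak_occurrence.csv"), overwrite = TRUE)
      file.copy(stage_dir(config, "loo", "roc.csv"),
                file.path(rep_dir, "roc_curve.csv"), overwrite = TRUE)
      log_run(config, "report")
      invisible(rep_dir)
    })
}

# provenance log: config hash (md5 of its YAML form), seed, package version
log_run <- function(config, stage) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  entry <- list(stage = stage, seed = config$seed,
                config_md5 = unname(tools::md5sum(tmp)),
                package_version =
                  as.character(utils::packageVersion("seldiflow")))
  jsonlite::write_json(entry, stage_dir(config,
                                        paste0("log_", stage, ".json")),
                       auto_unbox = TRUE)
}

#' Run the full pipeline end to end
#'
#' `simulate -> preprocess -> peaks -> qc -> stats -> loo -> report` under
#' one configuration. Deterministic and idempotent for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  for (st in c("simulate", "preprocess", "peaks", "qc", "stats", "loo",
               "report")) {
    run_stage(st, config)
  }
  invisible(stage_dir(config, "report"))
}
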