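#' Configuration for a full study run
#'
#' Bundles every knob of the end-to-end pipeline.  A single master seed
#' fans out to named sub-seeds (cohort simulation, split plan, tree,
#' Shapley) so stochastic stages are isolated and the manifest plus the
#' master seed fully determine every output.
#'
#' @param input Path to an RR CSV (see [read_rr_table()]), or `NULL` to
#'   simulate a cohort.
#' @param cohort A [cohort_config()] used when `input` is `NULL`.
#' @param segment_s Segment duration in seconds (default 300).
#' @param min_beats Minimum beats per segment (default 100).
#' @param windows Circadian windows to analyse (default
#'   `c("day", "night", "full")`; the first is also the source of the
#'   cross-window transfer evaluation).
#' @param gate Correlation gate for feature selection (default 0.6).
#' @param feature_cfg A [feature_config()].
#' @param tree_cfg A [tree_config()].
#' @param shapley_runs,shapley_samples Shapley resampling size
#'   (defaults 1000 runs x 100 samples).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, cohort = cohort_config(),
                       segment_s = 300, min_beats = 100,
                       windows = c("day", "night", "full"),
                       gate = 0.6, feature_cfg = feature_config(),
                       tree_cfg = tree_config(),
                       shapley_runs = 1000, shapley_samples = 100,
                       seed = 1L) {
  seed <- as.integer(seed)
  structure(list(input = input, cohort = cohort, segment_s = segment_s,
                 min_beats = min_beats, windows = windows, gate = gate,
                 feature_cfg = feature_cfg, tree_cfg = tree_cfg,
                 shapley_runs = shapley_runs,
                 shapley_samples = shapley_samples,
                 seed = seed,
                 sub_seeds = list(cohort = seed * 4L + 1L,
                                  split = seed * 4L + 2L,
                                  tree = seed * 4L + 3L,
                                  shapley = seed * 4L + 4L)),
            class = "run_config")
}

#' Run the full study pipeline and write its artifacts
#'
#' Simulate (or ingest) -> segment -> featurize -> select -> train ->
#' evaluate -> explain, for each requested circadian window, plus the
#' cross-window transfer evaluation of the first window's classifier on
#' the remaining windows.  All windows share one split plan, so the same
#' patients are held out everywhere.  Artifacts are plain CSV/JSON:
#' `manifest.json`, `feature_table.csv`, `selection_<w>.json`,
#' `evalreport_<w>.json`, `importance_<w>.json`, `transfer.json`,
#' `log.txt`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`features`,
#'   per-window `experiments`, `transfer`, `importance`) and
#'   `out_dir`.
#' @export
run_study <- function(config = run_config(), out_dir = tempfile("hfstrat_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)

  if (is.null(config$input)) {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- config$sub_seeds$cohort
    cohort <- simulate_cohort(cohort_cfg)
    log_line("simulated cohort: ", length(cohort), " patients")
  } else {
    cohort <- read_rr_table(config$input)
    log_line("read cohort from ", config$input, ": ", length(cohort),
             " patients, ", attr(cohort, "dropped_rows"),
             " invalid rows dropped")
  }

  feats <- feature_table(cohort, duration_s = config$segment_s,
                         min_beats = config$min_beats,
                         window = "full", config = config$feature_cfg)
  utils::write.csv(feats, file.path(out_dir, "feature_table.csv"),
                   row.names = FALSE)
  log_line("feature table: ", nrow(feats), " segments")

  pats <- unique(feats[stats::complete.cases(
    feats[, hrv_feature_names()]), c("patient_id", "label")])
  plan <- make_split_plan(pats$patient_id, pats$label,
                          seed = config$sub_seeds$split)

  experiments <- list()
  importance <- list()
  for (w in config$windows) {
    exp <- run_experiment(feats, window = w,
                          gate = config$gate,
                          tree_cfg = config$tree_cfg,
                          split_plan = plan)
    experiments[[w]] <- exp
    log_line("window ", w, ": selected [",
             paste(exp$selection$selected, collapse = ", "),
             "], segment ACC ", sprintf("%.1f", exp$report$acc),
             "%, dropped ", exp$n_dropped_na, " undefined segments")
    write_json_file(selection_to_list(exp$selection),
                    file.path(out_dir, paste0("selection_", w, ".json")))
    write_json_file(report_to_list(exp$report),
                    file.path(out_dir, paste0("evalreport_", w, ".json")))
    dev <- exp$data[!exp$data$patient_id %in% plan$test, , drop = FALSE]
    imp <- shapley_importance(exp$tree, dev,
                              n_runs = config$shapley_runs,
                              n_samples = config$shapley_samples,
                              seed = config$sub_seeds$shapley)
    importance[[w]] <- imp
    write_json_file(c(imp["n_runs"], imp["n_samples"], imp["seed"],
                      list(importance = imp$importance)),
                    file.path(out_dir, paste0("importance_", w, ".json")))
    utils::write.csv(imp$importance,
                     file.path(out_dir, paste0("importance_", w, ".csv")),
                     row.names = FALSE)
  }

  transfer <- list()
  src <- config$windows[1]
  for (w in setdiff(config$windows, src)) {
    rep <- transfer_evaluate(experiments[[src]], feats, w)
    transfer[[paste0(src, "_to_", w)]] <- rep
    log_line("transfer ", src, " -> ", w, ": segment ACC ",
             sprintf("%.1f", rep$acc), "%")
  }
  write_json_file(lapply(transfer, report_to_list),
                  file.path(out_dir, "transfer.json"))

  manifest <- list(config = serializable_config(config),
                   windows = config$windows,
                   n_patients = length(cohort),
                   n_segments = nrow(feats),
                   test_patients = plan$test)
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(features = feats, experiments = experiments,
                 transfer = transfer, importance = importance,
                 out_dir = out_dir))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

selection_to_list <- function(sel) {
  list(selected = sel$selected,
       accuracy_trajectory = sel$accuracy_trajectory,
       rejected_by_correlation = as.list(sel$rejected_by_correlation),
       stop_reason = sel$stop_reason)
}

report_to_list <- function(rep) {
  list(confusion = list(tp = rep$tp, fp = rep$fp, tn = rep$tn,
                        fn = rep$fn),
       acc = rep$acc, sensitivity = rep$sensitivity,
       specificity = rep$specificity, ppv = rep$ppv,
       patient_accuracy = rep$patient_accuracy,
       per_patient = rep$per_patient)
}

serializable_config <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out$feature_cfg <- unclass(out$feature_cfg)
  out$tree_cfg <- unclass(out$tree_cfg)
  out
}

#' Standalone featurization of an RR table
#'
#' Reads a cohort CSV, segments it and writes/returns the per-segment
#' feature table without any modelling.
#'
#' @param input Path to an RR CSV.
#' @param out Optional output CSV path.
#' @param segment_s,min_beats,window,config As in [feature_table()].
#' @return The feature table, invisibly if `out` is given.
#' @export
featurize_file <- function(input, out = NULL, segment_s = 300,
                           min_beats = 100, window = "full",
                           config = feature_config()) {
  cohort <- read_rr_table(input)
  feats <- feature_table(cohort, duration_s = segment_s,
                         min_beats = min_beats, window = window,
                         config = config)
  if (!is.null(out)) {
    utils::write.csv(feats, out, row.names = FALSE)
    return(invisible(feats))
  }
  feats
}
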