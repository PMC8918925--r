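segment_key <- function(data) paste(data$patient_id, data$segment_idx)

hash_rows <- function(data) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sort(segment_key(data)), f)
  unname(tools::md5sum(f))
}

#' Run one full selection / training / evaluation experiment
#'
#' The complete protocol on a featurized cohort: restrict to a circadian
#' window; drop segments with undefined feature values (count logged in
#' the result); build the patient-grouped split plan; run
#' correlation-gated greedy forward selection on the 5 folds; retrain the
#' final tree on all train+validation patients with the selected
#' features; evaluate once on the untouched test patients; and fit
#' single-feature baselines under the identical split and retrain
#' protocol.  The test rows are fingerprinted before selection and the
#' fingerprint re-checked at evaluation, so any modification of the test
#' set during model development is caught.
#'
#' @param features_df Feature table from [feature_table()] (full-day; the
#'   window filter is applied here).
#' @param window Circadian window: `"day"`, `"night"` or `"full"`.
#' @param split_seed Seed for the split plan.
#' @param gate Correlation gate for selection (default 0.6).
#' @param tree_cfg A [tree_config()].
#' @param feature_names Candidate features (default the canonical 14).
#' @param split_plan Optional pre-built [make_split_plan()] (so several
#'   windows can share the same test patients).
#' @return A list of class `experiment_result`: `selection`
#'   ([greedy_forward_select()] result), `tree` (final retrained tree),
#'   `report` ([evaluate_predictions()] on the test set),
#'   `single_feature` (named vector of single-feature test accuracies,
#'   percent), `split_plan`, `window`, `n_dropped_na`, `data` (the
#'   window-filtered, NA-free feature table, for downstream use such as
#'   importance estimation on the development patients).
#' @export
run_experiment <- function(features_df, window = "day", split_seed = 1L,
                           gate = 0.6, tree_cfg = tree_config(),
                           feature_names = hrv_feature_names(),
                           split_plan = NULL) {
  df <- features_df
  if (window != "full")
    df <- df[df$circadian_tag == window, , drop = FALSE]
  ok <- stats::complete.cases(df[, feature_names])
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("no usable segments in window '", window, "'")

  pats <- unique(df[, c("patient_id", "label")])
  if (is.null(split_plan))
    split_plan <- make_split_plan(pats$patient_id, pats$label,
                                  seed = split_seed)
  test_df <- df[df$patient_id %in% split_plan$test, , drop = FALSE]
  dev_df <- df[!df$patient_id %in% split_plan$test, , drop = FALSE]
  test_hash <- hash_rows(test_df)

  selection <- greedy_forward_select(dev_df, split_plan$folds,
                                     features = feature_names,
                                     gate = gate, tree_cfg = tree_cfg)
  tree <- train_tree(dev_df, selection$selected, tree_cfg)

  if (!identical(hash_rows(df[df$patient_id %in% split_plan$test, ,
                              drop = FALSE]), test_hash))
    stop("test-set fingerprint changed during model development")
  report <- evaluate_predictions(tree, test_df)

  single <- vapply(feature_names, function(f) {
    t1 <- train_tree(dev_df, f, tree_cfg)
    evaluate_predictions(t1, test_df)$acc
  }, numeric(1))

  structure(list(selection = selection, tree = tree, report = report,
                 single_feature = single, split_plan = split_plan,
                 window = window, n_dropped_na = n_dropped,
                 test_hash = test_hash, data = df),
            class = "experiment_result")
}

#' Evaluate a trained experiment on another circadian window
#'
#' Applies the final tree of a fitted experiment (e.g. day-optimised) to
#' the test patients' segments of a different window, emulating the
#' day-to-night transfer protocol.  Only test patients are used, so the
#' transfer evaluation is as leakage-free as the original one.
#'
#' @param experiment An [run_experiment()] result.
#' @param features_df The full-day feature table the experiment was
#'   built from.
#' @param window Target window.
#' @return An `eval_report`.
#' @export
transfer_evaluate <- function(experiment, features_df, window) {
  df <- features_df
  if (window != "full")
    df <- df[df$circadian_tag == window, , drop = FALSE]
  df <- df[stats::complete.cases(df[, hrv_feature_names()]), , drop = FALSE]
  df <- df[df$patient_id %in% experiment$split_plan$test, , drop = FALSE]
  if (nrow(df) == 0) stop("no test segments in window '", window, "'")
  evaluate_predictions(experiment$tree, df)
}
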