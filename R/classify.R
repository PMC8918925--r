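#' Decision-tree configuration
#'
#' CART-style binary classification tree (Gini impurity) with uniform
#' class priors: each class contributes equally to every split and to the
#' leaf posteriors regardless of how many segments it has, so a class
#' with more recorded segments cannot dominate by frequency alone.
#'
#' @param min_leaf Minimum segments per leaf (default 5).
#' @param cp Complexity parameter: a split must improve the overall fit
#'   by this fraction of the root impurity to be kept (default 0.01, the
#'   CART library default; splits that only chase noise are pruned).
#' @param max_depth Maximum tree depth (default 30, the deepest the CART
#'   backend supports — effectively uncapped).
#' @param seed Seed recorded with the model for provenance (tree fitting
#'   itself is deterministic).
#' @return A list of class `tree_config`.
#' @export
tree_config <- function(min_leaf = 5, cp = 0.01, max_depth = 30,
                        seed = 1L) {
  structure(list(min_leaf = min_leaf, cp = cp, max_depth = max_depth,
                 seed = as.integer(seed)),
            class = "tree_config")
}

class_levels <- function() c("AF-HF", "control")

#' Train a decision tree with uniform class priors
#'
#' @param data Feature table with a `label` column.
#' @param features Feature columns to use.
#' @param config A [tree_config()].
#' @return An `rpart` classification tree.
#' @export
train_tree <- function(data, features, config = tree_config()) {
  y <- factor(data$label, levels = class_levels())
  if (length(unique(data$label)) < 2)
    stop("training data must contain both classes")
  if (anyNA(data[, features]))
    stop("undefined feature values must be removed before training")
  form <- stats::as.formula(paste("label ~",
                                  paste(features, collapse = " + ")))
  df <- data[, features, drop = FALSE]
  df$label <- y
  rpart::rpart(form, data = df, method = "class",
               parms = list(prior = c(0.5, 0.5), split = "gini"),
               control = rpart::rpart.control(
                 minbucket = config$min_leaf,
                 minsplit = 2 * config$min_leaf,
                 cp = config$cp, maxdepth = config$max_depth,
                 xval = 0, maxcompete = 0, maxsurrogate = 0))
}

predict_class <- function(tree, data) {
  as.character(predict(tree, newdata = data, type = "class"))
}

#' Patient-grouped split plan: held-out test set plus 5 validation folds
#'
#' Randomly selects a class-balanced test set (6 patients per class at
#' the reference 52-patient cohort size, proportionally otherwise) that
#' is excluded from all model development, then partitions the remaining
#' patients into 5 class-balanced validation folds.  In each fold the
#' validation patients are held out and all other non-test patients form
#' the training set, so at the reference size each fold trains on 32 and
#' validates on 8 patients, and no patient ever appears on both sides of
#' a split.
#'
#' @param patients Character vector of patient ids.
#' @param labels Class labels aligned with `patients`.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param n_folds Number of validation folds (default 5).
#' @param test_frac Fraction of each class held out for the test set
#'   (default 6/26).
#' @return A list of class `split_plan`: `test` (patient ids), `folds`
#'   (list of `list(train, validation)`), `seed`.
#' @export
make_split_plan <- function(patients, labels, seed = 1L, n_folds = 5,
                            test_frac = 6 / 26) {
  stopifnot(length(patients) == length(labels))
  patients <- as.character(patients)
  set.seed(seed)
  test <- character(0)
  fold_val <- rep(list(character(0)), n_folds)
  for (cls in unique(labels)) {
    p <- patients[labels == cls]
    if (length(p) < 2) stop("need at least 2 patients per class")
    n_test <- max(1, round(length(p) * test_frac))
    test_p <- sample(p, n_test)
    rest <- sample(setdiff(p, test_p))
    if (length(rest) < n_folds)
      stop("cohort too small for ", n_folds, " folds: class ", cls,
           " has only ", length(rest), " non-test patients (needs >= ",
           n_folds, ")")
    assign_fold <- rep(seq_len(n_folds), length.out = length(rest))
    for (f in seq_len(n_folds))
      fold_val[[f]] <- c(fold_val[[f]], rest[assign_fold == f])
    test <- c(test, test_p)
  }
  nontest <- setdiff(patients, test)
  folds <- lapply(fold_val, function(v)
    list(train = setdiff(nontest, v), validation = v))
  structure(list(test = test, folds = folds, seed = as.integer(seed)),
            class = "split_plan")
}

#' Evaluate segment predictions and stratify patients by majority vote
#'
#' Computes segment-level confusion counts and metrics with AF-HF as the
#' positive class, the per-patient accuracy `ACC_i` (fraction of a
#' patient's segments classified correctly), and the majority-vote
#' patient call: a patient is assigned the class predicted for the
#' majority of their segments, i.e. the call is correct when more than
#' 50% of the segments are classified correctly.  An exact 50/50 tie is
#' broken toward AF-HF (screening posture) and flagged.
#'
#' @param tree A trained tree, or `NULL` if `predictions` are supplied.
#' @param data Feature table with `patient_id` and `label` columns.
#' @param predictions Optional character vector of predicted classes
#'   (overrides `tree`).
#' @return A list of class `eval_report`: confusion counts `tp`, `fp`,
#'   `tn`, `fn`; `acc`, `sensitivity`, `specificity`, `ppv` in percent;
#'   `per_patient` (data.frame `patient_id`, `label`, `n_segments`,
#'   `acc_i`, `call`, `tie`); `patient_accuracy` in percent.
#' @export
evaluate_predictions <- function(tree, data, predictions = NULL) {
  if (nrow(data) == 0) stop("empty evaluation dataset")
  if (is.null(predictions)) predictions <- predict_class(tree, data)
  stopifnot(length(predictions) == nrow(data))
  pos <- "AF-HF"
  truth <- data$label
  tp <- sum(predictions == pos & truth == pos)
  fp <- sum(predictions == pos & truth != pos)
  tn <- sum(predictions != pos & truth != pos)
  fn <- sum(predictions != pos & truth == pos)
  total <- tp + fp + tn + fn

  per <- lapply(split(seq_len(total), data$patient_id), function(idx) {
    lab <- truth[idx[1]]
    n_hf <- sum(predictions[idx] == pos)
    tie <- n_hf * 2 == length(idx)
    call <- if (n_hf * 2 > length(idx) || tie) pos else "control"
    data.frame(patient_id = data$patient_id[idx[1]], label = lab,
               n_segments = length(idx),
               acc_i = 100 * mean(predictions[idx] == lab),
               call = call, tie = tie, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    acc = 100 * (tp + tn) / total,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    ppv = 100 * tp / (tp + fp),
    per_patient = per,
    patient_accuracy = 100 * mean(per$call == per$label)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> %d segments: ACC %.1f%% | sens %.1f%%",
                     " | spec %.1f%% | PPV %.1f%%\n"),
              x$tp + x$fp + x$tn + x$fn, x$acc, x$sensitivity,
              x$specificity, x$ppv))
  cat(sprintf("  patients: %d/%d correct by majority vote (%.1f%%)\n",
              sum(x$per_patient$call == x$per_patient$label),
              nrow(x$per_patient), x$patient_accuracy))
  invisible(x)
}

#' Majority-vote patient calls from per-patient accuracies
#'
#' Applies the 50% threshold rule directly to per-patient accuracies
#' (percent of segments classified correctly): a patient is called
#' correctly when `acc_i > 50`; at exactly 50 the vote ties and the call
#' goes to AF-HF, so tied AF-HF patients are counted correct and tied
#' controls incorrect.
#'
#' @param acc_i Numeric vector of per-patient accuracies in percent.
#' @param labels Class labels aligned with `acc_i`.
#' @return Logical vector: was each patient called correctly?
#' @export
majority_vote_correct <- function(acc_i, labels) {
  acc_i > 50 | (acc_i == 50 & labels == "AF-HF")
}

#' One-tailed Wilcoxon rank-sum test on a feature's class difference
#'
#' @param data Feature table with `label`.
#' @param feature Feature column name.
#' @param direction Alternative hypothesis: `"less"` (default) tests
#'   whether the feature is lower in AF-HF than in controls (the
#'   direction reported for spectral entropy), `"greater"` the reverse.
#' @return List with `p_value`, `statistic` and `degenerate` (TRUE when
#'   every value is tied, in which case `p_value` is 0.5).
#' @export
wilcoxon_feature_test <- function(data, feature,
                                  direction = c("less", "greater")) {
  direction <- match.arg(direction)
  x <- data[[feature]][data$label == "AF-HF"]
  y <- data[[feature]][data$label == "control"]
  if (length(x) == 0 || length(y) == 0)
    stop("both classes must be represented")
  if (length(unique(c(x, y))) == 1)
    return(list(p_value = 0.5, statistic = NA_real_, degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = direction))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       degenerate = FALSE)
}
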