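#' Pairwise Pearson correlations of features
#'
#' @param data Feature table (one row per segment).
#' @param features Character vector of feature columns.
#' @return Symmetric correlation matrix with unit diagonal.  A
#'   zero-variance feature yields `NA` correlations, which the selection
#'   gate treats as blocking (conservative).
#' @export
pairwise_correlations <- function(data, features = hrv_feature_names()) {
  if (nrow(data) < 3) stop("need at least 3 segments for correlations")
  X <- as.matrix(data[, features, drop = FALSE])
  suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
}

#' Correlation-gated greedy forward feature selection
#'
#' Starts from the empty set.  Each iteration evaluates every
#' not-yet-selected feature whose absolute Pearson correlation with every
#' already-selected feature is below `gate` (computed on the pooled
#' non-test segments), scoring the candidate set by the mean validation
#' accuracy across the patient-grouped folds of a decision tree trained
#' on `selected + candidate`.  The best candidate is accepted iff the
#' mean validation accuracy increases by at least `min_improve`;
#' otherwise selection stops.  A small positive `min_improve` keeps the
#' wrapper from chasing chance fluctuations of the validation estimate
#' (with `min_improve = 0` any nominal increase, however tiny, counts).
#' Ties between candidates are broken toward the lower mean
#' absolute correlation with the already-selected features, then by
#' canonical feature order, so the procedure is deterministic.
#'
#' @param data Feature table of the train+validation patients only (rows
#'   with an undefined feature value must already be removed).
#' @param folds List of folds, each a list with `train` and `validation`
#'   patient-id vectors (see [make_split_plan()]).
#' @param features Candidate feature names (default the canonical 14).
#' @param gate Absolute-correlation threshold (default 0.6): a candidate
#'   correlated at or above the gate with any selected feature is
#'   excluded from that iteration.
#' @param tree_cfg A [tree_config()].
#' @param min_improve Minimal validation-accuracy gain (as a fraction;
#'   default 0.005, i.e. half a percentage point) required to accept a
#'   candidate after the first.
#' @return A list of class `selection_result`: `selected` (ordered),
#'   `accuracy_trajectory`, `rejected_by_correlation` (named character
#'   vector: blocked feature -> blocking feature), `stop_reason`
#'   (`"no-improvement"` or `"exhausted"`).
#' @export
greedy_forward_select <- function(data, folds,
                                  features = hrv_feature_names(),
                                  gate = 0.6, tree_cfg = tree_config(),
                                  min_improve = 0.005) {
  if (nrow(data) == 0) stop("empty dataset")
  if (length(features) < 2) stop("need at least 2 candidate features")
  if (anyNA(data[, features])) stop("remove undefined feature values first")
  cmat <- pairwise_correlations(data, features)
  fold_rows <- lapply(folds, function(f)
    list(train = which(data$patient_id %in% f$train),
         validation = which(data$patient_id %in% f$validation)))

  selected <- character(0)
  trajectory <- numeric(0)
  rejected <- character(0)
  best_acc <- -Inf
  stop_reason <- "exhausted"
  repeat {
    remaining <- setdiff(features, selected)
    if (length(remaining) == 0) { stop_reason <- "exhausted"; break }
    gated <- logical(length(remaining))
    blocker <- character(length(remaining))
    if (length(selected) > 0) {
      for (k in seq_along(remaining)) {
        r <- abs(cmat[remaining[k], selected])
        bad <- is.na(r) | r >= gate
        if (any(bad)) {
          gated[k] <- TRUE
          blocker[k] <- selected[which(bad)[1]]
        }
      }
    }
    rejected[remaining[gated]] <- blocker[gated]
    cand <- remaining[!gated]
    if (length(cand) == 0) { stop_reason <- "exhausted"; break }

    acc <- vapply(cand, function(f)
      cv_accuracy(data, fold_rows, c(selected, f), tree_cfg), numeric(1))
    top <- which(acc == max(acc))
    if (length(top) > 1 && length(selected) > 0) {
      meanr <- vapply(cand[top], function(f)
        mean(abs(cmat[f, selected])), numeric(1))
      top <- top[meanr == min(meanr)]
    }
    pick <- cand[top[1]]  # final tie: canonical feature order
    if (max(acc) > best_acc + if (is.finite(best_acc)) min_improve else 0) {
      selected <- c(selected, pick)
      best_acc <- max(acc)
      trajectory <- c(trajectory, best_acc)
    } else {
      stop_reason <- "no-improvement"
      break
    }
  }
  structure(list(selected = selected,
                 accuracy_trajectory = trajectory,
                 rejected_by_correlation = rejected,
                 stop_reason = stop_reason),
            class = "selection_result")
}

cv_accuracy <- function(data, fold_rows, features, tree_cfg) {
  accs <- vapply(fold_rows, function(fr) {
    tree <- train_tree(data[fr$train, , drop = FALSE], features, tree_cfg)
    pred <- predict_class(tree, data[fr$validation, , drop = FALSE])
    mean(pred == data$label[fr$validation])
  }, numeric(1))
  mean(accs)
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n  selected:",
      paste(x$selected, collapse = ", "), "\n  validation accuracy:",
      paste(sprintf("%.3f", x$accuracy_trajectory), collapse = " -> "),
      "\n  stop reason:", x$stop_reason, "\n")
  invisible(x)
}
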