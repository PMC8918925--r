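#' Flatten an rpart classification tree
#'
#' Extracts the node structure of an `rpart` tree into parallel vectors
#' (split variable, threshold, children, leaf positive-class
#' probability) for the exact Shapley kernel.  Only numeric primary
#' splits are supported, which covers every tree this package trains.
#'
#' @param tree An `rpart` classification tree.
#' @param features Feature names defining the column order that
#'   explicand/background matrices will use.
#' @return List of vectors `var` (1-based feature index, 0 at leaves),
#'   `split`, `left`, `right`, `value` (probability of the first class
#'   level, AF-HF), plus `features`.
#' @keywords internal
flatten_tree <- function(tree, features) {
  frame <- tree$frame
  n <- nrow(frame)
  node_id <- as.integer(rownames(frame))
  var <- integer(n); thr <- numeric(n)
  left <- integer(n); right <- integer(n)
  is_leaf <- frame$var == "<leaf>"
  # rows of tree$splits line up with non-leaf frame rows (no competes or
  # surrogates are stored: maxcompete = maxsurrogate = 0)
  split_row <- cumsum(!is_leaf)
  for (i in seq_len(n)) {
    if (is_leaf[i]) next
    f <- match(as.character(frame$var[i]), features)
    if (is.na(f)) stop("tree splits on unknown feature: ", frame$var[i])
    var[i] <- f
    s <- tree$splits[split_row[i], , drop = FALSE]
    thr[i] <- s[, "index"]
    # ncat = -1: left child takes x < threshold; +1: left takes x >= threshold
    goes_left_lt <- s[, "ncat"] < 0
    kids <- match(c(node_id[i] * 2L, node_id[i] * 2L + 1L), node_id)
    if (goes_left_lt) { left[i] <- kids[1]; right[i] <- kids[2] }
    else { left[i] <- kids[2]; right[i] <- kids[1] }
  }
  # leaf value: posterior probability of the first class level (AF-HF),
  # as produced by predict(type = "prob") — yval2 holds the class counts
  # followed by the prior-adjusted class probabilities
  nclass <- length(attr(tree, "ylevels"))
  prob1 <- frame$yval2[, 1 + nclass + 1]
  list(var = var, split = thr, left = left, right = right,
       value = as.numeric(prob1), features = features)
}

predict_flat <- function(flat, X) {
  vapply(seq_len(nrow(X)), function(i) {
    t <- 1L
    while (flat$var[t] != 0L) {
      t <- if (X[i, flat$var[t]] < flat$split[t]) flat$left[t]
      else flat$right[t]
    }
    flat$value[t]
  }, numeric(1))
}

#' Exact interventional Shapley values of a tree's AF-HF score
#'
#' For each explicand row, computes the exact Shapley values of the
#' tree's positive-class (AF-HF) probability with respect to an
#' interventional background: the value of a feature coalition is the
#' tree's expected score when the coalition's features are taken from
#' the explicand and the rest from a background row, averaged over the
#' background sample.  The computation enumerates root-to-leaf paths and
#' uses the closed-form Shapley value of the resulting conjunction
#' games, so it is exact (no permutation sampling) and satisfies local
#' accuracy: each row's values sum to its score minus the mean
#' background score.
#'
#' @param tree An `rpart` tree from [train_tree()].
#' @param explicands Feature table rows to explain.
#' @param background Feature table rows serving as the reference
#'   distribution.
#' @param features Feature names (default: those the tree may use).
#' @return Matrix (explicands x features) of Shapley values.
#' @export
tree_shapley <- function(tree, explicands, background,
                         features = attr(tree$terms, "term.labels")) {
  flat <- flatten_tree(tree, features)
  X <- as.matrix(explicands[, features, drop = FALSE])
  B <- as.matrix(background[, features, drop = FALSE])
  phi <- tree_shapley_cpp(flat$var, flat$split, flat$left, flat$right,
                          flat$value, X, B)
  colnames(phi) <- features
  phi
}

#' Resampled Shapley feature importance
#'
#' Repeats the exact Shapley computation `n_runs` times, each run on a
#' fresh random subsample of segments (drawn with replacement) used as
#' both the explicand set and the background, and summarises each
#' feature's importance as the mean absolute Shapley value per run.  The
#' spread across runs (SD) therefore measures sampling variability
#' alone, since the per-run values are exact.
#'
#' @param tree A trained tree.
#' @param data Feature table (typically the development segments).
#' @param n_runs Number of resampling runs (default 1000).
#' @param n_samples Segments drawn per run (default 100).
#' @param seed Integer seed.
#' @param replace Draw with replacement (default TRUE; if FALSE,
#'   `n_samples` must not exceed `nrow(data)`).
#' @return A list of class `importance_report`: data.frame `importance`
#'   (feature, mean, sd, ordered by mean importance), `n_runs`,
#'   `n_samples`, `seed`.
#' @export
shapley_importance <- function(tree, data, n_runs = 1000,
                               n_samples = 100, seed = 1L,
                               replace = TRUE) {
  stopifnot(nrow(data) > 0, n_runs >= 1)
  if (!replace && n_samples > nrow(data))
    stop("n_samples exceeds dataset size with replacement disabled")
  features <- attr(tree$terms, "term.labels")
  set.seed(seed)
  per_run <- matrix(NA_real_, n_runs, length(features),
                    dimnames = list(NULL, features))
  for (r in seq_len(n_runs)) {
    idx <- sample.int(nrow(data), n_samples, replace = replace)
    sub <- data[idx, , drop = FALSE]
    phi <- tree_shapley(tree, sub, sub, features)
    per_run[r, ] <- colMeans(abs(phi))
  }
  imp <- data.frame(feature = features,
                    mean = colMeans(per_run),
                    sd = apply(per_run, 2, stats::sd),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$mean), ]
  rownames(imp) <- NULL
  structure(list(importance = imp, n_runs = n_runs,
                 n_samples = n_samples, seed = as.integer(seed)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> %d runs x %d samples\n",
              x$n_runs, x$n_samples))
  print(x$importance, digits = 4)
  invisible(x)
}
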