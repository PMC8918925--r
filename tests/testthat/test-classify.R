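test_that("the split plan reproduces the 32/8/12 patient protocol", {
  pats <- sprintf("p%02d", 1:52)
  labs <- rep(c("AF-HF", "control"), each = 26)
  plan <- make_split_plan(pats, labs, seed = 1)
  expect_length(plan$test, 12)
  expect_equal(sum(labs[match(plan$test, pats)] == "AF-HF"), 6)
  for (f in plan$folds) {
    expect_length(f$train, 32)
    expect_length(f$validation, 8)
    expect_equal(sum(labs[match(f$validation, pats)] == "AF-HF"), 4)
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(c(f$train, f$validation), plan$test), 0)
  }
  # validation folds partition the 40 non-test patients
  vals <- unlist(lapply(plan$folds, `[[`, "validation"))
  expect_setequal(vals, setdiff(pats, plan$test))
  expect_equal(anyDuplicated(vals), 0)
  # determinism
  expect_identical(plan, make_split_plan(pats, labs, seed = 1))
  expect_false(identical(plan$test,
                         make_split_plan(pats, labs, seed = 2)$test))
  expect_error(make_split_plan(pats[1:8], labs[c(1:4, 27:30)], seed = 1),
               "too small")
})

test_that("trees separate a separable feature and demand two classes", {
  df <- make_feature_dataset(n_per_class = 5, segs = 10, d = 30,
                             informative = "dc", seed = 2)
  tree <- train_tree(df, "dc")
  expect_equal(mean(hfstrat:::predict_class(tree, df) == df$label), 1)
  expect_error(train_tree(df[df$label == "AF-HF", ], "dc"), "both classes")
})

test_that("uniform priors lift minority-class sensitivity", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    n1 <- 40; n0 <- 360  # 10/90 imbalance, overlapping classes
    df <- data.frame(
      label = c(rep("AF-HF", n1), rep("control", n0)),
      x = c(rnorm(n1, 1), rnorm(n0, 0)))
    uni <- rpart::rpart(label ~ x, df, method = "class",
                        parms = list(prior = c(0.5, 0.5)),
                        control = rpart::rpart.control(minbucket = 5,
                                                       cp = 0.001))
    freq <- rpart::rpart(label ~ x, df, method = "class",
                         control = rpart::rpart.control(minbucket = 5,
                                                        cp = 0.001))
    sens <- function(fit) {
      pred <- predict(fit, df, type = "class")
      sum(pred == "AF-HF" & df$label == "AF-HF") / n1
    }
    if (sens(uni) > sens(freq)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("evaluation metrics agree with a brute-force recount", {
  set.seed(4)
  df <- make_feature_dataset(n_per_class = 6, segs = 8, seed = 4)
  for (i in 1:20) {
    pred <- sample(c("AF-HF", "control"), nrow(df), replace = TRUE)
    rep <- evaluate_predictions(NULL, df, predictions = pred)
    o <- oracle_confusion(pred, df$label)
    expect_equal(rep$tp, o$tp); expect_equal(rep$fp, o$fp)
    expect_equal(rep$tn, o$tn); expect_equal(rep$fn, o$fn)
    expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, nrow(df))
    expect_equal(rep$acc, o$acc, tolerance = 1e-9)
    expect_equal(rep$sensitivity, o$sens, tolerance = 1e-9)
    expect_equal(rep$specificity, o$spec, tolerance = 1e-9)
    expect_equal(rep$ppv, o$ppv, tolerance = 1e-9)
    expect_true(all(rep$per_patient$acc_i >= 0 &
                    rep$per_patient$acc_i <= 100))
  }
})

test_that("perfect predictions give perfect metrics", {
  df <- make_feature_dataset(n_per_class = 4, segs = 5, seed = 6)
  rep <- evaluate_predictions(NULL, df, predictions = df$label)
  expect_equal(c(rep$acc, rep$sensitivity, rep$specificity, rep$ppv),
               rep(100, 4))
  expect_equal(rep$patient_accuracy, 100)
})

test_that("patient votes follow the 50% rule with AF-HF tie-break", {
  df <- data.frame(patient_id = rep(c("a", "b"), each = 4),
                   label = rep(c("AF-HF", "control"), each = 4),
                   segment_idx = rep(1:4, 2))
  # patient a: 2/4 correct (tie) -> called AF-HF -> correct
  # patient b: 2/4 correct (tie) -> called AF-HF -> miscall
  pred <- c("AF-HF", "AF-HF", "control", "control",
            "control", "control", "AF-HF", "AF-HF")
  rep <- evaluate_predictions(NULL, df, predictions = pred)
  pp <- rep$per_patient[order(rep$per_patient$patient_id), ]
  expect_true(all(pp$tie))
  expect_equal(pp$call, c("AF-HF", "AF-HF"))
  expect_equal(rep$patient_accuracy, 50)
})

test_that("majority voting amplifies above-chance segment accuracy", {
  set.seed(8)
  p <- 0.65  # per-segment success probability
  seg_acc <- patient_acc <- numeric(30)
  for (i in 1:30) {
    correct <- matrix(rbinom(20 * 41, 1, p), nrow = 20)  # 20 patients
    seg_acc[i] <- mean(correct)
    patient_acc[i] <- mean(rowMeans(correct) > 0.5)
  }
  expect_gt(mean(patient_acc), mean(seg_acc))
})

test_that("rank-sum p-values match exact enumeration and edge cases", {
  df <- data.frame(label = rep(c("AF-HF", "control"), each = 20),
                   x = c(rnorm(20, -10), rnorm(20, 10)))
  # complete separation in the hypothesised direction
  expect_lt(wilcoxon_feature_test(df, "x")$p_value, 1e-6)
  # identical values in both groups
  tied <- data.frame(label = rep(c("AF-HF", "control"), each = 5),
                     x = rep(1, 10))
  res <- wilcoxon_feature_test(tied, "x")
  expect_equal(res$p_value, 0.5)
  expect_true(res$degenerate)
  # same distribution -> p near 0.5 on average
  set.seed(9)
  ps <- vapply(1:40, function(i) {
    d <- data.frame(label = rep(c("AF-HF", "control"), each = 15),
                    x = rnorm(30))
    wilcoxon_feature_test(d, "x")$p_value
  }, numeric(1))
  # mean of 40 null p-values: SD = 1/sqrt(12*40) ~ 0.046; allow 3 SD
  expect_lt(abs(mean(ps) - 0.5), 0.14)
  # exhaustive permutation oracle at small n
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(6, 0.5)
    d <- data.frame(label = c(rep("AF-HF", 7), rep("control", 6)),
                    x = c(x, y))
    expect_equal(wilcoxon_feature_test(d, "x")$p_value,
                 oracle_ranksum_p(x, y), tolerance = 1e-9)
  }
})
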