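test_that("cohort_config validates its parameters", {
  expect_error(cohort_config(mean_hr = c(250, 80)), "mean_hr")
  expect_error(cohort_config(cv_rr = 0), "cv_rr")
  expect_error(cohort_config(ar_rho = 1.2), "ar_rho")
  cfg <- cohort_config(mean_hr = 85)  # scalar recycles to both classes
  expect_equal(cfg$mean_hr, c(85, 85))
})

test_that("simulated series satisfy every RR-series invariant", {
  cfg <- cohort_config(n_per_class = 3, duration_h = 2, seed = 2)
  co <- simulate_cohort(cfg)
  expect_length(co, 6)
  for (s in co) {
    expect_s3_class(s, "rr_series")
    expect_true(all(s$rr > 0))
    expect_true(all(diff(s$beat_times) > 0))
    expect_equal(diff(s$beat_times), s$rr[-1] / 1000, tolerance = 1e-9)
    expect_equal(s$start_clock, 8 * 3600)
  }
  expect_equal(sum(vapply(co, `[[`, character(1), "label") == "AF-HF"), 3)
})

test_that("a fixed seed reproduces the cohort and manifest exactly", {
  cfg <- cohort_config(n_per_class = 2, duration_h = 1, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a, `[[`, "rr"), lapply(b, `[[`, "rr"))
  expect_identical(attr(a, "manifest"), attr(b, "manifest"))
  # different seed, different beats
  c2 <- simulate_cohort(cohort_config(n_per_class = 2, duration_h = 1,
                                      seed = 10))
  expect_false(identical(a[[1]]$rr, c2[[1]]$rr))
})

test_that("the deterministic limit collapses to the target heart rate", {
  cfg <- cohort_config(n_per_class = 1, duration_h = 0.5,
                       mean_hr = c(80, 80), cv_rr = c(1e-4, 1e-4),
                       circadian_amp = 0, artifact_rate = 0,
                       sd_hr_between = 0, sd_rho_between = 0, seed = 3)
  s <- simulate_patient(cfg, "control", 42)
  expect_equal(mean(s$rr), 60000 / 80, tolerance = 1e-3)
  expect_lt(sd(s$rr), 1)
})

test_that("per-class mean heart rate tracks its target", {
  # heterogeneity off isolates the generator's calibration
  cfg <- cohort_config(n_per_class = 5, duration_h = 2,
                       sd_hr_between = 0, sd_rho_between = 0,
                       artifact_rate = 0, seed = 4)
  co <- simulate_cohort(cfg)
  hr <- vapply(co, function(s) 60 * length(s$rr) / sum(s$rr / 1000),
               numeric(1))
  lab <- vapply(co, `[[`, character(1), "label")
  expect_equal(mean(hr[lab == "AF-HF"]), 91.6, tolerance = 2 / 91.6)
  expect_equal(mean(hr[lab == "control"]), 78.7, tolerance = 2 / 78.7)
  # with between-patient spread the class contrast survives
  cfg2 <- cohort_config(n_per_class = 10, duration_h = 1, seed = 5)
  co2 <- simulate_cohort(cfg2)
  hr2 <- vapply(co2, function(s) 60 * length(s$rr) / sum(s$rr / 1000),
                numeric(1))
  lab2 <- vapply(co2, `[[`, character(1), "label")
  expect_gt(mean(hr2[lab2 == "AF-HF"]) - mean(hr2[lab2 == "control"]), 4)
})

test_that("autocorrelation lowers spectral entropy class-wide", {
  cfg <- cohort_config(n_per_class = 4, duration_h = 1,
                       mean_hr = c(85, 85), cv_rr = c(0.22, 0.22),
                       ar_rho = c(0.9, 0.0), circadian_amp = 0,
                       sd_hr_between = 0, sd_rho_between = 0, seed = 6)
  ft <- feature_table(simulate_cohort(cfg))
  m <- tapply(ft$specen_rr, ft$label, mean)
  expect_lt(m[["AF-HF"]], m[["control"]])
})

test_that("artifact gaps shorten the recording without breaking it", {
  cfg <- cohort_config(n_per_class = 1, duration_h = 2,
                       artifact_rate = 10, seed = 8)
  with_gaps <- simulate_patient(cfg, "control", 77)
  cfg0 <- cfg; cfg0$artifact_rate <- 0
  without <- simulate_patient(cfg0, "control", 77)
  expect_lt(length(with_gaps$rr), length(without$rr))
  expect_true(all(with_gaps$rr > 0))
})

test_that("widening the class gap raises downstream accuracy", {
  accs <- vapply(c(0, 0.4, 1), function(g) {
    mean(vapply(1:5, function(sd_i) {
      cfg <- cohort_config(n_per_class = 5, duration_h = 1,
                           mean_hr = c(78.7 + g * 12.9, 78.7),
                           ar_rho = c(0.05 + g * 0.5, 0.05),
                           seed = 100 + sd_i)
      ft <- feature_table(simulate_cohort(cfg))
      pats <- unique(ft[, c("patient_id", "label")])
      test_p <- c(pats$patient_id[pats$label == "AF-HF"][1:2],
                  pats$patient_id[pats$label == "control"][1:2])
      tr <- ft[!ft$patient_id %in% test_p, ]
      te <- ft[ft$patient_id %in% test_p, ]
      tree <- train_tree(tr, hrv_feature_names(), tree_config())
      evaluate_predictions(tree, te)$acc
    }, numeric(1)))
  }, numeric(1))
  expect_gt(accs[3], accs[1])
  expect_true(all(diff(accs) > -2))  # monotone on average, small slack
})
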