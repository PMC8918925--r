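test_that("time-domain statistics match closed forms and the loop oracle", {
  td <- time_domain(c(800, 800, 800))
  expect_equal(td$mean, 800)
  expect_equal(td$sd, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(time_domain(c(800, 810, 800))$rmssd, 10)
  expect_true(is.na(time_domain(800)$mean))
  set.seed(7)
  x <- rnorm(300, 800, 50)
  td <- time_domain(x)
  o <- oracle_time_domain(x)
  expect_equal(td$mean, o$mean, tolerance = 1e-9)
  expect_equal(td$sd, o$sd, tolerance = 1e-9)
  expect_equal(td$rmssd, o$rmssd, tolerance = 1e-9)
})

test_that("PRSA capacity telescopes on a ramp and flags empty anchor sets", {
  rr <- 800 + 2 * (0:99)  # per-beat increment of 2 ms
  expect_equal(prsa_capacity(rr, "decel"), 2, tolerance = 1e-12)
  # strictly decreasing series has no deceleration anchors
  expect_true(is.na(prsa_capacity(rev(rr), "decel")))
  expect_true(is.na(prsa_capacity(rep(800, 3), "decel")))  # too short
  # anchors with >20% beat-to-beat jumps are excluded
  rr2 <- rep(800, 50); rr2[25] <- 1100  # +37.5% jump
  set.seed(1); rr3 <- 800 + cumsum(rnorm(50, 0, 4))
  expect_equal(prsa_capacity(rr3, "decel"),
               oracle_prsa(rr3, "decel"), tolerance = 1e-9)
  expect_equal(prsa_capacity(rr3, "accel"),
               oracle_prsa(rr3, "accel"), tolerance = 1e-9)
})

test_that("deceleration reserve vanishes on time-symmetric series", {
  half <- 800 + 5 * sin(seq(0, 4 * pi, length.out = 60))
  pal <- c(half, rev(half))  # palindrome: reversal-invariant
  dc <- prsa_capacity(pal, "decel")
  ac <- prsa_capacity(pal, "accel")
  expect_equal(dc, -ac, tolerance = 1e-9)
  expect_equal(deceleration_reserve(pal), 0, tolerance = 1e-9)
  # asymmetric shape: large deceleration steps, gentle accelerations ->
  # the reserve is positive, and matches the brute-force oracle
  saw <- rep(c(seq(760, 840, by = 8), seq(836, 764, by = -4)), 8)
  expect_gt(deceleration_reserve(saw), 0)
  expect_equal(deceleration_reserve(saw),
               oracle_prsa(saw, "decel") + oracle_prsa(saw, "accel"),
               tolerance = 1e-9)
  # undefined AC propagates
  ramp <- 800 + 2 * (0:49)
  expect_true(is.na(deceleration_reserve(ramp)))
})

test_that("Shannon entropy covers the constant, uniform and random cases", {
  expect_equal(shannon_entropy(rep(700, 50)), 0)
  # exactly n/16 samples per bin -> log2(16) = 4 bits
  u <- rep(seq(0.5, 15.5, by = 1), each = 10) / 16
  expect_equal(shannon_entropy(u, 16), 4, tolerance = 1e-12)
  set.seed(11)
  x <- rnorm(400)
  expect_equal(shannon_entropy(x), oracle_shannon(x), tolerance = 1e-12)
  expect_true(is.na(shannon_entropy(5)))
})

test_that("sample entropy matches the distance-matrix oracle", {
  # constant series: every template matches -> 0
  expect_equal(sample_entropy(rep(800, 50), r = 1), 0)
  # too short for any m+1 comparison
  expect_true(is.na(sample_entropy(c(1, 2, 3), m = 2)))
  set.seed(3)
  for (x in list(rnorm(200), rlnorm(200, log(800), 0.2))) {
    expect_equal(sample_entropy(x, m = 2, r_factor = 0.2),
                 oracle_sampen(x, 2, 0.2 * sd(x)), tolerance = 1e-9)
    expect_equal(sample_entropy(x, m = 3, r_factor = 0.15),
                 oracle_sampen(x, 3, 0.15 * sd(x)), tolerance = 1e-9)
  }
})

test_that("spectral entropy spans its [0,1] range as the spectrum demands", {
  # pure alternation: all power in one bin
  expect_lt(spectral_entropy(rep(c(800, 900), 50)), 0.05)
  expect_true(is.na(spectral_entropy(rep(800, 100))))  # zero power
  expect_true(is.na(spectral_entropy(rnorm(5))))       # too short
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(if (i %% 2) 375 else 374)
    se <- spectral_entropy(x)
    expect_gte(se, 0); expect_lte(se, 1)
    expect_equal(se, oracle_specen(x), tolerance = 1e-9)
  }
  # welch option stays in range
  expect_true(spectral_entropy(rnorm(375), method = "welch") <= 1)
})

test_that("extract_all composes exactly as the individual operations", {
  co <- simulate_cohort(cohort_config(n_per_class = 1, duration_h = 1,
                                      seed = 21))
  seg <- segment_series(co[[1]])[[3]]
  fv <- extract_features(seg)
  expect_named(fv, c(hrv_feature_names(), "ac"))
  expect_false(anyNA(fv[hrv_feature_names()]))
  rr <- seg$rr
  rel <- to_relative(rr)
  expect_identical(unname(fv["mean_rr"]), time_domain(rr)$mean)
  expect_identical(unname(fv["rmssd_relrr"]), time_domain(rel)$rmssd)
  expect_identical(unname(fv["dc"]), prsa_capacity(rr, "decel"))
  expect_identical(unname(fv["dr"]), deceleration_reserve(rr))
  expect_identical(unname(fv["shanen_rr"]), shannon_entropy(rr))
  expect_identical(unname(fv["sampen_relrr"]), sample_entropy(rel))
  expect_identical(unname(fv["specen_rr"]), spectral_entropy(rr))
  # constant segment: degenerate closed forms
  const <- extract_features(rep(820, 200))
  expect_equal(unname(const["mean_rr"]), 820)
  expect_equal(unname(const["mean_relrr"]), 100)
  expect_equal(unname(const[c("sd_rr", "rmssd_rr", "shanen_rr")]),
               c(0, 0, 0))
})

test_that("features scale as dimensional analysis requires", {
  set.seed(13)
  co <- simulate_cohort(cohort_config(n_per_class = 1, duration_h = 1,
                                      seed = 13))
  rr <- segment_series(co[[1]])[[2]]$rr
  f1 <- extract_features(rr)
  f2 <- extract_features(2.5 * rr)
  linear <- c("mean_rr", "sd_rr", "rmssd_rr", "dc", "dr", "ac")
  invariant <- c("mean_relrr", "sd_relrr", "rmssd_relrr", "shanen_rr",
                 "shanen_relrr", "sampen_rr", "sampen_relrr",
                 "specen_rr", "specen_relrr")
  expect_equal(f2[linear], 2.5 * f1[linear], tolerance = 1e-9)
  expect_equal(f2[invariant], f1[invariant], tolerance = 1e-9)
})

test_that("additive noise does not lower mean spectral entropy", {
  set.seed(17)
  base <- as.numeric(arima.sim(list(ar = 0.8), 375, sd = 10)) + 700
  means <- vapply(c(0, 10, 30), function(amp)
    mean(vapply(1:50, function(i)
      spectral_entropy(base + rnorm(375, 0, amp)), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("feature_table keeps lineage and flags undefined features", {
  co <- simulate_cohort(cohort_config(n_per_class = 2, duration_h = 1,
                                      seed = 31))
  ft <- feature_table(co)
  expect_true(all(c("patient_id", "segment_idx", "circadian_tag",
                    "start_clock", "label", hrv_feature_names(), "ac")
                  %in% names(ft)))
  expect_setequal(unique(ft$patient_id),
                  vapply(co, `[[`, character(1), "patient_id"))
  expect_equal(nrow(ft), sum(vapply(co, function(s)
    length(segment_series(s)), numeric(1))))
})
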