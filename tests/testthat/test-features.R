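test_that("the feature catalog is exactly the 52-name battery", {
  cat52 <- feature_catalog()
  expect_length(cat52, 52)
  expect_length(unique(cat52), 52)
  expect_true(all(c("X_MEAN", "Y_PFREQ", "Z_COV", "MAG_MAD", "XZ_CORR",
                    "CADENCE", "STD_STRIDE_TIME") %in% cat52))
  expect_equal(sum(grepl("^(X|Y|Z|MAG)_", cat52)), 44)
  expect_equal(sum(grepl("_CORR$", cat52)), 3)
})

test_that("signal features match the brute-force oracle on random series", {
  withr::with_seed(101, {
    for (i in 1:200) {
      n <- sample(30:300, 1)
      x <- switch(sample(3, 1),
                  rnorm(n, sample(c(-1, 0, 1), 1), runif(1, 0.01, 2)),
                  runif(n, -2, 2),
                  sin(2 * pi * runif(1, 0.5, 5) * (0:(n - 1)) / 30) +
                    rnorm(n, 0, 0.2))
      got <- signal_features(x, 30)
      want <- oracle_signal_features(x, 30)
      expect_equal(got, want, tolerance = 1e-9)
      # pinned identity: RMS^2 = MEAN^2 + STD^2 (population convention)
      expect_equal(got[["RMS"]]^2,
                   got[["MEAN"]]^2 + got[["STD"]]^2, tolerance = 1e-9)
    }
  })
})

test_that("lag-1 autocorrelation mode also matches the oracle", {
  withr::with_seed(55, {
    x <- rnorm(120)
    expect_equal(signal_features(x, 30, acc_lag = "one"),
                 oracle_signal_features(x, 30, acc_lag = "one"),
                 tolerance = 1e-9)
  })
})

test_that("degenerate and closed-form series give the expected features", {
  f <- signal_features(rep(-0.9, 50), 30)
  expect_equal(f[["MEAN"]], -0.9)
  expect_equal(f[["STD"]], 0)
  expect_equal(f[["RMS"]], 0.9)
  expect_equal(f[["COV"]], 0)
  expect_equal(f[["MCR"]], 0)
  expect_equal(f[["SMA"]], 0.9)
  expect_equal(f[["P2P"]], 0)
  expect_equal(f[["MAD"]], 0)
  expect_true(is.na(f[["PFREQ"]]) && is.na(f[["ACC"]]))

  # 2 Hz sine, amplitude 0.5, 10 s at 30 Hz
  t <- (0:299) / 30
  s <- 0.5 * sin(2 * pi * 2 * t + 0.3)
  fs <- signal_features(s, 30)
  expect_equal(fs[["PFREQ"]], 2.0)
  expect_equal(fs[["RMS"]], 0.5 / sqrt(2), tolerance = 1e-9)
  expect_equal(fs[["P2P"]], 1.0, tolerance = 0.01)
  expect_equal(fs[["MCR"]], 4.0, tolerance = 0.1)
  expect_gt(fs[["ACC"]], 0.9)  # period-lag autocorrelation of a sine

  alt <- rep(c(1, -1), 20)
  fa <- signal_features(alt, 30)
  expect_equal(fa[["RMS"]], 1)
  expect_equal(fa[["MEAN"]], 0)
  expect_true(is.infinite(fa[["COV"]]))

  expect_error(signal_features(rnorm(10), 30), ">= 30")
  expect_error(signal_features(c(rnorm(40), NA), 30), "finite")
})

test_that("peak frequency is exact to one FFT bin for pure tones", {
  for (f0 in c(0.7, 1.5, 2.1, 3.3)) {
    t <- (0:299) / 30
    x <- sin(2 * pi * f0 * t) + rnorm(300, 0, 0.01)
    expect_lt(abs(signal_features(x, 30)[["PFREQ"]] - f0), 0.1 + 1e-9)
  }
})

test_that("cross-axis correlations use masked samples and handle degeneracy", {
  t <- (0:299) / 30
  x <- sin(2 * pi * 2 * t)
  mask <- make_mask(rep(TRUE, 300))
  w1 <- make_window(x, x, -x)
  cc <- cross_axis_correlations(w1, mask)
  expect_equal(cc[["XY_CORR"]], 1.0)
  expect_equal(cc[["XZ_CORR"]], -1.0)
  w2 <- make_window(x, rnorm(300), cos(2 * pi * 2 * t))
  expect_lt(abs(cross_axis_correlations(w2, mask)[["XZ_CORR"]]), 1e-6)
  w3 <- make_window(x, rep(0.5, 300), x)
  cc3 <- cross_axis_correlations(w3, mask)
  expect_equal(cc3[["XY_CORR"]], 0)
  expect_true("XY_CORR" %in% attr(cc3, "flagged"))
  expect_error(cross_axis_correlations(w1, make_mask(rep(FALSE, 300))),
               ">= 30")
})

test_that("step detection recovers simulated step intervals", {
  sim <- simulate_subject(clean_profile(cadence = 120, cv = 0,
                                        noise_sd = 0.02), 60, 30,
                          seed = 8)
  wins <- segment_windows(sim$tracing)
  w <- wins[[3]]
  ev <- detect_steps(w, good_walking_mask(w))
  expect_gte(nrow(ev), 4)
  iv <- unlist(lapply(split(ev$time, ev$run), diff))
  expect_true(all(abs(iv - 0.5) < 0.02))
})

test_that("a pure-noise window yields too few steps and missing gait features", {
  withr::with_seed(33, {
    w <- make_window(rnorm(300, 0, 0.02), rnorm(300, -0.95, 0.02),
                     rnorm(300, 0, 0.02))
    m <- good_walking_mask(w)
    ev <- detect_steps(w, m)
    expect_lt(nrow(ev), 4)
    expect_true(all(is.na(gait_features(ev))))
  })
})

test_that("gait features follow their definitions on hand-built events", {
  g <- gait_features(c(0, 0.5, 1.0, 1.5, 2.0))
  expect_equal(g[["MEAN_STEP_TIME"]], 0.5)
  expect_equal(g[["STD_STEP_TIME"]], 0)
  expect_equal(g[["MEAN_STRIDE_TIME"]], 1.0)
  expect_equal(g[["STD_STRIDE_TIME"]], 0)
  expect_equal(g[["CADENCE"]], 120)

  g2 <- gait_features(c(0, 0.4, 1.0, 1.4, 2.0))
  expect_equal(g2[["MEAN_STEP_TIME"]], 0.5)
  expect_equal(g2[["STD_STEP_TIME"]], 0.1)  # population SD of .4,.6,.4,.6

  expect_true(all(is.na(gait_features(c(0, 0.5, 1.0)))))
})

test_that("gait features are shift-invariant and scale-equivariant", {
  ev <- c(0, 0.45, 0.95, 1.5, 2.0, 2.45)
  base <- gait_features(ev)
  expect_equal(gait_features(ev + 7), base)
  doubled <- gait_features(ev * 2)
  expect_equal(doubled[["CADENCE"]], base[["CADENCE"]] / 2)
  expect_equal(doubled[["MEAN_STEP_TIME"]], 2 * base[["MEAN_STEP_TIME"]])
})

test_that("step intervals never bridge masked-out gaps", {
  # two runs separated by a gap: intervals computed within runs only
  ev <- structure(data.frame(time = c(0.5, 1.0, 1.5, 6.0, 6.5, 7.0),
                             run = c(1L, 1L, 1L, 2L, 2L, 2L)),
                  class = c("step_events", "data.frame"))
  g <- gait_features(ev)
  expect_equal(g[["MEAN_STEP_TIME"]], 0.5)   # the 4.5 s gap is excluded
  expect_equal(g[["STD_STEP_TIME"]], 0)
})

test_that("featurized windows carry the full 52-feature row", {
  sim <- simulate_subject(clean_profile(cadence = 124, cv = 0.03,
                                        noise_sd = 0.03), 60, 30,
                          seed = 12)
  w <- segment_windows(sim$tracing)[[2]]
  m <- good_walking_mask(w)
  row <- featurize_window(w, m)
  expect_true(all(feature_catalog() %in% names(row)))
  expect_false(anyNA(row[feature_catalog()]))
  expect_equal(row$subject_id, w$subject_id)
})

test_that("cohort featurization row counts match accepted windows", {
  sim <- simulate_cohort(cohort_spec(1, 2, duration_s = 60, seed = 6))
  fz <- featurize_cohort(sim$tracings, sim$cohort)
  expect_equal(nrow(fz$features), sum(fz$qc$accepted))
  expect_true(all(fz$features$label %in% c("high", "low")))
  expect_equal(unique(fz$features$label[fz$features$subject_id ==
                                          sim$cohort$subject_id[1]]),
               "high")
})
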