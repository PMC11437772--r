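test_that("decorrelation curve matches hand-computed toy example", {
  # frames: f0 = (1,2,3,4), f1 = (2,3,4,5), f2 = (4,3,2,1) over 4 pixels
  frames <- array(0, c(3, 2, 2))
  frames[1, , ] <- matrix(1:4, 2, 2)
  frames[2, , ] <- matrix(2:5, 2, 2)
  frames[3, , ] <- matrix(4:1, 2, 2)
  st <- frame_stack(frames, fps = 1)
  cv <- compute_decorrelation_curve(st, max_lag_frames = 2)
  # lag 1: mean(rho(f0,f1), rho(f1,f2)) = mean(1, -1) = 0; lag 2: rho(f0,f2) = -1
  expect_equal(cv$corr, c(1, 0, -1), tolerance = 1e-12)
  expect_equal(cv$lags, c(0, 1, 2))
  expect_equal(cv$n_pairs, c(3L, 2L, 1L))
})

test_that("static and i.i.d.-noise stacks give the degenerate curves", {
  st <- static_stack(12)
  cv <- compute_decorrelation_curve(st, max_lag_frames = 10)
  expect_equal(cv$corr, rep(1, 11), tolerance = 1e-12)

  noise <- random_stack(12, 32, 32, seed = 42)
  cvn <- compute_decorrelation_curve(noise, max_lag_frames = 10)
  expect_equal(cvn$corr[1], 1)
  expect_lt(max(abs(cvn$corr[-1])), 4 / sqrt(32 * 32))
})

test_that("degenerate zero-variance frame is reported by index", {
  frames <- array(sample(1:9, 12, TRUE), c(3, 2, 2))
  frames[2, , ] <- 7
  st <- frame_stack(frames, fps = 30)
  expect_error(compute_decorrelation_curve(st, 2), "frame 2")
})

test_that("curve estimator equals brute-force double loop on random stacks", {
  for (seed in 1:12) {
    set.seed(seed)
    st <- random_stack(sample(5:20, 1), sample(4:16, 1), sample(4:16, 1),
                       seed = seed)
    k <- min(4L, n_frames(st) - 1L)
    cv <- compute_decorrelation_curve(st, k)
    expect_equal(cv$corr, brute_decorrelation(st, k), tolerance = 1e-12)
  }
})

test_that("first-frame-reference mode correlates against frame 1 only", {
  st <- random_stack(8, 6, 6, seed = 3)
  cv <- compute_decorrelation_curve(st, 4, method = "first_frame")
  for (k in 1:4)
    expect_equal(cv$corr[k + 1],
                 pearson_frames(st$frames[1, , ], st$frames[1 + k, , ]),
                 tolerance = 1e-12)
  expect_equal(cv$n_pairs, rep(1L, 5))
})

test_that("tLASCA reproduces hand-computed values and the pixel-loop oracle", {
  # 1 pixel, intensities (2, 4): sample sd sqrt(2), mean 3
  st1 <- frame_stack(array(c(2, 4), c(2, 1, 1)), fps = 30)
  expect_equal(as.numeric(compute_tlasca(st1)), sqrt(2) / 3, tolerance = 1e-9)

  # second pixel constant 5 contributes 0; spatial mean halves it
  st2 <- frame_stack(array(c(2, 4, 5, 5), c(2, 1, 2)), fps = 30)
  expect_equal(as.numeric(compute_tlasca(st2)), sqrt(2) / 6, tolerance = 1e-9)

  # constant positive video -> exactly 0
  expect_equal(as.numeric(compute_tlasca(static_stack(6))), 0)

  for (seed in 1:10) {
    st <- random_stack(sample(3:10, 1), sample(3:8, 1), sample(3:8, 1),
                       seed = 100 + seed)
    expect_equal(as.numeric(compute_tlasca(st)), brute_tlasca(st),
                 tolerance = 1e-12)
  }
})

test_that("zero-temporal-mean pixels follow the configured policy", {
  frames <- array(c(0, 0, 2, 4), c(2, 1, 2))  # pixel 1 all-zero
  st <- frame_stack(frames, fps = 30)
  expect_message(v <- compute_tlasca(st), "1 zero-temporal-mean")
  expect_equal(as.numeric(v), sqrt(2) / 3, tolerance = 1e-9)
  expect_equal(attr(v, "n_excluded"), 1L)
  expect_error(compute_tlasca(st, zero_mean = "raise"), "zero temporal mean")
})

test_that("inertia moment matches enumerated co-occurrence examples", {
  # 1 pixel, quantized history (0, 1, 0) at 2 levels: transitions (0,1),(1,0)
  st <- frame_stack(array(c(0, 128, 0), c(3, 1, 1)), fps = 30)
  expect_equal(compute_inertia_moment(st, levels = 2), 1.0)

  # 2 pixels over 2 frames at 4 levels: histories (0,3) and (3,3)
  st2 <- frame_stack(array(c(0, 192, 192, 192), c(2, 1, 2)), fps = 30)
  expect_equal(compute_inertia_moment(st2, levels = 4), 4.5)

  expect_equal(compute_inertia_moment(static_stack(8)), 0)
})

test_that("inertia moment equals the THSP dictionary oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    st <- random_stack(sample(3:10, 1), sample(3:8, 1), sample(3:8, 1),
                       seed = 200 + seed)
    lv <- sample(c(2L, 4L, 8L, 256L), 1)
    expect_equal(compute_inertia_moment(st, levels = lv),
                 brute_inertia_moment(st, lv), tolerance = 1e-12)
  }
})

test_that("inertia moment validates levels against bit depth", {
  st <- random_stack(4, 4, 4)
  expect_error(compute_inertia_moment(st, levels = 512), "exceeds")
  expect_error(compute_inertia_moment(st, levels = 1), ">= 2")
})

test_that("intensity rescaling leaves curve and tLASCA unchanged, and IM in data-range mode", {
  st <- random_stack(8, 8, 8, seed = 9)
  st$frames <- st$frames %/% 4 + 1          # headroom for scaling
  scaled <- st
  scaled$frames <- st$frames * 3
  cv <- compute_decorrelation_curve(st, 5)
  cv_s <- compute_decorrelation_curve(scaled, 5)
  expect_equal(cv$corr, cv_s$corr, tolerance = 1e-12)
  expect_equal(as.numeric(compute_tlasca(st)),
               as.numeric(compute_tlasca(scaled)), tolerance = 1e-12)
  expect_equal(compute_inertia_moment(st, levels = 16, range = "data"),
               compute_inertia_moment(scaled, levels = 16, range = "data"))
})

test_that("analyze_stack composes the three coefficients and handles static input", {
  st <- simulate_speckle_stack(speckle_sim_config(
    n_frames = 120, height = 32, width = 32, tau_field = 0.5, seed = 4))
  res <- analyze_stack(st, channel = "RED")
  expect_s3_class(res, "speckle_coefficients")
  expect_equal(res$channel, "RED")
  expect_true(res$tau > 0 && res$tlasca > 0 && res$inertia_moment > 0)
  expect_true(is.na(res$fit_error))
  expect_equal(res$tau_star, log(res$tau))

  # identical input and config -> identical record
  res2 <- analyze_stack(st, channel = "RED")
  expect_identical(res, res2)

  stat <- analyze_stack(static_stack(10))
  expect_true(is.na(stat$tau))
  expect_match(stat$fit_error, "no measurable decay")
  expect_equal(stat$tlasca, 0)
  expect_equal(stat$inertia_moment, 0)
})

test_that("coefficient and curve CSV writers emit the contracted schema", {
  st <- simulate_speckle_stack(speckle_sim_config(
    n_frames = 60, height = 16, width = 16, seed = 5))
  res <- analyze_stack(st)
  p <- withr::local_tempfile(fileext = ".csv")
  write_coefficients_csv(res, p, config_comment = "test")
  df <- read.csv(p, comment.char = "#")
  expect_named(df, c("source_id", "channel", "tau", "tau_star", "beta",
                     "rmse", "converged", "fit_error", "tlasca", "im"))
  expect_equal(df$tau, res$tau, tolerance = 1e-10)

  cv <- compute_decorrelation_curve(st, 10)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, p2)
  df2 <- read.csv(p2, comment.char = "#")
  expect_named(df2, c("lag_s", "corr", "n_pairs"))
  expect_equal(nrow(df2), 11)
})
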