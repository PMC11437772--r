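test_that("first_derivative applies central/one-sided differences", {
  expect_equal(first_derivative(0:4, rep(7, 5)), rep(0, 5))
  expect_equal(first_derivative(0:4, 2 * (0:4)), rep(2, 5))
  expect_equal(first_derivative(c(0, 1, 2), c(0, 1, 4)), c(1, 2, 3))
  expect_error(first_derivative(c(0, 0, 1), c(1, 2, 3)), "duplicate")
  expect_error(first_derivative(0, 1), ">= 2")
})

test_that("derivative of a cumulative polynomial recovers the signal at interior points", {
  t <- seq(0, 2, by = 0.1)
  # linear integrand: exact everywhere
  expect_equal(first_derivative(t, 3 * t), rep(3, length(t)))
  # quadratic integrand t^2: central differences are exact for the cubic
  # cumulative only up to O(dt^2); check interior points
  cumq <- t^3 / 3
  d <- first_derivative(t, cumq)
  interior <- 2:(length(t) - 1)
  expect_equal(d[interior], t[interior]^2 + 0.1^2 / 3, tolerance = 1e-12)
})

test_that("sphere_equivalent_area matches the closed form", {
  expect_equal(sphere_equivalent_area(4 * pi / 3), 4 * pi, tolerance = 1e-9)
  expect_equal(sphere_equivalent_area(4 * pi / 3 * 8), 16 * pi,
               tolerance = 1e-9)
  expect_equal(sphere_equivalent_area(268.0826), 201.0619, tolerance = 1e-4)
  expect_error(sphere_equivalent_area(0), "positive")
  expect_error(sphere_equivalent_area(-3), "positive")
})

test_that("detect_considerable_change flags steps and spares flat series", {
  set.seed(1)
  flat <- rnorm(40, 10, 0.5)
  flags <- detect_considerable_change(flat, 1:20, k = 3)
  expect_true(mean(flags) < 0.1)

  stepped <- c(rnorm(20, 10, 0.5), rnorm(20, 10 + 10 * 0.5, 0.5))
  flags2 <- detect_considerable_change(stepped, 1:20, k = 3)
  expect_true(all(flags2[21:40]))

  # direction matters: a decrease is invisible to the "increase" rule
  dropped <- c(rnorm(20, 10, 0.5), rnorm(20, 5, 0.5))
  expect_false(any(detect_considerable_change(dropped, 1:20, k = 3)[21:40]))
  expect_true(all(detect_considerable_change(dropped, 1:20, k = 3,
                                             direction = "decrease")[21:40]))
})

test_that("zero baseline dispersion falls back to a relative threshold", {
  vals <- c(rep(10, 10), rep(12, 5))
  expect_message(flags <- detect_considerable_change(vals, 1:10, k = 3),
                 "relative threshold")
  expect_true(all(flags[11:15]))   # 20% change > 10% fallback
  expect_message(f2 <- detect_considerable_change(c(rep(10, 10), rep(10.5, 5)),
                                                  1:10, k = 3))
  expect_false(any(f2))
})

test_that("raising k never increases the number of flagged epochs", {
  set.seed(7)
  vals <- c(rnorm(20, 0, 1), rnorm(30, 3, 1))
  counts <- vapply(c(1, 2, 3, 5, 8), function(k)
    sum(detect_considerable_change(vals, 1:20, k = k)), 0)
  expect_true(all(diff(counts) <= 0))
})

make_toy_records <- function(step_tau = 0, step_cf = 0, step_resp = 0,
                             n_base = 15, n_post = 25) {
  n <- n_base + n_post
  set.seed(3)
  data.frame(
    apple_id = "a1",
    time_h = seq(0, by = 8 / 60, length.out = n),
    phase = c(rep("preconditioning", n_base), rep("zero_oxygen", n_post)),
    tau_star_ir = rnorm(n, 0.5, 0.02) + c(rep(0, n_base), rep(step_tau, n_post)),
    tau_star_red = rnorm(n, 0.5, 0.02),
    cf = rnorm(n, 300, 2) + c(rep(0, n_base), rep(step_cf, n_post)),
    respiration = rnorm(n, 10, 0.1) + c(rep(0, n_base), rep(step_resp, n_post)))
}

test_that("expert 2-of-3 rule labels per its vote count", {
  # all flat -> aerobic
  lab0 <- expert_label(make_toy_records())
  expect_true(all(lab0$label == "aerobic"))

  # tau and CF step up -> stress from the step onward
  lab2 <- expert_label(make_toy_records(step_tau = 1, step_cf = 60))
  expect_true(all(lab2$label[16:40] == "hypoxic_stress"))
  expect_true(all(lab2$label[1:15] == "aerobic"))

  # only CF steps -> 1-of-3 insufficient
  lab1 <- expert_label(make_toy_records(step_cf = 60))
  expect_true(all(lab1$label == "aerobic"))
})

test_that("expert_label validates inputs and is order-invariant across apples", {
  rec <- make_toy_records(step_tau = 1, step_resp = 3)
  expect_error(expert_label(rec[setdiff(names(rec), "cf")]), "cf")

  rec2 <- rec; rec2$apple_id <- "a2"
  both <- rbind(rec, rec2)
  shuffled <- both[rev(seq_len(nrow(both))), ]
  l1 <- expert_label(both)
  l2 <- expert_label(shuffled)
  expect_equal(l1[order(l1$apple_id, l1$time_h), "label"],
               l2[order(l2$apple_id, l2$time_h), "label"])
})

test_that("CF normalization emits a baseline-relative column", {
  lab <- expert_label(make_toy_records(), normalize_cf = TRUE)
  expect_true("cf_norm" %in% names(lab))
  expect_equal(median(lab$cf_norm[lab$phase == "preconditioning"]), 1,
               tolerance = 1e-9)
})

test_that("epoch and phenotype CSV ingestion validates headers and values", {
  sim <- simulate_experiment(experiment_sim_config(n_apples = 3, seed = 4))
  ep <- withr::local_tempfile(fileext = ".csv")
  ph <- withr::local_tempfile(fileext = ".csv")
  write.csv(sim$epochs, ep, row.names = FALSE)
  write.csv(sim$phenotypes, ph, row.names = FALSE)
  expect_silent(df <- read_epoch_table(ep))
  expect_equal(nrow(df), nrow(sim$epochs))
  phe <- read_phenotype_table(ph)
  expect_equal(phe$area, sphere_equivalent_area(phe$volume), tolerance = 1e-9)

  bad <- sim$epochs[setdiff(names(sim$epochs), "cf")]
  write.csv(bad, ep, row.names = FALSE)
  expect_error(read_epoch_table(ep), "cf")

  badph <- sim$phenotypes
  badph$area <- badph$area * 1.5
  write.csv(badph, ph, row.names = FALSE)
  expect_error(read_phenotype_table(ph), "inconsistent")
})

test_that("assemble_features builds the seven-predictor table", {
  sim <- simulate_experiment(experiment_sim_config(n_apples = 4, seed = 6))
  lab <- expert_label(sim$epochs)
  feats <- assemble_features(lab, sim$phenotypes)
  expect_true(all(c("tau_star_ir", "tau_star_red", "cf", "d_respiration",
                    "mass", "firmness", "ssc", "label") %in% names(feats)))
  expect_equal(nrow(feats), nrow(sim$epochs))
  # derivative column matches a per-apple recomputation
  a1 <- feats[feats$apple_id == feats$apple_id[1], ]
  expect_equal(a1$d_respiration,
               first_derivative(a1$time_h, a1$respiration))
})
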