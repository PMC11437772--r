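test_that("the variant registry mirrors the twelve-row design", {
  v <- model_variants()
  expect_length(v, 12)
  bases <- c("tau_star_ir", "tau_star_red", "cf", "d_respiration")
  for (i in 1:4) expect_equal(v[[i]]$predictors, bases[i])
  for (i in 5:8) expect_equal(v[[i]]$predictors, c(bases[i - 4], "mass"))
  for (i in 9:12) expect_equal(v[[i]]$predictors,
                               c(bases[i - 8], "mass", "firmness", "ssc"))
  expect_equal(vapply(v, `[[`, 1L, "variant_id"), 1:12)
})

test_that("confusion_metrics matches hand arithmetic and handles degeneracy", {
  m <- confusion_metrics(tp = 50, fp = 0, fn = 0, tn = 50)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  m2 <- confusion_metrics(tp = 8, fp = 2, fn = 4, tn = 6)
  expect_equal(m2$accuracy, 0.70)
  expect_equal(m2$precision, 0.80)
  expect_equal(m2$recall, 2 / 3, tolerance = 1e-9)
  expect_equal(m2$f1, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3), tolerance = 1e-9)
  expect_false(m2$flagged)

  expect_warning(m3 <- confusion_metrics(tp = 0, fp = 0, fn = 5, tn = 5),
                 "zero denominator")
  expect_equal(m3$precision, 0)
  expect_equal(m3$recall, 0)
  expect_equal(m3$f1, 0)
  expect_equal(m3$accuracy, 0.5)
  expect_true(m3$flagged)
  expect_error(confusion_metrics(0, 0, 0, 0), "all counts zero")
})

make_separable <- function(n = 200, seed = 1) {
  set.seed(seed)
  y <- rep(c("aerobic", "hypoxic_stress"), each = n / 2)
  data.frame(
    label = y,
    tau_star_ir = as.numeric(y == "hypoxic_stress") + rnorm(n, 0, 0.01),
    tau_star_red = rnorm(n), cf = rnorm(n), d_respiration = rnorm(n),
    mass = rnorm(n, 164, 13), firmness = rnorm(n, 41, 3),
    ssc = rnorm(n, 12.7, 0.9))
}

test_that("a separable table yields perfect test metrics and unit gain", {
  df <- make_separable()
  rep1 <- train_evaluate(df, model_variants()[[1]], seed = 5, n_splits = 5)
  expect_equal(unname(rep1$accuracy["test"]), 1.0)
  expect_equal(unname(rep1$precision["test"]), 1.0)
  expect_equal(unname(rep1$recall["test"]), 1.0)
  expect_equal(unname(rep1$f1["test"]), 1.0)
  # single-predictor variant: gain map is {predictor: 1}
  expect_equal(rep1$gain, c(tau_star_ir = 1))
  expect_equal(rep1$backend, "specklestress-gbdt")
})

test_that("permuted labels score at the analytic majority-class null", {
  set.seed(42)
  df <- make_separable(n = 300)
  df$label <- sample(df$label)        # break the feature-label link
  rep1 <- train_evaluate(df, model_variants()[[1]], seed = 6, n_splits = 20)
  # balanced classes: null accuracy 0.5; MC sigma of the 20-split mean
  ps <- rep1$per_split$test_accuracy
  mc_sigma <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(rep1$accuracy["test"] - 0.5),
            max(3 * mc_sigma, 3 * sqrt(0.25 / 90) / sqrt(20)))
})

test_that("reports are bit-identical under a fixed seed", {
  df <- make_separable(n = 120, seed = 3)
  df$tau_star_ir <- df$tau_star_ir + rnorm(120, 0, 0.8)  # imperfect signal
  r1 <- train_evaluate(df, model_variants()[[5]], seed = 17, n_splits = 4)
  r2 <- train_evaluate(df, model_variants()[[5]], seed = 17, n_splits = 4)
  expect_identical(r1, r2)
  r3 <- train_evaluate(df, model_variants()[[5]], seed = 18, n_splits = 4)
  expect_false(identical(r1$per_split, r3$per_split))
})

test_that("gain normalizes to 1 and near-constant features earn almost none", {
  df <- make_separable(n = 200, seed = 9)
  df$mass <- 164                      # uninformative constant
  rep5 <- train_evaluate(df, model_variants()[[5]], seed = 7, n_splits = 5)
  expect_equal(sum(rep5$gain), 1, tolerance = 1e-9)
  expect_lt(rep5$gain["mass"], 0.05)
})

test_that("train metrics dominate test metrics on noisy data", {
  set.seed(10)
  n <- 300
  y <- rep(c("aerobic", "hypoxic_stress"), each = n / 2)
  df <- data.frame(label = y,
                   tau_star_ir = as.numeric(y == "hypoxic_stress") + rnorm(n, 0, 1.2))
  rep1 <- train_evaluate(df, model_variants()[[1]], seed = 8, n_splits = 10)
  for (m in c("accuracy", "precision", "recall", "f1"))
    expect_gte(rep1[[m]]["train"], rep1[[m]]["test"])
})

test_that("run_variant_suite shares splits and flags missing predictors", {
  sim <- simulate_experiment(experiment_sim_config(n_apples = 6, seed = 15))
  feats <- assemble_features(expert_label(sim$epochs), sim$phenotypes)
  reports <- run_variant_suite(feats, seed = 21, n_splits = 3, nrounds = 50)
  expect_length(reports, 12)
  # shared seed -> identical split column across variants is implied by
  # determinism of make_splits; check paired per-split frames line up
  expect_equal(reports[[1]]$per_split$split, reports[[7]]$per_split$split)
  df <- reports_to_df(reports)
  expect_equal(nrow(df), 12)
  expect_true(all(is.na(df$gain_mass[1:4])))

  expect_error(run_variant_suite(feats[setdiff(names(feats), "ssc")],
                                 seed = 1), "ssc")
})

test_that("group-by-apple split mode keeps apples intact across partitions", {
  sim <- simulate_experiment(experiment_sim_config(n_apples = 8, seed = 19))
  feats <- assemble_features(expert_label(sim$epochs), sim$phenotypes)
  rep1 <- train_evaluate(feats, model_variants()[[1]], seed = 4,
                         n_splits = 2, group_by_apple = TRUE, nrounds = 50)
  expect_s3_class(rep1, "classifier_report")
})
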