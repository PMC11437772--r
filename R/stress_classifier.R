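#' Registry of the twelve predictor-set model variants
#'
#' Variants 1-4 use exactly one base signal (tau*_IR, tau*_RED, CF,
#' Delta-respiration); variants 5-8 add fruit mass (still non-destructive);
#' variants 9-12 add mass, firmness and soluble solids content (destructive
#' measurements).
#'
#' @return A list of 12 `model_variant` objects, each a list with
#'   `variant_id` and `predictors`.
#' @export
model_variants <- function() {
  bases <- c("tau_star_ir", "tau_star_red", "cf", "d_respiration")
  extras <- list(character(0), "mass", c("mass", "firmness", "ssc"))
  out <- list()
  id <- 0L
  for (ex in extras) for (b in bases) {
    id <- id + 1L
    out[[id]] <- structure(list(variant_id = id, predictors = c(b, ex)),
                           class = "model_variant")
  }
  out
}

#' Confusion-matrix performance metrics
#'
#' Accuracy, precision, recall and F1 from raw counts, with the stress class
#' positive. Ratios with a zero denominator are reported as 0 and flagged
#' (with a warning) rather than NaN.
#'
#' @param tp,fp,fn,tn Non-negative counts; their total must be positive.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, and `flagged`
#'   (TRUE when any ratio had a zero denominator).
#' @examples
#' confusion_metrics(tp = 8, fp = 2, fn = 4, tn = 6)
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all counts zero")
  flagged <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { flagged <<- TRUE; return(0) }
    num / den
  }
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (precision + recall == 0) { flagged <- TRUE; 0 }
        else 2 * precision * recall / (precision + recall)
  if (flagged)
    warning("zero denominator in confusion metrics; reporting 0")
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1, flagged = flagged)
}

# shared split generator: same (n, labels, seed) -> same splits for every
# variant, enabling paired comparisons. Stratified by class by default.
make_splits <- function(labels, n_splits, train_frac, seed,
                        stratify = TRUE, groups = NULL) {
  n <- length(labels)
  with_local_seed(seed, {
    lapply(seq_len(n_splits), function(s) {
      for (attempt in seq_len(10L)) {
        if (!is.null(groups)) {
          gu <- unique(groups)
          gtrain <- sample(gu, max(1L, round(train_frac * length(gu))))
          train <- which(groups %in% gtrain)
        } else if (stratify) {
          train <- unlist(lapply(split(seq_len(n), labels), function(idx)
            sample(idx, max(1L, round(train_frac * length(idx))))))
          train <- sort(train)
        } else {
          train <- sort(sample(n, round(train_frac * n)))
        }
        if (length(unique(labels[train])) >= 2L &&
            length(train) < n) return(train)
        message("single-class training split; resampling (attempt ",
                attempt, ")")
      }
      stop("could not draw a two-class training split in 10 attempts")
    })
  })
}

#' Train and evaluate one model variant
#'
#' Runs `n_splits` independent random 70/30 train/test splits (repeated
#' random subsampling, stratified by class unless grouped). Per split, fits
#' a gradient-boosted decision-tree binary classifier — logistic
#' (cross-entropy) objective, 500 boosting rounds, at most 6 leaves per
#' tree, learning rate 0.05 — on the variant's predictors, and scores both
#' partitions at a 0.5 probability threshold with `hypoxic_stress` as the
#' positive class. Reports the mean of each metric over splits, and the
#' mean per-feature gain importance normalized to sum to 1.
#'
#' @param records Feature table carrying the variant's predictors and a
#'   `label` column (`"hypoxic_stress"` / `"aerobic"`).
#' @param variant A `model_variant` (see [model_variants()]).
#' @param seed Split/RNG seed; identical seeds give identical splits across
#'   variants and bit-identical reports.
#' @param n_splits Number of random splits (default 20).
#' @param train_frac Training fraction (default 0.7).
#' @param stratify Stratify splits by class (default TRUE).
#' @param group_by_apple Split at the apple level instead of the epoch level
#'   (avoids within-fruit leakage; off by default to match the
#'   observation-level protocol). Requires an `apple_id` column.
#' @param nrounds,num_leaves,learning_rate Boosting hyperparameters; the
#'   defaults are the fixed regime used throughout.
#' @return A `classifier_report`: list with `variant_id`, `predictors`,
#'   metric summaries (`accuracy`, `precision`, `recall`, `f1`, each a
#'   named `c(test, train)` pair of split means), `gain` (named, sums
#'   to 1), `per_split` (data frame of per-split metrics), `n_splits`,
#'   `seed`, `backend`.
#' @export
train_evaluate <- function(records, variant, seed, n_splits = 20L,
                           train_frac = 0.7, stratify = TRUE,
                           group_by_apple = FALSE, nrounds = 500L,
                           num_leaves = 6L, learning_rate = 0.05) {
  stopifnot(inherits(variant, "model_variant"))
  if (!"label" %in% names(records)) stop("records must carry a `label` column")
  missing <- setdiff(variant$predictors, names(records))
  if (length(missing))
    stop("missing predictor column(s): ", paste(missing, collapse = ", "))
  y <- as.numeric(records$label == "hypoxic_stress")
  if (length(unique(y)) < 2L) stop("need both classes present")
  X <- as.matrix(records[variant$predictors])
  storage.mode(X) <- "double"
  groups <- if (group_by_apple) {
    if (!"apple_id" %in% names(records)) stop("group mode needs `apple_id`")
    records$apple_id
  } else NULL

  splits <- make_splits(records$label, n_splits, train_frac, seed,
                        stratify = stratify, groups = groups)
  p <- length(variant$predictors)
  gains <- matrix(0, n_splits, p, dimnames = list(NULL, variant$predictors))
  per_split <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    train <- splits[[s]]
    fit <- .gbdt_fit_cpp(X[train, , drop = FALSE], y[train],
                         as.integer(nrounds), as.integer(num_leaves),
                         learning_rate, 20L, 0, 1e-3)
    g <- fit$feature_gain
    gains[s, ] <- if (sum(g) > 0) g / sum(g) else rep(1 / p, p)
    m_test <- split_metrics(fit, X[-train, , drop = FALSE], y[-train])
    m_train <- split_metrics(fit, X[train, , drop = FALSE], y[train])
    # F1 harmonic-mean identity is enforced per split before averaging
    stopifnot(isTRUE(all.equal(
      m_test$f1,
      if (m_test$precision + m_test$recall == 0) 0 else
        2 * m_test$precision * m_test$recall /
        (m_test$precision + m_test$recall))))
    per_split[[s]] <- data.frame(
      split = s,
      test_accuracy = m_test$accuracy, test_precision = m_test$precision,
      test_recall = m_test$recall, test_f1 = m_test$f1,
      train_accuracy = m_train$accuracy, train_precision = m_train$precision,
      train_recall = m_train$recall, train_f1 = m_train$f1)
  }
  ps <- do.call(rbind, per_split)
  pair <- function(metric) c(test = mean(ps[[paste0("test_", metric)]]),
                             train = mean(ps[[paste0("train_", metric)]]))
  gain <- colMeans(gains)
  gain <- gain / sum(gain)
  structure(list(variant_id = variant$variant_id,
                 predictors = variant$predictors,
                 accuracy = pair("accuracy"), precision = pair("precision"),
                 recall = pair("recall"), f1 = pair("f1"),
                 gain = gain, per_split = ps,
                 n_splits = as.integer(n_splits), seed = as.integer(seed),
                 backend = "specklestress-gbdt"),
            class = "classifier_report")
}

split_metrics <- function(fit, X, y) {
  pred <- as.numeric(.gbdt_predict_cpp(fit, X) >= 0.5)
  suppressWarnings(confusion_metrics(tp = sum(pred == 1 & y == 1),
                                     fp = sum(pred == 1 & y == 0),
                                     fn = sum(pred == 0 & y == 1),
                                     tn = sum(pred == 0 & y == 0)))
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> variant %d [%s]\n", x$variant_id,
              paste(x$predictors, collapse = ", ")))
  for (m in c("accuracy", "precision", "recall", "f1"))
    cat(sprintf("  %-9s test %.3f (train %.3f)\n", m, x[[m]]["test"],
                x[[m]]["train"]))
  cat("  gain:", paste(sprintf("%s=%.3f", names(x$gain), x$gain),
                       collapse = " "), "\n")
  invisible(x)
}

#' Evaluate all twelve model variants with shared splits
#'
#' Runs [train_evaluate()] for every variant in the registry using the same
#' seed, so every variant sees identical train/test partitions and paired
#' comparisons across variants are valid.
#'
#' @param records Feature table carrying all seven candidate predictors and
#'   a `label` column.
#' @param seed Split seed shared across variants.
#' @param variants Variant list (default [model_variants()]).
#' @param ... Passed to [train_evaluate()].
#' @return List of `classifier_report`, one per variant.
#' @export
run_variant_suite <- function(records, seed, variants = model_variants(), ...) {
  all_pred <- unique(unlist(lapply(variants, `[[`, "predictors")))
  missing <- setdiff(all_pred, names(records))
  if (length(missing))
    stop("feature table missing predictor(s): ",
         paste(missing, collapse = ", "))
  lapply(variants, function(v) train_evaluate(records, v, seed = seed, ...))
}

#' Flatten classifier reports to a summary data frame
#'
#' @param reports A `classifier_report` or list of them.
#' @return Data frame, one row per variant: metrics (test and train means)
#'   and per-feature gains (NA for unused features).
#' @export
reports_to_df <- function(reports) {
  if (inherits(reports, "classifier_report")) reports <- list(reports)
  feats <- c("tau_star_ir", "tau_star_red", "cf", "d_respiration",
             "mass", "firmness", "ssc")
  do.call(rbind, lapply(reports, function(r) {
    row <- data.frame(variant_id = r$variant_id,
                      predictors = paste(r$predictors, collapse = "+"),
                      accuracy_test = r$accuracy["test"],
                      accuracy_train = r$accuracy["train"],
                      precision_test = r$precision["test"],
                      precision_train = r$precision["train"],
                      recall_test = r$recall["test"],
                      recall_train = r$recall["train"],
                      f1_test = r$f1["test"], f1_train = r$f1["train"],
                      n_splits = r$n_splits, seed = r$seed,
                      backend = r$backend, row.names = NULL)
    for (f in feats) row[[paste0("gain_", f)]] <-
      if (f %in% names(r$gain)) unname(r$gain[f]) else NA_real_
    row
  }))
}
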