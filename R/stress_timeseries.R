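#' First derivative of an irregularly sampled signal
#'
#' Central finite differences at interior points, one-sided differences at
#' the endpoints; exact for linear signals. Used to turn the CO2 respiration
#' rate into the respiration-dynamics feature consumed by the classifier.
#'
#' @param times Strictly increasing sample times (hours).
#' @param values Signal values, same length as `times` (>= 2 samples).
#' @return Derivative series (units/h), same length as the input.
#' @examples
#' first_derivative(c(0, 1, 2), c(0, 1, 4))  # 1, 2, 3
#' @export
first_derivative <- function(times, values) {
  n <- length(times)
  if (n < 2L || length(values) != n)
    stop("need >= 2 samples and equal-length times/values")
  if (any(diff(times) == 0)) stop("duplicate timestamps")
  if (any(diff(times) < 0)) stop("times must be strictly increasing")
  d <- numeric(n)
  d[1L] <- (values[2L] - values[1L]) / (times[2L] - times[1L])
  d[n] <- (values[n] - values[n - 1L]) / (times[n] - times[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    d[i] <- (values[i + 1L] - values[i - 1L]) / (times[i + 1L] - times[i - 1L])
  }
  d
}

#' Sphere-equivalent surface area from volume
#'
#' Fruit surface area estimated as that of the sphere with the same volume:
#' `A = 4 pi (3V / 4 pi)^(2/3)`.
#'
#' @param volume Volume in cm^3 (> 0); vectorized.
#' @return Surface area in cm^2.
#' @examples
#' sphere_equivalent_area(4 * pi / 3)  # unit-radius sphere: 4 pi
#' @export
sphere_equivalent_area <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be positive")
  4 * pi * (3 * volume / (4 * pi))^(2 / 3)
}

#' Flag epochs with considerable change relative to a baseline
#'
#' Robust step detector behind the expert labeling rule: an epoch is flagged
#' when its value departs from the baseline median by more than `k` times
#' the MAD-scaled baseline sigma, in the signal's stress direction. When the
#' baseline has zero dispersion the threshold falls back to `rel_fallback`
#' times the absolute baseline median (or `rel_fallback` itself when the
#' median is also zero), with a message.
#'
#' @param values Signal values, one per epoch.
#' @param baseline_idx Indices of the baseline epochs (non-empty; must
#'   precede the epochs being judged).
#' @param k Threshold multiplier (default 3).
#' @param direction Stress direction of the signal: `"increase"` (default
#'   for relaxation time, CF and respiration), `"decrease"`, or `"both"`.
#' @param rel_fallback Relative threshold used when baseline MAD is zero.
#' @return Logical vector, one flag per epoch.
#' @export
detect_considerable_change <- function(values, baseline_idx, k = 3,
                                       direction = c("increase", "decrease", "both"),
                                       rel_fallback = 0.1) {
  direction <- match.arg(direction)
  if (!length(baseline_idx)) stop("baseline window is empty")
  if (max(baseline_idx) > length(values)) stop("baseline index out of range")
  base <- values[baseline_idx]
  med <- stats::median(base)
  s <- stats::mad(base)            # MAD * 1.4826
  if (s == 0) {
    thr <- if (med != 0) rel_fallback * abs(med) else rel_fallback
    message("zero baseline dispersion; falling back to relative threshold ",
            format(thr))
  } else thr <- k * s
  dev <- values - med
  switch(direction,
         increase = dev > thr,
         decrease = -dev > thr,
         both = abs(dev) > thr)
}

epoch_required_cols <- c("apple_id", "time_h", "phase", "cf", "respiration",
                         "tau_star_red", "tau_star_ir")
phase_levels <- c("preconditioning", "zero_oxygen", "transition", "normal")

#' Expert 2-of-3 labeling of hypoxic-stress epochs
#'
#' Reproduces the reference labeling procedure: an epoch is labeled
#' `hypoxic_stress` when at least two of the three indicator signals —
#' speckle relaxation time (log-transformed, one laser channel),
#' chlorophyll fluorescence F0, and CO2 respiration rate — show a
#' considerable increase relative to that apple's pre-stress baseline
#' (epochs in `baseline_phase`), via [detect_considerable_change()].
#' Processing is strictly per apple, so labels are invariant to apple order.
#'
#' @param records Epoch data frame with columns `apple_id`, `time_h`,
#'   `phase`, `cf`, `respiration`, `tau_star_red`, `tau_star_ir`.
#' @param k Threshold multiplier passed to the change detector.
#' @param tau_signal Which relaxation-time column plays the speckle role;
#'   default `"tau_star_ir"` (the more stable channel).
#' @param baseline_phase Phase defining the per-apple baseline window.
#' @param normalize_cf Also emit `cf_norm`, CF divided by its baseline
#'   median (a monotone rescaling; flags are unaffected).
#' @return `records` with added columns `flag_tau`, `flag_cf`, `flag_resp`
#'   (logical) and `label` (`"hypoxic_stress"` / `"aerobic"`), plus
#'   `cf_norm` when requested.
#' @export
expert_label <- function(records, k = 3, tau_signal = "tau_star_ir",
                         baseline_phase = "preconditioning",
                         normalize_cf = TRUE) {
  need <- c("apple_id", "time_h", "phase", "cf", "respiration", tau_signal)
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("missing signal column(s): ", paste(missing, collapse = ", "))
  parts <- split(records, records$apple_id)
  out <- lapply(parts, function(df) {
    df <- df[order(df$time_h), , drop = FALSE]
    if (any(duplicated(df$time_h)))
      stop("duplicate time_h within apple ", df$apple_id[1L])
    base <- which(df$phase == baseline_phase)
    if (!length(base))
      stop("no '", baseline_phase, "' baseline epochs for apple ",
           df$apple_id[1L])
    df$flag_tau <- detect_considerable_change(df[[tau_signal]], base, k, "increase")
    df$flag_cf <- detect_considerable_change(df$cf, base, k, "increase")
    df$flag_resp <- detect_considerable_change(df$respiration, base, k, "increase")
    nflag <- df$flag_tau + df$flag_cf + df$flag_resp
    df$label <- ifelse(nflag >= 2L, "hypoxic_stress", "aerobic")
    if (normalize_cf) df$cf_norm <- df$cf / stats::median(df$cf[base])
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and validate an epoch signal table
#'
#' Strict-header CSV ingestion for per-apple, per-epoch signals. `#`-comment
#' lines are skipped. Checks column presence, phase vocabulary, and strictly
#' increasing non-negative times within each apple.
#'
#' @param path CSV with columns `apple_id`, `time_h`, `phase`, `cf`,
#'   `respiration`, `tau_star_red`, `tau_star_ir` (extra columns such as
#'   `label` are kept).
#' @return Validated data frame.
#' @export
read_epoch_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(epoch_required_cols, names(df))
  if (length(missing))
    stop("epoch table missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$phase), phase_levels)
  if (length(bad))
    stop("unknown phase value(s): ", paste(bad, collapse = ", "))
  for (df_a in split(df, df$apple_id)) {
    tt <- df_a$time_h[order(df_a$time_h)]
    if (any(tt < 0) || any(diff(tt) <= 0))
      stop("time_h must be non-negative and strictly increasing within apple ",
           df_a$apple_id[1L])
  }
  df
}

#' Read and validate a phenotype table
#'
#' @param path CSV with columns `apple_id`, `mass`, `firmness`, `ssc`,
#'   `volume`; an `area` column is recomputed/validated against the
#'   sphere-equivalent model and appended when absent.
#' @return Validated data frame including `area` (cm^2).
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("apple_id", "mass", "firmness", "ssc", "volume")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("phenotype table missing column(s): ", paste(missing, collapse = ", "))
  num <- df[c("mass", "firmness", "ssc", "volume")]
  if (any(!vapply(num, is.numeric, TRUE)) || any(unlist(num) <= 0))
    stop("phenotype values must be positive numbers")
  area <- sphere_equivalent_area(df$volume)
  if ("area" %in% names(df)) {
    if (any(abs(df$area - area) / area > 1e-6))
      stop("area column inconsistent with sphere-equivalent model")
  } else df$area <- area
  df
}

#' Assemble the classifier feature table
#'
#' Joins labeled epoch records with per-apple phenotypes and derives
#' `d_respiration` (first derivative of the respiration rate per apple,
#' units/h). The result carries the seven candidate predictors
#' (`tau_star_ir`, `tau_star_red`, `cf`, `d_respiration`, `mass`,
#' `firmness`, `ssc`) plus `apple_id`, `time_h` and `label`.
#'
#' @param records Labeled epoch table (see [expert_label()]).
#' @param phenotypes Phenotype table (see [read_phenotype_table()]).
#' @return Feature data frame, one row per epoch.
#' @export
assemble_features <- function(records, phenotypes) {
  if (!"label" %in% names(records))
    stop("records must carry a `label` column; run expert_label() first")
  parts <- split(records, records$apple_id)
  recs <- do.call(rbind, lapply(parts, function(df) {
    df <- df[order(df$time_h), , drop = FALSE]
    df$d_respiration <- first_derivative(df$time_h, df$respiration)
    df
  }))
  rownames(recs) <- NULL
  keep <- c("apple_id", "mass", "firmness", "ssc")
  out <- merge(recs, phenotypes[keep], by = "apple_id", sort = FALSE)
  out[order(out$apple_id, out$time_h), , drop = FALSE]
}

#' Write a labeled epoch table to CSV
#'
#' @param records Labeled data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
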