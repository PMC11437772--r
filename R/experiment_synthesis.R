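#' Configuration for the experiment-level synthetic data generator
#'
#' Encodes the climate-chamber protocol as the generator's stated world:
#' 2 h preconditioning in ambient atmosphere, 3.5 h of zero-oxygen storage,
#' then 1 h back in ambient air (6.5 h total), with measurements every
#' 8 min. Signals respond about 2.1 h after oxygen removal, rising over two
#' epochs to an elevated plateau; after atmosphere restoration the
#' relaxation-time and CF signals relax back while respiration stays
#' elevated through the final hour. A configurable fraction of fruit shows
#' no CF response at all (low-chlorophyll skin), which is exactly the case
#' where speckle-based sensing must carry the detection.
#'
#' @param n_apples Number of fruit (default 15).
#' @param epoch_minutes Measurement cadence in minutes (default 8).
#' @param phase_durations_h Named hours for `preconditioning`, `zero_oxygen`,
#'   `normal` (defaults 2, 3.5, 1).
#' @param transition_h Leading part of the final hour labeled `transition`
#'   (atmosphere ramp-back; default 0.25 h).
#' @param onset_delay_h Mean lag from oxygen removal to signal response
#'   (default 2.1 h).
#' @param onset_jitter_sd_h Spread of the per-apple onset delay; the delay is
#'   exponential-jittered: `delay = onset_delay_h + Exp(sd) - sd` (default
#'   10 min = 1/6 h).
#' @param effect_sizes Named per-signal step magnitudes in units of that
#'   signal's noise sigma (defaults 6 for all four signals — a clear step,
#'   comfortably above the 3-sigma labeling threshold).
#' @param noise_sigmas Named per-signal AR(1) noise standard deviations in
#'   signal units.
#' @param ar_coeff Within-apple AR(1) autocorrelation of the noise, in
#'   `[0, 1)` (default 0.3).
#' @param chlorophyll_low_fraction Fraction of apples whose CF effect size
#'   is forced to 0 (default 0.2).
#' @param recovery_lag_h Time after atmosphere restoration at which the
#'   relaxing signals cross their half-step level (default 0.25 h).
#' @param seed RNG seed.
#' @return A validated list of class `experiment_sim_config`.
#' @export
experiment_sim_config <- function(
    n_apples = 15L, epoch_minutes = 8,
    phase_durations_h = c(preconditioning = 2, zero_oxygen = 3.5, normal = 1),
    transition_h = 0.25,
    onset_delay_h = 2.1, onset_jitter_sd_h = 1 / 6,
    effect_sizes = c(tau_star_ir = 6, tau_star_red = 6, cf = 6, respiration = 6),
    noise_sigmas = c(tau_star_ir = 0.05, tau_star_red = 0.05, cf = 5,
                     respiration = 0.3),
    ar_coeff = 0.3, chlorophyll_low_fraction = 0.2,
    recovery_lag_h = 0.25, seed = 1L) {
  sig <- c("tau_star_ir", "tau_star_red", "cf", "respiration")
  stopifnot(n_apples >= 1L, epoch_minutes > 0,
            all(phase_durations_h > 0),
            all(c("preconditioning", "zero_oxygen", "normal") %in%
                  names(phase_durations_h)),
            transition_h >= 0, transition_h <= phase_durations_h[["normal"]],
            onset_delay_h >= 0, onset_jitter_sd_h >= 0,
            all(sig %in% names(effect_sizes)), all(effect_sizes >= 0),
            all(sig %in% names(noise_sigmas)), all(noise_sigmas > 0),
            ar_coeff >= 0, ar_coeff < 1,
            chlorophyll_low_fraction >= 0, chlorophyll_low_fraction <= 1,
            recovery_lag_h >= 0)
  structure(list(n_apples = as.integer(n_apples),
                 epoch_minutes = epoch_minutes,
                 phase_durations_h = phase_durations_h,
                 transition_h = transition_h,
                 onset_delay_h = onset_delay_h,
                 onset_jitter_sd_h = onset_jitter_sd_h,
                 effect_sizes = effect_sizes[sig],
                 noise_sigmas = noise_sigmas[sig],
                 ar_coeff = ar_coeff,
                 chlorophyll_low_fraction = chlorophyll_low_fraction,
                 recovery_lag_h = recovery_lag_h,
                 seed = as.integer(seed)),
            class = "experiment_sim_config")
}

# stationary AR(1) noise with marginal sd `sigma`
ar1_noise <- function(n, sigma, phi) {
  z <- stats::rnorm(n)
  e <- numeric(n)
  e[1L] <- z[1L]
  if (n > 1L) for (t in 2:n) e[t] <- phi * e[t - 1L] + sqrt(1 - phi^2) * z[t]
  sigma * e
}

#' Simulate a full hypoxic-stress experiment at the signal level
#'
#' Generates per-apple, per-epoch time courses of the four stress signals
#' (tau*_IR, tau*_RED, CF, respiration), per-apple phenotypes, and a
#' ground-truth table. Signal shape per apple: baseline level + step
#' `effect_size * noise_sigma` entered via a logistic rise spanning ~2
#' epochs, centered at `onset = O2-removal time + jittered delay`; tau* and
#' CF relax back through a logistic fall centered `recovery_lag_h` after
#' atmosphere restoration; respiration stays elevated to the end. AR(1)
#' noise is added per signal. tau*_RED receives a larger between-apple
#' baseline spread than tau*_IR (the red channel is the less repeatable
#' one). Phenotypes: mass ~ N(163.92, 12.87^2) g, firmness ~ N(41.15,
#' 3.32^2) N, SSC ~ N(12.67, 0.92^2) %, volume = mass / 0.8 g/cm^3 (+5%
#' noise), area from [sphere_equivalent_area()].
#'
#' The truth table marks an epoch as stressed when it lies between the
#' apple's onset and the recovery midpoint — provided at least one effect
#' size is positive (an all-zero-effect world contains no stress to detect).
#'
#' @param config An [experiment_sim_config()].
#' @return List with `epochs` (data frame matching [read_epoch_table()]'s
#'   schema), `phenotypes` (matching [read_phenotype_table()]), and `truth`
#'   (`apple_id`, `time_h`, `true_state`, `onset_epoch`).
#' @examples
#' sim <- simulate_experiment(experiment_sim_config(n_apples = 3, seed = 2))
#' table(sim$truth$true_state)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_sim_config"))
  ph <- config$phase_durations_h
  total_h <- sum(ph)
  t_off <- ph[["preconditioning"]]                       # O2 removed
  t_rest <- t_off + ph[["zero_oxygen"]]                  # atmosphere restored
  time_h <- seq(0, total_h, by = config$epoch_minutes / 60)
  n_ep <- length(time_h)
  phase <- cut(time_h,
               c(-Inf, t_off, t_rest, t_rest + config$transition_h, Inf),
               labels = c("preconditioning", "zero_oxygen", "transition",
                          "normal"), right = FALSE)
  phase <- as.character(phase)

  sig <- names(config$effect_sizes)
  # logistic scale giving a 10-90% rise over ~2 epochs
  w <- (2 * config$epoch_minutes / 60) / (2 * log(9))
  any_effect <- any(config$effect_sizes > 0)

  with_local_seed(config$seed, {
    n <- config$n_apples
    ids <- sprintf("apple_%02d", seq_len(n))
    n_low <- round(config$chlorophyll_low_fraction * n)
    low_cf <- sample(n, n_low)
    base <- list(
      tau_star_ir = stats::rnorm(n, 0.5, 0.1),
      tau_star_red = stats::rnorm(n, 0.5, 0.3),   # wider between-apple spread
      cf = stats::rnorm(n, 300, 30),
      respiration = stats::rnorm(n, 10, 1))
    delay <- config$onset_delay_h +
      if (config$onset_jitter_sd_h > 0)
        stats::rexp(n, 1 / config$onset_jitter_sd_h) - config$onset_jitter_sd_h
      else 0
    delay <- pmax(delay, 0)

    epochs <- vector("list", n); truth <- vector("list", n)
    mass <- stats::rnorm(n, 163.92, 12.87)
    firmness <- stats::rnorm(n, 41.15, 3.32)
    ssc <- stats::rnorm(n, 12.67, 0.92)
    volume <- mass / 0.8 * (1 + stats::rnorm(n, 0, 0.05))

    for (a in seq_len(n)) {
      onset <- t_off + delay[a]
      rise <- stats::plogis((time_h - onset) / w)
      fall <- 1 - stats::plogis((time_h - (t_rest + config$recovery_lag_h)) / w)
      df <- data.frame(apple_id = ids[a], time_h = time_h, phase = phase,
                       stringsAsFactors = FALSE)
      for (s in sig) {
        amp <- config$effect_sizes[[s]] * config$noise_sigmas[[s]]
        if (s == "cf" && a %in% low_cf) amp <- 0
        shape <- if (s == "respiration") rise else rise * fall
        df[[s]] <- base[[s]][a] + amp * shape +
          ar1_noise(n_ep, config$noise_sigmas[[s]], config$ar_coeff)
      }
      epochs[[a]] <- df
      stressed <- any_effect & time_h >= onset &
        time_h < t_rest + config$recovery_lag_h
      truth[[a]] <- data.frame(
        apple_id = ids[a], time_h = time_h,
        true_state = ifelse(stressed, "hypoxic_stress", "aerobic"),
        onset_epoch = if (any_effect) which(time_h >= onset)[1L] else NA_integer_,
        stringsAsFactors = FALSE)
    }
    list(
      epochs = do.call(rbind, epochs)[
        , c("apple_id", "time_h", "phase", "cf", "respiration",
            "tau_star_red", "tau_star_ir")],
      phenotypes = data.frame(apple_id = ids, mass = mass,
                              firmness = firmness, ssc = ssc, volume = volume,
                              area = sphere_equivalent_area(volume),
                              stringsAsFactors = FALSE),
      truth = do.call(rbind, truth))
  })
}
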