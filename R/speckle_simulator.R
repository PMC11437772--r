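#' Configuration for the dynamic speckle simulator
#'
#' The simulator draws a complex circular-Gaussian field with prescribed
#' spatial grain and temporal decorrelation and records its squared modulus,
#' so the ground-truth field correlation `g1(dt) = exp(-(dt/tau_field)^
#' beta_field)` is known exactly and the Siegert relation
#' `g2 - 1 = |g1|^2` maps it to the intensity correlation that the
#' estimators in this package measure.
#'
#' @param n_frames,height,width Stack geometry. Defaults mirror a 10-s clip
#'   at the nominal 30 fps on a 64x64 crop.
#' @param fps Frame rate (Hz).
#' @param tau_field Field correlation time (seconds, > 0). The *intensity*
#'   correlation then decays with effective time
#'   `tau_field * 2^(-1/beta_field)`.
#' @param beta_field Field stretch exponent in (0, 2].
#' @param grain_px Speckle grain size in pixels (>= 1); sets the spatial
#'   low-pass cutoff.
#' @param noise_sigma Additive Gaussian camera noise std in gray levels,
#'   applied after intensity scaling, before quantization.
#' @param bit_depth Output bit depth.
#' @param seed RNG seed; the stack is bit-reproducible from it.
#' @return A validated list of class `speckle_sim_config`.
#' @export
speckle_sim_config <- function(n_frames = 300L, height = 64L, width = 64L,
                               fps = 30, tau_field = 0.5, beta_field = 1,
                               grain_px = 2, noise_sigma = 0,
                               bit_depth = 8L, seed = 1L) {
  cfg <- structure(list(n_frames = as.integer(n_frames),
                        height = as.integer(height), width = as.integer(width),
                        fps = as.numeric(fps), tau_field = as.numeric(tau_field),
                        beta_field = as.numeric(beta_field),
                        grain_px = as.numeric(grain_px),
                        noise_sigma = as.numeric(noise_sigma),
                        bit_depth = as.integer(bit_depth),
                        seed = as.integer(seed)),
                   class = "speckle_sim_config")
  with(cfg, {
    stopifnot(n_frames >= 2L, height >= 2L, width >= 2L, fps > 0,
              tau_field > 0, beta_field > 0, beta_field <= 2,
              grain_px >= 1, noise_sigma >= 0, bit_depth >= 1L)
  })
  cfg
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a dynamic speckle video with known field dynamics
#'
#' Pipeline: (1) i.i.d. complex white Gaussian innovations per frame;
#' (2) spatial correlation by a circular Fourier low-pass with cutoff
#' `1 / (2 * grain_px)` cycles/px; (3) temporal correlation imposed by
#' mixing frames through the Cholesky factor of the
#' `exp(-(|dt|/tau_field)^beta_field)` covariance (1e-10 diagonal jitter);
#' (4) intensity = squared modulus; (5) scaling so the 99.9th intensity
#' percentile maps to `0.9 * (2^bit_depth - 1)` (avoids saturation-induced
#' correlation bias); (6) additive Gaussian camera noise; (7) rounding and
#' clamping to the output bit depth.
#'
#' @param config A [speckle_sim_config()].
#' @return A [frame_stack()], bit-identical for identical config and seed.
#' @examples
#' st <- simulate_speckle_stack(speckle_sim_config(n_frames = 30, height = 16,
#'   width = 16, seed = 7))
#' st
#' @export
simulate_speckle_stack <- function(config) {
  stopifnot(inherits(config, "speckle_sim_config"))
  c(nf, h, w) %<-% list(config$n_frames, config$height, config$width)
  npx <- h * w

  with_local_seed(config$seed, {
    re <- matrix(stats::rnorm(nf * npx), nf, npx)
    im <- matrix(stats::rnorm(nf * npx), nf, npx)
    noise <- if (config$noise_sigma > 0)
      matrix(stats::rnorm(nf * npx, sd = config$noise_sigma), nf, npx) else NULL
  })
  field <- matrix(complex(real = re, imaginary = im), nf, npx)

  # spatial low-pass: keep |f| <= 1/(2 grain) cycles/px (grain 1 = all-pass)
  if (config$grain_px > 1) {
    fy <- ((seq_len(h) - 1 + h %/% 2) %% h - h %/% 2) / h
    fx <- ((seq_len(w) - 1 + w %/% 2) %% w - w %/% 2) / w
    mask <- outer(fy^2, fx^2, `+`) <= (1 / (2 * config$grain_px))^2
    for (t in seq_len(nf)) {
      fr <- matrix(field[t, ], h, w)
      field[t, ] <- as.vector(stats::fft(stats::fft(fr) * mask, inverse = TRUE))
    }
  }

  dt <- abs(outer(seq_len(nf), seq_len(nf), `-`)) / config$fps
  C <- exp(-(dt / config$tau_field)^config$beta_field)
  L <- tryCatch(t(chol(C + diag(1e-10, nf))), error = function(e)
    stop("temporal covariance not positive definite; ",
         "use fewer frames or a larger beta_field"))
  field <- L %*% field

  intensity <- Re(field * Conj(field))
  scale <- 0.9 * (2^config$bit_depth - 1) /
    stats::quantile(intensity, 0.999, names = FALSE)
  intensity <- intensity * scale
  if (!is.null(noise)) intensity <- intensity + noise
  intensity <- pmin(pmax(round(intensity), 0), 2^config$bit_depth - 1)

  frames <- aperm(array(t(intensity), c(h, w, nf)), c(3L, 1L, 2L))
  frame_stack(frames, fps = config$fps, bit_depth = config$bit_depth,
              source_id = sprintf("sim:tau=%g,beta=%g,seed=%d",
                                  config$tau_field, config$beta_field,
                                  config$seed))
}

# tiny multi-assign helper used above
`%<-%` <- function(lhs, rhs) {
  vars <- as.character(substitute(lhs))[-1L]
  for (i in seq_along(vars))
    assign(vars[i], rhs[[i]], envir = parent.frame())
  invisible(NULL)
}

#' Siegert-predicted intensity correlation of a simulated stack
#'
#' Closed-form oracle for [simulate_speckle_stack()]: for a circular
#' Gaussian field the intensity correlation coefficient at lag `dt` is
#' `|g1(dt)|^2 = exp(-2 (dt / tau_field)^beta_field)`. With camera noise the
#' curve is attenuated by `c = var_signal / (var_signal + noise_sigma^2)`,
#' where the signal variance uses the fully-developed-speckle approximation
#' (exponential intensity: variance = mean^2, mean set by the 99.9th
#' percentile scaling of the simulator).
#'
#' @param config A [speckle_sim_config()].
#' @param lags Time lags in seconds.
#' @return Numeric vector of predicted correlation coefficients.
#' @examples
#' analytic_intensity_correlation(speckle_sim_config(tau_field = 0.5), 0.25)
#' @export
analytic_intensity_correlation <- function(config, lags) {
  stopifnot(inherits(config, "speckle_sim_config"))
  g1sq <- exp(-2 * (lags / config$tau_field)^config$beta_field)
  if (config$noise_sigma > 0) {
    mu <- 0.9 * (2^config$bit_depth - 1) / log(1000)  # q999 of Exp(mu) = mu ln 1000
    att <- mu^2 / (mu^2 + config$noise_sigma^2)
    g1sq <- att * g1sq
  }
  g1sq
}
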