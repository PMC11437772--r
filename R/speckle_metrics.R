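#' Analysis configuration for speckle activity coefficients
#'
#' Bundles the knobs shared by [analyze_stack()]: the decorrelation-curve lag
#' range and estimator, GLCM quantization, and the zero-temporal-mean pixel
#' policy for tLASCA.
#'
#' @param max_lag_frames Maximum lag (frames) of the decorrelation curve.
#'   `NULL` (default) uses half the clip length, limiting pair-count
#'   imbalance at long lags.
#' @param corr_method `"all_pairs"` (default) averages the Pearson
#'   correlation over every frame pair separated by the lag; `"first_frame"`
#'   correlates each frame against frame 1 only.
#' @param glcm_levels Gray levels for inertia-moment quantization. `NULL`
#'   keeps the native `2^bit_depth` levels (no re-quantization on 8-bit).
#' @param glcm_range `"bit_depth"` bins over `[0, 2^bit_depth - 1]`;
#'   `"data"` bins over the observed intensity range.
#' @param zero_mean Policy for pixels with zero temporal mean in tLASCA:
#'   `"exclude"` (default, count reported via message) or `"raise"`.
#' @param tol_decay A curve whose correlations all stay above
#'   `1 - tol_decay` has no measurable decay and cannot be fitted.
#' @return A list of class `speckle_params`.
#' @export
speckle_params <- function(max_lag_frames = NULL,
                           corr_method = c("all_pairs", "first_frame"),
                           glcm_levels = NULL,
                           glcm_range = c("bit_depth", "data"),
                           zero_mean = c("exclude", "raise"),
                           tol_decay = 1e-3) {
  structure(list(max_lag_frames = max_lag_frames,
                 corr_method = match.arg(corr_method),
                 glcm_levels = glcm_levels,
                 glcm_range = match.arg(glcm_range),
                 zero_mean = match.arg(zero_mean),
                 tol_decay = tol_decay),
            class = "speckle_params")
}

#' Frame-to-frame decorrelation curve of a speckle video
#'
#' Computes the Pearson correlation coefficient between the flattened pixel
#' vectors of frame pairs separated by each time lag `k = 0..max_lag_frames`,
#' averaged over all such pairs (or against frame 1 only, see
#' `method`). The curve describes how quickly the speckle pattern loses
#' similarity to itself — the raw material for the stretched-exponential
#' relaxation-time fit.
#'
#' @param stack A [frame_stack()].
#' @param max_lag_frames Largest lag in frames; must be `< n_frames`.
#'   Default: half the clip length.
#' @param method `"all_pairs"` or `"first_frame"` (see [speckle_params()]).
#' @return An object of class `decorrelation_curve`: list with `lags`
#'   (seconds, starting at 0), `corr` (in `[-1, 1]`, `corr[1] == 1`),
#'   `n_pairs` (pairs averaged per lag), and `fps`.
#' @examples
#' st <- simulate_speckle_stack(speckle_sim_config(n_frames = 60, height = 16,
#'   width = 16, tau_field = 0.3, seed = 1))
#' cv <- compute_decorrelation_curve(st)
#' head(cv$corr)
#' @export
compute_decorrelation_curve <- function(stack, max_lag_frames = NULL,
                                        method = c("all_pairs", "first_frame")) {
  validate_frame_stack(stack)
  method <- match.arg(method)
  nf <- n_frames(stack)
  if (is.null(max_lag_frames)) max_lag_frames <- max(2L, nf %/% 2L)
  max_lag_frames <- as.integer(max_lag_frames)
  if (max_lag_frames < 1L || max_lag_frames >= nf)
    stop("max_lag_frames must be in [1, n_frames - 1]")

  fm <- stack_matrix(stack)                      # n_frames x n_pixels
  np <- ncol(fm)
  mu <- rowMeans(fm)
  sd2 <- rowSums((fm - mu)^2) / (np - 1)
  degenerate <- which(sd2 <= 0)
  if (length(degenerate))
    stop(sprintf("frame %d has zero pixel variance; Pearson correlation undefined",
                 degenerate[1L]))
  z <- (fm - mu) / sqrt(sd2)
  gram <- tcrossprod(z) / (np - 1)               # gram[i, j] = Pearson(f_i, f_j)

  lags_f <- 0:max_lag_frames
  if (method == "all_pairs") {
    corr <- vapply(lags_f, function(k) {
      i <- seq_len(nf - k)
      mean(gram[cbind(i, i + k)])
    }, 1)
    n_pairs <- nf - lags_f
  } else {
    corr <- gram[1L, 1L + lags_f]
    n_pairs <- rep(1L, length(lags_f))
  }
  corr[1L] <- 1
  structure(list(lags = lags_f / stack$fps, corr = as.numeric(corr),
                 n_pairs = as.integer(n_pairs), fps = stack$fps),
            class = "decorrelation_curve")
}

#' @export
print.decorrelation_curve <- function(x, ...) {
  cat(sprintf("<decorrelation_curve> %d lags, 0..%.3f s, corr range [%.3f, 1]\n",
              length(x$lags), max(x$lags), min(x$corr)))
  invisible(x)
}

#' Fit a stretched-exponential (KWW) decay to a decorrelation curve
#'
#' Fits `CORR(t) = exp(-(t / tau)^beta)` by bounded nonlinear least squares
#' over all positive lags (the lag-0 point is excluded: the model passes
#' through 1 exactly). `tau` is the speckle pattern relaxation time in
#' seconds — larger tau means slower decorrelation, i.e. less internal
#' activity — and `beta` in `(0, 2]` is the stretch exponent (`beta = 1`
#' gives a simple exponential). `tau_star = log(tau)` is the
#' log-transformed coefficient used downstream for stress detection.
#'
#' Starting values: `beta = 1`, `tau` at the first lag where the curve
#' crosses `exp(-1)` (median positive lag if it never does). Bounds:
#' `tau` in `[lag_min/100, 100 * lag_max]`, `beta` in `[0.05, 2]`.
#'
#' @param curve A `decorrelation_curve` (>= 3 positive lags).
#' @param tol_decay No-decay guard: error if all correlations exceed
#'   `1 - tol_decay`.
#' @param max_iter Optimizer iteration budget; exhaustion is reported via
#'   `converged = FALSE`, not an error.
#' @return An object of class `stretched_exp_fit`: list with `tau`, `beta`,
#'   `tau_star`, `rmse` (on fitted lags), `converged`.
#' @examples
#' lags <- (0:30) / 30
#' cv <- structure(list(lags = lags, corr = exp(-(lags / 0.5)),
#'   n_pairs = rep(1L, 31), fps = 30), class = "decorrelation_curve")
#' fit_stretched_exponential(cv)
#' @export
fit_stretched_exponential <- function(curve, tol_decay = 1e-3,
                                      max_iter = 1000L) {
  stopifnot(inherits(curve, "decorrelation_curve"))
  pos <- curve$lags > 0
  t <- curve$lags[pos]; y <- curve$corr[pos]
  if (length(t) < 3L)
    stop("need at least 3 positive-lag points to fit")
  if (all(curve$corr >= 1 - tol_decay))
    stop("no measurable decay in decorrelation curve")

  below <- which(y < exp(-1))
  tau0 <- if (length(below)) t[below[1L]] else stats::median(t)
  lo <- c(min(t) / 100, 0.05)
  hi <- c(100 * max(t), 2)
  clamp <- function(p) pmin(pmax(p, lo), hi)
  sse <- function(p) sum((y - exp(-(t / p[1L])^p[2L]))^2)

  # linearized start: log(-log CORR) = beta log t - beta log tau is an exact
  # linear relation for model-generated data and a strong start otherwise
  starts <- list(c(tau0, 1))
  ok <- y > 1e-12 & y < 1 - 1e-12
  if (sum(ok) >= 2L) {
    co <- unname(stats::coef(stats::lm(log(-log(y[ok])) ~ log(t[ok]))))
    if (is.finite(co[2L]) && co[2L] > 0)
      starts <- c(starts, list(clamp(c(exp(-co[1L] / co[2L]), co[2L]))))
  }
  opt <- NULL
  for (s in starts) {
    o <- stats::optim(s, sse, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = max_iter, factr = 10))
    # high-precision polish on the same bounded objective
    o2 <- stats::nlminb(o$par, sse, lower = lo, upper = hi,
                        control = list(iter.max = max_iter,
                                       abs.tol = 0, rel.tol = 1e-15,
                                       x.tol = 1e-12))
    cand <- list(par = o2$par, value = o2$objective,
                 codes_ok = o$convergence == 0L || o2$convergence == 0L)
    if (cand$value > o$value)
      cand <- list(par = o$par, value = o$value,
                   codes_ok = o$convergence == 0L)
    if (is.null(opt) || cand$value < opt$value) opt <- cand
  }
  tau <- unname(opt$par[1L]); beta <- unname(opt$par[2L])
  # optimizers can flag machine-precision optima as "abnormal"; accept a
  # solution whose numerical gradient (or residual) has effectively vanished
  converged <- opt$codes_ok
  if (!converged) {
    h <- 1e-6 * pmax(abs(opt$par), 1e-3)
    grad <- vapply(1:2, function(i) {
      e <- c(0, 0); e[i] <- h[i]
      (sse(pmin(pmax(opt$par + e, lo), hi)) -
         sse(pmin(pmax(opt$par - e, lo), hi))) / (2 * h[i])
    }, 0)
    converged <- opt$value < 1e-16 || max(abs(grad)) < 1e-6 * (1 + opt$value)
  }
  structure(list(tau = tau, beta = beta, tau_star = log(tau),
                 rmse = sqrt(opt$value / length(t)),
                 converged = converged),
            class = "stretched_exp_fit")
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  cat(sprintf("<stretched_exp_fit> tau = %.4g s (tau* = %.4g), beta = %.3f, rmse = %.3g%s\n",
              x$tau, x$tau_star, x$beta, x$rmse,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Temporal laser speckle contrast (tLASCA)
#'
#' For every pixel, the ratio of the temporal standard deviation to the
#' temporal mean of its intensity across all frames, averaged over the
#' spatial domain. Sample (n-1) normalization is used for the standard
#' deviation. Faster speckle dynamics give larger contrast.
#'
#' @param stack A [frame_stack()] with >= 2 frames.
#' @param zero_mean Pixels whose temporal mean is zero have an undefined
#'   ratio: `"exclude"` drops them (count reported via a message) while
#'   `"raise"` errors.
#' @return Non-negative scalar. The number of excluded pixels is attached
#'   as attribute `n_excluded`.
#' @export
compute_tlasca <- function(stack, zero_mean = c("exclude", "raise")) {
  validate_frame_stack(stack)
  zero_mean <- match.arg(zero_mean)
  fm <- stack_matrix(stack)
  nf <- nrow(fm)
  mu <- colMeans(fm)
  sdv <- sqrt(colSums((fm - rep(mu, each = nf))^2) / (nf - 1))
  zero <- mu == 0
  if (any(zero)) {
    if (zero_mean == "raise")
      stop(sum(zero), " pixel(s) with zero temporal mean")
    message(sum(zero), " zero-temporal-mean pixel(s) excluded from tLASCA")
    if (all(zero)) stop("all pixels have zero temporal mean")
  }
  out <- mean(sdv[!zero] / mu[!zero])
  attr(out, "n_excluded") <- sum(zero)
  out
}

#' GLCM inertia moment of the time-history speckle pattern
#'
#' Builds the time-history speckle pattern (THSP: one row per pixel, one
#' column per frame), quantizes intensities to `levels` gray levels, and
#' accumulates a gray-level co-occurrence matrix over ordered
#' time-consecutive value pairs within each pixel's history. After
#' normalizing the GLCM by its total, returns the inertia (contrast) moment
#' `sum GLCM[i, j] * (i - j)^2`. Static speckle gives 0; faster fluctuation
#' spreads mass off the diagonal and raises the moment.
#'
#' @param stack A [frame_stack()] with >= 2 frames.
#' @param levels Number of gray levels (>= 2, <= `2^bit_depth`). Default:
#'   native `2^bit_depth` levels, i.e. no re-quantization of 8-bit input.
#' @param range Quantization support: `"bit_depth"` uses equal-width bins
#'   over `[0, 2^bit_depth - 1]`; `"data"` over the observed min..max, which
#'   makes the moment invariant to positive intensity rescaling.
#' @param symmetric Accumulate each pair also in reverse order. The inertia
#'   moment itself is unchanged (the weight is symmetric); the flag is kept
#'   for GLCM-convention compatibility.
#' @return Non-negative scalar.
#' @export
compute_inertia_moment <- function(stack, levels = NULL,
                                   range = c("bit_depth", "data"),
                                   symmetric = FALSE) {
  validate_frame_stack(stack)
  range <- match.arg(range)
  if (n_frames(stack) < 2L) stop("need at least 2 frames")
  if (is.null(levels)) levels <- 2L^stack$bit_depth
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (levels > 2L^stack$bit_depth)
    stop(sprintf("levels (%d) exceeds 2^bit_depth (%d)",
                 levels, 2L^stack$bit_depth))
  q <- quantize_stack(stack$frames, levels, range, stack$bit_depth)
  nf <- dim(q)[1L]
  a <- q[seq_len(nf - 1L), , , drop = FALSE]
  b <- q[1L + seq_len(nf - 1L), , , drop = FALSE]
  # normalized GLCM weight sum == mean squared level jump; symmetrizing
  # duplicates every (i, j) as (j, i) and leaves the moment unchanged
  mean((a - b)^2)
}

quantize_stack <- function(frames, levels, range, bit_depth) {
  if (range == "bit_depth") {
    span <- 2^bit_depth
    q <- floor(frames / span * levels)
  } else {
    lo <- min(frames); hi <- max(frames)
    if (hi <= lo) return(array(0, dim(frames)))
    q <- floor((frames - lo) / (hi - lo) * levels)
  }
  pmin(q, levels - 1L)
}

#' Compute all three speckle activity coefficients for one clip
#'
#' Composition of [compute_decorrelation_curve()],
#' [fit_stretched_exponential()], [compute_tlasca()] and
#' [compute_inertia_moment()] under one shared configuration. A clip with no
#' measurable decay (static speckle) yields a partial record: `tlasca` and
#' `inertia_moment` are reported, the fit fields are `NA` and `fit_error`
#' carries the message.
#'
#' @param stack A [frame_stack()].
#' @param channel Laser wavelength label, e.g. `"RED"` or `"IR"`.
#' @param params A [speckle_params()] configuration.
#' @return An object of class `speckle_coefficients`: list with `channel`,
#'   `source_id`, `tau`, `tau_star`, `beta`, `rmse`, `converged`,
#'   `fit_error` (`NA_character_` if the fit succeeded), `tlasca`,
#'   `inertia_moment`. Deterministic for a fixed stack and configuration.
#' @export
analyze_stack <- function(stack, channel = "IR", params = speckle_params()) {
  validate_frame_stack(stack)
  fit <- tryCatch({
    curve <- compute_decorrelation_curve(stack, params$max_lag_frames,
                                         params$corr_method)
    fit_stretched_exponential(curve, tol_decay = params$tol_decay)
  }, error = function(e) e)
  failed <- inherits(fit, "error")
  structure(list(
    channel = channel,
    source_id = stack$source_id,
    tau = if (failed) NA_real_ else fit$tau,
    tau_star = if (failed) NA_real_ else fit$tau_star,
    beta = if (failed) NA_real_ else fit$beta,
    rmse = if (failed) NA_real_ else fit$rmse,
    converged = if (failed) NA else fit$converged,
    fit_error = if (failed) conditionMessage(fit) else NA_character_,
    tlasca = as.numeric(compute_tlasca(stack, params$zero_mean)),
    inertia_moment = compute_inertia_moment(stack, params$glcm_levels,
                                            params$glcm_range)),
    class = "speckle_coefficients")
}

#' @export
print.speckle_coefficients <- function(x, ...) {
  cat(sprintf("<speckle_coefficients> [%s] tau = %s s, beta = %s, tLASCA = %.4g, IM = %.4g\n",
              x$channel,
              if (is.na(x$tau)) paste0("NA (", x$fit_error, ")") else sprintf("%.4g", x$tau),
              if (is.na(x$beta)) "NA" else sprintf("%.3f", x$beta),
              x$tlasca, x$inertia_moment))
  invisible(x)
}

#' Serialize coefficient records to CSV
#'
#' One row per analyzed clip; a leading `#`-comment line carries the
#' configuration so results are traceable.
#'
#' @param coeffs A `speckle_coefficients` or list of them.
#' @param path Output CSV path.
#' @param config_comment Free-text configuration note for the header line.
#' @return `path`, invisibly.
#' @export
write_coefficients_csv <- function(coeffs, path, config_comment = "") {
  if (inherits(coeffs, "speckle_coefficients")) coeffs <- list(coeffs)
  df <- do.call(rbind, lapply(coeffs, function(x)
    data.frame(source_id = x$source_id, channel = x$channel,
               tau = x$tau, tau_star = x$tau_star, beta = x$beta,
               rmse = x$rmse, converged = x$converged,
               fit_error = x$fit_error,
               tlasca = x$tlasca, im = x$inertia_moment)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# specklestress coefficients; ", config_comment), con)
  # quote only the free-text columns (source ids may contain commas)
  utils::write.csv(format(df, digits = 12, trim = TRUE), con,
                   row.names = FALSE,
                   quote = which(names(df) %in%
                                   c("source_id", "channel", "fit_error")))
  invisible(path)
}

#' Serialize a decorrelation curve to CSV
#'
#' @param curve A `decorrelation_curve`.
#' @param path Output CSV path.
#' @param config_comment Configuration note for the `#` header line.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, config_comment = "") {
  df <- data.frame(lag_s = curve$lags, corr = curve$corr,
                   n_pairs = curve$n_pairs)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# specklestress decorrelation curve; fps=", curve$fps,
                    "; ", config_comment), con)
  utils::write.csv(format(df, digits = 12, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
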