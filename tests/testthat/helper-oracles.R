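# Independent brute-force oracles and fixture builders. These deliberately
# take the dumbest correct route (explicit loops, dictionaries) so they stay
# independent of the vectorized implementations they check.

random_stack <- function(n_frames, h, w, bit_depth = 8L, seed = 1L,
                         fps = 30) {
  set.seed(seed)
  frame_stack(array(sample(0:(2^bit_depth - 1), n_frames * h * w,
                           replace = TRUE), c(n_frames, h, w)),
              fps = fps, bit_depth = bit_depth,
              source_id = paste0("random-", seed))
}

static_stack <- function(n_frames = 10L, h = 8L, w = 8L, seed = 1L) {
  set.seed(seed)
  one <- matrix(sample(1:255, h * w, replace = TRUE), h, w)
  frames <- array(0, c(n_frames, h, w))
  for (t in seq_len(n_frames)) frames[t, , ] <- one
  frame_stack(frames, fps = 30, source_id = "static")
}

# Pearson correlation of two frames, from first principles
pearson_frames <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sum((a - mean(a)) * (b - mean(b))) /
    ((length(a) - 1) * sd(a) * sd(b))
}

brute_decorrelation <- function(stack, max_lag) {
  nf <- n_frames(stack)
  corr <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    vals <- c()
    for (i in seq_len(nf - k))
      vals <- c(vals, pearson_frames(stack$frames[i, , ],
                                     stack$frames[i + k, , ]))
    corr[k + 1] <- mean(vals)
  }
  corr[1] <- 1
  corr
}

brute_tlasca <- function(stack) {
  d <- dim(stack$frames)
  vals <- c()
  for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
    px <- stack$frames[, r, cc]
    if (mean(px) != 0) vals <- c(vals, sd(px) / mean(px))
  }
  mean(vals)
}

# dictionary-based GLCM inertia moment on the materialized THSP matrix
brute_inertia_moment <- function(stack, levels) {
  d <- dim(stack$frames)
  span <- 2^stack$bit_depth
  thsp <- matrix(0L, d[2] * d[3], d[1])   # rows: pixels, cols: frames
  px <- 0L
  for (cc in seq_len(d[3])) for (r in seq_len(d[2])) {
    px <- px + 1L
    thsp[px, ] <- pmin(floor(stack$frames[, r, cc] / span * levels),
                       levels - 1L)
  }
  counts <- new.env()
  for (i in seq_len(nrow(thsp))) for (t in seq_len(d[1] - 1)) {
    key <- paste(thsp[i, t], thsp[i, t + 1])
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  total <- sum(unlist(as.list(counts)))
  im <- 0
  for (key in ls(counts)) {
    ij <- as.numeric(strsplit(key, " ")[[1]])
    im <- im + counts[[key]] / total * (ij[1] - ij[2])^2
  }
  im
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# noiseless KWW decorrelation curve fixture
kww_curve <- function(tau, beta, lags, fps = 30) {
  corr <- exp(-(lags / tau)^beta)
  corr[lags == 0] <- 1
  structure(list(lags = lags, corr = corr,
                 n_pairs = rep(1L, length(lags)), fps = fps),
            class = "decorrelation_curve")
}
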