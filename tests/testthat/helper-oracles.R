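# Independent brute-force oracles for the signal and statistics layers.
# These deliberately re-derive everything sample by sample (O(n*w) loops,
# textbook formulas, third-party implementations) so they share no code
# path with the package.

make_random_stream <- function(n, seed, fs = 10) {
  set.seed(seed)
  accel_stream(data.frame(time = (seq_len(n) - 1) / fs,
                          x = stats::rnorm(n, 0, 0.5),
                          y = stats::rnorm(n, 0, 0.5),
                          z = stats::rnorm(n, -1, 0.5)), fs)
}

constant_stream <- function(xyz, n = 30, fs = 10) {
  accel_stream(data.frame(time = (seq_len(n) - 1) / fs, x = xyz[1],
                          y = xyz[2], z = xyz[3]), fs)
}

# naive centred moving mean with truncated edges
oracle_moving_average <- function(v, w) {
  n <- length(v)
  h <- (w - 1) / 2
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - h):min(n, i + h)]), 0)
}

# per-sample re-evaluation of every derived channel
oracle_channels <- function(stream, w = 5) {
  n <- nrow(stream)
  xs <- oracle_moving_average(stream$x, w)
  ys <- oracle_moving_average(stream$y, w)
  zs <- oracle_moving_average(stream$z, w)
  xd <- stream$x - xs; yd <- stream$y - ys; zd <- stream$z - zs
  odba <- vedba <- mv <- en <- pit <- rol <- numeric(n)
  for (i in seq_len(n)) {
    odba[i] <- abs(xd[i]) + abs(yd[i]) + abs(zd[i])
    vedba[i] <- sqrt(xd[i]^2 + yd[i]^2 + zd[i]^2)
    en[i] <- sqrt(stream$x[i]^2 + stream$y[i]^2 + stream$z[i]^2)
    j <- min(i, n - 1)
    mv[i] <- if (n == 1) 0 else
      abs(stream$x[j + 1] - stream$x[j]) +
      abs(stream$y[j + 1] - stream$y[j]) +
      abs(stream$z[j + 1] - stream$z[j])
    den <- sqrt(ys[i]^2 + zs[i]^2)
    pit[i] <- if (den == 0) { if (xs[i] == 0) 0 else 90 * sign(-xs[i]) }
      else atan(-xs[i] / den) * 180 / pi
    rol[i] <- atan2(ys[i], zs[i]) * 180 / pi
  }
  data.frame(xs = xs, ys = ys, zs = zs, xd = xd, yd = yd, zd = zd,
             odba = odba, vedba = vedba, movvar = mv, energy = en,
             pitch = pit, roll = rol)
}

# textbook statistics via third-party code: sd (stats), moment skewness/
# excess kurtosis (e1071, type 1), quantiles by hand-rolled linear
# interpolation between order statistics.
oracle_quantile <- function(v, p) {
  s <- sort(v); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
oracle_stats <- function(v) {
  const <- length(unique(v)) == 1
  c(mean = mean(v),
    sd = if (const) 0 else stats::sd(v),
    min = min(v), max = max(v),
    skewness = if (const) 0 else e1071::skewness(v, type = 1),
    kurtosis = if (const) 0 else e1071::kurtosis(v, type = 1))
}

# brute-force confusion tally
oracle_confusion <- function(pred, obs, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(predicted = classes, observed = classes))
  for (i in seq_along(pred))
    m[pred[i], obs[i]] <- m[pred[i], obs[i]] + 1L
  m
}

# tiny labelled dataset for model-layer tests: two well-separated Gaussian
# classes in a 66-column table shaped like the real feature tables
gaussian_two_class <- function(n_per = 60, sep = 4, seed = 1) {
  set.seed(seed)
  feats <- feature_names()
  mk <- function(label, shift, ids) {
    m <- matrix(stats::rnorm(n_per * length(feats)), n_per)
    m[, 1:8] <- m[, 1:8] + shift
    df <- as.data.frame(m); names(df) <- feats
    df$label <- label
    df$event_id <- paste0(label, rep(ids, length.out = n_per))
    df
  }
  rbind(mk("a", 0, 1:6), mk("b", sep, 1:6))
}
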