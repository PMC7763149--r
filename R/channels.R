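#' Static acceleration by centred moving average
#'
#' Smooths each raw axis with a centred moving average (default five
#' samples) to estimate the gravity-dominated static component; at the
#' stream edges the window is truncated to the available samples, so the
#' output has the same length as the input.
#'
#' @param stream an [accel_stream()].
#' @param window odd window length in samples (default 5).
#' @return data.frame with columns `xs, ys, zs` (g).
#' @export
smooth_static <- function(stream, window = 5) {
  if (nrow(stream) == 0) stopf("empty stream")
  if (!is_count(window) || window < 1 || window %% 2 == 0)
    stopf("window must be an odd positive sample count (centre undefined)")
  data.frame(xs = moving_average(stream$x, window),
             ys = moving_average(stream$y, window),
             zs = moving_average(stream$z, window))
}

# Centred moving average with truncated edge windows, O(n) via cumsum.
moving_average <- function(v, window) {
  n <- length(v)
  h <- (window - 1) %/% 2
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Derive the per-sample signal channels
#'
#' Splits the raw axes into static (moving-average) and dynamic
#' (raw minus static) components and computes the six movement channels:
#' \describe{
#'   \item{odba}{overall dynamic body acceleration, |Xdyn|+|Ydyn|+|Zdyn|.}
#'   \item{vedba}{vectorial DBA, sqrt(Xdyn^2+Ydyn^2+Zdyn^2).}
#'   \item{movvar}{movement variation, |X[i+1]-X[i]|+|Y[i+1]-Y[i]|+
#'     |Z[i+1]-Z[i]| on the raw axes; the final sample repeats its
#'     predecessor's value so all channels share one index.}
#'   \item{energy}{magnitude of the raw vector, sqrt(X^2+Y^2+Z^2)
#'     (`energy_form = "squared"` gives X^2+Y^2+Z^2).}
#'   \item{pitch}{atan(-Xs / sqrt(Ys^2+Zs^2)) * 180/pi, degrees, from the
#'     static axes.}
#'   \item{roll}{atan2(Ys, Zs) * 180/pi, degrees, from the static axes.}
#' }
#' Posture angles use the static axes (gravity component); energy and
#' movement variation use the raw axes.
#'
#' @param stream an [accel_stream()].
#' @param window moving-average window for the static split.
#' @param energy_form `"magnitude"` (default) or `"squared"`.
#' @return a `derived_stream`: data.frame with `time,x,y,z`, static
#'   `xs,ys,zs`, dynamic `xd,yd,zd`, and
#'   `odba,vedba,movvar,energy,pitch,roll`; `sampling_rate` attribute kept.
#' @export
derive_channels <- function(stream, window = 5,
                            energy_form = c("magnitude", "squared")) {
  energy_form <- match.arg(energy_form)
  st <- smooth_static(stream, window)
  xd <- stream$x - st$xs
  yd <- stream$y - st$ys
  zd <- stream$z - st$zs
  n <- nrow(stream)
  if (n > 1) {
    mv <- abs(diff(stream$x)) + abs(diff(stream$y)) + abs(diff(stream$z))
    mv <- c(mv, mv[n - 1])
  } else mv <- 0
  sq <- stream$x^2 + stream$y^2 + stream$z^2
  energy <- if (energy_form == "magnitude") sqrt(sq) else sq
  denom <- sqrt(st$ys^2 + st$zs^2)
  pitch <- ifelse(denom == 0,
                  ifelse(st$xs == 0, 0, 90 * sign(-st$xs)),
                  atan(-st$xs / denom) * 180 / pi)
  if (any(denom == 0))
    message("derive_channels: Ys = Zs = 0 at some samples; pitch set to ",
            "+/-90 by the sign of -Xs, roll to 0")
  roll <- atan2(st$ys, st$zs) * 180 / pi
  roll[roll <= -180] <- 180
  out <- data.frame(time = stream$time, x = stream$x, y = stream$y,
                    z = stream$z, xs = st$xs, ys = st$ys, zs = st$zs,
                    xd = xd, yd = yd, zd = zd,
                    odba = abs(xd) + abs(yd) + abs(zd),
                    vedba = sqrt(xd^2 + yd^2 + zd^2),
                    movvar = mv, energy = energy, pitch = pitch, roll = roll)
  structure(out, sampling_rate = attr(stream, "sampling_rate"),
            class = c("derived_stream", "data.frame"))
}

#' @export
print.derived_stream <- function(x, ...) {
  cat(sprintf("<derived_stream> %d samples at %g Hz, channels: %s\n",
              nrow(x), attr(x, "sampling_rate"),
              paste(setdiff(names(x), "time"), collapse = ", ")))
  invisible(x)
}
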