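# Shared small helpers: angle arithmetic, RNG scoping, moving averages.

#' Wrap angles into [0, 360)
#' @param x angles in degrees.
#' @return angles wrapped to [0, 360).
#' @export
wrapAngle <- function(x) x %% 360

# signed circular difference a - b wrapped to (-180, 180]
circDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# circular mean of angles in degrees; NA if resultant vanishes
circMean <- function(x) {
  z <- mean(exp(1i * x * pi / 180))
  if (Mod(z) < .Machine$double.eps^0.5) return(NA_real_)
  wrapAngle(Arg(z) * 180 / pi)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards so package functions never clobber user RNG
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# derive a child seed from a master seed and a stage label (deterministic,
# independent streams per stage)
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Centred moving average with shrinking edge windows
#'
#' Smooths a series (or each row of a matrix) with a centred moving mean.
#' Near the edges the window shrinks to the available samples, so the output
#' has the same length as the input and a constant series is unchanged.
#'
#' @param x numeric vector, or matrix smoothed along rows.
#' @param k odd window length in samples.
#' @return smoothed object of the same shape.
#' @export
movingAverage <- function(x, k) {
  if (is.matrix(x)) return(t(apply(x, 1L, movingAverage, k = k)))
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a resultant-length time series
#'
#' Sliding average over a fixed temporal window (default 50 ms), the step
#' used to stabilise resultant-vector length time courses before
#' thresholding. The window length in samples is forced odd so the filter is
#' exactly centred (7 samples at 150 Hz).
#'
#' @param x numeric vector (one value per time sample) or matrix
#'   [series x time].
#' @param fs sampling rate of the series in Hz.
#' @param window window length in seconds (default 0.050).
#' @return smoothed series, same shape, same length.
#' @export
smoothSeries <- function(x, fs, window = 0.050) {
  k <- 2L * floor(window * fs / 2L) + 1L
  movingAverage(x, k)
}

# analytic signal via FFT: half-spectrum doubling (Marple 1999). Returns a
# complex vector whose modulus is the envelope and argument the phase.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
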