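# Synthetic alpha EEG: a sinusoid at the individual alpha frequency with a
# trial-random phase, projected through a signed two-pole topography
# (occipital-positive, frontal-negative), plus 1/f background noise.

#' The 17 posterior channel labels used for alpha-power channel ranking
#' @return character vector of labels.
#' @export
posteriorChannels <- function() {
  c("Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8", "P1", "P5",
    "PO7", "PO3", "POz", "PO4", "PO8", "P6", "P2")
}

#' Generative model of epoched alpha EEG
#'
#' Parameters of the synthetic EEG: an alpha oscillation at \code{iaf} whose
#' phase at stimulus onset is drawn uniformly per trial, projected to the
#' channels through signed \code{topography} weights (a dipole-like pattern:
#' posterior channels positive, AFz negative by default), on top of
#' independent 1/f ("pink") noise per channel.
#'
#' @param iaf individual alpha frequency in Hz (default 10; must lie in
#'   7-14).
#' @param alphaAmp alpha amplitude in microvolts (default 10).
#' @param pinkNoiseAmp RMS of the 1/f background in microvolts (default 5).
#' @param channels channel labels; default the 17 posterior labels plus AFz.
#' @param topography named numeric weights per channel; default +1 for
#'   posterior channels, -1 for AFz.
#' @param fs sampling rate in Hz (default 500).
#' @param epochWindow epoch span in seconds relative to stimulus onset
#'   (default c(-2, 2)).
#' @return list of class \code{"AlphaEEGModel"}.
#' @export
alphaEEGModel <- function(iaf = 10, alphaAmp = 10, pinkNoiseAmp = 5,
                          channels = c(posteriorChannels(), "AFz"),
                          topography = NULL, fs = 500,
                          epochWindow = c(-2, 2)) {
  if (iaf < 7 || iaf > 14) stop("iaf must lie within 7-14 Hz")
  if (fs <= 2 * (iaf + 2)) stop("fs must exceed twice the upper band edge")
  if (is.null(topography)) {
    topography <- stats::setNames(rep(1, length(channels)), channels)
    topography[channels == "AFz"] <- -1
  }
  if (!all(channels %in% names(topography)))
    stop("topography must provide a weight for every channel")
  structure(list(
    iaf = iaf, alphaAmp = alphaAmp, pinkNoiseAmp = pinkNoiseAmp,
    channels = channels, topography = topography[channels],
    fs = fs, epochWindow = epochWindow
  ), class = "AlphaEEGModel")
}

# one epoch of 1/f-amplitude noise, RMS-scaled
pinkNoise <- function(n, fs, rmsAmp) {
  if (rmsAmp == 0) return(numeric(n))
  X <- stats::fft(stats::rnorm(n))
  f <- fs * ifelse(0:(n - 1) > n / 2, 0:(n - 1) - n, 0:(n - 1)) / n
  g <- ifelse(f == 0, 0, 1 / sqrt(abs(f)))
  x <- Re(stats::fft(X * g, inverse = TRUE)) / n
  x * rmsAmp / sqrt(mean(x^2))
}

#' Simulate epoched alpha EEG for a trial table
#'
#' Each trial's voltage at channel ch is \code{topography(ch) * alphaAmp *
#' cos(2*pi*iaf*t + phi)} plus pink noise, where the trial phase \code{phi}
#' (at t = 0, cosine convention, degrees) is drawn uniformly and returned as
#' ground truth.
#'
#' @param table trial table (one row per trial).
#' @param model an \code{\link{alphaEEGModel}}.
#' @param seed integer seed.
#' @return list with \code{epochs} (an \code{EpochedSeries}) and
#'   \code{truePhase} (degrees per trial, phase at stimulus onset).
#' @export
simulateAlphaEEG <- function(table, model = alphaEEGModel(), seed = 1L) {
  nTrial <- nrow(table)
  if (nTrial == 0L) stop("trial table is empty")
  tm <- seq(model$epochWindow[1L], model$epochWindow[2L], by = 1 / model$fs)
  nS <- length(tm)
  nC <- length(model$channels)
  withLocalSeed(seed, {
    phi <- stats::runif(nTrial, 0, 360)
    dat <- array(0, dim = c(nTrial, nC, nS))
    for (i in seq_len(nTrial)) {
      osc <- model$alphaAmp * cos(2 * pi * model$iaf * tm + phi[i] * pi / 180)
      for (j in seq_len(nC)) {
        dat[i, j, ] <- model$topography[j] * osc +
          pinkNoise(nS, model$fs, model$pinkNoiseAmp)
      }
    }
    epochs <- methods::new("EpochedSeries", voltages = dat, time = tm,
                           channels = model$channels, fs = model$fs)
    list(epochs = epochs, truePhase = phi)
  })
}

#' Propagate ground-truth onset phases along the epoch
#'
#' Under the generative model the instantaneous alpha phase advances
#' linearly at the oscillation frequency, so the noise-free phase at time t
#' is \code{phi0 + 360 * iaf * t}. Returns the trial x time matrix of phases
#' on an arbitrary time grid — the analytic counterpart of running the
#' filter-Hilbert chain on noise-free data.
#'
#' @param phi0 phases at stimulus onset, degrees (one per trial).
#' @param iaf oscillation frequency in Hz.
#' @param time numeric vector of times in seconds.
#' @return matrix [trial x time] of phases in [0, 360).
#' @export
propagatePhase <- function(phi0, iaf, time) {
  wrapAngle(outer(phi0, 360 * iaf * time, "+"))
}
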