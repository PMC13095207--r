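# Phase-estimation chain: simplified preprocessing, IAF detection,
# post-stimulus taper, IAF +/- 2 Hz FIR band-pass, analytic-signal phase on
# a 150 Hz grid, phase binning, and alpha-power channel selection.

#' Preprocess epoched EEG
#'
#' Simplified preprocessing: 0.1 Hz high-pass, resampling to 500 Hz if
#' needed, threshold-based trial rejection (any sample exceeding
#' \code{rejectUv} inside \code{rejectWindow}), and average re-referencing.
#'
#' @param epochs an \code{EpochedSeries} (>= 500 Hz).
#' @param rejectUv rejection threshold in microvolts (default 150).
#' @param rejectWindow window (s) scanned for artifacts (default
#'   c(-0.8, 0.2)).
#' @param highpass high-pass cutoff in Hz (default 0.1; 0 disables).
#' @param medianRef also subtract the per-sample channel median first
#'   (default FALSE; gross-artifact guard for recorded data).
#' @return list with \code{epochs} (cleaned \code{EpochedSeries}) and
#'   \code{kept} (indices of surviving trials in the input).
#' @export
preprocessEpochs <- function(epochs, rejectUv = 150,
                             rejectWindow = c(-0.8, 0.2), highpass = 0.1,
                             medianRef = FALSE) {
  stopifnot(methods::is(epochs, "EpochedSeries"))
  if (epochs@fs < 500) stop("epochs must be sampled at >= 500 Hz")
  dat <- epochs@voltages
  tm <- epochs@time
  fs <- epochs@fs

  if (fs > 500) {
    dec <- fs / 500
    if (abs(dec - round(dec)) > 1e-9)
      stop("sampling rate must be an integer multiple of 500 Hz to resample")
    idx <- seq(1L, length(tm), by = as.integer(round(dec)))
    dat <- dat[, , idx, drop = FALSE]
    tm <- tm[idx]
    fs <- 500
  }

  if (highpass > 0) {
    bf <- signal::butter(2, highpass / (fs / 2), type = "high")
    d <- dim(dat)
    for (i in seq_len(d[1L])) for (j in seq_len(d[2L]))
      dat[i, j, ] <- signal::filtfilt(bf, dat[i, j, ])
  }

  if (medianRef) {
    for (i in seq_len(dim(dat)[1L])) {
      med <- apply(dat[i, , , drop = FALSE][1, , ], 2L, stats::median)
      dat[i, , ] <- sweep(dat[i, , , drop = FALSE][1, , ], 2L, med)
    }
  }

  win <- tm >= rejectWindow[1L] & tm <= rejectWindow[2L]
  bad <- apply(dat[, , win, drop = FALSE], 1L,
               function(x) any(abs(x) > rejectUv))
  kept <- which(!bad)
  if (length(kept) == 0L) stop("empty data: all trials rejected")
  dat <- dat[kept, , , drop = FALSE]

  # average reference: per-sample mean over channels removed
  for (i in seq_along(kept)) {
    m <- colMeans(dat[i, , , drop = FALSE][1, , ])
    dat[i, , ] <- sweep(dat[i, , , drop = FALSE][1, , ], 2L, m)
  }

  list(epochs = methods::new("EpochedSeries", voltages = dat, time = tm,
                             channels = epochs@channels, fs = fs),
       kept = kept)
}

#' Estimate the individual alpha frequency (IAF)
#'
#' Hamming-tapered, zero-padded spectra of the pre-stimulus window are
#' averaged over the listed channels and all trials; the IAF is the
#' frequency of the power-spectrum peak within \code{band}. A peak must be a
#' local maximum strictly inside the band and exceed the median band power
#' by the \code{prominence} factor — the operational version of the
#' "discernable alpha peak" inclusion criterion.
#'
#' @param epochs an \code{EpochedSeries}.
#' @param channels channels averaged for the spectrum (default P1, Pz, P2,
#'   PO3, POz, PO4).
#' @param window pre-stimulus window in seconds (default c(-0.5, 0)).
#' @param zeroPad zero-padding factor (default 5; frequency resolution
#'   fs / (zeroPad * n_window)).
#' @param band search band in Hz (default c(7, 14)).
#' @param prominence required peak/median band-power ratio (default 1.2).
#' @return list with \code{iaf} (Hz), \code{freq}, \code{power} (the
#'   averaged spectrum restricted to the band).
#' @export
estimateIAF <- function(epochs, channels = c("P1", "Pz", "P2", "PO3", "POz",
                                             "PO4"),
                        window = c(-0.5, 0), zeroPad = 5, band = c(7, 14),
                        prominence = 1.2) {
  stopifnot(methods::is(epochs, "EpochedSeries"))
  chIdx <- match(channels, epochs@channels)
  if (anyNA(chIdx)) stop("missing channels: ",
                         paste(channels[is.na(chIdx)], collapse = ", "))
  sel <- epochs@time >= window[1L] & epochs@time <= window[2L]
  if (!any(sel)) stop("window lies outside the epoch")
  nW <- sum(sel)
  nF <- as.integer(zeroPad * nW)
  taper <- signal::hamming(nW)
  freq <- (0:(nF - 1)) * epochs@fs / nF

  pow <- numeric(nF)
  nTrial <- dim(epochs@voltages)[1L]
  for (j in chIdx) {
    seg <- epochs@voltages[, j, sel, drop = FALSE][, 1L, , drop = TRUE]
    if (nTrial == 1L) seg <- matrix(seg, nrow = 1L)
    seg <- sweep(seg, 1L, rowMeans(seg)) * rep(taper, each = nTrial)
    padded <- cbind(seg, matrix(0, nTrial, nF - nW))
    sp <- Mod(stats::mvfft(t(padded)))^2
    pow <- pow + rowSums(sp) / nTrial
  }
  pow <- pow / length(chIdx)

  inBand <- which(freq >= band[1L] & freq <= band[2L])
  p <- pow[inBand]
  k <- which.max(p)
  peakIdx <- inBand[k]
  isLocal <- peakIdx > 1L && peakIdx < nF &&
    pow[peakIdx] > pow[peakIdx - 1L] && pow[peakIdx] >= pow[peakIdx + 1L] &&
    k > 1L && k < length(p)
  if (!isLocal || p[k] < prominence * stats::median(p))
    stop("no alpha peak: no prominent local maximum inside ",
         band[1L], "-", band[2L], " Hz")
  list(iaf = freq[peakIdx], freq = freq[inBand], power = p)
}

#' Apply the post-stimulus linear taper
#'
#' Multiplies each epoch by a gain profile that is 1 up to \code{ramp[1]}
#' (30 ms), falls linearly to 0 at \code{ramp[2]} (70 ms), and is exactly 0
#' afterwards, so stimulus-evoked activity cannot leak into pre-stimulus
#' phase estimates during filtering.
#'
#' @param epochs an \code{EpochedSeries}.
#' @param ramp start/end of the linear ramp in seconds (default
#'   c(0.030, 0.070)).
#' @return tapered \code{EpochedSeries}.
#' @export
applyPoststimTaper <- function(epochs, ramp = c(0.030, 0.070)) {
  stopifnot(methods::is(epochs, "EpochedSeries"))
  tm <- epochs@time
  if (ramp[1L] < min(tm) || ramp[2L] > max(tm))
    stop("ramp must lie within the epoch")
  gain <- rep(1, length(tm))
  inRamp <- tm > ramp[1L] & tm < ramp[2L]
  gain[inRamp] <- (ramp[2L] - tm[inRamp]) / (ramp[2L] - ramp[1L])
  gain[tm >= ramp[2L]] <- 0
  dat <- sweep(epochs@voltages, 3L, gain, "*")
  methods::new("EpochedSeries", voltages = dat, time = tm,
               channels = epochs@channels, fs = epochs@fs)
}

# Hamming-window sinc FIR band-pass kernel (odd length, symmetric ->
# zero-phase when applied centred). Length from the classic 3.3 / (tb / fs)
# Hamming rule with transition bandwidth `transWidth`.
firBandpassKernel <- function(fs, band, transWidth = 2) {
  ntaps <- ceiling(3.3 * fs / transWidth)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  signal::fir1(ntaps - 1L, band / (fs / 2), type = "pass")
}

# centred zero-phase FIR filtering of a vector via FFT convolution
firFilterCentred <- function(x, kern) {
  n <- length(x)
  k <- length(kern)
  half <- (k - 1L) %/% 2L
  nf <- stats::nextn(n + k - 1L, 2L)
  X <- stats::fft(c(x, numeric(nf - n)))
  K <- stats::fft(c(kern, numeric(nf - k)))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / nf
  full[(half + 1L):(half + n)]
}

#' Band-pass filter and extract instantaneous phase
#'
#' Zero-phase (symmetric-kernel Hamming-window sinc FIR) band-pass at
#' IAF +/- \code{halfBw}, analytic signal per trial and channel, then
#' decimation of the complex analytic signal onto the \code{fsOut} grid
#' before taking angles (order chosen to preserve phase). Phase uses the
#' cosine convention: 0 degrees at the oscillation peak.
#'
#' @param epochs a tapered \code{EpochedSeries}.
#' @param iaf centre frequency in Hz.
#' @param halfBw half bandwidth in Hz (default 2).
#' @param fsOut output sampling rate in Hz (default 150).
#' @param transWidth FIR transition bandwidth in Hz (default 1; the longer
#'   kernel keeps the post-stimulus taper's phase bias at stimulus onset
#'   well under a degree, where a 2 Hz transition leaves a systematic ~3
#'   degree offset).
#' @return a \code{\link{PhaseArray-class}} with phase (degrees) and
#'   amplitude envelope on the \code{fsOut} grid.
#' @export
bandpassPhase <- function(epochs, iaf, halfBw = 2, fsOut = 150,
                          transWidth = 1) {
  stopifnot(methods::is(epochs, "EpochedSeries"))
  band <- c(iaf - halfBw, iaf + halfBw)
  kern <- firBandpassKernel(epochs@fs, band, transWidth)
  nS <- length(epochs@time)
  if (nS < length(kern))
    stop("edge-artifact error: epoch shorter than the FIR kernel (",
         length(kern), " taps)")

  step <- 1 / fsOut
  tOut <- seq(ceiling(min(epochs@time) / step) * step,
              floor(max(epochs@time) / step) * step, by = step)
  d <- dim(epochs@voltages)
  ph <- array(NA_real_, dim = c(d[1L], d[2L], length(tOut)))
  am <- array(NA_real_, dim = c(d[1L], d[2L], length(tOut)))
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      filt <- firFilterCentred(epochs@voltages[i, j, ], kern)
      a <- analyticSignal(filt)
      re <- stats::approx(epochs@time, Re(a), tOut)$y
      im <- stats::approx(epochs@time, Im(a), tOut)$y
      z <- complex(real = re, imaginary = im)
      ph[i, j, ] <- wrapAngle(Arg(z) * 180 / pi)
      am[i, j, ] <- Mod(z)
    }
  }
  methods::new("PhaseArray", phase = ph, amplitude = am, time = tOut,
               channels = epochs@channels, fsOut = fsOut, iaf = iaf,
               band = band)
}

#' Centres of the eight phase bins
#' @return numeric vector c(0, 45, ..., 315) in degrees.
#' @export
phaseBinCenters <- function() seq(0, 315, by = 45)

#' Assign phase angles to the eight equally spaced bins
#'
#' Bins are centred at 0, 45, ..., 315 degrees with half-width 22.5; each
#' angle maps to the half-open interval [centre - 22.5, centre + 22.5)
#' containing it (lower-inclusive, modulo 360).
#'
#' @param angle phase angles in degrees (any shape; vectorised).
#' @return integer bin indices 1..8 (1 = centre 0 degrees), same shape.
#' @export
binPhase <- function(angle) {
  idx <- floor(((angle %% 360) + 22.5) %% 360 / 45) + 1L
  storage.mode(idx) <- "integer"
  if (!is.null(dim(angle))) dim(idx) <- dim(angle)
  idx
}

#' Select the channels with the strongest alpha
#'
#' Ranks candidate channels by pre-stimulus band power in IAF +/-
#' \code{halfBw} (averaged over trials) and returns the top \code{k} labels.
#' Ties break deterministically by candidate-list order.
#'
#' @param epochs an \code{EpochedSeries}.
#' @param iaf centre frequency in Hz.
#' @param candidates candidate labels (default the 17 posterior channels).
#' @param k number of channels to select (default 3).
#' @param window pre-stimulus window in seconds (default c(-0.5, 0)).
#' @param halfBw half bandwidth in Hz (default 2).
#' @return character vector of \code{k} selected labels (ranked).
#' @export
selectAlphaChannels <- function(epochs, iaf, candidates = posteriorChannels(),
                                k = 3L, window = c(-0.5, 0), halfBw = 2) {
  stopifnot(methods::is(epochs, "EpochedSeries"))
  if (k > length(candidates)) stop("k exceeds the number of candidates")
  chIdx <- match(candidates, epochs@channels)
  if (anyNA(chIdx)) stop("missing candidate channels: ",
                         paste(candidates[is.na(chIdx)], collapse = ", "))
  sel <- epochs@time >= window[1L] & epochs@time <= window[2L]
  nW <- sum(sel)
  freq <- (0:(nW - 1)) * epochs@fs / nW
  inBand <- freq >= iaf - halfBw & freq <= iaf + halfBw
  nTrial <- dim(epochs@voltages)[1L]
  power <- vapply(chIdx, function(j) {
    seg <- epochs@voltages[, j, sel, drop = FALSE][, 1L, , drop = TRUE]
    if (nTrial == 1L) seg <- matrix(seg, nrow = 1L)
    sp <- Mod(stats::mvfft(t(seg)))^2
    mean(colSums(sp[inBand, , drop = FALSE]))
  }, numeric(1L))
  # order() is stable, so equal powers keep candidate-list order
  candidates[order(-power)[seq_len(k)]]
}
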