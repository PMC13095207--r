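# Phase-behaviour coupling: phase-binned SDT metrics vectorised into
# resultant vectors over time and channels, permutation thresholds,
# cluster-size correction, and best-bin alignment.
#
# The permutation engine is fully vectorised: bin indices for all trials and
# time points are flattened once, and each permutation only re-tabulates the
# shuffled behaviour labels against them.

metricFromRates <- function(hr, far, metric) {
  switch(metric,
    dprime    = stats::qnorm(hr) - stats::qnorm(far),
    criterion = -(stats::qnorm(hr) + stats::qnorm(far)) / 2,
    hr        = hr,
    far       = far,
    stop("unknown metric: ", metric))
}

#' Phase-binned behavioural metric
#'
#' Splits trials by their phase-bin index, assembles per-bin hit/false-alarm
#' counts, applies the loglinear correction, and computes the requested
#' metric per bin. Bins with no trials of one class are still defined
#' through the correction (rate 0.5) and flagged.
#'
#' @param present logical target-present per trial.
#' @param response logical "yes" response per trial.
#' @param binIndex integer bin index 1..8 per trial (see
#'   \code{\link{binPhase}}).
#' @param metric "dprime", "criterion", "hr" or "far".
#' @return list with \code{values} (8), \code{nPerBin} (8), \code{metric},
#'   and \code{flagged} (bins lacking a trial class).
#' @export
binnedMetric <- function(present, response, binIndex,
                         metric = c("dprime", "criterion", "hr", "far")) {
  metric <- match.arg(metric)
  stopifnot(length(present) == length(binIndex),
            length(response) == length(binIndex))
  nHit <- tabulate(binIndex[present & response], 8L)
  nSig <- tabulate(binIndex[present], 8L)
  nFa  <- tabulate(binIndex[!present & response], 8L)
  nNoi <- tabulate(binIndex[!present], 8L)
  r <- loglinearRates(nHit, nSig, nFa, nNoi)
  list(values = metricFromRates(r$hr, r$far, metric),
       nPerBin = nHit + nFa + (nSig - nHit) + (nNoi - nFa),
       metric = metric, flagged = which(nSig == 0L | nNoi == 0L))
}

#' Resultant vector of eight phase-binned values
#'
#' Each bin value becomes a vector of that length pointing at its bin
#' centre; the resultant is their vector sum (default) or mean. A constant
#' profile cancels exactly (rho = 0); a profile a + A*cos(theta_b - phi)
#' yields rho = 4A and angle phi in sum mode.
#'
#' @param values eight bin values (ordered as \code{\link{phaseBinCenters}}).
#' @param centers bin centres in degrees.
#' @param mode "sum" (default) or "mean" (divides by the bin count).
#' @return list with \code{rho} (length) and \code{theta} (angle, degrees;
#'   NA when rho is numerically zero).
#' @export
resultantVector <- function(values, centers = phaseBinCenters(),
                            mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(values) == length(centers))
  z <- sum(values * exp(1i * centers * pi / 180))
  if (mode == "mean") z <- z / length(values)
  rho <- Mod(z)
  list(rho = rho,
       theta = if (rho < 1e-12) NA_real_ else wrapAngle(Arg(z) * 180 / pi))
}

# --- vectorised engine over a [trial x time] bin-index matrix -------------

# flatten bin indices with per-column offsets so one tabulate() call counts
# all (bin, time) cells at once
flattenBins <- function(binIdx) {
  nT <- nrow(binIdx)
  nTime <- ncol(binIdx)
  list(idx = as.integer(binIdx) +
         rep(seq.int(0L, 8L * (nTime - 1L), by = 8L), each = nT),
       nT = nT, nTime = nTime, nBins = 8L * nTime)
}

# complex resultant per time point for one behaviour labelling
engineResultant <- function(flat, present, response, metric, mode) {
  fSig <- rep(present, times = flat$nTime)
  fYes <- rep(response, times = flat$nTime)
  nHit <- tabulate(flat$idx[fSig & fYes], flat$nBins)
  nSig <- tabulate(flat$idx[fSig], flat$nBins)
  nFa  <- tabulate(flat$idx[!fSig & fYes], flat$nBins)
  nNoi <- tabulate(flat$idx[!fSig], flat$nBins)
  hr  <- (nHit + 0.5) / (nSig + 1)
  far <- (nFa + 0.5) / (nNoi + 1)
  v <- matrix(metricFromRates(hr, far, metric), nrow = 8L)
  ph <- exp(1i * phaseBinCenters() * pi / 180)
  z <- as.vector(crossprod(v, ph))   # complex resultant per time
  if (mode == "mean") z <- z / 8
  z
}

# channel-wise resultants -> channel-averaged length and angle series
channelAverage <- function(zList) {
  rhoC <- vapply(zList, Mod, numeric(length(zList[[1L]])))
  if (is.null(dim(rhoC))) rhoC <- matrix(rhoC, nrow = 1L)
  rho <- rowMeans(rhoC)
  # angle: circular mean of channel angles weighted by their lengths
  zSum <- Reduce(`+`, zList)
  theta <- ifelse(Mod(zSum) < 1e-12, NA_real_,
                  wrapAngle(Arg(zSum) * 180 / pi))
  list(rho = rho, theta = theta, rhoByChannel = t(rhoC),
       thetaByChannel = t(vapply(zList, function(z)
                         wrapAngle(Arg(z) * 180 / pi),
                         numeric(length(zList[[1L]])))))
}

#' Permutation null distribution of the coupling strength
#'
#' Shuffles the mapping between behaviour (target/response) and the trials'
#' phase time courses, recomputing the identical binned-metric ->
#' resultant -> channel-average -> smoothing chain for every permutation,
#' and returns the per-time-point 95th-percentile threshold alongside the
#' full null matrix.
#'
#' @param binIdx integer array of bin indices: [trial x time] or
#'   [trial x channel x time].
#' @param present,response logical behaviour per trial.
#' @param metric behavioural metric (see \code{\link{binnedMetric}}).
#' @param nPerm number of permutations (default 1000; < 100 warns).
#' @param seed integer seed (fixed seed gives identical thresholds).
#' @param fs sampling rate of the time axis in Hz (for smoothing).
#' @param smoothWindow smoothing window in seconds (default 0.050).
#' @param mode resultant mode, "sum" or "mean".
#' @param probs threshold quantile (default 0.95).
#' @return list with \code{permRho} [permutation x time] of smoothed
#'   channel-averaged lengths and \code{threshold} per time point.
#' @export
permutationNull <- function(binIdx, present, response, metric = "dprime",
                            nPerm = 1000L, seed = 1L, fs = 150,
                            smoothWindow = 0.050, mode = "sum",
                            probs = 0.95) {
  if (nPerm < 100L) warning("nPerm < 100: threshold quantiles are unstable")
  flats <- flattenBinArray(binIdx)
  nTrial <- length(present)
  withLocalSeed(seed, {
    permRho <- matrix(0, nPerm, flats[[1L]]$nTime)
    for (p in seq_len(nPerm)) {
      ord <- sample.int(nTrial)
      zL <- lapply(flats, engineResultant, present = present[ord],
                   response = response[ord], metric = metric, mode = mode)
      permRho[p, ] <- smoothSeries(channelAverage(zL)$rho, fs, smoothWindow)
    }
    list(permRho = permRho,
         threshold = apply(permRho, 2L, stats::quantile, probs = probs,
                           names = FALSE))
  })
}

# normalise [trial x time] or [trial x channel x time] input to a list of
# per-channel flattened bin structures
flattenBinArray <- function(binIdx) {
  if (length(dim(binIdx)) == 3L) {
    lapply(seq_len(dim(binIdx)[2L]), function(j)
      flattenBins(binIdx[, j, , drop = FALSE][, 1L, ]))
  } else {
    list(flattenBins(as.matrix(binIdx)))
  }
}

#' Cluster-size correction of supra-threshold coupling
#'
#' Temporally adjacent samples whose real coupling strength exceeds the
#' permutation threshold form clusters. The null distribution is the
#' maximum cluster size each permutation produces against the same
#' thresholds; a cluster's p-value is the fraction of permutations whose
#' maximum cluster is at least as large.
#'
#' @param rho real (smoothed, channel-averaged) coupling series.
#' @param threshold per-time-point permutation threshold.
#' @param permRho permutation null matrix [permutation x time].
#' @return data.frame with one row per cluster: \code{start}, \code{end}
#'   (sample indices), \code{size}, \code{p}, where p is the fraction of
#'   permutations whose maximum cluster is at least as large as the
#'   observed one.
#' @export
clusterCorrect <- function(rho, threshold, permRho) {
  runSizes <- function(above) {
    r <- rle(above)
    w <- which(r$values)
    ends <- cumsum(r$lengths)
    data.frame(start = ends[w] - r$lengths[w] + 1L, end = ends[w],
               size = r$lengths[w])
  }
  obs <- runSizes(rho > threshold)
  nullMax <- apply(permRho, 1L, function(p) {
    r <- rle(p > threshold)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
  obs$p <- vapply(obs$size, function(s) mean(nullMax >= s), numeric(1L))
  obs
}

#' Full phase-behaviour coupling analysis
#'
#' The complete chain for one subject: phase binning on the analysis grid,
#' per-channel phase-binned metric and resultant vectors at every time
#' point, channel averaging, 50 ms smoothing, permutation thresholds,
#' cluster correction, and the time-averaged subject-level significance
#' statistic.
#'
#' @param phase a \code{PhaseArray}, or a numeric array/matrix of phases in
#'   degrees ([trial x time] or [trial x channel x time]).
#' @param present,response logical behaviour per trial.
#' @param metric "dprime", "criterion", "hr" or "far".
#' @param channels channel labels to analyse (PhaseArray input only;
#'   default all).
#' @param window analysis window in seconds for thresholding (default
#'   c(-0.700, 0)).
#' @param subjectWindow window averaged for the subject-level statistic
#'   (default c(-0.450, 0)).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @param mode resultant mode, "sum" (default) or "mean".
#' @param smoothWindow smoothing window in seconds (default 0.050).
#' @param fs sampling rate in Hz when \code{phase} is a bare array (taken
#'   from the \code{PhaseArray} otherwise).
#' @param time time axis when \code{phase} is a bare array.
#' @return a \code{\link{ResultantSeries-class}}.
#' @export
phaseCoupling <- function(phase, present, response, metric = "dprime",
                          channels = NULL, window = c(-0.700, 0),
                          subjectWindow = c(-0.450, 0), nPerm = 1000L,
                          seed = 1L, mode = "sum", smoothWindow = 0.050,
                          fs = 150, time = NULL) {
  if (methods::is(phase, "PhaseArray")) {
    if (is.null(channels)) channels <- phase@channels
    chIdx <- match(channels, phase@channels)
    if (anyNA(chIdx)) stop("missing channels in PhaseArray")
    keep <- phase@time >= window[1L] & phase@time <= window[2L]
    time <- phase@time[keep]
    fs <- phase@fsOut
    arr <- phase@phase[, chIdx, keep, drop = FALSE]
  } else {
    arr <- phase
    if (length(dim(arr)) == 2L) arr <- array(arr, c(nrow(arr), 1L, ncol(arr)))
    if (is.null(time))
      time <- window[1L] + (seq_len(dim(arr)[3L]) - 1L) / fs
    keep <- time >= window[1L] & time <= window[2L]
    time <- time[keep]
    arr <- arr[, , keep, drop = FALSE]
    if (is.null(channels)) channels <- paste0("ch", seq_len(dim(arr)[2L]))
  }

  binIdx <- binPhase(arr)
  flats <- flattenBinArray(binIdx)
  zL <- lapply(flats, engineResultant, present = present,
               response = response, metric = metric, mode = mode)
  avg <- channelAverage(zL)
  rhoSm <- smoothSeries(avg$rho, fs, smoothWindow)

  null <- permutationNull(binIdx, present, response, metric = metric,
                          nPerm = nPerm, seed = seed, fs = fs,
                          smoothWindow = smoothWindow, mode = mode)
  clusters <- clusterCorrect(rhoSm, null$threshold, null$permRho)

  sIdx <- time >= subjectWindow[1L] & time <= subjectWindow[2L]
  subjectRho <- mean(rhoSm[sIdx])
  subjectThreshold <- stats::quantile(rowMeans(null$permRho[, sIdx,
                                                            drop = FALSE]),
                                      0.95, names = FALSE)

  methods::new("ResultantSeries",
    rho = rhoSm, theta = avg$theta, rhoByChannel = avg$rhoByChannel,
    thetaByChannel = avg$thetaByChannel, threshold = null$threshold,
    clusters = clusters, permRho = null$permRho, time = time,
    channels = channels, metric = metric, subjectRho = subjectRho,
    subjectThreshold = subjectThreshold)
}

#' Align per-subject bin profiles to the best-d' bin
#'
#' Circularly shifts each subject's binned metrics so the bin with the
#' highest d' lands at bin 8 (ties broken toward the lowest bin index),
#' applies the same shift to criterion, HR and FAR, drops bin 8, and
#' returns the per-subject shifted arrays plus the group mean. For
#' visualisation only — no inference is performed on aligned data.
#'
#' @param dprime matrix [subject x 8] of binned d' values.
#' @param ... further matrices [subject x 8] (e.g. criterion, hr, far),
#'   named.
#' @return list with \code{aligned} (named list of [subject x 7] matrices,
#'   d' first), \code{groupMean} (named list of length-7 vectors), and
#'   \code{shift} per subject.
#' @export
alignToBestBin <- function(dprime, ...) {
  extras <- list(...)
  stopifnot(ncol(dprime) == 8L)
  shift <- apply(dprime, 1L, function(v) 8L - which.max(v))
  shiftRow <- function(v, s) v[((seq_len(8L) - 1L - s) %% 8L) + 1L]
  alignOne <- function(m) {
    out <- t(vapply(seq_len(nrow(m)), function(i)
      shiftRow(m[i, ], shift[i]), numeric(8L)))
    out[, -8L, drop = FALSE]
  }
  aligned <- c(list(dprime = alignOne(dprime)), lapply(extras, alignOne))
  list(aligned = aligned, groupMean = lapply(aligned, colMeans),
       shift = shift)
}
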