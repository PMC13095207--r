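#' @import methods
NULL

#' Epoched multichannel voltage time series
#'
#' Container for epoched EEG voltages indexed trial x channel x sample, with
#' a sampling rate and a time axis whose zero is stimulus onset.
#'
#' @slot voltages numeric array \code{[trial, channel, sample]}, microvolts.
#' @slot time numeric vector of sample times in seconds (0 = stimulus onset).
#' @slot channels character vector of channel labels.
#' @slot fs sampling rate in Hz.
#'
#' @export
setClass("EpochedSeries",
  representation(
    voltages = "array",
    time     = "numeric",
    channels = "character",
    fs       = "numeric"
  )
)

setValidity("EpochedSeries", function(object) {
  d <- dim(object@voltages)
  if (length(d) != 3L)
    return("voltages must be a 3-D array [trial, channel, sample]")
  if (d[2L] != length(object@channels))
    return("dim 2 of voltages must match length(channels)")
  if (d[3L] != length(object@time))
    return("dim 3 of voltages must match length(time)")
  if (length(object@fs) != 1L || object@fs <= 0)
    return("fs must be a single positive number")
  TRUE
})

#' Instantaneous phase and amplitude envelope
#'
#' Phase angles (degrees, cosine convention: 0 at the oscillation peak) and
#' amplitude envelope of the analytic signal, indexed trial x channel x
#' sample on the downsampled time grid.
#'
#' @slot phase numeric array of phase angles in degrees, wrapped to [0, 360).
#' @slot amplitude numeric array of envelope magnitudes (same dimensions).
#' @slot time numeric vector of sample times (seconds).
#' @slot channels character vector of channel labels.
#' @slot fsOut output sampling rate in Hz.
#' @slot iaf individual alpha frequency (Hz) the band-pass was centred on.
#' @slot band numeric length-2 pass band in Hz.
#'
#' @export
setClass("PhaseArray",
  representation(
    phase     = "array",
    amplitude = "array",
    time      = "numeric",
    channels  = "character",
    fsOut     = "numeric",
    iaf       = "numeric",
    band      = "numeric"
  )
)

setValidity("PhaseArray", function(object) {
  d <- dim(object@phase)
  if (length(d) != 3L)
    return("phase must be a 3-D array [trial, channel, sample]")
  if (!identical(d, dim(object@amplitude)))
    return("phase and amplitude must have identical dimensions")
  if (d[2L] != length(object@channels))
    return("dim 2 of phase must match length(channels)")
  if (d[3L] != length(object@time))
    return("dim 3 of phase must match length(time)")
  if (any(object@phase < 0 | object@phase >= 360, na.rm = TRUE))
    return("phase angles must be wrapped to [0, 360)")
  TRUE
})

#' Phase-behaviour coupling result
#'
#' Resultant-vector length and angle of phase-binned behavioural metrics per
#' time point (channel-averaged), with permutation thresholds and
#' cluster-correction results.
#'
#' @slot rho channel-averaged, smoothed resultant length per time point.
#' @slot theta resultant angle (degrees) per time point.
#' @slot rhoByChannel matrix [channel x time] of unsmoothed lengths.
#' @slot thetaByChannel matrix [channel x time] of angles (degrees).
#' @slot threshold permutation 95th-percentile threshold per time point.
#' @slot clusters data.frame of supra-threshold clusters (start, end indices,
#'   size, p-value).
#' @slot permRho matrix [permutation x time] of permuted smoothed lengths.
#' @slot time time axis (seconds).
#' @slot channels channel labels entering the average.
#' @slot metric which behavioural metric was coupled ("dprime", "criterion",
#'   "hr" or "far").
#' @slot subjectRho time-averaged real resultant length (subject-level
#'   statistic).
#' @slot subjectThreshold 95th percentile of time-averaged permuted lengths.
#'
#' @export
setClass("ResultantSeries",
  representation(
    rho              = "numeric",
    theta            = "numeric",
    rhoByChannel     = "matrix",
    thetaByChannel   = "matrix",
    threshold        = "numeric",
    clusters         = "data.frame",
    permRho          = "matrix",
    time             = "numeric",
    channels         = "character",
    metric           = "character",
    subjectRho       = "numeric",
    subjectThreshold = "numeric"
  )
)

setValidity("ResultantSeries", function(object) {
  if (length(object@rho) != length(object@time))
    return("rho must have one value per time point")
  if (any(object@rho < 0, na.rm = TRUE))
    return("resultant lengths must be non-negative")
  TRUE
})

#' Quadrature Gabor filter bank
#'
#' A grid of Gabor filters in quadrature phase spanning spatial frequency and
#' orientation, used to extract stimulus energy profiles for reverse
#' correlation. Each cell holds a sine-phase and a cosine-phase kernel, both
#' normalised to unit energy.
#'
#' @slot sf spatial-frequency grid (cycles per degree).
#' @slot ori orientation grid (degrees from vertical).
#' @slot gsin matrix [pixel x cell] of vectorised sine-phase kernels.
#' @slot gcos matrix [pixel x cell] of vectorised cosine-phase kernels.
#' @slot patchPixels side length of the square patch raster.
#' @slot pixelsPerDegree raster resolution.
#'
#' @export
setClass("FilterBank",
  representation(
    sf              = "numeric",
    ori             = "numeric",
    gsin            = "matrix",
    gcos            = "matrix",
    patchPixels     = "integer",
    pixelsPerDegree = "numeric"
  )
)

setValidity("FilterBank", function(object) {
  ncell <- length(object@sf) * length(object@ori)
  if (ncol(object@gsin) != ncell || ncol(object@gcos) != ncell)
    return("kernel matrices must have one column per (sf, ori) cell")
  if (nrow(object@gsin) != object@patchPixels^2)
    return("kernel matrices must have patchPixels^2 rows")
  TRUE
})

#' Reverse-correlation classification image
#'
#' Probit regression slopes relating single-trial stimulus energy to the
#' detection response, on the spatial-frequency x orientation grid, with the
#' orientation-folded grid and (optionally) a 2-D Gaussian tuning fit.
#'
#' @slot beta matrix [sf x orientation] of probit slopes.
#' @slot intercepts matrix of probit intercepts, same shape.
#' @slot folded matrix [sf x |orientation|] after folding +/- orientations.
#' @slot sf spatial-frequency grid (cpd).
#' @slot ori orientation grid (degrees).
#' @slot oriFolded orientation-magnitude grid (degrees).
#' @slot fit list of 2-D Gaussian parameters (p1..p6, r2), possibly empty.
#' @slot modulation list of modulation factors vs a reference fit, possibly
#'   empty.
#'
#' @export
setClass("ClassificationImage",
  representation(
    beta       = "matrix",
    intercepts = "matrix",
    folded     = "matrix",
    sf         = "numeric",
    ori        = "numeric",
    oriFolded  = "numeric",
    fit        = "list",
    modulation = "list"
  )
)

setValidity("ClassificationImage", function(object) {
  if (!identical(dim(object@beta), c(length(object@sf), length(object@ori))))
    return("beta grid must be sf x orientation")
  TRUE
})
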