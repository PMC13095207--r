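# Stimulus synthesis: band-limited noise patches and Gabor targets on a
# square raster with a circular aperture, in mean-zero contrast units.

#' Stimulus geometry and target parameters
#'
#' Bundles the geometry of the stimulus patch and the target Gabor. The
#' raster is square with side \code{ceil(patchDiameter * pixelsPerDegree)}
#' pixels; all spatial frequencies are in cycles per degree (cpd).
#'
#' @param patchDiameter patch diameter in degrees of visual angle (3).
#' @param noiseBand lower/upper spatial-frequency band of the noise in cpd
#'   (0.25-4, uniform power inside the band).
#' @param noiseRmsContrast RMS contrast of the noise within the aperture
#'   (0.70).
#' @param targetSf target spatial frequency in cpd (2).
#' @param targetOrientation target orientation in degrees from vertical (0).
#' @param targetContrast target RMS contrast within the aperture (0.15, a
#'   typical titrated level).
#' @param pixelsPerDegree raster resolution (default 48, derived from a
#'   74 cm viewing distance on a 53.4 cm / 1920 px display).
#' @param envelopeSd optional Gaussian envelope SD of the target in degrees;
#'   \code{NULL} (default) windows the target by the aperture only.
#' @return list of class \code{"StimulusSpec"}.
#' @export
stimulusSpec <- function(patchDiameter = 3, noiseBand = c(0.25, 4),
                         noiseRmsContrast = 0.70, targetSf = 2,
                         targetOrientation = 0, targetContrast = 0.15,
                         pixelsPerDegree = 48, envelopeSd = NULL) {
  if (noiseBand[1L] >= noiseBand[2L])
    stop("noiseBand lower edge must be below the upper edge")
  if (noiseRmsContrast < 0 || noiseRmsContrast > 1)
    stop("noiseRmsContrast must be in [0, 1]")
  if (targetContrast <= 0 || targetContrast > 1)
    stop("targetContrast must be in (0, 1]")
  nyquist <- pixelsPerDegree / 2
  if (noiseBand[2L] > nyquist)
    stop("resolution error: noise band exceeds the raster Nyquist limit (",
         nyquist, " cpd)")
  structure(list(
    patchDiameter = patchDiameter, noiseBand = noiseBand,
    noiseRmsContrast = noiseRmsContrast, targetSf = targetSf,
    targetOrientation = targetOrientation, targetContrast = targetContrast,
    pixelsPerDegree = pixelsPerDegree, envelopeSd = envelopeSd
  ), class = "StimulusSpec")
}

# raster coordinate grids in degrees, centred on the patch
rasterGrid <- function(spec) {
  n <- ceiling(spec$patchDiameter * spec$pixelsPerDegree)
  px <- (seq_len(n) - (n + 1) / 2) / spec$pixelsPerDegree
  list(n = n, x = matrix(px, n, n, byrow = TRUE),
       y = matrix(px, n, n, byrow = FALSE))
}

apertureMask <- function(spec, grid = rasterGrid(spec)) {
  sqrt(grid$x^2 + grid$y^2) <= spec$patchDiameter / 2
}

#' Generate a band-limited noise patch
#'
#' Synthesises a noise image whose pre-aperture amplitude spectrum is uniform
#' inside \code{noiseBand} and zero outside (phases random), applies the
#' circular aperture, and rescales so the RMS contrast over aperture pixels
#' equals \code{noiseRmsContrast}. Pixel values are mean-zero contrast units.
#'
#' @param spec a \code{\link{stimulusSpec}}.
#' @param seed integer RNG key for this stimulus (both double-pass
#'   presentations use the same key).
#' @param aperture apply the circular aperture (default TRUE; FALSE exposes
#'   the raw band-limited field, e.g. for spectral checks).
#' @return numeric matrix (patch raster).
#' @export
generateNoisePatch <- function(spec, seed, aperture = TRUE) {
  grid <- rasterGrid(spec)
  n <- grid$n
  if (spec$pixelsPerDegree < 2 * spec$noiseBand[2L])
    stop("resolution error: raster cannot represent the upper band edge")
  withLocalSeed(seed, {
    white <- matrix(stats::rnorm(n * n), n, n)
    W <- stats::fft(white)
    f1 <- spec$pixelsPerDegree * ifelse(0:(n - 1) > n / 2,
                                        0:(n - 1) - n, 0:(n - 1)) / n
    fr <- sqrt(outer(f1^2, f1^2, "+"))
    band <- fr >= spec$noiseBand[1L] & fr <= spec$noiseBand[2L]
    # unit amplitude inside the band, zero outside; phases kept from the
    # white field so the inverse transform stays real
    A <- matrix(0, n, n)
    A[band] <- 1 / Mod(W[band])
    patch <- Re(stats::fft(W * A, inverse = TRUE)) / (n * n)
    mask <- apertureMask(spec, grid)
    if (!aperture) mask <- !logical(length(mask))
    patch[!mask] <- 0
    rms <- sqrt(mean(patch[mask]^2))
    if (spec$noiseRmsContrast == 0 || rms == 0) return(patch * 0)
    patch * (spec$noiseRmsContrast / rms)
  })
}

#' Generate a Gabor target patch
#'
#' A sinusoidal grating at the target spatial frequency and orientation,
#' windowed by the circular aperture (and optionally a Gaussian envelope),
#' scaled so its RMS contrast within the aperture equals
#' \code{targetContrast}. Orientation 0 is vertical: the grating modulates
#' along the horizontal axis only.
#'
#' @param spec a \code{\link{stimulusSpec}}.
#' @param phaseDeg spatial phase of the carrier in degrees.
#' @return numeric matrix (patch raster).
#' @export
generateGabor <- function(spec, phaseDeg = 0) {
  if (spec$targetContrast <= 0) stop("invalid target contrast")
  grid <- rasterGrid(spec)
  th <- spec$targetOrientation * pi / 180
  u <- grid$x * cos(th) - grid$y * sin(th)
  carrier <- cos(2 * pi * spec$targetSf * u + phaseDeg * pi / 180)
  env <- if (is.null(spec$envelopeSd)) 1 else
    exp(-(grid$x^2 + grid$y^2) / (2 * spec$envelopeSd^2))
  patch <- carrier * env
  mask <- apertureMask(spec, grid)
  patch[!mask] <- 0
  rms <- sqrt(mean(patch[mask]^2))
  patch * (spec$targetContrast / rms)
}

#' Render all stimuli of a session design
#'
#' Deterministically regenerates every unique stimulus from its RNG key
#' (noise patch, plus an embedded Gabor with a key-derived random spatial
#' phase on target-present trials) and returns a matrix of vectorised
#' patches aligned with the unique stimuli of the design.
#'
#' @param design trial table from \code{\link{makeSessionDesign}}.
#' @param spec a \code{\link{stimulusSpec}}.
#' @return list with \code{stimuli} (matrix [unique stimulus x pixel]),
#'   \code{stimulusId}, \code{targetPresent}.
#' @export
renderStimuli <- function(design, spec) {
  first <- design[design$pass_index == 1L, , drop = FALSE]
  mats <- lapply(seq_len(nrow(first)), function(i) {
    s <- generateNoisePatch(spec, first$stim_seed[i])
    if (first$target_present[i]) {
      ph <- withLocalSeed(first$stim_seed[i] + 1L, stats::runif(1, 0, 360))
      s <- s + generateGabor(spec, ph)
    }
    as.vector(s)
  })
  list(stimuli = do.call(rbind, mats),
       stimulusId = first$stimulus_id,
       targetPresent = first$target_present)
}
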