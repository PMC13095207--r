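# Quadrature Gabor filter bank and stimulus energy extraction for reverse
# correlation.

#' Build the quadrature Gabor filter bank
#'
#' Constructs sine/cosine quadrature Gabor pairs on a grid of spatial
#' frequencies (15 linear steps, 0.5-4 cpd by default) and orientations (19
#' linear steps, -80 to +80 degrees), centred on the patch. The isotropic
#' Gaussian envelope SD defaults to 0.8 carrier cycles of each filter's SF
#' (about one octave of bandwidth). Each kernel is normalised to unit
#' energy, and within a cell the two kernels are orthogonal.
#'
#' @param spec a \code{\link{stimulusSpec}} (supplies raster geometry).
#' @param nSf,sfRange spatial-frequency grid (default 15 steps in
#'   c(0.5, 4)).
#' @param nOri,oriRange orientation grid in degrees (default 19 steps in
#'   c(-80, 80)).
#' @param envelopeCycles envelope SD in carrier cycles (default 0.8).
#' @return a \code{\link{FilterBank-class}} with \code{nSf * nOri} cells,
#'   cells ordered SF-fastest (as \code{expand.grid(sf, ori)}).
#' @export
buildFilterBank <- function(spec, nSf = 15L, sfRange = c(0.5, 4),
                            nOri = 19L, oriRange = c(-80, 80),
                            envelopeCycles = 0.8) {
  grid <- rasterGrid(spec)
  if (spec$patchDiameter * sfRange[1L] < 1)
    stop("raster too small: the patch must span >= 1 cycle of the lowest SF")
  sf <- seq(sfRange[1L], sfRange[2L], length.out = nSf)
  ori <- seq(oriRange[1L], oriRange[2L], length.out = nOri)
  cells <- expand.grid(sf = sf, ori = ori)
  nPix <- grid$n^2
  gsin <- matrix(0, nPix, nrow(cells))
  gcos <- matrix(0, nPix, nrow(cells))
  r2 <- grid$x^2 + grid$y^2
  for (k in seq_len(nrow(cells))) {
    f <- cells$sf[k]
    th <- cells$ori[k] * pi / 180
    u <- grid$x * cos(th) - grid$y * sin(th)
    sdDeg <- envelopeCycles / f
    env <- exp(-r2 / (2 * sdDeg^2))
    ks <- env * sin(2 * pi * f * u)
    kc <- env * cos(2 * pi * f * u)
    kc <- kc - mean(kc) * env / mean(env)   # DC-balance the even kernel
    gsin[, k] <- ks / sqrt(sum(ks^2))
    gcos[, k] <- kc / sqrt(sum(kc^2))
  }
  methods::new("FilterBank", sf = sf, ori = ori, gsin = gsin, gcos = gcos,
               patchPixels = as.integer(grid$n),
               pixelsPerDegree = spec$pixelsPerDegree)
}

#' Quadrature energy of stimuli under the filter bank
#'
#' For each stimulus S and bank cell, E = sqrt((S . gsin)^2 + (S . gcos)^2):
#' the quadrature energy, invariant to the spatial phase of a matched
#' sinusoid.
#'
#' @param stimuli a single patch matrix, or a matrix [trial x pixel] of
#'   vectorised patches.
#' @param bank a \code{\link{FilterBank-class}} on the same raster.
#' @return matrix [trial x cell] of energies (single-trial input gives one
#'   row), cells ordered as in the bank.
#' @export
stimulusEnergy <- function(stimuli, bank) {
  stopifnot(methods::is(bank, "FilterBank"))
  if (is.matrix(stimuli) && nrow(stimuli) == bank@patchPixels &&
      ncol(stimuli) == bank@patchPixels)
    stimuli <- matrix(as.vector(stimuli), nrow = 1L)
  if (ncol(stimuli) != nrow(bank@gsin))
    stop("raster mismatch between stimuli and filter bank")
  ps <- stimuli %*% bank@gsin
  pc <- stimuli %*% bank@gcos
  sqrt(ps^2 + pc^2)
}
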