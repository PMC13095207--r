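# Energy normalisation, per-cell probit regressions, orientation folding,
# and the optimal/suboptimal trial split.

#' Normalise energy profiles within stimulus condition
#'
#' Z-scores each (SF, orientation) cell across trials separately for
#' target-present and target-absent trials, so the target's own energy does
#' not dominate and all trials can enter one regression.
#'
#' @param energy matrix [trial x cell] of raw energies.
#' @param targetPresent logical per trial.
#' @return matrix of normalised energies (per-cell, per-condition mean 0 and
#'   SD 1).
#' @export
normalizeEnergy <- function(energy, targetPresent) {
  stopifnot(nrow(energy) == length(targetPresent))
  out <- energy
  for (cond in c(TRUE, FALSE)) {
    rows <- which(targetPresent == cond)
    if (length(rows) == 0L) next
    if (length(rows) < 2L) stop("need >= 2 trials per condition")
    m <- colMeans(energy[rows, , drop = FALSE])
    s <- apply(energy[rows, , drop = FALSE], 2L, stats::sd)
    if (any(s == 0)) stop("degenerate stimulus set: zero-SD energy cell")
    out[rows, ] <- sweep(sweep(energy[rows, , drop = FALSE], 2L, m), 2L, s,
                         "/")
  }
  out
}

#' Per-cell probit regressions of response on energy
#'
#' Fits, independently for every (SF, orientation) cell, the probit GLM
#' p(yes) = Phi(b0 + b1 * E) of the detection response on that cell's
#' normalised single-trial energy. The slope grid is the classification
#' image. Cells with perfect separation get their slope capped at +/- 10
#' with a warning.
#'
#' @param energyNorm matrix [trial x cell] of normalised energies (cells
#'   ordered as the bank grid, SF fastest).
#' @param response logical (or 0/1) detection response per trial.
#' @param bank the \code{\link{FilterBank-class}} defining the grid.
#' @param betaCap cap on |slope| for separated cells (default 10).
#' @return a \code{\link{ClassificationImage-class}} with beta and intercept
#'   grids and the orientation-folded grid.
#' @export
probitClassificationImage <- function(energyNorm, response, bank,
                                      betaCap = 10) {
  y <- as.numeric(response)
  if (length(unique(y)) < 2L)
    stop("both response classes must be present")
  nCell <- ncol(energyNorm)
  beta0 <- beta1 <- numeric(nCell)
  capped <- 0L
  fam <- stats::binomial(link = "probit")
  for (k in seq_len(nCell)) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, energyNorm[, k]), y, family = fam,
                     control = list(epsilon = 1e-8, maxit = 100L)))
    b <- fit$coefficients
    if (!all(is.finite(b)) || abs(b[2L]) > betaCap) {
      b[2L] <- sign(if (is.finite(b[2L])) b[2L] else 1) * betaCap
      capped <- capped + 1L
    }
    beta0[k] <- b[1L]
    beta1[k] <- b[2L]
  }
  if (capped > 0L)
    warning(capped, " cell(s) showed (near-)perfect separation; slope capped")
  nSf <- length(bank@sf)
  nOri <- length(bank@ori)
  betaGrid <- matrix(beta1, nSf, nOri)
  folded <- foldOrientations(betaGrid, bank@ori)
  methods::new("ClassificationImage",
    beta = betaGrid, intercepts = matrix(beta0, nSf, nOri),
    folded = folded$grid, sf = bank@sf, ori = bank@ori,
    oriFolded = folded$ori, fit = list(), modulation = list())
}

#' Fold a classification image across orientation sign
#'
#' Averages columns at +theta and -theta (the grid must be symmetric about
#' 0); the 0-degree column is unchanged. Folding is idempotent.
#'
#' @param grid matrix [sf x orientation].
#' @param ori orientation grid in degrees, symmetric about 0.
#' @return list with \code{grid} (matrix [sf x |orientation|]) and
#'   \code{ori} (non-negative orientation magnitudes, ascending).
#' @export
foldOrientations <- function(grid, ori) {
  symmetric <- max(abs(sort(ori) + rev(sort(ori)))) <= 1e-9
  if (!symmetric && min(ori) < 0)
    stop("orientation grid must be symmetric about 0")
  # an all-non-negative grid is already folded; averaging per magnitude is
  # then the identity, which makes folding idempotent
  mags <- sort(unique(round(abs(ori), 9)))
  folded <- vapply(mags, function(m) {
    cols <- which(abs(abs(ori) - m) < 1e-9)
    rowMeans(grid[, cols, drop = FALSE])
  }, numeric(nrow(grid)))
  list(grid = matrix(folded, nrow = nrow(grid)), ori = mags)
}

#' Split trials into optimal- and suboptimal-phase sets
#'
#' Classifies each trial once: per channel, the trial's phase at stimulus
#' onset is compared (within 90 degrees) to that channel's time-averaged
#' resultant angle over the subject window; the trial is optimal when the
#' majority of channels agree, with ties counted as suboptimal.
#'
#' @param phase a \code{PhaseArray}.
#' @param thetaByChannel matrix [channel x time] of resultant angles on the
#'   coupling grid.
#' @param channels channel labels (default those of \code{thetaByChannel}
#'   rownames, else the first rows of the PhaseArray).
#' @param window time window whose angles are circularly averaged (default
#'   c(-0.450, 0)).
#' @param time time axis of \code{thetaByChannel} columns.
#' @return logical per trial, TRUE = optimal.
#' @export
splitTrialsByPhase <- function(phase, thetaByChannel, channels = NULL,
                               window = c(-0.450, 0), time = NULL) {
  stopifnot(methods::is(phase, "PhaseArray"))
  if (is.null(channels)) channels <- rownames(thetaByChannel)
  if (is.null(channels))
    channels <- phase@channels[seq_len(nrow(thetaByChannel))]
  chIdx <- match(channels, phase@channels)
  if (is.null(time)) time <- seq(window[1L], window[2L],
                                 length.out = ncol(thetaByChannel))
  useCol <- time >= window[1L] & time <= window[2L]
  t0 <- which.min(abs(phase@time))
  ph0 <- phase@phase[, chIdx, t0, drop = FALSE][, , 1L, drop = TRUE]
  if (is.null(dim(ph0))) ph0 <- matrix(ph0, ncol = length(chIdx))
  votes <- vapply(seq_along(chIdx), function(j) {
    avgAngle <- circMean(thetaByChannel[j, useCol])
    classifyOptimal(ph0[, j], avgAngle)
  }, logical(nrow(ph0)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  rowSums(votes) > length(chIdx) / 2
}
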