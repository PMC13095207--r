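# Phase-dependent signal-detection observers. Three mechanisms:
#   variance_reduction — internal-noise SD shrinks at the optimal phase, so
#     hits rise while false alarms fall (counterphase HR/FAR);
#   multiplicative_gain — evidence and noise are scaled together by a
#     phase-dependent gain, so hits and false alarms rise together;
#   template — evidence is a Gaussian-weighted readout of stimulus energy
#     whose tuning width broadens away from the optimal phase.

#' Define a phase-dependent observer
#'
#' @param kind one of "variance_reduction", "multiplicative_gain",
#'   "template".
#' @param dPrimeBase baseline sensitivity: separation of the signal and
#'   noise evidence means in units of the baseline noise SD (default 1.5).
#' @param lambda decision threshold on the evidence axis; default midway
#'   between the noise and signal means.
#' @param sigma0 baseline internal-noise SD (default 1).
#' @param modDepth phase-modulation depth m in [0, 1) (default 0.3).
#' @param phiOpt optimal phase in degrees (default 0).
#' @param muNoise mean of the noise evidence distribution (default 1, so a
#'   multiplicative gain raises the false-alarm rate as well as the hit
#'   rate).
#' @param templateCenter (sf cpd, orientation deg) centre of the readout
#'   template (template kind).
#' @param templateSd (sf, orientation) tuning SDs of the template.
#' @param templateSdMod tuning-width broadening factor at the worst phase
#'   (>= 1).
#' @param templateGain scale applied to the template readout before the
#'   decision (template kind; default 1).
#' @param confCutpoints three increasing cutpoints on |evidence - lambda|
#'   that map to confidence levels 1-4.
#' @return list of class \code{"ObserverModel"}.
#' @export
observerModel <- function(kind = c("variance_reduction",
                                   "multiplicative_gain", "template"),
                          dPrimeBase = 1.5, lambda = NULL, sigma0 = 1,
                          modDepth = 0.3, phiOpt = 0, muNoise = 1,
                          templateCenter = c(2, 0), templateSd = c(0.7, 20),
                          templateSdMod = 1.3, templateGain = 1,
                          confCutpoints = c(0.5, 1, 1.5)) {
  kind <- match.arg(kind)
  if (sigma0 <= 0) stop("sigma0 must be positive")
  if (modDepth < 0 || modDepth >= 1) stop("modDepth must lie in [0, 1)")
  if (sigma0 * (1 - modDepth) <= 0) stop("noise SD must stay positive")
  if (any(templateSd <= 0)) stop("template SDs must be positive")
  if (templateSdMod < 1) stop("templateSdMod must be >= 1")
  if (is.null(lambda)) lambda <- muNoise + dPrimeBase * sigma0 / 2
  structure(list(
    kind = kind, dPrimeBase = dPrimeBase, lambda = lambda, sigma0 = sigma0,
    modDepth = modDepth, phiOpt = phiOpt, muNoise = muNoise,
    templateCenter = templateCenter, templateSd = templateSd,
    templateSdMod = templateSdMod, templateGain = templateGain,
    confCutpoints = confCutpoints
  ), class = "ObserverModel")
}

# phase-dependent internal-noise SD: minimal (sigma0 * (1 - m)) at phiOpt
observerSigma <- function(obs, phi) {
  obs$sigma0 * (1 + obs$modDepth * cos((phi - obs$phiOpt - 180) * pi / 180))
}

# phase-dependent gain: maximal (1 + m) at phiOpt
observerGain <- function(obs, phi) {
  1 + obs$modDepth * cos((phi - obs$phiOpt) * pi / 180)
}

#' Simulate observer responses for a trial table
#'
#' Draws single-trial evidence under the observer's mechanism given the
#' alpha phase at stimulus onset, thresholds it at \code{lambda}, and adds
#' response and confidence columns to the trial table.
#'
#' For \code{variance_reduction}, evidence ~ Normal(mu, sigma(phi)^2) with
#' mu = muNoise for noise trials and muNoise + dPrimeBase * sigma0 for
#' target trials, and sigma(phi) minimal at the optimal phase. For
#' \code{multiplicative_gain}, evidence ~ Normal(g(phi) * mu,
#' (g(phi) * sigma0)^2) with g maximal at the optimal phase and a fixed
#' threshold. For \code{template}, evidence is the Gaussian-template-weighted
#' sum of the trial's stimulus energy profile (width broadened away from the
#' optimal phase) plus Normal(0, sigma(phi)) noise.
#'
#' @param table trial table (design columns).
#' @param truePhase alpha phase at stimulus onset per trial, degrees.
#' @param obs an \code{\link{observerModel}}.
#' @param energy matrix [trial x cell] of stimulus energies (template kind
#'   only), cells ordered as \code{expand.grid(sf, ori)} of \code{bank}.
#' @param bank the \code{FilterBank} whose grid indexes \code{energy}
#'   (template kind only).
#' @param seed integer seed.
#' @return the trial table with added \code{response} (logical "yes"),
#'   \code{confidence} (1-4) and \code{evidence} columns.
#' @export
simulateObserver <- function(table, truePhase, obs, energy = NULL,
                             bank = NULL, seed = 1L) {
  n <- nrow(table)
  stopifnot(length(truePhase) == n)
  withLocalSeed(seed, {
    phi <- truePhase
    if (obs$kind == "variance_reduction") {
      mu <- ifelse(table$target_present, obs$muNoise +
                     obs$dPrimeBase * obs$sigma0, obs$muNoise)
      x <- stats::rnorm(n, mu, observerSigma(obs, phi))
    } else if (obs$kind == "multiplicative_gain") {
      mu <- ifelse(table$target_present, obs$muNoise +
                     obs$dPrimeBase * obs$sigma0, obs$muNoise)
      g <- observerGain(obs, phi)
      x <- stats::rnorm(n, g * mu, g * obs$sigma0)
    } else {
      if (is.null(energy) || is.null(bank))
        stop("template observer requires stimulus energies and a filter bank")
      x <- templateEvidence(obs, phi, energy, bank) +
        stats::rnorm(n, 0, observerSigma(obs, phi))
    }
    response <- x > obs$lambda
    confidence <- 1L + rowSums(outer(abs(x - obs$lambda), obs$confCutpoints,
                                     ">"))
    table$response <- response
    table$confidence <- as.integer(confidence)
    table$evidence <- x
    table
  })
}

# Gaussian-template readout of the energy grid; tuning width interpolates
# from templateSd at phiOpt to templateSd * templateSdMod at phiOpt + 180
templateEvidence <- function(obs, phi, energy, bank) {
  grid <- expand.grid(sf = bank@sf, ori = bank@ori)
  broaden <- 1 + (obs$templateSdMod - 1) *
    (1 + cos((phi - obs$phiOpt - 180) * pi / 180)) / 2
  # weights depend on phase through the width, so build per-trial evidence
  # by grouping trials of (numerically) equal broadening when possible
  sapply(seq_along(phi), function(i) {
    w <- exp(-((grid$sf - obs$templateCenter[1L])^2 /
                 (2 * (obs$templateSd[1L] * broaden[i])^2) +
               (grid$ori - obs$templateCenter[2L])^2 /
                 (2 * (obs$templateSd[2L] * broaden[i])^2)))
    obs$templateGain * sum(w * energy[i, ]) / sum(w)
  })
}

#' Closed-form hit and false-alarm rates of a phase-dependent observer
#'
#' Analytic HR(phi) and FAR(phi) of the Gaussian evidence models, the oracle
#' the Monte-Carlo simulations converge to. Under variance reduction the two
#' curves are counterphase (HR maximal and FAR minimal at the optimal
#' phase); under multiplicative gain they share their maximum.
#'
#' @param obs an \code{\link{observerModel}} (not template kind).
#' @param phi phases in degrees.
#' @return data.frame with columns \code{phi}, \code{hr}, \code{far}.
#' @export
observerRates <- function(obs, phi) {
  muS <- obs$muNoise + obs$dPrimeBase * obs$sigma0
  if (obs$kind == "variance_reduction") {
    s <- observerSigma(obs, phi)
    hr <- 1 - stats::pnorm((obs$lambda - muS) / s)
    far <- 1 - stats::pnorm((obs$lambda - obs$muNoise) / s)
  } else if (obs$kind == "multiplicative_gain") {
    g <- observerGain(obs, phi)
    hr <- 1 - stats::pnorm((obs$lambda - g * muS) / (g * obs$sigma0))
    far <- 1 - stats::pnorm((obs$lambda - g * obs$muNoise) / (g * obs$sigma0))
  } else stop("no closed form for the template observer")
  data.frame(phi = phi, hr = hr, far = far)
}
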