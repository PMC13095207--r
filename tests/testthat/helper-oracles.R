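# Shared fixtures and independent oracles used across tests.

# absolute circular distance in degrees
circDist <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# brute-force resultant of 8 bin values (independent of the package path)
bruteResultant <- function(values, centers = seq(0, 315, by = 45)) {
  cx <- sum(values * cos(centers * pi / 180))
  sy <- sum(values * sin(centers * pi / 180))
  list(rho = sqrt(cx^2 + sy^2), theta = (atan2(sy, cx) * 180 / pi) %% 360)
}

# a small session + uniform onset phases + observer responses, shared by
# coupling/doublepass tests
makeCohortTrials <- function(nBlocks = 6, kind = "variance_reduction",
                             modDepth = 0.3, phiOpt = 90, seed = 1) {
  design <- makeSessionDesign(nBlocks = nBlocks, trialsPerBlock = 140,
                              uniqueStimuli = 70, seed = seed)
  phi <- withr::with_seed(seed + 1000, runif(nrow(design), 0, 360))
  obs <- observerModel(kind, modDepth = modDepth, phiOpt = phiOpt)
  trials <- simulateObserver(design, phi, obs, seed = seed + 2000)
  list(trials = trials, phi = phi, obs = obs)
}

# low-resolution stimulus spec for raster-heavy tests (defaults stay at the
# display-derived 48 px/deg; tests use a coarser raster for speed)
testSpec <- function(...) stimulusSpec(pixelsPerDegree = 16, ...)
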