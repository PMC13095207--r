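# Phase-estimation chain: preprocessing, IAF, taper, filter-Hilbert,
# binning, channel selection.

makeEpochs <- function(dat, fs = 500, t0 = -2) {
  nS <- dim(dat)[3]
  methods::new("EpochedSeries", voltages = dat,
               time = t0 + (seq_len(nS) - 1) / fs,
               channels = paste0("ch", seq_len(dim(dat)[2])), fs = fs)
}

test_that("preprocessing rejects spikes and average-references the rest", {
  tm <- seq(-2, 2, by = 1 / 500)
  dat <- array(0, c(3, 4, length(tm)))
  dat[1, , ] <- 1                                   # clean trial
  dat[2, 2, which.min(abs(tm + 0.3))] <- 200        # spike inside the window
  dat[3, 3, which.min(abs(tm - 1.5))] <- 400        # spike outside the window
  pp <- preprocessEpochs(makeEpochs(dat), highpass = 0)
  expect_equal(pp$kept, c(1L, 3L))
  # per-sample channel mean is zero after average reference
  mm <- apply(voltages(pp$epochs), c(1, 3), mean)
  expect_lt(max(abs(mm)), 1e-9)
  # all-zero input survives untouched
  z <- preprocessEpochs(makeEpochs(array(0, c(2, 3, length(tm)))),
                        highpass = 0)
  expect_equal(z$kept, c(1L, 2L))
  expect_true(all(voltages(z$epochs) == 0))
  expect_error(preprocessEpochs(makeEpochs(array(500, c(2, 2, length(tm)))),
                                highpass = 0), "all trials rejected")
})

test_that("IAF lands on the spectral peak within one padded-FFT bin", {
  tm <- seq(-2, 2, by = 1 / 500)
  mk <- function(f) {
    osc <- cos(2 * pi * f * tm)
    dat <- array(rep(osc, each = 12), c(4, 6, length(tm)))[, , , drop = FALSE]
    dat <- aperm(array(osc, c(length(tm), 4, 6)), c(2, 3, 1))
    methods::new("EpochedSeries", voltages = dat, time = tm,
                 channels = c("P1", "Pz", "P2", "PO3", "POz", "PO4"),
                 fs = 500)
  }
  binWidth <- 500 / (5 * sum(tm >= -0.5 & tm <= 0))
  expect_lt(abs(estimateIAF(mk(10))$iaf - 10), binWidth + 1e-9)
  expect_lt(abs(estimateIAF(mk(11.2))$iaf - 11.2), binWidth + 1e-9)
  # white noise has no discernable alpha peak
  noise <- withr::with_seed(1, array(rnorm(60 * 6 * length(tm)),
                                     c(60, 6, length(tm))))
  wn <- methods::new("EpochedSeries", voltages = noise, time = tm,
                     channels = c("P1", "Pz", "P2", "PO3", "POz", "PO4"),
                     fs = 500)
  expect_error(estimateIAF(wn), "no alpha peak")
})

test_that("the post-stimulus taper has the exact piecewise-linear gain", {
  tm <- seq(-2, 2, by = 1 / 500)
  dat <- array(1, c(1, 1, length(tm)))
  tp <- applyPoststimTaper(makeEpochs(dat))
  g <- voltages(tp)[1, 1, ]
  expect_equal(g[which.min(abs(tm - 0.050))], 0.5)
  expect_equal(g[which.min(abs(tm + 0.100))], 1)
  expect_equal(g[which.min(abs(tm - 0.100))], 0)
  expect_true(all(g[tm <= 0.030] == 1))
  expect_true(all(g[tm >= 0.070] == 0))
  ramp <- tm > 0.030 & tm < 0.070
  expect_equal(g[ramp], (0.070 - tm[ramp]) / 0.040)
})

test_that("filter-Hilbert recovers phase with the cosine convention", {
  tm <- seq(-2, 2, by = 1 / 500)
  x <- cos(2 * pi * 10 * tm)
  dat <- array(x, c(1, 1, length(tm)))
  pa <- bandpassPhase(makeEpochs(dat), iaf = 10)
  tOut <- timePoints(pa)
  interior <- tOut > -1.5 & tOut < 1.5
  # peaks of the cosine are multiples of 0.1 s and lie on the 150 Hz grid;
  # phase there must be ~0
  peaks <- tOut[interior][abs(tOut[interior] %% 0.1) < 1e-9]
  for (tp in peaks[1:5]) {
    ph <- phaseAngles(pa)[1, 1, which.min(abs(tOut - tp))]
    expect_lt(circDist(ph, 0), 1)
  }
  # troughs fall between grid samples; compare each sample nearest a trough
  # against the analytic phase at that sample's own time
  for (tp in peaks[1:5] + 0.05) {
    i <- which.min(abs(tOut - tp))
    expected <- (360 * 10 * tOut[i]) %% 360
    expect_lt(circDist(expected, 180), 13)  # nearest sample is near a trough
    expect_lt(circDist(phaseAngles(pa)[1, 1, i], expected), 1)
  }
})

test_that("the FIR chain is zero-phase and rejects DC", {
  tm <- seq(-2, 2, by = 1 / 500)
  x <- cos(2 * pi * 10 * tm)
  kern <- alphaSDT:::firBandpassKernel(500, c(8, 12), 1)
  y <- alphaSDT:::firFilterCentred(x, kern)
  mid <- tm > -1 & tm < 1
  # group delay <= 1 sample: cross-correlation peak at zero lag
  cc <- sapply(-2:2, function(l) sum(x[which(mid)] * y[which(mid) + l]))
  expect_true(which.max(cc) %in% c(2, 3, 4))
  expect_equal(cor(x[mid], y[mid]), 1, tolerance = 1e-5)
  # DC input leaves (near-)zero in-band envelope (stop-band rejection)
  dc <- array(1, c(1, 1, length(tm)))
  pa <- bandpassPhase(makeEpochs(dc), iaf = 10)
  tOut <- timePoints(pa)
  expect_lt(max(envelope(pa)[1, 1, tOut > -1 & tOut < 1]), 0.01)
})

test_that("pipeline phase at stimulus onset matches ground truth", {
  d <- makeSessionDesign(nBlocks = 1, trialsPerBlock = 40,
                         uniqueStimuli = 20, seed = 2)
  m <- alphaEEGModel(iaf = 10.3, alphaAmp = 5, pinkNoiseAmp = 0)
  sim <- simulateAlphaEEG(d, m, seed = 3)
  pa <- bandpassPhase(applyPoststimTaper(sim$epochs), iaf = 10.3)
  i0 <- which.min(abs(timePoints(pa)))
  oz <- match("Oz", channelLabels(pa))
  err <- circDist(phaseAngles(pa)[, oz, i0], sim$truePhase)
  expect_lt(sqrt(mean(err^2)), 2)
  # with realistic noise (SNR >= 10) circular correlation stays >= 0.99
  m2 <- alphaEEGModel(iaf = 10.3, alphaAmp = 10, pinkNoiseAmp = 1)
  sim2 <- simulateAlphaEEG(d, m2, seed = 4)
  pa2 <- bandpassPhase(applyPoststimTaper(sim2$epochs), iaf = 10.3)
  est <- phaseAngles(pa2)[, oz, which.min(abs(timePoints(pa2)))]
  rad <- function(x) x * pi / 180
  num <- sum(sin(rad(est) - mean(rad(est))) *
               sin(rad(sim2$truePhase) - mean(rad(sim2$truePhase))))
  # circular correlation (Fisher-Lee)
  ccor <- sum(sin(rad(est) - Arg(mean(exp(1i * rad(est))))) *
                sin(rad(sim2$truePhase) -
                      Arg(mean(exp(1i * rad(sim2$truePhase)))))) /
    sqrt(sum(sin(rad(est) - Arg(mean(exp(1i * rad(est)))))^2) *
           sum(sin(rad(sim2$truePhase) -
                     Arg(mean(exp(1i * rad(sim2$truePhase)))))^2))
  expect_gt(ccor, 0.99)
})

test_that("phase bins partition the circle with the boundary convention", {
  expect_equal(binPhase(10), 1L)
  expect_equal(binPhase(350), 1L)
  expect_equal(binPhase(22.5), 2L)       # lower-inclusive boundary
  expect_equal(binPhase(337.5), 1L)
  expect_equal(binPhase(337.4999), 8L)
  ang <- withr::with_seed(5, runif(80000, 0, 360))
  b <- binPhase(ang)
  expect_true(all(b %in% 1:8))
  occ <- tabulate(b, 8) / length(ang)
  expect_true(all(abs(occ - 1 / 8) < 4 * sqrt(0.125 * 0.875 / length(ang))))
  # every angle maps to the bin whose centre is nearest
  expect_true(all(circDist(ang, phaseBinCenters()[b]) <= 22.5))
})

test_that("alpha-power channel selection ranks by band power", {
  d <- makeSessionDesign(nBlocks = 1, trialsPerBlock = 10,
                         uniqueStimuli = 5, seed = 6)
  topo <- stats::setNames(rep(0, 18), c(posteriorChannels(), "AFz"))
  topo[c("O1", "Oz", "O2")] <- 1
  m <- alphaEEGModel(alphaAmp = 5, pinkNoiseAmp = 0.5, topography = topo)
  sim <- simulateAlphaEEG(d, m, seed = 7)
  expect_setequal(selectAlphaChannels(sim$epochs, iaf = 10),
                  c("O1", "Oz", "O2"))
  # identical channels tie-break to candidate-list order
  tm <- seq(-2, 2, by = 1 / 500)
  same <- array(rep(cos(2 * pi * 10 * tm), each = 2 * 17),
                c(2, 17, length(tm)))
  same <- aperm(array(cos(2 * pi * 10 * tm), c(length(tm), 2, 17)),
                c(2, 3, 1))
  ep <- methods::new("EpochedSeries", voltages = same, time = tm,
                     channels = posteriorChannels(), fs = 500)
  expect_equal(selectAlphaChannels(ep, iaf = 10), c("Pz", "P3", "P7"))
  # ranking is invariant to candidate order when powers are distinct
  sel1 <- selectAlphaChannels(sim$epochs, 10)
  sel2 <- selectAlphaChannels(sim$epochs, 10, candidates =
                                rev(posteriorChannels()))
  expect_setequal(sel1, sel2)
  expect_error(selectAlphaChannels(sim$epochs, 10, k = 20), "exceeds")
})
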