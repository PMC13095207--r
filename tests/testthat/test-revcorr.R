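# Reverse correlation: filter bank, energy, probit CIs, Gaussian fits,
# modulation factors, bootstrap, difference CI, phase splitting.

bankFixture <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- buildFilterBank(testSpec())
    bank
  }
})

test_that("the filter bank has the stated grid and quadrature structure", {
  bank <- bankFixture()
  expect_equal(length(bank@sf) * length(bank@ori), 285L)
  expect_equal(range(bank@sf), c(0.5, 4))
  expect_equal(range(bank@ori), c(-80, 80))
  # quadrature orthogonality within every cell
  expect_lt(max(abs(colSums(bank@gsin * bank@gcos))), 1e-3)
  # unit energy
  expect_equal(colSums(bank@gsin^2), rep(1, 285))
  expect_equal(colSums(bank@gcos^2), rep(1, 285))
  expect_error(buildFilterBank(stimulusSpec(patchDiameter = 1,
                                            pixelsPerDegree = 16),
                               sfRange = c(0.1, 4)), "raster too small")
})

test_that("quadrature energy is phase-invariant and maximal for a match", {
  bank <- bankFixture()
  spec <- testSpec()
  expect_equal(max(stimulusEnergy(matrix(0, bank@patchPixels,
                                         bank@patchPixels), bank)), 0)
  cell <- which(abs(rep(bank@sf, length(bank@ori)) - 2) < 1e-9 &
                  rep(bank@ori, each = length(bank@sf)) == 0)
  s <- matrix(bank@gsin[, cell], bank@patchPixels)
  E <- stimulusEnergy(s, bank)
  expect_equal(E[cell], 1, tolerance = 1e-9)
  expect_equal(which.max(E), cell)
  # energy at (2 cpd, 0 deg) invariant to the grating's spatial phase
  es <- vapply(seq(0, 330, by = 30), function(p)
    stimulusEnergy(generateGabor(spec, p), bank)[cell], numeric(1))
  expect_lt((max(es) - min(es)) / mean(es), 0.02)
  expect_error(stimulusEnergy(matrix(0, 5, 5), bank), "raster mismatch")
})

test_that("energy normalisation z-scores within condition", {
  raw <- withr::with_seed(1, matrix(rexp(200 * 10), 200, 10))
  present <- rep(c(TRUE, FALSE), 100)
  En <- normalizeEnergy(raw, present)
  for (cond in c(TRUE, FALSE)) {
    sub <- En[present == cond, ]
    expect_lt(max(abs(colMeans(sub))), 1e-9)
    expect_lt(max(abs(apply(sub, 2, sd) - 1)), 1e-9)
  }
  # affine invariance of the raw scale
  expect_equal(normalizeEnergy(raw * 2, present), En)
  expect_error(normalizeEnergy(cbind(raw, 1), present), "zero-SD")
})

test_that("probit regressions recover planted slopes and stay null-calibrated", {
  bank3 <- buildFilterBank(testSpec(), nSf = 3, sfRange = c(1, 3),
                           nOri = 1, oriRange = c(0, 0))
  E <- withr::with_seed(2, matrix(rnorm(10000 * 3), 10000, 3))
  y <- withr::with_seed(3, runif(10000)) < pnorm(0.2 + 0.5 * E[, 2])
  ci <- probitClassificationImage(E, y, bank3)
  expect_equal(betaGrid(ci)[2, 1], 0.5, tolerance = 0.05 / 0.5)
  expect_lt(abs(betaGrid(ci)[1, 1]), 0.05)
  expect_lt(abs(betaGrid(ci)[3, 1]), 0.05)
  # shuffled responses: slopes concentrate near zero
  ysh <- withr::with_seed(4, sample(y))
  ci0 <- probitClassificationImage(E, ysh, bank3)
  expect_lt(mean(abs(betaGrid(ci0))), 0.05)
})

test_that("a template observer's classification image peaks on its template", {
  spec <- testSpec()
  bank <- bankFixture()
  d <- makeSessionDesign(nBlocks = 20, seed = 21)
  rs <- renderStimuli(d, spec)
  E <- stimulusEnergy(rs$stimuli, bank)[match(d$stimulus_id,
                                              rs$stimulusId), ]
  phi <- withr::with_seed(22, runif(nrow(d), 0, 360))
  obs <- observerModel("template", modDepth = 0, phiOpt = 90,
                       templateSd = c(0.4, 12), lambda = 0)
  ev <- alphaSDT:::templateEvidence(obs, phi, E, bank)
  obs$lambda <- median(ev) + 0.4 * sd(ev)
  obs$sigma0 <- sd(ev) * 0.4
  tr <- simulateObserver(d, phi, obs, energy = E, bank = bank, seed = 23)
  En <- normalizeEnergy(E, d$target_present)
  ci <- probitClassificationImage(En, tr$response, bank)
  fg <- foldedGrid(ci)
  am <- arrayInd(which.max(fg), dim(fg))
  expect_equal(ci@sf[am[1]], 2)
  expect_equal(ci@oriFolded[am[2]], 0)
})

test_that("orientation folding is symmetric-correct and idempotent", {
  ori <- seq(-80, 80, length.out = 19)
  sym <- outer(1:15, abs(ori), "+")
  fs <- foldOrientations(sym, ori)
  expect_equal(fs$grid, sym[, 10:19])
  expect_equal(fs$ori, abs(ori)[10:19])
  anti <- outer(rep(1, 15), sign(ori))
  fa <- foldOrientations(anti, ori)
  expect_true(all(abs(fa$grid[, -1]) < 1e-12))
  rnd <- withr::with_seed(5, matrix(rnorm(15 * 19), 15, 19))
  once <- foldOrientations(rnd, ori)
  twice <- foldOrientations(once$grid, once$ori)
  expect_equal(twice$grid, once$grid)
  expect_error(foldOrientations(rnd, ori + 1), "symmetric")
})

test_that("the 2-D Gaussian fit is exact on noiseless surfaces", {
  sf <- seq(0.5, 4, length.out = 15)
  ori <- seq(0, 80, length.out = 10)
  x <- matrix(sf, 15, 10); y <- matrix(ori, 15, 10, byrow = TRUE)
  p <- c(0.4, 2, 0.7, 0, 20, 0.05)
  g <- matrix(alphaSDT:::gauss2dPredict(p, x, y), 15)
  fit <- fitGauss2d(g, sf, ori)
  expect_equal(unlist(fit[paste0("p", 1:6)]), p, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  flat <- fitGauss2d(matrix(0.3, 15, 10), sf, ori)
  expect_lt(abs(flat$p1), 0.01)
  expect_equal(flat$p6 + flat$p1 * 0, 0.3, tolerance = 0.02)
})

test_that("Gaussian widths survive 10 percent noise within 15 percent", {
  sf <- seq(0.5, 4, length.out = 15)
  ori <- seq(0, 80, length.out = 10)
  x <- matrix(sf, 15, 10); y <- matrix(ori, 15, 10, byrow = TRUE)
  p <- c(0.4, 2, 0.7, 0, 20, 0.05)
  clean <- alphaSDT:::gauss2dPredict(p, x, y)
  errs <- withr::with_seed(6, vapply(1:30, function(i) {
    g <- matrix(clean + rnorm(150, 0, 0.1 * p[1]), 15)
    f <- fitGauss2d(g, sf, ori, seed = i)
    max(abs(f$p3 - p[3]) / p[3], abs(f$p5 - p[5]) / p[5])
  }, numeric(1)))
  expect_lt(median(errs), 0.15)
})

test_that("modulation factors recover planted gain and width changes", {
  sf <- seq(0.5, 4, length.out = 15)
  ori <- seq(0, 80, length.out = 10)
  x <- matrix(sf, 15, 10); y <- matrix(ori, 15, 10, byrow = TRUE)
  p <- c(0.4, 2, 0.7, 0, 20, 0.05)
  ref <- fitGauss2d(matrix(alphaSDT:::gauss2dPredict(p, x, y), 15), sf, ori)
  # identical grid -> all factors 1
  same <- fitModulation(ref, matrix(alphaSDT:::gauss2dPredict(p, x, y), 15),
                        sf, ori)
  expect_equal(same$gainMod, 1, tolerance = 1e-3)
  expect_equal(same$sdMod, 1, tolerance = 1e-3)
  expect_equal(same$offsetMod, 1, tolerance = 1e-3)
  # widths scaled by 1.3
  wide <- matrix(alphaSDT:::gauss2dPredict(
    c(0.4, 2, 0.7 * 1.3, 0, 20 * 1.3, 0.05), x, y), 15)
  mw <- fitModulation(ref, wide, sf, ori)
  expect_equal(mw$sdMod, 1.3, tolerance = 0.1 / 1.3)
  expect_equal(mw$gainMod, 1, tolerance = 0.05)
  # gain scaled by 0.7
  dim7 <- matrix(alphaSDT:::gauss2dPredict(c(0.4 * 0.7, 2, 0.7, 0, 20, 0.05),
                                           x, y), 15)
  mg <- fitModulation(ref, dim7, sf, ori)
  expect_equal(mg$gainMod, 0.7, tolerance = 0.1 / 0.7)
  expect_equal(mg$sdMod, 1, tolerance = 0.05)
})

test_that("bootstrap modulation is centred and deterministic for null data", {
  sf <- seq(0.5, 4, length.out = 15)
  ori <- seq(0, 80, length.out = 10)
  x <- matrix(sf, 15, 10); y <- matrix(ori, 15, 10, byrow = TRUE)
  p <- c(0.4, 2, 0.7, 0, 20, 0.05)
  grids <- withr::with_seed(7, lapply(1:5, function(s)
    matrix(alphaSDT:::gauss2dPredict(p, x, y) + rnorm(150, 0, 0.02), 15)))
  bm <- bootstrapModulation(grids, grids, sf, ori, nBoot = 60, seed = 8)
  expect_equal(unname(bm$estimates["sdMod"]), 1, tolerance = 0.02)
  expect_gt(bm$p["sdMod"], 0.5)
  bm2 <- bootstrapModulation(grids, grids, sf, ori, nBoot = 60, seed = 8)
  expect_identical(bm$factors, bm2$factors)
  # identical conditions -> difference CI flat with p ~ 1
  dc <- differenceCI(bm$bootOptimal, bm$bootSuboptimal, sf, ori)
  expect_true(all(abs(dc$meanDiff) < 1e-12))
  expect_true(all(dc$p == 1))
})

test_that("difference CI carries the suboptimal-minus-optimal sign", {
  boA <- matrix(1, 50, 4)
  boB <- matrix(2, 50, 4)
  dc <- differenceCI(boA, boB, sf = c(1, 2), ori = c(0, 40))
  expect_true(all(dc$meanDiff == 1))      # suboptimal exceeds optimal
  expect_equal(dc$multipleComparisons, "uncorrected")
})

test_that("phase splitting follows the majority rule with ties suboptimal", {
  n <- 6
  tGrid <- seq(-0.45, 0, by = 1 / 150)
  nT <- length(tGrid)
  ph <- array(0, c(n, 3, nT))
  # trials 1-2: all channels at the optimal angle; 3-4: 2 of 3; 5: 1 of 3;
  # 6: exactly-90-degree boundary on every channel
  ph[1, , ] <- 90; ph[2, , ] <- 100
  ph[3, 1:2, ] <- 90; ph[3, 3, ] <- 270
  ph[4, 1:2, ] <- 120; ph[4, 3, ] <- 300
  ph[5, 1, ] <- 90; ph[5, 2:3, ] <- 270
  ph[6, , ] <- 180
  pa <- methods::new("PhaseArray", phase = ph, amplitude = array(1, dim(ph)),
                     time = tGrid, channels = c("Oz", "O1", "O2"),
                     fsOut = 150, iaf = 10, band = c(8, 12))
  theta <- matrix(90, 3, nT)
  opt <- splitTrialsByPhase(pa, theta, channels = c("Oz", "O1", "O2"),
                            time = tGrid)
  expect_equal(opt, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("optimal-phase trials show higher sensitivity under variance reduction", {
  d <- makeSessionDesign(nBlocks = 10, seed = 30)
  n <- nrow(d)
  phi <- withr::with_seed(31, runif(n, 0, 360))
  tr <- simulateObserver(d, phi, observerModel(modDepth = 0.3, phiOpt = 90),
                         seed = 32)
  tGrid <- seq(-0.45, 0, by = 1 / 150)
  pa <- methods::new("PhaseArray",
                     phase = array(propagatePhase(phi, 10, tGrid),
                                   c(n, 1, length(tGrid))),
                     amplitude = array(1, c(n, 1, length(tGrid))),
                     time = tGrid, channels = "Oz", fsOut = 150, iaf = 10,
                     band = c(8, 12))
  opt <- splitTrialsByPhase(pa, matrix(90, 1, length(tGrid)),
                            channels = "Oz", time = tGrid)
  dOpt <- sdtFromTrials(tr[opt, ])
  dSub <- sdtFromTrials(tr[!opt, ])
  expect_gt(dOpt$dprime, dSub$dprime)
  # criterion-stable observer: yes-rates stay close across the split
  expect_lt(abs(mean(tr$response[opt]) - mean(tr$response[!opt])), 0.05)
})
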