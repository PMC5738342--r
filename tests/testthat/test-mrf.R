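# MRF segmentation: unary features, clique construction, energy,
# Gibbs-marginal segmentation and binarisation.

test_that("unary features: flat frames, foreground structures, invariances", {
  # constant frame carries no evidence anywhere
  expect_equal(extractUnaryFeatures(matrix(5, 9, 9), radius = 2),
               matrix(0, 9, 9))

  # bright ring on dark disk scores above the far-field background
  fr <- makeRingDiskFrame()
  sc <- extractUnaryFeatures(fr, radius = 4)
  yy <- matrix(0:30, 31, 31); xx <- t(yy)
  d <- sqrt((xx - 15)^2 + (yy - 15)^2)
  inside <- d <= 7   # disk + ring
  far <- d > 12
  expect_gt(mean(sc[inside]), mean(sc[far]))
  # the body and ring proper (away from the smoothed transition) beat
  # every far-field pixel
  core <- d <= 3 | (d > 5.5 & d <= 6.5)
  expect_gt(min(sc[core]), max(sc[far]))

  # intensity rescaling leaves the variance-normalised score unchanged
  expect_equal(extractUnaryFeatures(fr * 7.3, radius = 4), sc,
               tolerance = 1e-10)

  # translation equivariance: shifting the frame shifts the score map
  fr2 <- makeRingDiskFrame(cx = 17, cy = 15)
  sc2 <- extractUnaryFeatures(fr2, radius = 4)
  expect_equal(sc2[, 6:29], sc[, 4:27], tolerance = 1e-10)

  expect_error(extractUnaryFeatures(matrix(1, 5, 5), radius = 3),
               class = "invalidInput")
})

test_that("clique construction: extreme counts, partition properties, texture purity", {
  fr <- matrix(runif(64), 8, 8)
  expect_equal(buildCliques(fr, 64), matrix(1:64, 8, 8))
  expect_equal(buildCliques(fr, 1), matrix(1L, 8, 8))
  expect_error(buildCliques(fr, 0), class = "invalidInput")

  # partition: disjoint cover with spatially connected cliques
  set.seed(3)
  fr <- matrix(runif(24 * 20), 24, 20)
  cl <- buildCliques(fr, 6)
  expect_true(all(cl >= 1))
  for (ci in unique(as.vector(cl))) {
    lab <- oracleFloodLabel(cl == ci)
    # oracle is 8-connected; re-check 4-connectivity directly
    sel <- cl == ci
    lab4 <- PhaseTrack:::labelComponents(sel, 4L)
    expect_equal(max(lab4), 1L)
  }

  # two-texture frame splits cleanly at nCliques = 2
  set.seed(4)
  two <- cbind(matrix(rnorm(32, 20, 3), 8, 4), matrix(rnorm(32, 80, 3), 8, 4))
  cl2 <- buildCliques(two, 2)
  for (ci in 1:2) {
    cols <- col(two)[cl2 == ci]
    frac <- max(mean(cols <= 4), mean(cols >= 5))
    expect_gte(frac, 0.9)
  }
})

test_that("energy matches its definition term by term", {
  params <- MrfParams(unaryScale = 0, beta = 0.7, gammaMax = 0,
                      featureRadius = 1)
  fr <- matrix(runif(25), 5, 5)
  cl <- buildCliques(fr, 2)
  expect_equal(mrfEnergy(matrix(1, 5, 5), fr, cl, params), 0)
  expect_equal(mrfEnergy(matrix(0, 5, 5), fr, cl, params), 0)

  # single clique, one minority pixel: truncated-linear formula
  params2 <- MrfParams(unaryScale = 0, beta = 0, gammaMax = 1.4,
                       truncationQ = 0.25, featureRadius = 1)
  lab <- matrix(1, 4, 4); lab[2, 3] <- 0
  cl1 <- matrix(1L, 4, 4)
  expect_equal(mrfEnergy(lab, matrix(0, 4, 4), cl1, params2,
                         unary = list(u0 = matrix(0, 4, 4),
                                      u1 = matrix(0, 4, 4))),
               min(1.4, 1.4 * 1 / (0.25 * 16)))

  # random labellings against a literal re-summation oracle
  set.seed(11)
  for (rep in 1:5) {
    fr <- matrix(runif(9, 0, 50), 3, 3)
    params3 <- MrfParams(unaryScale = runif(1, 0, 2), beta = runif(1),
                         gammaMax = runif(1), truncationQ = 0.3,
                         featureRadius = 1)
    cl3 <- buildCliques(fr, 2)
    unary <- PhaseTrack:::featureUnaries(extractUnaryFeatures(fr, 1))
    lab <- matrix(rbinom(9, 1, 0.5), 3, 3)
    expect_equal(mrfEnergy(lab, fr, cl3, params3, unary = unary),
                 oracleEnergyNaive(lab, unary, cl3, params3),
                 tolerance = 1e-12)
  }
  expect_error(mrfEnergy(matrix(1, 2, 2), matrix(0, 3, 3),
                         matrix(1L, 3, 3), params),
               class = "invalidInput")
})

test_that("segmentation: symmetry, factorised limit, marginal accuracy, determinism", {
  # constant frame: by label-flip symmetry every exact marginal is 0.5, so
  # the map is spatially constant up to sampling tolerance
  pm <- pixelData(segmentFrame(matrix(3, 8, 8),
                               MrfParams(featureRadius = 1),
                               nSweeps = 30000L, burnIn = 3000L))
  expect_lt(max(abs(pm - 0.5)), 0.05)

  # beta = gammaMax = 0 factorises to the per-pixel logistic exactly
  set.seed(5)
  fr <- matrix(runif(64, 0, 80), 8, 8)
  params <- MrfParams(unaryScale = 0.8, beta = 0, gammaMax = 0,
                      temperature = 1.3, featureRadius = 1)
  feat <- extractUnaryFeatures(fr, 1)
  un <- PhaseTrack:::featureUnaries(feat)
  closed <- 1 / (1 + exp(0.8 * (un$u1 - un$u0) / 1.3))
  expect_equal(pixelData(segmentFrame(fr, params)), closed,
               tolerance = 1e-10)

  # approximate marginals track the exhaustive enumeration oracle
  set.seed(6)
  for (rep in 1:4) {
    fr <- matrix(runif(16, 0, 100), 4, 4)
    params <- MrfParams(unaryScale = runif(1), beta = runif(1),
                        gammaMax = runif(1), truncationQ = 0.3,
                        nCliques = 2, featureRadius = 1)
    cl <- buildCliques(fr, 2)
    un <- PhaseTrack:::featureUnaries(extractUnaryFeatures(fr, 1))
    ex <- oracleEnumMarginals(fr, cl, params, un)
    ap <- pixelData(segmentFrame(fr, params, cliques = cl,
                                 nSweeps = 30000L, burnIn = 3000L))
    expect_lt(max(abs(ex - ap)), 0.05)
    expect_true(all(ap >= 0 & ap <= 1))
  }

  # identical inputs give bit-identical output
  fr <- matrix(runif(64, 0, 100), 8, 8)
  p1 <- pixelData(segmentFrame(fr, MrfParams(featureRadius = 1, nCliques = 2)))
  p2 <- pixelData(segmentFrame(fr, MrfParams(featureRadius = 1, nCliques = 2)))
  expect_identical(p1, p2)
})

test_that("binarisation conventions", {
  m <- matrix(0.5, 3, 3)
  expect_true(all(binarizeMap(m, 0.5)))
  ramp <- matrix(seq(0, 1, length.out = 9), 3, 3)
  expect_equal(binarizeMap(ramp, 0.7), ramp >= 0.7)
  # idempotence under re-thresholding the mask-as-probabilities
  mk <- binarizeMap(ramp, 0.4)
  expect_equal(binarizeMap(mk + 0, 0.5), mk)
  expect_error(binarizeMap(m, 0), class = "invalidInput")
  expect_error(binarizeMap(m, 1), class = "invalidInput")
})
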