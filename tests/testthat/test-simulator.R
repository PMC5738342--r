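# Synthetic monolayer: kinematics, non-overlap, rendering and the
# junction-fluorescence budget.

test_that("kinematics: noise-free linearity, elongation, reproducibility", {
  # single cell, no acceleration noise, no shape drift: exactly linear
  cfg <- SimConfig(nCells = 1, fieldSize = c(128, 128), nFrames = 10,
                   sigmaAcc = 0, sigmaShapeSim = 0, elongatingFraction = 0,
                   seed = 2)
  tt <- trackTable(simulateTracks(cfg))
  dx <- diff(tt$cx); dy <- diff(tt$cy)
  expect_lt(max(abs(dx - dx[1])), 1e-9)
  expect_lt(max(abs(dy - dy[1])), 1e-9)

  # elongating cells grow the major axis and conserve pi*a*b to 1%
  cfgE <- SimConfig(nCells = 8, fieldSize = c(256, 256), nFrames = 21,
                    elongatingFraction = 0.5, seed = 3)
  gtE <- simulateTracks(cfgE)
  el <- names(which(gtE@elongating))
  expect_gt(length(el), 0)
  ttE <- trackTable(gtE)
  for (id in as.integer(el)) {
    tr <- ttE[ttE$cell_id == id, ]
    areas <- pi * tr$a * tr$b
    expect_lt(max(abs(areas - areas[1])) / areas[1], 0.01)
    expect_gt(tr$a[21] / tr$a[1], cfgE@elongationRate^20 * 0.99)
  }

  gt1 <- simulateTracks(cfgE)
  expect_identical(trackTable(gt1), ttE)

  expect_error(simulateTracks(SimConfig(coverage = 0.9)),
               class = "configurationError")
})

test_that("ground-truth ellipses never overlap beyond 2% of the smaller area", {
  cfg <- SimConfig(nCells = 12, fieldSize = c(256, 256), nFrames = 12,
                   elongatingFraction = 0.4, seed = 5)
  tt <- trackTable(simulateTracks(cfg))
  for (f in c(0, 5, 11)) {
    tf <- tt[tt$frame == f, ]
    for (i in seq_len(nrow(tf) - 1)) for (j in (i + 1):nrow(tf)) {
      ov <- PhaseTrack:::ellipseOverlapArea(tf[i, ], tf[j, ])
      if (ov > 0) {
        smaller <- pi * min(tf$a[i] * tf$b[i], tf$a[j] * tf$b[j])
        expect_lte(ov / smaller, 0.02)
      }
    }
  }
})

test_that("phase-contrast render: halo/body contrast and noise statistics", {
  # sparse field so no halo band touches another cell
  cfg <- SimConfig(nCells = 4, fieldSize = c(160, 160), nFrames = 2,
                   noiseSd = 0, coverage = 0.15, seed = 7)
  gt <- simulateTracks(cfg)
  st <- renderPhaseContrast(gt, cfg)
  expect_equal(pixelSize(st), cfg@pixelSizeUm)
  fr <- getFrame(st, 0)
  tf <- trackTable(gt)[trackTable(gt)$frame == 0, ]
  for (i in 1:2) {
    body <- PhaseTrack:::ellipsePixelIdx(tf$cx[i], tf$cy[i], tf$a[i],
                                         tf$b[i], tf$theta[i], 160, 160)
    band <- setdiff(PhaseTrack:::ellipsePixelIdx(tf$cx[i], tf$cy[i],
                                                 tf$a[i] + 2, tf$b[i] + 2,
                                                 tf$theta[i], 160, 160),
                    body)
    expect_equal(mean(fr[band]) - mean(fr[body]),
                 cfg@haloAmplitude + cfg@bodyDepth, tolerance = 1e-10)
  }

  # empty ground truth renders pure background + noise
  cfg0 <- SimConfig(nCells = 1, fieldSize = c(64, 64), nFrames = 1,
                    noiseSd = 0, seed = 1)
  gt0 <- simulateTracks(cfg0)
  gt0@tracks <- gt0@tracks[0, ]
  fr0 <- getFrame(renderPhaseContrast(gt0, cfg0), 0)
  expect_true(all(fr0 == cfg0@background))

  # noise-only region moments match the configured Gaussian to 5%
  cfgN <- SimConfig(nCells = 1, fieldSize = c(256, 256), nFrames = 1,
                    noiseSd = 6, seed = 9)
  gtN <- simulateTracks(cfgN)
  frN <- getFrame(renderPhaseContrast(gtN, cfgN), 0)
  tfN <- trackTable(gtN)
  far <- frN[sqrt((col(frN) - 1 - tfN$cx[1])^2 +
                    (row(frN) - 1 - tfN$cy[1])^2) > tfN$a[1] + 6]
  expect_lt(abs(mean(far) - cfgN@background), 0.05 * 6)
  expect_lt(abs(sd(far) - 6) / 6, 0.05)
})

test_that("junction fluorescence: per-cell budget and dilution geometry", {
  # single cell: ribbon integral equals the emitted total exactly
  cfg1 <- SimConfig(nCells = 1, fieldSize = c(96, 96), nFrames = 1,
                    seed = 11)
  gt1 <- simulateTracks(cfg1)
  jf1 <- renderJunctionFluorescence(gt1, cfg1, frame = 0)
  expect_equal(sum(jf1$image[jf1$roi[[1]]]), cfg1@junctionTotalIntensity,
               tolerance = 1e-9)

  # full tessellation: each cell's own-ribbon integral matches its emitted
  # total within 5%, and line density dilutes with junction length
  cfg <- SimConfig(nCells = 10, fieldSize = c(256, 256), nFrames = 6,
                   elongatingFraction = 0.5, elongationRate = 1.05,
                   seed = 12)
  gt <- simulateTracks(cfg)
  jf <- renderJunctionFluorescence(gt, cfg, frame = 5)
  dens <- numeric(cfg@nCells)
  for (i in seq_len(cfg@nCells)) {
    got <- sum(jf$image[jf$roi[[i]]])
    # shared 2-px junction lines: own-side deposits only
    ownOnly <- jf$image[jf$roi[[i]]]
    expect_lt(abs(got - jf$emitted[i]) / jf$emitted[i], 0.05)
    dens[i] <- relVEcadC(jf$image, jf$roi[[i]], lengthUm = jf$lengthUm[i],
                         pixelSize = cfg@pixelSizeUm)$rel_vecad_c
  }
  # equal totals with unequal perimeters: density ratio ~ inverse length
  o <- order(jf$lengthUm)
  i1 <- o[1]; i2 <- o[cfg@nCells]
  expect_equal(dens[i1] / dens[i2], jf$lengthUm[i2] / jf$lengthUm[i1],
               tolerance = 0.02)
})
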