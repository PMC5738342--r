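# Trajectory model: transition densities, trajectory and collection
# scores, structural moves, posterior sampling and the Bayes decision.

test_that("transition log-density: mode, symmetry, closed form", {
  mm <- MotionModel(sigmaPos = 2, sigmaShape = 0.1, sigmaTheta = 0.2)
  base <- list(position = c(10, 10), velocity = c(1, 0),
               logAxes = log(c(8, 5)), theta = 0.4)
  atPred <- Ellipse(11, 10, 8, 5, 0.4)
  lpMax <- transitionLogProb(base$position, base$velocity, base$logAxes,
                             base$theta, atPred, mm)
  # any deviation scores lower than the exact prediction
  for (d in list(c(1, 0), c(0, -2), c(1.5, 1.5))) {
    off <- Ellipse(11 + d[1], 10 + d[2], 8, 5, 0.4)
    expect_lt(transitionLogProb(base$position, base$velocity, base$logAxes,
                                base$theta, off, mm), lpMax)
  }
  # sign symmetry of positional deviations
  lp1 <- transitionLogProb(base$position, base$velocity, base$logAxes,
                           base$theta, Ellipse(11 + 1.3, 10 + 0.7, 8, 5, 0.4),
                           mm)
  lp2 <- transitionLogProb(base$position, base$velocity, base$logAxes,
                           base$theta, Ellipse(11 - 1.3, 10 - 0.7, 8, 5, 0.4),
                           mm)
  expect_equal(lp1, lp2, tolerance = 1e-12)

  # deviation (3, 4) with sigmaPos = 2 equals the closed-form evaluation
  lp <- transitionLogProb(base$position, base$velocity, base$logAxes,
                          base$theta, Ellipse(11 + 3, 10 + 4, 8, 5, 0.4), mm)
  closed <- dnorm(3, 0, 2, log = TRUE) + dnorm(4, 0, 2, log = TRUE) +
    2 * dnorm(0, 0, 0.1, log = TRUE) +
    log(sum(dnorm(0 + (-3:3) * pi, 0, 0.2)))
  expect_equal(lp, closed, tolerance = 1e-10)
})

test_that("trajectory score assembles birth, death, coverage and transitions", {
  mm <- tinyMotionModel(); prior <- tinyPrior()
  hyps <- data.frame(id = 1:3, frame = 0:2, cx = c(10, 12, 14),
                     cy = c(10, 10.5, 11), a = c(8, 8.2, 8.1),
                     b = c(5, 5, 5.1), theta = c(0.3, 0.32, 0.31),
                     support = c(0.9, 0.95, 0.85))

  # singleton: no transitions
  s1 <- trajectoryLogScore(list(t0 = 0L, ids = 1L), hyps, mm, prior)
  expect_equal(s1, -2 - 2 + log(0.9) + 4, tolerance = 1e-12)

  # stationary identical ellipses: each transition at the zero-deviation mode
  st <- data.frame(id = 1:3, frame = 0:2, cx = 20, cy = 20, a = 8, b = 5,
                   theta = 1, support = 0.9)
  mx1 <- dnorm(0, 0, mm@sigmaPos * 2, log = TRUE) * 2 +
    dnorm(0, 0, mm@sigmaShape, log = TRUE) * 2 +
    log(sum(dnorm((-3:3) * pi, 0, mm@sigmaTheta)))
  mx2 <- dnorm(0, 0, mm@sigmaPos, log = TRUE) * 2 +
    dnorm(0, 0, mm@sigmaShape, log = TRUE) * 2 +
    log(sum(dnorm((-3:3) * pi, 0, mm@sigmaTheta)))
  sSt <- trajectoryLogScore(list(t0 = 0L, ids = 1:3), st, mm, prior)
  expect_equal(sSt, -4 + 3 * (log(0.9) + 4) + mx1 + mx2, tolerance = 1e-10)

  # 3-frame track with known deviations: term-by-term hand summation
  s3 <- trajectoryLogScore(list(t0 = 0L, ids = 1:3), hyps, mm, prior)
  hand <- prior@logBirth + prior@logDeath +
    sum(log(hyps$support)) + 3 * prior@logCoverage +
    # first transition: zero velocity, inflated sigmaPos
    dnorm(2, 0, 4, log = TRUE) + dnorm(0.5, 0, 4, log = TRUE) +
    dnorm(log(8.2 / 8), 0, 0.1, log = TRUE) +
    dnorm(log(5 / 5), 0, 0.1, log = TRUE) +
    log(sum(dnorm(0.02 + (-3:3) * pi, 0, 0.3))) +
    # second transition: velocity = previous displacement = (2, 0.5)
    dnorm(14 - 14, 0, 2, log = TRUE) + dnorm(11 - 11, 0, 2, log = TRUE) +
    dnorm(log(8.1 / 8.2), 0, 0.1, log = TRUE) +
    dnorm(log(5.1 / 5), 0, 0.1, log = TRUE) +
    log(sum(dnorm(-0.01 + (-3:3) * pi, 0, 0.3)))
  expect_equal(s3, hand, tolerance = 1e-10)

  expect_error(trajectoryLogScore(list(t0 = 0L, ids = c(1L, 99L)), hyps,
                                  mm, prior),
               class = "invalidReference")
})

test_that("collection score: empty, hard exclusion, overlap penalty", {
  mm <- tinyMotionModel()
  hyps <- data.frame(id = 1:2, frame = c(0L, 0L), cx = c(20, 26),
                     cy = c(20, 20), a = c(8, 8), b = c(6, 6),
                     theta = c(0, 0), support = c(0.9, 0.9))
  expect_equal(collectionLogScore(list(), hyps, mm, tinyPrior()), 0)

  prHard <- CollectionPrior(logBirth = -2, logDeath = -2, logCoverage = 4,
                            kappaOverlap = Inf)
  coll <- list(list(t0 = 0L, ids = 1L), list(t0 = 0L, ids = 2L))
  expect_equal(collectionLogScore(coll, hyps, mm, prHard), -Inf)

  # finite kappa: score difference vs disjoint placement is -kappa * area
  kappa <- 0.03
  prK <- CollectionPrior(logBirth = -2, logDeath = -2, logCoverage = 4,
                         kappaOverlap = kappa)
  hypsFar <- hyps; hypsFar$cx[2] <- 60
  sOver <- collectionLogScore(coll, hyps, mm, prK)
  sFar <- collectionLogScore(coll, hypsFar, mm, prK)
  ov <- oracleOverlapArea(list(cx = 20, cy = 20, a = 8, b = 6, theta = 0),
                          list(cx = 26, cy = 20, a = 8, b = 6, theta = 0))
  expect_equal(sOver - sFar, -kappa * ov, tolerance = kappa * ov * 0.1)

  dup <- list(list(t0 = 0L, ids = 1L), list(t0 = 0L, ids = 1L))
  expect_error(collectionLogScore(dup, hyps, mm, prK),
               class = "invalidCollection")
})

test_that("structural moves: applicability, reversibility bookkeeping", {
  hyps <- makeTinyInstance(3)
  set.seed(1)
  # birth on the empty collection creates one singleton
  b <- proposeMove(list(), hyps, "birth")
  expect_true(b$applicable)
  expect_length(b$collection, 1L)
  expect_length(b$collection[[1]]$ids, 1L)

  # death of that singleton restores the empty collection, and the two
  # proposal ratios cancel (detailed-balance bookkeeping)
  d <- proposeMove(b$collection, hyps, "death")
  expect_true(d$applicable)
  expect_length(d$collection, 0L)
  expect_equal(b$logQRatio + d$logQRatio, 0, tolerance = 1e-12)

  # extend past the last frame is a flagged no-op
  lastF <- max(hyps$frame)
  full <- list(list(t0 = min(hyps$frame),
                    ids = vapply(min(hyps$frame):lastF, function(f)
                      hyps$id[hyps$frame == f][1L], integer(1))))
  reps <- replicate(20, {
    p <- proposeMove(full, hyps, "extend",
                     assigned = hyps$id %in% full[[1]]$ids)
    p$applicable
  })
  # extension is only ever applicable if some frame end has free slots;
  # when every adjacent frame is exhausted each attempt is flagged no-op
  expect_true(all(!reps) ||
                any(!hyps$id[hyps$frame %in% c(min(hyps$frame), lastF)] %in%
                      full[[1]]$ids))
})

test_that("sampler respects the posterior: invariance on an enumerable instance", {
  # single hypothesis per frame over two frames: 5 feasible collections;
  # long-run visit frequencies match the Boltzmann weights
  hyps <- data.frame(id = 1:2, frame = 0:1, cx = c(20, 21.5),
                     cy = c(20, 20.3), a = 8, b = 6, theta = 0.5,
                     support = 0.92)
  mm <- tinyMotionModel(); prior <- tinyPrior()
  colls <- oracleEnumerateCollections(hyps)
  scores <- vapply(colls, function(cl)
    collectionLogScore(cl, hyps, mm, prior), numeric(1))
  keys <- vapply(colls, canonicalCollection, "")
  expect_length(colls, 5L)
  wgt <- exp(scores - max(scores)); wgt <- wgt / sum(wgt)

  post <- samplePosterior(hyps, mm, prior, nIter = 60000, seed = 9)
  seen <- vapply(post$samples, function(s) canonicalCollection(s$collection),
                 "")
  seen <- seen[seq_along(seen) > 0.2 * length(seen)]
  freq <- table(factor(seen, levels = keys)) / length(seen)
  expect_lt(max(abs(as.numeric(freq) - wgt)), 0.04)

  # best sampled collection is the enumerated MAP (the linked track)
  expect_equal(canonicalCollection(post$best),
               canonicalCollection(colls[[which.max(scores)]]))
})

test_that("sampler basics: empty input, determinism", {
  mm <- tinyMotionModel(); prior <- tinyPrior()
  empty <- data.frame(id = integer(0), frame = integer(0), cx = numeric(0),
                      cy = numeric(0), a = numeric(0), b = numeric(0),
                      theta = numeric(0), support = numeric(0))
  post <- samplePosterior(empty, mm, prior, nIter = 50, seed = 1)
  expect_true(all(vapply(post$samples, function(s)
    length(s$collection) == 0L, logical(1))))

  hyps <- makeTinyInstance(5)
  p1 <- samplePosterior(hyps, mm, prior, nIter = 2000, seed = 7)
  p2 <- samplePosterior(hyps, mm, prior, nIter = 2000, seed = 7)
  expect_identical(p1$samples[[2000]]$collection,
                   p2$samples[[2000]]$collection)
  expect_identical(p1$bestScore, p2$bestScore)
})

test_that("Bayes decision: degenerate posteriors and the 0.5 rule", {
  mm <- tinyMotionModel(); prior <- tinyPrior()
  hyps <- data.frame(id = 1:2, frame = 0:1, cx = c(20, 21), cy = c(20, 20),
                     a = 8, b = 6, theta = 0, support = 0.9)
  linked <- list(list(t0 = 0L, ids = c(1L, 2L)))
  split <- list(list(t0 = 0L, ids = 1L), list(t0 = 1L, ids = 2L))
  mkPost <- function(collections) {
    list(samples = lapply(seq_along(collections), function(i)
      list(collection = collections[[i]], iteration = i, accepted = TRUE,
           logScore = 0)), nIter = length(collections))
  }
  # all samples identical: the decision is that collection
  post <- mkPost(rep(list(linked), 10))
  dec <- bayesDecision(post, hyps, mm, prior, burnIn = 0)
  expect_equal(canonicalCollection(decidedAsList(dec)),
               canonicalCollection(linked))

  # link present in only 40% of samples is excluded
  post2 <- mkPost(c(rep(list(linked), 4), rep(list(split), 6)))
  dec2 <- bayesDecision(post2, hyps, mm, prior, burnIn = 0)
  expect_equal(canonicalCollection(decidedAsList(dec2)),
               canonicalCollection(split))

  expect_error(bayesDecision(mkPost(list(linked)), hyps, mm, prior,
                             burnIn = 1), class = "invalidInput")
})

test_that("decision matches the enumerated MAP on sharply peaked instances", {
  mm <- tinyMotionModel(); prior <- tinyPrior()
  used <- 0; agree <- 0; seed <- 0
  while (used < 5 && seed < 30) {
    seed <- seed + 1
    hyps <- makeTinyInstance(seed)
    colls <- oracleEnumerateCollections(hyps)
    scores <- vapply(colls, function(cl)
      collectionLogScore(cl, hyps, mm, prior), numeric(1))
    o <- order(-scores)
    if (scores[o[1]] - scores[o[2]] <= 2) next
    used <- used + 1
    post <- samplePosterior(hyps, mm, prior, nIter = 20000, seed = seed)
    dec <- bayesDecision(post, hyps, mm, prior)
    agree <- agree +
      identical(canonicalCollection(decidedAsList(dec)),
                canonicalCollection(colls[[o[1]]]))
  }
  expect_equal(used, 5)
  expect_gte(agree, 4)
})

test_that("hard exclusion and injectivity hold in decided collections", {
  # two well-supported overlapping hypotheses in one frame, kappa = Inf:
  # the decision never keeps both
  mm <- tinyMotionModel()
  prHard <- CollectionPrior(logBirth = -1, logDeath = -1, logCoverage = 4,
                            kappaOverlap = Inf)
  hyps <- data.frame(id = 1:3, frame = c(0L, 0L, 1L),
                     cx = c(20, 23, 20.5), cy = c(20, 20, 20.2),
                     a = 8, b = 6, theta = 0, support = c(0.95, 0.9, 0.92))
  post <- samplePosterior(hyps, mm, prHard, nIter = 5000, seed = 3)
  dec <- bayesDecision(post, hyps, mm, prHard)
  tab <- trackTable(dec)
  f0 <- tab[tab$frame == 0, ]
  if (nrow(f0) == 2L) {
    ov <- oracleOverlapArea(as.list(f0[1, c("cx", "cy", "a", "b", "theta")]),
                            as.list(f0[2, c("cx", "cy", "a", "b", "theta")]))
    expect_equal(ov, 0)
  } else {
    expect_lte(nrow(f0), 1L)
  }
  expect_false(anyDuplicated(tab$hyp[!is.na(tab$hyp)]) > 0)
})

test_that("raising the coverage reward never shrinks the MAP assignment", {
  mm <- tinyMotionModel()
  for (seed in c(2, 4)) {
    hyps <- makeTinyInstance(seed, withClutter = TRUE)
    colls <- oracleEnumerateCollections(hyps)
    nAssigned <- function(lc) {
      prior <- CollectionPrior(logBirth = -2, logDeath = -2,
                               logCoverage = lc, kappaOverlap = 0.01)
      scores <- vapply(colls, function(cl)
        collectionLogScore(cl, hyps, mm, prior), numeric(1))
      length(unlist(lapply(colls[[which.max(scores)]], `[[`, "ids")))
    }
    counts <- vapply(c(0, 2, 4, 6), nAssigned, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("average tracked cells over a frame range", {
  mk <- function(t0, n) list(t0 = t0, ids = seq_len(n) + 100L * t0)
  three <- list(mk(0L, 10L), mk(0L, 10L), mk(0L, 10L))
  expect_equal(averageTrackedCells(three, 0:9), 3)
  # full-span + a track alive frames 5..9
  two <- list(mk(0L, 10L), mk(5L, 5L))
  expect_equal(averageTrackedCells(two, 0:9), 1.5)
  expect_equal(averageTrackedCells(list(), 0:9), 0)
  expect_error(averageTrackedCells(three, integer(0)),
               class = "invalidInput")
})
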