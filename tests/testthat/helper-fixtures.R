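# Fixtures built in code: tiny frames, probability maps and hypothesis
# tables used across the suite.

# frame with a dark disk wearing a bright ring on a flat background
makeRingDiskFrame <- function(h = 31, w = 31, cx = 15, cy = 15, r = 5,
                              background = 100, body = 60, ring = 150) {
  fr <- matrix(background, h, w)
  for (x in 0:(w - 1)) for (y in 0:(h - 1)) {
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    if (d <= r) fr[y + 1, x + 1] <- body
    else if (d <= r + 2) fr[y + 1, x + 1] <- ring
  }
  fr
}

# binary probability map with filled disks (prob `inside` within, `outside`
# elsewhere)
makeDiskMap <- function(h, w, disks, inside = 1, outside = 0) {
  m <- matrix(outside, h, w)
  for (d in disks) {
    for (x in 0:(w - 1)) for (y in 0:(h - 1)) {
      if ((x - d[1])^2 + (y - d[2])^2 <= d[3]^2) m[y + 1, x + 1] <- inside
    }
  }
  m
}

# smooth random blobby probability map in [0, 1]
makeBlobbyMap <- function(h = 64, w = 64, nBlob = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(0.05, h, w)
  for (k in seq_len(nBlob)) {
    cx <- runif(1, 8, w - 9); cy <- runif(1, 8, h - 9)
    a <- runif(1, 4, 10); b <- runif(1, 3, a)
    th <- runif(1, 0, pi)
    for (x in max(0, floor(cx - a - 2)):min(w - 1, ceiling(cx + a + 2))) {
      for (y in max(0, floor(cy - a - 2)):min(h - 1, ceiling(cy + a + 2))) {
        dx <- x - cx; dy <- y - cy
        u <- (dx * cos(th) + dy * sin(th)) / a
        v <- (-dx * sin(th) + dy * cos(th)) / b
        if (u * u + v * v <= 1) m[y + 1, x + 1] <- runif(1, 0.85, 1)
      }
    }
  }
  m + matrix(runif(h * w, 0, 0.05), h, w)
}

# smoothly moving tracks with optional clutter, as a hypothesis table
makeTinyInstance <- function(seed, withClutter = FALSE) {
  set.seed(seed)
  nf <- sample(2:3, 1)
  nTrack <- sample(1:2, 1)
  rows <- list()
  for (tr in seq_len(nTrack)) {
    p <- runif(2, 15, 45)
    v <- rnorm(2, 0, 1)
    a <- runif(1, 6, 9); b <- runif(1, 4, 6); th <- runif(1, 0, pi)
    for (f in seq_len(nf) - 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = 0L, frame = f, cx = p[1], cy = p[2], a = a, b = b,
        theta = th %% pi, support = runif(1, 0.8, 0.99))
      p <- p + v + rnorm(2, 0, 0.5)
      a <- a * exp(rnorm(1, 0, 0.04)); b <- b * exp(rnorm(1, 0, 0.04))
      th <- th + rnorm(1, 0, 0.1)
    }
  }
  if (withClutter) {
    for (k in seq_len(sample(1:2, 1))) {
      f <- sample(seq_len(nf) - 1L, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        id = 0L, frame = f, cx = runif(1, 60, 90), cy = runif(1, 60, 90),
        a = runif(1, 6, 9), b = runif(1, 4, 6), theta = runif(1, 0, pi),
        support = runif(1, 0.55, 0.75))
    }
  }
  hyps <- do.call(rbind, rows)
  hyps <- hyps[order(hyps$frame), ]
  hyps <- do.call(rbind, lapply(split(hyps, hyps$frame), function(d)
    d[seq_len(min(3, nrow(d))), , drop = FALSE]))
  hyps$id <- seq_len(nrow(hyps))
  rownames(hyps) <- NULL
  hyps
}

tinyMotionModel <- function() MotionModel(sigmaPos = 2, sigmaShape = 0.1,
                                          sigmaTheta = 0.3)
tinyPrior <- function() CollectionPrior(logBirth = -2, logDeath = -2,
                                        logCoverage = 4,
                                        kappaOverlap = 0.01)
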