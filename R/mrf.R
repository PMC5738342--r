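# Per-frame binary foreground/background segmentation of phase-contrast
# frames with a Markov random field carrying pairwise Potts and robust
# higher-order Pn-Potts clique potentials. Applied to each frame of a movie
# independently; the output is a per-pixel foreground probability map.

#' Per-pixel foreground evidence for a phase-contrast frame
#'
#' Phase-contrast optics gives no direct intensity/foreground
#' correspondence, but it does impose a three-level structure: cell bodies
#' sit below the background grey level and are rimmed by a bright halo,
#' while the background itself is flat and intermediate. The score
#' therefore fits a three-component intensity model to the lightly
#' smoothed frame (deterministic one-dimensional three-means, centres
#' initialised at the 0.1/0.5/0.9 quantiles; the middle centre is taken as
#' background, the outer two as foreground levels) and measures, per
#' pixel, how much closer the intensity is to a foreground level than to
#' the background level, in squared standardised units (standardised by
#' the global intensity s.d., so the score map is invariant under
#' rescaling all intensities by a positive factor).
#'
#' @param frame numeric `H x W` matrix of intensities.
#' @param radius feature scale in px (`>= 1`); bounds the minimum frame
#'   size. The level model itself is fitted on a lightly (3 x 3) smoothed
#'   frame so that thin halo rims keep their own intensity mode.
#' @return numeric `H x W` score matrix; larger means more foreground-like
#'   (the score is the background-vs-foreground log-likelihood difference
#'   of the intensity model).
#' @export
extractUnaryFeatures <- function(frame, radius = 24) {
  if (!is.matrix(frame) || !is.numeric(frame))
    ptStop("frame must be a numeric matrix", "invalidInput")
  radius <- as.integer(radius)
  if (radius < 1L) ptStop("radius must be >= 1", "invalidInput")
  if (nrow(frame) < 2L * radius + 1L || ncol(frame) < 2L * radius + 1L)
    ptStop(sprintf("frame must be at least %d px in each dimension",
                   2L * radius + 1L), "invalidInput")
  if (any(!is.finite(frame)))
    ptStop("frame intensities must be finite", "invalidInput")
  s <- stats::sd(frame)
  if (s == 0) return(frame * 0)
  ism <- boxBlur(frame, 1L)
  cen <- kmeans1d(as.vector(ism), 3L)
  lo <- cen[1L]; mid <- cen[2L]; hi <- cen[3L]
  ((ism - mid)^2 - pmin((ism - lo)^2, (ism - hi)^2)) / (2 * s^2)
}

# Exact 1-d k-means on a histogram (dynamic programme over bin
# boundaries, globally optimal up to binning). Deterministic; returns
# sorted centres. A local-search k-means would routinely miss the small
# bright-halo mode of a phase-contrast histogram.
kmeans1d <- function(x, k, bins = 256L) {
  rng <- range(x)
  if (rng[2L] - rng[1L] < 1e-12) return(rep(mean(x), k))
  br <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), bins)
  mid <- (br[-1L] + br[-(bins + 1L)]) / 2
  W <- cumsum(cnt); WX <- cumsum(cnt * mid); WX2 <- cumsum(cnt * mid^2)
  sse <- function(i, j) {
    w <- W[j] - if (i > 1L) W[i - 1L] else 0
    if (w == 0) return(0)
    sx <- WX[j] - if (i > 1L) WX[i - 1L] else 0
    sx2 <- WX2[j] - if (i > 1L) WX2[i - 1L] else 0
    sx2 - sx * sx / w
  }
  D <- matrix(Inf, k, bins)
  B <- matrix(1L, k, bins)
  for (j in seq_len(bins)) D[1L, j] <- sse(1L, j)
  for (kk in 2:k) {
    for (j in kk:bins) {
      best <- Inf; bi <- kk
      for (i in kk:j) {
        v <- D[kk - 1L, i - 1L] + sse(i, j)
        if (v < best) { best <- v; bi <- i }
      }
      D[kk, j] <- best; B[kk, j] <- bi
    }
  }
  cen <- numeric(k)
  j <- bins
  for (kk in k:1) {
    i <- if (kk > 1L) B[kk, j] else 1L
    w <- W[j] - if (i > 1L) W[i - 1L] else 0
    sx <- WX[j] - if (i > 1L) WX[i - 1L] else 0
    cen[kk] <- if (w > 0) sx / w else mid[i]
    j <- i - 1L
    if (j < 1L) break
  }
  sort(cen)
}

# Two-class label energies from the score map: the score is already the
# log-likelihood difference, split antisymmetrically over the two labels.
featureUnaries <- function(feature) {
  list(u0 = feature / 2, u1 = -feature / 2)
}

#' Partition a frame into higher-order cliques
#'
#' Cliques are the regions of a seeded oversegmentation: seeds on a regular
#' grid, assignment by a compactness-weighted distance in (x, y, local mean
#' intensity), a few relocation iterations, then connectivity enforcement
#' (every clique is spatially 4-connected; orphaned fragments are merged
#' into the neighbouring clique they touch most).
#'
#' @param frame numeric `H x W` matrix.
#' @param nCliques target number of cliques, in `[1, H * W]`.
#' @param nIter relocation iterations.
#' @return integer `H x W` matrix of clique labels `1..K`; cliques are
#'   disjoint, cover the frame and are each spatially connected.
#' @export
buildCliques <- function(frame, nCliques, nIter = 3) {
  if (!is.matrix(frame)) ptStop("frame must be a matrix", "invalidInput")
  h <- nrow(frame); w <- ncol(frame)
  n <- as.integer(round(nCliques))
  if (n < 1L || n > h * w)
    ptStop("nCliques must lie in [1, H*W]", "invalidInput")
  if (n == h * w) return(matrix(seq_len(h * w), h, w))
  if (n == 1L) return(matrix(1L, h, w))

  sp <- sqrt(h * w / n)
  feat <- boxBlur(frame, max(1L, as.integer(round(sp / 4))))
  sigf <- max(stats::sd(feat), 1e-9)

  gr <- max(1L, as.integer(round(sqrt(n * h / w))))
  gc <- as.integer(ceiling(n / gr))
  sy <- (seq_len(gr) - 0.5) * h / gr
  sx <- (seq_len(gc) - 0.5) * w / gc
  seeds <- cbind(y = rep(sy, times = gc), x = rep(sx, each = gr))[seq_len(n), ,
                                                                 drop = FALSE]
  sf <- feat[cbind(pmin(h, pmax(1L, round(seeds[, "y"]))),
                   pmin(w, pmax(1L, round(seeds[, "x"]))))]

  Y <- matrix(seq_len(h), h, w)
  X <- matrix(rep(seq_len(w), each = h), h, w)
  lab <- matrix(0L, h, w)
  for (it in seq_len(nIter)) {
    best <- matrix(Inf, h, w)
    lab[] <- 0L
    for (k in seq_len(n)) {
      r0 <- max(1L, as.integer(floor(seeds[k, "y"] - 1.5 * sp)))
      r1 <- min(h, as.integer(ceiling(seeds[k, "y"] + 1.5 * sp)))
      c0 <- max(1L, as.integer(floor(seeds[k, "x"] - 1.5 * sp)))
      c1 <- min(w, as.integer(ceiling(seeds[k, "x"] + 1.5 * sp)))
      d2 <- ((Y[r0:r1, c0:c1] - seeds[k, "y"])^2 +
               (X[r0:r1, c0:c1] - seeds[k, "x"])^2) / sp^2 +
        ((feat[r0:r1, c0:c1] - sf[k]) / sigf)^2
      upd <- d2 < best[r0:r1, c0:c1]
      bb <- best[r0:r1, c0:c1]; ll <- lab[r0:r1, c0:c1]
      bb[upd] <- d2[upd]; ll[upd] <- k
      best[r0:r1, c0:c1] <- bb; lab[r0:r1, c0:c1] <- ll
    }
    # any pixel missed by every window: nearest seed spatially
    miss <- which(lab == 0L)
    if (length(miss)) {
      my <- ((miss - 1L) %% h) + 1L
      mx <- ((miss - 1L) %/% h) + 1L
      for (j in seq_along(miss)) {
        dd <- (seeds[, "y"] - my[j])^2 + (seeds[, "x"] - mx[j])^2
        lab[miss[j]] <- which.min(dd)
      }
    }
    for (k in seq_len(n)) {
      sel <- lab == k
      if (any(sel)) {
        seeds[k, "y"] <- mean(Y[sel]); seeds[k, "x"] <- mean(X[sel])
        sf[k] <- mean(feat[sel])
      }
    }
  }

  # connectivity: split labels into connected fragments, keep each label's
  # largest fragment, merge the rest into the most-touched neighbour label
  comp <- sameLabelComponents(lab)
  nc <- max(comp)
  if (nc > n) {
    compLab <- lab[match(seq_len(nc), comp)]
    sizes <- tabulate(comp, nc)
    keep <- rep(FALSE, nc)
    for (k in unique(compLab)) {
      ks <- which(compLab == k)
      keep[ks[which.max(sizes[ks])]] <- TRUE
    }
    orphan <- setdiff(order(sizes), which(keep))
    for (ci in orphan) {
      sel <- which(comp == ci)
      nbl <- integer(0)
      ry <- ((sel - 1L) %% h) + 1L; rx <- ((sel - 1L) %/% h) + 1L
      for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ry2 <- ry + o[1L]; rx2 <- rx + o[2L]
        ok <- ry2 >= 1L & ry2 <= h & rx2 >= 1L & rx2 <= w
        j2 <- (rx2[ok] - 1L) * h + ry2[ok]
        out <- comp[j2] != ci
        nbl <- c(nbl, lab[j2][out])
      }
      if (length(nbl)) {
        tt <- table(nbl)
        lab[sel] <- as.integer(names(tt)[which.max(tt)])
      }
    }
  }
  # compact labels
  u <- sort(unique(as.vector(lab)))
  matrix(match(lab, u), h, w)
}

# connected components of equal-label 4-adjacency
sameLabelComponents <- function(lab) {
  as.integer(.labelRegions(matrix(as.integer(lab), nrow(lab), ncol(lab)),
                           4L, 0L, FALSE))
}

#' Energy of a binary labelling under the MRF
#'
#' `E = unaryScale * sum_p u(label_p) + beta * #(disagreeing 4-neighbour
#' pairs) + sum_cliques min(gammaMax, gammaMax * minority /
#' (truncationQ * |clique|))`, where `minority` is the clique's
#' minority-label pixel count (robust Pn-Potts: the penalty is linear in the
#' number of dissenting pixels and saturates once a fraction `truncationQ`
#' of the clique disagrees).
#'
#' @param labels binary (0/1 or logical) `H x W` matrix.
#' @param frame numeric `H x W` matrix (used to derive the unary term when
#'   `unary` is not supplied).
#' @param cliques integer `H x W` clique-label matrix from [buildCliques()].
#' @param params a [MrfParams-class].
#' @param unary optional list with components `u0`, `u1` (per-pixel label
#'   energies); computed from `frame` when `NULL`.
#' @return numeric(1), finite.
#' @export
mrfEnergy <- function(labels, frame, cliques, params, unary = NULL) {
  if (is.logical(labels)) labels <- labels + 0
  if (!is.matrix(labels) || !identical(dim(labels), dim(frame)))
    ptStop("labels shape must match the frame", "invalidInput")
  if (!identical(dim(cliques), dim(frame)))
    ptStop("cliques shape must match the frame", "invalidInput")
  if (is.null(unary)) {
    unary <- featureUnaries(extractUnaryFeatures(frame, params@featureRadius))
  }
  eU <- params@unaryScale *
    sum(labels * unary$u1 + (1 - labels) * unary$u0)
  h <- nrow(labels); w <- ncol(labels)
  disagree <- 0
  if (h > 1L) disagree <- disagree +
      sum(labels[-1L, , drop = FALSE] != labels[-h, , drop = FALSE])
  if (w > 1L) disagree <- disagree +
      sum(labels[, -1L, drop = FALSE] != labels[, -w, drop = FALSE])
  eP <- params@beta * disagree
  eH <- 0
  if (params@gammaMax > 0) {
    fg <- as.vector(rowsum(as.vector(labels), as.vector(cliques)))
    nsz <- as.vector(rowsum(rep(1, length(labels)), as.vector(cliques)))
    m <- pmin(fg, nsz - fg)
    eH <- sum(pmin(params@gammaMax,
                   params@gammaMax * m / (params@truncationQ * nsz)))
  }
  eU + eP + eH
}

#' Segment one frame into per-pixel foreground probabilities
#'
#' Gibbs marginals of the MRF posterior are estimated by a
#' Rao-Blackwellised single-site Gibbs sampler (compiled): sites are
#' updated in a fixed scan order with their exact full conditionals, and
#' the marginal estimate is the average of those conditionals over the
#' kept sweeps, which is considerably lower-variance than averaging the
#' binary states. The sampler runs on a private RNG stream seeded by
#' `sweepSeed`, so the output is bit-reproducible for identical inputs and
#' R's RNG state is untouched. With `beta = gammaMax = 0` the model
#' factorises and the exact closed-form per-pixel logistic of the unary
#' term is returned.
#'
#' @param frame numeric `H x W` matrix.
#' @param params a [MrfParams-class].
#' @param timeIndex 0-based frame index recorded in the output.
#' @param cliques optional precomputed clique matrix; built from the frame
#'   otherwise.
#' @param nSweeps,burnIn total Gibbs sweeps and burn-in sweeps. The default
#'   suits movie-scale frames; for small frames the sampler is cheap and
#'   `nSweeps` can be raised freely for tighter marginals.
#' @param sweepSeed seed of the sampler's private RNG stream.
#' @return A [ForegroundMap-class].
#' @export
segmentFrame <- function(frame, params = MrfParams(), timeIndex = 0L,
                         cliques = NULL, nSweeps = 100L, burnIn = 30L,
                         sweepSeed = 0) {
  feat <- extractUnaryFeatures(frame, params@featureRadius)
  if (any(!is.finite(feat))) {
    bad <- which(!is.finite(feat))[1L]
    ptStop(sprintf("non-finite feature value at pixel (row %d, col %d)",
                   ((bad - 1L) %% nrow(feat)) + 1L,
                   ((bad - 1L) %/% nrow(feat)) + 1L), "computationError")
  }
  unary <- featureUnaries(feat)
  tm <- params@temperature
  du <- params@unaryScale * (unary$u0 - unary$u1) / tm
  if (params@beta == 0 && params@gammaMax == 0)
    return(ForegroundMap(stats::plogis(du), timeIndex))

  h <- nrow(frame); w <- ncol(frame)
  if (params@gammaMax > 0) {
    if (is.null(cliques)) cliques <- buildCliques(frame, params@nCliques)
    cvec <- as.integer(cliques)
  } else {
    cvec <- rep(1L, h * w)
  }
  probs <- .gibbsMarginals(as.vector(du), h, w, params@beta / tm,
                           params@gammaMax / tm, params@truncationQ, cvec,
                           as.integer(nSweeps), as.integer(burnIn),
                           as.numeric(sweepSeed))
  probs <- pmin(pmax(matrix(probs, h, w), 0), 1)
  ForegroundMap(probs, timeIndex)
}

#' Threshold a foreground map into a binary mask
#'
#' @param map a [ForegroundMap-class] (or a bare probability matrix).
#' @param tau threshold in `(0, 1)`; pixels with probability `>= tau` are
#'   foreground.
#' @return logical `H x W` mask.
#' @export
binarizeMap <- function(map, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    ptStop("tau must lie strictly inside (0, 1)", "invalidInput")
  p <- if (is(map, "ForegroundMap")) map@probs else map
  p >= tau
}

#' Segment every frame of a movie
#'
#' Applies [segmentFrame()] to each frame independently.
#'
#' @param stack an [ImageStack-class].
#' @param params a [MrfParams-class].
#' @param verbose report progress to stderr.
#' @return list of [ForegroundMap-class], one per frame.
#' @export
segmentStack <- function(stack, params = MrfParams(), verbose = FALSE) {
  nT <- nFrames(stack)
  lapply(seq_len(nT) - 1L, function(t) {
    if (verbose && t %% 10L == 0L)
      message(sprintf("[segment] frame %d / %d", t, nT))
    segmentFrame(getFrame(stack, t), params, timeIndex = t)
  })
}
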