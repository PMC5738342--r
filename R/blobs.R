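# Elliptical cell-candidate generation: foreground probability maps are
# turned into a superset of maximal elliptical blobs. Candidates are not
# final detections; the trajectory model makes the final decision.

#' Moment-based ellipse fit of a pixel region
#'
#' Centre = centroid; axis directions and ratio from the second central
#' moments; both axes rescaled so the ellipse area equals the region's pixel
#' count.
#'
#' @param x,y pixel-centre coordinates of the region (0-based px).
#' @return An [Ellipse-class].
#' @examples
#' px <- expand.grid(x = 0:39, y = 0:9)
#' fitEllipsePixels(px$x, px$y)  # theta ~ 0, a/b ~ 4
#' @export
fitEllipsePixels <- function(x, y) {
  if (length(x) != length(y) || length(x) < 5L)
    ptStop("region must contain at least 5 pixels", "degenerateGeometry")
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  n <- length(x)
  cxx <- sum(dx * dx) / n
  cyy <- sum(dy * dy) / n
  cxy <- sum(dx * dy) / n
  tr <- cxx + cyy
  dets <- cxx * cyy - cxy * cxy
  disc <- sqrt(max(0, tr * tr / 4 - dets))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l2 <= 1e-9 * max(1, l1))
    ptStop("region is collinear; no ellipse fit", "degenerateGeometry")
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  a0 <- 2 * sqrt(l1); b0 <- 2 * sqrt(l2)
  s <- sqrt(n / (pi * a0 * b0))
  Ellipse(mx, my, a0 * s, b0 * s, theta)
}

# mean foreground probability over the ellipse interior (support); NA when
# the discrete interior is empty
ellipseSupport <- function(probs, e) {
  .ellipseSupportC(probs, e@cx, e@cy, e@a, e@b, e@theta)
}

scaleEllipse <- function(e, s) Ellipse(e@cx, e@cy, e@a * s, e@b * s, e@theta)

#' Generate maximal elliptical blob hypotheses from a foreground map
#'
#' Seeds are local maxima of the smoothed probability map above `tau` with a
#' minimum separation of `minAxis` px. Around each seed, the thresholded
#' foreground component containing the seed (restricted to a window of
#' radius `maxAxis`) is moment-fitted; the fitted shape is then scaled
#' isotropically about its centre to the largest factor at which the mean
#' interior probability (the support) still reaches `tau` and the semi-major
#' axis stays within `maxAxis` (growth in 5% then 1% steps, so every emitted
#' ellipse fails the 1.05-scaling test). Hypotheses are a superset of the
#' true cells: overcounting is expected and only near-duplicates are pruned
#' via [deduplicateHypotheses()].
#'
#' @param map a [ForegroundMap-class] (or probability matrix).
#' @param tau detection threshold in `(0, 1)`. The default is deliberately
#'   high: a hypothesis should consist of high-probability pixels, and
#'   with a mean-interior-support criterion a low threshold would let
#'   ellipses absorb low-probability surroundings (for a binary disk of
#'   radius r the maximal ellipse has radius `r / sqrt(tau)`).
#' @param minAxis minimum semi-minor axis (px).
#' @param maxAxis maximum semi-major axis (px); must exceed `minAxis`.
#' @param maxIou overlap level above which duplicates are suppressed;
#'   `NULL` disables deduplication.
#' @param idOffset first hypothesis id minus one.
#' @return data.frame with columns `id`, `frame`, `cx`, `cy`, `a`, `b`,
#'   `theta`, `support`.
#' @export
generateHypotheses <- function(map, tau = 0.88, minAxis = 4, maxAxis = 60,
                               maxIou = 0.6, idOffset = 0L) {
  if (minAxis >= maxAxis)
    ptStop("minAxis must be smaller than maxAxis", "invalidInput")
  frameIdx <- if (is(map, "ForegroundMap")) map@frame else 0L
  probs <- if (is(map, "ForegroundMap")) map@probs else map
  h <- nrow(probs); w <- ncol(probs)
  empty <- data.frame(id = integer(0), frame = integer(0), cx = numeric(0),
                      cy = numeric(0), a = numeric(0), b = numeric(0),
                      theta = numeric(0), support = numeric(0))
  mask <- probs >= tau
  if (!any(mask)) return(empty)

  sm <- boxBlur(probs, max(2L, as.integer(round(minAxis / 2))))
  isMax <- sm >= shiftMat(sm, 1L, 0L, -Inf) & sm >= shiftMat(sm, -1L, 0L, -Inf) &
    sm >= shiftMat(sm, 0L, 1L, -Inf) & sm >= shiftMat(sm, 0L, -1L, -Inf) &
    sm >= shiftMat(sm, 1L, 1L, -Inf) & sm >= shiftMat(sm, -1L, -1L, -Inf) &
    sm >= shiftMat(sm, 1L, -1L, -Inf) & sm >= shiftMat(sm, -1L, 1L, -Inf)
  cand <- which(isMax & probs >= tau)
  if (length(cand) == 0L) return(empty)
  ord <- cand[order(sm[cand], decreasing = TRUE)]
  sy <- ((ord - 1L) %% h)
  sx <- ((ord - 1L) %/% h)
  keep <- rep(TRUE, length(ord))
  for (i in seq_along(ord)) {
    if (!keep[i]) next
    if (i < length(ord)) {
      later <- (i + 1L):length(ord)
      tooClose <- (sx[later] - sx[i])^2 + (sy[later] - sy[i])^2 < minAxis^2
      keep[later][tooClose] <- FALSE
    }
  }
  seeds <- cbind(x = sx[keep], y = sy[keep])

  comp <- labelComponents(mask, 4L)
  hyps <- list()
  for (si in seq_len(nrow(seeds))) {
    e <- seedEllipse(comp, seeds[si, "x"], seeds[si, "y"], maxAxis)
    if (is.null(e)) next
    # alternate maximal scaling with probability-weighted re-centring: an
    # off-centre moment fit (e.g. from halo-bridged components) would
    # otherwise stay off-centre, since scaling is about the centre
    for (rc in 1:3) {
      e <- maximalScale(probs, e, tau, maxAxis)
      if (is.null(e)) break
      cen <- .ellipseCentroidC(probs, e@cx, e@cy, e@a, e@b, e@theta)
      if (any(is.na(cen))) break
      shift <- sqrt((cen[1L] - e@cx)^2 + (cen[2L] - e@cy)^2)
      if (shift < 0.25) break
      e <- Ellipse(cen[1L], cen[2L], e@a, e@b, e@theta)
    }
    if (is.null(e)) next
    # final pass guarantees the emitted ellipse is maximal about its centre
    e <- maximalScale(probs, e, tau, maxAxis)
    if (is.null(e)) next
    sup <- ellipseSupport(probs, e)
    if (is.na(sup) || sup < tau) next
    if (e@b < minAxis || e@a > maxAxis) next
    hyps[[length(hyps) + 1L]] <-
      data.frame(cx = e@cx, cy = e@cy, a = e@a, b = e@b, theta = e@theta,
                 support = sup)
  }
  if (length(hyps) == 0L) return(empty)
  out <- do.call(rbind, hyps)
  out <- cbind(id = seq_len(nrow(out)) + as.integer(idOffset),
               frame = frameIdx, out)
  rownames(out) <- NULL
  if (!is.null(maxIou)) out <- deduplicateHypotheses(out, maxIou)
  out
}

# initial ellipse: moment fit of the thresholded component containing the
# seed, restricted to a window of radius maxAxis around it
seedEllipse <- function(comp, sx, sy, maxAxis) {
  h <- nrow(comp); w <- ncol(comp)
  r0 <- max(1L, as.integer(sy + 1 - maxAxis))
  r1 <- min(h, as.integer(sy + 1 + maxAxis))
  c0 <- max(1L, as.integer(sx + 1 - maxAxis))
  c1 <- min(w, as.integer(sx + 1 + maxAxis))
  cid <- comp[sy + 1L, sx + 1L]
  if (cid == 0L) return(NULL)
  sub <- comp[r0:r1, c0:c1, drop = FALSE]
  sel <- which(sub == cid)
  if (length(sel) < 5L) return(NULL)
  py <- ((sel - 1L) %% nrow(sub)) + r0 - 1L   # 0-based y
  px <- ((sel - 1L) %/% nrow(sub)) + c0 - 1L  # 0-based x
  tryCatch(fitEllipsePixels(px, py), error = function(err) NULL)
}

# largest isotropic scaling of e (about its centre) keeping support >= tau
# and a <= maxAxis; growth tried in 5% then 1% steps so the emitted ellipse
# is maximal under the 1.05-scaling criterion
maximalScale <- function(probs, e, tau, maxAxis) {
  sup <- ellipseSupport(probs, e)
  if (is.na(sup)) return(NULL)
  if (sup < tau) {
    # shrink: bisect for a supported scale
    lo <- 0.05; hi <- 1
    if (is.na(ellipseSupport(probs, scaleEllipse(e, lo))) ||
        ellipseSupport(probs, scaleEllipse(e, lo)) < tau) return(NULL)
    while (hi / lo > 1.01) {
      mid <- sqrt(lo * hi)
      sm <- ellipseSupport(probs, scaleEllipse(e, mid))
      if (!is.na(sm) && sm >= tau) lo <- mid else hi <- mid
    }
    e <- scaleEllipse(e, lo)
  }
  repeat {
    grown <- FALSE
    for (step in c(1.05, 1.01)) {
      e2 <- scaleEllipse(e, step)
      if (e2@a > maxAxis) next
      s2 <- ellipseSupport(probs, e2)
      if (!is.na(s2) && s2 >= tau) { e <- e2; grown <- TRUE; break }
    }
    if (!grown) break
  }
  e
}

#' Suppress near-duplicate hypotheses within a frame
#'
#' Greedy retention by descending support (ties broken by smaller id): a
#' hypothesis is dropped when its interior IoU with an already-retained
#' hypothesis of the same frame exceeds `maxIou`.
#'
#' @param hyps hypothesis data.frame (see [generateHypotheses()]).
#' @param maxIou overlap tolerance in `(0, 1)`.
#' @return filtered data.frame.
#' @export
deduplicateHypotheses <- function(hyps, maxIou = 0.6) {
  if (maxIou <= 0 || maxIou >= 1)
    ptStop("maxIou must lie strictly inside (0, 1)", "invalidInput")
  if (nrow(hyps) < 2L) return(hyps)
  out <- list()
  for (f in unique(hyps$frame)) {
    hf <- hyps[hyps$frame == f, , drop = FALSE]
    hf <- hf[order(-hf$support, hf$id), , drop = FALSE]
    em <- as.matrix(hf[, c("cx", "cy", "a", "b", "theta")])
    kept <- integer(0)
    for (i in seq_len(nrow(hf))) {
      dup <- FALSE
      for (j in kept) {
        if (.ellipseIoUC(em[i, ], em[j, ], 1) > maxIou) { dup <- TRUE; break }
      }
      if (!dup) kept <- c(kept, i)
    }
    out[[length(out) + 1L]] <- hf[kept, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res <- res[order(res$frame, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Generate hypotheses for every frame of a movie
#'
#' @param maps list of [ForegroundMap-class] (one per frame).
#' @param ... passed on to [generateHypotheses()].
#' @return one hypothesis data.frame with movie-unique ids.
#' @export
generateHypothesesStack <- function(maps, ...) {
  out <- list()
  offset <- 0L
  for (m in maps) {
    hf <- generateHypotheses(m, ..., idOffset = offset)
    if (nrow(hf)) offset <- max(hf$id)
    out[[length(out) + 1L]] <- hf
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
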