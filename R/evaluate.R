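# Tracking evaluation against simulator ground truth.

#' Evaluate a tracking against ground truth
#'
#' Per frame, predicted and ground-truth ellipses are matched one-to-one
#' greedily by descending interior IoU, keeping pairs with IoU at least
#' `iouMin`. Each predicted trajectory is then given the majority
#' ground-truth label among its matches; a match counts towards the match
#' rate only if its ground-truth cell equals that majority label (identity
#' consistency). Identity switches are counted along each ground-truth
#' track as changes of the matched predicted trajectory between
#' consecutively matched frames. Centre RMSE is over all matched pairs.
#'
#' @param pred a [TrackCollection-class].
#' @param gt a [GroundTruth-class] (or a `TrackCollection` used as ground
#'   truth).
#' @param iouMin IoU threshold for a valid match.
#' @return An [EvaluationReport-class].
#' @export
evaluateTracking <- function(pred, gt, iouMin = 0.5) {
  predTab <- trackTable(pred)
  gtTab <- if (is(gt, "GroundTruth")) trackTable(gt) else {
    tt <- trackTable(gt)
    tt
  }
  frames <- sort(unique(gtTab$frame))
  matches <- list()  # per match: frame, gt id, pred id, dist
  perFrame <- data.frame(frame = frames, nGt = 0L, nPred = 0L,
                         nMatched = 0L)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    g <- gtTab[gtTab$frame == f, , drop = FALSE]
    p <- predTab[predTab$frame == f, , drop = FALSE]
    perFrame$nGt[fi] <- nrow(g)
    perFrame$nPred[fi] <- nrow(p)
    if (nrow(g) == 0L || nrow(p) == 0L) next
    iou <- matrix(0, nrow(g), nrow(p))
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(nrow(p))) {
        d2 <- (g$cx[i] - p$cx[j])^2 + (g$cy[i] - p$cy[j])^2
        if (d2 > (g$a[i] + p$a[j])^2) next
        iou[i, j] <- ellipseIoU(g[i, ], p[j, ])
      }
    }
    while (TRUE) {
      m <- which(iou == max(iou), arr.ind = TRUE)[1L, , drop = TRUE]
      if (iou[m[1L], m[2L]] < iouMin) break
      i <- m[1L]; j <- m[2L]
      matches[[length(matches) + 1L]] <- data.frame(
        frame = f, gtId = g$cell_id[i], predId = p$cell_id[j],
        dist2 = (g$cx[i] - p$cx[j])^2 + (g$cy[i] - p$cy[j])^2)
      perFrame$nMatched[fi] <- perFrame$nMatched[fi] + 1L
      iou[i, ] <- -1; iou[, j] <- -1
    }
  }
  nGtTotal <- nrow(gtTab)
  if (length(matches) == 0L)
    return(new("EvaluationReport", matchRate = 0, idSwitches = 0L,
               centreRmsePx = NA_real_, perFrame = perFrame))
  mt <- do.call(rbind, matches)
  # majority ground-truth label per predicted trajectory
  majority <- vapply(split(mt$gtId, mt$predId), function(x) {
    tt <- sort(table(x), decreasing = TRUE)
    as.numeric(names(tt)[1L])
  }, numeric(1))
  consistent <- mt$gtId == majority[as.character(mt$predId)]
  matchRate <- sum(consistent) / nGtTotal
  switches <- 0L
  for (gid in unique(mt$gtId)) {
    sub <- mt[mt$gtId == gid, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (nrow(sub) > 1L)
      switches <- switches + sum(diff(as.numeric(factor(sub$predId))) != 0)
  }
  new("EvaluationReport", matchRate = matchRate,
      idSwitches = as.integer(switches),
      centreRmsePx = sqrt(mean(mt$dist2)), perFrame = perFrame)
}

#' Run the full pipeline on a simulated movie
#'
#' `simulate -> segment -> detect -> track -> decide`: the study-condition
#' pipeline used for validation. Stages can be tuned via the arguments;
#' defaults are the package defaults of each stage.
#'
#' @param cfg a [SimConfig-class].
#' @param params a [MrfParams-class].
#' @param mm a [MotionModel-class].
#' @param prior a [CollectionPrior-class].
#' @param tau detection threshold.
#' @param minAxis,maxAxis hypothesis axis bounds (px); `NULL` sizes them
#'   from the configured mean cell radius.
#' @param nIter sampler iterations.
#' @param burnIn burn-in fraction for the Bayes decision.
#' @param seed tracking seed (the simulation uses `cfg@seed`).
#' @param verbose progress messages.
#' @return list with `gt`, `stack`, `maps`, `hyps`, `post`, `decided`
#'   ([TrackCollection-class]) and `report` ([EvaluationReport-class]).
#' @export
runPipeline <- function(cfg = SimConfig(), params = MrfParams(),
                        mm = MotionModel(), prior = CollectionPrior(),
                        tau = 0.88, minAxis = NULL, maxAxis = NULL,
                        nIter = 8000, burnIn = 0.3, seed = cfg@seed,
                        verbose = FALSE) {
  gt <- simulateTracks(cfg)
  stack <- renderPhaseContrast(gt, cfg)
  r0 <- sqrt(cfg@coverage * prod(cfg@fieldSize) / (pi * cfg@nCells))
  if (is.null(minAxis)) minAxis <- max(2, 0.35 * r0)
  # the largest admissible semi-major axis must cover fully elongated cells
  if (is.null(maxAxis))
    maxAxis <- 1.5 * r0 * max(1.2, cfg@elongationRate^cfg@nFrames)
  maps <- segmentStack(stack, params, verbose = verbose)
  hyps <- generateHypothesesStack(maps, tau = tau, minAxis = minAxis,
                                  maxAxis = maxAxis)
  init <- greedyLinkCollection(hyps)
  post <- samplePosterior(hyps, mm, prior, nIter = nIter, seed = seed,
                          init = init, thin = max(1L, nIter %/% 2000L),
                          verbose = verbose)
  decided <- bayesDecision(post, hyps, mm, prior, burnIn = burnIn)
  report <- evaluateTracking(decided, gt)
  list(gt = gt, stack = stack, maps = maps, hyps = hyps, post = post,
       decided = decided, report = report)
}
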