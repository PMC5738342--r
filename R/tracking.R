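# Joint probabilistic model over collections of interacting trajectories.
# A trajectory is a temporally contiguous sequence of blob hypotheses scored
# by a Markov chain with a constant-velocity motion model and smooth shape
# change; trajectories interact through a same-frame non-overlap penalty.
# Collections are explored by Metropolis-Hastings over structural moves and
# the final tracking is a Bayes-risk decision on posterior link marginals.
#
# Internally a collection is a plain list of trajectories, each
# list(t0 = first frame, ids = hypothesis ids over consecutive frames).

#' Log-density of one trajectory transition
#'
#' Scores the step from a predicted state to the next ellipse: isotropic
#' Gaussian on the deviation of the next centre from the constant-velocity
#' prediction (`position + velocity`), Gaussians on the changes of
#' `log a` and `log b`, and a wrapped Gaussian (period pi) on the
#' orientation change.
#'
#' @param position,velocity numeric(2), current centre and velocity
#'   (px, px/frame).
#' @param logAxes numeric(2), current `c(log a, log b)`.
#' @param theta current orientation (radians).
#' @param nextEllipse an [Ellipse-class] (or list with `cx`, `cy`, `a`, `b`,
#'   `theta`).
#' @param mm a [MotionModel-class].
#' @param posInflation multiplier on `sigmaPos` (used for the first
#'   transition of a trajectory, where no velocity estimate exists yet).
#' @return numeric(1) log-density; symmetric in the sign of each deviation.
#' @export
transitionLogProb <- function(position, velocity, logAxes, theta,
                              nextEllipse, mm, posInflation = 1) {
  e <- nextEllipse
  ecx <- if (is(e, "Ellipse")) e@cx else e[["cx"]]
  ecy <- if (is(e, "Ellipse")) e@cy else e[["cy"]]
  ea <- if (is(e, "Ellipse")) e@a else e[["a"]]
  eb <- if (is(e, "Ellipse")) e@b else e[["b"]]
  eth <- if (is(e, "Ellipse")) e@theta else e[["theta"]]
  sp <- mm@sigmaPos * posInflation
  dx <- ecx - (position[1L] + velocity[1L])
  dy <- ecy - (position[2L] + velocity[2L])
  out <- stats::dnorm(dx, 0, sp, log = TRUE) +
    stats::dnorm(dy, 0, sp, log = TRUE) +
    stats::dnorm(log(ea) - logAxes[1L], 0, mm@sigmaShape, log = TRUE) +
    stats::dnorm(log(eb) - logAxes[2L], 0, mm@sigmaShape, log = TRUE) +
    logWrappedNorm(axialDiff(eth - theta), mm@sigmaTheta)
  out
}

# wrapped Gaussian log-density on orientations (period pi), 7-term wrap sum
logWrappedNorm <- function(d, sigma, period = pi) {
  k <- -3:3
  log(rowSums(outer(d, k, function(dd, kk)
    stats::dnorm(dd + kk * period, 0, sigma))))
}

# ---- fast internal scoring on the hypothesis table -------------------------

# hypothesis lookup environment: vectors indexed by row, id -> row map
hypIndex <- function(hyps) {
  list(id = hyps$id, frame = as.integer(hyps$frame), cx = hyps$cx,
       cy = hyps$cy, a = hyps$a, b = hyps$b, theta = hyps$theta,
       support = hyps$support, row = function(ids) match(ids, hyps$id))
}

# trajectory log-score from row indices into the hypothesis table
trajScoreRows <- function(rows, hx, mm, prior) {
  n <- length(rows)
  s <- prior@logBirth + prior@logDeath +
    sum(log(hx$support[rows])) + n * prior@logCoverage
  if (n >= 2L) {
    cx <- hx$cx[rows]; cy <- hx$cy[rows]
    la <- log(hx$a[rows]); lb <- log(hx$b[rows]); th <- hx$theta[rows]
    # predicted velocity: zero for the first transition, previous
    # displacement afterwards
    predvx <- c(0, diff(cx))[seq_len(n - 1L)]
    predvy <- c(0, diff(cy))[seq_len(n - 1L)]
    dx <- cx[-1L] - (cx[-n] + predvx)
    dy <- cy[-1L] - (cy[-n] + predvy)
    infl <- c(2, rep(1, n - 2L))
    sp <- mm@sigmaPos * infl
    s <- s + sum(stats::dnorm(dx, 0, sp, log = TRUE) +
                   stats::dnorm(dy, 0, sp, log = TRUE) +
                   stats::dnorm(diff(la), 0, mm@sigmaShape, log = TRUE) +
                   stats::dnorm(diff(lb), 0, mm@sigmaShape, log = TRUE) +
                   logWrappedNorm(axialDiff(diff(th)), mm@sigmaTheta))
  }
  s
}

#' Log-score of a single trajectory
#'
#' `logBirth + logDeath + sum(transitions) + sum(log support + logCoverage)`
#' over the trajectory's elements. The velocity entering each
#' constant-velocity prediction is the previous observed displacement; the
#' first transition uses zero velocity with `sigmaPos` inflated by 2.
#'
#' @param traj list with `t0` (first frame) and `ids` (hypothesis ids over
#'   consecutive frames), or a vector of hypothesis ids.
#' @param hyps hypothesis data.frame (see [generateHypotheses()]).
#' @param mm a [MotionModel-class].
#' @param prior a [CollectionPrior-class].
#' @return numeric(1).
#' @export
trajectoryLogScore <- function(traj, hyps, mm, prior) {
  ids <- if (is.list(traj)) traj$ids else traj
  rows <- match(ids, hyps$id)
  if (any(is.na(rows)))
    ptStop(sprintf("unknown hypothesis id(s): %s",
                   paste(ids[is.na(rows)], collapse = ", ")),
           "invalidReference")
  if (length(rows) > 1L && any(diff(hyps$frame[rows]) != 1L))
    ptStop("trajectory frames must be strictly consecutive", "invalidInput")
  trajScoreRows(rows, hypIndex(hyps), mm, prior)
}

# overlap penalty of one ellipse (hyps row r) against hyps rows `others`
# in the same frame; returns penalty (>= 0), Inf for hard violation
overlapPenaltyRow <- function(r, others, hx, kappa) {
  if (kappa == 0 || length(others) == 0L) return(0)
  pen <- 0
  e1 <- list(cx = hx$cx[r], cy = hx$cy[r], a = hx$a[r], b = hx$b[r],
             theta = hx$theta[r])
  for (o in others) {
    d2 <- (hx$cx[o] - e1$cx)^2 + (hx$cy[o] - e1$cy)^2
    if (d2 > (hx$a[o] + e1$a)^2) next
    ov <- ellipseOverlapArea(e1, list(cx = hx$cx[o], cy = hx$cy[o],
                                      a = hx$a[o], b = hx$b[o],
                                      theta = hx$theta[o]))
    if (ov > 0) {
      if (is.infinite(kappa)) return(Inf)
      pen <- pen + kappa * ov
    }
  }
  pen
}

#' Joint log-score of a trajectory collection
#'
#' Sum of [trajectoryLogScore()] over trajectories minus
#' `kappaOverlap * overlap area` summed over all same-frame trajectory
#' pairs; `-Inf` when `kappaOverlap = Inf` and any same-frame interiors
#' overlap. The hypothesis-to-trajectory assignment must be injective.
#'
#' @param collection list of trajectories (`list(t0, ids)`), or a
#'   [TrackCollection-class] whose `hyp` column references `hyps`.
#' @inheritParams trajectoryLogScore
#' @return numeric(1); `0` for the empty collection.
#' @export
collectionLogScore <- function(collection, hyps, mm, prior) {
  coll <- asCollList(collection)
  if (length(coll) == 0L) return(0)
  allIds <- unlist(lapply(coll, `[[`, "ids"))
  if (anyDuplicated(allIds))
    ptStop("hypothesis assigned to more than one trajectory",
           "invalidCollection")
  hx <- hypIndex(hyps)
  s <- sum(vapply(coll, function(tr) {
    rows <- match(tr$ids, hyps$id)
    if (any(is.na(rows)))
      ptStop("unknown hypothesis id in collection", "invalidReference")
    trajScoreRows(rows, hx, mm, prior)
  }, numeric(1)))
  if (prior@kappaOverlap > 0) {
    byFrame <- split(match(allIds, hyps$id), hx$frame[match(allIds, hyps$id)])
    for (rows in byFrame) {
      if (length(rows) < 2L) next
      for (i in seq_len(length(rows) - 1L)) {
        pen <- overlapPenaltyRow(rows[i], rows[(i + 1L):length(rows)], hx,
                                 prior@kappaOverlap)
        if (is.infinite(pen)) return(-Inf)
        s <- s - pen
      }
    }
  }
  s
}

asCollList <- function(collection) {
  if (is(collection, "TrackCollection")) {
    lapply(collection@trajectories, function(tr)
      list(t0 = tr$frame[1L], ids = tr$hyp))
  } else collection
}

# ---- structural moves ------------------------------------------------------

moveKinds <- c("birth", "death", "extend", "truncate", "switch")
defaultMoveWeights <- c(birth = 0.2, death = 0.2, extend = 0.25,
                        truncate = 0.15, switch = 0.2)

#' Propose a structural move on a trajectory collection
#'
#' One reversible structural change: `birth` starts a singleton trajectory
#' on a free hypothesis; `death` removes a singleton; `extend` appends a
#' free hypothesis at either trajectory end; `truncate` removes an end
#' element; `switch` swaps the tails of two trajectories after a frame in
#' which both are alive. The returned log proposal ratio
#' `log q(x | x') - log q(x' | x)` makes the mixture reversible for
#' Metropolis-Hastings. An inapplicable kind yields a flagged no-op, not an
#' error.
#'
#' @param collection list of trajectories (`list(t0, ids)`).
#' @param hyps hypothesis data.frame.
#' @param kind one of `"birth"`, `"death"`, `"extend"`, `"truncate"`,
#'   `"switch"`.
#' @param weights move-mixture weights (named as `moveKinds`).
#' @param assigned optional logical vector over `hyps` rows (which
#'   hypotheses are already used); computed when `NULL`.
#' @return list with `collection` (candidate), `logQRatio`, `applicable`,
#'   and `changed` (indices of replaced trajectories, for incremental
#'   scoring).
#' @export
proposeMove <- function(collection, hyps, kind,
                        weights = defaultMoveWeights, assigned = NULL) {
  kind <- match.arg(kind, moveKinds)
  if (is.null(assigned)) {
    used <- unlist(lapply(collection, `[[`, "ids"))
    assigned <- hyps$id %in% used
  }
  noop <- list(collection = collection, logQRatio = 0, applicable = FALSE,
               changed = list(removed = integer(0), added = list()))
  nTraj <- length(collection)
  frames <- as.integer(hyps$frame)
  frange <- if (nrow(hyps)) range(frames) else c(0L, -1L)
  lens <- if (nTraj) vapply(collection, function(tr) length(tr$ids),
                            integer(1)) else integer(0)

  if (kind == "birth") {
    freeRows <- which(!assigned)
    if (length(freeRows) == 0L) return(noop)
    r <- freeRows[sampleInt(length(freeRows))]
    newTraj <- list(t0 = frames[r], ids = hyps$id[r])
    cand <- c(collection, list(newTraj))
    nSingl2 <- sum(lens == 1L) + 1L
    lq <- (log(weights[["death"]]) - log(nSingl2)) -
      (log(weights[["birth"]]) - log(length(freeRows)))
    return(list(collection = cand, logQRatio = lq, applicable = TRUE,
                changed = list(removed = integer(0), added = list(newTraj))))
  }

  if (kind == "death") {
    singl <- which(lens == 1L)
    if (length(singl) == 0L) return(noop)
    i <- singl[sampleInt(length(singl))]
    cand <- collection[-i]
    nFree2 <- sum(!assigned) + 1L
    lq <- (log(weights[["birth"]]) - log(nFree2)) -
      (log(weights[["death"]]) - log(length(singl)))
    return(list(collection = cand, logQRatio = lq, applicable = TRUE,
                changed = list(removed = i, added = list())))
  }

  if (kind == "extend") {
    if (nTraj == 0L) return(noop)
    i <- sampleInt(nTraj)
    atHead <- stats::runif(1) < 0.5
    tr <- collection[[i]]
    tf <- if (atHead) tr$t0 - 1L else tr$t0 + length(tr$ids)
    if (tf < frange[1L] || tf > frange[2L]) return(noop)
    avail <- which(!assigned & frames == tf)
    if (length(avail) == 0L) return(noop)
    r <- avail[sampleInt(length(avail))]
    tr2 <- if (atHead) list(t0 = tf, ids = c(hyps$id[r], tr$ids))
           else list(t0 = tr$t0, ids = c(tr$ids, hyps$id[r]))
    cand <- collection; cand[[i]] <- tr2
    lq <- log(weights[["truncate"]]) - log(weights[["extend"]]) +
      log(length(avail))
    return(list(collection = cand, logQRatio = lq, applicable = TRUE,
                changed = list(removed = i, added = list(tr2))))
  }

  if (kind == "truncate") {
    if (nTraj == 0L) return(noop)
    i <- sampleInt(nTraj)
    tr <- collection[[i]]
    if (length(tr$ids) < 2L) return(noop)
    atHead <- stats::runif(1) < 0.5
    n <- length(tr$ids)
    tf <- if (atHead) tr$t0 else tr$t0 + n - 1L
    tr2 <- if (atHead) list(t0 = tr$t0 + 1L, ids = tr$ids[-1L])
           else list(t0 = tr$t0, ids = tr$ids[-n])
    cand <- collection; cand[[i]] <- tr2
    nAvail2 <- sum(!assigned & frames == tf) + 1L
    lq <- log(weights[["extend"]]) - log(weights[["truncate"]]) -
      log(nAvail2)
    return(list(collection = cand, logQRatio = lq, applicable = TRUE,
                changed = list(removed = i, added = list(tr2))))
  }

  # switch: swap tails of trajectories i and j after frame t, where both are
  # alive in frames t and t + 1
  opts <- switchOptions(collection, lens)
  if (nrow(opts) == 0L) return(noop)
  k <- sampleInt(nrow(opts))
  i <- opts$i[k]; j <- opts$j[k]
  ti <- collection[[i]]; tj <- collection[[j]]
  t <- opts$l[k] + sampleInt(opts$n[k]) - 1L  # uniform t in [l, u-1]
  cutI <- t - ti$t0 + 1L
  cutJ <- t - tj$t0 + 1L
  newI <- list(t0 = ti$t0, ids = c(ti$ids[seq_len(cutI)],
                                   tj$ids[-seq_len(cutJ)]))
  newJ <- list(t0 = tj$t0, ids = c(tj$ids[seq_len(cutJ)],
                                   ti$ids[-seq_len(cutI)]))
  cand <- collection
  cand[[i]] <- newI; cand[[j]] <- newJ
  lens2 <- lens
  lens2[i] <- length(newI$ids); lens2[j] <- length(newJ$ids)
  n2 <- sum(switchOptions(cand, lens2)$n)
  lq <- log(sum(opts$n)) - log(n2)
  list(collection = cand, logQRatio = lq, applicable = TRUE,
       changed = list(removed = c(i, j), added = list(newI, newJ)))
}

# enumerate switch-move options: pairs (i < j) with overlap interval
# [l, u] of length >= 2 in frames; n = number of valid cut frames
switchOptions <- function(collection, lens) {
  nTraj <- length(collection)
  out <- list(i = integer(0), j = integer(0), l = integer(0), n = integer(0))
  if (nTraj >= 2L) {
    t0 <- vapply(collection, `[[`, integer(1), "t0")
    t1 <- t0 + lens - 1L
    for (i in seq_len(nTraj - 1L)) {
      for (j in (i + 1L):nTraj) {
        l <- max(t0[i], t0[j]); u <- min(t1[i], t1[j])
        if (u - l >= 1L) {
          out$i <- c(out$i, i); out$j <- c(out$j, j)
          out$l <- c(out$l, l); out$n <- c(out$n, u - l)
        }
      }
    }
  }
  as.data.frame(out)
}

sampleInt <- function(n) {
  if (n == 1L) 1L else as.integer(floor(stats::runif(1) * n)) + 1L
}

# ---- posterior sampling ----------------------------------------------------

#' Sample trajectory collections from the joint model
#'
#' Metropolis-Hastings over the structural moves of [proposeMove()]: a move
#' kind is drawn from the mixture, the candidate is accepted with
#' probability `min(1, exp(delta score + log proposal ratio))`. Scoring is
#' incremental (only replaced trajectories and the affected same-frame
#' overlap terms are re-evaluated). The chain is reproducible given `seed`.
#'
#' @param hyps hypothesis data.frame.
#' @param mm a [MotionModel-class].
#' @param prior a [CollectionPrior-class].
#' @param nIter number of iterations (`>= 1`).
#' @param seed integer seed.
#' @param init optional initial collection (list of `list(t0, ids)`), e.g.
#'   from [greedyLinkCollection()]; empty by default.
#' @param thin record the state every `thin` iterations.
#' @param weights move-mixture weights.
#' @param verbose progress messages to stderr every 5000 iterations.
#' @return list with `samples` (each `list(collection, iteration, accepted,
#'   logScore)`), `best` (highest-scoring visited collection), `bestScore`,
#'   `acceptRate` and `nIter`.
#' @export
samplePosterior <- function(hyps, mm, prior, nIter, seed = 1L, init = NULL,
                            thin = 1L, weights = defaultMoveWeights,
                            verbose = FALSE) {
  if (nIter < 1L) ptStop("nIter must be >= 1", "invalidInput")
  set.seed(as.integer(seed))
  hx <- hypIndex(hyps)
  frames <- as.integer(hyps$frame)

  coll <- if (is.null(init)) list() else init
  assigned <- hyps$id %in% unlist(lapply(coll, `[[`, "ids"))
  trajScores <- vapply(coll, function(tr)
    trajScoreRows(match(tr$ids, hyps$id), hx, mm, prior), numeric(1))
  overlapPen <- totalOverlapPenalty(coll, hyps, hx, prior@kappaOverlap)
  score <- sum(trajScores) - overlapPen

  best <- coll; bestScore <- score
  samples <- vector("list", nIter %/% thin + 1L)
  nSamp <- 0L
  nAcc <- 0L
  wts <- weights[moveKinds] / sum(weights[moveKinds])

  for (it in seq_len(nIter)) {
    kind <- moveKinds[findInterval(stats::runif(1), cumsum(wts)) + 1L]
    prop <- proposeMove(coll, hyps, kind, weights = wts, assigned = assigned)
    accepted <- FALSE
    if (prop$applicable) {
      removed <- prop$changed$removed
      added <- prop$changed$added
      dTraj <- 0
      addScores <- numeric(0)
      if (length(added)) {
        addScores <- vapply(added, function(tr)
          trajScoreRows(match(tr$ids, hyps$id), hx, mm, prior), numeric(1))
        dTraj <- dTraj + sum(addScores)
      }
      if (length(removed)) dTraj <- dTraj - sum(trajScores[removed])
      dPen <- overlapDelta(kind, coll, prop$collection, prop$changed, hyps,
                           hx, prior@kappaOverlap)
      delta <- dTraj - dPen
      if (is.finite(delta) || delta == -Inf) {
        if (log(stats::runif(1)) < delta + prop$logQRatio) {
          # apply
          oldIds <- unlist(lapply(coll[removed], `[[`, "ids"))
          coll <- prop$collection
          if (kind == "death") {
            trajScores <- trajScores[-removed]
          } else if (length(removed)) {
            trajScores[removed] <- addScores
          } else {
            trajScores <- c(trajScores, addScores)
          }
          newIds <- unlist(lapply(added, `[[`, "ids"))
          if (length(oldIds)) assigned[match(oldIds, hyps$id)] <- FALSE
          if (length(newIds)) assigned[match(newIds, hyps$id)] <- TRUE
          overlapPen <- overlapPen + dPen
          score <- score + delta
          accepted <- TRUE
          nAcc <- nAcc + 1L
          if (score > bestScore) { best <- coll; bestScore <- score }
        }
      }
    }
    if (it %% thin == 0L) {
      nSamp <- nSamp + 1L
      samples[[nSamp]] <- list(collection = coll, iteration = it,
                               accepted = accepted, logScore = score)
    }
    if (verbose && it %% 5000L == 0L)
      message(sprintf("[track] iteration %d / %d, logScore %.2f, accept %.2f",
                      it, nIter, score, nAcc / it))
  }
  list(samples = samples[seq_len(nSamp)], best = best, bestScore = bestScore,
       acceptRate = nAcc / nIter, nIter = nIter)
}

totalOverlapPenalty <- function(coll, hyps, hx, kappa) {
  if (kappa == 0 || length(coll) < 2L) return(0)
  allRows <- match(unlist(lapply(coll, `[[`, "ids")), hyps$id)
  pen <- 0
  byFrame <- split(allRows, hx$frame[allRows])
  for (rows in byFrame) {
    if (length(rows) < 2L) next
    for (i in seq_len(length(rows) - 1L)) {
      p <- overlapPenaltyRow(rows[i], rows[(i + 1L):length(rows)], hx, kappa)
      if (is.infinite(p)) return(Inf)
      pen <- pen + p
    }
  }
  pen
}

# change of the overlap penalty caused by one structural move; only the
# ellipses added/removed in their frames need to be checked (a switch leaves
# the per-frame ellipse sets unchanged)
overlapDelta <- function(kind, coll, cand, changed, hyps, hx, kappa) {
  if (kappa == 0 || kind == "switch") return(0)
  delta <- 0
  if (kind %in% c("birth", "extend")) {
    tr <- changed$added[[1L]]
    old <- if (length(changed$removed)) coll[[changed$removed[1L]]] else NULL
    newIds <- if (is.null(old)) tr$ids else setdiff(tr$ids, old$ids)
    for (idNew in newIds) {
      r <- match(idNew, hyps$id)
      f <- hx$frame[r]
      others <- aliveRowsInFrame(coll, hyps, hx, f)
      p <- overlapPenaltyRow(r, others, hx, kappa)
      if (is.infinite(p)) return(Inf)
      delta <- delta + p
    }
  } else { # death, truncate: an ellipse disappears
    old <- coll[[changed$removed[1L]]]
    newTr <- if (length(changed$added)) changed$added[[1L]] else NULL
    gone <- if (is.null(newTr)) old$ids else setdiff(old$ids, newTr$ids)
    collWithout <- coll[-changed$removed[1L]]
    if (!is.null(newTr)) collWithout <- c(collWithout, list(newTr))
    for (idGone in gone) {
      r <- match(idGone, hyps$id)
      f <- hx$frame[r]
      others <- aliveRowsInFrame(collWithout, hyps, hx, f)
      p <- overlapPenaltyRow(r, others, hx, kappa)
      # removing cannot create a hard violation; Inf here means the current
      # state was already infeasible, which the sampler never enters
      delta <- delta - p
    }
  }
  delta
}

aliveRowsInFrame <- function(coll, hyps, hx, f) {
  ids <- integer(0)
  for (tr in coll) {
    k <- f - tr$t0 + 1L
    if (k >= 1L && k <= length(tr$ids)) ids <- c(ids, tr$ids[k])
  }
  match(ids, hyps$id)
}

# ---- decision and summaries ------------------------------------------------

#' Bayes-risk decision from posterior samples
#'
#' Under a symmetric 0-1 loss on every possible link (hypothesis at frame t
#' followed by hypothesis at frame t+1) and every possible inclusion, the
#' risk-minimising decision keeps exactly the events whose marginal
#' posterior frequency over the post-burn-in samples exceeds 0.5. Links are
#' assembled into contiguous trajectories greedily by descending frequency
#' (each hypothesis at most one incoming and one outgoing link); retained
#' inclusions not covered by any link become singleton trajectories.
#'
#' @param post result of [samplePosterior()].
#' @param hyps hypothesis data.frame.
#' @param mm,prior model parameters used to score the decided collection.
#' @param burnIn fraction of iterations discarded as burn-in.
#' @return A [TrackCollection-class].
#' @export
bayesDecision <- function(post, hyps, mm, prior, burnIn = 0.3) {
  iters <- vapply(post$samples, `[[`, numeric(1), "iteration")
  keep <- iters > burnIn * post$nIter
  if (!any(keep))
    ptStop("no post-burn-in samples available", "invalidInput")
  samp <- post$samples[keep]
  nS <- length(samp)

  linkCount <- new.env(hash = TRUE, parent = emptyenv())
  inclCount <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(env, keys) {
    for (k in keys) {
      v <- env[[k]]
      env[[k]] <- if (is.null(v)) 1L else v + 1L
    }
  }
  for (s in samp) {
    links <- character(0); incls <- character(0)
    for (tr in s$collection) {
      ids <- tr$ids
      incls <- c(incls, as.character(ids))
      if (length(ids) >= 2L)
        links <- c(links, paste(ids[-length(ids)], ids[-1L], sep = ">"))
    }
    bump(linkCount, unique(links))
    bump(inclCount, unique(incls))
  }

  linkKeys <- ls(linkCount)
  linkFreq <- vapply(linkKeys, function(k) linkCount[[k]] / nS, numeric(1))
  selLinks <- linkKeys[linkFreq > 0.5]
  selFreq <- linkFreq[linkFreq > 0.5]
  ord <- order(-selFreq)
  outUsed <- new.env(hash = TRUE, parent = emptyenv())
  inUsed <- new.env(hash = TRUE, parent = emptyenv())
  nextOf <- new.env(hash = TRUE, parent = emptyenv())
  hasPrev <- new.env(hash = TRUE, parent = emptyenv())
  for (k in ord) {
    ab <- strsplit(selLinks[k], ">", fixed = TRUE)[[1L]]
    if (is.null(outUsed[[ab[1L]]]) && is.null(inUsed[[ab[2L]]])) {
      outUsed[[ab[1L]]] <- TRUE
      inUsed[[ab[2L]]] <- TRUE
      nextOf[[ab[1L]]] <- ab[2L]
      hasPrev[[ab[2L]]] <- TRUE
    }
  }
  # chain heads: linked ids with no accepted incoming link
  heads <- setdiff(ls(nextOf), ls(hasPrev))
  trajIds <- list()
  covered <- character(0)
  for (hd in heads) {
    chain <- hd
    cur <- hd
    while (!is.null(nextOf[[cur]])) {
      cur <- nextOf[[cur]]
      chain <- c(chain, cur)
    }
    trajIds[[length(trajIds) + 1L]] <- as.integer(chain)
    covered <- c(covered, chain)
  }
  inclKeys <- ls(inclCount)
  inclFreq <- vapply(inclKeys, function(k) inclCount[[k]] / nS, numeric(1))
  singles <- setdiff(inclKeys[inclFreq > 0.5], covered)
  for (sg in singles) trajIds[[length(trajIds) + 1L]] <- as.integer(sg)

  coll <- lapply(trajIds, function(ids) {
    rows <- match(ids, hyps$id)
    list(t0 = as.integer(hyps$frame[rows[1L]]), ids = ids)
  })
  score <- collectionLogScore(coll, hyps, mm, prior)
  asTrackCollection(coll, hyps, score)
}

#' Materialise an internal collection as a TrackCollection
#'
#' @param collection list of `list(t0, ids)` trajectories.
#' @param hyps hypothesis data.frame.
#' @param logScore joint log-score to record.
#' @return A [TrackCollection-class].
#' @export
asTrackCollection <- function(collection, hyps, logScore = NA_real_) {
  trs <- lapply(collection, function(tr) {
    rows <- match(tr$ids, hyps$id)
    data.frame(frame = tr$t0 + seq_along(tr$ids) - 1L, hyp = tr$ids,
               cx = hyps$cx[rows], cy = hyps$cy[rows], a = hyps$a[rows],
               b = hyps$b[rows], theta = hyps$theta[rows])
  })
  TrackCollection(trs, logScore)
}

#' Average number of tracked cells over a frame range
#'
#' Mean over the frames of the number of trajectories alive in each frame;
#' the summary statistic reported for monolayer movies in which cells may
#' enter or leave the field.
#'
#' @param collection a [TrackCollection-class] (or internal collection
#'   list).
#' @param frameRange integer vector of 0-based frames.
#' @return numeric(1); `0` for an empty collection.
#' @export
averageTrackedCells <- function(collection, frameRange) {
  if (length(frameRange) == 0L)
    ptStop("frameRange must be non-empty", "invalidInput")
  coll <- asCollList(collection)
  if (length(coll) == 0L) return(0)
  t0 <- vapply(coll, `[[`, integer(1), "t0")
  t1 <- t0 + vapply(coll, function(tr) length(tr$ids), integer(1)) - 1L
  mean(vapply(frameRange, function(f) sum(t0 <= f & f <= t1), numeric(1)))
}

#' Greedy frame-to-frame initial collection
#'
#' A deterministic warm start for the sampler: hypotheses of each frame are
#' assigned to the constant-velocity predictions of active tracks greedily
#' by distance (within `gate` px); unassigned hypotheses start new tracks;
#' unmatched tracks terminate.
#'
#' @param hyps hypothesis data.frame.
#' @param gate gating distance in px.
#' @return list of `list(t0, ids)` trajectories.
#' @export
greedyLinkCollection <- function(hyps, gate = 15) {
  if (nrow(hyps) == 0L) return(list())
  frames <- sort(unique(as.integer(hyps$frame)))
  active <- list()  # each: list(t0, ids, pos, vel)
  done <- list()
  for (f in frames) {
    hf <- hyps[hyps$frame == f, , drop = FALSE]
    nA <- length(active)
    matched <- rep(FALSE, nrow(hf))
    if (nA > 0L && nrow(hf) > 0L) {
      pred <- t(vapply(active, function(a) a$pos + a$vel, numeric(2)))
      d <- sqrt(outer(pred[, 1L], hf$cx, `-`)^2 +
                  outer(pred[, 2L], hf$cy, `-`)^2)
      used <- rep(FALSE, nA)
      repeat {
        m <- which(d == min(d), arr.ind = TRUE)[1L, ]
        if (d[m[1L], m[2L]] > gate) break
        i <- m[1L]; j <- m[2L]
        a <- active[[i]]
        newPos <- c(hf$cx[j], hf$cy[j])
        a$vel <- newPos - a$pos
        a$pos <- newPos
        a$ids <- c(a$ids, hf$id[j])
        active[[i]] <- a
        used[i] <- TRUE; matched[j] <- TRUE
        d[i, ] <- Inf; d[, j] <- Inf
        if (all(used) || all(matched)) break
      }
      if (any(!used)) {
        done <- c(done, lapply(active[!used], function(a)
          list(t0 = a$t0, ids = a$ids)))
        active <- active[used]
      }
    } else if (nA > 0L) {
      done <- c(done, lapply(active, function(a) list(t0 = a$t0, ids = a$ids)))
      active <- list()
    }
    for (j in which(!matched)) {
      active[[length(active) + 1L]] <-
        list(t0 = f, ids = hf$id[j], pos = c(hf$cx[j], hf$cy[j]),
             vel = c(0, 0))
    }
  }
  c(done, lapply(active, function(a) list(t0 = a$t0, ids = a$ids)))
}
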