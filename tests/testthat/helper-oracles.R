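# Independent oracles used by the tests. These deliberately re-derive
# quantities by brute force (enumeration, literal re-summation, dense
# pixel counting) without touching the implementation paths they check.

# Exhaustive Gibbs marginals of the binary MRF on a tiny frame by
# enumerating all 2^(H*W) labellings and Boltzmann-weighting their
# energies (energies via mrfEnergy, the quantity under test being the
# *marginal approximation*, not the energy, which has its own
# re-summation oracle below).
oracleEnumMarginals <- function(frame, cliques, params, unary) {
  h <- nrow(frame); w <- ncol(frame); np <- h * w
  stopifnot(np <= 16L)
  L <- matrix(0, 2^np, np)
  for (p in seq_len(np))
    L[, p] <- bitwAnd(seq_len(2^np) - 1L, bitwShiftL(1L, p - 1L)) > 0
  eU <- params@unaryScale *
    (L %*% as.vector(unary$u1) + (1 - L) %*% as.vector(unary$u0))
  idx <- matrix(seq_len(np), h, w)
  pairs <- rbind(
    cbind(as.vector(idx[-h, , drop = FALSE]), as.vector(idx[-1, , drop = FALSE])),
    cbind(as.vector(idx[, -w, drop = FALSE]), as.vector(idx[, -1, drop = FALSE])))
  eP <- numeric(2^np)
  for (k in seq_len(nrow(pairs)))
    eP <- eP + (L[, pairs[k, 1L]] != L[, pairs[k, 2L]])
  eP <- params@beta * eP
  eH <- numeric(2^np)
  if (params@gammaMax > 0) {
    cvec <- as.vector(cliques)
    for (ci in unique(cvec)) {
      mem <- which(cvec == ci); n <- length(mem)
      fg <- rowSums(L[, mem, drop = FALSE])
      m <- pmin(fg, n - fg)
      eH <- eH + pmin(params@gammaMax,
                      params@gammaMax * m / (params@truncationQ * n))
    }
  }
  lw <- -(eU + eP + eH) / params@temperature
  wgt <- exp(lw - max(lw)); wgt <- wgt / sum(wgt)
  matrix(colSums(L * as.vector(wgt)), h, w)
}

# Literal term-by-term re-summation of the MRF energy with plain loops.
oracleEnergyNaive <- function(labels, unary, cliques, params) {
  h <- nrow(labels); w <- ncol(labels)
  e <- 0
  for (r in seq_len(h)) for (c in seq_len(w)) {
    e <- e + params@unaryScale *
      if (labels[r, c] == 1) unary$u1[r, c] else unary$u0[r, c]
    if (r < h && labels[r, c] != labels[r + 1, c]) e <- e + params@beta
    if (c < w && labels[r, c] != labels[r, c + 1]) e <- e + params@beta
  }
  for (ci in unique(as.vector(cliques))) {
    sel <- cliques == ci
    n <- sum(sel)
    m <- min(sum(labels[sel]), n - sum(labels[sel]))
    e <- e + min(params@gammaMax,
                 params@gammaMax * m / (params@truncationQ * n))
  }
  e
}

# Mean map value over ellipse-interior pixel centres by direct counting.
oracleSupport <- function(probs, cx, cy, a, b, theta) {
  h <- nrow(probs); w <- ncol(probs)
  tot <- 0; n <- 0
  for (x in max(0, floor(cx - a)):min(w - 1, ceiling(cx + a))) {
    for (y in max(0, floor(cy - a)):min(h - 1, ceiling(cy + a))) {
      dx <- x - cx; dy <- y - cy
      u <- (dx * cos(theta) + dy * sin(theta)) / a
      v <- (-dx * sin(theta) + dy * cos(theta)) / b
      if (u * u + v * v <= 1) { tot <- tot + probs[y + 1, x + 1]; n <- n + 1 }
    }
  }
  if (n == 0) NA_real_ else tot / n
}

# Dense-grid overlap area of two ellipse interiors (px^2).
oracleOverlapArea <- function(e1, e2, step = 0.5) {
  x0 <- floor(min(e1$cx - e1$a, e2$cx - e2$a))
  x1 <- ceiling(max(e1$cx + e1$a, e2$cx + e2$a))
  y0 <- floor(min(e1$cy - e1$a, e2$cy - e2$a))
  y1 <- ceiling(max(e1$cy + e1$a, e2$cy + e2$a))
  xs <- seq(x0, x1, by = step); ys <- seq(y0, y1, by = step)
  x <- rep(xs, each = length(ys)); y <- rep(ys, times = length(xs))
  ins <- function(e) {
    dx <- x - e$cx; dy <- y - e$cy
    u <- (dx * cos(e$theta) + dy * sin(e$theta)) / e$a
    v <- (-dx * sin(e$theta) + dy * cos(e$theta)) / e$b
    u * u + v * v <= 1
  }
  sum(ins(e1) & ins(e2)) * step^2
}

# Reference 8-connected flood fill (queue-based), independent of the
# package's labelling code.
oracleFloodLabel <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      r <- ((p - 1L) %% h) + 1L; c <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
          q <- (c2 - 1L) * h + r2
          if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

# ---- exhaustive trajectory-collection enumeration --------------------------

# All collections of disjoint contiguous trajectories over a small
# hypothesis table (frames 0-based and consecutive).
oracleEnumerateCollections <- function(hyps) {
  frames <- sort(unique(hyps$frame))
  trajs <- list()
  for (t0 in frames) for (t1 in frames[frames >= t0]) {
    if (!all(t0:t1 %in% frames)) next
    ids <- lapply(t0:t1, function(f) hyps$id[hyps$frame == f])
    if (any(vapply(ids, length, 1L) == 0L)) next
    combos <- expand.grid(ids, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos)))
      trajs[[length(trajs) + 1L]] <- list(t0 = t0,
                                          ids = as.integer(combos[r, ]))
  }
  colls <- list(list())
  addFrom <- function(coll, used, startIdx) {
    if (startIdx > length(trajs)) return(invisible())
    for (k in startIdx:length(trajs)) {
      tk <- trajs[[k]]
      if (any(tk$ids %in% used)) next
      newColl <- c(coll, list(tk))
      colls[[length(colls) + 1L]] <<- newColl
      addFrom(newColl, c(used, tk$ids), k + 1L)
    }
  }
  if (length(trajs)) addFrom(list(), integer(0), 1L)
  colls
}

canonicalCollection <- function(coll) {
  if (length(coll) == 0L) return("")
  paste(sort(vapply(coll, function(tr)
    paste(tr$t0, paste(tr$ids, collapse = ","), sep = ":"), "")),
    collapse = ";")
}

decidedAsList <- function(decided) {
  lapply(trajectories(decided), function(tr)
    list(t0 = tr$frame[1L], ids = tr$hyp))
}
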