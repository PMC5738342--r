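# Synthetic confluent-monolayer generator with ground truth: non-overlapping
# elliptical cells with constant-velocity kinematics plus acceleration
# noise, smooth shape change, an optional elongating subpopulation (area
# conserved), phase-contrast-like rendering (dark body, bright halo) and
# junction-fluorescence rendering with a fixed emitted total per cell.

#' Simulate ground-truth cell tracks
#'
#' Cells start on a jittered grid with random sizes and headings and follow
#' constant-velocity motion with Gaussian acceleration noise. Interiors are
#' kept disjoint by an iterated pairwise spring: whenever two cells'
#' effective radii along their centre line overlap, both are pushed apart by
#' `repulsionStrength` times half the overlap depth. The field boundary
#' reflects. Elongating cells multiply their semi-major axis by
#' `elongationRate` each frame while the minor axis shrinks to keep
#' `pi * a * b` constant; the rest drift in `log a`, `log b` with s.d.
#' `sigmaShapeSim`. Everything is reproducible from `cfg@seed`.
#'
#' @param cfg a [SimConfig-class].
#' @return A [GroundTruth-class].
#' @export
simulateTracks <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  h <- cfg@fieldSize[1L]; w <- cfg@fieldSize[2L]
  n <- cfg@nCells
  set.seed(cfg@seed)

  # mean cell area sized so total cell area is cfg@coverage of the field
  if (cfg@coverage > 0.9 / 1.2)
    ptStop("requested packing exceeds 90% of the field", "configurationError")
  r0 <- sqrt(cfg@coverage * h * w / (pi * n))

  gr <- max(1L, as.integer(round(sqrt(n * h / w))))
  gc <- as.integer(ceiling(n / gr))
  gy <- (rep(seq_len(gr), times = gc) - 0.5) * h / gr
  gx <- (rep(seq_len(gc), each = gr) - 0.5) * w / gc
  ord <- seq_len(n)
  cx <- gx[ord] + stats::runif(n, -0.15, 0.15) * w / gc
  cy <- gy[ord] + stats::runif(n, -0.15, 0.15) * h / gr
  ar <- stats::runif(n, 1.05, 1.35)                  # initial aspect ratio
  area <- pi * r0^2 * stats::runif(n, 0.8, 1.2)
  a <- sqrt(area * ar / pi)
  b <- area / (pi * a)
  theta <- stats::runif(n, 0, pi)
  heading <- stats::runif(n, 0, 2 * pi)
  speed <- abs(stats::rnorm(n, cfg@meanSpeed, cfg@meanSpeed / 3))
  vx <- speed * cos(heading); vy <- speed * sin(heading)
  elong <- rep(FALSE, n)
  if (cfg@elongatingFraction > 0)
    elong[sample.int(n, round(cfg@elongatingFraction * n))] <- TRUE
  areaRef <- pi * a * b

  if (sum(pi * a * b) > 0.9 * h * w)
    ptStop("requested packing exceeds 90% of the field", "configurationError")

  resolveOverlaps <- function(cx, cy, a, b, theta) {
    for (pass in 1:40) {
      moved <- FALSE
      for (i in seq_len(n - 1L)) {
        dx <- cx[(i + 1L):n] - cx[i]
        dy <- cy[(i + 1L):n] - cy[i]
        d <- sqrt(dx * dx + dy * dy)
        cand <- which(d < a[i] + a[(i + 1L):n] + 1) + i
        for (jj in cand) {
          ddx <- cx[jj] - cx[i]; ddy <- cy[jj] - cy[i]
          dd <- sqrt(ddx * ddx + ddy * ddy)
          if (dd < 1e-6) { ddx <- 1; ddy <- 0; dd <- 1 }
          phi <- atan2(ddy, ddx)
          ri <- radialSupport(a[i], b[i], theta[i], phi)
          rj <- radialSupport(a[jj], b[jj], theta[jj], phi + pi)
          depth <- ri + rj + 0.5 - dd   # 0.5 px safety clearance
          if (depth > 0) {
            push <- cfg@repulsionStrength * depth / 2
            ux <- ddx / dd; uy <- ddy / dd
            cx[i] <- cx[i] - push * ux; cy[i] <- cy[i] - push * uy
            cx[jj] <- cx[jj] + push * ux; cy[jj] <- cy[jj] + push * uy
            moved <- TRUE
          }
        }
      }
      cx <- pmin(pmax(cx, a), w - 1 - a)
      cy <- pmin(pmax(cy, a), h - 1 - a)
      if (!moved) break
    }
    list(cx = cx, cy = cy)
  }

  res <- resolveOverlaps(cx, cy, a, b, theta)
  cx <- res$cx; cy <- res$cy

  rows <- vector("list", cfg@nFrames)
  for (t in seq_len(cfg@nFrames) - 1L) {
    rows[[t + 1L]] <- data.frame(frame = t, cell_id = seq_len(n), cx = cx,
                                 cy = cy, a = a, b = b,
                                 theta = wrapTheta(theta))
    if (t == cfg@nFrames - 1L) break
    vx <- vx + stats::rnorm(n, 0, cfg@sigmaAcc)
    vy <- vy + stats::rnorm(n, 0, cfg@sigmaAcc)
    cx <- cx + vx; cy <- cy + vy
    # reflecting boundaries (with margin a)
    for (i in seq_len(n)) {
      if (cx[i] < a[i]) { cx[i] <- 2 * a[i] - cx[i]; vx[i] <- -vx[i] }
      if (cx[i] > w - 1 - a[i]) { cx[i] <- 2 * (w - 1 - a[i]) - cx[i]
        vx[i] <- -vx[i] }
      if (cy[i] < a[i]) { cy[i] <- 2 * a[i] - cy[i]; vy[i] <- -vy[i] }
      if (cy[i] > h - 1 - a[i]) { cy[i] <- 2 * (h - 1 - a[i]) - cy[i]
        vy[i] <- -vy[i] }
    }
    # shape update
    drift <- cfg@sigmaShapeSim
    if (drift > 0) {
      da <- stats::rnorm(n, 0, drift); db <- stats::rnorm(n, 0, drift)
      a[!elong] <- a[!elong] * exp(da[!elong])
      b[!elong] <- b[!elong] * exp(db[!elong])
    }
    a[elong] <- a[elong] * cfg@elongationRate
    b[elong] <- areaRef[elong] / (pi * a[elong])
    bad <- which(b > a)
    if (length(bad)) { tmp <- a[bad]; a[bad] <- b[bad]; b[bad] <- tmp
      theta[bad] <- wrapTheta(theta[bad] + pi / 2) }
    if (cfg@sigmaAcc > 0 || drift > 0 || any(elong)) {
      res <- resolveOverlaps(cx, cy, a, b, theta)
      cx <- res$cx; cy <- res$cy
    }
  }
  tracks <- do.call(rbind, rows)
  rownames(tracks) <- NULL
  totals <- rep(cfg@junctionTotalIntensity, n)
  names(totals) <- as.character(seq_len(n))
  names(elong) <- as.character(seq_len(n))
  new("GroundTruth", tracks = tracks, junctionTotals = totals,
      elongating = elong, config = cfg)
}

# radial extent of an ellipse in direction phi (support of the boundary
# point along the ray from the centre)
radialSupport <- function(a, b, theta, phi) {
  psi <- phi - theta
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

#' Render a ground truth as a phase-contrast-like movie
#'
#' Each frame starts at the background grey level; cell interiors sit
#' `bodyDepth` below background, a 2-px band around each ellipse boundary
#' sits `haloAmplitude` above background (the phase-contrast halo), and
#' i.i.d. Gaussian noise with s.d. `noiseSd` is added. Deterministic given
#' `cfg@seed`.
#'
#' @param gt a [GroundTruth-class].
#' @param cfg a [SimConfig-class]; defaults to the one stored in `gt`.
#' @return An [ImageStack-class].
#' @export
renderPhaseContrast <- function(gt, cfg = gt@config) {
  h <- cfg@fieldSize[1L]; w <- cfg@fieldSize[2L]
  nT <- cfg@nFrames
  arr <- array(cfg@background, dim = c(h, w, nT))
  tracks <- gt@tracks
  for (t in seq_len(nT) - 1L) {
    fr <- matrix(cfg@background, h, w)
    tf <- tracks[tracks$frame == t, , drop = FALSE]
    for (i in seq_len(nrow(tf))) {
      halo <- ellipsePixelIdx(tf$cx[i], tf$cy[i], tf$a[i] + 2, tf$b[i] + 2,
                              tf$theta[i], h, w)
      body <- ellipsePixelIdx(tf$cx[i], tf$cy[i], tf$a[i], tf$b[i],
                              tf$theta[i], h, w)
      fr[halo] <- cfg@background + cfg@haloAmplitude
      fr[body] <- cfg@background - cfg@bodyDepth
    }
    if (cfg@noiseSd > 0) {
      set.seed((cfg@seed + 7919L * (t + 1L)) %% .Machine$integer.max)
      fr <- fr + matrix(stats::rnorm(h * w, 0, cfg@noiseSd), h, w)
    }
    fr[fr < 0] <- 0
    arr[, , t + 1L] <- fr
  }
  ImageStack(arr, pixelSize = cfg@pixelSizeUm,
             frameInterval = cfg@frameIntervalS)
}

#' Render junction fluorescence for one frame
#'
#' Cell territories are the influence tessellation of the ellipse
#' interiors: every pixel joins the cell whose normalised elliptical
#' distance is smallest. Each cell's junction ribbon is the 1-px layer of
#' its own territory facing another territory or the field border, so the
#' junctions of two neighbouring cells form a 2-px line that receives both
#' cells' contributions. Every cell deposits its total junction intensity
#' (from `gt@junctionTotals`) uniformly over its own ribbon pixels; the
#' ribbon's junction length is the perimeter of the territory's boundary
#' polygon. Per-cell emitted totals, ribbon masks, outlines and lengths are
#' returned for conservation checks.
#'
#' @param gt a [GroundTruth-class].
#' @param cfg a [SimConfig-class]; defaults to the one stored in `gt`.
#' @param frame 0-based frame index.
#' @param noiseSd additive Gaussian noise s.d. on the rendered image
#'   (default 0: noise-free).
#' @return list with `image` (numeric matrix), and per-cell lists `roi`
#'   (logical ribbon masks), `lengthUm` (junction lengths), `outline`
#'   ([CellOutline-class] territory boundaries), `emitted` (deposited
#'   totals, a.u.).
#' @export
renderJunctionFluorescence <- function(gt, cfg = gt@config, frame = 0L,
                                       noiseSd = 0) {
  h <- cfg@fieldSize[1L]; w <- cfg@fieldSize[2L]
  tf <- gt@tracks[gt@tracks$frame == frame, , drop = FALSE]
  if (nrow(tf) == 0L)
    ptStop(sprintf("no ground truth for frame %d", frame), "invalidInput")
  n <- nrow(tf)
  X <- matrix(rep(0:(w - 1L), each = h), h, w)
  Y <- matrix(rep(0:(h - 1L), times = w), h, w)
  bestD <- matrix(Inf, h, w)
  owner <- matrix(0L, h, w)
  for (i in seq_len(n)) {
    dx <- X - tf$cx[i]; dy <- Y - tf$cy[i]
    ct <- cos(tf$theta[i]); st <- sin(tf$theta[i])
    u <- (dx * ct + dy * st) / tf$a[i]
    v <- (-dx * st + dy * ct) / tf$b[i]
    d <- u * u + v * v
    upd <- d < bestD
    bestD[upd] <- d[upd]
    owner[upd] <- i
  }
  img <- matrix(0, h, w)
  roi <- vector("list", n)
  lengthUm <- numeric(n)
  outlines <- vector("list", n)
  emitted <- numeric(n)
  for (i in seq_len(n)) {
    terr <- owner == i
    # keep the largest connected piece (tessellation cells are almost
    # always connected; guard against slivers)
    lab <- labelComponents(terr, 4L)
    if (max(lab) > 1L) {
      sizes <- tabulate(lab[lab > 0L])
      terr <- lab == which.max(sizes)
    }
    nbrOther <- (shiftMat(owner, 1L, 0L, 0L) != owner) |
      (shiftMat(owner, -1L, 0L, 0L) != owner) |
      (shiftMat(owner, 0L, 1L, 0L) != owner) |
      (shiftMat(owner, 0L, -1L, 0L) != owner)
    border <- matrix(FALSE, h, w)
    border[1L, ] <- TRUE; border[h, ] <- TRUE
    border[, 1L] <- TRUE; border[, w] <- TRUE
    ribbon <- terr & (nbrOther | border)
    npx <- sum(ribbon)
    if (npx == 0L) next
    poly <- boundaryPolygon(terr)
    outlines[[i]] <- CellOutline(poly, pixelSize = cfg@pixelSizeUm)
    lengthUm[i] <- polygonPerimeter(outlines[[i]])
    total <- gt@junctionTotals[i]
    img[ribbon] <- img[ribbon] + total / npx
    emitted[i] <- total
    roi[[i]] <- ribbon
  }
  if (noiseSd > 0) {
    set.seed((cfg@seed + 104729L + as.integer(frame)) %%
               .Machine$integer.max)
    img <- img + matrix(stats::rnorm(h * w, 0, noiseSd), h, w)
  }
  list(image = img, roi = roi, lengthUm = lengthUm, outline = outlines,
       emitted = emitted)
}
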