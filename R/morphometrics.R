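# Morphology and dynamics quantifications: elongation factor, perimeter,
# migration statistics, relative VE-cadherin concentration along junctions
# (Rel-VEcad-C), the total-VE-cadherin estimate, junction-associated plaque
# (JAIL) metrics and the pole/lateral boundary partition.

# ---- polygon geometry (closed simple polygons, vertices in px) -------------

polygonSignedArea <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# area, centroid and second central moments of the polygon interior
# (standard shoelace-based closed forms)
polygonMoments <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  n <- nrow(v)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12)
    ptStop("polygon encloses no area", "degenerateGeometry")
  cx <- sum((x + x[j]) * cr) / (6 * A)
  cy <- sum((y + y[j]) * cr) / (6 * A)
  ixx <- sum((y^2 + y * y[j] + y[j]^2) * cr) / 12
  iyy <- sum((x^2 + x * x[j] + x[j]^2) * cr) / 12
  ixy <- sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * cr) / 24
  s <- sign(A)
  list(area = abs(A), cx = cx, cy = cy,
       # central second moments per unit area
       mxx = s * iyy / abs(A) - cx^2,
       myy = s * ixx / abs(A) - cy^2,
       mxy = s * ixy / abs(A) - cx * cy)
}

#' Best-fit ellipse of a polygon interior
#'
#' Second-moment equivalent ellipse of the polygon's interior, scaled to
#' the polygon's area.
#'
#' @param outline a [CellOutline-class].
#' @return An [Ellipse-class] (px units).
#' @export
outlineEllipse <- function(outline) {
  m <- polygonMoments(outline@vertices)
  tr <- m$mxx + m$myy
  disc <- sqrt(max(0, (m$mxx - m$myy)^2 / 4 + m$mxy^2))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= 1e-6 * max(1, l1))
    ptStop("outline is degenerate; no ellipse fit", "degenerateGeometry")
  theta <- 0.5 * atan2(2 * m$mxy, m$mxx - m$myy)
  a0 <- 2 * sqrt(l1); b0 <- 2 * sqrt(l2)
  s <- sqrt(m$area / (pi * a0 * b0))
  Ellipse(m$cx, m$cy, a0 * s, b0 * s, theta)
}

#' @rdname elongationFactor
#' @export
setMethod("elongationFactor", "Ellipse", function(shape) shape@a / shape@b)

#' @rdname elongationFactor
#' @export
setMethod("elongationFactor", "CellOutline", function(shape) {
  e <- outlineEllipse(shape)
  e@a / e@b
})

#' Perimeter of a cell outline
#'
#' Sum of consecutive-vertex Euclidean edge lengths (the polygon is closed
#' implicitly), converted to micrometres by the outline's pixel size.
#'
#' @param outline a [CellOutline-class].
#' @return numeric(1), um.
#' @examples
#' sq <- CellOutline(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
#'                   pixelSize = 0.5)
#' polygonPerimeter(sq)  # 20
#' @export
polygonPerimeter <- function(outline) {
  v <- outline@vertices
  if (nrow(v) < 3L)
    ptStop("outline needs at least 3 vertices", "invalidInput")
  j <- c(2:nrow(v), 1L)
  sum(sqrt((v[j, 1L] - v[, 1L])^2 + (v[j, 2L] - v[, 2L])^2)) *
    outline@pixelSize
}

#' Migration summary of a centroid path
#'
#' Accumulated distance is the total path length travelled by the cell
#' (sum of step lengths); Euclidean distance is the straight-line distance
#' between the start and the end point of travel. Mean velocity is
#' accumulated distance over elapsed time (um/h); directionality is
#' Euclidean over accumulated distance (flagged `NA` for a stationary
#' cell).
#'
#' @param centroids n x 2 matrix of (x, y) positions in px, time-ordered.
#' @param pixelSize um/px.
#' @param frameIntervalS seconds between consecutive positions.
#' @return list with `accumulated_um`, `euclidean_um`,
#'   `mean_velocity_um_h`, `directionality`.
#' @examples
#' migrationSummary(rbind(c(0, 0), c(3, 0), c(3, 4)), 1, 3600)
#' @export
migrationSummary <- function(centroids, pixelSize = 1,
                             frameIntervalS = 60) {
  p <- as.matrix(centroids)
  if (nrow(p) < 2L)
    ptStop("at least 2 positions are required", "invalidInput")
  steps <- sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2) * pixelSize
  acc <- sum(steps)
  euc <- sqrt((p[nrow(p), 1L] - p[1L, 1L])^2 +
                (p[nrow(p), 2L] - p[1L, 2L])^2) * pixelSize
  hours <- (nrow(p) - 1L) * frameIntervalS / 3600
  list(accumulated_um = acc, euclidean_um = euc,
       mean_velocity_um_h = acc / hours,
       directionality = if (acc > 0) euc / acc else NA_real_)
}

#' Relative VE-cadherin concentration of a junction ROI
#'
#' The integrated junction-channel intensity of the region of interest
#' divided by the junction length of the ROI (a.u./um). The ROI is either a
#' logical ribbon mask with a known junction length, or a polyline (n x 2
#' px coordinates) that is rasterised into a ribbon of width `ribbonWidth`
#' px and measured along its own length. When `backgroundSubtract` is on,
#' the median intensity of the 2-px dilation ring around the ribbon is
#' subtracted from every ROI pixel before integration.
#'
#' @param intensity numeric matrix, junction-channel image.
#' @param roi logical mask (same shape as `intensity`) or an n x 2 polyline
#'   matrix.
#' @param lengthUm junction length of the ROI in um; required for mask
#'   ROIs, computed from the polyline otherwise.
#' @param pixelSize um/px.
#' @param ribbonWidth ribbon width in px used when `roi` is a polyline.
#' @param backgroundSubtract subtract the local background estimate.
#' @param cellId identifier copied into the output.
#' @return data.frame row with `cell_id`, `rel_vecad_c` (a.u./um),
#'   `junction_length_um`, `integrated_intensity`.
#' @export
relVEcadC <- function(intensity, roi, lengthUm = NULL, pixelSize = 1,
                      ribbonWidth = 3, backgroundSubtract = TRUE,
                      cellId = NA_integer_) {
  if (is.logical(roi) && is.matrix(roi)) {
    if (!identical(dim(roi), dim(intensity)))
      ptStop("roi mask must match the intensity image", "invalidInput")
    mask <- roi
    if (is.null(lengthUm))
      ptStop("lengthUm is required for a mask ROI", "invalidInput")
  } else {
    pl <- as.matrix(roi)
    if (nrow(pl) < 2L)
      ptStop("polyline ROI needs at least 2 points", "invalidInput")
    lengthUm <- sum(sqrt(diff(pl[, 1L])^2 + diff(pl[, 2L])^2)) * pixelSize
    mask <- rasterizePolyline(pl, nrow(intensity), ncol(intensity),
                              ribbonWidth)
  }
  if (!is.numeric(lengthUm) || lengthUm <= 0)
    ptStop("junction length must be > 0", "invalidInput")
  vals <- intensity[mask]
  bg <- 0
  if (backgroundSubtract) {
    ring <- dilateMask(mask, 2L) & !mask
    if (any(ring)) bg <- stats::median(intensity[ring])
  }
  tot <- sum(vals - bg)
  data.frame(cell_id = cellId, rel_vecad_c = tot / lengthUm,
             junction_length_um = lengthUm, integrated_intensity = tot)
}

# rasterise a polyline into a ribbon of the given width (px)
rasterizePolyline <- function(pl, h, w, width = 3) {
  mask <- matrix(FALSE, h, w)
  half <- (width - 1) / 2
  for (i in seq_len(nrow(pl) - 1L)) {
    p0 <- pl[i, ]; p1 <- pl[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len * 2) + 1L))
    xs <- p0[1L] + ts * (p1[1L] - p0[1L])
    ys <- p0[2L] + ts * (p1[2L] - p0[2L])
    for (k in seq_along(xs)) {
      c0 <- max(1L, as.integer(round(xs[k] - half)) + 1L)
      c1 <- min(w, as.integer(round(xs[k] + half)) + 1L)
      r0 <- max(1L, as.integer(round(ys[k] - half)) + 1L)
      r1 <- min(h, as.integer(round(ys[k] + half)) + 1L)
      if (r1 >= r0 && c1 >= c0) mask[r0:r1, c0:c1] <- TRUE
    }
  }
  mask
}

dilateMask <- function(mask, r) {
  out <- mask
  for (k in seq_len(r)) {
    out <- out | shiftMat(out, 1L, 0L, FALSE) | shiftMat(out, -1L, 0L, FALSE) |
      shiftMat(out, 0L, 1L, FALSE) | shiftMat(out, 0L, -1L, FALSE) |
      shiftMat(out, 1L, 1L, FALSE) | shiftMat(out, -1L, -1L, FALSE) |
      shiftMat(out, 1L, -1L, FALSE) | shiftMat(out, -1L, 1L, FALSE)
  }
  out
}

#' Estimate of the total VE-cadherin per cell
#'
#' Mean cell perimeter multiplied by mean Rel-VEcad-C: when junction line
#' density dilutes with growing perimeter, the product stays constant if
#' the total junctional VE-cadherin per cell is conserved.
#'
#' @param meanPerimeterUm mean cell perimeter, um.
#' @param meanRelVEcadC mean Rel-VEcad-C, a.u./um.
#' @return numeric(1), a.u.
#' @export
totalVEcadEstimate <- function(meanPerimeterUm, meanRelVEcadC) {
  if (meanPerimeterUm < 0 || meanRelVEcadC < 0)
    ptStop("inputs must be >= 0", "invalidInput")
  meanPerimeterUm * meanRelVEcadC
}

#' Plaque (JAIL) count and sizes from a binary mask
#'
#' Connected components (8-connectivity) of the plaque mask with area at
#' least `minAreaUm2` are counted and measured in um^2. When a cell outline
#' is supplied and the cell is elongated beyond `elongationCutoff`, each
#' plaque is additionally assigned to the `pole` or `lateral` zone by the
#' direction of its centroid from the cell centroid (see
#' [poleLateralPartition()]).
#'
#' @param mask logical plaque mask.
#' @param pixelSize um/px.
#' @param minAreaUm2 minimum plaque area (um^2).
#' @param outline optional [CellOutline-class] for zone assignment.
#' @param halfAngleDeg pole half-angle (degrees).
#' @param elongationCutoff minimum elongation factor for a pole/lateral
#'   partition to be meaningful.
#' @return list with `count`, `areas_um2`, `zones` (factor `pole`/`lateral`
#'   or `NA`), `centroids` (px).
#' @export
plaqueMetrics <- function(mask, pixelSize = 1, minAreaUm2 = 0,
                          outline = NULL, halfAngleDeg = 45,
                          elongationCutoff = 1.5) {
  if (!is.matrix(mask)) ptStop("mask must be a matrix", "invalidInput")
  mask <- mask > 0
  lab <- labelComponents(mask, 8L)
  k <- max(lab)
  if (k == 0L)
    return(list(count = 0L, areas_um2 = numeric(0),
                zones = factor(character(0), levels = c("pole", "lateral")),
                centroids = matrix(numeric(0), 0L, 2L)))
  idx <- which(lab > 0L)
  comp <- lab[idx]
  areas <- tabulate(comp, k) * pixelSize^2
  ys <- ((idx - 1L) %% nrow(mask))
  xs <- ((idx - 1L) %/% nrow(mask))
  cxs <- as.vector(rowsum(xs, comp)) / tabulate(comp, k)
  cys <- as.vector(rowsum(ys, comp)) / tabulate(comp, k)
  keep <- which(areas >= minAreaUm2)
  zones <- rep(NA_character_, length(keep))
  if (!is.null(outline) &&
      elongationFactor(outline) > elongationCutoff) {
    e <- outlineEllipse(outline)
    ang <- atan2(cys[keep] - e@cy, cxs[keep] - e@cx)
    d <- abs(axialDiff(ang - e@theta))
    zones <- ifelse(d <= halfAngleDeg * pi / 180, "pole", "lateral")
  }
  list(count = length(keep), areas_um2 = unname(areas[keep]),
       zones = factor(zones, levels = c("pole", "lateral")),
       centroids = cbind(cx = cxs[keep], cy = cys[keep]))
}

#' Partition a cell boundary into pole and lateral zones
#'
#' For an elongated cell, boundary points whose direction from the centroid
#' lies within `halfAngleDeg` of the major axis (either end) are `pole`;
#' the rest are `lateral`. The boundary is resampled at approximately unit
#' (1 px) spacing along the outline.
#'
#' @param outline a [CellOutline-class].
#' @param halfAngleDeg pole half-angle in degrees.
#' @param elongationCutoff the partition is only defined for cells with
#'   elongation factor above this cutoff.
#' @return list with `points` (m x 2 px coordinates), `zone` (factor),
#'   `poleFraction` (arc-length fraction labelled pole).
#' @export
poleLateralPartition <- function(outline, halfAngleDeg = 45,
                                 elongationCutoff = 1.5) {
  ef <- elongationFactor(outline)
  if (ef <= elongationCutoff)
    ptStop(sprintf(
      "pole/lateral partition needs elongation > %.2f (got %.2f)",
      elongationCutoff, ef), "notApplicable")
  e <- outlineEllipse(outline)
  v <- outline@vertices
  n <- nrow(v)
  j <- c(2:n, 1L)
  pts <- list()
  for (i in seq_len(n)) {
    p0 <- v[i, ]; p1 <- v[j[i], ]
    len <- sqrt(sum((p1 - p0)^2))
    m <- max(1L, ceiling(len))
    ts <- (seq_len(m) - 1L) / m
    pts[[i]] <- cbind(p0[1L] + ts * (p1[1L] - p0[1L]),
                      p0[2L] + ts * (p1[2L] - p0[2L]))
  }
  pts <- do.call(rbind, pts)
  ang <- atan2(pts[, 2L] - e@cy, pts[, 1L] - e@cx)
  d <- abs(axialDiff(ang - e@theta))
  zone <- factor(ifelse(d <= halfAngleDeg * pi / 180, "pole", "lateral"),
                 levels = c("pole", "lateral"))
  # arc-length weights: distance to the next resampled point
  nn <- nrow(pts)
  nxt <- c(2:nn, 1L)
  wlen <- sqrt((pts[nxt, 1L] - pts[, 1L])^2 + (pts[nxt, 2L] - pts[, 2L])^2)
  list(points = pts, zone = zone,
       poleFraction = sum(wlen[zone == "pole"]) / sum(wlen))
}

#' Per-cell morphometric table for a track collection
#'
#' Convenience summary: one row per trajectory with its mean elongation
#' factor, equivalent-ellipse perimeter (um) and migration statistics.
#'
#' @param collection a [TrackCollection-class].
#' @param pixelSize um/px.
#' @param frameIntervalS seconds per frame.
#' @return data.frame.
#' @export
morphometricsTable <- function(collection, pixelSize = 1,
                               frameIntervalS = 60) {
  trs <- trajectories(collection)
  if (length(trs) == 0L)
    return(data.frame(cell_id = integer(0), n_frames = integer(0),
                      elongation = numeric(0), perimeter_um = numeric(0),
                      accumulated_um = numeric(0), euclidean_um = numeric(0),
                      mean_velocity_um_h = numeric(0),
                      directionality = numeric(0)))
  rows <- lapply(seq_along(trs), function(i) {
    tr <- trs[[i]]
    elong <- mean(tr$a / tr$b)
    perim <- mean(ellipsePerimeterPx(tr$a, tr$b)) * pixelSize
    mig <- if (nrow(tr) >= 2L)
      migrationSummary(cbind(tr$cx, tr$cy), pixelSize, frameIntervalS)
    else list(accumulated_um = 0, euclidean_um = 0,
              mean_velocity_um_h = 0, directionality = NA_real_)
    data.frame(cell_id = i, n_frames = nrow(tr), elongation = elong,
               perimeter_um = perim, accumulated_um = mig$accumulated_um,
               euclidean_um = mig$euclidean_um,
               mean_velocity_um_h = mig$mean_velocity_um_h,
               directionality = mig$directionality)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Ramanujan approximation of the ellipse perimeter (px)
ellipsePerimeterPx <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}
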