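# Internal numeric helpers shared across modules. Coordinate convention:
# pixel centres sit at integer (x, y) with x = column - 1, y = row - 1
# (0-based), matching the CSV interfaces.

ptStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "PhaseTrackError")))
}

#' @noRd
wrapTheta <- function(theta) {
  out <- theta %% pi
  out[out >= pi] <- out[out >= pi] - pi
  out
}

# signed angular difference wrapped to [-pi/2, pi/2) for axial (period-pi)
# orientations
axialDiff <- function(d) d - pi * round(d / pi)

# Separable box mean filter with replicate padding; window = 2*r + 1.
boxBlur <- function(m, r) {
  if (r < 1) return(m)
  blur1 <- function(x, r) {
    n <- nrow(x)
    xp <- x[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    cs <- rbind(0, apply(xp, 2L, cumsum))
    (cs[(2L * r + 1L) + seq_len(n), , drop = FALSE] -
       cs[seq_len(n), , drop = FALSE]) / (2 * r + 1)
  }
  t(blur1(t(blur1(m, r)), r))
}

localVariance <- function(m, r) {
  v <- boxBlur(m * m, r) - boxBlur(m, r)^2
  v[v < 0] <- 0
  v
}

# Shift a matrix by (dr, dc), padding vacated cells with `fill`.
shiftMat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Connected-component labelling of a logical mask (4- or 8-connectivity).
# Returns an integer matrix, 0 on background, labels 1..k on foreground.
labelComponents <- function(mask, connectivity = 4L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  .labelRegions(m, as.integer(connectivity), 0L, TRUE)
}

# Closed boundary polygon of a connected mask by marching squares
# (level 0.5 of the zero-padded indicator, so regions touching the image
# border still yield a closed contour). Returns an n x 2 matrix of 0-based
# (x, y) coordinates; first vertex is not repeated.
boundaryPolygon <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) ptStop("empty mask has no contour", "degenerateGeometry")
  z <- matrix(0, h + 2L, w + 2L)
  z[2:(h + 1L), 2:(w + 1L)] <- as.numeric(mask)
  cl <- grDevices::contourLines(x = -1:h, y = -1:w, z = z, levels = 0.5)
  if (length(cl) == 0L) ptStop("mask has no contour", "degenerateGeometry")
  len <- vapply(cl, function(p) length(p$x), numeric(1))
  p <- cl[[which.max(len)]]
  # contourLines: first axis is x-argument = our row coordinate (y)
  xs <- p$y; ys <- p$x
  n <- length(xs)
  if (n > 1L && xs[1L] == xs[n] && ys[1L] == ys[n]) {
    xs <- xs[-n]; ys <- ys[-n]
  }
  cbind(x = xs, y = ys)
}

# ---- ellipse pixel geometry -------------------------------------------------

# Linear indices (into an h x w matrix) of pixel centres inside the ellipse.
ellipsePixelIdx <- function(cx, cy, a, b, theta, h, w) {
  x0 <- max(0L, floor(cx - a)); x1 <- min(w - 1L, ceiling(cx + a))
  y0 <- max(0L, floor(cy - a)); y1 <- min(h - 1L, ceiling(cy + a))
  if (x1 < x0 || y1 < y0) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx <- rep(xs, each = length(ys)) - cx
  dy <- rep(ys, times = length(xs)) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  ok <- u * u + v * v <= 1
  row <- rep(ys, times = length(xs)) + 1L
  col <- rep(xs, each = length(ys)) + 1L
  ((col - 1L) * h + row)[ok]
}

insideEllipse <- function(x, y, cx, cy, a, b, theta) {
  dx <- x - cx; dy <- y - cy
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  u * u + v * v <= 1
}

ellParamVec <- function(e) {
  if (is(e, "Ellipse")) c(e@cx, e@cy, e@a, e@b, e@theta)
  else c(e[["cx"]], e[["cy"]], e[["a"]], e[["b"]], e[["theta"]])
}

# Overlap area (px^2) of two ellipse interiors by unit-grid interior sampling.
ellipseOverlapArea <- function(e1, e2, step = 1) {
  .ellipseOverlapC(ellParamVec(e1), ellParamVec(e2), step)
}

# Intersection-over-union of two ellipse interiors by unit-grid sampling.
ellipseIoU <- function(e1, e2, step = 1) {
  .ellipseIoUC(ellParamVec(e1), ellParamVec(e2), step)
}
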