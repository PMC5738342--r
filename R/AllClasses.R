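#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core value classes
# ---------------------------------------------------------------------------

#' Parametric ellipse
#'
#' A cell-shape candidate: centre `(cx, cy)` in pixel coordinates (0-based
#' pixel centres), semi-major axis `a`, semi-minor axis `b` (both in px) and
#' the orientation `theta` of the major axis in radians, wrapped into
#' `[0, pi)`.
#'
#' @slot cx,cy numeric(1), centre in px.
#' @slot a,b numeric(1), semi-axes in px with `a >= b > 0`.
#' @slot theta numeric(1), orientation in radians, in `[0, pi)`.
#' @export
setClass("Ellipse",
  representation(cx = "numeric", cy = "numeric", a = "numeric",
                 b = "numeric", theta = "numeric"),
  validity = function(object) {
    v <- c(object@cx, object@cy, object@a, object@b, object@theta)
    if (length(v) != 5L || any(!is.finite(v)))
      return("all of cx, cy, a, b, theta must be finite scalars")
    if (!(object@a >= object@b && object@b > 0))
      return("semi-axes must satisfy a >= b > 0")
    if (object@theta < 0 || object@theta >= pi)
      return("theta must lie in [0, pi)")
    TRUE
  })

#' @param cx,cy,a,b,theta ellipse parameters; `theta` is wrapped into
#'   `[0, pi)`.
#' @return An `Ellipse` object.
#' @examples
#' Ellipse(10, 12, a = 8, b = 4, theta = pi / 3)
#' @rdname Ellipse-class
#' @export
Ellipse <- function(cx, cy, a, b, theta = 0) {
  new("Ellipse", cx = as.numeric(cx), cy = as.numeric(cy), a = as.numeric(a),
      b = as.numeric(b), theta = wrapTheta(as.numeric(theta)))
}

#' Calibrated image stack
#'
#' A `T`-frame grayscale movie stored as an `H x W x T` array together with
#' the spatial calibration (micrometre per pixel) and the frame interval in
#' seconds.
#'
#' @slot data numeric array, `H x W x T`, finite, non-negative.
#' @slot pixelSize numeric(1), um/px, `> 0`.
#' @slot frameInterval numeric(1), seconds per frame, `> 0`.
#' @export
setClass("ImageStack",
  representation(data = "array", pixelSize = "numeric",
                 frameInterval = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be an H x W x T array")
    if (d[1L] < 2L || d[2L] < 2L) return("frames must be at least 2 x 2")
    if (!all(is.finite(object@data))) return("intensities must be finite")
    if (any(object@data < 0)) return("intensities must be non-negative")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    if (object@frameInterval <= 0) return("frameInterval must be > 0")
    TRUE
  })

#' @param data `H x W x T` array (or `H x W` matrix for a single frame).
#' @param pixelSize um per pixel.
#' @param frameInterval seconds per frame.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(data, pixelSize = 1, frameInterval = 60) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  new("ImageStack", data = data, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval))
}

#' Per-pixel foreground probabilities for one frame
#'
#' @slot probs numeric matrix in `[0, 1]`, same shape as the source frame.
#' @slot frame integer(1), 0-based time index of the source frame.
#' @export
setClass("ForegroundMap",
  representation(probs = "matrix", frame = "integer"),
  validity = function(object) {
    p <- object@probs
    if (!is.numeric(p) || any(!is.finite(p))) return("probs must be finite")
    if (any(p < 0 | p > 1)) return("probs must lie in [0, 1]")
    if (object@frame < 0L) return("frame index must be >= 0")
    TRUE
  })

#' @param probs probability matrix.
#' @param frame 0-based time index.
#' @rdname ForegroundMap-class
#' @export
ForegroundMap <- function(probs, frame = 0L) {
  new("ForegroundMap", probs = probs, frame = as.integer(frame))
}

#' Closed cell outline polygon
#'
#' @slot vertices n x 2 numeric matrix of (x, y) vertex coordinates in px
#'   (0-based pixel centres); the polygon is implicitly closed.
#' @slot pixelSize numeric(1), um/px.
#' @export
setClass("CellOutline",
  representation(vertices = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    v <- object@vertices
    if (ncol(v) != 2L || nrow(v) < 3L)
      return("outline needs an n x 2 vertex matrix with n >= 3")
    if (any(!is.finite(v))) return("vertices must be finite")
    if (abs(polygonSignedArea(v)) <= .Machine$double.eps)
      return("outline must enclose positive area")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    TRUE
  })

#' @param vertices n x 2 matrix of (x, y) coordinates in px.
#' @param pixelSize um per pixel.
#' @rdname CellOutline-class
#' @export
CellOutline <- function(vertices, pixelSize = 1) {
  new("CellOutline", vertices = as.matrix(vertices),
      pixelSize = as.numeric(pixelSize))
}

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' MRF segmentation parameters
#'
#' Weights of the binary Markov random field used for per-frame foreground
#' segmentation: a data (unary) term, a pairwise Potts coupling on the
#' 4-neighbour grid and a robust higher-order Pn-Potts clique term whose
#' penalty grows linearly with the clique's minority-label count and
#' saturates at `gammaMax` once a fraction `truncationQ` of the clique
#' disagrees.
#'
#' @slot unaryScale weight `>= 0` on the data term.
#' @slot beta pairwise Potts coupling `>= 0`.
#' @slot gammaMax higher-order clique penalty ceiling `>= 0`.
#' @slot truncationQ fraction in `(0, 0.5]` of clique pixels allowed to
#'   disagree before the clique penalty saturates.
#' @slot nCliques target number of higher-order cliques per frame.
#' @slot temperature temperature `> 0` used when converting energies to
#'   probabilities.
#' @slot featureRadius radius (px) of the unary feature window.
#' @export
setClass("MrfParams",
  representation(unaryScale = "numeric", beta = "numeric",
                 gammaMax = "numeric", truncationQ = "numeric",
                 nCliques = "numeric", temperature = "numeric",
                 featureRadius = "numeric"),
  validity = function(object) {
    w <- c(object@unaryScale, object@beta, object@gammaMax)
    if (any(!is.finite(w)) || any(w < 0))
      return("unaryScale, beta and gammaMax must be finite and >= 0")
    if (object@truncationQ <= 0 || object@truncationQ > 0.5)
      return("truncationQ must lie in (0, 0.5]")
    if (object@nCliques < 1) return("nCliques must be >= 1")
    if (object@temperature <= 0) return("temperature must be > 0")
    if (object@featureRadius < 1) return("featureRadius must be >= 1")
    TRUE
  })

#' @param unaryScale,beta,gammaMax,truncationQ,nCliques,temperature,featureRadius
#'   see the corresponding slots.
#' @rdname MrfParams-class
#' @export
MrfParams <- function(unaryScale = 1, beta = 0.5, gammaMax = 0.5,
                      truncationQ = 0.1, nCliques = 64, temperature = 1,
                      featureRadius = 24) {
  new("MrfParams", unaryScale = unaryScale, beta = beta, gammaMax = gammaMax,
      truncationQ = truncationQ, nCliques = nCliques,
      temperature = temperature, featureRadius = featureRadius)
}

#' Trajectory motion model
#'
#' Constant-velocity Gaussian motion with smooth shape change: the next
#' centre deviates from the constant-velocity prediction with isotropic s.d.
#' `sigmaPos` (px/frame), the per-frame changes of `log a` and `log b` have
#' s.d. `sigmaShape`, and the per-frame orientation change follows a wrapped
#' Gaussian with s.d. `sigmaTheta` (radians, period pi).
#'
#' @slot sigmaPos,sigmaShape,sigmaTheta positive numeric(1).
#' @export
setClass("MotionModel",
  representation(sigmaPos = "numeric", sigmaShape = "numeric",
                 sigmaTheta = "numeric"),
  validity = function(object) {
    if (any(c(object@sigmaPos, object@sigmaShape, object@sigmaTheta) <= 0))
      return("all motion s.d. parameters must be > 0")
    TRUE
  })

#' @param sigmaPos,sigmaShape,sigmaTheta see slots.
#' @rdname MotionModel-class
#' @export
MotionModel <- function(sigmaPos = 2, sigmaShape = 0.05, sigmaTheta = 0.2) {
  new("MotionModel", sigmaPos = sigmaPos, sigmaShape = sigmaShape,
      sigmaTheta = sigmaTheta)
}

#' Prior over trajectory collections
#'
#' Governs the joint model over interacting trajectories: per-trajectory
#' start/end penalties, a per-assigned-hypothesis coverage reward (so large
#' consistent collections are favoured) and a penalty per px^2 of same-frame
#' interior overlap between trajectories (`Inf` encodes the hard non-overlap
#' constraint of a confluent monolayer).
#'
#' @slot logBirth,logDeath per-trajectory start/end log-penalties `<= 0`.
#' @slot logCoverage reward per assigned hypothesis `>= 0`.
#' @slot kappaOverlap overlap penalty per px^2 `>= 0`; may be `Inf`.
#' @export
setClass("CollectionPrior",
  representation(logBirth = "numeric", logDeath = "numeric",
                 logCoverage = "numeric", kappaOverlap = "numeric"),
  validity = function(object) {
    if (!is.finite(object@logBirth) || object@logBirth > 0)
      return("logBirth must be finite and <= 0")
    if (!is.finite(object@logDeath) || object@logDeath > 0)
      return("logDeath must be finite and <= 0")
    if (!is.finite(object@logCoverage) || object@logCoverage < 0)
      return("logCoverage must be finite and >= 0")
    if (is.na(object@kappaOverlap) || object@kappaOverlap < 0)
      return("kappaOverlap must be >= 0 (Inf allowed)")
    TRUE
  })

#' @param logBirth,logDeath,logCoverage,kappaOverlap see slots.
#' @rdname CollectionPrior-class
#' @export
CollectionPrior <- function(logBirth = -2, logDeath = -2, logCoverage = 4,
                            kappaOverlap = 0.005) {
  new("CollectionPrior", logBirth = logBirth, logDeath = logDeath,
      logCoverage = logCoverage, kappaOverlap = kappaOverlap)
}

# ---------------------------------------------------------------------------
# Result containers
# ---------------------------------------------------------------------------

#' Collection of cell trajectories
#'
#' A set of temporally contiguous trajectories. Each trajectory is stored as
#' a data.frame with columns `frame` (0-based, consecutive), `hyp`
#' (hypothesis id or `NA`), `cx`, `cy`, `a`, `b`, `theta`.
#'
#' @slot trajectories list of per-trajectory data.frames.
#' @slot logScore numeric(1), joint log-score under the trajectory model
#'   (`NA` when the collection was read from a file).
#' @export
setClass("TrackCollection",
  representation(trajectories = "list", logScore = "numeric"),
  validity = function(object) {
    for (tr in object@trajectories) {
      need <- c("frame", "hyp", "cx", "cy", "a", "b", "theta")
      if (!all(need %in% names(tr)))
        return("each trajectory needs columns frame, hyp, cx, cy, a, b, theta")
      if (nrow(tr) < 1L) return("trajectories must have length >= 1")
      if (nrow(tr) > 1L && any(diff(tr$frame) != 1L))
        return("trajectory frames must be strictly consecutive")
    }
    hid <- unlist(lapply(object@trajectories, function(tr) tr$hyp))
    hid <- hid[!is.na(hid)]
    if (anyDuplicated(hid))
      return("a hypothesis may be assigned to at most one trajectory")
    TRUE
  })

TrackCollection <- function(trajectories = list(), logScore = NA_real_) {
  new("TrackCollection", trajectories = trajectories,
      logScore = as.numeric(logScore))
}

#' Simulator configuration
#'
#' Parameters of the synthetic confluent-monolayer generator. Defaults
#' describe the reference study condition used throughout the test-suite:
#' 30 cells on a 512 x 512 px field over 60 frames with acceleration noise
#' 0.3 px/frame^2, an 8-bit phase-contrast render (halo amplitude 40, noise
#' s.d. 5) and a fixed junction-fluorescence budget per cell.
#'
#' @slot nCells integer `>= 1`.
#' @slot fieldSize integer(2), `c(H, W)` in px.
#' @slot nFrames integer `>= 1`.
#' @slot frameIntervalS seconds between frames.
#' @slot pixelSizeUm um per px.
#' @slot sigmaAcc acceleration noise s.d., px/frame^2.
#' @slot sigmaShapeSim per-frame log-axis drift s.d.
#' @slot elongatingFraction fraction of cells that progressively elongate.
#' @slot elongationRate per-frame multiplicative growth of the major axis of
#'   elongating cells (minor axis shrunk to preserve area).
#' @slot repulsionStrength step fraction of the overlap depth resolved per
#'   relaxation iteration.
#' @slot background,bodyDepth,haloAmplitude,noiseSd phase-contrast render:
#'   background grey level, how far the cell body sits below background, how
#'   far the 2-px halo band sits above background, and additive Gaussian
#'   noise s.d. (8-bit scale).
#' @slot junctionTotalIntensity total junction fluorescence emitted per cell
#'   (a.u.).
#' @slot coverage fraction of the field covered by total cell area; must
#'   stay below 0.9 for a feasible packing.
#' @slot meanSpeed mean initial speed, px/frame.
#' @slot seed integer random seed.
#' @export
setClass("SimConfig",
  representation(nCells = "integer", fieldSize = "integer",
                 nFrames = "integer", frameIntervalS = "numeric",
                 pixelSizeUm = "numeric", sigmaAcc = "numeric",
                 sigmaShapeSim = "numeric", elongatingFraction = "numeric",
                 elongationRate = "numeric", repulsionStrength = "numeric",
                 background = "numeric", bodyDepth = "numeric",
                 haloAmplitude = "numeric", noiseSd = "numeric",
                 junctionTotalIntensity = "numeric", coverage = "numeric",
                 meanSpeed = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nCells < 1L) return("nCells must be >= 1")
    if (length(object@fieldSize) != 2L || any(object@fieldSize < 32L))
      return("fieldSize must be c(H, W) with both >= 32")
    if (object@nFrames < 1L) return("nFrames must be >= 1")
    if (object@frameIntervalS <= 0 || object@pixelSizeUm <= 0)
      return("calibration must be positive")
    if (any(c(object@sigmaAcc, object@sigmaShapeSim, object@noiseSd) < 0))
      return("noise parameters must be >= 0")
    if (object@elongatingFraction < 0 || object@elongatingFraction > 1)
      return("elongatingFraction must lie in [0, 1]")
    if (object@elongationRate < 1) return("elongationRate must be >= 1")
    if (object@coverage <= 0 || object@coverage > 1)
      return("coverage must lie in (0, 1]")
    TRUE
  })

#' @param nCells,fieldSize,nFrames,frameIntervalS,pixelSizeUm,sigmaAcc
#'   see slots.
#' @param sigmaShapeSim,elongatingFraction,elongationRate,repulsionStrength
#'   see slots.
#' @param background,bodyDepth,haloAmplitude,noiseSd,junctionTotalIntensity
#'   see slots.
#' @param coverage,meanSpeed,seed see slots.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nCells = 30, fieldSize = c(512, 512), nFrames = 60,
                      frameIntervalS = 300, pixelSizeUm = 0.65,
                      sigmaAcc = 0.3, sigmaShapeSim = 0.005,
                      elongatingFraction = 0.3, elongationRate = 1.01,
                      repulsionStrength = 0.6, background = 100,
                      bodyDepth = 30, haloAmplitude = 40, noiseSd = 5,
                      junctionTotalIntensity = 5000, coverage = 0.52,
                      meanSpeed = 0.8, seed = 1) {
  new("SimConfig", nCells = as.integer(nCells),
      fieldSize = as.integer(fieldSize), nFrames = as.integer(nFrames),
      frameIntervalS = frameIntervalS, pixelSizeUm = pixelSizeUm,
      sigmaAcc = sigmaAcc, sigmaShapeSim = sigmaShapeSim,
      elongatingFraction = elongatingFraction,
      elongationRate = elongationRate,
      repulsionStrength = repulsionStrength, background = background,
      bodyDepth = bodyDepth, haloAmplitude = haloAmplitude,
      noiseSd = noiseSd, junctionTotalIntensity = junctionTotalIntensity,
      coverage = coverage, meanSpeed = meanSpeed, seed = as.integer(seed))
}

#' Simulator ground truth
#'
#' @slot tracks data.frame with columns `frame`, `cell_id`, `cx`, `cy`, `a`,
#'   `b`, `theta` (0-based frames, px units), contiguous per cell.
#' @slot junctionTotals named numeric, total junction fluorescence emitted
#'   per cell.
#' @slot elongating named logical, which cells elongate.
#' @slot config the generating [SimConfig-class].
#' @export
setClass("GroundTruth",
  representation(tracks = "data.frame", junctionTotals = "numeric",
                 elongating = "logical", config = "SimConfig"),
  validity = function(object) {
    need <- c("frame", "cell_id", "cx", "cy", "a", "b", "theta")
    if (!all(need %in% names(object@tracks)))
      return("tracks needs columns frame, cell_id, cx, cy, a, b, theta")
    for (id in unique(object@tracks$cell_id)) {
      f <- sort(object@tracks$frame[object@tracks$cell_id == id])
      if (length(f) > 1L && any(diff(f) != 1L))
        return("ground-truth tracks must be contiguous")
    }
    TRUE
  })

#' Tracking evaluation report
#'
#' @slot matchRate fraction of ground-truth detections matched at the IoU
#'   threshold with consistent identity, in `[0, 1]`.
#' @slot idSwitches integer count of identity changes along ground-truth
#'   tracks.
#' @slot centreRmsePx RMSE of matched centre positions, px.
#' @slot perFrame data.frame with per-frame ground-truth, predicted and
#'   matched counts.
#' @export
setClass("EvaluationReport",
  representation(matchRate = "numeric", idSwitches = "integer",
                 centreRmsePx = "numeric", perFrame = "data.frame"),
  validity = function(object) {
    if (object@matchRate < 0 || object@matchRate > 1)
      return("matchRate must lie in [0, 1]")
    if (!is.na(object@centreRmsePx) && object@centreRmsePx < 0)
      return("centreRmsePx must be >= 0")
    TRUE
  })

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "Ellipse", function(object) {
  cat(sprintf("Ellipse centre=(%.2f, %.2f) a=%.2f b=%.2f theta=%.3f rad\n",
              object@cx, object@cy, object@a, object@b, object@theta))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ImageStack: %d frame(s) of %d x %d px (%.3g um/px, %.3g s/frame)\n",
    d[3L], d[1L], d[2L], object@pixelSize, object@frameInterval))
})

setMethod("show", "ForegroundMap", function(object) {
  cat(sprintf("ForegroundMap frame %d: %d x %d px, mean prob %.3f\n",
              object@frame, nrow(object@probs), ncol(object@probs),
              mean(object@probs)))
})

setMethod("show", "TrackCollection", function(object) {
  n <- length(object@trajectories)
  len <- if (n) vapply(object@trajectories, nrow, numeric(1)) else numeric(0)
  cat(sprintf(
    "TrackCollection: %d trajectories (median length %s), logScore %s\n", n,
    if (n) format(stats::median(len)) else "NA",
    format(object@logScore, digits = 6)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d cells x %d frames (%d elongating)\n",
    length(unique(object@tracks$cell_id)),
    length(unique(object@tracks$frame)), sum(object@elongating)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport: match rate %.3f, %d id switches, centre RMSE %.2f px\n",
    object@matchRate, object@idSwitches, object@centreRmsePx))
})
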