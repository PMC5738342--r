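# Accessor generics. Kept deliberately small: heavy pipeline stages are plain
# exported functions; generics cover data access and the shape statistics
# that dispatch on Ellipse vs CellOutline.

#' Pixel data of an object
#' @param x an object with pixel data.
#' @param ... further arguments for methods.
#' @return For `ImageStack`, the `H x W x T` array; for `ForegroundMap`, the
#'   probability matrix.
#' @export
setGeneric("pixelData", function(x, ...) standardGeneric("pixelData"))

#' @rdname pixelData
#' @export
setMethod("pixelData", "ImageStack", function(x, ...) x@data)

#' @rdname pixelData
#' @export
setMethod("pixelData", "ForegroundMap", function(x, ...) x@probs)

#' Spatial calibration (um per pixel)
#' @param x an object carrying a calibration.
#' @return numeric(1), um/px.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "CellOutline", function(x) x@pixelSize)

#' Frame interval in seconds
#' @param x an `ImageStack`.
#' @return numeric(1), s/frame.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@frameInterval)

#' Number of frames
#' @param x an `ImageStack`.
#' @return integer(1).
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@data)[3L])

#' Extract one frame as a matrix
#' @param x an `ImageStack`.
#' @param i 0-based frame index.
#' @return numeric `H x W` matrix.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setMethod("getFrame", "ImageStack", function(x, i) {
  i <- as.integer(i)
  if (i < 0L || i >= dim(x@data)[3L])
    ptStop(sprintf("frame index %d out of range [0, %d]", i,
                   dim(x@data)[3L] - 1L), "invalidInput")
  x@data[, , i + 1L]
})

#' Trajectories of a collection
#' @param x a `TrackCollection`.
#' @return list of per-trajectory data.frames.
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))

#' @rdname trajectories
#' @export
setMethod("trajectories", "TrackCollection", function(x) x@trajectories)

#' Tracks of a collection or ground truth as one tidy table
#' @param x a `TrackCollection` or `GroundTruth`.
#' @return data.frame with columns `frame`, `cell_id`, `cx`, `cy`, `a`, `b`,
#'   `theta` (plus `hyp` for collections).
#' @export
setGeneric("trackTable", function(x) standardGeneric("trackTable"))

#' @rdname trackTable
#' @export
setMethod("trackTable", "TrackCollection", function(x) {
  if (length(x@trajectories) == 0L)
    return(data.frame(frame = integer(0), cell_id = integer(0),
                      cx = numeric(0), cy = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0), hyp = integer(0)))
  out <- do.call(rbind, lapply(seq_along(x@trajectories), function(i) {
    tr <- x@trajectories[[i]]
    data.frame(frame = tr$frame, cell_id = i, cx = tr$cx, cy = tr$cy,
               a = tr$a, b = tr$b, theta = tr$theta, hyp = tr$hyp)
  }))
  rownames(out) <- NULL
  out[order(out$frame, out$cell_id), , drop = FALSE]
})

#' @rdname trackTable
#' @export
setMethod("trackTable", "GroundTruth", function(x) x@tracks)

#' Elongation factor of a cell shape
#'
#' The aspect ratio of the shape: the length of the major axis divided by
#' the length of the minor axis of the ellipse that best fits the object
#' (for a polygon outline, the second-moment best-fit ellipse of its
#' interior).
#'
#' @param shape an [Ellipse-class] or [CellOutline-class].
#' @return numeric(1) `>= 1`.
#' @examples
#' elongationFactor(Ellipse(0, 0, 4, 2))  # 2
#' @export
setGeneric("elongationFactor", function(shape) {
  standardGeneric("elongationFactor")
})
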