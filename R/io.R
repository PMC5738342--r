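# I/O for the standard interchange formats: multi-page grayscale TIFF
# stacks, tracking CSV (frame,cell_id,cx,cy,a,b,theta), hypothesis CSV and
# flat key-value run configuration files.

#' Read a multi-page grayscale TIFF as an ImageStack
#'
#' 8-, 16- and 32-bit grayscale TIFFs are supported; integer inputs are
#' read with their native integer values so that a write/read round trip is
#' bit-identical.
#'
#' @param path TIFF file.
#' @param pixelSize um/px calibration to attach.
#' @param frameInterval s/frame calibration to attach.
#' @return An [ImageStack-class].
#' @export
readStack <- function(path, pixelSize = 1, frameInterval = 60) {
  if (!file.exists(path))
    ptStop(sprintf("no such file: %s", path), "invalidInput")
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e)
      ptStop(sprintf("cannot parse '%s' (file size %d bytes): %s", path,
                     file.size(path), conditionMessage(e)), "parseError"))
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3L)
      ptStop(sprintf(
        "multi-channel TIFF (H x W x %d channel layout) is unsupported; %s",
        dim(p)[3L], "expected single-channel grayscale"),
        "unsupportedFormat")
  }
  arr <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (!identical(dim(p), dim(pages[[1L]])))
      ptStop("pages have inconsistent dimensions", "unsupportedFormat")
    # integer samples come back normalised to [0, 1]; restore the native
    # integer values so integer round trips are exact. Float (32-bit)
    # pages carry no bits.per.sample attribute and are used as stored.
    bps <- attr(p, "bits.per.sample")
    if (!is.null(bps) && bps <= 16) p <- round(p * (2^bps - 1))
    arr[, , i] <- p
  }
  ImageStack(arr, pixelSize, frameInterval)
}

#' Write an ImageStack as a multi-page TIFF
#'
#' @param stack an [ImageStack-class] (or numeric array / list of
#'   matrices / [ForegroundMap-class] list).
#' @param path output file.
#' @param bitsPerSample 8 or 16 for integer output (values are stored as
#'   integers on that scale), 32 for float output (values stored as-is;
#'   probabilities in `[0, 1]` are typical).
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, bitsPerSample = 16) {
  if (is(stack, "ImageStack")) arr <- stack@data
  else if (is.list(stack)) {
    mats <- lapply(stack, function(m)
      if (is(m, "ForegroundMap")) m@probs else m)
    arr <- array(unlist(mats), dim = c(dim(mats[[1L]]), length(mats)))
  } else arr <- stack
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  pages <- lapply(seq_len(dim(arr)[3L]), function(i) {
    m <- arr[, , i]
    if (bitsPerSample %in% c(8, 16)) m / (2^bitsPerSample - 1) else m
  })
  if (bitsPerSample == 32 &&
      any(vapply(pages, function(m) any(m < 0 | m > 1), logical(1))))
    ptStop("32-bit float output stores values in [0, 1]; rescale first",
           "invalidInput")
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitsPerSample))
  invisible(path)
}

trackCsvCols <- c("frame", "cell_id", "cx", "cy", "a", "b", "theta")

#' Read tracks from CSV
#'
#' Expects the schema `frame,cell_id,cx,cy,a,b,theta` (0-based frames, px
#' units); each cell's frames must be contiguous. Orientations are wrapped
#' into `[0, pi)`.
#'
#' @param path CSV file.
#' @return A [TrackCollection-class] (with `hyp = NA`).
#' @export
readTracks <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(trackCsvCols, names(df))
  if (length(missing))
    ptStop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
           "schemaError")
  if (nrow(df) == 0L) return(TrackCollection(list()))
  df$theta <- wrapTheta(df$theta)
  trs <- lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    if (nrow(d) > 1L && any(diff(d$frame) != 1L))
      ptStop(sprintf("non-contiguous frames for cell_id %s", d$cell_id[1L]),
             "validationError")
    data.frame(frame = as.integer(d$frame), hyp = NA_integer_, cx = d$cx,
               cy = d$cy, a = d$a, b = d$b, theta = d$theta)
  })
  names(trs) <- NULL
  TrackCollection(trs)
}

#' Write tracks to CSV
#'
#' @param collection a [TrackCollection-class] or [GroundTruth-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(collection, path) {
  tab <- trackTable(collection)
  tab <- tab[, trackCsvCols, drop = FALSE]
  num <- c("cx", "cy", "a", "b", "theta")
  tab[num] <- lapply(tab[num], function(x) signif(x, 6))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write blob hypotheses CSV
#'
#' Schema: `frame,id,cx,cy,a,b,theta,support` (header required, 0-based
#' frames, px units).
#'
#' @param path CSV file.
#' @return data.frame of hypotheses.
#' @export
readHypotheses <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "id", "cx", "cy", "a", "b", "theta", "support")
  missing <- setdiff(need, names(df))
  if (length(missing))
    ptStop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
           "schemaError")
  df$theta <- wrapTheta(df$theta)
  df[, c("id", "frame", "cx", "cy", "a", "b", "theta", "support")]
}

#' @param hyps hypothesis data.frame.
#' @rdname readHypotheses
#' @export
writeHypotheses <- function(hyps, path) {
  tab <- hyps[, c("frame", "id", "cx", "cy", "a", "b", "theta", "support")]
  num <- c("cx", "cy", "a", "b", "theta", "support")
  tab[num] <- lapply(tab[num], function(x) signif(x, 6))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value` (comments with `#`). Keys must belong to
#' the declared parameter set; unknown keys are rejected.
#'
#' @param path configuration file.
#' @return named list of numeric values.
#' @export
readRunConfig <- function(path) {
  known <- c(
    "pixel_size_um", "frame_interval_s", "seed",
    "unary_scale", "beta", "gamma_max", "truncation_q", "n_cliques",
    "temperature", "feature_radius", "tau", "min_axis", "max_axis",
    "max_iou", "sigma_pos", "sigma_shape", "sigma_theta", "log_birth",
    "log_death", "log_coverage", "kappa_overlap", "n_iter", "burn_in",
    "n_cells", "field_h", "field_w", "n_frames", "noise_sd")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      ptStop(sprintf("malformed config line: '%s'", ln), "configurationError")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% known)
      ptStop(sprintf("unknown configuration key: '%s'", key),
             "configurationError")
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num))
      ptStop(sprintf("non-numeric value for '%s': '%s'", key, val),
             "configurationError")
    out[[key]] <- num
  }
  out
}
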