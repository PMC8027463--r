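#' Calibration profile for a video source
#'
#' Bundles the spatial and temporal sampling of an acquisition: how many
#' micrometres one pixel spans and how many frames are captured per second.
#' Both are required and have no defaults: the micron-per-pixel value depends
#' on the slit-lamp magnification and camera sensor and must be supplied by
#' the user from their own calibration.
#'
#' @param pixel_scale_um Micrometres per pixel (positive).
#' @param frame_rate_fps Frames per second (positive).
#' @param roi Optional integer vector `c(row0, col0, row1, col1)` (1-based,
#'   inclusive) restricting analysis to a rectangle.
#' @return An object of class `calibration_profile`.
#' @export
calibration_profile <- function(pixel_scale_um, frame_rate_fps, roi = NULL) {
  stopifnot(is.numeric(pixel_scale_um), length(pixel_scale_um) == 1L,
            is.finite(pixel_scale_um), pixel_scale_um > 0)
  stopifnot(is.numeric(frame_rate_fps), length(frame_rate_fps) == 1L,
            is.finite(frame_rate_fps), frame_rate_fps > 0)
  if (!is.null(roi)) {
    stopifnot(is.numeric(roi), length(roi) == 4L, roi[1] <= roi[3], roi[2] <= roi[4],
              all(roi >= 1))
  }
  structure(
    list(pixel_scale_um = as.numeric(pixel_scale_um),
         frame_rate_fps = as.numeric(frame_rate_fps),
         roi = roi),
    class = "calibration_profile"
  )
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("<calibration_profile> %.4g um/px, %.4g fps\n",
              x$pixel_scale_um, x$frame_rate_fps))
  invisible(x)
}

#' Read a calibration profile from JSON
#'
#' Expects a JSON object with fields `pixel_scale_um` and `frame_rate_fps`
#' (and optionally `roi`).
#'
#' @param path Path to a JSON file.
#' @return A [calibration_profile()].
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$pixel_scale_um) || is.null(obj$frame_rate_fps)) {
    stop("calibration JSON must define 'pixel_scale_um' and 'frame_rate_fps'")
  }
  calibration_profile(obj$pixel_scale_um, obj$frame_rate_fps, roi = obj$roi)
}

#' Construct a frame stack
#'
#' A frame stack is the raw material of the pipeline: a `H x W x T` numeric
#' array of intensities in `[0, 1]` plus its calibration. All downstream
#' stages (stabilization, vessel mapping, velocimetry) consume this container.
#'
#' @param frames Numeric array `H x W x T` (a matrix is promoted to `T = 1`,
#'   which is rejected: at least two frames are required).
#' @param calibration A [calibration_profile()].
#' @param source_id Label for the subject/eye/view the video came from.
#' @return An object of class `frame_stack` with elements `frames`,
#'   `calibration`, `source_id`.
#' @export
frame_stack <- function(frames, calibration, source_id = "stack") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3] < 2L) {
    stop("degenerate input: a frame stack needs at least 2 frames")
  }
  rng <- range(frames, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("frame intensities must lie in [0, 1]; rescale on load")
  }
  stopifnot(inherits(calibration, "calibration_profile"))
  structure(
    list(frames = frames, calibration = calibration,
         source_id = as.character(source_id)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> '%s': %d frames of %d x %d, %.4g um/px @ %.4g fps\n",
              x$source_id, d[3], d[1], d[2],
              x$calibration$pixel_scale_um, x$calibration$frame_rate_fps))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

# Reduce an H x W x C colour plane array to a single analysis channel.
# Erythrocyte (haemoglobin) contrast is strongest in green, the default.
collapse_channel <- function(img, channel = c("green", "luma")) {
  channel <- match.arg(channel)
  if (is.matrix(img)) return(img)
  nc <- dim(img)[3]
  if (nc == 1L) return(img[, , 1L])
  if (channel == "green") {
    img[, , 2L]
  } else {
    # Rec.601 luma
    0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  }
}

#' Load a video as a frame stack
#'
#' Reads a multi-page TIFF or a directory of numbered PNG/TIFF frames into a
#' calibrated [frame_stack()]. Colour sources are reduced to a single
#' analysis channel (green by default). Intensities are rescaled to
#' `[0, 1]` regardless of the source bit depth (the TIFF/PNG readers already
#' deliver that normalization for integer payloads).
#'
#' Frame directories are ordered by the natural numeric value embedded in
#' each file name (`frame_0002.png` before `frame_0010.png`), so
#' lexicographic quirks cannot scramble time.
#'
#' @param path Multi-page TIFF file or directory of `.png`/`.tif` frames.
#' @param calibration A [calibration_profile()]; required, no default.
#' @param channel Analysis channel for colour sources: `"green"` or `"luma"`.
#' @param source_id Optional label; defaults to the file/directory name.
#' @return A [frame_stack()].
#' @export
load_stack <- function(path, calibration, channel = c("green", "luma"),
                       source_id = NULL) {
  channel <- match.arg(channel)
  if (is.null(source_id)) source_id <- basename(path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) < 2L) stop("degenerate input: fewer than 2 frames in ", path)
    num <- suppressWarnings(as.numeric(gsub("\\D+", "", basename(files))))
    if (anyNA(num)) num <- seq_along(files)
    files <- files[order(num)]
    frames <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
      collapse_channel(img, channel)
    })
  } else if (file.exists(path)) {
    if (!grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
      stop("unsupported video container: ", path,
           " (supported: multi-page TIFF, PNG/TIFF frame directory)")
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L) stop("degenerate input: fewer than 2 frames in ", path)
    frames <- lapply(pages, collapse_channel, channel = channel)
  } else {
    stop("cannot read '", path, "': no such file or directory")
  }
  d1 <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d1), logical(1))
  if (!all(same)) stop("format error: frames have mixed sizes")
  arr <- array(unlist(frames, use.names = FALSE), dim = c(d1, length(frames)))
  arr[arr < 0] <- 0
  arr[arr > 1] <- 1
  frame_stack(arr, calibration, source_id = source_id)
}

#' Save a frame stack as a multi-page 16-bit TIFF
#'
#' Round-trips with [load_stack()] to within one part in 65535 per pixel
#' (16-bit quantization).
#'
#' @param stack A [frame_stack()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(n_frames(stack)), function(t) stack$frames[, , t])
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF to '", path, "'")
  invisible(path)
}
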