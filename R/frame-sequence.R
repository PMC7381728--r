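#' Contrast-mode image sequence
#'
#' A `frame_sequence` is a time-ordered stack of 2D contrast-mode frames with
#' the acquisition metadata needed for perfusion quantification: frame rate,
#' pixel spacing and the intensity scale (linear echo-power units or
#' log-compressed video codes). It is the raw material from which
#' time-intensity curves are extracted.
#'
#' Frame `i` (1-based) is timestamped `acquisition_start + (i - 1) / frame_rate`
#' seconds; no per-frame timing jitter is modelled.
#'
#' @param frames numeric array, `rows x cols x n_frames`, finite and
#'   non-negative on the linear scale. At least 2 frames.
#' @param frame_rate frames per second (Hz), positive.
#' @param pixel_spacing physical pixel size in mm, length 1 (isotropic) or 2
#'   `(row, col)`.
#' @param acquisition_start time of the first frame in seconds (default 0).
#' @param intensity_scale either `"linear"` or a list
#'   `list(type = "log_compressed", dynamic_range = <dB>, max_code = <code>,
#'   reference = <linear a.u. mapped to max_code>)`.
#'
#' @return An object of class `frame_sequence`.
#' @seealso [extract_tic()], [linearize()], [write_sequence()]
#' @export
frame_sequence <- function(frames, frame_rate, pixel_spacing,
                           acquisition_start = 0,
                           intensity_scale = "linear") {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a rows x cols x n_frames array", call. = FALSE)
  }
  if (dim(frames)[3] < 2L) stop("a frame_sequence needs at least 2 frames", call. = FALSE)
  if (any(!is.finite(frames))) stop("frame intensities must be finite", call. = FALSE)
  stop_if_not_scalar_pos(frame_rate, "frame_rate")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0)) {
    stop("`pixel_spacing` must be one or two positive values (mm)", call. = FALSE)
  }
  scale <- normalize_intensity_scale(intensity_scale)
  if (scale$type == "linear" && any(frames < 0)) {
    stop("linear-scale intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(
      frames = frames,
      frame_rate = frame_rate,
      pixel_spacing = as.numeric(pixel_spacing),
      acquisition_start = as.numeric(acquisition_start),
      intensity_scale = scale
    ),
    class = "frame_sequence"
  )
}

normalize_intensity_scale <- function(scale) {
  if (is.character(scale) && length(scale) == 1L && scale == "linear") {
    return(list(type = "linear"))
  }
  if (is.list(scale) && identical(scale$type, "linear")) return(list(type = "linear"))
  if (is.list(scale) && identical(scale$type, "log_compressed")) {
    if (is.null(scale$dynamic_range) || !is.finite(scale$dynamic_range) ||
        scale$dynamic_range <= 0) {
      stop("log_compressed scale requires a positive `dynamic_range` (dB)", call. = FALSE)
    }
    if (is.null(scale$max_code) || scale$max_code <= 0) {
      stop("log_compressed scale requires a positive `max_code`", call. = FALSE)
    }
    return(list(type = "log_compressed",
                dynamic_range = as.numeric(scale$dynamic_range),
                max_code = as.numeric(scale$max_code),
                reference = as.numeric(scale$reference %||% NA_real_)))
  }
  stop("`intensity_scale` must be \"linear\" or a log_compressed spec", call. = FALSE)
}

#' Frame timestamps of a sequence
#'
#' @param seq a [frame_sequence()].
#' @return Numeric vector of frame times in seconds.
#' @export
frame_times <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  seq$acquisition_start + (seq_len(dim(seq$frames)[3]) - 1) / seq$frame_rate
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d x %d pixels, %d frames @ %.3g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[3] / x$frame_rate))
  cat(sprintf("  pixel spacing: %.3g x %.3g mm; intensity scale: %s\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$intensity_scale$type))
  invisible(x)
}

#' Region-of-interest mask set
#'
#' Named set of binary 2D masks aligned to a sequence's frame shape. The labels
#' `treated` (sonopermeated focal zone), `control` (reference region outside
#' the treated area) and `background` are conventional but any labels are
#' allowed.
#'
#' @param ... named logical/0-1 matrices, or a single named list of them.
#' @return An object of class `region_mask_set`.
#' @export
region_mask_set <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1]]) && !is.matrix(masks[[1]])) {
    masks <- masks[[1]]
  }
  if (length(masks) == 0L || is.null(names(masks)) || any(names(masks) == "")) {
    stop("masks must be supplied as named matrices", call. = FALSE)
  }
  shp <- NULL
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.matrix(m)) stop(sprintf("mask '%s' is not a matrix", nm), call. = FALSE)
    m <- matrix(as.logical(m), nrow(m), ncol(m))
    if (anyNA(m)) stop(sprintf("mask '%s' contains NA", nm), call. = FALSE)
    if (is.null(shp)) shp <- dim(m)
    if (!identical(dim(m), shp)) {
      stop("all masks must share the same shape", call. = FALSE)
    }
    masks[[nm]] <- m
  }
  structure(masks, class = "region_mask_set")
}

#' @export
print.region_mask_set <- function(x, ...) {
  cat(sprintf("<region_mask_set> %d x %d pixels\n", nrow(x[[1]]), ncol(x[[1]])))
  for (nm in names(x)) cat(sprintf("  %-12s %d px\n", nm, sum(x[[nm]])))
  invisible(x)
}

check_masks_match <- function(seq, masks) {
  d <- dim(seq$frames)
  if (!identical(dim(masks[[1]]), d[1:2])) {
    stop(sprintf("mask shape %d x %d does not match frame shape %d x %d",
                 nrow(masks[[1]]), ncol(masks[[1]]), d[1], d[2]), call. = FALSE)
  }
  invisible(TRUE)
}
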