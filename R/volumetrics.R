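# 3D volumetrics from stepped 2D sweeps: tumor volume from stacked B-mode
# masks and contrast-derived blood volume, under a slab model where each
# slice represents a slab of thickness equal to the sweep step.

#' Stepped 2D sweep volume
#'
#' An ordered stack of 2D slices acquired by sweeping the transducer across
#' the tumor in fixed increments, with per-slice binary tumor masks and an
#' optional contrast-mode channel.
#'
#' @param tumor_masks list of logical matrices (one per slice), all the same
#'   shape.
#' @param step distance between consecutive slices, mm.
#' @param pixel_spacing in-plane pixel size, mm (scalar or `(row, col)`).
#' @param contrast optional list of numeric matrices (linear-scale contrast
#'   intensities), aligned with `tumor_masks`.
#' @param contrast_threshold intensity threshold below which contrast pixels
#'   are treated as non-vascular (default 0).
#' @param intensity_scale `"linear"` (required for contrast quantification)
#'   or `"log_compressed"`.
#' @return An object of class `sweep_volume`.
#' @export
sweep_volume <- function(tumor_masks, step, pixel_spacing, contrast = NULL,
                         contrast_threshold = 0, intensity_scale = "linear") {
  stop_if_not_scalar_pos(step, "step")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) stop("`pixel_spacing` must be positive", call. = FALSE)
  if (!length(tumor_masks)) stop("at least one slice mask is required", call. = FALSE)
  shp <- dim(tumor_masks[[1]])
  tumor_masks <- lapply(tumor_masks, function(m) {
    if (!identical(dim(m), shp)) stop("all slices must share one shape", call. = FALSE)
    matrix(as.logical(m), shp[1], shp[2])
  })
  if (!is.null(contrast)) {
    if (length(contrast) != length(tumor_masks)) {
      stop("`contrast` must have one slice per mask", call. = FALSE)
    }
    lapply(contrast, function(s) {
      if (!identical(dim(s), shp)) stop("contrast slices must match mask shape", call. = FALSE)
    })
  }
  structure(list(tumor_masks = tumor_masks, step = step,
                 pixel_spacing = as.numeric(pixel_spacing), contrast = contrast,
                 contrast_threshold = contrast_threshold,
                 intensity_scale = intensity_scale),
            class = "sweep_volume")
}

#' @export
print.sweep_volume <- function(x, ...) {
  cat(sprintf("<sweep_volume> %d slices (%d x %d px), step %.3g mm, spacing %.3g x %.3g mm%s\n",
              length(x$tumor_masks), nrow(x$tumor_masks[[1]]), ncol(x$tumor_masks[[1]]),
              x$step, x$pixel_spacing[1], x$pixel_spacing[2],
              if (is.null(x$contrast)) "" else ", with contrast channel"))
  invisible(x)
}

#' Tumor volume from a sweep
#'
#' Slab-model tumor volume: every slice contributes its mask area times the
#' sweep step, `TV = sum(mask pixels) * spacing_row * spacing_col * step`.
#'
#' @param sweep a [sweep_volume()].
#' @return Tumor volume in mm^3.
#' @export
tumor_volume <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_volume"))
  if (is.null(sweep$tumor_masks)) stop("sweep has no tumor masks", call. = FALSE)
  px <- sum(vapply(sweep$tumor_masks, sum, 0))
  px * sweep$pixel_spacing[1] * sweep$pixel_spacing[2] * sweep$step
}

#' Contrast-derived blood volume from a sweep
#'
#' Sums linear-scale contrast intensity over tumor-mask pixels exceeding the
#' sweep's contrast threshold ("arbitrary pixel units"); sub-threshold pixels
#' contribute 0. With `statistic = "count"` the supra-threshold pixel count is
#' returned instead of the intensity sum.
#'
#' @param sweep a [sweep_volume()] with a contrast channel.
#' @param statistic `"sum"` (default) or `"count"`.
#' @return Summed supra-threshold contrast (a.u.) or pixel count.
#' @export
contrast_blood_volume <- function(sweep, statistic = c("sum", "count")) {
  stopifnot(inherits(sweep, "sweep_volume"))
  statistic <- match.arg(statistic)
  if (is.null(sweep$contrast)) stop("sweep has no contrast channel", call. = FALSE)
  if (!identical(sweep$intensity_scale, "linear")) {
    stop("contrast channel is not on the linear scale; linearize before quantifying",
         call. = FALSE)
  }
  thr <- sweep$contrast_threshold
  total <- 0
  for (k in seq_along(sweep$contrast)) {
    v <- sweep$contrast[[k]][sweep$tumor_masks[[k]]]
    v <- v[v > thr]
    total <- total + if (statistic == "sum") sum(v) else length(v)
  }
  total
}

#' Tumor-volume-normalized blood volume
#'
#' `RBV / TV`: contrast-derived blood volume per unit tumor volume, the
#' vascularity metric used to compare phantoms/tumors of different sizes.
#' Accepts either a [sweep_volume()] (both quantities are computed from it) or
#' two numbers.
#'
#' @param rbv contrast-derived blood volume (a.u.), or a [sweep_volume()].
#' @param tv tumor volume (mm^3); ignored when `rbv` is a sweep.
#' @return Normalized RBV, a.u./mm^3.
#' @export
normalized_rbv <- function(rbv, tv = NULL) {
  if (inherits(rbv, "sweep_volume")) {
    tv <- tumor_volume(rbv)
    rbv <- contrast_blood_volume(rbv)
  }
  stopifnot(is.numeric(rbv), is.numeric(tv))
  if (tv <= 0) stop("tumor volume must be > 0 to normalize", call. = FALSE)
  rbv / tv
}

#' Full volumetric summary of a sweep
#'
#' @param sweep a [sweep_volume()] with a contrast channel.
#' @return A one-row data.frame with `tv_mm3`, `rbv_au`, `normalized_rbv`,
#'   `contrast_threshold`, `n_slices`.
#' @export
volumetrics_result <- function(sweep) {
  tv <- tumor_volume(sweep)
  rbv <- contrast_blood_volume(sweep)
  data.frame(tv_mm3 = tv, rbv_au = rbv,
             normalized_rbv = if (tv > 0) rbv / tv else NA_real_,
             contrast_threshold = sweep$contrast_threshold,
             n_slices = length(sweep$tumor_masks))
}
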