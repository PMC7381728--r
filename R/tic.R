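#' Time-intensity curve
#'
#' Mean linear-scale contrast intensity over an ROI, one value per frame.
#'
#' @param times frame times, seconds, strictly increasing.
#' @param intensities linear-scale ROI-mean intensities, `>= 0`, same length
#'   as `times`.
#' @param roi_label label of the ROI the curve was taken from.
#' @param n_pixels number of pixels in the ROI.
#' @return An object of class `tic`.
#' @export
tic <- function(times, intensities, roi_label = "roi", n_pixels = NA_integer_) {
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) {
    stop("`times` and `intensities` must have the same length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  structure(list(times = times, intensities = intensities,
                 roi_label = roi_label, n_pixels = as.integer(n_pixels)),
            class = "tic")
}

#' @export
print.tic <- function(x, ...) {
  cat(sprintf("<tic> roi '%s': %d samples over %.1f s (%s px), range [%.3g, %.3g] a.u.\n",
              x$roi_label, length(x$times), diff(range(x$times)),
              ifelse(is.na(x$n_pixels), "?", x$n_pixels),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
plot.tic <- function(x, ...) {
  plot(x$times, x$intensities, type = "l", xlab = "time (s)",
       ylab = "mean intensity (a.u.)", main = sprintf("TIC: %s", x$roi_label), ...)
  invisible(x)
}

#' @export
as.data.frame.tic <- function(x, ...) {
  data.frame(time_s = x$times, intensity = x$intensities,
             roi = x$roi_label, n_pixels = x$n_pixels)
}

#' Extract an ROI time-intensity curve from a sequence
#'
#' Computes, for every frame, the arithmetic mean of the linear-scale
#' intensities over the ROI's pixels. If a background label is given, that
#' ROI's per-frame mean is subtracted first and negative values are clamped
#' to 0. Log-compressed sequences must be passed through [linearize()] first;
#' averaging video codes would bias every downstream perfusion parameter.
#'
#' @param seq a linear-scale [frame_sequence()].
#' @param masks a [region_mask_set()] matching the frame shape.
#' @param label ROI label to extract.
#' @param background_label optional label of a background ROI to subtract.
#' @return A [tic()].
#' @export
extract_tic <- function(seq, masks, label, background_label = NULL) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(masks, "region_mask_set"))
  if (seq$intensity_scale$type != "linear") {
    stop("sequence is log-compressed; call linearize() before extracting TICs",
         call. = FALSE)
  }
  check_masks_match(seq, masks)
  roi_mean <- function(lab) {
    m <- masks[[lab]]
    if (is.null(m)) stop(sprintf("no mask labelled '%s'", lab), call. = FALSE)
    idx <- which(m)
    if (!length(idx)) stop(sprintf("mask '%s' is empty", lab), call. = FALSE)
    d <- dim(seq$frames)
    colMeans(matrix(seq$frames, d[1] * d[2], d[3])[idx, , drop = FALSE])
  }
  y <- roi_mean(label)
  if (!is.null(background_label)) {
    y <- pmax(y - roi_mean(background_label), 0)
  }
  tic(frame_times(seq), y, roi_label = label, n_pixels = sum(masks[[label]]))
}

#' Detect flash-destruction pulses on a TIC
#'
#' A flash-destruction pulse clears the microbubbles from the imaging plane,
#' so the ROI mean collapses within a frame or two. A frame is flagged when
#' its intensity has fallen by at least `drop_fraction` of the median of the
#' preceding `window` frames; flagged frames closer together than the
#' refractory period are merged to the first. Detection compares intensities
#' only as ratios, so it is invariant to global intensity scaling.
#'
#' @param tic a [tic()].
#' @param drop_fraction required fractional drop relative to the trailing
#'   median, in (0, 1). Default 0.5.
#' @param window trailing-median window length in frames.
#' @param refractory minimum spacing between distinct events, seconds.
#' @return Sorted numeric vector of event times (s); possibly empty.
#' @export
detect_flash_events <- function(tic, drop_fraction = 0.5, window = 5,
                                refractory = 5) {
  stopifnot(inherits(tic, "tic"))
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    stop("`drop_fraction` must lie in (0, 1)", call. = FALSE)
  }
  y <- tic$intensities; tt <- tic$times; n <- length(y)
  if (n <= window) return(numeric(0))
  cand <- logical(n)
  for (i in (window + 1):n) {
    m <- stats::median(y[(i - window):(i - 1)])
    if (m > 0 && y[i] <= (1 - drop_fraction) * m) cand[i] <- TRUE
  }
  times <- tt[cand]
  if (!length(times)) return(numeric(0))
  out <- times[1]
  for (t in times[-1]) if (t - out[length(out)] > refractory) out <- c(out, t)
  out
}

#' Replenishment segment of a TIC
#'
#' Portion of a TIC between a flash-destruction pulse and the next event (or
#' the end of the recording), restricted to the reflow phase and re-zeroed to
#' the onset of replenishment: `t' = t - (flash_time + recirc_delay)`.
#' Samples during the recirculation dead-time carry no kinetic information
#' (the plane is still bubble-free) and are excluded, so the fitted model
#' `y0 + A * (1 - exp(-beta * t'))` matches the data from `t' = 0`. Both the
#' flash time and the fit origin `t0` are recorded.
#'
#' @param tic a [tic()].
#' @param flash_times flash-pulse times (s), sorted, e.g. from
#'   [detect_flash_events()] or the acquisition protocol.
#' @param recirc_delay recirculation dead-time after each flash, seconds
#'   (default 30, matching a 30 s reflow gap).
#' @param end_policy `"next_flash"` ends each segment just before the next
#'   flash (or at the recording end for the last one); `"fixed"` caps each
#'   segment at `max_duration` seconds past its fit origin.
#' @param max_duration segment cap in seconds for `end_policy = "fixed"`.
#' @param start_offset_frames extra frames discarded at the segment start
#'   (default 1: the first post-delay frame may straddle the reflow onset).
#' @param min_samples segments with fewer samples are dropped with a warning
#'   (fit feasibility floor; default 8).
#' @return A list of `replenishment_segment` objects, each with fields
#'   `flash_time`, `t0`, `start`, `end`, `times` (re-zeroed), `intensities`.
#'   Dropped segments are reported in the `"dropped"` attribute.
#' @export
segment_replenishment <- function(tic, flash_times, recirc_delay = 30,
                                  end_policy = c("next_flash", "fixed"),
                                  max_duration = NULL,
                                  start_offset_frames = 1, min_samples = 8) {
  stopifnot(inherits(tic, "tic"))
  end_policy <- match.arg(end_policy)
  if (length(flash_times) && is.unsorted(flash_times)) {
    stop("`flash_times` must be sorted", call. = FALSE)
  }
  if (recirc_delay < 0) stop("`recirc_delay` must be >= 0", call. = FALSE)
  dt <- stats::median(diff(tic$times))
  segs <- list(); dropped <- numeric(0)
  for (j in seq_along(flash_times)) {
    fj <- flash_times[j]
    t0 <- fj + recirc_delay
    start <- t0 + start_offset_frames * dt
    end <- if (j < length(flash_times)) flash_times[j + 1] - dt / 2 else max(tic$times)
    if (end_policy == "fixed") {
      if (is.null(max_duration)) stop("`max_duration` required for end_policy 'fixed'",
                                      call. = FALSE)
      end <- min(end, t0 + max_duration)
    }
    sel <- tic$times > start & tic$times <= end
    if (sum(sel) < min_samples) {
      warning(sprintf("segment after flash at %.1f s has %d < %d samples; dropped",
                      fj, sum(sel), min_samples), call. = FALSE)
      dropped <- c(dropped, fj)
      next
    }
    segs[[length(segs) + 1L]] <- structure(
      list(flash_time = fj, t0 = t0, start = min(tic$times[sel]), end = end,
           times = tic$times[sel] - t0, intensities = tic$intensities[sel],
           roi_label = tic$roi_label),
      class = "replenishment_segment"
    )
  }
  attr(segs, "dropped") <- dropped
  segs
}

#' @export
print.replenishment_segment <- function(x, ...) {
  cat(sprintf("<replenishment_segment> flash %.1f s, fit origin %.1f s, %d samples on t' = [%.2f, %.2f] s\n",
              x$flash_time, x$t0, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
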