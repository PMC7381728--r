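# Readers and writers: multi-page TIFF sequences with JSON sidecars, label
# masks (TIFF/PNG), YAML protocol configs, CSV/JSON result tables.

sidecar_path <- function(path) sub("\\.tiff?$", "", path)

#' Write a sequence as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 32-bit TIFF samples. TIFF samples live in \[0, 1\], so
#' frames are divided by a power-of-two scale factor (recorded in the sidecar
#' and undone on read); the round trip is lossless to the 2^-32 sample
#' quantization, i.e. well below 1e-6 relative. The sidecar carries
#' `frame_rate`, `acquisition_start`, `pixel_spacing` and the intensity scale
#' (including log-compression parameters when present).
#'
#' @param seq a [frame_sequence()].
#' @param path output path; `.tif` is appended when missing. The sidecar is
#'   written next to it with extension `.json`.
#' @return Invisibly, the TIFF path.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  base <- sidecar_path(path)
  tif <- paste0(base, ".tif")
  mx <- max(seq$frames)
  scale_factor <- if (mx <= 0) 1 else 2^ceiling(log2(mx))
  pages <- lapply(seq_len(dim(seq$frames)[3]),
                  function(i) seq$frames[, , i] / scale_factor)
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    format = "sonoperf-sequence-v1",
    frame_rate = seq$frame_rate,
    acquisition_start = seq$acquisition_start,
    pixel_spacing = seq$pixel_spacing,
    intensity_scale = seq$intensity_scale,
    scale_factor = scale_factor,
    n_frames = dim(seq$frames)[3]
  )
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(tif)
}

#' Read a sequence from multi-page TIFF plus JSON sidecar
#'
#' The sidecar is required and validated: a missing `frame_rate` (or other
#' corrupt metadata) is a hard error naming the missing field, never guessed.
#'
#' @param path path to the `.tif` file (or its basename).
#' @param format only `"tiff"` (multi-page TIFF + JSON sidecar) is supported.
#' @return A [frame_sequence()].
#' @export
read_sequence <- function(path, format = "tiff") {
  format <- match.arg(format, "tiff")
  base <- sidecar_path(path)
  tif <- paste0(base, ".tif")
  side <- paste0(base, ".json")
  if (!file.exists(tif)) stop(sprintf("no such file: %s", tif), call. = FALSE)
  if (!file.exists(side)) stop(sprintf("sidecar missing: %s", side), call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("frame_rate", "pixel_spacing", "scale_factor")) {
    if (is.null(meta[[field]]) || !is.numeric(meta[[field]])) {
      stop(sprintf("%s missing from sidecar %s", field, side), call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (any(!vapply(pages, function(p) identical(dim(p), shp), TRUE))) {
    stop("mixed frame shapes in TIFF", call. = FALSE)
  }
  frames <- array(unlist(pages), dim = c(shp[1], shp[2], length(pages)))
  frames <- frames * meta$scale_factor
  scale <- meta$intensity_scale
  if (is.data.frame(scale)) scale <- as.list(scale)
  frame_sequence(frames, frame_rate = meta$frame_rate,
                 pixel_spacing = meta$pixel_spacing,
                 acquisition_start = meta$acquisition_start %||% 0,
                 intensity_scale = scale %||% "linear")
}

#' Linearize a log-compressed sequence
#'
#' Undoes amplitude (20 log10) video compression:
#' `v_lin = 10^((v / max_code - 1) * dynamic_range / 20)`, so the maximum code
#' maps to 1.0 and code 0 to the dynamic-range floor `10^(-DR/20)`. The
#' linear reference (the linear intensity originally mapped to `max_code`, if
#' recorded) is preserved in the `"linear_reference"` attribute. Already-linear
#' input is returned unchanged (a copy) with a message, so the operation is
#' idempotent.
#'
#' @param seq a [frame_sequence()].
#' @return A linear-scale [frame_sequence()] with intensities in
#'   `[10^(-DR/20), 1]`.
#' @seealso [log_compress()]
#' @export
linearize <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (seq$intensity_scale$type == "linear") {
    message("sequence already linear; nothing to do")
    return(seq)
  }
  dr <- seq$intensity_scale$dynamic_range
  mc <- seq$intensity_scale$max_code
  if (is.null(dr) || !is.finite(dr)) stop("unknown dynamic range", call. = FALSE)
  lin <- 10^((seq$frames / mc - 1) * dr / 20)
  out <- frame_sequence(lin, seq$frame_rate, seq$pixel_spacing,
                        seq$acquisition_start, intensity_scale = "linear")
  attr(out, "linear_reference") <- seq$intensity_scale$reference
  out
}

#' Log-compress a linear sequence
#'
#' Amplitude compression to video codes:
#' `v = max_code * (1 + 20 * log10(y / reference) / dynamic_range)`, clipped to
#' `[0, max_code]`. Codes are kept continuous (not quantized to integers) so
#' that compress -> linearize round trips are accurate to well under 0.1%.
#'
#' @param seq a linear-scale [frame_sequence()].
#' @param dynamic_range displayed dynamic range, dB.
#' @param max_code code mapped to the reference intensity (e.g. 255).
#' @param reference linear intensity mapped to `max_code`; defaults to the
#'   sequence maximum. Recorded in the output's intensity scale.
#' @return A log-compressed [frame_sequence()].
#' @export
log_compress <- function(seq, dynamic_range = 60, max_code = 255,
                         reference = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (seq$intensity_scale$type != "linear") {
    stop("sequence is already log-compressed", call. = FALSE)
  }
  reference <- reference %||% max(seq$frames)
  if (reference <= 0) stop("reference intensity must be > 0", call. = FALSE)
  u <- seq$frames / reference
  v <- max_code * (1 + 20 * log10(pmax(u, .Machine$double.xmin)) / dynamic_range)
  v <- pmin(pmax(v, 0), max_code)
  frame_sequence(array(v, dim(seq$frames)), seq$frame_rate, seq$pixel_spacing,
                 seq$acquisition_start,
                 intensity_scale = list(type = "log_compressed",
                                        dynamic_range = dynamic_range,
                                        max_code = max_code,
                                        reference = reference))
}

#' Write a region mask set as label image(s)
#'
#' Writes one 8-bit label TIFF (labels 1..n in mask order) plus a JSON file
#' mapping label values to names.
#'
#' @param masks a [region_mask_set()].
#' @param path output basename; `.tif` and `.json` are appended.
#' @return Invisibly, the TIFF path.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "region_mask_set"))
  base <- sidecar_path(path)
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  tiff::writeTIFF(lab / 255, paste0(base, ".tif"), bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(as.list(stats::setNames(seq_along(masks), names(masks))),
                       paste0(base, ".json"), auto_unbox = TRUE)
  invisible(paste0(base, ".tif"))
}

#' Read a region mask set from a label image
#'
#' Accepts an 8-bit label TIFF or PNG; label-to-name mapping comes from the
#' JSON written by [write_masks()] (or labels are named `region_<k>`).
#'
#' @param path path to the label image.
#' @return A [region_mask_set()].
#' @export
read_masks <- function(path) {
  base <- sidecar_path(sub("\\.png$", "", path))
  img_path <- if (file.exists(paste0(base, ".tif"))) paste0(base, ".tif")
              else paste0(base, ".png")
  if (!file.exists(img_path)) stop(sprintf("no such file: %s", img_path), call. = FALSE)
  img <- if (grepl("\\.png$", img_path)) png::readPNG(img_path)
         else tiff::readTIFF(img_path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  lab <- round(img * 255)
  side <- paste0(base, ".json")
  mapping <- if (file.exists(side)) {
    unlist(jsonlite::read_json(side, simplifyVector = TRUE))
  } else {
    vals <- sort(setdiff(unique(as.vector(lab)), 0))
    stats::setNames(vals, sprintf("region_%d", vals))
  }
  masks <- lapply(mapping, function(v) lab == v)
  region_mask_set(masks)
}

#' Write result tables as CSV with a JSON mirror
#'
#' Accepts a data.frame, or a (possibly empty) list of `perfusion_fit` /
#' `treatment_comparison` objects, and writes `<path>.csv` and `<path>.json`
#' with identical content: one row per (subject, ROI, phase). Numeric values
#' are written at full precision. An empty record list yields a header-only
#' CSV.
#'
#' @param records data.frame or list of fit/comparison objects.
#' @param path output basename (extensions appended).
#' @return Invisibly, the written data.frame.
#' @export
write_results <- function(records, path) {
  df <- if (is.data.frame(records)) records else results_table(records)
  base <- sub("\\.(csv|json)$", "", path)
  utils::write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(df, paste0(base, ".json"), digits = NA, na = "null")
  invisible(df)
}

# Flatten fits/comparisons into the canonical results table.
results_table <- function(records) {
  empty <- data.frame(subject = character(), roi = character(),
                      phase = character(), A = numeric(), beta = numeric(),
                      y0 = numeric(), sse = numeric(), r2 = numeric(),
                      n_samples = integer(), converged = logical())
  if (!length(records)) return(empty)
  rows <- lapply(records, function(rec) {
    if (inherits(rec, "perfusion_fit")) {
      fit_row(rec, subject = attr(rec, "subject") %||% NA_character_,
              roi = rec$roi_label %||% NA_character_,
              phase = attr(rec, "phase") %||% NA_character_)
    } else if (inherits(rec, "treatment_comparison")) {
      do.call(rbind, lapply(c("treated", "control"), function(roi) {
        do.call(rbind, lapply(c("pre", "post"), function(ph) {
          fit_row(rec$fits[[roi]][[ph]], subject = rec$subject_id,
                  roi = roi, phase = ph)
        }))
      }))
    } else {
      stop("records must be perfusion_fit or treatment_comparison objects",
           call. = FALSE)
    }
  })
  do.call(rbind, rows)
}

fit_row <- function(fit, subject, roi, phase) {
  data.frame(subject = subject, roi = roi, phase = phase,
             A = fit$A, beta = fit$beta, y0 = fit$y0, sse = fit$sse,
             r2 = fit$r2, n_samples = fit$n_samples, converged = fit$converged)
}

#' Read a protocol configuration from YAML/JSON
#'
#' Protocol files describe the acquisition/therapy run: optional explicit
#' `flash_times`, `recirculation_delay` (default 30 s), `normalization` mode,
#' `fit_offset`, `background` label and flash-detection settings.
#'
#' @param path YAML (or JSON) file.
#' @return A named list with defaults filled in (see [default_protocol()]).
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  utils::modifyList(default_protocol(), cfg)
}

#' Default monitoring protocol settings
#'
#' @return Named list: `flash_times` (NULL = auto-detect),
#'   `recirculation_delay` 30 s, `normalization` "difference", `fit_offset`
#'   TRUE, `background` NULL, `detect` (drop_fraction 0.5, window 5,
#'   refractory 5 s).
#' @export
default_protocol <- function() {
  list(flash_times = NULL, recirculation_delay = 30,
       normalization = "difference", fit_offset = TRUE, background = NULL,
       detect = list(drop_fraction = 0.5, window = 5, refractory = 5))
}
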