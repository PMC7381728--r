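# Synthetic CEUS phantom generator: the noiseless signal model, per-pixel
# image sequences, stepped 3D sweeps and multi-subject cohorts, all with
# recorded ground truth.

# Noiseless ROI signal of one region over a vector of times.
#
# Piecewise model:
#   t < first flash : infusion wash-in  y0 + A * (1 - exp(-r_in * t)),
#                     r_in chosen so ~99% of plateau is reached at
#                     infusion$time_to_steady;
#   after flash j   : y0 until recirculation_delay has elapsed, then
#                     y0 + A * (1 - exp(-beta_j * t')) with t' measured from
#                     flash_j + recirculation_delay.
# beta_j is the region's beta, times the treatment multiplier when the region
# is the treated one and j > treatment$after_flash.
region_signal <- function(times, region, config) {
  A <- region$A; beta <- region$beta; y0 <- region$y0
  tts <- config$infusion$time_to_steady %||% 300
  r_in <- log(100) / tts  # 99% of plateau at time_to_steady
  y <- y0 + A * (1 - exp(-r_in * pmax(times, 0)))
  fts <- config$flash_times
  if (length(fts)) {
    trt <- config$treatment
    for (j in seq_along(fts)) {
      bj <- beta
      if (!is.null(trt) && identical(trt$label, region$label) && j > trt$after_flash) {
        bj <- beta * trt$beta_multiplier
      }
      upper <- if (j < length(fts)) fts[j + 1] else Inf
      sel <- times >= fts[j] & times < upper
      tp <- times[sel] - fts[j] - config$recirculation_delay
      y[sel] <- ifelse(tp > 0, y0 + A * (1 - exp(-bj * tp)), y0)
    }
  }
  y
}

apply_noise <- function(x, noise) {
  n <- length(x)
  switch(noise$model,
    none = x,
    gaussian = pmax(x + stats::rnorm(n, 0, noise$scale), 0),
    gaussian_multiplicative = pmax(x * (1 + stats::rnorm(n, 0, noise$scale)), 0),
    rayleigh_multiplicative = {
      # mean-1 Rayleigh draw blended towards 1 by `scale`: factor >= 1 - scale,
      # E[factor] = 1, relative sd = scale * sqrt(4/pi - 1) ~= 0.52 * scale
      z <- sqrt(-2 * log(stats::runif(n))) / sqrt(pi / 2)
      x * ((1 - noise$scale) + noise$scale * z)
    }
  )
}

#' Simulate a region's time-intensity curve
#'
#' Evaluates the scenario's destruction-replenishment signal model for one
#' region and returns it as a [tic()]: baseline `y0` before contrast, infusion
#' wash-in to the plateau `y0 + A`, an instantaneous reset to `y0` at each
#' flash-destruction pulse, and exponential replenishment
#' `y0 + A * (1 - exp(-beta * t'))` once the recirculation delay has elapsed.
#' Noise (per the config's noise model) is applied as one draw per frame on
#' the ROI mean; pass a config with `noise$model = "none"` for the noiseless
#' expectation.
#'
#' @param config a [scenario_config()].
#' @param region_label which region to simulate.
#' @param seed optional RNG seed overriding `config$seed`.
#' @return A [tic()] with `n_pixels` set to the region's mask size.
#' @export
simulate_tic <- function(config, region_label, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  region <- config$regions[[region_label]]
  if (is.null(region)) {
    stop(sprintf("unknown region label '%s'", region_label), call. = FALSE)
  }
  times <- (seq_len(config$grid_shape[1]) - 1) / config$frame_rate
  y <- region_signal(times, region, config)
  y <- with_seed(seed, apply_noise(y, config$noise))
  n_px <- sum(build_mask(region$mask, config$grid_shape[2], config$grid_shape[3]))
  tic(times, y, roi_label = region_label, n_pixels = n_px)
}

#' Simulate a contrast image sequence with ground truth
#'
#' Renders the scenario on its pixel grid: each pixel follows its region's
#' kinetics (pixels outside every region stay at 0), noise is drawn
#' independently per pixel per frame, and, when the config requests log
#' compression, the stored frames are the compressed codes with the
#' compression parameters recorded in the sequence metadata. Identical config
#' and seed give bit-identical output.
#'
#' @param config a [scenario_config()].
#' @param seed optional RNG seed overriding `config$seed`.
#' @return A list with elements `sequence` ([frame_sequence()]), `masks`
#'   ([region_mask_set()]) and `truth` (a `ground_truth` list holding
#'   per-region pre/post `(A, beta)`, flash times, and per-pixel `A` and
#'   `beta` parameter maps).
#' @export
simulate_sequence <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  masks <- scenario_masks(config)
  nf <- config$grid_shape[1]; rows <- config$grid_shape[2]; cols <- config$grid_shape[3]
  times <- (seq_len(nf) - 1) / config$frame_rate
  px <- matrix(0, rows * cols, nf)
  A_map <- matrix(0, rows, cols)
  beta_pre_map <- matrix(NA_real_, rows, cols)
  beta_post_map <- matrix(NA_real_, rows, cols)
  truth_regions <- list()
  for (rg in config$regions) {
    idx <- which(masks[[rg$label]])
    sig <- region_signal(times, rg, config)
    px[idx, ] <- rep(sig, each = length(idx))
    mult <- if (!is.null(config$treatment) &&
                identical(config$treatment$label, rg$label)) {
      config$treatment$beta_multiplier
    } else 1
    A_map[idx] <- rg$A
    beta_pre_map[idx] <- rg$beta
    beta_post_map[idx] <- rg$beta * mult
    truth_regions[[rg$label]] <- list(A = rg$A, beta_pre = rg$beta,
                                      beta_post = rg$beta * mult, y0 = rg$y0)
  }
  px <- with_seed(seed, {
    if (config$noise$model == "none") px
    else matrix(apply_noise(as.vector(px), config$noise), nrow(px), ncol(px))
  })
  frames <- array(px, dim = c(rows, cols, nf))
  seq_out <- frame_sequence(frames, config$frame_rate, config$pixel_spacing)
  if (config$compression$model == "log") {
    seq_out <- log_compress(seq_out,
                            dynamic_range = config$compression$dynamic_range,
                            max_code = config$compression$max_code)
  }
  truth <- structure(
    list(regions = truth_regions, flash_times = config$flash_times,
         recirculation_delay = config$recirculation_delay,
         treatment = config$treatment,
         maps = list(A = A_map, beta_pre = beta_pre_map, beta_post = beta_post_map)),
    class = "ground_truth"
  )
  list(sequence = seq_out, masks = masks, truth = truth)
}

#' Simulate a stepped 2D sweep of a geometric phantom
#'
#' Emulates sweeping a linear transducer across a solid in fixed increments:
#' returns the stack of binary cross-section masks (pixel centers inside the
#' solid, slices at slab midpoints) together with the solid's closed-form
#' volume. Optionally paints a sparse "vessel" contrast pattern inside the
#' solid so contrast-derived blood volume can be exercised.
#'
#' @param shape `"sphere"` (uses `radius`), `"box"` (uses `edges`, mm
#'   `c(x, y, z)`) or `"ellipsoid"` (uses `semi_axes`, mm `c(a, b, c)`).
#' @param radius,edges,semi_axes solid dimensions in mm.
#' @param step sweep increment between slices, mm.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param contrast_fraction fraction of in-solid pixels carrying vascular
#'   contrast (0 disables the contrast channel).
#' @param contrast_intensity linear intensity of vessel pixels, a.u.
#' @param seed RNG seed for the vessel pattern.
#' @return A list with `sweep` (a [sweep_volume()]) and `analytic_volume`
#'   (mm^3, closed form).
#' @export
simulate_sweep <- function(shape = c("sphere", "box", "ellipsoid"),
                           radius = 5, edges = c(2, 3, 4), semi_axes = c(5, 4, 3),
                           step = 0.2, pixel_spacing = 0.1,
                           contrast_fraction = 0, contrast_intensity = 5,
                           seed = 1L) {
  shape <- match.arg(shape)
  stop_if_not_scalar_pos(step, "step")
  stop_if_not_scalar_pos(pixel_spacing, "pixel_spacing")
  half <- switch(shape,
    sphere = c(radius, radius, radius),
    box = edges / 2,
    ellipsoid = semi_axes
  )
  if (any(2 * half < c(pixel_spacing, pixel_spacing, step))) {
    stop("solid is smaller than one voxel at this sampling", call. = FALSE)
  }
  # pixel/slice centers on a symmetric midpoint grid covering the solid
  mid <- function(h, d) {
    n <- max(1L, ceiling(2 * h / d))
    (seq_len(n) - (n + 1) / 2) * d
  }
  xs <- mid(half[1], pixel_spacing)
  ys <- mid(half[2], pixel_spacing)
  zs <- mid(half[3], step)
  inside <- switch(shape,
    sphere = function(x, y, z) x^2 + y^2 + z^2 <= radius^2,
    box = function(x, y, z) abs(x) <= half[1] & abs(y) <= half[2] & abs(z) <= half[3],
    ellipsoid = function(x, y, z) (x / half[1])^2 + (y / half[2])^2 + (z / half[3])^2 <= 1
  )
  xg <- matrix(xs, length(xs), length(ys))
  yg <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  tumor_masks <- lapply(zs, function(z) inside(xg, yg, z))
  analytic <- switch(shape,
    sphere = 4 / 3 * pi * radius^3,
    box = prod(edges),
    ellipsoid = 4 / 3 * pi * prod(semi_axes)
  )
  contrast <- NULL
  if (contrast_fraction > 0) {
    contrast <- with_seed(seed, lapply(tumor_masks, function(m) {
      sl <- matrix(0, nrow(m), ncol(m))
      idx <- which(m)
      n_v <- round(contrast_fraction * length(idx))
      if (n_v > 0) sl[sample(idx, n_v)] <- contrast_intensity
      sl
    }))
  }
  sweep <- sweep_volume(tumor_masks = tumor_masks, step = step,
                        pixel_spacing = pixel_spacing, contrast = contrast)
  list(sweep = sweep, analytic_volume = analytic)
}

#' Simulate a cohort of monitored subjects
#'
#' Draws per-subject perfusion parameters around a template scenario and
#' applies a treatment-effect multiplier to the treated region's reperfusion
#' rate for replenishment after the first flash (the pre measurement is the
#' first-flash segment, the post measurement the final-flash segment, as in a
#' two-flash monitoring run). Per-subject seeds are derived deterministically
#' from the master seed.
#'
#' @param n_subjects number of subjects, `>= 1`.
#' @param config template [scenario_config()].
#' @param effect treated-region `beta` multiplier: a single positive number,
#'   or `list(dist = "lognormal", meanlog =, sdlog =)`, or
#'   `list(dist = "normal", mean =, sd =)` (non-positive normal draws are
#'   rejected and redrawn, with a message).
#' @param between_subject_sdlog lognormal sd of per-subject scaling applied to
#'   every region's `A` and `beta` (0 disables inter-subject variation).
#' @param seed master seed.
#' @param level `"tic"` draws ROI-mean curves directly (fast; one noise draw
#'   per frame); `"image"` renders full per-pixel sequences.
#' @return A list of subjects; each has `subject_id`, `config` (the subject's
#'   realized scenario), `multiplier`, and either `tics` (named list of
#'   [tic()]s) or `sequence`/`masks`/`truth` from [simulate_sequence()].
#' @export
simulate_cohort <- function(n_subjects, config = default_scenario(),
                            effect = 1, between_subject_sdlog = 0.15,
                            seed = 1L, level = c("tic", "image")) {
  level <- match.arg(level)
  stopifnot(n_subjects >= 1)
  draw_mult <- function() {
    if (is.numeric(effect)) return(effect)
    if (identical(effect$dist, "lognormal")) {
      return(stats::rlnorm(1, effect$meanlog, effect$sdlog))
    }
    if (identical(effect$dist, "normal")) {
      repeat {
        m <- stats::rnorm(1, effect$mean, effect$sd)
        if (m > 0) return(m)
        message("rejected non-positive multiplier draw; redrawing")
      }
    }
    stop("unsupported effect spec", call. = FALSE)
  }
  lapply(seq_len(n_subjects), function(i) {
    s_i <- derive_seed(seed, i)
    subj <- with_seed(s_i, {
      mult <- draw_mult()
      regions <- lapply(config$regions, function(rg) {
        if (between_subject_sdlog > 0) {
          rg$A <- rg$A * stats::rlnorm(1, 0, between_subject_sdlog)
          rg$beta <- rg$beta * stats::rlnorm(1, 0, between_subject_sdlog)
        }
        rg
      })
      list(mult = mult, regions = regions)
    })
    cfg <- config
    cfg$regions <- subj$regions
    cfg$treatment$beta_multiplier <- subj$mult
    cfg$seed <- derive_seed(s_i, 1L)
    out <- list(subject_id = sprintf("S%02d", i), config = cfg,
                multiplier = subj$mult)
    if (level == "tic") {
      out$tics <- list(
        treated = simulate_tic(cfg, "treated", seed = cfg$seed),
        control = simulate_tic(cfg, "control", seed = derive_seed(cfg$seed, 2L))
      )
    } else {
      sim <- simulate_sequence(cfg)
      out[c("sequence", "masks", "truth")] <- sim[c("sequence", "masks", "truth")]
    }
    out
  })
}
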