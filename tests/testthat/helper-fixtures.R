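# Shared fixtures: small, fast scenarios and independent oracles used across
# the test files. Everything is generated in code; no stored data.

# Small-grid monitoring scenario (same protocol timing as default_scenario,
# coarser grid/frame rate so image-level tests stay fast).
small_scenario <- function(beta_multiplier = 1, noise_scale = 0,
                           frame_rate = 1, duration = 720, seed = 1L) {
  default_scenario(beta_multiplier = beta_multiplier, noise_scale = noise_scale,
                   rows = 24, cols = 24, frame_rate = frame_rate,
                   duration = duration, seed = seed)
}

# Single-flash scenario for direct segment/fit tests.
single_flash_scenario <- function(A = 10, beta = 0.05, y0 = 0, duration = 160,
                                  frame_rate = 10, noise = list(model = "none"),
                                  flash_at = 0, recirc = 0, seed = 1L) {
  scenario_config(
    grid_shape = c(round(duration * frame_rate), 8, 8),
    frame_rate = frame_rate, pixel_spacing = 0.1,
    regions = list(perfusion_region("treated", list(shape = "full"),
                                    A = A, beta = beta, y0 = y0)),
    infusion = list(model = "exponential", time_to_steady = 1),
    flash_times = flash_at, recirculation_delay = recirc,
    treatment = NULL, noise = noise, seed = seed
  )
}

# Noisy replenishment segment drawn straight from the model (bypasses the
# scenario machinery so fit tests control every knob).
make_segment <- function(A, beta, y0 = 0, t = seq(0.2, 120, by = 0.2),
                         rel_noise = 0, seed = NULL) {
  y <- y0 + A * (1 - exp(-beta * t))
  if (rel_noise > 0) {
    y <- sonoperf:::with_seed(seed, pmax(y * (1 + rnorm(length(t), 0, rel_noise)), 0))
  }
  structure(list(flash_time = 0, t0 = 0, start = t[1], end = max(t),
                 times = t, intensities = y, roi_label = "test"),
            class = "replenishment_segment")
}

# Exact SSE of the two-parameter model over an (A, beta) grid; the brute-force
# oracle fits must dominate. Returns the grid minimum.
grid_sse_min <- function(t, y, A_grid, beta_grid) {
  yy <- sum(y^2)
  best <- Inf
  for (b in beta_grid) {
    bas <- 1 - exp(-b * t)
    bb <- sum(bas^2); yb <- sum(y * bas)
    sse <- yy - 2 * A_grid * yb + A_grid^2 * bb
    best <- min(best, min(sse))
  }
  best
}

# Exact two-sided signed-rank p-value by enumerating all sign assignments.
wilcoxon_enumeration <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  list(V = v_obs, p = min(p, 1))
}

# Hand-built converged perfusion_fit with prescribed parameters (for testing
# metrics that consume fits without exercising the optimizer).
manual_fit <- function(A, beta, y0 = 0) {
  structure(list(A = A, beta = beta, y0 = y0, sse = 0, r2 = 1,
                 n_samples = 100L, ci95 = NULL, converged = TRUE,
                 reason = NA_character_, fit_offset = TRUE, niter = 1L,
                 roi_label = NA_character_),
            class = "perfusion_fit")
}

# Minimal treatment_comparison carrying prescribed pre/post parameter values,
# for exercising cohort_statistics in isolation.
fake_comparison <- function(id, beta_pre, beta_post, A_pre = 10, A_post = 10) {
  mkfit <- function(A, beta) manual_fit(A, beta)
  fits <- list(treated = list(pre = mkfit(A_pre, beta_pre),
                              post = mkfit(A_post, beta_post)),
               control = list(pre = mkfit(8, 0.05), post = mkfit(8, 0.05)))
  delta <- list(treated = compare_pre_post(fits$treated$pre, fits$treated$post),
                control = compare_pre_post(fits$control$pre, fits$control$post))
  structure(list(subject_id = id, fits = fits, flash_times = c(300, 630),
                 delta = delta,
                 normalized = control_normalize(delta$treated, delta$control),
                 qc = character(0)),
            class = "treatment_comparison")
}
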