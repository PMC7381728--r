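# Phantom generator: closed-form signal values, noise calibration,
# determinism, sweep geometry, cohort draws.

test_that("noiseless TIC follows the closed-form replenishment model", {
  cfg <- single_flash_scenario(A = 10, beta = 0.05, y0 = 0, flash_at = 300,
                               duration = 400, frame_rate = 1, recirc = 0)
  tc <- simulate_tic(cfg, "treated")
  # one characteristic time after the flash: A * (1 - 1/e)
  expect_equal(tc$intensities[tc$times == 320], 10 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(tc$intensities[tc$times == 320], 6.321206, tolerance = 1e-6)
  # flash reset: the frame at the flash time is back at baseline
  expect_equal(tc$intensities[tc$times == 300], 0)
})

test_that("zero-amplitude region yields a flat curve at baseline", {
  cfg <- single_flash_scenario(A = 0, beta = 0.05, y0 = 3, flash_at = 50,
                               duration = 120, frame_rate = 2)
  tc <- simulate_tic(cfg, "treated")
  expect_true(all(tc$intensities == 3))
})

test_that("recirculation delay holds the signal at baseline before reflow", {
  cfg <- single_flash_scenario(A = 10, beta = 0.05, y0 = 1, flash_at = 100,
                               duration = 300, frame_rate = 2, recirc = 30)
  tc <- simulate_tic(cfg, "treated")
  during <- tc$times >= 100 & tc$times <= 130
  expect_true(all(tc$intensities[during] == 1))
  expect_equal(tc$intensities[tc$times == 150],
               1 + 10 * (1 - exp(-0.05 * 20)), tolerance = 1e-12)
})

test_that("unknown region label and out-of-duration flash are rejected", {
  cfg <- single_flash_scenario()
  expect_error(simulate_tic(cfg, "nope"), "unknown region")
  expect_error(
    single_flash_scenario(flash_at = 1e4),
    "within the sequence duration"
  )
})

test_that("Rayleigh speckle is mean-preserving on the plateau", {
  cfg <- scenario_config(
    grid_shape = c(10000, 4, 4), frame_rate = 10, pixel_spacing = 0.1,
    regions = list(perfusion_region("treated", list(shape = "full"),
                                    A = 10, beta = 0.05, y0 = 2)),
    infusion = list(model = "exponential", time_to_steady = 1),
    flash_times = numeric(0), treatment = NULL,
    noise = list(model = "rayleigh_multiplicative", scale = 0.1), seed = 7L
  )
  tc <- simulate_tic(cfg, "treated", seed = 7)
  plateau <- tc$intensities[tc$times > 50]
  expect_equal(mean(plateau), 12, tolerance = 0.01)
})

test_that("noiseless sequence equals the analytic model at every pixel", {
  cfg <- small_scenario(noise_scale = 0)
  sim <- simulate_sequence(cfg)
  tt <- frame_times(sim$sequence)
  for (lab in c("treated", "control")) {
    rg <- cfg$regions[[lab]]
    idx <- which(sim$masks[[lab]])[1]
    px <- sim$sequence$frames[(idx - 1) %% 24 + 1, (idx - 1) %/% 24 + 1, ]
    expect_equal(px, sonoperf:::region_signal(tt, rg, cfg), tolerance = 1e-14)
  }
  # pixels outside all regions stay dark
  outside <- !Reduce(`|`, sim$masks)
  expect_true(all(sim$sequence$frames[, , 10][outside] == 0))
})

test_that("identical config and seed give bit-identical sequences", {
  cfg <- small_scenario(noise_scale = 0.1, duration = 120, seed = 42)
  a <- simulate_sequence(cfg)
  b <- simulate_sequence(cfg)
  expect_identical(a$sequence$frames, b$sequence$frames)
  c_ <- simulate_sequence(cfg, seed = 43L)
  expect_false(identical(a$sequence$frames, c_$sequence$frames))
})

test_that("noiseless replenishment is monotone and bounded by the plateau", {
  for (mult in c(0.5, 1, 2)) {
    cfg <- small_scenario(beta_multiplier = mult, noise_scale = 0)
    tc <- simulate_tic(cfg, "treated")
    rg <- cfg$regions$treated
    segs <- segment_replenishment(tc, cfg$flash_times,
                                  recirc_delay = cfg$recirculation_delay)
    for (sg in segs) {
      expect_true(all(diff(sg$intensities) >= 0))
      expect_true(all(sg$intensities <= rg$y0 + rg$A + 1e-12))
    }
  }
})

test_that("ground truth records the treatment effect on beta only", {
  cfg <- small_scenario(beta_multiplier = 0.5, duration = 120)
  tr <- simulate_sequence(cfg)$truth
  expect_equal(tr$regions$treated$beta_post, tr$regions$treated$beta_pre * 0.5)
  expect_equal(tr$regions$control$beta_post, tr$regions$control$beta_pre)
  ctr <- round(cfg$regions$treated$mask$center)
  expect_equal(tr$maps$beta_post[ctr[1], ctr[2]],
               tr$regions$treated$beta_pre * 0.5)
})

test_that("overlapping region masks are rejected", {
  m1 <- matrix(FALSE, 8, 8); m1[1:4, ] <- TRUE
  m2 <- matrix(FALSE, 8, 8); m2[4:8, ] <- TRUE
  expect_error(
    simulate_sequence(scenario_config(
      grid_shape = c(10, 8, 8), frame_rate = 1, pixel_spacing = 0.1,
      regions = list(perfusion_region("a", m1, 1, 0.1),
                     perfusion_region("b", m2, 1, 0.1)),
      flash_times = numeric(0), treatment = NULL,
      noise = list(model = "none"))),
    "overlap")
})

test_that("sweep phantoms match closed-form volumes", {
  sph <- simulate_sweep("sphere", radius = 5, step = 0.2, pixel_spacing = 0.1)
  expect_equal(sph$analytic_volume, 4 / 3 * pi * 125, tolerance = 1e-12)
  expect_equal(tumor_volume(sph$sweep), sph$analytic_volume, tolerance = 0.02)
  box <- simulate_sweep("box", edges = c(2, 3, 4), step = 0.2, pixel_spacing = 0.1)
  expect_equal(box$analytic_volume, 24)
  expect_equal(tumor_volume(box$sweep), 24, tolerance = 1e-12)  # aligned grid
  expect_error(simulate_sweep("sphere", radius = 0.01), "smaller than one voxel")
})

test_that("cohort multipliers follow the requested distribution", {
  coh <- simulate_cohort(20, small_scenario(duration = 120),
                         effect = list(dist = "lognormal",
                                       meanlog = log(0.5), sdlog = 0.2),
                         seed = 11, level = "tic")
  mults <- vapply(coh, `[[`, 1, "multiplier")
  expect_equal(mean(mults), 0.51, tolerance = 0.05)
  # fixed effect reproduces exactly; per-subject seeds are deterministic
  coh2 <- simulate_cohort(3, small_scenario(duration = 120), effect = 0.5, seed = 5)
  coh3 <- simulate_cohort(3, small_scenario(duration = 120), effect = 0.5, seed = 5)
  expect_identical(coh2[[1]]$tics$treated$intensities,
                   coh3[[1]]$tics$treated$intensities)
  expect_true(all(vapply(coh2, `[[`, 1, "multiplier") == 0.5))
})

test_that("non-positive normal effect draws are rejected and redrawn", {
  expect_message(
    coh <- simulate_cohort(5, small_scenario(duration = 120),
                           effect = list(dist = "normal", mean = 0.2, sd = 0.5),
                           seed = 2, level = "tic"),
    "redrawing")
  expect_true(all(vapply(coh, `[[`, 1, "multiplier") > 0))
})
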