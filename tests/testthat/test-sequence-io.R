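# Sequence/mask/result I/O and the compression <-> linearization pair.

test_that("sequence write/read round trip preserves arrays and metadata", {
  cfg <- small_scenario(noise_scale = 0.1, duration = 60, seed = 8)
  sq <- simulate_sequence(cfg)$sequence
  path <- file.path(tempdir(), "roundtrip")
  write_sequence(sq, path)
  back <- read_sequence(paste0(path, ".tif"))
  expect_equal(back$frames, sq$frames, tolerance = 1e-6)
  expect_equal(back$frame_rate, sq$frame_rate)
  expect_equal(back$pixel_spacing, sq$pixel_spacing)
  expect_equal(back$intensity_scale, sq$intensity_scale)
  expect_identical(dim(back$frames), dim(sq$frames))
})

test_that("corrupt or missing sidecar metadata is a hard error", {
  cfg <- small_scenario(duration = 30)
  sq <- simulate_sequence(cfg)$sequence
  path <- file.path(tempdir(), "nometa")
  write_sequence(sq, path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$frame_rate <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_sequence(paste0(path, ".tif")), "frame_rate missing")
  file.remove(paste0(path, ".json"))
  expect_error(read_sequence(paste0(path, ".tif")), "sidecar missing")
})

test_that("linearize anchors match the closed-form decompression", {
  codes <- array(c(0, 127.5, 255), dim = c(1, 3, 2))
  codes[, , 2] <- c(255, 0, 127.5)
  sq <- frame_sequence(codes, frame_rate = 1, pixel_spacing = 0.1,
                       intensity_scale = list(type = "log_compressed",
                                              dynamic_range = 60, max_code = 255))
  lin <- linearize(sq)
  expect_equal(lin$frames[1, 3, 1], 1.0, tolerance = 1e-12)   # max code -> 1
  expect_equal(lin$frames[1, 1, 1], 1e-3, tolerance = 1e-12)  # code 0 -> 10^(-60/20)
  expect_identical(lin$intensity_scale$type, "linear")
  # strictly monotone in code
  v <- seq(0, 255, length.out = 50)
  sq2 <- frame_sequence(array(rep(v, 2), c(1, 50, 2)), 1, 0.1,
                        intensity_scale = list(type = "log_compressed",
                                               dynamic_range = 60, max_code = 255))
  expect_true(all(diff(linearize(sq2)$frames[1, , 1]) > 0))
})

test_that("linearize is idempotent on already-linear input", {
  sq <- frame_sequence(array(1:8, c(2, 2, 2)), 1, 0.1)
  expect_message(out <- linearize(sq), "already linear")
  expect_identical(out$frames, sq$frames)
})

test_that("compress -> linearize round trips within 0.1%", {
  set.seed(31)
  x <- array(10^runif(2 * 6 * 6, -2.5, 0), c(6, 6, 2))  # spans the 60 dB window
  sq <- frame_sequence(x, 1, 0.1)
  rt <- linearize(log_compress(sq, dynamic_range = 60, max_code = 255,
                               reference = 1))
  expect_equal(rt$frames, x, tolerance = 1e-3)
  # and code-space round trip: linearize then recompress recovers the codes
  codes <- array(runif(72, 0, 255), c(6, 6, 2))
  csq <- frame_sequence(codes, 1, 0.1,
                        intensity_scale = list(type = "log_compressed",
                                               dynamic_range = 60, max_code = 255))
  back <- log_compress(linearize(csq), dynamic_range = 60, max_code = 255,
                       reference = 1)
  expect_equal(back$frames, codes, tolerance = 1e-9)
})

test_that("simulated log-compressed sequences carry their parameters and linearize", {
  cfg <- small_scenario(noise_scale = 0, duration = 60)
  cfg$compression <- list(model = "log", dynamic_range = 60, max_code = 255)
  sim <- simulate_sequence(cfg)
  expect_identical(sim$sequence$intensity_scale$type, "log_compressed")
  expect_equal(sim$sequence$intensity_scale$dynamic_range, 60)
  expect_error(extract_tic(sim$sequence, sim$masks, "treated"), "linearize")
  lin <- linearize(sim$sequence)
  # relative structure survives: plateau / baseline ratio preserved
  raw <- simulate_sequence(small_scenario(noise_scale = 0, duration = 60))
  i1 <- which(sim$masks$treated)[1]; i2 <- which(sim$masks$control)[1]
  f <- 55
  expect_equal(lin$frames[, , f][i1] / lin$frames[, , f][i2],
               raw$sequence$frames[, , f][i1] / raw$sequence$frames[, , f][i2],
               tolerance = 1e-6)
})

test_that("mask sets round trip through label images", {
  cfg <- small_scenario(duration = 30)
  masks <- simulate_sequence(cfg)$masks
  path <- file.path(tempdir(), "masks")
  write_masks(masks, path)
  back <- read_masks(paste0(path, ".tif"))
  expect_identical(names(back), names(masks))
  for (nm in names(masks)) expect_identical(back[[nm]], masks[[nm]])
})

test_that("result tables mirror to CSV and JSON and read back exactly", {
  # empty record list: header-only CSV
  path <- file.path(tempdir(), "empty_results")
  write_results(list(), path)
  empty <- utils::read.csv(paste0(path, ".csv"))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("subject", "roi", "phase", "A", "beta", "y0", "sse", "r2")
                  %in% names(empty)))
  # one fit: one fully populated row, values preserved to 1e-9
  seg <- make_segment(A = 9.87654321, beta = 0.0456789, y0 = 1.23456789)
  fit <- fit_replenishment(seg)
  path2 <- file.path(tempdir(), "one_fit")
  write_results(list(fit), path2)
  df <- utils::read.csv(paste0(path2, ".csv"))
  expect_identical(nrow(df), 1L)
  expect_equal(df$A, fit$A, tolerance = 1e-9)
  expect_equal(df$beta, fit$beta, tolerance = 1e-9)
  expect_equal(df$y0, fit$y0, tolerance = 1e-9)
  js <- jsonlite::read_json(paste0(path2, ".json"), simplifyVector = TRUE)
  expect_equal(js$beta, fit$beta, tolerance = 1e-12)
})
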