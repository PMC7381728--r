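# Paired pre/post inference: percent changes, control normalization, cohort
# statistics (with a signed-rank enumeration oracle), and the end-to-end
# monitoring pipeline on simulated subjects.

test_that("pre/post percent changes follow their definition", {
  f <- manual_fit(10, 0.05)
  expect_equal(compare_pre_post(f, f), list(delta_rr_pct = 0, delta_rbv_pct = 0))
  half <- compare_pre_post(manual_fit(10, 0.05), manual_fit(10, 0.025))
  expect_equal(half$delta_rr_pct, -50)
  # a rate dropping from 0.05 to 0.0105 1/s is a 79% decrease
  big <- compare_pre_post(manual_fit(10, 0.05), manual_fit(10, 0.0105))
  expect_equal(big$delta_rr_pct, -79, tolerance = 1e-12)
  expect_equal(big$delta_rbv_pct, 0)
  bad <- fit_replenishment(make_segment(A = 0, beta = 0.1, y0 = 4, t = 1:50))
  expect_error(compare_pre_post(bad, f), "unidentifiable")
})

test_that("control normalization cancels shared drift in both modes", {
  d <- function(rr, rbv = 0) list(delta_rr_pct = rr, delta_rbv_pct = rbv)
  expect_equal(control_normalize(d(-50), d(0))$delta_rr_pct, -50)
  expect_equal(control_normalize(d(20), d(20))$delta_rr_pct, 0)
  # ratio mode: treated post/pre 0.5 against control post/pre 1.25 -> -60%
  rat <- control_normalize(d(-50), d(25), mode = "ratio")
  expect_equal(rat$delta_rr_pct, -60, tolerance = 1e-12)
  expect_identical(rat$mode, "ratio")
  expect_error(control_normalize(d(-50), d(-100), mode = "ratio"), "ratio")
})

test_that("signed-rank statistic and p-value match exhaustive enumeration", {
  diffs <- c(1, 2, 3, -4, 5)
  oracle <- wilcoxon_enumeration(diffs)
  expect_equal(oracle$V, 11)  # ranks 1+2+3+5 of the positive differences
  cmps <- lapply(seq_along(diffs), function(i) {
    fake_comparison(sprintf("S%d", i), beta_pre = 10, beta_post = 10 + diffs[i])
  })
  res <- cohort_statistics(cmps, metric = "rr", test = "wilcoxon")
  expect_equal(unname(res$wilcoxon$statistic), oracle$V)
  expect_equal(res$wilcoxon$p.value, oracle$p, tolerance = 1e-12)
  expect_identical(res$wilcoxon$note, "exact")
})

test_that("degenerate cohorts are summarized honestly", {
  cmps <- lapply(1:6, function(i) fake_comparison(sprintf("S%d", i), 0.05, 0.025))
  res <- cohort_statistics(cmps, metric = "rr")
  expect_equal(res$mean_delta_pct, -50)
  expect_equal(res$sd_delta_pct, 0)
  # all-identical pairs: Wilcoxon undefined, reported as such
  null_cmps <- lapply(1:5, function(i) fake_comparison(sprintf("S%d", i), 0.05, 0.05))
  res0 <- cohort_statistics(null_cmps, metric = "rr")
  expect_true(is.na(res0$wilcoxon$p.value))
  expect_match(res0$wilcoxon$note, "undefined")
  expect_error(cohort_statistics(cmps[1], metric = "rr"), "at least 2")
})

test_that("the image-level pipeline recovers a constructed halving of RR", {
  cfg <- default_scenario(beta_multiplier = 0.5, noise_scale = 0.05, seed = 21)
  sim <- simulate_sequence(cfg)
  cmp <- run_monitoring_pipeline(sim$sequence, sim$masks)
  expect_length(cmp$qc, 0)
  expect_equal(cmp$normalized$delta_rr_pct, -50, tolerance = 0.06)
  expect_lt(abs(cmp$normalized$delta_rbv_pct), 5)
  # flash anchors came from detection at the protocol times
  expect_true(all(abs(cmp$flash_times - c(300, 630)) <= 1 / cfg$frame_rate + 1e-9))
  # determinism: identical inputs give identical result tables
  cmp2 <- run_monitoring_pipeline(sim$sequence, sim$masks)
  expect_identical(sonoperf:::results_table(list(cmp)),
                   sonoperf:::results_table(list(cmp2)))
})

test_that("a null subject shows no treatment effect", {
  cfg <- default_scenario(beta_multiplier = 1, noise_scale = 0.1, seed = 33)
  sim <- simulate_sequence(cfg)
  cmp <- run_monitoring_pipeline(sim$sequence, sim$masks)
  expect_lt(abs(cmp$normalized$delta_rr_pct), 3)
})

test_that("pipeline artifacts are written when an output directory is given", {
  cfg <- default_scenario(beta_multiplier = 0.5, noise_scale = 0.1, seed = 2)
  coh <- simulate_cohort(1, cfg, effect = 0.5, seed = 2, level = "image")
  out <- file.path(tempdir(), "pipe_out")
  cmp <- run_monitoring_pipeline(coh[[1]]$sequence, coh[[1]]$masks,
                                 subject_id = "S01", out_dir = out)
  expect_true(file.exists(file.path(out, "tics.csv")))
  expect_true(file.exists(file.path(out, "fits.csv")))
  expect_true(file.exists(file.path(out, "comparison.json")))
  fits <- utils::read.csv(file.path(out, "fits.csv"))
  expect_identical(nrow(fits), 4L)  # treated/control x pre/post
  expect_identical(sort(unique(fits$roi)), c("control", "treated"))
})

test_that("fewer than two flash events without protocol times is an error", {
  cfg <- single_flash_scenario(duration = 200, frame_rate = 2, flash_at = 100,
                               recirc = 0)
  tc <- simulate_tic(cfg, "treated")
  expect_error(compare_rois(tc, tc, protocol = list(flash_times = NULL)),
               "at least two flash")
})

test_that("increasing the beta multiplier maps monotonically onto recovered dRR", {
  med <- sapply(c(0.5, 1, 1.5, 2), function(m) {
    coh <- simulate_cohort(4, default_scenario(noise_scale = 0.1), effect = m,
                           seed = 77, level = "tic")
    cs <- cohort_statistics(lapply(coh, analyze_subject), metric = "rr")
    cs$median_normalized_delta_pct
  })
  expect_true(all(diff(med) > 0))
  expect_true(med[4] > 0)  # a genuine increase never reads as a decrease
})

test_that("a halved reperfusion rate is detected in nearly every cohort", {
  rej <- vapply(1:20, function(r) {
    coh <- simulate_cohort(8, default_scenario(noise_scale = 0.1), effect = 0.5,
                           seed = 5000 + r, level = "tic")
    cohort_statistics(lapply(coh, analyze_subject), metric = "rr")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.9)
})

test_that("cohort statistics exclude QC-flagged subjects with a warning", {
  cmps <- lapply(1:4, function(i) fake_comparison(sprintf("S%d", i), 0.05, 0.03))
  bad <- cmps[[1]]
  bad$qc <- "treated/post: did not converge"
  cmps[[4]] <- bad
  expect_warning(res <- cohort_statistics(cmps, metric = "rr"), "excluded")
  expect_identical(res$n, 3L)
})
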