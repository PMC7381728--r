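# Paired pre/post, treated-vs-control inference: FD-1 and FD-2 segment fits
# per ROI, control-normalized percent changes in RR and RBV, cohort
# statistics, and the end-to-end monitoring pipeline.

#' Percent change between pre and post fits
#'
#' `delta_rr_pct = 100 * (beta_post - beta_pre) / beta_pre` and the analogous
#' change in `A`; the percent-change base is always the pre-phase parameter.
#'
#' @param pre_fit,post_fit converged [fit_replenishment()] results for the
#'   pre (initial-flash) and post (final-flash) replenishment segments.
#' @return List with `delta_rr_pct` and `delta_rbv_pct`.
#' @export
compare_pre_post <- function(pre_fit, post_fit) {
  for (f in list(pre_fit, post_fit)) {
    stopifnot(inherits(f, "perfusion_fit"))
    if (!isTRUE(f$converged)) {
      stop(sprintf("cannot compare: fit did not converge (%s)", f$reason),
           call. = FALSE)
    }
  }
  list(delta_rr_pct = 100 * (post_fit$beta - pre_fit$beta) / pre_fit$beta,
       delta_rbv_pct = 100 * (post_fit$A - pre_fit$A) / pre_fit$A)
}

#' Control-normalize treated-ROI percent changes
#'
#' Removes systemic drift (infusion-level, attenuation, physiology) shared by
#' both ROIs. `mode = "difference"` (default) subtracts the control ROI's
#' percent change from the treated one; `mode = "ratio"` forms
#' `100 * ((1 + d_t/100) / (1 + d_c/100) - 1)`, i.e. the treated post/pre
#' ratio relative to the control post/pre ratio.
#'
#' @param treated,control percent-change lists from [compare_pre_post()] (or
#'   single numbers, taken as `delta_rr_pct`).
#' @param mode `"difference"` or `"ratio"`.
#' @return List with normalized `delta_rr_pct`, `delta_rbv_pct` and the
#'   `mode` used.
#' @export
control_normalize <- function(treated, control, mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  as_deltas <- function(x) {
    if (is.numeric(x)) list(delta_rr_pct = x, delta_rbv_pct = NA_real_) else x
  }
  tr <- as_deltas(treated); ct <- as_deltas(control)
  norm1 <- function(dt, dc) {
    if (mode == "difference") return(dt - dc)
    rt <- 1 + dt / 100; rc <- 1 + dc / 100
    if (is.na(rc) || rc == 0) {
      if (is.na(rc)) return(NA_real_)
      stop("control ratio is 0; ratio normalization undefined", call. = FALSE)
    }
    100 * (rt / rc - 1)
  }
  list(delta_rr_pct = norm1(tr$delta_rr_pct, ct$delta_rr_pct),
       delta_rbv_pct = norm1(tr$delta_rbv_pct, ct$delta_rbv_pct),
       mode = mode)
}

#' Compare treated vs control ROIs from their TICs
#'
#' Core of the monitoring analysis, starting from extracted TICs: determine
#' the two flash-destruction anchors (from the protocol or by detection on
#' the treated TIC; the first and last events are taken as the pre/post
#' anchors, so intermediate therapy transients are never fitted), segment
#' both TICs, fit the initial-flash (pre) and final-flash (post) segments per
#' ROI, compute percent changes and control-normalize them.
#'
#' @param tic_treated,tic_control [tic()]s for the two ROIs.
#' @param protocol protocol settings, see [default_protocol()].
#' @param subject_id identifier stamped into the result.
#' @return A `treatment_comparison`: `subject_id`, `fits` (`treated`/`control`
#'   x `pre`/`post`), `flash_times` used, raw `delta` per ROI, `normalized`
#'   deltas (with mode), `qc` flags for non-converged fits.
#' @export
compare_rois <- function(tic_treated, tic_control,
                         protocol = default_protocol(),
                         subject_id = "subject") {
  stopifnot(inherits(tic_treated, "tic"), inherits(tic_control, "tic"))
  protocol <- utils::modifyList(default_protocol(), protocol)
  fts <- protocol$flash_times
  if (is.null(fts)) {
    det <- protocol$detect
    fts <- detect_flash_events(tic_treated, drop_fraction = det$drop_fraction,
                               window = det$window, refractory = det$refractory)
  }
  if (length(fts) < 2) {
    stop(sprintf(paste0("need at least two flash-destruction events (found %d); ",
                        "supply flash_times in the protocol"), length(fts)),
         call. = FALSE)
  }
  anchors <- c(fts[1], fts[length(fts)])
  fit_roi <- function(tc) {
    segs <- segment_replenishment(tc, anchors,
                                  recirc_delay = protocol$recirculation_delay)
    if (length(segs) != 2) {
      stop("could not form both pre and post replenishment segments", call. = FALSE)
    }
    list(pre = fit_replenishment(segs[[1]], fit_offset = protocol$fit_offset),
         post = fit_replenishment(segs[[2]], fit_offset = protocol$fit_offset))
  }
  fits <- list(treated = fit_roi(tic_treated), control = fit_roi(tic_control))
  qc <- character(0)
  for (roi in names(fits)) for (ph in c("pre", "post")) {
    f <- fits[[roi]][[ph]]
    if (!isTRUE(f$converged)) qc <- c(qc, sprintf("%s/%s: %s", roi, ph, f$reason))
  }
  delta <- normalized <- NULL
  if (!length(qc)) {
    delta <- list(treated = compare_pre_post(fits$treated$pre, fits$treated$post),
                  control = compare_pre_post(fits$control$pre, fits$control$post))
    normalized <- control_normalize(delta$treated, delta$control,
                                    mode = protocol$normalization)
  }
  structure(list(subject_id = subject_id, fits = fits, flash_times = anchors,
                 delta = delta, normalized = normalized, qc = qc),
            class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("<treatment_comparison> %s (flashes at %.1f / %.1f s)\n",
              x$subject_id, x$flash_times[1], x$flash_times[2]))
  if (length(x$qc)) {
    cat("  QC flags:", paste(x$qc, collapse = "; "), "\n")
  } else {
    cat(sprintf("  treated: dRR = %+.1f%%, dRBV = %+.1f%%\n",
                x$delta$treated$delta_rr_pct, x$delta$treated$delta_rbv_pct))
    cat(sprintf("  control: dRR = %+.1f%%, dRBV = %+.1f%%\n",
                x$delta$control$delta_rr_pct, x$delta$control$delta_rbv_pct))
    cat(sprintf("  normalized (%s): dRR = %+.1f%%, dRBV = %+.1f%%\n",
                x$normalized$mode, x$normalized$delta_rr_pct,
                x$normalized$delta_rbv_pct))
  }
  invisible(x)
}

#' Run the full monitoring pipeline on a sequence
#'
#' End-to-end treated-vs-control analysis of one monitoring run:
#' linearize (when log-compressed), extract the treated and control TICs
#' (with optional background subtraction), find the flash-destruction
#' anchors, fit the pre and post replenishment segments per ROI, and
#' control-normalize the percent changes. Deterministic given its inputs.
#' When `out_dir` is given, the intermediate TICs, the fit table and the
#' comparison JSON are written there.
#'
#' @param seq a [frame_sequence()] covering the whole run (both flashes).
#' @param masks a [region_mask_set()] with `treated` and `control` masks (and
#'   optionally the protocol's background label).
#' @param protocol protocol settings, see [default_protocol()].
#' @param subject_id identifier stamped into the outputs.
#' @param out_dir optional directory for intermediate artifacts.
#' @return A `treatment_comparison` (see [compare_rois()]).
#' @export
run_monitoring_pipeline <- function(seq, masks, protocol = default_protocol(),
                                    subject_id = "subject", out_dir = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  protocol <- utils::modifyList(default_protocol(), protocol)
  if (seq$intensity_scale$type == "log_compressed") seq <- linearize(seq)
  tic_t <- extract_tic(seq, masks, "treated", background_label = protocol$background)
  tic_c <- extract_tic(seq, masks, "control", background_label = protocol$background)
  cmp <- compare_rois(tic_t, tic_c, protocol = protocol, subject_id = subject_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rbind(as.data.frame(tic_t), as.data.frame(tic_c)),
                     file.path(out_dir, "tics.csv"), row.names = FALSE)
    write_results(list(cmp), file.path(out_dir, "fits"))
    jsonlite::write_json(
      list(subject = subject_id, flash_times = cmp$flash_times, qc = cmp$qc,
           delta = cmp$delta, normalized = cmp$normalized),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  cmp
}

#' Analyze one simulated cohort subject
#'
#' Dispatches a [simulate_cohort()] subject through the monitoring analysis:
#' image-level subjects go through [run_monitoring_pipeline()], tic-level
#' subjects directly through [compare_rois()].
#'
#' @param subject one element of a [simulate_cohort()] result.
#' @param protocol protocol settings; by default flash times are taken from
#'   the subject's scenario (set `flash_times = NULL` explicitly inside a
#'   non-default protocol to force detection).
#' @return A `treatment_comparison`.
#' @export
analyze_subject <- function(subject, protocol = NULL) {
  base <- default_protocol()
  base$flash_times <- subject$config$flash_times
  base$recirculation_delay <- subject$config$recirculation_delay
  protocol <- if (is.null(protocol)) base else utils::modifyList(base, protocol,
                                                                 keep.null = FALSE)
  if (!is.null(subject$tics)) {
    compare_rois(subject$tics$treated, subject$tics$control,
                 protocol = protocol, subject_id = subject$subject_id)
  } else {
    run_monitoring_pipeline(subject$sequence, subject$masks,
                            protocol = protocol, subject_id = subject$subject_id)
  }
}

#' Cohort-level statistics on paired pre/post parameters
#'
#' Summarizes per-subject treated-ROI changes and tests the paired pre-vs-post
#' parameter values: a two-sided paired Student's t-test, and a Wilcoxon
#' signed-rank test (exact distribution for n <= 25 without ties, normal
#' approximation otherwise; zero differences are dropped per the Wilcoxon
#' convention). When all pairs are identical the Wilcoxon statistic is
#' undefined and reported as such. The primary p-value follows `test`:
#' `"auto"` uses Wilcoxon for n < 8 and the t-test otherwise.
#'
#' @param comparisons list of `treatment_comparison` objects (QC-flagged ones
#'   are excluded with a warning).
#' @param metric `"rr"` (beta) or `"rbv"` (A).
#' @param roi which ROI's parameters to test (default `"treated"`).
#' @param test `"auto"`, `"wilcoxon"` or `"t"`.
#' @return A `cohort_result`: per-subject table, mean/sd/median of raw and
#'   control-normalized percent changes, both test results, the primary
#'   p-value, and `n`.
#' @export
cohort_statistics <- function(comparisons, metric = c("rr", "rbv"),
                              roi = "treated", test = c("auto", "wilcoxon", "t")) {
  metric <- match.arg(metric); test <- match.arg(test)
  ok <- vapply(comparisons, function(cm) !length(cm$qc), TRUE)
  if (any(!ok)) {
    warning(sprintf("%d subject(s) excluded for non-converged fits", sum(!ok)),
            call. = FALSE)
  }
  comparisons <- comparisons[ok]
  n <- length(comparisons)
  if (n < 2) stop("need at least 2 converged comparisons", call. = FALSE)
  par_name <- if (metric == "rr") "beta" else "A"
  delta_name <- if (metric == "rr") "delta_rr_pct" else "delta_rbv_pct"
  tab <- do.call(rbind, lapply(comparisons, function(cm) {
    data.frame(subject = cm$subject_id,
               pre = cm$fits[[roi]]$pre[[par_name]],
               post = cm$fits[[roi]]$post[[par_name]],
               delta_pct = cm$delta[[roi]][[delta_name]],
               normalized_delta_pct = cm$normalized[[delta_name]])
  }))
  t_res <- tryCatch(
    stats::t.test(tab$post, tab$pre, paired = TRUE),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_)
  )
  d <- tab$post - tab$pre
  wil <- if (all(d == 0)) {
    list(statistic = NA_real_, p.value = NA_real_,
         note = "all pairs identical; signed-rank statistic undefined")
  } else {
    exact <- sum(d != 0) <= 25 && !any(d == 0) &&
      !any(duplicated(abs(d[d != 0])))
    w <- suppressWarnings(stats::wilcox.test(tab$post, tab$pre, paired = TRUE,
                                             exact = exact))
    list(statistic = unname(w$statistic), p.value = w$p.value,
         note = if (exact) "exact" else "normal approximation")
  }
  primary <- switch(test,
    auto = if (n < 8) wil$p.value else t_res$p.value,
    wilcoxon = wil$p.value,
    t = t_res$p.value)
  structure(
    list(metric = metric, roi = roi, n = n, subjects = tab,
         mean_delta_pct = mean(tab$delta_pct), sd_delta_pct = stats::sd(tab$delta_pct),
         median_delta_pct = stats::median(tab$delta_pct),
         mean_normalized_delta_pct = mean(tab$normalized_delta_pct),
         sd_normalized_delta_pct = stats::sd(tab$normalized_delta_pct),
         median_normalized_delta_pct = stats::median(tab$normalized_delta_pct),
         t_test = list(statistic = unname(t_res$statistic), p.value = t_res$p.value),
         wilcoxon = wil, p_value = primary,
         primary_test = if (test == "auto") {
           if (n < 8) "wilcoxon" else "t"
         } else test),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s (%s ROI), n = %d\n", toupper(x$metric), x$roi, x$n))
  cat(sprintf("  delta: mean %+.1f%% (sd %.1f), median %+.1f%%\n",
              x$mean_delta_pct, x$sd_delta_pct, x$median_delta_pct))
  cat(sprintf("  control-normalized: mean %+.1f%% (sd %.1f), median %+.1f%%\n",
              x$mean_normalized_delta_pct, x$sd_normalized_delta_pct,
              x$median_normalized_delta_pct))
  cat(sprintf("  paired t: p = %.4g; Wilcoxon (%s): p = %.4g; primary (%s): p = %.4g\n",
              x$t_test$p.value, x$wilcoxon$note, x$wilcoxon$p.value,
              x$primary_test, x$p_value))
  invisible(x)
}
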