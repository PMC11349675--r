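#' End-of-work SmO2 baseline (Y_A)
#'
#' Arithmetic mean of the usable samples in the final `baseline_window_s`
#' seconds of the work interval, `[work_end - 30, work_end)`.
#'
#' @param trace An [smo2_trace()] (normally smoothed to the analysis rate).
#' @param work_end_s End of the work interval, seconds.
#' @param baseline_window_s Baseline window span, seconds.
#' @return Mean SmO2 (%), or `NA` if the window holds no usable sample.
#' @export
end_work_baseline <- function(trace, work_end_s, baseline_window_s = 30) {
  in_w <- trace$time_s >= work_end_s - baseline_window_s &
    trace$time_s < work_end_s & trace$usable
  if (!any(in_w)) return(NA_real_)
  mean(trace$smo2_pct[in_w])
}

#' Recovery time window for a stage
#'
#' Locomotor sites recover to the start of the next work stage; accessory
#' sites to 60 s after the start of the next work stage (their peaks fall
#' beyond passive rest); after the final work stage the window is 4 min for
#' every site.
#'
#' @param schedule A `stage_schedule`.
#' @param stage_index Stage whose recovery follows its work interval.
#' @param site Site code, or pass `site_class` directly.
#' @param final_window_s Window after the final stage, seconds.
#' @param accessory_extension_s Extension past next work start for accessory
#'   sites, seconds.
#' @return `c(start_s, end_s)`, half-open, measured in recording time.
#' @export
recovery_window <- function(schedule, stage_index, site,
                            final_window_s = 240,
                            accessory_extension_s = 60) {
  stopifnot(inherits(schedule, "stage_schedule"),
            stage_index %in% schedule$stage)
  k <- match(stage_index, schedule$stage)
  work_end <- schedule$work_end_s[k]
  if (k == nrow(schedule)) {
    return(c(work_end, work_end + final_window_s))
  }
  next_start <- schedule$work_start_s[k + 1]
  cls <- if (site %in% c("locomotor", "accessory")) site else site_class(site)
  end <- if (cls == "locomotor") next_start else
    next_start + accessory_extension_s
  c(work_end, end)
}

#' Detect the recovery peak (Y_B)
#'
#' The peak is the earliest usable sample in the window with no strictly
#' higher sample within the following `lookahead_s` seconds (intersected
#' with the window); equal values do not disqualify an earlier peak, so ties
#' resolve to the earliest time. Peaks whose lookahead is truncated by the
#' window edge are accepted and marked.
#'
#' @param trace An [smo2_trace()].
#' @param window `c(start_s, end_s)` recovery window, half-open.
#' @param lookahead_s No-higher-peak lookahead, seconds.
#' @return A list `(y_b, t_peak_s, truncated_lookahead)`, or `NULL` when the
#'   window has no usable samples.
#' @export
detect_peak <- function(trace, window, lookahead_s = 30) {
  in_w <- which(trace$time_s >= window[1] & trace$time_s < window[2] &
                  trace$usable)
  if (length(in_w) == 0) return(NULL)
  t <- trace$time_s[in_w]
  y <- trace$smo2_pct[in_w]
  for (i in seq_along(t)) {
    ahead <- which(t > t[i] & t <= t[i] + lookahead_s)
    if (!any(y[ahead] > y[i])) {
      return(list(y_b = y[i], t_peak_s = t[i],
                  truncated_lookahead = t[i] + lookahead_s > window[2]))
    }
  }
  NULL # unreachable: the last sample always qualifies
}

#' Half-recovery time (HRT)
#'
#' Time from the end of work until the smoothed SmO2 series first reaches
#' the midpoint between the end-work baseline `y_a` and the recovery peak
#' `y_b`, with linear interpolation between the bracketing samples to remove
#' sampling quantisation.
#'
#' @param trace An [smo2_trace()].
#' @param y_a,y_b Baseline and peak SmO2 (%). Requires `y_b > y_a`.
#' @param work_end_s End of work (HRT time origin), seconds.
#' @param t_peak_s Time of the detected peak; the search stops there.
#' @return HRT in seconds.
#' @export
half_recovery_time <- function(trace, y_a, y_b, work_end_s, t_peak_s) {
  if (!is.finite(y_a) || !is.finite(y_b) || y_b <= y_a) {
    stop("requires y_b > y_a (positive reoxygenation amplitude)",
         call. = FALSE)
  }
  thr <- y_a + (y_b - y_a) / 2
  idx <- which(trace$time_s >= work_end_s & trace$time_s <= t_peak_s &
                 trace$usable)
  t <- trace$time_s[idx]
  y <- trace$smo2_pct[idx]
  hit <- which(y >= thr)
  if (length(hit) == 0) {
    stop("threshold never reached before the peak; inconsistent inputs",
         call. = FALSE)
  }
  i <- hit[1]
  if (i == 1 || y[i - 1] >= thr) return(t[i] - work_end_s)
  t_cross <- t[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  t_cross - work_end_s
}

# pick, per target %Wpeak, the schedule stage nearest the target
select_target_stages <- function(schedule, targets, tolerance) {
  purrr::map_dfr(targets, function(tg) {
    d <- abs(schedule$pct_wpeak * 100 - tg)
    k <- which.min(d)
    if (d[k] > tolerance) return(tibble::tibble())
    tibble::tibble(target_pct = tg, stage = schedule$stage[k],
                   pct_wpeak = schedule$pct_wpeak[k])
  })
}

#' Extract all reoxygenation bouts of a study
#'
#' For each participant x trial x site and each target relative workload,
#' selects the stage nearest the target (within `tolerance` percentage
#' points of %Wpeak), screens the baseline and recovery windows, and
#' computes baseline `y_a`, peak `y_b`, amplitude and half-recovery time.
#' Failures become statuses rather than errors: `MISSING` (no baseline
#' data, or too much of the recovery window missing), `QUALITY_FAIL` (too
#' much of the window flagged by [screen_quality()]), `NO_PEAK`,
#' `ZERO_AMPLITUDE`, else `OK`.
#'
#' @param traces Tibble with columns `participant_id`, `trial`, `site` and a
#'   `trace` list-column of preprocessed traces (see [preprocess_traces()]),
#'   or an `smo2_study` (preprocessed automatically).
#' @param schedule A `stage_schedule` (taken from the study if omitted).
#' @param targets Target workloads, % of Wpeak.
#' @param tolerance Stage-selection tolerance, percentage points of %Wpeak.
#' @param max_missing_frac Missing/flagged fraction above which a recovery
#'   window is unusable.
#' @param baseline_window_s,lookahead_s,final_window_s,accessory_extension_s
#'   Passed to the per-bout operations.
#' @return A tibble of bouts with columns `participant_id`, `trial`, `site`,
#'   `stage_index`, `pct_wpeak`, `y_a`, `y_b`, `t_peak_s`, `amplitude_pct`,
#'   `hrt_s`, `status`, plus `target_pct`; an `accounting` attribute holds
#'   `scheduled`, `unusable` and `unusable_pct`.
#' @export
extract_bouts <- function(traces, schedule = NULL, targets = c(50, 75, 100),
                          tolerance = 6, max_missing_frac = 0.5,
                          baseline_window_s = 30, lookahead_s = 30,
                          final_window_s = 240, accessory_extension_s = 60) {
  if (inherits(traces, "smo2_study")) {
    schedule <- schedule %||% traces$schedule
    traces <- preprocess_traces(traces$traces)
  }
  stopifnot(inherits(schedule, "stage_schedule"))
  sel <- select_target_stages(schedule, targets, tolerance)
  if (nrow(sel) == 0) stop("no schedule stage within tolerance of any target",
                           call. = FALSE)

  bouts <- purrr::pmap_dfr(
    list(traces$participant_id, traces$trial, traces$site, traces$trace),
    function(pid, tr, site, trace) {
      purrr::pmap_dfr(sel, function(target_pct, stage, pct_wpeak) {
        b <- extract_one_bout(trace, schedule, stage, site,
                              max_missing_frac = max_missing_frac,
                              baseline_window_s = baseline_window_s,
                              lookahead_s = lookahead_s,
                              final_window_s = final_window_s,
                              accessory_extension_s = accessory_extension_s)
        tibble::tibble(participant_id = pid, trial = tr, site = site,
                       stage_index = stage, pct_wpeak = pct_wpeak,
                       target_pct = target_pct, !!!b)
      })
    })
  bouts <- bouts[, c("participant_id", "trial", "site", "stage_index",
                     "pct_wpeak", "y_a", "y_b", "t_peak_s", "amplitude_pct",
                     "hrt_s", "status", "target_pct")]
  n_bad <- sum(bouts$status != "OK")
  attr(bouts, "accounting") <- list(
    scheduled = nrow(bouts), unusable = n_bad,
    unusable_pct = 100 * n_bad / nrow(bouts))
  bouts
}

extract_one_bout <- function(trace, schedule, stage, site, max_missing_frac,
                             baseline_window_s, lookahead_s, final_window_s,
                             accessory_extension_s) {
  empty <- list(y_a = NA_real_, y_b = NA_real_, t_peak_s = NA_real_,
                amplitude_pct = NA_real_, hrt_s = NA_real_)
  k <- match(stage, schedule$stage)
  work_end <- schedule$work_end_s[k]
  win <- recovery_window(schedule, stage, site,
                         final_window_s = final_window_s,
                         accessory_extension_s = accessory_extension_s)
  win[2] <- min(win[2], trace$time_s[nrow(trace)] + 1e-9)

  y_a <- end_work_baseline(trace, work_end, baseline_window_s)
  if (is.na(y_a)) return(c(empty, status = "MISSING"))

  q <- window_quality(trace, win)
  if (q$n == 0 || q$frac_missing > max_missing_frac) {
    out <- empty; out$y_a <- y_a
    return(c(out, status = "MISSING"))
  }
  if (q$frac_flagged > max_missing_frac) {
    out <- empty; out$y_a <- y_a
    return(c(out, status = "QUALITY_FAIL"))
  }
  n_usable <- sum(trace$time_s >= win[1] & trace$time_s < win[2] &
                    trace$usable)
  if (n_usable < 2) {
    out <- empty; out$y_a <- y_a
    return(c(out, status = "NO_PEAK"))
  }
  pk <- detect_peak(trace, win, lookahead_s)
  if (is.null(pk)) {
    out <- empty; out$y_a <- y_a
    return(c(out, status = "NO_PEAK"))
  }
  amp <- pk$y_b - y_a
  if (amp <= 0) {
    return(list(y_a = y_a, y_b = pk$y_b, t_peak_s = pk$t_peak_s - work_end,
                amplitude_pct = amp, hrt_s = NA_real_,
                status = "ZERO_AMPLITUDE"))
  }
  hrt <- half_recovery_time(trace, y_a, pk$y_b, work_end, pk$t_peak_s)
  list(y_a = y_a, y_b = pk$y_b, t_peak_s = pk$t_peak_s - work_end,
       amplitude_pct = amp, hrt_s = hrt, status = "OK")
}

#' Preprocess every trace of a study table
#'
#' Applies [smooth_and_resample()] then [screen_quality()] to each trace.
#'
#' @param traces Tibble with a `trace` list-column.
#' @param window_s,out_rate_hz,max_jump_pct,max_missing_frac Parameters
#'   passed through.
#' @return The table with preprocessed traces.
#' @export
preprocess_traces <- function(traces, window_s = 5, out_rate_hz = 1,
                              max_jump_pct = 10, max_missing_frac = 0.5) {
  traces$trace <- purrr::map(traces$trace, function(tr) {
    screen_quality(smooth_and_resample(tr, window_s, out_rate_hz),
                   max_jump_pct = max_jump_pct,
                   max_missing_frac = max_missing_frac)
  })
  traces
}

#' Missing-data accounting for an extracted bout table
#'
#' @param bouts Output of [extract_bouts()].
#' @return Tibble with `scheduled`, `unusable`, `unusable_pct`.
#' @export
bout_accounting <- function(bouts) {
  acc <- attr(bouts, "accounting")
  if (is.null(acc)) {
    n_bad <- sum(bouts$status != "OK")
    acc <- list(scheduled = nrow(bouts), unusable = n_bad,
                unusable_pct = 100 * n_bad / nrow(bouts))
  }
  tibble::as_tibble(acc)
}

#' Write a bout table to the canonical tidy CSV
#'
#' Columns, in order: participant_id, trial, site, stage_index, pct_wpeak,
#' y_a, y_b, t_peak_s, amplitude_pct, hrt_s, status.
#'
#' @param bouts Output of [extract_bouts()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  cols <- c("participant_id", "trial", "site", "stage_index", "pct_wpeak",
            "y_a", "y_b", "t_peak_s", "amplitude_pct", "hrt_s", "status")
  readr::write_csv(bouts[, cols], path, na = "")
  invisible(path)
}
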