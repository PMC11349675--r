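#' Read a raw SmO2 recording from CSV
#'
#' Expects a header row and two numeric columns `time_s`, `smo2_pct`.
#' Samples outside the 0-100 % physical range are set to missing with a
#' warning; duplicated or non-increasing timestamps are an error.
#'
#' @param path CSV file path.
#' @param participant_id,trial,site Metadata attached to the trace.
#' @param rate_hz Nominal sampling rate of the recording.
#' @return An [smo2_trace()].
#' @export
read_trace <- function(path, participant_id = NA_character_,
                       trial = NA_integer_, site = NA_character_,
                       rate_hz = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "smo2_pct") %in% names(df))) {
    stop("expected columns `time_s` and `smo2_pct` in ", path, call. = FALSE)
  }
  y <- as.numeric(df$smo2_pct)
  bad <- !is.na(y) & (y < 0 | y > 100)
  if (any(bad)) {
    warning(sum(bad), " sample(s) outside 0-100 %SmO2 marked missing in ",
            basename(path), call. = FALSE)
    y[bad] <- NA_real_
  }
  smo2_trace(as.numeric(df$time_s), y, participant_id = participant_id,
             trial = trial, site = site, rate_hz = rate_hz)
}

#' Smooth a trace and resample to the analysis rate
#'
#' Applies a centred moving average of total span `window_s` (a symmetric
#' window of `window_s / 2` seconds each side), then resamples the smoothed
#' series to `out_rate_hz` by linear interpolation — the manufacturer-style
#' "5-s symmetrical moving average to 1 Hz" step. Edge windows shrink rather
#' than truncate, so the series keeps its full duration. Missing samples are
#' excluded from window means; windows containing no usable samples, and
#' output points bracketed by them, stay missing.
#'
#' @param trace An [smo2_trace()].
#' @param window_s Total moving-average span, seconds.
#' @param out_rate_hz Output sampling rate, Hz.
#' @return An `smo2_trace` at `out_rate_hz`, with a `smoothing` attribute
#'   recording the parameters used (also exported to the JSON sidecar by
#'   [write_trace()]).
#' @export
smooth_and_resample <- function(trace, window_s = 5, out_rate_hz = 1) {
  stopifnot(inherits(trace, "smo2_trace"))
  if (window_s <= 0) stop("`window_s` must be > 0", call. = FALSE)
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)

  t <- trace$time_s
  y <- ifelse(trace$usable, trace$smo2_pct, NA_real_)
  half <- window_s / 2
  eps <- 1e-9

  # windowed means over a (possibly irregular) time base via cumulative sums
  lo <- findInterval(t - half - eps, t) + 1
  hi <- findInterval(t + half + eps, t)
  ok <- !is.na(y)
  cs <- c(0, cumsum(ifelse(ok, y, 0)))
  cn <- c(0, cumsum(ok))
  sum_w <- cs[hi + 1] - cs[lo]
  n_w <- cn[hi + 1] - cn[lo]
  sm <- ifelse(n_w > 0, sum_w / n_w, NA_real_)

  grid <- seq(t[1], t[length(t)], by = 1 / out_rate_hz)
  keep <- !is.na(sm)
  if (sum(keep) < 2) stop("not enough usable samples to resample", call. = FALSE)
  yi <- stats::approx(t[keep], sm[keep], xout = grid, rule = 2)$y
  # a grid point is only trusted if its bracketing raw samples were usable
  prev_i <- pmax(findInterval(grid, t), 1)
  next_i <- pmin(prev_i + 1, length(t))
  on_sample <- abs(grid - t[prev_i]) < eps
  gap <- !keep[prev_i] | (!on_sample & !keep[next_i])
  yi[gap] <- NA_real_

  out <- restamp_trace(trace, grid, yi, usable = !is.na(yi),
                       rate_hz = out_rate_hz)
  attr(out, "smoothing") <- list(window_s = window_s,
                                 out_rate_hz = out_rate_hz,
                                 interpolation = "linear",
                                 edges = "shrunken symmetric window")
  out
}

#' Flag implausible samples by their sample-to-sample jump
#'
#' Marks both endpoints of any step whose absolute SmO2 change exceeds
#' `max_jump_pct` as unusable — such steps are an order of magnitude above
#' physiological rest-phase slopes and indicate light or motion artifact.
#' The missing-fraction threshold used downstream to declare whole bout
#' windows unusable is recorded on the trace. Idempotent: re-screening a
#' screened trace changes nothing.
#'
#' @param trace An [smo2_trace()].
#' @param max_jump_pct Jump threshold, %SmO2 per sample step.
#' @param max_missing_frac Fraction of missing/flagged samples above which a
#'   downstream analysis window is considered unusable.
#' @return The trace with an updated `usable` mask.
#' @export
screen_quality <- function(trace, max_jump_pct = 10, max_missing_frac = 0.5) {
  stopifnot(inherits(trace, "smo2_trace"))
  if (max_jump_pct <= 0 || max_missing_frac <= 0) {
    stop("thresholds must be > 0", call. = FALSE)
  }
  y <- trace$smo2_pct
  jump <- abs(diff(y))
  big <- !is.na(jump) & jump > max_jump_pct
  flag <- logical(nrow(trace))
  flag[which(big)] <- TRUE
  flag[which(big) + 1] <- TRUE
  trace$usable <- trace$usable & !flag & !is.na(y)
  attr(trace, "max_missing_frac") <- max_missing_frac
  attr(trace, "max_jump_pct") <- max_jump_pct
  trace
}

# fraction of a window's samples that are missing vs quality-flagged
window_quality <- function(trace, window) {
  in_w <- trace$time_s >= window[1] & trace$time_s < window[2]
  n <- sum(in_w)
  if (n == 0) {
    return(list(n = 0L, frac_missing = 1, frac_flagged = 0))
  }
  miss <- is.na(trace$smo2_pct[in_w])
  flagged <- !trace$usable[in_w] & !miss
  list(n = n, frac_missing = mean(miss), frac_flagged = mean(flagged))
}

#' Write a cleaned trace plus a JSON sidecar of processing parameters
#'
#' @param trace An [smo2_trace()].
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(trace[, c("time_s", "smo2_pct")], path, na = "")
  meta <- c(trace_meta(trace), list(smoothing = attr(trace, "smoothing")))
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           null = "null")),
             paste0(path, ".json"))
  invisible(path)
}
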