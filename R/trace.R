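#' Construct an SmO2 trace
#'
#' A trace is a tibble with one row per sample: `time_s` (strictly
#' increasing), `smo2_pct` (0-100 or `NA` for missing) and `usable` (logical
#' quality flag; missing samples are never usable). Recording metadata
#' (`participant_id`, `trial`, `site`, `rate_hz`) travels as attributes.
#'
#' @param time_s Sample times, seconds, strictly increasing.
#' @param smo2_pct SmO2 in percent; `NA` marks missing samples.
#' @param participant_id,trial,site Recording metadata. `site` is one of
#'   `"VL"`, `"RF"`, `"PS"`, `"DL"`.
#' @param rate_hz Nominal sampling rate.
#' @param usable Optional logical vector; defaults to `!is.na(smo2_pct)`.
#' @return An `smo2_trace` tibble.
#' @export
smo2_trace <- function(time_s, smo2_pct, participant_id = NA_character_,
                       trial = NA_integer_, site = NA_character_,
                       rate_hz = 0.5, usable = NULL) {
  stopifnot(length(time_s) == length(smo2_pct))
  if (length(time_s) == 0) stop("empty trace", call. = FALSE)
  d <- diff(time_s)
  if (any(d <= 0)) {
    stop("`time_s` must be strictly increasing (duplicated or reversed ",
         "timestamps found)", call. = FALSE)
  }
  if (is.null(usable)) usable <- !is.na(smo2_pct)
  usable <- usable & !is.na(smo2_pct)
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        smo2_pct = as.numeric(smo2_pct),
                        usable = usable)
  attr(out, "participant_id") <- participant_id
  attr(out, "trial") <- trial
  attr(out, "site") <- site
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("smo2_trace", class(tibble::tibble()))
  out
}

trace_meta <- function(trace) {
  list(participant_id = attr(trace, "participant_id"),
       trial = attr(trace, "trial"),
       site = attr(trace, "site"),
       rate_hz = attr(trace, "rate_hz"))
}

# rebuild a trace, carrying metadata (and any extra attrs passed) over
restamp_trace <- function(trace, time_s, smo2_pct, usable, rate_hz = NULL) {
  m <- trace_meta(trace)
  smo2_trace(time_s, smo2_pct,
             participant_id = m$participant_id, trial = m$trial,
             site = m$site, rate_hz = rate_hz %||% m$rate_hz,
             usable = usable)
}

#' Muscle-site class: locomotor or accessory
#'
#' Vastus lateralis (VL) and rectus femoris (RF) are locomotor sites;
#' lumbar paraspinal (PS) and lateral deltoid (DL) are accessory sites.
#' The distinction drives the recovery-window rule.
#'
#' @param site Character vector of site codes.
#' @return Character vector, `"locomotor"` or `"accessory"`.
#' @export
site_class <- function(site) {
  cls <- dplyr::case_when(
    site %in% c("VL", "RF") ~ "locomotor",
    site %in% c("PS", "DL") ~ "accessory",
    TRUE ~ NA_character_
  )
  if (anyNA(cls)) {
    stop("unknown muscle site(s): ",
         paste(unique(site[is.na(cls)]), collapse = ", "), call. = FALSE)
  }
  cls
}

#' @export
print.smo2_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat(sprintf("<smo2_trace> %s trial %s site %s | %d samples @ %g Hz, %.0f s\n",
              m$participant_id, m$trial, m$site, nrow(x), m$rate_hz,
              diff(range(x$time_s))))
  NextMethod()
}
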