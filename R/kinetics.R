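#' Fit a monoexponential recovery to one bout segment
#'
#' Least-squares fit of the delayed monoexponential
#' `y(t) = y0 + amp * (1 - exp(-(t - delay) / tau))` for `t >= delay` (and
#' `y = y0` before the onset delay), with `t = 0` at the end of work.
#' Fitting is by Levenberg-Marquardt from a deterministic multi-start grid
#' (`tau` in 2/5/10/20/40/80 s crossed with `delay` in 0/5/15 s); the lowest
#' residual sum of squares wins. A fit is accepted when its pseudo-R2
#' (`1 - SS_res / SS_tot`, `SS_tot` about the segment mean) is at least
#' `r2_min` and its mean response time `MRT = delay + tau` is plausible:
#' strictly between zero and the time of the SmO2 peak.
#'
#' @param time_s,smo2_pct Segment samples from the end of work to the
#'   recovery peak. `time_s` may be absolute if `t0` gives the work end.
#' @param t0 Time origin (end of work), subtracted from `time_s`.
#' @param t_peak_s Peak time, seconds from the end of work; defaults to the
#'   last sample.
#' @param r2_min Pseudo-R2 acceptance threshold.
#' @return A `monoexp_fit`: list with `y0`, `amp`, `tau_s`, `delay_s`,
#'   `mrt_s`, `pseudo_r2`, `accepted`, `reason`, `n_points`, `t_peak_s`.
#' @export
fit_monoexp <- function(time_s, smo2_pct, t0 = 0, t_peak_s = NULL,
                        r2_min = 0.85) {
  keep <- is.finite(time_s) & is.finite(smo2_pct)
  t <- time_s[keep] - t0
  y <- smo2_pct[keep]
  if (length(t) < 5) stop("need at least 5 usable samples to fit",
                          call. = FALSE)
  if (is.null(t_peak_s)) t_peak_s <- max(t)
  if (max(y) <= y[1]) stop("non-positive amplitude segment", call. = FALSE)

  model <- function(t, y0, amp, tau, delay) {
    y0 + amp * (1 - exp(-pmax(t - delay, 0) / tau))
  }
  df <- data.frame(t = t, y = y)
  starts <- expand.grid(tau = c(2, 5, 10, 20, 40, 80), delay = c(0, 5, 15))
  best <- NULL
  best_ss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + amp * (1 - exp(-pmax(t - delay, 0) / tau)),
        data = df,
        start = list(y0 = y[1], amp = max(y) - y[1],
                     tau = starts$tau[i], delay = starts$delay[i]),
        lower = c(y0 = -Inf, amp = 1e-6, tau = 1e-3, delay = 0),
        upper = c(y0 = Inf, amp = Inf, tau = Inf, delay = max(t)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(stats::resid(fit)^2)
      if (ss < best_ss - 1e-12) {
        best_ss <- ss
        best <- fit
      }
    }
  }

  if (is.null(best)) {
    out <- list(y0 = NA_real_, amp = NA_real_, tau_s = NA_real_,
                delay_s = NA_real_, mrt_s = NA_real_, pseudo_r2 = NA_real_,
                accepted = FALSE, reason = "no_convergence",
                n_points = length(t), t_peak_s = t_peak_s)
    return(structure(out, class = "monoexp_fit"))
  }
  cf <- stats::coef(best)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - best_ss / ss_tot else NA_real_
  mrt <- cf[["delay"]] + cf[["tau"]]
  plausible <- is.finite(mrt) && mrt > 0 && mrt < t_peak_s
  accepted <- isTRUE(r2 >= r2_min) && plausible
  reason <- if (accepted) NA_character_
  else if (!isTRUE(r2 >= r2_min)) "low_pseudo_r2"
  else "implausible_mrt"
  structure(list(y0 = cf[["y0"]], amp = cf[["amp"]], tau_s = cf[["tau"]],
                 delay_s = cf[["delay"]], mrt_s = mrt, pseudo_r2 = r2,
                 accepted = accepted, reason = reason,
                 n_points = length(t), t_peak_s = t_peak_s,
                 data = df),
            class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "<monoexp_fit> tau = %.2f s, delay = %.2f s, MRT = %.2f s, pseudo-R2 = %.3f [%s]\n",
    x$tau_s, x$delay_s, x$mrt_s, x$pseudo_r2,
    if (isTRUE(x$accepted)) "accepted" else paste0("rejected: ", x$reason)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy monoexp_fit
#' @export
tidy.monoexp_fit <- function(x, ...) {
  tibble::tibble(term = c("y0", "amp", "tau_s", "delay_s"),
                 estimate = c(x$y0, x$amp, x$tau_s, x$delay_s))
}

#' @method glance monoexp_fit
#' @export
glance.monoexp_fit <- function(x, ...) {
  tibble::tibble(tau_s = x$tau_s, delay_s = x$delay_s, mrt_s = x$mrt_s,
                 pseudo_r2 = x$pseudo_r2, accepted = x$accepted,
                 reason = x$reason, n_points = x$n_points)
}

#' Analytic half-recovery time of an accepted fit
#'
#' `HRT = delay + tau * ln 2`: the fitted curve crosses half its asymptotic
#' amplitude one log-2 time constant after the onset delay.
#'
#' @param fit A `monoexp_fit`.
#' @return HRT in seconds; `NA` with a warning for unaccepted fits.
#' @export
hrt_from_fit <- function(fit) {
  stopifnot(inherits(fit, "monoexp_fit"))
  if (!isTRUE(fit$accepted)) {
    warning("fit not accepted (", fit$reason, "); HRT not computed",
            call. = FALSE)
    return(NA_real_)
  }
  fit$delay_s + fit$tau_s * log(2)
}

#' Fit monoexponential kinetics to every OK bout of a study
#'
#' For each bout with status `OK`, fits [fit_monoexp()] to the smoothed
#' segment from the end of work to the detected peak and appends the fit
#' summary columns to the bout row.
#'
#' @param bouts Output of [extract_bouts()].
#' @param traces Preprocessed trace table (as used for extraction).
#' @param schedule The `stage_schedule`.
#' @param r2_min Pseudo-R2 acceptance threshold.
#' @return The bout table with columns `fit_tau_s`, `fit_delay_s`, `mrt_s`,
#'   `pseudo_r2`, `fit_accepted`, `reject_reason`, `fit_hrt_s` appended.
#' @export
fit_bouts <- function(bouts, traces, schedule, r2_min = 0.85) {
  key <- paste(traces$participant_id, traces$trial, traces$site)
  res <- purrr::pmap_dfr(
    bouts[, c("participant_id", "trial", "site", "stage_index", "t_peak_s",
              "status")],
    function(participant_id, trial, site, stage_index, t_peak_s, status) {
      blank <- tibble::tibble(fit_tau_s = NA_real_, fit_delay_s = NA_real_,
                              mrt_s = NA_real_, pseudo_r2 = NA_real_,
                              fit_accepted = FALSE,
                              reject_reason = "bout_not_ok",
                              fit_hrt_s = NA_real_)
      if (status != "OK") return(blank)
      trace <- traces$trace[[match(paste(participant_id, trial, site), key)]]
      work_end <- schedule$work_end_s[match(stage_index, schedule$stage)]
      seg <- trace$time_s >= work_end &
        trace$time_s <= work_end + t_peak_s & trace$usable
      if (sum(seg) < 5) {
        blank$reject_reason <- "too_few_points"
        return(blank)
      }
      fit <- fit_monoexp(trace$time_s[seg], trace$smo2_pct[seg],
                         t0 = work_end, t_peak_s = t_peak_s, r2_min = r2_min)
      tibble::tibble(fit_tau_s = fit$tau_s, fit_delay_s = fit$delay_s,
                     mrt_s = fit$mrt_s, pseudo_r2 = fit$pseudo_r2,
                     fit_accepted = fit$accepted,
                     reject_reason = fit$reason,
                     fit_hrt_s = if (fit$accepted)
                       fit$delay_s + fit$tau_s * log(2) else NA_real_)
    })
  dplyr::bind_cols(bouts, res)
}

#' Fraction of bouts whose kinetics do not conform to a monoexponential
#'
#' @param fits Output of [fit_bouts()] (only rows with bout status `OK` are
#'   assessed, mirroring the fit denominators).
#' @return A list with `overall` (fraction rejected) and `by_cell` (tibble
#'   by site and target workload).
#' @export
conformity_report <- function(fits) {
  ok <- fits[fits$status == "OK", ]
  if (nrow(ok) == 0) stop("no OK bouts to assess", call. = FALSE)
  by_cell <- ok |>
    dplyr::group_by(.data$site, .data$target_pct) |>
    dplyr::summarise(n = dplyr::n(),
                     frac_rejected = mean(!.data$fit_accepted),
                     .groups = "drop")
  list(overall = mean(!ok$fit_accepted), by_cell = by_cell)
}
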