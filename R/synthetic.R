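#' Site kinetics profile for the synthetic SmO2 generator
#'
#' Describes one muscle site's piecewise-monoexponential SmO2 behaviour:
#' during work the signal decays toward a workload-scaled desaturation
#' plateau with time constant `deoxy_tau_s`; during rest it recovers toward
#' the pre-exercise baseline with a workload-dependent time constant
#' `tau(p) = tau_base_s * (1 + tau_slope * (p - 0.5))` where `p` is the
#' stage workload as a fraction of Wpeak. `delay_s` is the onset delay
#' applied at every phase transition, so sites with a long delay keep
#' reoxygenating into the start of the next work stage — the behaviour that
#' motivates the extended recovery window for accessory sites.
#'
#' @param site Site code: `"VL"`, `"RF"`, `"PS"` or `"DL"`.
#' @param tau_base_s Reoxygenation time constant at 50 % Wpeak, seconds.
#' @param tau_slope Multiplicative increase in tau per unit %Wpeak.
#' @param delay_s Phase-transition onset delay, seconds.
#' @param deoxy_amplitude_pct Desaturation depth at 100 % Wpeak, %SmO2.
#' @param deoxy_tau_s Work-phase time constant, seconds.
#' @param baseline_pct Resting SmO2, percent.
#' @param overshoot_pct Supra-baseline recovery target offset (default 0).
#' @return A one-row tibble.
#' @export
site_profile <- function(site, tau_base_s, tau_slope = 0, delay_s = 0,
                         deoxy_amplitude_pct = 30, deoxy_tau_s = 25,
                         baseline_pct = 70, overshoot_pct = 0) {
  stopifnot(tau_base_s > 0, deoxy_tau_s > 0, delay_s >= 0,
            baseline_pct >= 0, baseline_pct <= 100)
  site_class(site) # validates the code
  tibble::tibble(site = site, tau_base_s = tau_base_s, tau_slope = tau_slope,
                 delay_s = delay_s, deoxy_amplitude_pct = deoxy_amplitude_pct,
                 deoxy_tau_s = deoxy_tau_s, baseline_pct = baseline_pct,
                 overshoot_pct = overshoot_pct)
}

#' Default site profiles
#'
#' Defaults chosen so the closed-form half-recovery times of the noiseless
#' model sit near published group medians for trained cyclists: fastest in
#' the vastus lateralis and sequentially slower in the order
#' VL < RF < PS < DL at matched relative workload, with reoxygenation
#' slowing as workload rises. Accessory sites (PS, DL) get longer onset
#' delays, so their peaks fall beyond the rest period.
#'
#' @return A four-row tibble of [site_profile()]s.
#' @export
default_site_profiles <- function() {
  dplyr::bind_rows(
    site_profile("VL", tau_base_s = 11.5, tau_slope = 2.2, delay_s = 0,
                 deoxy_amplitude_pct = 40, deoxy_tau_s = 25, baseline_pct = 70),
    site_profile("RF", tau_base_s = 23, tau_slope = 1.8, delay_s = 2,
                 deoxy_amplitude_pct = 30, deoxy_tau_s = 25, baseline_pct = 70),
    site_profile("PS", tau_base_s = 26, tau_slope = 1.4, delay_s = 8,
                 deoxy_amplitude_pct = 25, deoxy_tau_s = 35, baseline_pct = 75),
    site_profile("DL", tau_base_s = 30, tau_slope = 0.6, delay_s = 15,
                 deoxy_amplitude_pct = 30, deoxy_tau_s = 35, baseline_pct = 75)
  )
}

#' Population configuration for a synthetic study
#'
#' Between-participant and between-trial variation act multiplicatively on
#' the reoxygenation time constant via Gaussian effects on log tau (tau must
#' stay positive, so log-normal is the natural choice). One participant
#' effect is shared across that participant's four sites (fitness is a
#' systemic trait) with an additional smaller site-specific participant
#' effect.
#'
#' @param n_participants,n_trials Study dimensions.
#' @param between_sd SD of the shared participant effect on log tau.
#' @param site_sd SD of the site-specific participant effect on log tau.
#' @param within_sd SD of the trial-to-trial effect on log tau.
#' @param noise_sd_pct Additive Gaussian sample noise, %SmO2.
#' @param artifact_rate Probability that any rest bout receives an injected
#'   full-window dropout.
#' @param seed Integer RNG seed; expanded to per-trace substreams by a
#'   counter scheme so adding a participant leaves others' draws unchanged.
#' @return A `population_config` list.
#' @export
population_config <- function(n_participants = 21, n_trials = 2,
                              between_sd = 0.30, site_sd = 0.15,
                              within_sd = 0.15, noise_sd_pct = 1.5,
                              artifact_rate = 0, seed = 1) {
  stopifnot(n_participants >= 1, n_trials >= 1, between_sd >= 0,
            site_sd >= 0, within_sd >= 0, noise_sd_pct >= 0,
            artifact_rate >= 0, artifact_rate <= 1)
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 between_sd = between_sd, site_sd = site_sd,
                 within_sd = within_sd, noise_sd_pct = noise_sd_pct,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "population_config")
}

# deterministic substream seed below 2^31, counter-based
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.numeric(seed) * 1000003) %% 2147483647
  mult <- c(7919, 104729, 1299709, 15485863)
  for (i in seq_along(idx)) {
    s <- (s + idx[i] * mult[((i - 1) %% 4) + 1]) %% 2147483647
  }
  as.integer(s)
}

# piecewise-monoexponential trajectory: segments switch (target, tau) at
# phase boundaries shifted by the onset delay
trajectory_segments <- function(schedule, profile, tau_factor, final_window_s) {
  base <- profile$baseline_pct
  reco <- base + profile$overshoot_pct
  segs <- list(list(t0 = 0, target = base, tau = Inf))
  for (k in seq_len(nrow(schedule))) {
    pct <- schedule$pct_wpeak[k]
    tau_rest <- profile$tau_base_s * (1 + profile$tau_slope * (pct - 0.5)) *
      tau_factor
    segs <- c(segs, list(
      list(t0 = schedule$work_start_s[k] + profile$delay_s,
           target = base - profile$deoxy_amplitude_pct * pct,
           tau = profile$deoxy_tau_s),
      list(t0 = schedule$work_end_s[k] + profile$delay_s,
           target = reco, tau = max(tau_rest, 1e-6))
    ))
  }
  attr(segs, "t_end") <- schedule$work_end_s[nrow(schedule)] +
    final_window_s + 30
  segs
}

eval_trajectory <- function(segs, t) {
  starts <- vapply(segs, `[[`, numeric(1), "t0")
  y <- numeric(length(t))
  y_cur <- segs[[1]]$target
  for (i in seq_along(segs)) {
    t0 <- starts[i]
    t1 <- if (i < length(segs)) starts[i + 1] else Inf
    seg <- segs[[i]]
    in_seg <- t >= t0 & t < t1
    if (any(in_seg)) {
      y[in_seg] <- seg$target + (y_cur - seg$target) *
        exp(-(t[in_seg] - t0) / seg$tau)
    }
    if (is.finite(t1)) {
      y_cur <- seg$target + (y_cur - seg$target) * exp(-(t1 - t0) / seg$tau)
    }
  }
  y
}

#' Simulate one SmO2 recording
#'
#' Generates a noiseless piecewise-monoexponential trajectory over the
#' schedule (see [site_profile()]), adds Gaussian sample noise, clips to the
#' 0-100 % signal range and samples at `rate_hz`. The recording extends
#' `final_window_s` + 30 s past the final work stage so the final recovery
#' window is always covered.
#'
#' @param schedule A `stage_schedule`.
#' @param profile A [site_profile()] row.
#' @param tau_factor Multiplicative participant/trial factor on the
#'   reoxygenation time constant.
#' @param noise_sd_pct Additive noise SD, %SmO2.
#' @param seed Integer seed (required when `noise_sd_pct > 0`).
#' @param rate_hz Sampling rate (device-native 0.5 Hz by default).
#' @param final_window_s Recovery window after the final stage, seconds.
#' @param participant_id,trial Metadata stamped on the trace.
#' @return An [smo2_trace()] with a `truth` attribute: one row per stage
#'   with the generating `tau_s`, `delay_s`, asymptotic `amplitude_pct` and
#'   analytic half-recovery time `delay_s + tau_s * log(2)`.
#' @export
simulate_trace <- function(schedule, profile, tau_factor = 1,
                           noise_sd_pct = 0, seed = NULL, rate_hz = 0.5,
                           final_window_s = 240,
                           participant_id = "P01", trial = 1L) {
  stopifnot(inherits(schedule, "stage_schedule"))
  profile <- tibble::as_tibble(profile)
  stopifnot(nrow(profile) == 1)
  segs <- trajectory_segments(schedule, profile, tau_factor, final_window_s)
  t <- seq(0, attr(segs, "t_end"), by = 1 / rate_hz)
  y <- eval_trajectory(segs, t)

  # per-stage generating truth, from the noiseless trajectory
  pct <- schedule$pct_wpeak
  tau_rest <- profile$tau_base_s * (1 + profile$tau_slope * (pct - 0.5)) *
    tau_factor
  y_onset <- eval_trajectory(segs, schedule$work_end_s + profile$delay_s)
  truth <- tibble::tibble(
    participant_id = participant_id, trial = trial, site = profile$site,
    stage = schedule$stage, pct_wpeak = pct,
    tau_s = tau_rest, delay_s = profile$delay_s,
    amplitude_pct = profile$baseline_pct + profile$overshoot_pct - y_onset,
    analytic_hrt_s = profile$delay_s + tau_rest * log(2)
  )

  if (noise_sd_pct > 0) {
    if (is.null(seed)) stop("`seed` is required when noise_sd_pct > 0",
                            call. = FALSE)
    withr::local_seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd_pct)
  }
  y <- pmin(pmax(y, 0), 100)
  out <- smo2_trace(t, y, participant_id = participant_id, trial = trial,
                    site = profile$site, rate_hz = rate_hz)
  attr(out, "truth") <- truth
  out
}

#' Simulate a full test-retest study
#'
#' One trace per participant x trial x site over a common schedule, with
#' log-normal participant and trial variation on the reoxygenation time
#' constant and optional artifact injection. Identical seeds give identical
#' output.
#'
#' @param pop A [population_config()].
#' @param schedule A `stage_schedule`; defaults to the 7-stage, 70-kg
#'   incremental protocol (1.0 to 4.0 W/kg), which places stages 3, 5 and 7
#'   at exactly 50 %, 75 % and 100 % of Wpeak.
#' @param profiles Tibble of [site_profile()]s, one row per site.
#' @return An `smo2_study`: list with `traces` (tibble with a `trace`
#'   list-column keyed by participant, trial, site), `truth` (per-bout
#'   generating parameters), `schedule` and `config`.
#' @export
simulate_study <- function(pop = population_config(),
                           schedule = build_schedule(n_stages = 7,
                                                     body_mass_kg = 70),
                           profiles = default_site_profiles()) {
  stopifnot(inherits(pop, "population_config"))
  rows <- list()
  truths <- list()
  for (p in seq_len(pop$n_participants)) {
    pid <- sprintf("P%02d", p)
    p_seed <- substream_seed(pop$seed, p)
    withr::local_seed(p_seed)
    shared <- stats::rnorm(1, 0, pop$between_sd)
    site_eff <- stats::rnorm(nrow(profiles), 0, pop$site_sd)
    for (tr in seq_len(pop$n_trials)) {
      t_seed <- substream_seed(pop$seed, p, tr)
      withr::local_seed(t_seed)
      trial_eff <- stats::rnorm(nrow(profiles), 0, pop$within_sd)
      for (s in seq_len(nrow(profiles))) {
        tau_factor <- exp(shared + site_eff[s] + trial_eff[s])
        tr_seed <- substream_seed(pop$seed, p, tr, s)
        trace <- simulate_trace(schedule, profiles[s, ],
                                tau_factor = tau_factor,
                                noise_sd_pct = pop$noise_sd_pct,
                                seed = if (pop$noise_sd_pct > 0) tr_seed,
                                participant_id = pid, trial = tr)
        if (pop$artifact_rate > 0) {
          withr::local_seed(substream_seed(pop$seed, p, tr, s, 999))
          for (k in seq_len(nrow(schedule) - 1)) {
            if (stats::runif(1) < pop$artifact_rate) {
              trace <- inject_artifact(trace,
                                       c(schedule$work_end_s[k],
                                         schedule$rest_end_s[k]),
                                       mode = "dropout")
            }
          }
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = pid, trial = tr, site = profiles$site[s],
          trace = list(trace))
        truths[[length(truths) + 1]] <- attr(trace, "truth")
      }
    }
  }
  structure(list(traces = dplyr::bind_rows(rows),
                 truth = dplyr::bind_rows(truths),
                 schedule = schedule, config = pop),
            class = "smo2_study")
}

#' Inject an artifact into a trace
#'
#' `"dropout"` replaces the window's samples with missing values, emulating
#' a recording failure; `"noise_burst"` adds high-variance noise (clipped to
#' 0-100 %), emulating light/motion interference from a loose sensor.
#'
#' @param trace An [smo2_trace()].
#' @param window Length-2 numeric `c(start_s, end_s)` within the trace;
#'   half-open.
#' @param mode `"dropout"` or `"noise_burst"`.
#' @param noise_sd Burst noise SD, %SmO2.
#' @param seed Optional seed for the burst noise.
#' @return The modified trace.
#' @export
inject_artifact <- function(trace, window, mode = c("dropout", "noise_burst"),
                            noise_sd = 30, seed = NULL) {
  stopifnot(inherits(trace, "smo2_trace"), length(window) == 2)
  mode <- match.arg(mode)
  if (window[2] <= window[1]) {
    stop("artifact window must have positive length", call. = FALSE)
  }
  if (window[1] < trace$time_s[1] || window[2] > trace$time_s[nrow(trace)] + 1e-9) {
    stop("artifact window outside the trace", call. = FALSE)
  }
  idx <- which(trace$time_s >= window[1] & trace$time_s < window[2])
  if (length(idx) == 0) stop("artifact window contains no samples",
                             call. = FALSE)
  if (mode == "dropout") {
    trace$smo2_pct[idx] <- NA_real_
    trace$usable[idx] <- FALSE
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    trace$smo2_pct[idx] <- pmin(pmax(
      trace$smo2_pct[idx] + stats::rnorm(length(idx), 0, noise_sd), 0), 100)
  }
  trace
}

#' Write a synthetic study to CSV files
#'
#' One `time_s, smo2_pct` CSV per trace (missing samples as empty fields),
#' plus `manifest.csv` (participant, trial, site, file) and
#' `ground_truth.csv`.
#'
#' @param study An `smo2_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "smo2_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- study$traces |>
    dplyr::mutate(file = sprintf("%s_T%d_%s.csv", .data$participant_id,
                                 .data$trial, .data$site))
  purrr::pwalk(list(manifest$trace, manifest$file), function(trace, file) {
    readr::write_csv(trace[, c("time_s", "smo2_pct")],
                     file.path(dir, file), na = "")
  })
  readr::write_csv(manifest[, c("participant_id", "trial", "site", "file")],
                   file.path(dir, "manifest.csv"))
  readr::write_csv(study$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
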