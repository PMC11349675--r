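#' Build an incremental multi-stage cycling schedule
#'
#' Constructs the stage table for an incremental step protocol of `work_s`
#' seconds of work followed by `rest_s` seconds of passive rest per stage,
#' with relative workload starting at `start_wkg` and increasing by
#' `increment_wkg` per stage. Time is seconds from recording start, 0-based,
#' and every interval is half-open `[start, end)`.
#'
#' @param start_wkg Relative workload of stage 1 (W kg^-1).
#' @param increment_wkg Workload increment per stage (W kg^-1).
#' @param n_stages Number of stages (>= 1).
#' @param body_mass_kg Body mass used to convert W kg^-1 to absolute watts.
#' @param work_s Work-phase duration per stage, seconds.
#' @param rest_s Rest-phase duration per stage, seconds (>= 0).
#' @param wpeak_w Peak workload in watts. Defaults to the final stage's
#'   absolute workload (i.e. the final stage was fully completed); use
#'   [compute_wpeak()] + [set_wpeak()] for partially completed final stages.
#'
#' @return A `stage_schedule`: a tibble with one row per stage and columns
#'   `stage`, `workload_wkg`, `workload_w`, `pct_wpeak`, `work_start_s`,
#'   `work_end_s`, `rest_end_s`, carrying `wpeak_w` and `body_mass_kg` as
#'   attributes.
#' @examples
#' sched <- build_schedule(n_stages = 7, body_mass_kg = 70)
#' sched$workload_w[7] # 280 W
#' @export
build_schedule <- function(start_wkg = 1.0, increment_wkg = 0.5, n_stages,
                           body_mass_kg, work_s = 300, rest_s = 60,
                           wpeak_w = NULL) {
  stopifnot(length(n_stages) == 1, length(body_mass_kg) == 1)
  if (n_stages < 1) stop("`n_stages` must be >= 1", call. = FALSE)
  if (work_s <= 0) stop("`work_s` must be > 0", call. = FALSE)
  if (rest_s < 0) stop("`rest_s` must be >= 0", call. = FALSE)
  if (body_mass_kg <= 0) stop("`body_mass_kg` must be > 0", call. = FALSE)

  k <- seq_len(n_stages)
  cycle_s <- work_s + rest_s
  stages <- tibble::tibble(
    stage        = k,
    workload_wkg = start_wkg + (k - 1) * increment_wkg,
    workload_w   = (start_wkg + (k - 1) * increment_wkg) * body_mass_kg,
    work_start_s = (k - 1) * cycle_s,
    work_end_s   = (k - 1) * cycle_s + work_s,
    rest_end_s   = k * cycle_s
  )
  if (is.null(wpeak_w)) wpeak_w <- stages$workload_w[n_stages]
  new_stage_schedule(stages, wpeak_w = wpeak_w, body_mass_kg = body_mass_kg)
}

new_stage_schedule <- function(stages, wpeak_w, body_mass_kg) {
  if (any(stages$work_start_s >= stages$work_end_s) ||
      any(stages$work_end_s > stages$rest_end_s)) {
    stop("stage intervals must satisfy work_start < work_end <= rest_end",
         call. = FALSE)
  }
  if (nrow(stages) > 1 &&
      any(abs(stages$work_start_s[-1] - stages$rest_end_s[-nrow(stages)]) > 1e-9)) {
    stop("stages must be contiguous: stage k+1 must start when stage k ends",
         call. = FALSE)
  }
  stages$pct_wpeak <- stages$workload_w / wpeak_w
  out <- stages[, c("stage", "workload_wkg", "workload_w", "pct_wpeak",
                    "work_start_s", "work_end_s", "rest_end_s")]
  attr(out, "wpeak_w") <- wpeak_w
  attr(out, "body_mass_kg") <- body_mass_kg
  class(out) <- c("stage_schedule", class(tibble::tibble()))
  out
}

#' Peak workload from a schedule with a partially completed final stage
#'
#' Wpeak is the highest fully completed workload plus the fraction of the
#' final stage completed, prorated over the workload increment to the final
#' stage: `Wpeak = W_prev + fraction * (W_final - W_prev)`. A fraction of 1
#' yields the final stage's workload; with a single-stage schedule the
#' previous workload is taken as 0.
#'
#' @param schedule A `stage_schedule`.
#' @param completed_fraction_of_final Fraction in \[0, 1\] of the final
#'   stage's work phase that was completed.
#' @return Peak workload in watts (scalar).
#' @examples
#' s <- build_schedule(n_stages = 2, body_mass_kg = 70)
#' compute_wpeak(s, 0.5)
#' @export
compute_wpeak <- function(schedule, completed_fraction_of_final = 1) {
  stopifnot(inherits(schedule, "stage_schedule"), nrow(schedule) >= 1)
  f <- completed_fraction_of_final
  if (length(f) != 1 || is.na(f) || f < 0 || f > 1) {
    stop("`completed_fraction_of_final` must be a scalar in [0, 1]",
         call. = FALSE)
  }
  n <- nrow(schedule)
  w_final <- schedule$workload_w[n]
  w_prev <- if (n > 1) schedule$workload_w[n - 1] else 0
  w_prev + f * (w_final - w_prev)
}

#' Set the peak workload of a schedule and recompute relative workloads
#'
#' @param schedule A `stage_schedule`.
#' @param wpeak_w Peak workload in watts (> 0).
#' @return The schedule with updated `pct_wpeak` column and `wpeak_w`
#'   attribute.
#' @export
set_wpeak <- function(schedule, wpeak_w) {
  stopifnot(inherits(schedule, "stage_schedule"))
  if (length(wpeak_w) != 1 || wpeak_w <= 0) {
    stop("`wpeak_w` must be a positive scalar", call. = FALSE)
  }
  schedule$pct_wpeak <- schedule$workload_w / wpeak_w
  attr(schedule, "wpeak_w") <- wpeak_w
  schedule
}

#' Map recording time to protocol phase
#'
#' Resolves each time point to its owning stage and phase (`"work"` or
#' `"rest"`) using the half-open convention `[start, end)`; the very last
#' instant of the recording (`t == last rest_end_s`) is assigned to the final
#' rest phase.
#'
#' @param schedule A `stage_schedule`.
#' @param t Numeric vector of times in seconds from recording start.
#' @return A tibble with columns `time_s`, `phase`, `stage`.
#' @examples
#' s <- build_schedule(n_stages = 2, body_mass_kg = 70)
#' phase_at(s, c(0, 300, 360))
#' @export
phase_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "stage_schedule"))
  t_end <- schedule$rest_end_s[nrow(schedule)]
  if (any(t < 0 | t > t_end)) {
    stop("`t` outside the recording: must lie in [0, ", t_end, "]",
         call. = FALSE)
  }
  cycle_starts <- schedule$work_start_s
  idx <- findInterval(t, cycle_starts) # stage owning each t
  idx[t >= t_end] <- nrow(schedule)
  in_work <- t < schedule$work_end_s[idx] & t >= schedule$work_start_s[idx]
  tibble::tibble(
    time_s = t,
    phase = ifelse(in_work, "work", "rest"),
    stage = schedule$stage[idx]
  )
}

#' Read a protocol description from a YAML or JSON config file
#'
#' Two layouts are accepted. A parametric layout with keys `start_wkg`,
#' `increment_wkg`, `n_stages`, `body_mass_kg`, `work_s`, `rest_s` (and
#' optionally `wpeak_w`), or an explicit layout with a `stages` list where
#' each element has `index`, `watts`, `start`, `end`, `rest_end`.
#'
#' @param path Path to the config file.
#' @return A `stage_schedule`.
#' @export
read_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$stages)) {
    st <- dplyr::bind_rows(lapply(cfg$stages, tibble::as_tibble))
    mass <- cfg$body_mass_kg %||% NA_real_
    stages <- tibble::tibble(
      stage        = as.integer(st$index),
      workload_w   = as.numeric(st$watts),
      workload_wkg = if (is.na(mass)) NA_real_ else st$watts / mass,
      work_start_s = as.numeric(st$start),
      work_end_s   = as.numeric(st$end),
      rest_end_s   = as.numeric(st$rest_end)
    )
    wpeak <- cfg$wpeak_w %||% max(stages$workload_w)
    new_stage_schedule(stages, wpeak_w = wpeak, body_mass_kg = mass)
  } else {
    required <- c("n_stages", "body_mass_kg")
    missing <- setdiff(required, names(cfg))
    if (length(missing)) {
      stop("protocol config missing keys: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    build_schedule(
      start_wkg = cfg$start_wkg %||% 1.0,
      increment_wkg = cfg$increment_wkg %||% 0.5,
      n_stages = cfg$n_stages,
      body_mass_kg = cfg$body_mass_kg,
      work_s = cfg$work_s %||% 300,
      rest_s = cfg$rest_s %||% 60,
      wpeak_w = cfg$wpeak_w
    )
  }
}
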