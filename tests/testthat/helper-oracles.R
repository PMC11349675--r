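# Independent oracles used across the suite.

# O(n^2) brute-force peak rule: earliest sample with no strictly higher
# sample within the next `lookahead` seconds.
brute_force_peak <- function(t, y, lookahead = 30) {
  for (i in seq_along(t)) {
    higher <- FALSE
    for (j in seq_along(t)) {
      if (t[j] > t[i] && t[j] <= t[i] + lookahead && y[j] > y[i]) {
        higher <- TRUE
        break
      }
    }
    if (!higher) return(list(y_b = y[i], t_peak_s = t[i]))
  }
  NULL
}

# Hand-computed two-way ANOVA mean squares for the frozen 5x2 toy matrix
# {(8,10),(12,11),(17,15),(9,12),(14,13)}:
#   row means 9, 11.5, 16, 10.5, 13.5; column means 12, 12.2; grand 12.1
#   SS_rows = 2*29.7 = 59.4 -> MSR = 14.85
#   SS_cols = 5*0.02 = 0.1  -> MSC = 0.10
#   SS_tot  = 68.9, SS_err = 9.4 -> MSE = 2.35
#   ICC(2,1) = (14.85-2.35)/(14.85+2.35+(2/5)*(0.1-2.35)) = 12.5/16.3
toy_matrix <- function() {
  matrix(c(8, 10, 12, 11, 17, 15, 9, 12, 14, 13), ncol = 2, byrow = TRUE)
}
toy_oracle <- list(msr = 14.85, msc = 0.10, mse = 2.35,
                   icc = 12.5 / 16.3, sem = sqrt(2.35),
                   mdc = 1.96 * sqrt(2) * sqrt(2.35))

# mean squares via stats::aov, as a second independent route
aov_mean_squares <- function(mat) {
  d <- data.frame(y = as.vector(mat),
                  subj = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                  trial = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  tab <- summary(stats::aov(y ~ subj + trial, data = d))[[1]]
  list(msr = tab["subj", "Mean Sq"], msc = tab["trial", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

# a bare monoexponential recovery segment sampled at `rate` Hz
monoexp_segment <- function(tau, delay = 0, y0 = 40, amp = 30,
                            t_end = 180, rate = 1) {
  t <- seq(0, t_end, by = 1 / rate)
  y <- y0 + amp * (1 - exp(-pmax(t - delay, 0) / tau))
  list(t = t, y = y)
}

# schedule + profile pair giving a long, fully captured noiseless recovery
# after stage 1 (locomotor window = rest duration)
long_rest_setup <- function(tau, rest_s = 600) {
  sched <- build_schedule(n_stages = 2, body_mass_kg = 70,
                          work_s = 300, rest_s = rest_s)
  prof <- site_profile("VL", tau_base_s = tau, tau_slope = 0, delay_s = 0,
                       deoxy_amplitude_pct = 30, deoxy_tau_s = 20,
                       baseline_pct = 70)
  list(schedule = sched, profile = prof)
}

# extracted nonparametric HRT of stage 1 for a noiseless trace
pipeline_hrt <- function(tau, rest_s = 600) {
  su <- long_rest_setup(tau, rest_s)
  tr <- simulate_trace(su$schedule, su$profile)
  pp <- screen_quality(smooth_and_resample(tr))
  win <- recovery_window(su$schedule, 1, "VL")
  y_a <- end_work_baseline(pp, su$schedule$work_end_s[1])
  pk <- detect_peak(pp, win)
  half_recovery_time(pp, y_a, pk$y_b, su$schedule$work_end_s[1], pk$t_peak_s)
}

# random series generator for peak-oracle equivalence checks
random_series <- function(n = NULL) {
  if (is.null(n)) n <- sample(20:120, 1)
  t <- seq(0, n - 1)
  y <- cumsum(stats::rnorm(n, sd = 2)) + stats::rnorm(n, sd = 1)
  kind <- sample(3, 1)
  if (kind == 2) y <- y + seq(0, 10, length.out = n)      # drift up
  if (kind == 3) y <- round(y)                            # heavy ties
  list(t = t, y = y)
}
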