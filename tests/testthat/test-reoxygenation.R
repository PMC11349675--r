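test_that("end-work baseline is the mean of the final 30 s of work", {
  tr <- smo2_trace(0:400, rep(40, 401))
  expect_equal(end_work_baseline(tr, 300), 40)

  # linear 30 -> 40 % over the final 30 s sampled at 1 Hz
  y <- rep(30, 401)
  y[271:301] <- seq(30, 40, length.out = 31) # t = 270..300
  tr2 <- smo2_trace(0:400, y)
  # window [270, 300) holds samples t = 270..299
  expect_equal(end_work_baseline(tr2, 300), mean(y[271:300]))
  expect_equal(end_work_baseline(tr2, 300), 34.83333, tolerance = 1e-5)

  # fully missing window -> NA (MISSING downstream)
  y3 <- rep(50, 401); y3[271:301] <- NA
  expect_true(is.na(end_work_baseline(smo2_trace(0:400, y3), 300)))
})

test_that("recovery windows follow the locomotor/accessory/final rules", {
  s <- build_schedule(n_stages = 3, body_mass_kg = 70)
  expect_equal(recovery_window(s, 1, "VL"), c(300, 360))   # 60 s
  expect_equal(recovery_window(s, 1, "RF"), c(300, 360))
  expect_equal(recovery_window(s, 1, "PS"), c(300, 420))   # 120 s
  expect_equal(recovery_window(s, 1, "DL"), c(300, 420))
  # final stage: 4 min for every site
  expect_equal(recovery_window(s, 3, "VL"), c(1020, 1260))
  expect_equal(recovery_window(s, 3, "DL"), c(1020, 1260))
})

test_that("peak detection matches the brute-force oracle on random series", {
  withr::local_seed(101)
  for (rep in 1:300) {
    ser <- random_series()
    tr <- smo2_trace(ser$t, ser$y + 100 - max(ser$y)) # keep within scale
    win <- c(0, max(ser$t) + 1)
    got <- detect_peak(tr, win)
    want <- brute_force_peak(tr$time_s, tr$smo2_pct)
    expect_equal(got$y_b, want$y_b)
    expect_equal(got$t_peak_s, want$t_peak_s)
  }
})

test_that("peak rule: earliest wins on ties, monotone series peak at end", {
  # constant series: every sample qualifies, earliest wins
  tr <- smo2_trace(0:50, rep(55, 51))
  pk <- detect_peak(tr, c(0, 51))
  expect_equal(pk$t_peak_s, 0)

  # 50, 55, 54, 53, ... no later rise within 30 s -> peak 55 at t = 1
  y <- c(50, 55, seq(54, 54 - 48 * 0.1, by = -0.1))
  tr2 <- smo2_trace(seq_along(y) - 1, y)
  pk2 <- detect_peak(tr2, c(0, length(y)))
  expect_equal(pk2$y_b, 55)
  expect_equal(pk2$t_peak_s, 1)

  # strictly increasing series: only the last sample has no higher follower
  y3 <- seq(40, 70, length.out = 61)
  tr3 <- smo2_trace(0:60, y3)
  pk3 <- detect_peak(tr3, c(0, 61))
  expect_equal(pk3$t_peak_s, 60)
  expect_true(pk3$truncated_lookahead)

  # no usable samples -> NULL (NO_PEAK downstream)
  tr4 <- smo2_trace(0:10, rep(NA_real_, 11))
  expect_null(detect_peak(tr4, c(0, 11)))
})

test_that("half-recovery time interpolates between bracketing samples", {
  # 1 Hz ramp 40, 44, 48, ... with Y_A = 40
  y <- seq(40, 40 + 4 * 20, by = 4)
  tr <- smo2_trace(0:20, y)
  expect_equal(half_recovery_time(tr, 40, 56, 0, 20), 2)       # thr 48 exact
  expect_equal(half_recovery_time(tr, 40, 54, 0, 20), 1.75)    # thr 47
  # linear recovery from Y_A to Y_B over 40 s -> HRT 20 s by symmetry
  tr2 <- smo2_trace(0:40, seq(30, 60, length.out = 41))
  expect_equal(half_recovery_time(tr2, 30, 60, 0, 40), 20)
  expect_error(half_recovery_time(tr, 50, 45, 0, 20), "y_b > y_a")
})

test_that("HRT is invariant under positive affine rescaling of the signal", {
  withr::local_seed(55)
  su <- long_rest_setup(15, rest_s = 300)
  tr <- simulate_trace(su$schedule, su$profile, noise_sd_pct = 1, seed = 8)
  work_end <- su$schedule$work_end_s[1]
  win <- recovery_window(su$schedule, 1, "VL")
  for (ab in list(c(1, 0), c(0.5, 10), c(0.25, 30))) {
    tr2 <- tr
    tr2$smo2_pct <- ab[1] * tr$smo2_pct + ab[2]
    pp <- smooth_and_resample(tr2)
    y_a <- end_work_baseline(pp, work_end)
    pk <- detect_peak(pp, win)
    hrt <- half_recovery_time(pp, y_a, pk$y_b, work_end, pk$t_peak_s)
    if (ab[1] == 1) ref <- hrt else expect_equal(hrt, ref, tolerance = 1e-8)
  }
})

test_that("delayed monoexponential bouts shift HRT by the onset delay", {
  sched <- build_schedule(n_stages = 2, body_mass_kg = 70, rest_s = 600)
  prof <- site_profile("VL", tau_base_s = 20, tau_slope = 0, delay_s = 10,
                       deoxy_amplitude_pct = 30, deoxy_tau_s = 20)
  tr <- simulate_trace(sched, prof)
  pp <- screen_quality(smooth_and_resample(tr))
  y_a <- end_work_baseline(pp, 300)
  pk <- detect_peak(pp, recovery_window(sched, 1, "VL"))
  hrt <- half_recovery_time(pp, y_a, pk$y_b, 300, pk$t_peak_s)
  expect_lt(abs(hrt - (10 + 20 * log(2))), 1.5)
})

test_that("bout extraction assigns statuses and keeps OK-bout invariants", {
  study <- simulate_study(population_config(n_participants = 4, seed = 31))
  bouts <- extract_bouts(study)
  expect_equal(nrow(bouts), 4 * 2 * 4 * 3)
  expect_named(
    bouts,
    c("participant_id", "trial", "site", "stage_index", "pct_wpeak", "y_a",
      "y_b", "t_peak_s", "amplitude_pct", "hrt_s", "status", "target_pct"))
  ok <- bouts[bouts$status == "OK", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$amplitude_pct > 0))
  expect_true(all(ok$hrt_s >= 0 & ok$hrt_s <= ok$t_peak_s))
  expect_true(all(ok$y_a >= 0 & ok$y_a <= 100 & ok$y_b <= 100))

  # zero-amplitude traces are flagged, not errors
  s <- build_schedule(n_stages = 7, body_mass_kg = 70)
  flat <- simulate_trace(s, site_profile("VL", tau_base_s = 10,
                                         deoxy_amplitude_pct = 0))
  tt <- tibble::tibble(participant_id = "P01", trial = 1L, site = "VL",
                       trace = list(screen_quality(smooth_and_resample(flat))))
  bf <- extract_bouts(tt, s)
  expect_true(all(bf$status == "ZERO_AMPLITUDE"))
})

test_that("site ordering of median HRT survives extraction", {
  study <- simulate_study(population_config(n_participants = 8, seed = 47))
  bouts <- extract_bouts(study)
  med <- bouts |>
    dplyr::filter(.data$status == "OK") |>
    dplyr::group_by(.data$site, .data$target_pct) |>
    dplyr::summarise(m = stats::median(.data$hrt_s), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "site", values_from = "m")
  for (i in seq_len(nrow(med))) {
    expect_true(med$VL[i] < med$RF[i] && med$RF[i] < med$PS[i] &&
                  med$RF[i] < med$DL[i])
    if (med$target_pct[i] < 100) expect_true(med$PS[i] < med$DL[i])
  }
})

test_that("bout CSV export has the canonical column set", {
  study <- simulate_study(population_config(n_participants = 1, seed = 2))
  bouts <- extract_bouts(study)
  f <- withr::local_tempfile(fileext = ".csv")
  write_bouts(bouts, f)
  hdr <- names(readr::read_csv(f, show_col_types = FALSE, n_max = 1))
  expect_identical(hdr, c("participant_id", "trial", "site", "stage_index",
                          "pct_wpeak", "y_a", "y_b", "t_peak_s",
                          "amplitude_pct", "hrt_s", "status"))
})
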