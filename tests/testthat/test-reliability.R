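test_that("between-participant CV matches hand computation", {
  expect_equal(between_cv(c(10, 10, 10)), 0)
  expect_equal(between_cv(c(8, 12)), 100 * sd(c(8, 12)) / 10)
  expect_equal(between_cv(c(8, 12)), 28.28427, tolerance = 1e-5)
  expect_error(between_cv(7), "at least 2")
  expect_error(between_cv(c(-5, 5)), "positive")
})

test_that("ICC(2,1) matches the hand-computed ANOVA oracle", {
  m <- toy_matrix()
  # route 1: frozen hand-computed mean squares
  res <- icc_2_1(m)
  expect_equal(res$icc, toy_oracle$icc, tolerance = 1e-10)
  # route 2: stats::aov mean squares plugged into the ICC formula
  ms <- aov_mean_squares(m)
  expect_equal(ms$msr, toy_oracle$msr, tolerance = 1e-10)
  expect_equal(ms$mse, toy_oracle$mse, tolerance = 1e-10)
  icc_aov <- (ms$msr - ms$mse) /
    (ms$msr + ms$mse + (2 / 5) * (ms$msc - ms$mse))
  expect_equal(res$icc, icc_aov, tolerance = 1e-10)
  expect_true(res$ci_low < res$icc && res$icc < res$ci_high)

  # duplicated trials -> perfect agreement
  dup <- cbind(c(5, 9, 14, 21), c(5, 9, 14, 21))
  expect_equal(icc_2_1(dup)$icc, 1)

  # systematic offset is penalised by absolute agreement
  off <- cbind(c(10, 30, 50, 70, 90), c(12, 32, 52, 72, 92))
  expect_lt(icc_2_1(off)$icc, 1)
  expect_gt(icc_2_1(off)$icc, 0.9) # between-subject variance dominates

  expect_error(icc_2_1(toy_matrix()[1:2, ]), "at least 3")
  expect_warning(icc_2_1(matrix(5, 4, 2)), "zero total variance")
})

test_that("SEM and MDC come from the same ANOVA and keep their ratio", {
  m <- toy_matrix()
  res <- sem_mdc(m)
  expect_equal(res$sem, toy_oracle$sem, tolerance = 1e-10)
  expect_equal(res$mdc, toy_oracle$mdc, tolerance = 1e-10)
  expect_equal(res$mdc / res$sem, 1.96 * sqrt(2))
  expect_true(res$sem_ci_low < res$sem && res$sem < res$sem_ci_high)

  dup <- cbind(c(5, 9, 14, 21), c(5, 9, 14, 21))
  expect_equal(sem_mdc(dup)$sem, 0)
  expect_equal(sem_mdc(dup)$mdc, 0)

  # SEM of 12 s implies MDC of 33.26 s (33 at integer reporting precision)
  expect_equal(round(1.96 * sqrt(2) * 12), 33)
})

test_that("within-participant CV is the RMS of per-participant CVs", {
  dup <- cbind(c(5, 9, 14), c(5, 9, 14))
  expect_equal(within_cv(dup), 0)
  expect_equal(within_cv(matrix(c(8, 12), 1)), 28.28427, tolerance = 1e-5)
  m <- rbind(c(8, 12), c(20, 25), c(30, 28))
  oracle <- 100 * sqrt(mean(apply(m, 1, sd)^2 / rowMeans(m)^2))
  expect_equal(within_cv(m), oracle)
  expect_error(within_cv(rbind(c(0, 0), c(1, 2))), "zero participant mean")
})

test_that("ICC recovers known variance components in simulation", {
  withr::local_seed(314)
  n <- 500
  sd_b <- 2; sd_w <- 1 # true ICC = 4 / 5
  subj <- rnorm(n, 20, sd_b)
  m <- cbind(subj + rnorm(n, 0, sd_w), subj + rnorm(n, 0, sd_w))
  est <- icc_2_1(m)$icc
  expect_equal(est, sd_b^2 / (sd_b^2 + sd_w^2), tolerance = 0.05)
})

test_that("ICC bands follow the 0.5 / 0.75 / 0.9 interpretation cuts", {
  expect_equal(icc_band(c(0.2, 0.6, 0.8, 0.95)),
               c("poor", "moderate", "good", "excellent"))
  expect_true(is.na(icc_band(NA_real_)))
})

test_that("report tables have the study layout and honour listwise n", {
  study <- simulate_study(population_config(n_participants = 8, seed = 61))
  bouts <- extract_bouts(study)
  rep <- build_reports(bouts)
  expect_equal(nrow(rep$descriptives), 12) # 4 sites x 3 workloads
  expect_equal(nrow(rep$reliability), 12)
  expect_true(all(rep$reliability$mdc_s >= rep$reliability$sem_s))
  expect_true(all(rep$reliability$icc <= 1, na.rm = TRUE))

  # knock out one participant's trial-2 VL bout at one workload: the
  # descriptive n keeps the participant, the reliability n drops them
  hit <- bouts$participant_id == "P03" & bouts$trial == 2 &
    bouts$site == "VL" & bouts$target_pct == 75
  bouts$status[hit] <- "MISSING"
  bouts$hrt_s[hit] <- NA_real_
  rep2 <- build_reports(bouts)
  d_n <- rep2$descriptives$n[rep2$descriptives$site == "VL" &
                               rep2$descriptives$target_pct == 75]
  r_n <- rep2$reliability$n[rep2$reliability$site == "VL" &
                              rep2$reliability$target_pct == 75]
  expect_equal(d_n, 8)
  expect_equal(r_n, 7)
  expect_true(all(rep2$reliability$n <= rep2$descriptives$n))

  # median invariance under participant reordering
  shuf <- bouts[sample(nrow(bouts)), ]
  expect_equal(reox_descriptives(shuf)$median_s, rep2$descriptives$median_s)
})

test_that("degenerate studies give the expected reliability extremes", {
  # no noise, no within-trial variation -> trials identical -> ICC 1, SEM 0
  pop <- population_config(n_participants = 5, within_sd = 0,
                           noise_sd_pct = 0, seed = 5)
  bouts <- extract_bouts(simulate_study(pop))
  rel <- reliability_summary(bouts)
  expect_true(all(abs(rel$icc - 1) < 1e-6))
  expect_true(all(rel$sem_s < 1e-6))
  expect_true(all(rel$mdc_s < 1e-6))

  # within-participant variation dominating between -> poor ICC
  pop2 <- population_config(n_participants = 10, between_sd = 0.02,
                            site_sd = 0, within_sd = 0.8, noise_sd_pct = 0,
                            seed = 6)
  bouts2 <- extract_bouts(simulate_study(
    pop2, profiles = default_site_profiles()[1, ]))
  rel2 <- reliability_summary(bouts2)
  expect_true(all(rel2$icc < 0.5))
  expect_true(all(rel2$icc_band == "poor"))
})
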