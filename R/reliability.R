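#' Between-participant coefficient of variation
#'
#' `100 * SD / mean` over one value per participant (trial means).
#'
#' @param x Numeric vector, one value per participant.
#' @return CV in percent.
#' @export
between_cv <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(x)
  if (m <= 0) stop("mean must be positive for a CV", call. = FALSE)
  100 * stats::sd(x) / m
}

# listwise-complete matrix + two-way ANOVA mean squares (rows = subjects,
# cols = repeated trials)
reliability_anova <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 3) stop("need at least 3 complete participant rows", call. = FALSE)
  if (k < 2) stop("need at least 2 trials", call. = FALSE)
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(n = n, k = k,
       msr = ss_rows / (n - 1),
       msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` from the mean
#' squares of the two-way ANOVA (rows = participants, columns = trials),
#' with the standard F-based 95 % confidence interval (Satterthwaite
#' degrees of freedom for the lower-tail F).
#'
#' @param mat Numeric matrix or data frame, participants x trials;
#'   incomplete rows are dropped listwise.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `n`, `icc`, `ci_low`, `ci_high`.
#' @export
icc_2_1 <- function(mat, conf_level = 0.95) {
  a <- reliability_anova(mat)
  n <- a$n; k <- a$k
  denom <- a$msr + (k - 1) * a$mse + (k / n) * (a$msc - a$mse)
  if (denom <= 0) {
    warning("zero total variance; ICC undefined", call. = FALSE)
    return(tibble::tibble(n = n, icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_))
  }
  icc <- (a$msr - a$mse) / denom
  alpha <- 1 - conf_level
  aa <- (k * icc) / (n * (1 - icc))
  bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (aa * a$msc + bb * a$mse)^2 /
    ((aa * a$msc)^2 / (k - 1) + (bb * a$mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (a$msr - f_l * a$mse) /
    (f_l * (k * a$msc + (k * n - k - n) * a$mse) + n * a$msr)
  hi <- n * (f_u * a$msr - a$mse) /
    (k * a$msc + (k * n - k - n) * a$mse + n * f_u * a$msr)
  tibble::tibble(n = n, icc = icc, ci_low = lo, ci_high = hi)
}

#' SEM and MDC from the two-way ANOVA
#'
#' The standard error of measurement is the within-participant error term
#' of the same two-way ANOVA used for ICC(2,1): `SEM = sqrt(MS_E)`, in
#' original units. The minimal detectable change at 95 % confidence is
#' `MDC = 1.96 * sqrt(2) * SEM`. The SEM interval comes from chi-square
#' bounds on `MS_E` with `(n-1)(k-1)` degrees of freedom.
#'
#' @param mat Participants x trials matrix; incomplete rows dropped.
#' @param conf_level Confidence level for the SEM interval.
#' @param mdc_multiplier Normal quantile in the MDC (default the
#'   conventional 1.96).
#' @return A one-row tibble: `n`, `sem`, `sem_ci_low`, `sem_ci_high`, `mdc`.
#' @export
sem_mdc <- function(mat, conf_level = 0.95, mdc_multiplier = 1.96) {
  a <- reliability_anova(mat)
  df_e <- (a$n - 1) * (a$k - 1)
  alpha <- 1 - conf_level
  sem <- sqrt(a$mse)
  lo <- sqrt(df_e * a$mse / stats::qchisq(1 - alpha / 2, df_e))
  hi <- sqrt(df_e * a$mse / stats::qchisq(alpha / 2, df_e))
  tibble::tibble(n = a$n, sem = sem, sem_ci_low = lo, sem_ci_high = hi,
                 mdc = mdc_multiplier * sqrt(2) * sem)
}

#' Within-participant coefficient of variation
#'
#' Root mean square of the per-participant CVs across trials:
#' `100 * sqrt(mean(s_i^2 / m_i^2))` with `s_i`, `m_i` the trial SD and
#' mean of participant i.
#'
#' @param mat Participants x trials matrix; incomplete rows dropped.
#' @return CV in percent.
#' @export
within_cv <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 1) stop("need at least 1 complete row", call. = FALSE)
  m_i <- rowMeans(mat)
  if (any(m_i == 0)) stop("zero participant mean; CV undefined",
                          call. = FALSE)
  s_i <- apply(mat, 1, stats::sd)
  100 * sqrt(mean(s_i^2 / m_i^2))
}

#' Interpretation band for an ICC estimate
#'
#' poor below 0.5, moderate 0.5-0.75, good 0.75-0.9, excellent above 0.9.
#'
#' @param icc Numeric vector of ICC values.
#' @return Character vector of bands.
#' @export
icc_band <- function(icc) {
  dplyr::case_when(
    is.na(icc) ~ NA_character_,
    icc < 0.5 ~ "poor",
    icc <= 0.75 ~ "moderate",
    icc <= 0.9 ~ "good",
    TRUE ~ "excellent"
  )
}

# per participant x site x target: one HRT per trial, OK bouts only
hrt_by_trial <- function(bouts) {
  bouts |>
    dplyr::filter(.data$status == "OK", is.finite(.data$hrt_s)) |>
    dplyr::select("participant_id", "trial", "site", "target_pct", "hrt_s")
}

#' Descriptive reoxygenation summary (between-participant variability)
#'
#' Per site x target workload: participants with any usable bout, the
#' median and quartiles of per-participant HRT (trials averaged within
#' participant first; quartiles by linear interpolation of order
#' statistics, R type 7), and the between-participant CV.
#'
#' @param bouts Output of [extract_bouts()].
#' @return A tibble, one row per site x target.
#' @export
reox_descriptives <- function(bouts) {
  hrt_by_trial(bouts) |>
    dplyr::group_by(.data$participant_id, .data$site, .data$target_pct) |>
    dplyr::summarise(hrt_s = mean(.data$hrt_s), .groups = "drop") |>
    dplyr::group_by(.data$site, .data$target_pct) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_s = stats::median(.data$hrt_s),
      q1_s = stats::quantile(.data$hrt_s, 0.25, type = 7, names = FALSE),
      q3_s = stats::quantile(.data$hrt_s, 0.75, type = 7, names = FALSE),
      cv_between_pct = between_cv(.data$hrt_s),
      .groups = "drop")
}

#' Test-retest reliability summary
#'
#' Per site x target workload, over participants with both trials usable:
#' ICC(2,1) with its confidence interval and interpretation band, SEM with
#' its interval, MDC, and the within-participant CV.
#'
#' @param bouts Output of [extract_bouts()] for a two-trial study.
#' @param conf_level Confidence level.
#' @param mdc_multiplier Normal quantile in the MDC.
#' @return A tibble, one row per site x target.
#' @export
reliability_summary <- function(bouts, conf_level = 0.95,
                                mdc_multiplier = 1.96) {
  wide <- hrt_by_trial(bouts) |>
    tidyr::pivot_wider(names_from = "trial", values_from = "hrt_s",
                       names_prefix = "trial_")
  trial_cols <- grep("^trial_", names(wide), value = TRUE)
  wide |>
    dplyr::group_by(.data$site, .data$target_pct) |>
    dplyr::group_modify(function(d, key) {
      mat <- as.matrix(d[, trial_cols])
      ic <- icc_2_1(mat, conf_level)
      sm <- sem_mdc(mat, conf_level, mdc_multiplier)
      tibble::tibble(
        n = ic$n, icc = ic$icc, icc_ci_low = ic$ci_low,
        icc_ci_high = ic$ci_high, icc_band = icc_band(ic$icc),
        sem_s = sm$sem, sem_ci_low = sm$sem_ci_low,
        sem_ci_high = sm$sem_ci_high, mdc_s = sm$mdc,
        cv_within_pct = within_cv(mat))
    }) |>
    dplyr::ungroup()
}

#' Full reliability battery reports
#'
#' Convenience wrapper producing both report shapes from a bout table, and
#' optionally writing them to CSV.
#'
#' @param bouts Output of [extract_bouts()].
#' @param dir Optional directory to write `descriptives.csv` and
#'   `reliability.csv` into.
#' @inheritParams reliability_summary
#' @return List with `descriptives` and `reliability` tibbles.
#' @export
build_reports <- function(bouts, dir = NULL, conf_level = 0.95,
                          mdc_multiplier = 1.96) {
  desc <- reox_descriptives(bouts)
  rel <- reliability_summary(bouts, conf_level, mdc_multiplier)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(desc, file.path(dir, "descriptives.csv"))
    readr::write_csv(rel, file.path(dir, "reliability.csv"))
  }
  list(descriptives = desc, reliability = rel)
}
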