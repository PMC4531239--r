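#' Drop the block-initial run of go trials
#'
#' Before the first stop trial of a block the observer's beliefs rest on
#' little evidence, so the leading go trials of every block (about 3 on
#' average at a 25% stop rate, none at all a quarter of the time) are
#' excluded from analysis. The first stop trial and everything after it are
#' kept.
#'
#' @param records Trial records with `subject`, `block`, `trial`,
#'   `trial_type`.
#' @return The records minus each block's leading go trials.
#' @export
exclude_block_initial_go_runs <- function(records) {
  records |>
    group_by(.data$subject, .data$block) |>
    filter(cumsum(.data$trial_type == "stop") > 0) |>
    ungroup()
}

.check_chronological <- function(records) {
  bad <- records |>
    group_by(.data$subject) |>
    summarise(ok = all(diff(.data$trial) > 0), .groups = "drop")
  if (!all(bad$ok)) abort("records must be in chronological order within subject")
}

#' Attach model-derived predictors to a trial log
#'
#' Runs the DBM and the Kalman filter forward over each subject's
#' experienced go/stop sequence and SSDs, and attaches the *prior*
#' quantities for each trial: `pstop` (DBM predictive mean before the trial)
#' and `essd_s` (Kalman prior mean, seconds). No look-ahead: a trial's
#' predictors depend only on earlier trials. Must be applied to the full
#' chronological log, before any trial exclusion.
#'
#' @param records Trial records with `subject`, `trial`, `trial_type`,
#'   `ssd_ms` in chronological order per subject.
#' @param dbm A [dbm_params()] object.
#' @param kf A [kf_params()] object.
#' @return The records with `pstop` and `essd_s` columns (replaced if
#'   already present).
#' @export
attach_model_predictors <- function(records, dbm = dbm_params(),
                                    kf = kf_params()) {
  .check_chronological(records)
  records |>
    group_by(.data$subject) |>
    mutate(
      pstop = dbm_run(.data$trial_type == "stop", dbm)$pstop,
      essd_s = kf_run(ifelse(.data$trial_type == "stop",
                             .data$ssd_ms / 1000, NA_real_), kf)$essd_s
    ) |>
    ungroup()
}

# canonical pattern order: stop-trial frequency, then recency (most recent
# trial = last character)
.pattern_levels <- c("GGG", "SGG", "GSG", "GGS", "SSG", "SGS", "GSS", "SSS")

.add_patterns <- function(records) {
  records |>
    group_by(.data$subject) |>
    mutate(
      .t1 = lag(.data$trial_type, 1), .t2 = lag(.data$trial_type, 2),
      .t3 = lag(.data$trial_type, 3),
      .consec = .data$trial - lag(.data$trial, 3) == 3,
      pattern = ifelse(
        !is.na(.data$.consec) & .data$.consec,
        paste0(toupper(substr(.data$.t3, 1, 1)),
               toupper(substr(.data$.t2, 1, 1)),
               toupper(substr(.data$.t1, 1, 1))),
      NA_character_)
    ) |>
    ungroup() |>
    select(-".t1", -".t2", -".t3", -".consec")
}

#' Sequential-effect table over three-trial histories
#'
#' For every correct go trial immediately preceded by three consecutive
#' trials, records the stop/go pattern of those three trials (string of
#' G/S, most recent last) and averages the go RT — and the model P(stop)
#' when attached — within each of the 8 patterns, pooled over subjects.
#' Go RT and P(stop) both increase with the frequency and recency of stop
#' trials in the pattern.
#'
#' @param records Trial records (chronological; trials removed upstream
#'   break the consecutiveness requirement and are skipped automatically).
#' @return A `sst_pattern_table` tibble: `pattern`, `n`, `mean_rt`, `se_rt`
#'   and, if predictors are attached, `mean_pstop`, `se_pstop`.
#' @export
pattern_rts <- function(records) {
  .check_chronological(records)
  dat <- .add_patterns(records) |>
    filter(!is.na(.data$pattern), .data$outcome == "go_correct",
           !is.na(.data$rt_ms))
  out <- dat |>
    group_by(pattern = factor(.data$pattern, levels = .pattern_levels)) |>
    summarise(
      n = n(),
      mean_rt = mean(.data$rt_ms),
      se_rt = sd(.data$rt_ms) / sqrt(n()),
      .groups = "drop"
    )
  if ("pstop" %in% names(dat)) {
    ps <- dat |>
      group_by(pattern = factor(.data$pattern, levels = .pattern_levels)) |>
      summarise(mean_pstop = mean(.data$pstop),
                se_pstop = sd(.data$pstop) / sqrt(n()), .groups = "drop")
    out <- dplyr::left_join(out, ps, by = "pattern")
  }
  class(out) <- c("sst_pattern_table", class(out))
  out
}

#' @export
autoplot.sst_pattern_table <- function(object, value = c("rt", "pstop"), ...) {
  value <- match.arg(value)
  if (value == "rt") {
    ggplot(object, aes(x = .data$pattern, y = .data$mean_rt)) +
      geom_col(fill = "grey60") +
      geom_errorbar(aes(ymin = .data$mean_rt - .data$se_rt,
                        ymax = .data$mean_rt + .data$se_rt), width = 0.2) +
      labs(x = "three-trial history (most recent last)", y = "mean go RT (ms)") +
      theme_minimal()
  } else {
    ggplot(object, aes(x = .data$pattern, y = .data$mean_pstop)) +
      geom_col(fill = "grey60") +
      labs(x = "three-trial history (most recent last)", y = "mean P(stop)") +
      theme_minimal()
  }
}

#' Experienced-SSD predictor from the last two stop trials
#'
#' The model-free analogue of the Kalman predictor: for eligible go trials,
#' the mean SSD (ms) of the two most recently experienced stop trials. A go
#' trial is eligible only if it directly follows a stop trial, its response
#' was correct, and the two previous stop trials are separated by no more
#' than three go trials; all other trials are masked (NA).
#'
#' @param records Chronological trial records.
#' @return The records with columns `recent_ssd_ms` and `ssd_eligible`.
#' @export
recent_ssd_predictor <- function(records) {
  .check_chronological(records)
  records |>
    group_by(.data$subject) |>
    mutate(.out = {
      n <- n()
      val <- rep(NA_real_, n)
      last_stop <- -1L; prev_stop <- -1L        # row indices of last two stops
      last_ssd <- NA_real_; prev_ssd <- NA_real_
      tt <- .data$trial_type; oc <- .data$outcome
      tr <- .data$trial; ssd <- .data$ssd_ms
      for (i in seq_len(n)) {
        if (tt[i] == "go" && oc[i] == "go_correct" &&
            last_stop > 0 && prev_stop > 0 &&
            i > 1 && tr[i] - tr[i - 1] == 1 && i - 1 == last_stop) {
          gap <- tr[last_stop] - tr[prev_stop] - 1  # go trials between the stops
          if (gap <= 3) val[i] <- (last_ssd + prev_ssd) / 2
        }
        if (tt[i] == "stop") {
          prev_stop <- last_stop; prev_ssd <- last_ssd
          last_stop <- i; last_ssd <- ssd[i]
        }
      }
      val
    }) |>
    ungroup() |>
    mutate(recent_ssd_ms = .data$.out, ssd_eligible = !is.na(.data$.out)) |>
    select(-".out")
}

#' Equal-count binned linear regression
#'
#' Splits the predictor into `n_bins` equal-count bins (populations differ
#' by at most one trial), averages predictor and response within each bin,
#' and fits ordinary least squares to the bin means. This is the group-level
#' RT analysis: go RT against model P(stop) or expected SSD.
#'
#' @param data A data frame (rows with NA in either column are dropped).
#' @param predictor,response Column names (strings).
#' @param n_bins Number of equal-count bins (default 10).
#' @return An object of class `sst_binned_fit`; see [tidy.sst_binned_fit()].
#' @examples
#' d <- tibble::tibble(x = runif(200), y = 300 + 100 * runif(200))
#' binned_linear_regression(d, "x", "y", n_bins = 5)
#' @export
binned_linear_regression <- function(data, predictor, response = "rt_ms",
                                     n_bins = 10) {
  x <- data[[predictor]]; y <- data[[response]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 * n_bins) abort("need at least 2 data points per bin")
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  bin <- integer(n)
  bin[order(x)] <- rep(seq_len(n_bins), times = sizes)
  bins <- tibble(bin = bin, x = x, y = y) |>
    group_by(.data$bin) |>
    summarise(
      n = n(),
      mean_predictor = mean(.data$x), se_predictor = sd(.data$x) / sqrt(n()),
      mean_response = mean(.data$y), se_response = sd(.data$y) / sqrt(n()),
      .groups = "drop"
    )
  fit <- lm(mean_response ~ mean_predictor, data = bins)
  structure(
    list(bins = bins, fit = fit, n_bins = n_bins, n = n,
         predictor = predictor, response = response),
    class = "sst_binned_fit"
  )
}

#' @export
print.sst_binned_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Binned regression of %s on %s (%d bins, %d trials)\n",
              x$response, x$predictor, x$n_bins, x$n))
  cat(sprintf("  slope = %.4g, intercept = %.4g, R^2 = %.3f, p = %.3g\n",
              g$slope, g$intercept, g$r_squared, g$p_value))
  invisible(x)
}

#' Tidiers for binned regression fits
#'
#' `tidy()` returns the per-bin table (bin means and standard errors);
#' `glance()` the one-row fit summary (slope, intercept, R-squared and the
#' F-test p-value of the fit on the bin means).
#'
#' @param x An `sst_binned_fit`.
#' @param ... Unused.
#' @export
tidy.sst_binned_fit <- function(x, ...) x$bins

#' @rdname tidy.sst_binned_fit
#' @export
glance.sst_binned_fit <- function(x, ...) {
  s <- summary(x$fit)
  p <- if (is.null(s$fstatistic)) NA_real_ else
    unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
              lower.tail = FALSE))
  tibble(
    slope = unname(coef(x$fit)[2]), intercept = unname(coef(x$fit)[1]),
    r_squared = s$r.squared, p_value = p, n_bins = x$n_bins, n = x$n
  )
}

#' @export
autoplot.sst_binned_fit <- function(object, ...) {
  b <- object$bins
  ggplot(b, aes(x = .data$mean_predictor, y = .data$mean_response)) +
    geom_errorbar(aes(ymin = .data$mean_response - .data$se_response,
                      ymax = .data$mean_response + .data$se_response),
                  width = 0) +
    geom_point() +
    ggplot2::geom_abline(slope = coef(object$fit)[2],
                         intercept = coef(object$fit)[1]) +
    labs(x = object$predictor, y = object$response) +
    theme_minimal()
}

#' Partition binned RT variance between the two predictors
#'
#' Discretizes P(stop) and expected SSD into equal-count bins (5 per axis
#' by default), averages RT within each nonempty cell of the grid, and fits
#' two least-squares models to the cell means: P(stop) alone and
#' P(stop) + E\[SSD\]. Reports both R-squared values and their ratio, the
#' share of the combined model's explained variance attributable to
#' P(stop). Nesting guarantees the ratio is at most 1.
#'
#' @param records Trial records with predictors attached; only correct go
#'   trials with an RT enter.
#' @param n_bins_per_axis Bins per predictor (default 5).
#' @return An object of class `sst_var_partition`.
#' @export
variance_partition <- function(records, n_bins_per_axis = 5) {
  dat <- records |>
    filter(.data$outcome == "go_correct", !is.na(.data$rt_ms),
           !is.na(.data$pstop), !is.na(.data$essd_s))
  if (nrow(dat) < 2 * n_bins_per_axis^2) abort("too few analyzable trials")
  eq_bin <- function(x, nb) {
    b <- integer(length(x))
    sizes <- rep(length(x) %/% nb, nb) + (seq_len(nb) <= length(x) %% nb)
    b[order(x)] <- rep(seq_len(nb), times = sizes)
    b
  }
  cells <- dat |>
    mutate(.bp = eq_bin(.data$pstop, n_bins_per_axis),
           .be = eq_bin(.data$essd_s, n_bins_per_axis)) |>
    group_by(.data$.bp, .data$.be) |>
    summarise(n = n(), pstop = mean(.data$pstop), essd_s = mean(.data$essd_s),
              rt = mean(.data$rt_ms), .groups = "drop")
  f1 <- lm(rt ~ pstop, data = cells)
  f2 <- lm(rt ~ pstop + essd_s, data = cells)
  r1 <- summary(f1)$r.squared
  r2 <- summary(f2)$r.squared
  structure(
    list(cells = cells, fit_pstop = f1, fit_combined = f2,
         r2_pstop = r1, r2_combined = r2, fraction = r1 / r2,
         n_bins_per_axis = n_bins_per_axis, n = nrow(dat)),
    class = "sst_var_partition"
  )
}

#' @export
print.sst_var_partition <- function(x, ...) {
  cat(sprintf("Binned RT variance: P(stop) alone R^2 = %.3f; combined R^2 = %.3f\n",
              x$r2_pstop, x$r2_combined))
  cat(sprintf("  P(stop) share of explained variance: %.1f%% (%d cells, %d trials)\n",
              100 * x$fraction, nrow(x$cells), x$n))
  invisible(x)
}

#' @export
tidy.sst_var_partition <- function(x, ...) x$cells

#' @export
glance.sst_var_partition <- function(x, ...) {
  tibble(r2_pstop = x$r2_pstop, r2_combined = x$r2_combined,
         fraction = x$fraction, n_cells = nrow(x$cells), n = x$n,
         n_bins_per_axis = x$n_bins_per_axis)
}

#' Correlation between the two model predictors
#'
#' Product-moment correlation between the per-trial P(stop) and expected
#' SSD series, per subject, over correct go trials; because SSDs are drawn
#' independently of the stop/go sequence, the cohort mean is near zero and
#' the predictors can be treated as independent. Constant series yield NA.
#'
#' @param records Trial records with predictors attached.
#' @return A tibble with one row per subject (`subject`, `correlation`,
#'   `n`) carrying the cohort `mean` and `sd` as attributes, also printed.
#' @export
predictor_correlation <- function(records) {
  out <- records |>
    filter(.data$outcome == "go_correct", !is.na(.data$pstop),
           !is.na(.data$essd_s)) |>
    group_by(.data$subject) |>
    summarise(
      correlation = if (sd(.data$pstop) == 0 || sd(.data$essd_s) == 0)
        NA_real_ else cor(.data$pstop, .data$essd_s),
      n = n(), .groups = "drop"
    )
  structure(out, cohort_mean = mean(out$correlation, na.rm = TRUE),
            cohort_sd = sd(out$correlation, na.rm = TRUE),
            class = c("sst_pred_cor", class(out)))
}

#' @export
print.sst_pred_cor <- function(x, ...) {
  NextMethod()
  cat(sprintf("cohort mean correlation %.3f (sd %.3f)\n",
              attr(x, "cohort_mean"), attr(x, "cohort_sd")))
  invisible(x)
}
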