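# shared fit objective: OLS R^2 of RT on one predictor, per trial or binned
.rt_fit <- function(rec, predictor, n_bins) {
  if (is.null(n_bins)) {
    f <- lm(rec$rt_ms ~ rec[[predictor]])
    tibble(r_squared = summary(f)$r.squared, slope = unname(coef(f)[2]))
  } else {
    glance(binned_linear_regression(rec, predictor, "rt_ms", n_bins))
  }
}

#' Grid search for the DBM persistence parameter
#'
#' For each candidate `alpha`, recomputes the P(stop) predictor over the
#' full trial log (Beta prior shape held fixed), applies the block-initial
#' exclusion, and measures the R-squared of go RT against P(stop). Returns
#' the full profile and the maximizing `alpha`; no early stopping.
#'
#' By default the R-squared is computed over individual trials (equivalently,
#' equal-count bins of size one). Coarse equal-count binning is available via
#' `n_bins` for comparability with the group-level displays, but makes a poor
#' fitting objective: with wide bins the bin means are almost noise-free for
#' any smooth candidate predictor, so the binned R-squared saturates and
#' drifts toward the smoothest (largest-`alpha`) candidate rather than the
#' generating one.
#'
#' @param records Full chronological trial log (predictors recomputed
#'   internally).
#' @param alpha_grid Candidate persistence values in (0, 1).
#' @param dbm Template [dbm_params()] supplying the fixed `a`, `b`,
#'   `n_grid`.
#' @param n_bins Equal-count bins for the RT regression; NULL (default)
#'   fits on individual trials.
#' @return An object of class `sst_alpha_fit` with the profile tibble and
#'   `best_alpha`.
#' @export
fit_dbm_alpha <- function(records, alpha_grid = seq(0.55, 0.95, by = 0.05),
                          dbm = dbm_params(), n_bins = NULL) {
  stopifnot(all(alpha_grid > 0), all(alpha_grid < 1))
  profile <- purrr::map_dfr(alpha_grid, function(a) {
    pars <- dbm_params(alpha = a, a = dbm$a, b = dbm$b, n_grid = dbm$n_grid)
    rec <- records |>
      group_by(.data$subject) |>
      mutate(pstop = dbm_run(.data$trial_type == "stop", pars)$pstop) |>
      ungroup() |>
      exclude_block_initial_go_runs() |>
      filter(.data$outcome == "go_correct", !is.na(.data$rt_ms))
    g <- .rt_fit(rec, "pstop", n_bins)
    tibble(alpha = a, r_squared = g$r_squared, slope = g$slope)
  })
  structure(
    list(profile = profile,
         best_alpha = profile$alpha[which.max(profile$r_squared)],
         n_bins = n_bins),
    class = "sst_alpha_fit"
  )
}

#' @export
print.sst_alpha_fit <- function(x, ...) {
  cat(sprintf("DBM persistence fit: best alpha = %.3g (max R^2 = %.3f over %d grid points)\n",
              x$best_alpha, max(x$profile$r_squared), nrow(x$profile)))
  invisible(x)
}

#' @export
tidy.sst_alpha_fit <- function(x, ...) x$profile

#' @export
glance.sst_alpha_fit <- function(x, ...) {
  tibble(best_alpha = x$best_alpha,
         best_r_squared = max(x$profile$r_squared),
         n_grid = nrow(x$profile),
         n_bins = if (is.null(x$n_bins)) NA_integer_ else x$n_bins)
}

#' @export
autoplot.sst_alpha_fit <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$alpha, y = .data$r_squared)) +
    geom_line() + geom_point() +
    labs(x = "alpha", y = expression(R^2)) +
    theme_minimal()
}

#' Grid search for the Kalman noise parameters
#'
#' For each `(Q, R)` pair, recomputes the expected-SSD predictor over the
#' full trial log (`h0`, `P0` held fixed) and measures the R-squared of go
#' RT against it (per trial by default; see [fit_dbm_alpha()] for why coarse
#' binning is a poor fitting objective). The fit depends mainly on the ratio
#' `R/Q` (the steady-state gain), so `best_ratio` is the quantity to
#' interpret.
#'
#' @param records Full chronological trial log.
#' @param Q_grid,R_grid Positive candidate variances (s^2).
#' @param kf Template [kf_params()] supplying the fixed `h0`, `P0`.
#' @param n_bins Equal-count bins for the RT regression; NULL (default)
#'   fits on individual trials.
#' @return An object of class `sst_kf_fit` with the R-squared surface and
#'   the maximizing `Q`, `R` and their ratio.
#' @export
fit_kf_params <- function(records,
                          Q_grid = c(0.01, 0.02, 0.03, 0.05, 0.1),
                          R_grid = c(0.05, 0.1, 0.15, 0.25, 0.5),
                          kf = kf_params(), n_bins = NULL) {
  stopifnot(all(Q_grid > 0), all(R_grid > 0))
  surface <- tidyr::expand_grid(Q = Q_grid, R = R_grid) |>
    mutate(r_squared = purrr::map2_dbl(.data$Q, .data$R, function(qq, rr) {
      pars <- kf_params(Q = qq, R = rr, h0 = kf$h0, P0 = kf$P0)
      rec <- records |>
        group_by(.data$subject) |>
        mutate(essd_s = kf_run(ifelse(.data$trial_type == "stop",
                                      .data$ssd_ms / 1000, NA_real_),
                               pars)$essd_s) |>
        ungroup() |>
        exclude_block_initial_go_runs() |>
        filter(.data$outcome == "go_correct", !is.na(.data$rt_ms))
      .rt_fit(rec, "essd_s", n_bins)$r_squared
    }))
  best <- surface[which.max(surface$r_squared), ]
  structure(
    list(surface = surface, best_Q = best$Q, best_R = best$R,
         best_ratio = best$R / best$Q, n_bins = n_bins),
    class = "sst_kf_fit"
  )
}

#' @export
print.sst_kf_fit <- function(x, ...) {
  cat(sprintf("Kalman noise fit: best Q = %.3g, R = %.3g (R/Q = %.3g), max R^2 = %.3f\n",
              x$best_Q, x$best_R, x$best_ratio, max(x$surface$r_squared)))
  invisible(x)
}

#' @export
tidy.sst_kf_fit <- function(x, ...) x$surface

#' @export
glance.sst_kf_fit <- function(x, ...) {
  tibble(best_Q = x$best_Q, best_R = x$best_R, best_ratio = x$best_ratio,
         best_r_squared = max(x$surface$r_squared),
         n_bins = if (is.null(x$n_bins)) NA_integer_ else x$n_bins)
}

#' @export
autoplot.sst_kf_fit <- function(object, ...) {
  ggplot(object$surface,
         aes(x = factor(.data$Q), y = factor(.data$R),
             fill = .data$r_squared)) +
    geom_raster() +
    labs(x = "Q (s²)", y = "R (s²)", fill = expression(R^2)) +
    theme_minimal()
}
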