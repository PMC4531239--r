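#' Predicted go RT across prior beliefs
#'
#' The model's core behavioral prediction: mean go RT increases roughly
#' linearly with both the prior stop-trial probability and the expected
#' stop-signal delay. `rt_sweep()` simulates a batch of go trials for each
#' `(P(stop), E[SSD])` condition (computing or reusing the condition's
#' policy) and returns the condition means.
#'
#' @param r_values P(stop) priors to sweep.
#' @param essd_values E\[SSD\] priors to sweep, in time steps.
#' @param n_trials Go trials per condition (default 2000).
#' @param cache A [policy_cache()]; its lattice must cover the swept values.
#' @param expand If TRUE (default) the full grid of conditions is run,
#'   otherwise `r_values` and `essd_values` are paired.
#' @return A `sst_rt_sweep` tibble: `r`, `essd_steps`, `n_go`, `mean_rt_ms`,
#'   `sem_rt_ms`, `mean_tau`, `omission_rate`, `discrim_error_rate`.
#' @export
rt_sweep <- function(r_values, essd_values, n_trials = 2000,
                     cache = policy_cache(), expand = TRUE) {
  conds <- if (expand) {
    tidyr::expand_grid(r = r_values, essd_steps = essd_values)
  } else {
    tibble(r = r_values, essd_steps = essd_values)
  }
  out <- purrr::pmap_dfr(conds, function(r, essd_steps) {
    pol <- cache_get(cache, r, 1 / essd_steps)
    tr <- simulate_trials(pol, d = rbinom(n_trials, 1, 0.5), s = FALSE)
    go <- tr |> filter(.data$responded)
    tibble(
      r = r, essd_steps = essd_steps, n_go = nrow(go),
      mean_rt_ms = mean(go$rt_ms), sem_rt_ms = sd(go$rt_ms) / sqrt(nrow(go)),
      mean_tau = mean(go$tau),
      omission_rate = mean(!tr$responded),
      discrim_error_rate = mean(tr$outcome == "discrim_error")
    )
  })
  class(out) <- c("sst_rt_sweep", class(out))
  out
}

#' @export
autoplot.sst_rt_sweep <- function(object, x = c("r", "essd_steps"), ...) {
  x <- match.arg(x)
  xlab <- if (x == "r") "P(stop)" else "E[SSD] (steps)"
  ggplot(object, aes(x = .data[[x]], y = .data$mean_rt_ms)) +
    geom_errorbar(aes(ymin = .data$mean_rt_ms - .data$sem_rt_ms,
                      ymax = .data$mean_rt_ms + .data$sem_rt_ms), width = 0) +
    geom_point() + geom_line() +
    labs(x = xlab, y = "mean go RT (ms)") +
    theme_minimal()
}

#' Inhibition function and stop-error RTs
#'
#' Simulates stop trials at each true SSD under one policy and reports the
#' classical stop-signal effects: the stop-error fraction rises with SSD
#' (the inhibition function) and stop-error responses are faster than
#' correct go responses (an error implies the race was won before the
#' signal could be fully registered).
#'
#' @param policy An `sst_policy` in `"pair"` mode.
#' @param ssd_ms True SSD values in ms (default 100..600 by 100).
#' @param n_per_ssd Stop trials simulated per SSD (default 2000).
#' @return A tibble: `ssd_ms`, `n`, `stop_error_rate`, `mean_se_rt_ms`.
#' @export
inhibition_function <- function(policy, ssd_ms = seq(100, 600, by = 100),
                                n_per_ssd = 2000) {
  step_ms <- policy$gen$step_ms
  purrr::map_dfr(ssd_ms, function(ssd) {
    theta <- max(1, round(ssd / step_ms))
    tr <- simulate_trials(policy, d = rbinom(n_per_ssd, 1, 0.5), s = TRUE,
                          theta = theta)
    tibble(
      ssd_ms = ssd, n = n_per_ssd,
      stop_error_rate = mean(tr$outcome == "stop_error"),
      mean_se_rt_ms = mean(tr$rt_ms[tr$outcome == "stop_error"])
    )
  })
}
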