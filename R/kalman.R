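#' Kalman filter parameters for expected stop-signal delay
#'
#' A scalar Kalman filter tracks the (hidden) mean stop-signal delay in
#' seconds. The hidden mean diffuses between trials with variance `Q`;
#' observed SSDs are the mean corrupted by Gaussian noise of variance `R`.
#' Defaults follow a diffusion s.d. of `sqrt(0.03) ~ 0.17 s` and an
#' observation noise s.d. of `sqrt(0.15) ~ 0.39 s`, with initial belief
#' `N(0.35, 1)`.
#'
#' @param Q Diffusion variance per trial, s^2 (> 0).
#' @param R Observation variance, s^2 (> 0).
#' @param h0 Initial mean, s.
#' @param P0 Initial variance, s^2 (> 0).
#' @return An object of class `sst_kf_params`.
#' @export
kf_params <- function(Q = 0.03, R = 0.15, h0 = 0.35, P0 = 1) {
  stopifnot(Q > 0, R > 0, P0 > 0, is.numeric(h0), length(h0) == 1)
  structure(list(Q = Q, R = R, h0 = h0, P0 = P0), class = "sst_kf_params")
}

#' @export
print.sst_kf_params <- function(x, ...) {
  cat(sprintf("SSD Kalman filter: Q = %.3g, R = %.3g s^2; initial N(%.3g, %.3g)\n",
              x$Q, x$R, x$h0, x$P0))
  invisible(x)
}

#' Kalman filter state
#'
#' Gaussian prior/posterior over the mean SSD in seconds. `kf_init()` sets
#' the posterior to the initial belief `N(h0, P0)` at trial index 0.
#'
#' @param params A [kf_params()] object.
#' @return An object of class `sst_kf_state` with fields `k`, `h_prior`,
#'   `P_prior`, `h_post`, `P_post`, `K`.
#' @export
kf_init <- function(params) {
  structure(list(k = 0L, h_prior = NA_real_, P_prior = NA_real_,
                 h_post = params$h0, P_post = params$P0, K = NA_real_),
            class = "sst_kf_state")
}

#' @export
print.sst_kf_state <- function(x, ...) {
  cat(sprintf("KF state at trial %d: prior N(%.4g, %.4g), posterior N(%.4g, %.4g), K = %.4g\n",
              x$k, x$h_prior, x$P_prior, x$h_post, x$P_post, x$K))
  invisible(x)
}

#' Kalman predict, update and per-trial step
#'
#' `kf_predict()` diffuses the previous posterior into the prior for the
#' next trial: mean unchanged, variance grown by `Q`. `kf_update()`
#' assimilates an observed SSD `z` (seconds) with gain
#' `K = P_prior / (P_prior + R)`, giving a posterior mean between the prior
#' mean and the observation. `kf_step()` performs one trial: predict always;
#' update only when an SSD was observed (stop trials). On go trials the
#' posterior equals the prior — the belief diffuses but is not corrected,
#' so the influence of past SSDs fades with intervening go trials.
#'
#' @param state An `sst_kf_state`.
#' @param z Observed SSD in seconds (for `kf_step()`, `NA` on go trials).
#' @param params A [kf_params()] object.
#' @return An updated `sst_kf_state`.
#' @examples
#' st <- kf_init(kf_params())
#' st <- kf_step(st, 0.3, kf_params())   # stop trial with SSD 300 ms
#' st <- kf_step(st, NA, kf_params())    # go trial: diffusion only
#' @export
kf_predict <- function(state, params) {
  state$h_prior <- state$h_post
  state$P_prior <- state$P_post + params$Q
  state$k <- state$k + 1L
  state$K <- NA_real_
  state
}

#' @rdname kf_predict
#' @export
kf_update <- function(state, z, params) {
  if (!is.finite(z)) abort("observed SSD must be finite")
  K <- state$P_prior / (state$P_prior + params$R)
  state$K <- K
  state$h_post <- state$h_prior + K * (z - state$h_prior)
  state$P_post <- (1 - K) * state$P_prior
  state
}

#' @rdname kf_predict
#' @export
kf_step <- function(state, z, params) {
  if (!is.na(z) && z < 0) abort("SSD observation must be nonnegative")
  state <- kf_predict(state, params)
  if (is.na(z)) {
    state$h_post <- state$h_prior
    state$P_post <- state$P_prior
  } else {
    state <- kf_update(state, z, params)
  }
  state
}

#' Run the Kalman filter over a session
#'
#' @param z Numeric vector of observed SSDs in seconds, `NA` on go trials.
#' @param params A [kf_params()] object.
#' @return A tibble with one row per trial: `k`, `z`, prior and posterior
#'   moments and the gain; `essd_s` is the prior mean, the expected SSD fed
#'   to the within-trial model for that trial.
#' @export
kf_run <- function(z, params = kf_params()) {
  n <- length(z)
  if (any(!is.na(z) & z < 0)) abort("SSD observation must be nonnegative")
  h_prior <- P_prior <- h_post <- P_post <- K <- numeric(n)
  h <- params$h0; P <- params$P0
  for (k in seq_len(n)) {
    P <- P + params$Q                       # predict: diffuse
    h_prior[k] <- h; P_prior[k] <- P
    if (is.na(z[k])) {
      K[k] <- NA_real_                      # go trial: posterior = prior
    } else {
      g <- P / (P + params$R)
      K[k] <- g
      h <- h + g * (z[k] - h)
      P <- (1 - g) * P
    }
    h_post[k] <- h; P_post[k] <- P
  }
  tibble(k = seq_len(n), z = z, essd_s = h_prior,
         h_prior = h_prior, P_prior = P_prior,
         h_post = h_post, P_post = P_post, K = K)
}

#' Convert an expected SSD to the within-trial onset hazard
#'
#' The within-trial model's geometric onset has mean `1/q` steps; the prior
#' mean SSD (seconds) therefore maps to `q = 1 / (essd in steps)`, clipped
#' into `[1/D, 1]` so the generative parameters stay valid. A nonpositive
#' prior mean is an error (callers should clip upstream and log it).
#'
#' @param h_prior Prior mean SSD in seconds (> 0).
#' @param step_ms Step duration in ms.
#' @param D Deadline in steps (sets the lower clip `1/D`).
#' @return Hazard `q` per step.
#' @examples
#' essd_to_hazard(0.35, step_ms = 22, D = 50)  # ~ 0.0629
#' @export
essd_to_hazard <- function(h_prior, step_ms, D) {
  if (any(h_prior <= 0)) abort("prior mean SSD must be positive")
  steps <- h_prior * 1000 / step_ms
  pmin(1, pmax(1 / D, 1 / steps))
}
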