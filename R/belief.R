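#' Generative parameters for within-trial evidence
#'
#' Bundles the parameters of the within-trial generative model: two binary
#' evidence channels (one for the go-stimulus identity, one for the stop
#' signal), a geometric stop-signal onset time, and the prior probability
#' that the trial contains a stop signal.
#'
#' The go channel emits `x ~ Bernoulli(q_d)` when the true identity is
#' `d = 0` and `x ~ Bernoulli(1 - q_d)` when `d = 1`; the stop channel emits
#' `y ~ Bernoulli(q_s)` before the stop signal is on and
#' `y ~ Bernoulli(1 - q_s)` after. Channel informativeness is therefore
#' `|q_d - 0.5|` and `|q_s - 0.5|`. On a stop trial the signal onset step
#' `theta` is geometric with hazard `q`, so the expected stop-signal delay is
#' `1/q` steps.
#'
#' @param q_d Go-channel Bernoulli rate under `d = 0`, in (0, 1).
#' @param q_s Stop-channel Bernoulli rate before signal onset, in (0, 1).
#' @param q Per-step onset hazard, in (0, 1]; `1/q` is E\[SSD\] in steps.
#' @param r Prior probability that the trial is a stop trial, in \[0, 1\].
#' @param D Response deadline in time steps (integer, >= 2).
#' @param step_ms Duration of one time step in milliseconds. The default
#'   `1100 / D` makes the deadline in steps match an 1100 ms deadline.
#'
#' @return An object of class `sst_gen_params`.
#' @examples
#' gen_params(q_d = 0.55, q_s = 0.72, q = 0.1, r = 0.25, D = 50)
#' @export
gen_params <- function(q_d = 0.55, q_s = 0.72, q = 0.1, r = 0.25, D = 50L,
                       step_ms = 1100 / D) {
  stopifnot(
    is.numeric(q_d), length(q_d) == 1, q_d > 0, q_d < 1,
    is.numeric(q_s), length(q_s) == 1, q_s > 0, q_s < 1,
    is.numeric(q), length(q) == 1, q > 0, q <= 1,
    is.numeric(r), length(r) == 1, r >= 0, r <= 1,
    is.numeric(D), length(D) == 1, D >= 2, D == as.integer(D),
    is.numeric(step_ms), length(step_ms) == 1, step_ms > 0
  )
  structure(
    list(q_d = q_d, q_s = q_s, q = q, r = r, D = as.integer(D),
         step_ms = step_ms),
    class = "sst_gen_params"
  )
}

#' @export
print.sst_gen_params <- function(x, ...) {
  cat("Within-trial generative parameters\n")
  cat(sprintf("  q_d = %.3g, q_s = %.3g (channel rates)\n", x$q_d, x$q_s))
  cat(sprintf("  q = %.4g (E[SSD] = %.2f steps), r = P(stop) = %.3g\n",
              x$q, 1 / x$q, x$r))
  cat(sprintf("  D = %d steps of %.2f ms (deadline %.0f ms)\n",
              x$D, x$step_ms, x$D * x$step_ms))
  invisible(x)
}

#' Initial within-trial belief state
#'
#' The belief state is the posterior over the go-stimulus identity and the
#' stop-trial status. The stop-side posterior is carried as the exact
#' sufficient statistic, the triple `(w0, w1, w2)`: probability of a go
#' trial, of a stop trial whose signal has not yet started, and of a stop
#' trial whose signal is on. The scalar `p_s = w1 + w2` is the posterior
#' stop-trial probability; `p_d` is the posterior probability that the go
#' identity is `d = 1`. Tracking the triple (rather than `p_s` alone) is
#' required for exactness because the stop-channel likelihood differs before
#' and after signal onset.
#'
#' @param params An [gen_params()] object.
#' @return An object of class `sst_belief` with fields `t`, `p_d`, `w0`,
#'   `w1`, `w2`.
#' @examples
#' b <- init_belief(gen_params(r = 0.25))
#' p_stop_belief(b)   # 0.25
#' @export
init_belief <- function(params) {
  stopifnot(inherits(params, "sst_gen_params"))
  new_belief(0L, 0.5, 1 - params$r, params$r, 0)
}

new_belief <- function(t, p_d, w0, w1, w2) {
  structure(list(t = as.integer(t), p_d = p_d, w0 = w0, w1 = w1, w2 = w2),
            class = "sst_belief")
}

#' @rdname init_belief
#' @param b An `sst_belief` object.
#' @export
p_stop_belief <- function(b) b$w1 + b$w2

#' @export
print.sst_belief <- function(x, ...) {
  cat(sprintf("Belief state at t = %d: p_d = %.4f, p_s = %.4f (w = %.4f/%.4f/%.4f)\n",
              x$t, x$p_d, x$w1 + x$w2, x$w0, x$w1, x$w2))
  invisible(x)
}

#' One Bayes-filter step of the within-trial belief
#'
#' Advances the belief one time step given a pair of binary observations:
#' first the geometric onset transition moves mass `q * w1` from
#' "signal pending" to "signal on", then each component is reweighted by its
#' Bernoulli likelihood for `y` and the pair renormalized; the go posterior
#' `p_d` is updated independently from `x`.
#'
#' @param b An `sst_belief` state at time `t`.
#' @param x Binary go-channel observation (0 or 1).
#' @param y Binary stop-channel observation (0 or 1).
#' @param params A [gen_params()] object.
#' @return The belief state at `t + 1`.
#' @examples
#' p <- gen_params(q_d = 0.55, q_s = 0.72, q = 0.1, r = 0.25)
#' step_belief(init_belief(p), x = 1, y = 0, params = p)
#' @export
step_belief <- function(b, x, y, params) {
  stopifnot(inherits(b, "sst_belief"))
  if (!(length(x) == 1 && x %in% c(0, 1)) || !(length(y) == 1 && y %in% c(0, 1))) {
    abort("observations `x` and `y` must be 0 or 1")
  }
  q <- params$q; q_s <- params$q_s; q_d <- params$q_d

  # onset transition, then likelihood weighting of the stop triple
  w1 <- (1 - q) * b$w1
  w2 <- b$w2 + q * b$w1
  g0 <- if (y == 1) q_s else 1 - q_s       # pre-onset (and go-trial) channel
  g1 <- if (y == 1) 1 - q_s else q_s       # post-onset channel
  w0 <- b$w0 * g0
  w1 <- w1 * g0
  w2 <- w2 * g1
  z <- w0 + w1 + w2

  f0 <- if (x == 1) q_d else 1 - q_d
  f1 <- if (x == 1) 1 - q_d else q_d
  p_d <- b$p_d * f1 / (b$p_d * f1 + (1 - b$p_d) * f0)

  new_belief(b$t + 1L, p_d, w0 / z, w1 / z, w2 / z)
}

#' Predictive distribution of the next observation pair
#'
#' The one-step-ahead probability of each `(x, y)` outcome given the current
#' belief. The two channels are conditionally independent, so the table is
#' the outer product of the `x` and `y` marginals; the `y` marginal is taken
#' after the onset transition (the signal may switch on during the step).
#' Used to form the expectation over successor beliefs in the Bellman
#' backup of the stopping policy.
#'
#' @inheritParams step_belief
#' @return A tibble with columns `x`, `y`, `prob` (four rows summing to 1).
#' @export
predictive_obs_dist <- function(b, params) {
  stopifnot(inherits(b, "sst_belief"))
  q <- params$q; q_s <- params$q_s; q_d <- params$q_d
  w1p <- (1 - q) * b$w1
  w2p <- b$w2 + q * b$w1
  py1 <- (b$w0 + w1p) * q_s + w2p * (1 - q_s)
  px1 <- b$p_d * (1 - q_d) + (1 - b$p_d) * q_d
  tidyr::expand_grid(x = 0:1, y = 0:1) |>
    mutate(prob = ifelse(.data$x == 1, px1, 1 - px1) *
                  ifelse(.data$y == 1, py1, 1 - py1))
}

#' Geometric stop-signal onset distribution
#'
#' Probability that the stop signal switches on exactly at step `t` of a
#' stop trial, `q (1 - q)^(t - 1)`; the mean onset is `1/q` steps.
#'
#' @param q Per-step onset hazard in (0, 1].
#' @param t Step index (integer >= 1, vectorized).
#' @return Numeric vector of probabilities.
#' @examples
#' geometric_onset_pmf(0.5, 1:3)  # 0.5 0.25 0.125
#' @export
geometric_onset_pmf <- function(q, t) {
  stopifnot(q > 0, q <= 1)
  if (any(t < 1) || any(t != as.integer(t))) {
    abort("onset step `t` must be a positive integer")
  }
  q * (1 - q)^(t - 1)
}
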