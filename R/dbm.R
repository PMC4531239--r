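#' Dynamic belief model parameters
#'
#' The dynamic belief model (DBM) tracks the stop-trial rate `gamma` across
#' trials as a hidden Markov process: with probability `alpha` the rate
#' persists from the previous trial, with probability `1 - alpha` it is
#' redrawn from a fixed Beta(`a`, `b`) prior. The predictive mean of `gamma`
#' before each trial is the model's P(stop). `1 / (1 - alpha)` is the
#' assumed mean run length between environment changes (4 trials at the
#' default `alpha = 0.75`).
#'
#' @param alpha Persistence probability in \[0, 1\] (default 0.75).
#' @param a,b Shape parameters of the generic Beta prior (defaults 2.5 and
#'   7.5: prior mean 0.25, matching a session with 25% stop trials).
#' @param n_grid Number of rate bins on (0, 1) (midpoints; default 100).
#' @return An object of class `sst_dbm_params`.
#' @export
dbm_params <- function(alpha = 0.75, a = 2.5, b = 7.5, n_grid = 100L) {
  stopifnot(alpha >= 0, alpha <= 1, a > 0, b > 0, n_grid >= 10)
  m <- a / (a + b)
  stopifnot(m > 0, m < 1)
  grid <- (seq_len(n_grid) - 0.5) / n_grid
  p0 <- stats::dbeta(grid, a, b)
  p0 <- p0 / sum(p0)
  structure(list(alpha = alpha, a = a, b = b, n_grid = as.integer(n_grid),
                 grid = grid, p0 = p0),
            class = "sst_dbm_params")
}

#' @export
print.sst_dbm_params <- function(x, ...) {
  cat(sprintf("DBM: alpha = %.3g, p0 = Beta(%.3g, %.3g) on %d bins (prior mean %.3g)\n",
              x$alpha, x$a, x$b, x$n_grid, x$a / (x$a + x$b)))
  invisible(x)
}

.check_pmf <- function(p, params, what = "pmf") {
  if (length(p) != params$n_grid || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    abort(sprintf("`%s` must be a normalized pmf over the DBM grid", what))
  }
}

#' DBM predictive and posterior updates
#'
#' `dbm_predict()` maps the posterior over the stop-trial rate after trial
#' `k - 1` to the predictive distribution before trial `k`: the mixture
#' `alpha * posterior + (1 - alpha) * p0`. `dbm_observe()` conditions the
#' predictive distribution on the observed trial label `s_k` (1 = stop) via
#' the Bernoulli likelihood `gamma^s (1 - gamma)^(1 - s)`. `pstop()` is the
#' predictive mean: the probability that the upcoming trial is a stop trial,
#' which feeds the within-trial model as its prior `r`.
#'
#' @param posterior,predictive Normalized pmf over the rate grid.
#' @param s_k Observed trial label, 0 (go) or 1 (stop).
#' @param params A [dbm_params()] object.
#' @return `dbm_predict()` and `dbm_observe()` return a pmf;
#'   `pstop()` a scalar probability.
#' @examples
#' pars <- dbm_params()
#' pred <- dbm_predict(pars$p0, pars)
#' pstop(pred, pars)                     # 0.25 before any data
#' post <- dbm_observe(pred, 1, pars)    # saw a stop trial
#' pstop(dbm_predict(post, pars), pars)  # > 0.25
#' @export
dbm_predict <- function(posterior, params) {
  .check_pmf(posterior, params, "posterior")
  params$alpha * posterior + (1 - params$alpha) * params$p0
}

#' @rdname dbm_predict
#' @export
dbm_observe <- function(predictive, s_k, params) {
  .check_pmf(predictive, params, "predictive")
  if (!(length(s_k) == 1 && s_k %in% c(0, 1))) abort("`s_k` must be 0 or 1")
  lik <- if (s_k == 1) params$grid else 1 - params$grid
  post <- predictive * lik
  z <- sum(post)
  if (z <= 0) abort("internal: zero normalizer in DBM update")
  post / z
}

#' @rdname dbm_predict
#' @export
pstop <- function(predictive, params) {
  .check_pmf(predictive, params, "predictive")
  sum(params$grid * predictive)
}

#' Run the DBM over a trial sequence
#'
#' Applies predict/observe over a binary stop/go sequence and returns the
#' trial-by-trial predictive P(stop), i.e. the model's prior belief before
#' each trial is experienced (no look-ahead). The session starts from the
#' generic prior `p0`; by default block boundaries do not reset the model.
#'
#' @param s Integer/logical vector of trial labels (1 = stop).
#' @param params A [dbm_params()] object.
#' @param block Optional block index per trial; used only when
#'   `reset_blocks = TRUE`.
#' @param reset_blocks Reset the model to `p0` at each block start
#'   (default FALSE).
#' @return A tibble with columns `k`, `s`, `pstop` (predictive, before
#'   observing trial `k`) and `post_mean` (after).
#' @export
dbm_run <- function(s, params = dbm_params(), block = NULL,
                    reset_blocks = FALSE) {
  s <- as.integer(s)
  stopifnot(all(s %in% 0:1))
  n <- length(s)
  p_stop <- post_mean <- numeric(n)
  # carrying p0 into the first predict leaves it unchanged (the mixture of
  # p0 with itself), so the session-start predictive is the generic prior
  cur <- params$p0
  for (k in seq_len(n)) {
    if (reset_blocks && !is.null(block) && k > 1 && block[k] != block[k - 1]) {
      cur <- params$p0
    }
    pred <- dbm_predict(cur, params)
    p_stop[k] <- pstop(pred, params)
    cur <- dbm_observe(pred, s[k], params)
    post_mean[k] <- sum(params$grid * cur)
  }
  tibble(k = seq_len(n), s = s, pstop = p_stop, post_mean = post_mean)
}
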