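# Independent oracles, deliberately sharing no code with the package:
# posteriors by exhaustive enumeration over the latent variables, and policy
# values by recursion over the observation-history tree.

# Joint enumeration over (d, s, theta) for an observation history.
# Returns the exact posterior (p_d, w0, w1, w2) and the marginal likelihood.
enum_posterior <- function(xs, ys, gen) {
  t <- length(xs)
  stopifnot(length(ys) == t)
  f <- function(d, x) if (d == 1) ifelse(x == 1, 1 - gen$q_d, gen$q_d) else
    ifelse(x == 1, gen$q_d, 1 - gen$q_d)
  g <- function(z, y) if (z == 1) ifelse(y == 1, 1 - gen$q_s, gen$q_s) else
    ifelse(y == 1, gen$q_s, 1 - gen$q_s)
  lik_x <- c(prod(f(0, xs)), prod(f(1, xs)))          # by d
  # stop side: s=0; s=1 with onset theta in 1..t; s=1 with theta > t
  w <- c(`s0` = (1 - gen$r) * prod(g(0, ys)))
  w1_mass <- 0; w2_mass <- 0
  if (t > 0) {
    for (theta in seq_len(t)) {
      z <- as.integer(seq_len(t) >= theta)
      w2_mass <- w2_mass + gen$r * gen$q * (1 - gen$q)^(theta - 1) *
        prod(vapply(seq_len(t), function(i) g(z[i], ys[i]), 1.0))
    }
    w1_mass <- gen$r * (1 - gen$q)^t * prod(g(0, ys))
  } else {
    w1_mass <- gen$r
  }
  # x and y channels factorize; p_d uses the x side only
  px <- 0.5 * lik_x[1] + 0.5 * lik_x[2]
  py <- unname(w["s0"]) + w1_mass + w2_mass
  list(
    p_d = 0.5 * lik_x[2] / px,
    w0 = unname(w["s0"]) / py, w1 = w1_mass / py, w2 = w2_mass / py,
    marginal = px * py
  )
}

# Expected loss by recursion over the observation-history tree.
# `act` maps a history (list of xs, ys) to "go"/"wait"; NULL minimizes over
# actions, giving the optimum over all history-dependent policies.
oracle_tree_loss <- function(gen, cost, act = NULL) {
  D <- gen$D
  rec <- function(xs, ys) {
    t <- length(xs)
    post <- enum_posterior(xs, ys, gen)
    p_s <- post$w1 + post$w2
    go <- cost$c * t + cost$c_s * p_s +
      (1 - p_s) * min(post$p_d, 1 - post$p_d)
    wait <- if (t == D - 1) {
      cost$c * D + 1 - p_s
    } else {
      tot <- 0
      for (x in 0:1) for (y in 0:1) {
        child <- enum_posterior(c(xs, x), c(ys, y), gen)
        tot <- tot + (child$marginal / post$marginal) * rec(c(xs, x), c(ys, y))
      }
      tot
    }
    if (is.null(act)) min(go, wait)
    else if (identical(act(xs, ys), "go")) go else wait
  }
  tot <- 0
  root <- enum_posterior(integer(0), integer(0), gen)
  for (x in 0:1) for (y in 0:1) {
    child <- enum_posterior(x, y, gen)
    tot <- tot + (child$marginal / root$marginal) * rec(x, y)
  }
  tot
}

# conjugate Beta-Bernoulli predictive mean sequence (prior Beta(a, b)):
# P(stop) before trial k given the labels of trials 1..k-1
conjugate_pstop <- function(s, a, b) {
  k <- seq_along(s)
  (a + dplyr::lag(cumsum(s), default = 0)) / (a + b + k - 1)
}
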