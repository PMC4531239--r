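#' Cost parameters for the stopping policy
#'
#' Costs are normalized to the go-error cost: a discrimination or omission
#' error on a go trial costs 1, responding on a stop trial costs `c_s`, and
#' each time step of delay costs `c`.
#'
#' @param c Cost per time step of response delay (>= 0; 0 is the free-delay
#'   limit, where waiting is weakly optimal until the deadline).
#' @param c_s Stop-error penalty (> 0).
#' @return An object of class `sst_cost_params`.
#' @examples
#' cost_params(c = 0.002, c_s = 0.4)
#' @export
cost_params <- function(c = 0.002, c_s = 0.4) {
  stopifnot(is.numeric(c), length(c) == 1, c >= 0,
            is.numeric(c_s), length(c_s) == 1, c_s > 0)
  structure(list(c = c, c_s = c_s), class = "sst_cost_params")
}

#' @export
print.sst_cost_params <- function(x, ...) {
  cat(sprintf("Stopping costs: delay c = %.4g per step, stop error c_s = %.3g, go error = 1\n",
              x$c, x$c_s))
  invisible(x)
}

#' Bellman quantities of the stopping problem
#'
#' `terminal_value()` is the expected cost of reaching the deadline with
#' belief `b`: the accrued delay cost plus the probability that this was a
#' go trial (omission). `q_go()` is the expected cost of responding now:
#' accrued delay, the stop-error penalty weighted by `p_s`, and the
#' discrimination-error probability `min(p_d, 1 - p_d)` weighted by the
#' go-trial probability. `q_wait()` is the expected cost of waiting one more
#' step: the expectation of the next value function over the predictive
#' observation distribution, or, one step before the deadline, the terminal
#' expectation `c (t + 1) + 1 - p_s` (equal by the martingale property of
#' `p_s`).
#'
#' @param b An `sst_belief` state.
#' @param cost A [cost_params()] object.
#' @param D Deadline in steps.
#' @param t Current step (action taken at `t < D`).
#' @param next_values Matrix of values at `t + 1` over the `(p_d, p_s)` grid
#'   (bin midpoints, rows `p_d`); ignored when `t + 1 == D`.
#' @param gen A [gen_params()] object.
#' @return Expected cost (scalar).
#' @export
terminal_value <- function(b, cost, D) {
  cost$c * D + (1 - p_stop_belief(b))
}

#' @rdname terminal_value
#' @export
q_go <- function(b, t, cost) {
  p_s <- p_stop_belief(b)
  cost$c * t + cost$c_s * p_s + (1 - p_s) * min(b$p_d, 1 - b$p_d)
}

#' @rdname terminal_value
#' @export
q_wait <- function(b, t, next_values, gen, cost) {
  stopifnot(t < gen$D)
  if (t + 1 == gen$D) {
    return(cost$c * (t + 1) + 1 - p_stop_belief(b))
  }
  if (is.null(next_values)) abort("`next_values` required when t + 1 < D")
  n1 <- nrow(next_values); n2 <- ncol(next_values)
  pr <- predictive_obs_dist(b, gen)
  val <- purrr::pmap_dbl(pr, function(x, y, prob) {
    nb <- step_belief(b, x, y, gen)
    next_values[.bin(nb$p_d, n1), .bin(p_stop_belief(nb), n2)]
  })
  sum(pr$prob * val)
}

# containing-bin index on a midpoint grid over [0,1] (== nearest midpoint)
.bin <- function(p, n) pmin(n, pmax(1L, ceiling(p * n)))

#' Optimal Go/Wait stopping policy by backward induction
#'
#' Computes the optimal policy for the within-trial stopping problem on a
#' discretized belief grid, backwards from the deadline. In the default
#' `"pair"` mode the value function is indexed by `(p_d, p_s)` bin midpoints
#' (200 x 200 by default); for belief transitions, the stop-side posterior
#' `p_s` is split into pre-/post-onset components using the prior onset
#' dynamics, `P(signal on | stop trial, t) = 1 - (1 - q)^t`. The `"exact"`
#' mode discretizes the full `(p_d, w1, w2)` sufficient statistic and is
#' intended for small deadlines, where it can be checked against brute-force
#' policy enumeration.
#'
#' The optimal policy has two Go regions at extreme `p_d` and small `p_s`
#' and a central Wait region around `p_d = 0.5` and/or large `p_s`. Action
#' ties are resolved to Wait (Go only when strictly cheaper).
#'
#' @param gen A [gen_params()] object.
#' @param cost A [cost_params()] object.
#' @param grid Integer vector of two: bins for `p_d` and for `p_s` (in
#'   `"exact"` mode, for each of `w1` and `w2`).
#' @param mode `"pair"` (value over `(p_d, p_s)`, the default) or `"exact"`.
#' @param keep_values Keep the `V`, `Q_go`, `Q_wait` arrays (default TRUE);
#'   with FALSE only the action array is retained, which is enough to
#'   simulate trials and is what the policy cache stores.
#' @return An object of class `sst_policy`.
#' @examples
#' pol <- compute_policy(gen_params(D = 10), cost_params(), grid = c(40, 40))
#' @export
compute_policy <- function(gen, cost, grid = c(200L, 200L),
                           mode = c("pair", "exact"), keep_values = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(gen, "sst_gen_params"), inherits(cost, "sst_cost_params"),
            length(grid) == 2, all(grid >= 2))
  if (cost$c * gen$D >= 1 + cost$c_s) {
    warn("delay cost over the full deadline exceeds the worst error cost; the task degenerates to always-Go")
  }
  if (mode == "pair") {
    .policy_pair(gen, cost, as.integer(grid), keep_values)
  } else {
    .policy_exact(gen, cost, as.integer(grid), keep_values)
  }
}

.policy_pair <- function(gen, cost, grid, keep_values) {
  n1 <- grid[1]; n2 <- grid[2]
  D <- gen$D; cc <- cost$c; cs <- cost$c_s
  q <- gen$q; q_s <- gen$q_s; q_d <- gen$q_d
  pd <- (seq_len(n1) - 0.5) / n1
  ps <- (seq_len(n2) - 0.5) / n2

  action <- array(as.raw(0), dim = c(n1, n2, D - 1))
  if (keep_values) {
    V  <- array(NA_real_, dim = c(n1, n2, D))
    Qg <- array(NA_real_, dim = c(n1, n2, D - 1))
    Qw <- array(NA_real_, dim = c(n1, n2, D - 1))
  }

  # go-side transition pieces, time-invariant
  px1 <- pd * (1 - q_d) + (1 - pd) * q_d
  pd1 <- pd * (1 - q_d) / px1              # posterior after x = 1
  pd0 <- pd * q_d / (1 - px1)              # posterior after x = 0
  i1 <- .bin(pd1, n1); i0 <- .bin(pd0, n1)
  m_err <- pmin(pd, 1 - pd)

  v_next <- outer(rep(cc * D, n1), 1 - ps, `+`)   # terminal V^D
  if (keep_values) V[, , D] <- v_next

  for (t in seq(D - 1, 1)) {
    qg <- cc * t + outer(m_err, rep(1, n2)) * rep(1 - ps, each = n1) +
      rep(cs * ps, each = n1)
    if (t + 1 == D) {
      qw <- matrix(cc * (t + 1) + 1 - ps, n1, n2, byrow = TRUE)
    } else {
      # reconstruct the stop triple from p_s at time t via prior onset dynamics
      phi <- 1 - (1 - q)^t
      w1 <- ps * (1 - phi); w2 <- ps * phi; w0 <- 1 - ps
      w1p <- (1 - q) * w1; w2p <- w2 + q * w1
      py1 <- (w0 + w1p) * q_s + w2p * (1 - q_s)
      ps1 <- (w1p * q_s + w2p * (1 - q_s)) / py1        # posterior after y = 1
      ps0 <- (w1p * (1 - q_s) + w2p * q_s) / (1 - py1)  # posterior after y = 0
      j1 <- .bin(ps1, n2); j0 <- .bin(ps0, n2)
      qw <- outer(px1, py1) * v_next[i1, j1, drop = FALSE] +
        outer(px1, 1 - py1) * v_next[i1, j0, drop = FALSE] +
        outer(1 - px1, py1) * v_next[i0, j1, drop = FALSE] +
        outer(1 - px1, 1 - py1) * v_next[i0, j0, drop = FALSE]
    }
    v_next <- pmin(qg, qw)
    action[, , t] <- as.raw(qg < qw)
    if (keep_values) {
      V[, , t] <- v_next; Qg[, , t] <- qg; Qw[, , t] <- qw
    }
  }

  structure(
    list(mode = "pair", gen = gen, cost = cost, n_pd = n1, n_ps = n2,
         pd_mid = pd, ps_mid = ps, action = action,
         V = if (keep_values) V else NULL,
         Q_go = if (keep_values) Qg else NULL,
         Q_wait = if (keep_values) Qw else NULL),
    class = "sst_policy"
  )
}

.policy_exact <- function(gen, cost, grid, keep_values) {
  n1 <- grid[1]; n2 <- grid[2]
  D <- gen$D; cc <- cost$c; cs <- cost$c_s
  q <- gen$q; q_s <- gen$q_s; q_d <- gen$q_d
  pd <- (seq_len(n1) - 0.5) / n1
  w_mid <- (seq_len(n2) - 0.5) / n2

  # valid simplex cells: midpoint sum <= 1
  cell <- tidyr::expand_grid(j1 = seq_len(n2), j2 = seq_len(n2)) |>
    filter((.data$j1 - 0.5) + (.data$j2 - 0.5) <= n2)
  w1 <- w_mid[cell$j1]; w2 <- w_mid[cell$j2]
  w0 <- pmax(0, 1 - w1 - w2)
  nc <- nrow(cell)
  ps_cell <- w1 + w2

  # 3D value indexed [pd bin, cell]; action stored the same way
  action <- array(as.raw(0), dim = c(n1, nc, D - 1))
  if (keep_values) {
    V <- array(NA_real_, dim = c(n1, nc, D))
    Qg_a <- Qw_a <- array(NA_real_, dim = c(n1, nc, D - 1))
  }

  cell_index <- matrix(NA_integer_, n2, n2)
  cell_index[cbind(cell$j1, cell$j2)] <- seq_len(nc)

  px1 <- pd * (1 - q_d) + (1 - pd) * q_d
  i_x <- cbind(.bin(pd * q_d / (1 - px1), n1), .bin(pd * (1 - q_d) / px1, n1))
  m_err <- pmin(pd, 1 - pd)

  # stop-side transition per cell and y outcome (time-invariant given triple)
  w1p <- (1 - q) * w1; w2p <- w2 + q * w1
  py1 <- (w0 + w1p) * q_s + w2p * (1 - q_s)
  post <- lapply(0:1, function(y) {
    g0 <- if (y == 1) q_s else 1 - q_s
    g1 <- if (y == 1) 1 - q_s else q_s
    z <- w0 * g0 + w1p * g0 + w2p * g1
    cbind(w1p * g0 / z, w2p * g1 / z)
  })
  j_y <- lapply(post, function(m) {
    cell_index[cbind(.bin(m[, 1], n2), .bin(m[, 2], n2))]
  })
  if (anyNA(j_y[[1]]) || anyNA(j_y[[2]])) abort("internal: transition left the simplex grid")

  v_next <- outer(rep(cc * D, n1), 1 - ps_cell, `+`)
  if (keep_values) V[, , D] <- v_next

  # V^{D-1} is explicit (min of the Go cost and the terminal expectation),
  # so the backup at t = D-2 can evaluate successors exactly instead of
  # snapping them to grid cells; deeper layers use nearest-cell lookup.
  pd_x <- cbind(pd * q_d / (1 - px1), pd * (1 - q_d) / px1)
  ps_y <- lapply(post, rowSums)
  v_last <- function(pdv, psv) {
    pmin(cc * (D - 1) + outer(pmin(pdv, 1 - pdv), 1 - psv) +
           rep(cs * psv, each = length(pdv)),
         matrix(cc * D + 1 - psv, length(pdv), length(psv), byrow = TRUE))
  }

  for (t in seq(D - 1, 1)) {
    qg <- cc * t + outer(m_err, 1 - ps_cell) + rep(cs * ps_cell, each = n1)
    if (t + 1 == D) {
      qw <- matrix(cc * (t + 1) + 1 - ps_cell, n1, nc, byrow = TRUE)
    } else if (t + 2 == D) {
      qw <- outer(px1, py1) * v_last(pd_x[, 2], ps_y[[2]]) +
        outer(px1, 1 - py1) * v_last(pd_x[, 2], ps_y[[1]]) +
        outer(1 - px1, py1) * v_last(pd_x[, 1], ps_y[[2]]) +
        outer(1 - px1, 1 - py1) * v_last(pd_x[, 1], ps_y[[1]])
    } else {
      qw <- outer(px1, py1) * v_next[i_x[, 2], j_y[[2]], drop = FALSE] +
        outer(px1, 1 - py1) * v_next[i_x[, 2], j_y[[1]], drop = FALSE] +
        outer(1 - px1, py1) * v_next[i_x[, 1], j_y[[2]], drop = FALSE] +
        outer(1 - px1, 1 - py1) * v_next[i_x[, 1], j_y[[1]], drop = FALSE]
    }
    v_next <- pmin(qg, qw)
    action[, , t] <- as.raw(qg < qw)
    if (keep_values) {
      V[, , t] <- v_next; Qg_a[, , t] <- qg; Qw_a[, , t] <- qw
    }
  }

  structure(
    list(mode = "exact", gen = gen, cost = cost, n_pd = n1, n_w = n2,
         pd_mid = pd, cell = cell, cell_index = cell_index,
         action = action, V = if (keep_values) V else NULL,
         Q_go = if (keep_values) Qg_a else NULL,
         Q_wait = if (keep_values) Qw_a else NULL),
    class = "sst_policy"
  )
}

#' @export
print.sst_policy <- function(x, ...) {
  cat(sprintf("Optimal stopping policy (%s mode), D = %d steps\n",
              x$mode, x$gen$D))
  if (x$mode == "pair") {
    cat(sprintf("  grid %d x %d over (p_d, p_s); r = %.3g, E[SSD] = %.2f steps\n",
                x$n_pd, x$n_ps, x$gen$r, 1 / x$gen$q))
    go1 <- mean(x$action[, , 1] == as.raw(1))
    cat(sprintf("  Go fraction of the grid at t = 1: %.1f%%\n", 100 * go1))
  } else {
    cat(sprintf("  grid %d (p_d) x %d simplex cells over (w1, w2)\n",
                x$n_pd, nrow(x$cell)))
  }
  invisible(x)
}

# action lookup for a belief state; returns TRUE for Go
.policy_go <- function(policy, b) {
  t <- b$t
  if (t >= policy$gen$D) return(FALSE)
  i <- .bin(b$p_d, policy$n_pd)
  if (policy$mode == "pair") {
    j <- .bin(p_stop_belief(b), policy$n_ps)
    policy$action[i, j, t] == as.raw(1)
  } else {
    j <- policy$cell_index[.bin(b$w1, policy$n_w), .bin(b$w2, policy$n_w)]
    policy$action[i, j, t] == as.raw(1)
  }
}

#' Tidy a stopping policy into a flat table
#'
#' One row per time step and belief bin, with the optimal action and (when
#' retained) the value and Q-factors. Only `"pair"`-mode policies tidy; the
#' exact-triple mode is a verification device.
#'
#' @param x An `sst_policy`.
#' @param t Time steps to include (default all of `1..D-1`).
#' @param ... Unused.
#' @return A tibble with columns `t`, `p_d`, `p_s`, `action`, and `V`,
#'   `Q_go`, `Q_wait` when available.
#' @export
tidy.sst_policy <- function(x, t = NULL, ...) {
  stopifnot(x$mode == "pair")
  tt <- if (is.null(t)) seq_len(x$gen$D - 1) else as.integer(t)
  out <- tidyr::expand_grid(t = tt, p_d = x$pd_mid, p_s = x$ps_mid) |>
    arrange(.data$t, .data$p_d, .data$p_s)
  idx <- cbind(
    rep(rep(seq_len(x$n_pd), each = x$n_ps), times = length(tt)),
    rep(seq_len(x$n_ps), times = x$n_pd * length(tt)),
    rep(tt, each = x$n_pd * x$n_ps)
  )
  out$action <- ifelse(x$action[idx] == as.raw(1), "go", "wait")
  if (!is.null(x$V)) {
    out$V <- x$V[idx]
    out$Q_go <- x$Q_go[idx]
    out$Q_wait <- x$Q_wait[idx]
  }
  out
}

#' @rdname tidy.sst_policy
#' @param object An `sst_policy`.
#' @export
glance.sst_policy <- function(x, ...) {
  tibble(
    mode = x$mode, D = x$gen$D,
    n_pd = x$n_pd,
    n_ps = if (x$mode == "pair") x$n_ps else nrow(x$cell),
    r = x$gen$r, essd_steps = 1 / x$gen$q,
    c = x$cost$c, c_s = x$cost$c_s,
    go_fraction_t1 = mean(x$action[, , 1] == as.raw(1))
  )
}

#' Plot the Go/Wait regions of a policy
#'
#' @param object An `sst_policy` (`"pair"` mode).
#' @param t Time steps to display.
#' @param ... Unused.
#' @return A ggplot showing action regions over the `(p_d, p_s)` grid.
#' @export
autoplot.sst_policy <- function(object, t = c(1L, object$gen$D %/% 2), ...) {
  tidy(object, t = t) |>
    ggplot(aes(x = .data$p_d, y = .data$p_s, fill = .data$action)) +
    geom_raster() +
    facet_wrap(~t, labeller = ggplot2::label_both) +
    scale_fill_manual(values = c(go = "#D55E00", wait = "#0072B2")) +
    labs(x = "P(d = 1)", y = "P(stop trial)", fill = "action") +
    theme_minimal()
}

#' Export / import a policy table as delimited text
#'
#' Writes the tidy flat form (t, p_d, p_s, action, V, Q_go, Q_wait) for
#' inspection or caching; `read_policy_table()` returns the flat tibble.
#'
#' @param policy An `sst_policy` in `"pair"` mode.
#' @param path File path (tab-separated text).
#' @param t Time steps to write (default all).
#' @return `write_policy_table()` returns `path` invisibly.
#' @export
write_policy_table <- function(policy, path, t = NULL) {
  readr::write_tsv(tidy(policy, t = t), path)
  invisible(path)
}

#' @rdname write_policy_table
#' @export
read_policy_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Exact expected loss of a policy
#'
#' Evaluates a stopping policy's expected loss by exhaustive recursion over
#' all observation histories, carrying the exact Bayes-filter belief along
#' each branch; latent variables are marginalized analytically at each leaf.
#' Feasible for small deadlines (the tree has `4^(D-1)` leaves). The policy
#' may be an [compute_policy()] object or a function `(belief) -> "go"/"wait"`.
#'
#' @param policy An `sst_policy` or a function of the belief state.
#' @param gen A [gen_params()] object.
#' @param cost A [cost_params()] object.
#' @return The expected loss (scalar).
#' @export
policy_expected_loss <- function(policy, gen, cost) {
  act <- if (is.function(policy)) {
    function(b) identical(policy(b), "go")
  } else {
    function(b) .policy_go(policy, b)
  }
  D <- gen$D
  eval_node <- function(b) {
    if (b$t <= D - 1 && act(b)) {
      return(q_go(b, b$t, cost))
    }
    if (b$t == D - 1) {
      return(cost$c * D + 1 - p_stop_belief(b))
    }
    pr <- predictive_obs_dist(b, gen)
    sum(pr$prob *
          purrr::pmap_dbl(pr, function(x, y, prob) eval_node(step_belief(b, x, y, gen))))
  }
  b0 <- init_belief(gen)
  pr <- predictive_obs_dist(b0, gen)
  sum(pr$prob *
        purrr::pmap_dbl(pr, function(x, y, prob) eval_node(step_belief(b0, x, y, gen))))
}
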