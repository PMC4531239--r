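#' Session design configuration
#'
#' Describes the stop-signal session to synthesize: 12 blocks of 75 trials
#' by default, each trial independently a stop trial with probability
#' `stop_prob`, SSD drawn uniformly from `ssd_set` on stop trials, and an
#' 1100 ms response deadline.
#'
#' @param n_blocks Number of blocks (default 12).
#' @param block_len Trials per block (default 75).
#' @param stop_prob Probability a trial is a stop trial (default 0.25).
#' @param ssd_set SSD values in ms (default 100..600 by 100).
#' @param deadline_ms Response deadline in ms (default 1100).
#' @param exact_count If TRUE, each block contains exactly
#'   `round(block_len * stop_prob)` stop trials at random positions instead
#'   of iid assignment.
#' @param seed Optional integer seed applied by [generate_session()].
#' @return An object of class `sst_session_config`.
#' @export
session_config <- function(n_blocks = 12L, block_len = 75L, stop_prob = 0.25,
                           ssd_set = seq(100, 600, by = 100),
                           deadline_ms = 1100, exact_count = FALSE,
                           seed = NULL) {
  stopifnot(n_blocks >= 1, block_len >= 1, stop_prob > 0, stop_prob < 1,
            all(ssd_set > 0), all(ssd_set < deadline_ms), deadline_ms > 0)
  structure(list(n_blocks = as.integer(n_blocks),
                 block_len = as.integer(block_len), stop_prob = stop_prob,
                 ssd_set = ssd_set, deadline_ms = deadline_ms,
                 exact_count = isTRUE(exact_count), seed = seed),
            class = "sst_session_config")
}

#' Generate the trial specs of a synthetic session
#'
#' Samples the experimenter-controlled side of a session: trial types, SSDs
#' (uniform over the SSD set on stop trials) and go-stimulus identities
#' (fair coin). Behavior is added by [simulate_observer()].
#'
#' @param config A [session_config()] object.
#' @return A tibble with columns `block`, `trial` (global index),
#'   `trial_type` ("go"/"stop"), `ssd_ms` (NA on go trials) and `d` (true
#'   go identity, 0/1).
#' @export
generate_session <- function(config = session_config()) {
  stopifnot(inherits(config, "sst_session_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_blocks * config$block_len
  if (config$exact_count) {
    k <- round(config$block_len * config$stop_prob)
    is_stop <- as.vector(vapply(seq_len(config$n_blocks), function(b) {
      v <- logical(config$block_len)
      v[sample.int(config$block_len, k)] <- TRUE
      v
    }, logical(config$block_len)))
  } else {
    is_stop <- runif(n) < config$stop_prob
  }
  tibble(
    block = rep(seq_len(config$n_blocks), each = config$block_len),
    trial = seq_len(n),
    trial_type = ifelse(is_stop, "stop", "go"),
    ssd_ms = ifelse(is_stop,
                    sample(config$ssd_set, n, replace = TRUE), NA_real_),
    d = rbinom(n, 1, 0.5)
  )
}

# lean scalar within-trial simulation against a "pair"-mode policy.
# truth: d in {0,1}; s logical; theta onset step (NA on go trials).
.simulate_one <- function(policy, d, s, theta) {
  gen <- policy$gen
  D <- gen$D; q <- gen$q; q_s <- gen$q_s; q_d <- gen$q_d
  n1 <- policy$n_pd; n2 <- policy$n_ps
  act <- policy$action
  go_raw <- as.raw(1)
  pd <- 0.5
  w0 <- 1 - gen$r; w1 <- gen$r; w2 <- 0
  px1_d <- if (d == 1) 1 - q_d else q_d
  for (t in seq_len(D - 1)) {
    z_on <- s && t >= theta
    x <- runif(1) < px1_d
    y <- runif(1) < (if (z_on) 1 - q_s else q_s)
    w1p <- (1 - q) * w1
    w2p <- w2 + q * w1
    if (y) { g0 <- q_s; g1 <- 1 - q_s } else { g0 <- 1 - q_s; g1 <- q_s }
    w0 <- w0 * g0; w1 <- w1p * g0; w2 <- w2p * g1
    zz <- w0 + w1 + w2
    w0 <- w0 / zz; w1 <- w1 / zz; w2 <- w2 / zz
    if (x) { f1 <- 1 - q_d; f0 <- q_d } else { f1 <- q_d; f0 <- 1 - q_d }
    pd <- pd * f1 / (pd * f1 + (1 - pd) * f0)
    ps <- w1 + w2
    i <- min(n1, max(1L, ceiling(pd * n1)))
    j <- min(n2, max(1L, ceiling(ps * n2)))
    if (act[i, j, t] == go_raw) {
      delta <- if (pd > 0.5) 1L else if (pd < 0.5) 0L else
        as.integer(runif(1) < 0.5)
      return(list(tau = t, responded = TRUE, delta = delta))
    }
  }
  list(tau = D, responded = FALSE, delta = NA_integer_)
}

#' Simulate a single trial under a stopping policy
#'
#' Samples the two evidence channels from the true trial state, filters the
#' belief, and consults the policy at the nearest grid bin each step. A Go
#' action responds with the currently more probable go identity (exact tie:
#' fair coin); a trial with no Go action terminates at the deadline.
#'
#' @param policy An `sst_policy` in `"pair"` mode (its generative parameters
#'   define the observer's beliefs and the channel rates).
#' @param d True go identity (0/1).
#' @param s Is this a stop trial (logical).
#' @param theta Stop-signal onset step (>= 1) on stop trials; NA otherwise.
#' @return A one-row tibble: `tau` (termination step), `responded`, `delta`
#'   (chosen identity or NA), `rt_ms`, and `outcome`.
#' @export
simulate_trial <- function(policy, d, s, theta = NA) {
  stopifnot(inherits(policy, "sst_policy"), policy$mode == "pair",
            d %in% 0:1, is.logical(s) || s %in% 0:1)
  s <- as.logical(s)
  if (s && (is.na(theta) || theta < 1)) abort("stop trial needs onset `theta` >= 1")
  if (!s && !is.na(theta)) abort("go trial cannot have a finite onset")
  res <- .simulate_one(policy, d, s, theta)
  out <- .classify_one(s, d, res$responded, res$delta)
  tibble(tau = res$tau, responded = res$responded, delta = res$delta,
         rt_ms = ifelse(res$responded, res$tau * policy$gen$step_ms, NA_real_),
         outcome = out)
}

#' Simulate a batch of independent trials (vectorized)
#'
#' Same dynamics as [simulate_trial()] but vectorized across trials that
#' share one policy; used for the RT sweeps and the inhibition function,
#' where thousands of trials per condition are needed.
#'
#' @inheritParams simulate_trial
#' @param d,s,theta Vectors of per-trial truth (recycled to a common length).
#' @return A tibble with one row per trial: `d`, `s`, `theta`, `tau`,
#'   `responded`, `delta`, `rt_ms`, `outcome`.
#' @export
simulate_trials <- function(policy, d, s, theta = NA) {
  stopifnot(inherits(policy, "sst_policy"), policy$mode == "pair")
  n <- max(length(d), length(s), length(theta))
  d <- rep_len(as.integer(d), n); s <- rep_len(as.logical(s), n)
  theta <- rep_len(theta, n)
  gen <- policy$gen
  D <- gen$D; q <- gen$q; q_s <- gen$q_s; q_d <- gen$q_d
  n1 <- policy$n_pd; n2 <- policy$n_ps

  pd <- rep(0.5, n)
  w0 <- rep(1 - gen$r, n); w1 <- rep(gen$r, n); w2 <- rep(0, n)
  px1_d <- ifelse(d == 1, 1 - q_d, q_d)
  tau <- rep(D, n); responded <- rep(FALSE, n); delta <- rep(NA_integer_, n)
  active <- seq_len(n)

  for (t in seq_len(D - 1)) {
    if (length(active) == 0) break
    a <- active
    z_on <- s[a] & !is.na(theta[a]) & t >= theta[a]
    x <- runif(length(a)) < px1_d[a]
    y <- runif(length(a)) < ifelse(z_on, 1 - q_s, q_s)
    w1p <- (1 - q) * w1[a]
    w2p <- w2[a] + q * w1[a]
    g0 <- ifelse(y, q_s, 1 - q_s)
    g1 <- ifelse(y, 1 - q_s, q_s)
    v0 <- w0[a] * g0; v1 <- w1p * g0; v2 <- w2p * g1
    zz <- v0 + v1 + v2
    w0[a] <- v0 / zz; w1[a] <- v1 / zz; w2[a] <- v2 / zz
    f1 <- ifelse(x, 1 - q_d, q_d)
    f0 <- ifelse(x, q_d, 1 - q_d)
    pd[a] <- pd[a] * f1 / (pd[a] * f1 + (1 - pd[a]) * f0)
    ps <- w1[a] + w2[a]
    i <- pmin(n1, pmax(1L, ceiling(pd[a] * n1)))
    j <- pmin(n2, pmax(1L, ceiling(ps * n2)))
    go <- policy$action[cbind(i, j, t)] == as.raw(1)
    if (any(go)) {
      g <- a[go]
      tau[g] <- t
      responded[g] <- TRUE
      pg <- pd[g]
      delta[g] <- ifelse(pg > 0.5, 1L,
                         ifelse(pg < 0.5, 0L,
                                as.integer(runif(length(g)) < 0.5)))
      active <- a[!go]
    }
  }
  tibble(
    d = d, s = s, theta = theta, tau = tau, responded = responded,
    delta = delta,
    rt_ms = ifelse(responded, tau * gen$step_ms, NA_real_),
    outcome = .classify_vec(s, d, responded, delta)
  )
}

.classify_one <- function(s, d, responded, delta) {
  if (s) {
    if (responded) "stop_error" else "stop_success"
  } else if (!responded) {
    "omission"
  } else if (delta == d) "go_correct" else "discrim_error"
}

.classify_vec <- function(s, d, responded, delta) {
  out <- character(length(s))
  out[s & responded] <- "stop_error"
  out[s & !responded] <- "stop_success"
  out[!s & !responded] <- "omission"
  out[!s & responded & delta == d] <- "go_correct"
  out[!s & responded & delta != d] <- "discrim_error"
  out
}

#' Classify a trial outcome
#'
#' The five-way outcome of a stop-signal trial: `go_correct`,
#' `discrim_error` (wrong identity on a go trial), `omission` (no response
#' on a go trial), `stop_success` (withheld on a stop trial), `stop_error`
#' (responded on a stop trial).
#'
#' @param trial_type "go" or "stop" (vectorized).
#' @param d True go identity (0/1).
#' @param response Chosen identity (0/1) or NA for no response.
#' @param rt_ms Response time in ms (NA when no response).
#' @param deadline_ms Response deadline.
#' @return Character vector of outcome classes.
#' @export
classify_outcome <- function(trial_type, d, response, rt_ms = NA,
                             deadline_ms = 1100) {
  stopifnot(all(trial_type %in% c("go", "stop")))
  responded <- !is.na(response)
  if (any(responded & !is.na(rt_ms) & rt_ms > deadline_ms)) {
    abort("a response cannot occur after the deadline")
  }
  if (any(!responded & !is.na(rt_ms))) {
    abort("rt_ms must be NA when there is no response")
  }
  .classify_vec(trial_type == "stop", d, responded,
                ifelse(responded, response, NA_integer_))
}

#' Points lost in a session
#'
#' The task's incentive scheme: 50 points for each go error (discrimination
#' or omission) and each stop error, plus 3 points per 100 ms of response
#' delay (a trial that runs to the 1100 ms deadline accrues the maximal 33
#' delay points).
#'
#' @param records A trial-record tibble with `outcome` and `rt_ms`.
#' @param deadline_ms Response deadline in ms.
#' @return Total points lost (scalar).
#' @examples
#' score_session(tibble::tibble(outcome = "go_correct", rt_ms = 500))  # 15
#' @export
score_session <- function(records, deadline_ms = 1100) {
  if (nrow(records) == 0) return(0)
  err <- sum(records$outcome %in% c("discrim_error", "omission", "stop_error")) * 50
  delay_ms <- ifelse(is.na(records$rt_ms), deadline_ms, records$rt_ms)
  err + sum(3 * delay_ms / 100)
}

#' Policy cache over the learned-parameter lattice
#'
#' Recomputing the backward-induction policy on every trial would be
#' wasteful; instead policies are computed lazily on a lattice of
#' `(P(stop), E[SSD])` values spanning the ranges the learners visit
#' (defaults: P(stop) 0.10..0.75 by 0.05; E\[SSD\] 8..18 steps) and looked
#' up by nearest lattice point. Cached policies drop their value arrays to
#' bound memory.
#'
#' @param q_d,q_s Channel rates shared by all policies.
#' @param D Deadline in steps.
#' @param step_ms Step duration in ms.
#' @param cost A [cost_params()] object.
#' @param grid Belief grid resolution (default 200 x 200).
#' @param r_lattice P(stop) lattice values.
#' @param essd_lattice E\[SSD\] lattice values in steps.
#' @return An object of class `sst_policy_cache`.
#' @export
policy_cache <- function(q_d = 0.55, q_s = 0.72, D = 50L, step_ms = 1100 / D,
                         cost = cost_params(), grid = c(200L, 200L),
                         r_lattice = seq(0.10, 0.75, by = 0.05),
                         essd_lattice = 8:18) {
  structure(
    list(q_d = q_d, q_s = q_s, D = as.integer(D), step_ms = step_ms,
         cost = cost, grid = as.integer(grid),
         r_lattice = r_lattice, essd_lattice = essd_lattice,
         store = new.env(parent = emptyenv())),
    class = "sst_policy_cache"
  )
}

#' @rdname policy_cache
#' @param cache An `sst_policy_cache`.
#' @param r Current P(stop).
#' @param q Current onset hazard (1 / E\[SSD\] in steps).
#' @return `cache_get()` returns the `sst_policy` for the nearest lattice
#'   point (computing and caching it on first use).
#' @export
cache_get <- function(cache, r, q) {
  ri <- which.min(abs(cache$r_lattice - r))
  ei <- which.min(abs(cache$essd_lattice - 1 / q))
  key <- paste0("r", ri, "_e", ei)
  pol <- cache$store[[key]]
  if (is.null(pol)) {
    gen <- gen_params(q_d = cache$q_d, q_s = cache$q_s,
                      q = 1 / cache$essd_lattice[ei],
                      r = cache$r_lattice[ri],
                      D = cache$D, step_ms = cache$step_ms)
    pol <- compute_policy(gen, cache$cost, grid = cache$grid,
                          keep_values = FALSE)
    assign(key, pol, envir = cache$store)
  }
  pol
}

#' @export
print.sst_policy_cache <- function(x, ...) {
  cat(sprintf("Policy cache: %d x %d lattice (P(stop) x E[SSD]), %d computed\n",
              length(x$r_lattice), length(x$essd_lattice),
              length(ls(x$store))))
  invisible(x)
}

#' Closed-loop observer simulation of a session
#'
#' Runs the full model over a session's trial specs. Before each trial the
#' DBM predictive mean supplies P(stop) and the Kalman prior mean the
#' expected SSD; the matching cached policy simulates the trial; afterwards
#' the DBM observes the trial label and the Kalman filter assimilates the
#' SSD if one occurred (diffusing without correction on go trials). A
#' nonpositive Kalman prior mean is clipped to one time step for the hazard
#' conversion (counted in the `clipped_essd` attribute).
#'
#' @param session Trial specs from [generate_session()].
#' @param dbm A [dbm_params()] object.
#' @param kf A [kf_params()] object.
#' @param cache A [policy_cache()]; supply one to share policies across
#'   subjects, otherwise one is created.
#' @param subject Subject label attached to the records.
#' @return A trial-record tibble: the session columns plus `response`,
#'   `rt_ms`, `outcome`, and the model predictors `pstop` and `essd_s`
#'   (both strictly prior to the trial).
#' @export
simulate_observer <- function(session, dbm = dbm_params(), kf = kf_params(),
                              cache = policy_cache(), subject = 1L) {
  stopifnot(is.data.frame(session),
            all(c("trial_type", "ssd_ms", "d") %in% names(session)))
  n <- nrow(session)
  step_ms <- cache$step_ms
  is_stop <- session$trial_type == "stop"
  theta <- ifelse(is_stop, pmax(1, round(session$ssd_ms / step_ms)), NA_real_)

  cur <- dbm$p0
  kst <- kf_init(kf)
  p_stop <- essd <- rt <- numeric(n)
  responded <- logical(n)
  delta <- integer(n)
  n_clip <- 0L

  for (k in seq_len(n)) {
    pred <- dbm_predict(cur, dbm)
    r_k <- pstop(pred, dbm)
    kst <- kf_predict(kst, kf)
    h_k <- kst$h_prior
    h_eff <- h_k
    if (h_eff <= 0) { h_eff <- step_ms / 1000; n_clip <- n_clip + 1L }
    q_k <- essd_to_hazard(h_eff, step_ms, cache$D)

    pol <- cache_get(cache, r_k, q_k)
    res <- .simulate_one(pol, session$d[k], is_stop[k], theta[k])

    p_stop[k] <- r_k; essd[k] <- h_k
    responded[k] <- res$responded
    delta[k] <- if (res$responded) res$delta else NA_integer_
    rt[k] <- if (res$responded) res$tau * step_ms else NA_real_

    cur <- dbm_observe(pred, as.integer(is_stop[k]), dbm)
    if (is_stop[k]) {
      kst <- kf_update(kst, session$ssd_ms[k] / 1000, kf)
    } else {
      kst$h_post <- kst$h_prior; kst$P_post <- kst$P_prior
    }
  }

  out <- session |>
    mutate(
      subject = subject,
      response = dplyr::case_when(
        !responded ~ "none", delta == 1L ~ "right", TRUE ~ "left"
      ),
      rt_ms = ifelse(responded, rt, NA_real_),
      outcome = .classify_vec(is_stop, .data$d, responded, delta),
      pstop = p_stop,
      essd_s = essd
    ) |>
    select("subject", dplyr::everything())
  attr(out, "clipped_essd") <- n_clip
  out
}

#' Simulate a cohort of synthetic subjects
#'
#' Generates and simulates `n_subjects` independent sessions with a shared
#' policy cache. Optional per-subject heterogeneity: additive uniform jitter
#' ranges for the learning and cost parameters (`alpha`, `Q`, `R`, `c`,
#' `c_s`); the default is a homogeneous cohort at the supplied values.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param config A [session_config()].
#' @param dbm,kf,cache As in [simulate_observer()].
#' @param jitter Named list of `c(min, max)` additive offsets, e.g.
#'   `list(alpha = c(-0.1, 0.1))`; NULL for none.
#' @param seed Optional integer seed.
#' @return A trial-record tibble over all subjects.
#' @export
simulate_cohort <- function(n_subjects = 20L, config = session_config(),
                            dbm = dbm_params(), kf = kf_params(),
                            cache = policy_cache(), jitter = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  jit <- function(val, name) {
    if (is.null(jitter[[name]])) val
    else val + runif(1, jitter[[name]][1], jitter[[name]][2])
  }
  bind_rows(lapply(seq_len(n_subjects), function(sj) {
    dbm_j <- dbm_params(alpha = min(1, max(0, jit(dbm$alpha, "alpha"))),
                        a = dbm$a, b = dbm$b, n_grid = dbm$n_grid)
    kf_j <- kf_params(Q = max(1e-6, jit(kf$Q, "Q")),
                      R = max(1e-6, jit(kf$R, "R")),
                      h0 = kf$h0, P0 = kf$P0)
    cache_j <- if (is.null(jitter$c) && is.null(jitter$c_s)) cache else
      policy_cache(q_d = cache$q_d, q_s = cache$q_s, D = cache$D,
                   step_ms = cache$step_ms,
                   cost = cost_params(c = max(1e-5, jit(cache$cost$c, "c")),
                                      c_s = max(1e-3, jit(cache$cost$c_s, "c_s"))),
                   grid = cache$grid, r_lattice = cache$r_lattice,
                   essd_lattice = cache$essd_lattice)
    sess <- generate_session(config)
    simulate_observer(sess, dbm = dbm_j, kf = kf_j, cache = cache_j,
                      subject = sj)
  }))
}

#' Read and write trial logs
#'
#' Trial logs are tab-separated text with one row per trial and columns
#' `subject`, `block`, `trial`, `trial_type`, `ssd_ms`, `d`, `response`,
#' `rt_ms`, `outcome`, and optionally the model predictors `pstop` and
#' `essd_s`; missing values are empty fields.
#'
#' @param records A trial-record tibble.
#' @param path File path.
#' @return `read_trial_log()` returns a tibble; `write_trial_log()` returns
#'   `path` invisibly.
#' @export
write_trial_log <- function(records, path) {
  readr::write_tsv(records, path, na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  readr::read_tsv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(
                    trial_type = readr::col_character(),
                    response = readr::col_character(),
                    outcome = readr::col_character(),
                    .default = readr::col_guess()
                  ))
}
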