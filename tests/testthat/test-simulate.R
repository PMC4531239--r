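# small shared policies for trial-level tests
coarse_cache <- policy_cache(grid = c(60L, 60L))

all_action_policy <- function(action, D = 10L) {
  gen <- gen_params(D = D, q = 0.2, r = 0.25)
  structure(
    list(mode = "pair", gen = gen, cost = cost_params(), n_pd = 2L, n_ps = 2L,
         pd_mid = c(0.25, 0.75), ps_mid = c(0.25, 0.75),
         action = array(as.raw(action), dim = c(2, 2, D - 1))),
    class = "sst_policy"
  )
}

test_that("session generation matches the experimental design", {
  set.seed(707)
  sess <- generate_session(session_config())
  expect_equal(nrow(sess), 900)
  expect_equal(unique(table(sess$block)), 75L)
  n_stop <- sum(sess$trial_type == "stop")
  expect_true(abs(n_stop - 225) < 3 * sqrt(900 * 0.25 * 0.75))
  expect_true(all(is.na(sess$ssd_ms[sess$trial_type == "go"])))
  expect_true(all(sess$ssd_ms[sess$trial_type == "stop"] %in% seq(100, 600, 100)))

  # leading go-run length: mean (1-r)/r = 3, none at all 1/4 of the time
  many <- generate_session(session_config(n_blocks = 400, block_len = 75))
  runs <- many |>
    dplyr::group_by(block) |>
    dplyr::summarise(lead = which(trial_type == "stop")[1] - 1)
  expect_equal(mean(runs$lead), 3, tolerance = 0.15)
  expect_equal(mean(runs$lead == 0), 0.25, tolerance = 0.1)

  # exact-count design option
  ex <- generate_session(session_config(exact_count = TRUE))
  per_block <- tapply(ex$trial_type == "stop", ex$block, sum)
  expect_true(all(per_block == 19))
})

test_that("outcomes classify per the five-way scheme", {
  expect_equal(classify_outcome("go", 1, 1, 500), "go_correct")
  expect_equal(classify_outcome("go", 1, 0, 500), "discrim_error")
  expect_equal(classify_outcome("go", 1, NA), "omission")
  expect_equal(classify_outcome("stop", 0, NA), "stop_success")
  expect_equal(classify_outcome("stop", 0, 0, 400), "stop_error")
  expect_error(classify_outcome("go", 1, 1, 1200), "deadline")
  expect_error(classify_outcome("go", 1, NA, 500), "no response")
})

test_that("session scoring follows the point scheme", {
  expect_equal(score_session(tibble::tibble(outcome = character(), rt_ms = numeric())), 0)
  expect_equal(score_session(tibble::tibble(outcome = "omission", rt_ms = NA_real_)), 50 + 33)
  expect_equal(score_session(tibble::tibble(outcome = "stop_success", rt_ms = NA_real_)), 33)
  expect_equal(score_session(tibble::tibble(outcome = "go_correct", rt_ms = 500)), 15)
  expect_equal(score_session(tibble::tibble(outcome = "stop_error", rt_ms = 400)), 62)
})

test_that("degenerate policies terminate trials as expected", {
  go_pol <- all_action_policy(1)
  set.seed(808)
  tr <- simulate_trials(go_pol, d = rbinom(20, 1, 0.5), s = FALSE)
  expect_true(all(tr$tau == 1))
  expect_true(all(tr$responded))

  wait_pol <- all_action_policy(0)
  tr_go <- simulate_trials(wait_pol, d = 0, s = FALSE)
  tr_stop <- simulate_trials(wait_pol, d = 0, s = TRUE, theta = 3)
  expect_equal(tr_go$tau, wait_pol$gen$D)
  expect_equal(tr_go$outcome, "omission")
  expect_equal(tr_stop$outcome, "stop_success")

  one <- simulate_trial(go_pol, d = 1, s = FALSE)
  expect_equal(one$tau, 1)
  expect_equal(one$rt_ms, go_pol$gen$step_ms)
  expect_error(simulate_trial(go_pol, d = 1, s = TRUE, theta = NA), "theta")
  expect_error(simulate_trial(go_pol, d = 1, s = FALSE, theta = 3), "cannot")
})

test_that("cached policies equal a fresh computation at the lattice point", {
  cache <- policy_cache(grid = c(40L, 40L))
  pol <- cache_get(cache, r = 0.26, q = 1 / 9.8)   # snaps to (0.25, 10)
  fresh <- compute_policy(
    gen_params(q_d = cache$q_d, q_s = cache$q_s, q = 1 / 10, r = 0.25,
               D = cache$D, step_ms = cache$step_ms),
    cache$cost, grid = c(40L, 40L), keep_values = FALSE
  )
  expect_identical(pol$action, fresh$action)
  expect_equal(pol$gen$r, 0.25)
  expect_equal(1 / pol$gen$q, 10)
  # second lookup returns the cached object itself
  expect_identical(cache_get(cache, 0.25, 0.1), pol)
})

test_that("closed-loop simulation books outcomes and predictors coherently", {
  cfg <- session_config(n_blocks = 2, block_len = 40)
  set.seed(909)
  sess <- generate_session(cfg)
  rec <- simulate_observer(sess, cache = coarse_cache)
  expect_equal(nrow(rec), 80)
  expect_equal(sum(table(rec$outcome)), 80L)
  expect_true(all(rec$outcome[rec$trial_type == "stop"] %in%
                    c("stop_error", "stop_success")))
  expect_true(all(rec$outcome[rec$trial_type == "go"] %in%
                    c("go_correct", "discrim_error", "omission")))
  expect_true(all(is.na(rec$rt_ms) == (rec$response == "none")))
  # predictors are priors: trial 1 carries the fresh-prior values
  expect_equal(rec$pstop[1], 0.25, tolerance = 0.005)
  expect_equal(rec$essd_s[1], 0.35)
})

test_that("identical config and seed reproduce the trial log byte-for-byte", {
  cfg <- session_config(n_blocks = 2, block_len = 30)
  run <- function() {
    cache <- policy_cache(grid = c(60L, 60L))
    simulate_cohort(n_subjects = 2, config = cfg, cache = cache, seed = 99)
  }
  expect_identical(run(), run())
})

test_that("a frozen learner yields constant predictors", {
  cfg <- session_config(n_blocks = 1, block_len = 40)
  set.seed(111)
  sess <- generate_session(cfg)
  rec <- simulate_observer(
    sess,
    dbm = dbm_params(alpha = 0),
    kf = kf_params(Q = 1e-15, P0 = 1e-12),
    cache = coarse_cache
  )
  expect_true(all(abs(rec$pstop - rec$pstop[1]) < 1e-12))
  expect_true(all(abs(rec$essd_s - 0.35) < 1e-6))
})

test_that("after a stop trial the next-trial P(stop) exceeds the post-go value", {
  pars <- dbm_params()
  post_stop <- dbm_predict(dbm_observe(dbm_predict(pars$p0, pars), 1, pars), pars)
  post_go <- dbm_predict(dbm_observe(dbm_predict(pars$p0, pars), 0, pars), pars)
  expect_gt(pstop(post_stop, pars), pstop(post_go, pars))
})

test_that("trial logs round-trip through delimited text", {
  cfg <- session_config(n_blocks = 1, block_len = 25)
  set.seed(222)
  rec <- simulate_observer(generate_session(cfg), cache = coarse_cache)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_log(rec, path)
  back <- read_trial_log(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12,
               ignore_attr = "clipped_essd")
})
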