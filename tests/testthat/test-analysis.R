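# hand-built toy log: one subject, explicit structure
toy_records <- function(types, ssd = NULL, rt = NULL, block = NULL,
                        outcome = NULL, subject = 1) {
  n <- length(types)
  tibble::tibble(
    subject = subject,
    block = if (is.null(block)) rep(1, n) else block,
    trial = seq_len(n),
    trial_type = types,
    ssd_ms = if (is.null(ssd)) ifelse(types == "stop", 300, NA) else ssd,
    d = 1,
    rt_ms = if (is.null(rt)) ifelse(types == "go", 700, NA) else rt,
    outcome = if (is.null(outcome))
      ifelse(types == "go", "go_correct", "stop_success")
    else outcome
  )
}

test_that("block-initial go runs are excluded up to the first stop trial", {
  rec <- toy_records(c("go", "go", "stop", "go", "stop", "go"),
                     block = c(1, 1, 1, 1, 2, 2))
  out <- exclude_block_initial_go_runs(rec)
  expect_equal(out$trial, c(3, 4, 5, 6))  # two leading gos dropped; stop-first block intact
})

test_that("attached predictors are strictly prior quantities", {
  rec <- toy_records(c("go", "stop", "go", "stop", "go", "go"),
                     ssd = c(NA, 200, NA, 400, NA, NA))
  out <- attach_model_predictors(rec)
  dbm <- dbm_params(); kf <- kf_params()

  expect_equal(out$pstop[1], pstop(dbm$p0, dbm), tolerance = 1e-12)
  expect_equal(out$essd_s[1], kf$h0)

  # hand iteration of both recursions over the first trials
  pred <- dbm$p0; h <- kf$h0; P <- kf$P0
  for (k in 1:6) {
    pred_k <- dbm_predict(pred, dbm)
    expect_equal(out$pstop[k], pstop(pred_k, dbm), tolerance = 1e-12)
    pred <- dbm_observe(pred_k, as.integer(rec$trial_type[k] == "stop"), dbm)
    P <- P + kf$Q
    expect_equal(out$essd_s[k], h, tolerance = 1e-12)
    if (rec$trial_type[k] == "stop") {
      K <- P / (P + kf$R)
      h <- h + K * (rec$ssd_ms[k] / 1000 - h)
      P <- (1 - K) * P
    }
  }

  # causality: flipping a later trial leaves earlier predictors unchanged
  rec2 <- rec
  rec2$trial_type[5] <- "stop"; rec2$ssd_ms[5] <- 600
  out2 <- attach_model_predictors(rec2)
  expect_equal(out2$pstop[1:5], out$pstop[1:5])
  expect_equal(out2$essd_s[1:5], out$essd_s[1:5])
  expect_false(out2$pstop[6] == out$pstop[6])

  expect_error(attach_model_predictors(rec[c(2, 1, 3:6), ]), "chronological")
})

test_that("pattern table counts three-trial histories of correct go trials", {
  rec <- toy_records(c("go", "go", "go", "go"))
  tab <- pattern_rts(rec)
  expect_equal(nrow(tab), 1)
  expect_equal(as.character(tab$pattern), "GGG")
  expect_equal(tab$n, 1L)

  # a gap in trial numbering (excluded rows) invalidates spanning patterns
  rec2 <- toy_records(c("go", "stop", "go", "go", "go", "go", "go"))[-(1:2), ]
  tab2 <- pattern_rts(rec2)
  expect_equal(sum(tab2$n), 2L)  # trials 6 and 7 have consecutive predecessors
  expect_equal(as.character(tab2$pattern), "GGG")
  tab2b <- pattern_rts(rec2[rec2$trial != 4, ])
  expect_equal(sum(tab2b$n), 0L)  # the gap at trial 4 invalidates both patterns

  # stop-heavy recent history is keyed most-recent-last
  rec3 <- toy_records(c("stop", "stop", "go", "go"))
  expect_equal(as.character(pattern_rts(rec3)$pattern), "SSG")
})

test_that("recent-SSD eligibility follows the two-stop separation rule", {
  # two stops separated by four go trials: final go is masked
  rec <- toy_records(c("stop", "go", "go", "go", "go", "stop", "go"),
                     ssd = c(200, NA, NA, NA, NA, 400, NA))
  out <- recent_ssd_predictor(rec)
  expect_false(out$ssd_eligible[7])

  # separation of one go trial: eligible, predictor is the mean SSD
  rec2 <- toy_records(c("stop", "go", "stop", "go"),
                      ssd = c(200, NA, 400, NA))
  out2 <- recent_ssd_predictor(rec2)
  expect_true(out2$ssd_eligible[4])
  expect_equal(out2$recent_ssd_ms[4], 300)
  # the go trial after the first stop has no second stop yet
  expect_false(out2$ssd_eligible[2])

  # a go trial not directly after a stop is masked
  rec3 <- toy_records(c("stop", "go", "stop", "go", "go"),
                      ssd = c(200, NA, 400, NA, NA))
  expect_false(recent_ssd_predictor(rec3)$ssd_eligible[5])
})

test_that("equal-count binned regression recovers noiseless structure", {
  set.seed(313)
  x <- runif(503)
  d <- tibble::tibble(x = x, y = 200 + 150 * x + rnorm(503, 0, 1e-3))
  fit <- binned_linear_regression(d, "x", "y", n_bins = 10)
  g <- glance(fit)
  expect_equal(g$r_squared, 1, tolerance = 1e-6)
  expect_equal(g$slope, 150, tolerance = 1e-3)
  b_n <- tidy(fit)$n
  expect_lte(max(b_n) - min(b_n), 1)  # populations differ by at most 1

  d2 <- tibble::tibble(x = runif(4000), y = rnorm(4000))
  g2 <- glance(binned_linear_regression(d2, "x", "y", n_bins = 50))
  expect_lt(g2$r_squared, 0.3)

  expect_error(binned_linear_regression(d[1:15, ], "x", "y", 10), "per bin")
})

test_that("variance partition attributes binned RT variance correctly", {
  set.seed(414)
  n <- 4000
  rec <- tibble::tibble(
    subject = 1, trial = 1:n,
    pstop = runif(n, 0.1, 0.5), essd_s = runif(n, 0.2, 0.5),
    outcome = "go_correct", rt_ms = NA_real_
  )
  # RT a function of pstop alone
  rec$rt_ms <- 600 + 500 * rec$pstop + rnorm(n, 0, 5)
  vp1 <- variance_partition(rec)
  expect_gt(vp1$fraction, 0.95)
  expect_lte(vp1$r2_pstop, vp1$r2_combined)

  # RT a function of essd alone
  rec$rt_ms <- 600 + 500 * rec$essd_s + rnorm(n, 0, 5)
  vp2 <- variance_partition(rec)
  expect_lt(vp2$fraction, 0.2)
  expect_lte(vp2$r2_pstop, vp2$r2_combined)
  expect_true(all(glance(vp2)$r2_combined <= 1))
})

test_that("predictor correlation handles identical, opposed and constant series", {
  base <- tibble::tibble(
    subject = rep(1:3, each = 50), trial = rep(1:50, 3),
    outcome = "go_correct"
  )
  x <- rep(seq(0.1, 0.5, length.out = 50), 3)
  pc <- predictor_correlation(dplyr::mutate(base, pstop = x, essd_s = x))
  expect_equal(pc$correlation, rep(1, 3))
  pc2 <- predictor_correlation(dplyr::mutate(base, pstop = x, essd_s = -x))
  expect_equal(pc2$correlation, rep(-1, 3))
  pc3 <- predictor_correlation(dplyr::mutate(base, pstop = x, essd_s = 0.3))
  expect_true(all(is.na(pc3$correlation)))
})

test_that("grid-search fits cover their grids without early stopping", {
  set.seed(515)
  cfg <- session_config(n_blocks = 2, block_len = 50)
  sess1 <- generate_session(cfg)
  sess2 <- generate_session(cfg)
  rec <- dplyr::bind_rows(
    dplyr::mutate(sess1, subject = 1), dplyr::mutate(sess2, subject = 2)
  ) |>
    dplyr::mutate(
      rt_ms = ifelse(trial_type == "go", rnorm(dplyr::n(), 800, 50), NA),
      outcome = ifelse(trial_type == "go", "go_correct", "stop_success")
    )
  af <- fit_dbm_alpha(rec, alpha_grid = c(0.6, 0.75, 0.9), n_bins = 5)
  expect_equal(tidy(af)$alpha, c(0.6, 0.75, 0.9))
  expect_true(af$best_alpha %in% c(0.6, 0.75, 0.9))

  kfit <- fit_kf_params(rec, Q_grid = c(0.01, 0.1), R_grid = c(0.1, 0.3),
                        n_bins = 5)
  expect_equal(nrow(tidy(kfit)), 4)
  # RT independent of history: no informative structure anywhere
  expect_lt(max(tidy(af)$r_squared), 0.9)
})
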