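test_that("RT adjustment removes intercept, trend and switch structure", {
  # constant RTs, constant side -> the intercept absorbs everything
  adj <- adjust_rts(rep(0.5, 10), rep("left", 10))
  expect_equal(adj$residuals, rep(0, 10), tolerance = 1e-12)

  # a pure exponential trend is absorbed by the linear-trend column
  rts <- exp(-0.7 - 0.01 * (1:20))
  adj2 <- adjust_rts(rts, rep("right", 20))
  expect_equal(adj2$residuals, rep(0, 20), tolerance = 1e-10)

  # hand 6-trial example with one switch: residuals match an independent
  # normal-equations solution
  rts3 <- c(0.51, 0.48, 0.55, 0.47, 0.52, 0.49)
  sides3 <- c("left", "left", "right", "right", "right", "right")
  adj3 <- adjust_rts(rts3, sides3)
  X <- cbind(1, 1:6, c(0, 0, 1, 0, 0, 0))
  beta <- solve(t(X) %*% X, t(X) %*% log(rts3))
  expect_equal(adj3$residuals, as.vector(log(rts3) - X %*% beta),
               tolerance = 1e-10)
})

test_that("missing responses are dropped with the index map retained", {
  rts <- c(0.5, NA, 0.6, 0.55, NA, 0.52, 0.58)
  sides <- c("left", "right", "right", "left", "left", "right", "left")
  adj <- adjust_rts(rts, sides)
  expect_identical(adj$used, c(1L, 3L, 4L, 6L, 7L))
  expect_identical(adj$n, 5L)
  expect_error(adjust_rts(c(0.5, NA, NA, NA, 0.4), rep("left", 5)),
               "fewer than 4")
  expect_error(adjust_rts(c(0.5, -0.1, 0.4, 0.3), rep("left", 4)),
               "positive")
})

test_that("grid search recovers a known RW learning rate at near-zero noise", {
  sess <- generate_session(task_config(), seed = 21)
  ev <- rw_run(sess, alpha = 0.3)$ev
  rt <- simulate_rts(sess, ev,
                     rt_config(ev_weight = -1, noise_sd = 1e-8), seed = 5)
  adj <- adjust_rts(rt, sess$trials$side)
  fit <- fit_model_to_rts(adj, "RW", sess, grid_step = 0.001)
  expect_lte(abs(fit$best_param - 0.3), 0.001)
  expect_identical(fit$k, 1L)

  # argmin definition: SSE at best_param no larger than at probe points
  for (p in c(0.1, 0.25, 0.35, 0.9)) {
    probe <- pavlovhmm:::regression_sse(adj$residuals,
                                        rw_run(sess, p)$ev[adj$used])
    expect_lte(fit$sse, probe + 1e-12)
  }
})

test_that("coarse grid search is consistent with a 10x finer dense search", {
  sess <- generate_session(task_config(), seed = 22)
  ev <- ph_run(sess, s_intensity = 0.37)$ev
  rt <- simulate_rts(sess, ev,
                     rt_config(ev_weight = -0.8, noise_sd = 0.02), seed = 6)
  adj <- adjust_rts(rt, sess$trials$side)
  coarse <- fit_model_to_rts(adj, "PH", sess, grid_step = 0.01)
  dense <- fit_model_to_rts(adj, "PH", sess, grid_step = 0.001)
  expect_lte(abs(coarse$best_param - dense$best_param), 0.01)
  expect_lte(dense$sse, coarse$sse + 1e-12)
})

test_that("fixed-parameter models get a single regression and k = 0", {
  sess <- generate_session(task_config(), seed = 23)
  rt <- simulate_rts(sess, hmm_filter(sess)$ev, rt_config(), seed = 7)
  adj <- adjust_rts(rt, sess$trials$side)
  for (m in c("HMM", "ReducedHMM", "Baseline")) {
    fit <- fit_model_to_rts(adj, m, sess, seed = 11)
    expect_identical(fit$k, 0L)
    expect_true(is.na(fit$best_param))
    expect_gt(fit$sse, 0)
  }
  # the baseline's near-zero predictor leaves SSE at about the residual
  # sum of squares
  fitb <- fit_model_to_rts(adj, "Baseline", sess, seed = 11)
  expect_equal(fitb$sse, sum(adj$residuals^2), tolerance = 0.02)
  # an exactly constant trace is a singular regression, reported as such
  expect_error(fit_model_to_rts(adj, "Baseline", sess,
                                baseline_jitter_sd = 0),
               "Baseline")
})

test_that("the BIC follows the Gaussian-residual form", {
  expect_equal(compute_bic(100, 100, 0), 0)
  expect_equal(compute_bic(100, 100, 1), log(100))
  # doubling the SSE at fixed n, k raises BIC by n log 2
  expect_equal(compute_bic(8, 50, 1) - compute_bic(4, 50, 1), 50 * log(2))
  expect_error(compute_bic(0, 10, 1), "degenerate")
  expect_error(compute_bic(1, 2, 2), "n > k")
})

test_that("BIC ordering is invariant to rescaling the RT units", {
  sess <- generate_session(task_config(), seed = 24)
  rt <- simulate_rts(sess, hmm_filter(sess)$ev, rt_config(), seed = 8)
  fits <- function(r) {
    adj <- adjust_rts(r, sess$trials$side)
    vapply(c("HMM", "RW", "Baseline"), function(m) {
      fit_model_to_rts(adj, m, sess, grid_step = 0.02, seed = 3)$bic
    }, numeric(1))
  }
  b_s <- fits(rt)
  b_ms <- fits(rt * 1000)   # milliseconds
  expect_equal(order(b_s), order(b_ms))
  expect_equal(b_s, b_ms, tolerance = 1e-8)
})

test_that("the generating model wins the BIC comparison at low noise", {
  rtc <- rt_config(ev_weight = -0.5, noise_sd = 0.02)
  models <- c("HMM", "RW", "PH", "Hybrid", "Baseline")
  wins <- 0L
  n_sub <- 40L
  for (i in seq_len(n_sub)) {
    sess <- generate_session(task_config(), seed = 6000 + i)
    ev <- rw_run(sess, alpha = 0.35)$ev
    rt <- simulate_rts(sess, ev, rtc, seed = 6500 + i)
    adj <- adjust_rts(rt, sess$trials$side)
    bics <- vapply(models, function(m) {
      fit_model_to_rts(adj, m, sess, grid_step = 0.02, seed = i)$bic
    }, numeric(1))
    if (names(which.min(bics)) == "RW") wins <- wins + 1L
  }
  expect_gte(wins / n_sub, 0.95)
})

test_that("cohort fitting returns a complete subject-level fit table", {
  coh <- simulated_cohort(3, seed = 31)
  fits <- fit_sessions(coh, models = c("HMM", "RW", "Baseline"),
                       grid_step = 0.05, seed = 2)
  expect_identical(nrow(fits), 3L * 2L * 3L)
  expect_setequal(unique(fits$session), c("appetitive", "aversive"))
  expect_true(all(fits$sse > 0))
  expect_true(all(fits$n == 120L))
  # pooled mode: one row per model x session, n summed over subjects
  pooled <- fit_sessions(coh, models = c("HMM", "RW", "Baseline"),
                         grid_step = 0.05, mode = "pooled", seed = 2)
  expect_identical(nrow(pooled), 2L * 3L)
  expect_true(all(pooled$n == 3L * 120L))
})

test_that("subjects with too many missing responses are excluded", {
  coh <- simulated_cohort(3, seed = 32)
  bad <- coh[[2]]$appetitive$trials$rt_s
  bad[seq_len(80)] <- NA
  coh[[2]]$appetitive$trials$rt_s <- bad
  fits <- fit_sessions(coh, models = c("HMM", "Baseline"), grid_step = 0.1,
                       seed = 2)
  expect_setequal(unique(fits$subject), c(1L, 3L))
})
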