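test_that("transition matrices match their definitions and limits", {
  expect_equal(unname(h_transition_matrix(0)), diag(2))
  expect_equal(unname(h_transition_matrix(1)),
               matrix(c(0, 1, 0, 1), 2, byrow = TRUE))
  expect_equal(unname(h_transition_matrix(0.25)),
               matrix(c(0.75, 0.25, 0, 1), 2, byrow = TRUE))
  expect_error(h_transition_matrix(1.5), "probability")

  expect_equal(s_transition_given_h(0.7, 0), diag(2))
  expect_equal(s_transition_given_h(0.25, 1),
               matrix(c(0.75, 0.25, 0.25, 0.75), 2))
  expect_equal(s_transition_given_h(1, 1), matrix(c(0, 1, 1, 0), 2))
  expect_error(s_transition_given_h(-0.1, 1), "probability")
})

test_that("emission likelihoods encode the 0.6 / 0.4 schedule", {
  expect_equal(emission_likelihood(1, 1, "none"), 0.4)
  expect_equal(emission_likelihood(1, 1, "valenced"), 0.6)
  expect_equal(emission_likelihood(1, 1, "neutral"), 0)
  expect_equal(emission_likelihood(2, 1, "neutral"), 0.6)
  expect_equal(emission_likelihood(2, 1, "valenced"), 0)
})

test_that("the forward filter reproduces the hand-computed recursion", {
  # fresh pair: uniform prior over states -> EV 0.3 at cue onset
  sess <- manual_session(c(1, 1), c("valenced", "none"))
  tra <- hmm_filter(sess, hmm_params(alpha = 0.2, beta = 0.25))
  expect_equal(tra$ev[1], 0.3)
  # after observing cue 1 -> valenced (a zero-likelihood event for the
  # neutral mapping), the posterior is a point mass; one propagation step
  # leaves P(stay) = 0.8 * 1 + 0.2 * 0.75 = 0.95, EV = 0.6 * 0.95 = 0.57
  expect_equal(tra$posterior_S[2, 1], 0.95)
  expect_equal(tra$ev[2], 0.57)

  # aversive coding: certain state, presented cue valenced -> EV = -0.6
  sessa <- manual_session(c(1, 1), c("valenced", "valenced"),
                          valence = "aversive")
  traa <- hmm_filter(sessa, hmm_params(alpha = 0, beta = 0))
  expect_equal(traa$ev[2], -0.6)
})

test_that("the filter matches brute-force path enumeration on short sessions", {
  cases <- list(
    manual_session(c(1, 2, 1, 2, 1, 2),
                   c("valenced", "neutral", "none", "none", "neutral",
                     "valenced")),
    manual_session(c(1, 1, 2, 2, 1, 2, 1, 2),
                   c("none", "valenced", "none", "neutral", "none", "none",
                     "valenced", "neutral")),
    manual_session(c(2, 1, 2, 1, 2),
                   c("neutral", "none", "valenced", "valenced", "none"),
                   valence = "aversive")
  )
  for (params in list(hmm_params(), hmm_params(alpha = 0.05, beta = 0.6))) {
    for (sess in cases) {
      for (clamp in c(FALSE, TRUE)) {
        tra <- if (clamp) reduced_hmm_filter(sess, params)
               else hmm_filter(sess, params)
        oracle <- enumerate_hmm(sess, params, clamp_h1 = clamp)
        expect_lt(max(abs(tra$posterior_S - oracle$pred)), 1e-10)
        expect_lt(max(abs(tra$filtered_S - oracle$filt)), 1e-10)
      }
    }
  }
})

test_that("linear-space filtering agrees with a log-space recursion", {
  sess <- generate_session(task_config(), seed = 8)
  for (clamp in c(FALSE, TRUE)) {
    tra <- if (clamp) reduced_hmm_filter(sess) else hmm_filter(sess)
    expect_lt(max(abs(tra$posterior_S -
                        logspace_hmm(sess, clamp_h1 = clamp))), 1e-10)
  }
})

test_that("beliefs stay normalized and EV bounded on simulated sessions", {
  for (seed in c(2, 31, 77)) {
    sess <- generate_session(task_config(), seed)
    for (tra in list(hmm_filter(sess, keep_joint = TRUE),
                     reduced_hmm_filter(sess, keep_joint = TRUE))) {
      sums <- vapply(tra$joint, sum, numeric(1))
      expect_true(all(abs(sums - 1) <= 1e-12))
      expect_true(all(vapply(tra$joint, function(j) all(j >= 0),
                             logical(1))))
      expect_true(all(abs(tra$ev) <= 0.6 + 1e-12))
      expect_true(all(tra$precision >= 0 & tra$precision <= 1))
    }
  }
})

test_that("a zero-likelihood observation is reported with its trial index", {
  sess <- manual_session(c(1, 1), c("valenced", "neutral"))
  # beta = 0 with a point-mass posterior makes the neutral outcome for the
  # now-certainly-valenced cue impossible
  expect_error(hmm_filter(sess, hmm_params(alpha = 0, beta = 0)),
               "zero total likelihood at trial 2")
})

test_that("precision is a monotone-decreasing function of posterior entropy", {
  expect_equal(precision_from_posterior(c(0.5, 0.5)), 0)
  expect_equal(precision_from_posterior(c(1, 0)), 1)
  expect_equal(precision_from_posterior(c(0.9, 0.1)), 0.5310044, tolerance = 1e-6)
  # strictly decreasing in entropy along a path from point mass to uniform
  ps <- seq(0.5, 0.999, length.out = 20)
  prec <- vapply(ps, function(p) precision_from_posterior(c(p, 1 - p)),
                 numeric(1))
  expect_true(all(diff(prec) > 0))
  # reciprocal mode shares the ordering and the extremes' ranking
  prec_r <- vapply(ps, function(p) {
    precision_from_posterior(c(p, 1 - p), mode = "reciprocal")
  }, numeric(1))
  expect_true(all(diff(prec_r) > 0))
  expect_error(precision_from_posterior(c(0.5, 0.6)), "normalized")
})

test_that("full-model precision anticipates reversals, the reduced model's does not", {
  # consistent full reinforcement: every observation pins the state, so the
  # predictive precision at cue onset isolates the hazard each model assumes
  cues <- rep(c(1, 2), 12)
  outs <- ifelse(cues == 1, "valenced", "neutral")
  sess <- manual_session(cues, outs)
  full <- hmm_filter(sess)
  red <- reduced_hmm_filter(sess)
  # alpha-driven decline: the growing reversal expectation erodes precision
  # even though every outcome confirms the current contingency
  expect_true(all(diff(full$precision[2:24]) < 0))
  # the clamped model has a constant hazard: precision settles immediately
  # and shows no decline at all
  expect_true(all(abs(diff(red$precision[2:24])) < 1e-12))
  # with alpha = 0 the full model never grows a reversal expectation either
  full0 <- hmm_filter(sess, hmm_params(alpha = 0))
  expect_true(all(diff(full0$precision[2:24]) >= -1e-12))
})

test_that("reduced model with beta = 0 never infers a reversal", {
  cues <- rep(c(1, 2), 12)
  outs <- rep("none", 24)
  outs[c(1, 3)] <- "valenced"          # cue 1 valenced twice
  outs[c(18, 20, 22, 24)] <- "valenced"  # then cue 2 valenced (a reversal)
  sess <- manual_session(cues, outs)
  expect_error(reduced_hmm_filter(sess, hmm_params(beta = 0)),
               "zero total likelihood")
})

test_that("Rescorla-Wagner updates follow the delta rule", {
  sess <- manual_session(c(1, 1, 1), c("valenced", "none", "none"))
  tra <- rw_run(sess, alpha = 0.5)
  expect_equal(tra$ev, c(0, 0.5, 0.25))
  expect_equal(tra$prediction_error, c(1, -0.5, -0.25))

  # frozen hand value: Q = 0.5, R = 0, alpha = 0.54 -> 0.23
  sess3 <- manual_session(c(1, 1), c("none", "none"))
  tra3 <- rw_run(sess3, alpha = 0.54, q_init = 0.5)
  expect_equal(tra3$ev[2], 0.23)

  expect_equal(rw_run(sess, alpha = 0)$ev, rep(0, 3))  # no learning
  expect_error(rw_run(sess, alpha = 1.2), "0, 1")
})

test_that("Pearce-Hall associability tracks previous absolute prediction error", {
  sess <- manual_session(c(1, 1, 1), c("valenced", "none", "none"))
  tra <- ph_run(sess, s_intensity = 0.4)
  # first presentation: assoc_init = 1, R = 1 -> Q moves to 0.4
  expect_equal(tra$associability[1], 1)
  expect_equal(tra$ev[2], 0.4)
  # trial 2 associability = |R1 - Q1| = |1 - 0| = 1
  expect_equal(tra$associability[2], 1)
  # unreinforced trials leave Q unchanged (multiplicative reinforcer)
  expect_equal(tra$ev[3], tra$ev[2])
  # trial 3 associability = |R2 - Q2| = |0 - 0.4|
  expect_equal(tra$associability[3], 0.4)

  # perfectly predicted outcomes drive associability to zero
  sess2 <- manual_session(rep(1, 12), rep("none", 12))
  tra2 <- ph_run(sess2, s_intensity = 0.6)
  expect_true(all(tra2$associability[2:12] == 0))
})

test_that("the hybrid rule couples RW values with PH learning rates", {
  sess <- manual_session(c(1, 1, 1), c("valenced", "valenced", "none"))
  tra <- hybrid_run(sess, eta = 0.5, kappa = 1)
  # R sequence (1, 1): Q2 = 0 + 1 * 1 * 1 = 1, alpha2 = 0.5 * 1 + 0.5 * 1 = 1,
  # Q3 = 1
  expect_equal(tra$ev[2], 1)
  expect_equal(tra$associability[2], 1)
  expect_equal(tra$ev[3], 1)

  # eta = 0: constant associability, reduces to RW with rate kappa * assoc
  sessl <- generate_session(task_config(), 4)
  hy <- hybrid_run(sessl, eta = 0, kappa = 0.6, assoc_init = 1)
  rw <- rw_run(sessl, alpha = 0.6)
  expect_equal(hy$ev, rw$ev)
})

test_that("model-free values stay within the reward hull where the rule implies it", {
  for (seed in c(3, 14)) {
    sess <- generate_session(task_config(), seed)
    # RW, and Hybrid with kappa * associability <= 1, are convex updates
    for (tra in list(rw_run(sess, 0.54), hybrid_run(sess, 0.7, kappa = 0.9))) {
      expect_true(all(tra$ev >= 0 - 1e-12 & tra$ev <= 1 + 1e-12))
    }
  }
  # the Pearce-Hall rule as written is not a convex combination: two
  # reinforced presentations in a row can push Q above 1 at high intensity;
  # the trace reports the excursion rather than clipping it
  sess2 <- manual_session(c(1, 1, 1), rep("valenced", 3))
  tra2 <- ph_run(sess2, s_intensity = 0.8)
  expect_gt(max(tra2$ev), 1)
})

test_that("the baseline model is constant at 0.5 with reproducible jitter", {
  sess <- generate_session(task_config(), 6)
  expect_true(all(baseline_run(sess)$ev == 0.5))
  j1 <- baseline_run(sess, jitter_sd = 0.01, seed = 5)
  j2 <- baseline_run(sess, jitter_sd = 0.01, seed = 5)
  expect_identical(j1$ev, j2$ev)
  big <- manual_session(rep(c(1, 2), 5000), rep("none", 10000))
  expect_lt(abs(mean(baseline_run(big, jitter_sd = 0.01, seed = 1)$ev) - 0.5),
            3 * 0.01 / sqrt(10000))
})
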