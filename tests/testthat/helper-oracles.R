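# Hand-built sessions and independent oracles used across the suite.

# A session_sequence built directly from cue/outcome vectors (single cue
# pair unless new_pair marks more onsets).
manual_session <- function(cues, outcomes,
                           valence = "appetitive",
                           new_pair = c(TRUE, rep(FALSE, length(cues) - 1L))) {
  n <- length(cues)
  cfg <- task_config(n_trials_per_session = max(n, 96L), fixed_length = FALSE,
                     session_valence = valence)
  trials <- data.frame(
    trial = seq_len(n), phase = 0L, pair = 1L,
    cue = as.integer(cues), side = rep("left", n),
    outcome = outcomes, latent_state = 1L,
    is_reversal_onset = FALSE, is_new_pair_onset = new_pair,
    iti_s = rep(5, n), stringsAsFactors = FALSE
  )
  structure(list(config = cfg, seed = 0L, trials = trials),
            class = "session_sequence")
}

# Brute-force path enumeration over the joint (S, H) chain: for each trial t
# it sums over all 4^t joint paths, weighting by the prior, the transition
# products and the emission products, and returns the predictive (before
# outcome t) and filtered (after outcome t) marginals over S. Single-pair
# sessions only (no mid-session belief reset).
enumerate_hmm <- function(session, params = hmm_params(), clamp_h1 = FALSE) {
  tr <- session$trials
  n <- nrow(tr)
  stopifnot(n <= 8, sum(tr$is_new_pair_onset) == 1)
  TH <- h_transition_matrix(params$alpha)
  TSb <- s_transition_given_h(params$beta, 1)
  TS <- function(h) if (h == 1) TSb else diag(2)
  prior <- function(s, h) {
    if (clamp_h1) ifelse(h == 1, 0.5, 0) else ifelse(h == 0, 0.5, 0)
  }
  emis <- function(s, t) {
    emission_likelihood(s, tr$cue[t], tr$outcome[t], params)
  }
  pred <- filt <- matrix(NA_real_, n, 2)
  for (t in seq_len(n)) {
    paths <- expand.grid(rep(list(1:4), t))   # code: (s-1)*2 + h + 1
    s_of <- function(code) (code - 1) %/% 2 + 1
    h_of <- function(code) (code - 1) %% 2
    w_pred <- w_filt <- numeric(nrow(paths))
    for (r in seq_len(nrow(paths))) {
      s <- s_of(as.integer(paths[r, ])); h <- h_of(as.integer(paths[r, ]))
      w <- prior(s[1], h[1])
      if (t > 1) {
        for (i in 2:t) {
          w <- w * TH[h[i - 1] + 1, h[i] + 1] * TS(h[i])[s[i - 1], s[i]]
        }
      }
      w_emit_hist <- if (t > 1) prod(vapply(seq_len(t - 1), function(i) {
        emis(s[i], i)
      }, numeric(1))) else 1
      w_pred[r] <- w * w_emit_hist
      w_filt[r] <- w * w_emit_hist * emis(s[t], t)
    }
    s_last <- s_of(as.integer(paths[, t]))
    pred[t, ] <- vapply(1:2, function(k) sum(w_pred[s_last == k]),
                        numeric(1))
    pred[t, ] <- pred[t, ] / sum(pred[t, ])
    filt[t, ] <- vapply(1:2, function(k) sum(w_filt[s_last == k]),
                        numeric(1))
    filt[t, ] <- filt[t, ] / sum(filt[t, ])
  }
  list(pred = pred, filt = filt)
}

# Log-space forward recursion, mirroring the filter's conventions but
# carrying log-probabilities throughout (independent numerical route).
logspace_hmm <- function(session, params = hmm_params(), clamp_h1 = FALSE) {
  tr <- session$trials
  n <- nrow(tr)
  TH <- h_transition_matrix(params$alpha)
  TSb <- s_transition_given_h(params$beta, 1)
  fresh <- log(if (clamp_h1) matrix(c(0, 0, 0.5, 0.5), 2)
               else matrix(c(0.5, 0.5, 0, 0), 2))
  lse <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(x - m)))
  }
  lj <- fresh
  pred <- matrix(NA_real_, n, 2)
  for (t in seq_len(n)) {
    if (tr$is_new_pair_onset[t]) {
      lj <- fresh
    } else {
      new <- matrix(-Inf, 2, 2)
      for (s2 in 1:2) for (h2 in 1:2) {
        terms <- c()
        for (s1 in 1:2) for (h1 in 1:2) {
          ts <- if (h2 == 2) TSb[s1, s2] else as.numeric(s1 == s2)
          terms <- c(terms, lj[s1, h1] + log(TH[h1, h2]) + log(ts))
        }
        new[s2, h2] <- lse(terms)
      }
      if (clamp_h1) new[, 1] <- -Inf
      lj <- new
    }
    pred[t, ] <- exp(apply(lj, 1, lse) - lse(as.vector(lj)))
    lik <- vapply(1:2, emission_likelihood, numeric(1),
                  cue = tr$cue[t], outcome = tr$outcome[t], params = params)
    lj <- lj + log(lik)
    lj <- lj - lse(as.vector(lj))
  }
  pred
}

# Exceedance probability of a Dirichlet(alpha) by an independent route:
# closed form (Beta tail) for two models, a fresh large sampler otherwise.
dirichlet_xp_oracle <- function(alpha, n_draws = 1e6, seed = 123) {
  K <- length(alpha)
  if (K == 2) {
    x1 <- stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    return(c(x1, 1 - x1))
  }
  set.seed(seed)
  g <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
              n_draws, K)
  tabulate(max.col(g, ties.method = "first"), K) / n_draws
}

# Exact-posterior exceedance by importance sampling from the Dirichlet(1)
# prior over population model frequencies.
exact_xp_importance <- function(log_evidence, n_draws = 2e5, seed = 321) {
  set.seed(seed)
  K <- ncol(log_evidence)
  r <- matrix(stats::rgamma(n_draws * K, 1), n_draws, K)
  r <- r / rowSums(r)
  like <- exp(log_evidence - apply(log_evidence, 1, max))
  w <- rep(1, n_draws)
  for (n in seq_len(nrow(log_evidence))) w <- w * as.vector(r %*% like[n, ])
  vapply(seq_len(K), function(k) sum(w[max.col(r) == k]) / sum(w),
         numeric(1))
}

# Small RT-attached cohort used by fitting / selection tests.
simulated_cohort <- function(n_subjects, seed, generating_model = "HMM",
                             generating_param = NA, rtc = rt_config()) {
  coh <- generate_cohort(task_config(), n_subjects, seed)
  for (i in seq_along(coh)) {
    for (v in c("appetitive", "aversive")) {
      sess <- coh[[i]][[v]]
      ev <- switch(generating_model,
                   HMM = hmm_filter(sess)$ev,
                   RW = rw_run(sess, generating_param)$ev,
                   PH = ph_run(sess, generating_param)$ev,
                   Hybrid = hybrid_run(sess, generating_param)$ev)
      coh[[i]][[v]]$trials$rt_s <-
        simulate_rts(sess, ev, rtc, seed = seed + 7L * i +
                       match(v, c("appetitive", "aversive")))
    }
  }
  coh
}
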