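#' Parameters of the hidden Markov learner
#'
#' The learner performs Bayesian filtering over a joint belief on the
#' contingency state `S` (which cue of the current pair maps to the valenced
#' liquid) and a binary reversal-expectation node `H`. `alpha` is the
#' per-trial probability of entering the reversal-expectation state
#' (`H` 0 to 1; the transition is absorbing), `beta` the per-trial
#' probability of a contingency swap while a reversal is expected.
#'
#' The defaults are fixed a priori, not fitted: `beta = 0.25` equals the task
#' design's trigger hazard, and `alpha = 0.3` is calibrated so that the
#' expected-value traces of the full and reduced learners correlate at the
#' level this class of task produces (see the methods vignette and
#' [hmm_sensitivity_sweep()] for the sensitivity of that diagnostic to both
#' parameters).
#'
#' @param alpha Probability of the `H` 0 -> 1 transition per trial.
#' @param beta Probability of a state swap per trial while `H = 1`.
#' @param emit_deliver Probability that the presented cue's liquid is
#'   delivered (emission model; matches the schedule's reinforcement rate).
#' @param emit_none Probability of no delivery; must equal
#'   `1 - emit_deliver`.
#' @param reward_coding Named vector mapping delivered liquids to rewards;
#'   the valenced liquid is `+1` in appetitive sessions and `-1` in aversive
#'   sessions, the neutral liquid `0`.
#' @param precision_mode `"negentropy"` (default) or `"reciprocal"`; see
#'   [precision_from_posterior()].
#'
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(alpha = 0.3,
                       beta = 0.25,
                       emit_deliver = 0.6,
                       emit_none = 1 - emit_deliver,
                       reward_coding = c(valenced = 1, neutral = 0),
                       precision_mode = c("negentropy", "reciprocal")) {
  precision_mode <- match.arg(precision_mode)
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop("`alpha` and `beta` must be probabilities in [0, 1].", call. = FALSE)
  }
  if (abs(emit_deliver + emit_none - 1) > 1e-12) {
    stop("`emit_deliver` + `emit_none` must equal 1.", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta,
         emit_deliver = emit_deliver, emit_none = emit_none,
         reward_coding = reward_coding, precision_mode = precision_mode),
    class = "hmm_params"
  )
}

#' Transition matrix of the reversal-expectation node
#'
#' Rows index `H` at the previous trial, columns `H` at the current trial.
#' Entering the reversal-expectation state is absorbing: once a reversal is
#' expected there is no way back, so the (1 -> 0) entry is zero.
#'
#' @param alpha Probability of moving from `H = 0` to `H = 1`.
#' @return A 2x2 row-stochastic matrix with rows/columns named `"0"`, `"1"`.
#' @examples
#' h_transition_matrix(0.25)
#' @export
h_transition_matrix <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single probability in [0, 1].", call. = FALSE)
  }
  matrix(c(1 - alpha, alpha, 0, 1), 2, 2, byrow = TRUE,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Contingency-state transition matrix conditional on reversal expectation
#'
#' While no reversal is expected (`h = 0`) the contingency cannot change and
#' the matrix is the identity; while a reversal is expected (`h = 1`) the
#' cue-outcome mapping swaps with probability `beta` per trial.
#'
#' @param beta Swap probability under `h = 1`.
#' @param h Reversal-expectation value, 0 or 1.
#' @return A 2x2 row-stochastic matrix over the two contingency states.
#' @examples
#' s_transition_given_h(0.25, h = 1)
#' @export
s_transition_given_h <- function(beta, h) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1) {
    stop("`beta` must be a single probability in [0, 1].", call. = FALSE)
  }
  if (!h %in% c(0, 1)) stop("`h` must be 0 or 1.", call. = FALSE)
  if (h == 0) diag(2) else matrix(c(1 - beta, beta, beta, 1 - beta), 2, 2)
}

#' Emission likelihood of a cue-outcome observation
#'
#' Probability of the observed outcome given the contingency state and the
#' presented cue. If the state maps the presented cue to the valenced liquid,
#' a valenced delivery has probability `emit_deliver` (0.6 by default) and no
#' delivery `emit_none` (0.4); a neutral delivery is then impossible, and
#' symmetrically for a neutral mapping.
#'
#' @param state Contingency state: which cue (1 or 2) maps to the valenced
#'   liquid.
#' @param cue Presented cue, 1 or 2.
#' @param outcome `"valenced"`, `"neutral"` or `"none"`.
#' @param params An [hmm_params()].
#' @return A single probability.
#' @examples
#' emission_likelihood(1, 1, "none")       # 0.4
#' emission_likelihood(1, 1, "valenced")   # 0.6
#' emission_likelihood(1, 1, "neutral")    # 0
#' @export
emission_likelihood <- function(state, cue, outcome, params = hmm_params()) {
  maps_valenced <- state == cue
  switch(outcome,
         valenced = if (maps_valenced) params$emit_deliver else 0,
         neutral  = if (maps_valenced) 0 else params$emit_deliver,
         none     = params$emit_none,
         stop("unknown outcome '", outcome, "'.", call. = FALSE))
}

# Shared forward recursion for the full and reduced learners.
# clamp_h1 = TRUE pins the reversal-expectation node to H = 1 throughout
# (constant swap hazard beta), which removes the anticipatory growth of
# uncertainty between reversals.
hmm_forward <- function(session, params, clamp_h1, keep_joint = FALSE) {
  tr <- session$trials
  n <- nrow(tr)
  valence_sign <- if (session$config$session_valence == "aversive") {
    -abs(params$reward_coding[["valenced"]])
  } else {
    abs(params$reward_coding[["valenced"]])
  }
  TH <- h_transition_matrix(params$alpha)
  TSb <- s_transition_given_h(params$beta, 1)

  ev <- precision <- numeric(n)
  posterior_S <- filtered_S <- matrix(NA_real_, n, 2)
  joints <- if (keep_joint) vector("list", n) else NULL

  # joint[s, h]: columns h = 0, h = 1
  fresh <- if (clamp_h1) matrix(c(0, 0, 0.5, 0.5), 2)
           else matrix(c(0.5, 0.5, 0, 0), 2)
  joint <- fresh
  for (t in seq_len(n)) {
    if (tr$is_new_pair_onset[t]) {
      joint <- fresh
    } else {
      joint <- joint %*% TH            # H evolves first ...
      joint[, 2] <- TSb %*% joint[, 2] # ... then S swaps only under H = 1
      if (clamp_h1) joint[, 1] <- 0
    }
    pS <- rowSums(joint)
    posterior_S[t, ] <- pS
    ev[t] <- params$emit_deliver * valence_sign * pS[tr$cue[t]]
    precision[t] <- precision_from_posterior(pS, params$precision_mode)

    lik <- vapply(1:2, emission_likelihood,
                  numeric(1), cue = tr$cue[t], outcome = tr$outcome[t],
                  params = params)
    joint <- joint * lik
    total <- sum(joint)
    if (total <= 0) {
      stop("zero total likelihood at trial ", t,
           ": outcome '", tr$outcome[t], "' for cue ", tr$cue[t],
           " is impossible under every contingency state.", call. = FALSE)
    }
    joint <- joint / total
    filtered_S[t, ] <- rowSums(joint)
    if (keep_joint) joints[[t]] <- joint
  }
  out <- model_traces(model = if (clamp_h1) "ReducedHMM" else "HMM",
                      session = session, ev = ev, precision = precision,
                      posterior_S = posterior_S)
  out$filtered_S <- filtered_S
  if (keep_joint) out$joint <- joints
  out
}

#' Forward filter of the full hidden Markov learner
#'
#' Runs the Bayesian forward recursion over the joint belief on the
#' contingency state `S` and the reversal-expectation node `H`. On each
#' new-pair-onset trial the belief is reset to a uniform prior over `S` with
#' `H = 0`; on every later trial the belief is first propagated through the
#' `H` transition and the `H`-conditional `S` transition, then the predictive
#' expected value and precision are recorded at cue onset, and finally the
#' belief is conditioned on the observed cue-outcome combination and
#' renormalized.
#'
#' The expected value of the presented cue `j` is the predictive mean reward
#' `sum_S P(S) * emit_deliver * R(liquid of j under S)`, with the valenced
#' liquid coded `+1` (appetitive) or `-1` (aversive) and the neutral liquid
#' `0`; it is therefore bounded by `emit_deliver` in absolute value.
#'
#' @param session A `session_sequence`.
#' @param params An [hmm_params()].
#' @param keep_joint If `TRUE`, additionally store the per-trial joint
#'   posterior tables (for diagnostics).
#' @return A `model_traces` object with per-trial `ev`, `precision`,
#'   `posterior_S` (predictive, at cue onset) and `filtered_S`
#'   (post-outcome).
#' @seealso [reduced_hmm_filter()], [precision_from_posterior()]
#' @examples
#' sess <- generate_session(task_config(), seed = 1)
#' tra <- hmm_filter(sess)
#' range(tra$ev)
#' @export
hmm_filter <- function(session, params = hmm_params(), keep_joint = FALSE) {
  hmm_forward(session, params, clamp_h1 = FALSE, keep_joint = keep_joint)
}

#' Forward filter of the reduced (constant-hazard) learner
#'
#' Identical recursion to [hmm_filter()] with the reversal-expectation node
#' clamped to `H = 1`, so the chance of a contingency swap is a constant
#' `beta` per trial. The expected-value trace is nearly indistinguishable
#' from the full learner's, but the precision trace lacks the anticipatory
#' decline between reversals: uncertainty grows only after a reversal has
#' actually been experienced.
#'
#' @inheritParams hmm_filter
#' @return A `model_traces` object.
#' @export
reduced_hmm_filter <- function(session, params = hmm_params(),
                               keep_joint = FALSE) {
  hmm_forward(session, params, clamp_h1 = TRUE, keep_joint = keep_joint)
}

#' Precision of a posterior over contingency states
#'
#' A monotone-decreasing function of the Shannon entropy of the posterior:
#' maximal (1 in negentropy mode) at a point mass and minimal (0) at the
#' uniform distribution. The default normalized negentropy is
#' `1 - H(P) / log2(K)`; the literal reciprocal `1 / (H(P) + 1e-6)` is kept
#' behind the `"reciprocal"` mode (it diverges at point-mass posteriors,
#' which is why it is not the default).
#'
#' @param posterior_S Probability vector over states (need not be normalized
#'   to machine precision; a tolerance of 1e-8 is enforced).
#' @param mode `"negentropy"` or `"reciprocal"`.
#' @return A single non-negative scalar.
#' @examples
#' precision_from_posterior(c(0.5, 0.5))  # 0
#' precision_from_posterior(c(1, 0))      # 1
#' @export
precision_from_posterior <- function(posterior_S,
                                     mode = c("negentropy", "reciprocal")) {
  mode <- match.arg(mode)
  if (any(posterior_S < -1e-12) || abs(sum(posterior_S) - 1) > 1e-8) {
    stop("`posterior_S` must be a normalized probability vector.",
         call. = FALSE)
  }
  p <- pmax(posterior_S, 0)
  h <- -sum(ifelse(p > 0, p * log2(p), 0))
  if (mode == "negentropy") 1 - h / log2(length(p)) else 1 / (h + 1e-6)
}

#' Sensitivity of the full-vs-reduced EV correlation to alpha and beta
#'
#' For each (alpha, beta) combination, simulates sessions and reports the
#' mean Pearson correlation between the expected-value traces of the full
#' and reduced learners. Used to document how the a-priori transition
#' parameters shape this diagnostic.
#'
#' @param alphas,betas Numeric vectors of parameter values to cross.
#' @param n_sessions Sessions simulated per combination.
#' @param config A [task_config()].
#' @param seed Master seed.
#' @return A data frame with columns `alpha`, `beta`, `mean_r`.
#' @export
hmm_sensitivity_sweep <- function(alphas, betas, n_sessions = 19,
                                  config = task_config(), seed = 1L) {
  grid <- expand.grid(alpha = alphas, beta = betas)
  grid$mean_r <- mapply(function(a, b) {
    p <- hmm_params(alpha = a, beta = b)
    mean(vapply(seq_len(n_sessions), function(i) {
      sess <- generate_session(config, derive_seed(seed, 90L, i))
      trace_correlation(hmm_filter(sess, p)$ev,
                        reduced_hmm_filter(sess, p)$ev)
    }, numeric(1)))
  }, grid$alpha, grid$beta)
  grid
}
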