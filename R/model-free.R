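# model_traces: the common container for per-trial model output. All traces
# have one entry per session trial; fields that a model does not produce stay
# NULL.
model_traces <- function(model, session, ev,
                         precision = NULL, associability = NULL,
                         prediction_error = NULL, posterior_S = NULL) {
  structure(
    list(model = model, n = nrow(session$trials),
         session_valence = session$config$session_valence,
         ev = ev, precision = precision, associability = associability,
         prediction_error = prediction_error, posterior_S = posterior_S),
    class = "model_traces"
  )
}

#' @export
print.model_traces <- function(x, ...) {
  cat("model_traces: ", x$model, ", ", x$n, " trials (",
      x$session_valence, " session)\n", sep = "")
  cat("  ev in [", round(min(x$ev), 3), ", ", round(max(x$ev), 3), "]",
      if (!is.null(x$precision)) paste0(", precision in [",
        round(min(x$precision), 3), ", ", round(max(x$precision), 3), "]"),
      "\n", sep = "")
  invisible(x)
}

# reward coding shared by the model-free rules: 1 iff the valenced liquid was
# delivered, else 0 (salience coding in the aversive session as well).
model_free_reward <- function(outcome) as.numeric(outcome == "valenced")

#' Rescorla-Wagner learning rule
#'
#' Per presented cue `j`: `Q(j) <- Q(j) + alpha * (R - Q(j))`, with `R = 1`
#' iff the valenced liquid was delivered and 0 otherwise (in both sessions).
#' Values of cues not presented on a trial are unchanged; values reset to
#' `q_init` when a new cue pair is introduced. The recorded `ev` is the
#' pre-update value of the presented cue (the anticipatory prediction at cue
#' onset).
#'
#' @param session A `session_sequence`.
#' @param alpha Learning rate in \[0, 1\].
#' @param q_init Initial value for a fresh cue.
#' @return A `model_traces` object with `ev` and `prediction_error`.
#' @examples
#' rw_run(generate_session(task_config(), seed = 1), alpha = 0.5)
#' @export
rw_run <- function(session, alpha, q_init = 0) {
  if (alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1].", call. = FALSE)
  }
  tr <- session$trials
  n <- nrow(tr)
  ev <- pe <- numeric(n)
  Q <- c(q_init, q_init)
  for (t in seq_len(n)) {
    if (tr$is_new_pair_onset[t]) Q <- c(q_init, q_init)
    j <- tr$cue[t]
    R <- model_free_reward(tr$outcome[t])
    ev[t] <- Q[j]
    pe[t] <- R - Q[j]
    Q[j] <- Q[j] + alpha * (R - Q[j])
  }
  model_traces("RW", session, ev, prediction_error = pe)
}

#' Pearce-Hall learning rule
#'
#' Attention-weighted updating in which the associability of a cue tracks the
#' absolute prediction error of its previous presentation:
#' `assoc_t(j) = |R_prev(j) - Q_prev(j)|` (initialized at `assoc_init` for a
#' fresh cue) and `Q(j) <- Q(j) + s_intensity * assoc_t(j) * R`. With the
#' reinforcer entering multiplicatively, unreinforced trials leave the value
#' unchanged, and associability shrinks as outcomes become well predicted.
#'
#' @param session A `session_sequence`.
#' @param s_intensity CS-intensity parameter in \[0, 1\].
#' @param q_init Initial value for a fresh cue.
#' @param assoc_init Initial associability for a fresh cue.
#' @return A `model_traces` object with `ev`, `associability` (the value used
#'   on each trial for the presented cue) and `prediction_error`.
#' @export
ph_run <- function(session, s_intensity, q_init = 0, assoc_init = 1) {
  if (s_intensity < 0 || s_intensity > 1) {
    stop("`s_intensity` must lie in [0, 1].", call. = FALSE)
  }
  tr <- session$trials
  n <- nrow(tr)
  ev <- assoc <- pe <- numeric(n)
  Q <- c(q_init, q_init)
  last_R <- last_Q <- rep(NA_real_, 2)
  for (t in seq_len(n)) {
    if (tr$is_new_pair_onset[t]) {
      Q <- c(q_init, q_init)
      last_R <- last_Q <- rep(NA_real_, 2)
    }
    j <- tr$cue[t]
    R <- model_free_reward(tr$outcome[t])
    a <- if (is.na(last_R[j])) assoc_init else abs(last_R[j] - last_Q[j])
    ev[t] <- Q[j]
    assoc[t] <- a
    pe[t] <- R - Q[j]
    last_R[j] <- R
    last_Q[j] <- Q[j]
    Q[j] <- Q[j] + s_intensity * a * R
  }
  model_traces("PH", session, ev, associability = assoc,
               prediction_error = pe)
}

#' Hybrid Rescorla-Wagner / Pearce-Hall learning rule
#'
#' The value update follows the Rescorla-Wagner delta rule while the
#' effective learning rate is set by a Pearce-Hall associability that decays
#' toward recent absolute prediction errors: per presented cue `j`,
#' `delta = R - Q(j)`, `Q(j) <- Q(j) + kappa * assoc(j) * delta`,
#' `assoc(j) <- eta * |delta| + (1 - eta) * assoc(j)`.
#'
#' @param session A `session_sequence`.
#' @param eta Associability decay/update weight in \[0, 1\] (the searched
#'   parameter).
#' @param kappa Fixed scale of the learning rate (default 1).
#' @param q_init,assoc_init Initial value and associability for a fresh cue.
#' @return A `model_traces` object with `ev`, `associability` and
#'   `prediction_error`.
#' @export
hybrid_run <- function(session, eta, kappa = 1, q_init = 0, assoc_init = 1) {
  if (eta < 0 || eta > 1) stop("`eta` must lie in [0, 1].", call. = FALSE)
  if (kappa <= 0) stop("`kappa` must be > 0.", call. = FALSE)
  tr <- session$trials
  n <- nrow(tr)
  ev <- assoc <- pe <- numeric(n)
  Q <- c(q_init, q_init)
  A <- c(assoc_init, assoc_init)
  for (t in seq_len(n)) {
    if (tr$is_new_pair_onset[t]) {
      Q <- c(q_init, q_init)
      A <- c(assoc_init, assoc_init)
    }
    j <- tr$cue[t]
    R <- model_free_reward(tr$outcome[t])
    ev[t] <- Q[j]
    assoc[t] <- A[j]
    delta <- R - Q[j]
    pe[t] <- delta
    Q[j] <- Q[j] + kappa * A[j] * delta
    A[j] <- eta * abs(delta) + (1 - eta) * A[j]
  }
  model_traces("Hybrid", session, ev, associability = assoc,
               prediction_error = pe)
}

#' Constant-value baseline model
#'
#' Assumes outcomes occur completely at random and no learning takes place:
#' the expected value is a constant 0.5 on every trial. For regression-based
#' fitting a variant with small seeded Gaussian jitter is available (a
#' constant regressor would make the fit singular).
#'
#' @param session A `session_sequence`.
#' @param baseline_value The constant expected value.
#' @param jitter_sd Standard deviation of the Gaussian jitter; 0 gives the
#'   exact constant trace.
#' @param seed Integer seed for the jitter.
#' @return A `model_traces` object with `ev` only.
#' @examples
#' unique(baseline_run(generate_session(task_config(), seed = 1))$ev)  # 0.5
#' @export
baseline_run <- function(session, baseline_value = 0.5, jitter_sd = 0,
                         seed = 1L) {
  n <- nrow(session$trials)
  ev <- rep(baseline_value, n)
  if (jitter_sd > 0) {
    set.seed(as.integer(seed %% 2147483647))
    ev <- ev + stats::rnorm(n, 0, jitter_sd)
  }
  model_traces("Baseline", session, ev)
}
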