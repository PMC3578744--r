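#' Task configuration for a Pavlovian serial-reversal session
#'
#' Describes the probabilistic reward schedule of one conditioning session:
#' paired cue presentations with probabilistic liquid delivery, a minimum
#' block length per contingency phase, and a per-trial trigger hazard that
#' fires either a reversal of the cue-outcome mapping or the introduction of
#' a new cue pair.
#'
#' @param n_trials_per_session Number of trials in a fixed-length session.
#' @param reinforce_prob Probability that the presented cue's liquid is
#'   actually delivered on a trial (otherwise no liquid is given).
#' @param min_block Minimum number of trials in each contingency phase before
#'   the reversal / new-pair trigger becomes active.
#' @param trigger_hazard Per-trial probability, once the minimum block is
#'   complete, that the phase terminates (the next trial starts a reversal or
#'   a new cue pair).
#' @param n_pairs Number of distinct cue pairs per session; each pair has one
#'   acquisition phase and one reversal phase.
#' @param neutral_per_window Presentations of the currently neutral cue
#'   required in every non-overlapping 4-trial window.
#' @param iti_range_s Inter-trial interval range in seconds (uniform draw).
#' @param fixed_length If `TRUE`, phase extensions are redrawn until the
#'   session is exactly `n_trials_per_session` trials long; if `FALSE` the
#'   session runs open-ended until all `2 * n_pairs` phases complete.
#' @param session_valence `"appetitive"` or `"aversive"`; decides whether the
#'   valenced liquid is pleasant or unpleasant (and hence the sign of the
#'   hidden-Markov-model expected value).
#'
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$n_trials_per_session
#' @export
task_config <- function(n_trials_per_session = 120L,
                        reinforce_prob = 0.6,
                        min_block = 16L,
                        trigger_hazard = 0.25,
                        n_pairs = 3L,
                        neutral_per_window = 2L,
                        iti_range_s = c(2, 11),
                        fixed_length = TRUE,
                        session_valence = c("appetitive", "aversive")) {
  session_valence <- match.arg(session_valence)
  cfg <- list(
    n_trials_per_session = as.integer(n_trials_per_session),
    reinforce_prob = reinforce_prob,
    min_block = as.integer(min_block),
    trigger_hazard = trigger_hazard,
    n_pairs = as.integer(n_pairs),
    neutral_per_window = as.integer(neutral_per_window),
    iti_range_s = as.numeric(iti_range_s),
    fixed_length = isTRUE(fixed_length),
    session_valence = session_valence
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$reinforce_prob < 0 || cfg$reinforce_prob > 1) {
    stop("`reinforce_prob` must be a probability in [0, 1].", call. = FALSE)
  }
  if (cfg$trigger_hazard < 0 || cfg$trigger_hazard > 1) {
    stop("`trigger_hazard` must be a probability in [0, 1].", call. = FALSE)
  }
  if (cfg$n_pairs < 1L || cfg$min_block < 1L || cfg$n_trials_per_session < 1L) {
    stop("counts in a task_config must be positive.", call. = FALSE)
  }
  if (length(cfg$iti_range_s) != 2L || diff(cfg$iti_range_s) < 0) {
    stop("`iti_range_s` must be an increasing pair of seconds.", call. = FALSE)
  }
  if (cfg$fixed_length &&
      cfg$min_block * 2L * cfg$n_pairs > cfg$n_trials_per_session) {
    stop("infeasible task_config: the trial budget (",
         cfg$n_trials_per_session, ") is smaller than 2 * n_pairs * min_block (",
         2L * cfg$n_pairs * cfg$min_block, ").", call. = FALSE)
  }
  if (cfg$fixed_length && cfg$trigger_hazard <= 0) {
    stop("fixed-length sessions need `trigger_hazard` > 0.", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Pavlovian task configuration (", x$session_valence, " session)\n", sep = "")
  cat("  trials: ", x$n_trials_per_session,
      if (x$fixed_length) " (fixed length)" else " (open-ended)", "\n", sep = "")
  cat("  reinforcement p = ", x$reinforce_prob,
      ", min block = ", x$min_block,
      ", trigger hazard = ", x$trigger_hazard, "\n", sep = "")
  cat("  ", x$n_pairs, " cue pairs, ", x$neutral_per_window,
      " neutral presentations per 4-trial window\n", sep = "")
  invisible(x)
}

#' Reaction-time generator configuration
#'
#' Parameters of the synthetic reaction-time model. Log RTs are linear in the
#' generating model's expected value, with an additive linear trend over
#' trials, a side-switch cost, and Gaussian noise:
#' `log RT_t = intercept + trend * t + switch_effect * switch_t +
#' ev_weight * EV_t + noise`. This mirrors the structure removed by
#' [adjust_rts()] before model fitting, plus the EV signal the fit recovers.
#'
#' The default `ev_weight` is negative: responses speed up as a stronger
#' outcome prediction (more positive appetitive EV, or less negative aversive
#' EV) is associated with the presented cue.
#'
#' @param intercept Baseline log RT (log seconds); `exp(intercept)` is the
#'   typical RT.
#' @param trend_per_trial Linear drift in log RT per trial.
#' @param switch_effect Additive log-RT cost when the cue side differs from
#'   the previous trial.
#' @param ev_weight Log-RT change per unit of model expected value.
#' @param noise_sd Standard deviation of the Gaussian noise on log RT
#'   (must be > 0).
#' @param generating_model Name of the learning model whose EV trace drives
#'   the RTs (bookkeeping only; the trace itself is passed to
#'   [simulate_rts()]).
#' @param generating_params Named list of the generating model's parameters
#'   (bookkeeping only).
#'
#' @return An object of class `rt_config`.
#' @export
rt_config <- function(intercept = log(0.5),
                      trend_per_trial = -0.001,
                      switch_effect = 0.05,
                      ev_weight = -0.2,
                      noise_sd = 0.1,
                      generating_model = "HMM",
                      generating_params = list()) {
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be > 0 (use a tiny value for near-deterministic RTs).",
         call. = FALSE)
  }
  structure(
    list(intercept = intercept,
         trend_per_trial = trend_per_trial,
         switch_effect = switch_effect,
         ev_weight = ev_weight,
         noise_sd = noise_sd,
         generating_model = generating_model,
         generating_params = generating_params),
    class = "rt_config"
  )
}

# Deterministic sub-stream seeds below 2^31, derived from one master seed.
# stream/index are small non-negative integers (subject number, session slot,
# repetition counter ...).
derive_seed <- function(master_seed, stream, index = 0L) {
  (as.double(master_seed) * 48271 + stream * 100003 + index * 1009) %% 2147483647
}
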