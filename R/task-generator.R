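#' Generate one Pavlovian serial-reversal session
#'
#' Builds the trial sequence of a single conditioning session under the
#' probabilistic reward schedule described by a [task_config()]: `n_pairs` cue
#' pairs are introduced in turn, each undergoing one reversal; every
#' contingency phase lasts at least `min_block` trials and then terminates
#' with per-trial probability `trigger_hazard` (a geometric extension). In
#' fixed-length mode the six phase extensions are redrawn (rejection
#' sampling) until the session totals exactly `n_trials_per_session` trials,
#' so that every seed yields a complete session with all reversals observed.
#'
#' Within every non-overlapping 4-trial window, the currently neutral cue is
#' presented exactly `neutral_per_window` times (slots are shuffled within
#' the window). The presented cue's liquid is delivered with probability
#' `reinforce_prob`, otherwise no liquid is given. Sides are assigned
#' uniformly at random and inter-trial intervals uniformly over
#' `iti_range_s`.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the same seed reproduces the session exactly.
#'
#' @return An object of class `session_sequence`: a list with elements
#'   `config`, `seed` and `trials`, the latter a data frame with one row per
#'   trial and columns `trial` (1-based), `phase` (0-5, alternating
#'   acquisition/reversal per pair), `pair`, `cue` (1 or 2 within the pair),
#'   `side`, `outcome` (`"valenced"`, `"neutral"` or `"none"`),
#'   `latent_state` (which cue currently maps to the valenced liquid),
#'   `is_reversal_onset`, `is_new_pair_onset` and `iti_s`.
#' @seealso [generate_cohort()], [validate_session()]
#' @examples
#' sess <- generate_session(task_config(), seed = 1)
#' nrow(sess$trials)                      # 120
#' sum(sess$trials$is_reversal_onset)     # 3
#' @export
generate_session <- function(config = task_config(), seed = 1L) {
  validate_task_config(config)
  set.seed(as.integer(seed %% 2147483647))
  n_phases <- 2L * config$n_pairs

  # Phase lengths: min_block plus a geometric(hazard) extension on {1, 2, ...}.
  # In fixed-length mode, redraw until the extensions make the budget exactly.
  draw_ext <- function() {
    if (config$trigger_hazard >= 1) rep(1L, n_phases)
    else stats::rgeom(n_phases, config$trigger_hazard) + 1L
  }
  target_ext <- config$n_trials_per_session - n_phases * config$min_block
  if (config$fixed_length) {
    if (config$trigger_hazard >= 1 && target_ext != n_phases) {
      stop("fixed-length session is infeasible at trigger_hazard = 1.",
           call. = FALSE)
    }
    attempts <- 0L
    repeat {
      ext <- draw_ext()
      if (sum(ext) == target_ext) break
      attempts <- attempts + 1L
      if (attempts > 1e5) {
        stop("could not realize a fixed-length session in 1e5 draws: the ",
             "trial budget is too far from the expected total phase length (",
             n_phases * (config$min_block + 1 / config$trigger_hazard),
             " trials). Adjust the budget or use fixed_length = FALSE.",
             call. = FALSE)
      }
    }
  } else {
    ext <- draw_ext()
  }
  phase_len <- config$min_block + ext

  phase <- rep.int(seq_len(n_phases) - 1L, phase_len)
  n <- length(phase)
  pair <- phase %/% 2L + 1L
  in_reversal <- phase %% 2L == 1L
  # Cue 1 carries the valenced liquid during acquisition, cue 2 after reversal.
  latent_state <- ifelse(in_reversal, 2L, 1L)

  # Valenced/neutral slots, shuffled within aligned non-overlapping 4-trial
  # windows so the neutral cue appears exactly neutral_per_window times each.
  window <- 4L
  slot <- integer(n)
  i <- 1L
  while (i <= n) {
    w <- min(window, n - i + 1L)
    base <- c(rep(1L, window - config$neutral_per_window),
              rep(0L, config$neutral_per_window))
    slot[i:(i + w - 1L)] <- sample(base)[seq_len(w)]
    i <- i + w
  }
  cue <- ifelse(slot == 1L, latent_state, 3L - latent_state)

  delivered <- stats::runif(n) < config$reinforce_prob
  outcome <- ifelse(delivered, ifelse(slot == 1L, "valenced", "neutral"), "none")

  is_new_pair <- c(TRUE, diff(pair) != 0L)
  is_reversal <- c(FALSE, diff(phase) != 0L) & in_reversal

  trials <- data.frame(
    trial = seq_len(n),
    phase = phase,
    pair = pair,
    cue = as.integer(cue),
    side = sample(c("left", "right"), n, replace = TRUE),
    outcome = outcome,
    latent_state = latent_state,
    is_reversal_onset = is_reversal,
    is_new_pair_onset = is_new_pair,
    iti_s = stats::runif(n, config$iti_range_s[1], config$iti_range_s[2]),
    stringsAsFactors = FALSE
  )
  structure(list(config = config, seed = as.integer(seed), trials = trials),
            class = "session_sequence")
}

#' @export
print.session_sequence <- function(x, ...) {
  cat("session_sequence: ", nrow(x$trials), " trials, ",
      x$config$session_valence, " session, seed ", x$seed, "\n", sep = "")
  cat("  ", sum(x$trials$is_new_pair_onset), " cue pairs, ",
      sum(x$trials$is_reversal_onset), " reversals, ",
      round(mean(x$trials$outcome != "none"), 3),
      " of trials reinforced\n", sep = "")
  invisible(x)
}

#' Generate a counterbalanced cohort of subjects
#'
#' One appetitive and one aversive session per subject, with independent
#' per-session seeds derived deterministically from the master seed. Session
#' order alternates across subjects (odd-numbered subjects appetitive-first),
#' mirroring counterbalancing across a cohort.
#'
#' @param config A [task_config()]; its `session_valence` is overridden per
#'   session.
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Master integer seed.
#'
#' @return A list of class `cohort`; each element is a list with `subject`,
#'   `order` (session order as run) and the two `session_sequence` objects
#'   `appetitive` and `aversive`.
#' @examples
#' coh <- generate_cohort(task_config(), n_subjects = 2, seed = 11)
#' coh[[1]]$order
#' @export
generate_cohort <- function(config = task_config(), n_subjects, seed = 1L) {
  if (n_subjects < 1) {
    stop("`n_subjects` must be >= 1.", call. = FALSE)
  }
  subjects <- lapply(seq_len(n_subjects), function(s) {
    app_cfg <- config; app_cfg$session_valence <- "appetitive"
    ave_cfg <- config; ave_cfg$session_valence <- "aversive"
    app <- generate_session(app_cfg, derive_seed(seed, s, 1L))
    ave <- generate_session(ave_cfg, derive_seed(seed, s, 2L))
    order <- if (s %% 2L == 1L) c("appetitive", "aversive")
             else c("aversive", "appetitive")
    list(subject = s, order = order, appetitive = app, aversive = ave)
  })
  structure(subjects, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort of ", length(x), " subjects, 2 sessions each (",
    2L * length(x), " sessions)\n", sep = "")
  invisible(x)
}

#' Simulate reaction times from a model expected-value trace
#'
#' Draws per-trial reaction times whose log is linear in the supplied
#' expected-value trace plus a temporal trend, a side-switch cost, and
#' Gaussian noise (see [rt_config()]). RTs are strictly positive by
#' construction (log-normal noise model, matching the log transform applied
#' before fitting).
#'
#' @param session A `session_sequence` (provides trial count and sides).
#' @param ev_trace Numeric vector of per-trial expected values, one per trial.
#' @param config An [rt_config()].
#' @param seed Integer seed.
#'
#' @return Numeric vector of RTs in seconds.
#' @examples
#' sess <- generate_session(task_config(), seed = 1)
#' ev <- hmm_filter(sess)$ev
#' rt <- simulate_rts(sess, ev, rt_config(), seed = 2)
#' @export
simulate_rts <- function(session, ev_trace, config = rt_config(), seed = 1L) {
  n <- nrow(session$trials)
  if (length(ev_trace) != n) {
    stop("`ev_trace` has length ", length(ev_trace),
         " but the session has ", n, " trials.", call. = FALSE)
  }
  set.seed(as.integer(seed %% 2147483647))
  sides <- session$trials$side
  switch_t <- c(0, as.integer(sides[-1] != sides[-n]))
  log_rt <- config$intercept +
    config$trend_per_trial * seq_len(n) +
    config$switch_effect * switch_t +
    config$ev_weight * ev_trace +
    stats::rnorm(n, 0, config$noise_sd)
  exp(log_rt)
}

#' Empirical per-trial trigger hazard of a set of sessions
#'
#' Estimates the per-trial probability that a contingency phase terminates
#' once its minimum block is complete. Every trial beyond a phase's minimum
#' block is an at-risk trial; the phase's final trial is the one on which the
#' termination event fired. The pooled estimate is the number of completed
#' phases divided by the number of at-risk trials. Meaningful in
#' unconstrained-length mode; in fixed-length mode the rejection sampling
#' biases the empirical hazard (which is why both modes exist).
#'
#' @param sessions A list of `session_sequence` objects (or a single one).
#' @return A list with `hazard`, `n_events` and `n_at_risk`.
#' @export
empirical_trigger_hazard <- function(sessions) {
  if (inherits(sessions, "session_sequence")) sessions <- list(sessions)
  events <- at_risk <- 0L
  for (sess in sessions) {
    len <- as.integer(table(sess$trials$phase))
    events <- events + length(len)
    at_risk <- at_risk + sum(len - sess$config$min_block)
  }
  list(hazard = events / at_risk, n_events = events, n_at_risk = at_risk)
}

#' Validate a session against the task-protocol invariants
#'
#' Checks a `session_sequence` (generated or externally supplied) against the
#' schedule invariants: trial and reversal counts in fixed-length mode,
#' minimum phase length, neutral-cue balance in every complete 4-trial
#' window, consistency of outcomes with the latent contingency state, and
#' latent-state changes occurring exactly at reversal onsets.
#'
#' @param session A `session_sequence`.
#' @return A list with `violations` (character vector, empty when all
#'   invariants hold) and `reinforcement_rate` (fraction of trials on which a
#'   liquid was delivered).
#' @examples
#' validate_session(generate_session(task_config(), seed = 3))$violations
#' @export
validate_session <- function(session) {
  cfg <- session$config
  tr <- session$trials
  n <- nrow(tr)
  bad <- character(0)

  if (cfg$fixed_length && n != cfg$n_trials_per_session) {
    bad <- c(bad, sprintf("trial count %d != %d", n, cfg$n_trials_per_session))
  }
  if (cfg$fixed_length && sum(tr$is_reversal_onset) != cfg$n_pairs) {
    bad <- c(bad, sprintf("reversal-onset count %d != %d",
                          sum(tr$is_reversal_onset), cfg$n_pairs))
  }
  phase_len <- table(tr$phase)
  if (any(phase_len < cfg$min_block)) {
    bad <- c(bad, "phase shorter than min_block")
  }
  # neutral balance over complete aligned windows
  neutral <- tr$cue != tr$latent_state
  full_windows <- n %/% 4L
  if (full_windows > 0L) {
    counts <- tapply(neutral[seq_len(4L * full_windows)],
                     rep(seq_len(full_windows), each = 4L), sum)
    if (any(counts != cfg$neutral_per_window)) {
      bad <- c(bad, "neutral-cue balance violated in a 4-trial window")
    }
  }
  # outcome consistency with the latent mapping
  valenced_cue <- tr$cue == tr$latent_state
  if (any(tr$outcome == "valenced" & !valenced_cue) ||
      any(tr$outcome == "neutral" & valenced_cue)) {
    bad <- c(bad, "outcome inconsistent with latent contingency state")
  }
  # latent state changes exactly at reversal onsets
  changes <- c(FALSE, diff(tr$latent_state) != 0L) & !tr$is_new_pair_onset
  if (!identical(changes, tr$is_reversal_onset & !tr$is_new_pair_onset) ||
      any(tr$is_reversal_onset & tr$is_new_pair_onset)) {
    bad <- c(bad, "latent-state changes do not match reversal onsets")
  }
  list(violations = bad, reinforcement_rate = mean(tr$outcome != "none"))
}
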