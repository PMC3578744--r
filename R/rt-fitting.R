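#' Adjust reaction times for trend and side-switching
#'
#' Log-transforms the RTs and regresses them on an intercept, a linear trial
#' trend, and an indicator of whether the response side switched relative to
#' the previous trial. The residuals of this regression are the adjusted RTs
#' that the learning-model fits try to explain. Missing RTs (trials with no
#' button press) are dropped listwise; the retained trial indices are
#' returned so model EV traces can be aligned.
#'
#' @param rts Per-trial reaction times in seconds (`NA` for missing).
#' @param sides Per-trial cue sides, `"left"` / `"right"`.
#' @return A list of class `adjusted_rts` with `residuals`, `used` (1-based
#'   indices of retained trials), `n` (number used) and `coefficients` of the
#'   nuisance regression.
#' @examples
#' sess <- generate_session(task_config(), seed = 1)
#' rt <- simulate_rts(sess, hmm_filter(sess)$ev, rt_config(), seed = 2)
#' adj <- adjust_rts(rt, sess$trials$side)
#' length(adj$residuals)
#' @export
adjust_rts <- function(rts, sides) {
  if (length(rts) != length(sides)) {
    stop("`rts` and `sides` must have equal length.", call. = FALSE)
  }
  n_all <- length(rts)
  if (any(rts[!is.na(rts)] <= 0)) {
    stop("reaction times must be strictly positive.", call. = FALSE)
  }
  switch_t <- c(0, as.integer(sides[-1] != sides[-n_all]))
  used <- which(!is.na(rts))
  if (length(used) < 4L) {
    stop("fewer than 4 usable trials; cannot adjust reaction times.",
         call. = FALSE)
  }
  y <- log(rts[used])
  X <- cbind(intercept = 1, trend = used, switch = switch_t[used])
  qr_X <- qr(X)
  structure(
    list(residuals = unname(qr.resid(qr_X, y)), used = used,
         n = length(used), coefficients = unname(qr.coef(qr_X, y)),
         nuisance_qr = qr_X),
    class = "adjusted_rts"
  )
}

# EV trace of a named model on a session; `param` is the model's single free
# parameter where it has one. Returns the per-trial EV vector.
model_ev <- function(model, session, param = NULL,
                     hmm = hmm_params(), baseline_jitter_sd = 0.01,
                     seed = 1L) {
  switch(model,
    HMM        = hmm_filter(session, hmm)$ev,
    ReducedHMM = reduced_hmm_filter(session, hmm)$ev,
    RW         = rw_run(session, alpha = param)$ev,
    PH         = ph_run(session, s_intensity = param)$ev,
    Hybrid     = hybrid_run(session, eta = param)$ev,
    Baseline   = baseline_run(session, jitter_sd = baseline_jitter_sd,
                              seed = seed)$ev,
    stop("unknown model '", model, "'.", call. = FALSE))
}

# SSE of the regression adjusted ~ intercept + ev, computed in closed form.
# The EV regressor is first residualized against the same nuisance design
# (intercept, trend, switch) that adjusted the RTs, so the two-step fit
# equals the joint regression on [nuisance, EV] (Frisch-Waugh); without this
# the nuisance columns absorb part of the EV signal and parameter recovery
# is biased. A zero-variance EV trace returns NA so callers can react.
regression_sse <- function(resid, ev, nuisance_qr = NULL) {
  if (!is.null(nuisance_qr)) ev <- qr.resid(nuisance_qr, ev)
  see <- sum((ev - mean(ev))^2)
  if (see < 1e-14) return(NA_real_)
  r <- resid - mean(resid)
  sum(r^2) - sum((ev - mean(ev)) * r)^2 / see
}

#' Fit one learning model to adjusted reaction times
#'
#' Regresses the adjusted log-RT residuals on an intercept plus the model's
#' trial-by-trial expected values. For the models with a free parameter (RW
#' learning rate, PH and Hybrid CS intensity) the parameter is searched over
#' the grid `seq(0, 1, by = grid_step)` and the value with the minimal sum of
#' squared errors (SSE) is retained; the hidden-Markov learners (parameters
#' fixed a priori) and the baseline need a single regression. The baseline
#' uses its seeded jittered trace, since a constant regressor would be
#' singular.
#'
#' The SSE is converted to a Bayesian information criterion with
#' [compute_bic()], counting only the learning model's free parameters
#' (`k = 1` for RW/PH/Hybrid, `k = 0` otherwise).
#'
#' @param adjusted An `adjusted_rts` object from [adjust_rts()].
#' @param model One of `"HMM"`, `"ReducedHMM"`, `"RW"`, `"PH"`, `"Hybrid"`,
#'   `"Baseline"`.
#' @param session The `session_sequence` the RTs came from.
#' @param grid_step Grid increment for the free-parameter search; must divide
#'   1 evenly.
#' @param hmm [hmm_params()] used by the hidden-Markov learners.
#' @param baseline_jitter_sd Jitter SD for the baseline trace.
#' @param seed Seed for the baseline jitter.
#' @return A one-row data frame of class `fit_result` with columns `model`,
#'   `best_param` (`NA` where there is no free parameter), `sse`, `n`, `k`
#'   and `bic`.
#' @examples
#' sess <- generate_session(task_config(), seed = 1)
#' rt <- simulate_rts(sess, rw_run(sess, 0.3)$ev,
#'                    rt_config(noise_sd = 1e-5, ev_weight = -1), seed = 2)
#' adj <- adjust_rts(rt, sess$trials$side)
#' fit_model_to_rts(adj, "RW", sess, grid_step = 0.01)$best_param
#' @export
fit_model_to_rts <- function(adjusted, model, session, grid_step = 0.001,
                             hmm = hmm_params(), baseline_jitter_sd = 0.01,
                             seed = 1L) {
  stopifnot(inherits(adjusted, "adjusted_rts"))
  has_param <- model %in% c("RW", "PH", "Hybrid")
  resid <- adjusted$residuals
  used <- adjusted$used

  if (has_param) {
    steps <- 1 / grid_step
    if (abs(steps - round(steps)) > 1e-9) {
      stop("`grid_step` must divide 1 evenly.", call. = FALSE)
    }
    grid <- seq(0, 1, by = grid_step)
    sses <- vapply(grid, function(p) {
      regression_sse(resid, model_ev(model, session, p)[used],
                     adjusted$nuisance_qr)
    }, numeric(1))
    # zero-variance traces (e.g. a learning rate of exactly 0) cannot beat
    # any informative grid point; score them as the intercept-only SSE
    sses[is.na(sses)] <- sum((resid - mean(resid))^2)
    best <- which.min(sses)
    best_param <- grid[best]
    sse <- sses[best]
    k <- 1L
  } else {
    ev <- model_ev(model, session, hmm = hmm,
                   baseline_jitter_sd = baseline_jitter_sd, seed = seed)[used]
    sse <- regression_sse(resid, ev, adjusted$nuisance_qr)
    if (is.na(sse)) {
      stop("degenerate (zero-variance) EV trace for model '", model,
           "'; cannot regress. For the baseline use a positive jitter sd.",
           call. = FALSE)
    }
    best_param <- NA_real_
    k <- 0L
  }
  out <- data.frame(model = model, best_param = best_param, sse = sse,
                    n = adjusted$n, k = k,
                    bic = compute_bic(sse, adjusted$n, k),
                    stringsAsFactors = FALSE)
  class(out) <- c("fit_result", class(out))
  out
}

#' Bayesian information criterion for a Gaussian-residual fit
#'
#' `BIC = n * ln(sse / n) + k * ln(n)`, the Gaussian-residual form in which
#' the penalty is proportional to the number of free parameters; lower is
#' better. `-BIC / 2` is used downstream as an approximate log model
#' evidence.
#'
#' @param sse Sum of squared errors (> 0).
#' @param n Number of observations.
#' @param k Number of free parameters (`n > k >= 0`).
#' @return A single BIC value.
#' @examples
#' compute_bic(100, 100, 1)  # log(100)
#' @export
compute_bic <- function(sse, n, k) {
  if (sse <= 0) {
    stop("`sse` must be > 0; an exactly zero SSE indicates a degenerate fit.",
         call. = FALSE)
  }
  if (n <= k || k < 0) stop("need n > k >= 0.", call. = FALSE)
  n * log(sse / n) + k * log(n)
}

#' Fit a set of models to every subject and session of a cohort
#'
#' Runs [adjust_rts()] and [fit_model_to_rts()] over a cohort whose sessions
#' carry an `rt_s` column in their trial tables. In `"subject"` mode each
#' subject x session x model combination is fitted separately, yielding the
#' subject-level evidences used by random-effects model selection. In
#' `"pooled"` mode the adjusted residuals of all subjects are concatenated
#' per session type and a single grid search is run, so `n` is the total
#' number of trials per session across all subjects.
#'
#' Subjects whose usable-response fraction falls below `1 - max_missing` in
#' either session are excluded (listwise), mirroring the exclusion of
#' non-responders.
#'
#' @param cohort A `cohort` whose sessions have `trials$rt_s`.
#' @param models Character vector of model names (see [fit_model_to_rts()]).
#' @param grid_step Grid increment for the free-parameter search.
#' @param mode `"subject"` or `"pooled"`.
#' @param hmm [hmm_params()] for the hidden-Markov learners.
#' @param baseline_jitter_sd Jitter SD for the baseline trace.
#' @param seed Master seed (baseline jitter streams are derived from it).
#' @param max_missing Maximum tolerated fraction of missing responses per
#'   session before a subject is dropped.
#' @return A data frame with one row per fit: columns `subject` (`NA` in
#'   pooled mode), `session`, `model`, `best_param`, `sse`, `n`, `k`, `bic`.
#' @export
fit_sessions <- function(cohort,
                         models = c("HMM", "RW", "PH", "Hybrid", "Baseline"),
                         grid_step = 0.001,
                         mode = c("subject", "pooled"),
                         hmm = hmm_params(), baseline_jitter_sd = 0.01,
                         seed = 1L, max_missing = 0.5) {
  mode <- match.arg(mode)
  keep <- vapply(cohort, function(sub) {
    all(vapply(c("appetitive", "aversive"), function(v) {
      rt <- sub[[v]]$trials$rt_s
      mean(is.na(rt)) <= max_missing
    }, logical(1)))
  }, logical(1))
  cohort <- cohort[keep]
  if (length(cohort) == 0L) {
    stop("no subjects left after the missing-response exclusion.",
         call. = FALSE)
  }

  if (mode == "subject") {
    rows <- lapply(cohort, function(sub) {
      do.call(rbind, lapply(c("appetitive", "aversive"), function(v) {
        sess <- sub[[v]]
        adj <- adjust_rts(sess$trials$rt_s, sess$trials$side)
        do.call(rbind, lapply(models, function(m) {
          f <- fit_model_to_rts(adj, m, sess, grid_step, hmm,
                                baseline_jitter_sd,
                                seed = derive_seed(seed, sub$subject,
                                                   match(v, c("appetitive",
                                                              "aversive"))))
          cbind(data.frame(subject = sub$subject, session = v,
                           stringsAsFactors = FALSE), f)
        }))
      }))
    })
    out <- do.call(rbind, rows)
  } else {
    out <- do.call(rbind, lapply(c("appetitive", "aversive"), function(v) {
      adjs <- lapply(cohort, function(sub) {
        sess <- sub[[v]]
        adjust_rts(sess$trials$rt_s, sess$trials$side)
      })
      resid_all <- unlist(lapply(adjs, `[[`, "residuals"))
      n_all <- length(resid_all)
      ev_all <- function(m, p, s) {
        unlist(lapply(seq_along(cohort), function(i) {
          ev <- model_ev(m, cohort[[i]][[v]], p, hmm, baseline_jitter_sd,
                         seed = derive_seed(s, i, match(v, c("appetitive",
                                                             "aversive"))))[
            adjs[[i]]$used]
          qr.resid(adjs[[i]]$nuisance_qr, ev)
        }))
      }
      do.call(rbind, lapply(models, function(m) {
        if (m %in% c("RW", "PH", "Hybrid")) {
          grid <- seq(0, 1, by = grid_step)
          sses <- vapply(grid, function(p) {
            regression_sse(resid_all, ev_all(m, p, seed))
          }, numeric(1))
          sses[is.na(sses)] <- sum((resid_all - mean(resid_all))^2)
          best <- which.min(sses)
          best_param <- grid[best]; sse <- sses[best]; k <- 1L
        } else {
          sse <- regression_sse(resid_all, ev_all(m, NULL, seed))
          if (is.na(sse)) {
            stop("degenerate (zero-variance) EV trace for model '", m, "'.",
                 call. = FALSE)
          }
          best_param <- NA_real_; k <- 0L
        }
        data.frame(subject = NA_integer_, session = v, model = m,
                   best_param = best_param, sse = sse, n = n_all, k = k,
                   bic = compute_bic(sse, n_all, k),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  rownames(out) <- NULL
  out
}
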