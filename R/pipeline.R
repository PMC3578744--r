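# Flat data-frame views of cohort objects, and the CSV/JSON artifact writers
# used by run_pipeline(). Headers follow the artifact contracts exactly:
# sessions.csv: subject, session, trial, phase, pair, cue, side, outcome,
#               latent_state, reversal_onset, new_pair_onset, iti_s, rt_s
# traces.csv:   subject, session, trial, model, ev, precision, associability,
#               prediction_error
# fits.csv:     subject, session, model, best_param, sse, n, k, bic

#' Flatten a cohort to a sessions table
#'
#' @param cohort A `cohort` (sessions may or may not carry `rt_s`).
#' @return A data frame in the `sessions.csv` layout, trials numbered from 1.
#' @export
sessions_table <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(sub) {
    do.call(rbind, lapply(c("appetitive", "aversive"), function(v) {
      tr <- sub[[v]]$trials
      data.frame(subject = sub$subject, session = v, trial = tr$trial,
                 phase = tr$phase, pair = tr$pair, cue = tr$cue,
                 side = tr$side, outcome = tr$outcome,
                 latent_state = tr$latent_state,
                 reversal_onset = tr$is_reversal_onset,
                 new_pair_onset = tr$is_new_pair_onset,
                 iti_s = tr$iti_s,
                 rt_s = if (is.null(tr$rt_s)) NA_real_ else tr$rt_s,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Write / read the sessions artifact
#'
#' @param x A sessions table (or `cohort`, which is flattened first).
#' @param path File path of the CSV.
#' @return `read_sessions_csv` returns the sessions data frame.
#' @export
write_sessions_csv <- function(x, path) {
  if (inherits(x, "cohort")) x <- sessions_table(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions_csv
#' @export
read_sessions_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# one traces.csv block for a single model run on a single session
traces_rows <- function(subject, session_name, traces) {
  n <- traces$n
  pick <- function(x) if (is.null(x)) rep(NA_real_, n) else x
  data.frame(subject = subject, session = session_name, trial = seq_len(n),
             model = traces$model, ev = traces$ev,
             precision = pick(traces$precision),
             associability = pick(traces$associability),
             prediction_error = pick(traces$prediction_error),
             stringsAsFactors = FALSE)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' One call that chains every stage: simulate a counterbalanced cohort under
#' the task protocol, generate reaction times from the hidden-Markov
#' learner's expected values, adjust and fit the RTs for every model, run
#' random-effects Bayesian model selection per session type, run the
#' simulation-based baseline validation for every model, and write the
#' trace-comparison report. All artifacts (`sessions.csv`, `traces.csv`,
#' `fits.csv`, `bms.json`, `validation.json`, `report.json`) plus a
#' `manifest.json` recording seeds, configuration and package version are
#' written under `out_dir`. Re-running with the same seed reproduces every
#' artifact byte-for-byte (apart from the manifest timestamp).
#'
#' @param config `NULL` for defaults, a named list, or the path to a JSON
#'   file with any of the entries `task` ([task_config()] fields), `rt`
#'   ([rt_config()] fields), `hmm` ([hmm_params()] fields), `n_subjects`,
#'   `models`, `grid_step`, `fit_mode`, `bms_mc_samples`,
#'   `validation_reps`.
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed for every random stage.
#' @return Invisibly, a list with the in-memory results (`cohort`, `fits`,
#'   `bms`, `validation`, `report`) and the artifact `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1L) {
  cfg <- pipeline_config(config)
  if (cfg$n_subjects < 1) {
    stop("configuration error: `n_subjects` must be >= 1.", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  task <- do.call(task_config, cfg$task)
  rtc <- do.call(rt_config, cfg$rt)
  hmm <- do.call(hmm_params, cfg$hmm)

  # 1. simulate the cohort and its reaction times
  cohort <- generate_cohort(task, cfg$n_subjects, seed)
  for (i in seq_along(cohort)) {
    for (v in c("appetitive", "aversive")) {
      sess <- cohort[[i]][[v]]
      ev <- generating_ev(cfg$rt_generating_model, sess, hmm,
                          cfg$rt_generating_param)
      cohort[[i]][[v]]$trials$rt_s <-
        simulate_rts(sess, ev, rtc,
                     derive_seed(seed, 10L + i,
                                 match(v, c("appetitive", "aversive"))))
    }
  }

  # 2. fit every model to every subject x session
  fits <- fit_sessions(cohort, cfg$models, cfg$grid_step, mode = cfg$fit_mode,
                       hmm = hmm, seed = derive_seed(seed, 20L))

  # 3. random-effects model selection per session type
  bms <- lapply(c(appetitive = "appetitive", aversive = "aversive"),
                function(v) {
    f <- fits[fits$session == v, ]
    lev <- stats::reshape(f[, c("subject", "model", "bic")],
                          idvar = "subject", timevar = "model",
                          direction = "wide")
    mat <- -as.matrix(lev[, -1, drop = FALSE]) / 2
    colnames(mat) <- sub("^bic\\.", "", colnames(mat))
    bms_random_effects(mat, cfg$bms_mc_samples, derive_seed(seed, 30L))
  })

  # 4. baseline validation per model and session type
  adj <- lapply(cohort, function(sub) {
    lapply(c(appetitive = "appetitive", aversive = "aversive"), function(v) {
      adjust_rts(sub[[v]]$trials$rt_s, sub[[v]]$trials$side)
    })
  })
  val_models <- setdiff(cfg$models, "Baseline")
  validation <- lapply(c(appetitive = "appetitive", aversive = "aversive"),
                       function(v) {
    out <- lapply(val_models, function(m) {
      f <- fits[fits$session == v & fits$model == m, ]
      baseline_validation(f$bic[order(f$subject)],
                          lapply(adj[order(vapply(cohort, `[[`, 0,
                                                  "subject"))],
                                 `[[`, v),
                          n_reps = cfg$validation_reps,
                          seed = derive_seed(seed, 40L, match(m, val_models)))
    })
    stats::setNames(out, val_models)
  })

  # 5. trace-comparison report
  report <- signal_report(cohort, hmm)

  # artifacts
  paths <- c(sessions = file.path(out_dir, "sessions.csv"),
             traces = file.path(out_dir, "traces.csv"),
             fits = file.path(out_dir, "fits.csv"),
             bms = file.path(out_dir, "bms.json"),
             validation = file.path(out_dir, "validation.json"),
             report = file.path(out_dir, "report.json"))
  write_sessions_csv(cohort, paths[["sessions"]])

  traces_tab <- do.call(rbind, lapply(cohort, function(sub) {
    do.call(rbind, lapply(c("appetitive", "aversive"), function(v) {
      sess <- sub[[v]]
      do.call(rbind, lapply(cfg$models, function(m) {
        f <- fits[fits$session == v & fits$model == m &
                    (is.na(fits$subject) | fits$subject == sub$subject), ]
        param <- if (nrow(f)) f$best_param[1] else NA_real_
        tra <- run_model(m, sess, param, hmm,
                         seed = derive_seed(seed, 50L + sub$subject,
                                            match(v, c("appetitive",
                                                       "aversive"))))
        traces_rows(sub$subject, v, tra)
      }))
    }))
  }))
  utils::write.csv(traces_tab, paths[["traces"]], row.names = FALSE)
  utils::write.csv(fits, paths[["fits"]], row.names = FALSE)

  jsonlite::write_json(
    lapply(bms, function(b) {
      list(dirichlet_alpha = as.list(b$dirichlet_alpha),
           pp = as.list(b$posterior_prob),
           xp = as.list(b$exceedance_prob),
           n_subjects = b$n_subjects, mc_samples = b$mc_samples)
    }),
    paths[["bms"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(validation, function(per_model) {
      lapply(per_model, function(x) {
        list(per_subject_p = x$per_subject_p, n_reps = x$n_reps,
             fisher_chi2 = x$fisher_chi2, fisher_df = x$fisher_df,
             combined_p = x$combined_p)
      })
    }),
    paths[["validation"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(per_session = report$sessions, means = report$means),
    paths[["report"]], auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "pavlovhmm",
    version = as.character(utils::packageVersion("pavlovhmm")),
    seed = as.integer(seed),
    config = cfg[c("n_subjects", "models", "grid_step", "fit_mode",
                   "bms_mc_samples", "validation_reps")],
    task = unclass(task), rt = unclass(rtc),
    hmm = unclass(hmm)[c("alpha", "beta", "emit_deliver", "emit_none",
                         "precision_mode")],
    files = as.list(basename(paths)),
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, fits = fits, bms = bms,
                 validation = validation, report = report,
                 manifest = manifest))
}

# EV trace used to *generate* reaction times in the pipeline
generating_ev <- function(model, session, hmm, param) {
  switch(model,
         HMM = hmm_filter(session, hmm)$ev,
         ReducedHMM = reduced_hmm_filter(session, hmm)$ev,
         RW = rw_run(session, param)$ev,
         PH = ph_run(session, param)$ev,
         Hybrid = hybrid_run(session, param)$ev,
         Baseline = baseline_run(session)$ev,
         stop("unknown generating model '", model, "'.", call. = FALSE))
}

# full trace object of a named model (for the traces.csv artifact)
run_model <- function(model, session, param, hmm, seed = 1L) {
  switch(model,
         HMM = hmm_filter(session, hmm),
         ReducedHMM = reduced_hmm_filter(session, hmm),
         RW = rw_run(session, param),
         PH = ph_run(session, param),
         Hybrid = hybrid_run(session, param),
         Baseline = baseline_run(session, jitter_sd = 0.01, seed = seed),
         stop("unknown model '", model, "'.", call. = FALSE))
}

# merge user configuration (list or JSON path) over the defaults
pipeline_config <- function(config) {
  defaults <- list(
    task = list(), rt = list(), hmm = list(),
    n_subjects = 19L,
    models = c("HMM", "RW", "PH", "Hybrid", "Baseline"),
    grid_step = 0.001,
    fit_mode = "subject",
    bms_mc_samples = 1e6,
    validation_reps = 10000L,
    rt_generating_model = "HMM",
    rt_generating_param = NA_real_
  )
  if (is.null(config)) return(defaults)
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    stop("configuration error: `config` must be NULL, a list or a JSON path.",
         call. = FALSE)
  }
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}
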