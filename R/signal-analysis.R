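#' Pearson correlation between two per-trial traces
#'
#' Plain Pearson correlation with explicit guards: equal lengths of at least
#' 3 and nonzero variance in both traces (a constant trace has no defined
#' correlation and is reported as an error rather than `NA`).
#'
#' @param a,b Numeric vectors of equal length.
#' @return The Pearson correlation coefficient.
#' @examples
#' trace_correlation(1:10, (1:10) * 2 + 3)  # 1
#' @export
trace_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("traces must have equal length >= 3.", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance trace: correlation is undefined.", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Correlation between model-based precision and Pearce-Hall associability
#'
#' Computes the full hidden-Markov learner's precision trace and the
#' Pearce-Hall associability trace on the same session and returns their
#' Pearson correlation. Although both quantities are often read as
#' "uncertainty" signals, the model-based precision anticipates upcoming
#' contingency changes while associability reacts only to experienced
#' prediction errors, so across sessions this correlation is close to zero.
#'
#' @param session A `session_sequence`.
#' @param hmm [hmm_params()] for the precision trace.
#' @param ph_param Pearce-Hall CS-intensity; the default 0.4 is a moderate,
#'   fitted-group-level value (see the methods vignette).
#' @return The Pearson correlation coefficient.
#' @export
precision_vs_associability <- function(session, hmm = hmm_params(),
                                       ph_param = 0.4) {
  trace_correlation(hmm_filter(session, hmm)$precision,
                    ph_run(session, ph_param)$associability)
}

#' Bin an expected-value trace into reporting categories
#'
#' `two_bin` mode splits the trace at a fixed threshold: +0.3 for appetitive
#' sessions and -0.3 for aversive sessions (trials at or below the threshold
#' are `"low"`). `tertile` mode assigns `"low"` / `"medium"` / `"high"` by
#' empirical tertiles, with boundary values falling to the lower bin; a
#' degenerate all-equal trace yields a single `"low"` category.
#'
#' @param ev Numeric per-trial expected values.
#' @param session_type `"appetitive"` or `"aversive"`.
#' @param mode `"two_bin"` or `"tertile"`.
#' @return A factor of per-trial category labels.
#' @examples
#' bin_ev(c(0.1, 0.5), "appetitive")             # low, high
#' bin_ev(c(-0.5, -0.1), "aversive")             # low, high
#' @export
bin_ev <- function(ev, session_type = c("appetitive", "aversive"),
                   mode = c("two_bin", "tertile")) {
  session_type <- match.arg(session_type)
  mode <- match.arg(mode)
  if (mode == "two_bin") {
    thr <- if (session_type == "appetitive") 0.3 else -0.3
    factor(ifelse(ev > thr, "high", "low"), levels = c("low", "high"))
  } else {
    qs <- stats::quantile(ev, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    lab <- ifelse(ev <= qs[1], "low", ifelse(ev <= qs[2], "medium", "high"))
    factor(lab, levels = c("low", "medium", "high"))
  }
}

#' Trace-comparison report over a cohort
#'
#' Per session, computes the full-vs-reduced hidden-Markov expected-value
#' correlation, the precision-vs-associability correlation, and the two-bin
#' EV occupancy counts; correlations are computed per session and then
#' averaged per session type.
#'
#' @param cohort A `cohort`.
#' @param hmm [hmm_params()].
#' @param ph_param Pearce-Hall CS intensity for the associability trace.
#' @return A list with a per-session data frame (`sessions`) and per-valence
#'   means (`means`).
#' @export
signal_report <- function(cohort, hmm = hmm_params(), ph_param = 0.4) {
  rows <- do.call(rbind, lapply(cohort, function(sub) {
    do.call(rbind, lapply(c("appetitive", "aversive"), function(v) {
      sess <- sub[[v]]
      full <- hmm_filter(sess, hmm)
      red <- reduced_hmm_filter(sess, hmm)
      bins <- table(bin_ev(full$ev, v))
      data.frame(subject = sub$subject, session = v,
                 r_full_reduced = trace_correlation(full$ev, red$ev),
                 r_precision_assoc = precision_vs_associability(sess, hmm,
                                                                ph_param),
                 n_low_ev = as.integer(bins[["low"]]),
                 n_high_ev = as.integer(bins[["high"]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  means <- stats::aggregate(cbind(r_full_reduced, r_precision_assoc,
                           n_low_ev, n_high_ev) ~ session,
                     data = rows, FUN = mean)
  list(sessions = rows, means = means)
}
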