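#' Random-effects Bayesian model selection
#'
#' Variational treatment of model frequencies in a population: a Dirichlet
#' prior (all ones) over the frequencies is updated by iterating subject-wise
#' model responsibilities, proportional to `exp(log evidence + digamma
#' terms)`, against the Dirichlet counts until convergence. Posterior
#' probabilities (`pp`) are the normalized Dirichlet means; exceedance
#' probabilities (`xp`) -- the probability that each model is the most
#' frequent in the population -- are estimated by Monte-Carlo sampling from
#' the fitted Dirichlet.
#'
#' @param log_evidence Numeric matrix, subjects x models, of approximate log
#'   model evidences (e.g. `-BIC / 2`); column names label the models.
#' @param mc_samples Number of Dirichlet draws for the exceedance
#'   probabilities.
#' @param seed Integer seed for the Monte-Carlo step.
#' @param tol Convergence tolerance on the Dirichlet counts.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return An object of class `bms_result`: list with `dirichlet_alpha`,
#'   `posterior_prob`, `exceedance_prob`, `n_subjects`, `mc_samples`, `seed`.
#' @examples
#' lev <- cbind(HMM = c(-10, -12, -9), RW = c(-14, -13, -15))
#' bms_random_effects(lev, mc_samples = 1e5, seed = 1)$exceedance_prob
#' @export
bms_random_effects <- function(log_evidence, mc_samples = 1e6, seed = 1L,
                               tol = 1e-8, max_iter = 10000L) {
  lev <- as.matrix(log_evidence)
  if (nrow(lev) < 2L || ncol(lev) < 2L) {
    stop("need at least 2 subjects and 2 models.", call. = FALSE)
  }
  if (any(!is.finite(lev))) {
    stop("log evidences must all be finite.", call. = FALSE)
  }
  n <- nrow(lev); K <- ncol(lev)
  models <- colnames(lev)
  if (is.null(models)) models <- paste0("model", seq_len(K))

  alpha0 <- rep(1, K)
  alpha <- alpha0
  for (iter in seq_len(max_iter)) {
    w <- sweep(lev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- exp(w - apply(w, 1, max))
    g <- w / rowSums(w)                    # subject-wise responsibilities
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
    if (iter == max_iter) {
      stop("random-effects model selection did not converge after ",
           max_iter, " iterations.", call. = FALSE)
    }
  }

  pp <- alpha / sum(alpha)
  set.seed(as.integer(seed %% 2147483647))
  draws <- matrix(stats::rgamma(mc_samples * K, shape = rep(alpha,
                                                            each = mc_samples)),
                  mc_samples, K)
  xp <- tabulate(max.col(draws, ties.method = "first"), K) / mc_samples

  structure(
    list(dirichlet_alpha = stats::setNames(alpha, models),
         posterior_prob = stats::setNames(pp, models),
         exceedance_prob = stats::setNames(xp, models),
         n_subjects = n, mc_samples = mc_samples, seed = as.integer(seed)),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, digits = 3, ...) {
  cat("random-effects Bayesian model selection (", x$n_subjects,
      " subjects)\n", sep = "")
  tab <- rbind(alpha = x$dirichlet_alpha,
               pp = x$posterior_prob,
               xp = x$exceedance_prob)
  print(round(tab, digits))
  invisible(x)
}

#' Simulation-based baseline validation of model fits
#'
#' Tests, per subject, whether a model's fit to the adjusted reaction times
#' beats what random expected values achieve. On each repetition an i.i.d.
#' uniform \[0, 1\] EV trace is drawn per subject, regressed against that
#' subject's adjusted residuals (single regression, no free learner
#' parameter) and scored by BIC. The per-subject nonparametric p-value is the
#' (+1-corrected) fraction of repetitions in which the random-baseline BIC is
#' lower than the model's BIC; p-values are combined across subjects with
#' Fisher's method.
#'
#' @param model_bics Numeric vector, one model BIC per subject.
#' @param adjusted_rts List of `adjusted_rts` objects aligned with
#'   `model_bics`.
#' @param n_reps Number of random repetitions (the reference analysis uses
#'   10000).
#' @param seed Integer seed.
#' @return An object of class `validation_result`: list with
#'   `per_subject_p`, `n_reps`, `fisher_chi2`, `fisher_df`, `combined_p`.
#' @seealso [fisher_combine()]
#' @export
baseline_validation <- function(model_bics, adjusted_rts, n_reps = 10000L,
                                seed = 1L) {
  if (length(model_bics) != length(adjusted_rts)) {
    stop("`model_bics` and `adjusted_rts` must be aligned per subject.",
         call. = FALSE)
  }
  if (n_reps < 1L) stop("`n_reps` must be >= 1.", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  p <- vapply(seq_along(model_bics), function(i) {
    adj <- adjusted_rts[[i]]
    r <- adj$residuals - mean(adj$residuals)
    syy <- sum(r^2)
    n <- adj$n
    ev <- matrix(stats::runif(n * n_reps), n, n_reps)
    ev <- sweep(ev, 2, colMeans(ev))
    sse <- syy - colSums(ev * r)^2 / colSums(ev^2)
    bics <- n * log(sse / n)                     # k = 0
    (sum(bics < model_bics[i]) + 1) / (n_reps + 1)
  }, numeric(1))
  fc <- fisher_combine(p)
  structure(
    list(per_subject_p = p, n_reps = as.integer(n_reps),
         fisher_chi2 = fc$chi2, fisher_df = fc$df,
         combined_p = fc$combined_p),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat("baseline validation over ", length(x$per_subject_p), " subjects, ",
      x$n_reps, " repetitions each\n", sep = "")
  cat("  Fisher chi2 = ", signif(x$fisher_chi2, 4), " on ", x$fisher_df,
      " df, combined p = ", signif(x$combined_p, 3), "\n", sep = "")
  invisible(x)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via `chi2 = -2 * sum(log(p))`, referred to a
#' chi-square distribution with `2 * length(p)` degrees of freedom.
#'
#' @param p_values Probabilities in (0, 1\]; exact zeros are rejected (use a
#'   +1-corrected nonparametric p).
#' @return A list with `chi2`, `df` and `combined_p`.
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' @export
fisher_combine <- function(p_values) {
  if (any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1].", call. = FALSE)
  }
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chi2 = chi2, df = df,
       combined_p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
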