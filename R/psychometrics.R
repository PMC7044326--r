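#' Repeating stimulus evidence
#'
#' Projects the signed stimulus evidence onto the repeat/alternate axis of
#' the previous response: `e_hat_t = r_{t-1} * e_t`. Positive values favor
#' repeating the previous choice, negative values favor alternating. On
#' the first trial of a session (`prev_response` missing) the projection
#' is undefined and `NA` is returned.
#'
#' @param evidence Signed stimulus evidence `e_t`.
#' @param prev_response Previous response, `-1`/`+1` or `NA`.
#' @return Numeric vector of repeating evidence values.
#' @examples
#' repeating_evidence(0.23, -1)  # -0.23
#' @export
repeating_evidence <- function(evidence, prev_response) {
  bad <- !is.na(prev_response) & !(prev_response %in% c(-1, 1))
  if (any(bad)) stop("`prev_response` must be -1, +1 or NA")
  ifelse(is.na(prev_response), NA_real_, prev_response * evidence)
}

#' Fit a two-parameter probit psychometric curve
#'
#' Fits `P(y = 1 | x) = Phi(sensitivity * x + bias)` by Bernoulli maximum
#' likelihood (`stats::glm` with a probit link). For the rightward curve,
#' `x` is the stimulus evidence, `y` the rightward-response indicator and
#' `bias` the fixed side bias `B`; for the repeating curve, `x` is the
#' repeating evidence and `bias` the repeating bias `b`. Uncertainty is
#' estimated by a nonparametric bootstrap over trials.
#'
#' @param x Evidence values (at least two distinct levels).
#' @param y Binary responses (0/1 logical or numeric, or `-1`/`+1`).
#' @param n_boot Number of bootstrap resamples (default 1000; 0 disables
#'   the bootstrap).
#' @param min_cell Minimum trials per evidence level for the fit to be
#'   flagged stable (default 10).
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `psychometric_fit`: `sensitivity`, `bias`,
#'   bootstrap standard deviations and quartiles, per-level trial counts,
#'   `stable` flag and `separation` flag.
#' @examples
#' x <- rep(c(-1, -0.5, 0, 0.5, 1), each = 200)
#' y <- stats::rbinom(length(x), 1, pnorm(2 * x + 0.3))
#' fit_probit(x, y, n_boot = 0)
#' @export
fit_probit <- function(x, y, n_boot = 1000, min_cell = 10, seed = NULL) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (all(y %in% c(-1, 1))) y <- as.integer(y == 1)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("`y` must be binary")
  if (length(unique(x)) < 2) {
    stop("need at least two distinct evidence levels to fit a probit")
  }
  if (length(unique(y)) < 2) {
    stop("both response classes must be present")
  }
  fit1 <- function(xx, yy) {
    g <- suppressWarnings(
      stats::glm(yy ~ xx, family = stats::binomial(link = "probit")))
    c(bias = unname(stats::coef(g)[1]),
      sensitivity = unname(stats::coef(g)[2]),
      separation = as.numeric(!g$converged ||
                                any(abs(stats::coef(g)) > 50)))
  }
  est <- fit1(x, y)
  counts <- table(x)
  boot <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      n <- length(x)
      t(vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(fit1(x[idx], y[idx])[1:2],
                 error = function(e) c(bias = NA_real_, sensitivity = NA_real_))
      }, c(bias = 0, sensitivity = 0)))
    })
  }
  qs <- function(v) if (is.null(boot)) rep(NA_real_, 3) else
    stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
  structure(list(
    sensitivity = unname(est["sensitivity"]),
    bias = unname(est["bias"]),
    sensitivity_sd = if (is.null(boot)) NA_real_ else
      stats::sd(boot[, "sensitivity"], na.rm = TRUE),
    bias_sd = if (is.null(boot)) NA_real_ else
      stats::sd(boot[, "bias"], na.rm = TRUE),
    sensitivity_quartiles = qs(if (is.null(boot)) NULL else boot[, "sensitivity"]),
    bias_quartiles = qs(if (is.null(boot)) NULL else boot[, "bias"]),
    n_per_level = counts,
    n_trials = length(x),
    stable = all(counts >= min_cell),
    separation = est["separation"] > 0
  ), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "probit psychometric fit (%d trials, %d levels%s)\n",
    x$n_trials, length(x$n_per_level),
    if (x$stable) "" else "; UNSTABLE: some level has few trials"))
  cat(sprintf("  sensitivity %.3f (sd %.3f) | bias %.3f (sd %.3f)\n",
              x$sensitivity, x$sensitivity_sd, x$bias, x$bias_sd))
  if (isTRUE(x$separation)) cat("  warning: possible separation\n")
  invisible(x)
}

#' Rightward and repeating psychometric curves of a session
#'
#' `fit_rightward_curve` fits the proportion of rightward responses
#' against the stimulus evidence, returning the sensitivity `beta` and the
#' fixed side bias `B`. `fit_repeating_curve` fits the proportion of
#' repeated responses against the repeating evidence `e_hat = r_{t-1} e`,
#' returning `beta'` and the repeating bias `b` (positive = tendency to
#' repeat). Trials without a valid response, and (for the repeating curve)
#' trials without a defined previous response, are excluded.
#'
#' @param session A session table with responses.
#' @param subset Optional logical vector selecting trials.
#' @inheritParams fit_probit
#' @return A `psychometric_fit`.
#' @export
fit_rightward_curve <- function(session, subset = NULL, n_boot = 1000,
                                seed = NULL) {
  validate_session(session, require_responses = TRUE)
  keep <- !is.na(session$response)
  if (!is.null(subset)) keep <- keep & subset
  fit_probit(session$evidence[keep], session$response[keep] == 1,
             n_boot = n_boot, seed = seed)
}

#' @rdname fit_rightward_curve
#' @export
fit_repeating_curve <- function(session, subset = NULL, n_boot = 1000,
                                seed = NULL) {
  validate_session(session, require_responses = TRUE)
  if (!"prev_response" %in% names(session)) {
    session <- add_history_columns(session)
  }
  keep <- !is.na(session$response) & !is.na(session$prev_response)
  if (!is.null(subset)) keep <- keep & subset
  e_hat <- repeating_evidence(session$evidence[keep],
                              session$prev_response[keep])
  repeated <- session$response[keep] == session$prev_response[keep]
  fit_probit(e_hat, repeated, n_boot = n_boot, seed = seed)
}

#' History patterns over preceding trials
#'
#' A history pattern is a token sequence describing the trials immediately
#' preceding the trial of interest, oldest first, the last token applying
#' to trial `t - 1`. Tokens:
#' \describe{
#'   \item{`"rep+"`}{the trial was correct, the trial before it was
#'     correct, and the two responses repeated;}
#'   \item{`"alt+"`}{as `"rep+"` but the responses alternated;}
#'   \item{`"err"`}{the trial was an error;}
#'   \item{`"corr"`}{the trial was correct (any transition).}
#' }
#' Matching is anchored at `t - 1` and, by default, unconstrained further
#' back, so a pattern of `n` `"rep+"` tokens selects trials preceded by
#' *at least* `n` consecutive correct repetitions. Supplying
#' `exclude_older` requires that the given token does *not* also match
#' one position further back, turning a run pattern into an exact-length
#' one. `rep_pattern()` builds the common cases: exactly (default) or at
#' least `n` correct repetitions or alternations, optionally terminated
#' by a single error at `t - 1`.
#'
#' @param tokens Character vector of tokens, oldest first.
#' @param exclude_older Optional single token that must *fail* to match
#'   at the position just older than the pattern.
#' @return An object of class `history_pattern`.
#' @examples
#' rep_pattern(3)                              # exactly 3 correct repetitions
#' rep_pattern(3, terminated_by_error = TRUE)  # ... then an error
#' @export
history_pattern <- function(tokens, exclude_older = NULL) {
  allowed <- c("rep+", "alt+", "err", "corr")
  if (length(tokens) == 0 || !all(tokens %in% allowed)) {
    stop("tokens must be drawn from: ", paste(allowed, collapse = ", "))
  }
  if (!is.null(exclude_older) &&
      (length(exclude_older) != 1 || !exclude_older %in% allowed)) {
    stop("`exclude_older` must be a single valid token")
  }
  structure(list(tokens = tokens, exclude_older = exclude_older),
            class = "history_pattern")
}

#' @rdname history_pattern
#' @param n Number of correct transitions.
#' @param transition `"repeat"` or `"alternate"`.
#' @param terminated_by_error Append an error token at `t - 1`.
#' @param exact If `TRUE` (default), require the run to be exactly `n`
#'   transitions long (the run must not extend further back).
#' @export
rep_pattern <- function(n, transition = c("repeat", "alternate"),
                        terminated_by_error = FALSE, exact = TRUE) {
  transition <- match.arg(transition)
  stopifnot(n >= 1)
  run_tok <- if (transition == "repeat") "rep+" else "alt+"
  tok <- rep(run_tok, n)
  if (terminated_by_error) tok <- c(tok, "err")
  history_pattern(tok, exclude_older = if (exact) run_tok)
}

#' Match a history pattern against every trial of a session
#'
#' @param session A session table with responses.
#' @param pattern A [history_pattern()].
#' @return Logical vector, `TRUE` where the trials preceding trial `t`
#'   match the pattern (within the same session, all involved trials
#'   valid).
#' @export
match_history_pattern <- function(session, pattern) {
  stopifnot(inherits(pattern, "history_pattern"))
  n <- nrow(session)
  sid <- as.character(session$session_id)
  resp <- session$response
  corr <- !is.na(session$outcome) & session$outcome == "correct"
  valid <- !is.na(resp)
  lag_ok <- function(k) {
    # TRUE where trial t-k exists in the same session
    idx <- seq_len(n) - k
    idx >= 1 & c(rep(FALSE, k), sid[seq_len(n - k)] == sid[(k + 1):n])
  }
  shift <- function(x, k, fill) c(rep(fill, k), x[seq_len(n - k)])
  token_match <- function(tok, j) {
    ok_j <- lag_ok(j) & shift(valid, j, FALSE)
    switch(
      tok,
      "err" = ok_j & !shift(corr, j, FALSE),
      "corr" = ok_j & shift(corr, j, FALSE),
      {
        # transition tokens also involve trial t - j - 1
        ok_prev <- lag_ok(j + 1) & shift(valid, j + 1, FALSE)
        same <- shift(resp, j, NA) == shift(resp, j + 1, NA)
        same[is.na(same)] <- FALSE
        both_corr <- shift(corr, j, FALSE) & shift(corr, j + 1, FALSE)
        if (tok == "rep+") ok_j & ok_prev & both_corr & same
        else ok_j & ok_prev & both_corr & !same
      })
  }
  tokens <- rev(pattern$tokens)   # tokens[j] applies to trial t - j
  sel <- rep(TRUE, n)
  for (j in seq_along(tokens)) sel <- sel & token_match(tokens[j], j)
  if (!is.null(pattern$exclude_older)) {
    sel <- sel & !token_match(pattern$exclude_older, length(tokens) + 1L)
  }
  sel
}

#' Repeating bias conditioned on the preceding history
#'
#' Selects the trials whose immediately preceding history matches each
#' pattern and fits the repeating psychometric curve on that subset,
#' giving the sequence-conditioned repeating bias `b` (its build-up over
#' runs of correct repetitions or alternations, and its collapse after a
#' terminating error).
#'
#' @param session A session table with responses.
#' @param patterns A [history_pattern()], or a list of them (optionally
#'   named).
#' @param n_boot Bootstrap resamples per conditioned fit (default 200).
#' @param seed Optional seed.
#' @return A data frame with one row per pattern: `pattern`, `n_trials`,
#'   `bias`, `bias_sd`, quartiles, `sensitivity` and `stable`.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(n_sessions = 4, trials_per_session = 500, seed = 1)
#' repeating_bias_conditioned(sim, list(`1` = rep_pattern(1), `3` = rep_pattern(3)),
#'                            n_boot = 0)
#' }
#' @export
repeating_bias_conditioned <- function(session, patterns, n_boot = 200,
                                       seed = NULL) {
  if (inherits(patterns, "history_pattern")) patterns <- list(patterns)
  if (is.null(names(patterns))) {
    names(patterns) <- vapply(patterns, function(p)
      paste(p$tokens, collapse = " "), character(1))
  }
  session <- add_history_columns(validate_session(session,
                                                  require_responses = TRUE))
  rows <- lapply(names(patterns), function(nm) {
    sel <- match_history_pattern(session, patterns[[nm]])
    if (!any(sel)) stop("no trials match pattern: ", nm)
    fit <- fit_repeating_curve(session, subset = sel, n_boot = n_boot,
                               seed = seed)
    data.frame(pattern = nm, n_trials = fit$n_trials, bias = fit$bias,
               bias_sd = fit$bias_sd,
               bias_q25 = fit$bias_quartiles[[1]],
               bias_q75 = fit$bias_quartiles[[3]],
               sensitivity = fit$sensitivity, stable = fit$stable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
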