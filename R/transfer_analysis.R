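#' Per-trial transition-bias series implied by a fitted model
#'
#' Returns the deterministic transition bias `gamma_T` for every trial of
#' a session, either from the gated-accumulator model (latent recursion
#' under the given parameters) or from a fitted history GLM (the summed
#' transition regressors times their weights, which already include the
#' `r_{t-1}` projection).
#'
#' @param session A session table with responses.
#' @param model A [dynamic_params()], a [fit_dynamic_model()] result, or a
#'   [fit_glm()] result.
#' @param design Optional pre-built [build_design_matrix()] (GLM models
#'   only; rebuilt if missing).
#' @return Numeric vector of `gamma_T`, one per trial (`NA` where
#'   undefined, e.g. session starts for GLM models).
#' @export
infer_gamma_series <- function(session, model, design = NULL) {
  if (inherits(model, "dynamic_fit")) model <- model$params
  if (inherits(model, "dynamic_params")) {
    return(compute_latent_trace(session, model)$gamma_T)
  }
  if (inherits(model, "history_glm")) {
    if (is.null(design)) design <- build_design_matrix(session)
    tcols <- design$families$column[design$families$family %in%
                                      c("Tpp", "Tpm", "Tmp", "Tmm")]
    w <- model$weights[tcols]
    w[is.na(w)] <- 0
    g <- drop(design$X[, tcols, drop = FALSE] %*% w)
    out <- rep(NA_real_, nrow(session))
    out[design$row_index] <- g
    return(out)
  }
  stop("`model` must be dynamic_params, dynamic_fit or history_glm")
}

#' Lag-k outcome-conditioned transfer coefficient
#'
#' Quantifies how predictive the transition bias at trial `t` is of the
#' choice `k` trials later, conditioned on the outcomes of the
#' intervening trials `t ... t+k-1`. The coefficient is the probit
#' regression weight of the repeat-coded choice at `t+k`
#' (`r_{t+k} == r_{t+k-1}`) on the repeat-axis bias at `t`
#' (`gamma_T[t] * r_{t-1} = c_T z_T`), with the repeat-coded stimulus
#' evidence at `t+k` and the intervening transitions (trials
#' `t+1 ... t+k-1`) as covariates. Partialling out the intervening
#' transitions isolates the *carried-over* component of the bias, so
#' under gated dynamics the all-correct coefficients decay with lag the
#' way the GLM transition kernel does, and the coefficient rebounds
#' after an (error, correct) outcome pair; under a complete reset the
#' post-error coefficients stay at zero.
#'
#' @param session A session table with responses.
#' @param gamma Per-trial `gamma_T` series (see [infer_gamma_series()]).
#' @param k Trial lag (>= 1).
#' @param outcome_pattern Character vector of length `k` over
#'   `"correct"` / `"error"`: required outcomes of trials `t ... t+k-1`.
#' @param include_stim Include the stimulus covariate (default `TRUE`).
#' @param control_intervening Include the intervening transition signs as
#'   covariates (default `TRUE`).
#' @param se_method `"asymptotic"` (Wald, default) or `"bootstrap"`
#'   (resampling whole sessions).
#' @param n_boot Bootstrap resamples (when `se_method = "bootstrap"`).
#' @param seed Optional seed for the bootstrap.
#' @return A one-row data frame of class `transfer_result`: `lag`,
#'   `pattern`, `coefficient`, `se`, `ci_lo`, `ci_hi` (bootstrap 95%
#'   interval or Wald interval), `n_trials`.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(n_sessions = 6, trials_per_session = 400, seed = 1)
#' g <- infer_gamma_series(sim, dynamic_params())
#' transfer_coefficient(sim, g, k = 1, "correct")
#' }
#' @export
transfer_coefficient <- function(session, gamma, k, outcome_pattern,
                                 include_stim = TRUE,
                                 control_intervening = TRUE,
                                 se_method = c("asymptotic", "bootstrap"),
                                 n_boot = 200, seed = NULL) {
  se_method <- match.arg(se_method)
  stopifnot(k >= 1, length(outcome_pattern) == k,
            all(outcome_pattern %in% c("correct", "error")),
            length(gamma) == nrow(session))
  session <- add_history_columns(validate_session(session,
                                                  require_responses = TRUE))
  n <- nrow(session)
  sid <- as.character(session$session_id)
  resp <- session$response
  valid <- !is.na(resp)

  sel <- rep(FALSE, n)
  tmax <- n - k
  if (tmax >= 1) {
    tt <- seq_len(tmax)
    ok <- sid[tt] == sid[tt + k] &
      !is.na(gamma[tt]) & !is.na(session$prev_response[tt]) &
      valid[tt + k] & valid[tt + k - 1]
    for (j in seq_len(k)) {
      ok <- ok & valid[tt + j - 1] &
        (session$outcome[tt + j - 1] == outcome_pattern[j])
      ok[is.na(ok)] <- FALSE
    }
    sel[tt] <- ok
  }
  tt <- which(sel)
  if (length(tt) == 0) stop("no trials match the outcome pattern")

  dat <- data.frame(
    y = as.integer(resp[tt + k] == resp[tt + k - 1]),
    x1 = gamma[tt] * session$prev_response[tt],
    x2 = resp[tt + k - 1] * session$evidence[tt + k],
    sid = sid[tt]
  )
  rhs <- "x1"
  if (include_stim) rhs <- c(rhs, "x2")
  if (control_intervening && k >= 2) {
    for (j in seq_len(k - 1)) {
      dat[[paste0("tr", j)]] <- ifelse(resp[tt + j] == resp[tt + j - 1],
                                       1, -1)
      rhs <- c(rhs, paste0("tr", j))
    }
  }
  form <- stats::reformulate(rhs, response = "y")
  fit1 <- function(d) {
    g <- suppressWarnings(
      stats::glm(form, data = d, family = stats::binomial(link = "probit")))
    stats::coef(g)[["x1"]]
  }
  g0 <- suppressWarnings(
    stats::glm(form, data = dat, family = stats::binomial(link = "probit")))
  coefficient <- stats::coef(g0)[["x1"]]
  if (se_method == "asymptotic") {
    se <- sqrt(diag(stats::vcov(g0)))[["x1"]]
    ci <- coefficient + c(-1.96, 1.96) * se
  } else {
    ids <- unique(dat$sid)
    bygroup <- split(seq_len(nrow(dat)), dat$sid)
    bs <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      pick <- sample(ids, length(ids), replace = TRUE)
      d <- dat[unlist(bygroup[pick], use.names = FALSE), , drop = FALSE]
      tryCatch(fit1(d), error = function(e) NA_real_)
    }, numeric(1)))
    se <- stats::sd(bs, na.rm = TRUE)
    ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
  }
  structure(data.frame(
    lag = k,
    pattern = paste(substr(outcome_pattern, 1, 1), collapse = ""),
    coefficient = coefficient,
    se = se,
    ci_lo = ci[[1]], ci_hi = ci[[2]],
    n_trials = nrow(dat),
    stringsAsFactors = FALSE
  ), class = c("transfer_result", "data.frame"))
}

#' Transfer-coefficient profile over lags and outcome patterns
#'
#' Computes the standard set of conditioned transfer coefficients up to
#' `max_lag`: all-correct outcome sequences (bias carried forward),
#' all-error sequences (bias withheld), and error sequences terminated by
#' a single correct outcome (the rebound case).
#'
#' @inheritParams transfer_coefficient
#' @param max_lag Largest trial lag (default 3).
#' @return A `transfer_result` data frame, one row per (lag, pattern).
#' @export
transfer_profile <- function(session, gamma, max_lag = 3,
                             include_stim = TRUE,
                             se_method = c("asymptotic", "bootstrap"),
                             n_boot = 200, seed = NULL) {
  se_method <- match.arg(se_method)
  rows <- list()
  for (k in seq_len(max_lag)) {
    pats <- list(rep("correct", k), rep("error", k))
    if (k >= 2) pats <- c(pats, list(c(rep("error", k - 1), "correct")))
    for (p in pats) {
      rows[[length(rows) + 1L]] <- tryCatch(
        transfer_coefficient(session, gamma, k, p,
                             include_stim = include_stim,
                             se_method = se_method, n_boot = n_boot,
                             seed = seed),
        error = function(e) NULL)
    }
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  class(out) <- c("transfer_result", "data.frame")
  out
}
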