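.par_order <- c(
  "delta_L_plus", "delta_L_minus", "lambda_L_plus", "lambda_L_minus",
  "delta_T_pp", "delta_T_pm", "delta_T_mp", "delta_T_mm",
  "lambda_T_plus", "lambda_T_minus",
  "delta_C_plus", "delta_C_minus",
  "w_stim", "fixed_bias", "lapse_R", "lapse_L"
)

#' Parameters of the gated-accumulator model
#'
#' The generative model carries three latent variables per trial: lateral
#' evidence `z_L` (a running left/right tally of past responses),
#' transition evidence `z_T` (a running repeat/alternate tally of past
#' transitions between consecutive responses), and the gating signal
#' `c_T` in `[0, 1]` that modulates how strongly `z_T` biases the current
#' choice. After a trial with response `r`, outcome `o` (`+` correct, `-`
#' error) and transition `T = +1` (repetition) or `-1` (alternation) with
#' respect to the previous response (previous outcome `q`... here denoted
#' by the first superscript), the updates are
#' \deqn{z_L \leftarrow (1-\lambda_L^o) z_L + \Delta_L^o r}
#' \deqn{z_T \leftarrow (1-\lambda_T^o) z_T + \Delta_T^{o',o} T}
#' \deqn{c_T \leftarrow \mathrm{clip}(c_T + \Delta_C^o,\ 0,\ 1)}
#' where `o'` is the outcome of the previous trial. The choice on the next
#' trial is right with probability
#' \deqn{p = \pi_R + (1-\pi_R-\pi_L)\,\Phi(w\,x + \gamma_L + \gamma_T + B)}
#' with `x` the summed frame evidence, `gamma_L = z_L`,
#' `gamma_T = c_T z_T r_{t-1}`, fixed side bias `B` and lapse rates
#' `pi_R`, `pi_L`.
#'
#' Defaults describe a gating agent of realistic magnitude: only `++`
#' transitions update `z_T`, errors extinguish the gate
#' (`delta_C_minus = -1`) and any correct response fully restores it
#' (`delta_C_plus = +1`); the stimulus dominates the choice, the
#' transition bias is an order of magnitude weaker, and the lateral bias
#' weaker still.
#'
#' @param delta_L_plus,delta_L_minus Lateral updates after correct / error
#'   responses.
#' @param lambda_L_plus,lambda_L_minus Lateral leaks in `[0, 1]`
#'   (fraction lost per trial; 1 = full reset).
#' @param delta_T_pp,delta_T_pm,delta_T_mp,delta_T_mm Transition updates
#'   indexed by the outcomes of the two trials forming the transition
#'   (previous, current): `++`, `+-`, `-+`, `--`.
#' @param lambda_T_plus,lambda_T_minus Transition leaks in `[0, 1]`,
#'   applied according to the current trial's outcome.
#' @param delta_C_plus,delta_C_minus Gating updates in `[-1, 1]` after
#'   correct / error outcomes; `-1` extinguishes the gate, `+1` restores
#'   it to its maximum of 1.
#' @param w_stim Sensitivity to the summed frame evidence.
#' @param fixed_bias Fixed side bias (probit units).
#' @param lapse_R,lapse_L Lapse rates in `[0, 0.5]`.
#' @return An object of class `dynamic_params` (named list).
#' @examples
#' p <- dynamic_params()
#' p$delta_C_minus
#' @export
dynamic_params <- function(delta_L_plus = 0.1, delta_L_minus = -0.05,
                           lambda_L_plus = 0.5, lambda_L_minus = 0.5,
                           delta_T_pp = 0.3, delta_T_pm = 0,
                           delta_T_mp = 0, delta_T_mm = 0,
                           lambda_T_plus = 0.2, lambda_T_minus = 0.2,
                           delta_C_plus = 1, delta_C_minus = -1,
                           w_stim = 0.25, fixed_bias = 0,
                           lapse_R = 0, lapse_L = 0) {
  p <- list(
    delta_L_plus = delta_L_plus, delta_L_minus = delta_L_minus,
    lambda_L_plus = lambda_L_plus, lambda_L_minus = lambda_L_minus,
    delta_T_pp = delta_T_pp, delta_T_pm = delta_T_pm,
    delta_T_mp = delta_T_mp, delta_T_mm = delta_T_mm,
    lambda_T_plus = lambda_T_plus, lambda_T_minus = lambda_T_minus,
    delta_C_plus = delta_C_plus, delta_C_minus = delta_C_minus,
    w_stim = w_stim, fixed_bias = fixed_bias,
    lapse_R = lapse_R, lapse_L = lapse_L
  )
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("parameters must be finite")
  leaks <- vals[c("lambda_L_plus", "lambda_L_minus",
                  "lambda_T_plus", "lambda_T_minus")]
  if (any(leaks < 0 | leaks > 1)) stop("leaks must lie in [0, 1]")
  gates <- vals[c("delta_C_plus", "delta_C_minus")]
  if (any(gates < -1 | gates > 1)) stop("gating updates must lie in [-1, 1]")
  lapses <- vals[c("lapse_R", "lapse_L")]
  if (any(lapses < 0 | lapses > 0.5)) stop("lapses must lie in [0, 0.5]")
  structure(p, class = "dynamic_params")
}

#' @export
print.dynamic_params <- function(x, ...) {
  v <- unlist(x)
  cat("gated-accumulator parameters:\n")
  print(round(v, 4))
  invisible(x)
}

as_par_vector <- function(params) {
  stopifnot(inherits(params, "dynamic_params"))
  unlist(params)[.par_order]
}

par_vector_to_params <- function(v) {
  do.call(dynamic_params, as.list(v[.par_order]))
}

#' Reference agent variants
#'
#' `gating_params()` returns the default gating agent;
#' `complete_reset_params()` implements the complete-reset hypothesis
#' (transition evidence fully leaks after an error, `lambda_T_minus = 1`,
#' and the gate is inert at 1); `stimulus_only_params()` removes all
#' history terms so choices depend on the stimulus alone.
#'
#' @param ... Overrides passed on to [dynamic_params()].
#' @return A `dynamic_params` object.
#' @export
gating_params <- function(...) dynamic_params(...)

#' @rdname gating_params
#' @export
complete_reset_params <- function(...) {
  dynamic_params(lambda_T_minus = 1, delta_C_plus = 0, delta_C_minus = 0, ...)
}

#' @rdname gating_params
#' @export
stimulus_only_params <- function(...) {
  dynamic_params(delta_L_plus = 0, delta_L_minus = 0,
                 delta_T_pp = 0, delta_T_pm = 0, delta_T_mp = 0,
                 delta_T_mm = 0, delta_C_plus = 0, delta_C_minus = 0, ...)
}

#' One step of the latent dynamics
#'
#' Applies the update rules of the model after observing one trial. The
#' leak is selected by the current trial's outcome; the transition update
#' is indexed by the outcomes of the two trials forming the transition and
#' is skipped on the first trial of a session (`transition = NA`).
#'
#' @param state List with `z_L`, `z_T`, `c_T`.
#' @param response Response of the trial, `-1` or `+1`.
#' @param outcome `"correct"` or `"error"`.
#' @param prev_outcome Outcome of the previous trial (ignored when
#'   `transition` is `NA`).
#' @param transition `+1` (repetition), `-1` (alternation) or `NA` (first
#'   trial of a session).
#' @param params A [dynamic_params()].
#' @return Updated state list.
#' @examples
#' st <- list(z_L = 0, z_T = 0.6, c_T = 0.8)
#' update_latents(st, response = 1, outcome = "error", prev_outcome = "correct",
#'                transition = 1, dynamic_params(delta_T_pm = 0))
#' @export
update_latents <- function(state, response, outcome, prev_outcome = NULL,
                           transition = NA, params = dynamic_params()) {
  stopifnot(response %in% c(-1, 1), outcome %in% c("correct", "error"))
  o <- outcome == "correct"
  dL <- if (o) params$delta_L_plus else params$delta_L_minus
  lL <- if (o) params$lambda_L_plus else params$lambda_L_minus
  z_L <- (1 - lL) * state$z_L + dL * response
  z_T <- state$z_T
  if (!is.na(transition)) {
    stopifnot(transition %in% c(-1, 1),
              prev_outcome %in% c("correct", "error"))
    po <- prev_outcome == "correct"
    dT <- if (po) {
      if (o) params$delta_T_pp else params$delta_T_pm
    } else {
      if (o) params$delta_T_mp else params$delta_T_mm
    }
    lT <- if (o) params$lambda_T_plus else params$lambda_T_minus
    z_T <- (1 - lT) * z_T + dT * transition
  }
  c_T <- min(1, max(0, state$c_T + if (o) params$delta_C_plus else params$delta_C_minus))
  list(z_L = z_L, z_T = z_T, c_T = c_T)
}

#' Probability of a rightward response
#'
#' @param state List with `z_L`, `z_T`, `c_T` (state entering the trial).
#' @param stim_evidence Net stimulus evidence (summed frame evidence).
#' @param prev_response Previous response `-1`/`+1`, or `NA` on the first
#'   trial of a session (the transition bias is then undefined and drops
#'   out).
#' @param params A [dynamic_params()].
#' @return Probability of choosing right.
#' @examples
#' choice_probability(list(z_L = 0, z_T = 0, c_T = 1), 0, NA, dynamic_params())
#' @export
choice_probability <- function(state, stim_evidence, prev_response,
                               params = dynamic_params()) {
  gamma_T <- if (is.na(prev_response) || prev_response == 0) 0 else
    state$c_T * state$z_T * prev_response
  y <- params$w_stim * stim_evidence + state$z_L + gamma_T + params$fixed_bias
  params$lapse_R + (1 - params$lapse_R - params$lapse_L) * stats::pnorm(y)
}

# Shared data prep for the C++ recursions.
session_arrays <- function(session) {
  valid <- !is.na(session$response)
  list(
    resp = ifelse(valid, as.integer(session$response), 0L),
    correct = ifelse(valid & session$outcome == "correct", 1L, 0L),
    stim = stim_sum(session),
    new_session = new_session_flags(session),
    valid = valid
  )
}

#' Teacher-forced latent trace of a fitted or known model
#'
#' Recomputes the deterministic latent trajectories (`z_L`, `z_T`, `c_T`,
#' `gamma_L`, `gamma_T`) and the model's per-trial rightward probability
#' from the observed responses and outcomes of a session table. Row `t`
#' holds the state *entering* trial `t`.
#'
#' @param session A session table with responses and outcomes.
#' @param params A [dynamic_params()].
#' @return A data frame with columns `z_L`, `z_T`, `c_T`, `gamma_L`,
#'   `gamma_T`, `p_right`, one row per trial.
#' @export
compute_latent_trace <- function(session, params) {
  validate_session(session, require_responses = TRUE)
  a <- session_arrays(session)
  as.data.frame(latent_trace_cpp(a$resp, a$correct, a$stim, a$new_session,
                                 a$valid, as_par_vector(params)))
}

#' Simulate the agent on a stimulus session
#'
#' Runs the gated accumulator closed loop over the stimulus columns of a
#' session table: on each trial the choice is sampled from
#' [choice_probability()], the outcome is correct when the choice matches
#' the stimulus category, and the latents are updated. Latents reset at
#' every session boundary.
#'
#' @param stimuli Session table with stimulus columns (responses ignored).
#' @param params A [dynamic_params()].
#' @param seed Optional integer seed.
#' @param keep_trace If `TRUE` (default) the latent trace is appended as
#'   columns `z_L`, `z_T`, `c_T`, `gamma_L`, `gamma_T`, `p_right`.
#' @return The session table with `response`, `outcome`, `prev_response`,
#'   `prev_outcome` and (optionally) trace columns added.
#' @examples
#' sess <- generate_stimulus_session(task_config(), 50, seed = 1)
#' sim <- simulate_agent(sess, dynamic_params(), seed = 2)
#' mean(sim$outcome == "correct")
#' @export
simulate_agent <- function(stimuli, params = dynamic_params(), seed = NULL,
                           keep_trace = TRUE) {
  validate_session(stimuli)
  with_seed(seed, {
    u <- stats::runif(nrow(stimuli))
    sim <- simulate_cpp(as.integer(stimuli$category), stim_sum(stimuli),
                        new_session_flags(stimuli), u, as_par_vector(params))
    out <- stimuli
    out$response <- sim$response
    out$outcome <- ifelse(sim$correct == 1L, "correct", "error")
    if (keep_trace) {
      out <- cbind(out, as.data.frame(sim$trace))
    }
    out <- add_history_columns(out)
    class(out) <- c("session_table", "data.frame")
    out
  })
}

#' Simulate a multi-session experiment
#'
#' Convenience wrapper generating `n_sessions` stimulus sessions of
#' `trials_per_session` trials each and running [simulate_agent()] on the
#' combined table, under one seed.
#'
#' @param config A [task_config()].
#' @param params A [dynamic_params()].
#' @param n_sessions,trials_per_session Experiment size.
#' @param seed Optional integer seed.
#' @inheritParams simulate_agent
#' @return A session table covering all sessions.
#' @export
simulate_experiment <- function(config = task_config(),
                                params = dynamic_params(),
                                n_sessions = 20, trials_per_session = 500,
                                seed = NULL, keep_trace = TRUE) {
  with_seed(seed, {
    stim <- do.call(rbind, lapply(seq_len(n_sessions), function(i) {
      generate_stimulus_session(config, trials_per_session,
                                session_id = sprintf("s%03d", i))
    }))
    class(stim) <- c("session_table", "data.frame")
    simulate_agent(stim, params, keep_trace = keep_trace)
  })
}

# Negative log-posterior: exact sequential likelihood plus weak Gaussian
# priors (sd `prior_sd`) on the unbounded parameters; bounded parameters
# (leaks, gates, lapses) carry flat priors over their ranges.
.unbounded_pars <- c("delta_L_plus", "delta_L_minus",
                     "delta_T_pp", "delta_T_pm", "delta_T_mp", "delta_T_mm",
                     "w_stim", "fixed_bias")

neg_log_posterior <- function(par_free, free_names, par_full, arrays,
                              prior_sd) {
  par_full[free_names] <- par_free
  nll <- negloglik_cpp(arrays$resp, arrays$correct, arrays$stim,
                       arrays$new_session, arrays$valid, par_full[.par_order])
  pen <- sum(par_full[.unbounded_pars]^2) / (2 * prior_sd^2)
  nll + pen
}

param_bounds <- function() {
  lower <- stats::setNames(rep(-Inf, 16), .par_order)
  upper <- stats::setNames(rep(Inf, 16), .par_order)
  leaks <- c("lambda_L_plus", "lambda_L_minus", "lambda_T_plus", "lambda_T_minus")
  lower[leaks] <- 0; upper[leaks] <- 1
  gates <- c("delta_C_plus", "delta_C_minus")
  lower[gates] <- -1; upper[gates] <- 1
  lapses <- c("lapse_R", "lapse_L")
  lower[lapses] <- 0; upper[lapses] <- 0.5
  list(lower = lower, upper = upper)
}

random_start <- function(bounds, free_names) {
  v <- stats::setNames(numeric(length(.par_order)), .par_order)
  v[.unbounded_pars] <- stats::rnorm(length(.unbounded_pars), 0, 0.3)
  v["w_stim"] <- stats::runif(1, 0.05, 0.6)
  leaks <- c("lambda_L_plus", "lambda_L_minus", "lambda_T_plus", "lambda_T_minus")
  v[leaks] <- stats::runif(4, 0.05, 0.95)
  v[c("delta_C_plus", "delta_C_minus")] <- stats::runif(2, -1, 1)
  v[c("lapse_R", "lapse_L")] <- stats::runif(2, 0, 0.05)
  v[free_names]
}

#' Fit the gated-accumulator model by maximum a posteriori
#'
#' The latent variables are deterministic functions of the parameters and
#' the observed history, so the sequential likelihood is exact (no
#' filtering). The negative log-posterior (likelihood plus weak Gaussian
#' priors, sd 10, on the unbounded parameters) is minimized by
#' bound-constrained quasi-Newton (`L-BFGS-B`) from multiple starts: a
#' neutral start plus `n_starts - 1` random ones.
#'
#' @param session Session table with responses and outcomes.
#' @param init Optional [dynamic_params()] used as the first start.
#' @param n_starts Number of optimizer starts (default 10).
#' @param fixed Optional named numeric vector of parameters to hold fixed
#'   (e.g. `c(delta_C_plus = 0, delta_C_minus = 0)` for a no-gating
#'   variant).
#' @param prior_sd Standard deviation of the Gaussian priors.
#' @param seed Optional seed for the random starts.
#' @return An object of class `dynamic_fit`: fitted `params`,
#'   `log_posterior`, `log_lik`, `bic`, `n_trials`, `n_free`,
#'   `convergence` (0 = converged) and the per-start objective values.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(n_sessions = 2, trials_per_session = 200, seed = 1)
#' fit <- fit_dynamic_model(sim, n_starts = 2, seed = 1)
#' fit$params$delta_T_pp
#' }
#' @export
fit_dynamic_model <- function(session, init = NULL, n_starts = 10,
                              fixed = NULL, prior_sd = 10, seed = NULL) {
  validate_session(session, require_responses = TRUE)
  if (sum(!is.na(session$response)) == 0) stop("no valid trials to fit")
  arrays <- session_arrays(session)
  bounds <- param_bounds()
  par_full <- as_par_vector(if (is.null(init)) dynamic_params() else init)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), .par_order)
    if (length(bad) > 0) stop("unknown fixed parameters: ", paste(bad, collapse = ", "))
    par_full[names(fixed)] <- fixed
  }
  free_names <- setdiff(.par_order, names(fixed))
  neutral <- par_full[free_names]
  neutral[setdiff(free_names, c("w_stim", grep("lambda", free_names, value = TRUE)))] <- 0
  neutral[grep("lambda", free_names, value = TRUE)] <- 0.5
  if ("w_stim" %in% free_names) neutral["w_stim"] <- 0.2

  # canonical-hypothesis starts: the likelihood is multimodal (a no-gating
  # mode exists even for gated data), so plain random restarts are not
  # reliable; seed the optimizer with the gating and reset archetypes too
  archetype <- function(...) {
    v <- stats::setNames(numeric(length(.par_order)), .par_order)
    v[c("lambda_L_plus", "lambda_L_minus")] <- 0.5
    v[c("lambda_T_plus", "lambda_T_minus")] <- 0.2
    v["w_stim"] <- 0.2
    v["delta_T_pp"] <- 0.2
    over <- c(...)
    v[names(over)] <- over
    v[free_names]
  }
  starts <- with_seed(seed, {
    s <- list(if (is.null(init)) neutral else par_full[free_names])
    if (n_starts > 1) s <- c(s, list(neutral))
    if (n_starts > 2) {
      s <- c(s, list(archetype(delta_C_plus = 1, delta_C_minus = -1),
                     archetype(lambda_T_minus = 1)))
    }
    while (length(s) < n_starts) s <- c(s, list(random_start(bounds, free_names)))
    unique(s[seq_len(n_starts)])
  })

  runs <- lapply(starts, function(s0) {
    tryCatch(
      stats::optim(s0, neg_log_posterior, method = "L-BFGS-B",
                   lower = bounds$lower[free_names],
                   upper = bounds$upper[free_names],
                   control = list(maxit = 500, factr = 1e4),
                   free_names = free_names, par_full = par_full,
                   arrays = arrays, prior_sd = prior_sd),
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) stop("all optimizer starts failed")
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]
  # polish the winner with a tighter convergence tolerance
  polish <- tryCatch(
    stats::optim(best$par, neg_log_posterior, method = "L-BFGS-B",
                 lower = bounds$lower[free_names],
                 upper = bounds$upper[free_names],
                 control = list(maxit = 500, factr = 1e1),
                 free_names = free_names, par_full = par_full,
                 arrays = arrays, prior_sd = prior_sd),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  par_full[free_names] <- best$par
  nll <- negloglik_cpp(arrays$resp, arrays$correct, arrays$stim,
                       arrays$new_session, arrays$valid, par_full[.par_order])
  n_valid <- sum(arrays$valid)
  if (best$convergence != 0) {
    warning("optimizer did not report convergence (code ", best$convergence,
            "); returning best iterate")
  }
  structure(list(
    params = par_vector_to_params(par_full),
    fixed = fixed,
    log_posterior = -best$value,
    log_lik = -nll,
    n_trials = n_valid,
    n_free = length(free_names),
    bic = 2 * nll + length(free_names) * log(n_valid),
    convergence = best$convergence,
    start_values = values
  ), class = "dynamic_fit")
}

#' @export
print.dynamic_fit <- function(x, ...) {
  cat(sprintf("gated-accumulator MAP fit: %d trials, %d free parameters\n",
              x$n_trials, x$n_free))
  cat(sprintf("  log posterior %.2f | log lik %.2f | BIC %.2f | convergence %d\n",
              x$log_posterior, x$log_lik, x$bic, x$convergence))
  print(round(unlist(x$params), 4))
  invisible(x)
}

#' Decompose the repeating bias into lateral and transition contributions
#'
#' Projects the model's per-trial biases onto the repeat/alternate axis
#' (`gamma * r_{t-1}`) and averages them over the trials whose immediately
#' preceding history matches a pattern, giving the lateral and transition
#' contributions to the repeating bias and their sum.
#'
#' @param trace Latent trace (from [compute_latent_trace()] or
#'   [simulate_agent()]).
#' @param session The matching session table.
#' @param pattern A [history_pattern()] (or [rep_pattern()] output);
#'   `NULL` averages over all trials with a defined previous response.
#' @return A one-row data frame with `lateral`, `transition`, `total` and
#'   `n_trials`.
#' @export
decompose_repeating_bias <- function(trace, session, pattern = NULL) {
  stopifnot(nrow(trace) == nrow(session))
  if (!"prev_response" %in% names(session)) {
    session <- add_history_columns(session)
  }
  sel <- if (is.null(pattern)) !is.na(session$prev_response) else
    match_history_pattern(session, pattern)
  sel <- sel & !is.na(session$prev_response)
  if (!any(sel)) stop("no trials match the history pattern")
  pr <- session$prev_response[sel]
  data.frame(
    lateral = mean(trace$gamma_L[sel] * pr),
    transition = mean(trace$gamma_T[sel] * pr),
    total = mean((trace$gamma_L[sel] + trace$gamma_T[sel]) * pr),
    n_trials = sum(sel)
  )
}
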