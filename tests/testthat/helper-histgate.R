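# Build a session table with prescribed responses/outcomes. Categories are
# derived so that outcome == correct iff response == category; frames are
# all set to the trial evidence so the summed frame evidence is
# n_frames * evidence.
make_session <- function(response, outcome, category = NULL, evidence = NULL,
                         session_id = "s1", n_frames = 8, block = "repeating") {
  n <- length(response)
  stopifnot(length(outcome) == n)
  if (is.null(category)) {
    category <- ifelse(is.na(response), 1L,
                       ifelse(outcome == "correct", response, -response))
  }
  if (is.null(evidence)) evidence <- category * 0.23
  frames <- matrix(rep(evidence, n_frames), n, n_frames)
  colnames(frames) <- paste0("frame_", seq_len(n_frames))
  out <- data.frame(
    session_id = session_id, trial_index = seq_len(n), block = block,
    category = as.integer(category), strength = abs(evidence),
    evidence = evidence, frames,
    response = as.integer(response), outcome = outcome,
    stringsAsFactors = FALSE
  )
  class(out) <- c("session_table", "data.frame")
  out
}

# Independent brute-force oracle for the gated-accumulator recursion: the
# state entering trial t is recomputed from scratch by replaying trials
# 1..t-1, in plain R. Deliberately not shared with the package internals.
ref_state_before <- function(resp, corr, stim, p, t) {
  zL <- 0; zT <- 0; cT <- 1
  for (j in seq_len(t - 1)) {
    r <- resp[j]; o <- corr[j]
    dL <- if (o) p$delta_L_plus else p$delta_L_minus
    lL <- if (o) p$lambda_L_plus else p$lambda_L_minus
    zL <- (1 - lL) * zL + dL * r
    if (j >= 2) {
      Tj <- if (resp[j] == resp[j - 1]) 1 else -1
      po <- corr[j - 1]
      dT <- if (po && o) p$delta_T_pp else if (po && !o) p$delta_T_pm
            else if (!po && o) p$delta_T_mp else p$delta_T_mm
      lT <- if (o) p$lambda_T_plus else p$lambda_T_minus
      zT <- (1 - lT) * zT + dT * Tj
    }
    cT <- cT + if (o) p$delta_C_plus else p$delta_C_minus
    cT <- min(1, max(0, cT))
  }
  gT <- if (t >= 2) cT * zT * resp[t - 1] else 0
  y <- p$w_stim * stim[t] + zL + gT + p$fixed_bias
  pr <- p$lapse_R + (1 - p$lapse_R - p$lapse_L) * pnorm(y)
  list(z_L = zL, z_T = zT, c_T = cT, gamma_L = zL, gamma_T = gT,
       p_right = pr)
}

ref_latent_trace <- function(session, params) {
  fc <- grep("^frame_", names(session), value = TRUE)
  stim <- rowSums(as.matrix(session[, fc]))
  resp <- session$response
  corr <- session$outcome == "correct"
  n <- nrow(session)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("z_L", "z_T", "c_T", "gamma_L",
                                        "gamma_T", "p_right")))
  for (t in seq_len(n)) {
    out[t, ] <- unlist(ref_state_before(resp, corr, stim, params, t))
  }
  as.data.frame(out)
}

ref_negloglik <- function(session, params) {
  tr <- ref_latent_trace(session, params)
  p <- ifelse(session$response == 1, tr$p_right, 1 - tr$p_right)
  -sum(log(p))
}

# Sequential simulator of the history GLM itself (probit with lapses on
# hand-enumerated lagged regressors). Independent of build_design_matrix;
# used as the design-matrix/likelihood oracle in the GLM tests.
simulate_glm_agent <- function(n_trials, w_frame, w_tpp, w_lp, lapse = 0,
                               seed = 1) {
  set.seed(seed)
  cfg <- task_config()
  stim <- generate_stimulus_session(cfg, n_trials)
  fc <- grep("^frame_", names(stim), value = TRUE)
  frames <- as.matrix(stim[, fc])
  resp <- integer(n_trials); corr <- logical(n_trials)
  nl <- length(w_tpp)
  for (t in seq_len(n_trials)) {
    y <- sum(w_frame * frames[t, ])
    if (t >= 2) {
      for (k in seq_len(min(nl, t - 2))) {
        j <- t - k           # transition between trials j-1 and j
        if (j >= 2 && corr[j] && corr[j - 1]) {
          Tj <- if (resp[j] == resp[j - 1]) 1 else -1
          y <- y + w_tpp[k] * Tj * resp[t - 1]
        }
      }
      for (k in seq_len(min(length(w_lp), t - 1))) {
        if (corr[t - k]) y <- y + w_lp[k] * resp[t - k]
      }
    }
    p <- lapse + (1 - 2 * lapse) * pnorm(y)
    resp[t] <- if (runif(1) < p) 1L else -1L
    corr[t] <- resp[t] == stim$category[t]
  }
  stim$response <- resp
  stim$outcome <- ifelse(corr, "correct", "error")
  class(stim) <- c("session_table", "data.frame")
  stim
}
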