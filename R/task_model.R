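#' Generate a Markov-chain stimulus-category sequence
#'
#' Stimulus categories `c_k` in `{-1, +1}` form a two-state Markov chain:
#' each trial repeats the previous category with probability `p_rep` and
#' flips it otherwise, so the unconditioned probability of each category is
#' 1/2 for any `p_rep` in (0, 1).
#'
#' @param p_rep Repeat probability, in `[0, 1]`. May be a scalar or a vector
#'   of length `n_trials` (per-trial repeat probability, used for
#'   block-structured sessions).
#' @param n_trials Number of trials to generate (>= 1).
#' @param initial_category Category assumed on the (virtual) trial 0.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#'
#' @return Integer vector of `-1`/`+1` categories of length `n_trials`.
#' @examples
#' x <- generate_category_sequence(0.7, 1000, seed = 1)
#' mean(x[-1] == x[-1000])  # close to 0.7
#' @export
generate_category_sequence <- function(p_rep, n_trials,
                                       initial_category = 1L, seed = NULL) {
  stopifnot(n_trials >= 1, initial_category %in% c(-1L, 1L))
  if (any(p_rep < 0 | p_rep > 1)) stop("`p_rep` must lie in [0, 1]")
  p <- rep_len(p_rep, n_trials)
  with_seed(seed, {
    repeats <- stats::runif(n_trials) < p
    # cumulative product of +1 (repeat) / -1 (flip) steps
    steps <- ifelse(repeats, 1L, -1L)
    as.integer(initial_category * cumprod(steps))
  })
}

#' Per-trial block labels for a session
#'
#' Blocks of `block_length` trials alternate between the repeating and the
#' alternating stimulus statistics, starting with `config$first_block`.
#'
#' @param config A [task_config()].
#' @param n_trials Number of trials (>= 1).
#' @return Character vector of `"repeating"` / `"alternating"` labels.
#' @examples
#' table(generate_block_schedule(task_config(), 400))
#' @export
generate_block_schedule <- function(config, n_trials) {
  stopifnot(inherits(config, "task_config"), n_trials >= 1)
  block_idx <- (seq_len(n_trials) - 1L) %/% config$block_length
  types <- c("repeating", "alternating")
  if (config$first_block == "alternating") types <- rev(types)
  types[block_idx %% 2L + 1L]
}

# Shape parameters of the beta distribution on [0, 1] matching a stretched
# beta on [-1, 1] with mean `e` and variance `v`: u = (x + 1)/2 has mean
# m = (e + 1)/2 and variance v/4.
stretched_beta_shapes <- function(evidence, variance) {
  m <- (evidence + 1) / 2
  v <- variance / 4
  if (v >= m * (1 - m)) {
    stop(sprintf(
      "frame variance %.3g is infeasible for evidence %.3g (needs < %.3g)",
      variance, evidence, 4 * m * (1 - m)))
  }
  k <- m * (1 - m) / v - 1
  c(alpha = m * k, beta = (1 - m) * k)
}

#' Sample instantaneous frame evidence
#'
#' The instantaneous evidence of each 50 ms envelope frame is drawn i.i.d.
#' from a stretched beta distribution with support `[-1, 1]`, mean equal to
#' the trial's stimulus evidence `e` and fixed variance (0.06 by default in
#' [task_config()]). At `e = +/-1` the distribution degenerates to a point
#' mass and every frame equals `e` exactly.
#'
#' @param evidence Trial stimulus evidence `e = c * s`, in `[-1, 1]`.
#' @param n_frames Number of frames to draw (>= 1).
#' @param frame_variance Target variance for `|e| < 1`.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_frames` values in `[-1, 1]`.
#' @examples
#' mean(sample_frame_evidence(0.23, 1e4, seed = 1))  # close to 0.23
#' sample_frame_evidence(1, 4)                       # exactly 1, 1, 1, 1
#' @export
sample_frame_evidence <- function(evidence, n_frames, frame_variance = 0.06,
                                  seed = NULL) {
  stopifnot(length(evidence) == 1, abs(evidence) <= 1, n_frames >= 1,
            frame_variance > 0)
  if (abs(evidence) == 1) return(rep(evidence, n_frames))
  sh <- stretched_beta_shapes(evidence, frame_variance)
  with_seed(seed, 2 * stats::rbeta(n_frames, sh[["alpha"]], sh[["beta"]]) - 1)
}

#' Build the amplitude-modulated envelopes of one stimulus
#'
#' A stimulus is a superposition of two AM sounds whose per-frame amplitude
#' weights are set by the instantaneous evidence `S_f`:
#' `a^L = (1 + S_f) / 2` and `a^R = 1 - a^L`, so that `a^L + a^R = 1` in
#' every frame. Both are modulated by the common envelope factor
#' `1 + sin(2 * pi * f_am * t + phase)`, which is zero at `t = 0` for the
#' default phase `3 * pi / 2`; each frame spans one modulation cycle
#' (`1 / f_am`, i.e. 50 ms at 20 Hz).
#'
#' @param frames Vector of per-frame instantaneous evidence in `[-1, 1]`.
#' @param config A [task_config()] (AM frequency and phase).
#' @param sample_rate Samples per second; must exceed `2 * f_am`.
#' @return A list with `time`, `envelope_left`, `envelope_right` (amplitude
#'   weights over time), `modulation`, per-frame weights `amp_left`,
#'   `amp_right`, and `frame` (frame index per sample).
#' @examples
#' env <- build_am_stimulus(c(0.2, -0.5), task_config(), sample_rate = 1000)
#' range(env$envelope_left + env$envelope_right)  # exactly 1
#' @export
build_am_stimulus <- function(frames, config = task_config(),
                              sample_rate = 44100) {
  stopifnot(inherits(config, "task_config"))
  if (length(frames) == 0) stop("`frames` must be nonempty")
  if (any(abs(frames) > 1)) stop("frame evidence must lie in [-1, 1]")
  if (sample_rate <= 2 * config$f_am) {
    stop("`sample_rate` must exceed twice the AM frequency")
  }
  cycle <- 1 / config$f_am
  n_per_frame <- round(sample_rate * cycle)
  n <- n_per_frame * length(frames)
  t <- (seq_len(n) - 1L) / sample_rate
  frame_idx <- pmin((seq_len(n) - 1L) %/% n_per_frame + 1L, length(frames))
  amp_left <- (1 + frames) / 2
  amp_right <- 1 - amp_left            # bit-exact a^L + a^R = 1
  modulation <- 1 + sin(2 * pi * config$f_am * t + config$phase)
  list(
    time = t,
    envelope_left = amp_left[frame_idx],
    envelope_right = amp_right[frame_idx],
    modulation = modulation,
    amp_left = amp_left,
    amp_right = amp_right,
    frame = frame_idx
  )
}

#' Generate the stimulus side of a session
#'
#' Composes the block schedule, the Markov category sequence (with the
#' block's repeat probability applied trial by trial), independent uniform
#' draws of the stimulus strength, and stretched-beta frame evidence into a
#' session table (stimulus columns only; see [simulate_agent()] for
#' responses).
#'
#' @param config A [task_config()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param session_id Session identifier stored in the table.
#' @return A `session_table` data frame with columns `session_id`,
#'   `trial_index`, `block`, `category`, `strength`, `evidence` and
#'   `frame_1` ... `frame_<n_frames>`.
#' @examples
#' sess <- generate_stimulus_session(task_config(), 100, seed = 1)
#' head(sess[, 1:6])
#' @export
generate_stimulus_session <- function(config = task_config(), n_trials,
                                      seed = NULL, session_id = "s1") {
  stopifnot(inherits(config, "task_config"), n_trials >= 1)
  with_seed(seed, {
    block <- generate_block_schedule(config, n_trials)
    p_rep <- ifelse(block == "repeating",
                    config$p_rep_repeating, config$p_rep_alternating)
    category <- generate_category_sequence(p_rep, n_trials,
                                           config$initial_category)
    strength <- sample(config$strengths, n_trials, replace = TRUE,
                       prob = config$strength_probs)
    evidence <- category * strength
    frames <- matrix(NA_real_, n_trials, config$n_frames)
    for (t in seq_len(n_trials)) {
      frames[t, ] <- sample_frame_evidence(evidence[t], config$n_frames,
                                           config$frame_variance)
    }
    colnames(frames) <- paste0("frame_", seq_len(config$n_frames))
    out <- data.frame(
      session_id = session_id,
      trial_index = seq_len(n_trials),
      block = block,
      category = as.integer(category),
      strength = strength,
      evidence = evidence,
      frames,
      stringsAsFactors = FALSE
    )
    class(out) <- c("session_table", "data.frame")
    out
  })
}
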