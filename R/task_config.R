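#' Task configuration for the block-structured 2AFC stimulus generator
#'
#' Bundles the parameters of the stimulus side of the task: the two-state
#' Markov chain over stimulus categories, the block structure alternating
#' between repeating and alternating statistics, the set of stimulus
#' strengths, the per-frame instantaneous-evidence distribution and the
#' amplitude-modulation envelope.
#'
#' @param p_rep_repeating Probability that the stimulus category repeats the
#'   previous one inside a repeating block (default 0.7).
#' @param p_rep_alternating Repeat probability inside an alternating block
#'   (default 0.2).
#' @param block_length Number of trials per block (default 200).
#' @param strengths Set of stimulus strengths in `[0, 1]` from which the
#'   per-trial strength is drawn (default `c(0, 0.23, 0.48, 1)`).
#' @param strength_probs Sampling probabilities for `strengths`; default
#'   uniform.
#' @param frame_variance Variance of the stretched-beta distribution of the
#'   instantaneous frame evidence (default 0.06, in squared evidence units).
#' @param n_frames Number of envelope cycles (frames) per trial (default 8).
#' @param f_am Amplitude-modulation frequency in Hz (default 20, i.e. a
#'   50 ms cycle).
#' @param phase AM phase delay in radians (default `3 * pi / 2`, which makes
#'   the envelope zero at `t = 0`).
#' @param first_block Block type of the first block, `"repeating"` or
#'   `"alternating"`.
#' @param initial_category Category assumed before the first trial,
#'   `-1` or `+1`.
#'
#' @return An object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' cfg$p_rep_repeating
#' @export
task_config <- function(p_rep_repeating = 0.7,
                        p_rep_alternating = 0.2,
                        block_length = 200L,
                        strengths = c(0, 0.23, 0.48, 1),
                        strength_probs = NULL,
                        frame_variance = 0.06,
                        n_frames = 8L,
                        f_am = 20,
                        phase = 3 * pi / 2,
                        first_block = c("repeating", "alternating"),
                        initial_category = 1L) {
  first_block <- match.arg(first_block)
  stopifnot(
    p_rep_repeating >= 0, p_rep_repeating <= 1,
    p_rep_alternating >= 0, p_rep_alternating <= 1,
    block_length >= 1,
    all(strengths >= 0), all(strengths <= 1),
    frame_variance > 0,
    n_frames >= 1,
    f_am > 0,
    initial_category %in% c(-1L, 1L)
  )
  if (is.null(strength_probs)) {
    strength_probs <- rep(1 / length(strengths), length(strengths))
  }
  if (length(strength_probs) != length(strengths) ||
      any(strength_probs < 0) || abs(sum(strength_probs) - 1) > 1e-8) {
    stop("`strength_probs` must be a probability vector over `strengths`")
  }
  structure(
    list(
      p_rep_repeating = p_rep_repeating,
      p_rep_alternating = p_rep_alternating,
      block_length = as.integer(block_length),
      strengths = strengths,
      strength_probs = strength_probs,
      frame_variance = frame_variance,
      n_frames = as.integer(n_frames),
      f_am = f_am,
      phase = phase,
      first_block = first_block,
      initial_category = as.integer(initial_category)
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("2AFC task configuration\n")
  cat(sprintf("  P_rep: %.2f (repeating) / %.2f (alternating), blocks of %d trials\n",
              x$p_rep_repeating, x$p_rep_alternating, x$block_length))
  cat(sprintf("  strengths: {%s}, frame variance %.3f, %d frames/trial\n",
              paste(x$strengths, collapse = ", "), x$frame_variance, x$n_frames))
  cat(sprintf("  AM: %g Hz, phase %.4f rad, first block %s\n",
              x$f_am, x$phase, x$first_block))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL uses the ambient stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
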