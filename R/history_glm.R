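#' Build the trial-history design matrix
#'
#' Constructs the regressors of the history GLM. For trial `t`:
#' \itemize{
#'   \item `S_f1 ... S_fF`: the instantaneous evidence of each frame of
#'     the current stimulus;
#'   \item `A_k`: the summed frame evidence of trial `t - k` (sensory
#'     after-effect), `k = 1..n_lags`, with the last lag pooling trials
#'     `t - n_lags ... t - pool_to` under one weight;
#'   \item `Lp_k` / `Lm_k`: previous rewarded / unrewarded responses
#'     `r^+_{t-k}`, `r^-_{t-k}` coded `-1`/`+1` by side and 0 when the
#'     outcome does not match (same lag structure);
#'   \item `Tpp_k`, `Tpm_k`, `Tmp_k`, `Tmm_k`: previous transitions
#'     `T^{o,q}_{t-k} = r^o_{t-k-1} r^q_{t-k}` (+1 repetition, -1
#'     alternation, 0 when either outcome does not match the `o,q`
#'     slot), already multiplied by the projection `r_{t-1}`;
#'   \item `intercept`: the fixed side bias.
#' }
#' Trials without a defined previous response (session starts, trials
#' after invalid trials) are excluded; deeper missing history is
#' zero-padded.
#'
#' @param session A session table with responses.
#' @param n_lags Number of free history lags (default 6).
#' @param pool_to Deepest trial pooled into the last lag (default 10).
#' @return An object of class `design_matrix`: regressor matrix `X`,
#'   response indicator `y` (rightward = 1), `prev_outcome` per row,
#'   `row_index` into the session table, and a `families` table mapping
#'   columns to regressor family and lag.
#' @examples
#' sim <- simulate_experiment(n_sessions = 1, trials_per_session = 50, seed = 1)
#' d <- build_design_matrix(sim)
#' dim(d$X)
#' @export
build_design_matrix <- function(session, n_lags = 6, pool_to = 10) {
  session <- add_history_columns(validate_session(session,
                                                  require_responses = TRUE))
  stopifnot(n_lags >= 1, pool_to >= n_lags)
  n <- nrow(session)
  sid <- as.character(session$session_id)
  valid <- !is.na(session$response)
  resp <- ifelse(valid, session$response, 0L)
  corr <- valid & !is.na(session$outcome) & session$outcome == "correct"
  rp <- ifelse(corr, resp, 0)
  rm_ <- ifelse(valid & !corr, resp, 0)
  ssum <- stim_sum(session)

  shift <- function(x, k) {
    if (k >= n) return(rep(0, n))
    out <- c(rep(0, k), x[seq_len(n - k)])
    # zero out across session boundaries
    if (k > 0) {
      same <- c(rep(FALSE, k), sid[seq_len(n - k)] == sid[(k + 1):n])
      out[!same] <- 0
    }
    out
  }
  lagged <- function(x, k) if (k < n_lags) shift(x, k) else
    Reduce(`+`, lapply(n_lags:pool_to, function(j) shift(x, j)))

  frames <- as.matrix(session[, frame_cols(session), drop = FALSE])
  colnames(frames) <- sub("^frame_", "S_f", colnames(frames))

  # transitions at trial j, between j-1 and j
  tr_base <- list(
    Tpp = shift(rp, 1) * rp, Tpm = shift(rp, 1) * rm_,
    Tmp = shift(rm_, 1) * rp, Tmm = shift(rm_, 1) * rm_
  )
  r_prev <- shift(resp, 1)

  cols <- list()
  for (f in colnames(frames)) cols[[f]] <- frames[, f]
  for (k in seq_len(n_lags)) cols[[paste0("A_", k)]] <- lagged(ssum, k)
  for (fam in names(tr_base)) {
    for (k in seq_len(n_lags)) {
      cols[[paste0(fam, "_", k)]] <- lagged(tr_base[[fam]], k) * r_prev
    }
  }
  for (k in seq_len(n_lags)) cols[[paste0("Lp_", k)]] <- lagged(rp, k)
  for (k in seq_len(n_lags)) cols[[paste0("Lm_", k)]] <- lagged(rm_, k)
  cols[["intercept"]] <- rep(1, n)

  X <- do.call(cbind, cols)
  keep <- valid & !is.na(session$prev_response)
  fams <- data.frame(
    column = colnames(X),
    family = sub("_[0-9]+$", "", sub("^S_f[0-9]+$", "S", colnames(X))),
    lag = suppressWarnings(as.integer(sub("^.*_", "", colnames(X)))),
    stringsAsFactors = FALSE
  )
  fams$lag[fams$family %in% c("S", "intercept")] <- NA_integer_
  structure(list(
    X = X[keep, , drop = FALSE],
    y = as.integer(session$response[keep] == 1),
    prev_outcome = session$prev_outcome[keep],
    row_index = which(keep),
    families = fams,
    n_lags = n_lags, pool_to = pool_to
  ), class = "design_matrix")
}

glm_nll <- function(par, X, y, lambda, pen_idx) {
  p0 <- ncol(X)
  w <- par[seq_len(p0)]
  piR <- par[p0 + 1L]; piL <- par[p0 + 2L]
  p <- piR + (1 - piR - piL) * stats::pnorm(drop(X %*% w))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log1p(-p)) + lambda * sum(w[pen_idx]^2)
}

glm_grad <- function(par, X, y, lambda, pen_idx) {
  p0 <- ncol(X)
  w <- par[seq_len(p0)]
  piR <- par[p0 + 1L]; piL <- par[p0 + 2L]
  eta <- drop(X %*% w)
  Phi <- stats::pnorm(eta)
  phi <- stats::dnorm(eta)
  p <- piR + (1 - piR - piL) * Phi
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  resid <- (y - p) / (p * (1 - p))
  gw <- -drop(crossprod(X, resid * (1 - piR - piL) * phi))
  gw[pen_idx] <- gw[pen_idx] + 2 * lambda * w[pen_idx]
  gR <- -sum(resid * (1 - Phi))
  gL <- sum(resid * Phi)
  c(gw, gR, gL)
}

#' Fit the history GLM
#'
#' Penalized maximum likelihood for the probit-with-lapses choice model
#' `p(r_t = +1) = pi_R + (1 - pi_L - pi_R) Phi(y_t)` with `y_t` the linear
#' combination of the design-matrix regressors. A small L2 penalty
#' (default 1e-4) stabilizes the weights; lapses are bound-constrained to
#' `[0, 0.5]`. Rank-deficient regressors (exact collinearities arise at
#' low lags when conditioning on the previous outcome) are detected by a
#' QR rank check and dropped, keeping the earlier column in the design
#' order (stimulus, after-effect, transition, lateral); dropped weights
#' are reported as `NA`.
#'
#' @param design A [build_design_matrix()] result.
#' @param condition `"all"`, `"after_correct"` or `"after_error"`: which
#'   trials to fit, by previous outcome.
#' @param lambda L2 penalty on all weights except the intercept.
#' @param se One of `"hessian"` (observed information, default) or
#'   `"none"`.
#' @return An object of class `history_glm`: named `weights` and `se`
#'   (with `NA` for dropped columns), `lapse_R`, `lapse_L` (+ ses),
#'   `log_lik`, `n_trials`, `n_params`, `dropped`, `condition`,
#'   `convergence`.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(n_sessions = 4, trials_per_session = 250, seed = 1)
#' fit <- fit_glm(build_design_matrix(sim), condition = "after_correct")
#' glm_kernels(fit)[1:3, ]
#' }
#' @export
fit_glm <- function(design, condition = c("all", "after_correct", "after_error"),
                    lambda = 1e-4, se = c("hessian", "none")) {
  stopifnot(inherits(design, "design_matrix"))
  condition <- match.arg(condition)
  se <- match.arg(se)
  rows <- switch(condition,
                 all = rep(TRUE, length(design$y)),
                 after_correct = design$prev_outcome == "correct",
                 after_error = design$prev_outcome == "error")
  rows[is.na(rows)] <- FALSE
  X <- design$X[rows, , drop = FALSE]
  y <- design$y[rows]
  if (length(y) == 0) stop("no trials in condition ", condition)

  all_names <- colnames(X)
  nonzero <- colSums(abs(X)) > 0
  Xnz <- X[, nonzero, drop = FALSE]
  qrX <- qr(Xnz)
  kept_nz <- sort(qrX$pivot[seq_len(qrX$rank)])
  Xk <- Xnz[, kept_nz, drop = FALSE]
  kept <- colnames(Xk)
  dropped <- setdiff(all_names, kept)

  p0 <- ncol(Xk)
  pen_idx <- which(kept != "intercept")
  par0 <- c(rep(0, p0), 0.02, 0.02)
  lower <- c(rep(-Inf, p0), 0, 0)
  upper <- c(rep(Inf, p0), 0.5, 0.5)
  opt <- stats::optim(par0, glm_nll, glm_grad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 1000, factr = 1e4),
                      X = Xk, y = y, lambda = lambda, pen_idx = pen_idx)
  if (opt$convergence != 0) {
    warning("GLM fit did not report convergence (code ", opt$convergence, ")")
  }
  ses <- rep(NA_real_, p0 + 2)
  if (se == "hessian") {
    H <- stats::optimHess(opt$par, glm_nll, glm_grad,
                          X = Xk, y = y, lambda = lambda, pen_idx = pen_idx)
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      v <- diag(cov)
      pos <- is.finite(v) & v > 0
      ses[pos] <- sqrt(v[pos])
    }
  }
  full <- function(x) {
    out <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
    out[kept] <- x
    out
  }
  nll_unpen <- glm_nll(opt$par, Xk, y, 0, integer(0))
  structure(list(
    weights = full(opt$par[seq_len(p0)]),
    se = full(ses[seq_len(p0)]),
    lapse_R = opt$par[p0 + 1L], lapse_L = opt$par[p0 + 2L],
    lapse_R_se = ses[p0 + 1L], lapse_L_se = ses[p0 + 2L],
    log_lik = -nll_unpen,
    n_trials = length(y),
    n_params = p0 + 2L,
    dropped = dropped,
    condition = condition,
    lambda = lambda,
    families = design$families,
    convergence = opt$convergence
  ), class = "history_glm")
}

#' @export
print.history_glm <- function(x, ...) {
  cat(sprintf("history GLM fit [%s]: %d trials, %d parameters, log lik %.2f\n",
              x$condition, x$n_trials, x$n_params, x$log_lik))
  cat(sprintf("  lapses: pi_R %.3f, pi_L %.3f\n", x$lapse_R, x$lapse_L))
  if (length(x$dropped) > 0) {
    cat("  dropped (collinear/empty):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy kernel table of a history GLM fit
#'
#' @param fit A [fit_glm()] result.
#' @return Data frame with `condition`, `family`, `lag`, `weight`, `se`.
#' @export
glm_kernels <- function(fit) {
  stopifnot(inherits(fit, "history_glm"))
  fams <- fit$families
  data.frame(
    condition = fit$condition,
    family = fams$family,
    lag = fams$lag,
    weight = unname(fit$weights[fams$column]),
    se = unname(fit$se[fams$column]),
    stringsAsFactors = FALSE
  )
}

#' Per-trial choice probabilities under a fitted history GLM
#'
#' Dropped (collinear) columns contribute zero. Probabilities are bounded
#' in `[pi_R, 1 - pi_L]` by construction.
#'
#' @param fit A [fit_glm()] result.
#' @param design A [build_design_matrix()] result with the same column
#'   structure.
#' @return Numeric vector of rightward-response probabilities, one per
#'   design row.
#' @export
predict_glm <- function(fit, design) {
  stopifnot(inherits(fit, "history_glm"), inherits(design, "design_matrix"))
  if (!identical(colnames(design$X), names(fit$weights))) {
    stop("design columns do not match the fitted weights")
  }
  w <- ifelse(is.na(fit$weights), 0, fit$weights)
  eta <- drop(design$X %*% w)
  fit$lapse_R + (1 - fit$lapse_R - fit$lapse_L) * stats::pnorm(eta)
}

holdout_loglik <- function(fit, design) {
  rows <- switch(fit$condition,
                 all = rep(TRUE, length(design$y)),
                 after_correct = design$prev_outcome == "correct",
                 after_error = design$prev_outcome == "error")
  rows[is.na(rows)] <- FALSE
  sub <- design
  sub$X <- design$X[rows, , drop = FALSE]
  sub$y <- design$y[rows]
  p <- pmin(pmax(predict_glm(fit, sub), 1e-12), 1 - 1e-12)
  sum(sub$y * log(p) + (1 - sub$y) * log1p(-p))
}

#' Compare history GLM variants
#'
#' Ranks model variants by BIC on the training data and, optionally, by
#' log-likelihood on held-out sessions. A *model* is either a single
#' [fit_glm()] result or a list of fits over disjoint conditions (e.g.
#' the split after-correct / after-error model), whose likelihoods are
#' summed.
#'
#' @param fits Named list of models.
#' @param held_out Optional held-out session table.
#' @return Data frame with `model`, `n_params`, `train_loglik`,
#'   `train_n`, `bic` and (if `held_out` is given) `holdout_loglik`.
#' @export
compare_models <- function(fits, held_out = NULL) {
  if (inherits(fits, "history_glm")) fits <- list(model = fits)
  hdesign <- if (!is.null(held_out)) build_design_matrix(held_out)
  rows <- lapply(names(fits), function(nm) {
    m <- fits[[nm]]
    if (inherits(m, "history_glm")) m <- list(m)
    ll <- sum(vapply(m, `[[`, numeric(1), "log_lik"))
    k <- sum(vapply(m, `[[`, numeric(1), "n_params"))
    n <- sum(vapply(m, `[[`, numeric(1), "n_trials"))
    out <- data.frame(model = nm, n_params = k, train_loglik = ll,
                      train_n = n, bic = -2 * ll + k * log(n),
                      stringsAsFactors = FALSE)
    if (!is.null(hdesign)) {
      out$holdout_loglik <- sum(vapply(m, holdout_loglik, numeric(1),
                                       design = hdesign))
    }
    out
  })
  out <- do.call(rbind, rows)
  out[order(out$bic), , drop = FALSE]
}
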