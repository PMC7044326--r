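test_that("transition regressors encode hand-worked choice sequences", {
  # four correct choices R+ R+ R+ L+, then a current trial
  sess <- make_session(c(1L, 1L, 1L, -1L, 1L), rep("correct", 5))
  d <- build_design_matrix(sess)
  row5 <- d$X[d$row_index == 5, ]
  # transitions Rep++, Rep++, Alt++ at lags 3, 2, 1, projected by r4 = -1
  expect_equal(unname(row5[c("Tpp_1", "Tpp_2", "Tpp_3")]), c(1, -1, -1))
  expect_equal(unname(row5[c("Tpm_1", "Tmp_1", "Tmm_1")]), c(0, 0, 0))
  # lateral kernel sees correct responses only
  expect_equal(unname(row5[c("Lp_1", "Lp_2", "Lp_4")]), c(-1, 1, 1))
  expect_equal(unname(row5[c("Lm_1", "Lm_2")]), c(0, 0))
  # after-effect regressor carries the previous summed frame evidence
  expect_equal(unname(row5["A_1"]), sum(sess[4, grep("^frame_", names(sess))]))

  # R+ R+ R+ R-: the last transition becomes type +-
  sess2 <- make_session(c(1L, 1L, 1L, 1L, 1L),
                        c("correct", "correct", "correct", "error", "correct"))
  row5b <- d2row <- build_design_matrix(sess2)
  row5b <- d2row$X[d2row$row_index == 5, ]
  expect_equal(unname(row5b["Tpp_1"]), 0)
  expect_equal(unname(row5b["Tpm_1"]), 1)   # rp3 * rm4 * r4 = 1
  expect_equal(unname(row5b["Lp_1"]), 0)    # error at t-1 ...
  expect_equal(unname(row5b["Lm_1"]), 1)    # ... loads the unrewarded kernel
})

test_that("history beyond the session start is zero-padded and lag 6 pools to lag 10", {
  sim <- simulate_experiment(n_sessions = 1, trials_per_session = 30,
                             seed = 1, keep_trace = FALSE)
  d <- build_design_matrix(sim)
  row2 <- d$X[d$row_index == 2, ]
  deep <- grep("^(Tpp|Tpm|Tmp|Tmm)_[2-6]$|^(Lp|Lm|A)_[2-6]$", names(row2))
  expect_true(all(row2[deep] == 0))
  # pooled tail: lag-6 lateral regressor sums rewarded responses at lags 6..10
  t <- 15
  rowt <- d$X[d$row_index == t, ]
  rp <- ifelse(sim$outcome == "correct", sim$response, 0)
  expect_equal(unname(rowt["Lp_6"]), sum(rp[(t - 10):(t - 6)]))
  expect_equal(unname(rowt["Lp_3"]), rp[t - 3])
})

test_that("the GLM likelihood matches a brute-force enumeration on a tiny session", {
  sim <- simulate_experiment(n_sessions = 1, trials_per_session = 12,
                             seed = 2, keep_trace = FALSE)
  d <- build_design_matrix(sim, n_lags = 2, pool_to = 2)
  # independent enumeration of the regressors
  fcols <- grep("^frame_", names(sim))
  rp <- ifelse(sim$outcome == "correct", sim$response, 0)
  rm_ <- ifelse(sim$outcome == "error", sim$response, 0)
  ssum <- rowSums(sim[, fcols])
  for (t in 2:12) {
    row <- d$X[d$row_index == t, ]
    expect_equal(unname(row[paste0("S_f", 1:8)]),
                 unlist(sim[t, fcols], use.names = FALSE))
    for (k in 1:2) {
      expect_equal(unname(row[paste0("A_", k)]),
                   if (t - k >= 1) ssum[t - k] else 0)
      expect_equal(unname(row[paste0("Lp_", k)]),
                   if (t - k >= 1) rp[t - k] else 0)
      expect_equal(unname(row[paste0("Lm_", k)]),
                   if (t - k >= 1) rm_[t - k] else 0)
      tpp <- if (t - k >= 2) rp[t - k - 1] * rp[t - k] * sim$response[t - 1] else 0
      expect_equal(unname(row[paste0("Tpp_", k)]), tpp)
    }
    expect_equal(unname(row["intercept"]), 1)
  }
  # likelihood equality for an arbitrary weight setting, lapses included
  set.seed(3)
  w <- rnorm(ncol(d$X), 0, 0.3)
  piR <- 0.07; piL <- 0.11
  p_manual <- piR + (1 - piR - piL) * pnorm(drop(d$X %*% w))
  nll_manual <- -sum(ifelse(d$y == 1, log(p_manual), log(1 - p_manual)))
  nll_pkg <- histgate:::glm_nll(c(w, piR, piL), d$X, d$y, 0, integer(0))
  expect_equal(nll_pkg, nll_manual, tolerance = 1e-10)
})

test_that("fitting recovers the kernels of a synthetic GLM agent", {
  truth_tpp <- c(0.4, 0.2, 0.1, 0, 0, 0)
  truth_lp <- c(0.1, 0.05, 0, 0, 0, 0)
  sim <- simulate_glm_agent(20000, w_frame = rep(0.25, 8),
                            w_tpp = truth_tpp, w_lp = truth_lp, seed = 4)
  fit <- fit_glm(build_design_matrix(sim), condition = "all")
  k <- glm_kernels(fit)
  tpp <- k[k$family == "Tpp", ]
  expect_true(all(abs(tpp$weight[1:3] - truth_tpp[1:3]) <
                    3 * tpp$se[1:3] + 0.02))
  sf <- k[k$family == "S", ]
  expect_true(all(abs(sf$weight - 0.25) < 3 * sf$se + 0.02))
  expect_lt(fit$lapse_R, 0.05)
})

test_that("a stimulus-only agent yields flat history kernels and positive stimulus weights", {
  sim <- simulate_experiment(task_config(), stimulus_only_params(),
                             n_sessions = 20, trials_per_session = 500,
                             seed = 5, keep_trace = FALSE)
  fit <- fit_glm(build_design_matrix(sim), condition = "all")
  k <- glm_kernels(fit)
  hist_k <- k[k$family %in% c("Tpp", "Tpm", "Tmp", "Tmm", "Lp", "Lm") &
                !is.na(k$weight), ]   # lag-2 lateral terms are collinear
  expect_lt(max(abs(hist_k$weight)), 0.1)
  expect_true(all(k$weight[k$family == "S"] > 0))
})

test_that("mirroring left and right negates the intercept and preserves the kernels", {
  sim <- simulate_experiment(n_sessions = 8, trials_per_session = 300,
                             seed = 6, keep_trace = FALSE)
  mirror <- sim
  mirror$response <- -sim$response
  mirror$category <- -sim$category
  mirror$evidence <- -sim$evidence
  fcols <- grep("^frame_", names(sim), value = TRUE)
  mirror[, fcols] <- -sim[, fcols]
  f1 <- fit_glm(build_design_matrix(sim), condition = "all", se = "none")
  f2 <- fit_glm(build_design_matrix(mirror), condition = "all", se = "none")
  expect_equal(unname(f2$weights["intercept"]),
               -unname(f1$weights["intercept"]), tolerance = 2e-2)
  kk <- setdiff(names(f1$weights), "intercept")
  expect_equal(f1$weights[kk], f2$weights[kk], tolerance = 2e-2)
})

test_that("outcome conditioning drops the exactly collinear low-lag columns", {
  sim <- simulate_experiment(n_sessions = 10, trials_per_session = 500,
                             seed = 7, keep_trace = FALSE)
  d <- build_design_matrix(sim)
  fc <- fit_glm(d, "after_correct", se = "none")
  # conditioned on a correct previous trial, Tpp_1 coincides with Lp_2 and
  # the error families vanish at lag 1
  expect_true(all(c("Tpm_1", "Tmm_1", "Lm_1") %in% fc$dropped))
  expect_true("Lp_2" %in% fc$dropped)
  expect_false("Tpp_1" %in% fc$dropped)
  expect_true(is.na(fc$weights["Tpm_1"]))
  fe <- fit_glm(d, "after_error", se = "none")
  expect_true(all(c("Tpp_1", "Tmp_1", "Lp_1") %in% fe$dropped))
})

test_that("predictions respect the lapse bounds and zero weights give chance", {
  sim <- simulate_experiment(n_sessions = 2, trials_per_session = 200,
                             seed = 8, keep_trace = FALSE)
  d <- build_design_matrix(sim)
  fit <- fit_glm(d, "all", se = "none")
  p <- predict_glm(fit, d)
  expect_true(all(p >= fit$lapse_R - 1e-12))
  expect_true(all(p <= 1 - fit$lapse_L + 1e-12))
  fit0 <- fit
  fit0$weights[] <- 0
  fit0$lapse_R <- 0; fit0$lapse_L <- 0
  expect_equal(predict_glm(fit0, d), rep(0.5, length(d$y)))
})

test_that("the outcome-split model beats the pooled model on gating-agent data", {
  train <- simulate_experiment(n_sessions = 60, trials_per_session = 500,
                               seed = 9, keep_trace = FALSE)
  test_sess <- simulate_experiment(n_sessions = 4, trials_per_session = 500,
                                   seed = 10, keep_trace = FALSE)
  d <- build_design_matrix(train)
  pooled <- fit_glm(d, "all", se = "none")
  split <- list(fit_glm(d, "after_correct", se = "none"),
                fit_glm(d, "after_error", se = "none"))
  cmp <- compare_models(list(pooled = pooled, split = split),
                        held_out = test_sess)
  expect_identical(cmp$model[1], "split")                 # best BIC first
  sp <- cmp[cmp$model == "split", ]
  po <- cmp[cmp$model == "pooled", ]
  expect_gt(sp$holdout_loglik, po$holdout_loglik)
})
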