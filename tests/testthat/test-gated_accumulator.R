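test_that("gating updates extinguish and restore c_T at its bounds", {
  p <- dynamic_params(delta_C_plus = 1, delta_C_minus = -1)
  st <- list(z_L = 0, z_T = 0.5, c_T = 0.8)
  after_err <- update_latents(st, response = 1, outcome = "error",
                              prev_outcome = "correct", transition = 1,
                              params = dynamic_params(delta_T_pm = 0))
  expect_identical(after_err$c_T, 0)
  st0 <- list(z_L = 0, z_T = 0.5, c_T = 0)
  after_corr <- update_latents(st0, response = 1, outcome = "correct",
                               prev_outcome = "correct", transition = 1,
                               params = p)
  expect_identical(after_corr$c_T, 1)
})

test_that("the outcome-dependent leak retains the stated fraction of z_T", {
  p <- dynamic_params(lambda_T_minus = 0.2, delta_T_pm = 0)
  st <- list(z_L = 0, z_T = 0.6, c_T = 1)
  out <- update_latents(st, response = 1, outcome = "error",
                        prev_outcome = "correct", transition = 1, params = p)
  expect_equal(out$z_T, 0.48)
  # lateral update arithmetic
  p2 <- dynamic_params(delta_L_plus = 0.1, lambda_L_plus = 0.5)
  out2 <- update_latents(list(z_L = 0.4, z_T = 0, c_T = 1), response = -1,
                         outcome = "correct", prev_outcome = "correct",
                         transition = -1, params = p2)
  expect_equal(out2$z_L, 0.4 * 0.5 - 0.1)
})

test_that("c_T stays within [0, 1] for random parameters and histories", {
  set.seed(42)
  for (i in 1:10) {
    p <- dynamic_params(delta_C_plus = runif(1, -1, 1),
                        delta_C_minus = runif(1, -1, 1),
                        delta_T_pm = rnorm(1, 0, 0.3),
                        delta_T_mp = rnorm(1, 0, 0.3),
                        lambda_T_plus = runif(1), lambda_T_minus = runif(1))
    sim <- simulate_experiment(task_config(), p, n_sessions = 1,
                               trials_per_session = 300)
    expect_true(all(sim$c_T >= 0 & sim$c_T <= 1))
  }
})

test_that("choice probability is symmetric, gated and lapse-bounded", {
  p <- dynamic_params()
  st0 <- list(z_L = 0, z_T = 0, c_T = 1)
  expect_equal(choice_probability(st0, 0, NA, dynamic_params(fixed_bias = 0)),
               0.5)
  # a closed gate disconnects z_T from choice
  stA <- list(z_L = 0, z_T = 3, c_T = 0)
  stB <- list(z_L = 0, z_T = -7, c_T = 0)
  expect_equal(choice_probability(stA, 0.1, 1, p),
               choice_probability(stB, 0.1, 1, p))
  # lapse ceiling 1 - pi_L
  pl <- dynamic_params(lapse_R = 0.1, lapse_L = 0.1, w_stim = 1)
  expect_equal(choice_probability(st0, 50, 1, pl), 0.9)
  expect_equal(choice_probability(st0, -50, 1, pl), 0.1)
})

test_that("the sequential recursion matches brute-force recomputation from scratch", {
  sim <- simulate_experiment(n_sessions = 1, trials_per_session = 40,
                             seed = 31)
  for (pars in list(dynamic_params(),
                    dynamic_params(delta_T_pm = -0.2, delta_T_mp = 0.15,
                                   delta_C_plus = 0.4, delta_C_minus = -0.6,
                                   lambda_T_minus = 0.7, fixed_bias = 0.1,
                                   lapse_R = 0.05, lapse_L = 0.08))) {
    got <- compute_latent_trace(sim, pars)
    want <- ref_latent_trace(sim, pars)
    expect_equal(got, want, tolerance = 1e-12)
    a <- histgate:::session_arrays(sim)
    nll <- histgate:::negloglik_cpp(a$resp, a$correct, a$stim, a$new_session,
                                    a$valid, histgate:::as_par_vector(pars))
    expect_equal(nll, ref_negloglik(sim, pars), tolerance = 1e-10)
  }
})

test_that("latents restart at session boundaries", {
  sim1 <- simulate_experiment(n_sessions = 2, trials_per_session = 25,
                              seed = 32)
  tr <- compute_latent_trace(sim1, dynamic_params())
  start2 <- 26
  expect_identical(tr$z_L[start2], 0)
  expect_identical(tr$z_T[start2], 0)
  expect_identical(tr$c_T[start2], 1)
})

test_that("errors close the gate while transition evidence is retained", {
  sim <- simulate_experiment(n_sessions = 4, trials_per_session = 400,
                             seed = 33)
  post_error <- which(sim$prev_outcome == "error")
  expect_true(length(post_error) > 50)
  expect_true(all(sim$gamma_T[post_error] == 0))
  # z_T after an error keeps (1 - lambda_T_minus) of its value
  err <- which(sim$outcome == "error" & sim$trial_index > 1 &
                 sim$trial_index < 400)
  held <- sim$z_T[err + 1] - (1 - 0.2) * sim$z_T[err]
  expect_lt(max(abs(held)), 1e-12)   # delta_T_pm = delta_T_mm = 0
})

test_that("a history-free agent performs exactly at its stimulus-only probit level", {
  p <- stimulus_only_params(w_stim = 0.25)
  sim <- simulate_experiment(task_config(), p, n_sessions = 10,
                             trials_per_session = 500, seed = 34)
  stim <- rowSums(sim[, grep("^frame_", names(sim))])
  expected_acc <- mean(pnorm(0.25 * stim * sim$category))
  expect_lt(abs(mean(sim$outcome == "correct") - expected_acc), 0.02)
  expect_true(all(sim$gamma_T == 0))
  expect_true(all(sim$gamma_L == 0))
})

test_that("MAP fitting rejects empty sessions and recovers the main parameters", {
  empty <- make_session(c(NA_integer_, NA_integer_), c(NA, NA))
  expect_error(fit_dynamic_model(empty), "no valid trials")

  sim <- simulate_experiment(n_sessions = 8, trials_per_session = 400,
                             seed = 35, keep_trace = FALSE)
  fit <- fit_dynamic_model(sim, n_starts = 4, seed = 36)
  expect_identical(fit$convergence, 0L)
  expect_gt(fit$params$delta_T_pp, 0.1)
  expect_lt(fit$params$delta_C_minus, -0.3)
  expect_lt(abs(fit$params$w_stim - 0.25), 0.1)
  expect_lt(fit$bic, 2 * 0.6931 * fit$n_trials)  # beats a coin-flip model
})

test_that("a fixed no-gating variant stays fixed and fits worse on gating data", {
  sim <- simulate_experiment(n_sessions = 8, trials_per_session = 400,
                             seed = 37, keep_trace = FALSE)
  full <- fit_dynamic_model(sim, n_starts = 4, seed = 38)
  reduced <- fit_dynamic_model(sim, n_starts = 4, seed = 38,
                               fixed = c(delta_C_plus = 0, delta_C_minus = 0))
  expect_identical(reduced$params$delta_C_plus, 0)
  expect_identical(reduced$n_free, 14L)
  expect_lt(full$bic, reduced$bic)
})

test_that("the repeating bias decomposes into lateral and transition parts", {
  sim <- simulate_experiment(n_sessions = 20, trials_per_session = 500,
                             seed = 39)
  trace <- sim[, c("z_L", "z_T", "c_T", "gamma_L", "gamma_T", "p_right")]
  # series of correct repetitions: both contributions push to repeat
  drep <- decompose_repeating_bias(trace, sim, rep_pattern(3))
  expect_gt(drep$lateral, 0)
  expect_gt(drep$transition, 0)
  expect_equal(drep$total, drep$lateral + drep$transition)
  # series of correct alternations: lateral oscillates near zero
  dalt <- decompose_repeating_bias(trace, sim,
                                   rep_pattern(3, transition = "alternate"))
  expect_lt(dalt$transition, 0)
  expect_lt(abs(dalt$lateral), 0.5 * abs(dalt$transition))
  # zero history weights -> zero contributions
  p0 <- stimulus_only_params()
  sim0 <- simulate_experiment(task_config(), p0, n_sessions = 2,
                              trials_per_session = 200, seed = 40)
  tr0 <- sim0[, c("z_L", "z_T", "c_T", "gamma_L", "gamma_T", "p_right")]
  d0 <- decompose_repeating_bias(tr0, sim0, NULL)
  expect_identical(d0$lateral, 0)
  expect_identical(d0$transition, 0)
  expect_error(decompose_repeating_bias(tr0, sim0,
                                        history_pattern(rep("err", 150))),
               "no trials match")
})
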