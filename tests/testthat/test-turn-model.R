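test_that("the logit GLM evaluates the fitted parameters correctly", {
  g <- test_glm()
  expect_equal(lambda_of(g, 0), 1 / (1 + exp(0.3534)), tolerance = 1e-6)
  expect_equal(round(lambda_of(g, 0), 4), 0.4126)
  ## high firing suppresses turning
  expect_lt(lambda_of(g, 100), 1e-5)
  expect_equal(lambda_of(turn_glm_params(preset = NULL), 0), 0.5)
  ## monotone in the input for gamma1 < 0
  ys <- seq(0, 30, by = 1)
  expect_true(all(diff(lambda_of(g, ys)) < 0))
  expect_true(all(lambda_of(g, seq(-100, 100)) >= 0 &
                  lambda_of(g, seq(-100, 100)) <= 1))
})

test_that("rectified-linear link clamps to [0, 1]", {
  g <- turn_glm_params("rectified")
  expect_equal(lambda_of(g, 0), 0.3762)
  expect_equal(lambda_of(g, 100), 0)       # rectified at zero
  g2 <- turn_glm_params(preset = NULL, gamma0 = 2, gamma1 = 0,
                        link = "rectified_linear")
  expect_equal(lambda_of(g2, 5), 1)        # capped at one
})

test_that("derivative control model requires and uses its extra input", {
  g <- turn_glm_params("control_derivative")
  expect_error(lambda_of(g, 50), "derivative")
  l0 <- lambda_of(g, 50, derivative = 0)
  l1 <- lambda_of(g, 50, derivative = 10)
  expect_lt(l1, l0)   # gamma2 < 0: rising stimulus suppresses turning
  expect_error(turn_glm_params(preset = NULL,
                               input_kind = "stimulus+derivative"),
               "gamma2")
})

test_that("turn probability estimator matches direct counts and survival law", {
  ## 10 runs, exactly 2 end within the first window
  ens <- run_ensemble(c(0.6, 0.9, rep(3, 8)), rep(TRUE, 10),
                      min_duration = 0)
  est <- estimate_turn_probability(ens)
  expect_equal(est$lambda[which.min(abs(est$t - 0.5))], 0.2)
  ## all runs censored and outlasting the horizon: lambda 0 early on
  ens2 <- run_ensemble(rep(5, 6), rep(FALSE, 6), min_duration = 0)
  est2 <- estimate_turn_probability(ens2)
  expect_true(all(est2$lambda[est2$t < 4] == 0))
  ## i.i.d. exponential durations at rate r: flat lambda ~ 1 - exp(-r)
  set.seed(8)
  r <- 0.35
  ens3 <- run_ensemble(stats::rexp(4000, r), rep(TRUE, 4000),
                       min_duration = 0)
  est3 <- estimate_turn_probability(ens3)
  sel <- est3$reliable & est3$t > 0.5
  expect_equal(mean(est3$lambda[sel]), 1 - exp(-r), tolerance = 0.03)
  sm <- stats::filter(est3$lambda[sel], rep(1 / 31, 31), sides = 2)
  expect_lt(diff(range(sm, na.rm = TRUE)), 0.12)
  expect_error(estimate_turn_probability(run_ensemble(numeric(0),
                                                      logical(0))),
               "empty")
})

test_that("resampling error bars are reproducible and shrink with ensemble size", {
  set.seed(9)
  mk <- function(n) run_ensemble(stats::rexp(n, 0.4), rep(TRUE, n),
                                 min_duration = 0)
  e1 <- mk(150)
  a <- resample_errorbars(e1, n_resamples = 60, seed = 4)
  b <- resample_errorbars(e1, n_resamples = 60, seed = 4)
  expect_equal(a$std, b$std)
  e2 <- mk(600)
  big <- resample_errorbars(e2, n_resamples = 60, seed = 4)
  sel <- seq_len(min(nrow(a), nrow(big)))[a$t[seq_len(min(nrow(a),
                                                          nrow(big)))] < 3]
  expect_lt(mean(big$std[sel]), mean(a$std[sel]))
  ## identical runs: no variability
  e3 <- run_ensemble(rep(2.5, 30), rep(TRUE, 30), min_duration = 0)
  z <- resample_errorbars(e3, n_resamples = 20, seed = 1)
  expect_true(all(z$std[z$t < 1.8] == 0))
})

test_that("GLM regression inverts exactly generated logit data", {
  g <- test_glm()
  tt <- seq(0, 12, by = 1 / 30)
  y <- 10 + 8 * sin(tt / 2)
  lam <- lambda_of(g, y)
  lh <- data.frame(t = tt, lambda = lam, n_alive = rep(1e9, length(tt)),
                   reliable = TRUE)
  fit <- fit_turn_glm(list(lh), list(y))
  expect_equal(fit$gamma0, g$gamma0, tolerance = 1e-6)
  expect_equal(fit$gamma1, g$gamma1, tolerance = 1e-6)
  expect_error(fit_turn_glm(list(lh), list(rep(3, length(tt)))),
               "degenerate")
})

test_that("run likelihood follows the 1-s binning anchored at the run end", {
  ## 5.6-s turn-terminated run, constant lambda 0.5: five factors
  calls <- new.env(); calls$t <- numeric(0)
  lamf <- function(t) { calls$t <- c(calls$t, t); 0.5 }
  p <- run_likelihood(5.6, TRUE, lamf)
  expect_equal(p, 0.5^5)
  expect_equal(calls$t, c(0.6, 1.6, 2.6, 3.6, 4.6), tolerance = 1e-9)
  ## censored run under zero hazard is certain
  expect_equal(run_likelihood(3.2, FALSE, function(t) 0), 1)
  ## single-factor turn with lambda 1
  expect_equal(run_likelihood(1.7, TRUE, function(t) 1), 1)
  expect_error(run_likelihood(0.5, TRUE, function(t) 0.5), "minimum")
})

test_that("ensemble log-likelihood is additive and favors the generating model", {
  g <- test_glm()
  ## additivity
  e <- run_ensemble(c(2.5, 3.5), c(TRUE, TRUE),
                    inputs = list(rep(5, 75), rep(8, 105)),
                    min_duration = 1)
  ll1 <- ensemble_loglik(e, g)
  e2 <- run_ensemble(rep(c(2.5, 3.5), 2), rep(TRUE, 4),
                     inputs = rep(list(rep(5, 75), rep(8, 105)), 2),
                     min_duration = 1)
  expect_equal(as.numeric(ensemble_loglik(e2, g)), 2 * as.numeric(ll1))
  ## two known probabilities
  gz <- turn_glm_params(preset = NULL, gamma0 = 0, gamma1 = 0)  # lambda 0.5
  e3 <- run_ensemble(c(1.5, 2.5), c(TRUE, TRUE),
                     inputs = list(rep(0, 45), rep(0, 75)))
  expect_equal(as.numeric(ensemble_loglik(e3, gz)), log(0.5) + log(0.25))
  ## the generating model beats a mismatched one on average
  p <- light_params()
  yt <- integrate_transduction(p, make_ramp(ramp_suite("light")$exponential,
                                            pad_before = 0, pad_after = 8),
                               method = "rk4")$y
  ens <- make_turn_ensemble(g, yt, 400, seed = 21)
  wrong <- turn_glm_params(preset = NULL, gamma0 = 1, gamma1 = -0.4)
  expect_gt(as.numeric(ensemble_loglik(ens, g)),
            as.numeric(ensemble_loglik(ens, wrong)))
})

test_that("bootstrap comparison: degenerate self-test and order invariance", {
  g <- test_glm()
  set.seed(31)
  ens <- run_ensemble(1 + stats::rexp(60, 0.5), rep(TRUE, 60),
                      inputs = lapply(1:60, function(i) stats::runif(400, 0, 20)))
  self <- bootstrap_compare(ens, g, g, n = 200, seed = 2)
  expect_true(all(self$delta == 0))
  expect_equal(self$p_value, 0)
  expect_equal(self$p_label, "< 0.005")
  ## permuting run order leaves the full-set statistic unchanged
  perm <- sample(60)
  ens_p <- run_ensemble(ens$durations[perm], ens$turn_terminal[perm],
                        inputs = ens$inputs[perm])
  wrong <- turn_glm_params(preset = NULL, gamma0 = 0.3, gamma1 = -0.01)
  b1 <- bootstrap_compare(ens, g, wrong, n = 50, seed = 3)
  b2 <- bootstrap_compare(ens_p, g, wrong, n = 50, seed = 3)
  expect_equal(b1$delta_full, b2$delta_full)
})

test_that("turn-triggered average reproduces identical traces and respects coverage", {
  ## identical lambda traces: TTA equals the trace, SEM 0
  n <- 91
  tr <- seq(0.1, 0.4, length.out = n)
  ens <- run_ensemble(rep(3, 12), rep(TRUE, 12),
                      inputs = replicate(12, tr, simplify = FALSE))
  tta <- turn_triggered_average(ens, lookback = 2)
  cov <- tta$n == 12
  expect_lt(max(tta$sem[cov]), 1e-7)
  expect_equal(tail(tta$mean[cov], 1), tr[n], tolerance = 1e-6)
  expect_true(all(diff(tta$mean[cov]) > 0))
  expect_error(turn_triggered_average(
    run_ensemble(rep(3, 3), rep(FALSE, 3),
                 inputs = replicate(3, tr, simplify = FALSE))),
    "turn-terminated")
})

test_that("control input constructions behave on palindromes and constants", {
  v <- c(1, 3, 7, 3, 1)
  expect_equal(control_inputs(v, "time_reversed"), v)  # palindrome
  expect_equal(control_inputs(control_inputs(1:9, "time_reversed"),
                              "time_reversed"), 1:9)
  cst <- rep(4, 6)
  expect_equal(control_inputs(cst, "time_reversed"), cst)
  expect_equal(control_inputs(cst, "constant_mean"), cst)
  expect_equal(control_inputs(1:5, "constant_mean"), rep(3, 5))
  expect_error(control_inputs(v, "shuffled"))
})
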