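#' Stimulus-to-behavior GLM parameters
#'
#' Parameters of the generalized linear model mapping an input signal to the
#' probability lambda(t) that a surviving run terminates in a turn within a
#' 1-s window. The test model takes the predicted OSN firing rate as input
#' (`lambda = 1/(1 + exp(-(gamma0 + gamma1 * y)))`); the control models
#' bypass the OSN and take the stimulus intensity, optionally together with
#' its single-frame derivative. A rectified-linear link (no logit; negative
#' linear combinations clamped to 0) is available as a variant.
#'
#' Default presets are the fitted columns: the test model
#' (gamma0 = -0.3534, gamma1 = -0.1523 per Hz), the stimulus-only control
#' (-0.8156, -0.0114 per W/m^2), the stimulus + derivative control
#' (-0.8200, -0.0013, -0.0214), and the rectified-linear test variant
#' (0.3762, -0.0198).
#'
#' @param preset `"test"`, `"control_stimulus"`, `"control_derivative"`,
#'   `"rectified"`, or `NULL`.
#' @param gamma0 intercept (basal turn drive).
#' @param gamma1 input weight (per Hz for rate input, per W/m^2 for
#'   stimulus input).
#' @param gamma2 weight of the stimulus derivative (per W/m^2 per s), only
#'   for `input_kind = "stimulus+derivative"`.
#' @param input_kind `"rate"`, `"stimulus"`, or `"stimulus+derivative"`.
#' @param link `"logit"` or `"rectified_linear"`.
#' @return A `turn_glm_params` list.
#' @export
turn_glm_params <- function(preset = c("test", "control_stimulus",
                                       "control_derivative", "rectified"),
                            gamma0 = NULL, gamma1 = NULL, gamma2 = NULL,
                            input_kind = NULL, link = NULL) {
  presets <- list(
    test = list(gamma0 = -0.3534, gamma1 = -0.1523, gamma2 = NULL,
                input_kind = "rate", link = "logit"),
    control_stimulus = list(gamma0 = -0.8156, gamma1 = -0.0114,
                            gamma2 = NULL, input_kind = "stimulus",
                            link = "logit"),
    control_derivative = list(gamma0 = -0.8200, gamma1 = -0.0013,
                              gamma2 = -0.0214,
                              input_kind = "stimulus+derivative",
                              link = "logit"),
    rectified = list(gamma0 = 0.3762, gamma1 = -0.0198, gamma2 = NULL,
                     input_kind = "rate", link = "rectified_linear")
  )
  p <- if (is.null(preset)) {
    list(gamma0 = 0, gamma1 = 0, gamma2 = NULL, input_kind = "rate",
         link = "logit")
  } else {
    presets[[match.arg(preset)]]
  }
  if (!is.null(gamma0)) p$gamma0 <- gamma0
  if (!is.null(gamma1)) p$gamma1 <- gamma1
  if (!is.null(gamma2)) p$gamma2 <- gamma2
  if (!is.null(input_kind)) p$input_kind <- input_kind
  if (!is.null(link)) p$link <- link
  p$input_kind <- match.arg(p$input_kind,
                            c("rate", "stimulus", "stimulus+derivative"))
  p$link <- match.arg(p$link, c("logit", "rectified_linear"))
  if (identical(p$input_kind, "stimulus+derivative") && is.null(p$gamma2)) {
    stop("gamma2 is required when the derivative is part of the input")
  }
  if (!identical(p$input_kind, "stimulus+derivative")) p$gamma2 <- NULL
  structure(p, class = "turn_glm_params")
}

#' Turn probability predicted by the GLM
#'
#' @param params a [turn_glm_params()].
#' @param input numeric vector: firing rate (Hz) or stimulus intensity,
#'   per `input_kind`.
#' @param derivative stimulus derivative (per s), required for
#'   `input_kind = "stimulus+derivative"`.
#' @return lambda(t) in `[0, 1]`, same length as `input`.
#' @export
lambda_of <- function(params, input, derivative = NULL) {
  lin <- params$gamma0 + params$gamma1 * input
  if (identical(params$input_kind, "stimulus+derivative")) {
    if (is.null(derivative)) {
      stop("this model requires the stimulus derivative input")
    }
    lin <- lin + params$gamma2 * derivative
  }
  if (identical(params$link, "logit")) {
    1 / (1 + exp(-lin))
  } else {
    pmin(pmax(lin, 0), 1)
  }
}

#' Run ensemble
#'
#' A collection of runs time-aligned to run onset. Each run carries its
#' duration, whether it ended in a detected turn (versus censoring at the
#' end of the observation), and the per-frame model input experienced
#' during the run.
#'
#' @param durations run durations (s).
#' @param turn_terminal logical; `TRUE` if the run ended in a turn.
#' @param inputs optional list of per-run numeric input traces sampled at
#'   `dt` from run onset (firing rate or stimulus, model-dependent).
#' @param dt frame interval of the input traces (s).
#' @param min_duration runs shorter than this are dropped (default 1 s).
#' @param trajectory optional per-run trajectory id.
#' @return A `run_ensemble` list.
#' @export
run_ensemble <- function(durations, turn_terminal,
                         inputs = NULL, dt = 1 / 30, min_duration = 1,
                         trajectory = NULL) {
  stopifnot(length(durations) == length(turn_terminal))
  keep <- durations >= min_duration
  structure(list(durations = durations[keep],
                 turn_terminal = as.logical(turn_terminal)[keep],
                 inputs = if (!is.null(inputs)) inputs[keep],
                 trajectory = if (!is.null(trajectory)) trajectory[keep],
                 dt = dt, min_duration = min_duration),
            class = "run_ensemble")
}

#' @export
length.run_ensemble <- function(x) length(x$durations)

#' Empirical turn probability of a run ensemble
#'
#' Nonparametric estimator on runs aligned to run onset: for the i-th time
#' point, with `Nb` runs alive at the start of the centered 1-s window and
#' `Ne` still alive at its end, the turn probability is `(Nb - Ne)/Nb`.
#' The estimate becomes unreliable once few runs survive; time points where
#' fewer than `reliability_frac` of the initial runs remain are flagged.
#'
#' @param ensemble a [run_ensemble()].
#' @param window window length (s), default 1.
#' @param dt output grid step (s).
#' @param reliability_frac fraction of the initial runs below which the
#'   estimate is flagged unreliable (default 0.10).
#' @return Data frame `t`, `lambda`, `n_alive`, `reliable`.
#' @export
estimate_turn_probability <- function(ensemble, window = 1, dt = 1 / 30,
                                      reliability_frac = 0.10) {
  if (!length(ensemble)) stop("empty run ensemble")
  dur <- ensemble$durations
  n0 <- length(dur)
  t_max <- max(dur)
  tt <- seq(0, t_max, by = dt)
  nb <- vapply(tt - window / 2, function(a) sum(dur > max(a, 0)), 0L)
  ne <- vapply(tt + window / 2, function(b) sum(dur > b), 0L)
  lam <- ifelse(nb > 0, (nb - ne) / nb, NA_real_)
  data.frame(t = tt, lambda = lam, n_alive = nb,
             reliable = nb >= reliability_frac * n0)
}

#' Resampling error bars for the turn probability
#'
#' Standard deviation of [estimate_turn_probability()] across subsamples:
#' the ensemble is resampled `n_resamples` times without replacement, each
#' subsample containing half of the runs.
#'
#' @param ensemble a [run_ensemble()].
#' @param n_resamples number of resamples (default 100).
#' @param seed integer seed.
#' @inheritParams estimate_turn_probability
#' @return Data frame `t`, `std`.
#' @export
resample_errorbars <- function(ensemble, n_resamples = 100, seed = NULL,
                               window = 1, dt = 1 / 30) {
  if (length(ensemble) < 4L) stop("need at least 4 runs")
  if (!is.null(seed)) set.seed(seed)
  full <- estimate_turn_probability(ensemble, window = window, dt = dt)
  half <- floor(length(ensemble) / 2)
  mat <- vapply(seq_len(n_resamples), function(i) {
    idx <- sample(length(ensemble), half)
    sub <- ensemble
    sub$durations <- ensemble$durations[idx]
    sub$turn_terminal <- ensemble$turn_terminal[idx]
    est <- estimate_turn_probability(sub, window = window, dt = dt)
    stats::approx(est$t, est$lambda, xout = full$t, rule = 2)$y
  }, numeric(nrow(full)))
  data.frame(t = full$t, std = apply(mat, 1L, stats::sd))
}

#' Fit the turn GLM by regression on the logit of the turn probability
#'
#' The GLM parameters are obtained by ordinary least squares of
#' `logit(lambda_hat)` on the input(s), pooled over the training ramps and
#' restricted to reliable time points. Since empirical turn probabilities
#' can hit 0 or 1 (where the logit diverges), `lambda_hat` is first clipped
#' to `[1/(2N), 1 - 1/(2N)]`, with N the number of runs alive in the
#' window.
#'
#' @param lambda_hats list of data frames from
#'   [estimate_turn_probability()] (one per training condition).
#' @param inputs list of numeric input vectors on the same grids (firing
#'   rate or stimulus).
#' @param derivatives optional list of stimulus-derivative vectors (adds
#'   the gamma2 term).
#' @param input_kind recorded in the returned parameters.
#' @param weighted if `TRUE`, time points are weighted by the number of
#'   runs alive.
#' @return Fitted [turn_glm_params()] with attribute `fit` (the `lm`).
#' @export
fit_turn_glm <- function(lambda_hats, inputs, derivatives = NULL,
                         input_kind = "rate", weighted = FALSE) {
  if (!is.list(lambda_hats) || is.data.frame(lambda_hats)) {
    lambda_hats <- list(lambda_hats)
  }
  if (!is.list(inputs)) inputs <- list(inputs)
  stopifnot(length(lambda_hats) == length(inputs))
  pieces <- Map(function(lh, inp, i) {
    stopifnot(nrow(lh) == length(inp))
    ok <- lh$reliable & !is.na(lh$lambda)
    n <- lh$n_alive
    lam <- pmin(pmax(lh$lambda, 1 / (2 * pmax(n, 1))),
                1 - 1 / (2 * pmax(n, 1)))
    data.frame(z = log(lam / (1 - lam)), input = inp, w = n,
               deriv = if (!is.null(derivatives)) derivatives[[i]] else 0)[ok, ]
  }, lambda_hats, inputs, seq_along(inputs))
  dat <- do.call(rbind, pieces)
  if (stats::sd(dat$input) == 0 &&
      (is.null(derivatives) || stats::sd(dat$deriv) == 0)) {
    stop("degenerate design: constant input")
  }
  fml <- if (is.null(derivatives)) z ~ input else z ~ input + deriv
  fit <- if (weighted) stats::lm(fml, dat, weights = dat$w) else
    stats::lm(fml, dat)
  cf <- stats::coef(fit)
  out <- turn_glm_params(preset = NULL, gamma0 = unname(cf[1]),
                         gamma1 = unname(cf["input"]),
                         gamma2 = if (!is.null(derivatives))
                           unname(cf["deriv"]),
                         input_kind = if (!is.null(derivatives))
                           "stimulus+derivative" else input_kind,
                         link = "logit")
  attr(out, "fit") <- fit
  out
}

#' Likelihood of a single run under a turn-probability trace
#'
#' The run likelihood is built from 1-s bins anchored at the run end: for a
#' run of duration T the turn probability is evaluated at
#' `t_k = (T mod 1) + k` for `k = 0 .. floor(T) - 1` (for T = 5.6 s these
#' are 0.6, 1.6, 2.6, 3.6, 4.6 — five evaluations). All but the last
#' contribute survival factors `(1 - lambda)`; the last factor is `lambda`
#' if the run ended in a turn, and `(1 - lambda)` if it was censored.
#'
#' @param duration run duration (s), >= 1 (shorter runs are excluded
#'   upstream by the ensemble's minimum-duration filter).
#' @param turn_terminal logical.
#' @param lambda_fun function of time (s since run onset) returning
#'   lambda, or a numeric vector sampled at `dt`.
#' @param dt sampling interval of a numeric `lambda_fun`.
#' @return The run probability `p_i` in `[0, 1]`.
#' @export
run_likelihood <- function(duration, turn_terminal, lambda_fun, dt = 1 / 30) {
  if (duration < 1) stop("run shorter than the 1-s minimum duration")
  if (is.numeric(lambda_fun)) {
    v <- lambda_fun
    lambda_fun <- function(t) {
      v[pmin(pmax(floor(t / dt) + 1L, 1L), length(v))]
    }
  }
  k <- seq_len(floor(duration)) - 1
  tk <- (duration %% 1) + k
  lam <- vapply(tk, lambda_fun, 0)
  lam <- pmin(pmax(lam, 0), 1)
  n <- length(lam)
  surv <- if (n > 1) prod(1 - lam[-n]) else 1
  last <- if (turn_terminal) lam[n] else 1 - lam[n]
  surv * last
}

#' Log-likelihood of a run ensemble under a GLM
#'
#' Sums `log p_i` over the runs, with `lambda` computed from the model and
#' each run's input trace. Runs with zero probability are reported.
#'
#' @param ensemble a [run_ensemble()] carrying per-run input traces.
#' @param model a [turn_glm_params()].
#' @param derivatives optional list of per-run derivative traces.
#' @return `logL` (scalar) with attribute `p` (per-run probabilities).
#' @export
ensemble_loglik <- function(ensemble, model, derivatives = NULL) {
  stopifnot(!is.null(ensemble$inputs))
  p <- vapply(seq_len(length(ensemble)), function(i) {
    lam <- lambda_of(model, ensemble$inputs[[i]],
                     derivative = if (!is.null(derivatives))
                       derivatives[[i]])
    run_likelihood(ensemble$durations[i], ensemble$turn_terminal[i],
                   lam, dt = ensemble$dt)
  }, 0)
  ll <- sum(log(p))
  attr(ll, "p") <- p
  ll
}

#' Bootstrap comparison of a test and a control turn model
#'
#' Resamples the run ensemble with replacement `n` times; for each resample
#' the statistic `(logL_test - logL_control)/logL_test` is computed. The
#' p-value is the fraction of resamples in which the control is more likely
#' than the test model (raw log-likelihood comparison); a zero count is
#' reported as `< 1/n`.
#'
#' @param ensemble a [run_ensemble()] with per-run inputs for the test
#'   model.
#' @param test_model,control_model [turn_glm_params()].
#' @param control_inputs optional list of per-run input traces for the
#'   control model (defaults to the test inputs).
#' @param n number of bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return List `delta` (the n statistics), `delta_full` (on the original
#'   ensemble), `p_value`, `p_label`.
#' @export
bootstrap_compare <- function(ensemble, test_model, control_model,
                              control_inputs = NULL, n = 10000,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ## per-run log-probabilities once; resampling then just re-sums
  lp_run <- function(model, inputs) {
    vapply(seq_len(length(ensemble)), function(i) {
      lam <- lambda_of(model, inputs[[i]])
      log(run_likelihood(ensemble$durations[i], ensemble$turn_terminal[i],
                         lam, dt = ensemble$dt))
    }, 0)
  }
  lp_test <- lp_run(test_model, ensemble$inputs)
  lp_ctrl <- lp_run(control_model, control_inputs %||% ensemble$inputs)
  nn <- length(ensemble)
  stat <- function(idx) {
    lt <- sum(lp_test[idx]); lc <- sum(lp_ctrl[idx])
    c(delta = (lt - lc) / lt, worse = as.numeric(lc > lt))
  }
  full <- stat(seq_len(nn))
  draws <- vapply(seq_len(n), function(i) stat(sample(nn, replace = TRUE)),
                  numeric(2))
  n_worse <- sum(draws["worse", ])
  p <- n_worse / n
  list(delta = draws["delta", ], delta_full = unname(full["delta"]),
       p_value = p,
       p_label = if (n_worse == 0) sprintf("< %g", 1 / n) else
         sprintf("%g", p))
}

#' Turn-triggered average of a per-run signal
#'
#' Aligns per-run traces (typically the predicted turn probability) to the
#' moment of the turn and averages across runs at each pre-turn lag.
#' Censored runs are excluded; runs shorter than the lookback contribute
#' only to the lags they cover.
#'
#' @param ensemble a [run_ensemble()] with per-run input traces holding the
#'   signal to average (e.g. predicted lambda).
#' @param lookback how far before the turn to average (s).
#' @return Data frame `lag` (s, negative = before the turn), `mean`, `sem`,
#'   `n`.
#' @export
turn_triggered_average <- function(ensemble, lookback = 10) {
  sel <- which(ensemble$turn_terminal)
  if (!length(sel)) stop("no turn-terminated runs")
  dt <- ensemble$dt
  lags <- seq(-lookback, 0, by = dt)
  acc_n <- integer(length(lags))
  acc_s <- numeric(length(lags))
  acc_q <- numeric(length(lags))
  for (i in sel) {
    tr <- ensemble$inputs[[i]]
    n <- length(tr)
    ## trace sample j is at time (j-1)*dt after onset; turn at duration
    lag_i <- ((seq_len(n) - 1) * dt) - ensemble$durations[i]
    keep <- lag_i >= -lookback - dt / 2
    idx <- round((lag_i[keep] + lookback) / dt) + 1L
    ok <- idx >= 1L & idx <= length(lags)
    idx <- idx[ok]
    v <- tr[keep][ok]
    acc_n[idx] <- acc_n[idx] + 1L
    acc_s[idx] <- acc_s[idx] + v
    acc_q[idx] <- acc_q[idx] + v^2
  }
  m <- ifelse(acc_n > 0, acc_s / acc_n, NA_real_)
  va <- ifelse(acc_n > 1, (acc_q - acc_n * m^2) / (acc_n - 1), NA_real_)
  data.frame(lag = lags, mean = m,
             sem = sqrt(pmax(va, 0)) / sqrt(pmax(acc_n, 1)), n = acc_n)
}

#' Control input constructions for the closed-loop analysis
#'
#' Builds the uncoupled controls used against the test model: the
#' time-reversed stimulus (preserves the stimulus statistics but severs its
#' relation to behavior) and the constant-activity control (the mean
#' predicted rate of the trajectory, held constant — computed
#' trajectory-by-trajectory).
#'
#' @param trace full-trajectory numeric input trace (stimulus intensity or
#'   predicted rate).
#' @param mode `"time_reversed"` or `"constant_mean"`.
#' @return Numeric trace of the same length.
#' @export
control_inputs <- function(trace, mode = c("time_reversed",
                                           "constant_mean")) {
  mode <- match.arg(mode)
  switch(mode,
         time_reversed = rev(trace),
         constant_mean = rep(mean(trace), length(trace)))
}
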