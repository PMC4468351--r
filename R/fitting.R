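#' Pearson product-moment correlation
#'
#' Goodness-of-fit metric used throughout: the correlation between an
#' observed and a predicted trace.
#'
#' @param a,b numeric vectors of equal length (>= 2) with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_rho <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("need two equal-length vectors of length >= 2")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(a, b)
}

#' Coefficient of variation of the RMSE
#'
#' Root-mean-square error between observed and predicted traces, divided by
#' the mean of the observed trace.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return CV(RMSE), nonnegative.
#' @export
cv_rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  m <- mean(observed)
  if (m == 0) stop("observed mean is zero: CV(RMSE) undefined")
  sqrt(mean((observed - predicted)^2)) / m
}

#' Peristimulus time histogram from spike trains
#'
#' Trial-averaged firing rate on a sliding window: at each grid time the
#' rate is the spike count in a centered window divided by
#' `window * n_trials`; the across-trial standard deviation of the
#' single-trial rates is returned alongside. Optionally the mean is mildly
#' low-pass filtered with a Savitzky-Golay filter.
#'
#' @param spikes list of numeric vectors of spike times (s), one per trial.
#' @param t_grid output time grid (s).
#' @param window sliding window (s), default 50 ms.
#' @param smooth logical; apply mild Savitzky-Golay smoothing to the mean.
#' @return A [rate_trace()] with `std`.
#' @export
psth_from_spikes <- function(spikes, t_grid, window = 0.05, smooth = FALSE) {
  if (!length(spikes)) stop("no trials supplied")
  n_trials <- length(spikes)
  rates <- vapply(spikes, function(tr) {
    if (!length(tr)) return(numeric(length(t_grid)))
    lo <- findInterval(t_grid - window / 2, sort(tr))
    hi <- findInterval(t_grid + window / 2, sort(tr))
    (hi - lo) / window
  }, numeric(length(t_grid)))
  rates <- matrix(rates, nrow = length(t_grid))
  m <- rowMeans(rates)
  s <- apply(rates, 1L, stats::sd)
  if (n_trials == 1L) s <- rep(0, length(t_grid))
  if (smooth && length(t_grid) >= 9) {
    m <- pmax(signal::sgolayfilt(m, p = 3, n = 9), 0)
  }
  out <- rate_trace(t_grid, m, std = s)
  attr(out, "n_trials") <- n_trials
  out
}

#' Dataset for transduction-model fitting
#'
#' @param stimuli list of [stimulus_trace()]s.
#' @param psths list of [rate_trace()]s (mean + std), same grids.
#' @return A `fit_dataset` list of entries.
#' @export
fit_dataset <- function(stimuli, psths) {
  if (length(stimuli) != length(psths)) stop("stimuli/psths length mismatch")
  entries <- Map(function(s, p) {
    if (nrow(s) != nrow(p)) stop("entry grids differ")
    list(stimulus = s, psth = p)
  }, stimuli, psths)
  structure(entries, class = "fit_dataset")
}

## Gaussian log-likelihood of one entry given params. Two estimator-design
## points matter for unbiasedness with trial-limited PSTHs:
## - the residual sigma is the standard error of the PSTH *mean* (the
##   across-trial std divided by sqrt(n_trials) when the trial count is
##   known), with the noisy per-bin variance smoothed over ~0.5 s —
##   weighting by the raw per-bin trial std demonstrably biases the fit;
## - the per-entry scale factor (across-preparation variability) is
##   profiled out by *unweighted* regression through the origin, which is
##   unbiased because its weights do not depend on the bin noise, and is
##   clipped to [0.5, 2];
## - in near-silent stretches the empirical variance collapses to the
##   floor, which over-punishes small positive model rates and rewards
##   parameter sets that pin the model at zero; the variance is therefore
##   floored from below by the Poisson variance implied by the model
##   prediction, with the spiking variance factor calibrated from the
##   entry's own (variance vs rate) relation — a quasi-likelihood.
entry_loglik <- function(params, entry, sigma_floor = 0.5,
                         scale_bounds = c(0.5, 2)) {
  sol <- try(integrate_transduction(params, entry$stimulus, method = "rk4"),
             silent = TRUE)
  if (inherits(sol, "try-error") || any(!is.finite(sol$y))) {
    return(list(ll = -Inf, scale = NA_real_))
  }
  obs <- entry$psth$rate
  sig <- stable_sigma(entry$psth, sigma_floor)
  denom <- sum(sol$y^2)
  s <- if (denom > 0) sum(obs * sol$y) / denom else 1
  s <- min(max(s, scale_bounds[1]), scale_bounds[2])
  pred <- s * sol$y
  k_var <- variance_factor(entry$psth, sigma_floor)
  if (k_var > 0) sig <- pmax(sig, sqrt(k_var * pred))
  w <- 1 / sig^2
  resid <- obs - pred
  list(ll = -0.5 * sum(w * resid^2) - sum(log(sig)), scale = s)
}

## per-entry spiking variance factor: slope of the (PSTH-mean variance vs
## rate) relation, estimated robustly from informative bins
variance_factor <- function(psth, sigma_floor) {
  sig <- stable_sigma(psth, 0)
  ok <- psth$rate > 2 * sigma_floor & sig > 0
  if (sum(ok) < 20) return(0)
  stats::median(sig[ok]^2 / psth$rate[ok])
}

## stabilized standard error of the PSTH mean: the noisy per-bin trial
## variance smoothed over ~0.5 s, divided by sqrt(n_trials) when the trial
## count is recorded, floored
stable_sigma <- function(psth, sigma_floor = 0.5) {
  sig <- psth$std %||% rep(sigma_floor, nrow(psth))
  if (length(sig) >= 11) {
    v <- stats::filter(sig^2, rep(1 / 11, 11), sides = 2)
    v[is.na(v)] <- sig[is.na(v)]^2
    sig <- sqrt(as.numeric(v))
  }
  n_tr <- attr(psth, "n_trials") %||% 1
  pmax(sig / sqrt(n_tr), sigma_floor)
}

free_param_names <- function(variant) {
  switch(variant,
         IFF = c("alpha2", "beta1", "beta2", "beta3", "beta4", "beta5",
                 "theta"),
         IFB = c("alpha2", "alpha3", "beta1", "beta2", "beta3", "beta4",
                 "beta5", "theta"),
         IFF_IFB = c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3",
                     "beta4", "beta5", "theta"))
}

## Closed-form QSSA pre-fit for the pure IFF variant: fits the identifiable
## combinations (delta1, delta2, delta3, delta4, alpha2) directly, each
## objective evaluation being O(N) arithmetic (no ODE integration), then
## maps back to the native parameters. This lands the simplex start on the
## likelihood ridge so that the ODE-based refinement only has to resolve
## beta5/theta and the QSSA approximation error.
qssa_prefit <- function(dataset, p0, sigma_floor = 0.5, maxit = 1500) {
  obs <- lapply(dataset, function(e) e$psth$rate)
  sig <- lapply(dataset, function(e) stable_sigma(e$psth, sigma_floor))
  obj <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 25)) return(1e10)
    d1 <- exp(par[1]); d2 <- exp(par[2]); d3 <- stats::plogis(par[3])
    d4 <- exp(par[4]); a2 <- exp(par[5])
    ss <- 0
    for (i in seq_along(dataset)) {
      S <- scaling_term(dataset[[i]]$stimulus, a2)$S
      den <- d2 + dataset[[i]]$stimulus$x - d3 * S
      if (any(den <= 0)) return(1e10)
      pred <- pmax(d1 * dataset[[i]]$stimulus$x / den - d4, 0)
      ss <- ss + sum(((obs[[i]] - pred) / sig[[i]])^2)
    }
    if (!is.finite(ss)) 1e10 else ss
  }
  ## the (delta1, delta4) ridge has local flats: multi-start over the
  ## offset magnitude with delta1 tied to the observed peak rate
  yp <- max(vapply(dataset, function(e) max(e$psth$rate), 0))
  xs <- unlist(lapply(dataset, function(e) e$stimulus$x))
  best <- NULL
  for (d4_try in c(3, 10, 30, 100, 300)) {
    st <- c(log(d4_try + yp), log(0.05 * stats::median(xs)),
            stats::qlogis(0.2), log(d4_try), log(1))
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    fit <- tryCatch(stats::optim(fit$par, obj, method = "BFGS",
                                 control = list(maxit = 150)),
                    error = function(e) fit)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## one simplex restart at the incumbent (fresh simplex escapes flats)
  re <- stats::optim(best$par, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-10))
  if (re$value < best$value) best <- re
  d1 <- exp(best$par[1]); d2 <- exp(best$par[2])
  d3 <- stats::plogis(best$par[3]); d4 <- exp(best$par[4])
  a2 <- exp(best$par[5])
  ## invert to native parameters with alpha1 = 0.1 and the incumbent
  ## beta5/theta guesses
  b5 <- p0$beta5; th <- p0$theta
  b3 <- a2 * d3 / (0.1 * max(1 - d3, 1e-6))
  denom <- a2 + 0.1 * b3
  list(alpha2 = a2, beta1 = d1 * b5 * denom / a2, beta2 = d2 * denom / a2,
       beta3 = b3, beta4 = d4 * b5, beta5 = b5, theta = th)
}

## heuristic data-driven starting point: invert the QSSA dose-response for
## the output scale and offset given guesses of the kinetic rates
initial_guess <- function(variant, dataset) {
  ymax <- max(vapply(dataset, function(e) max(e$psth$rate), 0))
  xs <- unlist(lapply(dataset, function(e) e$stimulus$x))
  xb <- min(xs); xm <- max(xs)
  p0 <- list(alpha1 = 0.1, alpha2 = 1, alpha3 = 0.5, beta2 = 0.1 * stats::median(xs),
             beta3 = 2, beta5 = 10, theta = 0.5, n = 2)
  denom <- p0$alpha2 + 0.1 * p0$beta3
  d2 <- p0$beta2 * p0$alpha2 / denom
  ## solve delta1, delta4 from baseline ~ 0.3*ymax and peak ~ ymax
  yb <- max(0.1 * ymax, 0.5); yp <- ymax
  a_b <- xb / (xb + d2); a_p <- xm / (xm + d2)
  d1 <- (yp - yb) / max(a_p - a_b, 0.05)
  d4 <- max(d1 * a_b - yb, 1)
  p0$beta1 <- d1 * p0$beta5 * denom / p0$alpha2
  p0$beta4 <- d4 * p0$beta5
  p0
}

#' Fit a transduction model to PSTH data
#'
#' Maximum-likelihood estimation of the transduction ODE parameters against
#' one or more stimulus/PSTH pairs. Residuals are weighted by the PSTH
#' standard deviation (floored at `sigma_floor` Hz); a per-entry
#' multiplicative scale factor absorbing across-preparation variability is
#' profiled out analytically within `[0.5, 2]`. The likelihood is maximized
#' by Nelder-Mead simplex over log-parameters (positivity by construction),
#' refined by a quasi-Newton (BFGS) gradient search, with seeded multi-start
#' (`n_starts - 1` random log-normal perturbations of the initial guess
#' plus the unperturbed guess). For the pure IFF variant the start is
#' placed by a closed-form QSSA pre-fit of the identifiable combinations
#' (delta1..delta4, alpha2), which costs no ODE integrations and resolves
#' the delta1/delta4 likelihood ridge before the simplex runs.
#'
#' For the pure IFF variant `alpha1` is fixed at 0.1 (the units of u are
#' undefined, so one parameter of the u-equation must be pinned) and
#' `alpha3` at 0; the Hill exponent n is fixed at 2 throughout.
#'
#' @param variant `"IFF"`, `"IFB"` or `"IFF_IFB"`.
#' @param dataset a [fit_dataset()].
#' @param modality `"light"` or `"odor"`.
#' @param n_starts number of simplex starts (default 21).
#' @param n_restarts perturbation-restart cycles on the incumbent after the
#'   start phase.
#' @param seed integer seed for the start perturbations.
#' @param sigma_floor minimum residual standard deviation (Hz).
#' @param maxit simplex iteration cap per start.
#' @param corrections_enabled passed to the candidate parameter sets.
#' @return A `fit_result` list: `params`, `scales`, `logLik`, per-entry
#'   `rho` and `cv_rmse`, `convergence`, and `degenerate` flag (set when a
#'   single constant-stimulus entry makes the scale/output trade-off
#'   unidentifiable).
#' @export
fit_transduction <- function(variant = c("IFF", "IFB", "IFF_IFB"), dataset,
                             modality = "light", n_starts = 21,
                             n_restarts = 20, seed = 1, sigma_floor = 0.5,
                             maxit = 400, corrections_enabled = TRUE) {
  variant <- match.arg(variant)
  stopifnot(length(dataset) >= 1L)
  free <- free_param_names(variant)
  degenerate <- length(dataset) == 1L &&
    stats::sd(dataset[[1]]$stimulus$x) == 0
  if (degenerate) {
    warning("single constant-stimulus entry: fit is unidentifiable ",
            "(scale/drive trade-off); result flagged degenerate")
  }
  ## For the pure IFF variant the search runs in QSSA-derived coordinates
  ## (A = delta1 - delta4, delta2, delta3, delta4, alpha2, beta5, theta):
  ## the data constrain A, delta2, delta3 and alpha2 sharply while delta4
  ## is soft, so axis-aligning these directions lets the simplex converge
  ## where the native beta-space ridge stalls it.
  iff_coords <- variant == "IFF"
  from_coords <- function(par) {
    if (!iff_coords) {
      vals <- as.list(exp(par))
      names(vals) <- free
      return(vals)
    }
    A <- exp(par[1]); d2 <- exp(par[2]); d3 <- stats::plogis(par[3])
    d4 <- exp(par[4]); a2 <- exp(par[5]); b5 <- exp(par[6])
    th <- exp(par[7])
    d1 <- A + d4
    list(alpha2 = a2, beta1 = d1 * b5 / (1 - d3), beta2 = d2 / (1 - d3),
         beta3 = a2 * d3 / (0.1 * (1 - d3)), beta4 = d4 * b5,
         beta5 = b5, theta = th)
  }
  to_coords <- function(vals) {
    if (!iff_coords) return(log(unlist(vals[free])))
    denom <- vals$alpha2 + 0.1 * vals$beta3
    d1 <- vals$beta1 * vals$alpha2 / (vals$beta5 * denom)
    d4 <- vals$beta4 / vals$beta5
    d3 <- 0.1 * vals$beta3 / denom
    c(log(max(d1 - d4, 1e-3)), log(vals$beta2 * vals$alpha2 / denom),
      stats::qlogis(min(max(d3, 1e-4), 0.999)), log(d4),
      log(vals$alpha2), log(vals$beta5), log(vals$theta))
  }
  build <- function(par) {
    do.call(transduction_params,
            c(list(preset = NULL, modality = modality, variant = variant,
                   corrections_enabled = corrections_enabled),
              from_coords(par)))
  }
  ## Gauge fixing: the model has an exact one-parameter symmetry — scaling
  ## (beta1, beta4, theta) by c scales the whole rate trace by c, which the
  ## free per-entry scale factors absorb, leaving the likelihood flat along
  ## the family. The parameter set is defined in the gauge where the
  ## per-entry scales have unit geometric mean, enforced by a quadratic
  ## penalty on mean(log scale).
  gauge_w <- 1e4
  neg_ll <- function(p) {
    ent <- lapply(dataset, function(e) entry_loglik(p, e, sigma_floor))
    ll <- sum(vapply(ent, `[[`, 0, "ll"))
    if (!is.finite(ll)) return(1e10)
    sc <- vapply(ent, `[[`, 0, "scale")
    -ll + gauge_w * mean(log(sc))^2
  }
  objective <- function(logp) {
    if (any(!is.finite(logp)) || any(abs(logp) > 25)) return(1e10)
    p <- tryCatch(build(logp), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    neg_ll(p)
  }
  p0 <- initial_guess(variant, dataset)
  if (variant == "IFF" && !degenerate) {
    p0 <- tryCatch(qssa_prefit(dataset, p0, sigma_floor),
                   error = function(e) p0)
    ## second stage: resolve by ODE likelihood the coordinates the QSSA
    ## cannot see — the relaxation rate beta5, the Hill threshold theta,
    ## and the offset delta4 (the QSSA only pins delta1 - delta4); the
    ## sharp prefit combinations A, delta2, delta3, alpha2 are held.
    denom <- p0$alpha2 + 0.1 * p0$beta3
    d1_0 <- p0$beta1 * p0$alpha2 / (p0$beta5 * denom)
    d4_0 <- p0$beta4 / p0$beta5
    A0 <- max(d1_0 - d4_0, 1e-3)
    with_rates <- function(b5, th, d4) {
      q <- p0
      q$beta5 <- b5
      q$theta <- th
      q$beta1 <- (A0 + d4) * b5 * denom / p0$alpha2
      q$beta4 <- d4 * b5
      q
    }
    obj2 <- function(par) {
      if (any(!is.finite(par)) || any(abs(par) > 15)) return(1e10)
      q <- with_rates(exp(par[1]), exp(par[2]), exp(par[3]))
      pq <- do.call(transduction_params,
                    c(list(preset = NULL, modality = modality,
                           variant = variant,
                           corrections_enabled = corrections_enabled),
                      q[c("alpha2", "beta1", "beta2", "beta3", "beta4",
                          "beta5", "theta")]))
      neg_ll(pq)
    }
    s2 <- NULL
    for (d4_try in unique(c(d4_0, 10, 100))) {
      f2 <- stats::optim(c(log(p0$beta5), log(p0$theta), log(d4_try)),
                         obj2, method = "Nelder-Mead",
                         control = list(maxit = 150))
      if (is.null(s2) || f2$value < s2$value) s2 <- f2
    }
    p0 <- with_rates(exp(s2$par[1]), exp(s2$par[2]), exp(s2$par[3]))
  }
  log0 <- to_coords(p0)
  set.seed(seed)
  starts <- c(list(log0),
              replicate(max(n_starts - 1L, 0L),
                        log0 + stats::rnorm(length(log0), 0, 0.3),
                        simplify = FALSE))
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("objective non-finite at every start")
  }
  ## perturb-restart cycles on the incumbent
  for (i in seq_len(n_restarts)) {
    cand <- stats::optim(best$par + stats::rnorm(length(log0), 0, 0.1),
                         objective, method = "Nelder-Mead",
                         control = list(maxit = maxit))
    if (cand$value < best$value) best <- cand
  }
  ## gradient refinement (finite-difference quasi-Newton on log-params)
  ref <- try(stats::optim(best$par, objective, method = "BFGS",
                          control = list(maxit = 25)), silent = TRUE)
  if (!inherits(ref, "try-error") && ref$value < best$value) best <- ref
  params <- build(best$par)
  per <- lapply(dataset, function(e) {
    el <- entry_loglik(params, e, sigma_floor)
    sol <- integrate_transduction(params, e$stimulus, method = "rk4")
    pred <- el$scale * sol$y
    rho <- tryCatch(pearson_rho(e$psth$rate, pred),
                    error = function(e) NA_real_)
    list(scale = el$scale, rho = rho,
         cv_rmse = cv_rmse(e$psth$rate, pred))
  })
  structure(list(params = params,
                 scales = vapply(per, `[[`, 0, "scale"),
                 logLik = -best$value,
                 rho = vapply(per, `[[`, 0, "rho"),
                 cv_rmse = vapply(per, `[[`, 0, "cv_rmse"),
                 convergence = best$convergence,
                 degenerate = degenerate),
            class = "fit_result")
}
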