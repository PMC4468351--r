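#' Constants of the quasi-steady-state solution
#'
#' For the pure IFF motif the fast firing-rate equation can be collapsed by
#' a quasi-steady-state approximation (QSSA), giving a closed-form
#' input-output relation: a hyperbolic dose-response whose half-saturation
#' point is transiently rescaled by the recent history of the stimulus
#' derivative ("transient normalization"). Its constants are
#' \itemize{
#'   \item `delta1 = beta1 * alpha2 / (beta5 * (alpha2 + alpha1*beta3))`
#'     (Hz, output scale),
#'   \item `delta2 = beta2 * alpha2 / (alpha2 + alpha1*beta3)`
#'     (intensity, half-saturation),
#'   \item `delta3 = alpha1 * beta3 / (alpha2 + alpha1*beta3)`
#'     (dimensionless weight of the derivative history, < 1),
#'   \item `delta4 = beta4 / beta5` (Hz, offset).
#' }
#' For the fitted light parameters these evaluate to 103.66 Hz, 0.99 W/m^2,
#' 0.22 and 93.17 Hz.
#'
#' @param params pure-IFF [transduction_params()].
#' @return A `qssa_constants` list (`delta1`..`delta4`, plus the
#'   intermediates `beta1_over_beta5` and `alpha1_beta3` and the carried
#'   `alpha2`).
#' @export
qssa_constants <- function(params) {
  if (params$variant != "IFF") {
    stop("the QSSA is derived for the pure IFF motif only")
  }
  if (params$beta5 == 0) stop("beta5 must be positive")
  denom <- params$alpha2 + params$alpha1 * params$beta3
  structure(list(
    delta1 = params$beta1 * params$alpha2 / (params$beta5 * denom),
    delta2 = params$beta2 * params$alpha2 / denom,
    delta3 = params$alpha1 * params$beta3 / denom,
    delta4 = params$beta4 / params$beta5,
    beta1_over_beta5 = params$beta1 / params$beta5,
    alpha1_beta3 = params$alpha1 * params$beta3,
    alpha2 = params$alpha2
  ), class = "qssa_constants")
}

#' Exponentially weighted history of the stimulus derivative
#'
#' Computes `S(t) = integral_0^t exp(-alpha2 (t - t')) dx/dt(t') dt'`, the
#' scaling term of the transient normalization: a leaky memory of recent
#' intensity changes with characteristic timescale `1/alpha2` (about 1 s for
#' the fitted models). The convolution is discretized by the exact
#' exponential-kernel recursion for piecewise-linear stimuli (dx/dt constant
#' on each sample interval), so the result is exact on ramps and O(N).
#'
#' @param stimulus a [stimulus_trace()].
#' @param alpha2 decay rate of the kernel (1/s).
#' @return Data frame with columns `t` and `S` (units of intensity; for a
#'   constant slope k the term converges to k/alpha2).
#' @export
scaling_term <- function(stimulus, alpha2) {
  tt <- stimulus$t
  xx <- stimulus$x
  n <- length(tt)
  S <- numeric(n)
  ## exact update for dx/dt constant on each interval:
  ## S(t+h) = S(t) e^{-a h} + slope (1 - e^{-a h}) / a
  for (i in seq_len(n - 1L)) {
    h <- tt[i + 1L] - tt[i]
    slope <- (xx[i + 1L] - xx[i]) / h
    decay <- exp(-alpha2 * h)
    S[i + 1L] <- S[i] * decay + slope * (1 - decay) / alpha2
  }
  data.frame(t = tt, S = S)
}

#' Closed-form QSSA firing rate
#'
#' Evaluates the transient-normalization solution
#' `y_QSSA(t) = delta1 * x / (delta2 + x - delta3 * S(x, t)) - delta4`,
#' where `S(x, t)` is the alpha2-kernel convolution of the stimulus
#' derivative ([scaling_term()]). When the stimulus is
#' constant the scaling term vanishes and the expression reduces to the
#' hyperbolic dose-response `delta1 * x/(x + delta2) - delta4`. Rates are
#' clamped at zero (the QSSA linearizes the Hill gate, which is only valid
#' above the [validity_threshold()]); samples where the rescaled denominator
#' is not positive, or where the predicted rate falls below the validity
#' threshold, are flagged in the `valid` mask.
#'
#' @param params pure-IFF [transduction_params()].
#' @param stimulus a [stimulus_trace()].
#' @param epsilon Hill-term tolerance defining the validity threshold.
#' @return Data frame `t`, `x`, `y`, `valid` with attribute `constants`.
#' @export
qssa_rate <- function(params, stimulus, epsilon = 0.05) {
  k <- qssa_constants(params)
  conv <- scaling_term(stimulus, params$alpha2)$S
  denom <- k$delta2 + stimulus$x - k$delta3 * conv
  y_raw <- k$delta1 * stimulus$x / denom - k$delta4
  bad <- denom <= 0
  y <- pmax(ifelse(bad, NA_real_, y_raw), 0)
  ythr <- validity_threshold(params$theta, epsilon)
  out <- data.frame(t = stimulus$t, x = stimulus$x, y = y,
                    valid = !bad & !is.na(y) & y_raw > ythr)
  attr(out, "constants") <- k
  attr(out, "validity_threshold") <- ythr
  out
}

#' Firing-rate threshold of QSSA validity
#'
#' The QSSA linearizes the Hill gate of the offset decay, treating
#' `y^2/(y^2 + theta^2)` as 1. The approximation error is below `epsilon`
#' for rates above `y_tilde = theta * sqrt((1 - epsilon)/epsilon)`; with
#' theta = 0.3 Hz and epsilon = 0.05 this is 1.3 Hz.
#'
#' @param theta Hill threshold (Hz).
#' @param epsilon tolerated Hill-term deviation from 1, in (0, 1).
#' @return The validity threshold (Hz).
#' @export
validity_threshold <- function(theta, epsilon = 0.05) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  theta * sqrt((1 - epsilon) / epsilon)
}

#' Characteristic timescale of a stimulus
#'
#' Diagnostic helper: `tau_x = (x_max - x_min) / max |dx/dt|`, the time the
#' stimulus would take to traverse its range at its fastest rate. The QSSA
#' separation-of-timescales argument requires `tau_x` to be large compared
#' with `1/alpha2` and `1/beta5`.
#'
#' @param stimulus a [stimulus_trace()].
#' @return Timescale in seconds.
#' @export
stimulus_timescale <- function(stimulus) {
  d <- stimulus_derivative(stimulus)$dxdt
  (max(stimulus$x) - min(stimulus$x)) / max(abs(d))
}
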