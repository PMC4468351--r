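#' Reverse-correlation estimate of a linear stimulus-response filter
#'
#' Classic linear system identification: on sliding windows the filter is
#' estimated in the frequency domain as
#' `h = F^-1( F(y) conj(F(x)) / (F(x) conj(F(x)) + eps) )`,
#' the cross-spectrum divided by the (regularized) stimulus power spectrum.
#' Window means are subtracted before the FFT to cancel DC drifts; the
#' per-window filters are averaged. Serves as the baseline against which
#' the nonlinearity of the transduction model is judged: on responses
#' generated by the transduction ODE this filter is biphasic but fails on
#' graded ramps.
#'
#' @param x stimulus [stimulus_trace()].
#' @param y response [rate_trace()] on the same grid.
#' @param window window length (s), default 5.
#' @param overlap fractional window overlap (default 0.5).
#' @param eps_frac spectral regularization as a fraction of the peak
#'   stimulus power (default 1e-6).
#' @return A `linear_filter`: data frame `lag` (s), `h` (Hz per intensity
#'   unit per sample).
#' @export
estimate_filter <- function(x, y, window = 5, overlap = 0.5,
                            eps_frac = 1e-6) {
  if (nrow(x) != nrow(y)) stop("x and y must share a grid")
  dt <- trace_dt(x)
  n_w <- round(window / dt)
  if (n_w > nrow(x)) stop("window longer than the traces")
  if (stats::sd(x$x) == 0) stop("stimulus is constant: zero spectrum")
  step <- max(1L, round(n_w * (1 - overlap)))
  starts <- seq(1L, nrow(x) - n_w + 1L, by = step)
  acc <- numeric(n_w)
  for (s in starts) {
    xi <- x$x[s:(s + n_w - 1L)]
    yi <- y$rate[s:(s + n_w - 1L)]
    xi <- xi - mean(xi)
    yi <- yi - mean(yi)
    fx <- stats::fft(xi)
    fy <- stats::fft(yi)
    pxx <- Re(fx * Conj(fx))
    eps <- eps_frac * max(pxx)
    h <- Re(stats::fft(fy * Conj(fx) / (pxx + eps), inverse = TRUE)) / n_w
    acc <- acc + h
  }
  h <- acc / length(starts)
  structure(data.frame(lag = (seq_len(n_w) - 1L) * dt, h = h),
            class = c("linear_filter", "data.frame"))
}

#' Linear-filter prediction of the firing rate
#'
#' Convolves the estimated filter with a stimulus and rescales the output to
#' a target mean rate (the convolution output has arbitrary offset because
#' the filter is estimated on mean-subtracted windows). The raw rescaled
#' values are kept for correlation scoring; a rectified copy (negative rates
#' clamped at zero) is provided for downstream use as a rate.
#'
#' @param h a `linear_filter` from [estimate_filter()].
#' @param x a [stimulus_trace()] on the same sampling grid.
#' @param target_mean mean rate (Hz) the prediction is normalized to.
#' @return A [rate_trace()] with columns `t`, `rate` (rectified) and
#'   attribute `raw` (unrectified prediction).
#' @export
predict_linear <- function(h, x, target_mean) {
  n <- nrow(x)
  xc <- x$x - mean(x$x)
  ## causal convolution: prediction at t uses stimulus at lags 0..L-1
  raw <- stats::convolve(xc, rev(h$h), type = "open")[seq_len(n)]
  if (max(abs(raw)) < .Machine$double.eps^0.5) {
    warning("degenerate (zero) filter: prediction is the constant target mean")
    raw <- rep(0, n)
  }
  raw <- raw - mean(raw) + target_mean
  out <- rate_trace(x$t, pmax(raw, 0))
  attr(out, "raw") <- raw
  out
}
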